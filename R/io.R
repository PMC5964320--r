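# Configuration, serialization of run records, and human-readable run
# reports. All outputs embed the seed and a hash of the configuration so a
# run can be reproduced bit-for-bit.

config_defaults <- list(burn_in = 5L, tr = 2.0, f_max_mode = "max_predicted",
                        despike = TRUE, refresh = TRUE)
config_required <- c("protocol", "iterations", "seed")
config_optional <- c("space_file", "truth_file", "hyper", "output_dir",
                     "schema_version", names(config_defaults))

#' Load and validate an experiment configuration
#'
#' Reads a YAML or JSON configuration (by file extension), rejects unknown
#' keys, checks required keys and value ranges, and fills defaults
#' (`burn_in = 5`, `tr = 2.0`, `f_max_mode = "max_predicted"`).
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` config file.
#' @return A validated named list of class `experiment_config`.
#' @export
load_experiment_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else stop("config must be .yaml/.yml or .json")
  validate_experiment_config(cfg)
}

validate_experiment_config <- function(cfg) {
  stopifnot(is.list(cfg))
  unknown <- setdiff(names(cfg), c(config_required, config_optional))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  missing <- setdiff(config_required, names(cfg))
  if (length(missing))
    stop("missing required config key(s): ", paste(missing, collapse = ", "))
  for (k in names(config_defaults))
    if (is.null(cfg[[k]])) cfg[[k]] <- config_defaults[[k]]
  if (is.null(cfg$schema_version)) cfg$schema_version <- 1L
  if (!cfg$protocol %in% c("exp1", "exp2", "exp3"))
    stop("protocol must be exp1, exp2 or exp3")
  cfg$iterations <- as.integer(cfg$iterations)
  cfg$burn_in <- as.integer(cfg$burn_in)
  cfg$seed <- as.integer(cfg$seed)
  if (cfg$iterations < 1L) stop("iterations must be positive")
  if (cfg$burn_in < 1L || cfg$burn_in > cfg$iterations)
    stop("burn_in must be in [1, iterations]")
  if (!cfg$f_max_mode %in% c("max_predicted", "max_observed"))
    stop("f_max_mode must be max_predicted or max_observed")
  if (cfg$tr <= 0) stop("tr must be positive")
  for (k in c("space_file", "truth_file"))
    if (!is.null(cfg[[k]]) && !file.exists(cfg[[k]]))
      stop(k, " does not exist: ", cfg[[k]])
  structure(cfg, class = "experiment_config")
}

#' @rdname load_experiment_config
#' @param cfg An `experiment_config`.
#' @export
save_experiment_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "experiment_config"))
  obj <- unclass(cfg)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::write_yaml(obj, path)
  } else {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

# polynomial rolling hash of a serialized R object (stable fingerprint
# for reports; not cryptographic)
config_hash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2L))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Write closed-loop observations as CSV
#'
#' Columns `iteration, task_id, x1[, x2], contrast, phase`.
#'
#' @param record A `bo_run`.
#' @param path Output CSV path.
#' @export
write_observations <- function(record, path) {
  stopifnot(inherits(record, "bo_run"))
  obs <- record$observations
  cols <- c("iteration", "task_id", paste0("x", seq_len(record$space$dim)),
            "contrast", "phase")
  utils::write.csv(obs[, cols], path, row.names = FALSE)
  invisible(path)
}

#' Summarize one or more closed-loop runs
#'
#' Collects the headline numbers of a set of runs: pooled closed-loop
#' sampling frequencies, the Euclidean-distance trajectory (mean and SD
#' across runs per step), the modal task, and optionally the top
#' predictions of a group-level map. The summary embeds each run's seed and
#' a configuration hash so any report can be traced to its exact inputs.
#'
#' @param records List of `bo_run` objects (at least one).
#' @param map Optional `group_map` to report predictions from.
#' @param file Optional path; the summary is written there as JSON.
#' @return A `bo_report` list (invisibly when `file` is given).
#' @export
bo_report <- function(records, map = NULL, file = NULL) {
  if (inherits(records, "bo_run")) records <- list(records)
  if (!length(records)) stop("no runs to report")
  stopifnot(all(vapply(records, inherits, logical(1), "bo_run")))
  freq <- sampling_frequency(records)
  eds <- lapply(records, distance_trajectory)
  steps <- min(lengths(eds))
  ed_mat <- do.call(rbind, lapply(eds, function(e) e[seq_len(steps)]))
  rep_out <- list(
    n_runs = length(records),
    seeds = vapply(records, function(r) r$config$seed, numeric(1)),
    config_hash = config_hash(lapply(records, function(r) r$config)),
    sampling_frequency = as.list(freq),
    modal_task = names(freq)[which.max(freq)],
    ed_mean = colMeans(ed_mat),
    ed_sd = apply(ed_mat, 2L, stats::sd),
    best_observed = max(vapply(records, function(r)
      max(r$observations$contrast), numeric(1))))
  if (!is.null(map)) {
    stopifnot(inherits(map, "group_map"))
    ord <- order(-map$candidate_pred$mean)
    rep_out$predicted_best <- map$candidate_pred$id[ord[1L]]
    rep_out$candidate_predictions <- map$candidate_pred
  }
  class(rep_out) <- "bo_report"
  if (!is.null(file)) {
    out <- rep_out
    class(out) <- NULL
    if (!is.null(out$candidate_predictions))
      out$candidate_predictions <- as.list(out$candidate_predictions)
    jsonlite::write_json(out, file, auto_unbox = TRUE, digits = NA)
    return(invisible(rep_out))
  }
  rep_out
}

#' @export
print.bo_report <- function(x, ...) {
  cat("Closed-loop report: ", x$n_runs, " run(s), config hash ",
      x$config_hash, "\n", sep = "")
  cat("  modal closed-loop task: ", x$modal_task, "\n", sep = "")
  freq <- sort(unlist(x$sampling_frequency), decreasing = TRUE)
  top <- freq[seq_len(min(5, length(freq)))]
  cat("  top sampling frequencies: ",
      paste0(names(top), " ", round(100 * top, 1), "%", collapse = ", "),
      "\n", sep = "")
  if (!is.null(x$predicted_best))
    cat("  group-map predicted best: ", x$predicted_best, "\n", sep = "")
  cat("  mean successive distance (first ", length(x$ed_mean),
      " steps): ", paste(signif(x$ed_mean, 3), collapse = " "), "\n",
      sep = "")
  invisible(x)
}
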