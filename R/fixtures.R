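# Canonical synthetic experiments: self-contained bundles (task space,
# ground truth, pre-tuned GP hyperparameters, protocol and contrast
# definition) used by the tests, the vignette and the reproduction script.

# Illustrative task -> network recruitment probabilities for the 16-task
# space. These are synthetic stand-in values with the qualitative layout of
# executive-function meta-analyses (planning/reasoning tasks load the
# dorsal frontoparietal network, inhibition/listening tasks the ventral
# one); they are NOT estimates from any published meta-analysis.
synthetic_task_table <- function() {
  tab <- read.csv(text = "task_id,comp09,comp08,comp05,comp06
tower_of_london,0.85,0.25,0.40,0.35
deductive_reasoning,0.82,0.32,0.45,0.30
wisconsin_card_sorting,0.80,0.45,0.50,0.40
counting_calculation,0.70,0.40,0.55,0.35
n_back,0.65,0.50,0.50,0.45
mental_rotation,0.60,0.35,0.30,0.40
encoding,0.55,0.30,0.35,0.30
visual_search,0.50,0.40,0.30,0.35
spatial_attention,0.50,0.45,0.35,0.40
semantic_judgment,0.45,0.50,0.40,0.30
word_generation,0.40,0.45,0.50,0.35
reading,0.30,0.50,0.40,0.30
divided_auditory_attention,0.25,0.55,0.45,0.40
imagined_movement,0.20,0.65,0.40,0.45
go_no_go,0.20,0.70,0.50,0.45
passive_listening,0.15,0.60,0.35,0.30",
                  stringsAsFactors = FALSE)
  tab
}

# per-block contrast noise SD induced by white BOLD noise of unit SD, for
# the full design of a protocol (two independent ROI timecourses; motion
# columns excluded since simulated motion is exogenous and near-orthogonal)
unit_contrast_sd <- function(design) {
  conv <- convolve_design(design, nuisance = TRUE)
  n <- design$n_frames
  X <- cbind(conv, linear_trend = seq_len(n) - 1, intercept = 1)
  A <- solve(crossprod(X))
  idx <- seq_len(design$n_blocks)
  sqrt(2 * mean(diag(A)[idx]))
}

#' Build a canonical synthetic experiment fixture
#'
#' Deterministic, seeded bundles emulating the shapes of the three
#' optimization experiments:
#' \describe{
#'   \item{`exp1_like`}{16-candidate 2D probability space, four ROIs,
#'     pairwise dFPN > vFPN contrast, 20 blocks. The optimum sits on two
#'     adjacent high-planning tasks, with the single best task separated
#'     from the runner-up by `margin`.}
#'   \item{`exp2_reasoning`}{16-level 1D difficulty space with a plateauing
#'     quadratic activation profile peaking near the upper difficulty
#'     levels.}
#'   \item{`exp2_tol`}{8 x 2 (steps x convolution) space, quadratic in the
#'     number of steps with its peak at 6-7 steps and no convolution
#'     effect.}
#'   \item{`exp3_like`}{the 16-task space with a one-versus-mean contrast
#'     (dFPN against the mean of the three other FPNs), 15 blocks.}
#' }
#' The simulated BOLD noise SD is set so that the planted optimum margin
#' equals `margin_noise_ratio` per-block contrast-noise SDs under the full
#' design, and the GP hyperparameters are pre-tuned by Type-2 maximum
#' likelihood on seeded pilot observations (three pilot traversals of the
#' space), mirroring tuning on independent pilot subjects.
#'
#' @param name Fixture name.
#' @param seed Integer seed; same name + seed gives an identical bundle.
#' @param dir Optional directory; when given the bundle is serialized there
#'   (`space.json`, `truth.json`, `task_table.csv` where applicable,
#'   `hyper.json`, `config.json`).
#' @param margin_noise_ratio Planted optimum margin in units of the
#'   per-block contrast noise SD.
#' @return A `bo_fixture` object: list with `name`, `space`, `truth`,
#'   `hyper`, `protocol`, `target`, `others`, `n_blocks`, `optimum`,
#'   `margin`, `contrast_noise_sd`, `table` (exp1/exp3), `seed`.
#' @export
make_fixture <- function(name = c("exp1_like", "exp2_reasoning", "exp2_tol",
                                  "exp3_like"),
                         seed = 1L, dir = NULL, margin_noise_ratio = 2) {
  name <- match.arg(name)
  tab <- NULL
  if (name %in% c("exp1_like", "exp3_like")) {
    tab <- synthetic_task_table()
    space <- task_space_from_probabilities(tab, c("comp09", "comp08"),
                                           name = name)
    ids <- space$candidates$id
    p <- tab[match(ids, tab$task_id), ]
    protocol <- if (name == "exp1_like") "exp1" else "exp3"
    n_blocks <- if (name == "exp1_like") 20L else 15L
    scale <- 5                              # BOLD units per unit probability
    rois <- c("dfpn", "vfpn", "fpn3", "fpn4")
    comps <- c("comp09", "comp08", "comp05", "comp06")
    roi_means <- lapply(comps, function(cc) stats::setNames(scale * p[[cc]],
                                                            ids))
    names(roi_means) <- rois
    if (name == "exp1_like") {
      target <- "dfpn"; others <- "vfpn"
    } else {
      target <- "dfpn"; others <- c("vfpn", "fpn3", "fpn4")
    }
  } else {
    protocol <- "exp2"
    n_blocks <- 20L
    target <- "dfpn"; others <- "vfpn"
    if (name == "exp2_reasoning") {
      space <- task_space_parametric(16L, name = name)
      x <- space$candidates$x1
      # plateauing quadratic: peak near difficulty level 14 of 16
      amp <- 3 - 6 * (x - 0.87)^2
    } else {
      space <- task_space_parametric(c(8L, 2L), name = name)
      x <- space$candidates$x1
      # quadratic in number of steps, peak at 6-7 of 2..9 steps
      amp <- 3 - 6 * (x - 0.64)^2
    }
    ids <- space$candidates$id
    roi_means <- list(dfpn = stats::setNames(amp, ids),
                      vfpn = stats::setNames(rep(0, length(ids)), ids))
  }
  design <- block_design(protocol, n_blocks)
  true_contrast <- vapply(ids, function(id)
    roi_means[[target]][[id]] -
      mean(vapply(others, function(r) roi_means[[r]][[id]], numeric(1))),
    numeric(1))
  srt <- sort(true_contrast, decreasing = TRUE)
  margin <- srt[1] - srt[2]
  ucsd <- unit_contrast_sd(design)
  # discrete-optimum fixtures key the noise to the optimum margin; the
  # smooth parametric surfaces (near-tied neighboring levels) key it to a
  # tenth of the surface range instead
  contrast_noise_sd <- if (name %in% c("exp1_like", "exp3_like"))
    margin / margin_noise_ratio
  else (max(true_contrast) - min(true_contrast)) / 10
  noise_sd <- contrast_noise_sd / ucsd
  truth <- ground_truth(roi_means, noise_sd = noise_sd)
  # pre-tune GP hyperparameters on pilot data: three noisy traversals of
  # the candidate set, as if from pilot subjects
  coords <- space_coords(space)
  Xp <- coords[rep(seq_len(nrow(coords)), 3L), , drop = FALSE]
  yp <- with_seed(seed + 9901L,
                  rep(unname(true_contrast), 3L) +
                    stats::rnorm(3L * length(ids), sd = contrast_noise_sd))
  hyper <- gp_tune(Xp, yp, restarts = 3L, seed = seed + 7L,
                   ard = space$dim > 1L)
  fx <- structure(list(name = name, space = space, truth = truth,
                       hyper = hyper, protocol = protocol, target = target,
                       others = others, n_blocks = n_blocks,
                       optimum = names(srt)[1], margin = unname(margin),
                       contrast_noise_sd = unname(contrast_noise_sd),
                       true_contrast = true_contrast, table = tab,
                       seed = as.integer(seed)),
                  class = "bo_fixture")
  if (!is.null(dir)) write_fixture(fx, dir)
  fx
}

#' @export
print.bo_fixture <- function(x, ...) {
  cat("Synthetic experiment fixture '", x$name, "'\n", sep = "")
  cat("  ", nrow(x$space$candidates), " candidates (", x$space$dim,
      "D), protocol ", x$protocol, ", ", x$n_blocks, " blocks\n", sep = "")
  cat("  contrast: ", x$target, " > ",
      if (length(x$others) > 1) paste0("mean(", paste(x$others,
                                                      collapse = ", "), ")")
      else x$others, "\n", sep = "")
  cat("  planted optimum: ", x$optimum, " (margin ", signif(x$margin, 3),
      " = ", signif(x$margin / x$contrast_noise_sd, 3),
      " contrast-noise SDs)\n", sep = "")
  invisible(x)
}

write_fixture <- function(fx, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_task_space(fx$space, file.path(dir, "space.json"))
  jsonlite::write_json(
    list(roi_means = lapply(fx$truth$roi_means, as.list),
         noise_sd = fx$truth$noise_sd, drift_slope = fx$truth$drift_slope,
         spike_rate = fx$truth$spike_rate, spike_sd = fx$truth$spike_sd),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(
    list(signal_sd = fx$hyper$signal_sd,
         lengthscales = fx$hyper$lengthscales,
         noise_sd = fx$hyper$noise_sd),
    file.path(dir, "hyper.json"), auto_unbox = TRUE, digits = NA)
  if (!is.null(fx$table))
    utils::write.csv(fx$table, file.path(dir, "task_table.csv"),
                     row.names = FALSE)
  jsonlite::write_json(
    list(name = fx$name, protocol = fx$protocol, target = fx$target,
         others = fx$others, n_blocks = fx$n_blocks, optimum = fx$optimum,
         margin = fx$margin, contrast_noise_sd = fx$contrast_noise_sd,
         seed = fx$seed),
    file.path(dir, "config.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
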