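# The guided-search stage: expected-improvement acquisition over the
# discrete candidate set, and the closed-loop controller that alternates
# data modeling (incremental GLM -> GP) with task selection.

#' Expected improvement
#'
#' Closed-form expected improvement of a Gaussian predictive distribution
#' over the current best value:
#' \eqn{EI = (m - f_{max})\Phi(z) + s\,\phi(z)} with
#' \eqn{z = (m - f_{max})/s}. For \eqn{s = 0} the degenerate limit
#' \eqn{\max(m - f_{max}, 0)} is used. Always nonnegative.
#'
#' @param m Posterior mean(s).
#' @param sd Posterior standard deviation(s), >= 0.
#' @param f_max Current best value (maximum predicted or observed).
#' @return Expected improvement, vectorized over `m` / `sd`.
#' @export
expected_improvement <- function(m, sd, f_max) {
  if (any(sd < 0)) stop("sd must be nonnegative")
  d <- m - f_max
  out <- pmax(d, 0)
  pos <- sd > 0
  if (any(pos)) {
    z <- d[pos] / sd[pos]
    out[pos] <- d[pos] * stats::pnorm(z) + sd[pos] * stats::dnorm(z)
  }
  pmax(out, 0)
}

#' Select the next task by maximizing expected improvement
#'
#' Evaluates the GP posterior at every candidate task, sets `f_max` to
#' either the maximum predicted mean over the candidates
#' (`"max_predicted"`) or the maximum observed value (`"max_observed"`),
#' and returns the candidate with the highest expected improvement. Ties go
#' to the lowest candidate index (candidates are sorted by id).
#'
#' @param fit A [gp_fit()] posterior.
#' @param space A `task_space` supplying the candidate set.
#' @param f_max_mode `"max_predicted"` or `"max_observed"`.
#' @param observed Observed values so far (required for `"max_observed"`).
#' @return List with `index`, `id`, `coords`, `ei` (per-candidate expected
#'   improvement), `f_max`, `mean`, `sd`.
#' @export
select_next_task <- function(fit, space,
                             f_max_mode = c("max_predicted", "max_observed"),
                             observed = NULL) {
  f_max_mode <- match.arg(f_max_mode)
  stopifnot(inherits(space, "task_space"))
  Xc <- space_coords(space)
  if (nrow(Xc) < 1L) stop("space has no candidates")
  pr <- stats::predict(fit, Xc)
  f_max <- if (f_max_mode == "max_predicted") {
    max(pr$mean)
  } else {
    if (is.null(observed) || length(observed) == 0L)
      stop("max_observed mode requires at least one observation")
    max(observed)
  }
  ei <- expected_improvement(pr$mean, pr$sd, f_max)
  idx <- which.max(ei)        # first maximum = lowest candidate index
  list(index = idx, id = space$candidates$id[idx], coords = Xc[idx, ],
       ei = ei, f_max = f_max, mean = pr$mean, sd = pr$sd)
}

#' A replay source of precomputed contrast values
#'
#' Wraps a finite sequence of contrast observations so that a recorded run
#' can be replayed through [bo_run()] instead of simulating new data. The
#' source errors when exhausted.
#'
#' @param values Numeric vector of contrast values consumed in order.
#' @return Function `(task_id, iteration) -> value` with class
#'   `"replay_source"`.
#' @export
replay_source <- function(values) {
  values <- as.numeric(values)
  i <- 0L
  f <- function(task_id, iteration) {
    i <<- i + 1L
    if (i > length(values))
      stop("replay source exhausted after ", length(values), " observations")
    values[i]
  }
  class(f) <- c("replay_source", "function")
  f
}

#' Run closed-loop neuroadaptive Bayesian optimization
#'
#' The full closed loop on a simulated scanner: after a burn-in of
#' `burn_in` tasks sampled uniformly without replacement, each iteration
#' (1) re-estimates all block contrasts with the incremental GLM on the
#' despiked ROI timecourses observed so far, (2) conditions the GP
#' surrogate (fixed hyperparameters) on every (task, contrast) pair, and
#' (3) selects the next task by expected improvement. The simulated run
#' grows by one block per iteration; all betas are refreshed every
#' iteration, so earlier observations can be revised as more data arrive.
#'
#' @param space A `task_space`.
#' @param truth A [ground_truth()] surface (ignored when `objective` is
#'   given).
#' @param hyper Fixed [gp_hyper()] used throughout the loop.
#' @param target,others Contrast definition passed to
#'   [compute_contrasts()]; `others` may name several ROIs
#'   (one-versus-mean).
#' @param n_iterations Total number of blocks (>= `burn_in`).
#' @param burn_in Number of initial random blocks.
#' @param seed Integer seed controlling burn-in draws, simulation noise and
#'   motion.
#' @param protocol Block-design protocol (see [block_design()]).
#' @param f_max_mode Acquisition incumbent mode (see [select_next_task()]).
#' @param despike Apply [kalman_despike()] to each ROI timecourse before
#'   the GLM.
#' @param refresh Re-estimate all past contrasts each iteration (the
#'   incremental-GLM behaviour). `FALSE` keeps an append-only training set
#'   where each contrast is frozen at the iteration that produced it.
#' @param objective Optional function `(task_id, iteration) -> contrast`
#'   (e.g. [replay_source()]) replacing simulation + GLM entirely.
#' @return A `bo_run` object: list with `observations` (data frame
#'   `iteration`, `task_id`, coordinate columns, `contrast`, `phase`),
#'   `ei_trace` (iterations x candidates matrix of EI values, NA during
#'   burn-in), `f_max_trace`, `space`, `hyper`, `design`, `run` (the final
#'   `simulated_run`, NULL under `objective`), `true_optimum` (id of the
#'   best true mean contrast when simulating), `config`.
#' @seealso [distance_trajectory()], [sampling_frequency()]
#' @export
bo_run <- function(space, truth = NULL, hyper, target = NULL, others = NULL,
                   n_iterations = 20L, burn_in = 5L, seed = 1L,
                   protocol = "exp1",
                   f_max_mode = c("max_predicted", "max_observed"),
                   despike = TRUE, refresh = TRUE, objective = NULL) {
  f_max_mode <- match.arg(f_max_mode)
  stopifnot(inherits(space, "task_space"), inherits(hyper, "gp_hyper"))
  n_iterations <- as.integer(n_iterations)
  burn_in <- as.integer(burn_in)
  if (n_iterations < burn_in) stop("n_iterations must be >= burn_in")
  if (burn_in < 1L) stop("burn_in must be >= 1")
  simulate <- is.null(objective)
  if (simulate) {
    stopifnot(inherits(truth, "ground_truth"),
              !is.null(target), !is.null(others))
    if (!setequal(truth$task_ids, space$candidates$id))
      stop("ground truth and space must cover the same task ids")
  }
  ids <- space$candidates$id
  Xc <- space_coords(space)
  n_cand <- length(ids)

  # burn-in: uniform draws without replacement (recycled if burn_in > n)
  chosen <- integer(n_iterations)
  chosen[seq_len(burn_in)] <- with_seed(seed, {
    k <- min(burn_in, n_cand)
    s <- sample.int(n_cand, k)
    if (burn_in > k) s <- c(s, sample.int(n_cand, burn_in - k, replace = TRUE))
    s
  })

  sim <- NULL
  if (simulate) {
    sim <- loop_simulator(space, truth, hyper, n_iterations, seed, protocol)
  }

  ei_trace <- matrix(NA_real_, n_iterations, n_cand,
                     dimnames = list(NULL, ids))
  f_max_trace <- rep(NA_real_, n_iterations)
  y_obs <- numeric(0)      # training targets (refreshed or append-only)
  contrasts <- numeric(0)

  for (it in seq_len(n_iterations)) {
    if (it > burn_in) {
      fit <- gp_fit(Xc[chosen[seq_len(it - 1L)], , drop = FALSE], y_obs,
                    hyper)
      sel <- select_next_task(fit, space, f_max_mode, observed = y_obs)
      chosen[it] <- sel$index
      ei_trace[it, ] <- sel$ei
      f_max_trace[it] <- sel$f_max
    }
    if (simulate) {
      # the first GLM runs after the burn-in completes; before that there
      # is nothing for the surrogate model to consume
      if (it >= burn_in)
        contrasts <- sim$measure(chosen[seq_len(it)], target, others,
                                 despike)
    } else {
      new_val <- objective(ids[chosen[it]], it)
      contrasts <- c(contrasts, new_val)
    }
    if (refresh) {
      if (it >= burn_in || !simulate) y_obs <- contrasts
    } else {
      y_obs <- if (it < burn_in) y_obs
               else if (it == burn_in) contrasts[seq_len(it)]
               else c(y_obs, contrasts[it])
    }
  }

  obs <- data.frame(iteration = seq_len(n_iterations),
                    task_id = ids[chosen],
                    contrast = y_obs,
                    phase = ifelse(seq_len(n_iterations) <= burn_in,
                                   "burn_in", "closed_loop"),
                    stringsAsFactors = FALSE)
  for (d in seq_len(space$dim)) obs[[paste0("x", d)]] <- Xc[chosen, d]
  true_opt <- NULL
  if (simulate) {
    mu <- vapply(ids, function(id)
      mean(truth$roi_means[[target]][id]) -
        mean(vapply(others, function(r) truth$roi_means[[r]][id],
                    numeric(1))), numeric(1))
    true_opt <- ids[which.max(mu)]
  }
  structure(list(observations = obs, ei_trace = ei_trace,
                 f_max_trace = f_max_trace, space = space, hyper = hyper,
                 design = if (simulate) sim$design else NULL,
                 run = if (simulate) sim$finalize(chosen) else NULL,
                 true_optimum = true_opt,
                 config = list(n_iterations = n_iterations,
                               burn_in = burn_in, seed = seed,
                               protocol = protocol, f_max_mode = f_max_mode,
                               despike = despike, refresh = refresh,
                               target = target, others = others)),
            class = "bo_run")
}

# the convolved regressors depend only on protocol geometry, so repeated
# runs (e.g. seed sweeps) reuse them
.conv_cache <- new.env(parent = emptyenv())
cached_convolved_design <- function(design) {
  key <- paste(design$protocol, design$n_blocks, design$tr_seconds,
               sep = "_")
  if (is.null(.conv_cache[[key]]))
    .conv_cache[[key]] <- convolve_design(design, nuisance = TRUE)
  .conv_cache[[key]]
}

# Pre-generates everything about the simulated run that does not depend on
# which tasks get chosen (design regressors, motion, noise, drift, spikes),
# then composes signal incrementally as the loop assigns tasks to blocks.
loop_simulator <- function(space, truth, hyper, n_blocks, seed, protocol) {
  design <- block_design(protocol, n_blocks)
  lead <- design$lead_in_frames
  n_task_frames <- design$n_frames
  n_total <- lead + n_task_frames
  conv <- cached_convolved_design(design)
  block_cols <- paste0("block_", seq_len(n_blocks))
  rois <- truth$rois
  pieces <- with_seed(seed + 1L, {
    motion <- simulate_motion(n_total)
    noise <- matrix(stats::rnorm(n_total * length(rois),
                                 sd = truth$noise_sd),
                    n_total, length(rois), dimnames = list(NULL, rois))
    if (truth$spike_rate > 0 && truth$spike_sd > 0) {
      hit <- matrix(stats::runif(n_total * length(rois)) < truth$spike_rate,
                    n_total, length(rois))
      noise <- noise + hit * matrix(stats::rnorm(n_total * length(rois),
                                                 sd = truth$spike_sd),
                                    n_total, length(rois))
    }
    list(motion = motion, noise = noise)
  })
  drift <- truth$drift_slope * (seq_len(n_total) - 1L)
  tr <- design$tr_seconds
  task_ev <- design$events[design$events$role == "task_of_interest", ]
  block_end_frames <- ceiling((task_ev$onset + task_ev$duration) / tr)

  roi_signal <- function(chosen_idx) {
    tasks <- space$candidates$id[chosen_idx]
    amp <- vapply(rois, function(r) unname(truth$roi_means[[r]][tasks]),
                  numeric(length(tasks)))
    amp <- matrix(amp, nrow = length(tasks), ncol = length(rois),
                  dimnames = list(NULL, rois))
    k <- length(tasks)
    sig <- conv[, block_cols[seq_len(k)], drop = FALSE] %*% amp
    rbind(matrix(0, lead, length(rois)), sig) + drift
  }

  measure <- function(chosen_idx, target, others, despike) {
    k <- length(chosen_idx)
    frames <- min(block_end_frames[k] + 2L, n_task_frames)  # include HRF tail
    y_all <- roi_signal(chosen_idx)[seq_len(lead + frames), , drop = FALSE] +
      pieces$noise[seq_len(lead + frames), , drop = FALSE]
    des <- incremental_design(design, pieces$motion, frames, k_blocks = k,
                              conv = conv)
    need <- unique(c(target, others))
    fits <- lapply(need, function(r) {
      yr <- y_all[(lead + 1):(lead + frames), r]
      if (despike) yr <- kalman_despike(yr)
      fit_glm(yr, des)
    })
    names(fits) <- need
    compute_contrasts(fits, target, others)
  }

  finalize <- function(chosen_idx) {
    tasks <- space$candidates$id[chosen_idx]
    amp <- vapply(rois, function(r) unname(truth$roi_means[[r]][tasks]),
                  numeric(length(tasks)))
    amp <- matrix(amp, nrow = length(tasks), ncol = length(rois),
                  dimnames = list(NULL, rois))
    noiseless <- roi_signal(chosen_idx)
    colnames(noiseless) <- rois
    y <- noiseless + pieces$noise
    design_full <- block_design(protocol, n_blocks, block_conditions = tasks)
    structure(list(roi_timecourses = y, noiseless = noiseless,
                   voxel_data = NULL, motion = pieces$motion,
                   fd = framewise_displacement(pieces$motion),
                   design = design_full, true_block_betas = amp,
                   lead_in_frames = lead, seed = seed),
              class = "simulated_run")
  }

  list(design = design, measure = measure, finalize = finalize)
}

#' @export
print.bo_run <- function(x, ...) {
  cfg <- x$config
  cat("Closed-loop Bayesian optimization run\n")
  cat("  ", cfg$n_iterations, " iterations (burn-in ", cfg$burn_in,
      "), protocol ", cfg$protocol, ", f_max = ", cfg$f_max_mode,
      ", seed ", cfg$seed, "\n", sep = "")
  post <- x$observations[x$observations$phase == "closed_loop", ]
  if (nrow(post)) {
    tab <- sort(table(post$task_id), decreasing = TRUE)
    cat("  most sampled (closed loop): ",
        paste0(names(tab)[seq_len(min(3, length(tab)))], " (",
               tab[seq_len(min(3, length(tab)))], ")", collapse = ", "),
        "\n", sep = "")
  }
  if (!is.null(x$true_optimum))
    cat("  planted optimum: ", x$true_optimum, "\n", sep = "")
  invisible(x)
}

#' @export
summary.bo_run <- function(object, ...) {
  freq <- sampling_frequency(list(object))
  ed <- distance_trajectory(object)
  out <- list(sampling_frequency = freq,
              ed_trajectory = ed,
              mean_ed = mean(ed),
              best_observed = max(object$observations$contrast),
              modal_task = names(freq)[which.max(freq)],
              true_optimum = object$true_optimum,
              config = object$config)
  class(out) <- "summary.bo_run"
  out
}

#' @export
print.summary.bo_run <- function(x, ...) {
  cat("Closed-loop run summary\n")
  cat("  modal closed-loop task: ", x$modal_task, "\n", sep = "")
  if (!is.null(x$true_optimum))
    cat("  planted optimum:        ", x$true_optimum, "\n", sep = "")
  cat("  best observed contrast: ", signif(x$best_observed, 4), "\n",
      sep = "")
  cat("  mean successive distance: ", signif(x$mean_ed, 4), "\n", sep = "")
  cat("  sampling frequencies (closed loop):\n")
  print(round(sort(x$sampling_frequency, decreasing = TRUE), 3))
  invisible(x)
}

#' @export
plot.bo_run <- function(x, which = c("trajectory", "frequency"), ...) {
  which <- match.arg(which)
  if (which == "trajectory") {
    ed <- distance_trajectory(x)
    graphics::plot(seq_along(ed), ed, type = "b", xlab = "iteration step",
                   ylab = "Euclidean distance to previous task",
                   main = "Explore-to-exploit trajectory", ...)
    graphics::abline(v = x$config$burn_in - 0.5, lty = 2)
  } else {
    freq <- sampling_frequency(list(x))
    graphics::barplot(freq, las = 2, ylab = "sampling proportion",
                      main = "Closed-loop sampling frequency", ...)
  }
  invisible(x)
}

#' Euclidean distances between successively sampled tasks
#'
#' The explore-to-exploit diagnostic: distances in task-space coordinates
#' between consecutive chosen tasks. Large early distances indicate
#' exploration; shrinking distances indicate exploitation of an optimum.
#'
#' @param record A `bo_run`.
#' @return Numeric vector of length `n_iterations - 1`.
#' @export
distance_trajectory <- function(record) {
  stopifnot(inherits(record, "bo_run"))
  obs <- record$observations
  if (nrow(obs) < 2L) stop("need at least 2 observations")
  Xc <- as.matrix(obs[, paste0("x", seq_len(record$space$dim)), drop = FALSE])
  sqrt(rowSums((Xc[-1L, , drop = FALSE] - Xc[-nrow(Xc), , drop = FALSE])^2))
}

#' Closed-loop sampling frequency per task
#'
#' Proportion of post-burn-in samples falling on each candidate task,
#' pooled over one or more runs.
#'
#' @param records List of `bo_run` objects (or a single one).
#' @param exclude_burn_in Drop the burn-in phase (the random period).
#' @return Named numeric vector over all candidate ids, summing to 1.
#' @export
sampling_frequency <- function(records, exclude_burn_in = TRUE) {
  if (inherits(records, "bo_run")) records <- list(records)
  ids <- records[[1L]]$space$candidates$id
  picks <- unlist(lapply(records, function(r) {
    obs <- r$observations
    if (exclude_burn_in) obs <- obs[obs$phase == "closed_loop", ]
    obs$task_id
  }))
  if (length(picks) == 0L) stop("no post-burn-in observations")
  tab <- table(factor(picks, levels = ids))
  prop <- as.numeric(tab) / length(picks)
  names(prop) <- ids
  prop
}
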