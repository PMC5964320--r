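# Synthetic block-design BOLD: the stand-in for the scanner in the closed
# loop. Every run is reproducible from its seed; the true activation
# amplitudes behind every block are recorded so analyses can be checked
# against ground truth.

#' Ground-truth activation surface for simulation
#'
#' Defines, for each region of interest, the true BOLD activation amplitude
#' elicited by every candidate task, plus the noise model of the simulated
#' scanner.
#'
#' @param roi_means Named list: one entry per ROI, each a named numeric
#'   vector mapping task id to activation amplitude (arbitrary BOLD units,
#'   the peak response of one block).
#' @param noise_sd White observation noise SD added to each ROI timecourse.
#' @param drift_slope Linear drift per frame.
#' @param spike_rate Per-frame probability of an additive signal spike.
#' @param spike_sd SD of the spike amplitude (Gaussian).
#' @param voxel_noise_sd Independent noise SD added on top of the parent ROI
#'   signal for simulated voxels; defaults to `noise_sd`.
#' @return A `ground_truth` object.
#' @export
ground_truth <- function(roi_means, noise_sd = 0, drift_slope = 0,
                         spike_rate = 0, spike_sd = 0,
                         voxel_noise_sd = noise_sd) {
  stopifnot(is.list(roi_means), length(roi_means) >= 1L,
            !is.null(names(roi_means)))
  ids <- names(roi_means[[1L]])
  for (r in names(roi_means)) {
    m <- roi_means[[r]]
    if (is.null(names(m)) || !setequal(names(m), ids))
      stop("every ROI must define an amplitude for the same set of task ids")
    if (any(!is.finite(m))) stop("amplitudes must be finite")
  }
  if (noise_sd < 0 || spike_sd < 0 || voxel_noise_sd < 0 ||
      spike_rate < 0 || spike_rate > 1)
    stop("invalid noise parameters")
  structure(list(roi_means = roi_means, noise_sd = noise_sd,
                 drift_slope = drift_slope, spike_rate = spike_rate,
                 spike_sd = spike_sd, voxel_noise_sd = voxel_noise_sd,
                 task_ids = ids, rois = names(roi_means)),
            class = "ground_truth")
}

# evaluate an expression under a private RNG stream, restoring global state
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

# smooth rigid-body motion: random walks with small steps
simulate_motion <- function(n_frames, step_trans_mm = 0.02,
                            step_rot_rad = 2e-4) {
  steps <- cbind(matrix(stats::rnorm(n_frames * 3, sd = step_trans_mm),
                        ncol = 3),
                 matrix(stats::rnorm(n_frames * 3, sd = step_rot_rad),
                        ncol = 3))
  m <- apply(steps, 2L, cumsum)
  colnames(m) <- c("tx", "ty", "tz", "rx", "ry", "rz")
  m
}

#' Simulate one block-design BOLD run
#'
#' Generates per-ROI (and optionally per-voxel) timecourses for a fully
#' specified block design: each ROI's signal is the sum over blocks of the
#' true activation amplitude for the block's task times the HRF-convolved
#' block regressor, plus linear drift, white noise and optional additive
#' spikes. Motion is a smooth six-parameter random walk. The first
#' `design$lead_in_frames` frames model T1 equilibration (noise and drift
#' only) and are meant to be discarded by the analysis.
#'
#' @param space A `task_space`; every block condition must be a candidate id.
#' @param truth A [ground_truth()] surface covering all block conditions.
#' @param design A [block_design()] whose blocks all have assigned
#'   conditions.
#' @param voxels_per_roi Number of simulated voxels per ROI (0 = none).
#' @param seed Integer seed; identical inputs and seed give bit-identical
#'   runs.
#' @return A `simulated_run` object: list with `roi_timecourses` (frames x
#'   ROI matrix, lead-in frames first), `noiseless` (same minus noise and
#'   spikes), `voxel_data` (`data` frames x voxel matrix and `roi` labels,
#'   or NULL), `motion`, `fd`, `design`, `true_block_betas` (blocks x ROI),
#'   `lead_in_frames`, `seed`.
#' @export
simulate_run <- function(space, truth, design, voxels_per_roi = 0L, seed) {
  stopifnot(inherits(space, "task_space"), inherits(truth, "ground_truth"),
            inherits(design, "block_design"))
  if (design$n_blocks < 1L) stop("design has no blocks")
  tasks <- design$events$condition[design$events$role == "task_of_interest"]
  if (any(is.na(tasks)))
    stop("all blocks must have an assigned task condition")
  unknown <- setdiff(tasks, truth$task_ids)
  if (length(unknown))
    stop("task id(s) not in ground truth: ", paste(unknown, collapse = ", "))
  if (!all(tasks %in% space$candidates$id))
    stop("block conditions must be candidates of the space")
  lead <- design$lead_in_frames
  n_task_frames <- design$n_frames
  n_total <- lead + n_task_frames
  reg <- convolve_design(design, nuisance = FALSE)   # n_task_frames x blocks
  rois <- truth$rois
  betas <- sapply(rois, function(r) unname(truth$roi_means[[r]][tasks]))
  betas <- matrix(betas, nrow = design$n_blocks, ncol = length(rois),
                  dimnames = list(NULL, rois))
  drift <- truth$drift_slope * (seq_len(n_total) - 1L)
  noiseless <- matrix(0, n_total, length(rois), dimnames = list(NULL, rois))
  for (r in seq_along(rois)) {
    sig <- as.numeric(reg %*% betas[, r])
    noiseless[, r] <- c(rep(0, lead), sig) + drift
  }
  with_seed(seed, {
    motion <- simulate_motion(n_total)
    noise <- matrix(stats::rnorm(n_total * length(rois),
                                 sd = truth$noise_sd),
                    n_total, length(rois))
    y <- noiseless + noise
    if (truth$spike_rate > 0 && truth$spike_sd > 0) {
      hit <- matrix(stats::runif(n_total * length(rois)) < truth$spike_rate,
                    n_total, length(rois))
      y <- y + hit * matrix(stats::rnorm(n_total * length(rois),
                                         sd = truth$spike_sd),
                            n_total, length(rois))
    }
    voxel_data <- NULL
    if (voxels_per_roi > 0L) {
      n_vox <- voxels_per_roi * length(rois)
      vox_roi <- rep(rois, each = voxels_per_roi)
      vdata <- noiseless[, vox_roi, drop = FALSE] +
        matrix(stats::rnorm(n_total * n_vox, sd = truth$voxel_noise_sd),
               n_total, n_vox)
      colnames(vdata) <- paste0(vox_roi, "_v",
                                rep(seq_len(voxels_per_roi),
                                    times = length(rois)))
      voxel_data <- list(data = vdata, roi = vox_roi)
    }
    structure(list(roi_timecourses = y, noiseless = noiseless,
                   voxel_data = voxel_data, motion = motion,
                   fd = framewise_displacement(motion), design = design,
                   true_block_betas = betas, lead_in_frames = lead,
                   seed = seed),
              class = "simulated_run")
  })
}

#' @export
print.simulated_run <- function(x, ...) {
  cat("Simulated run: ", nrow(x$roi_timecourses), " frames (",
      x$lead_in_frames, " lead-in), ", ncol(x$roi_timecourses), " ROI(s), ",
      x$design$n_blocks, " blocks, seed ", x$seed, "\n", sep = "")
  invisible(x)
}

#' Write / read ROI timecourses as long-format CSV
#'
#' Columns `frame, roi, value`; frames are 1-based and include the lead-in.
#'
#' @param run A `simulated_run` (or any frames x ROI matrix).
#' @param path Output (input) CSV path.
#' @export
write_roi_timecourses <- function(run, path) {
  y <- if (inherits(run, "simulated_run")) run$roi_timecourses else as.matrix(run)
  long <- data.frame(frame = rep(seq_len(nrow(y)), times = ncol(y)),
                     roi = rep(colnames(y), each = nrow(y)),
                     value = as.numeric(y))
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_roi_timecourses
#' @export
read_roi_timecourses <- function(path) {
  long <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("frame", "roi", "value") %in% names(long)))
  rois <- unique(long$roi)
  n <- max(long$frame)
  y <- matrix(NA_real_, n, length(rois), dimnames = list(NULL, rois))
  for (r in rois) {
    sub <- long[long$roi == r, ]
    y[sub$frame, r] <- sub$value
  }
  y
}
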