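#' Canonical double-gamma hemodynamic response function
#'
#' Difference of two gamma densities with the canonical parameterization:
#' response peak at 6 s, undershoot peak at 16 s, unit dispersions, and a
#' peak-to-undershoot amplitude ratio of 6. The kernel is rescaled to unit
#' peak so regression amplitudes are interpretable as peak BOLD change.
#'
#' @param t Nonnegative, increasing time grid in seconds.
#' @param peak_delay,undershoot_delay Gamma density means in seconds.
#' @param peak_disp,undershoot_disp Gamma density dispersions (variance /
#'   mean) in seconds.
#' @param ratio Peak : undershoot amplitude ratio.
#' @return Kernel values on `t`, scaled to unit maximum.
#' @examples
#' tt <- seq(0, 32, by = 0.1)
#' h <- hrf_double_gamma(tt)
#' tt[which.max(h)]  # ~5 s (mode of a gamma with mean 6, dispersion 1)
#' @export
hrf_double_gamma <- function(t, peak_delay = 6, undershoot_delay = 16,
                             peak_disp = 1, undershoot_disp = 1, ratio = 6) {
  if (length(t) == 0L) stop("empty time grid")
  if (any(t < 0) || is.unsorted(t, strictly = FALSE))
    stop("time grid must be nonnegative and increasing")
  # gamma with mean m and dispersion d: shape m/d, scale d
  h <- stats::dgamma(t, shape = peak_delay / peak_disp, scale = peak_disp) -
    stats::dgamma(t, shape = undershoot_delay / undershoot_disp,
                  scale = undershoot_disp) / ratio
  h / max(h)
}

#' Block design for a closed-loop run
#'
#' Builds the event timing of one optimization run. Protocols `"exp1"` and
#' `"exp3"` use 62 s blocks: 5 s instruction (nuisance) + 3 s rest + 35 s
#' task (of interest) + 19 s rest. Protocol `"exp2"` uses 54 s blocks: 30 s
#' problem (of interest) + 5 s response interval (nuisance) + 19 s rest.
#' Ten lead-in frames for T1 equilibration precede the first block and are
#' discarded by every consumer.
#'
#' @param protocol One of `"exp1"`, `"exp2"`, `"exp3"`.
#' @param n_blocks Number of task blocks (>= 0). May exceed the length of
#'   `block_conditions` when the tasks are assigned later by the closed loop.
#' @param block_conditions Optional character vector of task ids occupying
#'   the blocks in order.
#' @param tr_seconds Repetition time in seconds.
#' @return A `block_design` object: list with `tr_seconds`, `events` (data
#'   frame `onset`, `duration`, `condition`, `role`, `block`),
#'   `lead_in_frames`, `n_blocks`, `block_seconds`, `total_seconds`,
#'   `n_frames` (excluding lead-in; `total_seconds / tr`), `protocol`.
#' @examples
#' d <- block_design("exp1", 20)
#' d$total_seconds / 60  # 20.67 min
#' @export
block_design <- function(protocol = c("exp1", "exp2", "exp3"), n_blocks,
                         block_conditions = NULL, tr_seconds = 2) {
  protocol <- match.arg(protocol)
  n_blocks <- as.integer(n_blocks)
  if (n_blocks < 0L) stop("n_blocks must be >= 0")
  if (!is.null(block_conditions) && length(block_conditions) > n_blocks)
    stop("more block conditions than blocks")
  layout <- switch(protocol,
    exp1 = ,
    exp3 = list(parts = data.frame(
      offset = c(0, 8), duration = c(5, 35),
      role = c("nuisance", "task_of_interest"),
      label = c("instruction", "task"), stringsAsFactors = FALSE),
      block_seconds = 62),
    exp2 = list(parts = data.frame(
      offset = c(0, 30), duration = c(30, 5),
      role = c("task_of_interest", "nuisance"),
      label = c("task", "response"), stringsAsFactors = FALSE),
      block_seconds = 54))
  events <- NULL
  if (n_blocks > 0L) {
    starts <- (seq_len(n_blocks) - 1L) * layout$block_seconds
    events <- do.call(rbind, lapply(seq_len(n_blocks), function(b) {
      cond <- if (!is.null(block_conditions) && b <= length(block_conditions))
        as.character(block_conditions[b]) else NA_character_
      data.frame(
        onset = starts[b] + layout$parts$offset,
        duration = layout$parts$duration,
        condition = ifelse(layout$parts$role == "task_of_interest",
                           cond, layout$parts$label),
        role = layout$parts$role,
        block = b,
        stringsAsFactors = FALSE)
    }))
    rownames(events) <- NULL
  } else {
    events <- data.frame(onset = numeric(0), duration = numeric(0),
                         condition = character(0), role = character(0),
                         block = integer(0), stringsAsFactors = FALSE)
  }
  total <- n_blocks * layout$block_seconds
  structure(list(tr_seconds = tr_seconds, events = events,
                 lead_in_frames = 10L, n_blocks = n_blocks,
                 block_seconds = layout$block_seconds,
                 total_seconds = total,
                 n_frames = as.integer(round(total / tr_seconds)),
                 protocol = protocol),
            class = "block_design")
}

#' @export
print.block_design <- function(x, ...) {
  cat("Block design (", x$protocol, "): ", x$n_blocks, " blocks x ",
      x$block_seconds, " s = ", x$total_seconds, " s (",
      round(x$total_seconds / 60, 2), " min), TR ", x$tr_seconds,
      " s, ", x$lead_in_frames, " lead-in frames\n", sep = "")
  invisible(x)
}

#' Convolve block regressors with the hemodynamic response
#'
#' Builds one regressor per requested column by convolving the column's
#' boxcar (1 during its events, 0 elsewhere) with the canonical double-gamma
#' HRF on a fine microtime grid, then sampling at the TR. Columns may be
#' individual blocks of interest (`blocks`) or pooled nuisance-event classes
#' (`nuisance`). Convolution is linear in the boxcar; the discrete
#' convolution is scaled by the microtime step so regressor amplitude is
#' independent of the microtime resolution.
#'
#' @param design A `block_design`.
#' @param blocks Integer vector of block numbers to give individual
#'   regressors (their `task_of_interest` events). Default: all blocks.
#' @param nuisance Logical; add one pooled regressor per nuisance event
#'   label (e.g. all instruction periods share a column).
#' @param microtime Microtime resolution in seconds.
#' @param n_frames Number of output frames; default `design$n_frames`.
#' @return Matrix (`n_frames` rows; the timeline starts at the end of the
#'   discarded lead-in, matching event onsets) with one named column per
#'   regressor (`"block_<b>"` and the nuisance labels).
#' @export
convolve_design <- function(design, blocks = seq_len(design$n_blocks),
                            nuisance = TRUE, microtime = 0.1,
                            n_frames = design$n_frames) {
  stopifnot(inherits(design, "block_design"))
  if (n_frames < 1L && length(blocks) == 0L && !nuisance)
    return(matrix(numeric(0), nrow = max(n_frames, 0L), ncol = 0L))
  ev <- design$events
  cols <- list()
  for (b in blocks) {
    e <- ev[ev$block == b & ev$role == "task_of_interest", , drop = FALSE]
    cols[[paste0("block_", b)]] <- e
  }
  if (nuisance && nrow(ev) > 0L) {
    nev <- ev[ev$role == "nuisance", , drop = FALSE]
    for (lab in unique(nev$condition)) {
      cols[[lab]] <- nev[nev$condition == lab, , drop = FALSE]
    }
  }
  if (length(cols) == 0L)
    return(matrix(numeric(0), nrow = n_frames, ncol = 0L))
  run_seconds <- n_frames * design$tr_seconds
  n_micro <- as.integer(ceiling(run_seconds / microtime)) + 1L
  hrf_t <- seq(0, 32, by = microtime)
  h <- hrf_double_gamma(hrf_t)
  nfft <- stats::nextn(n_micro + length(h) - 1L, 2L)
  H <- stats::fft(c(h, numeric(nfft - length(h))))
  out <- matrix(0, nrow = n_frames, ncol = length(cols),
                dimnames = list(NULL, names(cols)))
  # frame f (1-based) sampled at time (f-1)*TR
  frame_idx <- as.integer(round((seq_len(n_frames) - 1L) *
                                  design$tr_seconds / microtime)) + 1L
  for (j in seq_along(cols)) {
    e <- cols[[j]]
    box <- numeric(n_micro)
    for (k in seq_len(nrow(e))) {
      if (e$duration[k] <= 0) next
      i0 <- as.integer(floor(e$onset[k] / microtime)) + 1L
      i1 <- as.integer(ceiling((e$onset[k] + e$duration[k]) / microtime))
      i1 <- min(i1, n_micro)
      if (i1 >= i0) box[i0:i1] <- 1
    }
    B <- stats::fft(c(box, numeric(nfft - n_micro)))
    conv <- Re(stats::fft(B * H, inverse = TRUE))[seq_len(n_micro)] *
      (microtime / nfft)
    out[, j] <- conv[frame_idx]
  }
  out
}

#' Framewise displacement from a motion trace
#'
#' Power-style framewise displacement: the sum of absolute frame-to-frame
#' differences of the three translations (mm) plus the three rotations
#' (radians) converted to arc length on a 50 mm sphere. The first frame has
#' FD 0 by convention.
#'
#' @param motion Numeric matrix (frames x 6): columns 1-3 translations in mm,
#'   columns 4-6 rotations in radians.
#' @param radius_mm Sphere radius for the rotation-to-displacement
#'   conversion.
#' @return Numeric vector of per-frame FD in mm.
#' @export
framewise_displacement <- function(motion, radius_mm = 50) {
  motion <- as.matrix(motion)
  if (nrow(motion) < 1L || ncol(motion) != 6L)
    stop("motion must be a frames x 6 matrix")
  if (nrow(motion) == 1L) return(0)
  d <- abs(diff(motion))
  fd <- rowSums(d[, 1:3, drop = FALSE]) +
    radius_mm * rowSums(d[, 4:6, drop = FALSE])
  c(0, fd)
}
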