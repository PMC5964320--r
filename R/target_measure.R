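# The optimizer's objective: network contrasts from incremental GLMs on
# despiked ROI timecourses, plus the run-quality rules (motion scrubbing,
# Grubbs run exclusion) used offline.

#' Remove large signal spikes with a local-level Kalman filter
#'
#' Runs a scalar local-level state-space filter along the series. Frames
#' whose innovation exceeds `gate` times the innovation standard deviation
#' are candidate spikes; a candidate whose deviation does not persist into
#' the following frame is replaced by the filtered prediction (the state
#' update skips the contaminated observation), while a persistent deviation
#' in the same direction is accepted as a genuine signal change and the
#' state re-initializes on it. All other frames pass through unchanged.
#' The persistence rule keeps steep hemodynamic ramps intact even when the
#' evoked signal dwarfs the background noise.
#'
#' @param y Numeric series (>= 2 frames).
#' @param gate Spike threshold in innovation-SD multiples.
#' @param q_ratio Ratio of state-evolution variance to observation variance.
#'   The default tracks hemodynamic ramps quickly enough that sustained task
#'   blocks are not mistaken for spikes, while single-frame excursions beyond
#'   the gate are still caught.
#' @return Cleaned series, same length; attribute `"spikes"` holds the
#'   indices of replaced frames.
#' @export
kalman_despike <- function(y, gate = 3, q_ratio = 1) {
  y <- as.numeric(y)
  n <- length(y)
  if (n < 2L) stop("need at least 2 frames")
  if (gate <= 0) stop("gate must be positive")
  if (stats::sd(y) == 0) {
    attr(y, "spikes") <- integer(0)
    return(y)
  }
  # robust observation-noise estimate from first differences
  r <- (stats::mad(diff(y)) / sqrt(2))^2
  if (r == 0) r <- stats::var(diff(y)) / 2
  q <- q_ratio * r
  out <- y
  spikes <- integer(0)
  x <- y[1L]
  P <- r
  for (t in 2:n) {
    Pp <- P + q
    Fv <- Pp + r
    innov <- y[t] - x
    if (abs(innov) > gate * sqrt(Fv)) {
      persistent <- t < n &&
        abs(y[t + 1L] - x) > gate * sqrt(Fv) &&
        sign(y[t + 1L] - x) == sign(innov)
      if (persistent) {     # level change, not a transient: follow it
        x <- y[t]
        P <- r
      } else {
        out[t] <- x
        spikes <- c(spikes, t)
        P <- Pp             # observation discarded
      }
    } else {
      K <- Pp / Fv
      x <- x + K * innov
      P <- (1 - K) * Pp
    }
  }
  attr(out, "spikes") <- spikes
  out
}

#' Incremental GLM design matrix
#'
#' Builds the design matrix of the real-time analysis after `k_blocks`
#' completed blocks: one HRF-convolved regressor per block of interest, one
#' pooled regressor per nuisance event class (all instruction periods share
#' a column, likewise response intervals), six motion parameters, a linear
#' trend and an intercept. The matrix covers the first `frames_elapsed`
#' post-lead-in frames; lead-in frames are excluded throughout.
#'
#' @param design A [block_design()].
#' @param motion Full-run motion matrix (frames x 6) including lead-in rows.
#' @param frames_elapsed Number of post-lead-in frames available; must cover
#'   the end of block `k_blocks`'s task event.
#' @param k_blocks Number of completed blocks to model; default: all blocks
#'   whose task event has finished by `frames_elapsed`.
#' @param conv Optional precomputed [convolve_design()] matrix for the full
#'   design (all blocks + nuisance), to avoid reconvolving in tight loops.
#' @return List with `matrix` (frames_elapsed x p) and `roles` (per-column
#'   label: `"block_of_interest"`, `"nuisance_event"`, `"motion"`,
#'   `"linear_trend"`, `"intercept"`).
#' @export
incremental_design <- function(design, motion, frames_elapsed,
                               k_blocks = NULL, conv = NULL) {
  stopifnot(inherits(design, "block_design"))
  tr <- design$tr_seconds
  ev <- design$events
  task_ev <- ev[ev$role == "task_of_interest", , drop = FALSE]
  ends <- task_ev$onset + task_ev$duration
  complete <- which(ends <= frames_elapsed * tr)
  if (is.null(k_blocks)) k_blocks <- length(complete)
  if (k_blocks > 0 && (length(complete) < k_blocks))
    stop("frames_elapsed does not cover the end of block ", k_blocks)
  if (is.null(conv)) conv <- convolve_design(design, nuisance = TRUE)
  block_cols <- paste0("block_", seq_len(k_blocks))
  nuis_cols <- setdiff(colnames(conv), paste0("block_", seq_len(design$n_blocks)))
  rows <- seq_len(frames_elapsed)
  X <- cbind(conv[rows, block_cols, drop = FALSE],
             conv[rows, nuis_cols, drop = FALSE])
  lead <- design$lead_in_frames
  if (nrow(motion) < lead + frames_elapsed)
    stop("motion trace shorter than lead-in + frames_elapsed")
  mot <- as.matrix(motion)[lead + rows, , drop = FALSE]
  colnames(mot) <- paste0("motion_", 1:6)
  trend <- matrix(seq_len(frames_elapsed) - 1, ncol = 1,
                  dimnames = list(NULL, "linear_trend"))
  icept <- matrix(1, frames_elapsed, 1, dimnames = list(NULL, "intercept"))
  Xfull <- cbind(X, mot, trend, icept)
  roles <- c(rep("block_of_interest", k_blocks),
             rep("nuisance_event", length(nuis_cols)),
             rep("motion", 6L), "linear_trend", "intercept")
  list(matrix = Xfull, roles = roles)
}

#' Ordinary least-squares GLM fit
#'
#' Fits `y = X beta + e` by least squares. Rank-deficient designs (e.g. an
#' all-zero motion trace) are solved by the minimum-norm solution via the
#' singular value decomposition rather than raising an error.
#'
#' @param y Numeric response series.
#' @param design Either a matrix or the list returned by
#'   [incremental_design()].
#' @return A `glm_fit` object: `betas` (named), `roles`, `fitted`,
#'   `residual_variance` (RSS / dof, NA when dof = 0), `dof`
#'   (frames - rank), `rank`.
#' @export
fit_glm <- function(y, design) {
  roles <- NULL
  if (is.list(design) && !is.null(design$matrix)) {
    roles <- design$roles
    X <- design$matrix
  } else {
    X <- as.matrix(design)
  }
  y <- as.numeric(y)
  n <- length(y)
  if (n < 2L) stop("need at least 2 frames")
  if (nrow(X) != n) stop("design and data frame counts differ")
  sv <- svd(X)
  tol <- max(dim(X)) * max(sv$d) * .Machine$double.eps
  pos <- sv$d > tol
  rank <- sum(pos)
  dinv <- ifelse(pos, 1 / sv$d, 0)
  beta <- sv$v %*% (dinv * crossprod(sv$u, y))
  beta <- as.numeric(beta)
  names(beta) <- colnames(X)
  fitted <- as.numeric(X %*% beta)
  rss <- sum((y - fitted)^2)
  dof <- n - rank
  structure(list(betas = beta, roles = roles, fitted = fitted,
                 residual_variance = if (dof > 0) rss / dof else NA_real_,
                 dof = dof, rank = rank),
            class = "glm_fit")
}

#' @export
print.glm_fit <- function(x, ...) {
  cat("GLM fit: ", length(x$betas), " regressors, rank ", x$rank,
      ", dof ", x$dof, "\n", sep = "")
  invisible(x)
}

# per-block betas (block_of_interest columns, in block order)
block_betas <- function(fit) {
  if (!is.null(fit$roles)) {
    fit$betas[fit$roles == "block_of_interest"]
  } else {
    fit$betas[grepl("^block_", names(fit$betas))]
  }
}

#' Per-block network contrasts
#'
#' The optimizer's target measure: for every completed block, the difference
#' between the target network's block beta and either a single comparison
#' network's beta (pairwise) or the mean of several (one-versus-mean).
#'
#' @param fits Named list of [fit_glm()] results, one per ROI.
#' @param target Name of the target ROI.
#' @param others Character vector of comparison ROI name(s).
#' @return Numeric vector, one contrast per block (BOLD beta units).
#' @export
compute_contrasts <- function(fits, target, others) {
  stopifnot(is.list(fits), target %in% names(fits),
            all(others %in% names(fits)), !(target %in% others))
  b_t <- block_betas(fits[[target]])
  if (any(vapply(others, function(r)
    length(block_betas(fits[[r]])), integer(1)) != length(b_t)))
    stop("ROI fits have mismatched block counts")
  b_o <- vapply(others, function(r) as.numeric(block_betas(fits[[r]])),
                numeric(length(b_t)))
  b_o <- matrix(b_o, nrow = length(b_t))
  unname(b_t - rowMeans(b_o))
}

#' Motion scrubbing mask
#'
#' Frames whose framewise displacement exceeds the threshold are dropped
#' from offline analyses.
#'
#' @param fd Per-frame FD series (mm).
#' @param threshold FD threshold in mm; frames with `fd > threshold` are
#'   removed.
#' @return Logical keep-mask, same length as `fd`.
#' @export
scrub_frames <- function(fd, threshold = 1.5) {
  if (threshold <= 0) stop("threshold must be positive")
  as.numeric(fd) <= threshold
}

#' Iterative Grubbs outlier detection
#'
#' Repeatedly tests the single most extreme value with the two-sided Grubbs
#' statistic \eqn{G = \max_i |x_i - \bar x| / s} and removes it while
#' \eqn{G} exceeds the t-based critical value at level `alpha`. Used to
#' exclude runs with outlying head motion.
#'
#' @param x Numeric vector (n >= 3).
#' @param alpha Significance level of each Grubbs test.
#' @return Integer vector of outlier indices into the original `x` (possibly
#'   empty), in removal order.
#' @export
grubbs_outliers <- function(x, alpha = 0.05) {
  x <- as.numeric(x)
  if (length(x) < 3L) stop("Grubbs test requires at least 3 values")
  idx <- seq_along(x)
  out <- integer(0)
  repeat {
    n <- length(x)
    if (n < 3L) break
    s <- stats::sd(x)
    if (s == 0) break
    dev <- abs(x - mean(x))
    i <- which.max(dev)
    G <- dev[i] / s
    tcrit <- stats::qt(alpha / (2 * n), df = n - 2, lower.tail = FALSE)
    Gcrit <- ((n - 1) / sqrt(n)) * sqrt(tcrit^2 / (n - 2 + tcrit^2))
    if (G > Gcrit) {
      out <- c(out, idx[i])
      x <- x[-i]
      idx <- idx[-i]
    } else break
  }
  out
}
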