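# Post-hoc voxel-wise back-projection: repeat the real-time analysis on
# every (simulated) voxel's timecourse, correlate the resulting per-voxel
# prediction maps with reference maps, and test cluster means with
# max-statistic permutation correction.

#' Per-voxel GP prediction maps (back-projection)
#'
#' For every simulated voxel: scrub high-motion frames, linearly detrend,
#' fit the full-design GLM, contrast the voxel's block betas against the
#' reference ROI's block betas, feed the per-block contrasts into a GP
#' (hyperparameters tuned per voxel by Type-2 maximum likelihood) and
#' predict over the candidate tasks.
#'
#' @param run A [simulate_run()] result with `voxel_data`.
#' @param reference_roi ROI whose betas are subtracted from every voxel's.
#' @param space The `task_space` the run sampled from.
#' @param scrub_threshold FD scrubbing threshold in mm.
#' @param tune `TRUE` to tune per voxel (reduced restarts for speed), or a
#'   fixed [gp_hyper()] shared by all voxels.
#' @param restarts,seed Tuning controls (see [gp_tune()]).
#' @param bounds Hyperparameter bounds for per-voxel tuning.
#' @return A `voxel_maps` object: `predictions` (voxels x candidates
#'   matrix), `roi` (per-voxel parent labels), `contrasts` (voxels x blocks
#'   matrix), `space`.
#' @export
voxel_prediction_maps <- function(run, reference_roi, space,
                                  scrub_threshold = 1.5, tune = TRUE,
                                  restarts = 2L, seed = 1L,
                                  bounds = list(signal_sd = c(1e-3, 1e2),
                                                lengthscale = c(0.05, 10),
                                                noise_sd = c(1e-3, 1e2))) {
  stopifnot(inherits(run, "simulated_run"), inherits(space, "task_space"))
  if (is.null(run$voxel_data)) stop("run has no voxel data")
  stopifnot(reference_roi %in% colnames(run$roi_timecourses))
  design <- run$design
  lead <- run$lead_in_frames
  frames <- design$n_frames
  keep <- scrub_frames(run$fd[(lead + 1):(lead + frames)],
                       threshold = scrub_threshold)
  if (!any(keep)) stop("all frames scrubbed")
  des <- incremental_design(design, run$motion, frames)
  X <- des$matrix[keep, , drop = FALSE]
  roles <- des$roles
  tt <- seq_len(sum(keep))
  detrend <- function(y) stats::lm.fit(cbind(1, tt), y)$residuals + mean(y)
  fit_betas <- function(y) {
    y <- detrend(y[(lead + 1):(lead + frames)][keep])
    block_betas(fit_glm(y, list(matrix = X, roles = roles)))
  }
  ref_betas <- fit_betas(run$roi_timecourses[, reference_roi])
  vox <- run$voxel_data$data
  n_vox <- ncol(vox)
  tasks <- design$events$condition[design$events$role == "task_of_interest"]
  coords <- space_coords(space)[match(tasks, space$candidates$id), ,
                                drop = FALSE]
  ids <- space$candidates$id
  preds <- matrix(NA_real_, n_vox, length(ids),
                  dimnames = list(colnames(vox), ids))
  contr <- matrix(NA_real_, n_vox, design$n_blocks,
                  dimnames = list(colnames(vox), NULL))
  for (v in seq_len(n_vox)) {
    cv <- fit_betas(vox[, v]) - ref_betas
    contr[v, ] <- cv
    hv <- if (inherits(tune, "gp_hyper")) tune
          else gp_tune(coords, cv, bounds = bounds, restarts = restarts,
                       seed = seed + v, ard = space$dim > 1L)
    fit <- gp_fit(coords, cv, hv)
    preds[v, ] <- stats::predict(fit, space_coords(space))$mean
  }
  structure(list(predictions = preds, roi = run$voxel_data$roi,
                 contrasts = contr, space = space),
            class = "voxel_maps")
}

#' Spatial similarity of voxel maps to a reference map
#'
#' Pearson correlation, across candidate tasks, between every voxel's
#' prediction map and a reference map, then Fisher z-transformed with `r`
#' clipped to \eqn{\pm(1 - 10^{-7})} so z stays finite. Voxels with a
#' zero-variance map get `NA` and are flagged.
#'
#' @param maps A `voxel_maps` object (or voxels x candidates matrix).
#' @param reference Numeric vector over the same candidates (named vectors
#'   are aligned by candidate id).
#' @return Data frame with `voxel`, `roi` (if known), `r`, `z`.
#' @export
spatial_similarity <- function(maps, reference) {
  if (inherits(maps, "voxel_maps")) {
    P <- maps$predictions
    roi <- maps$roi
  } else {
    P <- as.matrix(maps)
    roi <- rep(NA_character_, nrow(P))
  }
  if (ncol(P) < 3L) stop("need at least 3 candidates to correlate")
  if (!is.null(names(reference)) && !is.null(colnames(P)))
    reference <- reference[colnames(P)]
  reference <- as.numeric(reference)
  if (length(reference) != ncol(P))
    stop("reference length does not match candidate count")
  if (stats::sd(reference) == 0) stop("reference map has zero variance")
  r <- rep(NA_real_, nrow(P))
  ok <- apply(P, 1L, stats::sd) > 0
  if (any(ok)) r[ok] <- as.numeric(stats::cor(t(P[ok, , drop = FALSE]),
                                              reference))
  z <- atanh(pmin(pmax(r, -(1 - 1e-7)), 1 - 1e-7))
  data.frame(voxel = if (!is.null(rownames(P))) rownames(P)
             else seq_len(nrow(P)),
             roi = roi, r = r, z = z, stringsAsFactors = FALSE)
}

#' Per-cluster mean Fisher z
#'
#' Averages per-voxel Fisher z within labeled clusters, dropping clusters
#' smaller than `min_voxels`, for each subject.
#'
#' @param z Subjects x voxels matrix of Fisher z values (a vector is one
#'   subject).
#' @param clusters Per-voxel cluster labels (`NA` = outside all clusters).
#' @param min_voxels Minimum cluster size; smaller clusters are excluded.
#' @return Subjects x clusters matrix of mean z values.
#' @export
cluster_mean_z <- function(z, clusters, min_voxels = 200L) {
  if (is.null(dim(z))) z <- matrix(z, nrow = 1L)
  clusters <- as.character(clusters)
  if (length(clusters) != ncol(z))
    stop("cluster labels must match voxel count")
  sizes <- table(clusters[!is.na(clusters)])
  keep <- names(sizes)[sizes >= min_voxels]
  if (length(keep) == 0L)
    stop("no cluster reaches the minimum size of ", min_voxels, " voxels")
  out <- sapply(keep, function(cl)
    rowMeans(z[, which(clusters == cl), drop = FALSE], na.rm = TRUE))
  out <- matrix(out, nrow = nrow(z), dimnames = list(rownames(z), keep))
  out
}

#' Max-statistic permutation test over clusters
#'
#' Family-wise-error-corrected inference on per-cluster subject means using
#' sign-flip permutations and the null distribution of the maximum
#' statistic across clusters (the tmax method). With n subjects the
#' sign-flip null has \eqn{2^n} members; it is enumerated exhaustively when
#' \eqn{2^n \le 2^{16}}, otherwise sampled with the identity assignment
#' always included. One-sample tests are two-tailed by default (max of
#' |t|); a paired test is the one-sample test on a difference matrix.
#'
#' @param x Subjects x clusters matrix: raw values (`test = "one_sample"`)
#'   or paired differences (`test = "paired"`).
#' @param test Label only; both tests sign-flip the rows of `x`.
#' @param alpha Family-wise error level.
#' @param two_tailed Use |t| (TRUE) or t (FALSE) in the max statistic.
#' @param n_perm Monte-Carlo permutation count when enumeration is
#'   infeasible.
#' @param seed Seed for Monte-Carlo sign draws.
#' @return A `tmax_perm` object: `t_obs`, `critical_t`, `p_corrected` (per
#'   cluster), `n_permutations`, `exhaustive`, `alpha`, `df`, `excluded`
#'   (zero-variance clusters).
#' @export
tmax_permutation <- function(x, test = c("one_sample", "paired"),
                             alpha = 0.05, two_tailed = TRUE,
                             n_perm = 10000L, seed = 1L) {
  test <- match.arg(test)
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 2L) stop("need at least 2 subjects")
  sds <- apply(x, 2L, stats::sd)
  mns <- colMeans(x)
  # all-zero clusters carry no evidence (t = 0); zero variance around a
  # nonzero mean leaves t undefined and the cluster is dropped
  bad <- sds == 0 & abs(mns) > 0
  excluded <- if (is.null(colnames(x))) which(bad) else colnames(x)[bad]
  if (any(bad))
    warning("excluding zero-variance cluster(s): ",
            paste(excluded, collapse = ", "))
  x <- x[, !bad, drop = FALSE]
  k <- ncol(x)
  if (k == 0L) stop("no testable cluster (all zero variance, nonzero mean)")
  t_from_means <- function(means, ss) {
    v <- (ss - n * means^2) / (n - 1)
    v[v < .Machine$double.eps] <- .Machine$double.eps
    means / sqrt(v / n)
  }
  ss <- colSums(x^2)                      # invariant under sign flips
  t_obs <- t_from_means(colMeans(x), ss)
  exhaustive <- 2^n <= 2^16
  S <- if (exhaustive) {
    m <- as.matrix(expand.grid(rep(list(c(1, -1)), n)))
    dimnames(m) <- NULL
    m
  } else {
    with_seed(seed, rbind(rep(1, n),
                          matrix(sample(c(1, -1), (n_perm - 1L) * n,
                                        replace = TRUE),
                                 n_perm - 1L, n)))
  }
  means_null <- (S %*% x) / n
  t_null <- means_null
  for (j in seq_len(k)) t_null[, j] <- t_from_means(means_null[, j], ss[j])
  max_null <- if (two_tailed) apply(abs(t_null), 1L, max)
              else apply(t_null, 1L, max)
  B <- nrow(S)
  crit <- sort(max_null)[ceiling((1 - alpha) * B)]
  stat_obs <- if (two_tailed) abs(t_obs) else t_obs
  p_corr <- vapply(stat_obs, function(s) mean(max_null >= s - 1e-12),
                   numeric(1))
  structure(list(t_obs = t_obs, critical_t = crit, p_corrected = p_corr,
                 n_permutations = B, exhaustive = exhaustive, alpha = alpha,
                 df = n - 1L, test = test, two_tailed = two_tailed,
                 excluded = excluded),
            class = "tmax_perm")
}

#' @export
print.tmax_perm <- function(x, ...) {
  cat("Max-statistic permutation test (", x$test, ", ",
      if (x$two_tailed) "two-tailed" else "one-tailed", ")\n", sep = "")
  cat("  ", x$n_permutations, " permutations (",
      if (x$exhaustive) "exhaustive" else "Monte-Carlo",
      "), critical t(", x$df, ") = ", signif(x$critical_t, 3),
      " at alpha ", x$alpha, "\n", sep = "")
  print(data.frame(cluster = names(x$t_obs) %||% seq_along(x$t_obs),
                   t = signif(x$t_obs, 4),
                   p_corrected = signif(x$p_corrected, 4),
                   significant = x$p_corrected < x$alpha),
        row.names = FALSE)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Compare back-projected maps with hypothesized predictions
#'
#' For each subject's voxel maps, computes two similarity values per voxel
#' (versus the group-level map and versus the hypothesized meta-analytic
#' map), Fisher z-transforms both, averages their difference within
#' clusters and tests the paired per-cluster differences with the tmax
#' permutation method.
#'
#' @param maps_list List over subjects of `voxel_maps` objects (identical
#'   voxel layout).
#' @param group_reference Numeric vector over candidates: the group-map
#'   predictions (named by candidate id or in candidate order).
#' @param hypothesized Numeric vector over candidates: the hypothesized
#'   scores.
#' @param clusters Per-voxel cluster labels.
#' @param min_voxels Minimum cluster size.
#' @param alpha,seed Passed to [tmax_permutation()].
#' @return List with `diff_matrix` (subjects x clusters mean z difference,
#'   group minus hypothesized), `perm` (a `tmax_perm`), `z_group`,
#'   `z_hypothesized` (subjects x clusters mean z).
#' @export
compare_with_hypothesized <- function(maps_list, group_reference,
                                      hypothesized, clusters,
                                      min_voxels = 200L, alpha = 0.05,
                                      seed = 1L) {
  stopifnot(length(maps_list) >= 2L)
  zs <- lapply(maps_list, function(m) {
    zg <- spatial_similarity(m, group_reference)$z
    zh <- spatial_similarity(m, hypothesized)$z
    list(zg = zg, zh = zh)
  })
  Zg <- do.call(rbind, lapply(zs, `[[`, "zg"))
  Zh <- do.call(rbind, lapply(zs, `[[`, "zh"))
  cg <- cluster_mean_z(Zg, clusters, min_voxels)
  ch <- cluster_mean_z(Zh, clusters, min_voxels)
  d <- cg - ch
  perm <- tmax_permutation(d, test = "paired", alpha = alpha, seed = seed)
  list(diff_matrix = d, perm = perm, z_group = cg, z_hypothesized = ch)
}
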