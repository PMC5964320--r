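test_that("despiker removes spikes and leaves clean frames untouched", {
  expect_equal(as.numeric(kalman_despike(rep(2, 50))), rep(2, 50))
  set.seed(21)
  y <- rnorm(400)
  spiked <- y
  spiked[200] <- spiked[200] + 10
  cleaned <- kalman_despike(spiked)
  expect_lt(abs(cleaned[200]), 3)
  expect_true(200 %in% attr(cleaned, "spikes"))
  # pure white noise passes through nearly unchanged
  clean2 <- kalman_despike(y)
  expect_gte(cor(y, as.numeric(clean2)), 0.95)
  # non-spike frames are not altered at all
  keep <- setdiff(seq_along(y), attr(clean2, "spikes"))
  expect_equal(as.numeric(clean2)[keep], y[keep])
  expect_error(kalman_despike(1), "2 frames")
  expect_error(kalman_despike(1:10, gate = 0), "positive")
})

test_that("incremental design grows one block column at a time", {
  d <- block_design("exp1", 20)
  motion <- matrix(rnorm((10 + d$n_frames) * 6, sd = 0.01),
                   ncol = 6)
  d1 <- incremental_design(d, motion, frames_elapsed = 31, k_blocks = 1)
  # 1 block + 1 pooled instruction + 6 motion + trend + intercept
  expect_equal(ncol(d1$matrix), 10L)
  expect_equal(sum(d1$roles == "block_of_interest"), 1L)
  d20 <- incremental_design(d, motion, frames_elapsed = d$n_frames)
  expect_equal(ncol(d20$matrix), 29L)
  expect_equal(sum(d20$roles == "block_of_interest"), 20L)
  expect_equal(sum(d20$roles == "nuisance_event"), 1L)
  expect_error(incremental_design(d, motion, frames_elapsed = 10,
                                  k_blocks = 1), "does not cover")
})

test_that("least squares matches the normal-equations oracle", {
  set.seed(4)
  X <- matrix(rnorm(60 * 8), 60, 8)
  beta0 <- rnorm(8)
  y <- X %*% beta0
  fit <- fit_glm(y, X)
  expect_equal(unname(fit$betas), beta0, tolerance = 1e-10)
  yn <- y + rnorm(60)
  expect_equal(unname(fit_glm(yn, X)$betas), oracle_ols(yn, X),
               tolerance = 1e-8)
  # orthonormal columns: betas are inner products
  Q <- qr.Q(qr(X))[, 1:4]
  expect_equal(unname(fit_glm(yn, Q)$betas),
               as.numeric(crossprod(Q, yn)), tolerance = 1e-10)
  expect_equal(fit_glm(yn, X)$dof, 60 - 8)
})

test_that("rank-deficient designs use the minimum-norm solution", {
  d <- block_design("exp1", 2)
  motion <- matrix(0, 10 + d$n_frames, 6)    # degenerate: zero motion
  des <- incremental_design(d, motion, d$n_frames)
  y <- rnorm(d$n_frames)
  fit <- fit_glm(y, des)
  expect_lt(fit$rank, ncol(des$matrix))
  expect_true(all(is.finite(fit$betas)))
  expect_equal(fit$betas[des$roles == "motion"], rep(0, 6),
               ignore_attr = TRUE)
})

test_that("contrasts are per-block beta differences", {
  mk <- function(b) structure(list(betas = b,
                                   roles = rep("block_of_interest",
                                               length(b))),
                              class = "glm_fit")
  fits <- list(dfpn = mk(c(2, 1)), vfpn = mk(c(1, 1)))
  expect_equal(compute_contrasts(fits, "dfpn", "vfpn"), c(1, 0))
  fits4 <- list(t = mk(c(2, 1)), a = mk(c(0, 1)), b = mk(c(1, 1)),
                c = mk(c(2, 1)))
  expect_equal(compute_contrasts(fits4, "t", c("a", "b", "c")), c(1, 0))
  bad <- list(dfpn = mk(c(2, 1)), vfpn = mk(1))
  expect_error(compute_contrasts(bad, "dfpn", "vfpn"), "mismatched")
})

test_that("noiseless end-to-end recovery is exact", {
  sp <- tiny_space()
  tr <- tiny_truth(sp)
  tasks <- c("a", "b", "c", "d", "a", "b")
  d <- block_design("exp1", 6, block_conditions = tasks)
  run <- simulate_run(sp, tr, d, seed = 1)
  des <- incremental_design(d, run$motion, d$n_frames)
  rows <- (run$lead_in_frames + 1):(run$lead_in_frames + d$n_frames)
  fits <- lapply(c("dfpn", "vfpn"), function(r)
    fit_glm(run$roi_timecourses[rows, r], des))
  names(fits) <- c("dfpn", "vfpn")
  cc <- compute_contrasts(fits, "dfpn", "vfpn")
  truth_c <- unname(tr$roi_means$dfpn[tasks] - tr$roi_means$vfpn[tasks])
  expect_equal(cc, truth_c, tolerance = 1e-8)
})

test_that("refreshing re-estimates earlier blocks consistently", {
  # on noiseless data later blocks must not perturb earlier estimates
  sp <- tiny_space()
  tr <- tiny_truth(sp)
  tasks <- c("a", "d", "b", "c")
  d <- block_design("exp1", 4, block_conditions = tasks)
  run <- simulate_run(sp, tr, d, seed = 2)
  rows <- function(n) (run$lead_in_frames + 1):(run$lead_in_frames + n)
  frames_k <- function(k) {
    ev <- d$events[d$events$role == "task_of_interest", ]
    min(ceiling((ev$onset[k] + ev$duration[k]) / d$tr_seconds) + 2,
        d$n_frames)
  }
  c3 <- local({
    f <- frames_k(3)
    des <- incremental_design(d, run$motion, f, k_blocks = 3)
    fits <- lapply(c("dfpn", "vfpn"), function(r)
      fit_glm(run$roi_timecourses[rows(f), r], des))
    names(fits) <- c("dfpn", "vfpn")
    compute_contrasts(fits, "dfpn", "vfpn")
  })
  c4 <- local({
    des <- incremental_design(d, run$motion, d$n_frames)
    fits <- lapply(c("dfpn", "vfpn"), function(r)
      fit_glm(run$roi_timecourses[rows(d$n_frames), r], des))
    names(fits) <- c("dfpn", "vfpn")
    compute_contrasts(fits, "dfpn", "vfpn")
  })
  expect_equal(c4[1:3], c3, tolerance = 1e-6)
})

test_that("scrubbing thresholds framewise displacement", {
  fd <- c(0, 0.2, 2.0, 0.1)
  expect_equal(scrub_frames(fd), c(TRUE, TRUE, FALSE, TRUE))
  expect_equal(scrub_frames(rep(0, 4)), rep(TRUE, 4))
  expect_equal(scrub_frames(numeric(0)), logical(0))
  expect_equal(scrub_frames(fd, threshold = Inf), rep(TRUE, 4))
  expect_length(scrub_frames(fd), length(fd))
})

test_that("iterative Grubbs flags gross outliers at the t-based cutoff", {
  x <- c(8, 8.1, 7.9, 8.2, 20)
  # oracle: direct computation of the statistic and critical value
  G <- max(abs(x - mean(x))) / sd(x)
  expect_gt(G, oracle_grubbs_crit(5))
  expect_equal(grubbs_outliers(x), 5L)
  expect_equal(grubbs_outliers(rep(3, 10)), integer(0))
  expect_error(grubbs_outliers(c(1, 2)), "at least 3")
  # values comfortably inside the critical envelope are kept
  set.seed(3)
  xn <- rnorm(50)
  crit <- oracle_grubbs_crit(50)
  xn <- xn[abs(xn - mean(xn)) / sd(xn) < 0.9 * crit]
  expect_equal(grubbs_outliers(xn), integer(0))
})
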