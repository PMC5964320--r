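test_that("a burn-in-only run holds exactly the random observations", {
  sp <- tiny_space()
  tr <- tiny_truth(sp, noise_sd = 0.2)
  r <- bo_run(sp, tr, default_hyper(), "dfpn", "vfpn",
              n_iterations = 4, burn_in = 4, seed = 10)
  expect_equal(nrow(r$observations), 4L)
  expect_true(all(r$observations$phase == "burn_in"))
  expect_true(all(is.na(r$ei_trace)))
  # burn-in draws are without replacement
  expect_equal(anyDuplicated(r$observations$task_id), 0L)
})

test_that("closed-loop runs are reproducible and recorded completely", {
  sp <- tiny_space()
  tr <- tiny_truth(sp, noise_sd = 0.3)
  h <- default_hyper()
  r1 <- bo_run(sp, tr, h, "dfpn", "vfpn", n_iterations = 8, burn_in = 3,
               seed = 5)
  r2 <- bo_run(sp, tr, h, "dfpn", "vfpn", n_iterations = 8, burn_in = 3,
               seed = 5)
  expect_identical(r1$observations, r2$observations)
  expect_identical(r1$ei_trace, r2$ei_trace)
  # EI values recorded for every closed-loop iteration and candidate
  post <- r1$ei_trace[4:8, ]
  expect_true(all(is.finite(post)))
  expect_true(all(post >= 0))
  # chosen task maximizes recorded EI (lowest index on ties)
  for (i in 4:8) {
    expect_equal(r1$observations$task_id[i],
                 sp$candidates$id[which.max(r1$ei_trace[i, ])])
  }
  expect_error(bo_run(sp, tr, h, "dfpn", "vfpn", n_iterations = 2,
                      burn_in = 3, seed = 1), ">= burn_in")
})

test_that("replay sources drive the loop and error when exhausted", {
  sp <- tiny_space()
  h <- default_hyper()
  r <- bo_run(sp, hyper = h, n_iterations = 6, burn_in = 2, seed = 3,
              objective = replay_source(seq(0.1, 0.6, by = 0.1)))
  expect_equal(r$observations$contrast, seq(0.1, 0.6, by = 0.1))
  expect_error(
    bo_run(sp, hyper = h, n_iterations = 7, burn_in = 2, seed = 3,
           objective = replay_source(rep(0, 6))),
    "exhausted")
})

test_that("append-only training differs from refreshed training", {
  sp <- tiny_space()
  tr <- tiny_truth(sp, noise_sd = 0.5)
  h <- default_hyper()
  r_ref <- bo_run(sp, tr, h, "dfpn", "vfpn", n_iterations = 10,
                  burn_in = 5, seed = 2, refresh = TRUE)
  r_app <- bo_run(sp, tr, h, "dfpn", "vfpn", n_iterations = 10,
                  burn_in = 5, seed = 2, refresh = FALSE)
  expect_equal(nrow(r_app$observations), 10L)
  # both modes agree on the very first post-burn-in choice (same data)
  expect_equal(r_ref$observations$task_id[6], r_app$observations$task_id[6])
})

test_that("distance trajectory and sampling frequency summarize the search", {
  sp <- tiny_space()
  h <- default_hyper()
  vals <- rep(0, 6)
  r <- bo_run(sp, hyper = h, n_iterations = 6, burn_in = 2, seed = 1,
              objective = replay_source(vals))
  ed <- distance_trajectory(r)
  expect_length(ed, 5L)
  Xc <- as.matrix(r$observations[, c("x1", "x2")])
  expect_equal(ed[1], sqrt(sum((Xc[2, ] - Xc[1, ])^2)))
  freq <- sampling_frequency(r)
  expect_equal(sum(freq), 1, tolerance = 1e-12)
  expect_named(freq, sp$candidates$id)
  # all post-burn-in picks on one task -> that task gets 1.0
  r2 <- r
  r2$observations$task_id[3:6] <- "a"
  expect_equal(unname(sampling_frequency(r2)["a"]), 1)
})

test_that("successful runs transition from exploration to exploitation", {
  fx <- make_fixture("exp1_like", seed = 1)
  hits <- 0; trans <- 0; n_seeds <- 12
  for (s in seq_len(n_seeds)) {
    r <- bo_run(fx$space, fx$truth, fx$hyper, fx$target, fx$others,
                n_iterations = 20, burn_in = 5, seed = 100 + s)
    freq <- sampling_frequency(r)
    hits <- hits + (names(which.max(freq)) == fx$optimum)
    ed <- distance_trajectory(r)
    trans <- trans + (mean(ed[15:19]) < mean(ed[5:9]))
  }
  expect_gte(hits / n_seeds, 0.75)
  expect_gte(trans / n_seeds, 0.6)
})

test_that("run records summarize and serialize", {
  sp <- tiny_space()
  tr <- tiny_truth(sp, noise_sd = 0.2)
  r <- bo_run(sp, tr, default_hyper(), "dfpn", "vfpn", n_iterations = 7,
              burn_in = 3, seed = 9)
  s <- summary(r)
  expect_s3_class(s, "summary.bo_run")
  expect_equal(s$true_optimum, "a")
  f <- withr::local_tempfile(fileext = ".csv")
  write_observations(r, f)
  back <- read.csv(f, stringsAsFactors = FALSE)
  expect_equal(back$task_id, r$observations$task_id)
  expect_equal(back$contrast, r$observations$contrast, tolerance = 1e-12)
})
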