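# Group-level synthesis: pooled GP prediction maps over the task space and
# mixed-model tests for quadratic trends in subject-level predictions.

#' Group-level GP prediction map
#'
#' Pools the observations of several closed-loop runs, retunes the GP
#' hyperparameters on the pooled data by Type-2 maximum likelihood, and
#' predicts the contrast surface over the candidate tasks and a dense grid.
#'
#' @param records List of `bo_run` objects, or a data frame with coordinate
#'   columns `x1[, x2]` and a `contrast` column.
#' @param space The shared `task_space`.
#' @param tune Retune hyperparameters on the pooled observations (`TRUE`),
#'   or a fixed [gp_hyper()] to use as-is.
#' @param restarts,seed,bounds Tuning controls passed to [gp_tune()].
#' @param grid_resolution Optional override for the dense prediction grid.
#' @return A `group_map` object: `candidate_pred` (data frame `id`, `mean`,
#'   `sd`), `grid` (coords + `mean`, `sd`), `hyper`, `fit`, `n_obs`.
#' @export
group_map <- function(records, space, tune = TRUE, restarts = 5L, seed = 1L,
                      bounds = list(signal_sd = c(1e-3, 1e3),
                                    lengthscale = c(0.01, 10),
                                    noise_sd = c(1e-3, 1e3)),
                      grid_resolution = NULL) {
  stopifnot(inherits(space, "task_space"))
  if (is.data.frame(records)) {
    obs <- records
  } else {
    if (inherits(records, "bo_run")) records <- list(records)
    obs <- do.call(rbind, lapply(records, function(r) r$observations))
  }
  coord_cols <- paste0("x", seq_len(space$dim))
  stopifnot(all(c(coord_cols, "contrast") %in% names(obs)))
  X <- as.matrix(obs[, coord_cols, drop = FALSE])
  y <- obs$contrast
  if (length(y) < 3L) stop("need at least 3 pooled observations")
  hyper <- if (inherits(tune, "gp_hyper")) {
    tune
  } else if (isTRUE(tune)) {
    gp_tune(X, y, bounds = bounds, restarts = restarts, seed = seed,
            ard = space$dim > 1L)
  } else {
    stop("'tune' must be TRUE or a gp_hyper object")
  }
  fit <- gp_fit(X, y, hyper)
  pc <- stats::predict(fit, space_coords(space))
  g <- prediction_grid(space, grid_resolution)
  pg <- stats::predict(fit, g)
  structure(list(candidate_pred = data.frame(id = space$candidates$id,
                                             mean = pc$mean, sd = pc$sd,
                                             stringsAsFactors = FALSE),
                 grid = cbind(as.data.frame(g), mean = pg$mean, sd = pg$sd),
                 hyper = hyper, fit = fit, n_obs = length(y),
                 space = space),
            class = "group_map")
}

#' @export
print.group_map <- function(x, ...) {
  cat("Group-level GP prediction map: ", x$n_obs, " pooled observations\n",
      sep = "")
  print(x$hyper)
  best <- x$candidate_pred[order(-x$candidate_pred$mean), ][1:min(3,
    nrow(x$candidate_pred)), ]
  cat("  top predicted tasks:\n")
  print(data.frame(id = best$id, mean = signif(best$mean, 4),
                   sd = signif(best$sd, 4)), row.names = FALSE)
  invisible(x)
}

#' @export
plot.group_map <- function(x, ...) {
  sp <- x$space
  if (sp$dim == 1L) {
    graphics::plot(x$grid$x1, x$grid$mean, type = "l",
                   xlab = "task coordinate", ylab = "predicted contrast",
                   main = "Group-level prediction map", ...)
    graphics::lines(x$grid$x1, x$grid$mean + x$grid$sd, lty = 3)
    graphics::lines(x$grid$x1, x$grid$mean - x$grid$sd, lty = 3)
    graphics::points(space_coords(sp), x$candidate_pred$mean, pch = 19)
  } else {
    res <- round(sqrt(nrow(x$grid)))
    z <- matrix(x$grid$mean, res, res)
    graphics::image(unique(x$grid$x1), unique(x$grid$x2), z,
                    xlab = "x1", ylab = "x2",
                    main = "Group-level prediction map",
                    col = grDevices::hcl.colors(64, "viridis"), ...)
    graphics::points(space_coords(sp), pch = 21, bg = "white")
  }
  invisible(x)
}

#' Simulate subject-level predictions over a parametric dimension
#'
#' Generates the kind of data entering [quadratic_trend_test()]: one
#' predicted contrast per subject and difficulty level, with a per-subject
#' random intercept, a linear trend, optional quadratic curvature centered
#' mid-range, and white noise.
#'
#' @param n_subjects Number of subjects.
#' @param levels Numeric vector of difficulty levels.
#' @param slope Linear fixed-effect slope per level unit.
#' @param curvature Quadratic coefficient on `(level - mean(level))^2`
#'   (negative = plateauing / inverted-U profile).
#' @param subject_sd SD of the per-subject random intercept.
#' @param noise_sd Residual SD.
#' @param seed Integer seed.
#' @return Data frame with `subject`, `level`, `prediction`.
#' @export
simulate_subject_predictions <- function(n_subjects = 10L,
                                         levels = 1:16, slope = 0.1,
                                         curvature = 0, subject_sd = 1,
                                         noise_sd = 1, seed = 1L) {
  with_seed(seed, {
    b0 <- stats::rnorm(n_subjects, sd = subject_sd)
    d <- expand.grid(subject = factor(seq_len(n_subjects)), level = levels)
    ctr <- d$level - mean(levels)
    d$prediction <- b0[as.integer(d$subject)] + slope * d$level +
      curvature * ctr^2 + stats::rnorm(nrow(d), sd = noise_sd)
    d
  })
}

#' Linear-versus-quadratic mixed-model trend test
#'
#' Tests whether subject-level GP predictions across a parametric task
#' dimension carry a quadratic component (e.g. plateauing activation with
#' difficulty), using nested linear mixed-effect models with a per-subject
#' random intercept, both fit by maximum likelihood, compared with a
#' likelihood ratio test. When a second (categorical) factor is supplied,
#' both models include its main effect and its interaction with the linear
#' term, and the quadratic model adds the squared term plus its interaction
#' with the factor (two added terms).
#'
#' @param data Data frame of subject-level predictions.
#' @param response,level,subject Column names of the predicted contrast, the
#'   continuous level (difficulty / number of steps) and the subject id.
#' @param factor2 Optional column name of a second categorical factor
#'   (e.g. convolution condition).
#' @return List with `statistic` (LRT chi-square), `df`, `p_value`,
#'   `singular` (any fit singular), `linear`, `quadratic` (the two
#'   `lmerMod` fits).
#' @export
quadratic_trend_test <- function(data, response = "prediction",
                                 level = "level", subject = "subject",
                                 factor2 = NULL) {
  stopifnot(is.data.frame(data),
            all(c(response, level, subject) %in% names(data)))
  if (length(unique(data[[level]])) < 4L)
    stop("need at least 4 distinct levels")
  if (length(unique(data[[subject]])) < 3L)
    stop("need at least 3 subjects")
  fixed_lin <- paste0("`", level, "`")
  add_quad <- paste0("I(`", level, "`^2)")
  if (!is.null(factor2)) {
    stopifnot(factor2 %in% names(data))
    fixed_lin <- paste0(fixed_lin, " + `", factor2, "` + `", level,
                        "`:`", factor2, "`")
    add_quad <- paste0(add_quad, " + I(`", level, "`^2):`", factor2, "`")
  }
  f_lin <- stats::as.formula(paste0("`", response, "` ~ ", fixed_lin,
                                    " + (1 | `", subject, "`)"))
  f_quad <- stats::as.formula(paste0("`", response, "` ~ ", fixed_lin,
                                     " + ", add_quad,
                                     " + (1 | `", subject, "`)"))
  ctl <- lme4::lmerControl(check.conv.singular = "ignore")
  m_lin <- suppressMessages(
    lme4::lmer(f_lin, data = data, REML = FALSE, control = ctl))
  m_quad <- suppressMessages(
    lme4::lmer(f_quad, data = data, REML = FALSE, control = ctl))
  singular <- lme4::isSingular(m_lin) || lme4::isSingular(m_quad)
  a <- stats::anova(m_lin, m_quad)
  list(statistic = a$Chisq[2L], df = a$Df[2L],
       p_value = a$`Pr(>Chisq)`[2L], singular = singular,
       linear = m_lin, quadratic = m_quad)
}
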