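# Gaussian-process surrogate model: zero-mean prior, squared-exponential
# (ARD) covariance, white observation noise. Hyperparameters are tuned by
# Type-2 maximum likelihood on held-out data and then fixed inside the
# closed loop.

#' Gaussian-process hyperparameters
#'
#' @param signal_sd Prior signal standard deviation \eqn{\sigma} (> 0); the
#'   kernel variance is \eqn{\sigma^2}.
#' @param lengthscales Kernel lengthscale(s) \eqn{l}, one per task-space
#'   dimension (automatic relevance determination), all > 0.
#' @param noise_sd White observation-noise SD \eqn{\sigma_{noise}} (> 0).
#' @return A `gp_hyper` object.
#' @export
gp_hyper <- function(signal_sd, lengthscales, noise_sd) {
  h <- list(signal_sd = as.numeric(signal_sd),
            lengthscales = as.numeric(lengthscales),
            noise_sd = as.numeric(noise_sd))
  if (any(!is.finite(unlist(h))) || h$signal_sd <= 0 || h$noise_sd <= 0 ||
      any(h$lengthscales <= 0))
    stop("GP hyperparameters must be finite and strictly positive")
  structure(h, class = "gp_hyper")
}

#' @export
print.gp_hyper <- function(x, ...) {
  cat("GP hyperparameters: signal_sd ", signif(x$signal_sd, 4),
      ", lengthscales (", paste(signif(x$lengthscales, 4), collapse = ", "),
      "), noise_sd ", signif(x$noise_sd, 4), "\n", sep = "")
  invisible(x)
}

#' Squared-exponential (ARD) kernel
#'
#' \eqn{k(x, y) = \sigma^2 \exp\{-\tfrac12 \sum_d ((x_d - y_d)/l_d)^2\}}:
#' points close in task space elicit similar responses, distant points may
#' differ.
#'
#' @param X,Y Coordinate matrices (rows = points, columns = dimensions) or
#'   vectors treated as single points.
#' @param hyper A [gp_hyper()]; `lengthscales` must match the coordinate
#'   dimension (a single lengthscale is shared across dimensions).
#' @return Kernel matrix `nrow(X)` x `nrow(Y)`.
#' @export
se_kernel <- function(X, Y, hyper) {
  d <- if (is.matrix(X) || is.data.frame(X)) ncol(X)
       else if (length(hyper$lengthscales) > 1L) length(hyper$lengthscales)
       else 1L
  X <- coord_mat(X, d); Y <- coord_mat(Y, d)
  if (ncol(Y) != d) stop("coordinate dimensions differ")
  l <- hyper$lengthscales
  if (length(l) == 1L) l <- rep(l, d)
  if (length(l) != d)
    stop("lengthscale count does not match coordinate dimension")
  Xs <- sweep(X, 2L, l, "/")
  Ys <- sweep(Y, 2L, l, "/")
  d2 <- outer(rowSums(Xs^2), rowSums(Ys^2), "+") - 2 * tcrossprod(Xs, Ys)
  d2[d2 < 0] <- 0
  hyper$signal_sd^2 * exp(-0.5 * d2)
}

# shape loose coordinate input into an n x d matrix: vectors are read as
# points along a 1D space unless d > 1, in which case they are one point
coord_mat <- function(x, d) {
  if (is.matrix(x)) return(x)
  if (is.data.frame(x)) return(as.matrix(x))
  matrix(as.numeric(x), ncol = d, byrow = TRUE)
}

# Cholesky with escalating jitter; the base jitter keeps
# noise-free interpolation numerically stable.
chol_jitter <- function(K, jitter = 1e-10) {
  n <- nrow(K)
  for (j in jitter * 10^(0:6)) {
    L <- tryCatch(chol(K + diag(j, n)), error = function(e) NULL)
    if (!is.null(L)) return(L)
  }
  stop("covariance matrix is singular even after jitter")
}

#' Condition a Gaussian process on observations
#'
#' Forms the zero-mean GP posterior given training coordinates and observed
#' contrasts, assuming white observation noise: the posterior is based on
#' \eqn{K + \sigma_{noise}^2 I}, factorized by Cholesky with a small jitter
#' fallback. With no observations the prior is returned (mean 0, SD
#' \eqn{\sigma} everywhere).
#'
#' @param X Training coordinates (n x dim matrix; n may be 0).
#' @param y Observed values (length n, finite).
#' @param hyper A [gp_hyper()].
#' @return A `gp_fit` object with a [predict.gp_fit()] method.
#' @export
gp_fit <- function(X, y, hyper) {
  stopifnot(inherits(hyper, "gp_hyper"))
  d <- length(hyper$lengthscales)
  X <- if (is.null(X) || length(X) == 0L) matrix(numeric(0), 0L, d)
       else coord_mat(X, d)
  y <- as.numeric(y)
  if (nrow(X) != length(y)) stop("X and y lengths differ")
  if (length(y) && any(!is.finite(y))) stop("observations must be finite")
  n <- nrow(X)
  if (n == 0L) {
    fit <- list(X = X, y = y, hyper = hyper, L = NULL, alpha = NULL, n = 0L)
  } else {
    K <- se_kernel(X, X, hyper) + diag(hyper$noise_sd^2, n)
    L <- chol_jitter(K)
    alpha <- backsolve(L, forwardsolve(t(L), y))
    fit <- list(X = X, y = y, hyper = hyper, L = L, alpha = alpha, n = n)
  }
  class(fit) <- "gp_fit"
  fit
}

#' Posterior mean and standard deviation of a fitted GP
#'
#' @param object A [gp_fit()].
#' @param newdata Coordinates to predict at (m x dim matrix or vector).
#' @param ... Unused.
#' @return List with `mean` and `sd` (length m); `sd` is the posterior SD of
#'   the latent function (it excludes observation noise).
#' @export
predict.gp_fit <- function(object, newdata, ...) {
  Xs <- coord_mat(newdata, ncol(object$X))
  h <- object$hyper
  if (object$n == 0L) {
    return(list(mean = rep(0, nrow(Xs)), sd = rep(h$signal_sd, nrow(Xs))))
  }
  Ks <- se_kernel(Xs, object$X, h)           # m x n
  mu <- as.numeric(Ks %*% object$alpha)
  v <- forwardsolve(t(object$L), t(Ks))      # n x m
  var <- h$signal_sd^2 - colSums(v^2)
  var[var < 0] <- 0
  list(mean = mu, sd = sqrt(var))
}

#' @export
print.gp_fit <- function(x, ...) {
  cat("Gaussian-process fit: n = ", x$n, ", dim = ", ncol(x$X), "\n",
      sep = "")
  print(x$hyper)
  invisible(x)
}

#' Log marginal likelihood of a GP model
#'
#' The Type-2 (evidence) objective: the log density of `y` under
#' \eqn{N(0, K + \sigma_{noise}^2 I)}.
#'
#' @inheritParams gp_fit
#' @return Scalar log marginal likelihood.
#' @export
gp_log_marginal <- function(X, y, hyper) {
  X <- coord_mat(X, length(hyper$lengthscales))
  y <- as.numeric(y)
  n <- length(y)
  if (n < 1L) stop("need at least one observation")
  K <- se_kernel(X, X, hyper) + diag(hyper$noise_sd^2, n)
  L <- chol_jitter(K)
  alpha <- backsolve(L, forwardsolve(t(L), y))
  -0.5 * sum(y * alpha) - sum(log(diag(L))) - 0.5 * n * log(2 * pi)
}

#' Tune GP hyperparameters by Type-2 maximum likelihood
#'
#' Multi-restart bounded maximization of [gp_log_marginal()] over
#' log-transformed hyperparameters with `optim(method = "L-BFGS-B")`.
#' Restart initializations are drawn log-uniformly inside the bounds from
#' the given seed; the best optimum (never worse than its own
#' initialization) is returned.
#'
#' @param X Training coordinates (n x dim, n >= 3).
#' @param y Observed values.
#' @param bounds List of `c(lo, hi)` bounds for `signal_sd`, `lengthscale`
#'   and `noise_sd` (shared across ARD dimensions).
#' @param restarts Number of random restarts.
#' @param seed Integer seed for the restart draws.
#' @param ard Use one lengthscale per dimension (TRUE) or a single shared
#'   one (FALSE).
#' @return A [gp_hyper()] with attribute `"lml"`, the achieved log marginal
#'   likelihood.
#' @export
gp_tune <- function(X, y, bounds = list(signal_sd = c(1e-3, 1e3),
                                        lengthscale = c(0.01, 10),
                                        noise_sd = c(1e-3, 1e3)),
                    restarts = 5L, seed = 1L, ard = TRUE) {
  if (!is.matrix(X) && !is.data.frame(X)) X <- cbind(X)
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (length(y) < 3L) stop("hyperparameter tuning needs n >= 3")
  d <- ncol(X)
  n_l <- if (ard) d else 1L
  lo <- log(c(bounds$signal_sd[1], rep(bounds$lengthscale[1], n_l),
              bounds$noise_sd[1]))
  hi <- log(c(bounds$signal_sd[2], rep(bounds$lengthscale[2], n_l),
              bounds$noise_sd[2]))
  unpack <- function(p) gp_hyper(exp(p[1]), exp(p[2:(1 + n_l)]),
                                 exp(p[length(p)]))
  nll <- function(p) {
    val <- tryCatch(-gp_log_marginal(X, y, unpack(p)),
                    error = function(e) Inf)
    if (!is.finite(val)) 1e10 else val
  }
  inits <- with_seed(seed, {
    lapply(seq_len(restarts), function(i)
      stats::runif(length(lo), lo, hi))
  })
  best <- NULL
  for (p0 in inits) {
    fit <- tryCatch(
      stats::optim(p0, nll, method = "L-BFGS-B", lower = lo, upper = hi,
                   control = list(maxit = 200)),
      error = function(e) NULL)
    cand <- list()
    if (!is.null(fit)) cand <- c(cand, list(list(p = fit$par, v = fit$value)))
    cand <- c(cand, list(list(p = p0, v = nll(p0))))
    for (cc in cand) {
      if (is.null(best) || cc$v < best$v) best <- cc
    }
  }
  if (is.null(best) || !is.finite(best$v))
    stop("all hyperparameter restarts failed")
  h <- unpack(best$p)
  attr(h, "lml") <- -best$v
  h
}
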