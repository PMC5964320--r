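# Independent brute-force oracles used to check the package's linear
# algebra and signal processing, plus small shared fixtures. The oracles
# deliberately use naive formulations (dense inverses, O(n^2) sums) that
# share no code with the implementation.

# direct discrete convolution: out[i] = sum_j box[j] h[i - j + 1] * dt
oracle_convolve <- function(box, h, dt) {
  n <- length(box)
  out <- numeric(n)
  for (i in seq_len(n)) {
    jmax <- min(i, length(h))
    out[i] <- sum(box[i - seq_len(jmax) + 1] * h[seq_len(jmax)]) * dt
  }
  out
}

# GP posterior through the textbook dense matrix-inverse equations
oracle_gp_posterior <- function(X, y, hyper, Xs) {
  k <- function(a, b) {
    l <- hyper$lengthscales
    if (length(l) == 1L) l <- rep(l, ncol(X))
    hyper$signal_sd^2 * exp(-0.5 * sum(((a - b) / l)^2))
  }
  n <- nrow(X); m <- nrow(Xs)
  K <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) K[i, j] <- k(X[i, ], X[j, ])
  K <- K + diag(hyper$noise_sd^2, n)
  Kinv <- solve(K)
  mu <- numeric(m); sd <- numeric(m)
  for (s in seq_len(m)) {
    ks <- vapply(seq_len(n), function(i) k(Xs[s, ], X[i, ]), numeric(1))
    mu[s] <- sum(ks * (Kinv %*% y))
    v <- hyper$signal_sd^2 - t(ks) %*% Kinv %*% ks
    sd[s] <- sqrt(max(v, 0))
  }
  list(mean = mu, sd = sd)
}

# GP log evidence via determinant and dense inverse
oracle_gp_lml <- function(X, y, hyper) {
  n <- length(y)
  K <- boldopt::se_kernel(X, X, hyper) + diag(hyper$noise_sd^2, n)
  -0.5 * t(y) %*% solve(K) %*% y - 0.5 * determinant(K)$modulus -
    0.5 * n * log(2 * pi)
}

# normal-equations least squares (full-rank designs only)
oracle_ols <- function(y, X) as.numeric(solve(crossprod(X), crossprod(X, y)))

# Pearson r from the raw covariance formula
oracle_pearson <- function(a, b) {
  n <- length(a)
  cov_ab <- sum((a - mean(a)) * (b - mean(b))) / (n - 1)
  cov_ab / sqrt(sum((a - mean(a))^2) / (n - 1)) /
    sqrt(sum((b - mean(b))^2) / (n - 1))
}

# two-sided Grubbs critical value from the t quantile
oracle_grubbs_crit <- function(n, alpha = 0.05) {
  tq <- qt(alpha / (2 * n), df = n - 2, lower.tail = FALSE)
  ((n - 1) / sqrt(n)) * sqrt(tq^2 / (n - 2 + tq^2))
}

# small shared fixtures -------------------------------------------------

tiny_table <- function() {
  data.frame(task_id = c("a", "b", "c", "d"),
             c09 = c(0.8, 0.6, 0.3, 0.2),
             c08 = c(0.2, 0.5, 0.6, 0.3),
             stringsAsFactors = FALSE)
}

tiny_space <- function() {
  task_space_from_probabilities(tiny_table(), c("c09", "c08"),
                                name = "tiny")
}

tiny_truth <- function(space, noise_sd = 0, ...) {
  ids <- space$candidates$id
  amp <- setNames(5 * (space$candidates$x1 - space$candidates$x2), ids)
  ground_truth(list(dfpn = amp, vfpn = setNames(rep(0, length(ids)), ids)),
               noise_sd = noise_sd, ...)
}

default_hyper <- function() gp_hyper(2, c(0.3, 0.3), 0.3)
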