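# Shared fixtures, all generated in code.

# two well-separated 2-D Gaussian blobs; the canonical separable RVM toy
make_blobs <- function(n_per_class = 20, sep = 2, seed = 42) {
  withr::with_seed(seed, {
    x <- rbind(
      matrix(stats::rnorm(2 * n_per_class, -sep), n_per_class, 2),
      matrix(stats::rnorm(2 * n_per_class, sep), n_per_class, 2)
    )
    list(x = x, y = rep(c(0L, 1L), each = n_per_class))
  })
}

# single-trial epoch set holding one channels x samples matrix
one_trial_epochs <- function(mat, label = 1L, fs = 250) {
  a <- array(0, c(1L, nrow(mat), ncol(mat)))
  a[1L, , ] <- mat
  epoch_set(a, label, fs)
}

# small synthetic-EEG preset used across pipeline tests
ci_config <- function(snr = 10, seed = 3, trials_per_class = 20, ...) {
  generator_config(n_channels = 8, n_samples = 250,
                   trials_per_class = trials_per_class,
                   snr = snr, seed = seed, ...)
}

# brute-force maximizer of the penalized Bernoulli log-likelihood; the
# independent oracle the Laplace mode is checked against
optim_penalized_mode <- function(phi, targets, alphas) {
  negobj <- function(w) {
    s <- drop(phi %*% w)
    sp <- ifelse(s > 0, s + log1p(exp(-s)), log1p(exp(s)))
    -(sum(targets * s - sp) - 0.5 * sum(alphas * w^2))
  }
  grad <- function(w) {
    y <- 1 / (1 + exp(-drop(phi %*% w)))
    -(drop(crossprod(phi, targets - y)) - alphas * w)
  }
  w <- rep(0, ncol(phi))
  for (restart in 1:3) {
    w <- stats::optim(w, negobj, grad, method = "BFGS",
                      control = list(maxit = 5000, reltol = 1e-15))$par
  }
  w
}

# expected bin probabilities of the arcsine law on equal-width bins of (0,1)
arcsine_bin_probs <- function(breaks) {
  cdf <- (2 / pi) * asin(sqrt(breaks))
  diff(cdf)
}
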