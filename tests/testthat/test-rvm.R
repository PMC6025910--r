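test_that("sigmoid is overflow-safe and symmetric", {
  expect_equal(sigmoid(0), 0.5)
  x <- withr::with_seed(41, stats::rnorm(20, sd = 3))
  expect_equal(sigmoid(x) + sigmoid(-x), rep(1, 20), tolerance = 1e-12)
  expect_equal(sigmoid(500), 1)
  expect_equal(sigmoid(-500), 0, tolerance = 1e-12)
  expect_true(all(is.finite(sigmoid(c(-1e8, 1e8)))))
})

test_that("an overwhelming prior forces the Laplace mode to zero", {
  b <- make_blobs(10, seed = 44)
  phi <- design_matrix(b$x, b$x, kernel_spec("gaussian"))
  fit <- laplace_mode(phi, b$y, rep(1e8, ncol(phi)))
  expect_lt(max(abs(fit$w)), 1e-5)
  expect_equal(sigmoid(drop(phi %*% fit$w)), rep(0.5, nrow(phi)),
               tolerance = 1e-4)
})

test_that("Laplace mode matches a generic optimizer of the same objective", {
  specs <- list(kernel_spec("chaos"), kernel_spec("gaussian"),
                kernel_spec("polynomial"))
  for (k in seq_along(specs)) {
    toy <- withr::with_seed(50 + k, {
      x <- matrix(stats::rnorm(2 * 15), 15, 2)
      list(x = x, y = as.numeric(x[, 1] + 0.5 * stats::rnorm(15) > 0))
    })
    phi <- design_matrix(toy$x, toy$x, specs[[k]])
    alphas <- rep(1, ncol(phi))
    fit <- laplace_mode(phi, toy$y, alphas)
    oracle <- optim_penalized_mode(phi, toy$y, alphas)
    expect_lt(max(abs(fit$w - oracle)), 1e-6)
    # stationarity: g = Phi'(t - y) - A w vanishes at the mode
    expect_lt(max(abs(fit$gradient)), 1e-6)
    # posterior covariance is symmetric positive definite
    expect_equal(fit$sigma, t(fit$sigma), tolerance = 1e-10)
    expect_gt(min(eigen(fit$sigma, symmetric = TRUE,
                        only.values = TRUE)$values), 0)
  }
})

test_that("1-D separable toy with a linear feature column matches the oracle", {
  phi <- cbind(1, c(-1, -1, 1, 1))
  targets <- c(0, 0, 1, 1)
  alphas <- c(1, 1)
  fit <- laplace_mode(phi, targets, alphas)
  oracle <- optim_penalized_mode(phi, targets, alphas)
  expect_lt(max(abs(fit$w - oracle)), 1e-6)
})

test_that("precision re-estimation follows the gamma / w^2 fixed point", {
  sig <- diag(c(0.5, 0.2))
  expect_equal(update_alphas(c(1, 1), c(1, 2), sig)[1], 0.5)
  # fixed point: alpha * Sigma_ii + alpha * w^2 = 1 leaves alpha unchanged
  a <- 2
  w <- 0.4
  s <- (1 - a * w^2) / a   # so that a * s + a * w^2 = 1
  expect_equal(update_alphas(c(a, 1), c(w, 1), diag(c(s, 0.5)))[1], a)
  # vanishing well-determinedness is a prune signal
  expect_equal(update_alphas(1, 1e-9, matrix(1 - 1e-12)), 1e9)
  # so is a vanishing weight
  expect_equal(update_alphas(1, 1e-13, matrix(0.5)), 1e9)
  expect_error(update_alphas(c(1, 1), 1, diag(2)), "dimension")
})

test_that("separable toy trains to perfect accuracy with a sparse model", {
  b <- make_blobs(20, seed = 42)
  for (fam in c("chaos", "gaussian", "polynomial")) {
    fit <- rvm_fit(b$x, b$y, kernel_spec(fam))
    pr <- predict(fit, b$x)
    expect_equal(mean(pr$classes == b$y), 1)
    expect_lt(length(fit$rv_index), length(b$y) / 2)
    expect_true(all(fit$alphas <= 1e9))
    # retained-basis count never grows across iterations
    expect_true(all(diff(fit$trace[, "retained"]) <= 0))
  }
})

test_that("flipping all labels complements the predicted probabilities", {
  b <- make_blobs(15, seed = 47)
  probes <- withr::with_seed(48, matrix(stats::rnorm(10), 5, 2))
  sp <- kernel_spec("chaos")
  f1 <- rvm_fit(b$x, b$y, sp)
  f2 <- rvm_fit(b$x, 1 - b$y, sp)
  p1 <- predict(f1, probes)$probabilities
  p2 <- predict(f2, probes)$probabilities
  expect_equal(p1 + p2, rep(1, 5), tolerance = 1e-6)
})

test_that("training-set order does not change the decision function", {
  b <- make_blobs(15, seed = 49)
  perm <- withr::with_seed(50, sample(length(b$y)))
  probes <- withr::with_seed(51, matrix(stats::rnorm(12), 6, 2))
  sp <- kernel_spec("gaussian")
  f1 <- rvm_fit(b$x, b$y, sp)
  f2 <- rvm_fit(b$x[perm, ], b$y[perm], sp)
  expect_equal(predict(f1, probes)$scores, predict(f2, probes)$scores,
               tolerance = 1e-8)
})

test_that("query at a relevance vector of the separable toy is classified", {
  b <- make_blobs(20, seed = 42)
  fit <- rvm_fit(b$x, b$y, kernel_spec("chaos"))
  rv_labels <- b$y[fit$rv_index]
  pr <- predict(fit, fit$relevance_vectors)
  expect_equal(pr$classes, rv_labels)
  expect_true(all(pr$probabilities > 0 & pr$probabilities < 1))
})

test_that("signal-free data prunes everything: error or bias-only fallback", {
  noise <- withr::with_seed(53, {
    list(x = matrix(stats::rnorm(60), 30, 2), y = rep(c(0, 1), 15))
  })
  sp <- kernel_spec("chaos")
  expect_error(rvm_fit(noise$x, noise$y, sp), "pruned")
  fit <- rvm_fit(noise$x, noise$y, sp,
                 rvm_control(on_empty = "bias_only"))
  expect_equal(length(fit$rv_index), 0L)
  pr <- predict(fit, noise$x)
  # constant probability near 1/2 on balanced labels
  expect_equal(stats::sd(pr$probabilities), 0)
  expect_lt(abs(pr$probabilities[1] - 0.5), 0.1)
})

test_that("serialized models give bit-identical predictions", {
  b <- make_blobs(10, seed = 55)
  fit <- rvm_fit(b$x, b$y, kernel_spec("chaos"))
  path <- withr::local_tempfile(fileext = ".rds")
  saveRDS(fit, path)
  fit2 <- readRDS(path)
  probes <- withr::with_seed(56, matrix(stats::rnorm(8), 4, 2))
  expect_identical(predict(fit, probes), predict(fit2, probes))
})
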