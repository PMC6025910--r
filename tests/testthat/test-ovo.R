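test_that("band-pass keeps in-band content and rejects out-of-band content", {
  fs <- 250
  ns <- 750
  tt <- (seq_len(ns) - 1) / fs
  mid <- 200:550  # settled zero-phase region away from edge transients
  sin_ep <- function(f) one_trial_epochs(matrix(sin(2 * pi * f * tt), 1), fs = fs)
  in_band <- bandpass_filter(sin_ep(10), 3, 24)$data[1, 1, ]
  expect_lt(abs(max(abs(in_band[mid])) - 1), 0.05)
  out_band <- bandpass_filter(sin_ep(50), 3, 24)$data[1, 1, ]
  expect_lt(20 * log10(max(abs(out_band[mid]))), -20)
  dc <- bandpass_filter(one_trial_epochs(matrix(1, 1, ns), fs = fs), 3, 24)
  expect_lt(max(abs(dc$data[1, 1, mid])), 0.01)
  expect_error(bandpass_filter(sin_ep(10), 3, 150), "Nyquist|sampling_rate")
  # dimensions unchanged
  ep <- withr::with_seed(61, epoch_set(array(stats::rnorm(2 * 3 * 250),
                                             c(2, 3, 250)), c(1, 2), fs))
  expect_equal(dim(bandpass_filter(ep, 3, 24)$data), dim(ep$data))
})

test_that("kappa: perfect, constant and uniform-error confusions", {
  expect_equal(cohens_kappa(diag(c(10, 10, 10, 10))), 1)
  # constant prediction on balanced truth: p_o = p_e = 0.25
  const <- matrix(0, 4, 4)
  const[, 1] <- 25
  expect_equal(cohens_kappa(const), 0)
  # balanced classes, accuracy 0.625, errors spread uniformly
  unif <- matrix(10, 4, 4)
  diag(unif) <- 50
  expect_equal(sum(diag(unif)) / sum(unif), 0.625)
  expect_equal(cohens_kappa(unif), (0.625 - 0.25) / 0.75, tolerance = 1e-12)
  # degenerate single-cell table
  deg <- matrix(0, 2, 2)
  deg[1, 1] <- 5
  expect_warning(k <- cohens_kappa(deg), "degenerate")
  expect_equal(k, 0)
  expect_error(cohens_kappa(matrix(0, 2, 2)), "empty")
})

# stub one-vs-one model whose units emit fixed constant probabilities
# (bias-only RVMs), exercising the voting rule in isolation
stub_ovo <- function(unit_probs) {
  classes <- 1:4
  pairs <- utils::combn(classes, 2L)
  units <- lapply(seq_len(ncol(pairs)), function(k) {
    filt <- structure(
      list(filter_matrix = diag(2), patterns = diag(2),
           eigenvalues = c(0.5, 0.5), m = 1L, classes = pairs[, k]),
      class = "csp_filter"
    )
    rvm <- structure(
      list(relevance_vectors = matrix(numeric(0), 0, 2),
           rv_index = integer(0),
           weights = logit_transform(unit_probs[k]),
           alphas = numeric(0),
           posterior_covariance = matrix(1),
           kernel = kernel_spec("chaos"),
           classes = pairs[, k], converged = TRUE, n_iterations = 1L,
           trace = NULL),
      class = "rvm"
    )
    list(pair = pairs[, k], csp = filt, rvm = rvm)
  })
  structure(list(units = units, classes = classes, m = 1L,
                 kernel = kernel_spec("chaos")), class = "ovo_model")
}

test_that("voting: unanimity, probability tie-break, single trials", {
  ep <- withr::with_seed(62, epoch_set(array(stats::rnorm(3 * 2 * 50),
                                             c(3, 2, 50)), c(1, 2, 3), 100))
  # pairs order: (1,2) (1,3) (1,4) (2,3) (2,4) (3,4); the stub probability
  # is that of each pair's larger label
  # every unit involving class 3 votes for it; others split
  unanimous <- stub_ovo(c(0.9, 0.9, 0.1, 0.9, 0.9, 0.1))
  # votes: (1,2)->2, (1,3)->3, (1,4)->1, (2,3)->3, (2,4)->4, (3,4)->3
  expect_equal(predict(unanimous, ep), rep(3L, 3))

  # three-way vote tie {1:2, 2:2, 4:2} with class 1 ahead on probability
  tied <- stub_ovo(c(0.05, 0.40, 0.60, 0.45, 0.45, 0.55))
  # votes: (1,2)->1, (1,3)->1, (1,4)->4, (2,3)->2, (2,4)->2, (3,4)->4
  # prob sums: 1: .95+.60+.40 = 1.95; 2: .05+.55+.55 = 1.15;
  #            4: .60+.45+.55 = 1.60  -> class 1 wins the tie-break
  expect_equal(predict(tied, ep), rep(1L, 3))

  # single-trial input gives one label with no state leakage
  single <- subset_epochs(ep, 1)
  expect_equal(predict(tied, single), predict(tied, ep)[1])
})

test_that("trained pipeline separates planted classes and is deterministic", {
  ep <- generate_epochs(ci_config(snr = 10, seed = 3))
  sp <- kernel_spec("chaos")
  model <- train_ovo(ep, sp)
  expect_length(model$units, 6L)
  pred <- predict(model, ep)
  expect_gt(mean(pred == ep$labels), 0.95)
  # every pairwise unit is accurate on its own training trials
  for (u in model$units) {
    sub <- subset_epochs(ep, ep$labels %in% u$pair)
    feats <- csp_features(u$csp, sub)
    acc <- mean(predict(u$rvm, feats)$classes == sub$labels)
    expect_gt(acc, 0.9)
  }
  # training is deterministic: same inputs, identical units
  model2 <- train_ovo(ep, sp)
  expect_equal(model$units[[1]]$rvm$weights, model2$units[[1]]$rvm$weights)
  expect_identical(pred, predict(model2, ep))
})

test_that("relabeling classes permutes the pairwise units equivalently", {
  ep <- generate_epochs(ci_config(snr = 10, seed = 7,
                                  trials_per_class = 10))
  sp <- kernel_spec("gaussian")
  # swap labels 1 <-> 2
  map <- c(2L, 1L, 3L, 4L)
  ep2 <- epoch_set(ep$data, map[ep$labels], ep$sampling_rate)
  m1 <- train_ovo(ep, sp)
  m2 <- train_ovo(ep2, sp)
  p1 <- predict(m1, ep)
  p2 <- predict(m2, ep)
  expect_gt(mean(map[p1] == p2), 0.95)
})

test_that("cross-validation is stratified, reproducible and leak-free", {
  ep <- generate_epochs(ci_config(snr = 10, seed = 5,
                                  trials_per_class = 10))
  sp <- kernel_spec("chaos")
  cv1 <- cross_validate(ep, sp, folds = 2, repeats = 2, seed = 17)
  cv2 <- cross_validate(ep, sp, folds = 2, repeats = 2, seed = 17)
  expect_identical(cv1, cv2)
  # summary statistics recompute from the fold-level values
  expect_equal(cv1$mean_accuracy, mean(cv1$per_fold_accuracy),
               tolerance = 1e-12)
  expect_equal(cv1$std_accuracy, stats::sd(as.vector(cv1$per_fold_accuracy)),
               tolerance = 1e-12)
  # pooled confusion row sums count each trial once per repeat
  expect_equal(unname(rowSums(cv1$confusion)), rep(10L * 2L, 4))
  expect_gt(cv1$mean_accuracy, 0.95)
  # the global RNG stream is not consumed
  s1 <- withr::with_seed(1, stats::runif(1))
  withr::with_seed(1, {
    invisible(cross_validate(ep, sp, folds = 2, repeats = 1, seed = 18))
    expect_equal(stats::runif(1), s1)
  })
  expect_error(cross_validate(ep, sp, folds = 11, repeats = 1, seed = 1),
               "fewer trials")
})

test_that("corrupting held-out trials cannot change the fitted model", {
  ep <- generate_epochs(ci_config(snr = 10, seed = 9, trials_per_class = 8))
  train_idx <- rep(c(TRUE, TRUE, TRUE, FALSE), 8)
  train <- subset_epochs(ep, train_idx)
  val <- subset_epochs(ep, !train_idx)
  sp <- kernel_spec("chaos")
  m1 <- train_ovo(train, sp)
  # corrupt the validation trials; the training set is untouched
  val_bad <- val
  val_bad$data[] <- 1e3 * val_bad$data[]
  m2 <- train_ovo(train, sp)
  for (k in 1:6) {
    expect_identical(m1$units[[k]]$csp$filter_matrix,
                     m2$units[[k]]$csp$filter_matrix)
    expect_identical(m1$units[[k]]$rvm$weights, m2$units[[k]]$rvm$weights)
  }
  # and predictions on a trial do not depend on the other queried trials
  p_all <- predict(m1, val)
  p_one <- vapply(seq_len(n_trials(val)),
                  function(i) predict(m1, subset_epochs(val, i)), integer(1))
  expect_equal(p_all, p_one)
})
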