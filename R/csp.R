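# Two-class common spatial patterns: trace-normalized covariances,
# composite whitening, and log-variance features.

#' Trace-normalized spatial covariance of one epoch
#'
#' `R = X X' / trace(X X')`: the channel covariance of a single epoch
#' normalized by total energy, so every trial contributes equally to the
#' class mean regardless of amplitude.
#'
#' @param epoch Numeric `channels x samples` matrix.
#' @return Symmetric positive semidefinite `channels x channels` matrix
#'   with unit trace.
#' @export
normalized_covariance <- function(epoch) {
  epoch <- as.matrix(epoch)
  cp <- tcrossprod(epoch)
  tr <- sum(diag(cp))
  if (tr <= 0) stop("degenerate (all-zero) epoch: trace is zero", call. = FALSE)
  cp / tr
}

#' Mean spatial covariance of one class
#'
#' Arithmetic mean of the per-trial normalized covariances over all trials
#' of `class_id`.
#'
#' @param epochs An [epoch_set()].
#' @param class_id Class label whose trials are averaged.
#' @return Symmetric `channels x channels` matrix with unit trace.
#' @export
class_mean_covariance <- function(epochs, class_id) {
  stopifnot(inherits(epochs, "epoch_set"))
  idx <- which(epochs$labels == class_id)
  if (length(idx) == 0L) {
    stop(sprintf("no trials with label %s", class_id), call. = FALSE)
  }
  nc <- dim(epochs$data)[2L]
  acc <- matrix(0, nc, nc)
  for (i in idx) acc <- acc + normalized_covariance(epochs$data[i, , ])
  acc / length(idx)
}

#' Fit a two-class CSP spatial filter
#'
#' Solves the generalized eigenproblem of `(cov_a, cov_a + cov_b)` by
#' whitening the composite covariance. The returned filter has `2m` rows:
#' the first `m` maximize the class-a variance ratio, the last `m` the
#' class-b ratio (in regular problems these are the bottom eigenvectors of
#' the whitened class-a covariance; they are computed from the whitened
#' class-b side so rank-deficient inputs still resolve them). Row signs are
#' fixed so each row's largest-magnitude entry is positive.
#'
#' If the composite covariance is ill-conditioned (condition number above
#' `1e12`) a ridge of `1e-10 * trace` is added before whitening; a
#' composite that remains singular is an error.
#'
#' @param cov_a,cov_b Symmetric PSD `channels x channels` matrices (class
#'   mean covariances).
#' @param m Number of filters kept per class (default 1, giving the most
#'   significant pair).
#' @param classes Optional length-2 vector recording which class labels the
#'   two sides correspond to.
#' @return An object of class `csp_filter` with fields:
#'   `filter_matrix` (`2m x channels`, rows are spatial filters),
#'   `patterns` (`channels x 2m`, the corresponding spatial patterns, i.e.
#'   columns of the inverse of the full filter bank), `eigenvalues`
#'   (class-a variance ratio per retained component), `m`, `classes`.
#' @export
fit_csp <- function(cov_a, cov_b, m = 1L, classes = c(NA_integer_, NA_integer_)) {
  cov_a <- as.matrix(cov_a)
  cov_b <- as.matrix(cov_b)
  n <- nrow(cov_a)
  m <- as.integer(m)
  if (!all(dim(cov_a) == c(n, n)) || !all(dim(cov_b) == c(n, n))) {
    stop("covariances must be square matrices of equal size", call. = FALSE)
  }
  if (is.na(m) || m < 1L || 2L * m > n) {
    stop("need 1 <= 2m <= n_channels", call. = FALSE)
  }
  comp <- (cov_a + cov_b)
  comp <- (comp + t(comp)) / 2
  ec <- eigen(comp, symmetric = TRUE)
  if (ec$values[1L] <= 0) {
    stop("composite covariance is not positive definite; regularize inputs",
         call. = FALSE)
  }
  if (ec$values[n] <= 0 || ec$values[1L] / ec$values[n] > 1e12) {
    comp <- comp + diag(1e-10 * sum(diag(comp)), n)
    ec <- eigen(comp, symmetric = TRUE)
    if (ec$values[n] <= 0) {
      stop("composite covariance is singular even after ridge ",
           "regularization; check the input epochs", call. = FALSE)
    }
  }
  P <- diag(1 / sqrt(ec$values), n) %*% t(ec$vectors)  # whitening transform
  Sa <- P %*% cov_a %*% t(P)
  Sb <- P %*% cov_b %*% t(P)
  ea <- eigen((Sa + t(Sa)) / 2, symmetric = TRUE)       # values descending
  eb <- eigen((Sb + t(Sb)) / 2, symmetric = TRUE)
  # full bank ordered by class-a ratio; last-m rows resolved on the b side
  Wa <- t(ea$vectors) %*% P
  Wb <- t(eb$vectors) %*% P
  rows <- rbind(Wa[seq_len(m), , drop = FALSE],
                Wb[rev(seq_len(m)), , drop = FALSE])
  rows <- fix_row_signs(rows)
  eigenvalues <- c(ea$values[seq_len(m)], rev(1 - eb$values[seq_len(m)]))
  # spatial patterns: composite covariance times the filters (the forward
  # model of each component), columns normalized to unit length
  patterns <- comp %*% t(rows)
  patterns <- sweep(patterns, 2L, sqrt(colSums(patterns^2)), "/")
  structure(
    list(filter_matrix = rows, patterns = patterns,
         eigenvalues = eigenvalues, m = m, classes = classes),
    class = "csp_filter"
  )
}

# flip each row so its largest-magnitude entry is positive (deterministic
# output across linear-algebra backends)
fix_row_signs <- function(w) {
  for (i in seq_len(nrow(w))) {
    j <- which.max(abs(w[i, ]))
    if (w[i, j] < 0) w[i, ] <- -w[i, ]
  }
  w
}

#' @export
print.csp_filter <- function(x, ...) {
  cat(sprintf("CSP filter pair (classes %s vs %s): m = %d, %d channels\n",
              x$classes[1], x$classes[2], x$m, ncol(x$filter_matrix)))
  cat("  component class-a variance ratios:",
      paste(sprintf("%.3f", x$eigenvalues), collapse = " "), "\n")
  invisible(x)
}

#' Normalized log-variance CSP features of one epoch
#'
#' Projects the epoch through the spatial filter (`Z = W X`) and returns
#' `f_k = log(var(Z_k) / sum_i var(Z_i))` over the `2m` components.
#' Variances are population variances (divide by the sample count). By
#' construction `sum(exp(f)) = 1`.
#'
#' @param filter A [fit_csp()] result.
#' @param epoch Numeric `channels x samples` matrix.
#' @return Numeric feature vector of length `2m`.
#' @export
extract_features <- function(filter, epoch) {
  stopifnot(inherits(filter, "csp_filter"))
  epoch <- as.matrix(epoch)
  if (ncol(filter$filter_matrix) != nrow(epoch)) {
    stop("epoch channel count does not match the filter", call. = FALSE)
  }
  z <- filter$filter_matrix %*% epoch
  v <- rowMeans((z - rowMeans(z))^2)
  tot <- sum(v)
  if (tot <= 0) stop("zero total variance after projection", call. = FALSE)
  log(v / tot)
}

#' CSP feature matrix for a whole epoch set
#'
#' @param filter A [fit_csp()] result.
#' @param epochs An [epoch_set()].
#' @return Numeric `n_trials x 2m` matrix of features.
#' @export
csp_features <- function(filter, epochs) {
  stopifnot(inherits(epochs, "epoch_set"))
  t(vapply(seq_len(n_trials(epochs)),
           function(i) extract_features(filter, epochs$data[i, , ]),
           numeric(2L * filter$m)))
}
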