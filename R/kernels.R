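# Kernel functions for the relevance vector machine: the chaos kernel
# derived from the logistic map's transformed invariant density, plus
# Gaussian and polynomial baselines, and design-matrix assembly.

#' Kernel specification
#'
#' Bundles a kernel family with its parameters, validated at construction.
#' One spec object is shared by all six pairwise classifiers of the
#' one-versus-one pipeline.
#'
#' Defaults follow the reference study: `beta = 0.5` (chaos),
#' `width = 0.95` (Gaussian), `scale = 1.26` and `degree = 2` (polynomial).
#'
#' @param family One of `"chaos"`, `"gaussian"`, `"polynomial"`.
#' @param beta Positive scale of the chaos kernel (distance multiplier).
#' @param width Positive width `sigma` of the Gaussian kernel.
#' @param scale Inner-product scale `a` of the polynomial kernel.
#' @param degree Polynomial degree `d` (positive integer).
#' @param gaussian_half If `TRUE` the Gaussian exponent uses
#'   `exp(-d^2 / (2 sigma^2))` instead of the default `exp(-d^2 / sigma^2)`;
#'   provided for cross-checks against implementations using the other
#'   convention.
#' @return An object of class `kernel_spec`.
#' @examples
#' kernel_spec("chaos", beta = 0.5)
#' kernel_spec("polynomial", scale = 1.26, degree = 2)
#' @export
kernel_spec <- function(family = c("chaos", "gaussian", "polynomial"),
                        beta = 0.5, width = 0.95, scale = 1.26, degree = 2L,
                        gaussian_half = FALSE) {
  family <- match.arg(family)
  degree <- as.integer(degree)
  if (family == "chaos" && (!is.numeric(beta) || beta <= 0)) {
    stop("chaos kernel requires `beta` > 0", call. = FALSE)
  }
  if (family == "gaussian" && (!is.numeric(width) || width <= 0)) {
    stop("gaussian kernel requires `width` > 0", call. = FALSE)
  }
  if (family == "polynomial" &&
      (!is.numeric(scale) || is.na(degree) || degree < 1L)) {
    stop("polynomial kernel requires numeric `scale` and `degree` >= 1",
         call. = FALSE)
  }
  structure(
    list(family = family, beta = beta, width = width, scale = scale,
         degree = degree, gaussian_half = isTRUE(gaussian_half)),
    class = "kernel_spec"
  )
}

#' @export
print.kernel_spec <- function(x, ...) {
  par <- switch(x$family,
    chaos = sprintf("beta = %g", x$beta),
    gaussian = sprintf("sigma = %g%s", x$width,
                       if (x$gaussian_half) " (half convention)" else ""),
    polynomial = sprintf("a = %g, d = %d", x$scale, x$degree)
  )
  cat(sprintf("Kernel: %s (%s)\n", x$family, par))
  invisible(x)
}

check_same_dim <- function(y1, y2) {
  if (length(y1) != length(y2)) {
    stop("feature vectors must have the same dimension", call. = FALSE)
  }
}

#' Chaos kernel
#'
#' `K(y1, y2) = (1/pi) * (exp(beta * d) + exp(-beta * d))` with `d` the
#' Euclidean distance between the arguments — equivalently
#' `(2/pi) * cosh(beta * d)`. Derived from the logit-transformed invariant
#' density of the chaotic logistic map. The kernel is symmetric, bounded
#' below by `2/pi` (attained iff the inputs coincide), and strictly
#' increasing in the distance. Its Gram matrix is not positive semidefinite
#' in general; the RVM does not require Mercer's condition.
#'
#' @param y1,y2 Numeric feature vectors of equal dimension.
#' @param beta Positive scale parameter (default 0.5).
#' @return A single kernel value, `>= 2/pi`.
#' @examples
#' chaos_kernel(c(0, 0), c(0, 0), 0.5)  # 2/pi
#' @export
chaos_kernel <- function(y1, y2, beta = 0.5) {
  check_same_dim(y1, y2)
  if (!is.numeric(beta) || beta <= 0) stop("`beta` must be > 0", call. = FALSE)
  .chaos_k(sqrt(sum((y1 - y2)^2)), beta)
}

# overflow-guarded (1/pi)(e^x + e^-x) at x = beta * d
.chaos_k <- function(d, beta) {
  x <- beta * d
  out <- ifelse(
    x > 700,
    exp(x - log(pi)) * (1 + exp(-2 * x)),
    2 * cosh(x) / pi
  )
  out
}

#' Gaussian (radial basis) kernel
#'
#' `K(y1, y2) = exp(-d^2 / sigma^2)` with `d` the Euclidean distance. The
#' no-factor-2 denominator is the package default; set `half = TRUE` for the
#' `2 sigma^2` convention.
#'
#' @param y1,y2 Numeric feature vectors of equal dimension.
#' @param width Positive width parameter `sigma` (default 0.95).
#' @param half Use the `exp(-d^2 / (2 sigma^2))` convention.
#' @return A single kernel value in `(0, 1]`.
#' @export
gaussian_kernel <- function(y1, y2, width = 0.95, half = FALSE) {
  check_same_dim(y1, y2)
  if (!is.numeric(width) || width <= 0) {
    stop("`width` must be > 0", call. = FALSE)
  }
  d2 <- sum((y1 - y2)^2)
  denom <- if (isTRUE(half)) 2 * width^2 else width^2
  exp(-d2 / denom)
}

#' Polynomial kernel
#'
#' `K(y1, y2) = (scale * <y1, y2> + 1)^degree`.
#'
#' @param y1,y2 Numeric feature vectors of equal dimension.
#' @param scale Inner-product scale `a` (default 1.26).
#' @param degree Polynomial degree `d` (default 2).
#' @return A single kernel value.
#' @export
polynomial_kernel <- function(y1, y2, scale = 1.26, degree = 2L) {
  check_same_dim(y1, y2)
  (scale * sum(y1 * y2) + 1)^as.integer(degree)
}

#' Kernel Gram matrix
#'
#' Evaluates the kernel of `spec` between every row of `x` and every row of
#' `y`, vectorized over both sets.
#'
#' @param x Numeric matrix, one sample per row.
#' @param y Numeric matrix, one center per row (same column count as `x`).
#' @param spec A [kernel_spec()].
#' @return A `nrow(x) x nrow(y)` matrix of kernel values.
#' @export
kernel_matrix <- function(x, y, spec) {
  stopifnot(inherits(spec, "kernel_spec"))
  x <- as.matrix(x)
  y <- as.matrix(y)
  if (ncol(x) != ncol(y)) {
    stop("feature vectors must have the same dimension", call. = FALSE)
  }
  if (spec$family == "polynomial") {
    return((spec$scale * tcrossprod(x, y) + 1)^spec$degree)
  }
  # squared Euclidean distances, clipped at 0 against round-off
  d2 <- outer(rowSums(x^2), rowSums(y^2), "+") - 2 * tcrossprod(x, y)
  d2[d2 < 0] <- 0
  if (spec$family == "gaussian") {
    denom <- if (spec$gaussian_half) 2 * spec$width^2 else spec$width^2
    exp(-d2 / denom)
  } else {
    .chaos_k(sqrt(d2), spec$beta)
  }
}

#' RVM design matrix
#'
#' Assembles the design matrix used by the relevance vector machine: a
#' leading column of ones (the bias) followed by kernel evaluations of each
#' sample against each center. During training the centers are the training
#' samples themselves, giving an `N x (N + 1)` matrix.
#'
#' @param samples Numeric matrix (or vector list coercible to one), one
#'   sample per row.
#' @param centers Numeric matrix of kernel centers, one per row.
#' @param spec A [kernel_spec()].
#' @return A `nrow(samples) x (nrow(centers) + 1)` matrix whose first
#'   column is all ones.
#' @export
design_matrix <- function(samples, centers, spec) {
  samples <- as.matrix(samples)
  centers <- as.matrix(centers)
  if (nrow(centers) == 0L) stop("`centers` must be non-empty", call. = FALSE)
  cbind(1, kernel_matrix(samples, centers, spec))
}
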