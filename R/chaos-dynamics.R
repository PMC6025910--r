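# Logistic-map dynamics: orbits, Lyapunov exponents and the invariant
# densities from which the chaos kernel is derived.

#' One step of the logistic map
#'
#' Applies the quadratic recurrence `rate * y * (1 - y)`, the classic
#' logistic map. For `rate <= 4` the unit interval is forward-invariant.
#'
#' @param y Current state, a number in `[0, 1]`.
#' @param rate Map parameter in `[0, 4]` (chaotic regime at 4).
#' @return The next iterate, a number in `[0, 1]`.
#' @examples
#' logistic_step(0.5, 4)   # 1, the maximum of the map
#' logistic_step(0.75, 4)  # 0.75, a fixed point
#' @export
logistic_step <- function(y, rate) {
  if (!is.numeric(y) || any(y < 0) || any(y > 1)) {
    stop("`y` must lie in [0, 1]", call. = FALSE)
  }
  if (!is.numeric(rate) || length(rate) != 1L || rate < 0 || rate > 4) {
    stop("`rate` must be a single number in [0, 4]", call. = FALSE)
  }
  rate * y * (1 - y)
}

#' Iterate the logistic map
#'
#' Generates `n` post-burn-in iterates of the logistic map starting from
#' `y0`. With `rate = 4` and a generic initial value the orbit is chaotic
#' and visits the unit interval with the arcsine invariant density (see
#' [arcsine_density()]).
#'
#' @param y0 Initial value, strictly inside `(0, 1)`.
#' @param rate Map parameter in `[0, 4]`.
#' @param n Number of iterates to return (positive integer).
#' @param burn_in Number of initial iterates to discard (default 0; density
#'   and Lyapunov estimation conventionally uses 1000).
#' @return An object of class `logistic_orbit`: a list with fields
#'   `rate`, `y0`, `burn_in` and `values` (numeric vector of length `n`).
#' @seealso [lyapunov_exponent()], [arcsine_density()]
#' @export
iterate_logistic <- function(y0, rate, n, burn_in = 0L) {
  if (!is.numeric(y0) || length(y0) != 1L || y0 <= 0 || y0 >= 1) {
    stop("`y0` must be strictly inside (0, 1)", call. = FALSE)
  }
  if (!is.numeric(rate) || length(rate) != 1L || rate < 0 || rate > 4) {
    stop("`rate` must be a single number in [0, 4]", call. = FALSE)
  }
  n <- as.integer(n)
  burn_in <- as.integer(burn_in)
  if (is.na(n) || n < 1L) stop("`n` must be a positive integer", call. = FALSE)
  if (is.na(burn_in) || burn_in < 0L) {
    stop("`burn_in` must be a non-negative integer", call. = FALSE)
  }
  y <- y0
  for (i in seq_len(burn_in)) y <- rate * y * (1 - y)
  values <- numeric(n)
  for (i in seq_len(n)) {
    y <- rate * y * (1 - y)
    values[i] <- y
  }
  structure(
    list(rate = rate, y0 = y0, burn_in = burn_in, values = values),
    class = "logistic_orbit"
  )
}

#' @export
print.logistic_orbit <- function(x, ...) {
  cat(sprintf(
    "Logistic-map orbit: rate = %g, y0 = %g, burn-in = %d, length = %d\n",
    x$rate, x$y0, x$burn_in, length(x$values)
  ))
  invisible(x)
}

#' Lyapunov exponent of the logistic map
#'
#' Estimates the Lyapunov exponent by averaging the log absolute derivative
#' `log|rate * (1 - 2 y)|` along a post-burn-in orbit. A positive value
#' indicates chaos; at `rate = 4` the exponent equals `log(2)` for almost
#' every initial value (the map is conjugate to the tent map).
#'
#' Iterates landing numerically on the critical point `y = 1/2`, where the
#' derivative vanishes, would contribute `-Inf`; their summand is floored at
#' `log(log_floor)` instead.
#'
#' @param rate Map parameter in `[0, 4]`.
#' @param n Number of iterates averaged over (after burn-in).
#' @param y0 Initial value in `(0, 1)`.
#' @param burn_in Iterates discarded before averaging (default 1000).
#' @param log_floor Floor applied to `|1 - 2 y|` inside the logarithm
#'   (default `1e-300`).
#' @return The estimated Lyapunov exponent (a single number).
#' @examples
#' lyapunov_exponent(4, n = 1e4, y0 = 0.123)  # close to log(2)
#' @export
lyapunov_exponent <- function(rate, n, y0, burn_in = 1000L,
                              log_floor = 1e-300) {
  orbit <- iterate_logistic(y0, rate, n, burn_in)
  d <- abs(1 - 2 * orbit$values)
  d[d < log_floor] <- log_floor
  mean(log(rate) + log(d))
}

#' Lyapunov spectrum over a grid of map parameters
#'
#' Estimates the Lyapunov exponent on a grid of rate values, the standard
#' companion to the bifurcation diagram: negative in periodic windows,
#' positive in the chaotic regime.
#'
#' @param rates Numeric vector of map parameters (default 2.5 to 4 in steps
#'   of 0.005).
#' @param n Iterates averaged per rate (default 2000).
#' @param burn_in Discarded transient per rate (default 1000).
#' @param seed Integer seed for the initial values, drawn uniformly from
#'   `(0.01, 0.99)` per rate.
#' @return A data frame with columns `rate` and `lyapunov`.
#' @export
lyapunov_spectrum <- function(rates = seq(2.5, 4, by = 0.005), n = 2000L,
                              burn_in = 1000L, seed = 1L) {
  y0s <- with_seed(seed, stats::runif(length(rates), 0.01, 0.99))
  lam <- vapply(
    seq_along(rates),
    function(i) lyapunov_exponent(rates[i], n, y0s[i], burn_in),
    numeric(1)
  )
  data.frame(rate = rates, lyapunov = lam)
}

#' Invariant density of the chaotic logistic map
#'
#' The arcsine density `1 / (pi * sqrt(y * (1 - y)))`, the invariant
#' probability density of the logistic map at `rate = 4`. It diverges at
#' both endpoints, which is why the logit-transformed density (see
#' [transformed_density()]) is preferred as the basis of a kernel.
#'
#' @param y Evaluation points, strictly inside `(0, 1)`.
#' @return Density values (positive reals).
#' @examples
#' arcsine_density(0.5)  # 2/pi
#' @export
arcsine_density <- function(y) {
  if (!is.numeric(y) || any(y <= 0) || any(y >= 1)) {
    stop("`y` must be strictly inside (0, 1); the density diverges at 0 and 1",
         call. = FALSE)
  }
  1 / (pi * sqrt(y * (1 - y)))
}

#' Logit transform
#'
#' `log(y / (1 - y))`, mapping `(0, 1)` onto the real line; the inverse of
#' [sigmoid()]. Applied to the iterates of the chaotic logistic map it
#' pushes the arcsine density forward to [transformed_density()].
#'
#' @param y Values strictly inside `(0, 1)`.
#' @return Real values.
#' @export
logit_transform <- function(y) {
  if (!is.numeric(y) || any(y <= 0) || any(y >= 1)) {
    stop("`y` must be strictly inside (0, 1)", call. = FALSE)
  }
  log(y / (1 - y))
}

#' Density of the logit-transformed chaotic orbit
#'
#' The push-forward of the arcsine invariant density through the logit
#' transform: `1 / (pi * (exp(z/2) + exp(-z/2)))`, a symmetric,
#' bell-shaped density on the whole real line that integrates to 1. The
#' chaos kernel is obtained from this expression by replacing `z` with a
#' scaled distance between feature vectors.
#'
#' @param z Evaluation points (any real numbers).
#' @return Density values (positive reals). Evaluation is overflow-safe for
#'   large `|z|`.
#' @examples
#' transformed_density(0)  # 1 / (2 * pi)
#' @export
transformed_density <- function(z) {
  if (!is.numeric(z)) stop("`z` must be numeric", call. = FALSE)
  a <- abs(z)
  # 1/(pi (e^{z/2} + e^{-z/2})) = e^{-|z|/2} / (pi (1 + e^{-|z|}))
  exp(-a / 2) / (pi * (1 + exp(-a)))
}
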