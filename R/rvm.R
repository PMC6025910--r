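# Binary relevance vector machine: Bernoulli likelihood, zero-mean
# Gaussian weight priors with per-weight precisions alpha, Laplace
# approximation at the posterior mode, and MacKay-style alpha
# re-estimation with pruning of irrelevant basis functions.

#' Logistic sigmoid
#'
#' `1 / (1 + exp(-x))`, overflow-safe; maps the RVM decision score to a
#' class probability.
#'
#' @param x Numeric vector.
#' @return Values in `(0, 1)`.
#' @export
sigmoid <- function(x) {
  out <- numeric(length(x))
  pos <- !is.na(x) & x >= 0
  out[pos] <- 1 / (1 + exp(-x[pos]))
  ex <- exp(x[!pos])
  out[!pos] <- ex / (1 + ex)
  out[is.na(x)] <- NA_real_
  out
}

# log(1 + exp(x)) without overflow
softplus <- function(x) {
  ifelse(x > 0, x + log1p(exp(-x)), log1p(exp(x)))
}

# penalized Bernoulli log-likelihood: log p(t | w) - w' A w / 2
penalized_loglik <- function(w, phi, targets, alphas) {
  s <- drop(phi %*% w)
  sum(targets * s - softplus(s)) - 0.5 * sum(alphas * w^2)
}

# Cholesky solve with escalating jitter (the chaos kernel is non-Mercer, so
# phi' B phi + A is not guaranteed PD by construction)
chol_jittered <- function(h) {
  jit <- 0
  base <- 1e-8 * mean(diag(h))
  for (k in 0:3) {
    ch <- tryCatch(chol(h + diag(jit, nrow(h))), error = function(e) NULL)
    if (!is.null(ch)) return(ch)
    jit <- if (jit == 0) base else jit * 10
  }
  stop("Hessian not positive definite even after jitter", call. = FALSE)
}

#' Laplace-approximation posterior mode for fixed alpha
#'
#' Maximizes the penalized Bernoulli log-likelihood
#' `log p(t | w) - w' A w / 2` (with `A = diag(alphas)`) by damped Newton
#' iteration, and returns the mode together with the Laplace posterior
#' covariance `(Phi' B Phi + A)^{-1}` evaluated there, where
#' `B = diag(y_i (1 - y_i))`.
#'
#' @param phi Design matrix including the leading bias column (see
#'   [design_matrix()]).
#' @param targets Binary 0/1 vector, one per row of `phi`.
#' @param alphas Positive prior precisions, one per column of `phi`.
#' @param w_init Optional starting weights (default zeros).
#' @param max_iter Newton iteration cap (default 100).
#' @param grad_tol Convergence threshold on the gradient infinity norm
#'   (default 1e-8).
#' @return A list with `w` (the mode), `sigma` (posterior covariance),
#'   `b` (the Bernoulli variance diagonal at the mode), `gradient`,
#'   `converged`, `n_iter`.
#' @export
laplace_mode <- function(phi, targets, alphas, w_init = NULL,
                         max_iter = 100L, grad_tol = 1e-8) {
  phi <- as.matrix(phi)
  p <- ncol(phi)
  if (length(alphas) != p) {
    stop("`alphas` must have one entry per design column", call. = FALSE)
  }
  if (any(alphas <= 0)) stop("`alphas` must be positive", call. = FALSE)
  if (!all(targets %in% c(0, 1))) {
    stop("`targets` must be 0/1", call. = FALSE)
  }
  w <- if (is.null(w_init)) numeric(p) else as.numeric(w_init)
  obj <- penalized_loglik(w, phi, targets, alphas)
  converged <- FALSE
  g <- numeric(p)
  it <- 0L
  for (it in seq_len(max_iter)) {
    y <- sigmoid(drop(phi %*% w))
    g <- drop(crossprod(phi, targets - y)) - alphas * w
    if (max(abs(g)) < grad_tol) {
      converged <- TRUE
      break
    }
    b <- y * (1 - y)
    h <- crossprod(phi, phi * b)
    diag(h) <- diag(h) + alphas
    ch <- chol_jittered(h)
    dw <- backsolve(ch, forwardsolve(t(ch), g))
    # step halving: Newton with damping until the objective improves
    eta <- 1
    repeat {
      w_new <- w + eta * dw
      obj_new <- penalized_loglik(w_new, phi, targets, alphas)
      if (is.finite(obj_new) && obj_new >= obj - 1e-12) break
      eta <- eta / 2
      if (eta < 2^-30) {
        w_new <- w
        obj_new <- obj
        break
      }
    }
    if (any(!is.finite(w_new))) {
      stop("non-finite weights during Newton iteration; check the kernel ",
           "parameters and feature scaling", call. = FALSE)
    }
    if (identical(w_new, w)) break  # no improving step: at numerical optimum
    w <- w_new
    obj <- obj_new
  }
  y <- sigmoid(drop(phi %*% w))
  g <- drop(crossprod(phi, targets - y)) - alphas * w
  b <- y * (1 - y)
  h <- crossprod(phi, phi * b)
  diag(h) <- diag(h) + alphas
  ch <- chol_jittered(h)
  sigma <- chol2inv(ch)
  list(w = w, sigma = sigma, b = b, gradient = g,
       converged = converged || max(abs(g)) < grad_tol, n_iter = it)
}

#' MacKay re-estimate of the prior precisions
#'
#' `alpha_i^new = (1 - alpha_i * Sigma_ii) / w_i^2`, the fixed-point update
#' driven by the "well-determinedness" `gamma_i = 1 - alpha_i * Sigma_ii`
#' of each weight. Weights whose `gamma_i` collapses toward zero (or whose
#' magnitude falls below `weight_floor`) are pushed to `alpha_ceiling`,
#' flagging the basis function for pruning.
#'
#' @param alphas Current positive precisions.
#' @param w_mp Posterior-mode weights (same length).
#' @param sigma Posterior covariance from [laplace_mode()].
#' @param weight_floor Magnitude below which a weight is treated as zero
#'   (default 1e-12).
#' @param alpha_ceiling Precision assigned to pruned directions
#'   (default 1e9).
#' @param gamma_floor Well-determinedness below which a basis is pruned
#'   (default 1e-10).
#' @return Updated precision vector.
#' @export
update_alphas <- function(alphas, w_mp, sigma, weight_floor = 1e-12,
                          alpha_ceiling = 1e9, gamma_floor = 1e-10) {
  p <- length(alphas)
  if (length(w_mp) != p || !all(dim(sigma) == c(p, p))) {
    stop("dimension mismatch among alphas, weights and covariance",
         call. = FALSE)
  }
  gam <- 1 - alphas * diag(sigma)
  if (any(gam < -1e-6)) {
    warning("negative well-determinedness clamped (finite-precision artifact)")
  }
  gam <- pmax(gam, 0)
  out <- numeric(p)
  prune <- gam < gamma_floor | abs(w_mp) < weight_floor
  out[prune] <- alpha_ceiling
  out[!prune] <- gam[!prune] / w_mp[!prune]^2
  pmin(out, alpha_ceiling)
}

#' RVM training controls
#'
#' @param alpha_init Initial prior precision for every weight (default
#'   1e-2: a broad prior, near-maximal initial flexibility).
#' @param alpha_ceiling Precisions above this are pruned (default 1e9).
#' @param weight_floor Weight magnitude treated as zero (default 1e-12).
#' @param tol Outer convergence: max |change in log10 alpha| over retained
#'   weights (default 1e-3).
#' @param max_outer Outer iteration cap (default 500).
#' @param newton_tol Inner Newton gradient tolerance (default 1e-8).
#' @param newton_max Inner Newton iteration cap (default 100).
#' @param on_empty What to do when every kernel basis function is pruned:
#'   `"error"` (default) aborts with a suggestion to review the kernel;
#'   `"bias_only"` returns a model with no relevance vectors whose
#'   prediction is the constant bias probability — the appropriate answer
#'   for signal-free data, and the setting the one-versus-one pipeline
#'   uses.
#' @return A list of class `rvm_control`.
#' @export
rvm_control <- function(alpha_init = 1e-2, alpha_ceiling = 1e9,
                        weight_floor = 1e-12, tol = 1e-3, max_outer = 500L,
                        newton_tol = 1e-8, newton_max = 100L,
                        on_empty = c("error", "bias_only")) {
  structure(
    list(alpha_init = alpha_init, alpha_ceiling = alpha_ceiling,
         weight_floor = weight_floor, tol = tol,
         max_outer = as.integer(max_outer), newton_tol = newton_tol,
         newton_max = as.integer(newton_max),
         on_empty = match.arg(on_empty)),
    class = "rvm_control"
  )
}

#' Fit a binary relevance vector machine
#'
#' Alternates the Laplace-mode weight update ([laplace_mode()]) with the
#' MacKay precision re-estimate ([update_alphas()]), pruning basis
#' functions whose precision reaches the ceiling, until the precisions
#' stabilize. Most precisions diverge during training, so the surviving
#' kernel centers — the relevance vectors — are a sparse subset of the
#' training samples. The bias column is never pruned.
#'
#' Class labels are encoded internally as `{0, 1}` with the smaller
#' original label mapped to 0, so the six pairwise models of the
#' one-versus-one scheme are deterministic.
#'
#' @param x Numeric feature matrix, one training sample per row.
#' @param y Class labels (exactly two distinct values).
#' @param spec A [kernel_spec()].
#' @param control An [rvm_control()].
#' @return An object of class `rvm`: `relevance_vectors` (retained
#'   centers), `rv_index` (their row indices in `x`), `weights` (bias
#'   first), `alphas`, `posterior_covariance`, `kernel`, `classes` (label
#'   for 0 then label for 1), `converged`, `n_iterations`, `trace`
#'   (per-iteration retained count and max precision movement).
#' @export
rvm_fit <- function(x, y, spec, control = rvm_control()) {
  stopifnot(inherits(spec, "kernel_spec"), inherits(control, "rvm_control"))
  x <- as.matrix(x)
  classes <- sort(unique(y))
  if (length(classes) != 2L) {
    stop("training data must contain exactly two classes", call. = FALSE)
  }
  t01 <- as.numeric(y == classes[2L])
  n <- nrow(x)
  phi_full <- design_matrix(x, x, spec)
  active <- seq_len(n + 1L)  # design columns; 1 = bias
  alphas <- rep(control$alpha_init, n + 1L)
  w <- numeric(n + 1L)
  converged <- FALSE
  trace <- list()
  it <- 0L
  sigma <- NULL
  for (it in seq_len(control$max_outer)) {
    lm <- laplace_mode(phi_full[, active, drop = FALSE], t01, alphas,
                       w_init = w, max_iter = control$newton_max,
                       grad_tol = control$newton_tol)
    w <- lm$w
    sigma <- lm$sigma
    new_alphas <- update_alphas(alphas, w, sigma,
                                weight_floor = control$weight_floor,
                                alpha_ceiling = control$alpha_ceiling)
    keep <- new_alphas < control$alpha_ceiling
    keep[1L] <- TRUE  # bias is never pruned
    delta <- max(abs(log10(new_alphas[keep]) - log10(alphas[keep])))
    trace[[it]] <- c(retained = sum(keep), max_dlog_alpha = delta)
    if (sum(keep) == 1L && control$on_empty == "error") {
      stop("all kernel basis functions pruned; review the kernel family ",
           "and its parameters", call. = FALSE)
    }
    active <- active[keep]
    alphas <- new_alphas[keep]
    w <- w[keep]
    sigma <- sigma[keep, keep, drop = FALSE]
    if (delta < control$tol) {
      converged <- TRUE
      break
    }
  }
  # final mode under the settled precisions
  lm <- laplace_mode(phi_full[, active, drop = FALSE], t01, alphas,
                     w_init = w, max_iter = control$newton_max,
                     grad_tol = control$newton_tol)
  rv_index <- active[-1L] - 1L  # design column j+1 is training sample j
  structure(
    list(relevance_vectors = x[rv_index, , drop = FALSE],
         rv_index = rv_index,
         weights = lm$w,
         alphas = alphas,
         posterior_covariance = lm$sigma,
         kernel = spec,
         classes = classes,
         converged = converged,
         n_iterations = it,
         trace = do.call(rbind, trace)),
    class = "rvm"
  )
}

#' @export
print.rvm <- function(x, ...) {
  cat(sprintf(
    "Relevance vector machine (%s kernel): %d relevance vectors, classes %s vs %s\n",
    x$kernel$family, length(x$rv_index), x$classes[1], x$classes[2]
  ))
  cat(sprintf("  converged: %s after %d outer iterations\n",
              x$converged, x$n_iterations))
  invisible(x)
}

#' Predict from a fitted RVM
#'
#' Scores are the kernel expansion `Phi(u*) w_MP` over the relevance
#' vectors; probabilities are their sigmoid; the predicted class is the
#' one whose probability is at least 0.5.
#'
#' @param object A fitted [rvm_fit()] model.
#' @param newdata Numeric matrix of query feature vectors (rows).
#' @param ... Unused.
#' @return A list with `scores`, `probabilities` (of the class encoded 1),
#'   and `classes` (labels on the original scale).
#' @export
predict.rvm <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != ncol(object$relevance_vectors)) {
    stop("query dimension does not match the relevance vectors", call. = FALSE)
  }
  if (nrow(object$relevance_vectors) == 0L) {
    # fully pruned model: constant bias score
    scores <- rep(object$weights[1L], nrow(newdata))
  } else {
    phi <- design_matrix(newdata, object$relevance_vectors, object$kernel)
    scores <- drop(phi %*% object$weights)
  }
  prob <- sigmoid(scores)
  cls <- object$classes[1L + as.integer(prob >= 0.5)]
  list(scores = scores, probabilities = prob, classes = cls)
}
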