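# Proximal solvers shared by all three dictionary-learning classifiers:
# soft thresholding (prox of the l1 norm), singular-value thresholding (prox
# of the nuclear norm), and an accelerated proximal-gradient (FISTA-type)
# lasso solver with a monotone safeguard. The lasso solver stops when the
# subgradient stationarity conditions are met within `tol`:
#   |D'(x - Da)|_j <= lambda1 + tol          where a_j = 0
#   |D'(x - Da)_j - lambda1 sign(a_j)| <= tol where a_j != 0

#' Elementwise soft thresholding
#'
#' `sign(v) * max(|v| - t, 0)`, the proximal operator of `t * ||.||_1`.
#' @param v numeric vector or matrix.
#' @param t threshold, >= 0.
#' @return shrunk object of the same shape.
#' @export
soft_threshold <- function(v, t) {
  if (length(t) != 1L || !is.finite(t) || t < 0)
    stop_wf("argument", "threshold must be a single value >= 0")
  sign(v) * pmax(abs(v) - t, 0)
}

#' Singular-value thresholding
#'
#' Soft-thresholds the singular values of `M`: the proximal operator of
#' `t * ||.||_*` (nuclear norm), used for the low-rank shared dictionary.
#' @param M numeric matrix.
#' @param t threshold, >= 0.
#' @return matrix of the same shape.
#' @export
svt <- function(M, t) {
  if (!all(is.finite(M))) stop_wf("argument", "non-finite matrix")
  if (length(t) != 1L || !is.finite(t) || t < 0)
    stop_wf("argument", "threshold must be a single value >= 0")
  s <- svd(M)
  d <- pmax(s$d - t, 0)
  keep <- d > 0
  if (!any(keep)) return(matrix(0, nrow(M), ncol(M)))
  s$u[, keep, drop = FALSE] %*% (d[keep] * t(s$v[, keep, drop = FALSE]))
}

# maximum stationarity violation of code A for min 1/2||X-DA||^2 + lam||A||_1
lasso_kkt_violation <- function(corr, A, lambda1) {
  zero <- A == 0
  v1 <- if (any(zero)) max(abs(corr[zero]) - lambda1, 0) else 0
  v2 <- if (any(!zero)) max(abs(corr[!zero] - lambda1 * sign(A[!zero]))) else 0
  max(v1, v2)
}

#' L1-regularized least-squares sparse coding
#'
#' Minimizes `1/2 ||x - D a||_2^2 + lambda1 ||a||_1` by accelerated proximal
#' gradient descent with fixed step `1/L` (`L` = largest eigenvalue of `D'D`,
#' by power iteration) and a monotone safeguard: an accelerated step that
#' would increase the objective is replaced by a plain proximal step, so the
#' objective never rises. `x` may be a matrix, in which case every column is
#' coded jointly (shared step size, convergence when every column satisfies
#' the stationarity conditions).
#'
#' @param D dictionary, `d x p` matrix (at least one atom).
#' @param x signal vector of length `d`, or `d x m` matrix.
#' @param lambda1 l1 regularization weight, >= 0.
#' @param tol stationarity tolerance (default 1e-6).
#' @param max_iter iteration cap (default 500); on hitting it the best
#'   iterate is returned with `converged = FALSE`.
#' @return a `sparse_code` list: `a` (vector, or `p x m` matrix), final
#'   `objective_value`, `n_iterations`, `converged`, `kkt_violation`.
#' @export
lasso_code <- function(D, x, lambda1, tol = 1e-6, max_iter = 500) {
  D <- as.matrix(D)
  vec_in <- is.null(dim(x))
  X <- if (vec_in) matrix(x, ncol = 1) else as.matrix(x)
  if (nrow(X) != nrow(D))
    stop_wf("argument", "signal dimension %d != atom dimension %d",
            nrow(X), nrow(D))
  if (ncol(D) < 1L) stop_wf("argument", "dictionary has no atoms")
  if (!all(is.finite(D)) || !all(is.finite(X)) || !is.finite(lambda1) ||
      lambda1 < 0)
    stop_wf("argument", "non-finite inputs to lasso_code")

  G <- crossprod(D)           # p x p
  DtX <- crossprod(D, X)      # p x m
  L <- max(power_eig(G), 1e-12) * 1.01  # safety margin over the power-iteration estimate
  obj <- function(A) {
    R <- X - D %*% A
    0.5 * sum(R^2) + lambda1 * sum(abs(A))
  }
  p <- ncol(D); m <- ncol(X)
  A <- matrix(0, p, m)
  Y <- A
  f_A <- obj(A)
  tk <- 1
  converged <- FALSE
  it <- 0L
  kkt <- Inf
  while (it < max_iter) {
    it <- it + 1L
    grad_Y <- G %*% Y - DtX
    A_new <- soft_threshold(Y - grad_Y / L, lambda1 / L)
    f_new <- obj(A_new)
    if (f_new > f_A) {            # monotone safeguard: plain step from A
      grad_A <- G %*% A - DtX
      A_new <- soft_threshold(A - grad_A / L, lambda1 / L)
      f_new <- obj(A_new)
      tk <- 1                     # restart momentum
    }
    t_next <- (1 + sqrt(1 + 4 * tk^2)) / 2
    Y <- A_new + ((tk - 1) / t_next) * (A_new - A)
    tk <- t_next
    A <- A_new
    f_A <- f_new
    kkt <- lasso_kkt_violation(DtX - G %*% A, A, lambda1)
    if (kkt <= tol) {
      converged <- TRUE
      break
    }
  }
  a <- if (vec_in) as.numeric(A) else A
  structure(list(a = a, objective_value = f_A, n_iterations = it,
                 converged = converged, kkt_violation = kkt),
            class = "sparse_code")
}

# Generic monotone accelerated proximal gradient for
#   min_Z g(Z) + tau ||Z||_1,
# used by the FDDL/LRSDL block updates. `gradfun(Z)` returns the gradient of
# the smooth part g, `objfun(Z)` its value. Guaranteed non-increasing in
# g(Z) + tau||Z||_1.
prox_l1_fista <- function(Z0, gradfun, objfun, L, tau, max_iter = 30,
                          tol = 1e-9) {
  Z <- Z0
  Y <- Z
  pen <- function(Z) tau * sum(abs(Z))
  f_Z <- objfun(Z) + pen(Z)
  tk <- 1
  for (it in seq_len(max_iter)) {
    Z_new <- soft_threshold(Y - gradfun(Y) / L, tau / L)
    f_new <- objfun(Z_new) + pen(Z_new)
    if (f_new > f_Z) {
      Z_new <- soft_threshold(Z - gradfun(Z) / L, tau / L)
      f_new <- objfun(Z_new) + pen(Z_new)
      tk <- 1
      if (f_new > f_Z) break    # L underestimated; keep the current iterate
    }
    t_next <- (1 + sqrt(1 + 4 * tk^2)) / 2
    Y <- Z_new + ((tk - 1) / t_next) * (Z_new - Z)
    tk <- t_next
    done <- abs(f_Z - f_new) <= tol * max(1, abs(f_Z))
    Z <- Z_new
    f_Z <- f_new
    if (done) break
  }
  Z
}
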