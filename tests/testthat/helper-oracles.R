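# Independent oracles and fixture builders used across the suite.

# plain cyclic coordinate-descent lasso: minimizes 1/2||x - D a||^2 + lam||a||_1,
# iterated until the subgradient stationarity conditions hold within kkt_tol
cd_lasso <- function(D, x, lam, max_sweeps = 100000, kkt_tol = 1e-9) {
  G <- crossprod(D)
  dtx <- as.numeric(crossprod(D, x))
  p <- ncol(D)
  a <- numeric(p)
  Ga <- numeric(p) # G %*% a, maintained incrementally
  for (s in seq_len(max_sweeps)) {
    for (j in seq_len(p)) {
      rj <- dtx[j] - Ga[j] + G[j, j] * a[j]
      aj <- sign(rj) * max(abs(rj) - lam, 0) / G[j, j]
      if (aj != a[j]) {
        Ga <- Ga + G[, j] * (aj - a[j])
        a[j] <- aj
      }
    }
    if (s %% 20 == 0 || s == max_sweeps) {
      corr <- dtx - Ga
      zero <- a == 0
      viol <- max(if (any(zero)) max(abs(corr[zero])) - lam else 0,
                  if (any(!zero)) max(abs(corr[!zero] - lam * sign(a[!zero])))
                  else 0)
      if (viol <= kkt_tol) break
    }
  }
  a
}

lasso_objective <- function(D, x, a, lam) {
  0.5 * sum((x - D %*% a)^2) + lam * sum(abs(a))
}

# random dictionary with orthonormal columns (p <= d)
random_orthonormal <- function(d, p) {
  qr.Q(qr(matrix(stats::rnorm(d * p), d, p)))[, seq_len(p), drop = FALSE]
}

# two classes drawn from disjoint random low-dimensional subspaces
subspace_classes <- function(n_train, n_test, d = 100, r = 5, noise = 0.01,
                             seed = 1) {
  set.seed(seed)
  gen_class <- function() {
    B <- qr.Q(qr(matrix(stats::rnorm(d * r), d, r)))
    gen <- function(n) {
      X <- B %*% matrix(stats::rnorm(r * n), r, n) +
        noise * matrix(stats::rnorm(d * n), d, n)
      sweep(X, 2, sqrt(colSums(X^2)), "/")
    }
    list(tr = gen(n_train), te = gen(n_test))
  }
  c1 <- gen_class()
  c2 <- gen_class()
  list(Xtr = cbind(c1$tr, c2$tr),
       ytr = rep(c("FALL", "ADL"), c(n_train, n_train)),
       Xte = cbind(c1$te, c2$te),
       yte = rep(c("FALL", "ADL"), c(n_test, n_test)))
}

# ZYX rotation matrix (body -> world), same convention as the package
rot_zyx <- function(yaw, pitch, roll) {
  Rz <- matrix(c(cos(yaw), sin(yaw), 0, -sin(yaw), cos(yaw), 0, 0, 0, 1), 3)
  Ry <- matrix(c(cos(pitch), 0, -sin(pitch), 0, 1, 0, sin(pitch), 0,
                 cos(pitch)), 3)
  Rx <- matrix(c(1, 0, 0, 0, cos(roll), sin(roll), 0, -sin(roll),
                 cos(roll)), 3)
  Rz %*% Ry %*% Rx
}

# small, fast simulation settings used by unit tests (not the study defaults)
tiny_sim <- function(seed = 1, ...) {
  simulation_config(n_subjects = 2, rate = 50, mean_duration = 6.5,
                    rest_prefix = 1, fall_reps = 1, adl_reps = 1,
                    seed = seed, ...)
}

# a small two-class feature set derived from the simulator
tiny_features <- function(seed = 1, scenario = "A_ACC", n_subjects = 3) {
  cfg <- simulation_config(n_subjects = n_subjects, rate = 50,
                           mean_duration = 6.5, rest_prefix = 1,
                           fall_reps = 1, adl_reps = 1, seed = seed)
  build_feature_matrix(simulate_recordings(cfg), scenario)
}
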