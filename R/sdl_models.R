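# The three dictionary-based classifiers with a common fit/predict contract.
#
# SRC:   dictionary = the training samples themselves; classification by
#        lasso coding + minimum class-wise reconstruction residual.
# FDDL:  class-structured dictionary D = [D_1 .. D_c] learned by alternating
#        minimization of
#          sum_i [ 1/2||X_i - D A_i||^2 + 1/2||X_i - D_i A_i^i||^2
#                  + 1/2 sum_{j!=i} ||D_j A_i^j||^2 ]
#          + lambda1 ||A||_1 + lambda2 ( tr S_W - tr S_B + ||A||_F^2 )
#        (discriminative fidelity + Fisher within/between-class scatter on
#        the codes, with an elastic term for convexity).
# LRSDL: FDDL plus a shared sub-dictionary D0 with shared codes A0; the
#        fidelity terms are applied to X - D0 A0, and the shared block adds
#          lambda1 ||A0||_1 + lambda2 ||A0 - mean(A0)||_F^2 + eta ||D0||_*
#        (similar shared codes; low-rank shared dictionary via
#        singular-value thresholding).
#
# Every block update is a proximal/projected gradient step with a valid step
# size, so the recorded objective trace is non-increasing. Atoms are
# constrained to the unit ball during optimization (a convex constraint,
# which keeps the trace monotone) and rescaled to exactly unit norm on the
# returned dictionary, with code rows rescaled inversely so reconstructions
# are unchanged.

#' Hyper-parameters for the SDL models
#'
#' Defaults follow the best-performing settings of the wrist-fall study:
#' `lambda = 0.01` for SRC coding, `lambda1 = lambda2 = 0.001` for FDDL, and
#' `lambda1 = 0.001, lambda2 = 0.01, eta = 0.02` for LRSDL.
#'
#' @param lambda1 l1 (sparsity) weight, >= 0.
#' @param lambda2 Fisher / shared-code-similarity weight, >= 0.
#' @param eta nuclear-norm weight on the shared dictionary, >= 0.
#' @param k atoms per class (dictionary size per class), >= 1.
#' @param k0 shared atoms (LRSDL only).
#' @param max_iter outer alternating iterations.
#' @param tol relative objective-change convergence tolerance.
#' @param seed seed for the (deterministic) dictionary initialization.
#' @param inner_iter proximal iterations per code-block update.
#' @return a `sdl_hyper` list.
#' @export
hyperparams <- function(lambda1 = 0.001, lambda2 = 0.001, eta = 0.02,
                        k = 50, k0 = 10, max_iter = 100, tol = 1e-5,
                        seed = 0, inner_iter = 20) {
  stopifnot(lambda1 >= 0, lambda2 >= 0, eta >= 0, k >= 1)
  structure(list(lambda1 = lambda1, lambda2 = lambda2, eta = eta,
                 k = as.integer(k), k0 = as.integer(k0),
                 max_iter = as.integer(max_iter), tol = tol,
                 seed = as.integer(seed), inner_iter = as.integer(inner_iter)),
            class = "sdl_hyper")
}

class_order <- function(labels) {
  cl <- sort(unique(labels))
  if ("FALL" %in% cl) cl <- c("FALL", setdiff(cl, "FALL"))
  cl
}

as_xy <- function(X, labels) {
  if (is.list(X) && !is.null(X$X)) {
    labels <- X$labels
    X <- X$X
  }
  X <- as.matrix(X)
  if (length(labels) != ncol(X))
    stop_wf("argument", "labels length != number of samples")
  list(X = X, labels = as.character(labels))
}

new_dictionary <- function(model, atoms, atom_class, class_labels, hyper,
                           shared_atoms = NULL, training_codes = NULL,
                           shared_codes = NULL, objective_trace = NULL,
                           converged = TRUE, extras = list()) {
  structure(list(model = model, atoms = atoms, atom_class = atom_class,
                 shared_atoms = shared_atoms, class_labels = class_labels,
                 hyper = hyper, training_codes = training_codes,
                 shared_codes = shared_codes,
                 objective_trace = objective_trace, converged = converged,
                 extras = extras),
            class = "learned_dictionary")
}

#' @export
print.learned_dictionary <- function(x, ...) {
  cat(sprintf("<learned_dictionary> %s: %d atoms (%s)%s, dim %d\n",
              toupper(x$model), ncol(x$atoms),
              paste(sprintf("%s:%d", x$class_labels,
                            tabulate(match(x$atom_class, x$class_labels))),
                    collapse = ", "),
              if (!is.null(x$shared_atoms))
                sprintf(" + %d shared", ncol(x$shared_atoms)) else "",
              nrow(x$atoms)))
  invisible(x)
}

#' Per-class reconstruction residuals
#'
#' For each class `i`, zeroes every coefficient of atoms not assigned to that
#' class and returns the squared reconstruction error
#' `r_i = ||x - D sigma_i(a)||_2^2`, the quantity minimized by the residual
#' classification rule.
#'
#' @param x signal vector.
#' @param dict a `learned_dictionary`.
#' @param a code vector over the class atoms of `dict` (a `sparse_code` or
#'   numeric vector whose length equals the atom count).
#' @return named numeric vector of residuals, one per class.
#' @export
class_residuals <- function(x, dict, a) {
  if (inherits(a, "sparse_code")) a <- a$a
  if (length(a) != ncol(dict$atoms))
    stop_wf("argument", "code length %d != atom count %d", length(a),
            ncol(dict$atoms))
  if (!all(dict$class_labels %in% dict$atom_class))
    stop_wf("configuration", "class without atoms: %s",
            paste(setdiff(dict$class_labels, dict$atom_class), collapse = ", "))
  vapply(dict$class_labels, function(cl) {
    sel <- dict$atom_class == cl
    r <- x - dict$atoms[, sel, drop = FALSE] %*% a[sel]
    sum(r^2)
  }, numeric(1))
}

residual_label <- function(residuals, class_labels, code = NULL) {
  rmin <- min(residuals)
  tied <- which(residuals - rmin <= 1e-9 * max(1, rmin))
  cands <- class_labels[tied]
  label <- if ("FALL" %in% cands) "FALL" else cands[1]
  degenerate <- length(tied) == length(residuals) ||
    (!is.null(code) && all(code == 0))
  list(label = label, degenerate = degenerate)
}

prediction_result <- function(label, residuals, code, degenerate) {
  structure(list(label = label, residuals = residuals, code = code,
                 degenerate = degenerate),
            class = "prediction_result")
}

# batch residual-rule prediction shared by all models
predict_batch <- function(dict, X, lambda1 = NULL, tol = 1e-6,
                          max_iter = 500) {
  X <- if (is.null(dim(X))) matrix(X, ncol = 1) else as.matrix(X)
  lambda1 <- lambda1 %||% dict$hyper$lambda1
  if (nrow(X) != nrow(dict$atoms))
    stop_wf("argument", "signal dimension %d != dictionary dimension %d",
            nrow(X), nrow(dict$atoms))
  Dfull <- cbind(dict$atoms, dict$shared_atoms)
  code <- lasso_code(Dfull, X, lambda1, tol = tol, max_iter = max_iter)
  A <- if (is.null(dim(code$a))) matrix(code$a, ncol = 1) else code$a
  p <- ncol(dict$atoms)
  n_shared <- if (is.null(dict$shared_atoms)) 0L else ncol(dict$shared_atoms)
  res <- lapply(seq_len(ncol(X)), function(j) {
    a <- A[seq_len(p), j]
    x <- X[, j]
    if (n_shared > 0) {
      a0 <- A[p + seq_len(n_shared), j]
      x <- x - dict$shared_atoms %*% a0 # residual rule on the non-shared part
    }
    r <- class_residuals(x, dict, a)
    lab <- residual_label(r, dict$class_labels, code = A[, j])
    prediction_result(lab$label, r,
                      structure(list(a = A[, j],
                                     objective_value = code$objective_value,
                                     n_iterations = code$n_iterations,
                                     converged = code$converged),
                                class = "sparse_code"),
                      lab$degenerate)
  })
  res
}

predict_one_or_many <- function(dict, x, lambda1, ...) {
  vec <- is.null(dim(x))
  out <- predict_batch(dict, x, lambda1, ...)
  if (vec) out[[1]] else out
}

# ---------------------------------------------------------------- SRC ------

#' Fit a sparse-representation classifier (SRC)
#'
#' No optimization is performed: the dictionary is the column-stacked,
#' L2-normalized training set grouped by class, and each atom keeps its
#' sample's label.
#'
#' @param X `d x n` feature matrix (or the list from
#'   [build_feature_matrix()]).
#' @param labels class label per column.
#' @param lambda1 coding weight stored for prediction (default 0.01).
#' @return a `learned_dictionary`.
#' @export
src_fit <- function(X, labels = NULL, lambda1 = 0.01) {
  xy <- as_xy(X, labels)
  cl <- class_order(xy$labels)
  if (length(cl) < 2L) stop_wf("argument", "need at least two classes")
  ord <- order(match(xy$labels, cl))
  D <- l2_normalize_cols(xy$X[, ord, drop = FALSE], fallback = FALSE)
  new_dictionary("src", D, xy$labels[ord], cl,
                 hyperparams(lambda1 = lambda1, k = min(table(xy$labels))))
}

#' Predict with an SRC dictionary
#'
#' Lasso-codes the input over the training dictionary and assigns the class
#' with minimum reconstruction residual; exact residual ties are broken
#' toward `FALL` (a missed fall is costlier than a false alarm).
#'
#' @param x feature vector, or `d x m` matrix of columns to classify.
#' @param dict a fitted SRC `learned_dictionary`.
#' @param lambda1 l1 coding weight (defaults to the fitted value).
#' @param ... passed to [lasso_code()] (`tol`, `max_iter`).
#' @return a `prediction_result` (`label`, `residuals`, `code`,
#'   `degenerate`), or a list of them for matrix input.
#' @export
src_predict <- function(x, dict, lambda1 = NULL, ...) {
  stopifnot(dict$model == "src")
  predict_one_or_many(dict, x, lambda1, ...)
}

# ------------------------------------------------------- FDDL / LRSDL ------

structured_init <- function(X, labels, classes, k, seed) {
  cols <- lapply(classes, function(cl) which(labels == cl))
  n_i <- lengths(cols)
  if (k > min(n_i))
    stop_wf("configuration",
            "k = %d atoms/class exceeds the smallest class (%d samples)",
            k, min(n_i))
  D <- matrix(0, nrow(X), k * length(classes))
  for (ci in seq_along(classes)) {
    pick <- with_seed(mix_seed(seed, ci), sample(cols[[ci]], k))
    D[, (ci - 1L) * k + seq_len(k)] <- X[, pick]
  }
  l2_normalize_cols(D)
}

# full objective of the structured models; D0/A0 NULL for FDDL
structured_objective <- function(X, cols, D, A, rows, lambda1, lambda2,
                                 D0 = NULL, A0 = NULL, eta = 0) {
  Xt <- if (is.null(D0)) X else X - D0 %*% A0
  E <- Xt - D %*% A
  J <- 0.5 * sum(E^2)
  c_n <- length(cols)
  for (i in seq_len(c_n)) {
    Ai <- A[, cols[[i]], drop = FALSE]
    for (j in seq_len(c_n)) {
      Dj <- D[, rows[[j]], drop = FALSE]
      P <- Dj %*% Ai[rows[[j]], , drop = FALSE]
      J <- J + if (j == i) 0.5 * sum((Xt[, cols[[i]], drop = FALSE] - P)^2)
               else 0.5 * sum(P^2)
    }
  }
  m <- rowMeans(A)
  fisher <- sum(A^2)   # elastic term
  for (i in seq_len(c_n)) {
    Ai <- A[, cols[[i]], drop = FALSE]
    mi <- rowMeans(Ai)
    fisher <- fisher + sum((Ai - mi)^2) - length(cols[[i]]) * sum((mi - m)^2)
  }
  J <- J + lambda1 * sum(abs(A)) + lambda2 * fisher
  if (!is.null(D0)) {
    m0 <- rowMeans(A0)
    J <- J + lambda1 * sum(abs(A0)) + lambda2 * sum((A0 - m0)^2) +
      eta * sum(svd(D0)$d)
  }
  J
}

# one code-block update (class i) by monotone accelerated proximal gradient
update_code_block <- function(Xt_i, D, G, rows, cols, i, A, lambda1, lambda2,
                              eigG, inner_iter) {
  p <- ncol(D)
  n <- ncol(A)
  ni <- length(cols[[i]])
  DtXi <- crossprod(D, Xt_i)
  cXi <- sum(Xt_i^2)
  rs_other <- rowSums(A[, -cols[[i]], drop = FALSE])
  mj_fixed <- lapply(seq_along(cols), function(j)
    if (j == i) NULL else rowMeans(A[, cols[[j]], drop = FALSE]))
  nj <- lengths(cols)

  block_quad <- function(Ai) {
    GA <- G %*% Ai
    v <- 0.5 * (cXi - 2 * sum(DtXi * Ai) + sum(Ai * GA))
    for (j in seq_along(cols)) {
      rj <- rows[[j]]
      q <- sum(Ai[rj, , drop = FALSE] *
                 (G[rj, rj, drop = FALSE] %*% Ai[rj, , drop = FALSE]))
      v <- v + if (j == i)
        0.5 * (cXi - 2 * sum(DtXi[rj, ] * Ai[rj, , drop = FALSE]) + q)
      else 0.5 * q
    }
    v
  }
  fisher_val <- function(Ai) {
    mi <- rowMeans(Ai)
    m <- (rs_other + rowSums(Ai)) / n
    f <- sum((Ai - mi)^2) - ni * sum((mi - m)^2) + sum(Ai^2)
    for (j in seq_along(cols)) if (j != i)
      f <- f - nj[j] * sum((mj_fixed[[j]] - m)^2)
    f
  }
  objfun <- function(Ai) block_quad(Ai) + lambda2 * fisher_val(Ai)
  gradfun <- function(Ai) {
    gr <- G %*% Ai - DtXi
    for (j in seq_along(cols)) {
      rj <- rows[[j]]
      gr[rj, ] <- gr[rj, ] + G[rj, rj, drop = FALSE] %*% Ai[rj, , drop = FALSE]
      if (j == i) gr[rj, ] <- gr[rj, ] - DtXi[rj, , drop = FALSE]
    }
    mi <- rowMeans(Ai)
    m <- (rs_other + rowSums(Ai)) / n
    gr + lambda2 * (2 * (Ai - mi) - 2 * (mi - m) + 2 * Ai)
  }
  L <- 2 * eigG * 1.01 + 8 * lambda2 + 1e-9
  prox_l1_fista(A[, cols[[i]], drop = FALSE], gradfun, objfun, L, lambda1,
                max_iter = inner_iter)
}

project_unit_ball <- function(M) {
  nrms <- sqrt(colSums(M^2))
  over <- nrms > 1
  if (any(over)) M[, over] <- sweep(M[, over, drop = FALSE], 2, nrms[over], "/")
  M
}

# class dictionary blocks by projected (unit-ball) gradient descent
update_dictionary_blocks <- function(Xt, D, A, rows, cols, inner = 10) {
  E <- Xt - D %*% A
  for (j in seq_along(rows)) {
    rj <- rows[[j]]
    Arj <- A[rj, , drop = FALSE]
    Sj <- tcrossprod(Arj)
    Lj <- 2 * power_eig(Sj) * 1.01
    if (Lj < 1e-12) next
    Ajj <- A[rj, cols[[j]], drop = FALSE]
    Sjj <- tcrossprod(Ajj)
    Xj <- Xt[, cols[[j]], drop = FALSE]
    Dj <- D[, rj, drop = FALSE]
    for (s in seq_len(inner)) {
      grad <- -E %*% t(Arj) +
        (Dj %*% Ajj - Xj) %*% t(Ajj) +
        Dj %*% (Sj - Sjj)
      Dj_new <- project_unit_ball(Dj - grad / Lj)
      E <- E - (Dj_new - Dj) %*% Arj
      if (max(abs(Dj_new - Dj)) < 1e-10) {
        Dj <- Dj_new
        break
      }
      Dj <- Dj_new
    }
    D[, rj] <- Dj
  }
  D
}

structured_fit <- function(X, labels, hyper, shared) {
  xy <- as_xy(X, labels)
  X <- xy$X
  labels <- xy$labels
  classes <- class_order(labels)
  if (length(classes) < 2L && shared)
    stop_wf("argument", "need at least two classes")
  cols <- lapply(classes, function(cl) which(labels == cl))
  k <- hyper$k
  D <- structured_init(X, labels, classes, k, hyper$seed)
  rows <- lapply(seq_along(classes), function(i) (i - 1L) * k + seq_len(k))
  atom_class <- rep(classes, each = k)
  n <- ncol(X)
  A <- matrix(0, ncol(D), n)
  D0 <- NULL
  A0 <- NULL
  if (shared) {
    k0 <- hyper$k0
    if (k0 < 1L)
      stop_wf("configuration",
              "k0 = 0 shared atoms is degenerate; use fddl_fit instead")
    Xc <- X - rowMeans(X)
    sv <- svd(Xc, nu = min(k0, min(dim(Xc))))
    D0 <- sv$u[, seq_len(min(k0, ncol(sv$u))), drop = FALSE]
    if (ncol(D0) < k0)   # pad (degenerate tiny problems)
      D0 <- cbind(D0, matrix(0, nrow(X), k0 - ncol(D0)))
    D0 <- l2_normalize_cols(D0)
    A0 <- matrix(0, k0, n)
  }

  objective <- function()
    structured_objective(X, cols, D, A, rows, hyper$lambda1, hyper$lambda2,
                         D0, A0, hyper$eta)
  trace <- objective()
  var_trace <- if (shared) sum((A0 - rowMeans(A0))^2) / max(1, n - 1)
  converged <- FALSE

  for (it in seq_len(hyper$max_iter)) {
    Xt <- if (shared) X - D0 %*% A0 else X
    G <- crossprod(D)
    eigG <- power_eig(G)
    for (i in seq_along(classes)) {
      A[, cols[[i]]] <- update_code_block(
        Xt[, cols[[i]], drop = FALSE], D, G, rows, cols, i, A,
        hyper$lambda1, hyper$lambda2, eigG, hyper$inner_iter)
    }
    D <- update_dictionary_blocks(Xt, D, A, rows, cols)

    if (shared) {
      DA <- D %*% A
      Xhat <- matrix(0, nrow(X), n)
      for (i in seq_along(classes))
        Xhat[, cols[[i]]] <- D[, rows[[i]], drop = FALSE] %*%
          A[rows[[i]], cols[[i]], drop = FALSE]
      V <- 2 * X - DA - Xhat
      G0 <- crossprod(D0)
      L0 <- 2 * power_eig(G0) * 1.01 + 2 * hyper$lambda2 + 1e-9
      gradA0 <- function(A0c) {
        m0 <- rowMeans(A0c)
        2 * (G0 %*% A0c) - crossprod(D0, V) +
          hyper$lambda2 * 2 * (A0c - m0)
      }
      objA0 <- function(A0c) {
        R1 <- X - D0 %*% A0c - DA
        R2 <- X - D0 %*% A0c - Xhat
        m0 <- rowMeans(A0c)
        0.5 * sum(R1^2) + 0.5 * sum(R2^2) +
          hyper$lambda2 * sum((A0c - m0)^2)
      }
      A0 <- prox_l1_fista(A0, gradA0, objA0, L0, hyper$lambda1,
                          max_iter = hyper$inner_iter)
      # shared dictionary: proximal gradient on the nuclear norm (SVT)
      S0 <- tcrossprod(A0)
      LD0 <- 2 * power_eig(S0) * 1.01
      if (LD0 > 1e-12) {
        objD0 <- function(D0c) {
          R1 <- X - D0c %*% A0 - DA
          R2 <- X - D0c %*% A0 - Xhat
          0.5 * sum(R1^2) + 0.5 * sum(R2^2) + hyper$eta * sum(svd(D0c)$d)
        }
        f_cur <- objD0(D0)
        for (s in seq_len(5)) {
          grad <- (2 * (D0 %*% S0)) - V %*% t(A0)
          D0_new <- svt(D0 - grad / LD0, hyper$eta / LD0)
          f_new <- objD0(D0_new)
          if (f_new > f_cur) break
          delta <- max(abs(D0_new - D0))
          D0 <- D0_new
          f_cur <- f_new
          if (delta < 1e-10) break
        }
      }
      var_trace <- c(var_trace, sum((A0 - rowMeans(A0))^2) / max(1, n - 1))
    }

    J <- objective()
    trace <- c(trace, J)
    prev <- trace[length(trace) - 1L]
    if (abs(prev - J) <= hyper$tol * max(1, abs(prev))) {
      converged <- TRUE
      break
    }
  }

  # exact unit-norm atoms on the returned dictionary; code rows rescaled so
  # every reconstruction D A is unchanged
  finalize <- function(M, codes) {
    nrms <- sqrt(colSums(M^2))
    Mn <- l2_normalize_cols(M)
    keep <- nrms > 1e-12
    codes[keep, ] <- codes[keep, , drop = FALSE] * nrms[keep]
    list(M = Mn, codes = codes)
  }
  extras <- list(atoms_raw = D, codes_raw = A)
  fin <- finalize(D, A)
  D_out <- fin$M
  A_out <- fin$codes
  D0_out <- NULL
  A0_out <- NULL
  if (shared) {
    extras$shared_raw <- D0
    extras$shared_codes_raw <- A0
    extras$shared_prenorm_fro <- sqrt(sum(D0^2))
    extras$shared_var_trace <- var_trace
    fin0 <- finalize(D0, A0)
    D0_out <- fin0$M
    A0_out <- fin0$codes
  }
  new_dictionary(if (shared) "lrsdl" else "fddl", D_out, atom_class, classes,
                 hyper, shared_atoms = D0_out, training_codes = A_out,
                 shared_codes = A0_out, objective_trace = trace,
                 converged = converged, extras = extras)
}

#' Fit a Fisher discrimination dictionary (FDDL)
#'
#' Alternating minimization: per-class code updates by accelerated proximal
#' gradient (l1 prox) on the discriminative-fidelity + Fisher objective, and
#' per-class dictionary updates by projected gradient descent on the unit
#' ball. The objective value is recorded once per outer iteration
#' (`$objective_trace`) and is non-increasing.
#'
#' @param X `d x n` training matrix (or [build_feature_matrix()] list).
#' @param labels class label per column (>= 2 classes).
#' @param hyper a [hyperparams()] object; `k` atoms per class must not
#'   exceed the smallest class size.
#' @return a `learned_dictionary` with per-atom class assignments,
#'   training codes, the objective trace and a convergence flag.
#' @export
fddl_fit <- function(X, labels = NULL, hyper = hyperparams()) {
  structured_fit(X, labels, hyper, shared = FALSE)
}

#' Predict with an FDDL dictionary
#'
#' Global lasso coding over the structured dictionary followed by the
#' minimum class-residual rule (ties toward `FALL`).
#' @inheritParams src_predict
#' @param dict a fitted FDDL `learned_dictionary`.
#' @return a `prediction_result`, or a list of them for matrix input.
#' @export
fddl_predict <- function(x, dict, lambda1 = NULL, ...) {
  stopifnot(dict$model == "fddl")
  predict_one_or_many(dict, x, lambda1, ...)
}

#' Fit a low-rank shared dictionary model (LRSDL)
#'
#' FDDL-style alternating updates extended with a shared sub-dictionary `D0`
#' updated under a nuclear-norm proximal step (singular-value thresholding,
#' weight `eta`) and a penalty pulling each sample's shared-coefficient
#' column toward the shared-coefficient mean. The per-iteration variance of
#' the shared codes is recorded in `$extras$shared_var_trace`.
#'
#' @inheritParams fddl_fit
#' @param hyper a [hyperparams()]; `k0 >= 1` shared atoms is required
#'   (use [fddl_fit()] for `k0 = 0`).
#' @return a `learned_dictionary` with `shared_atoms`.
#' @export
lrsdl_fit <- function(X, labels = NULL,
                      hyper = hyperparams(lambda1 = 0.001, lambda2 = 0.01,
                                          eta = 0.02)) {
  structured_fit(X, labels, hyper, shared = TRUE)
}

#' Predict with an LRSDL dictionary
#'
#' Codes the input over `[D | D0]`; the shared reconstruction `D0 a0` is
#' subtracted before the per-class residual rule, so shared patterns do not
#' bias any class.
#' @inheritParams src_predict
#' @param dict a fitted LRSDL `learned_dictionary`.
#' @return a `prediction_result`, or a list of them for matrix input.
#' @export
lrsdl_predict <- function(x, dict, lambda1 = NULL, ...) {
  stopifnot(dict$model == "lrsdl")
  predict_one_or_many(dict, x, lambda1, ...)
}
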