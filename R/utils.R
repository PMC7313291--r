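# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded blocks do not perturb the
#' caller's random stream.
#' @param seed integer seed
#' @param code expression to evaluate
#' @return value of `code`
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic seed mixing, kept below 2^31 - 1. Double arithmetic is exact
# here: 2^31 * 69069 < 2^53.
mix_seed <- function(seed, ...) {
  ks <- c(...)
  s <- as.double(seed %% 2147483647)
  for (k in ks) s <- (s * 69069 + as.double(k) + 1) %% 2147483647
  as.integer(s)
}

stop_wf <- function(kind, msg, ...) {
  stop(structure(
    class = c(paste0("wristfall_", kind), "wristfall_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

# largest eigenvalue of a symmetric PSD matrix by power iteration
power_eig <- function(G, iters = 100, tol = 1e-9) {
  p <- ncol(G)
  if (p == 0L) return(0)
  v <- rep(1 / sqrt(p), p)
  lam <- 0
  for (i in seq_len(iters)) {
    w <- G %*% v
    nw <- sqrt(sum(w^2))
    if (nw == 0) return(0)
    v_new <- as.numeric(w / nw)
    lam_new <- nw
    if (abs(lam_new - lam) <= tol * max(1, lam_new)) {
      lam <- lam_new
      break
    }
    v <- v_new
    lam <- lam_new
  }
  lam
}

l2_normalize_cols <- function(M, fallback = TRUE) {
  nrms <- sqrt(colSums(M^2))
  zero <- nrms < 1e-12
  nrms[zero] <- 1
  M <- sweep(M, 2, nrms, "/")
  if (fallback && any(zero)) {
    # degenerate (all-zero) atoms are replaced by the first canonical basis
    # vector so the unit-norm invariant holds
    M[1, zero] <- 1
  }
  M
}
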