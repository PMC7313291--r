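test_that("class residuals match brute-force per-class reconstruction", {
  set.seed(21)
  d <- wristfall:::new_dictionary(
    "src", wristfall:::l2_normalize_cols(matrix(rnorm(10 * 8), 10, 8)),
    rep(c("FALL", "ADL"), each = 4), c("FALL", "ADL"), hyperparams())
  for (i in 1:20) {
    x <- rnorm(10)
    a <- rnorm(8) * rbinom(8, 1, 0.6)
    r <- class_residuals(x, d, a)
    for (cl in c("FALL", "ADL")) {
      sel <- d$atom_class == cl
      brute <- sum((x - d$atoms[, sel] %*% a[sel])^2)
      expect_equal(unname(r[cl]), brute, tolerance = 1e-12)
    }
  }
  # exact reconstruction / zero-code limits
  x <- d$atoms[, 1]
  a <- c(1, rep(0, 7))
  r <- class_residuals(x, d, a)
  expect_equal(unname(r["FALL"]), 0, tolerance = 1e-12)
  expect_equal(unname(r["ADL"]), sum(x^2))
  r0 <- class_residuals(x, d, rep(0, 8))
  expect_true(all(abs(r0 - sum(x^2)) < 1e-12))
  expect_error(class_residuals(x, d, rep(0, 5)), class = "wristfall_argument")
})

test_that("SRC stacks the training samples unchanged, grouped by class", {
  set.seed(22)
  X <- matrix(rnorm(30 * 12), 30, 12)
  X[, 2] <- X[, 1] # duplicates are retained
  y <- rep(c("FALL", "ADL"), each = 6)
  d <- src_fit(X, y)
  expect_equal(ncol(d$atoms), 12L)
  expect_equal(sum(d$atom_class == "FALL"), 6L)
  expect_equal(colSums(d$atoms^2), rep(1, 12), tolerance = 1e-12)
  expect_equal(d$atoms[, 1], d$atoms[, 2])

  d2 <- src_fit(matrix(rnorm(10), 5, 2), c("FALL", "ADL"))
  expect_equal(ncol(d2$atoms), 2L)
  expect_error(src_fit(X, rep("FALL", 12)), class = "wristfall_argument")
})

test_that("SRC assigns a training atom to its own class with near-zero residual", {
  set.seed(23)
  ss <- subspace_classes(20, 5, d = 40, seed = 23)
  d <- src_fit(ss$Xtr, ss$ytr)
  x <- d$atoms[, 3] # a FALL training atom
  p <- src_predict(x, d, lambda1 = 1e-6, tol = 1e-9, max_iter = 5000)
  expect_equal(p$label, "FALL")
  expect_lt(p$residuals["FALL"], 1e-6)
})

test_that("the zero vector yields a degenerate tie broken toward FALL", {
  set.seed(24)
  d <- src_fit(matrix(rnorm(40), 10, 4), rep(c("FALL", "ADL"), each = 2))
  p <- src_predict(numeric(10), d)
  expect_true(all(p$code$a == 0))
  expect_true(p$degenerate)
  expect_equal(p$label, "FALL")
  expect_lt(diff(range(p$residuals)), 1e-12)
})

test_that("FDDL objective traces are non-increasing and atoms end unit-norm", {
  ss <- subspace_classes(30, 10, d = 50, seed = 25)
  d <- fddl_fit(ss$Xtr, ss$ytr, hyperparams(k = 8, max_iter = 15, seed = 2))
  expect_true(all(diff(d$objective_trace) <= 1e-8))
  expect_equal(sqrt(colSums(d$atoms^2)), rep(1, 16), tolerance = 1e-9)
  p <- vapply(fddl_predict(ss$Xte, d), `[[`, "", "label")
  expect_gte(mean(p == ss$yte), 0.99)
})

test_that("single-class FDDL with lambda2=0 reduces to plain dictionary learning", {
  set.seed(26)
  B <- qr.Q(qr(matrix(rnorm(30 * 4), 30, 4)))
  X <- B %*% matrix(rnorm(4 * 20), 4, 20)
  X <- sweep(X, 2, sqrt(colSums(X^2)), "/")
  h <- hyperparams(lambda1 = 0.01, lambda2 = 0, k = 5, max_iter = 10, seed = 3)
  d <- fddl_fit(X, rep("FALL", 20), h)
  # with one class the fidelity doubles the reconstruction term; recompute the
  # objective independently from the returned raw factors
  Dr <- d$extras$atoms_raw
  Ar <- d$extras$codes_raw
  J_indep <- sum((X - Dr %*% Ar)^2) + 0.01 * sum(abs(Ar))
  expect_equal(tail(d$objective_trace, 1), J_indep, tolerance = 1e-10)
})

test_that("FDDL predictions are invariant to atom permutation within a class", {
  ss <- subspace_classes(25, 8, d = 40, seed = 27)
  d <- fddl_fit(ss$Xtr, ss$ytr, hyperparams(k = 6, max_iter = 8, seed = 5))
  perm <- c(sample(1:6), sample(7:12)) # permute within each class block
  d2 <- d
  d2$atoms <- d$atoms[, perm]
  d2$atom_class <- d$atom_class[perm]
  p1 <- vapply(fddl_predict(ss$Xte, d, tol = 1e-8), `[[`, "", "label")
  p2 <- vapply(fddl_predict(ss$Xte, d2, tol = 1e-8), `[[`, "", "label")
  expect_equal(p1, p2)
})

test_that("atoms-per-class larger than a class is a configuration error", {
  ss <- subspace_classes(10, 2, d = 30, seed = 28)
  expect_error(fddl_fit(ss$Xtr, ss$ytr, hyperparams(k = 11)),
               class = "wristfall_configuration")
})

test_that("LRSDL requires at least one shared atom", {
  ss <- subspace_classes(10, 2, d = 30, seed = 29)
  expect_error(lrsdl_fit(ss$Xtr, ss$ytr, hyperparams(k = 4, k0 = 0)),
               class = "wristfall_configuration")
})

test_that("the shared dictionary explains shared structure, classes keep their own", {
  # hand-built structured dictionary: e1/e2 per class, shared atom e3
  d <- wristfall:::new_dictionary(
    "lrsdl", cbind(c(1, 0, 0, 0), c(0, 1, 0, 0)), c("FALL", "ADL"),
    c("FALL", "ADL"), hyperparams(lambda1 = 1e-4),
    shared_atoms = cbind(c(0, 0, 1, 0)))
  p_shared <- lrsdl_predict(c(0, 0, 1, 0), d, lambda1 = 1e-4, tol = 1e-9)
  expect_lt(diff(range(p_shared$residuals)), 1e-6) # near-equal residuals
  p_mix <- lrsdl_predict(c(0, 1, 0, 0) + c(0, 0, 1, 0), d, lambda1 = 1e-4,
                         tol = 1e-9)
  expect_equal(p_mix$label, "ADL")
  p_zero <- lrsdl_predict(numeric(4), d)
  expect_true(p_zero$degenerate)
})

test_that("a huge nuclear-norm weight drives the shared dictionary to zero (FDDL limit)", {
  ss <- subspace_classes(25, 50, d = 40, seed = 30)
  h_f <- hyperparams(lambda1 = 0.001, lambda2 = 0.001, k = 6, max_iter = 10,
                     seed = 7)
  d_f <- fddl_fit(ss$Xtr, ss$ytr, h_f)
  h_l <- hyperparams(lambda1 = 0.001, lambda2 = 0.001, eta = 1e6, k = 6,
                     k0 = 3, max_iter = 10, seed = 7)
  d_l <- lrsdl_fit(ss$Xtr, ss$ytr, h_l)
  expect_lt(d_l$extras$shared_prenorm_fro, 1e-6)
  p_f <- vapply(fddl_predict(ss$Xte, d_f), `[[`, "", "label")
  p_l <- vapply(lrsdl_predict(ss$Xte, d_l), `[[`, "", "label")
  expect_lte(sum(p_f != p_l), 1)
})

test_that("LRSDL pulls shared coefficients together on common-background data", {
  set.seed(31)
  n <- 30
  d_dim <- 40
  shared_pattern <- rnorm(d_dim)
  shared_pattern <- shared_pattern / sqrt(sum(shared_pattern^2))
  ss <- subspace_classes(n, 2, d = d_dim, noise = 0.02, seed = 31)
  X <- ss$Xtr + shared_pattern %o% rep(0.8, 2 * n) # common additive pattern
  X <- sweep(X, 2, sqrt(colSums(X^2)), "/")
  rel_spread <- function(lambda2) {
    h <- hyperparams(lambda1 = 1e-4, lambda2 = lambda2, eta = 0.001, k = 6,
                     k0 = 2, max_iter = 20, seed = 9)
    d <- lrsdl_fit(X, ss$ytr, h)
    expect_true(all(diff(d$objective_trace) <= 1e-8))
    A0 <- d$shared_codes
    expect_gt(sum(A0^2), 0) # the shared dictionary is actually used
    sum((A0 - rowMeans(A0))^2) / sum(A0^2)
  }
  # the similarity penalty shrinks the spread of the shared coefficients
  # relative to an unpenalized fit on the same data
  expect_lt(rel_spread(0.05), rel_spread(0))
})

test_that("LRSDL reports the expected total atom count", {
  ss <- subspace_classes(12, 2, d = 30, seed = 32)
  d <- lrsdl_fit(ss$Xtr, ss$ytr,
                 hyperparams(k = 5, k0 = 4, max_iter = 3, seed = 1))
  expect_equal(ncol(d$atoms) + ncol(d$shared_atoms), 2 * 5 + 4)
  expect_equal(sqrt(colSums(d$shared_atoms^2)), rep(1, 4), tolerance = 1e-9)
})

test_that("dictionaries survive a save/load round trip", {
  ss <- subspace_classes(10, 2, d = 20, seed = 33)
  d <- lrsdl_fit(ss$Xtr, ss$ytr,
                 hyperparams(k = 4, k0 = 2, max_iter = 3, seed = 1))
  dir <- withr::local_tempdir()
  save_dictionary(d, dir)
  back <- load_dictionary(dir)
  expect_equal(back$atoms, d$atoms, tolerance = 1e-12)
  expect_equal(back$shared_atoms, d$shared_atoms, tolerance = 1e-12)
  expect_equal(back$atom_class, d$atom_class)
  expect_equal(back$model, "lrsdl")
  p1 <- vapply(lrsdl_predict(ss$Xte, d), `[[`, "", "label")
  p2 <- vapply(lrsdl_predict(ss$Xte, back), `[[`, "", "label")
  expect_equal(p1, p2)
})
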