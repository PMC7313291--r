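test_that("the stratified split honors per-class fractions", {
  labels <- rep(c("FALL", "ADL"), each = 400)
  sp <- stratified_split(labels, 0.75, seed = 3)
  expect_equal(sum(labels[sp$train] == "FALL"), 300L)
  expect_equal(sum(labels[sp$test] == "FALL"), 100L)
  expect_equal(sum(labels[sp$train] == "ADL"), 300L)
  expect_length(intersect(sp$train, sp$test), 0L)
  expect_setequal(c(sp$train, sp$test), seq_along(labels))

  small <- rep(c("FALL", "ADL"), each = 4)
  sp2 <- stratified_split(small, 0.75, seed = 1)
  expect_equal(sum(small[sp2$train] == "FALL"), 3L)
  expect_equal(sum(small[sp2$test] == "FALL"), 1L)

  expect_identical(stratified_split(labels, seed = 9),
                   stratified_split(labels, seed = 9))
  expect_false(identical(stratified_split(labels, seed = 9),
                         stratified_split(labels, seed = 10)))

  expect_error(stratified_split(c("FALL", "ADL", "ADL")),
               class = "wristfall_argument")
})

test_that("subject-wise splitting keeps each subject on one side", {
  subjects <- rep(sprintf("S%02d", 1:8), each = 10)
  labels <- rep(rep(c("FALL", "ADL"), each = 5), 8)
  sp <- stratified_split(labels, 0.75, seed = 2, subjects = subjects)
  expect_length(intersect(unique(subjects[sp$train]),
                          unique(subjects[sp$test])), 0L)
  expect_equal(length(unique(subjects[sp$train])), 6L)
  expect_setequal(c(sp$train, sp$test), seq_along(labels))
  expect_identical(sp, stratified_split(labels, 0.75, seed = 2,
                                        subjects = subjects))
  expect_error(stratified_split(labels[1:10], 0.75, seed = 2,
                                subjects = subjects[1:10]),
               class = "wristfall_argument")
})

test_that("AC/SE/SP follow the confusion-count formulas", {
  labels <- c(rep("FALL", 10), rep("ADL", 10))
  preds <- c(rep("FALL", 9), "ADL", rep("ADL", 8), "FALL", "FALL")
  r <- compute_metrics(labels, preds)
  expect_equal(c(r$TP, r$FN, r$TN, r$FP), c(9, 1, 8, 2))
  expect_equal(r$SE, 90)
  expect_equal(r$SP, 80)
  expect_equal(r$AC, 85)

  perfect <- compute_metrics(labels, labels)
  expect_equal(c(perfect$AC, perfect$SE, perfect$SP), c(100, 100, 100))

  expect_error(compute_metrics(character(0), character(0)),
               class = "wristfall_argument")
  expect_warning(r2 <- compute_metrics(rep("ADL", 5), rep("ADL", 5)),
                 "sensitivity undefined")
  expect_true(is.nan(r2$SE))
})

test_that("metrics match brute-force counting and the prevalence identity", {
  set.seed(41)
  for (i in 1:100) {
    n <- sample(5:60, 1)
    labels <- sample(c("FALL", "ADL"), n, replace = TRUE)
    if (length(unique(labels)) < 2) labels[1:2] <- c("FALL", "ADL")
    preds <- sample(c("FALL", "ADL"), n, replace = TRUE)
    r <- compute_metrics(labels, preds)
    cm <- table(factor(labels, c("FALL", "ADL")),
                factor(preds, c("FALL", "ADL")))
    expect_identical(c(r$TP, r$FN, r$FP, r$TN),
                     c(cm[1, 1], cm[1, 2], cm[2, 1], cm[2, 2]))
    expect_equal(r$AC, 100 * (cm[1, 1] + cm[2, 2]) / n)
    # AC is the prevalence-weighted mean of SE and SP
    w_pos <- sum(labels == "FALL") / n
    expect_equal(r$AC, w_pos * r$SE + (1 - w_pos) * r$SP, tolerance = 1e-12)
  }
})

test_that("a single-size sweep entry equals a standalone run", {
  feats <- tiny_features(seed = 5, n_subjects = 4)
  h <- hyperparams(lambda1 = 0.001, lambda2 = 0.001, k = 4, max_iter = 4,
                   seed = 2, inner_iter = 10)
  sw <- sweep_dictionary_size(feats, "fddl", sizes = 4, hyper = h, seed = 6)
  expect_length(sw$reports, 1L)
  direct <- evaluate_model(feats, "fddl", h, seed = 6)
  expect_equal(sw$reports[["4"]]$AC, direct$AC)
  expect_equal(sw$reports[["4"]][c("TP", "TN", "FP", "FN")],
               direct[c("TP", "TN", "FP", "FN")])

  sw2 <- sweep_dictionary_size(feats, "fddl", sizes = 4, hyper = h, seed = 6)
  expect_identical(sw$table, sw2$table)
})

test_that("oversized sweep entries are skipped with a warning", {
  feats <- tiny_features(seed = 5, n_subjects = 4)
  h <- hyperparams(lambda1 = 0.001, lambda2 = 0.001, k = 4, max_iter = 2,
                   seed = 2, inner_iter = 5)
  expect_warning(sw <- sweep_dictionary_size(feats, "fddl",
                                             sizes = c(4, 1000), hyper = h,
                                             seed = 6),
                 "skipped")
  expect_length(sw$reports, 1L)
})

test_that("run_experiment is reproducible bit-for-bit and accurate on separable data", {
  cfg <- list(seed = 3, n_subjects = 3, scenario = "A_ACC", model = "src",
              lambda1 = 0.01)
  r1 <- run_experiment(cfg)
  r2 <- run_experiment(cfg)
  expect_identical(unclass(r1), unclass(r2))
  expect_gte(r1$AC, 95)
  r3 <- run_experiment(utils::modifyList(cfg, list(seed = 4)))
  expect_false(identical(unclass(r1), unclass(r3)))
})

test_that("scenarios demanding absent sensors fail fast at preprocessing", {
  dir <- withr::local_tempdir()
  df <- data.frame(t = seq(0, 9.19, by = 0.01), ax = 0, ay = 0, az = 1)
  df$az[500:520] <- 3
  write.csv(df, file.path(dir, "acc_only.csv"), row.names = FALSE)
  write_manifest(data.frame(file = "acc_only.csv", subject_id = "S01",
                            activity = "FALL_FORWARD"),
                 file.path(dir, "manifest.csv"))
  expect_error(
    run_experiment(list(manifest = file.path(dir, "manifest.csv"),
                        scenario = "B_EULER", model = "src")),
    class = "wristfall_missing_sensor")
})

test_that("experiment reports can be written to JSON", {
  out <- withr::local_tempfile(fileext = ".json")
  r <- run_experiment(list(seed = 3, n_subjects = 3, scenario = "A_ACC",
                           model = "src", out = out))
  expect_true(file.exists(out))
  js <- jsonlite::read_json(out)
  expect_equal(js$AC, r$AC)
  expect_equal(js$TP + js$TN + js$FP + js$FN, r$n)
})
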