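# Experiment protocol: stratified splitting, AC/SE/SP metrics, dictionary
# size sweeps and the end-to-end pipeline. FALL is the positive class
# throughout, so sensitivity is fall recall and specificity is ADL recall.

#' Stratified train/test split
#'
#' By default samples are shuffled and split per class, so windows from one
#' subject may land on both sides. Passing `subjects` switches to a
#' subject-wise split: whole subjects are assigned to train or test, which
#' is the stricter protocol when generalization across people is the
#' question.
#'
#' @param labels class label per sample.
#' @param train_fraction fraction per class assigned to training (default
#'   0.75, i.e. a 75/25 split).
#' @param seed integer seed for the per-class shuffle.
#' @param subjects optional subject id per sample; when given, the split is
#'   by subject rather than by window.
#' @return list with integer index vectors `train` and `test` (disjoint,
#'   covering all samples).
#' @export
stratified_split <- function(labels, train_fraction = 0.75, seed = 1,
                             subjects = NULL) {
  stopifnot(train_fraction > 0, train_fraction < 1)
  if (!is.null(subjects)) {
    stopifnot(length(subjects) == length(labels))
    ids <- sort(unique(subjects))
    if (length(ids) < 2L)
      stop_wf("argument", "subject-wise split needs >= 2 subjects")
    n_tr <- floor(length(ids) * train_fraction)
    if (n_tr < 1L || n_tr >= length(ids))
      stop_wf("argument", "split leaves no train or no test subjects")
    perm <- with_seed(mix_seed(seed, 271), sample(ids))
    train <- which(subjects %in% perm[seq_len(n_tr)])
    test <- which(subjects %in% perm[(n_tr + 1L):length(perm)])
    for (cl in class_order(labels))
      if (!any(labels[train] == cl) || !any(labels[test] == cl))
        stop_wf("argument", "subject-wise split left class %s empty", cl)
    return(list(train = train, test = test))
  }
  classes <- class_order(labels)
  train <- integer(0)
  test <- integer(0)
  for (ci in seq_along(classes)) {
    idx <- which(labels == classes[ci])
    if (length(idx) < 2L)
      stop_wf("argument", "class %s has %d sample(s); need >= 2",
              classes[ci], length(idx))
    n_tr <- floor(length(idx) * train_fraction)
    if (n_tr < 1L || n_tr >= length(idx))
      stop_wf("argument", "split leaves an empty set for class %s",
              classes[ci])
    perm <- with_seed(mix_seed(seed, ci), sample(idx))
    train <- c(train, perm[seq_len(n_tr)])
    test <- c(test, perm[(n_tr + 1L):length(perm)])
  }
  list(train = sort(train), test = sort(test))
}

#' Confusion counts and AC/SE/SP
#'
#' Accuracy `AC = 100 (TP+TN)/n`, sensitivity `SE = 100 TP/(TP+FN)` (fall
#' recall) and specificity `SP = 100 TN/(TN+FP)` (ADL recall), with `FALL`
#' as the positive class.
#'
#' @param labels true labels (`FALL`/`ADL`).
#' @param predictions predicted labels, same length.
#' @param config optional configuration echo stored on the report.
#' @return an `eval_report` with counts `TP,TN,FP,FN` and percentages
#'   `AC,SE,SP`.
#' @export
compute_metrics <- function(labels, predictions, config = NULL) {
  if (length(labels) == 0L) stop_wf("argument", "empty label vector")
  if (length(labels) != length(predictions))
    stop_wf("argument", "labels and predictions differ in length")
  pos <- labels == "FALL"
  ppos <- predictions == "FALL"
  TP <- sum(pos & ppos); FN <- sum(pos & !ppos)
  TN <- sum(!pos & !ppos); FP <- sum(!pos & ppos)
  SE <- if (TP + FN == 0) {
    warning("no FALL samples: sensitivity undefined")
    NaN
  } else 100 * TP / (TP + FN)
  SP <- if (TN + FP == 0) {
    warning("no ADL samples: specificity undefined")
    NaN
  } else 100 * TN / (TN + FP)
  structure(list(TP = TP, TN = TN, FP = FP, FN = FN,
                 AC = 100 * (TP + TN) / length(labels), SE = SE, SP = SP,
                 n = length(labels), config = config),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> n=%d  TP=%d FN=%d TN=%d FP=%d\n",
              x$n, x$TP, x$FN, x$TN, x$FP))
  cat(sprintf("  AC = %.1f%%   SE = %.1f%%   SP = %.1f%%\n", x$AC, x$SE, x$SP))
  if (!is.null(x$config) && length(x$config))
    cat("  config:", paste(names(x$config),
                           vapply(x$config, function(v)
                             paste(format(unlist(v)), collapse = "/"), ""),
                           sep = "=", collapse = " "), "\n")
  invisible(x)
}

fit_model <- function(model, X_train, y_train, hyper) {
  switch(model,
         src = src_fit(X_train, y_train, lambda1 = hyper$lambda1),
         fddl = fddl_fit(X_train, y_train, hyper),
         lrsdl = lrsdl_fit(X_train, y_train, hyper),
         stop_wf("argument", "unknown model '%s'", model))
}

predict_labels <- function(dict, X, lambda1 = NULL) {
  vapply(predict_batch(dict, X, lambda1), `[[`, "", "label")
}

#' Train and evaluate one configuration on a fixed split
#'
#' @param features list from [build_feature_matrix()].
#' @param model `"src"`, `"fddl"` or `"lrsdl"`.
#' @param hyper a [hyperparams()].
#' @param split list from [stratified_split()] (built from `seed` when
#'   omitted).
#' @param seed split seed used when `split` is `NULL`.
#' @return an `eval_report`.
#' @export
evaluate_model <- function(features, model, hyper = hyperparams(),
                           split = NULL, seed = 1) {
  split <- split %||% stratified_split(features$labels, seed = seed)
  dict <- fit_model(model, features$X[, split$train, drop = FALSE],
                    features$labels[split$train], hyper)
  pred <- predict_labels(dict, features$X[, split$test, drop = FALSE])
  compute_metrics(features$labels[split$test], pred,
                  config = list(model = model, scenario = features$scenario,
                                k = hyper$k, lambda1 = hyper$lambda1,
                                seed = seed))
}

#' Dictionary-size sweep
#'
#' Re-fits the model once per size on the same stratified split and collects
#' one report per size; sizes exceeding the per-class training count are
#' skipped with a warning.
#'
#' @param features list from [build_feature_matrix()].
#' @param model `"fddl"` or `"lrsdl"`.
#' @param sizes atoms-per-class values (default `seq(50, 300, by = 50)`).
#' @param hyper a [hyperparams()]; its `k` is overridden by each size.
#' @param seed split seed.
#' @return list with `reports` (one `eval_report` per retained size) and
#'   `table`, a plot-ready data frame of size vs AC/SE/SP.
#' @export
sweep_dictionary_size <- function(features, model = c("fddl", "lrsdl"),
                                  sizes = seq(50, 300, by = 50),
                                  hyper = hyperparams(), seed = 1) {
  model <- match.arg(model)
  split <- stratified_split(features$labels, seed = seed)
  min_class <- min(table(features$labels[split$train]))
  reports <- list()
  for (sz in sizes) {
    if (sz > min_class) {
      warning(sprintf("size %d > %d training samples per class; skipped",
                      sz, min_class))
      next
    }
    h <- hyper
    h$k <- as.integer(sz)
    rep_sz <- evaluate_model(features, model, h, split = split, seed = seed)
    rep_sz$config$k <- sz
    reports[[as.character(sz)]] <- rep_sz
  }
  tab <- do.call(rbind, lapply(reports, function(r)
    data.frame(size = r$config$k, AC = r$AC, SE = r$SE, SP = r$SP)))
  rownames(tab) <- NULL
  list(reports = reports, table = tab)
}

default_experiment_config <- function() {
  list(seed = 1, scenario = "A_ACC", model = "src",
       n_subjects = 22, noise_acc = 0.02, noise_gyr = 1, noise_mag = 0.005,
       train_fraction = 0.75,
       lambda1 = 0.01, lambda2 = 0.001, eta = 0.02,
       atoms_per_class = 50, shared_atoms = 10,
       max_iter = 100, tol = 1e-5, split_by_subject = FALSE,
       manifest = NULL, out = NULL, verbose = FALSE)
}

#' Run the full pipeline for one experiment configuration
#'
#' Data (simulated from `seed`, or loaded from `manifest`) -> windowing and
#' feature extraction for the chosen scenario -> stratified 75/25 split ->
#' model fit -> residual-rule prediction -> AC/SE/SP. Fully deterministic
#' given the configuration: reruns produce identical reports.
#'
#' @param config named list (or path to a YAML file, see
#'   [read_experiment_config()]). Recognized keys and defaults: `seed` (1),
#'   `scenario` (`"A_ACC"`), `model` (`"src"`), `n_subjects` (22),
#'   `noise_acc`/`noise_gyr`/`noise_mag` sensor noise SDs,
#'   `train_fraction` (0.75), `lambda1`, `lambda2`, `eta`,
#'   `atoms_per_class`, `shared_atoms`, `max_iter`, `tol`,
#'   `split_by_subject` (assign whole subjects to train or test; off by
#'   default), `manifest` (recording source instead of simulation), `out`
#'   (optional JSON report path), `verbose`.
#' @return an `eval_report`.
#' @export
run_experiment <- function(config = list()) {
  if (is.character(config)) config <- read_experiment_config(config)
  cfg <- utils::modifyList(default_experiment_config(), config)
  say <- function(fmt, ...) if (isTRUE(cfg$verbose)) message(sprintf(fmt, ...))

  t0 <- proc.time()[3]
  if (!is.null(cfg$manifest)) {
    recs <- load_dataset(cfg$manifest)
  } else {
    sim <- simulation_config(n_subjects = cfg$n_subjects,
                             noise_sd = list(acc = cfg$noise_acc,
                                             gyr = cfg$noise_gyr,
                                             mag = cfg$noise_mag),
                             seed = cfg$seed)
    recs <- simulate_recordings(sim)
  }
  say("data: %d recordings [%.1f s]", length(recs), proc.time()[3] - t0)

  feats <- build_feature_matrix(recs, cfg$scenario)
  say("features: %d x %d (%s)", nrow(feats$X), ncol(feats$X), cfg$scenario)

  split <- stratified_split(feats$labels, cfg$train_fraction,
                            seed = mix_seed(cfg$seed, 7),
                            subjects = if (isTRUE(cfg$split_by_subject))
                              feats$subjects)
  say("split: %d train / %d test", length(split$train), length(split$test))

  hyper <- hyperparams(lambda1 = cfg$lambda1, lambda2 = cfg$lambda2,
                       eta = cfg$eta, k = cfg$atoms_per_class,
                       k0 = cfg$shared_atoms, max_iter = cfg$max_iter,
                       tol = cfg$tol, seed = mix_seed(cfg$seed, 13))
  report <- evaluate_model(feats, cfg$model, hyper, split = split,
                           seed = cfg$seed)
  report$config <- c(report$config[setdiff(names(report$config), "seed")],
                     list(seed = cfg$seed, n_subjects = cfg$n_subjects))
  say("report: AC=%.1f SE=%.1f SP=%.1f [%.1f s total]",
      report$AC, report$SE, report$SP, proc.time()[3] - t0)
  if (!is.null(cfg$out)) {
    jsonlite::write_json(unclass(report), cfg$out, auto_unbox = TRUE,
                         digits = NA, null = "null")
    say("written: %s", cfg$out)
  }
  report
}
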