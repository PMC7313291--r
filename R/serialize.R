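# Portable on-disk form of a learned dictionary: a directory holding a
# versioned JSON metadata file plus plain-CSV matrices.

DICT_FORMAT_VERSION <- 1L

#' Save a learned dictionary
#'
#' Writes `meta.json` (model, class labels, per-atom classes,
#' hyper-parameters, format version) plus `atoms.csv` and, for LRSDL,
#' `shared.csv` into `dir`.
#'
#' @param dict a `learned_dictionary`.
#' @param dir destination directory (created if needed).
#' @return `dir`, invisibly.
#' @export
save_dictionary <- function(dict, dir) {
  stopifnot(inherits(dict, "learned_dictionary"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  meta <- list(format_version = DICT_FORMAT_VERSION, model = dict$model,
               class_labels = dict$class_labels, atom_class = dict$atom_class,
               hyper = unclass(dict$hyper), converged = dict$converged,
               objective_trace = dict$objective_trace)
  jsonlite::write_json(meta, file.path(dir, "meta.json"), digits = NA,
                       auto_unbox = TRUE, null = "null")
  utils::write.csv(dict$atoms, file.path(dir, "atoms.csv"), row.names = FALSE)
  if (!is.null(dict$shared_atoms))
    utils::write.csv(dict$shared_atoms, file.path(dir, "shared.csv"),
                     row.names = FALSE)
  invisible(dir)
}

#' Load a learned dictionary saved by [save_dictionary()]
#' @param dir directory written by [save_dictionary()].
#' @return a `learned_dictionary` (without training codes or raw factors).
#' @export
load_dictionary <- function(dir) {
  meta_path <- file.path(dir, "meta.json")
  if (!file.exists(meta_path)) stop_wf("io", "no dictionary at %s", dir)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  if (!identical(as.integer(meta$format_version), DICT_FORMAT_VERSION))
    stop_wf("format", "unsupported dictionary format version %s",
            meta$format_version)
  atoms <- as.matrix(utils::read.csv(file.path(dir, "atoms.csv")))
  dimnames(atoms) <- NULL
  shared <- NULL
  if (file.exists(file.path(dir, "shared.csv"))) {
    shared <- as.matrix(utils::read.csv(file.path(dir, "shared.csv")))
    dimnames(shared) <- NULL
  }
  hyper <- do.call(hyperparams, meta$hyper[c("lambda1", "lambda2", "eta", "k",
                                             "k0", "max_iter", "tol", "seed",
                                             "inner_iter")])
  new_dictionary(meta$model, atoms, meta$atom_class, meta$class_labels, hyper,
                 shared_atoms = shared,
                 objective_trace = meta$objective_trace,
                 converged = isTRUE(meta$converged))
}
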