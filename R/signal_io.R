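# Reading and writing wrist-IMU recordings, dataset manifests and experiment
# configuration. On-disk format is plain CSV:
#   recording: t,ax,ay,az[,gx,gy,gz][,mx,my,mz]   (t in seconds)
#   manifest:  file,subject_id,activity
# Units are fixed: accelerometer in g, gyroscope in deg/s, magnetometer in
# Gauss, matching the sensor full-scale ranges 4 g / 500 deg/s / 0.88 Gs.

SENSOR_RANGES <- list(acc = 4, gyr = 500, mag = 0.88)

clip_range <- function(M, lim) {
  M[M > lim] <- lim
  M[M < -lim] <- -lim
  M
}

#' Construct a sensor recording
#'
#' @param acc n x 3 accelerometer matrix (g). Required.
#' @param gyr optional n x 3 gyroscope matrix (deg/s).
#' @param mag optional n x 3 magnetometer matrix (Gauss).
#' @param rate sampling rate in Hz.
#' @param subject_id opaque subject identifier.
#' @param activity activity code from [activity_levels()], or `NA`.
#' @param clip clip each sensor to its full-scale range (the default emulates
#'   sensor saturation; raw files beyond range are clipped on read).
#' @return an object of class `sensor_recording` with fields `t`, `acc`,
#'   `gyr`, `mag`, `rate`, `subject_id`, `activity`, `duration`.
#' @export
sensor_recording <- function(acc, gyr = NULL, mag = NULL, rate = 100,
                             subject_id = NA_character_,
                             activity = NA_character_, clip = TRUE) {
  if (!is.numeric(rate) || rate <= 0) stop_wf("argument", "rate must be > 0")
  acc <- as.matrix(acc)
  if (ncol(acc) != 3L) stop_wf("format", "acc must have 3 columns")
  n <- nrow(acc)
  if (n < 1L) stop_wf("format", "empty recording")
  for (nm in c("gyr", "mag")) {
    M <- get(nm)
    if (!is.null(M)) {
      M <- as.matrix(M)
      if (ncol(M) != 3L || nrow(M) != n)
        stop_wf("format", "%s must be %d x 3 to match acc", nm, n)
      assign(nm, M)
    }
  }
  if (!all(is.finite(acc)) ||
      (!is.null(gyr) && !all(is.finite(gyr))) ||
      (!is.null(mag) && !all(is.finite(mag))))
    stop_wf("format", "non-finite sensor values")
  if (clip) {
    acc <- clip_range(acc, SENSOR_RANGES$acc)
    if (!is.null(gyr)) gyr <- clip_range(gyr, SENSOR_RANGES$gyr)
    if (!is.null(mag)) mag <- clip_range(mag, SENSOR_RANGES$mag)
  }
  if (!is.na(activity) && !activity %in% activity_levels())
    stop_wf("argument", "unknown activity '%s'", activity)
  structure(list(
    t = seq(0, by = 1 / rate, length.out = n),
    acc = unname(acc), gyr = if (is.null(gyr)) NULL else unname(gyr),
    mag = if (is.null(mag)) NULL else unname(mag),
    rate = rate, subject_id = subject_id, activity = activity,
    duration = n / rate
  ), class = "sensor_recording")
}

#' @export
print.sensor_recording <- function(x, ...) {
  sensors <- c("acc", if (!is.null(x$gyr)) "gyr", if (!is.null(x$mag)) "mag")
  cat(sprintf("<sensor_recording> %s / %s: %.2f s @ %g Hz (%d samples), sensors: %s\n",
              x$subject_id, x$activity, x$duration, x$rate, nrow(x$acc),
              paste(sensors, collapse = "+")))
  invisible(x)
}

#' Read a recording CSV
#'
#' Expects columns `t,ax,ay,az` and optionally the gyroscope (`gx,gy,gz`)
#' and magnetometer (`mx,my,mz`) blocks. A sensor block must be complete or
#' absent; absent blocks yield `NULL` series on the returned object. The
#' reader is locale-independent (decimal point).
#'
#' @param path CSV file path.
#' @param rate expected sampling rate in Hz; timestamps deviating from a
#'   uniform grid at this rate by more than 1% raise a sampling error.
#' @return a [sensor_recording()].
#' @export
read_recording <- function(path, rate = 100) {
  if (!file.exists(path)) stop_wf("io", "no such file: %s", path)
  df <- tryCatch(
    utils::read.csv(path, header = TRUE, dec = ".", check.names = FALSE),
    error = function(e) stop_wf("format", "malformed recording %s: %s",
                                path, conditionMessage(e))
  )
  if (nrow(df) == 0L) stop_wf("format", "empty recording file: %s", path)
  need <- c("t", "ax", "ay", "az")
  if (!all(need %in% names(df)))
    stop_wf("format", "%s: missing required columns (%s)", path,
            paste(setdiff(need, names(df)), collapse = ", "))
  get_block <- function(cols) {
    have <- cols %in% names(df)
    if (!any(have)) return(NULL)
    if (!all(have))
      stop_wf("format", "%s: incomplete sensor block (%s)", path,
              paste(cols[!have], collapse = ", "))
    M <- as.matrix(df[, cols])
    storage.mode(M) <- "double"
    if (anyNA(M)) stop_wf("format", "%s: non-numeric sensor values", path)
    M
  }
  tt <- as.numeric(df$t)
  if (anyNA(tt)) stop_wf("format", "%s: non-numeric time column", path)
  if (length(tt) >= 2L) {
    dt <- diff(tt)
    if (any(abs(dt - 1 / rate) > 0.01 / rate))
      stop_wf("sampling", "%s: non-uniform timestamps (> 1%% jitter at %g Hz)",
              path, rate)
  }
  sensor_recording(acc = get_block(c("ax", "ay", "az")),
                   gyr = get_block(c("gx", "gy", "gz")),
                   mag = get_block(c("mx", "my", "mz")),
                   rate = rate)
}

#' Write a recording CSV
#'
#' A write/read round trip reproduces all samples to better than 1e-6.
#'
#' @param rec a [sensor_recording()].
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "sensor_recording"))
  df <- data.frame(t = rec$t, ax = rec$acc[, 1], ay = rec$acc[, 2],
                   az = rec$acc[, 3])
  if (!is.null(rec$gyr))
    df <- cbind(df, gx = rec$gyr[, 1], gy = rec$gyr[, 2], gz = rec$gyr[, 3])
  if (!is.null(rec$mag))
    df <- cbind(df, mx = rec$mag[, 1], my = rec$mag[, 2], mz = rec$mag[, 3])
  ok <- tryCatch({
    utils::write.csv(format(df, digits = 15, scientific = FALSE, trim = TRUE),
                     path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok))
    stop_wf("io", "failed to write %s: %s", path, conditionMessage(ok))
  invisible(path)
}

#' Read a dataset manifest
#'
#' @param path manifest CSV with columns `file,subject_id,activity`; file
#'   paths are resolved relative to the manifest's directory.
#' @param check_paths verify that every referenced recording exists.
#' @return a `dataset_manifest`: a data frame with resolved `file`,
#'   `subject_id`, `activity`, plus per-class counts in `attr(, "counts")`.
#' @export
read_manifest <- function(path, check_paths = TRUE) {
  if (!file.exists(path)) stop_wf("io", "no such manifest: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("file", "subject_id", "activity")
  if (!all(need %in% names(df)))
    stop_wf("format", "%s: manifest needs columns %s", path,
            paste(need, collapse = ","))
  df$subject_id <- as.character(df$subject_id)
  bad <- !df$activity %in% activity_levels()
  if (any(bad))
    stop_wf("format", "%s: unknown activities: %s", path,
            paste(unique(df$activity[bad]), collapse = ", "))
  base <- dirname(normalizePath(path))
  abs <- ifelse(grepl("^(/|[A-Za-z]:)", df$file), df$file,
                file.path(base, df$file))
  if (check_paths) {
    miss <- !file.exists(abs)
    if (any(miss))
      stop_wf("io", "manifest %s references missing files: %s", path,
              paste(utils::head(df$file[miss], 5), collapse = ", "))
  }
  out <- data.frame(file = abs, subject_id = df$subject_id,
                    activity = df$activity, stringsAsFactors = FALSE)
  attr(out, "counts") <- table(binary_label(out$activity))
  class(out) <- c("dataset_manifest", "data.frame")
  out
}

#' Write a dataset manifest
#' @param manifest data frame with columns `file,subject_id,activity`.
#' @param path destination CSV.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.csv(manifest[, c("file", "subject_id", "activity")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Load every recording referenced by a manifest
#'
#' @param manifest a `dataset_manifest` (or path to one).
#' @param rate sampling rate passed to [read_recording()].
#' @return list of [sensor_recording()]s with subject and activity attached.
#' @export
load_dataset <- function(manifest, rate = 100) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  lapply(seq_len(nrow(manifest)), function(i) {
    rec <- read_recording(manifest$file[i], rate = rate)
    rec$subject_id <- manifest$subject_id[i]
    rec$activity <- manifest$activity[i]
    rec
  })
}

#' Read a flat YAML experiment configuration
#' @param path YAML file of scalar keys (scenario, model, hyper-parameters...).
#' @return named list.
#' @export
read_experiment_config <- function(path) {
  if (!file.exists(path)) stop_wf("io", "no such config: %s", path)
  yaml::read_yaml(path)
}
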