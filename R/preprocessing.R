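# From recordings to fixed-length feature vectors.
#
# Two scenario families are supported:
#   A: 4-s windows of raw per-axis sensor series for a chosen sensor
#      combination (accelerometer; + gyroscope; + magnetometer).
#   B: movement-decomposition features -- vertical acceleration / velocity /
#      displacement (VA, VV, VD) -- and/or per-sample Euler orientation
#      angles (yaw, pitch, roll) from accelerometer + magnetometer.
# Every feature vector is L2-normalized.

STANDARD_GRAVITY <- 9.81  # m/s^2 per g

SCENARIOS <- c("A_ACC", "A_ACC_GYR", "A_ACC_GYR_MAG",
               "B_VERT", "B_EULER", "B_VERT_EULER")

#' Sensors required by a preprocessing scenario
#' @param scenario one of `r paste(SCENARIOS, collapse=", ")`.
#' @return character vector drawn from `acc`, `gyr`, `mag`.
#' @export
scenario_sensors <- function(scenario) {
  switch(match.arg(scenario, SCENARIOS),
         A_ACC = "acc",
         A_ACC_GYR = c("acc", "gyr"),
         A_ACC_GYR_MAG = c("acc", "gyr", "mag"),
         B_VERT = "acc",
         B_EULER = c("acc", "mag"),
         B_VERT_EULER = c("acc", "mag"))
}

#' Feature dimension of a scenario
#'
#' A pure function of (scenario, rate, duration): `rate * duration` samples
#' per channel, 3 channels per sensor or per angle/vertical block.
#' @param scenario scenario code.
#' @param rate sampling rate (Hz).
#' @param duration window length (s).
#' @return integer dimension.
#' @export
feature_dim <- function(scenario, rate = 100, duration = 4) {
  n <- round(rate * duration)
  switch(match.arg(scenario, SCENARIOS),
         A_ACC = 3L * n, A_ACC_GYR = 6L * n, A_ACC_GYR_MAG = 9L * n,
         B_VERT = 3L * n, B_EULER = 3L * n, B_VERT_EULER = 6L * n)
}

#' Causal moving-average low-pass filter
#'
#' Averages the last `window` samples; at the start the window shrinks so the
#' output has the same length as the input.
#'
#' @param series numeric vector (length >= 2).
#' @param window window size in samples (default 40, i.e. 0.4 s at 100 Hz).
#' @return filtered series, same length.
#' @export
lowpass_filter <- function(series, window = 40) {
  if (!is.numeric(series) || length(series) < 2L)
    stop_wf("argument", "series must have at least 2 samples")
  window <- as.integer(window)
  if (window < 1L) stop_wf("argument", "window must be >= 1")
  if (length(series) < window)
    stop_wf("argument", "series shorter than the filter window")
  cs <- cumsum(series)
  n <- length(series)
  out <- numeric(n)
  head_idx <- seq_len(min(window, n))
  out[head_idx] <- cs[head_idx] / head_idx
  if (n > window) {
    idx <- (window + 1L):n
    out[idx] <- (cs[idx] - cs[idx - window]) / window
  }
  out
}

#' Remove the static 1 g offset from an acceleration-magnitude series
#'
#' @param acc_magnitude Euclidean norm of the (filtered) triaxial
#'   accelerometer, in g; must be non-negative.
#' @return the series minus 1 g; resting segments hover near zero.
#' @export
remove_gravity <- function(acc_magnitude) {
  if (any(acc_magnitude < 0))
    stop_wf("argument", "acceleration magnitudes must be non-negative")
  acc_magnitude - 1
}

acc_magnitude <- function(acc) sqrt(rowSums(acc^2))

#' Extract the 4-s event window from a recording
#'
#' The window is centered on the global maximum of the gravity-removed,
#' low-pass-filtered acceleration magnitude (the causal filter's group delay
#' of (window-1)/2 samples is compensated before centering) and clamped to
#' the recording bounds. All present sensors are sliced identically.
#'
#' @param rec a [sensor_recording()].
#' @param duration window length in seconds (default 4).
#' @param filter_window moving-average window for peak detection.
#' @return an `event_slices` list: `acc`/`gyr`/`mag` slices, `t`, `rate`,
#'   sample `indices`, the pre-window `gravity_axis` estimate (mean filtered
#'   accelerometer direction over the 0.5 s preceding the window), and the
#'   recording's metadata.
#' @export
extract_window <- function(rec, duration = 4, filter_window = 40) {
  stopifnot(inherits(rec, "sensor_recording"))
  n <- nrow(rec$acc)
  n_win <- round(duration * rec$rate)
  if (n < n_win)
    stop_wf("extraction", "recording (%.2f s) shorter than the %g-s window",
            rec$duration, duration)
  filt <- lowpass_filter(acc_magnitude(rec$acc), filter_window)
  sig <- remove_gravity(pmax(filt, 0))
  peak <- which.max(sig)
  center <- max(1L, peak - as.integer(floor(filter_window / 2)))
  start <- center - n_win %/% 2L
  start <- min(max(start, 1L), n - n_win + 1L)
  idx <- start:(start + n_win - 1L)

  pre <- max(1L, start - as.integer(0.5 * rec$rate)):(max(start - 1L, 1L))
  if (start == 1L) pre <- 1:min(n, as.integer(0.5 * rec$rate))
  facc <- apply(rec$acc, 2, lowpass_filter, window = min(filter_window, length(pre)))
  gdir <- colMeans(facc[pre, , drop = FALSE])
  gn <- sqrt(sum(gdir^2))
  gravity_axis <- if (gn < 1e-9) c(NA_real_, NA_real_, NA_real_) else gdir / gn

  structure(list(
    acc = rec$acc[idx, , drop = FALSE],
    gyr = if (!is.null(rec$gyr)) rec$gyr[idx, , drop = FALSE],
    mag = if (!is.null(rec$mag)) rec$mag[idx, , drop = FALSE],
    t = rec$t[idx], rate = rec$rate, indices = idx,
    gravity_axis = gravity_axis,
    subject_id = rec$subject_id, activity = rec$activity
  ), class = "event_slices")
}

#' Vertical movement decomposition (VA, VV, VD)
#'
#' Projects the accelerometer window onto the estimated gravity axis, removes
#' the static 1 g, and integrates twice (cumulative trapezoid) to obtain
#' vertical velocity and displacement, both starting at zero.
#'
#' @param acc n x 3 accelerometer window (g).
#' @param gravity_axis unit 3-vector estimating the gravity direction in the
#'   body frame (see [extract_window()]).
#' @param rate sampling rate (Hz).
#' @return list with `VA` (g), `VV` (m/s), `VD` (m).
#' @export
vertical_decomposition <- function(acc, gravity_axis, rate) {
  gn <- sqrt(sum(gravity_axis^2))
  if (!is.finite(gn) || gn < 1e-9)
    stop_wf("decomposition", "zero-norm gravity estimate")
  g <- gravity_axis / gn
  VA <- as.numeric(acc %*% g) - 1
  dt <- 1 / rate
  VV <- pracma::cumtrapz(seq_along(VA) * dt, VA * STANDARD_GRAVITY)[, 1]
  VD <- pracma::cumtrapz(seq_along(VV) * dt, VV)[, 1]
  list(VA = VA, VV = VV, VD = VD)
}

#' Euler angles from accelerometer and magnetometer samples
#'
#' Pitch and roll come from the accelerometer tilt; yaw from the
#' tilt-compensated magnetometer (ZYX convention, body -> world rotation
#' `Rz(yaw) Ry(pitch) Rx(roll)`). Samples with |pitch| > 89.9 degrees are
#' flagged as gimbal-proximal (angles still returned).
#'
#' @param acc n x 3 (or length-3) accelerometer sample(s), g.
#' @param mag n x 3 (or length-3) magnetometer sample(s), Gauss.
#' @return n x 3 matrix with columns `yaw`, `pitch`, `roll` (radians) and a
#'   logical attribute `gimbal` per sample.
#' @export
euler_from_acc_mag <- function(acc, mag) {
  if (is.null(dim(acc))) acc <- matrix(acc, 1)
  if (is.null(dim(mag))) mag <- matrix(mag, 1)
  if (any(sqrt(rowSums(acc^2)) < 1e-9))
    stop_wf("argument", "zero-norm accelerometer sample")
  if (any(sqrt(rowSums(mag^2)) < 1e-9))
    stop_wf("argument", "zero-norm magnetometer sample")
  ax <- acc[, 1]; ay <- acc[, 2]; az <- acc[, 3]
  pitch <- atan2(-ax, sqrt(ay^2 + az^2))
  roll <- atan2(ay, az)
  # de-rotate the magnetometer by roll then pitch, then read yaw in the
  # horizontal plane
  cr <- cos(roll); sr <- sin(roll)
  v1 <- mag[, 1]
  v2 <- cr * mag[, 2] - sr * mag[, 3]
  v3 <- sr * mag[, 2] + cr * mag[, 3]
  cp <- cos(pitch); sp <- sin(pitch)
  h1 <- cp * v1 + sp * v3
  h2 <- v2
  yaw <- atan2(-h2, h1)
  out <- cbind(yaw = yaw, pitch = pitch, roll = roll)
  attr(out, "gimbal") <- abs(pitch) > 89.9 * pi / 180
  out
}

#' Build the scenario feature vector of an event window
#'
#' Scenario A concatenates the raw per-axis series of the selected sensors;
#' `B_VERT` concatenates VA || VV || VD; `B_EULER` concatenates
#' yaw || pitch || roll; `B_VERT_EULER` both. The vector is L2-normalized.
#'
#' @param slices an `event_slices` object from [extract_window()].
#' @param scenario scenario code (see [scenario_sensors()]).
#' @return an `event_window` list: `x` (unit-norm feature vector), `label`
#'   (`FALL`/`ADL`), `scenario`, `subject_id`, `activity`.
#' @export
build_features <- function(slices, scenario) {
  scenario <- match.arg(scenario, SCENARIOS)
  for (s in scenario_sensors(scenario))
    if (is.null(slices[[s]]))
      stop_wf("missing_sensor", "scenario %s requires the %s sensor",
              scenario, s)
  x <- switch(scenario,
    A_ACC = as.numeric(slices$acc),
    A_ACC_GYR = c(as.numeric(slices$acc), as.numeric(slices$gyr)),
    A_ACC_GYR_MAG = c(as.numeric(slices$acc), as.numeric(slices$gyr),
                      as.numeric(slices$mag)),
    B_VERT = {
      v <- vertical_decomposition(slices$acc, slices$gravity_axis, slices$rate)
      c(v$VA, v$VV, v$VD)
    },
    B_EULER = as.numeric(euler_from_acc_mag(slices$acc, slices$mag)),
    B_VERT_EULER = {
      v <- vertical_decomposition(slices$acc, slices$gravity_axis, slices$rate)
      c(v$VA, v$VV, v$VD,
        as.numeric(euler_from_acc_mag(slices$acc, slices$mag)))
    })
  if (!all(is.finite(x))) stop_wf("format", "non-finite feature values")
  nx <- sqrt(sum(x^2))
  if (nx < 1e-12) stop_wf("format", "zero feature vector")
  act <- slices$activity
  structure(list(x = x / nx,
                 label = if (is.na(act)) NA_character_ else binary_label(act),
                 scenario = scenario, subject_id = slices$subject_id,
                 activity = act),
            class = "event_window")
}

#' Feature matrix for a set of recordings
#'
#' Runs [extract_window()] + [build_features()] over each recording (one
#' window per recording, as the protocol records one event per recording).
#'
#' @param recordings list of [sensor_recording()]s (e.g. from
#'   [simulate_recordings()] or [load_dataset()]).
#' @param scenario scenario code.
#' @param duration window length (s).
#' @return list with `X` (d x n feature matrix, unit-norm columns), `labels`,
#'   `subjects`, `activities`, `scenario`.
#' @export
build_feature_matrix <- function(recordings, scenario, duration = 4) {
  wins <- lapply(recordings, function(r)
    build_features(extract_window(r, duration), scenario))
  list(X = vapply(wins, `[[`, numeric(length(wins[[1]]$x)), "x"),
       labels = vapply(wins, `[[`, "", "label"),
       subjects = vapply(wins, `[[`, "", "subject_id"),
       activities = vapply(wins, `[[`, "", "activity"),
       scenario = scenario)
}
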