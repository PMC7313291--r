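# Synthetic wrist-IMU event generator.
#
# Each event is driven by an internal ground-truth orientation track
# (yaw/pitch/roll over time) and a prescribed body-frame linear acceleration.
# Accelerometer, gyroscope and magnetometer streams are synthesized
# consistently from that track:
#   acc = R(t)' * g_world + body_acc + noise          (g)
#   gyr = d(euler)/dt + noise                          (deg/s)
#   mag = R(t)' * earth_field + noise                  (Gauss)
# with R = Rz(yaw) Ry(pitch) Rx(roll) (body -> world, ZYX convention) and a
# fixed Earth field of 0.4 Gs horizontal + 0.3 Gs vertical. The true track is
# attached to each recording (attr "truth") so orientation and vertical
# features can be verified against known ground truth.

EARTH_FIELD <- c(0.4, 0, 0.3)

#' Simulation configuration
#'
#' Defaults emulate the acquisition protocol the package targets: 22 subjects,
#' 100 Hz sampling, events of ~9.2 s that begin with a resting arm followed by
#' a few steps, falls with one high-magnitude impact transient plus a
#' sustained orientation change, ADLs as periodic or step-like low-energy arm
#' motion.
#'
#' @param n_subjects number of simulated volunteers.
#' @param activities subset of [activity_levels()].
#' @param rate sampling rate (Hz).
#' @param mean_duration mean event duration (s); per-event jitter is +-10%
#'   and per-subject timing scale +-5%.
#' @param rest_prefix initial resting-arm segment (s).
#' @param impact_peak_range range (g) of the fall-impact half-sine peak.
#' @param gait_amplitude walking-oscillation amplitude (g).
#' @param noise_sd list of per-sensor Gaussian noise SDs:
#'   `acc` (g), `gyr` (deg/s), `mag` (Gauss).
#' @param fall_reps,adl_reps repetitions per subject of each fall / ADL
#'   activity (defaults give ~400 windows per binary class at 22 subjects).
#' @param seed integer; fully determines every simulated sample.
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(n_subjects = 22, activities = activity_levels(),
                              rate = 100, mean_duration = 9.2,
                              rest_prefix = 2,
                              impact_peak_range = c(2.6, 3.6),
                              gait_amplitude = 0.35,
                              noise_sd = list(acc = 0.02, gyr = 1, mag = 0.005),
                              fall_reps = 3, adl_reps = 4, seed = 1) {
  stopifnot(rate > 0, mean_duration > rest_prefix, rest_prefix >= 0,
            n_subjects >= 1, fall_reps >= 1, adl_reps >= 1)
  if (max(impact_peak_range) > SENSOR_RANGES$acc)
    stop_wf("argument", "impact peak must be <= %g g", SENSOR_RANGES$acc)
  bad <- setdiff(activities, activity_levels())
  if (length(bad)) stop_wf("argument", "unknown activities: %s",
                           paste(bad, collapse = ", "))
  structure(list(n_subjects = n_subjects, activities = activities,
                 rate = rate, mean_duration = mean_duration,
                 rest_prefix = rest_prefix,
                 impact_peak_range = impact_peak_range,
                 gait_amplitude = gait_amplitude, noise_sd = noise_sd,
                 fall_reps = fall_reps, adl_reps = adl_reps,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

# smoothstep ramp 0 -> 1 on [t0, t1]
smoothstep <- function(t, t0, t1) {
  u <- pmin(pmax((t - t0) / (t1 - t0), 0), 1)
  u * u * (3 - 2 * u)
}

# symmetric bump 0 -> 1 -> 0 on [t0, t1] with plateau fraction `hold`
bump <- function(t, t0, t1, hold = 0.3) {
  ramp <- (1 - hold) / 2 * (t1 - t0)
  smoothstep(t, t0, t0 + ramp) * (1 - smoothstep(t, t1 - ramp, t1))
}

half_sine <- function(t, t0, dur, peak) {
  inside <- t >= t0 & t <= t0 + dur
  out <- numeric(length(t))
  out[inside] <- peak * sin(pi * (t[inside] - t0) / dur)
  out
}

#' Simulate a single labeled wrist-IMU event
#'
#' Falls contain exactly one impact transient (half-sine burst of 0.1-0.3 s,
#' directed along the instantaneous gravity axis) followed by a sustained
#' change of the gravity direction of >= 60 degrees. ADLs are periodic or
#' step-like patterns whose body-acceleration peak stays below 2.5 g and whose
#' orientation returns near its starting point.
#'
#' @param activity an activity code.
#' @param cfg a [simulation_config()].
#' @param seed optional integer; when given, output is a pure function of
#'   `(activity, cfg, seed, scales)`.
#' @param subject_id identifier stamped on the recording.
#' @param amp_scale,time_scale per-subject amplitude / timing factors.
#' @return a [sensor_recording()] carrying an attribute `truth` with the
#'   ground-truth Euler track (rad), body acceleration (g), body-frame gravity
#'   direction and, for falls, the impact time (s).
#' @export
simulate_event <- function(activity, cfg = simulation_config(), seed = NULL,
                           subject_id = "S01", amp_scale = 1, time_scale = 1) {
  if (!activity %in% activity_levels())
    stop_wf("argument", "unknown activity '%s'", activity)
  if (!is.null(seed)) return(with_seed(seed, simulate_event(
    activity, cfg, NULL, subject_id, amp_scale, time_scale)))

  rate <- cfg$rate
  dur <- cfg$mean_duration * time_scale * stats::runif(1, 0.9, 1.1)
  dur <- max(dur, cfg$rest_prefix + 4.5)
  n <- round(dur * rate)
  t <- seq(0, by = 1 / rate, length.out = n)

  yaw <- rep(stats::runif(1, -0.3, 0.3), n)
  pitch <- rep(stats::runif(1, -0.12, 0.12), n)
  roll <- rep(stats::runif(1, -0.12, 0.12), n)
  body <- matrix(0, n, 3)
  impact_time <- NA_real_

  gait_f <- stats::runif(1, 1.7, 2.2)
  gait_amp <- cfg$gait_amplitude * amp_scale
  add_gait <- function(from, to, amp = gait_amp) {
    seg <- t >= from & t <= to
    ph <- 2 * pi * gait_f * t[seg] + stats::runif(1, 0, 2 * pi)
    env <- smoothstep(t[seg], from, from + 0.4) *
      (1 - smoothstep(t[seg], to - 0.4, to))
    body[seg, 1] <<- body[seg, 1] + amp * env * sin(ph)
    body[seg, 3] <<- body[seg, 3] + 0.5 * amp * env * sin(2 * ph)
    pitch[seg] <<- pitch[seg] + 0.05 * env * sin(ph)
  }

  if (is_fall_activity(activity)) {
    t_imp <- dur * stats::runif(1, 0.55, 0.72)
    impact_time <- t_imp
    add_gait(cfg$rest_prefix, t_imp - 0.5)
    jit <- function() stats::runif(1, -0.09, 0.09)
    d75 <- 75 * pi / 180
    delta <- switch(activity,
      FALL_FORWARD  = c(0, -d75 + jit(), jit()),
      FALL_BACKWARD = c(0,  d75 + jit(), jit()),
      FALL_RIGHT    = c(0, jit(),  d75 + jit()),
      FALL_LEFT     = c(0, jit(), -d75 + jit()),
      FALL_ROT_CW   = c( 1.75, -65 * pi / 180 + jit(), 0.5),
      FALL_ROT_CCW  = c(-1.75, -65 * pi / 180 + jit(), -0.5))
    s <- smoothstep(t, t_imp - 0.15, t_imp + 0.35)
    yaw <- yaw + delta[1] * s
    pitch <- pitch + delta[2] * s
    roll <- roll + delta[3] * s
    # impact burst along the instantaneous gravity axis (ground reaction)
    d_imp <- stats::runif(1, 0.1, 0.3)
    peak <- min(stats::runif(1, cfg$impact_peak_range[1],
                             cfg$impact_peak_range[2]) * amp_scale, 3.95)
    i_imp <- which.min(abs(t - t_imp))
    gdir <- c(-sin(pitch[i_imp]), cos(pitch[i_imp]) * sin(roll[i_imp]),
              cos(pitch[i_imp]) * cos(roll[i_imp]))
    gdir <- gdir + stats::runif(3, -0.15, 0.15)
    gdir <- gdir / sqrt(sum(gdir^2))
    burst <- half_sine(t, t_imp - d_imp / 2, d_imp, peak)
    body <- body + outer(burst, gdir)
  } else {
    t_act <- cfg$rest_prefix + stats::runif(1, 1, 2)
    if (activity == "ADL_WALK") {
      add_gait(cfg$rest_prefix, dur - 0.3, amp = gait_amp * 1.2)
    } else {
      add_gait(cfg$rest_prefix, t_act)
      t_end <- dur - 0.5
      if (activity == "ADL_CLAP") {
        clap_amp <- stats::runif(1, 1.0, 1.6) * amp_scale
        ct <- seq(t_act + 0.3, min(t_act + 3.5, t_end), by = 1 / 3)
        sgn <- 1
        for (tc in ct) {
          body[, 2] <- body[, 2] + sgn * half_sine(t, tc, 0.06, clap_amp)
          sgn <- -sgn
        }
        roll <- roll + 0.1 * bump(t, t_act, min(t_act + 3.8, t_end))
      } else if (activity == "ADL_MOVE_OBJECT") {
        for (tc in c(t_act + 0.2, (t_act + t_end) / 2)) {
          a <- stats::runif(1, 0.6, 0.9) * amp_scale
          body[, 1] <- body[, 1] + half_sine(t, tc, 0.8, a)
          body[, 3] <- body[, 3] - half_sine(t, tc + 0.9, 0.8, a * 0.7)
        }
        roll <- roll + 0.4 * bump(t, t_act, t_end)
      } else if (activity == "ADL_TIE_SHOES") {
        pitch <- pitch - 0.9 * bump(t, t_act, t_end, hold = 0.5)
        body[, 1] <- body[, 1] + half_sine(t, t_act, 0.8, 0.3 * amp_scale) -
          half_sine(t, t_end - 0.8, 0.8, 0.3 * amp_scale)
      } else if (activity == "ADL_SIT") {
        t_sit <- t_act + 0.5
        a <- stats::runif(1, 0.5, 0.9) * amp_scale
        body[, 3] <- body[, 3] - half_sine(t, t_sit, 0.6, a) +
          half_sine(t, t_sit + 0.65, 0.5, a * 0.6)
        pitch <- pitch + 0.15 * bump(t, t_act, t_act + 2)
      }
    }
  }

  # synthesize sensors from the truth track
  g_b <- cbind(-sin(pitch), cos(pitch) * sin(roll), cos(pitch) * cos(roll))
  cy <- cos(yaw); sy <- sin(yaw)
  v1 <- cy * EARTH_FIELD[1]; v2 <- -sy * EARTH_FIELD[1]; v3 <- EARTH_FIELD[3]
  cp <- cos(pitch); sp <- sin(pitch)
  w1 <- cp * v1 - sp * v3; w2 <- v2; w3 <- sp * v1 + cp * v3
  cr <- cos(roll); sr <- sin(roll)
  m_b <- cbind(w1, cr * w2 + sr * w3, -sr * w2 + cr * w3)
  eul <- cbind(yaw = yaw, pitch = pitch, roll = roll)
  gyr_true <- rbind(0, diff(eul)) * rate * 180 / pi
  nz <- function(sd) if (sd > 0) matrix(stats::rnorm(3 * n, 0, sd), n, 3) else 0

  acc <- g_b + body + nz(cfg$noise_sd$acc)
  gyr <- gyr_true[, c(3, 2, 1), drop = FALSE] + nz(cfg$noise_sd$gyr)
  mag <- m_b + nz(cfg$noise_sd$mag)

  rec <- sensor_recording(acc, gyr, mag, rate = rate, subject_id = subject_id,
                          activity = activity)
  attr(rec, "truth") <- list(euler = eul, body_acc = body,
                             gravity_body = g_b, impact_time = impact_time)
  rec
}

#' Simulate a full in-memory dataset
#'
#' One recording per (subject, activity, repetition). Per-subject amplitude
#' and timing scale factors are drawn once per subject from the seeded stream,
#' emulating volunteers of different builds.
#'
#' @param cfg a [simulation_config()].
#' @return list of recordings (see [simulate_event()]).
#' @export
simulate_recordings <- function(cfg = simulation_config()) {
  recs <- list()
  for (s in seq_len(cfg$n_subjects)) {
    scales <- with_seed(mix_seed(cfg$seed, s, 0),
                        c(stats::runif(1, 0.85, 1.15), stats::runif(1, 0.95, 1.05)))
    sid <- sprintf("S%02d", s)
    for (ai in seq_along(cfg$activities)) {
      act <- cfg$activities[ai]
      reps <- if (is_fall_activity(act)) cfg$fall_reps else cfg$adl_reps
      for (r in seq_len(reps)) {
        recs[[length(recs) + 1L]] <- simulate_event(
          act, cfg, seed = mix_seed(cfg$seed, s, ai * 101 + r),
          subject_id = sid, amp_scale = scales[1], time_scale = scales[2])
      }
    }
  }
  recs
}

#' Simulate a dataset and write it to disk
#'
#' @param cfg a [simulation_config()].
#' @param dir output directory (created if needed); recordings are written as
#'   CSV plus a `manifest.csv` in the [read_manifest()] format.
#' @return the `dataset_manifest`, invisibly.
#' @export
simulate_dataset <- function(cfg = simulation_config(), dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  recs <- simulate_recordings(cfg)
  files <- character(length(recs))
  counter <- new.env()
  for (i in seq_along(recs)) {
    rec <- recs[[i]]
    key <- paste(rec$subject_id, rec$activity, sep = "_")
    k <- (get0(key, counter) %||% 0L) + 1L
    assign(key, k, counter)
    files[i] <- sprintf("%s_%s_r%d.csv", rec$subject_id, rec$activity, k)
    write_recording(rec, file.path(dir, files[i]))
  }
  mf <- data.frame(file = files,
                   subject_id = vapply(recs, `[[`, "", "subject_id"),
                   activity = vapply(recs, `[[`, "", "activity"),
                   stringsAsFactors = FALSE)
  write_manifest(mf, file.path(dir, "manifest.csv"))
  invisible(read_manifest(file.path(dir, "manifest.csv")))
}
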