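# Synthetic recordings: a scripted scanpath (fixations, minimum-jerk
# saccades, pursuit, gaps) rendered into the packet dialect with known
# ground truth, so the whole pipeline is testable without hardware.
# Saccades use a minimum-jerk displacement profile because its peak
# velocity has the closed form 1.875 * amplitude / duration, giving exact
# oracles; this is a convenience, not a claim about real saccade dynamics.

#' Scanpath episode constructors
#'
#' Episodes compose a [wg_script()]. A fixation holds a target orientation
#' (optionally with one eye's packets dropped to emulate monocular loss); a
#' saccade moves to a target with a minimum-jerk profile; pursuit drifts
#' azimuth at constant speed; a gap deletes all gaze packets for its span.
#'
#' @param duration_ms Episode duration in milliseconds.
#' @param theta,phi Target azimuth / elevation in degrees.
#' @param eyes `"both"`, `"left"` or `"right"`: which eyes deliver data.
#' @param velocity_dps Pursuit speed in deg/s (azimuth drift).
#' @return A list describing the episode.
#' @export
ep_fixation <- function(duration_ms, theta = 0, phi = 0, eyes = "both")
  list(kind = "fixation", duration_ms = duration_ms, theta = theta,
       phi = phi, eyes = eyes)

#' @rdname ep_fixation
#' @export
ep_saccade <- function(duration_ms, theta, phi = 0)
  list(kind = "saccade", duration_ms = duration_ms, theta = theta, phi = phi,
       eyes = "both")

#' @rdname ep_fixation
#' @export
ep_pursuit <- function(duration_ms, velocity_dps)
  list(kind = "pursuit", duration_ms = duration_ms,
       velocity_dps = velocity_dps, eyes = "both")

#' @rdname ep_fixation
#' @export
ep_gap <- function(duration_ms)
  list(kind = "gap", duration_ms = duration_ms, eyes = "none")

#' Scanpath script for the synthetic generator
#'
#' @param episodes Ordered list of episodes built with [ep_fixation()] and
#'   friends.
#' @param noise_sd Per-eye iid Gaussian orientation noise in degrees:
#'   one value for both axes, or `c(azimuth, elevation)` (default 0.1, a
#'   realistic wearable-tracker precision).
#' @param rate_hz Nominal gaze rate, 50 or 100 Hz.
#' @param ttl_times TTL pulse times in seconds (e.g. button presses).
#' @param segment_split_s Optional time at which the recording is split
#'   into two on-disk segments, emulating the device's splitting of long
#'   recordings.
#' @param seed RNG seed; identical script + seed gives a byte-identical
#'   output tree.
#' @param calibration_status Written into the recording metadata.
#' @return A `wg_script`.
#' @export
wg_script <- function(episodes, noise_sd = 0.1, rate_hz = 50,
                      ttl_times = numeric(), segment_split_s = NULL,
                      seed = 1L, calibration_status = "calibrated") {
  if (!rate_hz %in% c(50, 100))
    wg_validation_error("rate_hz must be 50 or 100")
  if (length(episodes) == 0L ||
      any(vapply(episodes, `[[`, 0, "duration_ms") <= 0))
    wg_validation_error("episodes must be non-empty with positive durations")
  if (any(noise_sd < 0) || !length(noise_sd) %in% 1:2)
    wg_validation_error(
      "noise_sd must be non-negative (one value, or c(azimuth, elevation))")
  structure(list(episodes = episodes, noise_sd = noise_sd,
                 rate_hz = rate_hz, ttl_times = ttl_times,
                 segment_split_s = segment_split_s, seed = as.integer(seed),
                 calibration_status = calibration_status),
            class = "wg_script")
}

# minimum-jerk displacement fraction, s(0)=0, s(1)=1, peak ds/dtau = 1.875
.minjerk <- function(tau) 10 * tau^3 - 15 * tau^4 + 6 * tau^5

# noiseless trajectory + per-sample ground truth from a script
.script_truth <- function(script) {
  rate <- script$rate_hz
  dt <- 1 / rate
  th <- ph <- numeric(); lab <- eyes <- character()
  cur_th <- cur_ph <- 0
  # start at the first positional target so the trace opens on-target
  for (e in script$episodes)
    if (e$kind %in% c("fixation", "saccade")) {
      cur_th <- e$theta; cur_ph <- e$phi; break
    }
  for (e in script$episodes) {
    n <- max(1L, round(e$duration_ms / 1000 * rate))
    if (e$kind == "fixation") {
      cur_th <- e$theta; cur_ph <- e$phi
      th <- c(th, rep(cur_th, n)); ph <- c(ph, rep(cur_ph, n))
      lab <- c(lab, rep("slow", n))
    } else if (e$kind == "saccade") {
      tau <- (seq_len(n) - 1L) / n
      s <- .minjerk(tau)
      th <- c(th, cur_th + (e$theta - cur_th) * s)
      ph <- c(ph, cur_ph + (e$phi - cur_ph) * s)
      cur_th <- e$theta; cur_ph <- e$phi
      lab <- c(lab, rep("fast", n))
    } else if (e$kind == "pursuit") {
      drift <- e$velocity_dps * dt * (seq_len(n) - 1L)
      th <- c(th, cur_th + drift); ph <- c(ph, rep(cur_ph, n))
      cur_th <- cur_th + e$velocity_dps * dt * n
      lab <- c(lab, rep("slow", n))
    } else {                                   # gap
      th <- c(th, rep(NA_real_, n)); ph <- c(ph, rep(NA_real_, n))
      lab <- c(lab, rep("missing", n))
    }
    eyes <- c(eyes, rep(e$eyes, n))
  }
  data.frame(t = (seq_along(th) - 1L) * dt, theta = th, phi = ph,
             label = lab, eyes = eyes, stringsAsFactors = FALSE)
}

# render one eye's noisy packets for the present samples
.eye_packets <- function(truth, present, eye_on, eye, ts_us, noise_sd,
                         pupil_mm) {
  sel <- present & eye_on
  n <- sum(sel)
  if (n == 0L) return(.empty_packets())
  th <- truth$theta[sel] + stats::rnorm(n, 0, noise_sd[1L])
  ph <- truth$phi[sel] + stats::rnorm(n, 0, noise_sd[length(noise_sd)])
  gd <- fick_compose(th, ph)
  pcx <- if (eye == "left") -30 else 30
  pd <- pupil_mm + stats::rnorm(n, 0, 0.02)
  gidx <- which(sel) - 1L
  rbind(
    data.frame(ts = ts_us[sel], status = 0L, kind = "gaze_dir", eye = eye,
               gidx = gidx, p1 = gd[, 1L], p2 = gd[, 2L], p3 = gd[, 3L],
               stringsAsFactors = FALSE),
    data.frame(ts = ts_us[sel], status = 0L, kind = "pupil_center",
               eye = eye, gidx = gidx, p1 = pcx, p2 = 0, p3 = -20,
               stringsAsFactors = FALSE),
    data.frame(ts = ts_us[sel], status = 0L, kind = "pupil_diameter",
               eye = eye, gidx = gidx, p1 = pd, p2 = NA_real_,
               p3 = NA_real_, stringsAsFactors = FALSE)
  )
}

#' Generate a complete synthetic recording tree
#'
#' Renders the script into a full project tree
#' (`<project>/<recording>/segments/<k>/livedata.json.gz` plus
#' `segment.json` and `recording.json`) in the packet dialect, and returns
#' the ground truth needed for oracle comparisons: the noiseless per-sample
#' orientation and the true slow/fast/missing event stream.
#'
#' @param script A [wg_script()].
#' @param out_dir Directory in which the project tree is created.
#' @return A list: `rec_dir` (the recording directory), `truth`
#'   (data.frame `t`, `theta`, `phi`, `label`, `eyes`), `ground_truth`
#'   (an `event_stream`), `loss_fraction` (scripted gap fraction),
#'   `project_id`, `recording_id`.
#' @export
generate_recording <- function(script, out_dir) {
  stopifnot(inherits(script, "wg_script"))
  set.seed(script$seed)
  rate <- script$rate_hz
  dt_us <- 1e6 / rate
  truth <- .script_truth(script)
  n <- nrow(truth)
  ts0 <- 1e6
  ts_us <- ts0 + (seq_len(n) - 1L) * dt_us
  present <- truth$label != "missing"

  gaze_pk <- rbind(
    .eye_packets(truth, present, truth$eyes %in% c("both", "left"),
                 "left", ts_us, script$noise_sd, 3),
    .eye_packets(truth, present, truth$eyes %in% c("both", "right"),
                 "right", ts_us, script$noise_sd, 3.1)
  )
  # binocular video-gaze point and 3D gaze point from the noiseless trace
  sel <- present
  gidx <- which(sel) - 1L
  gd <- fick_compose(truth$theta[sel], truth$phi[sel])
  gp <- data.frame(ts = ts_us[sel], status = 0L, kind = "gaze_point_2d",
                   eye = "none", gidx = gidx,
                   p1 = pmin(1, pmax(0, 0.5 + truth$theta[sel] / 100)),
                   p2 = pmin(1, pmax(0, 0.5 - truth$phi[sel] / 100)),
                   p3 = NA_real_, stringsAsFactors = FALSE)
  gp3 <- data.frame(ts = ts_us[sel], status = 0L, kind = "gaze_point_3d",
                    eye = "none", gidx = gidx, p1 = 1000 * gd[, 1L],
                    p2 = 1000 * gd[, 2L], p3 = 1000 * gd[, 3L],
                    stringsAsFactors = FALSE)

  # IMU at its native 100 Hz, running through gaze gaps as hardware does
  dur_s <- n / rate
  nim <- floor(dur_s * 100)
  imu_ts <- ts0 + (seq_len(nim) - 1L) * 1e4
  gyro <- data.frame(ts = imu_ts, status = 0L, kind = "gyro", eye = "none",
                     gidx = NA_real_,
                     p1 = stats::rnorm(nim, 0, 0.5),
                     p2 = stats::rnorm(nim, 0, 0.5),
                     p3 = stats::rnorm(nim, 0, 0.5),
                     stringsAsFactors = FALSE)
  accel <- data.frame(ts = imu_ts, status = 0L, kind = "accel", eye = "none",
                      gidx = NA_real_,
                      p1 = stats::rnorm(nim, 0, 0.05),
                      p2 = -9.81 + stats::rnorm(nim, 0, 0.05),
                      p3 = stats::rnorm(nim, 0, 0.05),
                      stringsAsFactors = FALSE)
  ttl <- if (length(script$ttl_times))
    data.frame(ts = ts0 + round(script$ttl_times * 1e6), status = 0L,
               kind = "ttl", eye = "none", gidx = NA_real_, p1 = 1,
               p2 = NA_real_, p3 = NA_real_, stringsAsFactors = FALSE)
  else .empty_packets()

  pk <- rbind(gaze_pk, gp, gp3, gyro, accel, ttl)
  kind_rank <- match(pk$kind, c("gaze_dir", "pupil_center", "pupil_diameter",
                                "gaze_point_2d", "gaze_point_3d", "gyro",
                                "accel", "ttl", "vts"))
  eye_rank <- match(pk$eye, c("left", "right", "none"))
  pk <- pk[order(pk$ts, kind_rank, eye_rank), , drop = FALSE]

  # deterministic pseudo-random directory names, device-style
  rn <- function(k) paste(sample(letters, k, replace = TRUE), collapse = "")
  project_id <- rn(7L)
  recording_id <- rn(7L)
  rec_dir <- file.path(out_dir, project_id, recording_id)

  split_ts <- if (!is.null(script$segment_split_s))
    ts0 + script$segment_split_s * 1e6 else Inf
  seg_pks <- if (is.finite(split_ts))
    list(pk[pk$ts < split_ts, , drop = FALSE],
         pk[pk$ts >= split_ts, , drop = FALSE])
  else list(pk)
  seg_pks <- Filter(nrow, seg_pks)

  for (i in seq_along(seg_pks)) {
    sp <- seg_pks[[i]]
    seg_dir <- file.path(rec_dir, "segments", i)
    dir.create(seg_dir, recursive = TRUE, showWarnings = FALSE)
    # two video-timestamp pairs per segment: media time restarts per file
    vts <- data.frame(ts = c(sp$ts[1L], sp$ts[nrow(sp)]), status = 0L,
                      kind = "vts", eye = "none", gidx = NA_real_,
                      p1 = c(0, sp$ts[nrow(sp)] - sp$ts[1L]),
                      p2 = NA_real_, p3 = NA_real_, stringsAsFactors = FALSE)
    sp <- rbind(sp, vts)
    sp <- sp[order(sp$ts), , drop = FALSE]   # stable: vts sorts after peers
    write_segment(sp, file.path(seg_dir, "livedata.json.gz"))
    writeLines(jsonlite::toJSON(list(segment_index = i,
                                     nominal_rate_hz = rate,
                                     calibration_status =
                                       script$calibration_status),
                                auto_unbox = TRUE),
               file.path(seg_dir, "segment.json"), useBytes = TRUE)
  }

  meta <- list(project_id = project_id, project_name = "DemoProject",
               participant_id = "p01", participant_name = "Participant 1",
               recording_id = recording_id, recording_name = "Recording001",
               start_time = "2020-01-02T10:00:00Z",
               duration_s = dur_s,
               firmware_version = "synthetic-1.0",
               calibration_status = script$calibration_status)
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA),
             file.path(rec_dir, "recording.json"), useBytes = TRUE)

  r <- rle(truth$label)
  ends <- cumsum(r$lengths) / rate
  starts <- c(0, ends[-length(ends)])
  gt <- event_stream("ground_truth", c("slow", "fast", "missing"),
                     source = "classifier", duration_s = dur_s,
                     annotations = .ann_df(starts, ends, r$values))
  list(rec_dir = rec_dir, truth = truth, ground_truth = gt,
       loss_fraction = mean(truth$label == "missing"),
       project_id = project_id, recording_id = recording_id)
}

#' A ready-made demo script: visual search with button presses
#'
#' Five fixations separated by four saccades, with TTL button presses,
#' mirroring a search task (looking for targets, pressing a button on each
#' find). Used by the command-line `simulate` demo and the examples.
#'
#' @param rate_hz Sampling rate, 50 or 100 Hz.
#' @param noise_sd Orientation noise in degrees.
#' @param seed RNG seed.
#' @return A `wg_script`.
#' @export
demo_script <- function(rate_hz = 50, noise_sd = 0.1, seed = 1L) {
  wg_script(
    episodes = list(
      ep_fixation(1000, 0, 0),
      ep_saccade(50, 12, 2),
      ep_fixation(800, 12, 2),
      ep_saccade(50, -8, -4),
      ep_fixation(900, -8, -4),
      ep_saccade(50, 5, 8),
      ep_fixation(700, 5, 8),
      ep_saccade(50, -3, -6),
      ep_fixation(1000, -3, -6)
    ),
    noise_sd = noise_sd, rate_hz = rate_hz,
    ttl_times = c(1.5, 2.9, 4.1), seed = seed
  )
}
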