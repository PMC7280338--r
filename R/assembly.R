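# From raw packets to a synchronized, regularized recording. Gaze samples are
# snapped to the exact grid t0 + k/rate (nearest tick, ties to the earlier
# tick); unoccupied ticks become explicit "missing" samples so the sampling
# interval is preserved exactly. IMU streams keep their native timestamps.

.gaze_kinds <- c("gaze_dir", "pupil_center", "pupil_diameter",
                 "gaze_point_2d", "gaze_point_3d")

.sample_cols <- function() {
  c("ts_us",
    "l_gd_x", "l_gd_y", "l_gd_z", "l_az", "l_el", "l_pd",
    "l_pc_x", "l_pc_y", "l_pc_z", "l_valid",
    "r_gd_x", "r_gd_y", "r_gd_z", "r_az", "r_el", "r_pd",
    "r_pc_x", "r_pc_y", "r_pc_z", "r_valid",
    "gp_x", "gp_y", "gp3_x", "gp3_y", "gp3_z", "binocularity", "filled")
}

.empty_samples <- function(n = 0L) {
  df <- data.frame(matrix(NA_real_, n, length(.sample_cols())))
  names(df) <- .sample_cols()
  df$l_valid <- df$r_valid <- rep(FALSE, n)
  df$binocularity <- rep("missing", n)
  df$filled <- rep(FALSE, n)
  df
}

# first occurrence per gidx for one (kind, eye); conflicting duplicates keep
# the first in file order
.first_per_gidx <- function(pk, kind, eye = NULL) {
  sel <- pk$kind == kind & !is.na(pk$gidx)
  if (!is.null(eye)) sel <- sel & pk$eye == eye
  sub <- pk[sel, , drop = FALSE]
  sub[!duplicated(sub$gidx), , drop = FALSE]
}

#' Group gaze packets into per-sample gaze data
#'
#' Packets sharing a gaze-sample group index (`gidx`) are merged into one
#' sample. An eye is valid iff its gaze direction, pupil center and pupil
#' diameter packets are all present with status 0. Binocularity follows from
#' the two per-eye validity flags: both valid is binocular, one is
#' monocular, neither is missing. The sample timestamp is the timestamp of
#' the group's gaze-direction packet(s), the earlier one if the eyes differ.
#'
#' @param packets A packet data.frame (see [read_segment()]).
#' @return An irregular gaze sample data.frame (column `ts_us` plus per-eye
#'   direction, Fick angles, pupil fields, validity, the binocular video
#'   gaze point and `binocularity`), sorted by time.
#' @export
group_gaze_packets <- function(packets) {
  pk <- packets[packets$kind %in% .gaze_kinds & !is.na(packets$gidx), ,
                drop = FALSE]
  if (nrow(pk) == 0L) return(.empty_samples())
  gidx <- sort(unique(pk$gidx))
  n <- length(gidx)
  out <- .empty_samples(n)

  parts <- list(
    l_gd = .first_per_gidx(pk, "gaze_dir", "left"),
    r_gd = .first_per_gidx(pk, "gaze_dir", "right"),
    l_pc = .first_per_gidx(pk, "pupil_center", "left"),
    r_pc = .first_per_gidx(pk, "pupil_center", "right"),
    l_pd = .first_per_gidx(pk, "pupil_diameter", "left"),
    r_pd = .first_per_gidx(pk, "pupil_diameter", "right"),
    gp   = .first_per_gidx(pk, "gaze_point_2d"),
    gp3  = .first_per_gidx(pk, "gaze_point_3d")
  )
  ix <- lapply(parts, function(p) match(gidx, p$gidx))

  put3 <- function(part, idx, cols) {
    m <- matrix(NA_real_, n, length(cols))
    ok <- !is.na(idx)
    m[ok, ] <- as.matrix(part[idx[ok], c("p1", "p2", "p3")[seq_along(cols)]])
    out[cols] <<- m
  }
  put3(parts$l_gd, ix$l_gd, c("l_gd_x", "l_gd_y", "l_gd_z"))
  put3(parts$r_gd, ix$r_gd, c("r_gd_x", "r_gd_y", "r_gd_z"))
  put3(parts$l_pc, ix$l_pc, c("l_pc_x", "l_pc_y", "l_pc_z"))
  put3(parts$r_pc, ix$r_pc, c("r_pc_x", "r_pc_y", "r_pc_z"))
  put3(parts$gp,   ix$gp,   c("gp_x", "gp_y"))
  put3(parts$gp3,  ix$gp3,  c("gp3_x", "gp3_y", "gp3_z"))
  out$l_pd <- ifelse(is.na(ix$l_pd), NA_real_, parts$l_pd$p1[ix$l_pd])
  out$r_pd <- ifelse(is.na(ix$r_pd), NA_real_, parts$r_pd$p1[ix$r_pd])

  st <- function(part, idx) ifelse(is.na(idx), NA_integer_,
                                   part$status[idx])
  for (e in c("l", "r")) {
    v <- !is.na(ix[[paste0(e, "_gd")]]) &
         st(parts[[paste0(e, "_gd")]], ix[[paste0(e, "_gd")]]) == 0L &
         !is.na(ix[[paste0(e, "_pc")]]) &
         st(parts[[paste0(e, "_pc")]], ix[[paste0(e, "_pc")]]) == 0L &
         !is.na(ix[[paste0(e, "_pd")]]) &
         st(parts[[paste0(e, "_pd")]], ix[[paste0(e, "_pd")]]) == 0L
    v[is.na(v)] <- FALSE
    out[[paste0(e, "_valid")]] <- v
    # Fick angles only for valid eyes; renormalize against encoding rounding
    gd <- as.matrix(out[, paste0(e, c("_gd_x", "_gd_y", "_gd_z"))])
    nrm <- sqrt(rowSums(gd^2))
    usable <- v & is.finite(nrm) & nrm > 1e-6
    if (any(usable)) {
      fa <- fick_decompose(gd[usable, , drop = FALSE] / nrm[usable])
      out[[paste0(e, "_az")]][usable] <- fa$theta
      out[[paste0(e, "_el")]][usable] <- fa$phi
    }
    out[[paste0(e, "_valid")]] <- usable
    # invalid eyes expose no values downstream
    bad <- !usable
    out[bad, paste0(e, c("_az", "_el", "_pd"))] <- NA_real_
  }
  out$binocularity <- ifelse(out$l_valid & out$r_valid, "binocular",
                      ifelse(out$l_valid, "monocular_left",
                      ifelse(out$r_valid, "monocular_right", "missing")))

  # sample timestamp: gaze_dir packet ts, earliest across eyes; if a group
  # has no gaze_dir packet, the earliest packet in the group stands in
  ts_l <- ifelse(is.na(ix$l_gd), Inf, parts$l_gd$ts[ix$l_gd])
  ts_r <- ifelse(is.na(ix$r_gd), Inf, parts$r_gd$ts[ix$r_gd])
  ts <- pmin(ts_l, ts_r)
  if (any(!is.finite(ts))) {
    mn <- tapply(pk$ts, pk$gidx, min)
    ts[!is.finite(ts)] <- as.numeric(mn[as.character(gidx[!is.finite(ts)])])
  }
  out$ts_us <- ts
  out <- out[order(out$ts_us), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Infer the nominal gaze sampling rate
#'
#' The nominal rate is the member of \{50, 100\} Hz nearest to
#' `1 / median(dt)` over the irregular sample times; the median makes the
#' estimate robust to timestamp jitter. A warning is raised when the
#' empirical rate deviates from the chosen nominal rate by more than 10%.
#'
#' @param samples Irregular gaze samples from [group_gaze_packets()].
#' @return Integer rate in Hz (50 or 100).
#' @export
infer_rate <- function(samples) {
  if (nrow(samples) < 10L)
    wg_parse_error("too short: need at least 10 gaze samples to infer rate")
  dt <- diff(samples$ts_us) / 1e6
  dt <- dt[dt > 0]
  emp <- 1 / stats::median(dt)
  rates <- c(50L, 100L)
  rate <- rates[which.min(abs(rates - emp))]
  if (abs(emp - rate) / rate > 0.1)
    warning(sprintf(
      "empirical rate %.1f Hz is far from nominal %d Hz", emp, rate))
  rate
}

#' Snap gaze samples to the nominal grid and fill gaps
#'
#' Output timestamps form the exact grid `t0 + k/rate`. Each input sample
#' snaps to its nearest grid tick (a tie at exactly half an interval snaps
#' to the earlier tick); when two inputs snap to one tick the earlier is
#' kept and a drop counted. Unoccupied ticks between the first and last
#' sample are filled with samples whose binocularity is `"missing"`, so
#' gaps stay visible and the sampling interval is preserved exactly. No
#' gaze values are ever interpolated or invented.
#'
#' @param samples Irregular gaze samples, time-sorted.
#' @param rate Nominal rate in Hz.
#' @param t0_us Grid origin in microseconds; defaults to the first sample.
#' @return A list: `gaze` (regular data.frame with `t` in seconds from
#'   `t0_us`) and `report` (an `assembly_report`).
#' @export
regularize_and_fill <- function(samples, rate, t0_us = samples$ts_us[1L]) {
  stopifnot(nrow(samples) >= 1L)
  interval_us <- 1e6 / rate
  k <- (samples$ts_us - t0_us) / interval_us
  idx <- ceiling(k - 0.5)                       # nearest tick, ties earlier
  keep <- !duplicated(idx)
  n_dup <- sum(!keep)
  samples <- samples[keep, , drop = FALSE]
  idx <- idx[keep]
  K <- idx[length(idx)]
  grid <- idx[1L]:K
  out <- .empty_samples(length(grid))
  pos <- match(idx, grid)
  out[pos, ] <- samples
  out$filled <- TRUE
  out$filled[pos] <- FALSE
  out$binocularity[setdiff(seq_along(grid), pos)] <- "missing"
  out$l_valid[is.na(out$l_valid)] <- FALSE
  out$r_valid[is.na(out$r_valid)] <- FALSE
  out$ts_us <- t0_us + grid * interval_us
  t <- grid / rate
  gaze <- cbind(t = t, out[, setdiff(names(out), "ts_us")])
  report <- structure(list(
    n_raw_groups = nrow(samples),
    n_regularized = nrow(gaze),
    n_gap_filled = nrow(gaze) - nrow(samples),
    n_duplicates_dropped = n_dup,
    n_invalidated = sum(samples$binocularity == "missing"),
    inferred_rate_hz = as.integer(rate),
    segment_boundaries = numeric(),
    dropped_lines = 0L
  ), class = "assembly_report")
  list(gaze = gaze, report = report)
}

#' Build a video-time map from vts packets
#'
#' `vts` packets pair a media time (payload, microseconds within the video
#' file) with a data time (packet timestamp on the recording clock). The
#' map interpolates piecewise-linearly between pairs; with two or more
#' pairs, queries beyond the ends are clamped to the end values, while a
#' single pair defines a pure offset map.
#'
#' @param vts_packets Packet data.frame rows of kind `vts`.
#' @param stream_id `"scene"` or `"eyes"`.
#' @param t0_us Recording clock origin in microseconds.
#' @return A `video_time_map` list with `stream_id`, `media_s`, `data_s`.
#' @export
attach_video_map <- function(vts_packets, stream_id = "scene", t0_us = 0) {
  stopifnot(nrow(vts_packets) >= 1L)
  o <- order(vts_packets$ts)
  data_s <- (vts_packets$ts[o] - t0_us) / 1e6
  media_s <- vts_packets$p1[o] / 1e6
  if (any(diff(data_s) <= 0) || (length(media_s) > 1 && any(diff(media_s) <= 0)))
    wg_validation_error("video time map pairs must be strictly increasing")
  structure(list(stream_id = stream_id, media_s = media_s, data_s = data_s),
            class = "video_time_map")
}

#' @rdname attach_video_map
#' @param map A `video_time_map`.
#' @param t Times to convert, seconds.
#' @export
media_to_data <- function(map, t) {
  if (length(map$media_s) == 1L) return(t - map$media_s + map$data_s)
  stats::approx(map$media_s, map$data_s, xout = t, rule = 2L)$y
}

#' @rdname attach_video_map
#' @export
data_to_media <- function(map, t) {
  if (length(map$media_s) == 1L) return(t - map$data_s + map$media_s)
  stats::approx(map$data_s, map$media_s, xout = t, rule = 2L)$y
}

# split a segment's packets into the per-stream pieces used downstream
.split_segment <- function(packets) {
  imu_df <- function(kind) {
    p <- packets[packets$kind == kind, , drop = FALSE]
    data.frame(ts_us = p$ts, x = p$p1, y = p$p2, z = p$p3,
               valid = p$status == 0L)
  }
  ttl <- packets[packets$kind == "ttl", , drop = FALSE]
  list(
    gaze = group_gaze_packets(packets),
    gyro = imu_df("gyro"),
    accel = imu_df("accel"),
    ttl = data.frame(ts_us = ttl$ts, value = ttl$p1),
    vts = packets[packets$kind == "vts", , drop = FALSE]
  )
}

#' Concatenate recording segments into one recording
#'
#' Segments share one recording clock; their time ranges must not overlap
#' (an overlap indicates a hardware or parsing fault and is fatal rather
#' than silently re-offset). Segments are ordered by time regardless of
#' on-disk order, streams are concatenated, and the inter-segment span is
#' gap-filled like any other gap. All timestamps are expressed in seconds
#' with t = 0 at the first gaze sample.
#'
#' @param segments List of per-segment stream lists as built internally by
#'   [parse_recording()] (elements `gaze`, `gyro`, `accel`, `ttl`, `vts`).
#' @param meta Optional metadata list.
#' @param rate Nominal rate; inferred from the pooled samples when `NULL`.
#' @return A `wg_recording` with an `assembly_report` in `$report`.
#' @export
concat_segments <- function(segments, meta = list(), rate = NULL) {
  segments <- segments[vapply(segments, function(s) nrow(s$gaze) > 0, TRUE)]
  if (length(segments) == 0L) wg_parse_error("no gaze data in any segment")
  starts <- vapply(segments, function(s) s$gaze$ts_us[1L], 0)
  ends <- vapply(segments, function(s) s$gaze$ts_us[nrow(s$gaze)], 0)
  o <- order(starts)
  segments <- segments[o]; starts <- starts[o]; ends <- ends[o]
  if (length(segments) > 1L) {
    ov <- starts[-1L] <= ends[-length(ends)]
    if (any(ov))
      wg_validation_error(sprintf(
        "segment time ranges overlap by up to %.3f s",
        max((ends[-length(ends)] - starts[-1L])[ov]) / 1e6))
  }
  all_samples <- do.call(rbind, lapply(segments, `[[`, "gaze"))
  if (is.null(rate)) rate <- infer_rate(all_samples)
  t0_us <- all_samples$ts_us[1L]
  rf <- regularize_and_fill(all_samples, rate, t0_us)
  rf$report$segment_boundaries <- (starts[-1L] - t0_us) / 1e6

  cat_imu <- function(field) {
    df <- do.call(rbind, lapply(segments, `[[`, field))
    df <- df[order(df$ts_us), , drop = FALSE]
    out <- data.frame(t = (df$ts_us - t0_us) / 1e6,
                      x = df$x, y = df$y, z = df$z, valid = df$valid)
    rownames(out) <- NULL
    out
  }
  ttl <- do.call(rbind, lapply(segments, `[[`, "ttl"))
  ttl <- ttl[order(ttl$ts_us), , drop = FALSE]
  ttl <- data.frame(t = (ttl$ts_us - t0_us) / 1e6, value = ttl$value)

  # one map per segment: each segment has its own video file, so media
  # time restarts at every segment boundary
  video_maps <- list()
  for (i in seq_along(segments)) {
    vp <- segments[[i]]$vts
    if (nrow(vp))
      video_maps[[length(video_maps) + 1L]] <-
        attach_video_map(vp, "scene", t0_us)
  }

  meta$nominal_gaze_rate_hz <- as.integer(rate)
  meta$segment_count <- length(segments)
  meta$duration_s <- rf$gaze$t[nrow(rf$gaze)]
  structure(list(
    meta = meta,
    gaze = rf$gaze,
    gyro = cat_imu("gyro"),
    accel = cat_imu("accel"),
    ttl = ttl,
    video_maps = video_maps,
    derived = NULL,
    report = rf$report
  ), class = "wg_recording")
}

.read_meta_json <- function(path) {
  if (!file.exists(path)) return(NULL)
  tryCatch(jsonlite::fromJSON(path, simplifyVector = TRUE),
           error = function(e) {
             warning(sprintf("unreadable metadata file %s: %s",
                             path, conditionMessage(e)))
             NULL
           })
}

.segment_dirs <- function(rec_dir) {
  segroot <- file.path(rec_dir, "segments")
  if (!dir.exists(segroot)) return(character())
  d <- list.dirs(segroot, recursive = FALSE)
  d[file.exists(file.path(d, "livedata.json.gz"))]
}

#' Parse a recording directory into a synchronized recording
#'
#' Composes the full chain: read each segment's packet file, group gaze
#' packets into samples, infer the nominal rate, snap to the sampling grid
#' filling gaps, concatenate segments, and attach video-time maps. The
#' assembled result is cached in `livedata.processed.json.gz` inside the
#' recording directory; subsequent calls load the cache unless
#' `force = TRUE`.
#'
#' @param rec_dir Recording directory containing `recording.json` and
#'   `segments/<k>/livedata.json.gz`.
#' @param force Re-parse even if a cache file exists.
#' @return A `wg_recording`; its `$report` is the `assembly_report`.
#' @export
parse_recording <- function(rec_dir, force = FALSE) {
  if (!dir.exists(rec_dir))
    wg_missing_input(sprintf("recording directory not found: %s", rec_dir))
  cache <- file.path(rec_dir, "livedata.processed.json.gz")
  if (!force && file.exists(cache)) return(.load_cache(cache))

  segdirs <- .segment_dirs(rec_dir)
  if (length(segdirs) == 0L)
    wg_missing_input(sprintf("no data segments under %s", rec_dir))
  dropped <- 0L
  segments <- lapply(segdirs, function(d) {
    rs <- read_segment(file.path(d, "livedata.json.gz"))
    dropped <<- dropped + rs$n_dropped
    .split_segment(rs$packets)
  })
  if (all(vapply(segments, function(s) nrow(s$gaze) == 0L, TRUE)))
    wg_parse_error(sprintf("no gaze data in recording %s", rec_dir))

  rj <- .read_meta_json(file.path(rec_dir, "recording.json"))
  meta <- list(
    project_id = rj$project_id %||% NA_character_,
    project_name = rj$project_name %||% NA_character_,
    participant_id = rj$participant_id %||% NA_character_,
    participant_name = rj$participant_name %||% NA_character_,
    recording_id = rj$recording_id %||% basename(rec_dir),
    recording_name = rj$recording_name %||% basename(rec_dir),
    start_time = rj$start_time %||% NA_character_,
    firmware_version = rj$firmware_version %||% NA_character_,
    calibration_status = rj$calibration_status %||% "none"
  )
  rec <- concat_segments(segments, meta)
  rec$report$dropped_lines <- dropped
  .save_cache(rec, cache)
  rec
}

# --- processed-data cache: one gzipped JSON container per recording -------

.save_cache <- function(rec, path) {
  payload <- list(
    format = "weargaze-processed-v1",
    meta = rec$meta,
    report = unclass(rec$report),
    gaze = as.list(rec$gaze),
    gyro = as.list(rec$gyro),
    accel = as.list(rec$accel),
    ttl = as.list(rec$ttl),
    video_maps = lapply(rec$video_maps, unclass)
  )
  # digits = I(17): 17 significant digits, so doubles survive the text
  # round trip bit-exactly
  txt <- jsonlite::toJSON(payload, digits = I(17), auto_unbox = TRUE,
                          na = "null", null = "null")
  con <- gzfile(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(as.character(txt)), con)
  invisible(path)
}

.load_cache <- function(path) {
  con <- gzfile(path, "rb")
  txt <- tryCatch({
    chunks <- raw()
    repeat {
      b <- readBin(con, "raw", 1e6)
      if (length(b) == 0L) break
      chunks <- c(chunks, b)
    }
    rawToChar(chunks)
  }, finally = close(con))
  p <- tryCatch(jsonlite::fromJSON(txt, simplifyVector = TRUE),
                error = function(e)
                  wg_parse_error(sprintf("corrupt cache file %s", path)))
  if (!identical(p$format, "weargaze-processed-v1"))
    wg_parse_error(sprintf("unrecognized cache format in %s", path))
  as_df <- function(x) {
    df <- as.data.frame(x, stringsAsFactors = FALSE)
    for (cl in names(df)) {           # JSON integers come back as integer;
      if (is.integer(df[[cl]])) df[[cl]] <- as.numeric(df[[cl]])  # restore
    }
    rownames(df) <- NULL
    df
  }
  structure(list(
    meta = p$meta,
    gaze = as_df(p$gaze),
    gyro = as_df(p$gyro),
    accel = as_df(p$accel),
    ttl = as_df(p$ttl),
    video_maps = lapply(seq_len(NROW(p$video_maps)), function(i)
      structure(list(stream_id = p$video_maps$stream_id[i],
                     media_s = p$video_maps$media_s[[i]],
                     data_s = p$video_maps$data_s[[i]]),
                class = "video_time_map")),
    derived = NULL,
    report = structure(p$report, class = "assembly_report")
  ), class = "wg_recording")
}

#' @export
print.wg_recording <- function(x, ...) {
  m <- x$meta
  cat(sprintf("<wg_recording> %s / %s\n",
              m$project_name %||% "?", m$recording_name %||% "?"))
  cat(sprintf("  gaze: %d samples @ %d Hz (%.1f s, %d segment%s)\n",
              nrow(x$gaze), m$nominal_gaze_rate_hz, m$duration_s,
              m$segment_count, if (m$segment_count == 1L) "" else "s"))
  cat(sprintf("  gyro: %d, accel: %d, ttl events: %d, video maps: %d\n",
              nrow(x$gyro), nrow(x$accel), nrow(x$ttl),
              length(x$video_maps)))
  if (!is.null(x$derived))
    cat(sprintf("  kinematics: SG window %d, order %d\n",
                x$derived$settings$window_samples,
                x$derived$settings$poly_order))
  invisible(x)
}

#' @export
print.assembly_report <- function(x, ...) {
  cat("<assembly_report>\n")
  cat(sprintf("  raw groups %d; regularized %d (gap-filled %d, duplicates %d)\n",
              x$n_raw_groups, x$n_regularized, x$n_gap_filled,
              x$n_duplicates_dropped))
  cat(sprintf("  invalid samples %d; rate %d Hz; dropped lines %d\n",
              x$n_invalidated, x$inferred_rate_hz, x$dropped_lines))
  if (length(x$segment_boundaries))
    cat("  segment boundaries at",
        paste(sprintf("%.3f s", x$segment_boundaries), collapse = ", "), "\n")
  invisible(x)
}
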