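test_that("grouping applies the per-eye validity rule and binocularity", {
  pk <- rbind(full_group(0, 0),                               # both valid
              full_group(20000, 1, r_status = c(0L, 0L, 1L)), # right pd bad
              full_group(40000, 2, l_status = c(1L, 1L, 1L),
                         r_status = c(1L, 1L, 1L)))           # none valid
  g <- group_gaze_packets(pk)
  expect_equal(g$binocularity, c("binocular", "monocular_left", "missing"))
  expect_true(g$l_valid[2] && !g$r_valid[2])
  # angles finite iff the eye is valid
  expect_true(all(is.finite(c(g$l_az[1:2], g$r_az[1]))))
  expect_false(any(is.finite(c(g$r_az[2], g$l_az[3], g$r_el[3]))))
})

test_that("conflicting duplicate payloads keep the first occurrence", {
  pk <- rbind(full_group(0, 0, theta = 5),
              packet_row(100, "gaze_dir", "left", 0, fick_compose(9, 0)))
  g <- group_gaze_packets(pk)
  expect_equal(g$l_az[1], 5, tolerance = 1e-9)
})

test_that("sample timestamp is the earliest gaze_dir timestamp of the group", {
  pk <- full_group(1000, 0)
  pk$ts[pk$kind == "gaze_dir" & pk$eye == "right"] <- 900
  g <- group_gaze_packets(pk)
  expect_equal(g$ts_us, 900)
})

test_that("rate inference picks the nearest nominal rate, robust to jitter", {
  expect_equal(infer_rate(make_samples(seq(0, by = 20000, length.out = 50))),
               50L)
  set.seed(7)
  jit <- seq(0, by = 10000, length.out = 200) + rnorm(200, 0, 100)
  expect_equal(infer_rate(make_samples(sort(jit))), 100L)
  # 5-ms interval: nearest member is still 100 Hz, but flagged
  expect_warning(r <- infer_rate(make_samples(seq(0, by = 5000,
                                                  length.out = 50))))
  expect_equal(r, 100L)
  expect_error(infer_rate(make_samples(c(0, 20000))), class = "wg_parse_error")
})

test_that("a 100-ms hole at 50 Hz gets exactly 4 missing samples", {
  s <- make_samples(c(0, 20000, 40000, 140000, 160000))
  rf <- regularize_and_fill(s, 50)
  expect_equal(rf$report$n_gap_filled, 4L)
  expect_equal(rf$report$n_regularized, 9L)
  expect_equal(sum(rf$gaze$binocularity == "missing"), 4L)
  # grid preserved exactly
  expect_lt(max(abs(diff(rf$gaze$t) - 0.02)), 1e-9)
})

test_that("an already-regular series is returned unchanged", {
  s <- make_samples(seq(0, by = 20000, length.out = 100))
  rf <- regularize_and_fill(s, 50)
  expect_equal(rf$report$n_gap_filled, 0L)
  expect_equal(nrow(rf$gaze), 100L)
})

test_that("jittered input snaps to the exact grid, matching the brute-force oracle", {
  set.seed(11)
  for (rep in 1:5) {
    ts <- sort(seq(0, by = 20000, length.out = 150) +
               round(runif(150, -2000, 2000)))
    ts <- ts - ts[1]
    s <- make_samples(ts)
    rf <- regularize_and_fill(s, 50)
    expect_lt(max(abs(diff(rf$gaze$t) - 0.02)), 1e-9)
    idx <- oracle_snap(ts, 50)
    occupied <- which(!rf$gaze$filled) - 1L
    expect_equal(occupied, sort(unique(idx)))
  }
})

test_that("regularization is idempotent and conserves the time span", {
  set.seed(13)
  ts <- sort(sample(seq(0, by = 20000, length.out = 120), 80))
  s <- make_samples(ts)
  rf <- regularize_and_fill(s, 50)
  # feed the output back in (reconstruct microsecond timestamps)
  again <- rf$gaze
  again$ts_us <- ts[1] + round(again$t * 1e6)
  again <- again[, weargaze:::.sample_cols()]
  rf2 <- regularize_and_fill(again, 50)
  expect_equal(rf2$gaze$t, rf$gaze$t)
  expect_equal(rf2$gaze$binocularity, rf$gaze$binocularity)
  expect_equal(rf2$report$n_gap_filled, 0L)
  # conservation: tick count spans exactly [first, last]
  expect_equal(rf$report$n_regularized,
               as.integer(round((ts[length(ts)] - ts[1]) / 20000)) + 1L)
})

test_that("ties at half an interval snap to the earlier tick", {
  s <- make_samples(c(0, 30000))          # 30 ms = 1.5 ticks at 50 Hz
  rf <- regularize_and_fill(s, 50)
  expect_equal(which(!rf$gaze$filled), c(1L, 2L))   # tick 1, not 2
})

test_that("video time maps interpolate, clamp, and reject non-monotone pairs", {
  vp <- rbind(packet_row(0.5e6, "vts", payload = 0),
              packet_row(10.5e6, "vts", payload = 10e6))
  m <- attach_video_map(vp, "scene", 0)
  expect_equal(media_to_data(m, 5), 5.5)
  expect_equal(data_to_media(m, 5.5), 5)
  expect_equal(media_to_data(m, 50), 10.5)  # clamped
  single <- attach_video_map(packet_row(2e6, "vts", payload = 0), "scene", 0)
  expect_equal(media_to_data(single, 3), 5)  # pure offset
  bad <- rbind(packet_row(0, "vts", payload = 0),
               packet_row(1e6, "vts", payload = -1))
  expect_error(attach_video_map(bad, "scene", 0),
               class = "wg_validation_error")
})

test_that("multi-segment recordings are ordered, concatenated and gap-filled", {
  td <- withr::local_tempdir()
  s <- wg_script(list(ep_fixation(25000, 0, 0), ep_gap(1000),
                      ep_fixation(34000, 3, 1)),
                 noise_sd = 0, rate_hz = 50, segment_split_s = 25.5,
                 seed = 21)
  g <- generate_recording(s, td)
  rec <- parse_recording(g$rec_dir)
  expect_equal(rec$meta$segment_count, 2L)
  expect_length(rec$report$segment_boundaries, 1L)
  # scripted 1-s gap deletes 50 ticks worth of packets
  expect_equal(rec$report$n_gap_filled, 50L)
  expect_lt(max(abs(diff(rec$gaze$t) - 0.02)), 1e-9)
  # segments shuffled on disk parse identically: order is by time
  segs <- file.path(g$rec_dir, "segments", c("1", "2"))
  tmp <- file.path(g$rec_dir, "segments", "zz")
  file.rename(segs[1], tmp); file.rename(segs[2], segs[1])
  file.rename(tmp, segs[2])
  rec2 <- parse_recording(g$rec_dir, force = TRUE)
  expect_equal(rec2$gaze, rec$gaze)
})

test_that("overlapping segments are fatal", {
  seg <- function(ts0) {
    pk <- do.call(rbind, lapply(0:20, function(k)
      full_group(ts0 + k * 20000, k)))
    weargaze:::.split_segment(pk)
  }
  expect_error(concat_segments(list(seg(0), seg(100000))),
               class = "wg_validation_error")
})

test_that("parse_recording caches and reloads identically", {
  td <- withr::local_tempdir()
  g <- generate_recording(demo_script(rate_hz = 50, noise_sd = 0.1, seed = 3),
                          td)
  rec <- parse_recording(g$rec_dir)
  expect_true(file.exists(file.path(g$rec_dir, "livedata.processed.json.gz")))
  rec2 <- parse_recording(g$rec_dir)     # from cache
  expect_identical(rec$gaze, rec2$gaze)
  expect_identical(rec$gyro, rec2$gyro)
  expect_identical(rec$accel, rec2$accel)
  expect_identical(rec$ttl, rec2$ttl)
  expect_equal(rec$video_maps, rec2$video_maps)
})

test_that("a recording with only IMU packets is rejected", {
  td <- withr::local_tempdir()
  segdir <- file.path(td, "proj", "rec", "segments", "1")
  dir.create(segdir, recursive = TRUE)
  imu <- do.call(rbind, lapply(0:49, function(k)
    packet_row(k * 10000, "gyro", payload = c(0, 0, 0))))
  write_segment(imu, file.path(segdir, "livedata.json.gz"))
  expect_error(parse_recording(file.path(td, "proj", "rec")),
               class = "wg_parse_error")
})

test_that("a 60-s 50-Hz recording assembles to the expected length", {
  td <- withr::local_tempdir()
  s <- wg_script(list(ep_fixation(60000, 0, 0)), noise_sd = 0.05,
                 rate_hz = 50, seed = 5)
  g <- generate_recording(s, td)
  rec <- parse_recording(g$rec_dir)
  expect_true(abs(nrow(rec$gaze) - 3000) <= 1)
  expect_equal(rec$report$n_regularized, nrow(rec$gaze))
  expect_equal(rec$report$n_raw_groups + rec$report$n_gap_filled,
               rec$report$n_regularized)
})
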