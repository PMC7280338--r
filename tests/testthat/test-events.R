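cats2 <- list(list(label = "fixation", flags = character()),
              list(label = "saccade", flags = "vergence"))

test_that("add_annotation spans from the previous annotation's end to the click", {
  s <- event_stream("c", cats2, duration_s = 10)
  s <- add_annotation(s, 2.0, "fixation")
  expect_equal(s$annotations$start, 0)
  expect_equal(s$annotations$end, 2)
  s <- add_annotation(s, 3.0, "saccade")
  expect_equal(s$annotations$start, c(0, 2))
  # click beyond a gap: starts at the latest end before the click
  s2 <- event_stream("c", cats2, duration_s = 10)
  s2 <- add_annotation(s2, 1.0, "fixation")
  s2 <- add_annotation(s2, 3.0, "fixation")
  expect_equal(unlist(s2$annotations[2, c("start", "end")]),
               c(start = 1, end = 3))
  expect_error(add_annotation(s, 2.5, "fixation"),
               class = "wg_validation_error")
  expect_error(add_annotation(s, 11, "fixation"),
               class = "wg_validation_error")
})

test_that("split preserves label and flags; relabel+merge restores", {
  s <- event_stream("c", cats2, duration_s = 10)
  s <- add_annotation(s, 2.0, "saccade", flags = "vergence")
  sp <- split_annotation(s, 1.0)
  expect_equal(nrow(sp$annotations), 2L)
  expect_equal(sp$annotations$flags, c("vergence", "vergence"))
  expect_equal(sum(sp$annotations$end - sp$annotations$start), 2)
  merged <- merge_adjacent_equal(sp)
  expect_equal(merged$annotations, s$annotations)
  expect_error(split_annotation(s, 0), class = "wg_validation_error")
  expect_error(split_annotation(s, 5), class = "wg_validation_error")
})

test_that("relabel validates flags and move_boundary respects neighbors", {
  s <- event_stream("c", cats2, duration_s = 10)
  s <- add_annotation(s, 1.0, "fixation")
  s <- add_annotation(s, 2.0, "fixation")
  s2 <- relabel_annotation(s, 1, "saccade", "vergence")
  expect_equal(s2$annotations$label[1], "saccade")
  expect_error(relabel_annotation(s, 1, "fixation", "vergence"),
               class = "wg_validation_error")
  # shared boundary moves both annotations
  s3 <- move_boundary(s, 2, 1.5)
  expect_equal(s3$annotations$end[1], 1.5)
  expect_equal(s3$annotations$start[2], 1.5)
  expect_error(move_boundary(s, 2, 2.5), class = "wg_validation_error")
  s4 <- remove_annotation(s, 2)
  expect_equal(nrow(s4$annotations), 1L)
})

test_that("stream invariants survive thousands of random edits", {
  set.seed(71)
  ops_done <- 0L
  s <- event_stream("fuzz", cats2, duration_s = 100)
  for (i in 1:2000) {
    op <- sample(c("add", "split", "relabel", "remove", "move"), 1L)
    s_try <- tryCatch(switch(op,
      add = add_annotation(s, runif(1, 0, 100),
                           sample(c("fixation", "saccade"), 1L)),
      split = split_annotation(s, runif(1, 0, 100)),
      relabel = relabel_annotation(s, sample(max(1, nrow(s$annotations)), 1L),
                                   "fixation"),
      remove = remove_annotation(s, sample(max(1, nrow(s$annotations)), 1L)),
      move = move_boundary(s,
                           sample(max(1, 2 * nrow(s$annotations)), 1L),
                           runif(1, 0, 100))
    ), wg_error = function(e) NULL)
    if (is.null(s_try)) next
    s <- s_try
    ops_done <- ops_done + 1L
    a <- s$annotations
    if (nrow(a)) {
      expect_true(all(a$end > a$start))
      expect_true(all(a$start >= 0) && all(a$end <= 100))
      if (nrow(a) > 1) expect_true(all(a$start[-1] >= a$end[-nrow(a)] - 1e-12))
      expect_lte(sum(a$end - a$start), 100 + 1e-9)
    }
  }
  expect_gt(ops_done, 500L)
})

test_that("TTL streams follow the edge and level schemes and are locked", {
  ttl <- data.frame(t = c(1, 2), value = c(1, 0))
  lv <- ttl_stream(ttl, "levels", 0.02, 5)
  expect_equal(lv$annotations$start, c(1, 2))
  expect_equal(lv$annotations$end, c(2, 5))
  expect_equal(lv$annotations$label, c("1", "0"))
  ed <- ttl_stream(ttl, "edges", 0.02, 5)
  expect_equal(ed$annotations$end - ed$annotations$start, c(0.02, 0.02))
  expect_true(ed$locked)
  expect_error(add_annotation(ed, 3, "1"), class = "wg_validation_error")
  empty <- ttl_stream(data.frame(t = numeric(), value = numeric()),
                      "edges", 0.02, 5)
  expect_equal(nrow(empty$annotations), 0L)
})

test_that("button presses become one annotation per press", {
  td <- withr::local_tempdir()
  g <- generate_recording(demo_script(seed = 72), td)
  rec <- parse_recording(g$rec_dir)
  st <- ttl_stream(rec$ttl, "edges", 1 / rec$meta$nominal_gaze_rate_hz,
                   rec$meta$duration_s)
  expect_equal(nrow(st$annotations), 3L)   # three scripted presses
  expect_equal(st$annotations$start, c(1.5, 2.9, 4.1), tolerance = 1e-9)
})

test_that("text import validates, resets, and reserializes byte-identically", {
  f <- withr::local_tempfile()
  writeLines(c("start_s\tend_s\tlabel\tflags", "0\t2\tfix\t",
               "2\t3\tsac\tvergence", "4\t5\tfix\t"), f)
  s <- load_events_from_text(f, duration_s = 10)
  expect_equal(nrow(s$annotations), 3L)
  expect_equal(s$source, "file")
  edited <- remove_annotation(add_annotation(s, 9, "fix"), 1)
  restored <- reset_stream(edited)
  f2 <- withr::local_tempfile()
  write_events_text(restored, f2)
  expect_identical(readLines(f2), readLines(f))
  # overlapping rows are a format error naming rows
  f3 <- withr::local_tempfile()
  writeLines(c("start_s\tend_s\tlabel", "0\t2\ta", "1\t3\ta"), f3)
  expect_error(load_events_from_text(f3), class = "wg_parse_error")
  # unknown label against explicit categories
  expect_error(load_events_from_text(f, categories = "fix"),
               class = "wg_validation_error")
})

test_that("classifier registry validates parameters, names, and output", {
  td <- withr::local_tempdir()
  g <- generate_recording(demo_script(rate_hz = 100, noise_sd = 0, seed = 73),
                          td)
  rec <- compute_kinematics(parse_recording(g$rec_dir), sg_settings(3, 2))
  expect_error(classifier_spec("x", "slow_fast",
                               list(list(name = "velocity_threshold_dps",
                                         value = 5000, min = 10, max = 1000))),
               class = "wg_validation_error")
  expect_error(run_classifier(rec, classifier_spec("x", "nope")),
               class = "wg_validation_error")
  register_classifier("bad", function(recording, params)
    event_stream("bad", "a", duration_s = 10,
                 annotations = data.frame(start = c(0, 1), end = c(2, 3),
                                          label = "a", flags = "")))
  expect_error(run_classifier(rec, classifier_spec("x", "bad")),
               class = "wg_validation_error")
  out <- run_classifier(rec, classifier_spec(
    "my_stream", "slow_fast",
    list(list(name = "velocity_threshold_dps", value = 100, min = 10,
              max = 1000))))
  expect_equal(out$name, "my_stream")
  expect_equal(out$source, "classifier")
})

test_that("slow/fast classification recovers a scripted scanpath", {
  td <- withr::local_tempdir()
  g <- generate_recording(demo_script(rate_hz = 100, noise_sd = 0, seed = 74),
                          td)
  rec <- compute_kinematics(parse_recording(g$rec_dir), sg_settings(3, 2))
  st <- classify_slow_fast(rec)
  sf <- st$annotations[st$annotations$label %in% c("slow", "fast"), ]
  expect_equal(nrow(sf), 9L)
  expect_equal(sf$label, rep(c("slow", "fast"), length.out = 9))
  # boundary error <= 1 sample against the generator's ground truth
  gt <- g$ground_truth$annotations
  gt_fast <- gt[gt$label == "fast", ]
  cl_fast <- sf[sf$label == "fast", ]
  expect_lte(max(abs(gt_fast$start - cl_fast$start),
                 abs(gt_fast$end - cl_fast$end)), 0.01 + 1e-9)
  # full-timeline coverage without gaps or overlaps
  a <- st$annotations
  expect_equal(a$start[1], 0)
  expect_equal(a$end[nrow(a)], st$duration_s)
  expect_equal(a$start[-1], a$end[-nrow(a)])
  # determinism
  st2 <- classify_slow_fast(rec)
  expect_identical(st$annotations, st2$annotations)
})

test_that("short-run merging follows the duration rules", {
  # constant zero velocity -> one slow annotation
  lab <- weargaze:::.merge_short_runs(rep("slow", 100), 0.02,
                                      c(fast = 10, slow = 40))
  expect_equal(unique(lab), "slow")
  # a 1-sample fast blip at 50 Hz is 20 ms >= 10 ms: kept
  lab <- rep("slow", 50); lab[25] <- "fast"
  out <- weargaze:::.merge_short_runs(lab, 0.02, c(fast = 10, slow = 40))
  expect_equal(out[25], "fast")
  # the same blip at 100 Hz is 10 ms < threshold? exactly 10 ms: kept
  out <- weargaze:::.merge_short_runs(lab, 0.01, c(fast = 10, slow = 40))
  expect_equal(out[25], "fast")
  # a 1-sample blip below the minimum is merged into the slow surround
  out <- weargaze:::.merge_short_runs(lab, 0.005, c(fast = 10, slow = 40))
  expect_equal(unique(out), "slow")
  # missing spans are never merged
  lab <- c(rep("slow", 10), rep("missing", 2), rep("slow", 10))
  out <- weargaze:::.merge_short_runs(lab, 0.02, c(fast = 10, slow = 40))
  expect_equal(out, lab)
})

test_that("square-wave velocity alternation is recovered at block boundaries", {
  td <- withr::local_tempdir()
  # emulate alternating 200-ms slow/fast blocks via scripted pursuit speeds
  eps <- list()
  for (i in 1:4) {
    eps <- c(eps, list(ep_pursuit(200, 0),
                       ep_pursuit(200, if (i %% 2) 300 else -300)))
  }
  s <- wg_script(eps, noise_sd = 0, rate_hz = 50, seed = 75)
  g <- generate_recording(s, td)
  rec <- compute_kinematics(parse_recording(g$rec_dir), sg_settings(3, 2))
  st <- classify_slow_fast(rec)
  sf <- st$annotations[st$annotations$label %in% c("slow", "fast"), ]
  gt <- g$ground_truth$annotations
  # one episode per block, boundaries within 1 sample
  expect_equal(nrow(sf), 8L)
  for (i in seq_len(nrow(sf) - 1))
    expect_lte(min(abs(sf$end[i] - seq(0.2, 1.6, by = 0.2))), 0.02 + 1e-9)
})

test_that("a recording with no finite eye speed yields one missing annotation", {
  td <- withr::local_tempdir()
  s <- wg_script(list(ep_fixation(2000, 0, 0)), noise_sd = 0, rate_hz = 50,
                 seed = 76)
  g <- generate_recording(s, td)
  rec <- compute_kinematics(parse_recording(g$rec_dir))
  rec$derived$velocity$l_omega[] <- NA_real_
  rec$derived$velocity$r_omega[] <- NA_real_
  st <- classify_slow_fast(rec)
  expect_equal(nrow(st$annotations), 1L)
  expect_equal(st$annotations$label, "missing")
})

test_that("coding round-trips and tolerates externally added streams", {
  d <- withr::local_tempdir()
  s1 <- add_annotation(event_stream("a", cats2, duration_s = 10), 2, "fixation")
  s2 <- ttl_stream(data.frame(t = 1, value = 1), "edges", 0.02, 10)
  s3 <- event_stream("empty", "x", duration_s = 10)
  save_coding(list(s1, s2, s3), d)
  back <- load_coding(d)
  expect_length(back, 3L)
  expect_equal(back[[1]]$annotations, s1$annotations)
  expect_equal(back[[2]]$locked, TRUE)
  # an external tool appends a mapping stream
  j <- jsonlite::fromJSON(file.path(d, "coding.json"), simplifyVector = FALSE)
  j$streams[[4]] <- list(name = "mapping", source = "file", locked = FALSE,
                         duration_s = 10,
                         categories = list(list(label = "teapot",
                                                flags = list())),
                         annotations = list(list(start_s = 0, end_s = 1,
                                                 label = "teapot",
                                                 flags = list())))
  jsonlite::write_json(j, file.path(d, "coding.json"), auto_unbox = TRUE)
  back2 <- load_coding(d)
  expect_length(back2, 4L)
  expect_equal(back2[[4]]$name, "mapping")
  # empty directory -> empty stream set; corrupt file -> fatal
  expect_length(load_coding(withr::local_tempdir()), 0L)
  writeLines("{]", file.path(d, "coding.json"))
  expect_error(load_coding(d), class = "wg_parse_error")
})
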