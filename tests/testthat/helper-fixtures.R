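# Shared fixture builders. Everything is generated in code at test time;
# no stored data files.

# irregular gaze-sample frame with given timestamps (microseconds), all valid
make_samples <- function(ts_us, binocularity = "binocular") {
  s <- weargaze:::.empty_samples(length(ts_us))
  s$ts_us <- ts_us
  s$binocularity <- binocularity
  s$l_valid <- s$r_valid <- binocularity == "binocular"
  s$l_az <- s$l_el <- s$r_az <- s$r_el <- ifelse(binocularity == "missing",
                                                 NA_real_, 0)
  s
}

# one raw gaze-family packet row
packet_row <- function(ts, kind, eye = "none", gidx = NA, payload = 1,
                       status = 0L) {
  p <- rep(NA_real_, 3L)
  p[seq_along(payload)] <- payload
  data.frame(ts = as.numeric(ts), status = as.integer(status), kind = kind,
             eye = eye, gidx = as.numeric(gidx), p1 = p[1], p2 = p[2],
             p3 = p[3], stringsAsFactors = FALSE)
}

# a complete packet group for one gaze sample (both eyes valid)
full_group <- function(ts, gidx, theta = 0, phi = 0,
                       l_status = c(0L, 0L, 0L), r_status = c(0L, 0L, 0L)) {
  gd <- weargaze::fick_compose(theta, phi)
  rbind(
    packet_row(ts, "gaze_dir", "left", gidx, gd, l_status[1]),
    packet_row(ts, "gaze_dir", "right", gidx, gd, r_status[1]),
    packet_row(ts, "pupil_center", "left", gidx, c(-30, 0, -20), l_status[2]),
    packet_row(ts, "pupil_center", "right", gidx, c(30, 0, -20), r_status[2]),
    packet_row(ts, "pupil_diameter", "left", gidx, 3, l_status[3]),
    packet_row(ts, "pupil_diameter", "right", gidx, 3.1, r_status[3]),
    packet_row(ts, "gaze_point_2d", "none", gidx, c(0.5, 0.5)),
    packet_row(ts, "gaze_point_3d", "none", gidx, c(0, 0, 1000))
  )
}

# random valid packet stream for round-trip property tests
random_packets <- function(n, seed) {
  set.seed(seed)
  if (n == 0L) return(weargaze:::.empty_packets())
  kinds <- names(weargaze:::.payload_len)
  k <- sample(kinds, n, replace = TRUE)
  do.call(rbind, lapply(seq_len(n), function(i) {
    len <- weargaze:::.payload_len[[k[i]]]
    eye <- if (k[i] %in% weargaze:::.eye_kinds)
      sample(c("left", "right"), 1L) else "none"
    gidx <- if (k[i] %in% weargaze:::.gaze_kinds) sample(0:1000, 1L) else NA
    packet_row(ts = sample(0:1e7, 1L), kind = k[i], eye = eye, gidx = gidx,
               payload = round(stats::rnorm(len), 6),
               status = sample(0:1, 1L))
  }))
}

# brute-force nearest-tick snapping oracle (ties to the earlier tick)
oracle_snap <- function(ts_us, rate, t0_us = ts_us[1]) {
  interval <- 1e6 / rate
  kmax <- ceiling((max(ts_us) - t0_us) / interval) + 2
  grid <- t0_us + (0:kmax) * interval
  vapply(ts_us, function(t) {
    d <- abs(grid - t)
    which(d == min(d))[1] - 1L   # earlier tick on ties
  }, 0L)
}

# per-window least-squares polynomial fit oracle for SG differentiation
oracle_sg <- function(x, dt, window, order) {
  h <- (window - 1) %/% 2
  n <- length(x)
  out <- rep(NA_real_, n)
  j <- (-h):h
  for (i in (h + 1):(n - h)) {
    y <- x[(i - h):(i + h)]
    if (anyNA(y)) next
    fit <- stats::lm(y ~ stats::poly(j, order, raw = TRUE))
    out[i] <- stats::coef(fit)[2] / dt
  }
  out
}
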