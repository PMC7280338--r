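# Data-quality panel: windowed RMS sample-to-sample precision per eye and
# axis, and data loss. RMS-S2S is computed per axis (azimuth / elevation
# separately), with a dense moving window (stride 1 sample); windows that
# contain any missing sample are excluded entirely so every window's
# estimate rests on the same number of differences, and the median over
# windows estimates precision during slow-movement periods robustly.

#' Windowed RMS sample-to-sample precision of one axis series
#'
#' Slides a window (default 300 ms) one sample at a time over the series,
#' computes the root-mean-square of successive-sample differences inside
#' each fully valid window, and returns the median over windows. Windows
#' containing any missing sample are excluded.
#'
#' @param x Axis series in degrees on the regular gaze grid (`NA` = missing).
#' @param rate_hz Sampling rate of the grid.
#' @param window_ms Window length in milliseconds (default 300).
#' @return A list with `median_rms` (degrees; `NaN` with a warning when no
#'   fully valid window exists) and `n_windows_used`.
#' @export
rms_s2s <- function(x, rate_hz, window_ms = 300) {
  if (window_ms <= 0) wg_validation_error("window_ms must be positive")
  w <- max(2L, as.integer(round(window_ms / 1000 * rate_hz)))
  n <- length(x)
  if (n < w) {
    warning("series shorter than one RMS-S2S window")
    return(list(median_rms = NaN, n_windows_used = 0L))
  }
  ok <- is.finite(x)
  d2 <- diff(x)^2
  d2z <- ifelse(is.na(d2), 0, d2)
  nd <- w - 1L                        # differences per window
  csum <- c(0, cumsum(d2z))
  cok <- c(0, cumsum(!ok))
  starts <- seq_len(n - w + 1L)
  full <- (cok[starts + w] - cok[starts]) == 0L   # no missing sample inside
  if (!any(full)) {
    warning("no RMS-S2S window free of missing samples")
    return(list(median_rms = NaN, n_windows_used = 0L))
  }
  rms <- sqrt((csum[starts + nd] - csum[starts])[full] / nd)
  list(median_rms = stats::median(rms), n_windows_used = sum(full))
}

#' Data loss of a regularized gaze series
#'
#' The percentage of gaze samples carrying no valid gaze data from either
#' eye, over all regularized samples; gap-filled samples count as invalid.
#'
#' @param gaze Regularized gaze data.frame (needs column `binocularity`).
#' @return Percentage in `[0, 100]`.
#' @export
data_loss <- function(gaze) {
  n <- nrow(gaze)
  if (n == 0L) wg_parse_error("empty gaze series")
  100 * sum(gaze$binocularity == "missing") / n
}

#' Data-quality report for a recording
#'
#' Assembles the four per-eye, per-axis RMS-S2S precision cells and the
#' recording's data loss.
#'
#' @param recording A `wg_recording`.
#' @param window_ms RMS-S2S window length in milliseconds.
#' @return A `wg_quality` list: `window_ms`, `rms_s2s` (nested
#'   `left`/`right` by `azimuth`/`elevation`, degrees), `n_windows_used`,
#'   `data_loss_percent`.
#' @export
quality_report <- function(recording, window_ms = 300) {
  stopifnot(inherits(recording, "wg_recording"))
  g <- recording$gaze
  rate <- recording$meta$nominal_gaze_rate_hz
  cells <- list(left = list(), right = list())
  nwin <- list(left = list(), right = list())
  cols <- list(left = c(azimuth = "l_az", elevation = "l_el"),
               right = c(azimuth = "r_az", elevation = "r_el"))
  for (eye in names(cols)) for (axis in names(cols[[eye]])) {
    r <- rms_s2s(g[[cols[[eye]][[axis]]]], rate, window_ms)
    cells[[eye]][[axis]] <- r$median_rms
    nwin[[eye]][[axis]] <- r$n_windows_used
  }
  structure(list(
    window_ms = window_ms,
    rms_s2s = cells,
    n_windows_used = nwin,
    data_loss_percent = data_loss(g)
  ), class = "wg_quality")
}

#' Write a quality report as JSON
#'
#' @param quality A `wg_quality` report.
#' @param path Output path for `quality.json`.
#' @export
write_quality_json <- function(quality, path) {
  jsonlite::write_json(unclass(quality), path, auto_unbox = TRUE,
                       digits = NA, na = "string", pretty = TRUE)
  invisible(path)
}

#' @export
print.wg_quality <- function(x, ...) {
  cat(sprintf("<wg_quality> RMS-S2S (deg, %g-ms window, median):\n",
              x$window_ms))
  for (eye in c("left", "right"))
    cat(sprintf("  %-5s azimuth %.4f  elevation %.4f\n", eye,
                x$rms_s2s[[eye]]$azimuth, x$rms_s2s[[eye]]$elevation))
  cat(sprintf("  data loss: %.2f%%\n", x$data_loss_percent))
  invisible(x)
}
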