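# Eye orientation and velocity. Headset frame: x right, y up, z forward.
# Fick order: azimuth about the vertical axis first, then elevation, so
# theta = atan2(x, z) (positive rightward), phi = asin(y) (positive upward).

#' Decompose gaze direction vectors into Fick angles
#'
#' @param v A unit 3-vector, or an n x 3 matrix of unit vectors (columns
#'   x = right, y = up, z = forward). Vectors within `1e-6` of unit norm are
#'   renormalized; anything further off (including near-zero vectors) is
#'   rejected.
#' @return A list with `theta` (azimuth, degrees, positive rightward) and
#'   `phi` (elevation, degrees, positive upward), each of length n.
#' @examples
#' fick_decompose(c(0, 0, 1))                 # straight ahead: (0, 0)
#' fick_decompose(c(sin(pi / 18), 0, cos(pi / 18)))  # 10 deg rightward
#' @export
fick_decompose <- function(v) {
  if (is.null(dim(v))) v <- matrix(v, ncol = 3L, byrow = TRUE)
  nrm <- sqrt(rowSums(v^2))
  if (any(!is.finite(nrm)) || any(abs(nrm - 1) > 1e-6))
    wg_validation_error("gaze direction must be a unit vector (within 1e-6)")
  v <- v / nrm
  list(theta = atan2(v[, 1L], v[, 3L]) * 180 / pi,
       phi   = asin(pmin(1, pmax(-1, v[, 2L]))) * 180 / pi)
}

#' Compose a gaze direction vector from Fick angles
#'
#' Inverse of [fick_decompose()]; used by the synthetic generator and for
#' round-trip checks.
#'
#' @param theta Azimuth in degrees (positive rightward).
#' @param phi Elevation in degrees, strictly inside (-90, 90).
#' @return An n x 3 matrix of unit vectors.
#' @export
fick_compose <- function(theta, phi) {
  if (any(abs(phi) >= 90, na.rm = TRUE))
    wg_validation_error("|phi| must be < 90 degrees")
  th <- theta * pi / 180
  ph <- phi * pi / 180
  cbind(x = cos(ph) * sin(th), y = sin(ph), z = cos(ph) * cos(th))
}

#' Savitzky-Golay filter settings
#'
#' @param window_samples Odd number of filter taps, at least 3. The package
#'   default is `2 * round(0.05 * rate) + 1`, i.e. roughly a 100-ms window
#'   at the recording's sampling rate.
#' @param poly_order Polynomial order of the local fit, at least 1 and less
#'   than `window_samples`.
#' @return A list of class `sg_settings`.
#' @export
sg_settings <- function(window_samples, poly_order = 2L) {
  window_samples <- as.integer(window_samples)
  poly_order <- as.integer(poly_order)
  if (is.na(window_samples) || window_samples < 3L ||
      window_samples %% 2L == 0L)
    wg_validation_error("window_samples must be an odd integer >= 3")
  if (is.na(poly_order) || poly_order < 1L || poly_order >= window_samples)
    wg_validation_error("poly_order must be >= 1 and < window_samples")
  structure(list(window_samples = window_samples, poly_order = poly_order),
            class = "sg_settings")
}

.default_sg <- function(rate_hz) {
  sg_settings(2L * max(1L, round(0.05 * rate_hz)) + 1L, 2L)
}

#' Savitzky-Golay differentiation on a regular grid
#'
#' Fits a least-squares polynomial over each centered window and returns the
#' derivative of the fit at the window center, in units per second. The
#' output is `NA` wherever the window contains a missing value or is
#' truncated by the edge of the series: the filter bandwidth is constant, so
#' no shrunken edge windows are used.
#'
#' @param x Numeric series on a regular grid (may contain `NA`).
#' @param dt Sampling interval in seconds.
#' @param settings An [sg_settings()] object.
#' @return Numeric vector of the same length as `x`.
#' @export
sg_differentiate <- function(x, dt, settings) {
  if (!inherits(settings, "sg_settings"))
    settings <- do.call(sg_settings, as.list(settings))
  w <- settings$window_samples
  h <- (w - 1L) %/% 2L
  n <- length(x)
  out <- rep(NA_real_, n)
  if (n < w) return(out)
  # center row of the Savitzky-Golay derivative filter; signal::sgolay builds
  # the full projection matrix, ts scales the derivative to per-second
  fm <- signal::sgolay(p = settings$poly_order, n = w, m = 1L, ts = dt)
  coefs <- fm[h + 1L, ]
  # embed row r = x[r+w-1], ..., x[r]; NA anywhere in a window propagates
  M <- stats::embed(x, w)
  out[(h + 1L):(n - h)] <- as.numeric(M %*% rev(coefs))
  out
}

#' Angular eye speed from Fick-angle velocities
#'
#' Combines azimuthal and elevational angular velocity into total eye
#' rotation speed: `omega = sqrt(theta_dot^2 * cos(phi)^2 + phi_dot^2)`.
#' The `cos(phi)` factor accounts for the shrinking of azimuth circles away
#' from the equator of the eye-rotation sphere. Non-finite inputs propagate.
#'
#' @param theta_dot Azimuthal velocity, deg/s.
#' @param phi_dot Elevational velocity, deg/s.
#' @param phi Elevation, degrees.
#' @return Eye speed in deg/s (non-negative where finite).
#' @examples
#' eye_velocity(100, 0, 60)  # 50: azimuth motion at 60 deg elevation
#' eye_velocity(3, 4, 0)     # 5
#' @export
eye_velocity <- function(theta_dot, phi_dot, phi) {
  sqrt(theta_dot^2 * cospi(phi / 180)^2 + phi_dot^2)
}

#' Compute orientation and velocity traces for a recording
#'
#' Runs the kinematics chain per eye: Fick decomposition of the gaze
#' direction (done at assembly), Savitzky-Golay differentiation of azimuth
#' and elevation, and the eye-speed combination [eye_velocity()]. Velocity
#' is computed per eye; binocular averaging is left to callers.
#'
#' @param recording A `wg_recording` from [parse_recording()].
#' @param settings An [sg_settings()]; default is a ~100-ms window,
#'   order 2, derived from the recording's rate.
#' @return The recording with `$derived` set to a list holding `orientation`
#'   (data.frame `t`, `l_az`, `l_el`, `r_az`, `r_el`), `velocity`
#'   (data.frame `t`, `l_az_vel`, `l_el_vel`, `l_omega`, `r_az_vel`,
#'   `r_el_vel`, `r_omega`) and the `settings` used.
#' @export
compute_kinematics <- function(recording, settings = NULL) {
  stopifnot(inherits(recording, "wg_recording"))
  g <- recording$gaze
  rate <- recording$meta$nominal_gaze_rate_hz
  if (is.null(settings)) settings <- .default_sg(rate)
  if (!inherits(settings, "sg_settings"))
    settings <- do.call(sg_settings, as.list(settings))
  dt <- 1 / rate
  vel <- data.frame(t = g$t)
  for (e in c("l", "r")) {
    az <- g[[paste0(e, "_az")]]
    el <- g[[paste0(e, "_el")]]
    azd <- sg_differentiate(az, dt, settings)
    eld <- sg_differentiate(el, dt, settings)
    vel[[paste0(e, "_az_vel")]] <- azd
    vel[[paste0(e, "_el_vel")]] <- eld
    vel[[paste0(e, "_omega")]] <- eye_velocity(azd, eld, el)
  }
  recording$derived <- list(
    orientation = g[, c("t", "l_az", "l_el", "r_az", "r_el")],
    velocity = vel,
    settings = settings
  )
  recording
}
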