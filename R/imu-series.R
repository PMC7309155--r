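#' Construct an IMU time-series object
#'
#' Bundles the six synchronized channels recorded by a lumbar-worn inertial
#' sensor during a walking test: accelerations `a_ml`, `a_v`, `a_ap`
#' (mediolateral, vertical, anteroposterior; m/s^2) and angular velocities
#' `w_ml`, `w_v`, `w_ap` (deg/s), uniformly sampled. The object is a tibble
#' with a `t` column (seconds, 0-based) and a `sampling_rate` attribute.
#'
#' @param a_ml,a_v,a_ap Acceleration channels, m/s^2.
#' @param w_ml,w_v,w_ap Angular-velocity channels, deg/s.
#' @param sampling_rate Sampling rate in Hz (default 100).
#' @param t Optional time stamps in seconds; defaults to
#'   `(0:(n-1))/sampling_rate`.
#' @return An `imu_series` tibble with columns `t`, `a_ml`, `a_v`, `a_ap`,
#'   `w_ml`, `w_v`, `w_ap`.
#' @export
#' @examples
#' s <- imu_series(a_ml = rnorm(200), a_v = rnorm(200), a_ap = rnorm(200),
#'                 w_ml = rnorm(200), w_v = rnorm(200), w_ap = rnorm(200))
#' imu_duration(s)
imu_series <- function(a_ml, a_v, a_ap, w_ml, w_v, w_ap,
                       sampling_rate = 100, t = NULL) {
  chans <- list(a_ml = a_ml, a_v = a_v, a_ap = a_ap,
                w_ml = w_ml, w_v = w_v, w_ap = w_ap)
  n <- length(a_ml)
  if (is.null(t)) t <- (seq_len(n) - 1) / sampling_rate
  out <- tibble::new_tibble(c(list(t = as.numeric(t)),
                              lapply(chans, as.numeric)),
                            nrow = n,
                            sampling_rate = as.numeric(sampling_rate),
                            class = "imu_series")
  validate_imu_series(out)
}

#' @importFrom pillar tbl_sum
#' @export
tbl_sum.imu_series <- function(x, ...) {
  c("IMU series" = sprintf("%d samples @ %g Hz (%.1f s)",
                           nrow(x), imu_rate(x), imu_duration(x)))
}

#' Sampling rate of an IMU series, Hz
#' @param series An `imu_series`.
#' @return Scalar, Hz.
#' @export
imu_rate <- function(series) attr(series, "sampling_rate")

#' Recording duration of an IMU series, seconds
#'
#' Duration is `n / sampling_rate`: the time budget covered by the samples,
#' so that an exact number of fixed-duration frames fits a recording.
#' @param series An `imu_series`.
#' @return Scalar, seconds.
#' @export
imu_duration <- function(series) nrow(series) / imu_rate(series)

#' Validate IMU series invariants
#'
#' Checks that all six channels are present with equal length >= 2, values
#' are finite, and time stamps are uniform at `1/sampling_rate` within
#' 1e-9 s.
#'
#' @param series An `imu_series`.
#' @return The input, invisibly unchanged, or an error.
#' @export
validate_imu_series <- function(series) {
  need <- c("t", imu_channels())
  missing <- setdiff(need, names(series))
  if (length(missing)) {
    abort(sprintf("IMU series is missing column(s): %s",
                  paste(missing, collapse = ", ")),
          class = "gaitrisk_format_error")
  }
  if (nrow(series) < 2) {
    abort("IMU series must have at least 2 samples",
          class = "gaitrisk_format_error")
  }
  bad <- need[!map_lgl(need, function(cl) all(is.finite(series[[cl]])))]
  if (length(bad)) {
    abort(sprintf("non-finite values in column(s): %s",
                  paste(bad, collapse = ", ")),
          class = "gaitrisk_format_error")
  }
  rate <- imu_rate(series)
  if (is.null(rate) || !is.finite(rate) || rate <= 0) {
    abort("sampling_rate attribute must be a positive number",
          class = "gaitrisk_format_error")
  }
  dt <- diff(series$t)
  if (any(dt <= 0) || any(abs(dt - 1 / rate) > 1e-9)) {
    abort(sprintf("time stamps are not uniform at 1/%g s within 1e-9", rate),
          class = "gaitrisk_sampling_error")
  }
  series
}
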