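#' Fit a lognormal distribution to a median and quartiles
#'
#' Returns the lognormal whose log is Gaussian with `mu = log(median)` and
#' `sigma = log(q3/q1) / (2 * z_0.75)`, `z_0.75` the standard normal upper
#' quartile. When the printed quartiles are log-symmetric
#' (`q3/median = median/q1`) the fitted theoretical quartiles reproduce
#' them exactly; otherwise this is the symmetric-in-log compromise and the
#' residual shows up in the quartiles, never in the median.
#'
#' @param median,q1,q3 Positive numbers, `q1 < median < q3` (or all equal,
#'   giving a point mass).
#' @return List with `mu`, `sigma` (log scale).
#' @export
#' @examples
#' fit_lognormal_from_quartiles(23, 19, 31)  # TUG times of fallers
fit_lognormal_from_quartiles <- function(median, q1, q3) {
  if (any(c(median, q1, q3) <= 0)) abort("quartiles must be positive")
  if (!(q1 <= median && median <= q3)) abort("need q1 <= median <= q3")
  list(mu = log(median), sigma = log(q3 / q1) / (2 * qnorm(0.75)))
}

#' Group-level generator parameters
#'
#' All tunable knobs of the synthetic gait generator for one group
#' (fallers or nonfallers). Channel-wise targets are the cohort *medians*
#' the generator is calibrated to; between-participant spread of the SD
#' targets is lognormal with the given log-sigma.
#'
#' @param sd_median Named vector (6 channels) of target median SDs, in
#'   channel units (m/s^2 for `a_*`, deg/s for `w_*`).
#' @param sd_logspread Named vector of lognormal sigmas for the
#'   between-participant SD draw (dimensionless, log scale).
#' @param d_median Named vector of target median fractal dimensions, each
#'   in (1, 2).
#' @param stride_frequency Stride (carrier) frequency, Hz.
#' @param harmonic_amplitudes Relative amplitudes of the carrier harmonics.
#' @param noise_fraction Fraction of signal variance from the fractional
#'   Brownian component, in \[0, 1\].
#' @param turnaround_period Seconds between turnaround bursts (vertical
#'   angular velocity only).
#' @param turnaround_amplitude Peak amplitude of a turnaround burst, deg/s.
#' @param turnaround_width Gaussian time-width (sigma) of a burst, s.
#' @param tug_median,tug_q1,tug_q3 TUG time quartiles, seconds.
#' @param tug_imu_correlation Gaussian-copula correlation between the TUG
#'   draw and the anteroposterior SD draw (default 0 = independent).
#' @return A `group_params` list.
#' @seealso [faller_params()], [nonfaller_params()]
#' @export
group_params <- function(sd_median, sd_logspread, d_median,
                         stride_frequency = 0.85,
                         harmonic_amplitudes = c(1, 0.5, 0.25),
                         noise_fraction = 0.9,
                         turnaround_period = 30,
                         turnaround_amplitude = 90,
                         turnaround_width = 1.5,
                         tug_median, tug_q1, tug_q3,
                         tug_imu_correlation = 0) {
  ch <- imu_channels()
  stopifnot(setequal(names(sd_median), ch), setequal(names(sd_logspread), ch),
            setequal(names(d_median), ch))
  if (any(d_median <= 1 | d_median >= 2)) {
    abort("target fractal dimensions must lie strictly between 1 and 2")
  }
  if (noise_fraction < 0 || noise_fraction > 1) {
    abort("noise_fraction must be in [0, 1]")
  }
  if (!(tug_q1 <= tug_median && tug_median <= tug_q3)) {
    abort("need tug_q1 <= tug_median <= tug_q3")
  }
  structure(list(sd_median = sd_median[ch], sd_logspread = sd_logspread[ch],
                 d_median = d_median[ch],
                 stride_frequency = stride_frequency,
                 harmonic_amplitudes = harmonic_amplitudes,
                 noise_fraction = noise_fraction,
                 turnaround_period = turnaround_period,
                 turnaround_amplitude = turnaround_amplitude,
                 turnaround_width = turnaround_width,
                 tug_median = tug_median, tug_q1 = tug_q1, tug_q3 = tug_q3,
                 tug_imu_correlation = tug_imu_correlation),
            class = "group_params")
}

# sigma of the lognormal SD draw from printed quartiles
.sd_spread <- function(median, q1, q3) {
  fit_lognormal_from_quartiles(median, q1, q3)$sigma
}

#' Default generator parameters for the faller group
#'
#' Cohort targets for fallers: higher anteroposterior acceleration SD
#' (median 0.120 m/s^2), lower vertical-acceleration fractal dimension
#' (1.78) and slower TUG times (median 23 s, quartiles 19-31 s). Channels
#' without a group contrast share the nonfaller targets so that they stay
#' statistically indistinguishable between groups.
#'
#' @return A [group_params()] object.
#' @export
faller_params <- function() {
  p <- nonfaller_params()
  p$sd_median["a_ap"] <- 0.120
  p$sd_logspread["a_ap"] <- .sd_spread(0.120, 0.0901, 0.173)
  p$d_median["a_v"] <- 1.78
  p$tug_median <- 23; p$tug_q1 <- 19; p$tug_q3 <- 31
  p
}

#' Default generator parameters for the nonfaller group
#'
#' Median SD targets per channel (m/s^2 and deg/s), median fractal
#' dimension targets, and TUG quartiles 19 s \[16-25\].
#'
#' @return A [group_params()] object.
#' @export
nonfaller_params <- function() {
  sd_med <- c(a_ml = 0.0950, a_v = 0.101, a_ap = 0.0900,
              w_ml = 13.7, w_v = 18.4, w_ap = 8.79)
  sd_spr <- c(a_ml = .sd_spread(0.0950, 0.0747, 0.109),
              a_v = .sd_spread(0.101, 0.0868, 0.130),
              a_ap = .sd_spread(0.0900, 0.0753, 0.120),
              w_ml = .sd_spread(13.7, 11.1, 19.2),
              w_v = .sd_spread(18.4, 15.0, 21.9),
              w_ap = .sd_spread(8.79, 7.44, 12.6))
  d_med <- c(a_ml = 1.81, a_v = 1.81, a_ap = 1.79,
             w_ml = 1.78, w_v = 1.74, w_ap = 1.82)
  group_params(sd_median = sd_med, sd_logspread = sd_spr, d_median = d_med,
               tug_median = 19, tug_q1 = 16, tug_q3 = 25)
}

#' Calibrate the Hurst exponent against the fractal-dimension estimator
#'
#' The generator controls signal roughness through the Hurst exponent `H`
#' of its fractional Brownian component, but group targets are stated as
#' fractal dimensions *as measured by the package's own estimator*. This
#' Monte-Carlo calibration maps each grid `H` to the mean estimated
#' dimension of synthetic carrier+noise signals, so targets can be
#' inverted through it. The mapping must be monotone decreasing in `H`;
#' violations beyond Monte-Carlo error are flagged with a warning (the
#' table is still returned) and the inversion uses an isotonic fit.
#'
#' @param hurst_grid Grid of Hurst exponents in (0, 1).
#' @param noise_fraction Variance fraction of the fBm component.
#' @param n_reps Monte-Carlo replicates per grid point.
#' @param seed Integer seed (fixed default: the calibration is a design
#'   constant, not part of a cohort's randomness).
#' @param duration_s,sampling_rate Signal geometry used for calibration;
#'   match the cohorts you intend to generate.
#' @param stride_frequency,harmonic_amplitudes Carrier shape.
#' @param config Estimator [box_count_config()].
#' @return A `hurst_calibration` tibble (`hurst`, `d_mean`, `d_se`,
#'   `d_iso`) with the settings stored as attributes.
#' @export
calibrate_hurst <- function(hurst_grid = seq(0.05, 0.325, by = 0.025),
                            noise_fraction = 0.9, n_reps = 10, seed = 193L,
                            duration_s = 360, sampling_rate = 100,
                            stride_frequency = 0.85,
                            harmonic_amplitudes = c(1, 0.5, 0.25),
                            config = box_count_config()) {
  stopifnot(all(hurst_grid > 0 & hurst_grid < 1))
  hurst_grid <- sort(hurst_grid)
  n <- as.integer(round(duration_s * sampling_rate))
  tt <- (0:(n - 1)) / sampling_rate
  ds <- withr::with_seed(seed, {
    map(hurst_grid, function(H) {
      vapply(seq_len(n_reps), function(r) {
        x <- .gait_channel(n, tt, H, noise_fraction, stride_frequency,
                           harmonic_amplitudes)
        box_counting_dimension(x, t = tt, config = config)
      }, 0)
    })
  })
  out <- tibble(hurst = hurst_grid,
                d_mean = map_dbl(ds, mean),
                d_se = map_dbl(ds, ~ sd(.x) / sqrt(length(.x))))
  iso <- isoreg(out$hurst, -out$d_mean)
  out$d_iso <- -iso$yf
  viol <- which(diff(out$d_mean) > 2 * sqrt(out$d_se[-1]^2 +
                                              out$d_se[-nrow(out)]^2))
  if (length(viol)) {
    warn(sprintf(paste0("calibration not monotone decreasing beyond ",
                        "Monte-Carlo error at H = %s"),
                 paste(out$hurst[viol + 1], collapse = ", ")))
  }
  structure(out, class = c("hurst_calibration", class(out)),
            noise_fraction = noise_fraction, n_reps = n_reps, seed = seed,
            duration_s = duration_s, sampling_rate = sampling_rate)
}

#' Invert a Hurst calibration at a target dimension
#'
#' @param calibration A [calibrate_hurst()] table.
#' @param target_d Target estimated dimension(s).
#' @param tolerance Targets within this distance outside the calibrated
#'   range are clamped to the boundary (with a warning); farther targets
#'   error.
#' @return Hurst exponent(s) achieving the target(s) under the calibrated
#'   generator settings.
#' @export
hurst_for_dimension <- function(calibration, target_d, tolerance = 0.05) {
  rng <- range(calibration$d_iso)
  off <- pmax(target_d - rng[2], rng[1] - target_d, 0)
  if (any(off > tolerance)) {
    abort(sprintf("target D %.3f outside calibrated range [%.3f, %.3f]",
                  target_d[which.max(off)], rng[1], rng[2]),
          class = "gaitrisk_calibration_error")
  }
  if (any(off > 0)) {
    warn(sprintf("target D clamped to calibrated range [%.3f, %.3f]",
                 rng[1], rng[2]))
  }
  # d_iso is non-increasing in hurst; collapse ties for interpolation
  d <- rev(calibration$d_iso)
  h <- rev(calibration$hurst)
  keep <- !duplicated(d)
  approx(d[keep], h[keep], xout = pmin(pmax(target_d, rng[1]), rng[2]),
         rule = 2)$y
}

# cache for the default calibration (one per session)
.gaitrisk_cache <- new.env(parent = emptyenv())

#' Default Hurst calibration (computed once per session)
#'
#' [calibrate_hurst()] at the generator defaults, memoised.
#' @return A `hurst_calibration`.
#' @export
default_hurst_calibration <- function() {
  if (is.null(.gaitrisk_cache$calibration)) {
    .gaitrisk_cache$calibration <- suppressWarnings(calibrate_hurst())
  }
  .gaitrisk_cache$calibration
}

# one walking channel: stride-harmonic carrier + fBm roughness, unit SD
.gait_channel <- function(n, tt, hurst, noise_fraction, stride_frequency,
                          harmonic_amplitudes) {
  carrier <- 0
  for (h in seq_along(harmonic_amplitudes)) {
    carrier <- carrier + harmonic_amplitudes[h] *
      sin(2 * pi * h * stride_frequency * tt + runif(1, 0, 2 * pi))
  }
  if (noise_fraction >= 1) {
    noise <- fbm_sim(n, hurst)
    return(noise / sd(noise))
  }
  x <- carrier / sd(carrier) * sqrt(1 - noise_fraction)
  if (noise_fraction > 0) {
    noise <- fbm_sim(n, hurst)
    x <- x + noise / sd(noise) * sqrt(noise_fraction)
  }
  x / sd(x)
}

#' Generate one synthetic participant
#'
#' Draws a participant from a group model: each channel is a
#' stride-periodic harmonic carrier plus a fractional Brownian roughness
#' component (Hurst exponent calibrated so the estimated fractal dimension
#' matches the group target), the vertical angular velocity additionally
#' carries Gaussian-shaped turnaround bursts at the configured period, and
#' each channel is rescaled post hoc so its sample SD equals the
#' participant's SD target exactly. SD targets are drawn lognormally
#' around the group median; the TUG time is drawn from the lognormal
#' fitted to the group quartiles.
#'
#' @param params A [group_params()].
#' @param duration_s Recording duration, seconds (default 360).
#' @param sampling_rate Hz (default 100).
#' @param seed Integer seed; identical seeds give identical participants.
#' @param participant_id Identifier string.
#' @param faller Group label carried into the record (0/1).
#' @param calibration A `hurst_calibration`; default
#'   [default_hurst_calibration()]. Must match `noise_fraction`.
#' @return One-row cohort tibble: `participant_id`, `tug_s`, `faller`,
#'   `series` (list column holding the [imu_series()]) and `sd_target`
#'   (list column with the participant's drawn per-channel SD targets,
#'   which the generated channels match exactly).
#' @export
generate_participant <- function(params, duration_s = 360,
                                 sampling_rate = 100, seed,
                                 participant_id = "P1", faller = 0L,
                                 calibration = NULL) {
  stopifnot(inherits(params, "group_params"))
  if (is.null(calibration)) calibration <- default_hurst_calibration()
  ch <- imu_channels()
  # memoise the inversion per (targets, calibration): one clamp warning
  # per parameter set, not one per participant
  key <- paste(c(signif(params$d_median[ch], 10), attr(calibration, "seed"),
                 attr(calibration, "noise_fraction"), nrow(calibration)),
               collapse = "|")
  if (is.null(.gaitrisk_cache$hurst[[key]])) {
    if (is.null(.gaitrisk_cache$hurst)) .gaitrisk_cache$hurst <- list()
    .gaitrisk_cache$hurst[[key]] <-
      setNames(hurst_for_dimension(calibration, params$d_median[ch]), ch)
  }
  hs <- .gaitrisk_cache$hurst[[key]]
  n <- as.integer(round(duration_s * sampling_rate))
  tt <- (0:(n - 1)) / sampling_rate
  tugfit <- fit_lognormal_from_quartiles(params$tug_median, params$tug_q1,
                                         params$tug_q3)
  rec <- withr::with_seed(seed, {
    z <- rnorm(2)  # (TUG, a_ap SD) copula pair
    rho <- params$tug_imu_correlation
    z_sd_ap <- rho * z[1] + sqrt(1 - rho^2) * z[2]
    tug <- exp(tugfit$mu + tugfit$sigma * z[1])
    sd_targets <- setNames(vapply(ch, function(cl) {
      zc <- if (cl == "a_ap") z_sd_ap else rnorm(1)
      exp(log(params$sd_median[[cl]]) + params$sd_logspread[[cl]] * zc)
    }, 0), ch)
    sig <- lapply(ch, function(cl) {
      x <- .gait_channel(n, tt, hs[[cl]], params$noise_fraction,
                         params$stride_frequency,
                         params$harmonic_amplitudes)
      if (cl == "w_v" && params$turnaround_period > 0) {
        centers <- seq(params$turnaround_period, duration_s - 1,
                       by = params$turnaround_period)
        burst <- rep(0, n)
        for (cc in centers) {
          burst <- burst + exp(-(tt - cc)^2 / (2 * params$turnaround_width^2))
        }
        # bursts in physical units on top of the unit-SD walking signal
        x <- x + burst * params$turnaround_amplitude / sd_targets[[cl]]
      }
      x * (sd_targets[[cl]] / sd(x))  # post-hoc exact SD scaling
    })
    names(sig) <- ch
    list(tug = tug, sig = sig, sd_targets = sd_targets)
  })
  series <- imu_series(a_ml = rec$sig$a_ml, a_v = rec$sig$a_v,
                       a_ap = rec$sig$a_ap, w_ml = rec$sig$w_ml,
                       w_v = rec$sig$w_v, w_ap = rec$sig$w_ap,
                       sampling_rate = sampling_rate)
  tibble(participant_id = participant_id, tug_s = rec$tug,
         faller = as.integer(faller), series = list(series),
         sd_target = list(rec$sd_targets))
}

#' Generate a synthetic cohort of fallers and nonfallers
#'
#' Draws `n_fallers` + `n_nonfallers` independent participants (default
#' cohort composition 23/50) with per-participant seeds derived from the
#' master seed, so the whole cohort is reproducible.
#'
#' @param faller_params,nonfaller_params [group_params()] for each group.
#' @param n_fallers,n_nonfallers Group sizes (defaults 23 and 50).
#' @param seed Master integer seed.
#' @param duration_s,sampling_rate,calibration As in
#'   [generate_participant()].
#' @return Cohort tibble (`participant_id`, `tug_s`, `faller`, `series`).
#' @export
#' @examples
#' \donttest{
#' cohort <- generate_cohort(n_fallers = 2, n_nonfallers = 3, seed = 1,
#'                           duration_s = 40)
#' }
generate_cohort <- function(faller_params = gaitrisk::faller_params(),
                            nonfaller_params = gaitrisk::nonfaller_params(),
                            n_fallers = 23, n_nonfallers = 50, seed,
                            duration_s = 360, sampling_rate = 100,
                            calibration = NULL) {
  stopifnot(n_fallers >= 0, n_nonfallers >= 0, n_fallers + n_nonfallers >= 1)
  if (is.null(calibration)) calibration <- default_hurst_calibration()
  ntot <- n_fallers + n_nonfallers
  seeds <- withr::with_seed(seed, sample.int(2147483646L, ntot))
  ids <- c(sprintf("F%02d", seq_len(n_fallers)),
           sprintf("N%02d", seq_len(n_nonfallers)))
  labs <- rep(c(1L, 0L), c(n_fallers, n_nonfallers))
  prms <- c(rep(list(faller_params), n_fallers),
            rep(list(nonfaller_params), n_nonfallers))
  bind_rows(pmap(list(prms, seeds, ids, labs),
                 function(p, s, id, lb) {
                   generate_participant(p, duration_s = duration_s,
                                        sampling_rate = sampling_rate,
                                        seed = s, participant_id = id,
                                        faller = lb,
                                        calibration = calibration)
                 }))
}
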