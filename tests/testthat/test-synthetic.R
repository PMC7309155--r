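test_that("lognormal quartile fit reproduces the stated quartiles", {
  f <- fit_lognormal_from_quartiles(23, 19, 31)
  expect_equal(f$mu, log(23))
  # sampled median over 1e5 draws sits at the target median
  med <- withr::with_seed(1, median(rlnorm(1e5, f$mu, f$sigma)))
  expect_equal(med, 23, tolerance = 0.01 * 23)
  f2 <- fit_lognormal_from_quartiles(19, 16, 25)
  med2 <- withr::with_seed(2, median(rlnorm(1e5, f2$mu, f2$sigma)))
  expect_equal(med2, 19, tolerance = 0.01 * 19)
  # log-symmetric quartiles are reproduced exactly in theory
  f3 <- fit_lognormal_from_quartiles(10, 5, 20)
  expect_equal(exp(f3$mu + qnorm(0.75) * f3$sigma), 20, tolerance = 1e-9)
  expect_equal(exp(f3$mu - qnorm(0.75) * f3$sigma), 5, tolerance = 1e-9)
  # degenerate point mass
  expect_equal(fit_lognormal_from_quartiles(7, 7, 7)$sigma, 0)
  expect_error(fit_lognormal_from_quartiles(-1, 1, 2), "positive")
  expect_error(fit_lognormal_from_quartiles(3, 4, 5), "q1 <= median")
})

test_that("participants are seed-deterministic with exact SD scaling", {
  cal <- small_calibration()
  p1 <- suppressWarnings(generate_participant(
    small_params(TRUE), duration_s = 40, sampling_rate = 50, seed = 21,
    faller = 1, calibration = cal))
  p2 <- suppressWarnings(generate_participant(
    small_params(TRUE), duration_s = 40, sampling_rate = 50, seed = 21,
    faller = 1, calibration = cal))
  expect_identical(p1$series[[1]], p2$series[[1]])
  expect_identical(p1$tug_s, p2$tug_s)
  # post-hoc scaling: measured channel SD equals the drawn target exactly
  tgt <- p1$sd_target[[1]]
  for (ch in imu_channels()) {
    expect_lt(abs(sd(p1$series[[1]][[ch]]) - tgt[[ch]]), 1e-9)
  }
  expect_gt(p1$tug_s, 0)
})

test_that("cohorts have the requested composition and reproducibility", {
  coh <- small_cohort(3, 5, seed = 31)
  expect_equal(nrow(coh), 8)
  expect_equal(sum(coh$faller), 3)
  coh2 <- small_cohort(3, 5, seed = 31)
  expect_identical(coh$series, coh2$series)
  coh0 <- small_cohort(0, 4, seed = 31)
  expect_equal(sum(coh0$faller), 0)
  # default composition without generating signals: argument defaults
  expect_equal(formals(generate_cohort)$n_fallers, 23)
  expect_equal(formals(generate_cohort)$n_nonfallers, 50)
})

test_that("turnaround bursts sit in w_v at the configured period", {
  cal <- small_calibration()
  p <- suppressWarnings(generate_participant(
    small_params(FALSE), duration_s = 120, sampling_rate = 50, seed = 77,
    calibration = cal))
  s <- p$series[[1]]
  # matched filter with the burst template, then one argmax per burst
  g <- dnorm(seq(-4, 4, by = 1 / 50), 0, 1.5)
  mf <- stats::filter(s$w_v - median(s$w_v), g / sum(g))
  mf[is.na(mf)] <- 0
  thr <- 0.5 * max(mf)
  above <- which(mf > thr)
  groups <- cumsum(c(1, diff(above) > 5 * 50))  # gaps > 5 s split bursts
  centers <- tapply(above, groups, function(i) i[which.max(mf[i])])
  times <- s$t[unlist(centers)]
  expect_equal(length(times), 3)  # bursts at 30, 60, 90 s
  # the configured period is recovered to within one sample
  expect_lt(abs(median(diff(times)) - 30), 1 / 50 + 1e-9)
  # no comparable bursts in the other angular channel
  z_ml <- max(abs(s$w_ml - mean(s$w_ml))) / sd(s$w_ml)
  z_v <- max(s$w_v - mean(s$w_v)) / sd(s$w_v)
  expect_gt(z_v, z_ml)
})

test_that("Hurst calibration is monotone and matches fBm theory", {
  cal <- suppressWarnings(calibrate_hurst(
    hurst_grid = c(0.2, 0.5, 0.8), noise_fraction = 1, n_reps = 3,
    seed = 12, duration_s = 360, sampling_rate = 100))
  expect_true(all(diff(cal$d_iso) <= 0))
  expect_equal(cal$d_mean[cal$hurst == 0.5], 1.5, tolerance = 0.06)
  expect_equal(cal$d_mean[cal$hurst == 0.8], 1.2, tolerance = 0.08)
  expect_equal(cal$d_mean[cal$hurst == 0.2], 1.8, tolerance = 0.08)
  # inversion: h_for_d returns grid values at the tabulated dimensions
  h <- hurst_for_dimension(cal, cal$d_iso[2])
  expect_equal(h, 0.5, tolerance = 0.05)
  # unreachable target well outside the calibrated range errors
  expect_error(hurst_for_dimension(cal, 1.05),
               class = "gaitrisk_calibration_error")
})

test_that("estimated dimensions of generated signals stay inside [1, 2]", {
  coh <- small_cohort(2, 2, seed = 41, duration_s = 40)
  for (s in coh$series) {
    d <- suppressWarnings(variability_profile(s))$d
    expect_true(all(d >= 1 - 0.05 & d <= 2 + 0.05))
  }
})

test_that("faller cohorts separate on SDa_ap and Da_v as calibrated", {
  # group contrasts at the default calibration, shortened recordings;
  # SD draws are duration-free, the dimension gap survives at 120 s
  rej_sd <- 0
  rej_d <- 0
  n_seeds <- 6
  for (sd_ in seq_len(n_seeds)) {
    coh <- suppressWarnings(generate_cohort(
      seed = sd_, duration_s = 120, sampling_rate = 100,
      calibration = default_hurst_calibration()))
    sd_ap <- vapply(coh$series, function(s) sd(s$a_ap), 0)
    d_av <- vapply(coh$series, function(s)
      suppressWarnings(box_counting_dimension(s$a_v, t = s$t)), 0)
    f <- coh$faller == 1
    rej_sd <- rej_sd + (mann_whitney(sd_ap[f], sd_ap[!f], "greater")$p < 0.05)
    rej_d <- rej_d + (mann_whitney(d_av[f], d_av[!f], "less")$p < 0.05)
  }
  expect_gte(rej_d, ceiling(0.8 * n_seeds))
  expect_gte(rej_sd, ceiling(0.8 * n_seeds))
})
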