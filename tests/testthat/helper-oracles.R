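# Independent oracles used across the suite. Each deliberately takes a
# different algorithmic route than the package implementation.

# Brute-force graph box count: marks an occupancy grid cell-by-cell from
# the piecewise-linear segments, then derives the crossing count per time
# column (occupied cells minus one per occupied column). x, t raw; same
# unit-square normalization as the estimator.
brute_box_count <- function(x, t, k) {
  nb <- 2^k
  rx <- range(x)
  y <- (x - rx[1]) / diff(rx)
  tt <- (t - t[1]) / (t[length(t)] - t[1])
  grid <- matrix(FALSE, nb, nb)  # rows = y cells, cols = t cells
  cell <- function(v) pmin(floor(v * nb), nb - 1) + 1
  for (i in seq_len(length(y) - 1)) {
    t1 <- tt[i]; t2 <- tt[i + 1]; y1 <- y[i]; y2 <- y[i + 1]
    for (j in cell(t1):cell(t2)) {
      xs <- max(t1, (j - 1) / nb)
      xe <- min(t2, j / nb)
      ys <- y1 + (y2 - y1) * (xs - t1) / (t2 - t1)
      ye <- y1 + (y2 - y1) * (xe - t1) / (t2 - t1)
      grid[cell(min(ys, ye)):cell(max(ys, ye)), j] <- TRUE
    }
  }
  occ_cols <- colSums(grid) > 0
  max(sum(grid) - sum(occ_cols), 1)
}

# AUC by explicit pair counting (concordant + half ties)
brute_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# Youden threshold by direct evaluation of every candidate midpoint
brute_youden <- function(scores, labels) {
  s <- sort(unique(scores))
  cand <- c(s[1] - 1, (head(s, -1) + tail(s, -1)) / 2, s[length(s)] + 1)
  j <- vapply(cand, function(cut) {
    pred <- scores > cut
    mean(pred[labels == 1]) + mean(!pred[labels == 0]) - 1
  }, 0)
  list(threshold = cand[which(j == max(j))[1]], j = max(j))
}

# Exhaustive TUG+ grid accuracy maximum (value only)
brute_tugplus_best_acc <- function(indices, t_star, combine = "or") {
  grid_of <- function(v) {
    s <- sort(unique(v))
    c(s[1] - 1, (head(s, -1) + tail(s, -1)) / 2, s[length(s)] + 1)
  }
  best <- -Inf
  q1 <- indices$tug_s > t_star
  for (sc in grid_of(indices$sd_a_ap)) {
    for (dc in grid_of(indices$d_a_v)) {
      q2 <- indices$sd_a_ap > sc
      q3 <- indices$d_a_v < dc
      risk <- if (combine == "or") q1 | q2 | q3 else q1 & (q2 | q3)
      best <- max(best, mean(risk == (indices$faller == 1)))
    }
  }
  best
}

# Exact Mann-Whitney two-sided p by full enumeration of group assignments
enum_mw_p <- function(x, y) {
  nx <- length(x)
  all <- c(x, y)
  r <- rank(all)
  u_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  mu <- nx * length(y) / 2
  combs <- utils::combn(length(all), nx)
  us <- colSums(matrix(r[combs], nrow = nx)) - nx * (nx + 1) / 2
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

# tiny deterministic IMU series for structural tests
toy_series <- function(n = 200, rate = 50, seed = 1) {
  withr::with_seed(seed, {
    imu_series(a_ml = rnorm(n), a_v = rnorm(n), a_ap = rnorm(n),
               w_ml = rnorm(n), w_v = rnorm(n), w_ap = rnorm(n),
               sampling_rate = rate)
  })
}

# small, fast cohort for structural tests (coarse calibration cached)
.test_env <- new.env(parent = emptyenv())
small_calibration <- function() {
  if (is.null(.test_env$cal)) {
    .test_env$cal <- suppressWarnings(
      calibrate_hurst(hurst_grid = c(0.1, 0.2, 0.3), n_reps = 2,
                      duration_s = 40, sampling_rate = 50, seed = 5))
  }
  .test_env$cal
}
# group params with dimension targets reachable at the short test
# geometry (short signals measure lower D than 6-minute recordings)
small_params <- function(faller = FALSE) {
  p <- if (faller) faller_params() else nonfaller_params()
  p$d_median[] <- if (faller) 1.64 else 1.68
  p
}
small_cohort <- function(n_f = 3, n_n = 4, seed = 7, duration_s = 40,
                         rate = 50) {
  suppressWarnings(generate_cohort(
    small_params(TRUE), small_params(FALSE),
    n_fallers = n_f, n_nonfallers = n_n, seed = seed,
    duration_s = duration_s, sampling_rate = rate,
    calibration = small_calibration()))
}
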