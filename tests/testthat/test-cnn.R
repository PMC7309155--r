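# two-tone toy cohort: class 1 walks at 2 Hz, class 0 at 6 Hz; short
# recordings and a narrow network keep these fits fast
tone_cohort <- function(n_per_class = 3, duration = 24, rate = 25,
                        seed = 1) {
  withr::with_seed(seed, {
    mk <- function(freq, id, lab) {
      n <- duration * rate
      t <- (0:(n - 1)) / rate
      chan <- function() sin(2 * pi * freq * t + runif(1, 0, 2 * pi)) +
        rnorm(n, 0, 0.3)
      tibble::tibble(
        participant_id = id, tug_s = 20, faller = lab,
        series = list(imu_series(a_ml = chan(), a_v = chan(),
                                 a_ap = chan(), w_ml = chan(),
                                 w_v = chan(), w_ap = chan(),
                                 sampling_rate = rate)))
    }
    dplyr::bind_rows(
      lapply(seq_len(n_per_class), function(i) mk(2, sprintf("A%d", i), 1L)),
      lapply(seq_len(n_per_class), function(i) mk(6, sprintf("B%d", i), 0L)))
  })
}

tiny_config <- function(...) {
  cnn_config(window_s = 4, train_step_s = 2, conv_filters = c(4, 8),
             kernel_time = 5, stride = c(2, 1), pool = c(2, 2),
             dense_widths = c(8, 4), epochs = 15, batch_size = 16,
             patience = 15, val_fraction = 0.3, ...)
}

test_that("cohort splits are balanced, disjoint and reproducible", {
  coh <- tibble::tibble(participant_id = sprintf("P%02d", 1:73),
                        faller = rep(c(1L, 0L), c(23, 50)))
  sp <- split_cohort(coh, seed = 5)
  expect_length(sp$test_ids, 16)
  expect_length(sp$train_ids, 57)
  expect_length(intersect(sp$train_ids, sp$test_ids), 0)
  tf <- coh$faller[match(sp$test_ids, coh$participant_id)]
  expect_equal(sum(tf), 8)
  expect_equal(sum(coh$faller[match(sp$train_ids, coh$participant_id)]), 15)
  expect_identical(split_cohort(coh, seed = 5)$test_ids, sp$test_ids)
  sp0 <- split_cohort(coh, n_test_fallers = 0, seed = 5)
  expect_equal(sum(coh$faller[match(sp0$train_ids, coh$participant_id)]), 23)
  expect_error(split_cohort(coh[1:10, ], seed = 1), "not enough")
})

test_that("frame datasets standardize with frozen training statistics", {
  coh <- tone_cohort()
  d <- make_frame_dataset(coh, window_s = 4, step_s = 2,
                          frame_scale = "global")
  expect_equal(ncol(d$x), nrow(coh) * 11)  # (24-4)/2+1 frames each
  # pooled per-channel mean 0, SD 1 by construction
  ch <- rep(1:6, times = d$width)
  for (cl in 1:6) {
    expect_equal(mean(d$x[ch == cl, ]), 0, tolerance = 1e-9)
    expect_equal(sd(as.vector(d$x[ch == cl, ])), 1, tolerance = 0.01)
  }
  # test-set frames reuse the training stats unchanged
  d2 <- make_frame_dataset(coh[1:2, ], window_s = 4, step_s = 4,
                           stats = d$stats, frame_scale = "global")
  expect_identical(d2$stats, d$stats)
  # per-frame normalization gives every frame-channel unit SD
  d3 <- make_frame_dataset(coh, window_s = 4, step_s = 4,
                           frame_scale = "frame")
  arr <- array(d3$x * d3$stats$sd[rep(1:6, d3$width)], c(6, d3$width,
                                                         ncol(d3$x)))
  expect_equal(sd(arr[3, , 5]) * sqrt((d3$width - 1) / d3$width), 1,
               tolerance = 1e-6)
})

test_that("frames never leak a participant across the split", {
  coh <- tone_cohort()
  sp <- split_cohort(coh, n_test_fallers = 1, n_test_nonfallers = 1,
                     seed = 2)
  dtr <- make_frame_dataset(coh[coh$participant_id %in% sp$train_ids, ],
                            window_s = 4, step_s = 2)
  dte <- make_frame_dataset(coh[coh$participant_id %in% sp$test_ids, ],
                            window_s = 4, step_s = 4)
  expect_length(intersect(unique(dtr$participant_id),
                          unique(dte$participant_id)), 0)
})

test_that("participant risk is the frame-score mean with a strict cut", {
  d <- list(y = c(1, 1, 1), participant_id = rep("P1", 3))
  r <- participant_risk(NULL, d, scores = c(0.2, 0.4, 0.9))
  expect_equal(r$mean_score, 0.5)
  expect_equal(r$risk, 0L)  # mean exactly 0.5: no risk
  r2 <- participant_risk(NULL, d, scores = c(0.9, 0.9, 0.9))
  expect_equal(r2$mean_score, 0.9)
  expect_equal(r2$risk, 1L)
  # invariant to frame order
  d3 <- list(y = rep(0, 6), participant_id = rep(c("A", "B"), 3))
  s3 <- c(0.1, 0.9, 0.3, 0.8, 0.2, 0.7)
  perm <- c(5, 3, 1, 6, 4, 2)
  r3 <- participant_risk(NULL, d3, scores = s3)
  r4 <- participant_risk(NULL, list(y = rep(0, 6),
                                    participant_id = d3$participant_id[perm]),
                         scores = s3[perm])
  expect_equal(r3, r4)
  expect_error(participant_risk(NULL, list(y = numeric(),
                                           participant_id = character())),
               "no frames")
})

test_that("a constant-positive scorer gives se 1 and sp 0 downstream", {
  risks <- tibble::tibble(risk = rep(1L, 16),
                          faller = rep(c(1L, 0L), each = 8))
  ev <- evaluate_classifier(risks$risk, risks$faller)
  expect_equal(ev$metrics$se, 1)
  expect_equal(ev$metrics$sp, 0)
})

test_that("the CNN fits separable two-tone frames and is deterministic", {
  coh <- tone_cohort()
  d <- make_frame_dataset(coh, window_s = 4, step_s = 2,
                          frame_scale = "frame")
  m1 <- train_cnn(d, tiny_config(), seed = 3)
  expect_s3_class(m1, "gait_cnn")
  acc_train <- mean((predict(m1, d) > 0.5) == d$y)
  expect_gte(acc_train, 0.95)
  # identical seed reproduces identical weights
  m2 <- train_cnn(d, tiny_config(), seed = 3)
  expect_identical(m1$weights, m2$weights)
  # single-class training data is rejected
  d1 <- d
  d1$y <- rep(1, length(d$y))
  expect_error(train_cnn(d1, tiny_config(), seed = 1),
               class = "gaitrisk_single_class_error")
})

test_that("label-shuffled frames give chance-level held-out accuracy", {
  coh <- tone_cohort(n_per_class = 4, seed = 6)
  # shuffle labels at the participant level, then hold two participants out
  withr::with_seed(31, {
    coh$faller <- sample(coh$faller)
  })
  hold <- c("A1", "B3")
  dtr <- make_frame_dataset(coh[!coh$participant_id %in% hold, ],
                            window_s = 4, step_s = 2, frame_scale = "frame")
  dte <- make_frame_dataset(coh[coh$participant_id %in% hold, ],
                            window_s = 4, step_s = 4, stats = dtr$stats,
                            frame_scale = "frame")
  m <- train_cnn(dtr, tiny_config(), seed = 8)
  acc <- mean((predict(m, dte) > 0.5) == dte$y)
  expect_gte(acc, 0.2)
  expect_lte(acc, 0.8)
})

test_that("the full experiment pipeline composes and evaluates", {
  coh <- tone_cohort(n_per_class = 3)
  res <- run_ai_experiment(coh, tiny_config(), seed = 4,
                           n_test_fallers = 1, n_test_nonfallers = 1)
  expect_length(res$split$test_ids, 2)
  expect_equal(nrow(res$risks), 2)
  expect_true(all(res$risks$mean_score >= 0 & res$risks$mean_score <= 1))
  m <- res$metrics
  expect_equal(m$acc, (res$confusion$tp + res$confusion$tn) / 2)
})
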