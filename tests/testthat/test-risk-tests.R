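test_that("ROC curve endpoints, AUC identities and oracles agree", {
  # perfectly separated scores
  r <- roc_curve(c(1, 2, 3, 11, 12, 13), c(0, 0, 0, 1, 1, 1))
  expect_equal(roc_auc(r), 1)
  # all scores identical, labels arbitrary
  r2 <- roc_curve(rep(5, 8), c(1, 0, 1, 0, 1, 0, 1, 0))
  expect_equal(roc_auc(r2), 0.5)
  # hand example against pair-counting oracle
  sc <- c(25, 30, 21, 15, 18, 22)
  lb <- c(1, 1, 1, 0, 0, 0)
  expect_equal(roc_auc(roc_curve(sc, lb)), brute_auc(sc, lb))
  # random instances: AUC equals tie-corrected concordance to 1e-12,
  # and the Mann-Whitney identity U = n1*n2*AUC holds
  withr::with_seed(14, {
    for (i in 1:8) {
      n1 <- sample(3:10, 1); n0 <- sample(3:10, 1)
      s <- c(sample(1:12, n1, TRUE), sample(1:12, n0, TRUE))
      l <- rep(c(1, 0), c(n1, n0))
      auc <- roc_auc(roc_curve(s, l))
      expect_equal(auc, brute_auc(s, l), tolerance = 1e-12)
      u <- mann_whitney(s[l == 1], s[l == 0])$u
      expect_equal(u, n1 * n0 * auc, tolerance = 1e-12)
    }
  })
  # se is non-increasing in the threshold
  r3 <- withr::with_seed(3, roc_curve(rnorm(40), rbinom(40, 1, 0.4)))
  expect_true(all(diff(r3$se) <= 1e-12))
  expect_error(roc_curve(1:4, c(1, 1, 1, 1)),
               class = "gaitrisk_single_class_error")
})

test_that("ROC agrees with the pROC reference implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(25, {
    s <- c(rnorm(20, 1), rnorm(30))
    l <- rep(c(1, 0), c(20, 30))
  })
  auc_ref <- as.numeric(pROC::auc(pROC::roc(l, s, quiet = TRUE,
                                            direction = "<")))
  expect_equal(roc_auc(roc_curve(s, l)), auc_ref, tolerance = 1e-12)
})

test_that("Youden threshold is the midpoint maximizer, low on ties", {
  r <- roc_curve(c(15, 18, 19, 23, 25, 30), c(0, 0, 0, 1, 1, 1))
  y <- youden_threshold(r)
  expect_equal(y$threshold, 21)  # midpoint of the separating gap
  expect_equal(y$j, 1)
  # all identical scores: no usable cut, J = 0
  y0 <- youden_threshold(roc_curve(rep(4, 6), c(1, 0, 1, 0, 1, 0)))
  expect_equal(y0$j, 0)
  # exhaustive oracle on random 20-point sets
  withr::with_seed(16, {
    for (i in 1:6) {
      s <- round(runif(20, 10, 40), 1)
      l <- rbinom(20, 1, 0.4)
      if (length(unique(l)) < 2) next
      got <- youden_threshold(roc_curve(s, l))
      ref <- brute_youden(s, l)
      expect_equal(got$j, ref$j, tolerance = 1e-12)
      expect_equal(got$threshold, ref$threshold)
    }
  })
})

test_that("TUG classification uses a strict threshold", {
  expect_equal(tug_classify(23, 22.5), 1L)
  expect_equal(tug_classify(19, 22.5), 0L)
  expect_equal(tug_classify(22.5, 22.5), 0L)  # exactly at cut: no risk
})

test_that("TUG+ combination logic follows the rule", {
  rule <- tugplus_rule(22.5, 0.105, 1.795, combine = "or")
  # all answers negative / positive
  expect_equal(tugplus_classify(20, 0.08, 1.85, rule), 0L)
  expect_equal(tugplus_classify(25, 0.15, 1.70, rule), 1L)
  # kinematic-only positive still flags risk under the OR rule
  expect_equal(tugplus_classify(20, 0.15, 1.85, rule), 1L)
  # sequential variant requires the TUG question first
  seq_rule <- tugplus_rule(22.5, 0.105, 1.795, combine = "sequential")
  expect_equal(tugplus_classify(20, 0.15, 1.70, seq_rule), 0L)
  expect_equal(tugplus_classify(25, 0.15, 1.85, seq_rule), 1L)
  expect_equal(tugplus_classify(25, 0.08, 1.85, seq_rule), 0L)
  # with the kinematic questions switched off, TUG+ reduces to TUG
  off <- tugplus_rule(22.5, 10, 0)
  tugs <- c(18, 22.5, 23, 30)
  expect_equal(tugplus_classify(tugs, rep(0.1, 4), rep(1.8, 4), off),
               tug_classify(tugs, 22.5))
})

test_that("threshold fitting matches the exhaustive oracle", {
  withr::with_seed(18, {
    for (i in 1:4) {
      idx <- tibble::tibble(
        tug_s = round(runif(20, 12, 35), 1),
        sd_a_ap = round(rlnorm(20, log(0.1), 0.4), 4),
        d_a_v = round(runif(20, 1.7, 1.9), 3),
        faller = rbinom(20, 1, 0.4))
      if (length(unique(idx$faller)) < 2) next
      rule <- fit_tugplus_thresholds(idx, t_star = 22.5)
      expect_equal(attr(rule, "accuracy"),
                   brute_tugplus_best_acc(idx, 22.5))
      # reported accuracy is what the fitted rule actually achieves
      pred <- tugplus_classify(idx$tug_s, idx$sd_a_ap, idx$d_a_v, rule)
      expect_equal(mean(pred == idx$faller), attr(rule, "accuracy"))
      # never worse than the TUG-only rule in-sample
      acc_tug <- mean(tug_classify(idx$tug_s, 22.5) == idx$faller)
      expect_gte(attr(rule, "accuracy"), acc_tug)
    }
  })
})

test_that("a perfectly separating index yields accuracy 1", {
  idx <- tibble::tibble(tug_s = rep(20, 10),
                        sd_a_ap = c(1:5 / 10, 6:10 / 10),
                        d_a_v = rep(1.8, 10),
                        faller = rep(c(0, 1), each = 5))
  rule <- fit_tugplus_thresholds(idx, t_star = 22.5)
  expect_equal(attr(rule, "accuracy"), 1)
})

test_that("logistic fusion behaves sensibly and falls back on separation", {
  withr::with_seed(19, {
    n <- 60
    idx_null <- tibble::tibble(tug_s = runif(n, 15, 30),
                               sd_a_ap = rlnorm(n, log(0.1), 0.3),
                               d_a_v = runif(n, 1.7, 1.9),
                               faller = rbinom(n, 1, 0.3))
  })
  fit <- logistic_fusion_fit(idx_null)
  prev <- mean(idx_null$faller)
  # ML score equation: mean fitted probability equals the prevalence
  expect_equal(mean(predict(fit, idx_null, type = "prob")), prev,
               tolerance = 1e-6)
  # slopes stay small when labels are independent of the features
  expect_lt(abs(fit$coefficients["tug_s"]) * sd(idx_null$tug_s), 1)
  # a strongly predictive feature gets the right sign
  idx_sig <- idx_null
  idx_sig$faller <- as.integer(idx_sig$sd_a_ap +
                                 rnorm(n, 0, 0.02) > 0.1)
  fit2 <- logistic_fusion_fit(idx_sig)
  expect_gt(fit2$coefficients["sd_a_ap"], 0)
  # perfect separation triggers the ridge fallback with a warning
  idx_sep <- idx_null
  idx_sep$faller <- as.integer(idx_sep$tug_s > 22)
  ws <- testthat::capture_warnings(fit3 <- logistic_fusion_fit(idx_sep))
  expect_true(any(grepl("separation", ws)))
  expect_true(fit3$penalized)
  pred <- predict(fit3, idx_sep)
  expect_equal(pred, idx_sep$faller)
  # strict probability cut
  expect_equal(predict(fit3, idx_sep, cut = 1), rep(0L, n))
})
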