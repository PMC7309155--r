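#' Classify fall risk from the TUG time alone
#'
#' Risk is declared when the TUG time strictly exceeds the threshold
#' (a time exactly at the threshold is not at risk).
#'
#' @param tug_time TUG time(s), seconds.
#' @param t_star Threshold, seconds (> 0), typically the Youden-optimal
#'   cut of the cohort's TUG ROC curve.
#' @return Integer 0/1 risk.
#' @export
#' @examples
#' tug_classify(c(23, 19, 22.5), t_star = 22.5)  # 1, 0, 0
tug_classify <- function(tug_time, t_star) {
  stopifnot(t_star > 0)
  as.integer(tug_time > t_star)
}

#' TUG+ decision rule
#'
#' The fitted thresholds and combination logic of the augmented TUG test:
#' a TUG time cut `t_star`, an anteroposterior-acceleration SD cut
#' `sd_aap_star` (risk direction: larger), and a vertical-acceleration
#' fractal-dimension cut `d_av_star` (risk direction: smaller). The three
#' binary answers are combined either disjunctively (`combine = "or"`,
#' default: any positive answer flags risk) or sequentially
#' (`combine = "sequential"`: TUG-positives are re-tested by the two
#' kinematic indices).
#'
#' @param t_star TUG threshold, s.
#' @param sd_aap_star SD threshold for `a_ap`, m/s^2.
#' @param d_av_star Dimension threshold for `a_v`.
#' @param combine `"or"` or `"sequential"`.
#' @return A `tugplus_rule` object.
#' @export
tugplus_rule <- function(t_star, sd_aap_star, d_av_star,
                         combine = c("or", "sequential")) {
  combine <- match.arg(combine)
  stopifnot(t_star > 0, sd_aap_star >= 0)
  structure(list(t_star = t_star, sd_aap_star = sd_aap_star,
                 d_av_star = d_av_star, combine = combine),
            class = "tugplus_rule")
}

#' @export
print.tugplus_rule <- function(x, ...) {
  cat(sprintf(paste0("TUG+ rule (%s): TUG > %.4g s | SDa_ap > %.4g m/s^2 | ",
                     "Da_v < %.4g\n"),
              x$combine, x$t_star, x$sd_aap_star, x$d_av_star))
  invisible(x)
}

#' Classify fall risk with a TUG+ rule
#'
#' Evaluates the three binary answers (TUG above its cut, SDa_ap above its
#' cut, Da_v below its cut) and applies the rule's combination logic. All
#' comparisons are strict, so classifications are invariant to
#' infinitesimal perturbation of midpoint thresholds.
#'
#' @param tug_time,sd_aap,d_av Participant feature vectors.
#' @param rule A [tugplus_rule()].
#' @return Integer 0/1 risk.
#' @export
tugplus_classify <- function(tug_time, sd_aap, d_av, rule) {
  stopifnot(inherits(rule, "tugplus_rule"))
  q1 <- tug_time > rule$t_star
  q2 <- sd_aap > rule$sd_aap_star
  q3 <- d_av < rule$d_av_star
  risk <- switch(rule$combine,
                 or = q1 | q2 | q3,
                 sequential = q1 & (q2 | q3))
  as.integer(risk)
}

#' Fit the TUG+ kinematic thresholds on a cohort
#'
#' Holds the TUG cut fixed at its Youden value and exhaustively searches
#' the grid of observed-value midpoints for the (SDa_ap, Da_v) cut pair
#' maximizing in-sample accuracy of [tugplus_classify()] - the same
#' full-population fitting the clinical rule was designed with (no
#' cross-validation by default). Grid candidates include cuts beyond the
#' observed extremes, so switching either kinematic question off entirely
#' is in the search space and the fitted rule can never be less accurate
#' in-sample than the TUG-only rule. Ties are broken toward higher
#' sensitivity, then lower `sd_aap_star`, then higher `d_av_star`.
#'
#' @param indices Cohort index table from [cohort_indices()] (needs
#'   `tug_s`, `sd_a_ap`, `d_a_v`, `faller`).
#' @param t_star Fixed TUG threshold, s.
#' @param combine Combination logic, as in [tugplus_rule()].
#' @return The fitted [tugplus_rule()], with attributes `accuracy` and
#'   `sensitivity` (in-sample).
#' @export
fit_tugplus_thresholds <- function(indices, t_star,
                                   combine = c("or", "sequential")) {
  combine <- match.arg(combine)
  need <- c("tug_s", "sd_a_ap", "d_a_v", "faller")
  stopifnot(all(need %in% names(indices)))
  truth <- indices$faller
  check_binary(truth)
  if (length(unique(truth)) < 2) {
    abort("cohort must contain both classes",
          class = "gaitrisk_single_class_error")
  }
  sd_cand <- midpoint_grid(indices$sd_a_ap)
  d_cand <- midpoint_grid(indices$d_a_v)
  q1 <- indices$tug_s > t_star
  n <- length(truth)
  best <- NULL
  for (sc in sd_cand) {
    q2 <- indices$sd_a_ap > sc
    for (dc in d_cand) {
      q3 <- indices$d_a_v < dc
      risk <- if (combine == "or") q1 | q2 | q3 else q1 & (q2 | q3)
      acc <- sum(risk == (truth == 1)) / n
      se <- sum(risk & truth == 1) / sum(truth == 1)
      better <- is.null(best) || acc > best$acc ||
        (acc == best$acc && (se > best$se ||
                               (se == best$se && (sc < best$sd ||
                                                    (sc == best$sd && dc > best$d)))))
      if (better) best <- list(acc = acc, se = se, sd = sc, d = dc)
    }
  }
  rule <- tugplus_rule(t_star, best$sd, best$d, combine = combine)
  attr(rule, "accuracy") <- best$acc
  attr(rule, "sensitivity") <- best$se
  rule
}

# candidate cutpoints: midpoints between adjacent distinct observed
# values, plus one candidate below the minimum and one above the maximum
# (the latter switch the corresponding question off under strict
# comparison)
midpoint_grid <- function(x) {
  s <- sort(unique(x))
  if (length(s) == 1) return(c(s - 1, s + 1))
  c(s[1] - 1, (head(s, -1) + tail(s, -1)) / 2, s[length(s)] + 1)
}

#' Logistic-regression fusion of TUG and variability indices
#'
#' Maximum-likelihood logistic regression of the faller label on the TUG
#' time, SDa_ap and Da_v - the model-based alternative to the TUG+
#' checklist. Under perfect separation (infinite ML coefficients) the fit
#' falls back to a lightly ridge-penalized solution (lambda = 1e-4) with a
#' warning.
#'
#' @param indices Cohort index table (needs `tug_s`, `sd_a_ap`, `d_a_v`,
#'   `faller`).
#' @return A `logistic_fusion` object (list with `coefficients`,
#'   `penalized`, `model`).
#' @export
logistic_fusion_fit <- function(indices) {
  need <- c("tug_s", "sd_a_ap", "d_a_v", "faller")
  stopifnot(all(need %in% names(indices)))
  dat <- indices[need]
  check_binary(dat$faller)
  fit <- withCallingHandlers(
    glm(faller ~ tug_s + sd_a_ap + d_a_v, data = dat, family = binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  separated <- !fit$converged || any(abs(coef(fit)) > 1e3) ||
    fit$boundary
  if (separated) {
    warn("perfect separation detected; using ridge-penalized fit (1e-4)")
    X <- cbind(1, as.matrix(dat[c("tug_s", "sd_a_ap", "d_a_v")]))
    beta <- ridge_logistic(X, dat$faller, lambda = 1e-4)
    cf <- setNames(beta, c("(Intercept)", "tug_s", "sd_a_ap", "d_a_v"))
  } else {
    cf <- coef(fit)
  }
  structure(list(coefficients = cf, penalized = separated,
                 model = if (separated) NULL else fit),
            class = "logistic_fusion")
}

# ridge-penalized logistic IRLS (intercept unpenalized)
ridge_logistic <- function(X, y, lambda = 1e-4, maxit = 100, tol = 1e-10) {
  p <- ncol(X)
  pen <- diag(c(0, rep(lambda, p - 1)))
  beta <- rep(0, p)
  for (i in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    new <- solve(crossprod(X, w * X) + pen, crossprod(X, w * z))
    if (max(abs(new - beta)) < tol) {
      beta <- drop(new)
      break
    }
    beta <- drop(new)
  }
  beta
}

#' @export
print.logistic_fusion <- function(x, ...) {
  cat("Logistic fall-risk fusion", if (x$penalized) "(ridge fallback)", "\n")
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Tidy a logistic fusion fit
#' @param x A `logistic_fusion` object.
#' @param ... Ignored.
#' @return Tibble with `term`, `estimate` (and Wald columns for the
#'   unpenalized fit).
#' @export
tidy.logistic_fusion <- function(x, ...) {
  if (!is.null(x$model)) {
    s <- summary(x$model)$coefficients
    tibble(term = rownames(s), estimate = s[, 1], std.error = s[, 2],
           statistic = s[, 3], p.value = s[, 4])
  } else {
    tibble(term = names(x$coefficients), estimate = unname(x$coefficients))
  }
}

#' Predict risk from a logistic fusion model
#'
#' @param object A [logistic_fusion_fit()] result.
#' @param indices Feature table with `tug_s`, `sd_a_ap`, `d_a_v`.
#' @param cut Probability cut (default 0.5, strict).
#' @param type `"risk"` (0/1) or `"prob"`.
#' @param ... Ignored.
#' @return Integer risks or probabilities.
#' @export
predict.logistic_fusion <- function(object, indices, cut = 0.5,
                                    type = c("risk", "prob"), ...) {
  type <- match.arg(type)
  X <- cbind(1, as.matrix(indices[c("tug_s", "sd_a_ap", "d_a_v")]))
  prob <- plogis(drop(X %*% object$coefficients))
  if (type == "prob") prob else as.integer(prob > cut)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
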