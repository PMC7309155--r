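#' Confusion matrix of a binary classifier
#'
#' @param pred Predicted risk, binary 0/1.
#' @param truth True labels, binary 0/1 (1 = faller).
#' @return A `confusion_matrix` list with integer counts `tp`, `fp`,
#'   `fn`, `tn`.
#' @export
#' @examples
#' confusion(c(1, 0, 1, 0), c(1, 0, 0, 1))
confusion <- function(pred, truth) {
  if (length(pred) != length(truth)) abort("pred and truth lengths differ")
  if (!length(pred)) abort("need at least one prediction")
  check_binary(pred, "pred")
  check_binary(truth, "truth")
  structure(list(tp = sum(pred == 1 & truth == 1),
                 fp = sum(pred == 1 & truth == 0),
                 fn = sum(pred == 0 & truth == 1),
                 tn = sum(pred == 0 & truth == 0)),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2,
              dimnames = list(pred = c("risk", "no risk"),
                              truth = c("faller", "nonfaller")))
  print(m)
  invisible(x)
}

#' Diagnostic-test statistics from a confusion matrix
#'
#' The seven standard diagnostic statistics: sensitivity
#' `Se = TP/(TP+FN)`, specificity `Sp = TN/(TN+FP)`, positive and negative
#' predictive values `PPV = TP/(TP+FP)`, `NPV = TN/(TN+FN)`, accuracy
#' `Acc = (TP+TN)/total`, and the likelihood ratios `LR+ = Se/(1-Sp)`
#' (infinite when Sp = 1) and `LR- = (1-Se)/Sp` (undefined when Sp = 0).
#' Ratios with an empty margin are returned as `NaN`/`Inf` and flagged
#' rather than silently propagated.
#'
#' @param cm A [confusion()] matrix, or anything coercible via
#'   `confusion(pred, truth)` when `truth` is supplied.
#' @param truth Optional; when given, `cm` is taken as predictions.
#' @return A one-row tibble: `se`, `sp`, `ppv`, `npv`, `acc`, `lr_pos`,
#'   `lr_neg`, plus a `flags` character column naming undefined
#'   statistics (empty string when all defined).
#' @export
#' @examples
#' diagnostic_metrics(confusion(c(1, 1, 0, 0), c(1, 0, 1, 0)))
diagnostic_metrics <- function(cm, truth = NULL) {
  if (!is.null(truth)) cm <- confusion(cm, truth)
  stopifnot(inherits(cm, "confusion_matrix"))
  total <- cm$tp + cm$fp + cm$fn + cm$tn
  div <- function(num, den) if (den > 0) num / den else NaN
  se <- div(cm$tp, cm$tp + cm$fn)
  sp <- div(cm$tn, cm$tn + cm$fp)
  ppv <- div(cm$tp, cm$tp + cm$fp)
  npv <- div(cm$tn, cm$tn + cm$fn)
  acc <- (cm$tp + cm$tn) / total
  lr_pos <- if (is.nan(se) || is.nan(sp)) NaN
            else if (sp == 1) Inf else se / (1 - sp)
  lr_neg <- if (is.nan(se) || is.nan(sp)) NaN
            else if (sp == 0) NaN else (1 - se) / sp
  flags <- c(se = is.nan(se), sp = is.nan(sp), ppv = is.nan(ppv),
             npv = is.nan(npv), lr_pos = is.nan(lr_pos) || is.infinite(lr_pos),
             lr_neg = is.nan(lr_neg))
  tibble(se = se, sp = sp, ppv = ppv, npv = npv, acc = acc,
         lr_pos = lr_pos, lr_neg = lr_neg,
         flags = paste(names(flags)[flags], collapse = ","))
}

#' Likelihood ratios from printed sensitivity and specificity
#'
#' Recomputes `LR+ = Se/(1-Sp)` and `LR- = (1-Se)/Sp` from rounded
#' sensitivity/specificity values, as used to cross-check published
#' diagnostic tables.
#'
#' @param se,sp Sensitivity and specificity, fractions.
#' @return Tibble with `lr_pos`, `lr_neg`.
#' @export
likelihood_ratios <- function(se, sp) {
  tibble(lr_pos = ifelse(sp < 1, se / (1 - sp), Inf),
         lr_neg = ifelse(sp > 0, (1 - se) / sp, NaN))
}

#' Evaluate a binary classifier against truth
#'
#' Composition of [confusion()] and [diagnostic_metrics()].
#'
#' @inheritParams confusion
#' @return List with `confusion` and `metrics`.
#' @export
evaluate_classifier <- function(pred, truth) {
  cm <- confusion(pred, truth)
  list(confusion = cm, metrics = diagnostic_metrics(cm))
}

#' Tidy a confusion matrix
#' @param x A `confusion_matrix`.
#' @param ... Ignored.
#' @return A four-row tibble of cell counts.
#' @export
tidy.confusion_matrix <- function(x, ...) {
  tibble(cell = c("tp", "fp", "fn", "tn"),
         count = c(x$tp, x$fp, x$fn, x$tn))
}

#' Glance at a confusion matrix
#' @param x A `confusion_matrix`.
#' @param ... Ignored.
#' @return One-row tibble of the seven diagnostic statistics.
#' @export
glance.confusion_matrix <- function(x, ...) diagnostic_metrics(x)

#' Mann-Whitney (Wilcoxon rank-sum) group comparison
#'
#' Two-sided Mann-Whitney test used to compare index distributions of
#' fallers and nonfallers. Uses the exact null distribution when the
#' smaller group has at most 8 observations and there are no ties;
#' otherwise the normal approximation with tie correction and continuity
#' correction.
#'
#' @param x,y Numeric samples for the two groups.
#' @param alternative Passed to [stats::wilcox.test()] (default
#'   two-sided).
#' @return List with `u` (Mann-Whitney U for `x` vs `y`) and `p`.
#' @export
mann_whitney <- function(x, y,
                         alternative = c("two.sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  if (!length(x) || !length(y)) abort("both groups must be non-empty")
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- min(length(x), length(y)) <= 8 && !ties
  res <- suppressWarnings(
    wilcox.test(x, y, alternative = alternative, exact = exact,
                correct = TRUE))
  list(u = unname(res$statistic), p = res$p.value)
}

#' McNemar comparison of two paired classifiers
#'
#' Compares two classifiers evaluated on the same participants through
#' their discordant counts: `b` = A correct and B wrong, `c` = A wrong and
#' B correct. By default (`variant = "auto"`) the continuity-corrected
#' chi-squared statistic `(|b-c|-1)^2/(b+c)` (1 df) is used when
#' `b + c >= 25`, and the exact two-sided binomial test otherwise. With no
#' discordant pairs the statistic is 0 and p = 1.
#'
#' @param pred_a,pred_b Predictions of the two classifiers, binary.
#' @param truth True labels, binary.
#' @param variant `"auto"`, `"exact"` or `"chisq"`.
#' @return List with `b`, `c`, `statistic` (chi-squared variant only,
#'   else `NA`), `p`, `method`.
#' @export
mcnemar_compare <- function(pred_a, pred_b, truth,
                            variant = c("auto", "exact", "chisq")) {
  variant <- match.arg(variant)
  stopifnot(length(pred_a) == length(truth), length(pred_b) == length(truth))
  check_binary(pred_a, "pred_a")
  check_binary(pred_b, "pred_b")
  check_binary(truth, "truth")
  ok_a <- pred_a == truth
  ok_b <- pred_b == truth
  b <- sum(ok_a & !ok_b)
  cc <- sum(!ok_a & ok_b)
  if (b + cc == 0) {
    return(list(b = b, c = cc, statistic = 0, p = 1, method = "degenerate"))
  }
  use_chisq <- switch(variant, chisq = TRUE, exact = FALSE,
                      auto = (b + cc) >= 25)
  if (use_chisq) {
    stat <- (abs(b - cc) - 1)^2 / (b + cc)
    list(b = b, c = cc, statistic = stat,
         p = pchisq(stat, df = 1, lower.tail = FALSE),
         method = "continuity-corrected chi-squared")
  } else {
    p <- binom.test(b, b + cc, p = 0.5)$p.value
    list(b = b, c = cc, statistic = NA_real_, p = p,
         method = "exact binomial")
  }
}
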