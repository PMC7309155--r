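#' ROC curve of a risk score
#'
#' One operating point per distinct score plus the two endpoints, for the
#' rule "positive when score > threshold" (higher score = riskier). The
#' area under the curve is the trapezoidal area over (1 - Sp, Se), which
#' for a finite sample equals the tie-corrected concordance statistic
#' (probability that a random positive outscores a random negative, ties
#' counting one half).
#'
#' @param scores Numeric risk scores (e.g. TUG times in seconds).
#' @param labels Binary truth (1 = faller), both classes present.
#' @return A `gait_roc` tibble (`threshold`, `se`, `sp`) ordered by
#'   increasing threshold, with attribute `auc`.
#' @export
#' @examples
#' r <- roc_curve(c(25, 30, 21, 15, 18, 22), c(1, 1, 1, 0, 0, 0))
#' roc_auc(r)
roc_curve <- function(scores, labels) {
  check_binary(labels)
  stopifnot(length(scores) == length(labels))
  if (length(unique(labels)) < 2) {
    abort("both classes must be present to build a ROC curve",
          class = "gaitrisk_single_class_error")
  }
  npos <- sum(labels == 1)
  nneg <- sum(labels == 0)
  thr <- c(-Inf, sort(unique(scores)))
  se <- map_dbl(thr, ~ sum(scores > .x & labels == 1) / npos)
  sp <- map_dbl(thr, ~ sum(scores <= .x & labels == 0) / nneg)
  out <- tibble(threshold = thr, se = se, sp = sp)
  fpr <- 1 - out$sp
  auc <- sum((head(fpr, -1) - tail(fpr, -1)) *
               (head(out$se, -1) + tail(out$se, -1)) / 2)
  structure(out, class = c("gait_roc", class(out)), auc = auc,
            n_pos = npos, n_neg = nneg)
}

#' Area under a ROC curve
#' @param roc A [roc_curve()] object.
#' @return Scalar AUC in \[0, 1\].
#' @export
roc_auc <- function(roc) attr(roc, "auc")

#' Youden-index optimal threshold
#'
#' The cutpoint maximizing Youden's J = Se + Sp - 1 over all candidate
#' thresholds, i.e. the operating point farthest above the chance
#' diagonal. Candidates are midpoints between adjacent distinct scores
#' (plus one below the minimum and one above the maximum), so the chosen
#' rule is invariant to infinitesimal score perturbations. Ties are broken
#' toward the lower threshold (the more sensitive rule).
#'
#' @param roc A [roc_curve()] object.
#' @return List with `threshold` (midpoint) and `j` (maximal Youden
#'   index).
#' @export
youden_threshold <- function(roc) {
  stopifnot(inherits(roc, "gait_roc"))
  j <- roc$se + roc$sp - 1
  s <- roc$threshold[is.finite(roc$threshold)]  # sorted distinct scores
  # candidate cuts equivalent to each ROC row: anything below the minimum
  # (row 1, all positive), midpoints between adjacent distinct scores
  # (rows 2..m), anything above the maximum (row m+1, all negative)
  cand <- c(s[1] - 1, (head(s, -1) + tail(s, -1)) / 2, s[length(s)] + 1)
  best <- which(j == max(j))[1]  # ties -> lowest threshold (more sensitive)
  list(threshold = cand[best], j = j[best])
}

#' Plot a ROC curve
#' @param object A [roc_curve()] result.
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.gait_roc <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = 1 - .data$sp, y = .data$se)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::geom_step(direction = "vh") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "1 - specificity", y = "sensitivity",
                  title = sprintf("ROC (AUC = %.3f)", roc_auc(object))) +
    ggplot2::theme_minimal()
}

check_binary <- function(x, what = "labels") {
  if (!all(x %in% c(0, 1))) {
    abort(sprintf("%s must be binary 0/1", what),
          class = "gaitrisk_binary_error")
  }
  invisible(x)
}
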