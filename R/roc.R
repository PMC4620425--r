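#' Area under the ROC curve (Mann-Whitney form)
#'
#' The probability that a uniformly random positive example outscores a
#' uniformly random negative one, with half credit for ties:
#' `(# concordant pairs + 0.5 * # tied pairs) / (P * N)`, computed via
#' midranks.
#'
#' @param scores Numeric vector.
#' @param labels Binary labels, 1 = positive.
#' @return AUC in `[0, 1]`.
#' @examples
#' auc_mw(c(1, 2, 3, 4), c(0, 0, 1, 1)) # 1
#' auc_mw(c(3, 1, 2, 4), c(0, 0, 1, 1)) # 0.75
#' @export
auc_mw <- function(scores, labels) {
  labels <- validate_labels(labels, n = length(scores))
  P <- sum(labels == 1L)
  N <- sum(labels == 0L)
  r <- rank(scores)
  (sum(r[labels == 1L]) - P * (P + 1) / 2) / (P * N)
}

#' Signed AUC (chance-centered)
#'
#' `auc - 0.5`: negative exactly when the empirical ROC curve lies below the
#' chance diagonal (a "concave" curve, i.e. a reversed-prediction feature).
#' The absolute value is the selection strength used by ROC-Boosting; the
#' sign gives the weak classifier's polarity. Flipping a concave curve around
#' the diagonal is equivalent to negating the scores.
#'
#' @inheritParams auc_mw
#' @return A value in `[-0.5, 0.5]`.
#' @export
signed_auc <- function(scores, labels) {
  auc_mw(scores, labels) - 0.5
}

#' Empirical ROC curve
#'
#' Sweeps the decision threshold over the distinct score values (predicting
#' positive above the threshold). Tied scores contribute a single combined
#' step, so ties appear as diagonal segments. The trapezoid area under the
#' returned polyline equals [auc_mw()] exactly.
#'
#' @inheritParams auc_mw
#' @return A tibble of class `roc_curve` with columns
#'   `threshold, fpr, tpr`, from (0, 0) to (1, 1).
#' @export
roc_points <- function(scores, labels) {
  labels <- validate_labels(labels, n = length(scores))
  P <- sum(labels == 1L)
  N <- sum(labels == 0L)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  l <- labels[ord]
  last <- c(s[-1] != s[-length(s)], TRUE)
  out <- tibble(
    threshold = c(Inf, s[last]),
    fpr = c(0, cumsum(l == 0L)[last] / N),
    tpr = c(0, cumsum(l == 1L)[last] / P)
  )
  class(out) <- c("roc_curve", class(out))
  out
}

#' Trapezoid area under an ROC polyline
#'
#' @param curve A [roc_points()] tibble.
#' @return The area under the curve.
#' @export
roc_trapezoid <- function(curve) {
  sum(diff(curve$fpr) * (head(curve$tpr, -1) + tail(curve$tpr, -1)) / 2)
}

#' Fit a single-feature threshold classifier (weak learner)
#'
#' The polarity is the sign of the signed AUC (ties resolve to +1); a
#' concave-curve feature is handled by flipping, i.e. predicting positive
#' below its threshold. The threshold maximizes Youden's
#' J = sensitivity + specificity - 1 over all midpoints between consecutive
#' distinct (polarity-adjusted) values plus the two all-one-class boundary
#' cuts, so the fitted J is never negative. Ties in J break toward the higher
#' specificity, then the smaller threshold.
#'
#' @param values Feature column.
#' @param labels Binary labels, 1 = positive.
#' @param feature Optional feature index carried into the result.
#' @return A list of class `weak_classifier`: `feature`, `threshold`,
#'   `polarity` (+1/-1), `auc`, `strength` (`|auc - 0.5|`), `j`,
#'   `sensitivity`, `specificity`. Prediction rule: positive iff
#'   `polarity * (value - threshold) > 0`.
#' @export
fit_weak <- function(values, labels, feature = NA_integer_) {
  labels <- validate_labels(labels, n = length(values))
  a <- auc_mw(values, labels)
  pol <- if (a >= 0.5) 1L else -1L
  s <- pol * values
  P <- sum(labels == 1L)
  N <- sum(labels == 0L)
  d <- sort(unique(s))
  cand <- c(d[1] - 1, if (length(d) > 1) (d[-1] + d[-length(d)]) / 2,
            d[length(d)] + 1)
  ord <- order(s)
  ss <- s[ord]
  cpos <- cumsum(labels[ord] == 1L)
  cneg <- cumsum(labels[ord] == 0L)
  k <- findInterval(cand, ss)
  below_pos <- ifelse(k == 0L, 0L, cpos[pmax(k, 1L)])
  below_neg <- ifelse(k == 0L, 0L, cneg[pmax(k, 1L)])
  sens <- (P - below_pos) / P
  spec <- below_neg / N
  j <- sens + spec - 1
  theta <- pol * cand
  best <- order(-j, -spec, theta)[1]
  structure(
    list(feature = feature, threshold = theta[best], polarity = pol,
         auc = a, strength = abs(a - 0.5), j = j[best],
         sensitivity = sens[best], specificity = spec[best]),
    class = "weak_classifier"
  )
}

#' Predictions of a weak classifier
#'
#' @param wc A [fit_weak()] object (or a list with `polarity`, `threshold`).
#' @param values Feature values.
#' @return Logical vector: predicted positive.
#' @export
predict_weak <- function(wc, values) {
  wc$polarity * (values - wc$threshold) > 0
}

#' @export
print.weak_classifier <- function(x, ...) {
  cat(sprintf(
    "<weak_classifier> feature %s, auc %.4f (strength %.4f), polarity %+d, threshold %.4g, J %.3f\n",
    x$feature, x$auc, x$strength, x$polarity, x$threshold, x$j
  ))
  invisible(x)
}
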