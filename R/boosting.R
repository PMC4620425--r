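#' Selection condition for ROC-Boosting
#'
#' Every mode requires a candidate's strength `|a - 0.5|` to exceed
#' `epsilon_stop` (a weak classifier must beat the random guess).
#' `"ratio_constrained"` (the default, and the condition designed for
#' imbalanced classes) additionally requires `|r - r'| <= ratio_tolerance`
#' where r = `p/n` is the positive/negative ratio of the remaining examples
#' and `r' = p'/n'` the same ratio among the examples the candidate's weak
#' classifier labels correctly; candidates that classify no positive or no
#' negative correctly have an undefined ratio and are inadmissible.
#' `"auc_only"` imposes no second condition. `"sens_spec"` instead requires
#' the fitted operating point to reach `min_sensitivity` and
#' `min_specificity` (the face-detection-style variant).
#'
#' @param mode One of `"ratio_constrained"`, `"auc_only"`, `"sens_spec"`.
#' @param epsilon_stop Minimal admissible strength (exclusive). Default 0:
#'   any classifier strictly better than chance qualifies.
#' @param ratio_tolerance Maximal admissible `|r - r'|` (default 1, i.e.
#'   permissive; tighten it to penalize one-class features).
#' @param min_sensitivity,min_specificity Operating-point minima for
#'   `"sens_spec"`.
#' @return A list of class `boost_condition`.
#' @export
boost_condition <- function(mode = c("ratio_constrained", "auc_only",
                                     "sens_spec"),
                            epsilon_stop = 0,
                            ratio_tolerance = 1,
                            min_sensitivity = 0.5,
                            min_specificity = 0.5) {
  mode <- match.arg(mode)
  stopifnot(epsilon_stop >= 0, ratio_tolerance > 0)
  structure(list(mode = mode, epsilon_stop = epsilon_stop,
                 ratio_tolerance = ratio_tolerance,
                 min_sensitivity = min_sensitivity,
                 min_specificity = min_specificity),
            class = "boost_condition")
}

#' Positive/negative ratio statistics
#'
#' r = `p/n` over all examples and r' = `p'/n'` over the correctly classified
#' ones, where `p`/`n` count positive/negative examples and `p'`/`n'` count
#' positives/negatives the prediction gets right. `r'` is `NA` (undefined)
#' when no negative is classified correctly.
#'
#' @param labels Binary labels, 1 = positive.
#' @param predictions Logical (or 0/1) predicted-positive indicator.
#' @return One-row tibble `r, r_prime, p, n, p_prime, n_prime`.
#' @export
ratio_stats <- function(labels, predictions) {
  labels <- validate_labels(labels, n = length(predictions))
  predictions <- as.logical(predictions)
  p <- sum(labels == 1L)
  n <- sum(labels == 0L)
  if (n == 0L) abort("No negative examples: r = p/n is undefined.")
  p_prime <- sum(predictions & labels == 1L)
  n_prime <- sum(!predictions & labels == 0L)
  tibble(r = p / n,
         r_prime = if (n_prime == 0L) NA_real_ else p_prime / n_prime,
         p = p, n = n, p_prime = p_prime, n_prime = n_prime)
}

# Evaluate one candidate: weak fit + ratio stats + admissibility.
evaluate_candidate <- function(col, labels, feature, condition) {
  wc <- fit_weak(col, labels, feature = feature)
  pred <- predict_weak(wc, col)
  rs <- ratio_stats(labels, pred)
  gap <- if (is.na(rs$r_prime)) Inf else abs(rs$r - rs$r_prime)
  admissible <- switch(
    condition$mode,
    auc_only = TRUE,
    ratio_constrained = rs$p_prime > 0L && rs$n_prime > 0L &&
      gap <= condition$ratio_tolerance,
    sens_spec = wc$sensitivity >= condition$min_sensitivity &&
      wc$specificity >= condition$min_specificity
  )
  list(wc = wc, pred = pred, rs = rs, gap = gap, admissible = admissible)
}

#' Select one feature under a ROC-Boosting condition
#'
#' Computes each remaining feature's AUC strength, then — in decreasing
#' strength order — fits the weak classifier and checks the condition; the
#' admissible candidate with maximal strength wins. Ties in strength break
#' toward the smaller `|r - r'|`, then the lower feature index, so selection
#' is deterministic.
#'
#' @param values Matrix of remaining examples x remaining features.
#' @param labels Binary labels for the remaining examples.
#' @param condition A [boost_condition()].
#' @return A list: either `found = TRUE` with `index` (column in `values`),
#'   `classifier`, `prediction`, `stats`, `gap`; or `found = FALSE` with a
#'   `reason` (`"no_feature_beats_guess"` or the condition-specific
#'   `"ratio_condition_unmet"`).
#' @export
select_feature <- function(values, labels, condition = boost_condition()) {
  if (!is.matrix(values) || ncol(values) == 0L || nrow(values) == 0L) {
    abort("`values` must be a non-empty matrix.")
  }
  labels <- validate_labels(labels, n = nrow(values))
  aucs <- apply(values, 2L, auc_mw, labels = labels)
  strength <- abs(aucs - 0.5)
  lvl <- sort(unique(strength[strength > condition$epsilon_stop]),
              decreasing = TRUE)
  any_strong <- length(lvl) > 0L
  for (s in lvl) {
    members <- which(strength == s)
    evals <- lapply(members, function(jj) {
      evaluate_candidate(values[, jj], labels, jj, condition)
    })
    gaps <- vapply(evals, `[[`, numeric(1), "gap")
    ok <- vapply(evals, `[[`, logical(1), "admissible")
    if (any(ok)) {
      pick <- order(!ok, gaps, members)[1]
      ev <- evals[[pick]]
      return(list(found = TRUE, index = members[pick], classifier = ev$wc,
                  prediction = ev$pred, stats = ev$rs, gap = ev$gap))
    }
  }
  reason <- if (!any_strong) "no_feature_beats_guess" else
    switch(condition$mode,
           ratio_constrained = "ratio_condition_unmet",
           sens_spec = "ratio_condition_unmet",
           auc_only = "no_feature_beats_guess")
  list(found = FALSE, reason = reason)
}

#' ROC-Boosting feature selection
#'
#' The selection loop: fit a weak classifier per remaining feature, pick the
#' admissible one with the largest AUC deviation from chance
#' (see [select_feature()]), record the round's diagnostics, remove the
#' examples the chosen classifier labels correctly and the chosen feature,
#' and repeat. The loop stops when no admissible feature remains, when one
#' class is exhausted among the remaining examples, or at `max_rounds`.
#'
#' @param values Examples x features matrix (optionally with a `"specs"`
#'   attribute, as produced by [haar_values()]).
#' @param labels Binary labels, 1 = positive.
#' @param condition A [boost_condition()].
#' @param max_rounds Safety bound on the number of rounds.
#' @param verbose Emit one message per round with the diagnostics.
#' @return An object of class `roc_boost`: `classifiers` (tibble),
#'   `rounds` (tibble of per-round diagnostics), `stop_reason`, `condition`,
#'   `n_examples`, `n_features`, `ensemble_auc_train`.
#' @export
roc_boost <- function(values, labels, condition = boost_condition(),
                      max_rounds = 100L, verbose = FALSE) {
  if (!is.matrix(values)) values <- as.matrix(values)
  labels <- validate_labels(labels, n = nrow(values))
  if (ncol(values) < 1L) abort("Need at least one feature.")
  feat_names <- colnames(values) %||% paste0("f", seq_len(ncol(values)))
  ex_left <- seq_len(nrow(values))
  ft_left <- seq_len(ncol(values))
  rounds <- list()
  classifiers <- list()
  stop_reason <- "max_rounds"
  round_i <- 0L
  while (round_i < max_rounds) {
    lab <- labels[ex_left]
    if (length(ft_left) == 0L) { stop_reason <- "no_feature_beats_guess"; break }
    if (length(unique(lab)) < 2L) { stop_reason <- "class_exhausted"; break }
    sel <- select_feature(values[ex_left, ft_left, drop = FALSE], lab,
                          condition)
    if (!sel$found) { stop_reason <- sel$reason; break }
    round_i <- round_i + 1L
    feat <- ft_left[sel$index]
    wc <- sel$classifier
    wc$feature <- feat
    correct <- sel$prediction == (lab == 1L)
    n_removed <- sum(correct)
    rounds[[round_i]] <- tibble(
      round = round_i, feature = feat, feature_name = feat_names[feat],
      auc = wc$auc, strength = wc$strength,
      threshold = wc$threshold, polarity = wc$polarity,
      r = sel$stats$r, r_prime = sel$stats$r_prime,
      p = sel$stats$p, n = sel$stats$n,
      p_prime = sel$stats$p_prime, n_prime = sel$stats$n_prime,
      ratio_gap = ifelse(is.finite(sel$gap), sel$gap, NA_real_),
      n_removed = n_removed,
      n_remaining_after = length(ex_left) - n_removed
    )
    classifiers[[round_i]] <- wc
    if (verbose) {
      inform(sprintf(
        "round %d: feature %s |a-0.5|=%.4f r=%.4f r'=%s removed=%d remaining=%d",
        round_i, feat_names[feat], wc$strength, sel$stats$r,
        ifelse(is.na(sel$stats$r_prime), "NA",
               sprintf("%.4f", sel$stats$r_prime)),
        n_removed, length(ex_left) - n_removed
      ))
    }
    ex_left <- ex_left[!correct]
    ft_left <- setdiff(ft_left, feat)
    if (n_removed == 0L) { stop_reason <- "no_feature_beats_guess"; break }
  }
  cls <- dplyr::bind_rows(lapply(classifiers, function(w) {
    tibble(feature = w$feature, feature_name = feat_names[w$feature],
           threshold = w$threshold, polarity = w$polarity, auc = w$auc,
           strength = w$strength, sensitivity = w$sensitivity,
           specificity = w$specificity)
  }))
  fit <- structure(
    list(classifiers = cls, rounds = dplyr::bind_rows(rounds),
         stop_reason = stop_reason, condition = condition,
         n_examples = nrow(values), n_features = ncol(values),
         specs = attr(values, "specs")),
    class = "roc_boost"
  )
  fit$ensemble_auc_train <- if (nrow(cls) > 0) {
    auc_mw(ensemble_score(fit, values), labels)
  } else NA_real_
  fit
}

#' Ensemble score of the selected weak classifiers
#'
#' Each selected classifier casts a polarity-adjusted vote (+1 for predicted
#' positive, -1 otherwise) per example; the score is the vote sum. The
#' ensemble's AUC is the AUC of this score against the labels. With
#' `weighting = "strength"` votes are weighted by `|auc - 0.5|`.
#'
#' @param object A `roc_boost` fit, or a classifier tibble with columns
#'   `feature, threshold, polarity, strength`.
#' @param values Feature matrix with the same column order the fit saw.
#' @param weighting `"none"` (default) or `"strength"`.
#' @return Numeric score per example (row).
#' @export
ensemble_score <- function(object, values, weighting = c("none", "strength")) {
  weighting <- match.arg(weighting)
  cls <- if (inherits(object, "roc_boost")) object$classifiers else object
  if (NROW(cls) == 0L) abort("Need at least one selected classifier.")
  if (!is.matrix(values)) values <- as.matrix(values)
  if (max(cls$feature) > ncol(values)) {
    abort("Classifier feature index exceeds the number of columns in `values`.")
  }
  w <- if (weighting == "strength") cls$strength else rep(1, nrow(cls))
  score <- numeric(nrow(values))
  for (i in seq_len(nrow(cls))) {
    vote <- ifelse(cls$polarity[i] * (values[, cls$feature[i]] -
                                        cls$threshold[i]) > 0, 1, -1)
    score <- score + w[i] * vote
  }
  score
}

#' @export
print.roc_boost <- function(x, ...) {
  cat(sprintf(
    "<roc_boost> %d selected feature(s) from %d (on %d examples), stop: %s\n",
    nrow(x$classifiers), x$n_features, x$n_examples, x$stop_reason
  ))
  if (!is.na(x$ensemble_auc_train)) {
    cat(sprintf("  training ensemble AUC: %.3f\n", x$ensemble_auc_train))
  }
  if (nrow(x$rounds) > 0) print(x$rounds, n = 5)
  invisible(x)
}

#' @rdname roc_boost
#' @param x A `roc_boost` object.
#' @param ... Unused.
#' @export
tidy.roc_boost <- function(x, ...) {
  x$rounds
}

#' @rdname roc_boost
#' @export
glance.roc_boost <- function(x, ...) {
  tibble(
    n_selected = nrow(x$classifiers),
    n_features = x$n_features,
    n_examples = x$n_examples,
    stop_reason = x$stop_reason,
    ensemble_auc_train = x$ensemble_auc_train,
    mean_strength = if (nrow(x$classifiers)) mean(x$classifiers$strength)
      else NA_real_
  )
}

#' Predict from a ROC-Boosting ensemble
#'
#' @param object A `roc_boost` fit.
#' @param newdata Feature matrix (same column order as at fit time).
#' @param type `"score"` (vote sum) or `"label"` (score > 0).
#' @param ... Unused.
#' @return Numeric scores or integer 0/1 labels.
#' @export
predict.roc_boost <- function(object, newdata, type = c("score", "label"),
                              ...) {
  type <- match.arg(type)
  s <- ensemble_score(object, newdata)
  if (type == "score") s else as.integer(s > 0)
}

#' Selected specs of a fit
#'
#' When the fitted matrix carried Haar spec metadata, returns the spec rows
#' of the selected features, in selection order.
#'
#' @param fit A `roc_boost` fit.
#' @return A spec tibble.
#' @export
selected_specs <- function(fit) {
  if (is.null(fit$specs)) abort("Fit carries no spec metadata.")
  fit$specs[fit$classifiers$feature, , drop = FALSE]
}
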