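#' Table of screen thresholds used per test
#'
#' The per-test t-screen significance cutoffs used throughout the package's
#' experiments: 0.05 for the A-vs-B contrast (test 1), 0.00005 for A-vs-C
#' (test 2) and 0.0005 for A-vs-B+C (test 3).
#'
#' @param test 1, 2 or 3.
#' @return The threshold.
#' @export
default_p_threshold <- function(test) {
  switch(as.character(test), `1` = 0.05, `2` = 0.00005, `3` = 0.0005,
         abort("`test` must be 1, 2 or 3."))
}

#' End-to-end screening + boosting pipeline on a tongue dataset
#'
#' Extracts Haar features for the requested group contrast, screens them by
#' t-test, runs ROC-Boosting on the surviving columns, and (optionally)
#' evaluates the ensemble on an independent dataset generated under the same
#' configuration. Classifier feature indices in the returned fit refer to
#' columns of the full (pre-screen) matrix, so the fit can score any matrix
#' extracted with the same specs.
#'
#' @param dataset A `tongue_dataset` (training data).
#' @param test Group contrast, 1 (A vs B), 2 (A vs C) or 3 (A vs B+C).
#' @param specs Haar spec tibble; defaults to [haar_grid_coarse()].
#' @param p_threshold Screen cutoff; defaults to [default_p_threshold()].
#' @param condition A [boost_condition()].
#' @param eval_dataset Optional held-out `tongue_dataset` for the reported
#'   ensemble AUC. An ensemble with no selected classifier scores 0.5.
#' @param max_rounds Passed to [roc_boost()].
#' @return A list of class `tongue_pipeline`: `fit`, `screen`, `specs`,
#'   `test`, `auc_train`, `auc_eval` (NA without `eval_dataset`),
#'   `eval_pred_rate`, `eval_true_rate`.
#' @export
tongue_pipeline <- function(dataset, test = 2L, specs = haar_grid_coarse(),
                            p_threshold = default_p_threshold(test),
                            condition = boost_condition(),
                            eval_dataset = NULL, max_rounds = 100L) {
  tl <- test_labels(dataset, test)
  X <- haar_values(dataset$images[tl$indices], specs)
  scr <- t_screen(X, tl$labels, p_threshold = p_threshold)
  keep <- attr(scr, "kept")
  out <- list(screen = scr, specs = specs, test = test, fit = NULL,
              auc_train = NA_real_, auc_eval = NA_real_,
              eval_pred_rate = NA_real_, eval_true_rate = NA_real_)
  if (length(keep) > 0L) {
    fit <- roc_boost(screen_keep(X, scr), tl$labels, condition = condition,
                     max_rounds = max_rounds)
    # re-index classifiers to full-matrix columns
    if (nrow(fit$classifiers) > 0L) {
      fit$classifiers$feature <- keep[fit$classifiers$feature]
      fit$rounds$feature <- keep[fit$rounds$feature]
      fit$specs <- specs
    }
    out$fit <- fit
    out$auc_train <- fit$ensemble_auc_train
  }
  if (!is.null(eval_dataset)) {
    tle <- test_labels(eval_dataset, test)
    out$eval_true_rate <- mean(tle$labels == 1L)
    if (!is.null(out$fit) && nrow(out$fit$classifiers) > 0L) {
      Xe <- haar_values(eval_dataset$images[tle$indices], specs)
      se <- ensemble_score(out$fit, Xe)
      out$auc_eval <- auc_mw(se, tle$labels)
      out$eval_pred_rate <- mean(se > 0)
    } else {
      out$auc_eval <- 0.5
      out$eval_pred_rate <- 0
    }
  }
  class(out) <- "tongue_pipeline"
  out
}

#' @export
print.tongue_pipeline <- function(x, ...) {
  cat(sprintf("<tongue_pipeline> test %d: %d screened-in features\n",
              x$test, attr(x$screen, "n_kept")))
  if (!is.null(x$fit)) print(x$fit)
  if (!is.na(x$auc_eval)) cat(sprintf("  held-out ensemble AUC: %.3f\n",
                                      x$auc_eval))
  invisible(x)
}
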