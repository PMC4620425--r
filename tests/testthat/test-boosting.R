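test_that("ratio statistics follow the class and correctness counts", {
  # perfect predictions reproduce the class ratio exactly
  labels <- rep(c(1L, 0L), times = c(6, 10))
  rs <- ratio_stats(labels, labels == 1L)
  expect_equal(rs$r, rs$r_prime)
  # the three-group composition 148 / 332 + 842 gives r = 148/1174
  lab3 <- rep(c(1L, 0L), times = c(148, 332 + 842))
  rs3 <- ratio_stats(lab3, rep(TRUE, 1322))
  expect_equal(rs3$r, 148 / 1174)
  expect_equal(rs3$p, 148)
  expect_equal(rs3$n, 1174)
  # correct on positives only: n' = 0, r' undefined
  rs0 <- ratio_stats(labels, rep(TRUE, 16))
  expect_equal(rs0$n_prime, 0L)
  expect_true(is.na(rs0$r_prime))
})

test_that("a one-class feature is inadmissible under the ratio condition", {
  # positives all at 10, a quarter of the negatives tied with them: the
  # Youden point gets every positive and 3/4 of the negatives right, so
  # r' = 4/24 drifts from r = 4/32 and a tight tolerance rejects the feature
  labels <- rep(c(1L, 0L), times = c(4, 32))
  v <- c(rep(10, 4), rep(10, 8), rep(0, 24))
  X <- cbind(v)
  sel <- select_feature(X, labels,
                        boost_condition("ratio_constrained",
                                        ratio_tolerance = 1e-6))
  expect_false(sel$found)
  expect_equal(sel$reason, "ratio_condition_unmet")
  sel2 <- select_feature(X, labels, boost_condition("auc_only"))
  expect_true(sel2$found)
})

test_that("selection matches the brute-force argmax with tie-breaks", {
  set.seed(42)
  for (rep in 1:5) {
    n <- 60
    K <- 15
    labels <- c(1L, 0L, rbinom(n - 2, 1, 0.3))
    X <- matrix(sample(0:20, n * K, replace = TRUE), n, K)
    X[, 3] <- X[, 3] + 6 * labels
    for (mode in c("auc_only", "ratio_constrained")) {
      cond <- boost_condition(mode, ratio_tolerance = 0.6)
      sel <- select_feature(X, labels, cond)
      # oracle: run one loop round
      or <- oracle_boost(X, labels, mode = mode, tol = 0.6, max_rounds = 1)
      if (sel$found) {
        expect_equal(sel$index, or[1])
      } else {
        expect_length(or, 0)
      }
    }
  }
})

test_that("constant features stop the loop immediately", {
  labels <- rep(c(1L, 0L), 10)
  X <- matrix(5, 20, 4)
  sel <- select_feature(X, labels, boost_condition())
  expect_false(sel$found)
  expect_equal(sel$reason, "no_feature_beats_guess")
  fit <- roc_boost(X, labels)
  expect_equal(nrow(fit$classifiers), 0)
  expect_equal(fit$stop_reason, "no_feature_beats_guess")
})

test_that("a perfectly separating feature ends the loop in one round", {
  labels <- rep(c(1L, 0L), each = 8)
  X <- cbind(sig = ifelse(labels == 1, 10, 0), noise = rep(1, 16))
  fit <- roc_boost(X, labels)
  expect_equal(nrow(fit$classifiers), 1)
  expect_equal(fit$classifiers$feature, 1)
  expect_equal(fit$classifiers$strength, 0.5)
  expect_equal(fit$stop_reason, "class_exhausted")
  expect_equal(fit$rounds$n_removed, 16)
  expect_equal(fit$ensemble_auc_train, 1)
})

test_that("pure-noise features with a strength floor select nothing much", {
  set.seed(43)
  labels <- rep(c(1L, 0L), each = 40)
  X <- matrix(rnorm(80 * 10), 80, 10)
  fit <- roc_boost(X, labels, boost_condition(epsilon_stop = 0.25))
  expect_lte(nrow(fit$classifiers), 2)
  expect_equal(fit$stop_reason, "no_feature_beats_guess")
})

test_that("boosting progresses, removes features, and respects admissibility", {
  set.seed(44)
  n <- 80
  K <- 12
  labels <- rbinom(n, 1, 0.4)
  labels[1:2] <- c(1L, 0L)
  X <- matrix(rnorm(n * K), n, K)
  X[, 2] <- X[, 2] + 1.2 * labels
  X[, 7] <- X[, 7] - 0.8 * labels
  cond <- boost_condition("ratio_constrained", epsilon_stop = 0.02,
                          ratio_tolerance = 0.8)
  fit <- roc_boost(X, labels, cond)
  expect_gt(nrow(fit$rounds), 0)
  # distinct features, strictly decreasing example counts
  expect_equal(anyDuplicated(fit$rounds$feature), 0)
  remaining <- c(n, fit$rounds$n_remaining_after)
  expect_true(all(diff(remaining) < 0))
  expect_equal(fit$rounds$n_removed,
               -diff(remaining))
  # every selected round satisfies the condition it was selected under
  expect_true(all(fit$rounds$strength > cond$epsilon_stop))
  expect_true(all(fit$rounds$ratio_gap <= cond$ratio_tolerance))
  expect_true(all(fit$rounds$p_prime > 0 & fit$rounds$n_prime > 0))
})

test_that("full selection sequences replay under the brute-force oracle", {
  set.seed(45)
  for (rep in 1:4) {
    n <- 70
    K <- 18
    labels <- c(1L, 1L, 0L, 0L, rbinom(n - 4, 1, 0.35))
    X <- matrix(sample(0:30, n * K, replace = TRUE), n, K)
    X[, 5] <- X[, 5] + 8 * labels
    X[, 11] <- X[, 11] - 5 * labels
    for (mode in c("auc_only", "ratio_constrained")) {
      fit <- roc_boost(X, labels,
                       boost_condition(mode, ratio_tolerance = 0.7))
      expect_equal(fit$rounds$feature,
                   oracle_boost(X, labels, mode = mode, tol = 0.7),
                   info = paste("mode", mode, "rep", rep))
    }
  }
})

test_that("ensemble voting reduces to its parts", {
  set.seed(46)
  labels <- rep(c(1L, 0L), each = 20)
  X <- matrix(rnorm(40 * 5), 40, 5)
  X[, 1] <- X[, 1] + 1.5 * labels
  fit <- roc_boost(X, labels, max_rounds = 1)
  expect_equal(nrow(fit$classifiers), 1)
  s <- ensemble_score(fit, X)
  # a lone +/-1 vote dichotomizes the feature at its threshold, so the
  # ensemble AUC is the balanced accuracy of that operating point
  expect_equal(auc_mw(s, labels),
               (fit$classifiers$sensitivity[1] +
                  fit$classifiers$specificity[1]) / 2)
  # ... and coincides with the feature AUC exactly for a perfect separator
  perf <- roc_boost(cbind(ifelse(labels == 1, 9, 0)), labels, max_rounds = 1)
  expect_equal(auc_mw(ensemble_score(perf, cbind(ifelse(labels == 1, 9, 0))),
                      labels),
               perf$classifiers$auc[1])
  # duplicating a classifier scales the votes, leaving the ranking unchanged
  doubled <- dplyr::bind_rows(fit$classifiers, fit$classifiers)
  expect_equal(auc_mw(ensemble_score(doubled, X), labels), auc_mw(s, labels))
  # hand-tallied votes on six examples, three hand-set classifiers
  cls <- tibble::tibble(feature = c(1L, 2L, 3L),
                        threshold = c(0.5, 0.5, 0.5),
                        polarity = c(1L, -1L, 1L),
                        strength = c(0.3, 0.2, 0.1))
  M <- cbind(c(0, 1, 0, 1, 0, 1), c(0, 0, 1, 1, 0, 0), c(1, 1, 1, 0, 0, 0))
  # votes: f1: -,+,-,+,-,+ ; f2 (reversed): +,+,-,-,+,+ ; f3: +,+,+,-,-,-
  expect_equal(ensemble_score(cls, M), c(1, 3, -1, -1, -1, 1))
  expect_error(ensemble_score(cls, M[, 1:2]), "exceeds")
})

test_that("tidiers expose rounds and summary", {
  set.seed(47)
  labels <- rep(c(1L, 0L), each = 12)
  X <- matrix(rnorm(24 * 4), 24, 4)
  X[, 2] <- X[, 2] + 2 * labels
  fit <- roc_boost(X, labels)
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_true(all(c("round", "feature", "strength", "r", "r_prime")
                  %in% names(td)))
  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$n_selected, nrow(fit$classifiers))
  expect_equal(predict(fit, X, type = "label"),
               as.integer(ensemble_score(fit, X) > 0))
})
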