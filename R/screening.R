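#' Two-sample t-test feature screen
#'
#' Computes a per-column two-sample t statistic between the positive
#' (`label == 1`) and negative group and keeps the features with
#' `p < p_threshold` (strict). The default is Welch's unequal-variance
#' statistic; `var_equal = TRUE` restores the pooled-variance Student
#' variant. Columns with zero variance in both groups (and equal means) have
#' no defined statistic: they are dropped with a warning. No multiplicity
#' correction is applied — this is a screen that thins a feature pool by
#' orders of magnitude before boosting, not an inferential procedure.
#'
#' @param values Numeric matrix, examples in rows, features in columns.
#' @param labels Integer/logical vector, 1 = positive; both classes need at
#'   least two examples.
#' @param p_threshold Significance cutoff in (0, 1).
#' @param var_equal Use the pooled-variance statistic.
#' @return A tibble of class `screen_result` with columns
#'   `feature` (column index), `feature_name`, `p_value`, `kept`; attributes
#'   `p_threshold`, `n_kept`, `kept` (kept column indices).
#' @export
t_screen <- function(values, labels, p_threshold = 0.05, var_equal = FALSE) {
  if (!is.matrix(values)) values <- as.matrix(values)
  labels <- validate_labels(labels, n = nrow(values))
  if (p_threshold <= 0 || p_threshold >= 1) {
    abort("`p_threshold` must be in (0, 1).")
  }
  pos <- labels == 1L
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 < 2L || n0 < 2L) abort("Each class needs at least 2 examples.")
  X1 <- values[pos, , drop = FALSE]
  X0 <- values[!pos, , drop = FALSE]
  m1 <- colMeans(X1); m0 <- colMeans(X0)
  v1 <- colSums(sweep(X1, 2L, m1)^2) / (n1 - 1)
  v0 <- colSums(sweep(X0, 2L, m0)^2) / (n0 - 1)
  if (var_equal) {
    sp2 <- ((n1 - 1) * v1 + (n0 - 1) * v0) / (n1 + n0 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n0))
    df <- rep(n1 + n0 - 2, length(se))
  } else {
    se <- sqrt(v1 / n1 + v0 / n0)
    df <- (v1 / n1 + v0 / n0)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v0 / n0)^2 / (n0 - 1))
  }
  p <- 2 * pt(-abs(m1 - m0) / se, df)
  zero_se <- se == 0
  # zero variance in both groups: no statistic if the means agree; perfectly
  # separated constants otherwise
  p[zero_se & m1 != m0] <- 0
  degenerate <- zero_se & m1 == m0
  p[degenerate] <- NA_real_
  if (any(degenerate)) {
    warn(sprintf("%d feature(s) with zero variance in both groups dropped.",
                 sum(degenerate)))
  }
  kept <- !is.na(p) & p < p_threshold
  out <- tibble(
    feature = seq_len(ncol(values)),
    feature_name = colnames(values) %||% paste0("f", seq_len(ncol(values))),
    p_value = unname(p),
    kept = unname(kept)
  )
  attr(out, "p_threshold") <- p_threshold
  attr(out, "n_kept") <- sum(kept)
  attr(out, "kept") <- unname(which(kept))
  class(out) <- c("screen_result", class(out))
  out
}

#' Subset a feature matrix to the screened-in columns
#'
#' @param values The matrix passed to [t_screen()].
#' @param screen A `screen_result`.
#' @return The kept columns of `values` (spec attribute subset accordingly).
#' @export
screen_keep <- function(values, screen) {
  keep <- attr(screen, "kept")
  out <- values[, keep, drop = FALSE]
  sp <- attr(values, "specs")
  if (!is.null(sp)) attr(out, "specs") <- sp[keep, , drop = FALSE]
  out
}

validate_labels <- function(labels, n = NULL) {
  if (is.logical(labels)) labels <- as.integer(labels)
  if (is.factor(labels)) labels <- as.integer(labels == levels(labels)[2])
  if (!all(labels %in% c(0L, 1L))) {
    abort("`labels` must be binary (0/1 or logical); 1 marks the positive class.")
  }
  if (!is.null(n) && length(labels) != n) {
    abort("`labels` length must match the number of examples.")
  }
  if (length(unique(labels)) < 2L) {
    abort("Both classes must be present in `labels`.")
  }
  as.integer(labels)
}
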