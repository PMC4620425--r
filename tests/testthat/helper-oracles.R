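# Independent brute-force oracles used to validate the fast implementations.
# These deliberately use the most literal computation available (double loops,
# exhaustive threshold search, pairwise comparisons) and never call the code
# paths they check.

# naive rectangle sum by explicit submatrix
naive_rect_sum <- function(mat, r1, c1, r2, c2) {
  s <- 0
  for (r in r1:r2) for (cc in c1:c2) s <- s + mat[r, cc]
  s
}

# literal five-partition feature value: center minus corner-free border
naive_haar_value <- function(image, spec) {
  ci <- match(spec$channel, c("red", "green", "blue"))
  m <- unclass(image)[, , ci]
  x <- spec$x; y <- spec$y; w <- spec$w; h <- spec$h; t <- spec$t
  center <- sum(m[(y + t):(y + t + h - 1), (x + t):(x + t + w - 1)])
  outer <- sum(m[y:(y + h + 2 * t - 1), x:(x + w + 2 * t - 1)])
  corners <- sum(m[y:(y + t - 1), x:(x + t - 1)]) +
    sum(m[y:(y + t - 1), (x + w + t):(x + w + 2 * t - 1)]) +
    sum(m[(y + h + t):(y + h + 2 * t - 1), x:(x + t - 1)]) +
    sum(m[(y + h + t):(y + h + 2 * t - 1), (x + w + t):(x + w + 2 * t - 1)])
  as.numeric(center - (outer - center - corners))
}

# Mann-Whitney AUC by exhaustive pairwise comparison with half credit for ties
pair_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  sum(cmp) / (length(pos) * length(neg))
}

# exhaustive weak-learner fit mirroring the documented contract:
# polarity from the AUC sign, Youden-maximal midpoint threshold, ties to
# higher specificity then smaller threshold
oracle_weak <- function(values, labels) {
  a <- pair_auc(values, labels)
  pol <- if (a >= 0.5) 1 else -1
  s <- pol * values
  P <- sum(labels == 1)
  N <- sum(labels == 0)
  d <- sort(unique(s))
  cand <- c(d[1] - 1, if (length(d) > 1) (d[-1] + d[-length(d)]) / 2,
            d[length(d)] + 1)
  best <- NULL
  for (th in cand) {
    pred <- s > th
    sens <- sum(pred & labels == 1) / P
    spec <- sum(!pred & labels == 0) / N
    j <- sens + spec - 1
    theta <- pol * th
    better <- is.null(best) || j > best$j ||
      (j == best$j && spec > best$spec) ||
      (j == best$j && spec == best$spec && theta < best$theta)
    if (better) best <- list(j = j, spec = spec, sens = sens, theta = theta)
  }
  list(polarity = pol, threshold = best$theta, auc = a, j = best$j,
       sensitivity = best$sens, specificity = best$spec)
}

oracle_predict <- function(wc, values) {
  wc$polarity * (values - wc$threshold) > 0
}

# Brute-force replay of the whole selection loop, evaluating every remaining
# feature every round.
oracle_boost <- function(X, labels, mode = "ratio_constrained", eps = 0,
                         tol = 1, max_rounds = 100) {
  ex <- seq_len(nrow(X))
  ft <- seq_len(ncol(X))
  sel <- integer()
  repeat {
    if (length(sel) >= max_rounds) break
    lab <- labels[ex]
    if (length(ft) == 0 || length(unique(lab)) < 2) break
    cand <- NULL
    for (j in ft) {
      v <- X[ex, j]
      a <- pair_auc(v, lab)
      st <- abs(a - 0.5)
      if (st <= eps) next
      wc <- oracle_weak(v, lab)
      pred <- oracle_predict(wc, v)
      p <- sum(lab == 1); n <- sum(lab == 0)
      pp <- sum(pred & lab == 1); np <- sum(!pred & lab == 0)
      gap <- if (np == 0) Inf else abs(p / n - pp / np)
      ok <- switch(mode,
                   auc_only = TRUE,
                   ratio_constrained = pp > 0 && np > 0 && gap <= tol,
                   sens_spec = wc$sensitivity >= 0.5 && wc$specificity >= 0.5)
      if (!ok) next
      better <- is.null(cand) || st > cand$st ||
        (st == cand$st && gap < cand$gap)
      if (better) cand <- list(j = j, st = st, gap = gap, wc = wc,
                               pred = pred)
    }
    if (is.null(cand)) break
    sel <- c(sel, cand$j)
    correct <- cand$pred == (lab == 1)
    ex <- ex[!correct]
    ft <- setdiff(ft, cand$j)
    if (sum(correct) == 0) break
  }
  sel
}

# small random test image
rand_image <- function(seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  as_tongue_image(array(sample(0:255, 120 * 100 * 3, replace = TRUE),
                        dim = c(120, 100, 3)))
}

# random admissible spec
rand_spec <- function(n = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  out <- lapply(seq_len(n), function(i) {
    repeat {
      w <- sample(4:40, 1)
      h <- sample(4:40, 1)
      t <- compute_t(w, h)
      if (t < 1) next
      xm <- 100 - w - 2 * t + 1
      ym <- 120 - h - 2 * t + 1
      if (xm < 1 || ym < 1) next
      return(tibble::tibble(channel = sample(c("red", "green", "blue"), 1),
                            x = sample(xm, 1), y = sample(ym, 1),
                            w = w, h = h, t = t))
    }
  })
  dplyr::bind_rows(out)
}
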