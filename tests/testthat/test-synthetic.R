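test_that("generator is deterministic and localized by construction", {
  cfg0 <- synth_config(noise_sd = 0, patch_shift = c(0, 0, 0), seed = 9)
  a <- generate_image("A", cfg0, idx = 1)
  b <- generate_image("B", cfg0, idx = 1)
  c3 <- generate_image("C", cfg0, idx = 1)
  # null effect: the three groups are pixel-identical without noise or shift
  expect_identical(unclass(a), unclass(b))
  expect_identical(unclass(a), unclass(c3))
  # planted shift alters pixels exactly and only inside patch & ellipse
  cfgs <- synth_config(noise_sd = 0, patch_shift = c(-50, 0, 0), seed = 9)
  cs <- generate_image("C", cfgs, idx = 1)
  diff <- unclass(a) - unclass(cs)
  pm <- rocboost:::patch_mask(cfgs$patch_rect) & rocboost:::tongue_mask()
  expect_true(all(diff[, , 2:3] == 0))
  expect_true(all(diff[, , 1][pm] == 50))
  expect_true(all(diff[, , 1][!pm] == 0))
  # bit-identical regeneration under the same seed
  cfgn <- synth_config(seed = 77)
  expect_identical(unclass(generate_image("C", cfgn, idx = 3)),
                   unclass(generate_image("C", cfgn, idx = 3)))
  expect_error(generate_image("D", cfgn), "group")
})

test_that("background is zero outside the ellipse and values stay in range", {
  img <- generate_image("A", synth_config(noise_sd = 30, seed = 2), idx = 1)
  ell <- rocboost:::tongue_mask()
  for (ch in 1:3) {
    expect_true(all(unclass(img)[, , ch][!ell] == 0))
  }
  expect_gte(min(img), 0)
  expect_lte(max(img), 255)
})

test_that("datasets carry group structure and per-image substreams", {
  ds <- generate_dataset(synth_config(n_healthy = 5, n_ill_normal = 5,
                                      n_ill_abnormal = 5, seed = 4))
  expect_length(ds$images, 15)
  expect_equal(as.integer(table(ds$meta$group)), c(5, 5, 5))
  ds2 <- generate_dataset(synth_config(n_healthy = 5, n_ill_normal = 5,
                                       n_ill_abnormal = 5, seed = 4))
  expect_identical(lapply(ds$images, unclass), lapply(ds2$images, unclass))
  # adding group-B images leaves A and C images untouched
  ds3 <- generate_dataset(synth_config(n_healthy = 5, n_ill_normal = 8,
                                       n_ill_abnormal = 5, seed = 4))
  expect_identical(unclass(ds$images[[1]]), unclass(ds3$images[[1]]))
  expect_identical(unclass(ds$images[[11]]), unclass(ds3$images[[14]]))
})

test_that("test contrasts produce the documented label splits", {
  # lightweight dataset shell: labels depend only on the group table
  meta <- tibble::tibble(
    image_id = as.character(1:1322),
    group = rep(c("A", "B", "C"), times = c(148, 332, 842))
  )
  ds <- structure(list(images = list(), meta = meta), class = "tongue_dataset")
  t1 <- test_labels(ds, 1)
  expect_equal(sum(t1$labels == 1), 148)
  expect_equal(sum(t1$labels == 0), 332)
  t2 <- test_labels(ds, 2)
  expect_equal(sum(t2$labels == 0), 842)
  t3 <- test_labels(ds, 3)
  expect_equal(sum(t3$labels == 1), 148)
  expect_equal(sum(t3$labels == 0), 1174)
  expect_equal(length(t3$labels), 1322)
  expect_error(test_labels(ds, 4), "test")
})

test_that("recovery score is the mean fractional overlap of outer rectangles", {
  truth <- c(x = 1L, y = 1L, w = 30L, h = 60L)
  inside <- tibble::tibble(channel = "red", x = 3L, y = 5L, w = 10L, h = 10L,
                           t = 2L) # outer 14 x 14 at (3, 5): inside truth
  expect_equal(recovery_score(inside, truth), 1)
  outside <- dplyr::mutate(inside, x = 60L, y = 80L)
  expect_equal(recovery_score(outside, truth), 0)
  # outer rect 24 wide at x = 19: columns 19..42, half of them within x <= 30
  half <- tibble::tibble(channel = "red", x = 19L, y = 10L, w = 16L, h = 26L,
                         t = 4L)
  expect_equal(recovery_score(half, truth), 0.5)
  expect_equal(recovery_score(dplyr::bind_rows(inside, outside), truth), 0.5)
  expect_error(recovery_score(inside[0, ], truth), "at least one")
})

test_that("pipeline selects almost nothing when no signal is planted", {
  # full pipeline (stringent A-vs-C screen) on null data: the screen passes
  # essentially no feature, so boosting selects at most a couple per run
  n_sel <- vapply(1:8, function(rep) {
    ds <- generate_dataset(synth_config(
      n_healthy = 15, n_ill_normal = 0, n_ill_abnormal = 30,
      patch_shift = c(0, 0, 0), seed = 500 + rep
    ))
    pl <- suppressWarnings(tongue_pipeline(
      ds, test = 2, specs = haar_grid_coarse("red"),
      condition = boost_condition(epsilon_stop = 0.05)
    ))
    if (is.null(pl$fit)) 0L else nrow(pl$fit$classifiers)
  }, integer(1))
  expect_lte(mean(n_sel), 2)
})

test_that("the ensemble keeps pace with the best single feature", {
  # weak-learnability sanity: the vote ensemble should not fall more than
  # a whisker below the strongest screened-in feature on planted signal
  for (seed in 1:3) {
    ds <- generate_dataset(synth_config(n_healthy = 20, n_ill_normal = 0,
                                        n_ill_abnormal = 40,
                                        patch_shift = c(-20, 0, 0),
                                        seed = 900 + seed))
    tl <- test_labels(ds, 2)
    X <- haar_values(ds$images[tl$indices], haar_grid_coarse("red"))
    scr <- suppressWarnings(t_screen(X, tl$labels,
                                     p_threshold = default_p_threshold(2)))
    Xk <- screen_keep(X, scr)
    fit <- roc_boost(Xk, tl$labels)
    best_single <- max(vapply(seq_len(ncol(Xk)), function(j) {
      a <- auc_mw(Xk[, j], tl$labels)
      max(a, 1 - a)
    }, numeric(1)))
    expect_gte(fit$ensemble_auc_train, best_single - 0.02)
  }
})

test_that("indistinguishable groups give a chance-level held-out ensemble", {
  # A-vs-B with subtle_shift 0: screened-in features are pure noise and the
  # held-out ensemble AUC sits near 0.5
  aucs <- vapply(1:5, function(rep) {
    mk <- function(seed) synth_config(n_healthy = 30, n_ill_normal = 66,
                                      n_ill_abnormal = 0, seed = seed)
    ds <- generate_dataset(mk(700 + rep))
    ev <- generate_dataset(mk(7700 + rep))
    pl <- suppressWarnings(tongue_pipeline(ds, test = 1,
                                           specs = haar_grid_coarse("red"),
                                           eval_dataset = ev))
    pl$auc_eval
  }, numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 0.07)
})
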