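#' Configuration for the synthetic tongue-image generator
#'
#' The generator emulates the inputs the pipeline was designed for: segmented
#' tongue photographs standardized to 120 x 100, with three subject groups —
#' A (healthy), B (ill but with a normal-looking tongue) and C (ill with a
#' visibly abnormal tongue). Each image is an axis-aligned ellipse of a base
#' tongue colour plus i.i.d. Gaussian pixel noise on a zero background. Group
#' C receives an intensity shift inside a planted rectangular patch
#' (intersected with the ellipse); group B receives `subtle_shift` in the same
#' patch (0 by default, i.e. indistinguishable from A).
#'
#' Default group sizes are 30/66/168, the clinical 148/332/842 composition
#' scaled down ~5x for desk-scale experiments; the full sizes are one argument
#' away.
#'
#' @param n_healthy,n_ill_normal,n_ill_abnormal Group sizes for A, B, C.
#' @param base_color Length-3 RGB mean of the elliptical foreground.
#' @param patch_rect Named vector `c(x, y, w, h)` of the planted patch in
#'   1-based image coordinates.
#' @param patch_shift Length-3 per-channel intensity offset added inside the
#'   patch for group C.
#' @param subtle_shift Same for group B (default `c(0, 0, 0)`).
#' @param noise_sd Per-pixel Gaussian noise standard deviation.
#' @param seed Integer seed; every image derives its own substream from it so
#'   changing one group's count does not alter other groups' images.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_healthy = 30L, n_ill_normal = 66L,
                         n_ill_abnormal = 168L,
                         base_color = c(175, 110, 120),
                         patch_rect = c(x = 25L, y = 40L, w = 40L, h = 40L),
                         patch_shift = c(-45, 0, 0),
                         subtle_shift = c(0, 0, 0),
                         noise_sd = 12,
                         seed = 1L) {
  stopifnot(
    n_healthy >= 0, n_ill_normal >= 0, n_ill_abnormal >= 0,
    length(base_color) == 3, length(patch_shift) == 3,
    length(subtle_shift) == 3, noise_sd >= 0,
    all(c("x", "y", "w", "h") %in% names(patch_rect))
  )
  pr <- patch_rect
  if (pr[["x"]] < 1 || pr[["y"]] < 1 ||
      pr[["x"]] + pr[["w"]] - 1 > TONGUE_WIDTH ||
      pr[["y"]] + pr[["h"]] - 1 > TONGUE_HEIGHT) {
    abort("`patch_rect` must lie inside the 120 x 100 frame.")
  }
  structure(
    list(n_healthy = as.integer(n_healthy),
         n_ill_normal = as.integer(n_ill_normal),
         n_ill_abnormal = as.integer(n_ill_abnormal),
         base_color = base_color, patch_rect = patch_rect,
         patch_shift = patch_shift, subtle_shift = subtle_shift,
         noise_sd = noise_sd, seed = as.integer(seed)),
    class = "synth_config"
  )
}

# Elliptical foreground mask: inscribed in the frame with a 5-px margin.
tongue_mask <- function() {
  cy <- (TONGUE_HEIGHT + 1) / 2
  cx <- (TONGUE_WIDTH + 1) / 2
  a <- (TONGUE_HEIGHT - 10) / 2
  b <- (TONGUE_WIDTH - 10) / 2
  row <- matrix(seq_len(TONGUE_HEIGHT), TONGUE_HEIGHT, TONGUE_WIDTH)
  col <- matrix(seq_len(TONGUE_WIDTH), TONGUE_HEIGHT, TONGUE_WIDTH,
                byrow = TRUE)
  ((row - cy) / a)^2 + ((col - cx) / b)^2 <= 1
}

patch_mask <- function(patch_rect) {
  m <- matrix(FALSE, TONGUE_HEIGHT, TONGUE_WIDTH)
  rows <- patch_rect[["y"]]:(patch_rect[["y"]] + patch_rect[["h"]] - 1L)
  cols <- patch_rect[["x"]]:(patch_rect[["x"]] + patch_rect[["w"]] - 1L)
  m[rows, cols] <- TRUE
  m
}

image_seed <- function(seed, group, idx) {
  code <- match(group, c("A", "B", "C"))
  as.integer((as.numeric(seed) * 97 + code * 1e6 + idx * 271) %% 2147483647)
}

#' Generate one synthetic tongue image
#'
#' @param group `"A"`, `"B"`, or `"C"`.
#' @param config A [synth_config()].
#' @param idx Within-group image index (drives the per-image RNG substream).
#' @return A tongue image array.
#' @export
generate_image <- function(group, config, idx = 1L) {
  if (!group %in% c("A", "B", "C")) abort("`group` must be 'A', 'B' or 'C'.")
  ell <- tongue_mask()
  pm <- patch_mask(config$patch_rect) & ell
  shift <- switch(group, A = c(0, 0, 0), B = config$subtle_shift,
                  C = config$patch_shift)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(image_seed(config$seed, group, idx))
  arr <- array(0, dim = c(TONGUE_HEIGHT, TONGUE_WIDTH, 3L))
  for (ch in 1:3) {
    plane <- matrix(config$base_color[ch], TONGUE_HEIGHT, TONGUE_WIDTH)
    if (config$noise_sd > 0) {
      plane <- plane + matrix(rnorm(length(plane), sd = config$noise_sd),
                              TONGUE_HEIGHT, TONGUE_WIDTH)
    }
    plane[pm] <- plane[pm] + shift[ch]
    plane[!ell] <- 0
    arr[, , ch] <- pmin(pmax(round(plane), 0), 255)
  }
  as_tongue_image(arr)
}

#' Generate a labeled synthetic dataset
#'
#' @param config A [synth_config()] (or arguments passed on to it).
#' @param ... Passed to [synth_config()] when `config` is missing.
#' @return A list of class `tongue_dataset`: `images` (list of arrays), `meta`
#'   (tibble `image_id, group`), `truth_rect` (the planted patch) and
#'   `config`.
#' @export
generate_dataset <- function(config = synth_config(...), ...) {
  stopifnot(inherits(config, "synth_config"))
  groups <- c(rep("A", config$n_healthy),
              rep("B", config$n_ill_normal),
              rep("C", config$n_ill_abnormal))
  if (length(groups) == 0) abort("Dataset must contain at least one image.")
  idx <- unlist(lapply(c(config$n_healthy, config$n_ill_normal,
                         config$n_ill_abnormal), seq_len))
  images <- purrr::map2(groups, idx, generate_image, config = config)
  meta <- tibble(
    image_id = sprintf("%s%03d", groups, idx),
    group = groups
  )
  structure(list(images = images, meta = meta,
                 truth_rect = config$patch_rect, config = config),
            class = "tongue_dataset")
}

#' @export
print.tongue_dataset <- function(x, ...) {
  cat("<tongue_dataset> ", length(x$images), " images (",
      paste(sprintf("%s: %d", names(table(x$meta$group)),
                    as.integer(table(x$meta$group))), collapse = ", "),
      ")\n", sep = "")
  invisible(x)
}

#' Binary labels for one of the three group contrasts
#'
#' Test 1 contrasts A vs B, test 2 A vs C, test 3 A vs B+C. Healthy (group A)
#' is the positive class throughout.
#'
#' @param dataset A `tongue_dataset`.
#' @param test 1, 2 or 3.
#' @return A list: `indices` into the dataset, `labels` (integer 0/1,
#'   1 = healthy), `meta` (subset tibble with a `label` column).
#' @export
test_labels <- function(dataset, test) {
  stopifnot(inherits(dataset, "tongue_dataset"))
  if (!test %in% 1:3) abort("`test` must be 1, 2 or 3.")
  keep_groups <- switch(test, `1` = c("A", "B"), `2` = c("A", "C"),
                        `3` = c("A", "B", "C"))
  idx <- which(dataset$meta$group %in% keep_groups)
  labels <- as.integer(dataset$meta$group[idx] == "A")
  if (length(unique(labels)) < 2L) {
    abort("Both classes must be non-empty for the requested test.")
  }
  list(indices = idx, labels = labels,
       meta = dplyr::mutate(dataset$meta[idx, ], label = labels))
}

#' Overlap of selected features with the planted patch
#'
#' For each selected spec, the fraction of its outer rectangle's area that
#' falls inside `truth_rect`; the score is the mean over specs. 1 when every
#' selected feature lies wholly inside the planted region, 0 when all are
#' disjoint from it.
#'
#' @param specs Spec tibble (columns `x, y, w, h, t`).
#' @param truth_rect Named vector `c(x, y, w, h)`.
#' @return A number in `[0, 1]`.
#' @export
recovery_score <- function(specs, truth_rect) {
  if (nrow(specs) == 0) abort("Need at least one selected spec.")
  ox1 <- specs$x; oy1 <- specs$y
  ox2 <- specs$x + specs$w + 2L * specs$t - 1L
  oy2 <- specs$y + specs$h + 2L * specs$t - 1L
  tx1 <- truth_rect[["x"]]; ty1 <- truth_rect[["y"]]
  tx2 <- tx1 + truth_rect[["w"]] - 1L
  ty2 <- ty1 + truth_rect[["h"]] - 1L
  iw <- pmax(0, pmin(ox2, tx2) - pmax(ox1, tx1) + 1)
  ih <- pmax(0, pmin(oy2, ty2) - pmax(oy1, ty1) + 1)
  mean(iw * ih / ((ox2 - ox1 + 1) * (oy2 - oy1 + 1)))
}
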