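#' Border width of the improved Haar-like feature
#'
#' The improved five-partition Haar-like feature consists of a central
#' `w x h` rectangle surrounded by a border of width `t`. The border width is
#' chosen so the pixel count of the center approximately equals the pixel
#' count of the four corner-free border partitions, `2 t (w + h)`:
#' `t = floor(w h / (2 w + 2 h))`.
#'
#' @param w,h Center-partition width and height in pixels (positive integers,
#'   vectorized).
#' @return Integer border width(s).
#' @examples
#' compute_t(10, 10) # 2
#' compute_t(60, 72) # 16
#' @export
compute_t <- function(w, h) {
  if (length(w) == 0 || length(h) == 0 || anyNA(w) || anyNA(h) ||
      any(w < 1) || any(h < 1)) {
    abort("`w` and `h` must be positive.")
  }
  as.integer(floor(w * h / (2 * w + 2 * h)))
}

#' Enumerate the improved Haar-like feature grid
#'
#' Produces one row per feature specification. For each center size `(w, h)`
#' the border width is `t = compute_t(w, h)`; the feature occupies the outer
#' rectangle `(w + 2t) x (h + 2t)` whose top-left corner is `(x, y)` in
#' 1-based image coordinates (`x` horizontal across the 100-px width, `y`
#' vertical down the 120-px height). Positions run over
#' `x in {x_start, x_start + x_step, ...}` while `x <= width - w - 2t + 1`,
#' and analogously for `y`. Enumeration order is channel-major, then
#' `w`, `h`, `y`, `x`, and is fully deterministic.
#'
#' The default arguments reproduce the reduced parameter grid used for
#' 120 x 100 tongue images: `W in {10, 12, ..., 60}`, `H in {10, 12, ..., 72}`,
#' `x` from 1 in steps of 5, `y` from 1 in steps of 6, all three channels.
#'
#' @param w_values,h_values Integer vectors of admissible center sizes.
#' @param x_start,x_step,y_start,y_step Position grid (1-based).
#' @param channels Subset of `c("red", "green", "blue")`.
#' @param frame_width,frame_height Image frame, default 100 x 120.
#' @return A tibble of class `haar_grid` with columns
#'   `spec_id, channel, x, y, w, h, t`.
#' @examples
#' nrow(haar_grid(w_values = 60, h_values = 72, channels = "red")) # 6
#' @export
haar_grid <- function(w_values = seq(10L, 60L, 2L),
                      h_values = seq(10L, 72L, 2L),
                      x_start = 1L, x_step = 5L,
                      y_start = 1L, y_step = 6L,
                      channels = CHANNELS,
                      frame_width = TONGUE_WIDTH,
                      frame_height = TONGUE_HEIGHT) {
  channels <- match.arg(channels, CHANNELS, several.ok = TRUE)
  if (length(w_values) == 0 || length(h_values) == 0) {
    abort("`w_values` and `h_values` must be non-empty.")
  }
  wh <- tidyr::expand_grid(w = as.integer(sort(w_values)),
                           h = as.integer(sort(h_values)))
  wh$t <- compute_t(wh$w, wh$h)
  one_channel <- purrr::pmap(wh, function(w, h, t) {
    x_max <- frame_width - w - 2L * t + 1L
    y_max <- frame_height - h - 2L * t + 1L
    if (x_max < x_start || y_max < y_start) return(NULL)
    xs <- seq.int(x_start, x_max, by = x_step)
    ys <- seq.int(y_start, y_max, by = y_step)
    tidyr::expand_grid(y = as.integer(ys), x = as.integer(xs)) |>
      dplyr::mutate(w = w, h = h, t = t)
  })
  empty <- tibble(y = integer(), x = integer(), w = integer(),
                  h = integer(), t = integer())
  one_channel <- dplyr::bind_rows(c(list(empty), one_channel))
  out <- dplyr::bind_rows(lapply(channels, function(ch) {
    dplyr::mutate(one_channel, channel = ch, .before = 1)
  }))
  out <- dplyr::select(out, "channel", "x", "y", "w", "h", "t")
  out <- dplyr::mutate(out, spec_id = dplyr::row_number(), .before = 1)
  class(out) <- c("haar_grid", class(out))
  out
}

#' Desk-scale Haar grid
#'
#' A reduced enumeration (four center widths and heights, coarser position
#' steps) used by the synthetic-data experiments and the command-line default;
#' roughly 3,000 features over three channels instead of ~3 x 10^5.
#'
#' @inheritParams haar_grid
#' @return A `haar_grid` tibble.
#' @export
haar_grid_coarse <- function(channels = CHANNELS) {
  haar_grid(w_values = c(12L, 20L, 28L, 36L),
            h_values = c(12L, 24L, 36L, 48L),
            x_step = 8L, y_step = 10L, channels = channels)
}

validate_specs <- function(specs,
                           frame_width = TONGUE_WIDTH,
                           frame_height = TONGUE_HEIGHT) {
  needed <- c("channel", "x", "y", "w", "h", "t")
  if (!all(needed %in% names(specs))) {
    abort(paste("Spec table must have columns", paste(needed, collapse = ", ")))
  }
  bad <- specs$w < 1 | specs$h < 1 | specs$t < 1 |
    specs$x < 1 | specs$y < 1 |
    specs$x + specs$w + 2 * specs$t - 1 > frame_width |
    specs$y + specs$h + 2 * specs$t - 1 > frame_height
  if (any(bad)) {
    abort(sprintf("%d spec(s) do not fit inside the %d x %d frame.",
                  sum(bad), frame_height, frame_width))
  }
  if (!all(specs$channel %in% CHANNELS)) {
    abort("Spec channel must be one of red, green, blue.")
  }
  invisible(specs)
}

#' Integral image of one channel
#'
#' Cumulative-sum table of a single-channel pixel matrix, padded with a zero
#' row and column so any rectangle sum is four table lookups.
#'
#' @param mat Numeric matrix (rows x columns).
#' @return `(nrow + 1) x (ncol + 1)` matrix; entry `[r + 1, c + 1]` is the sum
#'   of `mat[1:r, 1:c]`.
#' @export
integral_image <- function(mat) {
  if (!is.matrix(mat)) abort("`mat` must be a matrix.")
  nr <- nrow(mat)
  nc <- ncol(mat)
  out <- matrix(0, nr + 1L, nc + 1L)
  cs <- apply(mat, 2L, cumsum)
  if (nr == 1L) cs <- matrix(cs, nrow = 1L)
  out[-1L, -1L] <- t(apply(cs, 1L, cumsum))
  out
}

#' Rectangle sum from an integral image
#'
#' @param int An [integral_image()] table.
#' @param r1,c1,r2,c2 1-based inclusive pixel bounds (vectorized).
#' @return Numeric vector of rectangle sums.
#' @export
rect_sum <- function(int, r1, c1, r2, c2) {
  int[cbind(r2 + 1L, c2 + 1L)] - int[cbind(r1, c2 + 1L)] -
    int[cbind(r2 + 1L, c1)] + int[cbind(r1, c1)]
}

# Linear-index lookup plan for a spec table on one channel: 24 index columns
# (6 rectangles x 4 corners) and their +/- coefficients. The feature value is
# S_center - S_border with the four t x t corner squares excluded from the
# border, i.e. 2*S_center - S_outer + S_corners.
haar_index_plan <- function(specs, frame_height = TONGUE_HEIGHT) {
  x <- specs$x; y <- specs$y; w <- specs$w; h <- specs$h; t <- specs$t
  rects <- list(
    center = cbind(y + t, x + t, y + t + h - 1L, x + t + w - 1L),
    outer  = cbind(y, x, y + h + 2L * t - 1L, x + w + 2L * t - 1L),
    tl = cbind(y, x, y + t - 1L, x + t - 1L),
    tr = cbind(y, x + w + t, y + t - 1L, x + w + 2L * t - 1L),
    bl = cbind(y + h + t, x, y + h + 2L * t - 1L, x + t - 1L),
    br = cbind(y + h + t, x + w + t, y + h + 2L * t - 1L, x + w + 2L * t - 1L)
  )
  rcoef <- c(center = 2, outer = -1, tl = 1, tr = 1, bl = 1, br = 1)
  nri <- frame_height + 1L # rows of the integral table
  lin <- function(r, c) (c - 1L) * nri + r
  idx <- vector("list", 24L)
  coef <- numeric(24L)
  k <- 0L
  for (nm in names(rects)) {
    rc <- rects[[nm]]
    r1 <- rc[, 1]; c1 <- rc[, 2]; r2 <- rc[, 3]; c2 <- rc[, 4]
    corners <- list(lin(r2 + 1L, c2 + 1L), lin(r1, c2 + 1L),
                    lin(r2 + 1L, c1), lin(r1, c1))
    signs <- c(1, -1, -1, 1)
    for (j in 1:4) {
      k <- k + 1L
      idx[[k]] <- corners[[j]]
      coef[k] <- rcoef[[nm]] * signs[j]
    }
  }
  list(idx = matrix(unlist(idx), ncol = 24L), coef = coef)
}

#' Improved Haar-like feature values
#'
#' Computes the value of every spec on every image: the pixel sum of the
#' center partition minus the pixel sum of the four side partitions (the four
#' `t x t` corner squares are excluded from the border). All arithmetic is on
#' exact integer pixel sums via integral images.
#'
#' @param images A `tongue_dataset`, a list of tongue images, or a single
#'   image array.
#' @param specs A `haar_grid` tibble (or any tibble with
#'   `channel, x, y, w, h, t`).
#' @return Numeric matrix, images in rows, specs in columns; column names are
#'   `f<spec_id>` (or `f<row>` if `spec_id` is absent). The spec table is
#'   attached as attribute `"specs"`.
#' @export
haar_values <- function(images, specs) {
  if (inherits(images, "tongue_dataset")) images <- images$images
  if (is.array(images) && length(dim(images)) == 3L) images <- list(images)
  images <- lapply(images, function(im) as_tongue_image(unclass(im)))
  validate_specs(specs)
  ids <- if ("spec_id" %in% names(specs)) specs$spec_id else seq_len(nrow(specs))
  out <- matrix(0, nrow = length(images), ncol = nrow(specs),
                dimnames = list(NULL, paste0("f", ids)))
  for (ch in unique(specs$channel)) {
    sel <- which(specs$channel == ch)
    plan <- haar_index_plan(specs[sel, , drop = FALSE])
    ci <- match(ch, CHANNELS)
    for (i in seq_along(images)) {
      int <- integral_image(images[[i]][, , ci])
      iv <- as.vector(int)
      looked <- matrix(iv[plan$idx], ncol = 24L)
      out[i, sel] <- drop(looked %*% plan$coef)
    }
  }
  attr(out, "specs") <- specs
  out
}

#' Single-spec feature value
#'
#' Convenience wrapper around [haar_values()] for one image and one spec.
#'
#' @param image A tongue image.
#' @param spec A one-row spec tibble.
#' @return A single numeric value.
#' @export
haar_value <- function(image, spec) {
  if (nrow(spec) != 1L) abort("`spec` must be a single row.")
  unname(haar_values(image, spec)[1, 1])
}
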