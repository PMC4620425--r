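#' Standard tongue-image frame
#'
#' All images entering the pipeline are standardized to a 120-pixel-high by
#' 100-pixel-wide RGB raster. These constants are used throughout for
#' validation and for the Haar-grid admissibility bounds.
#'
#' @format Integer scalars.
#' @name tongue_frame
NULL

TONGUE_HEIGHT <- 120L
TONGUE_WIDTH <- 100L
CHANNELS <- c("red", "green", "blue")

#' Validate and coerce a tongue image
#'
#' A tongue image is a `120 x 100 x 3` numeric array of 8-bit intensities
#' (`0..255`), dimension order row (vertical, y), column (horizontal, x),
#' channel (red, green, blue). Background pixels left over from segmentation
#' are encoded as 0 and take part in all pixel sums.
#'
#' @param x A numeric array.
#' @return The validated array, invisibly classed `tongue_image`.
#' @export
as_tongue_image <- function(x) {
  if (!is.array(x) || length(dim(x)) != 3L) {
    abort("A tongue image must be a 3-d array (row, column, channel).")
  }
  d <- dim(x)
  if (d[1] != TONGUE_HEIGHT || d[2] != TONGUE_WIDTH || d[3] != 3L) {
    abort(sprintf(
      "Image must be %d x %d x 3 after standardization, got %d x %d x %d.",
      TONGUE_HEIGHT, TONGUE_WIDTH, d[1], d[2], d[3]
    ))
  }
  if (anyNA(x) || min(x) < 0 || max(x) > 255) {
    abort("Pixel intensities must lie in [0, 255] with no missing values.")
  }
  class(x) <- c("tongue_image", class(x))
  x
}

#' Read a PNG as a standardized tongue image
#'
#' Reads an 8-bit PNG, drops any alpha channel, maps intensities to `0..255`
#' integers and, when the raster is not already 120 x 100, rescales it with
#' the requested resampling filter (EBImage does the resampling).
#'
#' @param path Path to a PNG file.
#' @param resample One of `"bilinear"` (default), `"nearest"`, or `"none"`.
#'   With `"none"` a non-standard raster is an error.
#' @return A [as_tongue_image()] array.
#' @export
read_tongue_png <- function(path, resample = c("bilinear", "nearest", "none")) {
  resample <- match.arg(resample)
  raw <- png::readPNG(path)
  if (length(dim(raw)) == 2L) raw <- array(rep(raw, 3L), dim = c(dim(raw), 3L))
  if (dim(raw)[3] > 3L) raw <- raw[, , 1:3, drop = FALSE]
  d <- dim(raw)
  if (d[1] != TONGUE_HEIGHT || d[2] != TONGUE_WIDTH) {
    if (resample == "none") {
      abort(sprintf("Image is %d x %d, expected %d x %d and resample = 'none'.",
                    d[1], d[2], TONGUE_HEIGHT, TONGUE_WIDTH))
    }
    rlang::check_installed("EBImage", reason = "to rescale images to 120 x 100")
    filt <- if (resample == "bilinear") "bilinear" else "none"
    # EBImage stores images as (x, y, channel)
    eb <- EBImage::Image(aperm(raw, c(2, 1, 3)), colormode = "Color")
    eb <- EBImage::resize(eb, w = TONGUE_WIDTH, h = TONGUE_HEIGHT, filter = filt)
    raw <- aperm(EBImage::imageData(eb), c(2, 1, 3))
  }
  as_tongue_image(round(pmin(pmax(raw, 0), 1) * 255))
}

#' Write a tongue image to PNG
#'
#' @param image A tongue image array (values `0..255`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tongue_png <- function(image, path) {
  image <- as_tongue_image(unclass(image))
  png::writePNG(unclass(image) / 255, target = path)
  invisible(path)
}
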