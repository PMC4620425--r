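#' Read and write Haar spec tables
#'
#' CSV columns are exactly `channel,x,y,w,h,t` in 1-based image coordinates;
#' the JSON form is a record array of the same fields.
#'
#' @param specs A spec tibble.
#' @param path File path.
#' @return `write_*` return `path` invisibly; `read_*` return a spec tibble.
#' @name spec_io
NULL

#' @rdname spec_io
#' @export
write_spec_csv <- function(specs, path) {
  readr::write_csv(specs[, c("channel", "x", "y", "w", "h", "t")], path)
  invisible(path)
}

#' @rdname spec_io
#' @export
read_spec_csv <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           channel = readr::col_character(),
                           .default = readr::col_integer()
                         ))
  out <- dplyr::mutate(out, spec_id = dplyr::row_number(), .before = 1)
  validate_specs(out)
  out
}

#' @rdname spec_io
#' @export
write_spec_json <- function(specs, path) {
  jsonlite::write_json(specs[, c("channel", "x", "y", "w", "h", "t")], path,
                       digits = NA)
  invisible(path)
}

#' @rdname spec_io
#' @export
read_spec_json <- function(path) {
  out <- tibble::as_tibble(jsonlite::read_json(path, simplifyVector = TRUE))
  out <- dplyr::mutate(out,
                       dplyr::across(c("x", "y", "w", "h", "t"), as.integer),
                       spec_id = dplyr::row_number(), .before = 1)
  validate_specs(out)
  out
}

#' Feature-matrix serialization
#'
#' Writes the examples x features matrix as CSV (first column `image_id`)
#' with a JSON sidecar of the spec metadata next to it
#' (`<path>.specs.json`).
#'
#' @param values Matrix from [haar_values()].
#' @param path CSV path.
#' @param image_ids Row identifiers.
#' @return `path` invisibly / the matrix with `"specs"` attribute restored.
#' @name feature_io
NULL

#' @rdname feature_io
#' @export
write_feature_csv <- function(values, path,
                              image_ids = rownames(values) %||%
                                sprintf("img%04d", seq_len(nrow(values)))) {
  df <- tibble::as_tibble(values)
  df <- dplyr::mutate(df, image_id = image_ids, .before = 1)
  readr::write_csv(df, path)
  sp <- attr(values, "specs")
  if (!is.null(sp)) write_spec_json(sp, paste0(path, ".specs.json"))
  invisible(path)
}

#' @rdname feature_io
#' @export
read_feature_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  ids <- df$image_id
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- ids
  sidecar <- paste0(path, ".specs.json")
  if (file.exists(sidecar)) attr(m, "specs") <- read_spec_json(sidecar)
  m
}

#' Label-table serialization (`image_id,group,label`)
#'
#' @param meta Tibble with `image_id`, `group` and optionally `label`.
#' @param path CSV path.
#' @return `path` invisibly / a tibble.
#' @name label_io
NULL

#' @rdname label_io
#' @export
write_labels_csv <- function(meta, path) {
  if (!"label" %in% names(meta)) {
    meta$label <- ifelse(meta$group == "A", "healthy", "ill")
  }
  readr::write_csv(meta[, c("image_id", "group", "label")], path)
  invisible(path)
}

#' @rdname label_io
#' @export
read_labels_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(.default = readr::col_character()))
}

#' Screen-result serialization (`feature_id,p_value,kept`)
#'
#' @param screen A `screen_result`.
#' @param path CSV path.
#' @return `path` invisibly / a `screen_result` tibble.
#' @name screen_io
NULL

#' @rdname screen_io
#' @export
write_screen_csv <- function(screen, path) {
  readr::write_csv(
    tibble(feature_id = screen$feature, p_value = screen$p_value,
           kept = screen$kept),
    path
  )
  invisible(path)
}

#' @rdname screen_io
#' @export
read_screen_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  out <- tibble(feature = as.integer(df$feature_id),
                feature_name = paste0("f", df$feature_id),
                p_value = df$p_value, kept = df$kept)
  attr(out, "n_kept") <- sum(out$kept)
  attr(out, "kept") <- which(out$kept)
  class(out) <- c("screen_result", class(out))
  out
}

#' Boost-result serialization
#'
#' JSON carries the selected classifiers, the per-round diagnostics, the
#' stop reason and the condition; the flat per-round CSV duplicates the
#' diagnostics table for spreadsheet use.
#'
#' @param fit A `roc_boost` object.
#' @param path JSON path.
#' @return `path` invisibly / a reconstructed `roc_boost` object.
#' @name boost_io
NULL

#' @rdname boost_io
#' @export
write_boost_json <- function(fit, path) {
  payload <- list(
    classifiers = fit$classifiers,
    rounds = fit$rounds,
    stop_reason = fit$stop_reason,
    condition = unclass(fit$condition),
    n_examples = fit$n_examples,
    n_features = fit$n_features,
    ensemble_auc_train = fit$ensemble_auc_train
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' @rdname boost_io
#' @export
read_boost_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  cond <- do.call(boost_condition, raw$condition)
  structure(
    list(classifiers = tibble::as_tibble(raw$classifiers),
         rounds = tibble::as_tibble(raw$rounds),
         stop_reason = raw$stop_reason, condition = cond,
         n_examples = raw$n_examples, n_features = raw$n_features,
         ensemble_auc_train = raw$ensemble_auc_train %||% NA_real_,
         specs = NULL),
    class = "roc_boost"
  )
}

#' Write a dataset as PNGs plus a label CSV
#'
#' Materializes a synthetic dataset in the on-disk layout the command-line
#' pipeline consumes: `<dir>/<image_id>.png` for each image and
#' `<dir>/labels.csv` with `image_id,group,label`.
#'
#' @param dataset A `tongue_dataset`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(dataset$images)) {
    write_tongue_png(dataset$images[[i]],
                     file.path(dir, paste0(dataset$meta$image_id[i], ".png")))
  }
  write_labels_csv(dataset$meta, file.path(dir, "labels.csv"))
  invisible(dir)
}

#' Read a PNG + label CSV layout back into a dataset
#'
#' @param dir Directory produced by [write_dataset()] (or hand-assembled in
#'   the same layout).
#' @return A `tongue_dataset` (without a `truth_rect`).
#' @export
read_dataset <- function(dir) {
  meta <- read_labels_csv(file.path(dir, "labels.csv"))
  images <- lapply(meta$image_id, function(id) {
    read_tongue_png(file.path(dir, paste0(id, ".png")))
  })
  structure(list(images = images, meta = meta, truth_rect = NULL,
                 config = NULL),
            class = "tongue_dataset")
}
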