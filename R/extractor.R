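#' Image-to-feature extractor plugin registry
#'
#' The package's mathematics operates on feature tables; producing those
#' features from images is delegated to pluggable extractor backends (for
#' example a pre-trained convolutional network living in another process or
#' package). A backend is any function taking a list of normalized image
#' arrays and returning one feature row per image with a declared, fixed
#' width. The core package ships no backend and none is required for any of
#' its functionality.
#'
#' @param name backend name.
#' @param fn function `(images) -> matrix` with `length(images)` rows.
#' @param width declared feature width (e.g. 512 for a ResNet18 penultimate
#'   layer); enforced on every call.
#' @return `name`, invisibly.
#' @export
register_extractor <- function(name, fn, width) {
  stopifnot(is.character(name), length(name) == 1L, is.function(fn))
  width <- as.integer(width)
  if (width < 1L) stop("`width` must be a positive integer.")
  assign(name, list(fn = fn, width = width), envir = extractor_registry)
  invisible(name)
}

extractor_registry <- new.env(parent = emptyenv())

#' List registered extractor backends
#' @return character vector of backend names.
#' @export
list_extractors <- function() ls(extractor_registry)

#' Normalize one image for feature extraction (internal)
#'
#' Per-image standardization: subtract the image mean, divide by its
#' standard deviation (guarded by eps = 1e-8 for constant images); no
#' augmentation. `per_channel` applies the same standardization slice-wise
#' along the third array dimension instead.
#' @noRd
normalize_image <- function(x, per_channel = FALSE, eps = 1e-8) {
  x <- as.array(x) * 1.0
  if (per_channel && length(dim(x)) == 3L) {
    for (ch in seq_len(dim(x)[3])) {
      sl <- x[, , ch]
      x[, , ch] <- (sl - mean(sl)) / (stats::sd(sl) + eps)
    }
    x
  } else {
    (x - mean(x)) / (stats::sd(as.numeric(x)) + eps)
  }
}

#' Extract features from images through a registered backend
#'
#' Applies per-image standardization (subtract the image mean, divide by
#' its standard deviation; constant images map to all-zero inputs via an
#' epsilon guard) and hands the normalized batch to the named backend,
#' enforcing the declared feature width on the result.
#'
#' @param name a backend registered with [register_extractor()].
#' @param images list of numeric arrays (one per image).
#' @param per_channel standardize each channel (third array dimension)
#'   separately instead of per image; default FALSE.
#' @return numeric matrix, one row per image, `width` columns.
#' @export
run_extractor <- function(name, images, per_channel = FALSE) {
  if (!exists(name, envir = extractor_registry, inherits = FALSE)) {
    stop(
      "no extractor backend named `", name, "` is registered",
      if (length(list_extractors())) {
        paste0(" (available: ", paste(list_extractors(), collapse = ", "), ")")
      } else {
        ""
      },
      ". Register one with register_extractor(name, fn, width)."
    )
  }
  backend <- get(name, envir = extractor_registry)
  stopifnot(is.list(images), length(images) >= 1L)
  norm <- lapply(images, normalize_image, per_channel = per_channel)
  out <- backend$fn(norm)
  out <- as.matrix(out)
  if (nrow(out) != length(images) || ncol(out) != backend$width) {
    stop(
      "backend `", name, "` violated its contract: returned ",
      nrow(out), " x ", ncol(out), ", expected ", length(images),
      " x ", backend$width, "."
    )
  }
  storage.mode(out) <- "double"
  out
}
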