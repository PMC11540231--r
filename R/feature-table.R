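#' Assemble a feature table
#'
#' A *feature table* is the package's central data structure: a tibble with
#' one row per image, an `id` column, a `label` column giving the class, and
#' one numeric column per feature (`f0`, `f1`, ...). Every modelling function
#' in the package takes such a table as its first argument.
#'
#' Class identity is positional: classes are ordered by first appearance in
#' the `label` column, and that order defines class indices `0..C-1` used
#' throughout (e.g. which class is "class 1" in binary scatter statistics).
#'
#' @param features numeric matrix, one row per image (N x M).
#' @param labels vector of length N with the class of each row. Any atomic
#'   type; coerced to character.
#' @param ids optional character vector of row identifiers; defaults to
#'   `"img_1" ... "img_N"`.
#' @return A tibble with columns `id`, `label`, `f0..f{M-1}`.
#' @examples
#' ft <- feature_table(matrix(rnorm(20), 5, 4), labels = c(0, 0, 1, 1, 1))
#' ft
#' @export
feature_table <- function(features, labels, ids = NULL) {
  features <- as.matrix(features)
  storage.mode(features) <- "double"
  n <- nrow(features)
  if (length(labels) != n) {
    stop("`labels` must have one entry per row of `features` (", n, ").")
  }
  if (is.null(ids)) ids <- paste0("img_", seq_len(n))
  colnames(features) <- paste0("f", seq_len(ncol(features)) - 1L)
  out <- tibble::as_tibble(features)
  out <- tibble::add_column(out,
    id = as.character(ids),
    label = as.character(labels),
    .before = 1L
  )
  validate_feature_table(out)
  out
}

#' Validate a feature table
#'
#' Checks the invariants every modelling function assumes: a `label` column,
#' at least one numeric feature column, at least one row, all feature entries
#' finite, and every class non-empty. Errors with a descriptive message when
#' a check fails; returns the table invisibly otherwise.
#'
#' @param data a feature table (see [feature_table()]).
#' @return `data`, invisibly.
#' @export
validate_feature_table <- function(data) {
  if (!is.data.frame(data)) stop("feature table must be a data frame.")
  if (!"label" %in% names(data)) stop("feature table must have a `label` column.")
  if (nrow(data) == 0L) stop("feature table has zero rows.")
  feat_cols <- feature_columns(data)
  if (length(feat_cols) == 0L) stop("feature table has no numeric feature columns.")
  max_m <- getOption("fewsubspace.max_features", 4096L)
  if (length(feat_cols) > max_m) {
    stop(
      "feature table has ", length(feat_cols), " features; the cap is ", max_m,
      " (see option 'fewsubspace.max_features')."
    )
  }
  for (cl in feat_cols) {
    v <- data[[cl]]
    if (!is.numeric(v)) stop("feature column `", cl, "` is not numeric.")
    if (anyNA(v) || any(!is.finite(v))) {
      stop("feature column `", cl, "` contains non-finite values.")
    }
  }
  if (anyNA(data$label)) stop("`label` contains missing values.")
  invisible(data)
}

#' @noRd
feature_columns <- function(data) {
  setdiff(names(data), c("id", "label"))
}

#' Split a feature table into matrix + label parts (internal)
#'
#' Classes are indexed 0..C-1 in order of first appearance in `label`.
#' @noRd
ft_parts <- function(data) {
  validate_feature_table(data)
  feat_cols <- feature_columns(data)
  Y <- as.matrix(data[, feat_cols, drop = FALSE])
  storage.mode(Y) <- "double"
  labs <- as.character(data$label)
  classes <- unique(labs)
  label_idx <- match(labs, classes) - 1L
  counts <- as.integer(table(factor(labs, levels = classes)))
  list(
    Y = Y, labels = label_idx, classes = classes, counts = counts,
    n = nrow(Y), m = ncol(Y), c = length(classes),
    feature_names = feat_cols,
    ids = if ("id" %in% names(data)) as.character(data$id) else NULL
  )
}

#' Read a feature table from delimited text
#'
#' Expects a header `id,label,f0,...,f{M-1}` (comma-separated, UTF-8, `.`
#' decimal). Row order is preserved and the result is validated.
#'
#' @param path path to a CSV file.
#' @return a feature table tibble.
#' @seealso [write_feature_table()]
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  data <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                          progress = FALSE)
  if (nrow(data) == 0L) {
    stop("feature table at ", path, " has zero rows (header only).")
  }
  if (!"label" %in% names(data)) {
    stop("feature table at ", path, " is missing the `label` column.")
  }
  for (cl in feature_columns(data)) {
    # strtod via as.numeric is correctly rounded, so %.17g round-trips exactly
    v <- suppressWarnings(as.numeric(data[[cl]]))
    if (anyNA(v) && !anyNA(data[[cl]])) {
      stop("feature column `", cl, "` in ", path, " is not numeric.")
    }
    data[[cl]] <- v
  }
  validate_feature_table(data)
  data
}

#' Write a feature table to delimited text
#'
#' @param data a feature table.
#' @param path destination CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(data, path) {
  validate_feature_table(data)
  out <- data
  for (cl in feature_columns(out)) {
    # 17 significant digits round-trip doubles exactly
    out[[cl]] <- sprintf("%.17g", out[[cl]])
  }
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}
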