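#' Write an evaluation report to JSON (+ companion CSV)
#'
#' Serializes an [evaluate_pipeline()] report to JSON — config echo,
#' per-repeat per-K accuracy table, summary statistics, and a provenance
#' block (package version, seeds) sufficient to re-run the evaluation —
#' plus a companion CSV of the accuracy table next to it.
#'
#' @param report an `"eval_report"`.
#' @param path destination `.json` path; the CSV uses the same stem.
#' @return `path`, invisibly.
#' @seealso [read_eval_report()]
#' @export
write_eval_report <- function(report, path) {
  stopifnot(inherits(report, "eval_report"))
  cfg <- unclass(report$config)
  cfg$dim <- cfg$dim %||% NA_integer_
  cfg$coupling_weight <- cfg$coupling_weight %||% NA_real_
  payload <- list(
    provenance = list(
      package = "fewsubspace",
      version = as.character(utils::packageVersion("fewsubspace")),
      master_seed = report$config$master_seed
    ),
    config = cfg,
    n_classes = report$n_classes,
    dim_used = report$dim_used,
    mean_accuracy = report$mean_accuracy,
    sd_accuracy = report$sd_accuracy,
    sd_accuracy_pooled = report$sd_accuracy_pooled,
    per_repeat = report$per_repeat,
    accuracy = report$accuracy
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null", dataframe = "columns")
  readr::write_csv(report$accuracy, sub("\\.json$", ".csv", path),
                   progress = FALSE)
  invisible(path)
}

#' Read an evaluation report back from JSON
#'
#' Inverse of [write_eval_report()]: reconstructs an `"eval_report"` whose
#' summary statistics and accuracy table equal the written ones.
#'
#' @param path a JSON file written by [write_eval_report()].
#' @return an `"eval_report"`.
#' @export
read_eval_report <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- payload$config
  config <- eval_config(
    method = cfg$method,
    per_class_train = cfg$per_class_train,
    per_class_test = cfg$per_class_test,
    dim = if (is.null(cfg$dim) || is.na(cfg$dim)) NULL else cfg$dim,
    knn_k = cfg$knn_k,
    n_repeats = cfg$n_repeats,
    delta = cfg$delta,
    nmf_iters = cfg$nmf_iters,
    classifier = cfg$classifier,
    coupling_weight = if (is.null(cfg$coupling_weight) || is.na(cfg$coupling_weight)) NULL else cfg$coupling_weight,
    master_seed = cfg$master_seed,
    center_pca = cfg$center_pca
  )
  acc <- tibble::as_tibble(payload$accuracy)
  acc$repeat_id <- as.integer(acc$repeat_id)
  acc$k <- as.integer(acc$k)
  structure(
    list(
      accuracy = acc,
      per_repeat = as.numeric(payload$per_repeat),
      mean_accuracy = payload$mean_accuracy,
      sd_accuracy = payload$sd_accuracy,
      sd_accuracy_pooled = payload$sd_accuracy_pooled,
      config = config,
      n_classes = payload$n_classes,
      dim_used = payload$dim_used
    ),
    class = "eval_report"
  )
}

#' Serialize a fitted subspace or factorization to JSON
#'
#' Writes the full numeric content of a fitted object (`"linear_subspace"`,
#' `"foley_sammon"` or `"nmf_fit"`) at maximum double precision so that
#' [read_fit()] round-trips it bit-identically.
#'
#' @param object the fitted object.
#' @param path destination `.json` path.
#' @return `path`, invisibly.
#' @export
write_fit <- function(object, path) {
  kind <- class(object)[1]
  if (!kind %in% c("linear_subspace", "foley_sammon", "nmf_fit")) {
    stop("cannot serialize objects of class `", kind, "`.")
  }
  payload <- list(kind = kind, fields = serialize_fields(object))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

# doubles are written as %.17g strings: 17 significant digits round-trip
# IEEE 754 doubles exactly, which plain JSON number emission does not
#' @noRd
serialize_fields <- function(object) {
  lapply(unclass(object), function(v) {
    if (is.matrix(v)) {
      list(.matrix = TRUE, nrow = nrow(v), data = I(sprintf("%.17g", as.numeric(v))))
    } else if (is.double(v)) {
      list(.num = TRUE, data = I(sprintf("%.17g", v)))
    } else if (inherits(v, "binary_scatter_stats")) {
      list(.stats = TRUE, fields = serialize_fields(v))
    } else if (is.list(v) && all(vapply(v, is.matrix, logical(1)))) {
      list(.matrices = TRUE, items = lapply(v, function(mm) {
        list(nrow = nrow(mm), data = I(sprintf("%.17g", as.numeric(mm))))
      }))
    } else {
      v
    }
  })
}

#' @noRd
deserialize_fields <- function(fields) {
  lapply(fields, function(v) {
    if (is.list(v) && isTRUE(v$.matrix)) {
      matrix(as.numeric(v$data), nrow = v$nrow)
    } else if (is.list(v) && isTRUE(v$.num)) {
      as.numeric(v$data)
    } else if (is.list(v) && isTRUE(v$.stats)) {
      structure(deserialize_fields(v$fields), class = "binary_scatter_stats")
    } else if (is.list(v) && isTRUE(v$.matrices)) {
      lapply(v$items, function(mm) matrix(as.numeric(mm$data), nrow = mm$nrow))
    } else {
      v
    }
  })
}

#' Read a fitted object written by [write_fit()]
#'
#' @param path a JSON file written by [write_fit()].
#' @return the reconstructed fitted object.
#' @export
read_fit <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  fields <- deserialize_fields(payload$fields)
  for (nm in c("m", "dim", "n_iter", "seed", "rank", "n")) {
    if (!is.null(fields[[nm]]) && !is.na(fields[[nm]])) {
      fields[[nm]] <- as.integer(fields[[nm]])
    }
  }
  structure(fields, class = payload$kind)
}

#' Read and validate a YAML run configuration
#'
#' Loads a YAML file describing an evaluation run and converts it to an
#' [eval_config()]. Unknown keys are rejected so typos never silently fall
#' back to defaults.
#'
#' @param path path to a YAML file. Recognized keys: `method`, `dim`,
#'   `per_class_train`, `per_class_test`, `knn_k`, `n_repeats`, `delta`,
#'   `nmf_iters`, `classifier`, `coupling_weight`, `master_seed`,
#'   `center_pca`, plus pass-through `input` and `output` paths.
#' @return list with `config` (an `eval_config`), `input`, `output`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  allowed <- c(
    "method", "dim", "per_class_train", "per_class_test", "knn_k",
    "n_repeats", "delta", "nmf_iters", "classifier", "coupling_weight",
    "master_seed", "center_pca", "input", "output"
  )
  unknown <- setdiff(names(raw), allowed)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         ". Allowed: ", paste(allowed, collapse = ", "), ".")
  }
  args <- raw[setdiff(names(raw), c("input", "output"))]
  config <- do.call(eval_config, args)
  list(config = config, input = raw$input, output = raw$output)
}
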