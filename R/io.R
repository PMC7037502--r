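# Plain-text persistence: datasets as CSV (one spectrum per row, columns
# wavenumber_1..wavenumber_n, label, split) with a JSON sidecar holding
# the generating configuration and the wavenumber axis; evaluation
# reports as JSON; run configurations as YAML.

sidecar_path <- function(path) paste0(path, ".json")

#' Write a spectra dataset to CSV
#'
#' Columns are `wavenumber_1 ... wavenumber_n` (absorbance values),
#' `label` and `split`. A JSON sidecar `<path>.json` records the
#' wavenumber axis, class names, preprocessing state and, when present,
#' the synthetic-study configuration, so [read_spectra()] can rebuild
#' the dataset faithfully.
#'
#' @param ds A [spectra_dataset].
#' @param path Output CSV path.
#' @param sidecar Write the JSON sidecar (default `TRUE`).
#' @return `path`, invisibly.
#' @export
write_spectra <- function(ds, path, sidecar = TRUE) {
  df <- data.table::as.data.table(ds$absorbance)
  data.table::setnames(df, paste0("wavenumber_", seq_len(n_points(ds))))
  df$label <- ds$labels
  df$split <- ds$split
  data.table::fwrite(df, path)
  if (sidecar) {
    meta <- list(grid = list(n_points = n_points(ds),
                             wn_min = min(ds$grid), wn_max = max(ds$grid)),
                 class_names = ds$class_names,
                 preprocessed = ds$preprocessed)
    if (!is.null(ds$config)) meta$config <- unclass(ds$config)
    jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(path)
}

#' Read a spectra dataset from CSV
#'
#' Inverse of [write_spectra()]: the round trip reproduces the
#' absorbance matrix to float-text precision. Ragged rows, non-numeric
#' absorbance cells, out-of-range labels and a column count that
#' disagrees with the wavenumber grid are all rejected with the
#' offending row or column named.
#'
#' @param path CSV path in the [write_spectra()] dialect.
#' @param grid Optional [wavenumber_grid()] the file must match; by
#'   default the sidecar's grid (or a default axis over the file's
#'   column count) is used.
#' @return A [spectra_dataset].
#' @export
read_spectra <- function(path, grid = NULL) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  dt <- tryCatch(
    suppressWarnings(data.table::fread(path, header = TRUE,
                                       data.table = TRUE)),
    error = function(e) abort(sprintf("Failed to parse %s: %s", path,
                                      conditionMessage(e))))
  if (is.null(dt) || nrow(dt) == 0L || ncol(dt) < 3L) {
    abort(sprintf("%s contains no spectra.", path))
  }
  if (!all(c("label", "split") %in% names(dt))) {
    abort("Expected `label` and `split` columns.")
  }
  wn_cols <- setdiff(names(dt), c("label", "split"))
  for (cn in wn_cols) {
    col <- dt[[cn]]
    if (!is.numeric(col)) {
      bad <- which(is.na(suppressWarnings(as.numeric(col))))[1L]
      abort(sprintf("Non-numeric absorbance in column %s, row %d.",
                    cn, if (is.na(bad)) 1L else bad))
    }
  }
  meta <- NULL
  if (file.exists(sidecar_path(path))) {
    meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  }
  if (is.null(grid)) {
    grid <- if (!is.null(meta)) {
      wavenumber_grid(meta$grid$n_points, meta$grid$wn_min, meta$grid$wn_max)
    } else {
      wavenumber_grid(length(wn_cols))
    }
  }
  if (length(wn_cols) != length(grid)) {
    abort(sprintf(
      "File has %d absorbance columns but the grid has %d points.",
      length(wn_cols), length(grid)))
  }
  absorbance <- as.matrix(dt[, wn_cols, with = FALSE])
  labels <- dt$label
  class_names <- if (!is.null(meta)) meta$class_names else NULL
  K <- if (is.null(class_names)) max(labels) else length(class_names)
  bad <- which(labels < 1L | labels > K)[1L]
  if (!is.na(bad)) {
    abort(sprintf("Label out of range 1..%d in row %d.", K, bad))
  }
  ds <- spectra_dataset(absorbance, labels, dt$split, grid, class_names,
                        preprocessed = isTRUE(meta$preprocessed))
  if (!is.null(meta$config)) {
    ds$config <- do.call(synth_config, meta$config[names(meta$config) %in%
                                                     names(formals(synth_config))])
  }
  ds
}

#' Write / read an evaluation report
#'
#' Serializes an `eval_report` as JSON: percent accuracy, counts, class
#' names, per-class accuracy and the confusion matrix stored row-major
#' in class-name order (rows = true class).
#'
#' @param report An `eval_report` from [evaluate()].
#' @param path JSON path.
#' @return `write_report()`: `path`, invisibly. `read_report()`: the
#'   reconstructed `eval_report`.
#' @export
write_report <- function(report, path) {
  if (!inherits(report, "eval_report")) {
    abort("`report` must be an eval_report.")
  }
  obj <- list(accuracy = report$accuracy, n_correct = report$n_correct,
              n_total = report$n_total, class_names = report$class_names,
              per_class_accuracy = unname(report$per_class_accuracy),
              confusion = lapply(seq_len(nrow(report$confusion)),
                                 function(r) unname(report$confusion[r, ])))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  K <- length(obj$class_names)
  confusion <- if (is.matrix(obj$confusion)) {
    matrix(as.integer(obj$confusion), K, K)       # already rows = true class
  } else {
    matrix(as.integer(unlist(obj$confusion)), K, K, byrow = TRUE)
  }
  dimnames(confusion) <- list(true = obj$class_names,
                              predicted = obj$class_names)
  structure(list(accuracy = obj$accuracy, n_correct = obj$n_correct,
                 n_total = obj$n_total, confusion = confusion,
                 per_class_accuracy = setNames(obj$per_class_accuracy,
                                               obj$class_names),
                 class_names = obj$class_names),
            class = "eval_report")
}

run_config_keys <- list(
  data = "character", output_dir = "character", seed = "integer",
  monitor = "character",
  preprocessing = c("window", "polyorder", "deriv"),
  model = c("family", "stages", "conv_width", "pool_width", "feature_maps",
            "image_side", "n_components"),
  training = c("learning_rate", "batch_size", "max_epochs", "dropout_p",
               "patience"))

#' Read a run configuration from YAML
#'
#' Top-level keys: `data` (CSV path, must exist), `output_dir`, `seed`,
#' `monitor`, and the nested blocks `preprocessing`, `model`,
#' `training`. Unknown keys anywhere are rejected.
#'
#' @param path YAML path.
#' @return Named list with defaults filled in.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  unknown <- setdiff(names(cfg), names(run_config_keys))
  if (length(unknown)) {
    abort(sprintf("Unknown run-config key(s): %s",
                  paste(unknown, collapse = ", ")))
  }
  for (blk in c("preprocessing", "model", "training")) {
    extra <- setdiff(names(cfg[[blk]]), run_config_keys[[blk]])
    if (length(extra)) {
      abort(sprintf("Unknown key(s) in `%s`: %s", blk,
                    paste(extra, collapse = ", ")))
    }
  }
  if (is.null(cfg$data)) abort("Run config must name a `data` file.")
  if (!file.exists(cfg$data)) {
    abort(sprintf("Data file not found: %s", cfg$data))
  }
  cfg$seed <- if (is.null(cfg$seed)) 1L else as.integer(cfg$seed)
  cfg$output_dir <- cfg$output_dir %||% "."
  cfg$monitor <- cfg$monitor %||% "validation"
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a
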