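benchmark_meta_fields <- c("fs", "T", "freq_grid", "master_seed", "generator")
benchmark_columns <- c("split", "window_id", "analyte", "label", "carrier_freq",
                       "occupancy", "isd", "seed", "clean", "noisy")

#' Write a benchmark dataset to disk
#'
#' Persists the window table as Parquet (list columns hold the traces) next to
#' a JSON sidecar carrying all generator metadata (sampling rate, window
#' length, frequency grid, master seed and the full generator configuration),
#' so a written dataset is self-describing.
#'
#' @param dataset A `sinw_benchmark`.
#' @param path Output directory.
#' @param overwrite Allow writing over an existing dataset.
#' @return `path`, invisibly.
#' @export
write_benchmark <- function(dataset, path, overwrite = FALSE) {
  if (dir.exists(path) && file.exists(file.path(path, "windows.parquet")) && !overwrite) {
    abort(sprintf("'%s' already holds a dataset; use overwrite = TRUE", path))
  }
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  arrow::write_parquet(tibble::as_tibble(dataset[benchmark_columns]),
                       file.path(path, "windows.parquet"))
  meta <- list(
    fs = attr(dataset, "fs"), T = attr(dataset, "T"),
    freq_grid = attr(dataset, "freq_grid"),
    master_seed = attr(dataset, "master_seed"),
    generator = attr(dataset, "generator"),
    package_version = as.character(utils::packageVersion("sinwfet"))
  )
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a benchmark dataset from disk
#'
#' Validates the schema strictly: a missing column or metadata attribute
#' raises an error naming it.
#'
#' @param path Dataset directory written by [write_benchmark()].
#' @return A `sinw_benchmark`.
#' @export
read_benchmark <- function(path) {
  pq <- file.path(path, "windows.parquet")
  mj <- file.path(path, "meta.json")
  if (!file.exists(pq)) abort(sprintf("no dataset at '%s' (missing windows.parquet)", path))
  if (!file.exists(mj)) abort(sprintf("dataset at '%s' lacks metadata (missing meta.json)", path))
  ds <- tibble::as_tibble(arrow::read_parquet(pq))
  missing_cols <- setdiff(benchmark_columns, names(ds))
  if (length(missing_cols)) {
    abort(sprintf("dataset schema invalid: missing column(s) %s",
                  paste(missing_cols, collapse = ", ")))
  }
  meta <- jsonlite::read_json(mj, simplifyVector = TRUE)
  for (f in benchmark_meta_fields) {
    if (is.null(meta[[f]])) abort(sprintf("dataset metadata invalid: missing attribute '%s'", f))
  }
  ds$clean <- lapply(ds$clean, as.numeric)
  ds$noisy <- lapply(ds$noisy, as.numeric)
  attr(ds, "fs") <- meta$fs
  attr(ds, "T") <- as.integer(meta$T)
  attr(ds, "freq_grid") <- as.numeric(meta$freq_grid)
  attr(ds, "master_seed") <- as.integer(meta$master_seed)
  attr(ds, "generator") <- meta$generator
  class(ds) <- c("sinw_benchmark", class(ds))
  ds
}

#' Export one window to CSV
#'
#' Two columns, `clean` and `noisy`, in ampere.
#' @param dataset A `sinw_benchmark`.
#' @param window_id Window id (row of `dataset$window_id`).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
export_window_csv <- function(dataset, window_id, path) {
  i <- match(window_id, dataset$window_id)
  if (is.na(i)) abort(sprintf("window_id %s not found", window_id))
  write.csv(data.frame(clean = dataset$clean[[i]], noisy = dataset$noisy[[i]]),
            path, row.names = FALSE)
  invisible(path)
}

#' Import a window CSV
#' @param path CSV written by [export_window_csv()].
#' @return A list with numeric vectors `clean` and `noisy`.
#' @export
import_window_csv <- function(path) {
  df <- read.csv(path)
  for (col in c("clean", "noisy")) {
    if (!col %in% names(df)) abort(sprintf("window CSV invalid: missing column '%s'", col))
  }
  list(clean = df$clean, noisy = df$noisy)
}

#' Save / load a trained or quantized denoiser
#'
#' The archive holds the layer configuration, all weight tensors, the
#' standardization constants and training metadata in one portable file.
#'
#' @param model A `trained_denoiser` or `quantized_denoiser`.
#' @param path Archive path (`.rds`).
#' @return `path` (write) or the model (read).
#' @export
write_denoiser <- function(model, path) {
  stopifnot(inherits(model, c("trained_denoiser", "quantized_denoiser")))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname write_denoiser
#' @export
read_denoiser <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, c("trained_denoiser", "quantized_denoiser"))) {
    abort(sprintf("'%s' does not contain a denoiser archive", path))
  }
  model
}
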