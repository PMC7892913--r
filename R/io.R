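#' Read and write pipeline objects
#'
#' Datasets, epoch sets and model checkpoints are stored as single-file RDS
#' containers (R-native serialisation); sensor layouts, gaze logs and
#' labeled-trial tables use plain CSV with fixed schemas so that they can be
#' inspected and produced by other tools.
#'
#' @param x object to write.
#' @param path file path.
#' @return `read_*` functions return the object; `write_*` return `path`
#'   invisibly.
#' @name fixdecode-io
NULL

#' @rdname fixdecode-io
#' @export
write_dataset <- function(x, path) {
  saveRDS(x, path)
  invisible(path)
}

#' @rdname fixdecode-io
#' @export
read_dataset <- function(path) {
  if (!file.exists(path)) stop("data error: file not found: ", path)
  readRDS(path)
}

#' @rdname fixdecode-io
#' @export
write_layout <- function(x, path) {
  stopifnot(inherits(x, "sensor_layout"))
  df <- data.frame(channel_id = x$channel_ids,
                   x = x$positions[, 1], y = x$positions[, 2],
                   frontal = as.integer(x$frontal_mask))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname fixdecode-io
#' @export
read_layout <- function(path) {
  if (!file.exists(path)) stop("data error: file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  structure(list(channel_ids = df$channel_id,
                 positions = cbind(df$x, df$y),
                 frontal_mask = df$frontal == 1),
            class = "sensor_layout")
}

#' @rdname fixdecode-io
#' @export
write_gaze_log <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' @rdname fixdecode-io
#' @export
read_gaze_log <- function(path) {
  if (!file.exists(path)) stop("data error: file not found: ", path)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' @rdname fixdecode-io
#' @export
write_labeled_trials <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' @rdname fixdecode-io
#' @export
save_model <- function(x, path) {
  stopifnot(inherits(x, "fixdecode_model"))
  saveRDS(x, path)
  invisible(path)
}

#' @rdname fixdecode-io
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop("data error: file not found: ", path)
  x <- readRDS(path)
  if (!inherits(x, "fixdecode_model")) stop("data error: not a model file")
  x
}
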