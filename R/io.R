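#' @section File formats:
#' All tabular containers are plain CSV (comma-separated, header row, UTF-8,
#' '.' decimal). Container metadata that does not fit a column (sampling
#' rate, session type, duration) is written to a JSON sidecar at
#' `<path>.meta.json`. Movies are stored with R native serialization
#' (`saveRDS`), which preserves the array bit-exactly.
#' @name vpcalcium-io
#' @keywords internal
NULL

meta_path <- function(path) paste0(path, ".meta.json")

write_meta <- function(path, meta) {
  jsonlite::write_json(meta, meta_path(path), auto_unbox = TRUE, digits = NA)
}

read_meta <- function(path) {
  mp <- meta_path(path)
  if (!file.exists(mp)) stop("missing metadata sidecar: ", mp)
  jsonlite::read_json(mp, simplifyVector = TRUE)
}

check_columns <- function(df, required, what) {
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop(sprintf("malformed %s file: missing column(s) %s", what,
                 paste(missing, collapse = ", ")))
  }
  invisible(df)
}

read_csv_strict <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
}

write_csv_plain <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
}

#' Read and write pipeline containers
#'
#' Write-then-read returns a value equal to the input: bit-exact for
#' integers and labels, within formatting precision (15 significant digits)
#' for reals.
#'
#' @param x Object to write.
#' @param path Destination file. CSV containers also get a
#'   `<path>.meta.json` sidecar.
#' @return `write_*` returns `path` invisibly; `read_*` returns the
#'   reconstructed object.
#' @name io
NULL

#' @rdname io
#' @export
write_traces <- function(x, path) {
  stopifnot(inherits(x, "trace_set"))
  df <- data.frame(cell_id = x$cell_ids, cell_type = x$cell_type,
                   stringsAsFactors = FALSE)
  tr <- x$traces
  colnames(tr) <- sprintf("s%06d", seq_len(ncol(tr)) - 1L)
  df <- cbind(df, as.data.frame(tr))
  write_csv_plain(df, path)
  write_meta(path, list(container = "trace_set", fs = x$fs,
                        session = x$session, n_samples = ncol(x$traces)))
  invisible(path)
}

#' @rdname io
#' @export
read_traces <- function(path) {
  meta <- read_meta(path)
  df <- read_csv_strict(path)
  check_columns(df, c("cell_id", "cell_type"), "trace_set")
  sample_cols <- grep("^s[0-9]+$", names(df), value = TRUE)
  if (!length(sample_cols)) stop("malformed trace_set file: no sample columns (s000000...)")
  tr <- as.matrix(df[, sample_cols, drop = FALSE])
  dimnames(tr) <- NULL
  trace_set(tr, fs = meta$fs, cell_ids = df$cell_id,
            cell_type = df$cell_type, session = meta$session)
}

#' @rdname io
#' @export
write_events <- function(x, path) {
  stopifnot(inherits(x, "event_train"))
  write_csv_plain(x$events, path)
  write_meta(path, list(container = "event_train", duration_s = x$duration_s,
                        session = x$session, cell_ids = x$cell_ids,
                        cell_type = x$cell_type))
  invisible(path)
}

#' @rdname io
#' @export
read_events <- function(path) {
  meta <- read_meta(path)
  df <- read_csv_strict(path)
  check_columns(df, c("cell_id", "time_s", "amplitude_dff"), "event_train")
  df$cell_id <- as.character(df$cell_id)
  event_train(df, cell_ids = as.character(meta$cell_ids),
              duration_s = meta$duration_s, cell_type = meta$cell_type,
              session = meta$session)
}

#' @rdname io
#' @export
write_behavior <- function(x, path) {
  stopifnot(inherits(x, "behavior_session"))
  write_csv_plain(x$events, path)
  write_meta(path, list(container = "behavior_session",
                        session_type = x$session_type,
                        duration_s = x$duration_s))
  invisible(path)
}

#' @rdname io
#' @export
read_behavior <- function(path) {
  meta <- read_meta(path)
  df <- read_csv_strict(path)
  check_columns(df, c("time_s", "event"), "behavior_session")
  behavior_session(df, session_type = meta$session_type,
                   duration_s = meta$duration_s)
}

#' @rdname io
#' @export
write_centroids <- function(centroids, path) {
  df <- as.data.frame(centroids)
  check_columns(df, c("x", "y"), "centroid")
  if (is.null(df$cell_id)) df <- cbind(cell_id = sprintf("cell%04d", seq_len(nrow(df))), df)
  write_csv_plain(df[, c("cell_id", "x", "y")], path)
  invisible(path)
}

#' @rdname io
#' @export
read_centroids <- function(path) {
  df <- read_csv_strict(path)
  check_columns(df, c("cell_id", "x", "y"), "centroid")
  df
}

#' @rdname io
#' @export
write_labels <- function(labels, path) {
  df <- as.data.frame(labels)
  write_csv_plain(df, path)
  invisible(path)
}

#' @rdname io
#' @export
read_labels <- function(path) {
  df <- read_csv_strict(path)
  if (!ncol(df)) stop("malformed label file: no columns")
  df
}

#' @rdname io
#' @export
write_movie <- function(x, path) {
  stopifnot(inherits(x, "fluo_movie"))
  saveRDS(x, path)
  invisible(path)
}

#' @rdname io
#' @export
read_movie <- function(path) {
  x <- readRDS(path)
  if (!inherits(x, "fluo_movie")) stop("malformed movie file: not a fluo_movie")
  x
}

#' @rdname io
#' @export
write_results_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname io
#' @export
read_results_json <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
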