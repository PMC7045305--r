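#' Trace set: cells x samples dF/F matrix with metadata
#'
#' @param traces Numeric matrix, one row per cell, one column per sample.
#' @param fs Sampling rate in Hz. Sample j (1-based) covers time
#'   (j-1)/fs, i.e. left-edge convention from session start.
#' @param cell_ids Character vector of cell identifiers.
#' @param cell_type Character vector (`"Glu"`, `"GABA"`, `"Penk"`) or a
#'   scalar recycled to all cells.
#' @param session Session label (e.g. `"Ext1"`, `"Ext10"`, `"Reinst"`).
#' @return An object of class `trace_set`.
#' @export
trace_set <- function(traces, fs, cell_ids = NULL, cell_type = NA_character_,
                      session = NA_character_) {
  traces <- as.matrix(traces)
  storage.mode(traces) <- "double"
  n <- nrow(traces)
  if (is.null(cell_ids)) cell_ids <- sprintf("cell%04d", seq_len(n))
  if (length(cell_type) == 1L) cell_type <- rep(cell_type, n)
  stopifnot(fs > 0, length(cell_ids) == n, length(cell_type) == n)
  structure(list(traces = traces, fs = as.numeric(fs),
                 cell_ids = as.character(cell_ids),
                 cell_type = as.character(cell_type),
                 session = as.character(session)[1]),
            class = "trace_set")
}

#' @export
print.trace_set <- function(x, ...) {
  cat(sprintf("<trace_set> %d cells x %d samples @ %g Hz (%.1f s), session %s\n",
              nrow(x$traces), ncol(x$traces), x$fs,
              ncol(x$traces) / x$fs, x$session))
  invisible(x)
}

#' Duration of a trace set in seconds
#' @param x A `trace_set`.
#' @return Numeric scalar, seconds.
#' @export
trace_duration <- function(x) ncol(x$traces) / x$fs

#' Event train: per-cell Ca2+ event times and amplitudes
#'
#' @param events Data frame with columns `cell_id`, `time_s` (seconds from
#'   session start) and `amplitude_dff`.
#' @param cell_ids All cell ids (cells with zero events included).
#' @param duration_s Session duration in seconds.
#' @param cell_type,session Optional labels, as in [trace_set()].
#' @return An object of class `event_train`.
#' @export
event_train <- function(events, cell_ids, duration_s,
                        cell_type = NA_character_, session = NA_character_) {
  stopifnot(is.data.frame(events),
            all(c("cell_id", "time_s", "amplitude_dff") %in% names(events)))
  if (length(cell_type) == 1L) cell_type <- rep(cell_type, length(cell_ids))
  stopifnot(length(cell_type) == length(cell_ids))
  events <- events[order(match(events$cell_id, cell_ids), events$time_s), ,
                   drop = FALSE]
  rownames(events) <- NULL
  if (nrow(events)) {
    stopifnot(all(events$time_s >= 0), all(events$time_s < duration_s),
              all(events$amplitude_dff > 0),
              all(events$cell_id %in% cell_ids))
    for (id in unique(events$cell_id)) {
      tt <- events$time_s[events$cell_id == id]
      if (any(diff(tt) <= 0)) stop("event times must be strictly increasing per cell")
    }
  }
  structure(list(events = events, cell_ids = as.character(cell_ids),
                 duration_s = as.numeric(duration_s),
                 cell_type = as.character(cell_type),
                 session = as.character(session)[1]),
            class = "event_train")
}

#' @export
print.event_train <- function(x, ...) {
  cat(sprintf("<event_train> %d events over %d cells, %.1f s, session %s\n",
              nrow(x$events), length(x$cell_ids), x$duration_s, x$session))
  invisible(x)
}

#' Behavioral session event log
#'
#' @param events Data frame with columns `time_s` and `event`; recognised
#'   event types are `active_poke`, `inactive_poke`, `cue_on`, `cue_off`,
#'   `infusion`.
#' @param session_type One of `"SA"`, `"Ext1"`, `"Ext10"`, `"Reinst"`.
#' @param duration_s Session duration in seconds.
#' @return An object of class `behavior_session`.
#' @export
behavior_session <- function(events, session_type, duration_s) {
  stopifnot(is.data.frame(events), all(c("time_s", "event") %in% names(events)))
  session_type <- match.arg(session_type, c("SA", "Ext1", "Ext10", "Reinst"))
  events <- events[order(events$time_s), , drop = FALSE]
  rownames(events) <- NULL
  if (nrow(events)) stopifnot(all(events$time_s >= 0), all(events$time_s <= duration_s))
  structure(list(events = events, session_type = session_type,
                 duration_s = as.numeric(duration_s)),
            class = "behavior_session")
}

#' @export
print.behavior_session <- function(x, ...) {
  tab <- table(x$events$event)
  cat(sprintf("<behavior_session> %s, %.0f s: %s\n", x$session_type,
              x$duration_s,
              paste(sprintf("%s=%d", names(tab), as.integer(tab)), collapse = ", ")))
  invisible(x)
}

#' Count active pokes in a behavioral session
#' @param session A `behavior_session`.
#' @param limit_min Optional analysis limit in minutes (from session start).
#' @return Integer count.
#' @export
active_pokes <- function(session, limit_min = Inf) {
  ev <- session$events
  sum(ev$event == "active_poke" & ev$time_s < limit_min * 60)
}

#' Fluorescence movie (frames x height x width)
#'
#' @param frames 3-D numeric array, time x height x width.
#' @param fs Frame rate in Hz.
#' @param dff Logical: are values dF/F normalized (`TRUE`) or raw (`FALSE`)?
#' @return An object of class `fluo_movie`.
#' @export
fluo_movie <- function(frames, fs, dff = FALSE) {
  stopifnot(is.array(frames), length(dim(frames)) == 3L, fs > 0)
  structure(list(frames = frames, fs = as.numeric(fs), dff = isTRUE(dff)),
            class = "fluo_movie")
}

#' @export
print.fluo_movie <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<fluo_movie> %d frames of %dx%d px @ %g Hz (%s)\n",
              d[1], d[2], d[3], x$fs, if (x$dff) "dF/F" else "raw"))
  invisible(x)
}

#' Spatial point pattern with field bounds
#'
#' @param points n x 2 numeric matrix of (x, y) positions in pixels.
#' @param bounds Length-4 numeric `c(xmin, xmax, ymin, ymax)`.
#' @param mode `"CSR"` (complete spatial randomness) or `"clustered"`.
#' @return An object of class `spatial_pattern`.
#' @export
spatial_pattern <- function(points, bounds, mode = c("CSR", "clustered")) {
  mode <- match.arg(mode)
  points <- as.matrix(points)
  stopifnot(ncol(points) == 2L, length(bounds) == 4L,
            bounds[1] < bounds[2], bounds[3] < bounds[4])
  if (nrow(points)) {
    stopifnot(all(points[, 1] >= bounds[1] & points[, 1] <= bounds[2]),
              all(points[, 2] >= bounds[3] & points[, 2] <= bounds[4]))
  }
  colnames(points) <- c("x", "y")
  structure(list(points = points, bounds = as.numeric(bounds), mode = mode),
            class = "spatial_pattern")
}

#' @export
print.spatial_pattern <- function(x, ...) {
  cat(sprintf("<spatial_pattern> %d points in [%g,%g]x[%g,%g] (%s)\n",
              nrow(x$points), x$bounds[1], x$bounds[2], x$bounds[3],
              x$bounds[4], x$mode))
  invisible(x)
}
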