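#' Ca2+ transient event detection
#'
#' The trace is first smoothed with a short centered moving average
#' (`smooth_points`, default 5 samples, i.e. 0.33 s at 15 Hz), which
#' suppresses sample-to-sample noise peaks without shifting transient
#' timing. An event is then a local maximum whose prominence (peak minus the
#' preceding trough) is at least `thresh_mads` times the MAD of the smoothed
#' trace and whose rise from that trough takes at most `max_rise_s` seconds.
#' Events closer than `min_separation_s` are merged, keeping the larger
#' peak; the default merge radius (0.35 s) is about the trough-to-peak rise
#' time of a GCaMP6f transient, so noise-split peaks on a single transient
#' merge while genuinely consecutive transients stay resolved. The event
#' amplitude is the prominence (peak dF/F minus the preceding trough); the
#' event time is the transient onset, taken as the last sample before the
#' peak at which the trace is still within `onset_fraction` of the
#' prominence above the trough.
#'
#' @param x A [trace_set()] of dF/F traces.
#' @param thresh_mads Prominence threshold in MAD units (default 6; see the
#'   methods vignette for the calibration that sets the null false-event
#'   rate below 0.1/min).
#' @param max_rise_s Maximum trough-to-peak rise time, seconds (default 2).
#' @param min_separation_s Merge radius for nearby events, seconds.
#' @param smooth_points Centered moving-average length (samples) applied
#'   before peak finding; 1 disables smoothing.
#' @param onset_fraction Rise fraction defining the reported onset time.
#' @return An [event_train()].
#' @export
detect_events <- function(x, thresh_mads = 6, max_rise_s = 2,
                          min_separation_s = 0.35, smooth_points = 5L,
                          onset_fraction = 0.2) {
  stopifnot(inherits(x, "trace_set"))
  bad <- which(!apply(is.finite(x$traces), 1, all))
  if (length(bad)) {
    stop("non-finite samples in cells: ", paste(x$cell_ids[bad], collapse = ", "))
  }
  fs <- x$fs
  n <- ncol(x$traces)
  all_ev <- vector("list", nrow(x$traces))
  for (ci in seq_len(nrow(x$traces))) {
    v <- moving_average(x$traces[ci, ], smooth_points)
    if (n < 3) { all_ev[[ci]] <- NULL; next }
    core <- 2:(n - 1)
    is_pk <- v[core] > v[core - 1] & v[core] >= v[core + 1]
    pk <- core[is_pk]
    if (!length(pk)) next
    thr <- thresh_mads * stats::mad(v)
    times <- amps <- numeric(0)
    prev <- 1L
    for (p in pk) {
      seg <- prev:p
      tr_idx <- seg[which.min(v[seg])]
      prom <- v[p] - v[tr_idx]
      rise <- (p - tr_idx) / fs
      if (prom >= thr && prom > 0 && rise <= max_rise_s) {
        below <- which(v[tr_idx:p] <= v[tr_idx] + onset_fraction * prom)
        onset <- tr_idx + (if (length(below)) below[length(below)] else 1L) - 1L
        times <- c(times, (onset - 1) / fs)
        amps <- c(amps, prom)
      }
      prev <- p
    }
    if (length(times) > 1 && min_separation_s > 0) {
      keep_t <- times[1]; keep_a <- amps[1]
      for (j in 2:length(times)) {
        last <- length(keep_t)
        if (times[j] - keep_t[last] < min_separation_s) {
          if (amps[j] > keep_a[last]) {
            keep_t[last] <- times[j]; keep_a[last] <- amps[j]
          }
        } else {
          keep_t <- c(keep_t, times[j]); keep_a <- c(keep_a, amps[j])
        }
      }
      times <- keep_t; amps <- keep_a
    }
    if (length(times)) {
      all_ev[[ci]] <- data.frame(cell_id = x$cell_ids[ci], time_s = times,
                                 amplitude_dff = amps, stringsAsFactors = FALSE)
    }
  }
  ev <- do.call(rbind, all_ev)
  if (is.null(ev)) {
    ev <- data.frame(cell_id = character(0), time_s = numeric(0),
                     amplitude_dff = numeric(0), stringsAsFactors = FALSE)
  }
  event_train(ev, cell_ids = x$cell_ids, duration_s = trace_duration(x),
              cell_type = x$cell_type, session = x$session)
}

#' Per-cell and per-group event statistics
#'
#' Rates and amplitudes are computed over the configured analysis window only
#' (default: the first 60 min of the session); group summaries are mean +/-
#' SEM by cell type and session.
#'
#' @param et An [event_train()].
#' @param limit_min Analysis window from session start, minutes.
#' @return List of class `event_stats` with `per_cell` and `by_group` data
#'   frames.
#' @export
event_stats <- function(et, limit_min = 60) {
  stopifnot(inherits(et, "event_train"), limit_min > 0)
  lim_s <- min(limit_min * 60, et$duration_s)
  eff_min <- lim_s / 60
  ev <- et$events[et$events$time_s < limit_min * 60, , drop = FALSE]
  per_cell <- data.frame(cell_id = et$cell_ids, cell_type = et$cell_type,
                         session = et$session, stringsAsFactors = FALSE)
  cnt <- table(factor(ev$cell_id, levels = et$cell_ids))
  per_cell$n_events <- as.integer(cnt)
  per_cell$rate_per_min <- per_cell$n_events / eff_min
  amp <- tapply(ev$amplitude_dff, factor(ev$cell_id, levels = et$cell_ids), mean)
  per_cell$mean_amplitude <- as.numeric(amp)
  sem <- function(v) stats::sd(v) / sqrt(length(v))
  grp <- split(per_cell, list(per_cell$cell_type, per_cell$session), drop = TRUE)
  by_group <- do.call(rbind, lapply(grp, function(g) {
    data.frame(cell_type = g$cell_type[1], session = g$session[1],
               n_cells = nrow(g),
               rate_mean = mean(g$rate_per_min), rate_sem = sem(g$rate_per_min),
               amp_mean = mean(g$mean_amplitude, na.rm = TRUE),
               amp_sem = sem(g$mean_amplitude[!is.na(g$mean_amplitude)]),
               stringsAsFactors = FALSE)
  }))
  rownames(by_group) <- NULL
  structure(list(per_cell = per_cell, by_group = by_group,
                 limit_min = limit_min),
            class = "event_stats")
}

#' @export
print.event_stats <- function(x, ...) {
  cat(sprintf("<event_stats> first %g min\n", x$limit_min))
  print(x$by_group)
  invisible(x)
}

#' Cumulative event counts over time
#'
#' @param et An [event_train()].
#' @param bin_s Bin width in seconds (default 60).
#' @param limit_min Window length in minutes; default the full session.
#' @return List of class `cumulative_events` with `time_s` (right bin edges),
#'   `counts` (cells x bins cumulative matrix) and `group_mean` (mean curve
#'   per cell type).
#' @export
cumulative_events <- function(et, bin_s = 60, limit_min = NULL) {
  stopifnot(inherits(et, "event_train"), bin_s > 0)
  lim_s <- if (is.null(limit_min)) et$duration_s else min(limit_min * 60, et$duration_s)
  edges <- seq(0, lim_s, by = bin_s)
  if (edges[length(edges)] < lim_s) edges <- c(edges, lim_s)
  nb <- length(edges) - 1L
  counts <- matrix(0L, length(et$cell_ids), nb,
                   dimnames = list(et$cell_ids, NULL))
  ev <- et$events[et$events$time_s < lim_s, , drop = FALSE]
  if (nrow(ev)) {
    b <- findInterval(ev$time_s, edges, rightmost.closed = TRUE,
                      left.open = FALSE)
    tab <- table(factor(ev$cell_id, levels = et$cell_ids),
                 factor(b, levels = seq_len(nb)))
    counts <- matrix(as.integer(tab), nrow(tab), nb,
                     dimnames = list(et$cell_ids, NULL))
  }
  cum <- t(apply(counts, 1, cumsum))
  if (nb == 1L) cum <- matrix(cum, ncol = 1, dimnames = list(et$cell_ids, NULL))
  types <- unique(et$cell_type)
  gm <- lapply(stats::setNames(types, types), function(ty) {
    colMeans(cum[et$cell_type == ty, , drop = FALSE])
  })
  structure(list(time_s = edges[-1], counts = cum, group_mean = gm),
            class = "cumulative_events")
}

#' Extinction criterion: responding below 40% of the first extinction day
#'
#' A subject counts as extinguished when active pokes on the late extinction
#' session are strictly below 40% of the first extinction session.
#'
#' @param ext1,ext10 [behavior_session()] objects (or active-poke counts).
#' @param limit_min Optional analysis window in minutes.
#' @param threshold Fraction of Ext1 responding (default 0.40).
#' @return Logical scalar.
#' @export
extinction_criterion <- function(ext1, ext10, limit_min = Inf, threshold = 0.40) {
  n1 <- if (inherits(ext1, "behavior_session")) active_pokes(ext1, limit_min) else ext1
  n10 <- if (inherits(ext10, "behavior_session")) active_pokes(ext10, limit_min) else ext10
  if (n1 <= 0) stop("Ext1 active-poke count must be positive")
  n10 < threshold * n1
}
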