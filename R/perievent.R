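#' Nose-poke-aligned peri-event analysis
#'
#' Fluorescence around each selected nose poke is windowed (-10 to +20 s by
#' default), smoothed with a running 10-point moving average, z-scored within
#' the window, and averaged across trials per cell. Population magnitude uses
#' the absolute z-trace; responder classification uses the signed trial
#' average with a 2-SD rule on the pre-poke baseline.
#'
#' @name vpcalcium-perievent
#' @keywords internal
NULL

#' Select nose pokes that enter the peri-event analysis
#'
#' Extinction sessions keep active pokes separated by at least
#' `min_separation_s` from both the previous and next active poke (to prevent
#' cross-contamination between responses); self-administration and
#' reinstatement sessions keep only cued pokes, i.e. pokes falling outside
#' the `cue_timeout_s` timeout started by the previous cued poke. Only pokes
#' within the first `limit_min` minutes are returned.
#'
#' @param session A [behavior_session()].
#' @param limit_min Analysis window, minutes.
#' @param min_separation_s Minimum spacing for extinction pokes, seconds.
#' @param cue_timeout_s Cue timeout for SA/reinstatement sessions, seconds.
#' @return Numeric vector of trial times (s), possibly empty (with warning).
#' @export
select_trials <- function(session, limit_min = 60, min_separation_s = 20,
                          cue_timeout_s = 20) {
  stopifnot(inherits(session, "behavior_session"))
  pokes <- sort(session$events$time_s[session$events$event == "active_poke"])
  if (session$session_type %in% c("Ext1", "Ext10")) {
    if (length(pokes) == 0L) keep <- numeric(0)
    else if (length(pokes) == 1L) keep <- pokes
    else {
      gap_prev <- c(Inf, diff(pokes))
      gap_next <- c(diff(pokes), Inf)
      keep <- pokes[gap_prev >= min_separation_s & gap_next >= min_separation_s]
    }
  } else { # SA / Reinst: cued pokes only
    keep <- numeric(0)
    last_cue <- -Inf
    for (t in pokes) {
      if (t - last_cue >= cue_timeout_s) {
        keep <- c(keep, t)
        last_cue <- t
      }
    }
  }
  keep <- keep[keep < limit_min * 60]
  if (!length(keep)) warning("no trials survive the selection rules")
  keep
}

moving_average <- function(x, k) {
  n <- length(x)
  if (k <= 1L || n == 0L) return(x)
  hl <- floor((k - 1) / 2)
  hr <- ceiling((k - 1) / 2)
  cs <- cumsum(c(0, x))
  i <- seq_len(n)
  lo <- pmax(1L, i - hl)
  hi <- pmin(n, i + hr)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Build the peri-event tensor
#'
#' For each cell and trial: extract the window around the poke, smooth with a
#' centered running `smoothing_points` moving average (shrinking at the
#' window edges), and z-score using the mean and SD of that same windowed
#' segment. Trials without a full window inside the recording are dropped;
#' cell-trials with zero-variance windows are set to `NA` with a warning.
#'
#' @param x A [trace_set()] (dF/F or z-scored; z-scoring removes scale).
#' @param trial_times Trial (nose-poke) times in seconds.
#' @param window_s Length-2 window around the poke, seconds.
#' @param smoothing_points Moving-average length in samples.
#' @return Object of class `perievent_tensor`: `values` (cells x trials x
#'   bins, z-units), `time_rel` (bin times relative to the poke), and labels.
#' @export
build_perievent <- function(x, trial_times, window_s = c(-10, 20),
                            smoothing_points = 10L) {
  stopifnot(inherits(x, "trace_set"), length(window_s) == 2L,
            window_s[1] < window_s[2])
  fs <- x$fs
  n <- ncol(x$traces)
  nb <- as.integer(round((window_s[2] - window_s[1]) * fs))
  eps <- 1e-9
  j0 <- ceiling((trial_times + window_s[1]) * fs - eps) + 1L
  full <- j0 >= 1L & (j0 + nb - 1L) <= n
  if (any(!full)) {
    warning(sprintf("%d trial(s) dropped: window extends beyond the recording",
                    sum(!full)))
  }
  trial_times <- trial_times[full]
  j0 <- j0[full]
  nt <- length(trial_times)
  if (nt == 0L) stop("no trials with a full peri-event window")
  vals <- array(NA_real_, c(nrow(x$traces), nt, nb))
  n_dropped <- 0L
  for (ci in seq_len(nrow(x$traces))) {
    v <- x$traces[ci, ]
    for (tj in seq_len(nt)) {
      seg <- moving_average(v[j0[tj]:(j0[tj] + nb - 1L)], smoothing_points)
      s <- stats::sd(seg)
      if (!is.finite(s) || s == 0) { n_dropped <- n_dropped + 1L; next }
      vals[ci, tj, ] <- (seg - mean(seg)) / s
    }
  }
  if (n_dropped > 0L) {
    warning(sprintf("%d cell-trial window(s) dropped (zero variance)", n_dropped))
  }
  time_rel <- window_s[1] + (seq_len(nb) - 1L) / fs
  structure(list(values = vals, time_rel = time_rel,
                 trial_times = trial_times, cell_ids = x$cell_ids,
                 cell_type = x$cell_type, session = x$session, fs = fs,
                 window_s = window_s),
            class = "perievent_tensor")
}

#' @export
print.perievent_tensor <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<perievent_tensor> %d cells x %d trials x %d bins over [%g, %g] s\n",
              d[1], d[2], d[3], x$window_s[1], x$window_s[2]))
  invisible(x)
}

# Trial-averaged (cells x bins) z traces; na.rm over dropped cell-trials.
trial_average <- function(pet) {
  apply(pet$values, c(1, 3), mean, na.rm = TRUE)
}

window_mask <- function(time_rel, win) {
  # half-open, right-closed: t in (a, b]
  time_rel > win[1] + 1e-9 & time_rel <= win[2] + 1e-9
}

#' Population response magnitude around nose pokes
#'
#' The per-cell trial-averaged z trace is transformed to absolute values (so
#' increases and decreases both count as responses); per-cell pre and post
#' means are taken over (-2, 0] and (0, 2] s, and group curves are mean +/-
#' SEM across cells of each type.
#'
#' @param pet A `perievent_tensor` from [build_perievent()].
#' @param pre,post Length-2 comparison windows, seconds (half-open,
#'   right-closed).
#' @return Object of class `population_response` with `per_cell` (pre/post
#'   means of |z|) and `group_curves` (per cell type: mean and SEM |z|
#'   traces).
#' @export
population_response <- function(pet, pre = c(-2, 0), post = c(0, 2)) {
  stopifnot(inherits(pet, "perievent_tensor"))
  avg <- trial_average(pet)
  aavg <- abs(avg)
  mpre <- window_mask(pet$time_rel, pre)
  mpost <- window_mask(pet$time_rel, post)
  per_cell <- data.frame(cell_id = pet$cell_ids, cell_type = pet$cell_type,
                         pre_mean = rowMeans(aavg[, mpre, drop = FALSE]),
                         post_mean = rowMeans(aavg[, mpost, drop = FALSE]),
                         stringsAsFactors = FALSE)
  types <- unique(pet$cell_type)
  curves <- lapply(stats::setNames(types, types), function(ty) {
    m <- aavg[pet$cell_type == ty, , drop = FALSE]
    list(time_rel = pet$time_rel, mean = colMeans(m),
         sem = apply(m, 2, stats::sd) / sqrt(nrow(m)))
  })
  structure(list(per_cell = per_cell, group_curves = curves,
                 session = pet$session),
            class = "population_response")
}

#' Classify cells as increased, decreased, or unchanged responders
#'
#' On the signed trial-averaged z trace, the baseline is the mean and SD over
#' the pre window (-2, 0]; a cell is `increased` when its mean over the post
#' window (0, 2] exceeds baseline mean + `sd_threshold` x baseline SD,
#' `decreased` when below baseline mean - threshold x SD, else `unchanged`.
#' Zero-variance baselines yield `unchanged` and are flagged.
#'
#' @param pet A `perievent_tensor`.
#' @param sd_threshold SD multiple (default 2).
#' @param pre,post Comparison windows, seconds.
#' @return List of class `responder_classes`: `per_cell` data frame (class,
#'   baseline stats, post mean) and `fractions` per cell type (sum to 1).
#' @export
classify_cells <- function(pet, sd_threshold = 2, pre = c(-2, 0),
                           post = c(0, 2)) {
  stopifnot(inherits(pet, "perievent_tensor"))
  avg <- trial_average(pet)
  mpre <- window_mask(pet$time_rel, pre)
  mpost <- window_mask(pet$time_rel, post)
  base_mean <- rowMeans(avg[, mpre, drop = FALSE])
  base_sd <- apply(avg[, mpre, drop = FALSE], 1, stats::sd)
  post_mean <- rowMeans(avg[, mpost, drop = FALSE])
  flagged <- !is.finite(base_sd) | base_sd == 0
  cls <- rep("unchanged", length(base_mean))
  up <- !flagged & post_mean > base_mean + sd_threshold * base_sd
  dn <- !flagged & post_mean < base_mean - sd_threshold * base_sd
  cls[up] <- "increased"
  cls[dn] <- "decreased"
  per_cell <- data.frame(cell_id = pet$cell_ids, cell_type = pet$cell_type,
                         class = cls, pre_mean = base_mean, baseline_sd = base_sd,
                         post_mean = post_mean, flagged = flagged,
                         stringsAsFactors = FALSE)
  lv <- c("increased", "decreased", "unchanged")
  types <- unique(pet$cell_type)
  fractions <- do.call(rbind, lapply(types, function(ty) {
    sub <- per_cell$class[per_cell$cell_type == ty]
    p <- as.numeric(table(factor(sub, levels = lv))) / length(sub)
    data.frame(cell_type = ty, class = lv, fraction = p,
               n_cells = length(sub), stringsAsFactors = FALSE)
  }))
  structure(list(per_cell = per_cell, fractions = fractions,
                 sd_threshold = sd_threshold, session = pet$session),
            class = "responder_classes")
}

#' Heatmap row ordering by response class and magnitude
#'
#' Rows sort by class (increased, unchanged, decreased), then by |post - pre|
#' descending within class, with ties broken by cell id so the ordering is
#' invariant to the input row permutation.
#'
#' @param classes A `responder_classes` object from [classify_cells()].
#' @return Character vector of cell ids in display order.
#' @export
order_heatmap <- function(classes) {
  pc <- classes$per_cell
  rank_class <- match(pc$class, c("increased", "unchanged", "decreased"))
  mag <- abs(pc$post_mean - pc$pre_mean)
  pc$cell_id[order(rank_class, -mag, pc$cell_id)]
}
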