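#' Pipeline configuration
#'
#' Bundles the scalar constants used throughout the pipeline. Defaults are the
#' published analysis parameters: 15 Hz acquisition, spatial downsampling by a
#' factor of 4, a peri-event window of -10 to +20 s around the nose poke, a
#' running 10-point moving-average filter, pre/post comparison windows of
#' (-2, 0] and (0, 2] s, a 2-SD responder threshold, a 20-s minimum trial
#' separation, a 20-s cue timeout, analysis restricted to the first 60 min,
#' k = 10 nearest neighbors with 1000 shuffles for the spatial clustering
#' test, and alpha = 0.05.
#'
#' @param frame_rate_hz Acquisition frame rate in Hz.
#' @param spatial_downsample Integer spatial block-mean pooling factor.
#' @param perievent_window_s Length-2 numeric, window around each trial in
#'   seconds (start, end), start < end.
#' @param smoothing_points Number of samples in the running moving average.
#' @param prepost_window_s List of two length-2 windows (pre, post) in
#'   seconds, used for the population-magnitude and responder analyses.
#' @param responder_sd_threshold SD multiple for increased/decreased calls.
#' @param min_trial_separation_s Minimum spacing between extinction-session
#'   nose pokes entering the peri-event analysis.
#' @param cue_timeout_s Cue timeout in seconds (FR1 schedule).
#' @param analysis_limit_min Analysis window from session start, minutes.
#' @param knn_k Neighbor order for the spatial clustering statistic.
#' @param n_shuffles Number of uniform redraws for the clustering null.
#' @param alpha Significance level.
#' @param rng_seed Integer seed split into per-stage substreams.
#'
#' @return An object of class `pipeline_config` (a validated list).
#' @export
pipeline_config <- function(frame_rate_hz = 15,
                            spatial_downsample = 4L,
                            perievent_window_s = c(-10, 20),
                            smoothing_points = 10L,
                            prepost_window_s = list(pre = c(-2, 0), post = c(0, 2)),
                            responder_sd_threshold = 2,
                            min_trial_separation_s = 20,
                            cue_timeout_s = 20,
                            analysis_limit_min = 60,
                            knn_k = 10L,
                            n_shuffles = 1000L,
                            alpha = 0.05,
                            rng_seed = 1L) {
  cfg <- list(
    frame_rate_hz = as.numeric(frame_rate_hz),
    spatial_downsample = as.integer(spatial_downsample),
    perievent_window_s = as.numeric(perievent_window_s),
    smoothing_points = as.integer(smoothing_points),
    prepost_window_s = lapply(prepost_window_s, as.numeric),
    responder_sd_threshold = as.numeric(responder_sd_threshold),
    min_trial_separation_s = as.numeric(min_trial_separation_s),
    cue_timeout_s = as.numeric(cue_timeout_s),
    analysis_limit_min = as.numeric(analysis_limit_min),
    knn_k = as.integer(knn_k),
    n_shuffles = as.integer(n_shuffles),
    alpha = as.numeric(alpha),
    rng_seed = as.integer(rng_seed)
  )
  validate_pipeline_config(cfg)
  structure(cfg, class = "pipeline_config")
}

validate_pipeline_config <- function(cfg) {
  stopifnot(
    cfg$frame_rate_hz > 0,
    cfg$spatial_downsample >= 1L,
    length(cfg$perievent_window_s) == 2L,
    cfg$perievent_window_s[1] < cfg$perievent_window_s[2],
    cfg$smoothing_points >= 1L,
    length(cfg$prepost_window_s) == 2L,
    cfg$prepost_window_s[[1]][1] < cfg$prepost_window_s[[1]][2],
    cfg$prepost_window_s[[2]][1] < cfg$prepost_window_s[[2]][2],
    cfg$responder_sd_threshold > 0,
    cfg$min_trial_separation_s > 0,
    cfg$cue_timeout_s > 0,
    cfg$analysis_limit_min > 0,
    cfg$knn_k >= 1L,
    cfg$n_shuffles >= 1L,
    cfg$alpha > 0, cfg$alpha < 1
  )
  invisible(cfg)
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config>\n")
  flat <- unlist(x)
  for (nm in names(flat)) cat(sprintf("  %-24s %s\n", nm, flat[[nm]]))
  invisible(x)
}

#' Derive a per-stage RNG substream seed from a global seed
#'
#' One global seed is split deterministically into independent per-stage
#' seeds: the stage name is hashed with a 31-bit polynomial rolling hash
#' (base 31) and combined with the global seed by a Lehmer-style multiplier,
#' modulo 2^31 - 1. Identical (seed, stage) pairs always map to the same
#' substream; distinct stages map to well-separated streams.
#'
#' @param seed Integer global seed.
#' @param stage Character scalar naming the pipeline stage.
#' @param index Optional non-negative integer for stage-internal replicates.
#' @return An integer seed suitable for `set.seed()`.
#' @export
split_seed <- function(seed, stage, index = 0L) {
  stopifnot(is.character(stage), length(stage) == 1L)
  m <- 2147483647 # 2^31 - 1
  h <- 0
  for (cc in utf8ToInt(stage)) h <- (h * 31 + cc) %% m
  s <- (as.numeric(seed) %% m) + 1
  out <- (s * 48271) %% m
  out <- (out + h * 69621) %% m
  out <- (out + as.numeric(index) * 16807) %% m
  as.integer(out %% 2147483646 + 1)
}
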