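#' Synthetic-data generators
#'
#' Seed-deterministic generators that emulate the statistical structure the
#' downstream analyses assume: GCaMP6f-like transients riding on noisy
#' baselines at configurable per-type event rates, FR1 operant sessions with
#' 20-s cue timeouts, extinction decay, cued reinstatement, clustered vs
#' uniformly random spatial point patterns, and Bernoulli D1/D2 upstream
#' labels. Every generator exports the ground truth needed to score the
#' corresponding analysis stage.
#'
#' @name vpcalcium-synth
#' @keywords internal
NULL

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Calcium transient kernel parameters
#'
#' Double-exponential transient shape standing in for the GCaMP6f response:
#' `h(t) = exp(-t/decay) - exp(-t/rise)`, normalized to unit peak. Defaults
#' (rise 0.2 s, decay 0.6 s, peak amplitude 0.25 dF/F) are typical of
#' GCaMP6f in one-photon recordings.
#'
#' @param rise_tau_s Rise time constant, seconds.
#' @param decay_tau_s Decay time constant, seconds; must exceed the rise.
#' @param peak_dff Mean event amplitude in dF/F units.
#' @return An object of class `kernel_params`.
#' @export
kernel_params <- function(rise_tau_s = 0.2, decay_tau_s = 0.6, peak_dff = 0.25) {
  stopifnot(rise_tau_s > 0, decay_tau_s > 0, peak_dff > 0,
            decay_tau_s > rise_tau_s)
  structure(list(rise_tau_s = rise_tau_s, decay_tau_s = decay_tau_s,
                 peak_dff = peak_dff), class = "kernel_params")
}

# Unit-peak kernel evaluated at offsets t (s) from event onset.
eval_kernel <- function(t, kp) {
  h <- exp(-t / kp$decay_tau_s) - exp(-t / kp$rise_tau_s)
  tpk <- kp$rise_tau_s * kp$decay_tau_s / (kp$decay_tau_s - kp$rise_tau_s) *
    log(kp$decay_tau_s / kp$rise_tau_s)
  hpk <- exp(-tpk / kp$decay_tau_s) - exp(-tpk / kp$rise_tau_s)
  out <- h / hpk
  out[t < 0] <- 0
  out
}

# Kernel support: onset to decay below 0.5% of peak.
kernel_support_s <- function(kp) kp$decay_tau_s * log(200)

#' Generate synthetic dF/F traces with Poisson event ground truth
#'
#' Event times per cell are homogeneous Poisson at `rate_per_min`; each event
#' adds one kernel transient with a lognormal amplitude (mean `peak_dff`,
#' sdlog 0.25, so amplitudes are positive and right-skewed); white Gaussian
#' baseline noise is scaled so that `peak_dff / noise SD = snr`.
#'
#' @param n_cells Number of cells.
#' @param duration_s Session duration in seconds.
#' @param rate_per_min Mean event rate, events/min.
#' @param kernel A [kernel_params()] object.
#' @param snr Peak amplitude over noise SD; must be > 0.
#' @param fs Sampling rate in Hz (default 15).
#' @param cell_type,session Labels propagated to the trace set.
#' @param amp_sdlog Lognormal sdlog of event amplitudes.
#' @param seed Integer seed.
#' @return List with elements `traces` (a [trace_set()]) and `truth` (per-cell
#'   event times and amplitudes).
#' @export
gen_traces <- function(n_cells, duration_s, rate_per_min,
                       kernel = kernel_params(), snr = 8, fs = 15,
                       cell_type = NA_character_, session = NA_character_,
                       amp_sdlog = 0.25, seed = 1L) {
  stopifnot(n_cells >= 1, rate_per_min >= 0, snr > 0, fs > 0)
  if (duration_s < kernel_support_s(kernel)) {
    stop(sprintf("duration_s = %g too short for one kernel transient (need >= %.2f s)",
                 duration_s, kernel_support_s(kernel)))
  }
  n_samp <- as.integer(round(duration_s * fs))
  t_grid <- (seq_len(n_samp) - 1L) / fs
  noise_sd <- kernel$peak_dff / snr
  meanlog <- log(kernel$peak_dff) - amp_sdlog^2 / 2
  support <- kernel_support_s(kernel)

  with_seed(seed, {
    traces <- matrix(0, n_cells, n_samp)
    ev_times <- vector("list", n_cells)
    ev_amps <- vector("list", n_cells)
    for (i in seq_len(n_cells)) {
      n_ev <- stats::rpois(1, rate_per_min * duration_s / 60)
      tt <- sort(stats::runif(n_ev, 0, duration_s))
      aa <- stats::rlnorm(n_ev, meanlog, amp_sdlog)
      x <- numeric(n_samp)
      for (e in seq_len(n_ev)) {
        j0 <- floor(tt[e] * fs) + 1L
        j1 <- min(n_samp, j0 + as.integer(ceiling(support * fs)))
        if (j0 > n_samp) next
        idx <- j0:j1
        x[idx] <- x[idx] + aa[e] * eval_kernel(t_grid[idx] - tt[e], kernel)
      }
      traces[i, ] <- x + stats::rnorm(n_samp, 0, noise_sd)
      ev_times[[i]] <- tt
      ev_amps[[i]] <- aa
    }
    ts <- trace_set(traces, fs = fs, cell_type = cell_type, session = session)
    truth <- structure(list(event_times = stats::setNames(ev_times, ts$cell_ids),
                            event_amplitudes = stats::setNames(ev_amps, ts$cell_ids),
                            cell_type = ts$cell_type,
                            rate_per_min = rate_per_min,
                            kernel = kernel, snr = snr),
                       class = "ground_truth")
    list(traces = ts, truth = truth)
  })
}

gaussian_footprint <- function(h, w, cx, cy, sigma) {
  xs <- matrix(seq_len(w), h, w, byrow = TRUE)
  ys <- matrix(seq_len(h), h, w)
  exp(-((xs - cx)^2 + (ys - cy)^2) / (2 * sigma^2))
}

#' Render a synthetic miniscope movie from traces and cell centroids
#'
#' Each cell is a 2-D Gaussian footprint with a static (resting
#' fluorescence) component plus a dynamic component modulated by its dF/F
#' trace, over a constant background:
#' `F(t, y, x) = B * (1 + sum_i a_i(y, x) (g + s_i(t)))` with static gain
#' `g`, plus white pixel noise. The static component gives frames the
#' persistent spatial structure that motion registration needs (set
#' `static_gain = 0` for a purely dynamic scene). Optionally a slow
#' zero-mean sinusoidal rigid drift of known per-frame magnitude is applied
#' (returned in the `shifts` attribute), which provides a planted-shift
#' oracle for motion correction.
#'
#' @param centroids n_cells x 2 matrix of (x, y) centers in pixels.
#' @param traces A [trace_set()]; its length sets the movie length.
#' @param frame_dims `c(height, width)` in pixels.
#' @param footprint_sigma Gaussian footprint SD, pixels.
#' @param background Constant baseline fluorescence level B (> 0).
#' @param noise_sd Pixel noise SD (same units as B).
#' @param static_gain Static footprint brightness g relative to B.
#' @param drift_px Peak rigid drift in pixels (0 disables drift).
#' @param seed Integer seed for the pixel noise.
#' @return A [fluo_movie()] with attribute `shifts` (frames x 2 matrix of the
#'   applied (dx, dy) drift).
#' @export
gen_movie <- function(centroids, traces, frame_dims = c(40, 40),
                      footprint_sigma = 2, background = 1, noise_sd = 0.02,
                      static_gain = 0.3, drift_px = 0, seed = 1L) {
  centroids <- matrix(as.numeric(centroids), ncol = 2)
  n_cells <- nrow(centroids)
  if (n_cells != nrow(traces$traces)) {
    stop("centroids and traces disagree on the number of cells")
  }
  h <- frame_dims[1]; w <- frame_dims[2]
  if (n_cells && (any(centroids[, 1] < 1 | centroids[, 1] > w) ||
                  any(centroids[, 2] < 1 | centroids[, 2] > h))) {
    stop("centroids outside the frame")
  }
  if (n_cells > 1 && anyDuplicated(round(centroids, 6))) {
    warning("overlapping identical centroids; cells will be inseparable")
  }
  n_t <- ncol(traces$traces)
  shifts <- if (drift_px > 0) {
    ph <- 2 * pi * (seq_len(n_t) - 1L) / n_t
    cbind(dx = drift_px * sin(ph), dy = drift_px * sin(2 * ph) / 2)
  } else {
    matrix(0, n_t, 2, dimnames = list(NULL, c("dx", "dy")))
  }
  mov <- with_seed(seed, {
    if (n_cells == 0L) {
      array(background + stats::rnorm(n_t * h * w, 0, noise_sd), c(n_t, h, w))
    } else if (drift_px == 0) {
      fp <- vapply(seq_len(n_cells), function(i) {
        as.vector(gaussian_footprint(h, w, centroids[i, 1], centroids[i, 2],
                                     footprint_sigma))
      }, numeric(h * w))                     # (h*w) x n_cells
      sig <- fp %*% (traces$traces + static_gain) # (h*w) x n_t
      arr <- array(0, c(n_t, h, w))
      arr[] <- background * (1 + t(sig)) +
        stats::rnorm(n_t * h * w, 0, noise_sd)
      arr
    } else {
      arr <- array(0, c(n_t, h, w))
      for (t in seq_len(n_t)) {
        fr <- matrix(0, h, w)
        for (i in seq_len(n_cells)) {
          fr <- fr + (traces$traces[i, t] + static_gain) *
            gaussian_footprint(h, w, centroids[i, 1] + shifts[t, 1],
                               centroids[i, 2] + shifts[t, 2], footprint_sigma)
        }
        arr[t, , ] <- background * (1 + fr) + stats::rnorm(h * w, 0, noise_sd)
      }
      arr
    }
  })
  out <- fluo_movie(mov, fs = traces$fs, dff = FALSE)
  attr(out, "shifts") <- shifts
  out
}

default_poke_rates <- function() {
  # active pokes per minute by session type; Ext10 is set well below 40% of
  # Ext1 so simulated cohorts satisfy the extinction criterion
  c(SA = 1.0, Ext1 = 1.5, Ext10 = 0.4, Reinst = 1.2)
}

renewal_times <- function(duration_s, rate_per_min, refractory_s = 1) {
  if (rate_per_min <= 0) return(numeric(0))
  mean_iei <- 60 / rate_per_min
  if (mean_iei <= refractory_s) stop("rate too high for the refractory floor")
  tt <- numeric(0)
  t <- 0
  repeat {
    t <- t + refractory_s + stats::rexp(1, 1 / (mean_iei - refractory_s))
    if (t >= duration_s) break
    tt <- c(tt, t)
  }
  tt
}

#' Simulate an operant behavioral session
#'
#' Nose pokes follow a renewal process (exponential inter-poke intervals with
#' a 1-s refractory floor) at a per-session-type intensity. Under `SA`, every
#' active poke outside a 20-s cue timeout triggers an infusion plus a
#' tone/light cue and restarts the timeout; under extinction (`Ext1`,
#' `Ext10`) pokes have no consequence; under `Reinst` cued pokes trigger the
#' cue only. Default intensities make expected `Ext10` active poking well
#' below 40% of `Ext1`.
#'
#' @param session_type `"SA"`, `"Ext1"`, `"Ext10"` or `"Reinst"`.
#' @param duration_s Session length in seconds (default 7200; analyses use
#'   the first 3600).
#' @param active_rate_per_min Active-poke intensity; defaults by session type.
#' @param inactive_rate_per_min Inactive-poke intensity.
#' @param cue_timeout_s Cue timeout, seconds.
#' @param cue_duration_s Cue (tone + light) duration, seconds.
#' @param refractory_s Refractory floor of the poke renewal process.
#' @param seed Integer seed.
#' @return A [behavior_session()].
#' @export
gen_behavior <- function(session_type, duration_s = 7200,
                         active_rate_per_min = NULL,
                         inactive_rate_per_min = 0.2,
                         cue_timeout_s = 20, cue_duration_s = 5,
                         refractory_s = 1, seed = 1L) {
  session_type <- match.arg(session_type, c("SA", "Ext1", "Ext10", "Reinst"))
  stopifnot(duration_s > 0)
  if (is.null(active_rate_per_min)) {
    active_rate_per_min <- default_poke_rates()[[session_type]]
  }
  with_seed(seed, {
    act <- renewal_times(duration_s, active_rate_per_min, refractory_s)
    inact <- renewal_times(duration_s, inactive_rate_per_min, refractory_s)
    ev <- data.frame(time_s = c(act, inact),
                     event = c(rep("active_poke", length(act)),
                               rep("inactive_poke", length(inact))),
                     stringsAsFactors = FALSE)
    if (session_type %in% c("SA", "Reinst")) {
      last_cue <- -Inf
      for (t in act) {
        if (t - last_cue >= cue_timeout_s) {
          add <- data.frame(time_s = c(t, min(t + cue_duration_s, duration_s)),
                            event = c("cue_on", "cue_off"),
                            stringsAsFactors = FALSE)
          if (session_type == "SA") {
            add <- rbind(add, data.frame(time_s = t, event = "infusion",
                                         stringsAsFactors = FALSE))
          }
          ev <- rbind(ev, add)
          last_cue <- t
        }
      }
    }
    behavior_session(ev, session_type = session_type, duration_s = duration_s)
  })
}

#' Generate a spatial point pattern (CSR or clustered)
#'
#' `CSR` draws `n` points uniformly in `bounds` (the null model of the
#' clustering test). `clustered` draws a Thomas-type parent-offspring
#' process: `n_parents` uniform parents, each point assigned to a parent and
#' displaced by an isotropic Gaussian of SD `sigma`, resampled until inside
#' the bounds, with exactly `n` points returned. `sigma = 0` collapses the
#' offspring onto their parents.
#'
#' @param n Number of points (>= 12 so a 10-NN statistic is defined).
#' @param mode `"CSR"` or `"clustered"`.
#' @param cluster_params List with `n_parents` and `sigma` (pixels).
#' @param bounds `c(xmin, xmax, ymin, ymax)`.
#' @param seed Integer seed.
#' @return A [spatial_pattern()].
#' @export
gen_point_pattern <- function(n, mode = c("CSR", "clustered"),
                              cluster_params = list(n_parents = 5, sigma = 10),
                              bounds = c(0, 500, 0, 500), seed = 1L) {
  mode <- match.arg(mode)
  if (n < 12) stop("n must be >= 12 for a k = 10 nearest-neighbor analysis")
  with_seed(seed, {
    if (mode == "CSR") {
      pts <- cbind(stats::runif(n, bounds[1], bounds[2]),
                   stats::runif(n, bounds[3], bounds[4]))
    } else {
      np <- cluster_params$n_parents
      sg <- cluster_params$sigma
      stopifnot(np >= 1, sg >= 0)
      parents <- cbind(stats::runif(np, bounds[1], bounds[2]),
                       stats::runif(np, bounds[3], bounds[4]))
      assign_p <- sample.int(np, n, replace = TRUE)
      pts <- matrix(NA_real_, n, 2)
      for (i in seq_len(n)) {
        repeat {
          p <- parents[assign_p[i], ] + stats::rnorm(2, 0, sg)
          if (p[1] >= bounds[1] && p[1] <= bounds[2] &&
              p[2] >= bounds[3] && p[2] <= bounds[4]) break
        }
        pts[i, ] <- p
      }
    }
    spatial_pattern(pts, bounds = bounds, mode = mode)
  })
}

#' Generate Bernoulli D1/D2 upstream-input labels
#'
#' Emulates the rabies-tracing label tables: each labeled input neuron is
#' independently D1 with probability `p_d1`, else D2.
#'
#' @param n_inputs Number of labeled input cells.
#' @param p_d1 Probability that an input is a D1-MSN, in `[0, 1]`.
#' @param seed Integer seed.
#' @return Data frame with columns `input_id` and `label` ("D1"/"D2").
#' @export
gen_input_labels <- function(n_inputs, p_d1, seed = 1L) {
  stopifnot(n_inputs >= 1, p_d1 >= 0, p_d1 <= 1)
  with_seed(seed, {
    lab <- ifelse(stats::runif(n_inputs) < p_d1, "D1", "D2")
    data.frame(input_id = sprintf("in%05d", seq_len(n_inputs)),
               label = lab, stringsAsFactors = FALSE)
  })
}

#' Generate a multi-marker cell-label field
#'
#' Draws boolean marker labels (Vglut2, Vgat, Penk) for `n` cells with the
#' published marginal probabilities and Penk nested inside Vgat (Penk cells
#' also Vgat-positive with probability `p_penk_vgat`), Vglut2 essentially
#' Vgat-negative.
#'
#' @param n Number of cells.
#' @param p_glu,p_gaba,p_penk Marginal probabilities of the markers
#'   (defaults 0.23, 0.73, 0.16).
#' @param p_penk_vgat Probability that a Penk cell co-expresses Vgat
#'   (default 0.95, i.e. > 90% co-expression).
#' @param p_glu_vgat Probability that a Vglut2 cell co-expresses Vgat
#'   (default 0.03, i.e. < 5%).
#' @param seed Integer seed.
#' @return Data frame with logical columns `Vglut2`, `Vgat`, `Penk`.
#' @export
gen_marker_field <- function(n, p_glu = 0.23, p_gaba = 0.73, p_penk = 0.16,
                             p_penk_vgat = 0.95, p_glu_vgat = 0.03,
                             seed = 1L) {
  stopifnot(n >= 1)
  with_seed(seed, {
    penk <- stats::runif(n) < p_penk
    glu <- !penk & (stats::runif(n) < p_glu / (1 - p_penk))
    vgat <- logical(n)
    vgat[penk] <- stats::runif(sum(penk)) < p_penk_vgat
    vgat[glu] <- stats::runif(sum(glu)) < p_glu_vgat
    rest <- !penk & !glu
    # fill remaining cells so the Vgat marginal hits p_gaba in expectation
    p_rest <- (p_gaba - p_penk * p_penk_vgat - p_glu * p_glu_vgat) / mean(rest)
    p_rest <- min(max(p_rest, 0), 1)
    vgat[rest] <- stats::runif(sum(rest)) < p_rest
    data.frame(cell_id = sprintf("c%05d", seq_len(n)),
               Vglut2 = glu, Vgat = vgat, Penk = penk,
               stringsAsFactors = FALSE)
  })
}
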