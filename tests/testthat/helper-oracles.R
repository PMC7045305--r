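# Shared independent oracles for the test suite.

# Greedy matching of detected event times to ground-truth times.
match_event_times <- function(detected, truth, tol_s = 0.5) {
  used <- rep(FALSE, length(truth))
  tp <- 0L
  for (t in detected) {
    j <- which(!used & abs(truth - t) <= tol_s)
    if (length(j)) {
      used[j[1]] <- TRUE
      tp <- tp + 1L
    }
  }
  c(tp = tp, fp = length(detected) - tp, fn = sum(!used))
}

# Precision/recall of detect_events against generator ground truth.
detection_scores <- function(gen, et, tol_s = 0.5) {
  tot <- c(tp = 0L, fp = 0L, fn = 0L)
  for (ci in seq_along(gen$truth$event_times)) {
    id <- gen$traces$cell_ids[ci]
    det <- et$events$time_s[et$events$cell_id == id]
    tot <- tot + match_event_times(det, gen$truth$event_times[[ci]], tol_s)
  }
  c(precision = tot[["tp"]] / max(1, tot[["tp"]] + tot[["fp"]]),
    recall = tot[["tp"]] / max(1, tot[["tp"]] + tot[["fn"]]))
}

# O(n^2) brute-force mean k-NN distance via the full distance matrix.
brute_knn <- function(pts, k, value = "kth") {
  n <- nrow(pts)
  out <- numeric(n)
  for (i in seq_len(n)) {
    d <- sqrt((pts[, 1] - pts[i, 1])^2 + (pts[, 2] - pts[i, 2])^2)
    d <- sort(d[-i])
    out[i] <- if (value == "kth") d[k] else mean(d[seq_len(k)])
  }
  mean(out)
}

# Planted Gaussian footprint (same parameterization as the movie generator).
planted_footprint <- function(h, w, cx, cy, sigma = 2) {
  xs <- matrix(seq_len(w), h, w, byrow = TRUE)
  ys <- matrix(seq_len(h), h, w)
  exp(-((xs - cx)^2 + (ys - cy)^2) / (2 * sigma^2))
}

# Build a perievent_tensor directly from a cells x bins matrix of planted
# z traces (single trial), bypassing build_perievent.
make_tensor <- function(zmat, fs = 15, window_s = c(-10, 20),
                        cell_type = "Glu", session = "Ext1") {
  nb <- ncol(zmat)
  vals <- array(NA_real_, c(nrow(zmat), 1L, nb))
  vals[, 1, ] <- zmat
  structure(list(values = vals,
                 time_rel = window_s[1] + (seq_len(nb) - 1L) / fs,
                 trial_times = 100,
                 cell_ids = sprintf("cell%04d", seq_len(nrow(zmat))),
                 cell_type = rep(cell_type, nrow(zmat)),
                 session = session, fs = fs, window_s = window_s),
            class = "perievent_tensor")
}
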