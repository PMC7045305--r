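#' Movie preprocessing and cellular source extraction
#'
#' The preprocessing chain is fixed: spatial downsampling, then rigid-body
#' motion correction, then dF/F normalization, then PCA/ICA source
#' extraction. Running dF/F before the spatial steps is rejected as a
#' configuration error.
#'
#' @name vpcalcium-extract
#' @keywords internal
NULL

#' Spatially downsample a movie by block-mean pooling
#'
#' If the frame dimensions are not divisible by `factor`, the frame is
#' cropped to the largest divisible region (top-left anchored) with a
#' message.
#'
#' @param movie A [fluo_movie()], raw (pre-dF/F).
#' @param factor Integer pooling factor (default 4).
#' @return A [fluo_movie()] with dimensions `H/factor x W/factor`.
#' @export
downsample_spatial <- function(movie, factor = 4L) {
  stopifnot(inherits(movie, "fluo_movie"), factor >= 1)
  if (movie$dff) stop("config error: spatial downsampling must precede dF/F")
  factor <- as.integer(factor)
  if (factor == 1L) return(movie)
  d <- dim(movie$frames)
  hb <- d[2] %/% factor; wb <- d[3] %/% factor
  if (hb < 1 || wb < 1) stop("frame smaller than the downsampling factor")
  a <- movie$frames
  if (d[2] != hb * factor || d[3] != wb * factor) {
    message(sprintf("cropping %dx%d frames to %dx%d for factor-%d pooling",
                    d[2], d[3], hb * factor, wb * factor, factor))
    a <- a[, seq_len(hb * factor), seq_len(wb * factor), drop = FALSE]
  }
  dim(a) <- c(d[1], factor, hb, factor, wb)
  pooled <- colMeans(aperm(a, c(2, 4, 1, 3, 5)), dims = 2)
  fluo_movie(pooled, fs = movie$fs, dff = movie$dff)
}

# Shift a frame by (dx, dy) with bilinear interpolation; out-of-range pixels
# take the frame median.
shift_frame <- function(fr, dx, dy) {
  h <- nrow(fr); w <- ncol(fr)
  fill <- stats::median(fr)
  xs <- matrix(seq_len(w), h, w, byrow = TRUE) - dx
  ys <- matrix(seq_len(h), h, w) - dy
  x0 <- floor(xs); y0 <- floor(ys)
  fx <- xs - x0; fy <- ys - y0
  val <- function(yy, xx) {
    ok <- yy >= 1 & yy <= h & xx >= 1 & xx <= w
    out <- matrix(fill, h, w)
    out[ok] <- fr[cbind(yy[ok], xx[ok])]
    out
  }
  (1 - fy) * ((1 - fx) * val(y0, x0) + fx * val(y0, x0 + 1)) +
    fy * ((1 - fx) * val(y0 + 1, x0) + fx * val(y0 + 1, x0 + 1))
}

# Parabolic 1-D subpixel refinement around a discrete peak.
quad_interp <- function(cm, c0, cp) {
  den <- cm - 2 * c0 + cp
  if (den >= 0) return(0) # flat or inverted curvature: keep integer peak
  max(-0.5, min(0.5, 0.5 * (cm - cp) / den))
}

#' Rigid-body motion correction by cross-correlation
#'
#' Each frame's (dx, dy) translation relative to a reference image (default:
#' the temporal mean) is estimated from the peak of the FFT cross-correlogram
#' with parabolic subpixel refinement, then removed by bilinear resampling.
#' When no explicit reference is given, a second pass re-registers against
#' the mean of the corrected movie, which sharpens a drift-smeared reference.
#'
#' @param movie A [fluo_movie()], raw (pre-dF/F).
#' @param reference Reference image (H x W matrix); default temporal mean
#'   (with a refinement pass).
#' @param max_shift Maximum allowed shift magnitude per axis, pixels.
#' @param n_passes Registration passes when the reference is the temporal
#'   mean (default 2).
#' @return List with `movie` (corrected) and `shifts` (frames x 2 matrix of
#'   estimated (dx, dy); the correction applied is their negation).
#' @export
motion_correct_rigid <- function(movie, reference = NULL, max_shift = 10,
                                 n_passes = 2L) {
  stopifnot(inherits(movie, "fluo_movie"))
  if (movie$dff) stop("config error: motion correction must precede dF/F")
  a <- movie$frames
  d <- dim(a)
  if (all(a == 0)) {
    warning("all-zero movie: no structure to register, returning zero shifts")
    return(list(movie = movie,
                shifts = matrix(0, d[1], 2, dimnames = list(NULL, c("dx", "dy")))))
  }
  h <- d[2]; w <- d[3]
  max_shift <- min(max_shift, floor((min(h, w) - 1) / 2))
  lag_ok_y <- c(seq_len(max_shift + 1), h - seq_len(max_shift) + 1) # 0..+m, -m..-1
  lag_ok_x <- c(seq_len(max_shift + 1), w - seq_len(max_shift) + 1)
  estimate_pass <- function(frames, ref) {
    fr_ref <- stats::fft(ref - mean(ref))
    shifts <- matrix(0, d[1], 2, dimnames = list(NULL, c("dx", "dy")))
    for (t in seq_len(d[1])) {
      fr <- frames[t, , ]
      cc <- Re(stats::fft(stats::fft(fr - mean(fr)) * Conj(fr_ref),
                          inverse = TRUE))
      ccs <- cc[lag_ok_y, lag_ok_x, drop = FALSE]
      pk <- arrayInd(which.max(ccs), dim(ccs))
      iy <- lag_ok_y[pk[1]]; ix <- lag_ok_x[pk[2]]
      dy <- if (iy <= max_shift + 1) iy - 1 else iy - 1 - h
      dx <- if (ix <= max_shift + 1) ix - 1 else ix - 1 - w
      wrap <- function(i, n) ((i - 1) %% n) + 1
      ddy <- quad_interp(cc[wrap(iy - 1, h), ix], cc[iy, ix],
                         cc[wrap(iy + 1, h), ix])
      ddx <- quad_interp(cc[iy, wrap(ix - 1, w)], cc[iy, ix],
                         cc[iy, wrap(ix + 1, w)])
      shifts[t, ] <- c(dx + ddx, dy + ddy)
    }
    shifts
  }
  apply_shifts <- function(frames, shifts) {
    out <- array(0, d)
    for (t in seq_len(d[1])) {
      out[t, , ] <- shift_frame(frames[t, , ], -shifts[t, 1], -shifts[t, 2])
    }
    out
  }
  if (!is.null(reference)) n_passes <- 1L
  total <- matrix(0, d[1], 2, dimnames = list(NULL, c("dx", "dy")))
  cur <- a
  for (pass in seq_len(max(1L, n_passes))) {
    ref <- if (is.null(reference)) colMeans(cur, dims = 1) else reference
    s <- estimate_pass(cur, ref)
    total <- total + s
    cur <- apply_shifts(a, total) # always resample from the original frames
  }
  list(movie = fluo_movie(cur, fs = movie$fs, dff = FALSE), shifts = total)
}

running_percentile <- function(x, fs, window_s, p, stride = NULL) {
  n <- length(x)
  half <- max(1L, as.integer(round(window_s * fs / 2)))
  if (is.null(stride)) stride <- max(1L, as.integer(round(fs)))
  centers <- unique(c(seq(1L, n, by = stride), n))
  q <- vapply(centers, function(i) {
    stats::quantile(x[max(1, i - half):min(n, i + half)], p, names = FALSE)
  }, numeric(1))
  if (length(centers) == 1L) return(rep(q, n))
  stats::approx(centers, q, xout = seq_len(n), rule = 2)$y
}

#' dF/F normalization
#'
#' Computes `(F - F0) / F0`. The default baseline `F0` is a running 20th
#' percentile over a 30-s window (evaluated on a 1-s grid and linearly
#' interpolated); `"global_mean"` uses the temporal mean instead. For movies
#' the baseline is computed per pixel; for trace sets per cell.
#'
#' @param x A [fluo_movie()] or [trace_set()] of raw fluorescence.
#' @param baseline_method `"running_percentile"` or `"global_mean"`.
#' @param window_s Window for the running percentile, seconds.
#' @param percentile Baseline percentile in `[0, 1]`.
#' @return Same class as the input, dF/F normalized.
#' @export
compute_dff <- function(x, baseline_method = c("running_percentile", "global_mean"),
                        window_s = 30, percentile = 0.2) {
  baseline_method <- match.arg(baseline_method)
  dff_vec <- function(v, fs, label) {
    f0 <- if (baseline_method == "global_mean") rep(mean(v), length(v))
          else running_percentile(v, fs, window_s, percentile)
    if (any(f0 <= 0)) {
      stop(sprintf("non-positive baseline F0 at %s (first sample %d)", label,
                   which(f0 <= 0)[1]))
    }
    (v - f0) / f0
  }
  if (inherits(x, "trace_set")) {
    tr <- x$traces
    for (i in seq_len(nrow(tr))) {
      tr[i, ] <- dff_vec(tr[i, ], x$fs, sprintf("cell %s", x$cell_ids[i]))
    }
    out <- x
    out$traces <- tr
    return(out)
  }
  if (inherits(x, "fluo_movie")) {
    if (x$dff) stop("movie is already dF/F normalized")
    a <- x$frames
    d <- dim(a)
    for (i in seq_len(d[2])) for (j in seq_len(d[3])) {
      a[, i, j] <- dff_vec(a[, i, j], x$fs, sprintf("pixel (%d,%d)", i, j))
    }
    return(fluo_movie(a, fs = x$fs, dff = TRUE))
  }
  stop("compute_dff expects a trace_set or fluo_movie")
}

row_skewness <- function(v) {
  v <- v - mean(v)
  s <- sqrt(mean(v^2))
  if (s == 0) return(0)
  mean(v^3) / s^3
}

# Symmetric FastICA (logcosh nonlinearity) on a k x m data matrix.
# Returns the k x k unmixing matrix applied after whitening has been folded
# in, i.e. sources = W %*% sweep(D, 1, rowMeans(D)).
fastica_sym <- function(D, seed = 1L, max_iter = 200L, tol = 1e-6) {
  k <- nrow(D)
  D <- D - rowMeans(D)
  C <- tcrossprod(D) / ncol(D)
  eg <- eigen(C, symmetric = TRUE)
  vals <- pmax(eg$values, max(eg$values) * 1e-12)
  K <- diag(1 / sqrt(vals), k) %*% t(eg$vectors)
  Z <- K %*% D
  decorrelate <- function(W) {
    sw <- eigen(tcrossprod(W), symmetric = TRUE)
    sw$vectors %*% diag(1 / sqrt(pmax(sw$values, 1e-15)), k) %*%
      t(sw$vectors) %*% W
  }
  W <- with_seed(seed, matrix(stats::rnorm(k * k), k, k))
  W <- decorrelate(W)
  for (it in seq_len(max_iter)) {
    WZ <- W %*% Z
    G <- tanh(WZ)
    W1 <- G %*% t(Z) / ncol(Z) - diag(rowMeans(1 - G^2), k) %*% W
    W1 <- decorrelate(W1)
    delta <- max(abs(abs(diag(W1 %*% t(W))) - 1))
    W <- W1
    if (delta < tol) break
  }
  W %*% K
}

#' PCA/ICA cellular source extraction
#'
#' Dimensionality reduction to `n_components` principal components followed
#' by spatio-temporal independent component analysis: ICA runs on the
#' concatenation of the temporal and spatial principal components weighted by
#' `ica_weight` (0 = purely temporal, 1 = purely spatial ICA). The resulting
#' rotation is applied to both domains; component signs are fixed so each
#' temporal trace has non-negative skewness (calcium transients are
#' positive-going), spatial maps are rectified, and intensity-weighted
#' centroids computed.
#'
#' @param movie A dF/F-normalized [fluo_movie()].
#' @param n_components Number of components to extract (over-extraction with
#'   subsequent QC is the intended usage).
#' @param ica_weight Spatial weight mu in `[0, 1]` (default 0.1).
#' @param seed Seed for the ICA initialization.
#' @return List with `footprints` (class `cell_footprints`: `maps` array
#'   `n x H x W`, `centroids` n x 2) and `traces` (a [trace_set()]).
#' @export
extract_sources <- function(movie, n_components, ica_weight = 0.1, seed = 1L) {
  stopifnot(inherits(movie, "fluo_movie"), n_components >= 1,
            ica_weight >= 0, ica_weight <= 1)
  d <- dim(movie$frames)
  n_t <- d[1]; h <- d[2]; w <- d[3]
  X <- matrix(movie$frames, n_t, h * w) # column p = pixel (col-major over h,w)
  X <- sweep(X, 2, colMeans(X))
  tot_var <- sum(X^2)
  if (tot_var < 1e-12) stop("movie has (near-)zero variance; nothing to extract")
  k <- as.integer(n_components)
  if (k > min(n_t, h * w) - 1L) stop("n_components exceeds the data rank")
  if (h * w <= n_t) {
    eg <- eigen(crossprod(X), symmetric = TRUE)
    keep <- which(eg$values > max(eg$values) * 1e-10)
    k <- min(k, length(keep))
    V <- eg$vectors[, seq_len(k), drop = FALSE]
    dvals <- sqrt(eg$values[seq_len(k)])
    U <- X %*% V %*% diag(1 / dvals, k)
  } else {
    eg <- eigen(tcrossprod(X), symmetric = TRUE)
    keep <- which(eg$values > max(eg$values) * 1e-10)
    k <- min(k, length(keep))
    U <- eg$vectors[, seq_len(k), drop = FALSE]
    dvals <- sqrt(eg$values[seq_len(k)])
    V <- crossprod(X, U) %*% diag(1 / dvals, k)
  }
  mu <- ica_weight
  D <- t(rbind((1 - mu) * sqrt(n_t) * U, mu * sqrt(h * w) * V)) # k x (T+P)
  Wt <- if (k == 1L) matrix(1, 1, 1) else fastica_sym(D, seed = seed)
  traces_mat <- U %*% diag(dvals, k) %*% t(Wt) # T x k
  maps_mat <- V %*% t(Wt)                      # P x k
  for (i in seq_len(k)) {
    if (row_skewness(traces_mat[, i]) < 0) {
      traces_mat[, i] <- -traces_mat[, i]
      maps_mat[, i] <- -maps_mat[, i]
    }
  }
  maps <- array(0, c(k, h, w))
  centroids <- matrix(NA_real_, k, 2, dimnames = list(NULL, c("x", "y")))
  xs <- matrix(seq_len(w), h, w, byrow = TRUE)
  ys <- matrix(seq_len(h), h, w)
  for (i in seq_len(k)) {
    m <- matrix(pmax(maps_mat[, i], 0), h, w)
    if (max(m) > 0) m <- m / max(m)
    maps[i, , ] <- m
    wgt <- m^2
    sw <- sum(wgt)
    if (sw > 0) centroids[i, ] <- c(sum(xs * wgt), sum(ys * wgt)) / sw
  }
  fps <- structure(list(maps = maps, centroids = centroids),
                   class = "cell_footprints")
  list(footprints = fps,
       traces = trace_set(t(traces_mat), fs = movie$fs,
                          cell_ids = sprintf("ic%03d", seq_len(k))))
}

#' @export
print.cell_footprints <- function(x, ...) {
  d <- dim(x$maps)
  cat(sprintf("<cell_footprints> %d components on %dx%d px\n", d[1], d[2], d[3]))
  invisible(x)
}

#' Automated component quality control
#'
#' Keeps components whose footprint is compact (fraction of footprint energy
#' — squared map values, which discounts the diffuse noise floor — within
#' `radius_px` of the centroid above `min_compactness`), whose
#' temporal trace is positively skewed (transient-like), and whose footprint
#' area (pixels above half max) lies within `[min_area_px, max_area_px]`.
#' This is an automated surrogate for per-cell visual inspection.
#'
#' @param footprints A `cell_footprints` object from [extract_sources()].
#' @param traces Matching [trace_set()].
#' @param criteria List of thresholds: `min_skew`, `min_area_px`,
#'   `max_area_px`, `min_compactness`, `radius_px`.
#' @return List with accepted `footprints` and `traces`, plus a `rejections`
#'   data frame (component index and reason).
#' @export
qc_components <- function(footprints, traces,
                          criteria = list(min_skew = 0.2, min_area_px = 3,
                                          max_area_px = 300,
                                          min_compactness = 0.5,
                                          radius_px = 6)) {
  n <- dim(footprints$maps)[1]
  if (n == 0L) {
    return(list(footprints = footprints, traces = traces,
                rejections = data.frame(component = integer(0),
                                        reason = character(0))))
  }
  h <- dim(footprints$maps)[2]; w <- dim(footprints$maps)[3]
  xs <- matrix(seq_len(w), h, w, byrow = TRUE)
  ys <- matrix(seq_len(h), h, w)
  keep <- logical(n)
  reasons <- character(n)
  for (i in seq_len(n)) {
    m <- footprints$maps[i, , ]
    area <- sum(m >= 0.5 * max(m))
    skew <- row_skewness(traces$traces[i, ])
    ctr <- footprints$centroids[i, ]
    within <- (xs - ctr[1])^2 + (ys - ctr[2])^2 <= criteria$radius_px^2
    compact <- if (sum(m^2) > 0) sum(m[within]^2) / sum(m^2) else 0
    if (skew < criteria$min_skew) {
      reasons[i] <- sprintf("trace skewness %.2f < %.2f", skew, criteria$min_skew)
    } else if (area < criteria$min_area_px) {
      reasons[i] <- sprintf("footprint area %d px < %d", area, criteria$min_area_px)
    } else if (area > criteria$max_area_px) {
      reasons[i] <- sprintf("footprint area %d px > %d (diffuse)", area,
                            criteria$max_area_px)
    } else if (compact < criteria$min_compactness) {
      reasons[i] <- sprintf("compactness %.2f < %.2f", compact,
                            criteria$min_compactness)
    } else {
      keep[i] <- TRUE
    }
  }
  fps <- structure(list(maps = footprints$maps[keep, , , drop = FALSE],
                        centroids = footprints$centroids[keep, , drop = FALSE]),
                   class = "cell_footprints")
  tr <- trace_set(traces$traces[keep, , drop = FALSE], fs = traces$fs,
                  cell_ids = traces$cell_ids[keep],
                  cell_type = traces$cell_type[keep], session = traces$session)
  list(footprints = fps, traces = tr,
       rejections = data.frame(component = which(!keep),
                               reason = reasons[!keep],
                               stringsAsFactors = FALSE))
}

#' Run the fixed preprocessing chain on a raw movie
#'
#' Downsample, motion-correct, dF/F-normalize and extract sources in the
#' fixed order; each stage refuses inputs that are already normalized, so the
#' order cannot be permuted.
#'
#' @param movie Raw [fluo_movie()].
#' @param config A [pipeline_config()].
#' @param n_components Components for [extract_sources()]; default 1.5 x
#'   `expected_cells`.
#' @param expected_cells Expected cell count used to size over-extraction.
#' @param baseline_method Passed to [compute_dff()].
#' @return List with `movie` (dF/F), `shifts`, `footprints`, `traces`.
#' @export
preprocess_movie <- function(movie, config = pipeline_config(),
                             expected_cells = 10,
                             n_components = ceiling(1.5 * expected_cells),
                             baseline_method = "global_mean") {
  ds <- downsample_spatial(movie, config$spatial_downsample)
  mc <- motion_correct_rigid(ds)
  dff <- compute_dff(mc$movie, baseline_method = baseline_method)
  src <- extract_sources(dff, n_components = n_components,
                         seed = split_seed(config$rng_seed, "extract"))
  qc <- qc_components(src$footprints, src$traces)
  list(movie = dff, shifts = mc$shifts, footprints = qc$footprints,
       traces = qc$traces, rejections = qc$rejections)
}
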