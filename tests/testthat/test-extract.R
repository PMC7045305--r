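test_that("spatial downsampling is exact block-mean pooling", {
  mv <- fluo_movie(array(2.5, c(3, 4, 4)), fs = 15)
  expect_identical(downsample_spatial(mv, 1)$frames, mv$frames)
  d4 <- downsample_spatial(mv, 4)
  expect_equal(dim(d4$frames), c(3, 1, 1))
  expect_equal(as.numeric(d4$frames), rep(2.5, 3))
  # explicit block-mean oracle on a random 8x8 frame
  set.seed(1)
  fr <- matrix(rnorm(64), 8, 8)
  a <- array(0, c(1, 8, 8)); a[1, , ] <- fr
  d2 <- downsample_spatial(fluo_movie(a, 15), 2)
  for (i in 1:4) for (j in 1:4) {
    expect_equal(d2$frames[1, i, j],
                 mean(fr[(2 * i - 1):(2 * i), (2 * j - 1):(2 * j)]))
  }
  # non-divisible frames crop to the largest divisible region
  a9 <- array(rnorm(81), c(1, 9, 9))
  expect_message(d3 <- downsample_spatial(fluo_movie(a9, 15), 4), "cropping")
  expect_equal(dim(d3$frames), c(1, 2, 2))
})

test_that("motion correction recovers planted rigid drift within 0.5 px", {
  set.seed(2)
  ctr <- cbind(x = c(8, 20, 32), y = c(10, 30, 18))
  g <- gen_traces(3, 40, 4, snr = 20, seed = 21)
  mv <- gen_movie(ctr, g$traces, frame_dims = c(40, 40), noise_sd = 0.005,
                  drift_px = 3, seed = 22)
  mc <- motion_correct_rigid(mv)
  err <- mc$shifts - attr(mv, "shifts")
  expect_lt(max(abs(err)), 0.5)
  # already-aligned movie: shifts within 0.25 px of zero
  mv0 <- gen_movie(ctr, g$traces, frame_dims = c(40, 40), noise_sd = 0.005,
                   drift_px = 0, seed = 23)
  mc0 <- motion_correct_rigid(mv0)
  expect_lt(max(abs(mc0$shifts)), 0.25)
})

test_that("motion correction is robust to structureless input", {
  noise <- fluo_movie(array(rnorm(20 * 16 * 16), c(20, 16, 16)), 15)
  mc <- motion_correct_rigid(noise, max_shift = 5)
  expect_true(all(abs(mc$shifts) <= 5 + 0.5))
  zero <- fluo_movie(array(0, c(4, 8, 8)), 15)
  expect_warning(mz <- motion_correct_rigid(zero), "all-zero")
  expect_true(all(mz$shifts == 0))
})

test_that("dF/F normalization has the expected closed forms", {
  ts <- trace_set(matrix(5, 2, 50), fs = 15)
  d <- compute_dff(ts, baseline_method = "global_mean")
  expect_true(all(abs(d$traces) < 1e-12))
  # brief doubling over a steady baseline: running-percentile dF/F ~ 1
  v <- rep(2, 600)
  v[300:315] <- 4
  d2 <- compute_dff(trace_set(matrix(v, 1), fs = 15))
  expect_equal(max(d2$traces), 1, tolerance = 0.02)
  expect_lt(abs(median(d2$traces)), 0.02)
  # non-positive baseline is an error naming the offender
  expect_error(compute_dff(trace_set(matrix(0, 1, 50), fs = 15),
                           baseline_method = "global_mean"), "cell")
})

test_that("dF/F recovers planted transient amplitudes from raw fluorescence", {
  g <- gen_traces(4, 120, 2, snr = 50, seed = 31)
  f0 <- 3
  raw <- trace_set(f0 * (1 + g$traces$traces), fs = 15)
  d <- compute_dff(raw)
  for (ci in 1:4) {
    tt <- g$truth$event_times[[ci]]
    if (!length(tt)) next
    peaks_in <- max(g$traces$traces[ci, ])
    peaks_out <- max(d$traces[ci, ])
    expect_equal(peaks_out, peaks_in, tolerance = 0.1 * peaks_in)
  }
})

test_that("PCA/ICA recovers a single planted cell's centroid within 2 px", {
  g <- gen_traces(1, 40, 6, snr = 20, seed = 41)
  mv <- gen_movie(cbind(12.3, 17.8), g$traces, frame_dims = c(30, 30),
                  noise_sd = 0.005, seed = 42)
  dff <- compute_dff(mv, baseline_method = "global_mean")
  src <- extract_sources(dff, n_components = 1, seed = 43)
  expect_lt(sqrt(sum((src$footprints$centroids[1, ] - c(12.3, 17.8))^2)), 2)
  expect_gte(min(src$footprints$maps), 0)
})

test_that("a zero-variance movie cannot be decomposed", {
  flat <- fluo_movie(array(1, c(10, 8, 8)), 15, dff = TRUE)
  expect_error(extract_sources(flat, 2), "variance")
})

test_that("end-to-end source extraction recovers planted populations", {
  set.seed(1)
  ctr <- cbind(x = rep(c(8, 16, 24, 32, 36), 2),
               y = rep(c(10, 30), each = 5)) + runif(20, -1, 1)
  g <- gen_traces(10, 800 / 15, 6, snr = 20, seed = 21)
  mv <- gen_movie(ctr, g$traces, frame_dims = c(40, 40), noise_sd = 0.005,
                  seed = 22)
  dff <- compute_dff(mv, baseline_method = "global_mean")
  src <- extract_sources(dff, n_components = 15, seed = 23)
  qc <- qc_components(src$footprints, src$traces)
  hits <- 0L
  trace_cors <- c()
  for (i in 1:10) {
    fp_true <- planted_footprint(40, 40, ctr[i, 1], ctr[i, 2])
    sc <- vapply(seq_len(dim(qc$footprints$maps)[1]), function(j) {
      cor(as.vector(fp_true), as.vector(qc$footprints$maps[j, , ]))
    }, numeric(1))
    j <- which.max(sc)
    if (sc[j] > 0.8) {
      hits <- hits + 1L
      trace_cors <- c(trace_cors, cor(qc$traces$traces[j, ], g$traces$traces[i, ]))
    }
  }
  expect_gte(hits, 9L)            # >= 90% of planted cells recovered
  expect_gt(min(trace_cors), 0.7) # with faithful temporal traces
})

test_that("component QC rejects diffuse and non-transient components", {
  # planted compact cell passes
  g <- gen_traces(1, 40, 6, snr = 20, seed = 51)
  mv <- gen_movie(cbind(10, 10), g$traces, frame_dims = c(20, 20),
                  noise_sd = 0.005, seed = 52)
  src <- extract_sources(compute_dff(mv, baseline_method = "global_mean"),
                         n_components = 1, seed = 53)
  qc <- qc_components(src$footprints, src$traces)
  expect_identical(dim(qc$footprints$maps)[1], 1L)
  expect_identical(nrow(qc$rejections), 0L)
  # spatially diffuse component with symmetric trace is rejected
  maps <- array(1, c(1, 30, 30)) # covers the full frame
  fps <- structure(list(maps = maps, centroids = cbind(x = 15, y = 15)),
                   class = "cell_footprints")
  tr <- trace_set(matrix(sin(seq(0, 20, length.out = 200)), 1), fs = 15)
  qc2 <- qc_components(fps, tr)
  expect_identical(dim(qc2$footprints$maps)[1], 0L)
  expect_identical(nrow(qc2$rejections), 1L)
  # empty input passes through
  fps0 <- structure(list(maps = array(0, c(0, 5, 5)),
                         centroids = matrix(0, 0, 2)),
                    class = "cell_footprints")
  tr0 <- trace_set(matrix(0, 0, 10), fs = 15)
  qc3 <- qc_components(fps0, tr0)
  expect_identical(dim(qc3$footprints$maps)[1], 0L)
})

test_that("the preprocessing order cannot be permuted", {
  dffmv <- fluo_movie(array(rnorm(40), c(10, 2, 2)), 15, dff = TRUE)
  expect_error(downsample_spatial(dffmv, 2), "config error")
  expect_error(motion_correct_rigid(dffmv), "config error")
  expect_error(compute_dff(dffmv), "already dF/F")
})
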