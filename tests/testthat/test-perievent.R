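ext_session <- function(poke_times, duration_s = 7200, type = "Ext1") {
  behavior_session(data.frame(time_s = poke_times,
                              event = "active_poke"), type, duration_s)
}

test_that("trial selection applies the 20-s separation rule in extinction", {
  s <- ext_session(c(0, 10, 40))
  expect_equal(select_trials(s), 40)
  # a lone poke has no neighbor to violate separation
  expect_equal(select_trials(ext_session(123)), 123)
  # trials beyond the first 60 min are excluded
  expect_equal(select_trials(ext_session(c(40, 3700))), 40)
  expect_warning(out <- select_trials(ext_session(c(0, 10))), "no trials")
  expect_length(out, 0)
})

test_that("trial selection keeps only cued pokes under reinstatement", {
  s <- behavior_session(data.frame(time_s = c(100, 105),
                                   event = "active_poke"), "Reinst", 3600)
  expect_equal(select_trials(s), 100) # 105 falls inside the 20-s timeout
  s2 <- behavior_session(data.frame(time_s = c(100, 105, 125),
                                    event = "active_poke"), "Reinst", 3600)
  expect_equal(select_trials(s2), c(100, 125))
})

test_that("trial selection is invariant to input row order", {
  set.seed(3)
  tt <- sort(runif(40, 0, 3000))
  df <- data.frame(time_s = tt, event = "active_poke")
  perm <- df[sample(nrow(df)), ]
  expect_identical(select_trials(behavior_session(df, "Ext1", 3600)),
                   select_trials(behavior_session(perm, "Ext1", 3600)))
  expect_identical(select_trials(behavior_session(df, "Reinst", 3600)),
                   select_trials(behavior_session(perm, "Reinst", 3600)))
})

test_that("every peri-event window is z-scored to mean 0 and SD 1", {
  g <- gen_traces(5, 400, 2, snr = 8, seed = 5)
  pet <- build_perievent(g$traces, c(60, 150, 290))
  for (ci in 1:5) for (tj in 1:3) {
    seg <- pet$values[ci, tj, ]
    expect_lt(abs(mean(seg)), 1e-9)
    expect_lt(abs(sd(seg) - 1), 1e-9)
  }
  expect_identical(dim(pet$values)[3], as.integer(30 * 15))
})

test_that("degenerate windows and out-of-recording trials are dropped", {
  flat <- trace_set(matrix(1, 1, 1200), fs = 15)
  expect_warning(pet <- build_perievent(flat, 40), "zero variance")
  expect_true(all(is.na(pet$values)))
  g <- gen_traces(2, 100, 2, snr = 8, seed = 6)
  expect_warning(pet2 <- build_perievent(g$traces, c(5, 50, 95)),
                 "dropped")
  expect_identical(length(pet2$trial_times), 1L)
  expect_error(suppressWarnings(build_perievent(g$traces, 3)), "no trials")
})

test_that("a transient planted after each poke peaks at the right latency", {
  k <- kernel_params()
  fs <- 15
  tgrid <- (0:(500 * fs - 1)) / fs
  trials <- c(60, 160, 260, 360, 460)
  set.seed(7)
  v <- rnorm(length(tgrid), 0, 0.02)
  for (tt in trials) v <- v + 0.4 * vpcalcium:::eval_kernel(tgrid - (tt + 0.5), k)
  pet <- build_perievent(trace_set(matrix(v, 1), fs), trials)
  avg <- colMeans(pet$values[1, , , drop = TRUE])
  peak_t <- pet$time_rel[which.max(avg)]
  expect_gt(peak_t, 0.3)  # onset +0.5 s plus rise
  expect_lt(peak_t, 1.5)
})

test_that("population magnitude treats increases and decreases alike", {
  nb <- 450
  tr <- seq(-10, 20 - 1 / 15, by = 1 / 15)
  up <- numeric(nb); up[tr > 0 & tr <= 2] <- 1
  dn <- -up
  pet <- make_tensor(rbind(up, dn))
  pr <- population_response(pet)
  expect_equal(pr$per_cell$post_mean[1], pr$per_cell$post_mean[2],
               tolerance = 1e-9)
  # flat z trace: pre and post magnitudes are zero
  pet0 <- make_tensor(matrix(0, 1, nb))
  pr0 <- population_response(pet0)
  expect_equal(pr0$per_cell$pre_mean, 0)
  expect_equal(pr0$per_cell$post_mean, 0)
  # planted +1 z step on (0, 2]: post - pre = 1 up to bin effects
  step <- matrix(0, 1, nb); step[1, tr > 0 & tr <= 2] <- 1
  prs <- population_response(make_tensor(step))
  expect_equal(prs$per_cell$post_mean - prs$per_cell$pre_mean, 1,
               tolerance = 0.01)
})

test_that("responder classification implements the 2-SD baseline rule", {
  nb <- 450
  tr <- seq(-10, 20 - 1 / 15, by = 1 / 15)
  set.seed(8)
  base_noise <- rnorm(nb, 0, 0.2)
  up <- base_noise
  up[tr > 0 & tr <= 2] <- up[tr > 0 & tr <= 2] + 5 * sd(base_noise[tr > -2 & tr <= 0])
  flat <- rnorm(nb, 0, 0.2)
  const <- rep(0, nb) # zero baseline SD
  cl <- classify_cells(make_tensor(rbind(up, flat, const)))
  expect_identical(cl$per_cell$class[1], "increased")
  expect_identical(cl$per_cell$class[3], "unchanged")
  expect_true(cl$per_cell$flagged[3])
  # fractions partition each group
  frac_sum <- tapply(cl$fractions$fraction, cl$fractions$cell_type, sum)
  expect_true(all(abs(frac_sum - 1) < 1e-12))
})

test_that("classification agrees with a brute-force restatement of the rule", {
  g <- gen_traces(120, 400, 0, snr = 8, seed = 9) # null cells: noise only
  trials <- c(60, 150, 240, 330)
  pet <- build_perievent(g$traces, trials)
  cl <- classify_cells(pet)
  # independent oracle: loop over cells, re-deriving the rule from scratch
  oracle <- character(120)
  for (ci in 1:120) {
    m <- colMeans(pet$values[ci, , , drop = TRUE])
    pre <- m[pet$time_rel > -2 + 1e-9 & pet$time_rel <= 0 + 1e-9]
    post <- m[pet$time_rel > 0 + 1e-9 & pet$time_rel <= 2 + 1e-9]
    oracle[ci] <- if (mean(post) > mean(pre) + 2 * sd(pre)) "increased"
      else if (mean(post) < mean(pre) - 2 * sd(pre)) "decreased"
      else "unchanged"
  }
  expect_identical(cl$per_cell$class, oracle)
  # smoothing correlates bins, so the null rate exceeds the nominal 4.6%;
  # it must still be a minority of cells
  null_rate <- mean(cl$per_cell$class != "unchanged")
  expect_lt(null_rate, 0.5)
})

test_that("classification is invariant to affine rescaling of the traces", {
  g <- gen_traces(30, 400, 2, snr = 8, seed = 10)
  trials <- c(60, 150, 240, 330)
  cl1 <- classify_cells(build_perievent(g$traces, trials))
  resc <- trace_set(3.7 * g$traces$traces + 11, fs = 15)
  cl2 <- classify_cells(build_perievent(resc, trials))
  expect_identical(cl1$per_cell$class, cl2$per_cell$class)
})

test_that("planted responder fractions are recovered", {
  k <- kernel_params()
  fs <- 15
  n_cells <- 150
  f <- 0.3
  trials <- c(60, 150, 240, 330)
  tgrid <- (0:(400 * fs - 1)) / fs
  set.seed(11)
  responder <- seq_len(n_cells) <= f * n_cells
  tr <- matrix(rnorm(n_cells * length(tgrid), 0, 0.03), n_cells)
  for (ci in which(responder)) {
    for (tt in trials) {
      tr[ci, ] <- tr[ci, ] + 0.4 * vpcalcium:::eval_kernel(tgrid - (tt + 0.3), k)
    }
  }
  cl <- classify_cells(build_perievent(trace_set(tr, fs), trials))
  null_rate <- mean(cl$per_cell$class[!responder] == "increased")
  got <- mean(cl$per_cell$class == "increased")
  expected <- f + (1 - f) * null_rate
  expect_lt(abs(got - expected),
            1.96 * sqrt(expected * (1 - expected) / n_cells) + 0.02)
  expect_gt(mean(cl$per_cell$class[responder] == "increased"), 0.9)
})

test_that("heatmap ordering sorts by class then magnitude, permutation-stably", {
  pc <- data.frame(cell_id = c("c1", "c2", "c3", "c4"),
                   cell_type = "Glu",
                   class = c("decreased", "increased", "unchanged", "increased"),
                   pre_mean = c(0, 0, 0, 0),
                   post_mean = c(-2, 1, 0.1, 3),
                   stringsAsFactors = FALSE)
  cl <- structure(list(per_cell = pc), class = "responder_classes")
  expect_identical(order_heatmap(cl), c("c4", "c2", "c3", "c1"))
  perm <- cl
  perm$per_cell <- pc[c(3, 1, 4, 2), ]
  expect_identical(order_heatmap(perm), order_heatmap(cl))
  # all unchanged: magnitude only
  pc2 <- pc; pc2$class <- "unchanged"
  expect_identical(order_heatmap(structure(list(per_cell = pc2),
                                           class = "responder_classes")),
                   c("c4", "c1", "c2", "c3"))
})
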