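test_that("paired t test matches hand computations and df contracts", {
  x <- c(3, 1, 4, 1, 5)
  r <- paired_t(x, x)
  expect_equal(r$statistic, 0)
  expect_equal(r$p, 1)
  # differences (1, 2, 3): t = mean/se = 2 / (1/sqrt(3)) = 2*sqrt(3)
  y <- c(10, 12, 9)
  r2 <- paired_t(y + c(1, 2, 3), y)
  expect_equal(r2$statistic, 2 * sqrt(3), tolerance = 1e-12)
  expect_equal(r2$df, 2)
  r3 <- paired_t(rnorm(7), rnorm(7))
  expect_equal(r3$df, 6) # seven pairs report t[6]
})

test_that("one-sample t test matches hand computations", {
  r <- one_sample_t(c(-1, 0, 1), mu = 0)
  expect_equal(r$statistic, 0)
  r2 <- one_sample_t(c(1, 2, 3), mu = 0)
  expect_equal(r2$statistic, 2 * sqrt(3), tolerance = 1e-12)
  expect_equal(r2$df, 2)
  expect_equal(one_sample_t(rnorm(1000), 0)$df, 999)
})

test_that("one-way RM ANOVA agrees with aov and handles trivial designs", {
  # identical conditions per subject: F = 0
  d0 <- data.frame(subject = rep(1:5, each = 3), within = rep(letters[1:3], 5),
                   value = rep(rnorm(5), each = 3))
  expect_equal(rm_anova(d0)$effects$F, 0, tolerance = 1e-20)
  # 2-level design: epsilon = 1 and F equals the squared paired t
  set.seed(1)
  d2 <- data.frame(subject = rep(1:8, each = 2), within = rep(c("a", "b"), 8),
                   value = rnorm(16))
  r2 <- rm_anova(d2)
  expect_equal(r2$effects$epsilon, 1)
  tt <- paired_t(d2$value[d2$within == "a"], d2$value[d2$within == "b"])
  expect_equal(r2$effects$F, tt$statistic^2, tolerance = 1e-10)
  expect_equal(r2$effects$p, tt$p, tolerance = 1e-10)
  # 5 subjects x 3 levels: F matches aov, epsilon matches the eigenvalue form
  set.seed(2)
  d3 <- data.frame(subject = factor(rep(1:5, each = 3)),
                   within = factor(rep(letters[1:3], 5)),
                   value = rnorm(15) + rep(c(0, 0.5, 1), 5))
  r3 <- rm_anova(d3)
  fit <- summary(stats::aov(value ~ within + Error(subject / within), data = d3))
  f_aov <- fit[["Error: subject:within"]][[1]]["within", "F value"]
  expect_equal(r3$effects$F, f_aov, tolerance = 1e-10)
  Y <- matrix(d3$value, 5, 3, byrow = TRUE)
  S <- stats::cov(Y)
  k <- 3
  Cmat <- diag(k) - matrix(1 / k, k, k)
  lam <- eigen(Cmat %*% S %*% Cmat, symmetric = TRUE)$values[1:(k - 1)]
  expect_equal(r3$effects$epsilon, sum(lam)^2 / ((k - 1) * sum(lam^2)),
               tolerance = 1e-10)
  expect_equal(r3$effects$df1_corrected, r3$effects$epsilon * 2)
  # incomplete designs are refused
  expect_error(rm_anova(d3[-1, ]), "unbalanced|incomplete")
})

test_that("mixed two-way RM ANOVA matches aov on a balanced design", {
  set.seed(3)
  n_per <- 6
  d <- expand.grid(subject = 1:(2 * n_per), within = c("Ext1", "Ext10", "Reinst"))
  d$between <- ifelse(d$subject <= n_per, "Glu", "GABA")
  d$value <- rnorm(nrow(d)) + ifelse(d$between == "Glu", 0.8, 0) +
    ifelse(d$within == "Reinst", 0.5, 0)
  r <- rm_anova(d)
  d$subject <- factor(d$subject); d$within <- factor(d$within)
  d$between <- factor(d$between)
  fit <- summary(stats::aov(value ~ between * within + Error(subject / within),
                            data = d))
  f_between <- fit[["Error: subject"]][[1]]["between", "F value"]
  wtab <- fit[["Error: subject:within"]][[1]]
  eff <- r$effects
  expect_equal(eff$F[eff$effect == "between"], f_between, tolerance = 1e-10)
  expect_equal(eff$F[eff$effect == "within"], wtab["within", "F value"],
               tolerance = 1e-10)
  expect_equal(eff$F[eff$effect == "between:within"],
               wtab["between:within", "F value"], tolerance = 1e-10)
  eps <- eff$epsilon[eff$effect == "within"]
  expect_gte(eps, 1 / 2)
  expect_lte(eps, 1)
})

test_that("GG epsilon always lies in [1/(k-1), 1]", {
  set.seed(4)
  for (i in 1:25) {
    k <- sample(3:6, 1)
    n <- sample(6:12, 1)
    d <- data.frame(subject = rep(seq_len(n), each = k),
                    within = rep(seq_len(k), n),
                    value = rnorm(n * k))
    eps <- rm_anova(d)$effects$epsilon
    expect_gte(eps, 1 / (k - 1) - 1e-12)
    expect_lte(eps, 1)
  }
})

test_that("Newman-Keuls reduces to a paired comparison for two groups", {
  nk <- newman_keuls(c(a = 0, b = 1), ms_error = 2, df_error = 10, n = 5)
  q <- 1 / sqrt(2 / 5)
  t_stat <- 1 / sqrt(2 * 2 / 5)
  expect_equal(nk$p["a", "b"],
               2 * stats::pt(t_stat, 10, lower.tail = FALSE), tolerance = 1e-6)
  expect_equal(nk$p["a", "b"],
               stats::ptukey(q, 2, 10, lower.tail = FALSE), tolerance = 1e-12)
})

test_that("Newman-Keuls propagates non-significance inside accepted spans", {
  # all means equal: nothing rejected
  nk0 <- newman_keuls(c(a = 1, b = 1, c = 1), 1, 12, 6)
  expect_false(any(nk0$significant))
  # one distant mean: extremes differ, near-equal pair does not
  nk1 <- newman_keuls(c(a = 0, b = 0.05, c = 4), ms_error = 0.5,
                      df_error = 20, n = 8)
  expect_true(nk1$significant["a", "c"])
  expect_true(nk1$significant["b", "c"])
  expect_false(nk1$significant["a", "b"])
})

test_that("the studentized-range CDF matches a Monte-Carlo oracle", {
  set.seed(5)
  B <- 4e5
  k <- 3; df <- 10
  z <- matrix(rnorm(B * k), B, k)
  rng <- apply(z, 1, max) - apply(z, 1, min)
  s <- sqrt(rchisq(B, df) / df)
  mc <- mean(rng / s > 3.0)
  expect_equal(stats::ptukey(3.0, k, df, lower.tail = FALSE), mc,
               tolerance = 0.005)
})

test_that("chi-square matches hand computation and clamps Bonferroni", {
  independent <- outer(c(30, 70), c(40, 60)) / 100
  r0 <- chi_square(independent)
  expect_equal(r0$statistic, 0, tolerance = 1e-12)
  r <- chi_square(rbind(c(10, 20), c(20, 10)))
  expect_equal(r$statistic, 20 / 3, tolerance = 1e-10)
  expect_equal(r$df, 1)
  r2 <- chi_square(rbind(c(12, 8), c(8, 12)), bonferroni_m = 3)
  expect_equal(r2$p_adjusted, min(1, 3 * r2$p))
  r3 <- chi_square(rbind(c(11, 9), c(9, 11)), bonferroni_m = 3)
  expect_equal(r3$p_adjusted, 1) # m * p exceeds 1 and clamps
  expect_error(chi_square(rbind(c(0, 0), c(1, 1))), "degenerate")
})

test_that("tests hold their nominal type-I error under the null", {
  set.seed(6)
  alpha <- 0.05
  n_sim <- 400
  rej <- c(paired = 0, one = 0, chi = 0)
  for (i in seq_len(n_sim)) {
    rej["paired"] <- rej["paired"] + (paired_t(rnorm(10), rnorm(10))$p < alpha)
    rej["one"] <- rej["one"] + (one_sample_t(rnorm(10))$p < alpha)
    tab <- rbind(table(factor(rbinom(80, 1, 0.5), levels = 0:1)),
                 table(factor(rbinom(80, 1, 0.5), levels = 0:1)))
    rej["chi"] <- rej["chi"] + (chi_square(tab)$p < alpha)
  }
  ci <- 1.96 * sqrt(alpha * (1 - alpha) / n_sim)
  for (nm in names(rej)) {
    expect_lt(abs(rej[[nm]] / n_sim - alpha), ci + 0.02)
  }
})
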