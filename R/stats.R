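#' Inferential statistics used by the pipeline
#'
#' Paired and one-sample t tests, repeated-measures ANOVA with
#' Greenhouse-Geisser sphericity correction, Student-Newman-Keuls stepwise
#' post hoc comparisons (spelled "Neumann-Keuls" in some reports), and
#' Pearson chi-square with Bonferroni adjustment.
#'
#' @name vpcalcium-stats
#' @keywords internal
NULL

stat_result <- function(test, statistic, df, p, ...) {
  structure(c(list(test = test, statistic = unname(statistic),
                   df = unname(df), p = unname(p)), list(...)),
            class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  dfs <- paste(signif(x$df, 4), collapse = ", ")
  cat(sprintf("<stat_result> %s: statistic = %.4g, df = %s, p = %.4g\n",
              x$test, x$statistic, dfs, x$p))
  invisible(x)
}

#' Paired Student's t test
#'
#' @param x,y Paired numeric vectors of equal length (n >= 2).
#' @return A `stat_result` (t on the differences, df = n - 1, two-sided p).
#' @export
paired_t <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  d <- x - y
  if (stats::sd(d) == 0) { # constant differences: t.test() refuses these
    t0 <- if (mean(d) == 0) 0 else sign(mean(d)) * Inf
    return(stat_result("paired t", t0, length(d) - 1,
                       if (mean(d) == 0) 1 else 0, mean_difference = mean(d)))
  }
  tt <- stats::t.test(x, y, paired = TRUE)
  stat_result("paired t", tt$statistic, tt$parameter, tt$p.value,
              mean_difference = unname(tt$estimate))
}

#' One-sample t test
#'
#' @param sample Numeric vector (n >= 2).
#' @param mu Null value.
#' @return A `stat_result` (df = n - 1, two-sided p).
#' @export
one_sample_t <- function(sample, mu = 0) {
  stopifnot(length(sample) >= 2)
  if (stats::sd(sample) == 0) {
    dev <- mean(sample) - mu
    t0 <- if (dev == 0) 0 else sign(dev) * Inf
    return(stat_result("one-sample t", t0, length(sample) - 1,
                       if (dev == 0) 1 else 0, mean = mean(sample), mu = mu))
  }
  tt <- stats::t.test(sample, mu = mu)
  stat_result("one-sample t", tt$statistic, tt$parameter, tt$p.value,
              mean = mean(sample), mu = mu)
}

# Greenhouse-Geisser epsilon from a covariance matrix of k repeated measures.
gg_epsilon <- function(S) {
  k <- nrow(S)
  C <- S - matrix(rowMeans(S), k, k) - matrix(colMeans(S), k, k, byrow = TRUE) +
    mean(S)
  if (sum(C^2) == 0) return(1) # no repeated-measures variance: sphericity holds
  tr <- sum(diag(C))
  eps <- tr^2 / ((k - 1) * sum(C^2))
  min(1, max(eps, 1 / (k - 1)))
}

safe_f <- function(ss_num, df_num, ss_den, df_den) {
  if (ss_den == 0) return(if (ss_num == 0) 0 else Inf)
  (ss_num / df_num) / (ss_den / df_den)
}

#' Repeated-measures ANOVA with Greenhouse-Geisser correction
#'
#' One-way within-subject designs (`data` columns: `subject`, `within`,
#' `value`) or two-way mixed designs with a between-subjects factor (add a
#' `between` column; cell type is between-units, session is within). The
#' design must be balanced and complete (no imputation). Greenhouse-Geisser
#' epsilon is computed from the (pooled) sample covariance of the repeated
#' measures and applied to the degrees of freedom of every within-subject
#' test; corrected (possibly fractional) df are reported.
#'
#' @param data Long-format data frame.
#' @param gg_correction Apply the sphericity correction (default TRUE).
#' @return Object of class `rm_anova_result`: a data frame `effects` with F,
#'   uncorrected and corrected df, epsilon, and p per effect.
#' @export
rm_anova <- function(data, gg_correction = TRUE) {
  stopifnot(is.data.frame(data),
            all(c("subject", "within", "value") %in% names(data)))
  mixed <- "between" %in% names(data)
  data$subject <- as.character(data$subject)
  data$within <- as.character(data$within)
  wl <- sort(unique(data$within))
  k <- length(wl)
  stopifnot(k >= 2)
  subj <- sort(unique(data$subject))
  n <- length(subj)
  if (nrow(data) != n * k || anyDuplicated(data[c("subject", "within")])) {
    stop("unbalanced or incomplete design: each subject needs every within level exactly once")
  }
  Y <- matrix(NA_real_, n, k, dimnames = list(subj, wl))
  Y[cbind(match(data$subject, subj), match(data$within, wl))] <- data$value
  if (anyNA(Y)) stop("missing cells in the design (no imputation)")
  grand <- mean(Y)
  if (!mixed) {
    mw <- colMeans(Y)
    ms <- rowMeans(Y)
    ss_w <- n * sum((mw - grand)^2)
    resid <- Y - outer(ms, rep(1, k)) - outer(rep(1, n), mw) + grand
    ss_err <- sum(resid^2)
    df1 <- k - 1; df2 <- (n - 1) * (k - 1)
    Fw <- safe_f(ss_w, df1, ss_err, df2)
    eps <- if (gg_correction) gg_epsilon(stats::cov(Y)) else 1
    effects <- data.frame(
      effect = "within", F = Fw, df1 = df1, df2 = df2, epsilon = eps,
      df1_corrected = eps * df1, df2_corrected = eps * df2,
      p = stats::pf(Fw, eps * df1, eps * df2, lower.tail = FALSE),
      stringsAsFactors = FALSE)
    ms_error <- ss_err / df2
  } else {
    btab <- unique(data[c("subject", "between")])
    if (anyDuplicated(btab$subject)) stop("each subject must have one between level")
    bet <- btab$between[match(subj, btab$subject)]
    bl <- sort(unique(bet))
    g <- length(bl)
    ng <- table(factor(bet, levels = bl))
    if (length(unique(ng)) != 1) stop("unbalanced between-subject groups")
    ni <- ng[[1]]
    mg <- as.vector(tapply(rowMeans(Y), bet, mean)[bl]) # group means
    mw <- colMeans(Y)                               # within-level means
    mc <- t(vapply(bl, function(b) colMeans(Y[bet == b, , drop = FALSE]),
                   numeric(k)))                     # g x k cell means
    ms <- as.vector(rowMeans(Y))                    # subject means
    ss_b <- k * ni * sum((mg - grand)^2)
    ss_subj <- k * sum((ms - mg[match(bet, bl)])^2)
    ss_w <- g * ni * sum((mw - grand)^2)
    ss_bw <- ni * sum((mc - outer(mg, rep(1, k)) -
                         outer(rep(1, g), mw) + grand)^2)
    fitted_w <- mc[match(bet, bl), , drop = FALSE] + (ms - mg[match(bet, bl)])
    ss_err_w <- sum((Y - fitted_w)^2)
    df_b <- g - 1; df_subj <- n - g
    df_w <- k - 1; df_bw <- (g - 1) * (k - 1); df_err <- (n - g) * (k - 1)
    Sp <- Reduce(`+`, lapply(bl, function(b) {
      (sum(bet == b) - 1) * stats::cov(Y[bet == b, , drop = FALSE])
    })) / (n - g)
    eps <- if (gg_correction) gg_epsilon(Sp) else 1
    Fb <- safe_f(ss_b, df_b, ss_subj, df_subj)
    Fw <- safe_f(ss_w, df_w, ss_err_w, df_err)
    Fbw <- safe_f(ss_bw, df_bw, ss_err_w, df_err)
    effects <- data.frame(
      effect = c("between", "within", "between:within"),
      F = c(Fb, Fw, Fbw),
      df1 = c(df_b, df_w, df_bw), df2 = c(df_subj, df_err, df_err),
      epsilon = c(NA, eps, eps),
      df1_corrected = c(df_b, eps * df_w, eps * df_bw),
      df2_corrected = c(df_subj, eps * df_err, eps * df_err),
      p = c(stats::pf(Fb, df_b, df_subj, lower.tail = FALSE),
            stats::pf(Fw, eps * df_w, eps * df_err, lower.tail = FALSE),
            stats::pf(Fbw, eps * df_bw, eps * df_err, lower.tail = FALSE)),
      stringsAsFactors = FALSE)
    ms_error <- ss_err_w / df_err
  }
  rownames(effects) <- NULL
  structure(list(effects = effects, ms_error = ms_error,
                 n_subjects = n, k_within = k,
                 gg_correction = gg_correction),
            class = "rm_anova_result")
}

#' @export
print.rm_anova_result <- function(x, ...) {
  cat("<rm_anova_result>\n")
  print(x$effects, digits = 4)
  invisible(x)
}

#' Student-Newman-Keuls stepwise post hoc comparisons
#'
#' Means are sorted; the extreme pair of each span is tested against the
#' studentized-range critical value for that span (`q = diff /
#' sqrt(MS_error / n)`), recursing inward only where the enclosing span is
#' significant, so non-significance propagates to all enclosed pairs.
#'
#' @param means Named vector of group means.
#' @param ms_error Error mean square from the ANOVA.
#' @param df_error Error degrees of freedom.
#' @param n Per-group sample size (harmonic mean for mild imbalance).
#' @param alpha Significance level (default 0.05).
#' @return List with matrices `p` (nominal SNK p per pair) and `significant`
#'   (after propagation), in the original group order.
#' @export
newman_keuls <- function(means, ms_error, df_error, n, alpha = 0.05) {
  kk <- length(means)
  stopifnot(kk >= 2, ms_error >= 0, df_error >= 1, n >= 1)
  if (is.null(names(means))) names(means) <- paste0("g", seq_len(kk))
  ord <- order(means)
  ms <- means[ord]
  se <- sqrt(ms_error / n)
  pmat <- matrix(NA_real_, kk, kk, dimnames = list(names(ms), names(ms)))
  sig <- matrix(NA, kk, kk, dimnames = list(names(ms), names(ms)))
  for (i in seq_len(kk - 1)) for (j in (i + 1):kk) {
    r <- j - i + 1
    q <- if (se == 0) if (ms[j] == ms[i]) 0 else Inf else (ms[j] - ms[i]) / se
    pmat[i, j] <- pmat[j, i] <- stats::ptukey(q, r, df_error, lower.tail = FALSE)
  }
  mark_nonsig <- function(i, j) {
    for (a in i:(j - 1)) for (b in (a + 1):j) {
      if (is.na(sig[a, b])) sig[a, b] <<- sig[b, a] <<- FALSE
    }
  }
  test_span <- function(i, j) {
    if (j <= i) return(invisible())
    if (!is.na(sig[i, j])) return(invisible())
    if (pmat[i, j] < alpha) {
      sig[i, j] <<- sig[j, i] <<- TRUE
      test_span(i, j - 1)
      test_span(i + 1, j)
    } else {
      mark_nonsig(i, j)
    }
  }
  test_span(1, kk)
  diag(sig) <- FALSE
  back <- match(names(means), names(ms))
  list(p = pmat[back, back, drop = FALSE],
       significant = sig[back, back, drop = FALSE])
}

#' Pearson chi-square test with Bonferroni adjustment
#'
#' Without continuity correction by default. The adjusted p is
#' `min(1, m * p)` for `m` planned comparisons.
#'
#' @param table Non-negative integer contingency table (matrix).
#' @param bonferroni_m Number of comparisons in the family (default 1).
#' @param correct Apply Yates continuity correction (default FALSE).
#' @return A `stat_result` with `p_adjusted`.
#' @export
chi_square <- function(table, bonferroni_m = 1, correct = FALSE) {
  table <- as.matrix(table)
  stopifnot(all(table >= 0), all(table == round(table)), bonferroni_m >= 1)
  expected <- outer(rowSums(table), colSums(table)) / sum(table)
  if (any(expected <= 0)) stop("zero expected counts; table is degenerate")
  res <- suppressWarnings(stats::chisq.test(table, correct = correct))
  stat_result("chi-square", res$statistic, res$parameter, res$p.value,
              p_adjusted = min(1, bonferroni_m * res$p.value),
              bonferroni_m = bonferroni_m)
}
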