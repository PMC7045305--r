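#' Spatial clustering, colocalization counting and input fractions
#'
#' @name vpcalcium-spatial
#' @keywords internal
NULL

#' Mean k-nearest-neighbor distance of a point pattern
#'
#' The clustering statistic: for each point, the Euclidean distance to its
#' k-th nearest neighbor (`value = "kth"`, default) or the mean of its k
#' nearest distances (`value = "mean_k"`); averaged over points.
#'
#' @param points n x 2 matrix of positions.
#' @param k Neighbor order (default 10).
#' @param value `"kth"` or `"mean_k"`.
#' @return Numeric scalar.
#' @export
mean_knn_distance <- function(points, k = 10L, value = c("kth", "mean_k")) {
  value <- match.arg(value)
  points <- as.matrix(points)
  mean_knn_distance_cpp(points, as.integer(k),
                        method = if (value == "kth") 0L else 1L)
}

#' k-nearest-neighbor spatial clustering permutation test
#'
#' The observed mean k-NN distance is compared against the same statistic on
#' `n_shuffles` redraws of equally many uniformly distributed points (the
#' complete-spatial-randomness null). The primary p value is the one-sided
#' permutation p, `(1 + #{null <= observed}) / (n_shuffles + 1)`, which is
#' exactly calibrated: under randomness the test rejects at `alpha`. A
#' one-sample t of the null sample against the observed value
#' (df = `n_shuffles - 1`) is also reported as a descriptive effect summary
#' (`t`, `p_t`); it is not calibrated as a single-pattern test because its
#' standard error shrinks with the number of shuffles, so it is never used
#' for the clustered call. The pattern is called clustered when the observed
#' statistic is below the null mean and the permutation p < `alpha`.
#'
#' @param pattern A [spatial_pattern()] (or n x 2 point matrix).
#' @param k Neighbor order (default 10).
#' @param n_shuffles Number of uniform redraws (default 1000).
#' @param seed Integer seed for the shuffles.
#' @param alpha Significance level (default 0.05).
#' @param region `"bounds"` shuffles inside the pattern's stated field
#'   bounds; `"bbox"` inside the bounding box of the observed points.
#' @param value k-NN statistic flavor, see [mean_knn_distance()].
#' @return Object of class `knn_result`: observed statistic, null
#'   distribution, t, df, p, and the clustered call.
#' @export
knn_clustering_test <- function(pattern, k = 10L, n_shuffles = 1000L,
                                seed = 1L, alpha = 0.05,
                                region = c("bounds", "bbox"),
                                value = c("kth", "mean_k")) {
  region <- match.arg(region)
  value <- match.arg(value)
  if (inherits(pattern, "spatial_pattern")) {
    pts <- pattern$points
    bounds <- pattern$bounds
  } else {
    pts <- as.matrix(pattern)
    region <- "bbox"
    bounds <- NULL
  }
  n <- nrow(pts)
  if (n < k + 2) stop("need at least k + 2 points")
  degenerate <- all(pts[, 1] == pts[1, 1]) && all(pts[, 2] == pts[1, 2])
  observed <- if (degenerate) 0 else mean_knn_distance(pts, k, value)
  if (region == "bbox" || is.null(bounds)) {
    bounds <- c(range(pts[, 1]), range(pts[, 2]))
  }
  if (degenerate) {
    warning("degenerate pattern: all points identical")
    bounds <- bounds + c(-0.5, 0.5, -0.5, 0.5) # avoid a zero-area region
  }
  method <- if (value == "kth") 0L else 1L
  null <- with_seed(seed, knn_null_cpp(n, as.integer(k),
                                       as.integer(n_shuffles),
                                       as.numeric(bounds), method))
  tt <- stats::t.test(null, mu = observed)
  p_perm <- (1 + sum(null <= observed)) / (n_shuffles + 1)
  structure(list(observed = observed, null = as.numeric(null),
                 null_mean = mean(null),
                 t = unname(tt$statistic), df = unname(tt$parameter),
                 p = p_perm, p_t = tt$p.value,
                 clustered = observed < mean(null) && p_perm < alpha,
                 alpha = alpha, k = as.integer(k),
                 n_shuffles = as.integer(n_shuffles),
                 degenerate = degenerate),
            class = "knn_result")
}

#' @export
print.knn_result <- function(x, ...) {
  cat(sprintf(
    "<knn_result> observed %.4g vs null %.4g (k=%d, %d shuffles): t(%d) = %.3f, p = %.3g -> %s\n",
    x$observed, x$null_mean, x$k, x$n_shuffles, x$df, x$t, x$p,
    if (x$clustered) "clustered" else "not clustered"))
  invisible(x)
}

#' Colocalization / density counting over marker labels
#'
#' Tabulates marginal counts and percentages per marker and the disjoint
#' (Venn-style) partition over all marker combinations; partition counts sum
#' to the total cell count.
#'
#' @param labels Data frame with one logical column per marker (any non-
#'   logical columns are treated as identifiers and ignored).
#' @return Object of class `density_table` with `n`, `marginals` and
#'   `combinations` data frames.
#' @export
count_colocalization <- function(labels) {
  stopifnot(is.data.frame(labels))
  markers <- names(labels)[vapply(labels, is.logical, logical(1))]
  if (!length(markers)) stop("label table has no logical marker columns")
  n <- nrow(labels)
  marginals <- data.frame(
    marker = markers,
    count = vapply(markers, function(m) sum(labels[[m]]), integer(1)),
    stringsAsFactors = FALSE)
  marginals$percent <- 100 * marginals$count / n
  pattern <- apply(labels[markers], 1, function(r) {
    if (!any(r)) "none" else paste(markers[r], collapse = "+")
  })
  tab <- table(pattern)
  combinations <- data.frame(combination = names(tab),
                             count = as.integer(tab),
                             stringsAsFactors = FALSE)
  combinations$percent <- 100 * combinations$count / n
  rownames(marginals) <- NULL
  structure(list(n = n, marginals = marginals, combinations = combinations),
            class = "density_table")
}

#' @export
print.density_table <- function(x, ...) {
  cat(sprintf("<density_table> %d cells\n", x$n))
  print(x$marginals)
  invisible(x)
}

#' D1/D2 input fractions per starter cell type
#'
#' For each starter type, counts D1- and D2-labeled upstream inputs and the
#' D1 percentage; all pairwise 2x2 chi-square tests (without continuity
#' correction) are Bonferroni-adjusted across the number of pairs.
#'
#' @param tables Named list (one element per starter type) of data frames
#'   with a `label` column coded `"D1"`/`"D2"`.
#' @return Object of class `input_fraction_table` with `per_type` and
#'   `pairwise` data frames.
#' @export
input_fractions <- function(tables) {
  stopifnot(is.list(tables), length(tables) >= 2, !is.null(names(tables)))
  per_type <- do.call(rbind, lapply(names(tables), function(nm) {
    lab <- tables[[nm]]$label
    stopifnot(all(lab %in% c("D1", "D2")))
    d1 <- sum(lab == "D1")
    data.frame(starter = nm, n = length(lab), d1 = d1,
               d2 = length(lab) - d1, pct_d1 = 100 * d1 / length(lab),
               stringsAsFactors = FALSE)
  }))
  pairs <- utils::combn(names(tables), 2)
  m <- ncol(pairs)
  pairwise <- do.call(rbind, lapply(seq_len(m), function(i) {
    a <- per_type[per_type$starter == pairs[1, i], ]
    b <- per_type[per_type$starter == pairs[2, i], ]
    tab <- rbind(c(a$d1, a$d2), c(b$d1, b$d2))
    res <- chi_square(tab, bonferroni_m = m)
    data.frame(type_a = pairs[1, i], type_b = pairs[2, i],
               chi_square = res$statistic, df = res$df, p = res$p,
               p_adjusted = res$p_adjusted, stringsAsFactors = FALSE)
  }))
  structure(list(per_type = per_type, pairwise = pairwise,
                 bonferroni_m = m),
            class = "input_fraction_table")
}

#' @export
print.input_fraction_table <- function(x, ...) {
  cat("<input_fraction_table>\n")
  print(x$per_type)
  invisible(x)
}

#' Derived subpopulation shares from marker densities
#'
#' From the overall Penk and Vgat percentages, the Penk share of the
#' GABAergic population is `100 * penk / vgat`, rounded to an integer; the
#' complement is the enkephalin-negative share. With the published densities
#' (Penk 16%, Vgat 73%) this yields 22% and 78%.
#'
#' @param penk_pct Penk-positive percentage of all neurons.
#' @param vgat_pct Vgat-positive percentage of all neurons (> 0).
#' @return List with `penk_share_of_gaba` and `complement` (integers, %).
#' @export
derive_subpopulation_fractions <- function(penk_pct, vgat_pct) {
  stopifnot(penk_pct >= 0, vgat_pct > 0, penk_pct <= vgat_pct)
  share <- as.integer(round(100 * penk_pct / vgat_pct))
  list(penk_share_of_gaba = share, complement = 100L - share)
}
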