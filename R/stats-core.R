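#' Pearson correlation with significance
#'
#' Sample Pearson r with a two-sided p-value from the t transform
#' t = r * sqrt((n - 2) / (1 - r^2)) on n - 2 degrees of freedom.
#'
#' @param x,y numeric vectors of equal length n >= 3, each with nonzero
#'   variance.
#' @return a `test_result` list: `statistic` (r), `p_value`, `df_or_n`,
#'   `method = "pearson"`.
#' @export
pearson_test <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  if (length(x) < 3L) stop("need n >= 3 observations", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant input: zero variance", call. = FALSE)
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  test_result(unname(ct$estimate), ct$p.value, length(x), "pearson")
}

#' Kruskal-Wallis H-test with tie correction
#'
#' Rank-based k-group test; ties get midranks and the H statistic is divided
#' by 1 - sum(t^3 - t) / (N^3 - N). The p-value comes from the chi-square
#' approximation on k - 1 df; for tiny pooled N an exact Monte-Carlo
#' permutation p-value is available.
#'
#' @param groups list of >= 2 nonempty numeric vectors, pooled N >= 3.
#' @param exact if `TRUE`, p-value by permutation of group labels
#'   (`n_perm` resamples) instead of the chi-square approximation.
#' @param n_perm number of permutations when `exact = TRUE`.
#' @return a `test_result` with `statistic` (H), `p_value`, `df_or_n`
#'   (k - 1), `method = "kruskal_wallis"`.
#' @export
kruskal_wallis_test <- function(groups, exact = FALSE, n_perm = 10000L) {
  if (!is.list(groups) || length(groups) < 2L)
    stop("need at least 2 groups", call. = FALSE)
  if (any(lengths(groups) == 0L)) stop("empty group", call. = FALSE)
  pooled <- unlist(groups, use.names = FALSE)
  if (length(pooled) < 3L) stop("need pooled N >= 3", call. = FALSE)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  if (length(unique(pooled)) == 1L)
    return(test_result(0, 1, length(groups) - 1L, "kruskal_wallis"))
  kt <- stats::kruskal.test(pooled, g)
  h <- unname(kt$statistic)
  p <- kt$p.value
  if (exact) {
    hits <- 0L
    for (i in seq_len(n_perm)) {
      hp <- unname(stats::kruskal.test(pooled, sample(g))$statistic)
      if (hp >= h - 1e-12) hits <- hits + 1L
    }
    p <- (hits + 1) / (n_perm + 1)
  }
  test_result(h, p, length(groups) - 1L, "kruskal_wallis")
}

#' Benjamini-Hochberg step-up adjustment
#'
#' q(i) = min over j >= i of p(j) * m / j on the sorted p-values, capped at
#' 1 and mapped back to input order (stable sort, so ties share treatment).
#'
#' @param p numeric vector of raw p-values in \[0, 1\].
#' @return list with `raw` and `adjusted` vectors in input order.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  list(raw = p, adjusted = stats::p.adjust(p, method = "BH"))
}

#' Median-of-ratios size factors
#'
#' Per-sample scaling factors: median across features of the ratio of each
#' count to the feature's geometric mean, computed over features nonzero in
#' every sample.
#'
#' @param counts features x samples count matrix.
#' @return numeric vector of size factors, one per column.
#' @export
estimate_size_factors <- function(counts) {
  keep <- rowSums(counts == 0) == 0L
  if (!any(keep)) return(rep(1, ncol(counts)))
  lg <- log(counts[keep, , drop = FALSE])
  geo <- rowMeans(lg)
  apply(lg, 2L, function(col) exp(stats::median(col - geo)))
}

#' Two-group negative-binomial Wald test
#'
#' Fits per-group NB means on size-factor-scaled counts, estimates a common
#' dispersion by method of moments (floored at 1e-8), and tests the log fold
#' change with a two-sided Wald z. Under the NB model var = mu + alpha*mu^2,
#' so var(log mean_g) ~ (1/mu_g + alpha)/n_g by the delta method. Features
#' zero in both groups return p = 1 and log2FC = 0; a group whose mean is
#' zero is floored at 0.5/n so the fold change stays finite.
#'
#' @param counts_a,counts_b count vectors for the two groups (n >= 2 each).
#' @param size_factors positive scaling factors, length
#'   `length(counts_a) + length(counts_b)` (group a first), or a single 1
#'   for unscaled counts.
#' @return a `test_result` with `statistic` (Wald z), `p_value`, `df_or_n`
#'   (total n), `method = "nb_wald"`, plus `log2_fold_change` (b over a).
#' @export
nb_wald_two_group <- function(counts_a, counts_b,
                              size_factors = rep(1, length(counts_a) + length(counts_b))) {
  na <- length(counts_a); nb <- length(counts_b)
  if (na < 2L || nb < 2L) stop("each group needs n >= 2", call. = FALSE)
  if (length(size_factors) == 1L) size_factors <- rep(size_factors, na + nb)
  if (length(size_factors) != na + nb)
    stop("size_factors length must match total sample count", call. = FALSE)
  if (any(size_factors <= 0)) stop("size factors must be > 0", call. = FALSE)
  sa <- size_factors[seq_len(na)]
  sb <- size_factors[na + seq_len(nb)]
  qa <- counts_a / sa
  qb <- counts_b / sb
  mu_a <- mean(qa); mu_b <- mean(qb)
  if (mu_a == 0 && mu_b == 0) {
    res <- test_result(0, 1, na + nb, "nb_wald")
    res$log2_fold_change <- 0
    return(res)
  }
  # method-of-moments dispersion pooled across groups, floored
  mom <- function(q, mu, n) if (n > 1L && mu > 0) (stats::var(q) - mu) / mu^2 else NA_real_
  alphas <- c(mom(qa, mu_a, na), mom(qb, mu_b, nb))
  alpha <- max(mean(alphas, na.rm = TRUE), 1e-8)
  if (is.na(alpha)) alpha <- 1e-8
  fa <- max(mu_a, 0.5 / na)
  fb <- max(mu_b, 0.5 / nb)
  se2 <- (1 / fa + alpha) / na + (1 / fb + alpha) / nb
  z <- (log(fb) - log(fa)) / sqrt(se2)
  res <- test_result(z, 2 * stats::pnorm(-abs(z)), na + nb, "nb_wald")
  res$log2_fold_change <- log2(fb / fa)
  res
}

test_result <- function(statistic, p_value, df_or_n, method) {
  structure(list(statistic = statistic, p_value = p_value,
                 df_or_n = as.integer(df_or_n), method = method),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("<test_result> %s: statistic=%.4g, p=%.4g (df/n=%d)\n",
              x$method, x$statistic, x$p_value, x$df_or_n))
  if (!is.null(x$log2_fold_change))
    cat(sprintf("  log2FC=%.4g\n", x$log2_fold_change))
  invisible(x)
}
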