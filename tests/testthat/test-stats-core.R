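test_that("pearson matches closed-form cases and errors on degenerate input", {
  expect_equal(pearson_test(c(1, 2, 3), c(2, 4, 6))$statistic, 1)
  expect_equal(pearson_test(c(1, 2, 3), c(3, 2, 1))$statistic, -1)
  r <- pearson_test(c(1, 2, 3, 4), c(1, 3, 2, 4))
  expect_equal(r$statistic, 0.8)
  # p from the t transform: t = r*sqrt((n-2)/(1-r^2)), df = n-2
  t_stat <- 0.8 * sqrt(2 / (1 - 0.64))
  expect_equal(r$p_value, 2 * pt(-t_stat, df = 2))
  expect_error(pearson_test(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_error(pearson_test(c(1, 2), c(1, 2)), "n >= 3")
})

test_that("pearson is symmetric, affine-invariant and sign-flipped by negative slope", {
  set.seed(11)
  for (i in 1:20) {
    x <- rnorm(10); y <- rnorm(10)
    a <- pearson_test(x, y)
    expect_equal(a$statistic, pearson_test(y, x)$statistic)
    b <- pearson_test(2.5 * x + 7, y)
    expect_equal(b$statistic, a$statistic, tolerance = 1e-12)
    d <- pearson_test(-x, y)
    expect_equal(d$statistic, -a$statistic, tolerance = 1e-12)
    expect_equal(d$p_value, a$p_value, tolerance = 1e-12)
  }
})

test_that("kruskal-wallis reproduces hand-computed H with and without ties", {
  no_ties <- kruskal_wallis_test(list(c(1, 2, 3), c(4, 5, 6)))
  expect_equal(no_ties$statistic, 3.857, tolerance = 5e-4)
  expect_equal(no_ties$p_value, 0.0495, tolerance = 1e-3)

  ties <- kruskal_wallis_test(list(c(1, 1), c(2, 2)))
  expect_equal(ties$statistic, 3.0)  # 2.4 / (1 - 12/60) tie divisor 0.8

  ident <- kruskal_wallis_test(list(c(5, 5, 5), c(5, 5, 5)))
  expect_equal(ident$statistic, 0)
  expect_equal(ident$p_value, 1)

  expect_error(kruskal_wallis_test(list(c(1, 2, 3))), "2 groups")
})

test_that("kruskal-wallis is invariant under strictly monotone transforms", {
  set.seed(22)
  for (i in 1:20) {
    g <- list(rnorm(5), rnorm(4) + 0.5, rnorm(6))
    a <- kruskal_wallis_test(g)
    b <- kruskal_wallis_test(lapply(g, function(v) exp(v)))
    expect_equal(b$statistic, a$statistic, tolerance = 1e-12)
    expect_equal(b$p_value, a$p_value, tolerance = 1e-12)
  }
})

test_that("permutation p-value agrees with full enumeration at small N", {
  # independent oracle: enumerate all assignments of 6 values into 3+3
  g <- list(c(1.3, 2.1, 0.4), c(2.9, 3.7, 1.8))
  pooled <- unlist(g)
  h_obs <- kruskal_wallis_test(g)$statistic
  combs <- utils::combn(6, 3)
  h_all <- apply(combs, 2, function(idx) {
    kruskal_wallis_test(list(pooled[idx], pooled[-idx]))$statistic
  })
  p_exact <- mean(h_all >= h_obs - 1e-12)
  set.seed(33)
  p_perm <- kruskal_wallis_test(g, exact = TRUE, n_perm = 4000)$p_value
  expect_equal(p_perm, p_exact, tolerance = 0.03)
})

test_that("benjamini-hochberg matches hand-computed step-up vectors", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04))$adjusted,
               c(0.04, 0.04, 0.04, 0.04))
  expect_equal(bh_adjust(c(0.5))$adjusted, 0.5)
  expect_equal(bh_adjust(c(0.005, 0.04, 0.03))$adjusted,
               c(0.015, 0.04, 0.04))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  # adjusted >= raw, monotone when sorted by raw
  set.seed(44)
  p <- runif(50)
  adj <- bh_adjust(p)$adjusted
  expect_true(all(adj >= p))
  expect_true(all(diff(adj[order(p)]) >= -1e-12))
})

test_that("BH controls the false discovery proportion on null uniforms", {
  set.seed(55)
  alpha <- 0.05
  fdp <- replicate(500, {
    adj <- bh_adjust(runif(200))$adjusted
    as.numeric(any(adj < alpha))  # all nulls: any rejection is false
  })
  se <- sd(fdp) / sqrt(length(fdp))
  expect_lte(mean(fdp), alpha + 3 * se)
})

test_that("nb wald test handles symmetry, zeros and a large-count oracle", {
  same <- nb_wald_two_group(c(10, 12, 11), c(10, 12, 11))
  expect_lt(abs(same$log2_fold_change), 1e-9)
  expect_equal(same$p_value, 1, tolerance = 1e-6)

  zz <- nb_wald_two_group(c(0, 0, 0), c(0, 0, 0))
  expect_equal(zz$log2_fold_change, 0)
  expect_equal(zz$p_value, 1)

  # large-count normal-approximation oracle: ratio ~ 4 -> log2FC ~ 2
  big <- nb_wald_two_group(c(100, 110, 90, 105), c(400, 380, 420, 410))
  expect_equal(big$log2_fold_change, 2.0, tolerance = 0.1)
  expect_lt(big$p_value, 1e-3)

  expect_error(nb_wald_two_group(c(5), c(1, 2)), "n >= 2")
  expect_error(nb_wald_two_group(c(5, 6), c(1, 2), c(1, -1, 1, 1)), "> 0")
})

test_that("size factors scale counts back to a common reference", {
  set.seed(66)
  base <- matrix(rpois(200, 50), 20, 10)
  rownames(base) <- sprintf("f%d", 1:20); colnames(base) <- sprintf("s%d", 1:10)
  sf_true <- runif(10, 0.5, 2)
  scaled <- sweep(base, 2, sf_true, "*")
  sf <- estimate_size_factors(scaled)
  # recovered up to a common constant
  expect_lt(sd(sf / sf_true) / mean(sf / sf_true), 0.1)
})

test_that("nb wald agrees with an independent DESeq2 fit on the same counts", {
  skip_if_not_installed("DESeq2")
  set.seed(77)
  n <- 8
  mu <- exp(runif(20, log(20), log(200)))
  lfc_true <- c(rep(0, 14), c(2, -2, 3, -3, 2.5, -2.5))
  counts <- t(vapply(seq_along(mu), function(i) {
    c(rnbinom(n, mu = mu[i], size = 10),
      rnbinom(n, mu = mu[i] * 2^lfc_true[i], size = 10))
  }, numeric(2 * n)))
  rownames(counts) <- sprintf("g%02d", seq_along(mu))
  colnames(counts) <- sprintf("s%02d", seq_len(2 * n))
  ours <- vapply(seq_len(nrow(counts)), function(i) {
    nb_wald_two_group(counts[i, 1:n], counts[i, n + 1:n])$log2_fold_change
  }, 0)
  suppressMessages({
    dds <- DESeq2::DESeqDataSetFromMatrix(
      counts, data.frame(group = factor(rep(c("a", "b"), each = n))),
      ~group)
    DESeq2::sizeFactors(dds) <- rep(1, 2 * n)
    dds <- DESeq2::DESeq(dds, quiet = TRUE)
    ref <- DESeq2::results(dds)$log2FoldChange
  })
  expect_gt(cor(ours, ref), 0.95)
  expect_equal(ours[15:20], lfc_true[15:20], tolerance = 0.6)
})
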