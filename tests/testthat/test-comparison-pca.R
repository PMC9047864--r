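# Tumor vs peritumor comparison routing and PCA reduction.

test_that("identical samples are not significant; constants are degenerate", {
  x <- c(1.2, 3.4, 2.2, 5.1, 4.4)
  r <- compare_tissues(x, x)
  expect_false(r$significant)
  d <- compare_tissues(rep(2, 5), rep(2, 5))
  expect_true(d$degenerate)
  expect_equal(d$p_value, 1)
})

test_that("normality routing picks ANOVA for Gaussian and KW for heavy tails", {
  set.seed(42)
  r1 <- compare_tissues(rnorm(19, 5.93, 0.1), rnorm(19, 6.81, 0.1))
  expect_equal(r1$test, "anova")
  heavy <- rcauchy(30); heavy2 <- rcauchy(30) + 5
  r2 <- compare_tissues(heavy, heavy2)
  expect_equal(r2$test, "kruskal")
})

test_that("the published tumor/peritumor separation is detected with high power", {
  # means 5.93 vs 6.81 (dependence-entropy scale), sd 0.1, n = 19 per group
  set.seed(7)
  hits <- mean(replicate(100, {
    compare_tissues(rnorm(19, 5.93, 0.1), rnorm(19, 6.81, 0.1))$significant
  }))
  expect_gte(hits, 0.95)
})

test_that("two-group Kruskal-Wallis agrees in direction with a rank-sum oracle", {
  set.seed(31)
  for (rep in 1:20) {
    a <- rnorm(sample(5:12, 1), sample(0:3, 1))
    b <- rnorm(sample(5:12, 1), sample(0:3, 1))
    kw <- stats::kruskal.test(list(a, b))
    # brute-force rank-sum: permutation reference via normal approximation
    ws <- stats::wilcox.test(a, b, exact = FALSE, correct = FALSE)
    expect_equal(kw$p.value < 0.05, ws$p.value < 0.05)
    expect_equal(kw$p.value, ws$p.value, tolerance = 1e-6)
  }
})

test_that("PCA handles rank-1 and single-feature input", {
  x <- rnorm(30)
  one <- pca_reduce(matrix(x, ncol = 1))
  expect_equal(one$proportion, 1)
  expect_equal(one$n90, 1)
  dup <- pca_reduce(cbind(a = x, b = 3 * x + 2))
  expect_equal(dup$proportion[1], 1, tolerance = 1e-9)
  expect_equal(dup$n90, 1)
})

test_that("independent standardized features split variance evenly", {
  set.seed(99)
  X <- matrix(rnorm(2 * 10000), ncol = 2)
  p <- pca_reduce(X)
  expect_equal(p$proportion, c(0.5, 0.5), tolerance = 0.03)
  expect_equal(p$n90, 2)
})

test_that("PCA proportions sum to 1, scores are centred, reconstruction works", {
  set.seed(13)
  X <- matrix(rnorm(40 * 6, 50, 9), 40)
  X[, 6] <- X[, 1] * 2 + rnorm(40, 0, 0.1)
  p <- pca_reduce(X)
  expect_equal(sum(p$proportion), 1, tolerance = 1e-9)
  expect_true(all(abs(colMeans(p$scores)) < 1e-10))
  expect_true(all(diff(p$cumulative) >= -1e-12))
  # reconstruction: scores %*% t(rotation) recovers the z-scored matrix
  pr <- stats::prcomp(X, center = TRUE, scale. = TRUE)
  Z <- scale(X)
  attr(Z, "scaled:center") <- attr(Z, "scaled:scale") <- NULL
  expect_equal(unname(pr$x %*% t(pr$rotation)), unname(Z), tolerance = 1e-8)
})

test_that("zero-variance features are dropped with a warning", {
  X <- cbind(a = rnorm(20), b = rep(3, 20))
  expect_warning(p <- pca_reduce(X), "zero-variance")
  expect_equal(p$dropped, "b")
  expect_length(p$proportion, 1)
})

test_that("n_components_for is correct and monotone in the fraction", {
  pc <- list(cumulative = cumsum(c(0.5, 0.3, 0.15, 0.05)))
  expect_equal(n_components_for(pc, 0.9), 3)
  expect_equal(n_components_for(pc, 1.0), 4)
  expect_equal(n_components_for(list(cumulative = 1), 0.9), 1)
  expect_error(n_components_for(pc, 0), "fraction")
  fr <- seq(0.05, 1, by = 0.05)
  expect_true(all(diff(vapply(fr, function(f)
    n_components_for(pc, f), numeric(1))) >= 0))
})
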