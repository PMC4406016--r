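# Statistical primitives vs independent oracles (base R implementations and
# brute-force enumeration written in the helpers).

test_that("pearson matches the covariance/sd formula and cor.test", {
  x <- c(1, 2, 3, 4); y <- c(1, 3, 2, 4)
  r_manual <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  res <- pearson_test(x, y)
  expect_equal(res$statistic, r_manual, tolerance = 1e-12)
  set.seed(11)
  for (k in 1:10) {
    a <- rnorm(5 + k); b <- rnorm(5 + k)
    res <- pearson_test(a, b)
    ct <- cor.test(a, b)
    expect_equal(res$statistic, unname(ct$estimate), tolerance = 1e-12)
    expect_equal(res$p, ct$p.value, tolerance = 1e-12)
  }
})

test_that("pearson handles perfect and degenerate cases", {
  x <- 1:10
  expect_equal(pearson_test(x, 2 * x + 1)$statistic, 1)
  expect_equal(pearson_test(x, -x)$statistic, -1)
  expect_equal(pearson_test(x, 2 * x + 1)$p, 0)
  res <- pearson_test(rep(1, 5), rnorm(5))
  expect_true(is.na(res$statistic))
  expect_match(res$reason, "variance")
  expect_true(is.na(pearson_test(1:2, 2:3)$statistic))
})

test_that("spearman exact p equals permutation enumeration and cor.test", {
  set.seed(21)
  for (n in c(4, 5, 6)) {
    x <- rnorm(n); y <- rnorm(n)
    res <- spearman_test(x, y)
    expect_equal(res$p, spearman_enum_p(x, y), tolerance = 1e-12)
  }
  # against cor.test's exact algorithm (AS 89) for larger n without ties
  for (n in c(8, 9)) {
    x <- rnorm(n); y <- rnorm(n)
    res <- spearman_test(x, y)
    ct <- cor.test(x, y, method = "spearman", exact = TRUE)
    expect_equal(res$statistic, unname(ct$estimate), tolerance = 1e-12)
    expect_equal(res$p, ct$p.value, tolerance = 1e-9)
  }
})

test_that("spearman handles monotone, tied and degenerate inputs", {
  res <- spearman_test(1:5, c(2, 4, 6, 9, 20))
  expect_equal(res$statistic, 1)
  expect_equal(res$p, 2 / 120)   # only the two perfect orderings
  # a tie pair: rho must equal the rank-formula (ties averaged)
  x <- c(1, 2, 2, 3, 5, 6, 7)
  y <- c(2, 1, 4, 3, 6, 5, 8)
  res <- spearman_test(x, y)
  expect_equal(res$statistic, cor(rank(x), rank(y)), tolerance = 1e-12)
  expect_true(is.na(spearman_test(rep(1, 5), rnorm(5))$statistic))
  # approximate mode agrees with cor.test's t-approximation
  set.seed(3)
  a <- rnorm(30); b <- a + rnorm(30)
  res <- spearman_test(a, b)
  ct <- suppressWarnings(cor.test(a, b, method = "spearman", exact = FALSE))
  expect_equal(res$p, ct$p.value, tolerance = 1e-9)
})

test_that("mann-whitney exact p equals labeling enumeration", {
  res <- mann_whitney_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$statistic, 0)     # min-U convention
  expect_equal(res$p, 0.1)           # 2/20 labelings as extreme
  set.seed(31)
  for (k in 1:25) {
    na <- sample(2:8, 1); nb <- sample(2:8, 1)
    a <- rnorm(na); b <- rnorm(nb)
    res <- mann_whitney_test(a, b)
    expect_equal(res$p, mw_enum_p(a, b), tolerance = 1e-12,
                 label = sprintf("na=%d nb=%d", na, nb))
  }
})

test_that("mann-whitney approximate mode matches wilcox.test", {
  set.seed(41)
  a <- c(1, 2, 2, 3, 5, 7, 7); b <- c(2, 3, 3, 4, 8, 9, 10, 11)
  res <- mann_whitney_test(a, b)         # ties force the normal approximation
  wt <- wilcox.test(a, b, exact = FALSE, correct = TRUE)
  expect_equal(res$p, wt$p.value, tolerance = 1e-12)
  x <- rnorm(20); y <- rnorm(15) + 0.5   # n > exact_max
  res <- mann_whitney_test(x, y)
  wt <- wilcox.test(x, y, exact = FALSE, correct = TRUE)
  expect_equal(res$p, wt$p.value, tolerance = 1e-12)
  # identical samples: p = 1 by exchangeability
  z <- c(1, 2, 3, 4)
  expect_equal(mann_whitney_test(z, z)$p, 1)
  expect_true(is.na(mann_whitney_test(numeric(0), z)$statistic))
})

test_that("kruskal-wallis matches the rank formula and kruskal.test", {
  # hand-computed instance: groups {1,2},{3,4},{5}, no ties -> H = 3.6
  res <- kruskal_wallis_test(list(c(1, 2), c(3, 4), 5))
  expect_equal(res$statistic, 3.6, tolerance = 1e-12)
  set.seed(51)
  for (k in 1:10) {
    g <- list(rnorm(6), rnorm(5) + 0.3, rnorm(7), rnorm(4) - 0.2)
    res <- kruskal_wallis_test(g)
    kt <- kruskal.test(g)
    expect_equal(res$statistic, unname(kt$statistic), tolerance = 1e-12)
    expect_equal(res$p, kt$p.value, tolerance = 1e-12)
  }
  expect_equal(kruskal_wallis_test(list(c(1, 1), c(1, 1), c(1, 1)))$statistic,
               NA_real_)
})

test_that("two-group kruskal-wallis equals uncorrected mann-whitney", {
  set.seed(61)
  for (k in 1:10) {
    a <- rnorm(8 + k); b <- rnorm(12) + 0.3
    kw <- kruskal_wallis_test(list(a, b))
    mw <- mann_whitney_test(a, b, exact_max = 0, correct = FALSE)
    expect_equal(kw$p, mw$p, tolerance = 1e-9)
  }
})

test_that("bh adjustment equals the step-up oracle and p.adjust", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(0.2, 10)), rep(0.2, 10))
  set.seed(71)
  for (k in 1:20) {
    p <- runif(sample(5:200, 1))
    q <- bh_adjust(p)
    expect_equal(q, bh_oracle(p), tolerance = 1e-12)
    expect_equal(q, p.adjust(p, "BH"), tolerance = 1e-12)
    expect_true(all(q >= p))
    expect_false(is.unsorted(q[order(p)]))        # monotone with p
  }
  # NA passthrough: NAs keep their place and do not count towards m
  p <- c(0.01, NA, 0.04)
  q <- bh_adjust(p)
  expect_true(is.na(q[2]))
  expect_equal(q[c(1, 3)], bh_oracle(c(0.01, 0.04)), tolerance = 1e-12)
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("ward clustering matches hclust ward.D2 on random data", {
  set.seed(81)
  for (k in 1:10) {
    n <- sample(4:8, 1)
    X <- matrix(rnorm(n * 5), n)
    mine <- ward_cluster(X)
    ref <- hclust(dist(X), "ward.D2")
    expect_equal(mine$height, ref$height, tolerance = 1e-9)
    expect_equal(as.matrix(cophenetic(mine)), as.matrix(cophenetic(ref)),
                 tolerance = 1e-9)
  }
})

test_that("ward clustering recovers planted structure", {
  # two identical rows merge first, at height 0
  set.seed(91)
  X <- rbind(rnorm(6), rnorm(6), rnorm(6))
  X <- rbind(X, X[2, ])
  tree <- ward_cluster(X)
  expect_equal(tree$height[1], 0)
  expect_true(all(sort(abs(tree$merge[1, ])) == c(2, 4)))
  # 4 samples = 2 planted pairs: cutree at k=2 equals the planted pairing
  base <- matrix(rnorm(2 * 10), 2)
  X <- rbind(base[1, ] + rnorm(10, 0, 0.01), base[1, ] + rnorm(10, 0, 0.01),
             base[2, ] + rnorm(10, 0, 0.01), base[2, ] + rnorm(10, 0, 0.01))
  cl <- unname(cutree(ward_cluster(X), k = 2))
  expect_equal(cl[1], cl[2])
  expect_equal(cl[3], cl[4])
  expect_true(cl[1] != cl[3])
  expect_error(ward_cluster(matrix(1, 1, 3)), "at least 2")
})
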