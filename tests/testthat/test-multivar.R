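test_that("Bray-Curtis matches hand-evaluated cases", {
  m <- as_abund(cbind(a = c(1, 2), b = c(2, 1), c = c(1, 2),
                      d = c(0, 0), e = c(0, 0)))
  d <- as.matrix(bray_curtis(m))
  expect_equal(d["a", "b"], 1 / 3)     # (|1-2|+|2-1|) / (3+3)
  expect_equal(d["a", "c"], 0)         # identical samples
  expect_equal(d["a", "d"], 1)         # disjoint support
  expect_equal(d["d", "e"], 0)         # all-zero pair defined as 0
  expect_true(all(d >= 0 & d <= 1))
  expect_error(bray_curtis(as_abund(matrix(c(-1, 1), 1))), "negative")
})

test_that("Jaccard matches set arithmetic on presence/absence", {
  m <- as_abund(cbind(s1 = c(1, 5, 2, 0), s2 = c(0, 3, 9, 4),
                      s3 = c(1, 5, 2, 0), s4 = c(0, 0, 0, 7)))
  d <- as.matrix(jaccard(m))
  expect_equal(d["s1", "s2"], 0.5)     # {A,B,C} vs {B,C,D}: 1 - 2/4
  expect_equal(d["s1", "s3"], 0)       # identical presence sets
  expect_equal(d["s1", "s4"], 1)       # disjoint sets
})

test_that("ANOSIM reaches its extremes on constructed distance structure", {
  # two groups, all between-distances larger than all within-distances
  m <- matrix(0, 6, 6)
  m[lower.tri(m)] <- 0.2
  groups <- rep(c("A", "B"), each = 3)
  between <- outer(groups, groups, "!=")
  m[lower.tri(m) & between] <- 0.9
  d <- as.dist(m)
  res <- anosim_test(d, groups, permutations = 999)
  expect_equal(res$statistic, 1)
  # R is invariant under strictly monotone transforms (rank-based)
  res2 <- anosim_test(as.dist(m^3 + 0.01), groups, permutations = 999)
  expect_equal(res2$statistic, res$statistic)
})

test_that("ANOSIM R near zero for structureless distances", {
  set.seed(99)
  vals <- replicate(30, {
    x <- as_abund(matrix(runif(8 * 10), 8))
    anosim_test(bray_curtis(x), rep(c("A", "B"), each = 5),
                permutations = 99)$statistic
  })
  expect_lt(abs(mean(vals)), 0.1)
})

test_that("ANOSIM exact p equals full-relabelling enumeration", {
  set.seed(7)
  designs <- list(c(2, 2), c(2, 3), c(3, 3), c(3, 4), c(4, 4), c(2, 6))
  for (sizes in designs) {
    n <- sum(sizes)
    x <- as_abund(matrix(rexp(6 * n), 6))
    d <- bray_curtis(x)
    groups <- rep(c("A", "B"), sizes)
    res <- anosim_test(d, groups, permutations = 9999)
    expect_true(res$exact)
    expect_equal(res$p_value, oracle_anosim_exact_p(d, groups),
                 tolerance = 1e-12)
    expect_equal(res$statistic, oracle_anosim_r(d, groups),
                 tolerance = 1e-12)
  }
})

test_that("ANOSIM statistic agrees with the reference ecology implementation", {
  skip_if_not_installed("vegan")
  set.seed(21)
  x <- as_abund(matrix(rpois(12 * 9, 20), 12))
  groups <- rep(c("A", "B", "C"), each = 3)
  d <- bray_curtis(x)
  ours <- anosim_test(d, groups, permutations = 99)
  ref <- vegan::anosim(d, grouping = groups, permutations = 99)
  expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-12)
})

test_that("ANOSIM guards its preconditions", {
  d <- dist(matrix(runif(12), 4))
  expect_error(anosim_test(d, c("A", "A", "A", "B"), 99), "singleton")
  expect_error(anosim_test(d, rep("A", 4), 99), "2 groups")
  expect_warning(
    anosim_test(as.dist(matrix(1, 4, 4)), c("A", "A", "B", "B"), 99),
    "equal")
})

test_that("group-mean padding balances the design without moving group means", {
  m <- as_abund(matrix(rpois(5 * 8, 10), 5))
  groups <- rep(c("A", "B"), c(5, 3))
  bal <- balance_groups(m, groups)
  expect_equal(table(bal$groups)[["A"]], 5)
  expect_equal(table(bal$groups)[["B"]], 5)
  expect_equal(sum(bal$padded), 2)
  b_mean <- rowMeans(m[, groups == "B"])
  for (col in which(bal$padded)) {
    expect_equal(unname(bal$matrix[, col]), unname(b_mean))
  }
  expect_equal(rowMeans(bal$matrix[, bal$groups == "B"]), b_mean)
  # already balanced: identity
  bal2 <- balance_groups(m[, 1:6], rep(c("A", "B"), each = 3))
  expect_identical(bal2$matrix, m[, 1:6])
  # singleton group: padding replicates the single sample
  bal3 <- balance_groups(m[, 1:4], c("A", "A", "A", "B"))
  pad_cols <- bal3$matrix[, bal3$padded, drop = FALSE]
  expect_true(all(pad_cols == m[, 4]))
})

test_that("SIMPER contributions decompose Bray-Curtis and sum to 100 percent", {
  # symmetric 2-taxon toy: each taxon carries half the dissimilarity
  toy <- as_abund(cbind(g1 = c(10, 0), g2 = c(0, 10)))
  res <- simper_analysis(toy, c("A", "B"))
  expect_equal(res[[1]]$percent, c(50, 50))
  # single-taxon community: it explains everything
  one <- as_abund(matrix(c(3, 8), 1, dimnames = list("t1", c("x", "y"))))
  expect_equal(simper_analysis(one, c("A", "B"))[[1]]$percent, 100)
  # per-pair contributions sum to the Bray-Curtis dissimilarity
  set.seed(5)
  m <- as_abund(matrix(rexp(6 * 4), 6))
  groups <- rep(c("A", "B"), each = 2)
  res <- simper_analysis(m, groups)
  total_contrib <- sum(res[[1]]$average)
  bc <- as.matrix(bray_curtis(m))
  between <- mean(c(bc[3, 1], bc[3, 2], bc[4, 1], bc[4, 2]))
  expect_equal(total_contrib, between)
  expect_equal(sum(res[[1]]$percent), 100, tolerance = 1e-9)
  expect_equal(res[[1]]$cumulative[nrow(res[[1]])], 100, tolerance = 1e-9)
})

test_that("SIMPER agrees with the reference ecology implementation", {
  skip_if_not_installed("vegan")
  set.seed(31)
  m <- as_abund(matrix(rpois(7 * 8, 15), 7))
  groups <- rep(c("A", "B"), each = 4)
  ours <- simper_analysis(m, groups)[[1]]
  ref <- summary(vegan::simper(t(m), groups, permutations = 0))[[1]]
  expect_equal(ours$average[match(rownames(ref), ours$taxon)],
               unname(ref$average), tolerance = 1e-10)
})

test_that("nMDS recovers embeddable geometry and handles duplicates", {
  set.seed(13)
  pts <- matrix(rnorm(16), 8, 2)
  d <- dist(pts)
  res <- nmds(d, restarts = 5, seed = 1)
  expect_lt(res$stress, 1e-3)
  # duplicated samples land near-coincident
  pts2 <- rbind(pts, pts[1, ])
  res2 <- nmds(dist(pts2), restarts = 5, seed = 1)
  dup <- sqrt(sum((res2$points[9, ] - res2$points[1, ])^2))
  spread <- max(dist(res2$points))
  expect_lt(dup, 0.05 * spread)
})

test_that("nMDS stress matches an independent gradient-free minimization", {
  diss <- as.dist(matrix(c(0, 1, 2, 3,
                           1, 0, 4, 2.5,
                           2, 4, 0, 1.5,
                           3, 2.5, 1.5, 0), 4, byrow = TRUE))
  res <- nmds(diss, restarts = 20, seed = 3)
  # the reported stress is exactly stress-1 of the returned configuration
  expect_equal(res$stress, oracle_stress1(res$points, diss),
               tolerance = 1e-4)
  # and no independently found configuration does meaningfully better
  set.seed(17)
  best_oracle <- Inf
  for (r in 1:30) {
    start <- as.vector(matrix(rnorm(8), 4, 2))
    opt <- optim(start, function(v) oracle_stress1(matrix(v, 4, 2), diss),
                 method = "Nelder-Mead",
                 control = list(maxit = 2000, reltol = 1e-10))
    best_oracle <- min(best_oracle, opt$value)
  }
  expect_lt(res$stress, best_oracle + 1e-3)
})
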