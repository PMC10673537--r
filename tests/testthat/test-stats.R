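test_that("Mann-Whitney exact branch matches full enumeration by hand", {
  # a = {1,2,3}, b = {4,5,6}: U = 0; of the C(6,3) = 20 equally likely
  # assignments only U = 0 and U = 9 are as extreme, so p = 2/20
  r <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 0.1)
  expect_equal(r$method, "exact enumeration")

  # identical samples: maximal p
  r2 <- mann_whitney(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r2$p_value, 1, tolerance = 1e-12)
})

test_that("Mann-Whitney exact p agrees with the reference implementation", {
  set.seed(31)
  for (i in 1:15) {
    # continuous draws: ties would push wilcox.test off its exact branch
    a <- rnorm(sample(3:7, 1))
    b <- rnorm(sample(3:7, 1))
    ours <- mann_whitney(a, b, exact = TRUE)
    ref <- wilcox.test(a, b, exact = TRUE, correct = FALSE)
    # wilcox.test W counts pairs where a > b; same statistic
    expect_equal(ours$statistic, unname(ref$statistic))
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-10)
  }
  # with ties the enumeration is still a valid permutation test; check a
  # hand-countable tied case: a = {1,2}, b = {2,3}
  r <- mann_whitney(c(1, 2), c(2, 3), exact = TRUE)
  expect_equal(r$statistic, 0.5)  # one loss, one tie
  # enumerating the C(4,2)=6 splits of {1,2,2,3} gives
  # U in {0.5, 0.5, 2, 2, 3.5, 3.5}; lower tail 2/6, doubled
  expect_equal(r$p_value, 2 / 3, tolerance = 1e-10)
})

test_that("exact and normal-approximation branches agree at n = 8 per group", {
  set.seed(13)
  for (i in 1:12) {
    a <- rnorm(8)
    b <- rnorm(8, mean = sample(c(0, 0.5, 1), 1))
    pe <- mann_whitney(a, b, exact = TRUE)$p_value
    pn <- mann_whitney(a, b, exact = FALSE)$p_value
    expect_lte(abs(pe - pn), 0.02)
  }
})

test_that("Mann-Whitney validates its inputs", {
  expect_error(mann_whitney(numeric(0), 1:3), "non-empty")
  expect_error(mann_whitney(c(1, NA), 1:3), "NA")
})

test_that("Kruskal-Wallis matches a first-principles H and handles ties", {
  r <- kruskal_wallis(list(c(1, 2, 3), c(1, 2, 3), c(1, 2, 3)))
  expect_equal(r$statistic, 0, tolerance = 1e-12)
  expect_equal(r$p_value, 1, tolerance = 1e-12)

  g <- list(c(1, 2), c(3, 4))
  expect_equal(kruskal_wallis(g)$statistic, oracle_kw_h(g), tolerance = 1e-10)

  tied <- list(c(1, 1, 2), c(2, 3, 3), c(4, 4, 5))
  expect_equal(kruskal_wallis(tied)$statistic, oracle_kw_h(tied),
               tolerance = 1e-10)

  expect_error(kruskal_wallis(list(1:3)), "2 groups")
  expect_error(kruskal_wallis(list(1:3, numeric(0))), "non-empty")
})

test_that("Kruskal-Wallis separates samples drawn from the three class
           distributions", {
  set.seed(17)
  g <- list(C = pmin(pmax(rnorm(50, 16.34, 5.3), 2.3), 30),
            D = pmin(pmax(rnorm(50, 45.39, 4.5), 33.75), 67.5),
            E = pmin(pmax(rnorm(50, 94.09, 5.5), 80), 135))
  expect_lt(kruskal_wallis(g)$p_value, 0.001)
})

test_that("two-group Kruskal-Wallis is monotonically tied to Mann-Whitney", {
  # both are rank statistics on the same basis; with 2 groups
  # H = z^2 up to the continuity correction, so orderings must agree
  set.seed(19)
  cases <- lapply(1:8, function(i) {
    list(a = rnorm(20), b = rnorm(20, mean = runif(1, 0, 1.5)))
  })
  p_kw <- vapply(cases, function(cs) {
    kruskal_wallis(list(cs$a, cs$b))$p_value
  }, numeric(1))
  p_mw <- vapply(cases, function(cs) {
    mann_whitney(cs$a, cs$b)$p_value
  }, numeric(1))
  expect_equal(order(p_kw), order(p_mw))
})

test_that("Spearman rho matches the rank-difference formula", {
  expect_equal(spearman_rho(1:6, (1:6)^3)$statistic, 1)
  expect_equal(spearman_rho(1:6, -(1:6)^3)$statistic, -1)
  r <- spearman_rho(c(1, 2, 3, 4), c(2, 1, 4, 3))
  expect_equal(r$statistic, 0.6)
  expect_equal(r$statistic, oracle_spearman(c(1, 2, 3, 4), c(2, 1, 4, 3)))
  expect_error(spearman_rho(1:4, 1:5), "equal length")
})

test_that("Spearman rho is invariant under strictly monotone transforms and
           accepts class letters as ordinals", {
  set.seed(29)
  x <- rnorm(40)
  y <- x + rnorm(40, sd = 0.8)
  base <- spearman_rho(x, y)$statistic
  expect_equal(spearman_rho(exp(x), y)$statistic, base)
  expect_equal(spearman_rho(x, y^3)$statistic, base)

  cls <- c("A", "B", "C", "D", "E")
  r <- spearman_rho(cls, c(0, 1, 15, 45, 90))
  expect_equal(r$statistic, 1)
  # ties get average ranks: two 0-MME visits against distinct class letters
  tied <- spearman_rho(cls, c(0, 0, 15, 45, 90))
  expect_equal(tied$statistic,
               suppressWarnings(cor(1:5, rank(c(0, 0, 15, 45, 90)))),
               tolerance = 1e-10)
  rv <- spearman_rho(cls, c(0, 0, 15, 45, 90), verbose = TRUE)
  expect_true(!is.null(rv$tau))
})

test_that("Shapiro-Wilk rejects uniform data and guards degenerate input", {
  expect_error(shapiro_wilk(c(1, 2)), "at least 3")
  expect_error(shapiro_wilk(rep(1, 10)), "constant")
  # power against U(0,1) at n = 50 is ~0.76 (measured by direct
  # simulation); assert comfortably above a coin flip
  set.seed(37)
  rejections <- mean(vapply(1:100, function(i) {
    shapiro_wilk(runif(50))$p_value < 0.05
  }, logical(1)))
  expect_gte(rejections, 0.65)
})

test_that("the cohort validation battery runs and reports sane p-values", {
  cohort <- generate_cohort(seed = 3)
  aug <- augment_cohort(cohort)
  res <- validate_cohort(aug)
  expect_true(all(res$p_value >= 0 & res$p_value <= 1))
  kw <- res$p_value[grepl("Kruskal", res$test_name)]
  expect_lt(kw, 0.001)
  mw <- res$p_value[grepl("narcotic use", res$test_name)]
  expect_lt(mw, 0.001)
  rho_row <- res[grepl("class vs MME", res$test_name), ]
  expect_gt(rho_row$statistic, 0.5)
  expect_true(any(grepl("gender", res$test_name)))
})
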