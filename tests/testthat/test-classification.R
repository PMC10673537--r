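test_that("operational classifier reproduces the A-E scheme", {
  cl <- classify_visit(c(0, 0, 20, 45, 94), c(FALSE, TRUE, TRUE, TRUE, TRUE),
                       c(FALSE, FALSE, TRUE, TRUE, TRUE))
  expect_equal(as.character(cl), c("A", "B", "C", "D", "E"))
  # boundary inclusivity: 30 is still C, 80 is already E
  expect_equal(as.character(classify_visit(30, TRUE, TRUE)), "C")
  expect_equal(as.character(classify_visit(80, TRUE, TRUE)), "E")
})

test_that("inconsistent visit flags are rejected", {
  expect_error(classify_visit(-1, TRUE, TRUE), "non-negative")
  expect_error(classify_visit(0, TRUE, TRUE), "Inconsistent")
  expect_error(classify_visit(10, FALSE, FALSE), "Inconsistent")
  expect_error(classify_visit(10, FALSE, TRUE), "implies")
})

test_that("classifier partitions the MME axis with no gaps and is monotone", {
  mme <- c(seq(0.01, 150, by = 0.07), 29.999, 30, 30.001, 79.999, 80, 80.001)
  cl <- classify_visit(mme, TRUE, TRUE)
  # every positive dose lands in exactly one narcotic class
  expect_true(all(as.character(cl) %in% c("C", "D", "E")))
  # monotone: sorted MME gives non-decreasing classes
  ord <- order(mme)
  expect_true(!is.unsorted(cl[ord]))
  # interval edges
  expect_equal(as.character(classify_visit(c(30, 30.001, 79.999, 80), TRUE, TRUE)),
               c("C", "D", "D", "E"))
})

test_that("DIPA ratings concatenate and round-trip", {
  expect_equal(make_dipa_rating("C", 1), "C1")
  expect_equal(make_dipa_rating("A", 0), "A0")
  expect_equal(make_dipa_rating("E", 2), "E2")
  expect_error(make_dipa_rating("C", 3), "ipa")
  expect_error(make_dipa_rating("F", 1), "class")

  codes <- make_dipa_rating(c("A", "B", "C", "D", "E"), c(0, 1, 2, 0, 1))
  parsed <- parse_dipa_rating(codes)
  expect_equal(make_dipa_rating(parsed$med_class, parsed$ipa), codes)
  expect_error(parse_dipa_rating("Z9"), "Not a DIPA rating")
})

test_that("two point masses recover the brute-force 2-means solution", {
  x <- c(10, 10, 10, 100, 100, 100)
  res <- derive_boundaries(x, k = 2)
  expect_equal(res$clustering$centers, oracle_kmeans2(x))
  expect_equal(res$clustering$extremes$min, c(10, 100))
  expect_equal(res$clustering$extremes$max, c(10, 100))

  # a harder mixed case, still checked against exhaustive enumeration
  y <- c(1.2, 2.5, 3.1, 8.9, 9.4, 11.0, 12.3)
  expect_equal(derive_boundaries(y, k = 2)$clustering$centers,
               oracle_kmeans2(y), tolerance = 1e-8)
})

test_that("k = 1 degenerates to the sample mean and range", {
  res <- derive_boundaries(c(5, 6, 7), k = 1)
  expect_equal(res$clustering$centers, 6)
  expect_equal(res$clustering$extremes$min, 5)
  expect_equal(res$clustering$extremes$max, 7)
  expect_null(res$boundaries)
})

test_that("degenerate and invalid clustering inputs error", {
  expect_error(derive_boundaries(numeric(0)), "non-empty")
  expect_error(derive_boundaries(c(-1, 5)), "positive")
  expect_error(derive_boundaries(c(5, 5, 5), k = 2), "Degenerate")
})

test_that("cluster-derived boundaries are deterministic and order-invariant", {
  set.seed(7)
  x <- c(rnorm(60, 16, 5), rnorm(60, 45, 5), rnorm(60, 94, 6))
  x <- x[x > 0]
  a <- derive_boundaries(x, k = 3, seed = 1976)
  b <- derive_boundaries(sample(x), k = 3, seed = 1976)
  expect_equal(a$clustering$centers, b$clustering$centers, tolerance = 1e-9)
  expect_equal(a$boundaries$c_high, b$boundaries$c_high)
  expect_equal(a$boundaries$e_min, b$boundaries$e_min)
  # repeated runs are bitwise-stable given the seed
  expect_identical(a$clustering$centers,
                   derive_boundaries(x, k = 3, seed = 1976)$clustering$centers)
})

test_that("auto-k silhouette search finds three well-separated classes", {
  set.seed(11)
  x <- c(rnorm(80, 16, 3), rnorm(80, 45, 3), rnorm(80, 94, 4))
  x <- x[x > 0]
  res <- derive_boundaries(x, k = "auto")
  expect_equal(res$clustering$k, 3L)
})

test_that("derived boundaries recover generating labels on separated data", {
  set.seed(23)
  n <- 150
  truth <- rep(c("C", "D", "E"), each = n)
  x <- c(pmin(pmax(rnorm(n, 16.34, 5.3), 2.3), 30),
         pmin(pmax(rnorm(n, 45.39, 4.5), 33.75), 67.5),
         pmin(pmax(rnorm(n, 94.09, 5.5), 80), 135))
  res <- derive_boundaries(x, k = 3)
  b <- res$boundaries
  pred <- ifelse(x <= b$c_high, "C", ifelse(x < b$e_min, "D", "E"))
  expect_gte(mean(pred == truth), 0.99)
  expect_equal(b$source, "cluster_derived")
})

test_that("boundaries survive a JSON round trip", {
  b <- operational_boundaries()
  path <- tempfile(fileext = ".json")
  boundaries_to_json(b, path)
  b2 <- boundaries_from_json(path)
  expect_equal(b2$c_high, 30)
  expect_equal(b2$e_min, 80)
  expect_equal(b2$source, "operational_default")
  # classification agrees under the round-tripped boundaries
  mme <- seq(0.5, 120, by = 0.5)
  expect_equal(classify_visit(mme, TRUE, TRUE, b),
               classify_visit(mme, TRUE, TRUE, b2))
})

test_that("usage mismatches are annotated, not reclassified", {
  expect_true(flag_usage_mismatch("C", "consistent"))
  expect_true(flag_usage_mismatch("D", "occasional"))
  expect_false(flag_usage_mismatch("C", "occasional"))
  expect_false(flag_usage_mismatch("D", "consistent"))
  expect_false(flag_usage_mismatch("A", NA))
})
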