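five_cols <- c("manual_workers_pct", "unemployment_pct", "temporary_workers_pct",
               "low_education_pct", "low_education_young_pct")

test_that("rank-1 indicators give variance explained 1 and the common column back", {
  set.seed(1)
  base <- rnorm(30, 20, 5)
  X <- matrix(rep(base, 5), ncol = 5, dimnames = list(NULL, five_cols))
  X <- sweep(X, 2, c(0, 5, 10, 15, 20), "+")  # per-column shifts only
  idx <- compute_index(X)
  expect_equal(idx$variance_explained, 1.0, tolerance = 1e-12)
  expect_equal(unname(idx$x), as.vector(scale(base)), tolerance = 1e-10)
})

test_that("the index is standardized, deprivation-oriented and scale-invariant", {
  set.seed(2)
  lat <- generate_lattice(10, 10)
  X <- generate_indicators(lat$tracts, lat$graph, seed = 2)
  idx <- compute_index(X)
  expect_lt(abs(mean(idx$x)), 1e-8)
  expect_lt(abs(sd(idx$x) - 1), 1e-8)
  expect_gte(cor(idx$x, X[, "unemployment_pct"]), 0)
  # arbitrary affine rescaling of the raw indicators leaves the score unchanged
  X2 <- sweep(sweep(X, 2, c(2, 0.5, 10, 1, 3), "*"), 2, c(1, -4, 0, 7, 2), "+")
  idx2 <- compute_index(X2)
  expect_equal(idx2$x, idx$x, tolerance = 1e-10)
})

test_that("permuting tracts permutes scores and leaves percentiles unchanged", {
  set.seed(3)
  lat <- generate_lattice(6, 6)
  X <- generate_indicators(lat$tracts, lat$graph, seed = 3)
  idx <- compute_index(X)
  perm <- sample(nrow(X))
  idxp <- compute_index(X[perm, ])
  expect_equal(unname(idxp$x), unname(idx$x[perm]), tolerance = 1e-10)
  expect_equal(idxp$q5, idx$q5, tolerance = 1e-10)
  expect_equal(idxp$q95, idx$q95, tolerance = 1e-10)
})

test_that("degenerate indicator input is rejected with informative errors", {
  X <- matrix(rnorm(20), 4, 5, dimnames = list(NULL, five_cols))
  expect_error(compute_index(X[1:2, ]), "3 tracts")
  X[, 3] <- 7
  expect_error(compute_index(X), "temporary_workers_pct")
  X[, 3] <- NA
  expect_error(compute_index(X), "missing")
})

test_that("septile assignment splits ranks into near-equal ordered groups", {
  # 14 distinct scores: exactly two per septile
  s14 <- assign_septiles(rnorm(14))
  expect_equal(as.integer(table(s14)), rep(2L, 7))
  # 15 scores: sizes differ by at most one
  s15 <- assign_septiles(rnorm(15))
  expect_lte(diff(range(table(s15))), 1)
  # monotone scores map to their own rank
  expect_equal(assign_septiles(1:7), 1:7)
  # most deprived (largest score) always gets label 7
  x <- rnorm(21)
  expect_equal(assign_septiles(x)[which.max(x)], 7L)
  expect_error(assign_septiles(rnorm(6)), "at least 7")
})

test_that("septile labels depend on ranks only and break ties by input order", {
  x <- c(5, 1, 1, 3, 2, 9, 7)
  expect_equal(assign_septiles(x), assign_septiles(rank(x, ties.method = "first")))
  expect_equal(assign_septiles(c(1, 1, 1, 1, 1, 1, 1)), 1:7)
})

test_that("percentile span uses linear interpolation of order statistics", {
  sp <- percentile_span(c(0, 1))
  expect_equal(unname(sp), c(0.05, 0.95))
  # standard normal: q95 - q5 = 2 * 1.6449
  set.seed(4)
  z <- rnorm(10000)
  expect_equal(unname(diff(percentile_span(z))), 2 * qnorm(0.95), tolerance = 0.05)
  # affine equivariance
  sp1 <- percentile_span(z)
  sp2 <- percentile_span(3 * z + 2)
  expect_equal(unname(sp2), unname(3 * sp1 + 2), tolerance = 1e-12)
  expect_error(percentile_span(rep(1, 10)), "constant")
})
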