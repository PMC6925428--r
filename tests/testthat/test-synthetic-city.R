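test_that("zero-noise indicators with equal loadings are identical up to a shift", {
  lat <- generate_lattice(4, 4)
  ind <- generate_indicators(lat$tracts, lat$graph, loadings = rep(1, 5),
                             noise_sd = 0, seed = 5)
  centred <- sweep(ind, 2, colMeans(ind))
  for (j in 2:5) expect_equal(centred[, j], centred[, 1], ignore_attr = TRUE)
})

test_that("one dominant latent factor drives most indicator variance", {
  lat <- generate_lattice(20, 20)
  ind <- generate_indicators(lat$tracts, lat$graph, loadings = rep(1, 5),
                             noise_sd = 0.1, seed = 21)
  pc1_share <- prcomp(ind, scale. = TRUE)$sdev[1]^2 / 5
  expect_gt(pc1_share, 0.75)
})

test_that("indicator generation is deterministic under a fixed seed and validates noise", {
  lat <- generate_lattice(3, 3)
  a <- generate_indicators(lat$tracts, lat$graph, seed = 3)
  b <- generate_indicators(lat$tracts, lat$graph, seed = 3)
  expect_identical(a, b)
  expect_error(generate_indicators(lat$tracts, lat$graph, noise_sd = -1), "noise_sd")
  expect_error(generate_indicators(lat$tracts, lat$graph, loadings = 1:3), "5 loadings")
})

make_truth <- function(n, alpha, beta = rep(0, length(alpha)), seed = 1) {
  ground_truth(alpha = alpha, beta = beta, tau_u = 1, tau_v = 1,
               u = rep(0, n), v = rep(0, n), seed = seed)
}

test_that("simulated counts obey the Poisson cell-mean structure", {
  lat <- generate_lattice(2, 2)
  n <- 4
  truth <- make_truth(n, alpha = log(0.05))
  # empty population cells never produce births
  N0 <- matrix(c(0, 1000, 1000, 1000), n, 1)
  cc <- simulate_counts(lat$tracts, lat$graph, rep(0, n), truth, N0, seed = 2)
  expect_equal(cc$births[cc$women == 0], 0L)

  # mean count N * exp(alpha) = 50, checked over replicates
  set.seed(4)
  N <- matrix(1000, n, 1)
  reps <- replicate(1000, sum(simulate_counts(lat$tracts, lat$graph, rep(0, n),
                                              truth, N)$births))
  # total over 4 cells: mean 200, var 200
  se <- sqrt(200 / 1000)
  expect_lt(abs(mean(reps) / 4 - 50), 3 * se)

  # doubling N doubles the expected count (checked in expectation)
  set.seed(5)
  reps2 <- replicate(1000, sum(simulate_counts(lat$tracts, lat$graph, rep(0, n),
                                               truth, 2 * N)$births))
  expect_equal(mean(reps2) / mean(reps), 2, tolerance = 0.05)
})

test_that("count simulation rejects overflowing rates and bad inputs", {
  lat <- generate_lattice(2, 2)
  truth <- make_truth(4, alpha = 800)
  expect_error(simulate_counts(lat$tracts, lat$graph, rep(0, 4), truth,
                               matrix(1, 4, 1)), "rescale")
  truth2 <- make_truth(4, alpha = log(0.05))
  expect_error(simulate_counts(lat$tracts, lat$graph, rep(0, 4), truth2,
                               matrix(-1, 4, 1)), "non-negative")
  expect_error(simulate_counts(lat$tracts, lat$graph, c(0, Inf, 0, 0), truth2,
                               matrix(1, 4, 1)), "finite")
})

test_that("ground truth validates its invariants", {
  expect_error(ground_truth(0, c(0, 1), 1, 1, c(0, 0), c(0, 0), 1), "per period")
  expect_error(ground_truth(0, 0, -1, 1, c(0, 0), c(0, 0), 1), "precisions")
  expect_error(ground_truth(0, 0, 1, 1, c(1, 1), c(0, 0), 1), "sum to zero")
})

test_that("a full synthetic city is reproducible and internally consistent", {
  city <- simulate_city(n_rows = 5, n_cols = 5, seed = 17)
  city2 <- simulate_city(n_rows = 5, n_cols = 5, seed = 17)
  expect_identical(city$counts, city2$counts)
  expect_identical(city$indicators, city2$indicators)

  # the 15-49 rows equal the sum of the four narrow age groups
  broad <- city$counts[city$counts$age_group == "15-49", ]
  narrow <- city$counts[city$counts$age_group != "15-49", ]
  agg <- aggregate(cbind(births, women) ~ tract_id + period + nationality,
                   data = narrow, FUN = sum)
  m <- merge(broad, agg, by = c("tract_id", "period", "nationality"))
  expect_equal(m$births.x, m$births.y)
  expect_equal(m$women.x, m$women.y)

  # true slopes encode the requested RR contrast on the realized index span
  tr <- city$truth[["25-34:Spanish"]]
  expect_equal(exp(tr$beta * city$span), c(1.0, 1.5, 2.0), tolerance = 1e-12)
})

test_that("city files round-trip through the interchange formats", {
  city <- simulate_city(n_rows = 4, n_cols = 4, seed = 23, stratified = FALSE)
  dir <- withr::local_tempdir()
  paths <- write_city(city, dir)
  expect_true(all(file.exists(paths)))
  cc <- read_counts(paths[["counts"]])
  expect_equal(nrow(cc), nrow(city$counts))
  expect_equal(sum(cc$births), sum(city$counts$births))
  ind <- read_indicators(paths[["indicators"]])
  expect_equal(unname(ind), unname(city$indicators[, colnames(ind)]),
               tolerance = 1e-12)
  g <- read_gal(paths[["adjacency"]])
  expect_equal(g$nb, city$graph$nb)
  truth <- jsonlite::read_json(paths[["truth"]])
  expect_equal(truth$overall$tau_u, 10)
})
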