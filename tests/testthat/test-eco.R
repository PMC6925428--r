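test_that("relative risk obeys its closed forms on known coefficient draws", {
  # null effect: RR exactly 1, no flags
  d0 <- fake_eco_draws(b1 = rep(0, 100), span = 2)
  rr0 <- relative_risk(d0)
  expect_equal(rr0$rr, rep(1, 3))
  expect_false(attr(rr0, "sig_12"))
  expect_false(attr(rr0, "sig_23"))

  # constant slope log(2)/span doubles the rate across the contrast
  span <- 3.1
  d2 <- fake_eco_draws(b1 = rep(log(2) / span, 50), span = span)
  expect_equal(relative_risk(d2)$rr, rep(2, 3))

  # lognormal closed form at 1e5 draws
  set.seed(1)
  mu <- 0.12; sig <- 0.05; span <- 3.3
  dn <- fake_eco_draws(b1 = rnorm(1e5, mu, sig), span = span)
  rrn <- relative_risk(dn)
  expect_equal(rrn$rr[1], exp(mu * span), tolerance = 0.01)
  expect_equal(rrn$lo95[1], exp((mu - 1.96 * sig) * span), tolerance = 0.01)
  expect_equal(rrn$hi95[1], exp((mu + 1.96 * sig) * span), tolerance = 0.01)
})

test_that("relative risk is monotone in the slope draws", {
  set.seed(2)
  b <- rnorm(500, 0.1, 0.2)
  r1 <- relative_risk(fake_eco_draws(b1 = b, span = 2))
  r2 <- relative_risk(fake_eco_draws(b1 = b + 0.3, span = 2))
  expect_true(all(r2$rr > r1$rr))
  expect_true(all(r2$lo95 > r1$lo95))
  expect_true(all(r2$hi95 > r1$hi95))
})

test_that("period-change flags read the interaction posteriors", {
  set.seed(3)
  d <- fake_eco_draws(b1 = rnorm(2000, 0, 0.01),
                      delta2 = rnorm(2000, 0.5, 0.05),
                      delta3 = rnorm(2000, 0.5, 0.05), span = 3)
  rr <- relative_risk(d)
  expect_true(attr(rr, "sig_12"))    # delta2 clearly nonzero
  expect_false(attr(rr, "sig_23"))   # delta3 - delta2 centred at 0
  # the change rule is invariant to reparameterizing via beta_p differences:
  # delta3 - delta2 = beta_3 - beta_2 by construction
  co <- fertimap:::pool_coef_draws(d)
  beta2 <- co$b1 + co$delta[, 2]; beta3 <- co$b1 + co$delta[, 3]
  expect_equal(co$delta[, 3] - co$delta[, 2], beta3 - beta2)
})

test_that("relative risk validates the percentile span", {
  d <- fake_eco_draws(b1 = rep(0, 10))
  expect_error(relative_risk(d, span = c(2, 1)), "exceed")
  expect_error(relative_risk(d, span = 1), "pair")
})

test_that("the regression recovers a known deprivation effect", {
  # covariate drawn independently of the fields, so the slope is clean:
  # this isolates the fitting machinery from spatial confounding
  set.seed(41)
  lat <- generate_lattice(8, 8)
  n <- lat$graph$n_tracts
  x <- as.vector(scale(rnorm(n)))
  names(x) <- lat$tracts$tract_id
  span <- unname(diff(percentile_span(x)))
  truth_rr <- c(1.0, 1.5, 2.0)
  truth <- ground_truth(alpha = rep(log(0.04), 3), beta = log(truth_rr) / span,
                        tau_u = 10, tau_v = 100,
                        u = sample_icar_field(lat$graph, 10),
                        v = rnorm(n, 0, 0.1), seed = 41)
  cc <- simulate_counts(lat$tracts, lat$graph, x, truth,
                        matrix(500, n, 3))
  fit <- suppressWarnings(fit_ecoregression(
    cc, x, lat$graph, mcmc_control(2, 1500, 1000, 1, seed = 7)))
  rr <- relative_risk(fit)
  expect_true(all(rr$lo95 <= truth_rr & truth_rr <= rr$hi95))
  expect_true(all(rr$lo95 <= rr$rr & rr$rr <= rr$hi95))
  expect_true(all(diff(rr$rr) > 0))
})

test_that("input validation catches missing periods and constant exposure", {
  city <- simulate_city(n_rows = 4, n_cols = 4, seed = 53, stratified = FALSE)
  cc <- city$counts[city$counts$period != "P2", ]
  expect_error(
    suppressWarnings(fit_ecoregression(cc, city$index, city$graph, quick_mcmc(1))),
    "period")
  expect_error(
    fit_ecoregression(city$counts, rep(1, 16), city$graph, quick_mcmc(1)),
    "constant")
})

test_that("consistent tract relabelling leaves the posterior unchanged", {
  city <- simulate_city(n_rows = 5, n_cols = 5, seed = 54, stratified = FALSE)
  mc <- mcmc_control(2, 800, 800, 1, seed = 55)
  fit <- suppressWarnings(fit_ecoregression(city$counts, city$index, city$graph, mc))

  # shuffling the row order of the counts table changes nothing
  set.seed(99)
  cc_shuf <- city$counts[sample(nrow(city$counts)), ]
  fit_shuf <- suppressWarnings(fit_ecoregression(cc_shuf, city$index,
                                                 city$graph, mc))
  expect_identical(fit$chains, fit_shuf$chains)

  # renaming every tract id consistently across all inputs changes nothing
  map <- setNames(paste0("zone-", seq_len(city$graph$n_tracts)),
                  city$graph$tract_id)
  g2 <- tract_graph(unname(map), graph_edges(city$graph))
  cc2 <- city$counts
  cc2$tract_id <- unname(map[cc2$tract_id])
  x2 <- setNames(unname(city$index$x), unname(map[names(city$index$x)]))
  fit2 <- suppressWarnings(fit_ecoregression(cc2, x2, g2, mc))
  expect_identical(fit$chains, fit2$chains)
})

test_that("the stratified analysis has the reporting shape and flags sparsity", {
  city <- simulate_city(n_rows = 4, n_cols = 4, seed = 56)
  res <- suppressWarnings(run_stratified_analysis(
    city$counts, city$index, city$graph, quick_mcmc(57)))
  expect_equal(nrow(res), 5 * 2 * 3)  # age groups x nationalities x periods
  expect_setequal(unique(res$age_group),
                  c("15-19", "20-24", "25-34", "35-49", "15-49"))
  expect_setequal(unique(res$nationality), c("Spanish", "LIC"))
  expect_true(all(res$rr > 0))
  expect_true(all(res$lo95 <= res$rr & res$rr <= res$hi95))
  wide <- rr_wide(res)
  expect_equal(nrow(wide), 10L)
  expect_true(all(c("RR_P1", "RR_P2", "RR_P3") %in% names(wide)))
})

test_that("a stratum with no woman-years in a period is an error naming it", {
  city <- simulate_city(n_rows = 4, n_cols = 4, seed = 58)
  cc <- city$counts
  kill <- cc$age_group == "15-19" & cc$nationality == "LIC" & cc$period == "P2"
  cc$women[kill] <- 0L
  cc$births[kill] <- 0L
  expect_error(
    suppressWarnings(run_stratified_analysis(cc, city$index, city$graph,
                                             quick_mcmc(59))),
    "15-19 x LIC")
})

test_that("an all-zero-births stratum is fitted but flagged sparse", {
  city <- simulate_city(n_rows = 4, n_cols = 4, seed = 60, stratified = FALSE)
  cc <- city$counts
  cc$births <- 0L
  res <- suppressWarnings(run_stratified_analysis(cc, city$index, city$graph,
                                                  quick_mcmc(61)))
  expect_true(all(res$sparse))
})
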