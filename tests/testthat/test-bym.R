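# small Poisson dataset used by several fits
small_data <- function(seed = 101, n_side = 4, rate = 0.05, women = 400) {
  set.seed(seed)
  lat <- generate_lattice(n_side, n_side)
  n <- lat$graph$n_tracts
  N <- rep(women, n)
  O <- rpois(n, N * rate)
  list(lat = lat, O = O, N = N)
}

test_that("model construction validates counts against the graph", {
  d <- small_data()
  expect_s3_class(bym_model(d$O, d$N, d$lat$graph), "bym_model")
  expect_error(bym_model(d$O[-1], d$N, d$lat$graph), "per tract")
  expect_error(bym_model(-d$O, d$N, d$lat$graph), "non-negative")
  expect_error(bym_model(d$O, rep(0, 16), d$lat$graph), "positive woman-years")
  O2 <- d$O; N2 <- d$N; N2[1] <- 0; O2[1] <- 3L
  expect_error(bym_model(O2, N2, d$lat$graph), "zero woman-years")
})

test_that("the precision Gibbs conditional matches brute-force density evaluation", {
  # independent oracle: numerically integrate the unnormalized conditional
  # tau^(a_u + (n-1)/2 - 1) exp(-tau (b_u + ss/2)) on a grid and compare the
  # posterior mean with the closed-form Gamma mean the sampler uses
  set.seed(5)
  g <- random_connected_graph(5)
  u <- rnorm(5); u <- u - mean(u)
  pri <- bym_priors()
  ss <- sum((function(e) (u[e[, 1]] - u[e[, 2]])^2)(graph_edges(g)))
  shape <- pri$a_u + (5 - 1) / 2
  rate <- pri$b_u + ss / 2
  grid <- seq(1e-6, shape / rate * 8, length.out = 20000)
  # grid log-density from the ICAR kernel itself (the other code path)
  logd <- vapply(grid, function(tau)
    icar_log_kernel(u, g, tau) + dgamma(tau, pri$a_u, rate = pri$b_u, log = TRUE),
    0)
  w <- exp(logd - max(logd))
  expect_equal(sum(grid * w) / sum(w), shape / rate, tolerance = 1e-3)
})

test_that("with fields disabled the rate posterior matches the Poisson-Gamma closed form", {
  d <- small_data()
  model <- bym_model(d$O, d$N, d$lat$graph)
  fit <- suppressWarnings(
    fit_bym(model, mcmc_control(2, 2500, 1000, 1, seed = 3), fields = "none"))
  lam <- unlist(lapply(fit$chains, function(ch) exp(ch$alpha)))
  # flat prior on alpha implies lambda ~ Gamma(sum O, sum N)
  post_mean <- sum(d$O) / sum(d$N)
  post_var <- sum(d$O) / sum(d$N)^2
  expect_lt(abs(mean(lam) - post_mean), 3 * mcse_mean(lam))
  sq <- (lam - mean(lam))^2
  expect_lt(abs(var(lam) - post_var), 3 * mcse_mean(sq) + 1e-12)
})

test_that("fits are bit-reproducible under a fixed seed", {
  d <- small_data()
  model <- bym_model(d$O, d$N, d$lat$graph)
  f1 <- suppressWarnings(fit_bym(model, quick_mcmc(77)))
  f2 <- suppressWarnings(fit_bym(model, quick_mcmc(77)))
  expect_identical(f1$chains, f2$chains)
})

test_that("retained spatial-field draws always sum to zero", {
  d <- small_data()
  fit <- suppressWarnings(fit_bym(bym_model(d$O, d$N, d$lat$graph), quick_mcmc(13)))
  for (ch in fit$chains)
    expect_lt(max(abs(rowSums(ch$u))), 1e-8)
})

test_that("smoothed rates shrink toward the centre and track data-rich tracts", {
  # one tract with a huge population: likelihood dominates the prior
  set.seed(8)
  lat <- generate_lattice(3, 3)
  N <- c(1e6, rep(500, 8))
  O <- rpois(9, N * 0.05)
  fit <- suppressWarnings(fit_bym(bym_model(O, N, lat$graph),
                                  mcmc_control(2, 1500, 1500, 1, seed = 19)))
  sm <- smoothed_rates(fit)
  crude <- 1000 * O / N
  expect_lt(abs(sm$mean[1] - crude[1]), 0.01 * crude[1])
  expect_lte(var(sm$mean), var(crude))
  expect_true(all(sm$lo95 <= sm$mean & sm$mean <= sm$hi95))
})

test_that("tracts without woman-years are flagged in the smoothed output", {
  set.seed(9)
  lat <- generate_lattice(3, 3)
  N <- c(0, rep(500, 8))
  O <- c(0L, rpois(8, 500 * 0.05))
  fit <- suppressWarnings(fit_bym(bym_model(O, N, lat$graph), quick_mcmc(23)))
  sm <- smoothed_rates(fit)
  expect_true(sm$no_data[1])
  expect_false(any(sm$no_data[-1]))
})

test_that("degenerate draws summarize to a point interval", {
  fake <- structure(list(
    chains = list(list(alpha = rep(log(0.05), 20),
                       u = matrix(0, 20, 2), v = matrix(0, 20, 2),
                       tau_u = rep(1, 20), tau_v = rep(1, 20))),
    model = list(graph = list(tract_id = c("a", "b"), n_tracts = 2L),
                 N = c(10, 10)),
    fields = "bym"), class = c("bym_draws", "mcmc_draws"))
  sm <- smoothed_rates(fake)
  expect_equal(sm$mean, rep(50, 2))
  expect_equal(sm$lo95, sm$hi95)
})

test_that("split R-hat separates mixed from unmixed chains", {
  set.seed(12)
  # same stationary distribution: R-hat near 1
  good <- list(cbind(x = rnorm(10000)), cbind(x = rnorm(10000)))
  expect_lt(gelman_rubin(good)["x"], 1.01)
  # chains centred 10 apart: R-hat far above 1.1
  bad <- list(cbind(x = rnorm(1000, 0)), cbind(x = rnorm(1000, 10)))
  expect_gt(gelman_rubin(bad)["x"], 5)
  # degenerate constant parameter reports 1
  const <- list(cbind(x = rep(2, 100)), cbind(x = rep(2, 100)))
  expect_equal(unname(gelman_rubin(const)["x"]), 1)
  expect_error(gelman_rubin(list(cbind(x = rnorm(100)))), "2 chains")
})

test_that("posterior concentrates on the truth as the population grows", {
  lat <- generate_lattice(2, 2)
  rate <- 0.05
  err <- vapply(c(1e2, 1e4, 1e6), function(Nval) {
    set.seed(42)
    N <- rep(Nval, 4)
    O <- rpois(4, N * rate)
    fit <- suppressWarnings(fit_bym(bym_model(O, N, lat$graph),
                                    mcmc_control(2, 1000, 1000, 1, seed = 6)))
    sm <- smoothed_rates(fit)
    mean(abs(sm$mean - 1000 * rate))
  }, 0)
  expect_lt(err[3], err[1])
  expect_lt(err[3], 1)  # within 1 per 1000 at N = 1e6
})
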