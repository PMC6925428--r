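#' Ground truth for a simulated city
#'
#' Bundles the parameters a synthetic city is generated from, so recovery
#' experiments can compare posteriors against the values that produced the
#' data: per-period log baseline rates `alpha`, per-period deprivation
#' slopes `beta` (per unit of the standardized index), precisions of the
#' spatial (`tau_u`) and heterogeneous (`tau_v`) fields, and the simulated
#' field vectors themselves.
#'
#' @param alpha numeric vector of per-period log baseline rates.
#' @param beta numeric vector, same length, of per-period slopes.
#' @param tau_u,tau_v positive precisions.
#' @param u spatial field (must sum to zero within 1e-8).
#' @param v heterogeneous field, same length as `u`.
#' @param seed integer seed the city was generated from.
#' @return an object of class `ground_truth`.
#' @export
ground_truth <- function(alpha, beta, tau_u, tau_v, u, v, seed) {
  if (length(alpha) != length(beta))
    stop("alpha and beta must have one entry per period")
  if (!is.finite(tau_u) || tau_u <= 0 || !is.finite(tau_v) || tau_v <= 0)
    stop("precisions must be > 0")
  if (length(u) != length(v)) stop("u and v must have equal length")
  if (abs(sum(u)) > 1e-8 * max(1, max(abs(u))))
    stop("spatial field u must sum to zero")
  structure(list(alpha = alpha, beta = beta, tau_u = tau_u, tau_v = tau_v,
                 u = u, v = v, seed = as.integer(seed)),
            class = "ground_truth")
}

#' Generate correlated socioeconomic indicators
#'
#' Emulates the five census indicators behind a deprivation index: one
#' latent deprivation factor per tract — spatially smooth, an ICAR draw
#' plus independent Gaussian noise, standardized to mean 0 / sd 1 — and
#' five observed indicators
#' `indicator_j = mu_j + scale * (loading_j * factor + N(0, noise_sd))`,
#' returned on that raw (percentage-like) scale.
#'
#' @param tracts tracts data.frame (needs `tract_id`).
#' @param graph a connected [tract_graph()] over the same tracts.
#' @param loadings numeric length 5; factor loading per indicator.
#' @param noise_sd non-negative indicator noise sd, on the factor scale.
#' @param seed optional integer seed.
#' @param factor_tau ICAR precision of the latent factor's smooth part.
#' @param factor_noise_sd sd of the factor's unstructured part.
#' @param mu baseline level per indicator (percentage points).
#' @param scale percentage points per factor unit.
#' @return numeric matrix `n_tracts x 5` with the standard MEDEA indicator
#'   column names; the latent factor is attached as attribute `"factor"`.
#' @export
generate_indicators <- function(tracts, graph, loadings = rep(1, 5),
                                noise_sd = 0.1, seed = NULL,
                                factor_tau = 5, factor_noise_sd = 0.5,
                                mu = c(38, 14, 28, 22, 30), scale = 8) {
  if (length(loadings) != 5L) stop("exactly 5 loadings are required")
  if (!is.finite(noise_sd) || noise_sd < 0) stop("noise_sd must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(tracts)
  f <- sample_icar_field(graph, factor_tau) + stats::rnorm(n, 0, factor_noise_sd)
  f <- as.vector(scale(f))  # latent factor on a unit scale
  cols <- c("manual_workers_pct", "unemployment_pct", "temporary_workers_pct",
            "low_education_pct", "low_education_young_pct")
  out <- matrix(NA_real_, n, 5L, dimnames = list(tracts$tract_id, cols))
  for (j in 1:5)
    out[, j] <- mu[j] + scale * (loadings[j] * f + stats::rnorm(n, 0, noise_sd))
  attr(out, "factor") <- f
  out
}

#' Simulate stratified Poisson birth counts
#'
#' Forward-simulates the count model the inference stages fit: for tract i
#' and period p,
#' \deqn{O_{ip} \sim \mathrm{Poisson}\!\big(N_{ip}\,
#'   e^{\alpha_p + \beta_p x_i + u_i + v_i}\big).}
#'
#' @param tracts tracts data.frame (`tract_id`).
#' @param graph the adjacency graph (used only for validation of lengths).
#' @param index per-tract covariate `x` (numeric vector in tract order).
#' @param truth a [ground_truth()].
#' @param population women per tract and period: either an
#'   `n_tracts x n_periods` matrix or a long data.frame with columns
#'   `tract_id`, `period`, `women`.
#' @param seed optional integer seed.
#' @param periods period labels; default `P1..P`.
#' @return long data.frame `tract_id, period, births, women`.
#' @export
simulate_counts <- function(tracts, graph, index, truth, population,
                            seed = NULL, periods = NULL) {
  stopifnot(inherits(truth, "ground_truth"))
  n <- nrow(tracts)
  P <- length(truth$alpha)
  if (length(index) != n) stop("index must have one value per tract")
  if (!all(is.finite(index))) stop("index must be finite")
  if (is.null(periods)) periods <- paste0("P", seq_len(P))
  if (is.data.frame(population)) {
    N <- matrix(NA_real_, n, P, dimnames = list(tracts$tract_id, periods))
    ii <- match(population$tract_id, tracts$tract_id)
    pp <- match(population$period, periods)
    if (anyNA(ii) || anyNA(pp)) stop("population refers to unknown tracts or periods")
    N[cbind(ii, pp)] <- population$women
    if (anyNA(N)) stop("population table is incomplete")
  } else {
    N <- as.matrix(population)
    if (!all(dim(N) == c(n, P))) stop("population matrix must be n_tracts x n_periods")
  }
  if (any(N < 0)) stop("population must be non-negative")
  if (!is.null(seed)) set.seed(seed)
  eta <- outer(index, truth$beta) + truth$u + truth$v +
    matrix(truth$alpha, n, P, byrow = TRUE)
  if (max(eta) > 700)
    stop("log-rate exceeds 700; Poisson mean would overflow -- rescale alpha/beta/fields")
  O <- matrix(stats::rpois(n * P, lambda = as.vector(N * exp(eta))), n, P)
  O[N == 0] <- 0L
  data.frame(
    tract_id = rep(tracts$tract_id, times = P),
    period = rep(periods, each = n),
    births = as.integer(O),
    women = as.integer(round(as.vector(N))),
    stringsAsFactors = FALSE
  )
}

period_labels <- c("P1", "P2", "P3")
narrow_age_groups <- c("15-19", "20-24", "25-34", "35-49")
nationality_groups <- c("Spanish", "LIC")

# plausible per-1000-women period baselines for a large Spanish city,
# constant across periods; period trends enter through the slopes
default_baseline_rates <- function() {
  rbind(
    data.frame(age_group = narrow_age_groups, nationality = "Spanish",
               rate = c(4, 11, 63, 26)),
    data.frame(age_group = narrow_age_groups, nationality = "LIC",
               rate = c(23, 48, 53, 21))
  )
}

#' Simulate a synthetic city
#'
#' End-to-end generator of a study-shaped dataset with known ground truth:
#' a rook lattice of tracts, five spatially correlated deprivation
#' indicators dominated by one latent factor, the deprivation index
#' computed from them, and Poisson birth counts per tract x period x
#' age group x nationality whose log-rates contain a period intercept, a
#' period-specific deprivation slope, an ICAR spatial field and unstructured
#' noise. The per-period slopes are set so the relative risk comparing the
#' 95th to the 5th percentile of the realized index equals `rr_95_5`.
#'
#' Defaults encode the reference experiment: a 20x20 lattice, three periods,
#' RR(95th vs 5th) = (1.0, 1.5, 2.0), and log-normal tract populations with
#' a median of 500 women per tract-stratum.
#'
#' @param n_rows,n_cols lattice dimensions.
#' @param seed integer seed; all randomness flows from it.
#' @param rr_95_5 per-period target relative risks (95th vs 5th percentile
#'   of deprivation), either a numeric vector of length `n_periods` or a
#'   function `(age_group, nationality) -> numeric(n_periods)` for
#'   stratum-specific truths.
#' @param n_periods number of periods (labelled `P1..`).
#' @param tau_u,tau_v true precisions of the spatial and heterogeneous fields.
#' @param median_women,sdlog_women log-normal population model per
#'   tract-stratum (median and log-sd); populations are rounded to integers.
#' @param loadings,noise_sd passed to [generate_indicators()].
#' @param baseline_rates data.frame `age_group, nationality, rate` of
#'   per-1000 baseline fertility rates; `NULL` (with `stratified = FALSE`)
#'   uses a single overall stratum at `overall_rate`.
#' @param stratified simulate the full age x nationality stratification
#'   (`TRUE`) or a single 15-49 overall stratum (`FALSE`).
#' @param overall_rate baseline per-1000 rate for the unstratified variant.
#' @return list with `tracts`, `graph`, `indicators`, `index` (a
#'   `deprivation_index`), `truth` (per-stratum [ground_truth()] list or a
#'   single one), `counts` (long data.frame with `tract_id, period,
#'   age_group, nationality, births, women`; stratified cities include the
#'   aggregated `15-49` rows), and `seed`.
#' @export
simulate_city <- function(n_rows = 20, n_cols = 20, seed = 1,
                          rr_95_5 = c(1.0, 1.5, 2.0), n_periods = 3,
                          tau_u = 10, tau_v = 100,
                          median_women = 500, sdlog_women = 0.3,
                          loadings = rep(1, 5), noise_sd = 0.1,
                          baseline_rates = default_baseline_rates(),
                          stratified = TRUE, overall_rate = 35) {
  set.seed(seed)
  lat <- generate_lattice(n_rows, n_cols)
  n <- lat$graph$n_tracts
  periods <- paste0("P", seq_len(n_periods))
  ind <- generate_indicators(lat$tracts, lat$graph, loadings = loadings,
                             noise_sd = noise_sd)
  index <- compute_index(ind)
  span <- unname(index$q95 - index$q5)
  u <- sample_icar_field(lat$graph, tau_u)
  v <- stats::rnorm(n, 0, 1 / sqrt(tau_v))
  rr_fun <- if (is.function(rr_95_5)) rr_95_5 else function(a, g) rr_95_5
  strata <- if (stratified) {
    baseline_rates
  } else {
    data.frame(age_group = "15-49", nationality = "Spanish", rate = overall_rate)
  }
  counts <- list(); truths <- list()
  for (k in seq_len(nrow(strata))) {
    rr <- rr_fun(strata$age_group[k], strata$nationality[k])
    if (length(rr) != n_periods) stop("rr_95_5 must give one RR per period")
    truth <- ground_truth(
      alpha = rep(log(strata$rate[k] / 1000), n_periods),
      beta = log(rr) / span,
      tau_u = tau_u, tau_v = tau_v, u = u, v = v, seed = seed
    )
    N <- matrix(round(stats::rlnorm(n * n_periods, log(median_women),
                                    sdlog_women)), n, n_periods)
    cc <- simulate_counts(lat$tracts, lat$graph, index$x, truth, N,
                          periods = periods)
    cc$age_group <- strata$age_group[k]
    cc$nationality <- strata$nationality[k]
    counts[[k]] <- cc
    truths[[paste(strata$age_group[k], strata$nationality[k], sep = ":")]] <- truth
  }
  counts <- do.call(rbind, counts)
  counts <- counts[, c("tract_id", "period", "age_group", "nationality",
                       "births", "women")]
  if (stratified) counts <- rbind(counts, aggregate_age_15_49(counts))
  rownames(counts) <- NULL
  list(tracts = lat$tracts, graph = lat$graph, indicators = ind,
       index = index, truth = if (stratified) truths else truths[[1L]],
       counts = counts, span = span, seed = as.integer(seed))
}

#' Aggregate the four narrow age groups into 15-49
#'
#' @param counts long counts data.frame with the four narrow age groups.
#' @return data.frame of `15-49` rows (births and women summed per
#'   tract x period x nationality).
#' @export
aggregate_age_15_49 <- function(counts) {
  narrow <- counts[counts$age_group %in% narrow_age_groups, , drop = FALSE]
  agg <- stats::aggregate(cbind(births, women) ~ tract_id + period + nationality,
                          data = narrow, FUN = sum)
  agg$age_group <- "15-49"
  agg[, c("tract_id", "period", "age_group", "nationality", "births", "women")]
}

#' Write a synthetic city to disk
#'
#' Emits the interchange files downstream stages read: `counts.csv`,
#' `indicators.csv`, `adjacency.gal` and `truth.json`.
#'
#' @param city result of [simulate_city()].
#' @param dir output directory (created if needed).
#' @return named character vector of the paths written, invisibly.
#' @export
write_city <- function(city, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(counts = file.path(dir, "counts.csv"),
             indicators = file.path(dir, "indicators.csv"),
             adjacency = file.path(dir, "adjacency.gal"),
             truth = file.path(dir, "truth.json"))
  utils::write.csv(city$counts, paths[["counts"]], row.names = FALSE)
  ind <- data.frame(tract_id = rownames(city$indicators), city$indicators,
                    row.names = NULL, check.names = FALSE)
  utils::write.csv(ind, paths[["indicators"]], row.names = FALSE)
  write_gal(city$graph, paths[["adjacency"]])
  truths <- city$truth
  if (inherits(truths, "ground_truth")) truths <- list(overall = truths)
  jsonlite::write_json(lapply(truths, unclass), paths[["truth"]],
                       auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
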