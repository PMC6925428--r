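#' Fit the three-period ecological regression
#'
#' Joint Poisson regression of tract birth counts on the deprivation index
#' across periods, with period interactions and period-specific BYM fields:
#' \deqn{O_{ip} \sim \mathrm{Poisson}\!\big(N_{ip}\,
#'   e^{\alpha_p + (\beta_1 + \delta_p) x_i + u_{ip} + v_{ip}}\big),
#'   \qquad \delta_1 \equiv 0,}
#' so \eqn{\beta_p = \beta_1 + \delta_p} is the period-p slope and the
#' paper-style period-change questions read directly off the posteriors of
#' \eqn{\delta_2} (first to second period) and \eqn{\delta_3 - \delta_2}
#' (second to third). Priors: flat on each \eqn{\alpha_p}, Normal(0, 10^2)
#' on \eqn{\beta_1, \delta_2, \delta_3}, ICAR(\eqn{\tau_u}) on each
#' period's spatial field and iid Normal(0, 1/\eqn{\tau_v}) heterogeneous
#' effects, with the two precisions shared across periods and given
#' [bym_priors()] Gamma hyperpriors. Sampling machinery and convergence
#' contracts are those of [fit_bym()].
#'
#' @param counts long data.frame for one age x nationality stratum:
#'   `tract_id, period, births, women`, complete over tracts x periods.
#' @param index a `deprivation_index` from [compute_index()], or a numeric
#'   per-tract covariate in graph order (must be non-constant).
#' @param graph a connected [tract_graph()].
#' @param mcmc an [mcmc_control()].
#' @param priors a [bym_priors()].
#' @param beta_prior_sd sd of the Normal prior on the slope parameters.
#' @param keep_fields store the full field draws (memory-heavy; the RR
#'   summaries only need the regression coefficients).
#' @param n_periods number of periods the study design expects (default 3);
#'   counts covering fewer are rejected as having a missing period.
#' @return object of class `eco_draws`: chains with `alpha` (draws x P),
#'   `b1`, `delta` (draws x P, first column 0), `tau_u`, `tau_v`; plus
#'   `periods`, `x`, `span`, `graph`, `rhat`.
#' @export
fit_ecoregression <- function(counts, index, graph, mcmc = mcmc_control(),
                              priors = bym_priors(), beta_prior_sd = 10,
                              keep_fields = FALSE, n_periods = 3) {
  stopifnot(inherits(graph, "tract_graph"), inherits(mcmc, "mcmc_control"))
  if (mcmc$n_chains < 2)
    stop("at least 2 chains are required for convergence diagnostics")
  stop_if_disconnected(graph)
  x <- if (inherits(index, "deprivation_index")) index$x else index
  if (length(x) != graph$n_tracts)
    stop("index must have one value per tract")
  if (!is.null(names(x)) && all(graph$tract_id %in% names(x)))
    x <- x[graph$tract_id]
  x <- as.numeric(x)
  if (length(unique(x)) < 2L) stop("deprivation index is constant")
  if (!all(is.finite(x))) stop("deprivation index must be finite")
  periods <- sort(unique(counts$period))
  P <- length(periods)
  if (P < n_periods)
    stop("missing period(s): the design expects ", n_periods,
         " but counts cover only ", paste(periods, collapse = ", "))
  n <- graph$n_tracts
  O <- matrix(NA_integer_, n, P, dimnames = list(graph$tract_id, periods))
  N <- matrix(NA_real_, n, P)
  ii <- match(counts$tract_id, graph$tract_id)
  pp <- match(counts$period, periods)
  if (anyNA(ii)) stop("counts refer to tracts missing from the graph")
  O[cbind(ii, pp)] <- counts$births
  N[cbind(ii, pp)] <- counts$women
  if (anyNA(O) || anyNA(N)) {
    miss <- periods[colSums(is.na(O)) > 0]
    stop("incomplete counts: missing tract x period cells in period(s) ",
         paste(miss, collapse = ", "))
  }
  if (any(O < 0) || any(N < 0)) stop("counts must be non-negative")
  fl <- flatten_adjacency(graph)
  set.seed(mcmc$seed)
  alpha0 <- log((colSums(O) + 0.5) / (colSums(N) + 1))
  chains <- vector("list", mcmc$n_chains)
  for (c in seq_len(mcmc$n_chains)) {
    chains[[c]] <- .eco_chain(
      O, N, as.numeric(x), fl$adj, fl$start, fl$edges,
      priors$a_u, priors$b_u, priors$a_v, priors$b_v, beta_prior_sd,
      mcmc$burn_in, mcmc$n_retained, mcmc$thin,
      alpha0 + stats::rnorm(P, 0, 0.15), keep_fields
    )
  }
  out <- structure(list(chains = chains, periods = periods, x = x,
                        span = unname(diff(percentile_span(x))),
                        graph = graph, mcmc = mcmc, rhat = NULL),
                   class = c("eco_draws", "mcmc_draws"))
  out$rhat <- gelman_rubin(out)
  if (any(out$rhat > 1.1, na.rm = TRUE))
    warning("MCMC may not have converged: split R-hat > 1.1 for ",
            paste(names(out$rhat)[out$rhat > 1.1], collapse = ", "))
  out
}

#' @export
print.eco_draws <- function(x, ...) {
  cat("eco_draws:", length(x$chains), "chains x", length(x$chains[[1]]$b1),
      "retained draws;", x$graph$n_tracts, "tracts x",
      length(x$periods), "periods\n")
  cat("  split R-hat:", paste(names(x$rhat), round(x$rhat, 3), sep = "=",
                              collapse = "  "), "\n")
  invisible(x)
}

# pooled coefficient draws across chains: list(b1, delta [draws x P])
pool_coef_draws <- function(draws) {
  list(b1 = unlist(lapply(draws$chains, `[[`, "b1")),
       delta = do.call(rbind, lapply(draws$chains, `[[`, "delta")))
}

#' Relative risks at the 95th vs 5th deprivation percentile
#'
#' For each retained draw and period, the relative risk of the exposure
#' contrast is \eqn{RR_p = e^{(\beta_1+\delta_p)(q_{95}-q_5)}}, summarized
#' by the posterior median (invariant under the exp transform; the mean is
#' also emitted) and the equal-tailed 95% credible interval. Period-change
#' flags are raised when the 95% interval of \eqn{\delta_2} (change from
#' period 1 to 2) or of \eqn{\delta_3 - \delta_2} (change from period 2 to
#' 3) excludes zero.
#'
#' @param draws an `eco_draws` from [fit_ecoregression()].
#' @param span the percentile pair `c(q5, q95)` from [percentile_span()],
#'   or `NULL` to use the span of the covariate the model was fitted on.
#' @return object of class `rr_result`: data.frame with one row per period
#'   (`period, rr, lo95, hi95, rr_mean`) and attributes `sig_12`, `sig_23`.
#' @export
relative_risk <- function(draws, span = NULL) {
  stopifnot(inherits(draws, "eco_draws"))
  s <- if (is.null(span)) draws$span else {
    if (length(span) != 2L) stop("span must be the (q5, q95) pair")
    if (span[2L] <= span[1L]) stop("q95 must exceed q5")
    unname(span[2L] - span[1L])
  }
  co <- pool_coef_draws(draws)
  P <- ncol(co$delta)
  beta_p <- co$b1 + co$delta           # draws x P, recycled columnwise
  rr <- exp(beta_p * s)
  summ <- t(apply(rr, 2L, function(r)
    c(rr = stats::median(r),
      lo95 = unname(stats::quantile(r, 0.025)),
      hi95 = unname(stats::quantile(r, 0.975)),
      rr_mean = mean(r))))
  out <- data.frame(period = draws$periods, summ, row.names = NULL,
                    stringsAsFactors = FALSE)
  excl0 <- function(z) {
    q <- stats::quantile(z, c(0.025, 0.975))
    q[1L] > 0 || q[2L] < 0
  }
  attr(out, "sig_12") <- if (P >= 2) excl0(co$delta[, 2L]) else NA
  attr(out, "sig_23") <- if (P >= 3) excl0(co$delta[, 3L] - co$delta[, 2L]) else NA
  class(out) <- c("rr_result", "data.frame")
  out
}

#' @export
print.rr_result <- function(x, ...) {
  df <- as.data.frame(x)
  df$rr <- sprintf("%.3f (%.3f-%.3f)", df$rr, df$lo95, df$hi95)
  print(df[, c("period", "rr")], row.names = FALSE)
  cat("  change P1->P2 significant:", attr(x, "sig_12"),
      " | P2->P3 significant:", attr(x, "sig_23"), "\n")
  invisible(x)
}

#' Run the ecological regression across all strata
#'
#' Independent [fit_ecoregression()] fits per age group x nationality
#' stratum, consolidated into one long table shaped like the reporting
#' panels (age-group rows, one RR per period with interval and
#' period-change flags). A stratum with zero woman-years throughout a
#' period is an error naming the stratum; a stratum with no births at all
#' is still fitted and flagged `sparse` (its intervals are prior-driven and
#' wide).
#'
#' @param counts long stratified counts (`tract_id, period, age_group,
#'   nationality, births, women`).
#' @param index a `deprivation_index` (or per-tract covariate).
#' @param graph a connected [tract_graph()].
#' @param mcmc an [mcmc_control()]; each stratum gets a deterministic child
#'   seed derived from `mcmc$seed` and the stratum label.
#' @param ... passed on to [fit_ecoregression()].
#' @return data.frame: `age_group, nationality, period, rr, lo95, hi95,
#'   rr_mean, sig_12, sig_23, sparse, max_rhat`.
#' @export
run_stratified_analysis <- function(counts, index, graph,
                                    mcmc = mcmc_control(), ...) {
  strata <- unique(counts[, c("age_group", "nationality")])
  strata <- strata[order(strata$nationality, strata$age_group), , drop = FALSE]
  out <- vector("list", nrow(strata))
  for (k in seq_len(nrow(strata))) {
    a <- strata$age_group[k]; g <- strata$nationality[k]
    cc <- counts[counts$age_group == a & counts$nationality == g, , drop = FALSE]
    byp <- tapply(cc$women, cc$period, sum)
    if (any(byp == 0))
      stop("stratum ", a, " x ", g, " has zero woman-years in period(s) ",
           paste(names(byp)[byp == 0], collapse = ", "))
    sparse <- sum(cc$births) == 0
    m <- mcmc
    m$seed <- stage_seed(mcmc$seed, paste(a, g, sep = ":"))
    fit <- fit_ecoregression(cc, index, graph, mcmc = m, ...)
    rr <- relative_risk(fit)
    out[[k]] <- data.frame(age_group = a, nationality = g,
                           as.data.frame(rr),
                           sig_12 = attr(rr, "sig_12"),
                           sig_23 = attr(rr, "sig_23"),
                           sparse = sparse,
                           max_rhat = max(fit$rhat),
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Wide RR table
#'
#' Reshapes the stratified RR results to the reporting layout: one row per
#' age group and nationality, one formatted `RR (lo-hi)` column per period,
#' with `*` marking a significant period-1-to-2 change and `+` a
#' significant period-2-to-3 change.
#'
#' @param rr_long output of [run_stratified_analysis()].
#' @return data.frame in wide period layout.
#' @export
rr_wide <- function(rr_long) {
  fmt <- sprintf("%.2f (%.2f-%.2f)", rr_long$rr, rr_long$lo95, rr_long$hi95)
  periods <- sort(unique(rr_long$period))
  flags <- rep("", nrow(rr_long))
  if (length(periods) >= 2L)
    flags[rr_long$period == periods[2L] & rr_long$sig_12 %in% TRUE] <- "*"
  if (length(periods) >= 3L)
    flags[rr_long$period == periods[3L] & rr_long$sig_23 %in% TRUE] <- "+"
  df <- data.frame(rr_long[, c("age_group", "nationality", "period")],
                   cell = paste0(fmt, flags), stringsAsFactors = FALSE)
  wide <- stats::reshape(df, idvar = c("age_group", "nationality"),
                         timevar = "period", direction = "wide")
  names(wide) <- sub("^cell\\.", "RR_", names(wide))
  rownames(wide) <- NULL
  wide[order(wide$nationality, wide$age_group), , drop = FALSE]
}
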