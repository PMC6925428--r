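#' MCMC settings
#'
#' @param n_chains number of independent chains (>= 2 so convergence can be
#'   assessed).
#' @param n_retained retained draws per chain after burn-in and thinning.
#' @param burn_in discarded adaptation sweeps per chain (proposal scales
#'   adapt only here, so retained draws target the exact posterior).
#' @param thin keep every `thin`-th post-burn-in sweep.
#' @param seed integer seed; all chains flow deterministically from it.
#' @return list of class `mcmc_control`.
#' @export
mcmc_control <- function(n_chains = 2, n_retained = 5000, burn_in = 2000,
                         thin = 2, seed = 1) {
  stopifnot(n_chains >= 1, n_retained >= 1, burn_in >= 0, thin >= 1)
  structure(list(n_chains = as.integer(n_chains),
                 n_retained = as.integer(n_retained),
                 burn_in = as.integer(burn_in), thin = as.integer(thin),
                 seed = as.integer(seed)),
            class = "mcmc_control")
}

#' Gamma hyperpriors on the field precisions
#'
#' Weakly-informative disease-mapping default: Gamma(0.5, 0.0005) on both
#' the spatial and the heterogeneous precision. The intercept prior is flat
#' (posterior proper whenever total births > 0).
#'
#' @param a_u,b_u shape and rate for `tau_u`.
#' @param a_v,b_v shape and rate for `tau_v`.
#' @return list of class `bym_priors`.
#' @export
bym_priors <- function(a_u = 0.5, b_u = 0.0005, a_v = 0.5, b_v = 0.0005) {
  stopifnot(a_u > 0, b_u > 0, a_v > 0, b_v > 0)
  structure(list(a_u = a_u, b_u = b_u, a_v = a_v, b_v = b_v),
            class = "bym_priors")
}

#' Specify a BYM smoothing model
#'
#' The Besag-York-Mollie count model for one stratum:
#' \deqn{O_i \sim \mathrm{Poisson}(N_i e^{\alpha + u_i + v_i}),}
#' with `u` an intrinsic CAR (spatially structured) field on the tract
#' adjacency graph and `v` iid Normal(0, 1/tau_v) heterogeneous effects.
#'
#' @param O integer births per tract (graph order).
#' @param N woman-years per tract; non-negative, at least one positive.
#' @param graph a connected [tract_graph()] covering all tracts.
#' @param priors a [bym_priors()].
#' @return list of class `bym_model`.
#' @export
bym_model <- function(O, N, graph, priors = bym_priors()) {
  stopifnot(inherits(graph, "tract_graph"), inherits(priors, "bym_priors"))
  if (length(O) != graph$n_tracts || length(N) != graph$n_tracts)
    stop("O and N must have one entry per tract of the graph")
  if (any(O < 0) || any(N < 0)) stop("counts must be non-negative")
  if (!any(N > 0)) stop("at least one tract must have positive woman-years")
  if (any(O[N == 0] > 0)) stop("births observed in tracts with zero woman-years")
  stop_if_disconnected(graph)
  structure(list(O = as.integer(round(O)), N = as.numeric(N), graph = graph,
                 priors = priors),
            class = "bym_model")
}

# CSR-style flattening of the neighbour lists for the C++ sampler (0-based)
flatten_adjacency <- function(graph) {
  deg <- lengths(graph$nb)
  list(adj = as.integer(unlist(graph$nb) - 1L),
       start = as.integer(c(0L, cumsum(deg))),
       edges = graph_edges(graph) - 1L)
}

#' Fit the BYM model by MCMC
#'
#' Metropolis-within-Gibbs: conjugate Gibbs updates for the two precisions
#' (`tau_u | u ~ Gamma(a_u + (n-1)/2, b_u + 0.5 sum_(i~j) (u_i-u_j)^2)` and
#' the analogous `tau_v | v`), single-site adaptive random-walk Metropolis
#' for the intercept and every `u_i`, `v_i`, and a re-centring of `u` to
#' sum to zero (its mean folded into the intercept) after every sweep.
#' Proposal scales adapt during burn-in only. Convergence is assessed with
#' split-R-hat on the intercept and the precisions; values above 1.1 raise
#' a warning and are recorded on the result, never silent.
#'
#' @param model a [bym_model()].
#' @param mcmc an [mcmc_control()] with at least 2 chains.
#' @param fields `"bym"` (default) fits both random-effect fields;
#'   `"none"` disables them, leaving the exchangeable Poisson model with a
#'   common rate (used for conjugate-limit validation).
#' @return object of class `bym_draws`: list with `chains` (each a list of
#'   `alpha`, `tau_u`, `tau_v` vectors and `u`, `v` matrices), the `model`,
#'   `mcmc`, `fields` flag and `rhat`.
#' @export
fit_bym <- function(model, mcmc = mcmc_control(), fields = c("bym", "none")) {
  stopifnot(inherits(model, "bym_model"), inherits(mcmc, "mcmc_control"))
  fields <- match.arg(fields)
  if (mcmc$n_chains < 2)
    stop("at least 2 chains are required for convergence diagnostics")
  fl <- flatten_adjacency(model$graph)
  set.seed(mcmc$seed)
  alpha0 <- log((sum(model$O) + 0.5) / (sum(model$N) + 1))
  chains <- vector("list", mcmc$n_chains)
  for (c in seq_len(mcmc$n_chains)) {
    chains[[c]] <- .bym_chain(
      model$O, model$N, fl$adj, fl$start, fl$edges,
      model$priors$a_u, model$priors$b_u, model$priors$a_v, model$priors$b_v,
      mcmc$burn_in, mcmc$n_retained, mcmc$thin,
      fields == "bym",
      alpha0 + stats::rnorm(1, 0, 0.15)
    )
  }
  out <- structure(list(chains = chains, model = model, mcmc = mcmc,
                        fields = fields, rhat = NULL),
                   class = c("bym_draws", "mcmc_draws"))
  out$rhat <- gelman_rubin(out)
  check <- out$rhat[c("alpha", if (fields == "bym") c("tau_u", "tau_v"))]
  if (any(check > 1.1, na.rm = TRUE))
    warning("MCMC may not have converged: split R-hat > 1.1 for ",
            paste(names(check)[check > 1.1], collapse = ", "))
  out
}

#' @export
print.bym_draws <- function(x, ...) {
  cat("bym_draws:", length(x$chains), "chains x", length(x$chains[[1]]$alpha),
      "retained draws;", x$model$graph$n_tracts, "tracts; fields:", x$fields, "\n")
  cat("  split R-hat:", paste(names(x$rhat), round(x$rhat, 3), sep = "=",
                              collapse = "  "), "\n")
  invisible(x)
}

# per-chain matrices of the scalar parameters a draws object monitors
scalar_draws <- function(draws) UseMethod("scalar_draws")

#' @export
scalar_draws.bym_draws <- function(draws) {
  lapply(draws$chains, function(ch)
    cbind(alpha = ch$alpha, tau_u = ch$tau_u, tau_v = ch$tau_v))
}

#' @export
scalar_draws.eco_draws <- function(draws) {
  lapply(draws$chains, function(ch) {
    P <- ncol(ch$alpha)
    m <- cbind(ch$alpha, b1 = ch$b1,
               ch$delta[, -1L, drop = FALSE], tau_u = ch$tau_u, tau_v = ch$tau_v)
    colnames(m) <- c(paste0("alpha_", seq_len(P)), "b1",
                     paste0("delta_", 2:P), "tau_u", "tau_v")
    m
  })
}

#' Split Gelman-Rubin diagnostic
#'
#' Split-R-hat per monitored scalar parameter: each chain is halved, and
#' R-hat is the usual between/within variance ratio over the resulting
#' 2 x n_chains half-chains. Parameters with (numerically) zero variance in
#' every half-chain are reported as 1.
#'
#' @param draws a fitted `bym_draws`/`eco_draws` object, or a list of
#'   per-chain numeric matrices (iterations x parameters).
#' @return named numeric vector of R-hat values (all >= 1).
#' @export
gelman_rubin <- function(draws) {
  mats <- if (inherits(draws, "mcmc_draws")) scalar_draws(draws) else draws
  if (!is.list(mats) || length(mats) < 2L)
    stop("at least 2 chains are required for the Gelman-Rubin diagnostic")
  mats <- lapply(mats, as.matrix)
  iters <- unique(vapply(mats, nrow, 1L))
  if (length(iters) != 1L) stop("chains must have equal length")
  if (iters < 10L) stop("at least 10 retained draws per chain are required")
  half <- iters %/% 2L
  halves <- unlist(lapply(mats, function(m)
    list(m[seq_len(half), , drop = FALSE],
         m[(iters - half + 1L):iters, , drop = FALSE])), recursive = FALSE)
  p <- ncol(mats[[1L]])
  out <- vapply(seq_len(p), function(j) {
    xs <- vapply(halves, function(m) mean(m[, j]), 0)
    ws <- vapply(halves, function(m) stats::var(m[, j]), 0)
    W <- mean(ws)
    B <- half * stats::var(xs)
    if (W <= 0 || !is.finite(W)) return(1)
    sqrt(((half - 1) / half * W + B / half) / W)
  }, 0)
  stats::setNames(out, colnames(mats[[1L]]))
}

#' Posterior smoothed rates
#'
#' Per-tract smoothed fertility rate: for each retained draw the rate is
#' `1000 * exp(alpha + u_i + v_i)`, summarized by the posterior mean and the
#' equal-tailed 95% credible interval. Tracts with zero woman-years carry no
#' likelihood information; their interval is prior-predictive and they are
#' flagged.
#'
#' @param draws a `bym_draws` from [fit_bym()].
#' @return data.frame `tract_id, mean, lo95, hi95, no_data`.
#' @export
smoothed_rates <- function(draws) {
  stopifnot(inherits(draws, "bym_draws"))
  model <- draws$model
  n <- model$graph$n_tracts
  rate <- do.call(rbind, lapply(draws$chains, function(ch)
    1000 * exp(ch$alpha + ch$u + ch$v)))
  q <- apply(rate, 2L, stats::quantile, probs = c(0.025, 0.975), names = FALSE)
  data.frame(tract_id = model$graph$tract_id,
             mean = colMeans(rate), lo95 = q[1L, ], hi95 = q[2L, ],
             no_data = model$N == 0,
             stringsAsFactors = FALSE)
}
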