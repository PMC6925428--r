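# shared fixtures: tiny graphs, brute-force oracles, MCMC error helpers

# random connected graph on k nodes: a random spanning tree plus extra edges
random_connected_graph <- function(k, extra = k %/% 2) {
  ids <- paste0("g", seq_len(k))
  edges <- cbind(2:k, vapply(2:k, function(i) sample.int(i - 1L, 1L), 1L))
  if (extra > 0) {
    all_pairs <- t(combn(k, 2))
    more <- all_pairs[sample.int(nrow(all_pairs), min(extra, nrow(all_pairs))), ,
                      drop = FALSE]
    edges <- rbind(edges, more)
  }
  edges <- edges[edges[, 1] != edges[, 2], , drop = FALSE]
  tract_graph(ids, edges)
}

path_graph <- function(k) {
  tract_graph(paste0("p", seq_len(k)), cbind(seq_len(k - 1L), 2:k))
}

two_tract_graph <- function() tract_graph(c("a", "b"), cbind(1L, 2L))

# independent oracle for the ICAR quadratic form: explicit Laplacian algebra
laplacian_quadform <- function(u, graph, tau) {
  L <- graph_laplacian(graph)
  -(tau / 2) * as.numeric(t(u) %*% L %*% u)
}

# Monte-Carlo standard error of a chain mean by batch means
mcse_mean <- function(x, n_batches = 50) {
  m <- length(x) %/% n_batches
  bm <- vapply(seq_len(n_batches), function(b) mean(x[((b - 1) * m + 1):(b * m)]), 0)
  sd(bm) / sqrt(n_batches)
}

quick_mcmc <- function(seed, n_retained = 400, burn_in = 400) {
  mcmc_control(n_chains = 2, n_retained = n_retained, burn_in = burn_in,
               thin = 1, seed = seed)
}

# hand-built eco_draws with known coefficient draws, for closed-form checks
fake_eco_draws <- function(b1, delta2 = NULL, delta3 = NULL, span = 1,
                           periods = c("P1", "P2", "P3")) {
  P <- length(periods)
  k <- length(b1)
  delta <- matrix(0, k, P)
  if (!is.null(delta2)) delta[, 2] <- delta2
  if (!is.null(delta3)) delta[, 3] <- delta3
  structure(list(
    chains = list(list(b1 = b1, delta = delta,
                       alpha = matrix(0, k, P),
                       tau_u = rep(1, k), tau_v = rep(1, k))),
    periods = periods, span = span, x = NULL, graph = NULL,
    mcmc = NULL, rhat = NULL
  ), class = c("eco_draws", "mcmc_draws"))
}
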