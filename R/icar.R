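#' ICAR log-kernel
#'
#' Log-density, up to an additive constant, of the intrinsic conditional
#' autoregressive (ICAR) prior with precision `tau_u` on the neighbour
#' structure of `graph`:
#' \deqn{\frac{n-1}{2}\log\tau_u \;-\; \frac{\tau_u}{2}\sum_{i \sim j}(u_i-u_j)^2,}
#' the sum running over unordered neighbour pairs. The quadratic form equals
#' `-(tau_u/2) * t(u) %*% (D - W) %*% u` with the graph Laplacian `D - W`;
#' the normalizing rank is `n - 1` because the prior is improper along the
#' constant direction (hence the sum-to-zero constraint elsewhere).
#'
#' @param u numeric vector, one value per tract in graph order.
#' @param graph a [tract_graph()].
#' @param tau_u positive precision.
#' @return scalar log-kernel value.
#' @export
icar_log_kernel <- function(u, graph, tau_u) {
  stopifnot(inherits(graph, "tract_graph"))
  if (length(u) != graph$n_tracts)
    stop("u has length ", length(u), " but the graph has ",
         graph$n_tracts, " tracts")
  if (!all(is.finite(u))) stop("u must be finite")
  if (!is.finite(tau_u) || tau_u <= 0) stop("tau_u must be > 0")
  ss <- pair_diff_ss(u, graph)
  ((graph$n_tracts - 1) / 2) * log(tau_u) - (tau_u / 2) * ss
}

# sum over unordered neighbour pairs of (u_i - u_j)^2
pair_diff_ss <- function(u, graph) {
  e <- graph_edges(graph)
  if (!nrow(e)) return(0)
  sum((u[e[, 1L]] - u[e[, 2L]])^2)
}

#' Sample an ICAR field
#'
#' Draws one realization of the intrinsic CAR distribution with precision
#' `tau_u` on a connected graph, constrained to sum to zero. The draw is
#' taken on the rank-(n-1) eigenspace of the graph Laplacian: with
#' eigenpairs \eqn{(\lambda_k, e_k)} of `D - W`, the field is
#' \eqn{u = \sum_{\lambda_k > 0} e_k z_k / \sqrt{\tau_u \lambda_k}},
#' \eqn{z_k \sim N(0,1)}, so `cov(u)` is the Moore-Penrose pseudoinverse of
#' `tau_u * (D - W)` and `sum(u) = 0` exactly (the null eigenvector is the
#' constant).
#'
#' @param graph a connected [tract_graph()].
#' @param tau_u positive precision.
#' @param seed optional integer; when given, `set.seed(seed)` is called first.
#' @return numeric vector `u` with `sum(u)` zero to numerical precision.
#' @export
sample_icar_field <- function(graph, tau_u, seed = NULL) {
  stopifnot(inherits(graph, "tract_graph"))
  if (!is.finite(tau_u) || tau_u <= 0) stop("tau_u must be > 0")
  stop_if_disconnected(graph)
  if (!is.null(seed)) set.seed(seed)
  basis <- icar_basis(graph)
  z <- stats::rnorm(ncol(basis$vectors))
  u <- as.vector(basis$vectors %*% (z / sqrt(tau_u * basis$values)))
  u - mean(u)  # remove numerical drift off the sum-zero plane
}

# eigenbasis of the Laplacian restricted to the non-null eigenspace;
# cached per call site by callers that draw repeatedly
icar_basis <- function(graph) {
  L <- graph_laplacian(graph)
  eig <- eigen(L, symmetric = TRUE)
  keep <- eig$values > max(eig$values) * 1e-10
  list(values = eig$values[keep], vectors = eig$vectors[, keep, drop = FALSE])
}
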