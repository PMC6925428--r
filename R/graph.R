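#' Tract adjacency graph
#'
#' A symmetric neighbour structure over a set of census tracts: the spatial
#' support of the ICAR prior and of everything downstream. Stored as an
#' adjacency (neighbour) list indexed in the stable tract order.
#'
#' @param tract_id character or integer vector of unique tract identifiers,
#'   in the order used throughout the pipeline.
#' @param edges two-column matrix (or data.frame) of tract indices or ids,
#'   one row per undirected edge. Duplicate and reversed rows are collapsed.
#'
#' @return An object of class `tract_graph`: a list with elements
#'   `tract_id`, `nb` (list of integer neighbour indices per tract, sorted),
#'   `n_tracts` and `n_edges`.
#' @export
tract_graph <- function(tract_id, edges) {
  tract_id <- as.character(tract_id)
  if (anyDuplicated(tract_id)) stop("tract ids must be unique")
  n <- length(tract_id)
  if (n < 2L) stop("a tract graph needs at least 2 tracts")
  edges <- as.matrix(edges)
  if (ncol(edges) != 2L) stop("edges must have two columns")
  if (is.character(edges)) {
    idx <- matrix(match(edges, tract_id), ncol = 2L)
    if (anyNA(idx)) {
      bad <- unique(edges[is.na(match(edges, tract_id))])
      stop("edge refers to unknown tract id(s): ", paste(bad, collapse = ", "))
    }
    edges <- idx
  } else {
    storage.mode(edges) <- "integer"
    if (anyNA(edges) || any(edges < 1L) || any(edges > n))
      stop("edge indices out of range 1..", n)
  }
  if (any(edges[, 1L] == edges[, 2L])) stop("self-loops are not allowed")
  # canonical undirected form: (min, max), deduplicated
  e <- cbind(pmin(edges[, 1L], edges[, 2L]), pmax(edges[, 1L], edges[, 2L]))
  e <- unique(e)
  e <- e[order(e[, 1L], e[, 2L]), , drop = FALSE]
  nb <- rep(list(integer(0)), n)
  for (k in seq_len(nrow(e))) {
    i <- e[k, 1L]; j <- e[k, 2L]
    nb[[i]] <- c(nb[[i]], j)
    nb[[j]] <- c(nb[[j]], i)
  }
  nb <- lapply(nb, sort)
  structure(
    list(tract_id = tract_id, nb = nb, n_tracts = n, n_edges = nrow(e)),
    class = "tract_graph"
  )
}

#' @export
print.tract_graph <- function(x, ...) {
  cat("tract_graph:", x$n_tracts, "tracts,", x$n_edges, "edges\n")
  invisible(x)
}

#' Edge list of a tract graph
#'
#' @param graph a [tract_graph()].
#' @return integer matrix with columns `i`, `j` (i < j), one row per edge.
#' @export
graph_edges <- function(graph) {
  stopifnot(inherits(graph, "tract_graph"))
  n <- graph$n_tracts
  out <- matrix(0L, nrow = graph$n_edges, ncol = 2L,
                dimnames = list(NULL, c("i", "j")))
  k <- 0L
  for (i in seq_len(n)) {
    js <- graph$nb[[i]]
    js <- js[js > i]
    for (j in js) {
      k <- k + 1L
      out[k, ] <- c(i, j)
    }
  }
  out
}

#' Graph Laplacian D - W
#'
#' Dense Laplacian matrix of the adjacency graph; the ICAR precision is
#' `tau_u * (D - W)`. Intended for oracles and small-graph computations.
#'
#' @param graph a [tract_graph()].
#' @return an `n_tracts` x `n_tracts` numeric matrix.
#' @export
graph_laplacian <- function(graph) {
  stopifnot(inherits(graph, "tract_graph"))
  n <- graph$n_tracts
  L <- matrix(0, n, n)
  for (i in seq_len(n)) {
    js <- graph$nb[[i]]
    L[i, js] <- -1
    L[i, i] <- length(js)
  }
  L
}

#' Connected components of a tract graph
#'
#' @param graph a [tract_graph()].
#' @return integer vector of component labels (1-based) per tract.
#' @export
graph_components <- function(graph) {
  stopifnot(inherits(graph, "tract_graph"))
  n <- graph$n_tracts
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      i <- queue[[1L]]
      queue <- queue[-1L]
      for (j in graph$nb[[i]]) {
        if (comp[j] == 0L) {
          comp[j] <- cur
          queue <- c(queue, j)
        }
      }
    }
  }
  comp
}

stop_if_disconnected <- function(graph) {
  comp <- graph_components(graph)
  if (max(comp) > 1L) {
    sizes <- table(comp)
    stop("adjacency graph is disconnected: ", max(comp),
         " components of sizes ", paste(sizes, collapse = ", "),
         "; the sum-to-zero ICAR constraint requires a connected graph")
  }
  invisible(TRUE)
}

#' Generate a rook-adjacency lattice of census tracts
#'
#' Builds a rectangular grid of synthetic census tracts with 4-neighbour
#' (rook) contiguity, the stand-in for a real tract map. Tract ids are
#' assigned in row-major order as `"t0001"`, `"t0002"`, ...
#'
#' @param n_rows,n_cols grid dimensions; the product must be at least 2
#'   (the ICAR prior is undefined on a single tract).
#' @return a list with `tracts` (data.frame: `tract_id`, `row`, `col`) and
#'   `graph` (a [tract_graph()]).
#' @examples
#' lat <- generate_lattice(2, 2)
#' lat$graph$n_edges  # 4
#' @export
generate_lattice <- function(n_rows, n_cols) {
  n_rows <- as.integer(n_rows); n_cols <- as.integer(n_cols)
  if (n_rows < 1L || n_cols < 1L) stop("grid dimensions must be >= 1")
  n <- n_rows * n_cols
  if (n < 2L) stop("a 1x1 lattice has no neighbour structure (ICAR undefined)")
  id_at <- function(r, c) (r - 1L) * n_cols + c
  tract_id <- sprintf("t%04d", seq_len(n))
  rows <- rep(seq_len(n_rows), each = n_cols)
  cols <- rep(seq_len(n_cols), times = n_rows)
  # rook edges: right and down from each cell
  e <- matrix(0L, nrow = n_rows * (n_cols - 1L) + n_cols * (n_rows - 1L), ncol = 2L)
  k <- 0L
  for (r in seq_len(n_rows)) {
    for (c in seq_len(n_cols)) {
      if (c < n_cols) { k <- k + 1L; e[k, ] <- c(id_at(r, c), id_at(r, c + 1L)) }
      if (r < n_rows) { k <- k + 1L; e[k, ] <- c(id_at(r, c), id_at(r + 1L, c)) }
    }
  }
  list(
    tracts = data.frame(tract_id = tract_id, row = rows, col = cols,
                        stringsAsFactors = FALSE),
    graph = tract_graph(tract_id, e)
  )
}

#' Unit-square polygons for a lattice
#'
#' Planar polygon rings for the tracts of [generate_lattice()], usable with
#' [write_choropleth()]. Coordinates are grid units; (col, -row) so maps
#' render with row 1 on top.
#'
#' @param tracts the `tracts` data.frame from [generate_lattice()].
#' @return named list of 5x2 coordinate matrices (closed rings), one per tract.
#' @export
lattice_polygons <- function(tracts) {
  stopifnot(all(c("tract_id", "row", "col") %in% names(tracts)))
  polys <- lapply(seq_len(nrow(tracts)), function(i) {
    r <- tracts$row[i]; c <- tracts$col[i]
    x0 <- c - 1; x1 <- c; y0 <- -r; y1 <- -(r - 1)
    matrix(c(x0, y0, x1, y0, x1, y1, x0, y1, x0, y0),
           ncol = 2L, byrow = TRUE)
  })
  names(polys) <- tracts$tract_id
  polys
}
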