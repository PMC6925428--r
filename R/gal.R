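#' Read a GAL spatial-weights file
#'
#' GAL is the de-facto interchange format for contiguity weights: a header
#' line with the number of units, then for each unit a line `id n_neighbours`
#' followed by a line listing the neighbour ids. Asymmetric entries (i lists
#' j but j does not list i) are symmetrized with a warning; a neighbour id
#' that is never declared as a unit is an error.
#'
#' @param path path to the GAL file.
#' @return a [tract_graph()].
#' @export
read_gal <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty GAL file: ", path)
  header <- strsplit(lines[[1L]], "\\s+")[[1L]]
  # GAL headers are either "n" or "0 n shapefile field"; the count is the
  # sole number, or the second token in the 4-token variant
  n <- if (length(header) >= 2L) as.integer(header[[2L]]) else as.integer(header[[1L]])
  if (is.na(n) || n < 1L) stop("cannot parse GAL header: ", lines[[1L]])
  ids <- character(n)
  nb_ids <- vector("list", n)
  ln <- 1L
  for (k in seq_len(n)) {
    ln <- ln + 1L
    if (ln > length(lines)) stop("GAL file truncated at line ", ln)
    head_k <- strsplit(lines[[ln]], "\\s+")[[1L]]
    if (length(head_k) != 2L)
      stop("malformed GAL record header at line ", ln, ": ", lines[[ln]])
    ids[[k]] <- head_k[[1L]]
    cnt <- as.integer(head_k[[2L]])
    if (is.na(cnt) || cnt < 0L)
      stop("bad neighbour count at line ", ln, ": ", lines[[ln]])
    if (cnt > 0L) {
      ln <- ln + 1L
      if (ln > length(lines)) stop("GAL file truncated at line ", ln)
      nbk <- strsplit(lines[[ln]], "\\s+")[[1L]]
      if (length(nbk) != cnt)
        stop("expected ", cnt, " neighbour ids at line ", ln,
             ", found ", length(nbk))
      nb_ids[[k]] <- nbk
    } else {
      nb_ids[[k]] <- character(0)
    }
  }
  for (k in seq_len(n)) {
    dangling <- setdiff(nb_ids[[k]], ids)
    if (length(dangling))
      stop("neighbour id(s) not declared as units (record for ", ids[[k]],
           "): ", paste(dangling, collapse = ", "))
  }
  idx <- lapply(nb_ids, match, table = ids)
  # symmetrize, warning when one-sided
  asym <- character(0)
  for (i in seq_len(n)) {
    for (j in idx[[i]]) {
      if (!(i %in% idx[[j]])) asym <- c(asym, paste0(ids[[i]], "->", ids[[j]]))
    }
  }
  if (length(asym))
    warning("asymmetric GAL entries symmetrized: ", paste(asym, collapse = ", "))
  edges <- do.call(rbind, lapply(seq_len(n), function(i) {
    if (length(idx[[i]])) cbind(i, idx[[i]]) else NULL
  }))
  if (is.null(edges)) stop("GAL file declares no edges; graph would be disconnected")
  tract_graph(ids, edges)
}

#' Write a GAL spatial-weights file
#'
#' @param graph a [tract_graph()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gal <- function(graph, path) {
  stopifnot(inherits(graph, "tract_graph"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(as.character(graph$n_tracts), con)
  for (i in seq_len(graph$n_tracts)) {
    js <- graph$nb[[i]]
    writeLines(paste(graph$tract_id[i], length(js)), con)
    if (length(js))
      writeLines(paste(graph$tract_id[js], collapse = " "), con)
  }
  invisible(path)
}
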