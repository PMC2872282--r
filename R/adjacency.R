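#' Symmetric adjacency graph for areal units
#'
#' Constructs the neighbourhood structure used by the intrinsic CAR (ICAR)
#' prior on latent area effects. The graph must be symmetric and free of
#' self-loops; isolated areas ("islands") are permitted and flagged, and the
#' ICAR machinery treats them as free Normal(0, sigma^2) effects.
#'
#' Connected components, the graph Laplacian and the sum of the logs of its
#' non-null eigenvalues (per component) are precomputed at construction, so
#' that ICAR log-densities can be evaluated with their full normalising
#' constant and ICAR fields can be sampled spectrally.
#'
#' @param neighbours list of integer vectors, one per node, giving the
#'   indices (1-based) of adjacent nodes. An empty vector marks an island.
#' @return An object of class \code{jp_graph} with elements \code{n},
#'   \code{nbr}, \code{degree}, \code{component} (membership labels),
#'   \code{n_components}, \code{island} (logical), \code{laplacian} and
#'   \code{slogdet} (sum of log non-null Laplacian eigenvalues over all
#'   components of size >= 2).
#' @export
adjacency_graph <- function(neighbours) {
  if (!is.list(neighbours) || length(neighbours) == 0L) {
    stop("'neighbours' must be a non-empty list of integer vectors")
  }
  n <- length(neighbours)
  nbr <- lapply(neighbours, function(v) sort(unique(as.integer(v))))
  for (i in seq_len(n)) {
    v <- nbr[[i]]
    if (length(v) && (min(v) < 1L || max(v) > n)) {
      stop("neighbour index out of range at node ", i)
    }
    if (i %in% v) stop("self-loop at node ", i)
  }
  # symmetry check
  for (i in seq_len(n)) {
    for (j in nbr[[i]]) {
      if (!(i %in% nbr[[j]])) {
        stop("adjacency not symmetric: node ", i, " lists ", j,
             " but not vice versa")
      }
    }
  }
  deg <- vapply(nbr, length, integer(1))
  comp <- .graph_components(nbr)
  L <- diag(deg, nrow = n)
  for (i in seq_len(n)) L[i, nbr[[i]]] <- -1
  # pseudo-log-determinant: sum of log eigenvalues over the non-null space
  # of each component with >= 2 nodes
  slogdet <- 0
  for (k in seq_len(max(comp))) {
    idx <- which(comp == k)
    if (length(idx) >= 2L) {
      ev <- eigen(L[idx, idx, drop = FALSE], symmetric = TRUE,
                  only.values = TRUE)$values
      slogdet <- slogdet + sum(log(ev[ev > 1e-9]))
    }
  }
  structure(list(n = n, nbr = nbr, degree = deg, component = comp,
                 n_components = max(comp), island = deg == 0L,
                 laplacian = L, slogdet = slogdet),
            class = "jp_graph")
}

# connected-component labels by breadth-first search
.graph_components <- function(nbr) {
  n <- length(nbr)
  comp <- integer(n)
  lab <- 0L
  for (s in seq_len(n)) {
    if (comp[s] > 0L) next
    lab <- lab + 1L
    queue <- s
    comp[s] <- lab
    while (length(queue)) {
      i <- queue[[1L]]
      queue <- queue[-1L]
      for (j in nbr[[i]]) {
        if (comp[j] == 0L) {
          comp[j] <- lab
          queue <- c(queue, j)
        }
      }
    }
  }
  comp
}

#' @export
print.jp_graph <- function(x, ...) {
  cat("jp_graph:", x$n, "nodes,", sum(x$degree) / 2, "edges,",
      x$n_components, "component(s),", sum(x$island), "island(s)\n")
  invisible(x)
}

#' Edge list of an adjacency graph
#'
#' Returns each undirected edge once (i < j); used by the ICAR
#' pairwise-difference kernel and by Moran-type statistics.
#'
#' @param graph a \code{jp_graph}
#' @return two-column integer matrix of edges
#' @export
graph_edges <- function(graph) {
  stopifnot(inherits(graph, "jp_graph"))
  ii <- rep.int(seq_len(graph$n), graph$degree)
  jj <- unlist(graph$nbr, use.names = FALSE)
  keep <- ii < jj
  cbind(i = ii[keep], j = jj[keep])
}

#' Read a GAL-style neighbour list
#'
#' The GAL dialect accepted here is: a first line holding the node count,
#' then for each node a line \code{id degree} followed by a line (or the same
#' line) of neighbour ids. Asymmetric input is symmetrised with a warning.
#'
#' @param path path to a GAL file
#' @return a \code{jp_graph}
#' @export
read_adjacency_gal <- function(path) {
  toks <- scan(path, what = integer(), quiet = TRUE)
  if (length(toks) < 1L) stop("empty GAL file: ", path)
  n <- toks[[1L]]
  if (n < 1L) stop("GAL node count must be >= 1")
  nbr <- vector("list", n)
  pos <- 2L
  for (k in seq_len(n)) {
    if (pos + 1L > length(toks) + 1L) stop("truncated GAL file: ", path)
    id <- toks[[pos]]
    d <- toks[[pos + 1L]]
    if (id < 1L || id > n) stop("GAL node id out of range: ", id)
    if (d < 0L || pos + 1L + d > length(toks)) {
      stop("truncated GAL record for node ", id)
    }
    v <- if (d > 0L) toks[(pos + 2L):(pos + 1L + d)] else integer(0)
    if (length(v) && (min(v) < 1L || max(v) > n)) {
      stop("GAL neighbour id out of range for node ", id)
    }
    nbr[[id]] <- as.integer(v)
    pos <- pos + 2L + d
  }
  # symmetrise if needed
  asym <- FALSE
  for (i in seq_len(n)) {
    for (j in nbr[[i]]) {
      if (!(i %in% nbr[[j]])) {
        nbr[[j]] <- c(nbr[[j]], i)
        asym <- TRUE
      }
    }
  }
  if (asym) warning("asymmetric GAL input symmetrised: ", path)
  adjacency_graph(nbr)
}

#' Write a GAL-style neighbour list
#'
#' @param graph a \code{jp_graph}
#' @param path output path
#' @return \code{path}, invisibly
#' @export
write_adjacency_gal <- function(graph, path) {
  stopifnot(inherits(graph, "jp_graph"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(as.character(graph$n), con)
  for (i in seq_len(graph$n)) {
    writeLines(paste(i, graph$degree[[i]]), con)
    if (graph$degree[[i]] > 0L) {
      writeLines(paste(graph$nbr[[i]], collapse = " "), con)
    }
  }
  invisible(path)
}
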