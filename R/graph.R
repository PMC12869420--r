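#' Feature graphs
#'
#' A `feature_graph` is a node-labelled graph over a fixed, ordered feature
#' space. It is the common currency of the package: the external biological
#' network, the tree-ensemble-generated graph and the simulator's scale-free
#' network are all `feature_graph` objects. Node identity is positional
#' against `node_labels`; all adjacency matrices are aligned to that ordering.
#' Isolated nodes are permitted and preserved.
#'
#' Edges are stored as a two-column integer matrix of 1-based node indices
#' (source, target). For undirected graphs edges are stored canonically with
#' `source <= target` and expand symmetrically in adjacency form. Duplicate
#' edges collapse to one; self-loops are not stored as edges (self-loops are
#' added globally through [add_self_loops()]).
#'
#' @param node_labels character vector of feature identifiers (length p).
#' @param edges two-column matrix of node indices, or a zero-row matrix /
#'   `NULL` for an edgeless graph. Character labels are also accepted and
#'   matched against `node_labels`.
#' @param directed logical; directed edges (`source -> target`) or undirected.
#' @return An object of class `feature_graph` with elements `node_labels`,
#'   `edges` (integer matrix) and `directed`.
#' @examples
#' g <- feature_graph(c("g1", "g2", "g3"), rbind(c(1, 2)), directed = FALSE)
#' to_adjacency(g)
#' @export
feature_graph <- function(node_labels, edges = NULL, directed = FALSE) {
  node_labels <- as.character(node_labels)
  p <- length(node_labels)
  if (p < 1L) stop("a feature_graph needs at least one node")
  if (anyDuplicated(node_labels)) stop("node labels must be unique")
  if (is.null(edges) || (is.matrix(edges) && nrow(edges) == 0L)) {
    edges <- matrix(integer(0), ncol = 2L)
  } else {
    edges <- as.matrix(edges)
    if (ncol(edges) != 2L) stop("edges must have two columns (source, target)")
    if (is.character(edges)) {
      idx <- match(edges, node_labels)
      if (anyNA(idx)) {
        stop("unknown node labels in edges: ",
             paste(unique(edges[is.na(idx)]), collapse = ", "))
      }
      edges <- matrix(idx, ncol = 2L)
    }
    storage.mode(edges) <- "integer"
    if (any(edges < 1L) || any(edges > p)) {
      stop("edge indices must lie in [1, ", p, "]")
    }
  }
  edges <- edges[edges[, 1L] != edges[, 2L], , drop = FALSE]
  if (!directed && nrow(edges)) {
    swap <- edges[, 1L] > edges[, 2L]
    edges[swap, ] <- edges[swap, c(2L, 1L), drop = FALSE]
  }
  edges <- unique(edges)
  edges <- edges[order(edges[, 1L], edges[, 2L]), , drop = FALSE]
  dimnames(edges) <- list(NULL, c("source", "target"))
  structure(list(node_labels = node_labels, edges = edges,
                 directed = isTRUE(directed)),
            class = "feature_graph")
}

#' @export
print.feature_graph <- function(x, ...) {
  cat(sprintf("feature_graph: %d nodes, %d %s edges\n",
              length(x$node_labels), nrow(x$edges),
              if (x$directed) "directed" else "undirected"))
  invisible(x)
}

n_nodes <- function(g) length(g$node_labels)

#' Binary adjacency matrix of a feature graph
#'
#' Entry `(u, v)` is 1 iff the edge `u -> v` exists; for undirected graphs
#' each edge fills both `(u, v)` and `(v, u)`. The result carries a
#' `self_loops` attribute (`FALSE` here); see [add_self_loops()].
#'
#' @param g a [feature_graph()].
#' @return p x p 0/1 matrix with `dimnames` set to the node labels.
#' @export
to_adjacency <- function(g) {
  stopifnot(inherits(g, "feature_graph"))
  p <- n_nodes(g)
  a <- matrix(0, p, p, dimnames = list(g$node_labels, g$node_labels))
  if (nrow(g$edges)) {
    a[g$edges] <- 1
    if (!g$directed) a[g$edges[, c(2L, 1L), drop = FALSE]] <- 1
  }
  attr(a, "self_loops") <- FALSE
  a
}

#' Augment an adjacency matrix with self-loops
#'
#' Returns the self-loop-augmented adjacency used to mask the first network
#' layer, computed entrywise as `A + I` clipped to `{0, 1}` so pre-existing
#' self-loops do not produce entries of 2. Off-diagonal entries are unchanged.
#'
#' @param a square 0/1 adjacency matrix.
#' @return The augmented matrix with unit diagonal and attribute
#'   `self_loops = TRUE`.
#' @export
add_self_loops <- function(a) {
  if (!is.matrix(a) || nrow(a) != ncol(a)) stop("adjacency must be square")
  a <- pmin(a + diag(nrow(a)), 1)
  attr(a, "self_loops") <- TRUE
  a
}

#' Union of feature graphs over a shared node space
#'
#' Merges the edge sets of several graphs defined on the same ordered label
#' space (used to aggregate per-tree graphs into the generated graph).
#' Idempotent, associative and commutative.
#'
#' @param graphs non-empty list of [feature_graph()]s with identical
#'   `node_labels` and `directed` flags.
#' @return A single `feature_graph` whose edge set is the union.
#' @export
union_graphs <- function(graphs) {
  if (!length(graphs)) stop("cannot union an empty list of graphs")
  ref <- graphs[[1L]]
  for (g in graphs) {
    if (!identical(g$node_labels, ref$node_labels) ||
        !identical(g$directed, ref$directed)) {
      stop("all graphs must share node labels and directedness")
    }
  }
  edges <- do.call(rbind, lapply(graphs, `[[`, "edges"))
  feature_graph(ref$node_labels, edges, directed = ref$directed)
}

#' Read a feature graph from a two-column edge list
#'
#' Parses whitespace- or tab-delimited text with two label columns
#' (source, target); `#`-prefixed lines are comments. Edge labels are matched
#' against `node_labels`; unknown labels either abort (`unknown = "fail"`) or
#' are dropped with a warning (`unknown = "skip"`).
#'
#' @param path file path.
#' @param node_labels the canonical ordered feature label space.
#' @param directed logical.
#' @param unknown policy for labels absent from `node_labels`.
#' @param header logical; skip a first non-comment header line.
#' @return A [feature_graph()].
#' @export
read_edge_list <- function(path, node_labels, directed = FALSE,
                           unknown = c("fail", "skip"), header = FALSE) {
  unknown <- match.arg(unknown)
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  lines <- lines[keep]
  lineno <- which(keep)
  if (header && length(lines)) {
    lines <- lines[-1L]
    lineno <- lineno[-1L]
  }
  if (!length(lines)) return(feature_graph(node_labels, directed = directed))
  parts <- strsplit(trimws(lines), "[[:space:],]+")
  bad <- which(vapply(parts, length, 1L) < 2L)
  if (length(bad)) {
    stop("unparseable edge on line ", lineno[bad[1L]], " of ", path)
  }
  src <- vapply(parts, `[[`, "", 1L)
  dst <- vapply(parts, `[[`, "", 2L)
  known <- src %in% node_labels & dst %in% node_labels
  if (!all(known)) {
    missing <- setdiff(unique(c(src[!known], dst[!known])), node_labels)
    if (unknown == "fail") {
      stop("edge list references unknown labels: ",
           paste(missing, collapse = ", "))
    }
    warning("dropped ", sum(!known), " edge(s) with unknown labels: ",
            paste(missing, collapse = ", "))
    src <- src[known]; dst <- dst[known]
  }
  feature_graph(node_labels, cbind(src, dst), directed = directed)
}

#' Write a feature graph as an edge list
#'
#' Two tab-separated label columns, one edge per line; the inverse of
#' [read_edge_list()] (round-trips losslessly).
#'
#' @param g a [feature_graph()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(g, path) {
  stopifnot(inherits(g, "feature_graph"))
  lab <- g$node_labels
  lines <- if (nrow(g$edges)) {
    paste(lab[g$edges[, 1L]], lab[g$edges[, 2L]], sep = "\t")
  } else character(0)
  writeLines(lines, path)
  invisible(path)
}

# Convert to an igraph object (used for centrality; keeps node order).
as_igraph <- function(g) {
  ig <- igraph::make_empty_graph(n = n_nodes(g), directed = g$directed)
  igraph::V(ig)$name <- g$node_labels
  if (nrow(g$edges)) ig <- igraph::add_edges(ig, t(g$edges))
  ig
}
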