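# Cyclic permutation graph (cp-graph).
#
# The VD-vector calculus ignores signs; the cp-graph brings them back.  Its
# vertices are the signed elements of pi and it has an edge {pi_i, pi_j} of
# weight c_ij(X) for every positive crossing value, so the total edge weight
# is cn(X).  A connected component is odd when it contains an odd number of
# negative elements; each odd component costs one extra 1-reversal, which is
# what ties cn(X) + cc^-(G) to the sorting distance.

# component labels for n vertices and an edge list (two-column matrix)
component_labels <- function(n, edges) {
  parent <- seq_len(n)
  find <- function(a) {
    while (parent[a] != a) {
      parent[a] <<- parent[parent[a]]
      a <- parent[a]
    }
    a
  }
  if (length(edges))
    for (e in seq_len(nrow(edges))) {
      ra <- find(edges[e, 1L])
      rb <- find(edges[e, 2L])
      if (ra != rb) parent[ra] <- rb
    }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

#' Build the cyclic permutation graph
#'
#' Constructs \eqn{G^X_\pi}: vertices are the signed elements
#' \eqn{\pi_1..\pi_n}; for every ordered pair with \eqn{c_{ij}(X) > 0} there
#' is an edge \eqn{\{\pi_i, \pi_j\}} of weight \eqn{c_{ij}(X)}.  Edge weights
#' sum to \eqn{cn(X)}.
#'
#' @param pi an \code{sso_perm}.
#' @param X a VD-vector valid for \code{pi}.
#' @return an object of class \code{cp_graph}: a list with the vertex
#'   elements, the edge table (positions, elements, weights), per-vertex
#'   component labels, per-component parity (\code{"odd"}/\code{"even"} by
#'   count of negative elements), \code{cn} and the component count.
#' @examples
#' p <- signed_permutation(c(4, 2, 3, -1, -5))
#' g <- cp_graph(p, c(3, 0, 0, -3, 0))
#' g$cn                 # 5
#' odd_components(g)    # 2
#' @export
cp_graph <- function(pi, X) {
  if (!validate_vd(X, pi))
    stop("X is not a valid displacement vector for pi")
  n <- length(pi)
  C <- crossing_matrix(X)
  pos <- which(C > 0L, arr.ind = TRUE)      # each unordered pair once
  w <- C[pos]
  comp <- component_labels(n, pos)
  neg <- unclass(pi) < 0L
  parity <- vapply(seq_len(max(comp)), function(cc)
    if (sum(neg[comp == cc]) %% 2L == 1L) "odd" else "even", character(1))
  structure(list(
    elements = unclass(pi),
    edges = data.frame(i = pos[, 1L], j = pos[, 2L],
                       from = unclass(pi)[pos[, 1L]],
                       to = unclass(pi)[pos[, 2L]],
                       weight = w),
    membership = comp,
    parity = parity,
    cn = sum(w),
    cc = max(comp)
  ), class = "cp_graph")
}

#' Number of odd components
#'
#' Counts connected components of a cp-graph containing an odd number of
#' negative elements (written \eqn{cc^-}).  Each such component requires one
#' 1-reversal that no swap can replace.
#'
#' @param g a \code{cp_graph}.
#' @return a nonnegative integer.
#' @export
odd_components <- function(g) {
  stopifnot(inherits(g, "cp_graph"))
  sum(g$parity == "odd")
}

#' @export
print.cp_graph <- function(x, ...) {
  cat("cp-graph on ", length(x$elements), " elements: cn = ", x$cn,
      ", cc = ", x$cc, ", cc- = ", odd_components(x), "\n", sep = "")
  if (nrow(x$edges)) {
    lab <- sprintf("{%+d,%+d}x%d", x$edges$from, x$edges$to, x$edges$weight)
    cat("  edges: ", paste(lab, collapse = " "), "\n", sep = "")
  }
  invisible(x)
}

#' Convert a cp-graph to an igraph object
#'
#' Vertices are named by their signed element (e.g. \code{"+4"}); edge
#' weights are the crossing values.
#'
#' @param g a \code{cp_graph}.
#' @return an \code{igraph} graph with a \code{weight} edge attribute.
#' @export
as_igraph <- function(g) {
  stopifnot(inherits(g, "cp_graph"))
  vnames <- sprintf("%+d", g$elements)
  ig <- igraph::make_empty_graph(n = length(vnames), directed = FALSE)
  ig <- igraph::set_vertex_attr(ig, "name", value = vnames)
  if (nrow(g$edges)) {
    ig <- igraph::add_edges(ig, rbind(g$edges$i, g$edges$j))
    ig <- igraph::set_edge_attr(ig, "weight", value = g$edges$weight)
  }
  ig
}

#' Export a cp-graph in DOT format
#'
#' Writes an undirected DOT graph with weight labels, for rendering with
#' Graphviz.
#'
#' @param g a \code{cp_graph}.
#' @param file optional path; when missing the DOT text is returned.
#' @return the DOT text, invisibly when written to a file.
#' @export
cp_graph_dot <- function(g, file = NULL) {
  stopifnot(inherits(g, "cp_graph"))
  node <- sprintf('  "%+d";', g$elements)
  edge <- if (nrow(g$edges))
    sprintf('  "%+d" -- "%+d" [label=%d];',
            g$edges$from, g$edges$to, g$edges$weight)
  else character(0)
  txt <- paste(c("graph cp {", node, edge, "}"), collapse = "\n")
  if (is.null(file)) return(txt)
  writeLines(txt, file)
  invisible(txt)
}
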