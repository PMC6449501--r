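#' Construct a morphology graph
#'
#' A `morph_graph` is the undirected geometric graph view of a traced neuron
#' or neuron cluster: reconstruction points with 3D coordinates and radii,
#' undirected edges between them, and a set of designated soma nodes. It is
#' the common currency of all other functions in the package. Unlike a plain
#' SWC tree it carries no parent/child direction: in a multi-soma cluster the
#' direction stored by upstream tracers is unreliable, so only connectivity is
#' kept.
#'
#' @param nodes data.frame with columns `id` (unique positive integers),
#'   `type` (SWC type code, 1 = soma), `x`, `y`, `z` (micrometres),
#'   `radius` (micrometres, >= 0).
#' @param edges two-column integer matrix of undirected edges (node ids).
#'   Self loops and duplicate edges are rejected.
#' @param soma_ids integer vector of node ids acting as somas; must be a
#'   nonempty subset of `nodes$id`.
#' @return an object of class `morph_graph` with elements `nodes` (sorted by
#'   id), `edges` (canonicalized, sorted) and `soma_ids` (sorted).
#' @export
morph_graph <- function(nodes, edges, soma_ids) {
  stopifnot(is.data.frame(nodes))
  need <- c("id", "type", "x", "y", "z", "radius")
  if (!all(need %in% names(nodes)))
    .gcut_stop(paste("nodes must have columns:", paste(need, collapse = ", ")),
               "gcut_structure_error")
  if (nrow(nodes) == 0L) .gcut_stop("graph has zero nodes", "gcut_empty_input")
  nodes$id <- as.integer(nodes$id)
  if (anyDuplicated(nodes$id))
    .gcut_stop("duplicate node ids", "gcut_structure_error")
  if (any(nodes$id <= 0L)) .gcut_stop("node ids must be positive", "gcut_structure_error")
  if (any(nodes$radius < 0)) .gcut_stop("negative radius", "gcut_structure_error")
  nodes <- nodes[order(nodes$id), need, drop = FALSE]
  rownames(nodes) <- NULL

  edges <- matrix(as.integer(edges), ncol = 2L)
  if (nrow(edges) > 0L) {
    if (!all(edges %in% nodes$id))
      .gcut_stop("edge references unknown node id", "gcut_structure_error")
    if (any(edges[, 1L] == edges[, 2L]))
      .gcut_stop("self-loop edge", "gcut_structure_error")
    edges <- cbind(pmin(edges[, 1L], edges[, 2L]), pmax(edges[, 1L], edges[, 2L]))
    edges <- edges[order(edges[, 1L], edges[, 2L]), , drop = FALSE]
    if (anyDuplicated(edges) > 0L)
      .gcut_stop("duplicate edge", "gcut_structure_error")
  }
  soma_ids <- sort(unique(as.integer(soma_ids)))
  if (length(soma_ids) == 0L)
    .gcut_stop("at least one soma node is required", "gcut_structure_error")
  if (!all(soma_ids %in% nodes$id))
    .gcut_stop("soma_ids contains an unknown node id", "gcut_structure_error")

  structure(list(nodes = nodes, edges = edges, soma_ids = soma_ids),
            class = "morph_graph")
}

#' @export
print.morph_graph <- function(x, ...) {
  cat(sprintf("<morph_graph> %d nodes, %d edges, %d soma(s)\n",
              nrow(x$nodes), nrow(x$edges), length(x$soma_ids)))
  invisible(x)
}

# index of a node id into the (id-sorted) nodes table
.node_index <- function(g, ids) match(ids, g$nodes$id)

#' Node coordinates
#' @param g a [morph_graph()]
#' @param ids node ids (default all, in id order)
#' @return numeric matrix with columns x, y, z
#' @export
node_xyz <- function(g, ids = g$nodes$id) {
  as.matrix(g$nodes[.node_index(g, ids), c("x", "y", "z"), drop = FALSE])
}

# degree of every node, named by id
.node_degrees <- function(g) {
  deg <- integer(nrow(g$nodes))
  names(deg) <- g$nodes$id
  if (nrow(g$edges) > 0L) {
    t <- table(factor(as.vector(g$edges), levels = g$nodes$id))
    deg[] <- as.integer(t)
  }
  deg
}

.as_igraph <- function(g, drop_nodes = integer()) {
  keep <- setdiff(g$nodes$id, drop_nodes)
  e <- g$edges
  if (nrow(e) > 0L)
    e <- e[e[, 1L] %in% keep & e[, 2L] %in% keep, , drop = FALSE]
  igraph::graph_from_data_frame(
    data.frame(from = as.character(e[, 1L]), to = as.character(e[, 2L])),
    directed = FALSE,
    vertices = data.frame(name = as.character(keep)))
}

#' Is a morphology graph connected?
#' @param g a [morph_graph()]
#' @return logical
#' @export
is_connected_graph <- function(g) {
  if (nrow(g$nodes) == 1L) return(TRUE)
  igraph::is_connected(.as_igraph(g))
}

#' Classify every node by its topological role
#'
#' Nodes fall into four roles. Somas are whatever the input designates as
#' cell bodies, regardless of degree. Of the remaining nodes, those with more
#' than two neighbours are branch (bifurcation) nodes, those with exactly one
#' neighbour are leaves, and degree-2 nodes are path nodes that only carry
#' geometry. Somas, branch nodes and leaves are jointly the topological
#' nodes; branches of the morphology run between consecutive topological
#' nodes.
#'
#' @param g a [morph_graph()]
#' @return character vector named by node id with values
#'   `"soma"`, `"branch"`, `"leaf"` or `"path"`
#' @export
classify_nodes <- function(g) {
  deg <- .node_degrees(g)
  role <- ifelse(deg > 2L, "branch", ifelse(deg == 2L, "path", "leaf"))
  # degree-0 isolated nodes are degenerate leaves unless they are somas
  role[as.character(g$soma_ids)] <- "soma"
  role
}

#' Decompose a morphology graph into branches
#'
#' A branch is a maximal curve joining two topological nodes
#' (soma/branch/leaf) whose interior consists only of path nodes. Branches
#' partition the edge set and are the atomic unit of soma assignment.
#'
#' Branch node paths are canonically oriented (smaller endpoint id first) and
#' branches are numbered 1..n in a deterministic order, so identical graphs
#' always yield identical branch ids.
#'
#' @param g a [morph_graph()]
#' @return list of branches; each branch is a list with `id`, `node_path`
#'   (integer node ids from endpoint a to endpoint b), `ends` (the two
#'   endpoint ids) and `length` (arc length, micrometres). A cycle made
#'   entirely of path nodes has no branch decomposition and raises an error.
#' @export
extract_branches <- function(g) {
  role <- classify_nodes(g)
  topo <- g$nodes$id[role[as.character(g$nodes$id)] != "path"]
  if (nrow(g$edges) == 0L) return(list())

  # adjacency list by node id
  adj <- split(c(g$edges[, 2L], g$edges[, 1L]),
               factor(c(g$edges[, 1L], g$edges[, 2L]), levels = g$nodes$id))
  edge_key <- function(a, b) paste0(pmin(a, b), "-", pmax(a, b))
  used <- new.env(parent = emptyenv())

  paths <- list()
  for (t in sort(topo)) {
    for (nb in sort(adj[[as.character(t)]])) {
      k <- edge_key(t, nb)
      if (!is.null(used[[k]])) next
      # walk from t through nb across path nodes until next topological node
      path <- c(t, nb)
      used[[k]] <- TRUE
      prev <- t; cur <- nb
      while (role[[as.character(cur)]] == "path") {
        nxt <- setdiff(adj[[as.character(cur)]], prev)
        if (length(nxt) != 1L) break  # defensive; degree-2 guaranteed by role
        used[[edge_key(cur, nxt)]] <- TRUE
        path <- c(path, nxt)
        prev <- cur; cur <- nxt
      }
      paths[[length(paths) + 1L]] <- path
    }
  }
  # any edge not swept lies on a cycle of pure path nodes
  n_used <- length(ls(used))
  if (n_used != nrow(g$edges))
    .gcut_stop("graph contains a cycle composed solely of path nodes; no branch decomposition exists",
               "gcut_unsupported_topology")

  # canonical orientation + dedupe (each branch was found from both ends)
  canon <- lapply(paths, function(p) {
    n <- length(p)
    rev_p <- rev(p)
    if (p[1L] > p[n]) p <- rev_p
    else if (p[1L] == p[n]) {          # loop anchored at one topological node
      if (n >= 2L && rev_p[2L] < p[2L]) p <- rev_p
    }
    p
  })
  keys <- vapply(canon, function(p) paste(p, collapse = ","), "")
  canon <- canon[!duplicated(keys)]

  ord <- order(vapply(canon, `[`, 0L, 1L),
               vapply(canon, function(p) p[length(p)], 0L),
               vapply(canon, function(p) if (length(p) >= 2L) p[2L] else 0L,
                      0L))
  canon <- canon[ord]

  lapply(seq_along(canon), function(i) {
    p <- canon[[i]]
    list(id = i,
         node_path = p,
         ends = c(p[1L], p[length(p)]),
         length = .polyline_length(node_xyz(g, p)))
  })
}

# coordinates of a branch's node path, optionally reversed
.branch_coords <- function(g, br, reverse = FALSE) {
  p <- br$node_path
  if (reverse) p <- rev(p)
  node_xyz(g, p)
}
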