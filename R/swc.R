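#' Read a neuron or neuron-cluster morphology from an SWC file
#'
#' The SWC dialect accepted here is the de-facto standard: '#' comment lines,
#' seven whitespace-separated columns (id, type, x, y, z, radius, parent),
#' parent -1 marking a root. Unlike single-neuron SWC, multiple roots and
#' multiple type-1 (soma) nodes are permitted, which is how multi-soma neuron
#' clusters are serialized by upstream tracers.
#'
#' A soma traced as several adjacent type-1 nodes is collapsed to a single
#' node at their centroid (the assignment model treats a soma as a point);
#' set `collapse_somas = FALSE` to keep the raw nodes.
#'
#' @param path SWC file path
#' @param soma_ids optional explicit soma node ids; overrides the default
#'   rule (all type-1 nodes are somas)
#' @param collapse_somas collapse connected groups of soma nodes to their
#'   centroid (default TRUE)
#' @param scale optional length-3 numeric, multiplies x/y/z (anisotropic
#'   voxel-to-micrometre scaling)
#' @param require_connected error if the file describes a disconnected graph
#' @return a [morph_graph()]
#' @export
read_swc <- function(path, soma_ids = NULL, collapse_somas = TRUE,
                     scale = c(1, 1, 1), require_connected = TRUE) {
  if (!file.exists(path)) .gcut_stop(paste("file not found:", path), "gcut_io_error")
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) .gcut_stop("SWC file contains zero nodes", "gcut_empty_input")

  fields <- strsplit(trimws(lines), "\\s+")
  bad <- which(lengths(fields) != 7L)
  if (length(bad) > 0L)
    .gcut_stop(sprintf("malformed SWC line %d: expected 7 fields, got %d",
                       lineno[bad[1L]], length(fields[[bad[1L]]])),
               "gcut_parse_error")
  m <- matrix(as.numeric(unlist(fields)), ncol = 7L, byrow = TRUE)
  if (anyNA(m))
    .gcut_stop(sprintf("malformed SWC line %d: non-numeric field",
                       lineno[which(rowSums(is.na(m)) > 0)[1L]]),
               "gcut_parse_error")

  nodes <- data.frame(id = as.integer(m[, 1L]), type = as.integer(m[, 2L]),
                      x = m[, 3L] * scale[1L], y = m[, 4L] * scale[2L],
                      z = m[, 5L] * scale[3L], radius = m[, 6L])
  parent <- as.integer(m[, 7L])
  if (anyDuplicated(nodes$id))
    .gcut_stop("duplicate node id in SWC file", "gcut_structure_error")
  has_par <- parent != -1L
  if (any(has_par & !(parent %in% nodes$id)))
    .gcut_stop(sprintf("dangling parent id %d", parent[has_par & !(parent %in% nodes$id)][1L]),
               "gcut_structure_error")
  edges <- cbind(nodes$id[has_par], parent[has_par])

  if (is.null(soma_ids)) soma_ids <- nodes$id[nodes$type == 1L]
  if (length(soma_ids) == 0L)
    .gcut_stop("no soma: no type-1 node and no explicit soma_ids", "gcut_structure_error")
  if (!all(soma_ids %in% nodes$id))
    .gcut_stop("soma_ids contains an unknown node id", "gcut_structure_error")

  g <- morph_graph(nodes, edges, soma_ids)
  if (collapse_somas) g <- collapse_soma_nodes(g)
  if (require_connected && !is_connected_graph(g))
    .gcut_stop("input graph is disconnected; expected a single connected cluster",
               "gcut_disconnected_input")
  g
}

#' Collapse adjacent soma nodes to single point somas
#'
#' Real tracings often represent the soma extent by several connected type-1
#' nodes. The assignment model treats each soma as a single point, so every
#' connected group of soma nodes is replaced by one node at the group
#' centroid (keeping the smallest id and the largest radius of the group);
#' edges to the group are rerouted to the collapsed node.
#'
#' @param g a [morph_graph()]
#' @return a [morph_graph()] with point somas; the id remapping is attached
#'   as attribute `"soma_collapse"`
#' @export
collapse_soma_nodes <- function(g) {
  s <- g$soma_ids
  if (length(s) <= 1L) return(g)
  e <- g$edges
  ss <- e[e[, 1L] %in% s & e[, 2L] %in% s, , drop = FALSE]
  if (nrow(ss) == 0L) return(g)
  # connected groups among soma nodes
  ig <- igraph::graph_from_data_frame(
    data.frame(from = as.character(ss[, 1L]), to = as.character(ss[, 2L])),
    directed = FALSE, vertices = data.frame(name = as.character(s)))
  comp <- igraph::components(ig)$membership
  grp <- split(as.integer(names(comp)), comp)

  remap <- stats::setNames(g$nodes$id, g$nodes$id)
  nodes <- g$nodes
  for (ids in grp) {
    if (length(ids) == 1L) next
    keep <- min(ids)
    i <- .node_index(g, ids)
    k <- .node_index(g, keep)
    nodes$x[k] <- mean(g$nodes$x[i]); nodes$y[k] <- mean(g$nodes$y[i])
    nodes$z[k] <- mean(g$nodes$z[i]); nodes$radius[k] <- max(g$nodes$radius[i])
    remap[as.character(setdiff(ids, keep))] <- keep
  }
  e2 <- cbind(remap[as.character(e[, 1L])], remap[as.character(e[, 2L])])
  e2 <- e2[e2[, 1L] != e2[, 2L], , drop = FALSE]
  e2 <- unique(cbind(pmin(e2[, 1L], e2[, 2L]), pmax(e2[, 1L], e2[, 2L])))
  keep_ids <- sort(unique(unname(remap)))
  out <- morph_graph(nodes[nodes$id %in% keep_ids, , drop = FALSE], e2,
                     sort(unique(unname(remap[as.character(s)]))))
  attr(out, "soma_collapse") <- remap[remap != as.integer(names(remap))]
  out
}

#' Read a morphology from vertex and edge list files
#'
#' The vertex file has one `id, x, y, z, radius` record per line; the edge
#' file has one `id, id` pair per line. Fields may be separated by commas or
#' whitespace; '#' comments are ignored. This format, unlike SWC, can
#' describe arbitrary undirected graphs (e.g. clusters containing cycles).
#'
#' @param vertex_path,edge_path input files
#' @param soma_ids integer vector of soma node ids (required; the format has
#'   no type column)
#' @inheritParams read_swc
#' @return a [morph_graph()]
#' @export
read_edge_list <- function(vertex_path, edge_path, soma_ids,
                           require_connected = TRUE) {
  rd <- function(p, ncol_want) {
    if (!file.exists(p)) .gcut_stop(paste("file not found:", p), "gcut_io_error")
    lines <- readLines(p, warn = FALSE)
    lines <- lines[!grepl("^\\s*(#|$)", lines)]
    if (length(lines) == 0L) return(matrix(numeric(), ncol = ncol_want))
    fields <- strsplit(trimws(lines), "[,\\s]+")
    if (any(lengths(fields) != ncol_want))
      .gcut_stop(sprintf("malformed line in %s: expected %d fields", p, ncol_want),
                 "gcut_parse_error")
    m <- matrix(as.numeric(unlist(fields)), ncol = ncol_want, byrow = TRUE)
    if (anyNA(m)) .gcut_stop(paste("non-numeric field in", p), "gcut_parse_error")
    m
  }
  v <- rd(vertex_path, 5L)
  if (nrow(v) == 0L) .gcut_stop("vertex file contains zero nodes", "gcut_empty_input")
  e <- rd(edge_path, 2L)
  nodes <- data.frame(id = as.integer(v[, 1L]), type = 3L,
                      x = v[, 2L], y = v[, 3L], z = v[, 4L], radius = v[, 5L])
  nodes$type[nodes$id %in% soma_ids] <- 1L
  if (nrow(e) > 0L && !all(as.integer(e) %in% nodes$id))
    .gcut_stop("edge references unknown vertex id", "gcut_structure_error")
  g <- morph_graph(nodes, matrix(as.integer(e), ncol = 2L), soma_ids)
  if (require_connected && !is_connected_graph(g))
    .gcut_stop("input graph is disconnected; expected a single connected cluster",
               "gcut_disconnected_input")
  g
}

#' Write a morphology graph to an SWC file
#'
#' The graph must be acyclic (a tree or forest), since SWC encodes edges as
#' parent pointers. Each connected component is rooted at its smallest soma
#' id (or smallest node id if it contains no soma). Output is deterministic:
#' nodes are renumbered 1..n in original-id order.
#'
#' @param g a [morph_graph()]
#' @param path output file
#' @return invisibly, the path
#' @export
write_swc <- function(g, path) {
  n <- nrow(g$nodes)
  if (nrow(g$edges) >= n)  # |E| <= |V| - #components for a forest
    .gcut_stop("graph contains cycles and cannot be written as SWC; use write_edge_list()",
               "gcut_unsupported_topology")
  new_id <- stats::setNames(seq_len(n), g$nodes$id)

  # BFS forest: parent pointer per node
  adj <- split(c(g$edges[, 2L], g$edges[, 1L]),
               factor(c(g$edges[, 1L], g$edges[, 2L]), levels = g$nodes$id))
  parent <- stats::setNames(rep(NA_integer_, n), g$nodes$id)
  visited <- stats::setNames(logical(n), g$nodes$id)
  roots <- c(sort(g$soma_ids), sort(g$nodes$id))
  for (r in roots) {
    rk <- as.character(r)
    if (visited[[rk]]) next
    visited[[rk]] <- TRUE
    queue <- r
    while (length(queue) > 0L) {
      u <- queue[1L]; queue <- queue[-1L]
      for (v in sort(adj[[as.character(u)]])) {
        vk <- as.character(v)
        if (!visited[[vk]]) {
          visited[[vk]] <- TRUE
          parent[[vk]] <- u
          queue <- c(queue, v)
        }
      }
    }
  }
  if (sum(!is.na(parent)) != nrow(g$edges))
    .gcut_stop("graph contains cycles and cannot be written as SWC; use write_edge_list()",
               "gcut_unsupported_topology")
  par_new <- ifelse(is.na(parent), -1L, new_id[as.character(parent)])
  out <- sprintf("%d %d %.9g %.9g %.9g %.9g %d",
                 new_id[as.character(g$nodes$id)], g$nodes$type,
                 g$nodes$x, g$nodes$y, g$nodes$z, g$nodes$radius, par_new)
  writeLines(c("# SWC written by gcut", out), path)
  invisible(path)
}

#' Write a morphology graph as vertex and edge list files
#'
#' @param g a [morph_graph()]
#' @param vertex_path,edge_path output files
#' @return invisibly, the two paths
#' @export
write_edge_list <- function(g, vertex_path, edge_path) {
  writeLines(sprintf("%d,%.9g,%.9g,%.9g,%.9g", g$nodes$id,
                     g$nodes$x, g$nodes$y, g$nodes$z, g$nodes$radius),
             vertex_path)
  writeLines(sprintf("%d,%d", g$edges[, 1L], g$edges[, 2L]), edge_path)
  invisible(c(vertex_path, edge_path))
}

#' Write one single-neuron SWC file per soma from a branch assignment
#'
#' Realizes a segmentation as individual neuron files. Every branch must be
#' assigned to exactly one soma; each output file is a valid single-root SWC
#' tree rooted at its soma, with shared junction nodes duplicated per neuron
#' as needed. The union of output edge sets equals the input edge set.
#'
#' @param g a [morph_graph()]
#' @param assignment integer vector of soma ids, named by branch id (as
#'   produced by [segment_cluster()]; `NA` entries are not allowed here)
#' @param out_dir output directory (created if absent)
#' @param prefix file name prefix; files are `<prefix>_<somaid>.swc`
#' @return invisibly, a character vector of file paths, named by soma id
#' @export
write_neuron_swc <- function(g, assignment, out_dir, prefix = "neuron") {
  branches <- extract_branches(g)
  ids <- vapply(branches, `[[`, 0L, "id")
  if (!all(as.character(ids) %in% names(assignment)) || anyNA(assignment))
    .gcut_stop("assignment does not cover every branch", "gcut_incomplete_assignment")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  neurons <- split_assignment(g, assignment, branches)
  paths <- character(0)
  for (s in names(neurons)) {
    p <- file.path(out_dir, sprintf("%s_%s.swc", prefix, s))
    write_swc(neurons[[s]], p)
    paths[s] <- p
  }
  invisible(paths)
}

#' Split a cluster into per-soma single-neuron graphs
#'
#' @param g a [morph_graph()]
#' @param assignment integer soma id per branch, named by branch id; `NA`
#'   (unassigned fragments) are dropped
#' @param branches optional precomputed [extract_branches()] result
#' @return named list of single-soma [morph_graph()]s, one per soma id
#' @export
split_assignment <- function(g, assignment, branches = NULL) {
  branches <- branches %||% extract_branches(g)
  out <- list()
  for (s in sort(unique(stats::na.omit(as.integer(assignment))))) {
    bids <- as.integer(names(assignment))[!is.na(assignment) & assignment == s]
    node_ids <- sort(unique(c(s, unlist(lapply(branches[bids], `[[`, "node_path")))))
    edges <- do.call(rbind, lapply(branches[bids], function(b) {
      p <- b$node_path
      cbind(p[-length(p)], p[-1L])
    }))
    nodes <- g$nodes[.node_index(g, node_ids), , drop = FALSE]
    nodes$type[nodes$id != s & nodes$type == 1L] <- 3L  # other somas demoted
    out[[as.character(s)]] <- morph_graph(nodes, edges %||% matrix(integer(), ncol = 2L), s)
  }
  out
}
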