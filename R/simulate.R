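# --- template neurons -----------------------------------------------------

# unit vector helpers
.unit <- function(v) v / sqrt(sum(v * v))
.rand_unit <- function() .unit(stats::rnorm(3L))

# rotate `v` by angle `ang` towards a random direction orthogonal to it
.tilt <- function(v, ang) {
  o <- .rand_unit()
  o <- o - sum(o * v) * v
  if (sqrt(sum(o * o)) < 1e-8) return(.tilt(v, ang))
  o <- .unit(o)
  .unit(cos(ang) * v + sin(ang) * o)
}

#' Procedurally generated template neuron
#'
#' Grows a random outward-branching tree from a soma at the origin: several
#' stems leave the soma in random directions, each neurite extends as a
#' slightly meandering polyline biased away from the soma, and tips
#' bifurcate with plausible inter-daughter angles up to a maximum depth.
#' The templates emulate the statistics that matter for segmentation —
#' branches predominantly oriented away from their soma, realistic branch
#' lengths, bifurcation-dominated topology — but not imaging noise, varying
#' radii, or tracing artifacts. Uses the current RNG state; seed outside.
#'
#' @param n_stems number of primary neurites (default random 4-6)
#' @param max_depth bifurcation depth (default 2)
#' @param branch_len_range branch arc-length range, micrometres
#' @param step segment step, micrometres
#' @param bifurcate_prob probability a tip bifurcates (per depth level)
#' @return a single-soma [morph_graph()] with the soma (id 1) at the origin
#' @export
template_neuron <- function(n_stems = sample(4:6, 1L), max_depth = 2L,
                            branch_len_range = c(60, 120), step = 4,
                            bifurcate_prob = 0.75) {
  coords <- matrix(0, nrow = 1L, ncol = 3L)
  edges <- matrix(integer(), ncol = 2L)
  # stack of growth fronts: (node index, direction, depth)
  fronts <- lapply(seq_len(n_stems), function(i)
    list(node = 1L, dir = .rand_unit(), depth = 0L))
  while (length(fronts) > 0L) {
    f <- fronts[[1L]]; fronts <- fronts[-1L]
    len <- stats::runif(1L, branch_len_range[1L], branch_len_range[2L])
    n_seg <- max(2L, ceiling(len / step))
    cur <- f$node
    dir <- f$dir
    pos <- coords[cur, ]
    for (j in seq_len(n_seg)) {
      # meander, with a mild outward (radial) bias so branches grow away
      dir <- .unit(dir + 0.25 * .rand_unit() + 0.10 * .unit(pos + 1e-6))
      pos <- pos + dir * step
      coords <- rbind(coords, pos)
      new <- nrow(coords)
      edges <- rbind(edges, c(cur, new))
      cur <- new
    }
    if (f$depth < max_depth && stats::runif(1L) < bifurcate_prob) {
      for (k in 1:2) {
        ang <- stats::runif(1L, 20, 40) * pi / 180
        fronts[[length(fronts) + 1L]] <-
          list(node = cur, dir = .tilt(dir, ang), depth = f$depth + 1L)
      }
    }
  }
  nodes <- data.frame(id = seq_len(nrow(coords)),
                      type = c(1L, rep(3L, nrow(coords) - 1L)),
                      x = coords[, 1L], y = coords[, 2L], z = coords[, 3L],
                      radius = c(5, rep(0.5, nrow(coords) - 1L)))
  morph_graph(nodes, edges, 1L)
}

#' Hand-made star and Y template neurons
#'
#' `star_neuron` places `k` straight radial arms around a central soma —
#' every branch has GOF exactly 0, making penalties analytic. `y_neuron` is
#' a single stem that bifurcates once.
#'
#' @param k number of arms
#' @param arm arm length, micrometres
#' @param step segment step, micrometres
#' @return a single-soma [morph_graph()] with the soma (id 1) at the origin
#' @export
star_neuron <- function(k = 6L, arm = 50, step = 5) {
  dirs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                c(0, 0, 1), c(0, 0, -1),
                c(1, 1, 0) / sqrt(2), c(-1, -1, 0) / sqrt(2),
                c(1, 0, 1) / sqrt(2), c(0, 1, 1) / sqrt(2))
  stopifnot(k >= 1L, k <= nrow(dirs))
  coords <- matrix(0, 1L, 3L)
  edges <- matrix(integer(), ncol = 2L)
  for (i in seq_len(k)) {
    cur <- 1L
    for (r in seq(step, arm, by = step)) {
      coords <- rbind(coords, dirs[i, ] * r)
      new <- nrow(coords)
      edges <- rbind(edges, c(cur, new))
      cur <- new
    }
  }
  nodes <- data.frame(id = seq_len(nrow(coords)),
                      type = c(1L, rep(3L, nrow(coords) - 1L)),
                      x = coords[, 1L], y = coords[, 2L], z = coords[, 3L],
                      radius = c(5, rep(0.5, nrow(coords) - 1L)))
  morph_graph(nodes, edges, 1L)
}

#' @rdname star_neuron
#' @export
y_neuron <- function(arm = 30, step = 5) {
  pts <- rbind(matrix(c(seq(0, arm, by = step), rep(0, 2 * (arm / step + 1))),
                      ncol = 3L))
  n0 <- nrow(pts)
  up <- cbind(arm + seq(step, arm, by = step) / sqrt(2),
              seq(step, arm, by = step) / sqrt(2), 0)
  dn <- cbind(arm + seq(step, arm, by = step) / sqrt(2),
              -seq(step, arm, by = step) / sqrt(2), 0)
  coords <- rbind(pts, up, dn)
  edges <- rbind(cbind(seq_len(n0 - 1L), seq_len(n0 - 1L) + 1L),
                 cbind(c(n0, n0 + seq_len(nrow(up) - 1L)),
                       n0 + seq_len(nrow(up))),
                 cbind(c(n0, n0 + nrow(up) + seq_len(nrow(dn) - 1L)),
                       n0 + nrow(up) + seq_len(nrow(dn))))
  nodes <- data.frame(id = seq_len(nrow(coords)),
                      type = c(1L, rep(3L, nrow(coords) - 1L)),
                      x = coords[, 1L], y = coords[, 2L], z = coords[, 3L],
                      radius = c(5, rep(0.5, nrow(coords) - 1L)))
  morph_graph(nodes, edges, 1L)
}

# --- rigid placement ------------------------------------------------------

# Haar-uniform random rotation matrix
.rand_rotation <- function() {
  q <- qr.Q(qr(matrix(stats::rnorm(9L), 3L)))
  if (det(q) < 0) q[, 1L] <- -q[, 1L]
  q
}

# apply rigid motion to a morph_graph (soma assumed at origin)
.pose <- function(g, rot, shift) {
  xyz <- as.matrix(g$nodes[, c("x", "y", "z")]) %*% t(rot)
  g$nodes$x <- xyz[, 1L] + shift[1L]
  g$nodes$y <- xyz[, 2L] + shift[2L]
  g$nodes$z <- xyz[, 3L] + shift[3L]
  g
}

#' Place template neurons at random rigid poses in a volume
#'
#' Each of `scale` neurons is a template (drawn with replacement) under an
#' independent Haar-uniform 3D rotation and a uniform translation inside the
#' volume, with soma positions kept pairwise at least `min_sep` apart
#' (rejection sampling with bounded retries). Rigid motion preserves branch
#' lengths and GOF values. Uses the current RNG state; seed outside.
#'
#' @param templates list of single-soma [morph_graph()]s with soma at the
#'   origin (e.g. [template_neuron()] output)
#' @param scale number of neurons to place
#' @param volume length-3 box extent in micrometres
#' @param min_sep minimum pairwise soma distance, micrometres
#' @param max_tries retries for the separation constraint
#' @return list of posed [morph_graph()]s with attributes `template`
#'   (index drawn) and `soma_xyz`
#' @export
place_neurons <- function(templates, scale, volume = c(220, 220, 220),
                          min_sep = 50, max_tries = 200L) {
  stopifnot(scale >= 1L, length(templates) >= 1L)
  pick <- sample.int(length(templates), scale, replace = TRUE)
  pos <- matrix(NA_real_, scale, 3L)
  for (i in seq_len(scale)) {
    ok <- FALSE
    for (t in seq_len(max_tries)) {
      p <- stats::runif(3L) * volume
      if (i == 1L || all(sqrt(rowSums((pos[seq_len(i - 1L), , drop = FALSE] -
                                         matrix(p, i - 1L, 3L, byrow = TRUE))^2)) >= min_sep)) {
        pos[i, ] <- p; ok <- TRUE; break
      }
    }
    if (!ok)
      .gcut_stop("could not satisfy soma separation; increase volume or lower min_sep",
                 "gcut_placement_error")
  }
  lapply(seq_len(scale), function(i) {
    g <- .pose(templates[[pick[i]]], .rand_rotation(), pos[i, ])
    attr(g, "template") <- pick[i]
    attr(g, "soma_xyz") <- pos[i, ]
    attr(g, "branches") <- attr(templates[[pick[i]]], "branches")
    g
  })
}

# --- spurious linking -----------------------------------------------------

# map every node id to the id of one branch containing it
.node_branch_map <- function(node_ids, branches) {
  out <- integer(length(node_ids))
  names(out) <- node_ids
  for (b in rev(branches)) out[as.character(b$node_path)] <- b$id
  out
}

#' Bridge posed neurons with spurious links into one cluster
#'
#' Emulates what dense labeling plus automated tracing does to proximal
#' neurites: wherever two branches of different neurons pass within
#' `threshold` of each other, one spurious edge is added between the closest
#' node pair of that branch pair (at most one link per branch pair). Nodes
#' of the merged cluster are renumbered per neuron with disjoint id blocks;
#' ground truth (source neuron per node and per edge, and the list of added
#' links) is recorded.
#'
#' @param posed list of posed neurons from [place_neurons()]
#' @param threshold proximity threshold in micrometres (default 5)
#' @return object of class `synthetic_cluster`: list with `cluster`
#'   (a multi-soma [morph_graph()]), `soma_ids`, `truth_nodes` (neuron index
#'   per node id), `truth_branches` (neuron index per cluster branch id; NA
#'   for branches containing a spurious link), `spurious_links` (matrix of
#'   node-id pairs), `neurons` (the posed inputs, renumbered),
#'   `scale`, `entanglement`, and `connected` (logical)
#' @export
link_proximal <- function(posed, threshold = 5) {
  stopifnot(length(posed) >= 2L)
  scale <- length(posed)
  # renumber into disjoint blocks
  offset <- 0L
  offsets <- integer(scale)
  merged_nodes <- list(); merged_edges <- list()
  soma_ids <- integer(scale)
  node_src <- integer(0)
  renum <- vector("list", scale)
  for (i in seq_len(scale)) {
    offsets[i] <- offset
    g <- posed[[i]]
    map <- stats::setNames(seq_len(nrow(g$nodes)) + offset, g$nodes$id)
    nd <- g$nodes
    nd$id <- unname(map[as.character(nd$id)])
    ed <- cbind(map[as.character(g$edges[, 1L])], map[as.character(g$edges[, 2L])])
    soma_ids[i] <- unname(map[as.character(g$soma_ids)])
    merged_nodes[[i]] <- nd
    merged_edges[[i]] <- ed
    node_src <- c(node_src, rep(i, nrow(nd)))
    g2 <- g; g2$nodes <- nd; g2$edges <- ed; g2$soma_ids <- soma_ids[i]
    renum[[i]] <- g2
    offset <- offset + nrow(g$nodes)
  }
  nodes <- do.call(rbind, merged_nodes)
  edges <- do.call(rbind, merged_edges)
  names(node_src) <- nodes$id
  xyz <- as.matrix(nodes[, c("x", "y", "z")])

  # per-neuron branch id of every node, for the one-link-per-branch-pair
  # rule; template branch decompositions (topology only) are reused when the
  # poses carry them
  nb_map <- unlist(lapply(seq_len(scale), function(i) {
    tb <- attr(posed[[i]], "branches")
    if (is.null(tb))
      return(.node_branch_map(renum[[i]]$nodes$id, extract_branches(renum[[i]])))
    m <- .node_branch_map(posed[[i]]$nodes$id, tb)
    names(m) <- as.integer(names(m)) + offsets[i]
    m
  }))

  links <- matrix(integer(), ncol = 2L)
  for (i in seq_len(scale - 1L)) for (j in seq(i + 1L, scale)) {
    ai <- which(node_src == i & nodes$id != soma_ids[i])
    aj <- which(node_src == j & nodes$id != soma_ids[j])
    nn <- RANN::nn2(xyz[aj, , drop = FALSE], xyz[ai, , drop = FALSE], k = 1L,
                    searchtype = "radius", radius = threshold)
    hit <- which(nn$nn.idx[, 1L] > 0L)
    if (length(hit) == 0L) next
    cand <- data.frame(a = nodes$id[ai[hit]],
                       b = nodes$id[aj[nn$nn.idx[hit, 1L]]],
                       dist = nn$nn.dists[hit, 1L])
    cand$bp <- paste(nb_map[as.character(cand$a)], nb_map[as.character(cand$b)])
    cand <- cand[order(cand$dist, cand$a, cand$b), , drop = FALSE]
    cand <- cand[!duplicated(cand$bp), , drop = FALSE]      # closest pair per branch pair
    links <- rbind(links, cbind(cand$a, cand$b))
  }

  cluster <- morph_graph(nodes, rbind(edges, links), soma_ids)
  connected <- is_connected_graph(cluster)
  truth_branches <- NULL
  if (connected) {
    cbr <- extract_branches(cluster)
    attr(cluster, "branches") <- cbr
    link_key <- paste(pmin(links[, 1L], links[, 2L]), pmax(links[, 1L], links[, 2L]))
    truth_branches <- vapply(cbr, function(b) {
      p <- b$node_path
      ek <- paste(pmin(p[-length(p)], p[-1L]), pmax(p[-length(p)], p[-1L]))
      if (any(ek %in% link_key)) return(NA_integer_)
      src <- unique(node_src[as.character(p)])
      if (length(src) == 1L) src else NA_integer_
    }, 0L)
    names(truth_branches) <- vapply(cbr, `[[`, 0L, "id")
  }
  structure(list(cluster = cluster, soma_ids = soma_ids,
                 truth_nodes = node_src, truth_branches = truth_branches,
                 spurious_links = links, neurons = renum,
                 scale = scale, entanglement = nrow(links),
                 connected = connected),
            class = "synthetic_cluster")
}

#' @export
print.synthetic_cluster <- function(x, ...) {
  cat(sprintf("<synthetic_cluster> scale %d, entanglement %d, %sconnected\n",
              x$scale, x$entanglement, if (x$connected) "" else "NOT "))
  invisible(x)
}

#' Generate one connected synthetic cluster
#'
#' Repeats place-and-link until the cluster is connected (spurious links must
#' bridge all neurons) and, optionally, until the entanglement (spurious link
#' count) falls inside `[ent_min, ent_max]`. A single seed governs template
#' choice, poses and all rejection loops, so outputs are reproducible.
#'
#' @param scale number of neurons
#' @param seed RNG seed for this cluster
#' @param templates template pool; defaults to 10 [template_neuron()]s
#'   drawn under the same seed
#' @param ent_min,ent_max admissible entanglement range (inclusive)
#' @param threshold,volume,min_sep see [place_neurons()] / [link_proximal()]
#' @param max_attempts bound on rejection iterations
#' @return a `synthetic_cluster` (see [link_proximal()]), with `seed`
#'   recorded; errors if no admissible cluster is found in `max_attempts`
#' @export
generate_cluster <- function(scale, seed, templates = NULL,
                             ent_min = scale - 1L, ent_max = Inf,
                             threshold = 5, volume = c(220, 220, 220),
                             min_sep = 50, max_attempts = 500L) {
  set.seed(seed)
  templates <- templates %||% lapply(1:10, function(i) template_neuron())
  templates <- lapply(templates, function(t) {
    if (is.null(attr(t, "branches"))) attr(t, "branches") <- extract_branches(t)
    t
  })
  for (a in seq_len(max_attempts)) {
    posed <- place_neurons(templates, scale, volume = volume, min_sep = min_sep)
    cl <- link_proximal(posed, threshold = threshold)
    if (cl$connected && cl$entanglement >= ent_min && cl$entanglement <= ent_max) {
      cl$seed <- seed
      cl$attempts <- a
      return(cl)
    }
  }
  .gcut_stop(sprintf("no admissible cluster after %d attempts (scale %d, entanglement [%s, %s])",
                     max_attempts, scale, ent_min, ent_max),
             "gcut_simulation_error")
}

#' Generate a dataset over a series of cluster scales
#'
#' For each scale, draws `n_per_scale` connected clusters whose entanglement
#' does not exceed the cap for that scale. Per-cluster sub-seeds are derived
#' deterministically from the master seed.
#'
#' @param scales integer vector of cluster scales
#' @param n_per_scale clusters per scale
#' @param entanglement_cap single value, or one cap per scale
#' @param seed master seed
#' @param ... passed to [generate_cluster()]
#' @return list of `synthetic_cluster`s with attributes `scale` recorded in
#'   each element
#' @export
generate_scale_series <- function(scales, n_per_scale, entanglement_cap = Inf,
                                  seed = 1L, ...) {
  caps <- rep_len(entanglement_cap, length(scales))
  set.seed(seed)
  sub <- sample.int(.Machine$integer.max - 1L, length(scales) * n_per_scale)
  out <- list()
  k <- 0L
  for (i in seq_along(scales)) {
    for (j in seq_len(n_per_scale)) {
      k <- k + 1L
      cl <- generate_cluster(scales[i], seed = sub[k], ent_max = caps[i], ...)
      out[[k]] <- cl
    }
  }
  out
}

#' Stratified sampling of clusters by entanglement at fixed scale
#'
#' The entanglement distribution at fixed scale is long-tailed: high link
#' counts are rare. Rejection-samples clusters until every requested
#' entanglement bin holds `n_per_bin` clusters, within a bounded number of
#' attempts; unreachable bins are reported with a warning and a partial
#' dataset is returned.
#'
#' @param scale cluster scale
#' @param bins list of inclusive link-count ranges, e.g.
#'   `list(c(5, 6), c(7, 8))`
#' @param n_per_bin clusters per bin
#' @param seed master seed
#' @param max_attempts total attempt bound
#' @param ... passed to [generate_cluster()]
#' @return list with one element per bin, each a list of
#'   `synthetic_cluster`s (possibly short of `n_per_bin`)
#' @export
sample_by_entanglement <- function(scale, bins, n_per_bin, seed = 1L,
                                   max_attempts = 2000L, ...) {
  set.seed(seed)
  sub <- sample.int(.Machine$integer.max - 1L, max_attempts)
  out <- lapply(bins, function(b) list())
  lo <- vapply(bins, `[`, 0, 1L); hi <- vapply(bins, `[`, 0, 2L)
  for (a in seq_len(max_attempts)) {
    if (all(lengths(out) >= n_per_bin)) break
    cl <- tryCatch(generate_cluster(scale, seed = sub[a], max_attempts = 1L, ...),
                   gcut_simulation_error = function(e) NULL)
    if (is.null(cl)) next
    bi <- which(cl$entanglement >= lo & cl$entanglement <= hi)
    for (b in bi) {
      if (length(out[[b]]) < n_per_bin)
        out[[b]][[length(out[[b]]) + 1L]] <- cl
    }
  }
  short <- which(lengths(out) < n_per_bin)
  if (length(short) > 0L)
    warning(sprintf("entanglement bin(s) %s not filled after %d attempts",
                    paste(short, collapse = ", "), max_attempts))
  names(out) <- vapply(bins, function(b) sprintf("%g-%g", b[1L], b[2L]), "")
  out
}
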