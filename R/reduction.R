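# --- penalty tables -------------------------------------------------------

#' Penalty table for every (branch, soma, orientation) triple
#'
#' Precomputes `penalty = weight * (1 - TailDist(GOF))` for both traversal
#' directions of every branch against every soma of the cluster. Orientation
#' 1 is the branch's stored node order, orientation 2 its reverse.
#'
#' @param g a [morph_graph()]
#' @param branches [extract_branches()] output (computed if NULL)
#' @param d a [gof_distribution()]
#' @param weight_mode `"length"` (weight = arc length, default) or
#'   `"normalized"` (weight = arc length / total cluster arc length)
#' @return list with `pen` (array branch x soma x 2), `gof` (same shape),
#'   `weights` (per branch), `branches`
#' @export
penalty_table <- function(g, d, branches = NULL, weight_mode = c("length", "normalized")) {
  weight_mode <- match.arg(weight_mode)
  branches <- branches %||% extract_branches(g)
  nb <- length(branches)
  ns <- length(g$soma_ids)
  soma_xyz <- node_xyz(g, g$soma_ids)
  lens <- vapply(branches, `[[`, 0, "length")
  weights <- if (weight_mode == "length") lens else lens / sum(lens)
  gof <- array(NA_real_, dim = c(nb, ns, 2L),
               dimnames = list(NULL, as.character(g$soma_ids), c("fwd", "rev")))
  for (bi in seq_len(nb)) {
    fwd <- .branch_coords(g, branches[[bi]])
    rev <- fwd[rev(seq_len(nrow(fwd))), , drop = FALSE]
    for (si in seq_len(ns)) {
      gof[bi, si, 1L] <- branch_gof(fwd, soma_xyz[si, ])
      gof[bi, si, 2L] <- branch_gof(rev, soma_xyz[si, ])
    }
  }
  pen <- array(weights, dim = dim(gof), dimnames = dimnames(gof)) *
    (1 - array(tail_dist(d, as.numeric(gof)), dim = dim(gof)))
  list(pen = pen, gof = gof, weights = weights, branches = branches)
}

# --- topological reduction ------------------------------------------------

#' Pre-assign branches reachable from a single soma only
#'
#' A branch whose every path to a soma (ignoring direction) meets the same
#' soma first is unambiguous: it can only have grown from that soma.
#' Operationally: delete all soma nodes; a branch's candidate somas are the
#' somas adjacent to its residual component (plus its own soma endpoints).
#' Branches with exactly one candidate are fixed; branches with several are
#' ambiguous and passed to the optimization; branches whose component touches
#' no soma belong to disconnected fragments and are reported unassigned.
#'
#' @param g a [morph_graph()]
#' @param branches optional precomputed [extract_branches()] result
#' @return list with `fixed` (integer soma id named by branch id),
#'   `ambiguous` (integer branch ids), `unassigned` (integer branch ids),
#'   `candidates` (list of candidate soma sets per branch id)
#' @export
assign_unambiguous <- function(g, branches = NULL) {
  branches <- branches %||% extract_branches(g)
  somas <- g$soma_ids
  non_soma <- setdiff(g$nodes$id, somas)

  comp_of <- integer(0)
  comp_somas <- list()
  if (length(non_soma) > 0L) {
    ig <- .as_igraph(g, drop_nodes = somas)
    memb <- igraph::components(ig)$membership
    comp_of <- stats::setNames(as.integer(memb), names(memb))
    # somas adjacent to each residual component
    e <- g$edges
    is_s1 <- e[, 1L] %in% somas
    is_s2 <- e[, 2L] %in% somas
    mixed <- xor(is_s1, is_s2)
    if (any(mixed)) {
      s_side <- ifelse(is_s1[mixed], e[mixed, 1L], e[mixed, 2L])
      n_side <- ifelse(is_s1[mixed], e[mixed, 2L], e[mixed, 1L])
      cids <- comp_of[as.character(n_side)]
      comp_somas <- lapply(split(s_side, cids), function(x) sort(unique(x)))
    }
  }

  fixed <- integer(0)
  ambiguous <- integer(0)
  unassigned <- integer(0)
  cand_list <- vector("list", length(branches))
  for (bi in seq_along(branches)) {
    b <- branches[[bi]]
    ns_nodes <- setdiff(b$node_path, somas)
    cand <- if (length(ns_nodes) == 0L) {
      sort(unique(b$ends))                       # direct soma-soma branch
    } else {
      cid <- as.character(comp_of[[as.character(ns_nodes[1L])]])
      comp_somas[[cid]] %||% integer(0)
    }
    cand_list[[bi]] <- cand
    if (length(cand) == 0L) unassigned <- c(unassigned, b$id)
    else if (length(cand) == 1L) fixed[as.character(b$id)] <- cand
    else ambiguous <- c(ambiguous, b$id)
  }
  list(fixed = fixed, ambiguous = ambiguous, unassigned = unassigned,
       candidates = cand_list)
}

# --- shortest-path trees over directed branches ---------------------------

# Dijkstra over the branch graph. Vertices are topological nodes; traversing
# branch b from endpoint u to endpoint v costs the penalty of b in that
# orientation. Ties broken by (fewer branch hops, smaller entering branch
# id). `blocked` nodes are never expanded (infinite exit cost): the path may
# end there but not pass through.
.branch_dijkstra <- function(g, source, pen_s, branches, blocked = integer()) {
  ends <- t(vapply(branches, `[[`, c(0L, 0L), "ends"))
  tn <- sort(unique(as.integer(ends)))
  if (!(source %in% tn)) tn <- sort(c(tn, source))  # isolated soma
  idx <- stats::setNames(seq_along(tn), tn)
  n <- length(tn)

  # directed adjacency: from node -> (to node, branch, orientation)
  nb <- nrow(ends)
  from <- c(ends[, 1L], ends[, 2L])
  to <- c(ends[, 2L], ends[, 1L])
  bid <- rep(seq_len(nb), 2L)
  ori <- rep(c(1L, 2L), each = nb)
  # orientation: stored node_path runs ends[1] -> ... -> ends[2] only if
  # node_path[1] == ends[1]; extract_branches guarantees that.
  loops <- ends[, 1L] == ends[, 2L]
  keep <- !rep(loops, 2L)
  adj <- split(data.frame(to = to[keep], b = bid[keep], ori = ori[keep]),
               factor(from[keep], levels = tn))

  INF <- Inf
  dist <- rep(INF, n); hops <- rep(NA_integer_, n)
  prevb <- rep(NA_integer_, n); prevn <- rep(NA_integer_, n)
  done <- logical(n)
  si <- idx[[as.character(source)]]
  dist[si] <- 0; hops[si] <- 0L
  eps <- 1e-9

  for (it in seq_len(n)) {
    # deterministic extraction: min dist, then min hops, then smallest id
    open <- which(!done & is.finite(dist))
    if (length(open) == 0L) break
    o <- open[order(dist[open], hops[open], tn[open])][1L]
    done[o] <- TRUE
    u <- tn[o]
    if (u %in% blocked && u != source) next   # infinite exit cost
    a <- adj[[as.character(u)]]
    if (is.null(a) || nrow(a) == 0L) next
    for (r in seq_len(nrow(a))) {
      v <- a$to[r]; b <- a$b[r]; orient <- a$ori[r]
      vi <- idx[[as.character(v)]]
      if (done[vi]) next
      nd <- dist[o] + pen_s[b, orient]
      nh <- hops[o] + 1L
      old_pb <- if (is.na(prevb[vi])) Inf else prevb[vi]
      better <- nd < dist[vi] - eps ||
        (abs(nd - dist[vi]) <= eps &&
           (nh < hops[vi] || (nh == hops[vi] && b < old_pb)))
      if (better) {
        dist[vi] <- nd; hops[vi] <- nh; prevb[vi] <- b; prevn[vi] <- u
      }
    }
  }
  list(nodes = tn, dist = dist, hops = hops, prev_branch = prevb,
       prev_node = prevn, idx = idx)
}

#' Per-soma shortest-path tree over branches
#'
#' Runs a shortest-path search from one soma over the branch graph, where
#' traversing a branch in a given orientation costs that orientation's
#' penalty. Every reachable branch receives the orientation and parent
#' branch realized by its minimal-penalty path from the soma, turning the
#' undirected cluster into a tree of directed branches rooted at the soma —
#' the maximum-probability growth history if the whole cluster belonged to
#' that soma. Equal-cost paths are resolved deterministically (fewer branch
#' hops, then smallest branch id).
#'
#' @param g a [morph_graph()]
#' @param s soma node id (must be in `g$soma_ids`)
#' @param d a [gof_distribution()]
#' @param pt optional precomputed [penalty_table()]
#' @param restrict_branches optional integer branch ids; the search only
#'   traverses these branches
#' @param block_somas if TRUE, paths may not pass through somas other than
#'   `s` (their exit cost is infinite)
#' @return object of class `soma_tree`: list with `root` and `branches`, a
#'   data.frame with columns `branch_id`, `orientation` (1 = stored order,
#'   2 = reversed), `parent` (parent branch id or NA if adjacent to the
#'   root), `cost` (cumulative penalty including the branch itself), `hops`.
#'   Unreachable branches are absent.
#' @export
soma_tree <- function(g, s, d, pt = NULL, restrict_branches = NULL,
                      block_somas = FALSE) {
  stopifnot(s %in% g$soma_ids)
  pt <- pt %||% penalty_table(g, d)
  branches <- pt$branches
  sel <- if (is.null(restrict_branches)) seq_along(branches)
         else which(vapply(branches, `[[`, 0L, "id") %in% restrict_branches)
  sub <- branches[sel]
  pen_s <- pt$pen[sel, as.character(s), , drop = FALSE]
  dim(pen_s) <- c(length(sel), 2L)
  blocked <- if (block_somas) setdiff(g$soma_ids, s) else integer()
  dj <- .branch_dijkstra(g, s, pen_s, sub, blocked = blocked)

  rows <- lapply(seq_along(sub), function(bi) {
    b <- sub[[bi]]
    u <- b$ends[1L]; v <- b$ends[2L]
    if (u == v) {                                    # loop branch
      ui <- dj$idx[[as.character(u)]]
      if (!is.finite(dj$dist[ui])) return(NULL)
      if (u %in% blocked && u != s) return(NULL)
      orient <- which.min(pen_s[bi, ])
      return(data.frame(branch_id = b$id, orientation = orient,
                        parent = .prev_bid(dj, sub, u),
                        cost = dj$dist[ui] + pen_s[bi, orient],
                        hops = dj$hops[ui] + 1L))
    }
    ui <- dj$idx[[as.character(u)]]; vi <- dj$idx[[as.character(v)]]
    cu <- if (is.finite(dj$dist[ui]) && !(u %in% blocked && u != s))
      dj$dist[ui] + pen_s[bi, 1L] else Inf
    cv <- if (is.finite(dj$dist[vi]) && !(v %in% blocked && v != s))
      dj$dist[vi] + pen_s[bi, 2L] else Inf
    if (!is.finite(cu) && !is.finite(cv)) return(NULL)
    eps <- 1e-9
    pick_u <- if (abs(cu - cv) <= eps) {
      hu <- dj$hops[ui] + 1L; hv <- dj$hops[vi] + 1L
      hu < hv || (hu == hv && TRUE)                 # prefer stored orientation
    } else cu < cv
    tail <- if (pick_u) u else v
    ti <- dj$idx[[as.character(tail)]]
    data.frame(branch_id = b$id, orientation = if (pick_u) 1L else 2L,
               parent = .prev_bid(dj, sub, tail),
               cost = min(cu, cv), hops = dj$hops[ti] + 1L)
  })
  br <- do.call(rbind, rows)
  if (is.null(br))
    br <- data.frame(branch_id = integer(), orientation = integer(),
                     parent = integer(), cost = numeric(), hops = integer())
  structure(list(root = s, branches = br[order(br$branch_id), , drop = FALSE],
                 dijkstra = dj),
            class = "soma_tree")
}

# branch id (in original numbering) of the tree edge entering node `node`
.prev_bid <- function(dj, sub, node) {
  i <- dj$idx[[as.character(node)]]
  pb <- dj$prev_branch[i]
  if (is.na(pb)) NA_integer_ else sub[[pb]]$id
}

#' Minimal-penalty common path between two somas
#'
#' The cheapest directed branch path from `s1` to `s2` that passes through
#' no third soma: the exit cost of every non-source soma is infinite, so a
#' path may end at a soma but never cross one. Branches along this path are
#' reachable from both somas and hence ambiguous.
#'
#' @inheritParams soma_tree
#' @param s1,s2 distinct soma node ids
#' @return integer vector of branch ids ordered from `s1` to `s2`; empty if
#'   no admissible path exists
#' @export
common_paths <- function(g, s1, s2, d, pt = NULL) {
  stopifnot(s1 != s2, s1 %in% g$soma_ids, s2 %in% g$soma_ids)
  pt <- pt %||% penalty_table(g, d)
  pen_s <- pt$pen[, as.character(s1), , drop = FALSE]
  dim(pen_s) <- c(length(pt$branches), 2L)
  dj <- .branch_dijkstra(g, s1, pen_s, pt$branches,
                         blocked = setdiff(g$soma_ids, s1))
  .walk_back(dj, pt$branches, s2)
}

.walk_back <- function(dj, branches, target) {
  ti <- dj$idx[[as.character(target)]]
  if (is.null(ti) || !is.finite(dj$dist[ti])) return(integer())
  path <- integer()
  cur <- target
  repeat {
    i <- dj$idx[[as.character(cur)]]
    pb <- dj$prev_branch[i]
    if (is.na(pb)) break
    path <- c(branches[[pb]]$id, path)
    cur <- dj$prev_node[i]
  }
  path
}

#' Split a cluster into independent units of entangled somas
#'
#' Two somas are entangled when a nonempty common path joins them. The
#' connected components of this entanglement relation are the independent
#' units: branch assignments inside one unit cannot influence assignments in
#' any other, so each unit is optimized separately. A unit carries the union
#' of the branches on its member common paths (both directions of each soma
#' pair) as its ambiguous branch set.
#'
#' @inheritParams soma_tree
#' @return list of units, each a list with `somas` (integer soma ids),
#'   `ambiguous_branches` (sorted branch ids) and `pairs` (data.frame of
#'   entangled soma pairs). Somas entangled with nobody appear in no unit.
#' @export
independent_units <- function(g, d, pt = NULL) {
  pt <- pt %||% penalty_table(g, d)
  somas <- g$soma_ids
  if (length(somas) < 2L) return(list())
  nb <- length(pt$branches)
  # one blocked search per source soma gives paths to all the others
  paths <- list()
  for (s in somas) {
    pen_s <- pt$pen[, as.character(s), , drop = FALSE]
    dim(pen_s) <- c(nb, 2L)
    dj <- .branch_dijkstra(g, s, pen_s, pt$branches,
                           blocked = setdiff(somas, s))
    for (t in setdiff(somas, s))
      paths[[sprintf("%d>%d", s, t)]] <- .walk_back(dj, pt$branches, t)
  }
  pairs <- t(utils::combn(somas, 2L))
  linked <- apply(pairs, 1L, function(p) {
    length(paths[[sprintf("%d>%d", p[1L], p[2L])]]) > 0L ||
      length(paths[[sprintf("%d>%d", p[2L], p[1L])]]) > 0L
  })
  if (!any(linked)) return(list())
  ig <- igraph::graph_from_data_frame(
    data.frame(from = as.character(pairs[linked, 1L]),
               to = as.character(pairs[linked, 2L])),
    directed = FALSE, vertices = data.frame(name = as.character(somas)))
  memb <- igraph::components(ig)$membership
  units <- list()
  for (cid in sort(unique(memb))) {
    us <- sort(as.integer(names(memb)[memb == cid]))
    if (length(us) < 2L) next
    up <- pairs[linked & pairs[, 1L] %in% us & pairs[, 2L] %in% us, , drop = FALSE]
    amb <- sort(unique(unlist(c(
      lapply(seq_len(nrow(up)), function(i)
        paths[[sprintf("%d>%d", up[i, 1L], up[i, 2L])]]),
      lapply(seq_len(nrow(up)), function(i)
        paths[[sprintf("%d>%d", up[i, 2L], up[i, 1L])]])))))
    units[[length(units) + 1L]] <-
      list(somas = us, ambiguous_branches = amb,
           pairs = data.frame(s1 = up[, 1L], s2 = up[, 2L]))
  }
  # a branch can belong to at most one unit by construction
  all_amb <- unlist(lapply(units, `[[`, "ambiguous_branches"))
  if (anyDuplicated(all_amb) > 0L)
    .gcut_stop("internal error: branch shared between independent units",
               "gcut_internal_error")
  units
}
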