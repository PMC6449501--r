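# --- shared fixtures -------------------------------------------------------

# straight chain soma - path - path - leaf along x
chain_graph <- function() {
  nodes <- data.frame(id = 1:4, type = c(1L, 3L, 3L, 3L),
                      x = c(0, 1, 2, 3), y = 0, z = 0, radius = c(2, 1, 1, 1))
  morph_graph(nodes, cbind(1:3, 2:4), 1L)
}

# two somas joined by a chain of path nodes, each soma with a private leaf
two_soma_dumbbell <- function() {
  nodes <- data.frame(
    id = 1:7, type = c(1L, 3L, 3L, 1L, 3L, 3L, 3L),
    x = c(0, 1, 2, 3, -1, 4, 1.5), y = c(0, 0, 0, 0, 0, 0, 0.0),
    z = 0, radius = 1)
  # 1-2-3-4 bridge; 1-5 and 4-6 private leaves; node 7 unused -> drop
  nodes <- nodes[1:6, ]
  morph_graph(nodes, rbind(c(1, 2), c(2, 3), c(3, 4), c(1, 5), c(4, 6)),
              c(1L, 4L))
}

# Y-shape: soma - center, center bearing two leaves (3 branches)
y_graph <- function() {
  nodes <- data.frame(id = 1:4, type = c(1L, 3L, 3L, 3L),
                      x = c(0, 1, 2, 2), y = c(0, 0, 1, -1),
                      z = 0, radius = 1)
  morph_graph(nodes, rbind(c(1, 2), c(2, 3), c(2, 4)), 1L)
}

# uniform GOF distribution on [0, pi]
uniform_gof <- function(n_bins = 180L) {
  gof_distribution(seq(0, pi, length.out = n_bins + 1L),
                   rep(1 / n_bins, n_bins), provenance = "uniform")
}

# deterministic template pool shared across tests
test_templates <- function(n = 6L, seed = 424L) {
  set.seed(seed)
  lapply(seq_len(n), function(i) template_neuron())
}

# --- independent oracles ---------------------------------------------------

# dense numeric integration of the continuous GOF along a polyline:
# resample the polyline at a fine arc step, evaluate the integrand angle at
# each sub-segment, integrate by summation (independent of branch_gof's
# midpoint formula only through much finer resolution)
gof_integral_oracle <- function(coords, soma, step = 0.1) {
  coords <- as.matrix(coords)
  total <- 0; L <- 0
  for (j in seq_len(nrow(coords) - 1L)) {
    a <- coords[j, ]; b <- coords[j + 1L, ]
    seg <- sqrt(sum((b - a)^2))
    if (seg == 0) next
    n <- max(2L, ceiling(seg / step))
    t <- (seq_len(n) - 0.5) / n
    pts <- outer(rep(1, n), a) + outer(t, b - a)
    u <- (b - a) / seg
    r <- sweep(pts, 2L, soma)
    rn <- sqrt(rowSums(r^2))
    ang <- acos(pmin(pmax(rowSums(r * rep(u, each = n)) / rn, -1), 1))
    total <- total + sum(ang) * seg / n
    L <- L + seg
  }
  total / L
}

# exhaustive minimal-cost directed-branch path oracle: enumerate every
# simple path over branches from the source soma and record, per branch,
# the cheapest (cost, hops) at which it can be reached
path_enum_oracle <- function(g, s, pen_s, branches, blocked = integer()) {
  ends <- t(vapply(branches, `[[`, c(0L, 0L), "ends"))
  best <- lapply(seq_along(branches), function(i) c(Inf, NA))
  recurse <- function(node, cost, hops, used) {
    for (bi in seq_along(branches)) {
      if (used[bi]) next
      u <- ends[bi, 1L]; v <- ends[bi, 2L]
      hit <- if (u == node) c(v, 1L) else if (v == node) c(u, 2L) else NULL
      if (is.null(hit)) next
      nc <- cost + pen_s[bi, hit[2L]]
      if (nc < best[[bi]][1L] - 1e-12 ||
          (abs(nc - best[[bi]][1L]) <= 1e-12 && hops + 1L < best[[bi]][2L])) {
        best[[bi]] <<- c(nc, hops + 1L)
      }
      nxt <- hit[1L]
      if (!(nxt %in% blocked)) {
        used[bi] <- TRUE
        recurse(nxt, nc, hops + 1L, used)
        used[bi] <- FALSE
      }
    }
  }
  recurse(s, 0, 0L, logical(length(branches)))
  do.call(rbind, best)
}

# brute-force reachability: somas first-reachable from each branch by any
# path that stops at the first soma met (path enumeration over nodes)
reach_oracle <- function(g) {
  adj <- split(c(g$edges[, 2L], g$edges[, 1L]),
               factor(c(g$edges[, 1L], g$edges[, 2L]), levels = g$nodes$id))
  somas <- g$soma_ids
  branches <- extract_branches(g)
  lapply(branches, function(b) {
    # BFS from any non-soma node of the branch (or its endpoints if none),
    # never expanding out of a soma
    starts <- setdiff(b$node_path, somas)
    if (length(starts) == 0L) return(sort(unique(b$ends)))
    seen <- starts[1L]
    queue <- starts[1L]
    found <- integer()
    while (length(queue) > 0L) {
      u <- queue[1L]; queue <- queue[-1L]
      if (u %in% somas) { found <- c(found, u); next }
      for (v in adj[[as.character(u)]]) {
        if (!(v %in% seen)) { seen <- c(seen, v); queue <- c(queue, v) }
      }
    }
    sort(unique(found))
  })
}

# exhaustive integral-assignment oracle for a unit LP: enumerate every map
# branch -> soma, keep maps consistent with the per-soma parent forests
# (a branch may go to s only if its whole parent chain under s goes to s),
# return the minimum penalty and all argmin assignments
lp_enum_oracle <- function(lp) {
  vars <- lp$vars
  branches <- sort(unique(vars$branch))
  somas <- sort(unique(vars$soma))
  nb <- length(branches)
  g_of <- function(b, s) {
    i <- which(vars$branch == b & vars$soma == s)
    if (length(i) == 0L) NA_real_ else vars$g[i]
  }
  par_of <- function(b, s) {
    i <- which(vars$branch == b & vars$soma == s)
    if (length(i) == 0L) NA_integer_ else vars$parent[i]
  }
  combos <- as.matrix(expand.grid(rep(list(somas), nb)))
  best <- Inf; argmins <- list()
  for (r in seq_len(nrow(combos))) {
    a <- combos[r, ]
    cost <- 0; ok <- TRUE
    for (i in seq_len(nb)) {
      b <- branches[i]; s <- a[i]
      gi <- g_of(b, s)
      if (is.na(gi)) { ok <- FALSE; break }       # unreachable pair
      p <- par_of(b, s)
      if (!is.na(p) && a[match(p, branches)] != s) { ok <- FALSE; break }
      cost <- cost + gi
    }
    if (!ok) next
    if (cost < best - 1e-12) { best <- cost; argmins <- list(a) }
    else if (abs(cost - best) <= 1e-12) argmins[[length(argmins) + 1L]] <- a
  }
  list(min = best, argmins = argmins, branches = branches)
}

# random small geometric multi-soma cluster for reduction/LP oracles:
# a few small star/tree neurons placed close together and force-linked
random_small_cluster <- function(seed, n_somas = 2L) {
  set.seed(seed)
  tpl <- lapply(seq_len(n_somas), function(i)
    template_neuron(n_stems = 2L, max_depth = 1L, bifurcate_prob = 0.5,
                    branch_len_range = c(15, 30), step = 5))
  for (tries in 1:50) {
    posed <- place_neurons(tpl, n_somas, volume = c(60, 60, 60), min_sep = 25,
                           max_tries = 500L)
    cl <- link_proximal(posed, threshold = 12)
    if (cl$connected) return(cl)
  }
  NULL
}

# three-branch fixture with exactly known lengths: a Y of arms 30/30/30
three_branch_truth <- function() y_neuron(arm = 30, step = 5)

# the same neuron with one 30 um arm removed
drop_one_arm <- function(g) {
  br <- extract_branches(g)
  drop <- br[[length(br)]]
  keep_edges <- g$edges
  p <- drop$node_path
  tags <- paste(pmin(p[-length(p)], p[-1L]), pmax(p[-length(p)], p[-1L]))
  all_tags <- paste(keep_edges[, 1L], keep_edges[, 2L])
  keep_edges <- keep_edges[!(all_tags %in% tags), , drop = FALSE]
  keep_nodes <- g$nodes[g$nodes$id %in% c(unique(as.integer(keep_edges)), g$soma_ids), ]
  list(g = morph_graph(keep_nodes, keep_edges, g$soma_ids),
       removed = drop$length)
}

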