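#' Growth Orientation Feature of a directed branch
#'
#' The GOF of a branch with respect to a candidate soma is the
#' length-weighted mean, over the branch's segments, of the angle between the
#' segment direction and the radial unit vector pointing from the soma to the
#' segment midpoint:
#' \deqn{GOF = \frac{\sum_j |v_j|\,\arccos\langle (p^*_j - s)/|p^*_j - s|,\ v_j/|v_j|\rangle}{\sum_j |v_j|}}
#' with \eqn{p^*_j} the midpoint of segment j and \eqn{v_j} its displacement.
#' A branch growing radially away from the soma scores 0; one growing
#' straight back towards it scores \eqn{\pi}. The value depends on the
#' traversal direction: reversing the branch generally changes the GOF.
#'
#' Degenerate cases: zero-length segments are skipped with a warning
#' (they carry no length); if the soma coincides with a segment midpoint the
#' radial direction is undefined and that segment's angle is taken as 0.
#'
#' @param coords k x 3 numeric matrix of branch points, in traversal order
#'   (the directed branch a -> b is its rows top to bottom; reverse the rows
#'   for b -> a)
#' @param soma_xyz length-3 numeric, soma coordinates
#' @return angle in radians, in \[0, pi\]
#' @export
branch_gof <- function(coords, soma_xyz) {
  coords <- as.matrix(coords)
  k <- nrow(coords)
  if (k < 2L) .gcut_stop("branch needs at least one segment", "gcut_structure_error")
  v <- coords[-1L, , drop = FALSE] - coords[-k, , drop = FALSE]
  len <- .row_norms(v)
  if (any(len == 0)) {
    warning("zero-length segment skipped in GOF computation")
    keep <- len > 0
    v <- v[keep, , drop = FALSE]
    coords <- coords  # midpoints recomputed below on kept segments
    mid <- (coords[-1L, , drop = FALSE] + coords[-k, , drop = FALSE]) / 2
    mid <- mid[keep, , drop = FALSE]
    len <- len[keep]
  } else {
    mid <- (coords[-1L, , drop = FALSE] + coords[-k, , drop = FALSE]) / 2
  }
  if (length(len) == 0L)
    .gcut_stop("branch has zero total length", "gcut_structure_error")
  r <- sweep(mid, 2L, as.numeric(soma_xyz))
  rn <- .row_norms(r)
  cosang <- rowSums(r * v) / (rn * len)
  ang <- acos(.clamp(cosang, -1, 1))
  if (any(rn == 0)) {
    warning("soma coincides with a segment midpoint; angle taken as 0")
    ang[rn == 0] <- 0
  }
  sum(len * ang) / sum(len)
}

#' Construct a GOF distribution object
#'
#' An empirical distribution of the Growth Orientation Feature over
#' \[0, pi\]: histogram bin edges, per-bin probability mass, and the implied
#' CDF at the bin edges. Usually built from a corpus with
#' [build_gof_distribution()] rather than directly.
#'
#' @param bin_edges increasing numeric grid from 0 to pi
#' @param pdf_mass nonnegative mass per bin; renormalized (with a warning)
#'   if it does not sum to 1
#' @param provenance free-text label for the corpus the distribution came
#'   from (species, brain region, "fixture", ...)
#' @return object of class `gof_dist` with elements `bin_edges`, `pdf_mass`,
#'   `cdf` (length `length(bin_edges)`, from 0 to 1) and `provenance`
#' @export
gof_distribution <- function(bin_edges, pdf_mass, provenance = "custom") {
  bin_edges <- as.numeric(bin_edges)
  pdf_mass <- as.numeric(pdf_mass)
  if (length(bin_edges) != length(pdf_mass) + 1L)
    .gcut_stop("need length(bin_edges) == length(pdf_mass) + 1", "gcut_structure_error")
  if (is.unsorted(bin_edges, strictly = TRUE))
    .gcut_stop("bin_edges must be strictly increasing", "gcut_structure_error")
  if (abs(bin_edges[1L]) > 1e-9 || abs(bin_edges[length(bin_edges)] - pi) > 1e-9)
    .gcut_stop("bin_edges must span [0, pi]", "gcut_structure_error")
  if (any(pdf_mass < 0)) .gcut_stop("negative bin mass", "gcut_structure_error")
  tot <- sum(pdf_mass)
  if (tot <= 0) .gcut_stop("distribution has zero total mass", "gcut_structure_error")
  if (abs(tot - 1) > 1e-9) {
    warning(sprintf("GOF mass sums to %.6g; renormalizing", tot))
    pdf_mass <- pdf_mass / tot
  }
  structure(list(bin_edges = bin_edges,
                 pdf_mass = pdf_mass / sum(pdf_mass),
                 cdf = c(0, cumsum(pdf_mass / sum(pdf_mass))),
                 provenance = provenance),
            class = "gof_dist")
}

#' @export
print.gof_dist <- function(x, ...) {
  cat(sprintf("<gof_dist> %d bins over [0, pi], provenance: %s\n",
              length(x$pdf_mass), x$provenance))
  invisible(x)
}

# branch orientation away from the soma for a single-neuron tree:
# BFS from the soma over branch endpoints; a branch is traversed from the
# endpoint discovered first
.tree_directed_branches <- function(g, branches) {
  s <- g$soma_ids[1L]
  ends <- t(vapply(branches, `[[`, c(0L, 0L), "ends"))
  # branch adjacency by endpoint
  inc <- split(rep(seq_along(branches), 2L), c(ends[, 1L], ends[, 2L]))
  seen_b <- logical(length(branches))
  dist_node <- new.env(parent = emptyenv())
  assign(as.character(s), 0L, envir = dist_node)
  queue <- s
  out <- vector("list", length(branches))
  while (length(queue) > 0L) {
    u <- queue[1L]; queue <- queue[-1L]
    for (bi in inc[[as.character(u)]] %||% integer()) {
      if (seen_b[bi]) next
      seen_b[bi] <- TRUE
      b <- branches[[bi]]
      from <- u
      to <- if (b$ends[1L] == u) b$ends[2L] else b$ends[1L]
      rev <- b$node_path[1L] != from
      out[[bi]] <- list(id = b$id, reverse = rev)
      if (is.null(get0(as.character(to), envir = dist_node)))
        { assign(as.character(to), 1L, envir = dist_node); queue <- c(queue, to) }
    }
  }
  out[!vapply(out, is.null, TRUE)]
}

#' Build an empirical GOF distribution from a morphology corpus
#'
#' For every branch of every single-soma neuron in the corpus, the GOF is
#' computed in the branch's anatomical orientation (directed away from the
#' soma along the tree) against that neuron's soma, and the values are
#' histogrammed over \[0, pi\]. Each branch contributes one value with equal
#' weight.
#'
#' @param corpus either a list of single-soma [morph_graph()]s or a path to
#'   a directory of single-neuron SWC files
#' @param n_bins number of histogram bins (default 180, i.e. 1-degree bins)
#' @param provenance corpus label stored in the result
#' @return a [gof_distribution()]; corpus entries with other than exactly one
#'   soma are rejected with a per-entry warning
#' @export
build_gof_distribution <- function(corpus, n_bins = 180L, provenance = "custom") {
  if (is.character(corpus)) {
    files <- sort(list.files(corpus, pattern = "\\.swc$", full.names = TRUE))
    if (length(files) == 0L) .gcut_stop("no SWC files in corpus directory", "gcut_empty_input")
    corpus <- lapply(files, read_swc)
    names(corpus) <- basename(files)
  }
  if (length(corpus) == 0L) .gcut_stop("empty corpus", "gcut_empty_input")
  vals <- numeric(0)
  for (i in seq_along(corpus)) {
    g <- corpus[[i]]
    if (length(g$soma_ids) != 1L) {
      warning(sprintf("corpus entry %s rejected: %d somas (need exactly 1)",
                      names(corpus)[i] %||% i, length(g$soma_ids)))
      next
    }
    branches <- extract_branches(g)
    if (length(branches) == 0L) next
    soma <- as.numeric(node_xyz(g, g$soma_ids))
    dirs <- .tree_directed_branches(g, branches)
    vals <- c(vals, vapply(dirs, function(d) {
      branch_gof(.branch_coords(g, branches[[d$id]], reverse = d$reverse), soma)
    }, 0))
  }
  if (length(vals) == 0L)
    .gcut_stop("corpus yielded no branches", "gcut_empty_input")
  edges <- seq(0, pi, length.out = n_bins + 1L)
  h <- graphics::hist(.clamp(vals, 0, pi), breaks = edges, plot = FALSE)
  gof_distribution(edges, h$counts / sum(h$counts), provenance)
}

#' Tail distribution of the GOF
#'
#' `TailDist(x) = 1 - CDF(x)`: the probability that a corpus branch has GOF
#' larger than `x`, used as the likelihood proxy that a branch-soma pairing
#' with that GOF occurs in a real neuron. The CDF is linearly interpolated
#' inside bins, so TailDist is continuous and nonincreasing with
#' `TailDist(0) = 1` and `TailDist(pi) = 0`.
#'
#' @param d a [gof_distribution()]
#' @param x angle(s) in radians, in \[0, pi\]
#' @return probability in \[0, 1\] (vectorized)
#' @export
tail_dist <- function(d, x) {
  stopifnot(inherits(d, "gof_dist"))
  if (any(x < -1e-12 | x > pi + 1e-12))
    .gcut_stop("tail_dist: x outside [0, pi]", "gcut_domain_error")
  x <- .clamp(x, 0, pi)
  1 - stats::approx(d$bin_edges, d$cdf, xout = x, rule = 2)$y
}

#' Penalty of a directed branch with respect to a soma
#'
#' `penalty = weight * (1 - TailDist(GOF))`: the complement of the fitness
#' score, so that both the shortest-path orientation step and the final
#' linear program can minimize. With the default length weight, a branch
#' growing radially away from the soma costs 0 and one growing straight back
#' costs its full arc length; the weight suppresses the influence of very
#' short (often spurious) branches.
#'
#' @inheritParams branch_gof
#' @param d a [gof_distribution()]
#' @param weight branch weight; default the branch arc length (micrometres)
#' @return nonnegative penalty, at most `weight`
#' @export
branch_penalty <- function(coords, soma_xyz, d, weight = NULL) {
  coords <- as.matrix(coords)
  w <- weight %||% .polyline_length(coords)
  w * (1 - tail_dist(d, branch_gof(coords, soma_xyz)))
}

#' Kullback-Leibler divergence between two GOF distributions
#'
#' `KL(d1 || d2) = sum p log(p / q)` over the shared bin grid (nats). Bins
#' where `q` is zero are handled by adding 1e-10 mass to empty bins of both
#' distributions and renormalizing before the divergence is taken.
#'
#' @param d1,d2 [gof_distribution()]s on identical bin grids
#' @return nonnegative divergence; 0 iff the distributions are identical
#' @export
kl_divergence <- function(d1, d2) {
  stopifnot(inherits(d1, "gof_dist"), inherits(d2, "gof_dist"))
  if (length(d1$bin_edges) != length(d2$bin_edges) ||
      any(abs(d1$bin_edges - d2$bin_edges) > 1e-12))
    .gcut_stop("kl_divergence: mismatched bin grids", "gcut_structure_error")
  smooth <- function(p) { p[p == 0] <- 1e-10; p / sum(p) }
  p <- smooth(d1$pdf_mass); q <- smooth(d2$pdf_mass)
  sum(p * log(p / q))
}

#' Save / load a GOF distribution as JSON
#'
#' The file stores a format version, the provenance label, bin edges and bin
#' masses; save followed by load is the identity. A loaded distribution
#' whose mass does not sum to 1 is renormalized with a warning.
#'
#' @param d a [gof_distribution()]
#' @param path file path
#' @return `save_gof_distribution`: invisibly, the path;
#'   `load_gof_distribution`: a [gof_distribution()]
#' @export
save_gof_distribution <- function(d, path) {
  stopifnot(inherits(d, "gof_dist"))
  jsonlite::write_json(list(format = "gcut-gof-dist", version = 1L,
                            provenance = d$provenance,
                            bin_edges = d$bin_edges, pdf_mass = d$pdf_mass),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_gof_distribution
#' @export
load_gof_distribution <- function(path) {
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) .gcut_stop(
                    paste("cannot parse distribution file:", conditionMessage(e)),
                    "gcut_parse_error"))
  if (!identical(obj$format, "gcut-gof-dist"))
    .gcut_stop("not a gcut GOF distribution file", "gcut_parse_error")
  gof_distribution(obj$bin_edges, obj$pdf_mass, obj$provenance %||% "custom")
}

.gcut_cache <- new.env(parent = emptyenv())

#' Packaged default GOF distribution
#'
#' Built from a deterministic corpus of procedurally generated template
#' neurons (see [template_neuron()]) and labeled with provenance
#' `"fixture"`. It reflects the outward-growing statistics of the simulator's
#' templates, not any real species; for real data, build a distribution from
#' a matching morphology corpus with [build_gof_distribution()].
#'
#' @param n_neurons corpus size (default 30)
#' @param n_bins histogram bins
#' @return a [gof_distribution()], memoized per session
#' @export
default_gof_distribution <- function(n_neurons = 30L, n_bins = 180L) {
  key <- sprintf("fixture_%d_%d", n_neurons, n_bins)
  if (!is.null(.gcut_cache[[key]])) return(.gcut_cache[[key]])
  old <- .Random.seed_exists()
  corpus <- local({
    if (old$has) on.exit(assign(".Random.seed", old$seed, envir = globalenv()))
    set.seed(20240401L)
    lapply(seq_len(n_neurons), function(i) template_neuron())
  })
  d <- build_gof_distribution(corpus, n_bins = n_bins, provenance = "fixture")
  .gcut_cache[[key]] <- d
  d
}

.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    list(has = TRUE, seed = get(".Random.seed", envir = globalenv()))
  else list(has = FALSE, seed = NULL)
}
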