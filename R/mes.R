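# --- Miss-Extra-Score evaluation ------------------------------------------

# resample every edge of a morphology into points carrying arc length:
# each edge is cut into pieces of at most `step`; one sample point sits at
# each piece midpoint and carries the piece length
.length_samples <- function(g, step) {
  if (nrow(g$edges) == 0L)
    return(list(pts = matrix(numeric(), ncol = 3L), len = numeric()))
  a <- node_xyz(g, g$edges[, 1L])
  b <- node_xyz(g, g$edges[, 2L])
  seg_len <- .row_norms(b - a)
  n_piece <- pmax(1L, ceiling(seg_len / step))
  idx <- rep(seq_len(nrow(a)), n_piece)
  piece <- unlist(lapply(n_piece, seq_len))
  frac <- (piece - 0.5) / n_piece[idx]
  pts <- a[idx, , drop = FALSE] + (b[idx, , drop = FALSE] - a[idx, , drop = FALSE]) * frac
  list(pts = pts, len = seg_len[idx] / n_piece[idx])
}

#' Miss-Extra-Score between a segmented neuron and its ground truth
#'
#' Both morphologies are resampled to uniform arc-length points (step
#' `tol/2`). A ground-truth point is *hit* when any test point lies within
#' `tol`; the miss length is the summed arc length of unhit truth points,
#' and symmetrically the extra length is the summed arc length of test
#' points unmatched in the truth. The score is
#' \deqn{MES = (L_{gt} - miss) / (L_{gt} + extra)}
#' which is 1 exactly when the test neuron reproduces the ground truth and
#' decreases with either missed or extra structure. Matching is purely
#' geometric (point proximity), since node ids and topology generally differ
#' between independent tracings. Note the score is not symmetric in its
#' arguments: swapping test and truth swaps the miss and extra roles.
#'
#' @param test segmented neuron as a [morph_graph()] (may be NULL/empty:
#'   scores 0 with `miss = L_gt`)
#' @param truth ground-truth neuron as a [morph_graph()]
#' @param tol matching tolerance in micrometres (default 2)
#' @return object of class `mes_score`: list with `score`, `miss_length`,
#'   `extra_length`, `truth_length`
#' @export
mes <- function(test, truth, tol = 2) {
  step <- tol / 2
  tr <- .length_samples(truth, step)
  te <- if (is.null(test) || nrow(test$edges) == 0L) NULL
        else .length_samples(test, step)
  .mes_from_samples(te, tr, tol)
}

# core of the score on precomputed length samples
.mes_from_samples <- function(te, tr, tol) {
  L_gt <- sum(tr$len)
  if (is.null(te) || nrow(te$pts) == 0L)
    return(structure(list(score = 0, miss_length = L_gt, extra_length = 0,
                          truth_length = L_gt), class = "mes_score"))
  d_tr <- RANN::nn2(te$pts, tr$pts, k = 1L)$nn.dists[, 1L]
  d_te <- RANN::nn2(tr$pts, te$pts, k = 1L)$nn.dists[, 1L]
  miss <- sum(tr$len[d_tr > tol])
  extra <- sum(te$len[d_te > tol])
  structure(list(score = (L_gt - miss) / (L_gt + extra),
                 miss_length = miss, extra_length = extra,
                 truth_length = L_gt),
            class = "mes_score")
}

#' @export
print.mes_score <- function(x, ...) {
  cat(sprintf("<mes_score> %.4f (miss %.1f um, extra %.1f um of %.1f um truth)\n",
              x$score, x$miss_length, x$extra_length, x$truth_length))
  invisible(x)
}

#' Score a segmentation of a synthetic cluster against its ground truth
#'
#' Splits the cluster by the given assignment, matches each soma to the
#' ground-truth neuron with the nearest soma, and computes per-neuron MES.
#'
#' @param cl a `synthetic_cluster` from [link_proximal()] /
#'   [generate_cluster()]
#' @param seg a [segment_cluster()] result on `cl$cluster` (or a bare
#'   assignment vector)
#' @param tol MES tolerance, micrometres
#' @param branches optional precomputed [extract_branches()] for the cluster
#' @return data.frame with one row per ground-truth neuron: `neuron`,
#'   `soma_id`, `score`, `miss_length`, `extra_length`, `truth_length`
#' @export
score_cluster <- function(cl, seg, tol = 2, branches = NULL) {
  assignment <- if (inherits(seg, "gcut_segmentation")) seg$assignment else seg
  branches <- branches %||% attr(cl$cluster, "branches") %||%
    extract_branches(cl$cluster)
  pred <- split_assignment(cl$cluster, assignment, branches = branches)
  truth_samples <- attr(cl, "truth_samples")
  if (is.null(truth_samples) || !identical(attr(truth_samples, "tol"), tol))
    truth_samples <- lapply(cl$neurons, .length_samples, step = tol / 2)
  rows <- lapply(seq_along(cl$neurons), function(i) {
    s <- cl$soma_ids[i]
    p <- pred[[as.character(s)]]
    te <- if (is.null(p) || nrow(p$edges) == 0L) NULL
          else .length_samples(p, step = tol / 2)
    m <- .mes_from_samples(te, truth_samples[[i]], tol)
    data.frame(neuron = i, soma_id = s, score = m$score,
               miss_length = m$miss_length, extra_length = m$extra_length,
               truth_length = m$truth_length)
  })
  do.call(rbind, rows)
}

#' Aggregate MES over a dataset of segmented clusters
#'
#' @param results list of [segment_cluster()] results (or assignment
#'   vectors), one per cluster
#' @param clusters list of `synthetic_cluster`s of equal length
#' @param by optional vector of condition labels (e.g. scale or
#'   entanglement bin) per cluster
#' @param tol MES tolerance, micrometres
#' @return data.frame of per-neuron scores with columns `cluster`,
#'   `condition`, plus the [score_cluster()] columns; the per-condition
#'   summary (mean, median, quartiles over neurons) is attached as attribute
#'   `"summary"`
#' @export
evaluate_dataset <- function(results, clusters, by = NULL, tol = 2) {
  stopifnot(length(results) == length(clusters))
  by <- by %||% rep("all", length(clusters))
  rows <- lapply(seq_along(clusters), function(i) {
    df <- score_cluster(clusters[[i]], results[[i]], tol = tol)
    cbind(cluster = i, condition = by[i], df)
  })
  out <- do.call(rbind, rows)
  sm <- do.call(rbind, lapply(split(out$score, out$condition), function(s)
    data.frame(n = length(s), mean = mean(s), median = stats::median(s),
               q25 = unname(stats::quantile(s, 0.25)),
               q75 = unname(stats::quantile(s, 0.75)))))
  sm$condition <- rownames(sm)
  attr(out, "summary") <- sm
  out
}

#' Random-assignment baseline for a synthetic cluster
#'
#' Reference point for segmentation accuracy: ambiguous unit branches are
#' assigned to a uniformly random unit soma (fixed branches keep their
#' topological assignment, side branches follow by propagation as in
#' [segment_cluster()]), and the per-cluster mean MES is averaged over
#' `n_draws` random draws.
#'
#' @param cl a `synthetic_cluster`
#' @param d GOF distribution (used only to delimit units, as in the real
#'   pipeline)
#' @param n_draws random assignments to average over
#' @param seed RNG seed
#' @param tol MES tolerance
#' @return list with `mean_score` (averaged over draws) and `per_draw`
#' @export
random_baseline <- function(cl, d = default_gof_distribution(), n_draws = 10L,
                            seed = 1L, tol = 2) {
  g <- cl$cluster
  branches <- attr(g, "branches") %||% extract_branches(g)
  pt <- penalty_table(g, d, branches = branches)
  pre <- assign_unambiguous(g, branches)
  units <- independent_units(g, d, pt = pt)
  attr(cl, "truth_samples") <- structure(
    lapply(cl$neurons, .length_samples, step = tol / 2), tol = tol)
  set.seed(seed)
  scores <- vapply(seq_len(n_draws), function(k) {
    assignment <- stats::setNames(rep(NA_integer_, length(branches)),
                                  vapply(branches, `[[`, 0L, "id"))
    assignment[names(pre$fixed)] <- pre$fixed
    for (u in units) {
      picks <- sample(u$somas, length(u$ambiguous_branches), replace = TRUE)
      assignment[as.character(u$ambiguous_branches)] <- picks
    }
    assignment <- .propagate_dangling(g, branches, assignment, pre$ambiguous, units)
    mean(score_cluster(cl, assignment, tol = tol, branches = branches)$score)
  }, 0)
  list(mean_score = mean(scores), per_draw = scores)
}

# shared propagation rule for ambiguous branches outside every unit
.propagate_dangling <- function(g, branches, assignment, ambiguous, units) {
  todo <- setdiff(ambiguous, unlist(lapply(units, `[[`, "ambiguous_branches")))
  if (length(todo) == 0L) return(assignment)
  node_of <- lapply(branches, `[[`, "node_path")
  repeat {
    resolved <- !is.na(assignment)
    if (all(resolved[as.character(todo)])) break
    progress <- FALSE
    for (b in sort(todo)) {
      bc <- as.character(b)
      if (!is.na(assignment[[bc]])) next
      nb_ids <- which(vapply(node_of, function(p)
        any(node_of[[b]] %in% p), TRUE))
      nb_ids <- nb_ids[nb_ids != b & !is.na(assignment[as.character(nb_ids)])]
      if (length(nb_ids) == 0L) next
      assignment[[bc]] <- assignment[[as.character(min(nb_ids))]]
      progress <- TRUE
    }
    if (!progress) break
  }
  assignment
}
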