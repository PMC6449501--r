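#' Segment a multi-soma neuron cluster into individual neurons
#'
#' End-to-end pipeline: classify nodes and extract branches; fix every
#' branch that is reachable from a single soma only; split the remaining
#' ambiguous branches into independent units of entangled somas; within each
#' unit, orient branches by per-soma minimal-penalty trees, solve the
#' membership linear program, and round to a discrete assignment; finally
#' propagate assignments to ambiguous side branches that hang off the
#' optimized common paths (their only access to any soma runs through an
#' already-assigned branch, so they follow it). The result is a map from
#' every branch to exactly one soma (or NA for disconnected fragments).
#'
#' With a single soma the whole procedure degenerates to the identity: all
#' branches are assigned to that soma and no LP is run.
#'
#' @param g a [morph_graph()] (a connected cluster; see [read_swc()])
#' @param d a [gof_distribution()]; defaults to the packaged fixture
#'   distribution
#' @param weight_mode branch weight used in penalties: `"length"` or
#'   `"normalized"` (see [penalty_table()])
#' @return object of class `gcut_segmentation`: list with
#'   * `assignment`: integer soma id named by branch id (NA = unassigned),
#'   * `branches`: the [extract_branches()] result,
#'   * `objective`: total LP penalty over all units,
#'   * `units`: per-unit detail (somas, branches, membership, objective),
#'   * `diagnostics`: counts of fixed/ambiguous/propagated/unassigned
#'     branches, fractional variables and connectivity repairs.
#' @export
segment_cluster <- function(g, d = default_gof_distribution(),
                            weight_mode = c("length", "normalized")) {
  weight_mode <- match.arg(weight_mode)
  branches <- attr(g, "branches") %||% extract_branches(g)
  nb <- length(branches)
  assignment <- stats::setNames(rep(NA_integer_, nb),
                                vapply(branches, `[[`, 0L, "id"))
  if (nb == 0L)
    return(structure(list(assignment = assignment, branches = branches,
                          objective = 0, units = list(),
                          diagnostics = list(fixed = 0L, ambiguous = 0L,
                                             propagated = 0L, unassigned = 0L,
                                             n_fractional = 0L, repairs = 0L)),
                     class = "gcut_segmentation"))

  if (length(g$soma_ids) == 1L) {
    pre <- assign_unambiguous(g, branches)
    assignment[names(pre$fixed)] <- pre$fixed
    return(structure(list(assignment = assignment, branches = branches,
                          objective = 0, units = list(),
                          diagnostics = list(fixed = length(pre$fixed),
                                             ambiguous = 0L, propagated = 0L,
                                             unassigned = length(pre$unassigned),
                                             n_fractional = 0L, repairs = 0L)),
                     class = "gcut_segmentation"))
  }

  pt <- penalty_table(g, d, branches = branches, weight_mode = weight_mode)
  pre <- assign_unambiguous(g, branches)
  assignment[names(pre$fixed)] <- pre$fixed

  units <- independent_units(g, d, pt = pt)
  objective <- 0
  n_frac <- 0L; repairs <- 0L
  unit_out <- list()
  for (u in units) {
    trees <- stats::setNames(lapply(u$somas, function(s)
      soma_tree(g, s, d, pt = pt, restrict_branches = u$ambiguous_branches,
                block_somas = TRUE)), as.character(u$somas))
    lp <- build_lp(u, trees, pt)
    m <- solve_unit(lp)
    a <- finalize_assignment(m, trees)
    assignment[names(a)] <- a
    objective <- objective + m$objective
    n_frac <- n_frac + m$n_fractional
    repairs <- repairs + attr(a, "repairs")
    unit_out[[length(unit_out) + 1L]] <-
      list(somas = u$somas, ambiguous_branches = u$ambiguous_branches,
           membership = m$w, objective = m$objective)
  }

  # ambiguous side branches not on any common path: follow the assigned
  # branch they attach to (wavefront propagation from the resolved set)
  before <- sum(is.na(assignment))
  assignment <- .propagate_dangling(g, branches, assignment, pre$ambiguous, units)
  propagated <- before - sum(is.na(assignment))

  structure(list(assignment = assignment, branches = branches,
                 objective = objective, units = unit_out,
                 diagnostics = list(fixed = length(pre$fixed),
                                    ambiguous = length(pre$ambiguous),
                                    propagated = propagated,
                                    unassigned = sum(is.na(assignment)),
                                    n_fractional = n_frac,
                                    repairs = repairs)),
            class = "gcut_segmentation")
}

#' @export
print.gcut_segmentation <- function(x, ...) {
  d <- x$diagnostics
  cat(sprintf(paste0("<gcut_segmentation> %d branches -> %d soma(s); ",
                     "%d fixed, %d ambiguous (%d units), %d propagated, %d unassigned\n",
                     "objective %.4f, %d fractional weight(s), %d repair(s)\n"),
              length(x$assignment),
              length(unique(stats::na.omit(x$assignment))),
              d$fixed, d$ambiguous, length(x$units), d$propagated, d$unassigned,
              x$objective, d$n_fractional, d$repairs))
  invisible(x)
}
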