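# --- linear-programming branch assignment ---------------------------------

#' Build the per-unit membership linear program
#'
#' For an independent unit, introduces one membership variable `w(C, s)` per
#' (ambiguous branch, candidate soma) pair where `C` is reachable in the
#' per-soma tree of `s`. The objective is the total penalty
#' `sum g(C,s) w(C,s)` with `g` taken at the orientation the tree of `s`
#' assigns to `C`. Constraints:
#' * each branch's memberships sum to 1 across somas (equality),
#' * memberships are nonnegative (variable bounds),
#' * `w(C,s) <= w(par(C,s), s)` whenever the parent on the growth path from
#'   `s` is itself a unit branch — a downstream branch cannot belong to a
#'   soma more than the branch it grew out of.
#' Pairs where `C` is unreachable from `s` have `w(C,s)` fixed at 0 (no
#' variable is created).
#'
#' @param unit one unit from [independent_units()]
#' @param trees named list of [soma_tree()]s, one per unit soma (names are
#'   soma ids), built on the unit subgraph
#' @param pt a [penalty_table()] for the cluster
#' @return list with `vars` (data.frame branch/soma/g/parent), `objective`,
#'   `A_eq`, `b_eq`, `A_ub`, `b_ub`, and the `unit`
#' @export
build_lp <- function(unit, trees, pt) {
  br_ids <- unit$ambiguous_branches
  somas <- unit$somas
  vars <- do.call(rbind, lapply(as.character(somas), function(sc) {
    tb <- trees[[sc]]$branches
    tb <- tb[tb$branch_id %in% br_ids, , drop = FALSE]
    if (nrow(tb) == 0L) return(NULL)
    data.frame(branch = tb$branch_id, soma = as.integer(sc),
               g = pt$pen[cbind(tb$branch_id, match(as.integer(sc), as.integer(colnames(pt$pen))),
                                tb$orientation)],
               parent = ifelse(tb$parent %in% br_ids, tb$parent, NA_integer_))
  }))
  if (is.null(vars) || nrow(vars) == 0L)
    .gcut_stop("unit has no reachable (branch, soma) pairs", "gcut_internal_error")
  vars <- vars[order(vars$branch, vars$soma), , drop = FALSE]
  rownames(vars) <- NULL
  covered <- unique(vars$branch)
  if (!all(br_ids %in% covered))
    warning(sprintf("%d ambiguous branch(es) unreachable from every unit soma",
                    sum(!(br_ids %in% covered))))

  n <- nrow(vars)
  vkey <- paste(vars$branch, vars$soma)
  # equality rows: sum_s w(C, s) = 1 per branch
  A_eq <- t(vapply(covered, function(b) as.numeric(vars$branch == b),
                   numeric(n)))
  b_eq <- rep(1, length(covered))
  # inequality rows: w(C, s) - w(par(C, s), s) <= 0
  hasp <- which(!is.na(vars$parent))
  A_ub <- NULL
  if (length(hasp) > 0L) {
    A_ub <- matrix(0, nrow = length(hasp), ncol = n)
    for (r in seq_along(hasp)) {
      i <- hasp[r]
      A_ub[r, i] <- 1
      j <- match(paste(vars$parent[i], vars$soma[i]), vkey)
      if (is.na(j))
        .gcut_stop("internal error: parent branch has no membership variable",
                   "gcut_internal_error")
      A_ub[r, j] <- -1
    }
  }
  list(vars = vars, objective = vars$g,
       A_eq = A_eq, b_eq = b_eq,
       A_ub = A_ub, b_ub = if (is.null(A_ub)) NULL else rep(0, nrow(A_ub)),
       unit = unit)
}

#' Solve a unit LP to optimal membership weights
#'
#' Minimizes the total penalty with a dense two-phase primal simplex using
#' Bland's anti-cycling rule (the membership LPs are heavily degenerate —
#' many zero penalties and zero right-hand sides — so anti-cycling and
#' deterministic pivoting matter more than speed at these sizes).
#' Costs are pre-scaled by `1/max(g)` for conditioning; the returned
#' solution is verified against all constraints to `tol` and the LP is
#' guaranteed feasible (every branch is reachable from at least one soma and
#' the constraints are never contradictory).
#'
#' @param lp a [build_lp()] result
#' @param tol feasibility tolerance (default 1e-8)
#' @return object of class `membership`: list with `w` (matrix branch x
#'   soma, NA where no variable exists), `vars` (the variable table with a
#'   `w` column), `objective` (at the optimum, unscaled), `n_fractional`
#'   (variables away from {0,1} by more than 1e-6)
#' @export
solve_unit <- function(lp, tol = 1e-8) {
  g <- lp$objective
  sc <- max(g, 1e-12)
  res <- .lp_solve_simplex(g / sc, A_eq = lp$A_eq, b_eq = lp$b_eq,
                           A_ub = lp$A_ub, b_ub = lp$b_ub)
  if (res$status != "optimal")
    .gcut_stop(paste0("LP solver failed (", res$status, "); ",
                      nrow(lp$vars), " variables, ",
                      length(lp$b_eq), " equalities, ",
                      length(lp$b_ub %||% numeric()), " inequalities"),
               "gcut_solver_error")
  w <- as.numeric(res$x)
  # feasibility audit
  if (any(w < -tol)) .gcut_stop("LP solution violates nonnegativity", "gcut_solver_error")
  if (any(abs(lp$A_eq %*% w - lp$b_eq) > tol))
    .gcut_stop("LP solution violates membership-sum constraint", "gcut_solver_error")
  if (!is.null(lp$A_ub) && any(lp$A_ub %*% w - lp$b_ub > tol))
    .gcut_stop("LP solution violates parent-membership constraint", "gcut_solver_error")

  vars <- lp$vars
  vars$w <- w
  branches <- sort(unique(vars$branch))
  somas <- sort(unique(vars$soma))
  W <- matrix(NA_real_, length(branches), length(somas),
              dimnames = list(branches, somas))
  W[cbind(match(vars$branch, branches), match(vars$soma, somas))] <- w
  structure(list(w = W, vars = vars,
                 objective = sum(g * w),
                 n_fractional = sum(w > 1e-6 & w < 1 - 1e-6)),
            class = "membership")
}

#' Finalize a membership matrix into a discrete assignment
#'
#' Each branch goes to the soma with the largest membership weight, ties
#' broken by smallest soma id. Argmax rounding of a fractional optimum can
#' orphan a branch from its growth path, so a repair pass (parents first)
#' reassigns any branch whose parent branch went to a different soma to that
#' parent's soma, restoring per-neuron tree connectivity; repairs are
#' counted in the `repairs` attribute.
#'
#' @param m a [solve_unit()] result
#' @param trees the unit [soma_tree()]s used to build the LP (for parent
#'   relations); may be NULL to skip the repair pass
#' @return integer soma id named by branch id, with attribute `repairs`
#' @export
finalize_assignment <- function(m, trees = NULL) {
  W <- m$w
  somas <- as.integer(colnames(W))
  pick <- apply(W, 1L, function(row) {
    ok <- which(!is.na(row))
    ok[which.max(row[ok])]      # which.max takes the first (smallest id) on ties
  })
  assign <- stats::setNames(somas[pick], rownames(W))

  repairs <- 0L
  if (!is.null(trees)) {
    max_pass <- 10L + nrow(W)
    for (pass in seq_len(max_pass)) {
      changed <- FALSE
      for (sc in as.character(somas)) {
        tb <- trees[[sc]]$branches
        tb <- tb[order(tb$hops), , drop = FALSE]   # parents before children
        for (r in seq_len(nrow(tb))) {
          b <- as.character(tb$branch_id[r]); p <- tb$parent[r]
          if (!(b %in% names(assign)) || is.na(p)) next
          pc <- as.character(p)
          if (!(pc %in% names(assign))) next
          if (assign[[b]] == as.integer(sc) && assign[[pc]] != as.integer(sc)) {
            assign[[b]] <- assign[[pc]]
            repairs <- repairs + 1L
            changed <- TRUE
          }
        }
      }
      if (!changed) break
      if (pass == max_pass) warning("connectivity repair did not converge")
    }
  }
  attr(assign, "repairs") <- repairs
  assign
}
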