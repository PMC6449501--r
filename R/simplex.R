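# Dense two-phase primal simplex with Bland's anti-cycling rule.
#
# Solves  min c'x  s.t.  A_eq x = b_eq,  A_ub x <= b_ub,  x >= 0.
# The membership LPs are small (tens to a few hundred variables) but highly
# degenerate (many zero penalties and zero right-hand sides), which trips up
# general-purpose tableau codes without anti-cycling; Bland's rule guarantees
# finite termination and makes every solve deterministic.

.lp_solve_simplex <- function(cost, A_eq = NULL, b_eq = NULL,
                              A_ub = NULL, b_ub = NULL, tol = 1e-9) {
  n <- length(cost)
  rows <- list(); rhs <- numeric(0); slack <- integer(0)
  if (!is.null(A_ub) && nrow(A_ub) > 0L) {
    for (i in seq_len(nrow(A_ub))) { rows[[length(rows) + 1L]] <- A_ub[i, ]; rhs <- c(rhs, b_ub[i]); slack <- c(slack, 1L) }
  }
  if (!is.null(A_eq) && nrow(A_eq) > 0L) {
    for (i in seq_len(nrow(A_eq))) { rows[[length(rows) + 1L]] <- A_eq[i, ]; rhs <- c(rhs, b_eq[i]); slack <- c(slack, 0L) }
  }
  m <- length(rows)
  A <- do.call(rbind, rows)
  ns <- sum(slack == 1L)
  # add slack columns for inequalities
  S <- matrix(0, m, ns)
  si <- which(slack == 1L)
  for (k in seq_along(si)) S[si[k], k] <- 1
  A <- cbind(A, S)
  # flip rows to nonnegative rhs
  neg <- rhs < 0
  A[neg, ] <- -A[neg, , drop = FALSE]
  rhs[neg] <- -rhs[neg]
  ntot <- ncol(A)

  # tableau with artificial basis: [A | I | rhs]
  Tb <- cbind(A, diag(m), rhs)
  basis <- ntot + seq_len(m)

  pivot <- function(Tb, pr, pc) {
    Tb[pr, ] <- Tb[pr, ] / Tb[pr, pc]
    for (r in seq_len(nrow(Tb))) {
      if (r != pr && abs(Tb[r, pc]) > 0) Tb[r, ] <- Tb[r, ] - Tb[r, pc] * Tb[pr, ]
    }
    Tb
  }

  run_phase <- function(Tb, basis, obj_row, allowed) {
    # obj_row: reduced-cost vector over columns (length ncol(Tb) - 1)
    repeat {
      enter <- 0L
      for (j in allowed) {                       # Bland: smallest eligible index
        if (obj_row[j] < -tol && !(j %in% basis)) { enter <- j; break }
      }
      if (enter == 0L) break
      col <- Tb[, enter]
      rc <- ncol(Tb)
      ratio <- ifelse(col > tol, Tb[, rc] / col, Inf)
      if (all(!is.finite(ratio)))
        return(list(Tb = Tb, basis = basis, obj = obj_row, status = "unbounded"))
      best <- min(ratio)
      cand <- which(abs(ratio - best) <= tol * (1 + abs(best)) & is.finite(ratio))
      leave <- cand[which.min(basis[cand])]      # Bland on the leaving variable
      Tb <- pivot(Tb, leave, enter)
      # update reduced costs by the same elimination
      obj_row <- obj_row - obj_row[enter] * Tb[leave, seq_along(obj_row)]
      basis[leave] <- enter
      basis <- basis
    }
    list(Tb = Tb, basis = basis, obj = obj_row, status = "optimal")
  }

  # phase 1: minimize sum of artificials; canonical reduced costs
  obj1 <- c(-colSums(Tb[, seq_len(ntot), drop = FALSE]), rep(0, m))
  ph1 <- run_phase(Tb, basis, obj1, seq_len(ntot))
  Tb <- ph1$Tb; basis <- ph1$basis
  p1val <- sum(Tb[basis > ntot, ncol(Tb)])
  if (p1val > 1e-7)
    return(list(status = "infeasible"))
  # drive remaining artificials out of the basis where possible
  for (r in which(basis > ntot)) {
    pc <- which(abs(Tb[r, seq_len(ntot)]) > tol)[1L]
    if (!is.na(pc)) { Tb <- pivot(Tb, r, pc); basis[r] <- pc }
  }

  # phase 2 on the original cost
  cost_full <- c(cost, rep(0, ns))
  obj2 <- c(cost_full, rep(0, m))
  for (r in seq_len(m)) {
    if (basis[r] <= ntot && abs(obj2[basis[r]]) > 0)
      obj2 <- obj2 - obj2[basis[r]] * Tb[r, seq_len(ntot + m)]
  }
  ph2 <- run_phase(Tb, basis, obj2, seq_len(ntot))
  if (ph2$status != "optimal") return(list(status = ph2$status))
  Tb <- ph2$Tb; basis <- ph2$basis
  x <- numeric(ntot)
  vals <- Tb[, ncol(Tb)]
  x[basis[basis <= ntot]] <- vals[basis <= ntot]
  list(status = "optimal", x = x[seq_len(n)],
       value = sum(cost * x[seq_len(n)]))
}
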