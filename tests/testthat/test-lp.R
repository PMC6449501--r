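# build unit LPs for a cluster, returning (lp, trees) per unit
unit_lps <- function(g, d, max_somas = Inf, max_branches = Inf) {
  pt <- penalty_table(g, d)
  units <- independent_units(g, d, pt = pt)
  out <- list()
  for (u in units) {
    if (length(u$somas) > max_somas ||
        length(u$ambiguous_branches) > max_branches) next
    trees <- stats::setNames(lapply(u$somas, function(s)
      soma_tree(g, s, d, pt = pt, restrict_branches = u$ambiguous_branches,
                block_somas = TRUE)), as.character(u$somas))
    out[[length(out) + 1L]] <- list(lp = build_lp(u, trees, pt), trees = trees)
  }
  out
}

test_that("LP dimensions: one bridge branch between two somas", {
  g <- two_soma_dumbbell()
  ul <- unit_lps(g, uniform_gof())
  expect_length(ul, 1L)
  lp <- ul[[1L]]$lp
  expect_equal(nrow(lp$vars), 2L)       # (bridge, soma1), (bridge, soma4)
  expect_equal(nrow(lp$A_eq), 1L)
  expect_null(lp$A_ub)                  # bridge adjacent to both roots
})

test_that("LP dimensions: chain of two branches between two somas", {
  # somas 1 and 5; junction node 3 carries a leaf to make it topological
  nodes <- data.frame(id = 1:6, type = c(1L, 3L, 3L, 3L, 1L, 3L),
                      x = c(0, 1, 2, 3, 4, 2), y = c(0, 0, 0, 0, 0, 1),
                      z = 0, radius = 1)
  g <- morph_graph(nodes, rbind(c(1, 2), c(2, 3), c(3, 4), c(4, 5), c(3, 6)),
                   c(1L, 5L))
  ul <- unit_lps(g, uniform_gof())
  lp <- ul[[1L]]$lp
  expect_equal(nrow(lp$vars), 4L)       # 2 chain branches x 2 somas
  expect_equal(nrow(lp$A_eq), 2L)
  expect_equal(nrow(lp$A_ub), 2L)       # one parent inequality per soma tree
  # every inequality row is a (+1, -1) pair
  expect_true(all(apply(lp$A_ub, 1L, function(r) sum(r == 1) == 1 && sum(r == -1) == 1)))
})

test_that("constraint matrix agrees with an independently coded constructor", {
  # second construction: directly from the variable table, looping over
  # branches for equalities and over (branch, soma) for parent rows
  d <- uniform_gof()
  cl <- random_small_cluster(8, n_somas = 2L)
  skip_if(is.null(cl), "no connected fixture")
  ul <- unit_lps(cl$cluster, d)
  for (x in ul) {
    lp <- x$lp
    v <- lp$vars
    A_eq2 <- matrix(0, length(unique(v$branch)), nrow(v))
    for (i in seq_len(nrow(v)))
      A_eq2[match(v$branch[i], sort(unique(v$branch))), i] <- 1
    expect_equal(unname(lp$A_eq[order(sort(unique(v$branch))), , drop = FALSE]),
                 A_eq2)
    rows <- which(!is.na(v$parent))
    if (length(rows) > 0L) {
      A_ub2 <- matrix(0, length(rows), nrow(v))
      for (k in seq_along(rows)) {
        i <- rows[k]
        A_ub2[k, i] <- 1
        A_ub2[k, which(v$branch == v$parent[i] & v$soma == v$soma[i])] <- -1
      }
      expect_equal(unname(lp$A_ub), A_ub2)
    } else {
      expect_null(lp$A_ub)
    }
  }
})

test_that("1-branch unit: dominance and tie rules", {
  g <- two_soma_dumbbell()
  ul <- unit_lps(g, uniform_gof())
  lp <- ul[[1L]]$lp
  # dominance: force known penalties
  lp$objective <- c(0.1, 0.9)
  m <- solve_unit(lp)
  expect_equal(m$objective, 0.1, tolerance = 1e-9)
  expect_equal(unname(m$w[1L, ]), c(1, 0))
  fin <- finalize_assignment(m)
  expect_equal(as.integer(fin), lp$vars$soma[1L])
  # symmetric penalties: objective equals the common value, tie to smaller id
  lp$objective <- c(0.4, 0.4)
  m2 <- solve_unit(lp)
  expect_equal(m2$objective, 0.4, tolerance = 1e-9)
  fin2 <- finalize_assignment(m2)
  expect_equal(as.integer(fin2), min(lp$vars$soma))
})

test_that("assignment flips when the winning soma's penalty is raised", {
  g <- two_soma_dumbbell()
  ul <- unit_lps(g, uniform_gof())
  lp <- ul[[1L]]$lp
  lp$objective <- c(0.2, 0.5)
  a1 <- finalize_assignment(solve_unit(lp))
  lp$objective <- c(0.6, 0.5)   # raise past the alternative
  a2 <- finalize_assignment(solve_unit(lp))
  expect_false(unname(a1) == unname(a2))
})

test_that("LP optimum equals exhaustive enumeration on random units", {
  d <- uniform_gof()
  set.seed(31)
  seeds <- sample.int(1e6, 60L)
  tested <- 0L
  for (seed in seeds) {
    if (tested >= 12L) break
    ns <- 2L + (seed %% 2L)
    cl <- tryCatch(random_small_cluster(seed, n_somas = ns),
                   error = function(e) NULL)
    if (is.null(cl)) next
    ul <- unit_lps(cl$cluster, d, max_somas = 3L, max_branches = 8L)
    for (x in ul) {
      m <- solve_unit(x$lp)
      oracle <- lp_enum_oracle(x$lp)
      expect_equal(m$objective, oracle$min, tolerance = 1e-6)
      # feasibility at the solver return
      w <- x$lp$vars$w <- m$vars$w
      expect_true(all(w >= -1e-8))
      expect_true(all(abs(x$lp$A_eq %*% w - 1) <= 1e-8))
      if (!is.null(x$lp$A_ub))
        expect_true(all(x$lp$A_ub %*% w <= 1e-8))
      # unique integral argmin must be reproduced
      if (length(oracle$argmins) == 1L && m$n_fractional == 0L) {
        fin <- finalize_assignment(m, x$trees)
        want <- stats::setNames(oracle$argmins[[1L]], oracle$branches)
        expect_equal(unname(fin[names(want)]), unname(want))
      }
      tested <- tested + 1L
    }
  }
  expect_gt(tested, 5L)
})

test_that("internal simplex agrees with boot::simplex where the latter works", {
  d <- uniform_gof()
  checked <- 0L
  for (seed in c(8, 17, 23, 29)) {
    cl <- random_small_cluster(seed, n_somas = 2L)
    if (is.null(cl)) next
    for (x in unit_lps(cl$cluster, d)) {
      lp <- x$lp
      A1 <- lp$A_ub %||% matrix(c(1, rep(0, nrow(lp$vars) - 1L)), nrow = 1L)
      b1 <- if (is.null(lp$A_ub)) 1 else lp$b_ub
      ref <- tryCatch(
        boot::simplex(a = lp$objective, A1 = A1, b1 = b1,
                      A3 = lp$A_eq, b3 = lp$b_eq, maxi = FALSE,
                      n.iter = 5000L),
        error = function(e) NULL)
      if (is.null(ref) || ref$solved != 1L) next
      m <- solve_unit(lp)
      expect_equal(m$objective, unname(ref$value), tolerance = 1e-7)
      checked <- checked + 1L
    }
  }
  expect_gt(checked, 0L)
})

test_that("segmentation conserves branches and is deterministic", {
  d <- uniform_gof()
  cl <- random_small_cluster(17, n_somas = 3L)
  skip_if(is.null(cl), "no connected fixture")
  seg1 <- segment_cluster(cl$cluster, d)
  seg2 <- segment_cluster(cl$cluster, d)
  expect_identical(seg1$assignment, seg2$assignment)
  expect_equal(length(seg1$assignment),
               length(extract_branches(cl$cluster)))
  expect_equal(sum(!is.na(seg1$assignment)) + seg1$diagnostics$unassigned,
               length(seg1$assignment))
  # every assigned soma is a real soma
  expect_true(all(stats::na.omit(seg1$assignment) %in% cl$cluster$soma_ids))
})

test_that("single neuron passes through segmentation unchanged", {
  set.seed(5)
  g <- template_neuron()
  seg <- segment_cluster(g, uniform_gof())
  expect_true(all(seg$assignment == g$soma_ids))
  expect_equal(seg$objective, 0)
  expect_length(seg$units, 0L)
})

test_that("two orthogonally linked stars are recovered exactly", {
  # star A at origin, star B shifted along x; one spurious link between
  # two arm tips; every branch penalty is analytically 0 for its own soma
  a <- star_neuron(6, arm = 50, step = 5)
  b <- star_neuron(6, arm = 50, step = 5)
  b$nodes$x <- b$nodes$x + 130   # +x arm of A approaches -x arm of B
  b$nodes$id <- b$nodes$id + 100L
  b$edges <- b$edges + 100L
  b$soma_ids <- b$soma_ids + 100L
  # link the facing tips (50,0,0) and (80,0,0): distance 30
  tip_a <- a$nodes$id[a$nodes$x == 50 & a$nodes$y == 0 & a$nodes$z == 0]
  tip_b <- b$nodes$id[b$nodes$x == 80 & b$nodes$y == 0 & b$nodes$z == 0]
  g <- morph_graph(rbind(a$nodes, b$nodes),
                   rbind(a$edges, b$edges, c(tip_a, tip_b)),
                   c(1L, 101L))
  seg <- segment_cluster(g, uniform_gof())
  br <- extract_branches(g)
  for (i in seq_along(br)) {
    owner <- seg$assignment[[as.character(i)]]
    nodes_of <- br[[i]]$node_path
    if (all(nodes_of <= 100L)) expect_equal(owner, 1L)
    else if (all(nodes_of > 100L)) expect_equal(owner, 101L)
  }
})

test_that("reduction soundness: fixed branches keep their assignment without BFS", {
  # run the LP over ALL branches (no unambiguous pre-assignment) on oracle
  # sized instances and check the fixed branches come out identically
  d <- uniform_gof()
  tested <- 0L
  for (seed in c(8, 17, 23, 35)) {
    if (tested >= 2L) break
    cl <- random_small_cluster(seed, n_somas = 2L)
    if (is.null(cl)) next
    g <- cl$cluster
    pt <- penalty_table(g, d)
    pre <- assign_unambiguous(g)
    all_b <- seq_along(pt$branches)
    somas <- g$soma_ids
    trees <- stats::setNames(lapply(somas, function(s)
      soma_tree(g, s, d, pt = pt, block_somas = TRUE)), as.character(somas))
    unit_all <- list(somas = somas, ambiguous_branches = all_b)
    lp <- suppressWarnings(build_lp(unit_all, trees, pt))
    m <- solve_unit(lp)
    fin <- finalize_assignment(m, trees)
    seg <- segment_cluster(g, d)
    for (b in names(pre$fixed)) {
      if (b %in% names(fin))
        expect_equal(unname(fin[[b]]), unname(seg$assignment[[b]]))
    }
    tested <- tested + 1L
  }
  expect_gt(tested, 0L)
})
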