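test_that("analytic GOF cases: radial out is 0, radial in is pi, oblique is pi/4", {
  s <- c(0, 0, 0)
  expect_equal(branch_gof(rbind(c(1, 0, 0), c(2, 0, 0)), s), 0)
  expect_equal(branch_gof(rbind(c(2, 0, 0), c(1, 0, 0)), s), pi)
  # single segment (1,0,0)->(1,2,0): midpoint (1,1,0), tangent (0,1,0),
  # angle = arccos(1/sqrt(2)) = pi/4
  expect_equal(branch_gof(rbind(c(1, 0, 0), c(1, 2, 0)), s), pi / 4)
  # and reversing the branch changes the value
  expect_false(isTRUE(all.equal(
    branch_gof(rbind(c(1, 2, 0), c(1, 0, 0)), s), pi / 4)))
})

test_that("discrete GOF converges to the dense integral oracle", {
  # quarter circle of radius 10 around the soma, sampled ever more finely
  s <- c(0, 0, 0)
  errs <- vapply(c(6L, 12L, 48L), function(n) {
    t <- seq(0, pi / 2, length.out = n + 1L)
    coords <- cbind(10 * cos(t), 10 * sin(t), 0)
    abs(branch_gof(coords, s) - gof_integral_oracle(coords, s, step = 0.05))
  }, 0)
  expect_lt(errs[3L], errs[1L] + 1e-12)
  expect_lt(errs[3L], 1e-3)
  # a tangential arc around the soma has angle ~ pi/2 everywhere
  t <- seq(0, pi / 2, length.out = 49L)
  expect_equal(branch_gof(cbind(10 * cos(t), 10 * sin(t), 0), s), pi / 2,
               tolerance = 1e-3)
})

test_that("GOF agrees with the integral oracle on random smooth polylines", {
  set.seed(11)
  for (k in 1:12) {
    # smooth random curve: cumulative sum of slowly rotating directions
    n <- 40L
    dir <- c(1, 0, 0)
    pts <- matrix(0, n + 1L, 3L)
    pts[1L, ] <- stats::runif(3L, 5, 15)
    for (j in seq_len(n)) {
      dir <- dir + 0.15 * stats::rnorm(3L)
      dir <- dir / sqrt(sum(dir^2))
      pts[j + 1L, ] <- pts[j, ] + dir * 0.5
    }
    s <- stats::runif(3L, -5, 5)
    expect_equal(branch_gof(pts, s), gof_integral_oracle(pts, s, step = 0.05),
                 tolerance = 1e-3)
  }
})

test_that("GOF is invariant under rigid motion and scaling", {
  set.seed(7)
  pts <- cbind(cumsum(runif(8, 0.5, 2)), cumsum(rnorm(8, 0, 0.5)), 0)
  s <- c(-1, 0.5, 2)
  base <- branch_gof(pts, s)
  # rotation + translation applied to both branch and soma
  q <- qr.Q(qr(matrix(rnorm(9), 3))); if (det(q) < 0) q[, 1] <- -q[, 1]
  shift <- c(5, -3, 11)
  expect_equal(branch_gof(pts %*% t(q) + rep(shift, each = 8), as.numeric(q %*% s + shift)),
               base)
  # uniform scaling leaves the angle unchanged but scales the length penalty
  expect_equal(branch_gof(pts * 3, s * 3), base)
  d <- uniform_gof()
  expect_equal(branch_penalty(pts * 3, s * 3, d), 3 * branch_penalty(pts, s, d),
               tolerance = 1e-12)
})

test_that("degenerate segments are handled as documented", {
  s <- c(0, 0, 0)
  expect_warning(v <- branch_gof(rbind(c(1, 0, 0), c(1, 0, 0), c(2, 0, 0)), s),
                 "zero-length")
  expect_equal(v, 0)
  # soma on a segment midpoint: angle defined as 0
  expect_warning(v2 <- branch_gof(rbind(c(-1, 0, 0), c(1, 0, 0)), s),
                 "midpoint")
  expect_equal(v2, 0)
})

test_that("corpus distribution: radial star corpus concentrates at 0", {
  d <- build_gof_distribution(list(star_neuron(6)), n_bins = 36L,
                              provenance = "star")
  expect_equal(sum(d$pdf_mass), 1)
  expect_equal(d$pdf_mass[1L], 1)          # all mass in the first bin
  expect_lt(tail_dist(d, 0.2), 0.05)
  expect_equal(d$provenance, "star")
})

test_that("corpus distribution matches the analytic mixture CDF", {
  # each neuron: a long radial stem to a junction at distance R, then two
  # single-segment daughter branches at prescribed angles in the xy plane;
  # with R >> 1 each daughter's GOF equals its prescribed angle, so the
  # corpus GOF sample is the mixture 1/3 * delta(0) + 2/3 * Uniform[0, pi]
  mk <- function(t1, t2) {
    R <- 5000
    nodes <- data.frame(id = 1:4, type = c(1L, 3L, 3L, 3L),
                        x = c(0, R, R + cos(t1), R + cos(t2)),
                        y = c(0, 0, sin(t1), -sin(t2)), z = 0, radius = 1)
    morph_graph(nodes, rbind(c(1, 2), c(2, 3), c(2, 4)), 1L)
  }
  thetas <- seq(0.005, pi - 0.005, length.out = 80L)
  corpus <- mapply(mk, thetas, rev(thetas), SIMPLIFY = FALSE)
  d <- build_gof_distribution(corpus, n_bins = 36L, provenance = "mixture-fixture")
  # analytic tails of the mixture: 2/3 * (1 - x/pi)
  expect_equal(tail_dist(d, pi / 2), 2 / 3 * 0.5, tolerance = 0.05)
  expect_equal(tail_dist(d, pi / 4), 2 / 3 * 0.75, tolerance = 0.05)
  # duplicating every neuron leaves the distribution unchanged
  d2 <- build_gof_distribution(c(corpus, corpus), n_bins = 36L)
  expect_equal(d2$pdf_mass, d$pdf_mass)
})

test_that("corpus entries without exactly one soma are rejected with a report", {
  expect_warning(
    d <- build_gof_distribution(list(two_soma_dumbbell(), star_neuron(4)),
                                n_bins = 18L),
    "rejected")
  expect_s3_class(d, "gof_dist")
  expect_error(suppressWarnings(build_gof_distribution(list(two_soma_dumbbell()))),
               class = "gcut_empty_input")
  expect_error(build_gof_distribution(list()), class = "gcut_empty_input")
})

test_that("tail distribution endpoints, monotonicity and domain", {
  d <- build_gof_distribution(test_templates(3L), n_bins = 90L)
  expect_equal(tail_dist(d, 0), 1)
  expect_equal(tail_dist(d, pi), 0)
  xs <- seq(0, pi, length.out = 400L)
  td <- tail_dist(d, xs)
  expect_true(all(diff(td) <= 1e-12))
  expect_true(all(td >= 0 & td <= 1))
  expect_error(tail_dist(d, -0.1), class = "gcut_domain_error")
  expect_error(tail_dist(d, 3.5), class = "gcut_domain_error")
})

test_that("branch penalty composes weight and tail distribution", {
  d <- uniform_gof()
  s <- c(0, 0, 0)
  out <- rbind(c(1, 0, 0), c(2, 0, 0))
  inw <- rbind(c(2, 0, 0), c(1, 0, 0))
  expect_equal(branch_penalty(out, s, d), 0)
  expect_equal(branch_penalty(inw, s, d), 1)           # L = 1, TailDist(pi) = 0
  # pi/4 fixture with uniform distribution: L * (1 - 0.75) = 2 * 0.25
  obl <- rbind(c(1, 0, 0), c(1, 2, 0))
  expect_equal(branch_penalty(obl, s, d), 0.5, tolerance = 1e-9)
})

test_that("KL divergence: zero on identity, hand value, asymmetric", {
  edges2 <- c(0, pi / 2, pi)
  p <- gof_distribution(edges2, c(0.5, 0.5))
  q <- gof_distribution(edges2, c(0.9, 0.1))
  expect_equal(kl_divergence(p, p), 0)
  expect_equal(kl_divergence(p, q),
               0.5 * log(0.5 / 0.9) + 0.5 * log(0.5 / 0.1),
               tolerance = 1e-9)
  expect_false(isTRUE(all.equal(kl_divergence(p, q), kl_divergence(q, p))))
  expect_gt(kl_divergence(q, p), 0)
  d3 <- gof_distribution(seq(0, pi, length.out = 4L), rep(1 / 3, 3L))
  expect_error(kl_divergence(p, d3), class = "gcut_structure_error")
})

test_that("distribution save/load round trip preserves everything", {
  d <- build_gof_distribution(test_templates(2L), n_bins = 45L,
                              provenance = "round trip label")
  f <- withr::local_tempfile(fileext = ".json")
  save_gof_distribution(d, f)
  d2 <- load_gof_distribution(f)
  expect_equal(d2$bin_edges, d$bin_edges)
  expect_equal(d2$pdf_mass, d$pdf_mass)
  expect_equal(d2$provenance, "round trip label")
  # un-normalized file triggers renormalization warning
  obj <- jsonlite::read_json(f, simplifyVector = TRUE)
  obj$pdf_mass <- obj$pdf_mass * 0.9
  jsonlite::write_json(obj, f, auto_unbox = TRUE, digits = NA)
  expect_warning(d3 <- load_gof_distribution(f), "renormaliz")
  expect_equal(sum(d3$pdf_mass), 1)
  writeLines("not json at all {", f)
  expect_error(load_gof_distribution(f), class = "gcut_parse_error")
})
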