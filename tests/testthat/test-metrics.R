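## Output metrics: arc lengths, ROA, compaction, field summaries, order
## parameter, cost function.

test_that("piecewise-quadratic arc length is at least second-order accurate", {
  ## analytic quarter circle, radius 5
  arc <- function(n) {
    th <- seq(0, pi / 2, length.out = n)
    arc_length_quadratic(cbind(5 * cos(th), 5 * sin(th)))
  }
  exact <- 5 * pi / 2
  e1 <- abs(arc(11) - exact)
  e2 <- abs(arc(21) - exact)
  expect_lt(e2, e1 / 3.5)  ## >= 2nd order: refinement much better than halves
  ## straight segment is exact
  pts <- cbind(seq(0, 3, length.out = 7), seq(0, 4, length.out = 7))
  expect_equal(arc_length_quadratic(pts), 5, tolerance = 1e-12)
})

test_that("profile lengths scale exactly under similarity transforms", {
  m <- coarse_d1
  l0 <- profile_lengths(m)
  ms <- m
  ms$nodes <- 0.9 * ms$nodes
  ms$meta$grid$mid_grid <- 0.9 * ms$meta$grid$mid_grid
  ## lengths are computed from the node sheets, so scaling nodes suffices
  l1 <- profile_lengths(ms)
  expect_equal(unname(l1 / l0), c(0.9, 0.9), tolerance = 1e-8)
})

test_that("ROA of a constructed central gap matches an independent coverage oracle", {
  ## widen each leaflet laterally (so neighbors overlap sideways) and pull
  ## it radially outward along its bisector: a clean, bounded central gap
  ## opens between the three retracted free edges
  m <- coarse_d2
  ms <- m
  ms$nodes[, 1] <- 1.25 * ms$nodes[, 1]
  ms$nodes[, 2] <- ms$nodes[, 2] + 0.4
  roa <- as.numeric(regurgitant_orifice_area(ms, n_rays = 4000L))
  expect_gt(roa, 0)
  ## independent oracle: Monte-Carlo coverage of the same three plan
  ## polygons with an even-odd point-in-polygon test
  poly0 <- tehvsim:::leaflet_plan_polygon(ms)
  set.seed(5)
  px <- runif(400000, -3, 3); py <- runif(400000, -3, 3)
  covered <- rep(FALSE, length(px))
  for (a in c(0, 2 * pi / 3, -2 * pi / 3)) {
    R2 <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
    pr <- poly0 %*% t(R2)
    covered <- covered | point_in_poly(px, py, pr)
  }
  mc_area <- 36 * mean(!covered)
  expect_equal(roa, mc_area, tolerance = 0.05)
  ## angular-resolution robustness of the orifice integral
  roa_lo <- as.numeric(regurgitant_orifice_area(ms, n_rays = 1440L))
  expect_lt(abs(roa_lo - roa) / roa, 1e-2)
})

test_that("fully coapted valves report zero orifice area", {
  expect_equal(as.numeric(regurgitant_orifice_area(coarse_d2)), 0)
  expect_equal(as.numeric(regurgitant_orifice_area(coarse_d1)), 0)
})

test_that("field summaries: von Mises closed forms and principal log strain", {
  ## hydrostatic stress -> zero von Mises; uniaxial -> the stress itself
  hyd <- array(0, c(1, 3, 3)); for (d in 1:3) hyd[1, d, d] <- -7
  expect_equal(tehvsim:::von_mises(hyd), 0)
  uni <- array(0, c(1, 3, 3)); uni[1, 1, 1] <- 13
  expect_equal(tehvsim:::von_mises(uni), 13)
  ## F = diag(1.2, 1, 1) -> max principal log strain ln(1.2)
  m <- make_fixtures("patch")
  sol <- solve_static(m, bcs = boundary_conditions(pressure = 0,
                                                   contact = FALSE))
  sol$F[] <- 0
  for (k in seq_len(dim(sol$F)[1])) {
    sol$F[k, , ] <- diag(c(1.2, 1, 1))
  }
  fs <- field_summaries(sol)
  expect_equal(fs$peak_log_strain[fs$region == "global"], log(1.2),
               tolerance = 1e-12)
})

test_that("order parameter: isotropy, perfect alignment, two-point oracle", {
  fb <- fiber_directions(30)
  expect_equal(order_parameter(rep(1, 30), fb), 0, tolerance = 1e-12)
  phi <- numeric(30); phi[1] <- 1             ## gamma = 0
  expect_equal(order_parameter(phi, fb), 1)
  ## all mass at gamma = pi/2 (direction index 16 of 30)
  phi <- numeric(30); phi[16] <- 2
  expect_equal(order_parameter(phi, fb), -1)
  ## equal mass at gamma = 0 and pi/4: S = (1 + 0) / 2
  gam <- c(0, pi / 4)
  expect_equal(order_parameter(c(1, 1), gam), 0.5)
  expect_error(order_parameter(rep(0, 30), fb), "undefined")
  ## mirror symmetry of the distribution leaves S unchanged
  set.seed(3)
  phi <- runif(30)
  expect_equal(order_parameter(phi, fb), order_parameter(rev(phi),
                                                         rev(pi - fb$gamma)),
               tolerance = 1e-12)
  ## bounds for arbitrary nonnegative distributions
  for (k in 1:20) {
    S <- order_parameter(runif(30), fb)
    expect_gte(S, -1); expect_lte(S, 1)
  }
})

test_that("cost function: perfect design, normalized extremes, monotonicity", {
  batch <- data.frame(peak_stress = c(0, 10, 20), roa = c(0, 2, 4))
  out <- cost_evaluate(batch, cost_spec())
  expect_equal(out$C_tot[1], 0)
  ## single parameter at the batch max with target at the min -> C_tot = 1
  b2 <- data.frame(peak_stress = c(0, 5))
  o2 <- cost_evaluate(b2, cost_spec(targets = c(peak_stress = 0)))
  expect_equal(o2$C_tot[2], 1)
  ## direct Eq-style arithmetic on a generic batch
  expect_equal(out$C_tot[2],
               sqrt(((10 / 20)^2 + (2 / 4)^2) / 2), tolerance = 1e-12)
  ## raising one design's stress never lowers its total cost
  b3 <- data.frame(peak_stress = c(5, 12, 20), roa = c(1, 1, 1))
  o3a <- cost_evaluate(b3, cost_spec(targets = c(peak_stress = 0)))
  b3$peak_stress[2] <- 18
  o3b <- cost_evaluate(b3, cost_spec(targets = c(peak_stress = 0)))
  expect_gte(o3b$C_tot[2], o3a$C_tot[2])
  ## zero-range parameter dropped with a warning
  expect_warning(cost_evaluate(data.frame(peak_stress = c(1, 2),
                                          roa = c(3, 3)), cost_spec()),
                 "zero range")
})

test_that("directional compaction recovers a prescribed isotropic shrinkage", {
  ## free square patch with uniform growth stretch 0.9 in all directions:
  ## the equilibrium in-plane shrinkage matches a single-material-point
  ## solve of the same balance
  p <- default_params
  m <- make_fixtures("patch", nx = 2L, ny = 2L, lx = 2, ly = 2,
                     distort = 0)
  f <- tissue_field(m, p)
  f$state$lam_g[] <- 0.9
  sol <- free_block_solve(m, f, p)   ## rigid modes fixed only
  comp <- directional_compaction(sol)
  lam_eq <- free_shrink_oracle(0.9, p)
  expect_equal(unname(comp), rep(100 * log(lam_eq), 2), tolerance = 1e-3)
  expect_lt(comp[["circumferential"]], 0)
  expect_lt(comp[["radial"]], 0)
})
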