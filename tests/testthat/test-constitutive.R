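## Material-point constitutive and remodeling behavior.

test_that("stress-fiber stress law matches direct evaluation and scales with sigma_max", {
  p <- default_params; f <- default_funcs
  expect_equal(stress_fiber_stress(0.05, 0.1, material_params(sigma_max = 0), f), 0)
  ## direct evaluation of the shipped response forms at the active optimum
  eps <- 0
  expected <- p$sigma_max * (exp(-(eps / p$eps0)^2) +
                               (max(eps, 0) / p$eps1)^2) * 1
  expect_equal(stress_fiber_stress(eps, 0, p, f), expected, tolerance = 1e-14)
  ## generic strain/rate point, fully independent arithmetic
  eps <- 0.08; rate <- 0.12
  expected <- 40 * (exp(-(0.08 / 0.12)^2) + (0.08 / 0.17)^2) *
    1 / (1 + (50 * 0.12)^2)
  expect_equal(stress_fiber_stress(eps, rate, p, f), expected,
               tolerance = 1e-12)
})

test_that("collagen fiber stress is tension-only and matches high-precision evaluation", {
  p <- default_params
  expect_equal(collagen_fiber_stress(1, p), 0)
  expect_equal(collagen_fiber_stress(0.9, p), 0)
  ## independent evaluation (plain exp form) on randomized stretches
  set.seed(42)
  lam <- runif(50, 1.001, 1.15)
  direct <- 33.01 * lam^2 * (exp(11.74 * (lam^2 - 1)) - 1)
  expect_lt(max(abs(collagen_fiber_stress(lam, p) - direct) / direct), 1e-10)
  ## strictly increasing above 1
  lam <- seq(1.0001, 1.2, length.out = 40)
  expect_true(all(diff(collagen_fiber_stress(lam, p)) > 0))
})

test_that("ECM stress: stress-free reference, isochoric and dilatational forms", {
  p <- default_params
  expect_equal(ecm_stress(diag(3), p), matrix(0, 3, 3))
  ## isochoric simple shear: volumetric term vanishes
  F <- matrix(c(1, 0.3, 0, 0, 1, 0, 0, 0, 1), 3, 3)
  B <- F %*% t(F)
  expect_equal(ecm_stress(F, p), p$phi_ecm * p$G * (B - diag(3)),
               tolerance = 1e-12)
  ## pure dilation against symbolic evaluation
  a <- 1.07; J <- a^3
  expected <- p$phi_ecm * (p$kappa_ecm * log(J) / J +
                             p$G / J * (a^2 - J^(2 / 3))) * diag(3)
  expect_equal(ecm_stress(a * diag(3), p), expected, tolerance = 1e-12)
})

test_that("stress-fiber tensor reduces to direct 30-direction summation", {
  p <- default_params; f <- default_funcs
  st <- tissue_state(fibers30, p)
  ## no polymerized fibers -> zero tensor
  expect_equal(stress_fiber_tensor(st, diag(3), p, f), matrix(0, 3, 3))
  ## single active direction -> rank-one along that direction
  st1 <- st
  st1$phi_sf[1, 7] <- 0.02
  st1$phi_mon <- st1$phi_a - rowMeans(st1$phi_sf)
  sig <- stress_fiber_tensor(st1, diag(3), p, f)
  g <- fibers30$gamma[7]
  e <- c(cos(g), sin(g), 0)
  mag <- 0.02 * stress_fiber_stress(0, 0, p, f) / 30
  expect_equal(sig, mag * outer(e, e), tolerance = 1e-12)
  ## isotropic fractions at F = I: in-plane isotropic, zero out-of-plane
  sti <- st
  sti$phi_sf[] <- 0.03
  sti$phi_mon <- sti$phi_a - rowMeans(sti$phi_sf)
  sig <- stress_fiber_tensor(sti, diag(3), p, f)
  sig_i <- rep(stress_fiber_stress(0, 0, p, f), 30)
  oracle <- direct_sf_tensor(rep(0.03, 30), sig_i, fibers30$gamma)
  expect_equal(sig, oracle, tolerance = 1e-12)
  expect_lt(abs(sig[1, 2]), 1e-12)
  expect_equal(sig[1, 1], sig[2, 2], tolerance = 1e-12)
  expect_equal(sig[3, 3], 0)
})

test_that("preferred stress-fiber fractions: closed-form steady state and symmetry", {
  p0 <- material_params(k1_sf = 0)
  f0 <- sf_response_functions(p0)
  phi_p <- preferred_sf_fraction(rep(0.05, 30), rep(0.01, 30), 0.85, p0, f0)
  ## with k1 = 0 the stationary ratio phi_sf / phi_mon equals k0 / kd
  expect_equal(as.numeric(phi_p) / attr(phi_p, "phi_mon"),
               rep(p0$k0_sf / p0$kd_sf, 30), tolerance = 1e-12)
  ## strain-free static state -> isotropic preferred fractions
  p <- default_params; f <- default_funcs
  phi_p <- preferred_sf_fraction(rep(0, 30), rep(0, 30), 0.85, p, f)
  expect_equal(max(phi_p) - min(phi_p), 0)
  ## actin conservation holds at the preferred state
  expect_equal(mean(phi_p) + attr(phi_p, "phi_mon"), p$phi_a,
               tolerance = 1e-12)
})

test_that("stress-fiber update is an exact exponential relaxation", {
  p <- default_params
  st <- tissue_state(fibers30, p)
  target <- runif(30, 0, 0.04)
  ## semigroup: two half steps equal one full step
  s1 <- update_stress_fibers(update_stress_fibers(st, target, 900, p),
                             target, 900, p)
  s2 <- update_stress_fibers(st, target, 1800, p)
  expect_equal(s1$phi_sf, s2$phi_sf, tolerance = 1e-12)
  ## dt = tau ln 2 -> halfway to target
  sh <- update_stress_fibers(st, target, p$tau_sf * log(2), p)
  expect_equal(sh$phi_sf[1, ], (st$phi_sf[1, ] + target) / 2,
               tolerance = 1e-12)
  ## dt -> infinity reaches the target
  sinf <- update_stress_fibers(st, target, 1e9, p)
  expect_equal(sinf$phi_sf[1, ], target, tolerance = 1e-12)
  validate_tissue_state(sinf)
})

test_that("preferred growth stretch solves the stress balance", {
  p <- default_params
  expect_equal(as.numeric(preferred_growth_stretch(1.07, 0, p)), 1.07)
  set.seed(7)
  lam <- runif(40, 1.0, 1.15)
  tgt <- runif(40, 0.1, 60)
  lg <- preferred_growth_stretch(lam, tgt, p)
  resid <- abs(collagen_fiber_stress(lam / lg, p) - tgt)
  expect_lt(max(resid[!attr(lg, "bracket_failed")]), 1e-8)
})

test_that("collagen growth relaxation: fixed point and halfway step", {
  p <- default_params
  st <- tissue_state(fibers30, p)
  s0 <- update_collagen_growth(st, st$lam_g, 3600, p)
  expect_equal(s0$lam_g, st$lam_g)
  target <- matrix(0.93, 1, 30)
  sh <- update_collagen_growth(st, target, p$tau_lambda * log(2), p)
  expect_equal(sh$lam_g[1, ], rep((1 + 0.93) / 2, 30), tolerance = 1e-12)
})

test_that("collagen turnover conserves total fraction and favors strained directions", {
  p <- default_params; f <- default_funcs
  st <- tissue_state(fibers30, p)
  ## uniform strain from an isotropic start leaves the distribution unchanged
  s1 <- collagen_turnover(st, rep(0.05, 30), 1800, p, f)
  expect_equal(s1$phi_cf, st$phi_cf, tolerance = 1e-12)
  ## anisotropic strain: the more strained direction retains more collagen
  eps <- 0.08 * cos(fibers30$gamma)^2
  s2 <- collagen_turnover(st, eps, 3600, p, f)
  expect_equal(sum(s2$phi_cf), p$phi_cf, tolerance = 1e-10)
  expect_gt(s2$phi_cf[1, 1], s2$phi_cf[1, 16])  ## gamma=0 vs gamma=pi/2
  validate_tissue_state(s2)
})

test_that("total stress is the sum of its three parts and respects symmetry", {
  p <- default_params; f <- default_funcs
  st <- tissue_state(fibers30, p)
  st$phi_sf[] <- 0.03
  st$phi_mon <- st$phi_a - rowMeans(st$phi_sf)
  st$lam_g[] <- 0.98
  F <- diag(c(1.06, 1.06, 0.95))
  tot <- total_stress(F, st, p, f)
  ## additivity against the component operations
  sf_part <- stress_fiber_tensor(st, F, p, f)
  p_cf <- p; p_cf$phi_ecm <- 0; p_cf$G <- 0; p_cf$kappa_ecm <- 0
  st_cf <- st; st_cf$phi_sf[] <- 0
  cf_part <- tehvsim:::cauchy_stress_field(F, st_cf, p_cf, f)[1, , ]
  ecm_part <- ecm_stress(F, p)
  expect_equal(tot, sf_part + cf_part + ecm_part, tolerance = 1e-12)
  ## equibiaxial stretch of an isotropic state: equal in-plane normals
  expect_equal(tot[1, 1], tot[2, 2], tolerance = 1e-10)
  ## all fractions zero -> zero stress
  p0 <- material_params(phi_a = 0, phi_cf = 0, phi_ecm = 0)
  st0 <- tissue_state(fibers30, p0)
  expect_equal(total_stress(diag(c(1.1, 0.9, 1)), st0, p0,
                            sf_response_functions(p0)),
               matrix(0, 3, 3), tolerance = 1e-14)
})

test_that("Cauchy stress is objective under rigid rotations", {
  p <- default_params; f <- default_funcs
  set.seed(11)
  st <- tissue_state(fibers30, p)
  st$phi_sf[] <- runif(30, 0, 0.05)
  st$phi_mon <- st$phi_a - rowMeans(st$phi_sf)
  st$lam_g[] <- runif(30, 0.95, 1.0)
  F <- diag(3) + matrix(rnorm(9, 0, 0.05), 3, 3)
  if (det(F) <= 0) F <- diag(3) + 0.05 * matrix(1:9 / 9, 3, 3)
  rate <- runif(30, -0.1, 0.1)
  sig <- total_stress(F, st, p, f, rate = rate)
  for (k in 1:5) {
    Q <- tehvsim:::random_rotation()
    sig_rot <- total_stress(Q %*% F, st, p, f, rate = rate)
    expect_equal(sig_rot, Q %*% sig %*% t(Q), tolerance = 1e-10)
  }
})

test_that("doubling the fiber count barely changes the isotropic-state stress", {
  p <- default_params
  F <- diag(c(1.05, 1.02, 0.97))
  sig_of <- function(N) {
    fb <- fiber_directions(N)
    st <- tissue_state(fb, p)
    st$phi_sf[] <- 0.03
    st$phi_mon <- st$phi_a - rowMeans(st$phi_sf)
    total_stress(F, st, p, sf_response_functions(p))
  }
  s30 <- sig_of(30L); s60 <- sig_of(60L)
  expect_lt(max(abs(s60 - s30)) / max(abs(s30)), 0.005)
})

test_that("material-point driver: no stimulus keeps isotropy; constant stretch reaches a balanced fixed point", {
  p <- default_params; f <- default_funcs
  hist_id <- make_fixtures("point_histories", mode = "cyclic", stretch = 1,
                           n_steps = 10L, dt = 600)
  out <- suppressWarnings(simulate_material_point(hist_id, p, f, fibers30))
  expect_equal(out$trajectory$S_cf[nrow(out$trajectory)], 0, tolerance = 1e-12)
  expect_equal(out$trajectory$S_sf[nrow(out$trajectory)], 0, tolerance = 1e-12)

  ## constant anisotropic stretch held for a long horizon
  Fl <- diag(c(1.08, 1.01, 1))
  hist <- lapply(0:80, function(k) list(time = k * 1800, F_loaded = Fl,
                                        F_unloaded = Fl))
  out2 <- suppressWarnings(simulate_material_point(hist, p, f, fibers30,
                                                   turnover = FALSE))
  tail_change <- utils::tail(out2$trajectory$step_change, 1)
  expect_lt(tail_change, 1e-6)
  ## stress balance where compaction occurred
  dl <- deformation_point(Fl, fibers30)
  sig_sf <- stress_fiber_stress(dl$eps, 0, p, f)
  lam_e <- dl$lam / out2$state$lam_g[1, ]
  sig_cf <- collagen_fiber_stress(lam_e, p)
  compacted <- out2$state$lam_g[1, ] < 1 - 1e-6
  if (any(compacted)) {
    expect_lt(max(abs(sig_cf[compacted] - sig_sf[compacted])), 1e-6)
  }
})

test_that("conservation invariants survive long random update sequences", {
  p <- default_params; f <- default_funcs
  set.seed(99)
  st <- tissue_state(fibers30, p, npoints = 4L)
  for (k in 1:2500) {
    eps_l <- matrix(runif(120, -0.02, 0.1), 4)
    eps_u <- eps_l - matrix(runif(120, 0, 0.05), 4)
    lam_l <- sqrt(pmax(2 * eps_l + 1, 0.25))
    st <- tehvsim:::remodel_step(st, eps_l, eps_u, lam_l, dt = runif(1, 60, 3600),
                       period = 0.85, params = p, funcs = f)
  }
  expect_equal(st$phi_mon + rowMeans(st$phi_sf), rep(p$phi_a, 4),
               tolerance = 1e-10)
  expect_equal(rowSums(st$phi_cf), rep(p$phi_cf, 4), tolerance = 1e-10)
  expect_true(all(st$lam_g > 0))
  expect_true(all(st$phi_sf >= 0))
})
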