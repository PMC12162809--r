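## Nonlinear FE verification: reference equilibrium, one-element oracle,
## patch test, load balance, symmetry, contact admissibility.

ecm_only <- material_params(phi_a = 0, phi_cf = 0)

test_that("reference state is in equilibrium at machine precision", {
  m <- make_fixtures("strip")
  sol <- solve_static(m, bcs = boundary_conditions(pressure = 0,
                                                   contact = FALSE))
  expect_equal(max(abs(sol$u)), 0)
  expect_lt(max(abs(sol$residual[sol$free_dofs])), 1e-10)
})

test_that("single ECM element under face pressure matches the 0-D oracle", {
  ## unit cube, ECM only; bottom fixed in z, side pairs fixed in their
  ## normals, pressure p on top: homogeneous uniaxial-strain compression
  p_load <- 0.5
  m <- tehvsim:::block_mesh(lx = 1, ly = 1, thickness = 1, nx = 1L, ny = 1L,
                  n_layers = 1L, order = 1L)
  pre <- tehvsim:::fe_precompute(m)
  params <- ecm_only
  funcs <- sf_response_functions(params)
  field <- tissue_field(m, params)
  stress_fn <- function(Fa) tehvsim:::cauchy_stress_field(
    Fa, field$state, params, funcs, basis = pre$basis, rate = field$rate)
  nd <- m$nodes
  fx <- c(3L * (which(abs(nd[, 3] - min(nd[, 3])) < 1e-9) - 1L) + 3L,
          3L * (which(abs(nd[, 1] - min(nd[, 1])) < 1e-9 |
                        abs(nd[, 1] - max(nd[, 1])) < 1e-9) - 1L) + 1L,
          3L * (which(abs(nd[, 2] - min(nd[, 2])) < 1e-9 |
                        abs(nd[, 2] - max(nd[, 2])) < 1e-9) - 1L) + 2L)
  free <- setdiff(seq_len(pre$ndof), sort(unique(fx)))
  bcs <- boundary_conditions(pressure = p_load, contact = FALSE)
  res <- tehvsim:::newton_solve(m, pre, stress_fn, matrix(0, pre$nn, 3),
                                p_load, bcs, solver_settings(), free,
                                0, numeric(pre$nn))
  expect_true(res$converged)
  ## independent arithmetic: solve sigma_zz(diag(1,1,lam)) = -p for lam
  lam_oracle <- uniroot(function(l) {
    ecm_stress(diag(c(1, 1, l)), params)[3, 3] + p_load
  }, c(0.2, 1), tol = 1e-12)$root
  top <- which(abs(nd[, 3] - max(nd[, 3])) < 1e-9)
  expect_equal(unname(res$u[top, 3]), rep(lam_oracle - 1, length(top)),
               tolerance = 1e-6)
})

test_that("distorted patch reproduces a constant-strain state exactly", {
  m <- tehvsim:::block_mesh(lx = 2, ly = 2, thickness = 1, nx = 3L, ny = 3L,
                  n_layers = 2L, order = 1L, distort = 0.2)
  pre <- tehvsim:::fe_precompute(m)
  params <- ecm_only
  field <- tissue_field(m, params)
  funcs <- sf_response_functions(params)
  stress_fn <- function(Fa) tehvsim:::cauchy_stress_field(
    Fa, field$state, params, funcs, basis = pre$basis, rate = field$rate)
  ## affine displacement field u = (A - I) X
  A <- matrix(c(1.03, 0.01, 0, 0.02, 0.98, 0.01, 0, 0.005, 1.02), 3, 3,
              byrow = TRUE)
  u_affine <- m$nodes %*% t(A) - m$nodes
  ## boundary nodes = nodes of the block's outer surface
  nd <- m$nodes
  on_bdry <- abs(nd[, 1] - min(nd[, 1])) < 1e-9 |
    abs(nd[, 1] - max(nd[, 1])) < 1e-9 |
    abs(nd[, 2] - min(nd[, 2])) < 1e-9 |
    abs(nd[, 2] - max(nd[, 2])) < 1e-9 |
    abs(nd[, 3] - min(nd[, 3])) < 1e-6 |
    abs(nd[, 3] - max(nd[, 3])) < 1e-6
  ## the warped mid-surface makes top/bottom non-planar; classify by sheet
  id <- m$meta$grid$id_grid
  sheet_b <- as.vector(id[, , 1]); sheet_t <- as.vector(id[, , dim(id)[3]])
  on_bdry[c(sheet_b, sheet_t)] <- TRUE
  interior <- which(!on_bdry)
  expect_gt(length(interior), 0L)
  free <- as.vector(vapply(interior, function(n) 3L * (n - 1L) + 1:3,
                           integer(3)))
  bcs <- boundary_conditions(pressure = 0, contact = FALSE)
  res <- tehvsim:::newton_solve(m, pre, stress_fn, u_affine, 0, bcs,
                                solver_settings(), free, 0,
                                numeric(pre$nn))
  expect_true(res$converged)
  ## interior nodes recover the affine field; stress constant at all points
  expect_equal(res$u[interior, ], u_affine[interior, ], tolerance = 1e-8)
  Fall <- tehvsim:::compute_F_all(pre, m$nodes + res$u)
  sig <- stress_fn(Fall)
  sref <- ecm_stress(A, ecm_only)
  for (i in 1:3) for (j in 1:3) {
    expect_lt(max(abs(sig[, i, j] - sref[i, j])), 1e-8)
  }
})

test_that("reactions balance the integrated pressure load", {
  m <- make_fixtures("strip")
  sol <- solve_static(m, bcs = boundary_conditions(pressure = 0.05,
                                                   contact = FALSE),
                      settings = solver_settings(load_increments = 1L))
  ## support forces balance the applied load: sum(reactions) = -sum(f_ext)
  fr <- colSums(sol$reactions)
  fe <- colSums(matrix(sol$f_ext, ncol = 3, byrow = TRUE))
  expect_lt(sqrt(sum((fr + fe)^2)) / sqrt(sum(fe^2)), 1e-6)
})

test_that("a mirrored problem yields the mirrored solution", {
  m <- coarse_d1
  tight <- solver_settings(newton_tol = 1e-11)
  sol <- solve_static(m, bcs = boundary_conditions(pressure = 2),
                      settings = tight)
  mm <- mirror_mesh(m)
  sol_m <- solve_static(mm, bcs = boundary_conditions(pressure = 2),
                        settings = tight)
  u_ref <- sol$u
  u_ref[, 1] <- -u_ref[, 1]
  expect_lt(max(abs(sol_m$u - u_ref)), 1e-8)
})

test_that("augmented-Lagrange contact keeps penetration below tolerance", {
  m <- coarse_d1
  sol <- solve_static(m, bcs = boundary_conditions(pressure = 2),
                      settings = solver_settings(
                        contact_method = "augmented",
                        penetration_tol = 1e-3))
  expect_gt(min(sol$gaps), -1e-3)
})

test_that("a compacted free patch shrinks as the 0-D stress balance predicts", {
  p <- default_params
  m <- make_fixtures("patch", nx = 2L, ny = 2L, lx = 2, ly = 2, distort = 0)
  f <- tissue_field(m, p)
  f$state$lam_g[] <- 0.95
  sol <- free_block_solve(m, f, p)   ## rigid modes fixed only
  lam_eq <- free_shrink_oracle(0.95, p)
  ## mean in-plane stretch of the far edge against the 0-D value
  fe_nodes <- m$sets$free_edge
  stretch <- 1 + mean(sol$u[fe_nodes, 1]) / max(m$nodes[, 1])
  expect_equal(stretch, lam_eq, tolerance = 1e-3)
})

test_that("uncompacted isotropic state stays at identity when unloaded", {
  m <- coarse_d1
  sol <- unloaded_configuration(m, params = default_params)
  expect_lt(max(abs(sol$u)), 1e-8)
})
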