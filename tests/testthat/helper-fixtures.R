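## Shared fixtures and small independent oracles used across test files.

default_params <- material_params()
default_funcs <- sf_response_functions(default_params)
fibers30 <- fiber_directions(30L)

## independent de Casteljau evaluation (oracle for Bezier points)
de_casteljau <- function(cp, t) {
  pts <- cp
  while (nrow(pts) > 1L) {
    pts <- (1 - t) * pts[-nrow(pts), , drop = FALSE] +
      t * pts[-1, , drop = FALSE]
  }
  pts[1, ]
}

## independent direct-summation stress-fiber tensor (oracle for Eq-5 style
## summation): per-direction stress supplied explicitly
direct_sf_tensor <- function(phi_sf, sig_i, gamma, F = diag(3)) {
  N <- length(gamma)
  out <- matrix(0, 3, 3)
  for (i in seq_len(N)) {
    e0 <- c(cos(gamma[i]), sin(gamma[i]), 0)
    ef <- as.numeric(F %*% e0)
    ef <- ef / sqrt(sum(ef^2))
    out <- out + phi_sf[i] * sig_i[i] * outer(ef, ef) / N
  }
  out
}

## shoelace polygon area (oracle for projected orifice areas)
shoelace <- function(xy) {
  n <- nrow(xy)
  j <- c(2:n, 1)
  abs(sum(xy[, 1] * xy[j, 2] - xy[j, 1] * xy[, 2])) / 2
}

## tiny leaflet meshes shared by solver/remodeling tests (built once)
coarse_d1 <- local({
  build_design1_leaflet(design1_params(), n_profile = 7L, n_span = 7L,
                        n_layers = 1L, order = 1L)
})
coarse_d2 <- local({
  build_design2_leaflet(design2_params(), n_profile = 7L, n_span = 7L,
                        n_layers = 1L, order = 1L)
})

## lazily computed scaled-down remodeling batches shared by the acceptance
## checks (36-element half-leaflets, 4 h remodeling steps, 3 simulated
## days)
.accept_cache <- new.env(parent = emptyenv())

scaled_pulmonary_study <- function() {
  if (is.null(.accept_cache$pulm)) {
    cfg <- study_config(designs = 1L, conditions = "pulmonary",
                        n_profile = 7L, n_span = 7L, n_layers = 1L,
                        order = 1L, remodel_step = 4, max_duration = 3)
    .accept_cache$pulm <- run_study(cfg)
  }
  .accept_cache$pulm
}

scaled_aortic_mm <- function() {
  if (is.null(.accept_cache$aortic_mm)) {
    m <- build_design1_leaflet(design1_params(), n_profile = 7L,
                               n_span = 7L, n_layers = 1L, order = 1L)
    .accept_cache$aortic_mm <- run_remodeling(
      m, prot = protocol("aortic", remodel_step = 4, max_duration = 3))
  }
  .accept_cache$aortic_mm
}

## minimally constrained static solve (3-2-1 rigid-body fixing) of a block
## fixture: returns displacements and per-point deformation gradients, for
## genuinely free shrinkage/retraction comparisons against 0-D balances
free_block_solve <- function(mesh, field, params,
                             funcs = sf_response_functions(params)) {
  pre <- tehvsim:::fe_precompute(mesh)
  stress_fn <- function(Fa) tehvsim:::cauchy_stress_field(
    Fa, field$state, params, funcs, basis = pre$basis, rate = field$rate)
  nd <- mesh$nodes
  n1 <- which.min(rowSums(nd^2))
  n2 <- which.max((abs(nd[, 2]) < 1e-9) * nd[, 1])  ## on the x-axis
  n3 <- which.max((abs(nd[, 1]) < 1e-9) * nd[, 2])  ## on the y-axis
  fx <- c(3L * (n1 - 1L) + 1:3, 3L * (n2 - 1L) + 2:3, 3L * (n3 - 1L) + 3L)
  free <- setdiff(seq_len(pre$ndof), fx)
  res <- tehvsim:::newton_solve(mesh, pre, stress_fn,
                                matrix(0, pre$nn, 3), 0,
                                boundary_conditions(0, contact = FALSE),
                                solver_settings(), free, 0,
                                numeric(pre$nn))
  stopifnot(res$converged)
  Fall <- tehvsim:::compute_F_all(pre, mesh$nodes + res$u)
  list(u = res$u, F = Fall, idx_e = pre$idx_e, mesh = mesh)
}

## 0-D oracle: free in-plane shrink of a uniformly compacted tissue
## (solves sigma_xx = 0 with the thickness stretch solving sigma_zz = 0)
free_shrink_oracle <- function(lam_g, p, funcs = default_funcs) {
  st <- tissue_state(fibers30, p)
  st$lam_g[] <- lam_g
  szz <- function(l, lt) total_stress(diag(c(l, l, lt)), st, p, funcs)[3, 3]
  sxx <- function(l) {
    lt <- uniroot(function(lt) szz(l, lt), c(0.3, 2), tol = 1e-12)$root
    total_stress(diag(c(l, l, lt)), st, p, funcs)[1, 1]
  }
  uniroot(sxx, c(0.7, 1.0), tol = 1e-12)$root
}

## independent even-odd point-in-polygon (Monte-Carlo coverage oracle)
point_in_poly <- function(px, py, poly) {
  n <- nrow(poly)
  j <- c(n, 1:(n - 1))
  inside <- rep(FALSE, length(px))
  for (k in 1:n) {
    xi <- poly[k, 1]; yi <- poly[k, 2]
    xj <- poly[j[k], 1]; yj <- poly[j[k], 2]
    cross <- (yi > py) != (yj > py)
    xint <- (xj - xi) * (py - yi) / (yj - yi) + xi
    inside <- xor(inside, cross & (px < xint))
  }
  inside
}
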