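## Parametric leaflet geometry: curves, meshes, grids, invariants.

test_that("cubic Bezier: endpoint interpolation, degeneracy, de Casteljau agreement", {
  cp <- rbind(c(0, 0), c(1, 2), c(3, -1), c(4, 1))
  expect_equal(bezier_point(cp, 0)[1, ], cp[1, ])
  expect_equal(bezier_point(cp, 1)[1, ], cp[4, ])
  same <- rbind(c(2, 3), c(2, 3), c(2, 3), c(2, 3))
  for (t in c(0, 0.25, 0.8, 1)) {
    expect_equal(bezier_point(same, t)[1, ], c(2, 3))
  }
  expect_equal(bezier_point(cp, 0.5)[1, ], de_casteljau(cp, 0.5),
               tolerance = 1e-14)
  expect_error(bezier_point(cp, 1.2), "\\[0, 1\\]")
})

test_that("Design 1 attachment curve wraps onto the cylinder with the right extents", {
  p <- design1_params()
  att <- design1_attachment_curve(p, 40L)
  ## axial extent equals the valve height
  expect_equal(max(att$xyz[, 3]) - min(att$xyz[, 3]), 14.3, tolerance = 1e-9)
  ## every point on the cylinder of radius R
  r <- sqrt(att$xyz[, 1]^2 + att$xyz[, 2]^2)
  expect_lt(max(abs(r - p$R)), 1e-9 * p$R)
  ## planar arc-length coordinate at t = 1 equals -(2 pi / 6) R
  expect_equal(att$planar[nrow(att$planar), 2], -(2 * pi / 6) * 11.5,
               tolerance = 1e-9)
})

test_that("Design 1 belly curve runs from the annulus point to the tip", {
  p <- design1_params()
  bel <- design1_belly_curve(p, 30L)
  expect_equal(bel$uv[1, ], c(-p$R, 0), tolerance = 1e-9)
  expect_equal(bel$uv[nrow(bel$uv), 1], 0.125, tolerance = 1e-9)
  ## collinear guide point -> straight chord
  ps <- p; ps$D12 <- tehvsim:::design1_chord_d12(p)
  bs <- design1_belly_curve(ps, 20L)
  chord_dir <- bs$uv[20, ] - bs$uv[1, ]
  for (k in 2:19) {
    d <- bs$uv[k, ] - bs$uv[1, ]
    expect_lt(abs(d[1] * chord_dir[2] - d[2] * chord_dir[1]), 1e-8)
  }
})

test_that("baseline Design 1 mesh: invariants, 17-degree free edge, element budget", {
  m <- build_design1_leaflet(design1_params(), order = 1L)
  expect_silent(validate_mesh(m))
  ## attachment nodes lie on the wrapped Bezier cylinder
  P <- m$meta$grid$mid_grid
  em <- m$meta$edge_map
  j_att <- if (identical(em$jmin, "attachment_edge")) 1L else dim(P)[2]
  r <- sqrt(P[, j_att, 1]^2 + P[, j_att, 2]^2)
  expect_lt(max(abs(r - 11.5)), 1e-6)
  expect_equal(free_edge_angle(m), 17, tolerance = 1e-9)
  expect_lt(abs(nrow(m$elems) - 346), 0.3 * 346)
})

test_that("Design 2 mesh: paraboloid sampling, coaptation plane, radius trim", {
  p <- design2_params()
  m <- build_design2_leaflet(p, order = 1L)
  pre <- m$meta$pre_rotation
  resid <- pre[, , 1]^2 / p$D21^2 + pre[, , 2]^2 / p$D22^2 - pre[, , 3]
  expect_lt(max(abs(resid)), 1e-9)
  ## displaced coaptation grid points lie exactly on y = tan(30deg)|x|
  Pm <- m$meta$grid$mid_grid
  clm <- m$meta$clamped
  expect_gt(sum(clm), 0)
  gap <- Pm[, , 2] - tan(pi / 6) * abs(Pm[, , 1])
  expect_lt(max(abs(gap[clm])), 1e-9)
  ## no mid-surface point outside the valve radius
  rr <- sqrt(Pm[, , 1]^2 + Pm[, , 2]^2)
  expect_lt(max(rr), p$R + 1e-6)
  expect_silent(validate_mesh(m))
})

test_that("design grids enumerate nine unique geometries with the printed corner codes", {
  g1 <- enumerate_design_grid(1)
  expect_length(g1, 9L)
  codes <- vapply(g1, `[[`, "", "code")
  expect_length(unique(codes), 9L)
  expect_true(all(c("Ns", "Nc", "Ws", "Wc") %in% codes))
  g2 <- enumerate_design_grid(2)
  d21 <- sort(unique(vapply(g2, function(e) e$params$D21, 0)))
  d22 <- sort(unique(vapply(g2, function(e) e$params$D22, 0)))
  expect_equal(d21, c(2.8, 3.4, 4.0))
  expect_equal(d22, c(1.4, 1.9, 2.4))
  expect_length(unique(vapply(g2, `[[`, "", "code")), 9L)
})

test_that("all nine default Design 2 valves are fully closed at rest", {
  for (ent in enumerate_design_grid(2)) {
    m <- build_design2_leaflet(ent$params, n_profile = 10L, n_span = 10L,
                               n_layers = 1L, order = 1L)
    expect_equal(as.numeric(regurgitant_orifice_area(m)), 0,
                 info = ent$code)
  }
})

test_that("mirrored half-leaflet is C1-continuous across the symmetry plane", {
  p <- design1_params()
  m <- build_design1_leaflet(p, order = 1L)
  ## the analytic surface tangent plane at the symmetry boundary contains
  ## the x-axis (zero normal x-component), so the mirrored surface is C1
  surf <- m$meta$grid$surface_fn
  h <- 1e-5
  for (t0 in c(0.2, 0.5, 0.8, 1)) {
    p1 <- surf(t0, 1)[1, ]
    dt_s <- (p1 - surf(t0, 1 - h)[1, ]) / h            ## d/ds at s = 1
    dt_t <- (surf(min(t0 + h, 1), 1)[1, ] -
               surf(t0 - h, 1)[1, ]) / (min(t0 + h, 1) - (t0 - h))
    nrm <- c(dt_t[2] * dt_s[3] - dt_t[3] * dt_s[2],
             dt_t[3] * dt_s[1] - dt_t[1] * dt_s[3],
             dt_t[1] * dt_s[2] - dt_t[2] * dt_s[1])
    nrm <- nrm / sqrt(sum(nrm^2))
    expect_lt(abs(nrm[1]), 1e-3)
  }
  ## mirror symmetry: reflecting the mesh preserves element validity
  mm <- mirror_mesh(m)
  expect_gt(tehvsim:::min_jacobian(mm), 0)
})

test_that("belly-profile length grows monotonically with belly curvature", {
  ## Design 1: deeper sag below the chord -> longer belly profile
  lens1 <- vapply(c(0, 2.5, 5), function(sag) {
    p <- design1_params()
    p$D12 <- tehvsim:::design1_chord_d12(p) - sag
    m <- build_design1_leaflet(p, n_profile = 10L, n_span = 10L,
                               n_layers = 1L, order = 1L)
    profile_lengths(m)[["belly_profile_length"]]
  }, 0)
  expect_true(all(diff(lens1) > 0))
  ## Design 2: decreasing D22 -> longer belly profile
  lens2 <- vapply(c(2.4, 1.9, 1.4), function(d22) {
    m <- build_design2_leaflet(design2_params(D22 = d22), n_profile = 10L,
                               n_span = 10L, n_layers = 1L, order = 1L)
    profile_lengths(m)[["belly_profile_length"]]
  }, 0)
  expect_true(all(diff(lens2) > 0))
})

test_that("surface refinement changes profile lengths by less than 0.1 percent", {
  p <- design1_params()
  m1 <- build_design1_leaflet(p, n_profile = 12L, n_span = 12L,
                              n_layers = 1L, order = 1L)
  m2 <- build_design1_leaflet(p, n_profile = 24L, n_span = 24L,
                              n_layers = 1L, order = 1L)
  l1 <- profile_lengths(m1); l2 <- profile_lengths(m2)
  expect_lt(abs(l1[["belly_profile_length"]] - l2[["belly_profile_length"]]) /
              l2[["belly_profile_length"]], 1e-3)
  expect_lt(abs(l1[["free_edge_length"]] - l2[["free_edge_length"]]) /
              l2[["free_edge_length"]], 1e-3)
})

test_that("geometry parameter validation catches bad inputs", {
  expect_error(design1_params(D11 = 1.5), "D11")
  expect_error(design1_params(R = -1))
  expect_warning(design2_params(D21 = 5), "outside the design range")
  expect_warning(design2_params(D22 = 1.0), "outside the design range")
})
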