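## Design 1: leaflet from a wrapped cubic-Bezier attachment curve and a
## guided quadratic belly curve, lofted by connector curves with a fillet
## blend into the symmetry plane.
##
## Frame: valve axis +z, annulus plane z = 0, the leaflet sector is
## centered on +y, the half-leaflet occupies x <= 0 with symmetry plane
## x = 0. The attachment Bezier is drawn in (height, arc-length) planar
## coordinates and wrapped around the cylinder of radius R; the belly curve
## lies in the symmetry plane in (radial, height) coordinates running from
## the annulus attachment point (radius R, z = 0) to the leaflet tip, which
## crosses the valve axis by 0.125 mm. The tip sits sin(17 deg) * (pi R / 3)
## below the commissure so that the free edge makes a 17 degree planform
## angle with the commissure point.

#' Design 1 geometry parameters
#'
#' @param R valve radius, mm. @param H valve height, mm.
#' @param D11 attachment-curve shape factor in `[0, 1]` (0 = narrow,
#'   1 = wide commissures).
#' @param D12 belly guiding-point height (y-coordinate of the middle
#'   control point of the belly curve), mm; `NULL` places it a default sag
#'   of 2.5 mm below the straight chord (the medium belly curvature level).
#' @param thickness leaflet thickness, mm.
#' @param tip_extension extra free-edge length added at the leaflet tip, mm.
#' @return object of class `design1_params`.
#' @export
design1_params <- function(R = 11.5, H = 14.3, D11 = 0.5, D12 = NULL,
                           thickness = 0.6, tip_extension = 0) {
  if (R <= 0 || H <= 0) stop("R and H must be positive")
  if (D11 < 0 || D11 > 1) stop("D11 must lie in [0, 1]")
  if (thickness <= 0) stop("thickness must be positive")
  p <- structure(list(R = R, H = H, D11 = D11, D12 = NA_real_,
                      thickness = thickness, tip_extension = tip_extension),
                 class = "design1_params")
  p$D12 <- D12 %||% (design1_chord_d12(p) - 2.5)
  p
}

## tip height: commissure height minus the 17-degree drop over the half
## attachment arc
design1_tip_height <- function(p) p$H - sin(17 * pi / 180) * (pi * p$R / 3)

## D12 value for which the belly control points are collinear (straight
## belly chord)
design1_chord_d12 <- function(p) {
  p6y <- design1_tip_height(p)
  ## chord from P4 = (-R, 0) to P6 = (0.125, p6y), evaluated at u = 0
  p6y * (p$R / (p$R + 0.125))
}

#' Attachment curve of Design 1
#'
#' Cubic Bezier in (height, arc-length) coordinates with
#' `P0 = (0, 0)`, `P3 = (H, -pi R / 3)`, `P1 = (0, D11 * P3_z)`,
#' `P2 = (D11 * H, P3_z)`, wrapped around the cylinder of radius R. The
#' returned 3D curve runs from the annulus point on the symmetry plane
#' (plan angle 90 deg) to the commissure (plan angle 150 deg, height H).
#'
#' @param params `design1_params`. @param n_samples number of points
#'   (arc-length uniform).
#' @return list with `xyz` (n x 3), `planar` (n x 2: height, arc
#'   coordinate), and the Bezier parameters `t`.
#' @export
design1_attachment_curve <- function(params, n_samples = 26L) {
  if (n_samples < 2L) stop("need at least 2 samples")
  S <- -(2 * pi / 6) * params$R
  cp <- rbind(c(0, 0),
              c(0, params$D11 * S),
              c(params$D11 * params$H, S),
              c(params$H, S))
  fn <- function(t) bezier_point(cp, t)
  tt <- arc_uniform_params(fn, n_samples)
  pl <- fn(tt)
  phi <- -pl[, 2] / params$R            ## wrap: arc length -> angle
  theta <- pi / 2 + phi
  xyz <- cbind(params$R * cos(theta), params$R * sin(theta), pl[, 1])
  list(xyz = xyz, planar = pl, t = tt)
}

#' Belly curve of Design 1
#'
#' Quadratic curve in symmetry-plane (radial, height) coordinates guided by
#' `P4 = (-R, 0)`, `P5 = (0, D12)`, `P6 = (0.125, tip height)`; an optional
#' tip extension continues the curve along its end tangent. Returned points
#' are arc-length uniform.
#'
#' @param params `design1_params`. @param n_samples number of points.
#' @return list with `uv` (n x 2 planar coordinates), `xyz` (n x 3, in the
#'   symmetry plane x = 0).
#' @export
design1_belly_curve <- function(params, n_samples = 26L) {
  if (n_samples < 2L) stop("need at least 2 samples")
  p6 <- c(0.125, design1_tip_height(params))
  cp <- rbind(c(-params$R, 0), c(0, params$D12), p6)
  base_fn <- function(t) bezier2_point(cp, t)
  ext <- params$tip_extension
  if (ext > 0) {
    ## end tangent of the quadratic: 2 (P6 - P5)
    tgt <- 2 * (p6 - cp[2, ])
    tgt <- tgt / sqrt(sum(tgt^2))
    base_len <- arc_length_quadratic(base_fn(seq(0, 1, length.out = 200)))
    split <- base_len / (base_len + ext)
    fn <- function(t) {
      out <- matrix(0, length(t), 2)
      a <- t <= split
      if (any(a)) out[a, ] <- base_fn(t[a] / split)
      if (any(!a)) {
        s <- (t[!a] - split) / (1 - split) * ext
        out[!a, ] <- rep(p6, each = sum(!a)) + outer(s, tgt)
      }
      out
    }
  } else {
    fn <- base_fn
  }
  tt <- arc_uniform_params(fn, n_samples)
  uv <- fn(tt)
  list(uv = uv, xyz = cbind(0, -uv[, 1], uv[, 2]), t = tt)
}

#' Build a Design 1 half-leaflet mesh
#'
#' Lofts connector curves from points on the wrapped attachment spline to
#' corresponding points on the belly spline (both arc-length uniform), with
#' a fillet blend (default 2 mm) that turns each connector into the
#' symmetry plane perpendicularly, making the mirrored full leaflet
#' C1-continuous across the plane. The mid-surface is extruded along its
#' normals into hexahedra.
#'
#' @param params `design1_params`.
#' @param n_profile points along each spline (connector count).
#' @param n_span points along each connector.
#' @param n_layers through-thickness element layers.
#' @param order 1 (8-node) or 2 (20-node) bricks.
#' @param fillet fillet blend length at the symmetry plane, mm.
#' @return `leaflet_mesh`.
#' @export
build_design1_leaflet <- function(params, n_profile = 14L, n_span = 14L,
                                  n_layers = 2L, order = 2L, fillet = 2) {
  att <- design1_attachment_curve(params, 400L)
  bel <- design1_belly_curve(params, 400L)
  ## smooth interpolants (arc-uniform parameter t in [0,1])
  s_att <- seq(0, 1, length.out = 400L)
  att_fn <- function(t) cbind(stats::spline(s_att, att$xyz[, 1], xout = t)$y,
                              stats::spline(s_att, att$xyz[, 2], xout = t)$y,
                              stats::spline(s_att, att$xyz[, 3], xout = t)$y)
  bel_fn <- function(t) cbind(0,
                              stats::spline(s_att, bel$xyz[, 2], xout = t)$y,
                              stats::spline(s_att, bel$xyz[, 3], xout = t)$y)

  surf <- function(ti, sj) {
    t0 <- ti[1]
    A <- att_fn(t0)[1, ]
    B <- bel_fn(t0)[1, ]
    chord <- sqrt(sum((B - A)^2))
    if (chord < 1e-12) {
      return(matrix(rep(A, each = length(sj)), length(sj), 3))
    }
    h <- min(fillet, 0.4 * chord)
    ## cubic connector: departs along the chord, arrives perpendicular to
    ## the symmetry plane (+x direction) for mirror C1 continuity
    cp <- rbind(A, A + (B - A) / 3, B - c(h, 0, 0), B)
    bezier_point(cp, sj)
  }

  mesh <- build_solid_mesh(surf, nt = n_profile, ns = n_span,
                           thickness = params$thickness,
                           n_layers = n_layers, order = order,
                           collapse_i1 = TRUE,
                           edge_map = list(jmin = "attachment_edge",
                                           jmax = "symmetry_plane",
                                           imax = "free_edge"),
                           meta = list(design = "design1", params = params))
  ## snap symmetry-plane nodes onto x = 0 (normal offsets are O(h^2))
  sym <- mesh$sets$symmetry_plane
  off <- abs(mesh$nodes[sym, 1])
  if (any(off > 0.2 * params$thickness)) {
    stop(sprintf("symmetry-plane nodes off-plane by %.3g mm: belly guide D12=%.3g produces a degenerate surface",
                 max(off), params$D12))
  }
  mesh$nodes[sym, 1] <- 0

  comm <- att_fn(1)[1, ]
  tipp <- bel_fn(1)[1, ]
  mesh <- label_regions(mesh, comm, tipp, bel$xyz)
  mesh$meta$attachment <- att
  mesh$meta$belly <- bel
  ok <- try(validate_mesh(mesh), silent = TRUE)
  if (inherits(ok, "try-error")) {
    stop(sprintf("Design 1 geometry failed (D11=%.3g, D12=%.3g): %s",
                 params$D11, params$D12, attr(ok, "condition")$message))
  }
  with_fe_cache(mesh)
}

#' Planform free-edge angle of a generated leaflet
#'
#' The angle whose sine is the drop of the leaflet tip below the commissure
#' divided by the half attachment arc length `pi R / 3`, read back from the
#' mesh (commissure = highest attachment node, tip = free-edge node on the
#' symmetry plane, R = largest attachment plan radius). Degrees.
#'
#' @param mesh `leaflet_mesh`.
#' @return angle in degrees.
#' @export
free_edge_angle <- function(mesh) {
  P <- mesh$meta$grid$mid_grid
  em <- mesh$meta$edge_map
  nt_f <- dim(P)[1]; ns_f <- dim(P)[2]
  j_of <- function(set) {
    nm <- names(em)[vapply(em, identical, logical(1), set)]
    if (!length(nm)) stop("set not on a grid boundary: ", set)
    switch(nm, jmin = 1L, jmax = ns_f,
           stop("set not on a j boundary: ", set))
  }
  j_att <- j_of("attachment_edge")
  j_sym <- j_of("symmetry_plane")
  ## free edge is the last i-row; commissure and tip are its end corners
  comm <- P[nt_f, j_att, ]
  tip <- P[nt_f, j_sym, ]
  R <- max(sqrt(P[, j_att, 1]^2 + P[, j_att, 2]^2))
  asin((comm[3] - tip[3]) / (pi * R / 3)) * 180 / pi
}
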