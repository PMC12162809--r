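## Design 2: leaflet sampled from an elliptic paraboloid
## x^2 / D21^2 + y^2 / D22^2 - z = 0, rotated by atan(R / (2 H)) about the
## x-axis. Points that cross into a neighboring leaflet's domain are
## displaced onto the inter-leaflet plane y = tan(30 deg) |x| (the initial
## coaptation area); the surface is trimmed at the valve radius so the
## outer boundary is the attachment edge.

#' Design 2 geometry parameters
#'
#' @param R valve radius, mm. @param H valve height, mm (enters through the
#'   rotation angle `atan(R / (2 H))`; raising H to 16.31 mm is the
#'   increased-coaptation variant).
#' @param D21 circumferential curvature parameter, mm (design range
#'   2.8--4.0; larger = flatter/wider attachment).
#' @param D22 radial curvature parameter, mm (design range 1.4--2.4;
#'   smaller = more curved, longer belly profile).
#' @param thickness leaflet thickness, mm.
#' @return object of class `design2_params`.
#' @export
design2_params <- function(R = 11.5, H = 14.3, D21 = 3.4, D22 = 1.9,
                           thickness = 0.6) {
  if (R <= 0 || H <= 0 || thickness <= 0) stop("R, H, thickness must be positive")
  if (D21 < 2.8 || D21 > 4.0) {
    warning(sprintf("D21 = %.3g outside the design range [2.8, 4.0]", D21))
  }
  if (D22 < 1.4 || D22 > 2.4) {
    warning(sprintf("D22 = %.3g outside the design range [1.4, 2.4]", D22))
  }
  structure(list(R = R, H = H, D21 = D21, D22 = D22, thickness = thickness),
            class = "design2_params")
}

## map pre-rotation polar coordinates (psi, rho) to the final surface;
## returns xyz after rotation and coaptation clamp, plus the pre-rotation
## point and the clamp flag
design2_map <- function(psi, rho, params, crease_radius = 2) {
  alpha <- atan(params$R / (2 * params$H))
  x0 <- rho * cos(psi)
  y0 <- rho * sin(psi)
  z0 <- x0^2 / params$D21^2 + y0^2 / params$D22^2
  y <- y0 * cos(alpha) + z0 * sin(alpha)
  z <- z0 * cos(alpha) - y0 * sin(alpha)
  tanb <- tan(pi / 6)
  ## one-sided C1-rounded clamp onto the inter-leaflet plane: every point
  ## with gap g <= 0 lands exactly on the plane (the coaptation area);
  ## the fold is rounded on the belly side only, over a band of width r
  g <- y - tanb * abs(x0)
  r <- crease_radius
  gp <- ifelse(g >= r, g, ifelse(g <= 0, 0, g^2 * (2 * r - g) / r^2))
  y <- tanb * abs(x0) + gp
  clamp <- g <= 0
  list(xyz = cbind(x0, y, z), pre = cbind(x0, y0, z0), clamped = clamp,
       gap_raw = g)
}

## radial extent of a pre-rotation ray: rho at which the (clamped) plan
## radius reaches the valve radius R
design2_rho_att <- function(psi, params) {
  f <- function(rho) {
    m <- design2_map(psi, rho, params)
    sqrt(m$xyz[1, 1]^2 + m$xyz[1, 2]^2) - params$R
  }
  hi <- 2 * params$R
  while (f(hi) < 0) hi <- hi * 1.5
  stats::uniroot(f, c(1e-9, hi), tol = 1e-12)$root
}

#' Build a Design 2 half-leaflet mesh
#'
#' Samples the rotated elliptic paraboloid over pre-rotation polar
#' coordinates: the symmetry ray (x = 0) to the coaptation ray, each ray
#' trimmed at the valve radius. Points outside the leaflet's 120 degree
#' sector are displaced onto the plane `y = tan(30 deg) |x|`, producing the
#' initial coaptation strip whose boundary is the free edge; the collapsed
#' ray origin is the leaflet tip on the valve axis.
#'
#' @param params `design2_params`.
#' @param n_profile points along each pre-rotation ray (radial direction).
#' @param n_span number of rays (circumferential direction).
#' @param n_layers through-thickness element layers.
#' @param order 1 (8-node) or 2 (20-node) bricks.
#' @return `leaflet_mesh`.
#' @export
build_design2_leaflet <- function(params, n_profile = 14L, n_span = 14L,
                                  n_layers = 2L, order = 2L) {
  ## tabulate ray extents once on a fine psi grid
  psis <- seq(pi / 2, pi, length.out = 200L)
  rho_tab <- vapply(psis, design2_rho_att, numeric(1), params = params)
  rho_fn <- stats::splinefun(psis, rho_tab)

  ## map s (column parameter) to psi by arc length along each i-row so the
  ## coaptation strip (where clamped points bunch) keeps well-sized cells
  psi_of_s <- function(t0, s) {
    pd <- seq(pi / 2, pi, length.out = 200L)
    pts <- design2_map(pd, t0 * rho_fn(pd), params)$xyz
    seg <- sqrt(rowSums(diff(pts)^2))
    cl <- c(0, cumsum(seg))
    if (cl[200] < 1e-12) return(pd[1] + s * (pi / 2))
    stats::approx(cl / cl[200], pd, xout = s, ties = "ordered")$y
  }
  surf <- function(ti, sj) {
    t0 <- ti[1]
    psi <- psi_of_s(t0, sj)
    rho <- t0 * rho_fn(psi)
    design2_map(psi, rho, params)$xyz
  }
  ## precompute the (fine) grid and smooth the apex neighborhood: the
  ## belly-to-coaptation fold sharpens toward the apex below the leaflet
  ## half-thickness; a bend-radius floor is imposed by local Laplacian
  ## smoothing of the rows within ~2.5 mm of the apex
  nt_f <- if (order == 2L) 2L * n_profile - 1L else n_profile
  ns_f <- if (order == 2L) 2L * n_span - 1L else n_span
  ## graded radial distribution: the first ring is widened (exponent < 1)
  ## so the collapsed fan wedges at the apex stay larger than the
  ## half-thickness offsets
  tg <- seq(0, 1, length.out = nt_f)^0.55
  sj_f <- seq(0, 1, length.out = ns_f)
  Pf <- array(0, c(nt_f, ns_f, 3))
  for (i in seq_len(nt_f)) Pf[i, , ] <- surf(rep(tg[i], ns_f), sj_f)
  Pf[, 1, 1] <- 0      ## symmetry column exactly on the plane x = 0
  ## axial placement: the rotated paraboloid is a funnel whose coaptation
  ## seams descend from the commissures toward the valve axis; diastolic
  ## pressure on its concave (arterial) face loads the walls in membrane
  ## tension. Shift so the annulus plane z = 0 sits at the lowest
  ## attachment point, the leaflet pocket hanging below it.
  Pf[, , 3] <- Pf[, , 3] - min(Pf[nt_f, , 3])
  mesh <- build_solid_mesh(Pf, nt = n_profile, ns = n_span,
                           thickness = params$thickness,
                           n_layers = n_layers, order = order,
                           collapse_i1 = TRUE,
                           edge_map = list(jmin = "symmetry_plane",
                                           jmax = "free_edge",
                                           imax = "attachment_edge"),
                           meta = list(design = "design2", params = params))
  ## record the pre-rotation samples and clamp mask of the mid-surface grid
  nt_f <- dim(mesh$meta$grid$mid_grid)[1]
  ns_f <- dim(mesh$meta$grid$mid_grid)[2]
  em <- mesh$meta$edge_map
  sj <- seq(0, 1, length.out = ns_f)
  if (identical(em$jmax, "symmetry_plane")) sj <- rev(sj)  ## grid was flipped
  pre <- array(0, c(nt_f, ns_f, 3))
  for (i in seq_len(nt_f)) {
    psi <- psi_of_s(tg[i], sj)
    m <- design2_map(psi, tg[i] * rho_fn(psi), params)
    pre[i, , ] <- m$pre
  }
  mesh$meta$pre_rotation <- pre
  mesh <- prune_degenerate_elements(mesh)
  ## coaptation nodes: mid-surface grid points lying on the inter-leaflet
  ## plane (apex smoothing may lift a few former band nodes off it)
  Pm <- mesh$meta$grid$mid_grid
  gap <- Pm[, , 2] - tan(pi / 6) * abs(Pm[, , 1])
  mesh$meta$clamped <- abs(gap) < 1e-9

  sym <- mesh$sets$symmetry_plane
  mesh$nodes[sym, 1] <- 0
  comm <- surf(1, 1)[1, ]
  tip <- c(0, 0, 0)
  j_sym <- if (identical(em$jmin, "symmetry_plane")) 1L else ns_f
  belly_curve <- mesh$meta$grid$mid_grid[, j_sym, ]
  mesh <- label_regions(mesh, comm, tip, belly_curve)
  validate_mesh(mesh)
  with_fe_cache(mesh)
}
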