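## Output parameters: regurgitant orifice area, profile lengths,
## directional compaction, regional stress/strain summaries, fiber order
## parameter, and the design cost function.

## deformed mid-surface grid positions: average of the two outer sheets
mid_surface_points <- function(mesh, x = NULL) {
  x <- x %||% mesh$nodes
  id <- mesh$meta$grid$id_grid
  nsheet <- mesh$meta$grid$nsheet
  nt_f <- dim(id)[1]; ns_f <- dim(id)[2]
  P <- array(NA_real_, c(nt_f, ns_f, 3))
  bot <- id[, , 1]; top <- id[, , nsheet]
  okm <- !is.na(bot) & !is.na(top)
  idxs <- which(okm)
  for (d in 1:3) {
    v <- matrix(NA_real_, nt_f, ns_f)
    v[idxs] <- (x[bot[idxs], d] + x[top[idxs], d]) / 2
    P[, , d] <- v
  }
  P
}

## ordered mid-surface path along a named boundary set
boundary_path <- function(mesh, set, x = NULL) {
  P <- mid_surface_points(mesh, x)
  em <- mesh$meta$edge_map
  nt_f <- dim(P)[1]; ns_f <- dim(P)[2]
  nm <- names(em)[vapply(em, identical, logical(1), set)]
  if (!length(nm)) stop("set is not a grid boundary: ", set)
  pts <- switch(nm,
                imin = P[1, , ], imax = P[nt_f, , ],
                jmin = P[, 1, ], jmax = P[, ns_f, ])
  pts[stats::complete.cases(pts), , drop = FALSE]
}

#' Belly-profile and free-edge lengths of a configuration
#'
#' Belly profile = arc length of the mid-surface intersection with the
#' symmetry plane (attachment to free edge); free edge = arc length of the
#' free-edge curve. Piecewise-quadratic integration.
#'
#' @param sol `fe_solution`, or a `leaflet_mesh` for the reference
#'   configuration.
#' @return named vector (mm): `belly_profile_length`, `free_edge_length`.
#' @export
profile_lengths <- function(sol) {
  mesh <- if (inherits(sol, "fe_solution")) sol$mesh else sol
  x <- if (inherits(sol, "fe_solution")) sol$x else NULL
  belly <- boundary_path(mesh, "symmetry_plane", x)
  fe <- boundary_path(mesh, "free_edge", x)
  c(belly_profile_length = arc_length_quadratic(belly),
    free_edge_length = arc_length_quadratic(fe))
}

## closed plan-projection polygon of the full leaflet (half + mirror)
leaflet_plan_polygon <- function(mesh, x = NULL) {
  att <- boundary_path(mesh, "attachment_edge", x)
  fe <- boundary_path(mesh, "free_edge", x)
  ## orient: attachment from its symmetry-side end to the commissure,
  ## free edge from the commissure to the symmetry plane
  if (sum(att[1, 1]^2) > sum(att[nrow(att), 1]^2)) att <- att[nrow(att):1, ]
  d1 <- sum((fe[1, ] - att[nrow(att), ])^2)
  d2 <- sum((fe[nrow(fe), ] - att[nrow(att), ])^2)
  if (d2 < d1) fe <- fe[nrow(fe):1, ]
  half <- rbind(att, fe)
  mir <- half[nrow(half):1, ]
  mir[, 1] <- -mir[, 1]
  poly <- rbind(half, mir)
  poly[, 1:2, drop = FALSE]
}

## radii at which a plan ray (angle theta) crosses a closed polygon;
## returns sorted positive crossing radii
ray_polygon_crossings <- function(theta, poly) {
  d <- c(cos(theta), sin(theta))
  p <- poly
  q <- rbind(poly[-1, , drop = FALSE], poly[1, , drop = FALSE])
  ex <- q[, 1] - p[, 1]; ey <- q[, 2] - p[, 2]
  den <- d[1] * (-ey) - d[2] * (-ex)
  ok <- abs(den) > 1e-14
  s <- (p[, 1] * (-ey) + p[, 2] * ex)
  s[!ok] <- NA
  s <- s / den
  t <- (d[1] * p[, 2] - d[2] * p[, 1]) / den
  hit <- ok & s > 0 & t >= 0 & t < 1
  sort(s[hit])
}

#' Regurgitant orifice area of a (deformed) valve
#'
#' The half-leaflet is mirrored into a full leaflet and replicated to three
#' leaflets by 120 degree rotations; their plan outlines (projection along
#' the valve axis) are ray-cast from the valve axis, and the central
#' orifice area not covered by any leaflet is integrated as
#' `1/2 * r_gap(theta)^2 dtheta`. A fully coapted valve returns 0.
#'
#' @param sol `fe_solution` (diastolic configuration) or `leaflet_mesh`
#'   (as-built configuration).
#' @param n_rays angular resolution of the orifice integral.
#' @param snap radii below `snap` (mm) are treated as closed.
#' @return orifice area, mm^2; attribute `"r_gap"` carries the per-ray
#'   profile.
#' @export
regurgitant_orifice_area <- function(sol, n_rays = 1440L, snap = 1e-4) {
  mesh <- if (inherits(sol, "fe_solution")) sol$mesh else sol
  x <- if (inherits(sol, "fe_solution")) sol$x else NULL
  poly0 <- leaflet_plan_polygon(mesh, x)
  thetas <- seq(0, 2 * pi, length.out = n_rays + 1L)[-(n_rays + 1L)] +
    2.391e-7   ## avoid rays through polygon vertices / coaptation lines
  rot <- c(0, 2 * pi / 3, -2 * pi / 3)
  polys <- lapply(rot, function(a) {
    R <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
    poly0 %*% t(R)
  })
  r_gap <- vapply(thetas, function(th) {
    best <- Inf
    for (pl in polys) {
      s <- ray_polygon_crossings(th, pl)
      if (!length(s)) next
      entry <- if (length(s) %% 2L == 1L) 0 else s[1]  ## odd = axis covered
      best <- min(best, entry)
    }
    if (!is.finite(best)) best <- 0  ## degenerate projection
    best
  }, numeric(1))
  r_gap[r_gap < snap] <- 0
  area <- sum(0.5 * r_gap^2) * (2 * pi / n_rays)
  structure(area, r_gap = r_gap)
}

#' Mean directional logarithmic strain in the belly region
#'
#' Projects the per-element deformation gradient of (usually) the unloaded,
#' remodeled configuration onto the reference circumferential (`v1`) and
#' radial (`v2`) element frames and averages the logarithmic strains over
#' the belly elements. Negative values indicate compaction.
#'
#' @param sol `fe_solution`.
#' @param region region label to average over (default `"belly"`).
#' @return named vector (percent): `circumferential`, `radial`.
#' @export
directional_compaction <- function(sol, region = "belly") {
  mesh <- sol$mesh
  els <- which(mesh$regions == region)
  if (!length(els)) stop("no elements labelled ", region)
  idx <- sol$idx_e %in% els
  Fm <- sol$F[idx, , , drop = FALSE]
  eidx <- sol$idx_e[idx]
  v1 <- mesh$frames$v1[eidx, , drop = FALSE]
  v2 <- mesh$frames$v2[eidx, , drop = FALSE]
  stretch_along <- function(v) {
    f1 <- Fm[, 1, 1] * v[, 1] + Fm[, 1, 2] * v[, 2] + Fm[, 1, 3] * v[, 3]
    f2 <- Fm[, 2, 1] * v[, 1] + Fm[, 2, 2] * v[, 2] + Fm[, 2, 3] * v[, 3]
    f3 <- Fm[, 3, 1] * v[, 1] + Fm[, 3, 2] * v[, 2] + Fm[, 3, 3] * v[, 3]
    sqrt(f1^2 + f2^2 + f3^2)
  }
  c(circumferential = 100 * mean(log(stretch_along(v1))),
    radial = 100 * mean(log(stretch_along(v2))))
}

#' Regional peak von Mises stress and peak principal logarithmic strain
#'
#' Maxima over the integration points of each region (and globally): the
#' von Mises equivalent of the Cauchy stress, and the largest principal
#' logarithmic strain (half the log of the largest eigenvalue of the left
#' Cauchy--Green tensor).
#'
#' @param sol `fe_solution`.
#' @return data frame with columns `region`, `peak_von_mises` (kPa),
#'   `peak_log_strain`.
#' @export
field_summaries <- function(sol) {
  mesh <- sol$mesh
  vm <- von_mises(sol$sigma)
  npt <- dim(sol$F)[1]
  lstr <- numeric(npt)
  for (k in seq_len(npt)) {
    B <- sol$F[k, , ] %*% t(sol$F[k, , ])
    lstr[k] <- 0.5 * log(max(eigen(B, symmetric = TRUE,
                                   only.values = TRUE)$values))
  }
  regs <- mesh$regions[sol$idx_e]
  out <- data.frame(region = c("global", levels(regs)),
                    peak_von_mises = NA_real_, peak_log_strain = NA_real_)
  out$peak_von_mises[1] <- max(vm)
  out$peak_log_strain[1] <- max(lstr)
  for (r in levels(regs)) {
    i <- which(regs == r)
    j <- which(out$region == r)
    if (length(i)) {
      out$peak_von_mises[j] <- max(vm[i])
      out$peak_log_strain[j] <- max(lstr[i])
    }
  }
  out
}

#' Fiber order parameter
#'
#' `S = sum(phi_i cos(2 gamma_i)) / sum(phi_i)` over the direction set:
#' +1 for perfect circumferential alignment, 0 for isotropy, -1 for
#' perfect radial alignment.
#'
#' @param phi nonnegative per-direction fractions (vector of length N, or
#'   an npt x N matrix which is summed over points first).
#' @param fibers `fiber_directions` (or a numeric vector of angles).
#' @return scalar S in `[-1, 1]`.
#' @export
order_parameter <- function(phi, fibers = fiber_directions(length(phi))) {
  gamma <- if (is.numeric(fibers)) fibers else fibers$gamma
  if (is.matrix(phi)) phi <- colSums(phi)
  if (any(phi < 0)) stop("fractions must be nonnegative")
  tot <- sum(phi)
  if (tot <= 0) stop("order parameter undefined for zero total fraction")
  sum(phi * cos(2 * gamma)) / tot
}

#' Cost-function specification
#'
#' @param targets named numeric targets `T_P` (defaults: stress 0, ROA 0).
#' @param weights named weights, default 1 each.
#' @return object of class `cost_spec`.
#' @export
cost_spec <- function(targets = c(peak_stress = 0, roa = 0),
                      weights = NULL) {
  if (is.null(weights)) weights <- stats::setNames(rep(1, length(targets)),
                                                   names(targets))
  if (all(weights == 0)) stop("at least one weight must be positive")
  if (any(weights < 0)) stop("weights must be nonnegative")
  structure(list(targets = targets, weights = weights), class = "cost_spec")
}

#' Evaluate the design cost function over a batch of designs
#'
#' Per parameter P: `C_P = ((T_P - P) / N_P)^2` with the normalizer `N_P`
#' the batch range (max - min) of that parameter; total cost
#' `C_tot = sqrt(sum(w_p C_p) / sum(w_p))`. Parameters with zero batch
#' range are dropped with a warning.
#'
#' @param batch data frame with one row per design and a column per
#'   cost parameter (names matching `spec$targets`).
#' @param spec `cost_spec`.
#' @return `batch` with appended component columns `C_<param>` and `C_tot`.
#' @export
cost_evaluate <- function(batch, spec = cost_spec()) {
  if (nrow(batch) < 2L) stop("need at least 2 designs to form ranges")
  comps <- list(); wts <- c()
  for (p in names(spec$targets)) {
    if (!p %in% names(batch)) stop("batch lacks cost parameter: ", p)
    v <- batch[[p]]
    rng <- max(v) - min(v)
    if (rng <= 0) {
      warning("zero range for parameter '", p, "'; dropped from the cost")
      next
    }
    comps[[p]] <- ((spec$targets[[p]] - v) / rng)^2
    wts[p] <- spec$weights[[p]]
  }
  if (!length(comps)) stop("no usable cost parameters")
  for (p in names(comps)) batch[[paste0("C_", p)]] <- comps[[p]]
  num <- Reduce(`+`, Map(`*`, comps, wts))
  batch$C_tot <- sqrt(num / sum(wts))
  batch
}
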