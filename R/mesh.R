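## Leaflet mesh container and structured-grid hexahedral mesh generation.
##
## Half-leaflet mid-surfaces are generated as structured (i, j) grids whose
## first i-row may be collapsed to a single point (a fan of degenerate
## bricks around the leaflet tip / bottom point). The mid-surface is
## extruded along its normals into 8-node (linear) or 20-node (quadratic)
## hexahedra with a configurable number of through-thickness layers.
## Coordinates: valve axis +z toward outflow, annulus plane z = 0, the
## leaflet occupies one 120 degree sector centered on +y, symmetry plane
## x = 0 (the half-leaflet lies in x <= 0), inter-leaflet contact planes
## y = tan(30 deg) |x|.

#' Leaflet mesh object
#'
#' @param nodes numeric matrix (n_nodes x 3), mm.
#' @param elems integer matrix (n_elems x 8 or x 20) of node indices.
#' @param order element interpolation order (1 = 8-node, 2 = 20-node brick).
#' @param sets named list of node index vectors: `attachment_edge`,
#'   `symmetry_plane`, `free_edge`, `arterial_surface`,
#'   `ventricular_surface`.
#' @param pressure_faces list of faces on the arterial surface for follower
#'   pressure: each a list(elem, nodes) with outward-ordered node indices.
#' @param regions factor of length n_elems with levels
#'   belly/commissure/tip/other.
#' @param frames list with `v1`, `v2` (n_elems x 3): per-element reference
#'   circumferential and radial unit vectors, tangent to the mid-surface.
#' @param meta list of provenance (design, params, grid dims, surface
#'   function, ...).
#' @return object of class `leaflet_mesh`.
#' @export
leaflet_mesh <- function(nodes, elems, order, sets, pressure_faces,
                         regions, frames, meta = list()) {
  structure(list(nodes = nodes, elems = elems, order = as.integer(order),
                 sets = sets, pressure_faces = pressure_faces,
                 regions = regions, frames = frames, meta = meta),
            class = "leaflet_mesh")
}

#' @export
print.leaflet_mesh <- function(x, ...) {
  cat(sprintf("<leaflet_mesh> %d nodes, %d elements (order %d)\n",
              nrow(x$nodes), nrow(x$elems), x$order))
  cat(sprintf("  design: %s  regions: %s\n",
              x$meta$design %||% "?",
              paste(sprintf("%s=%d", levels(x$regions),
                            tabulate(x$regions, nbins = nlevels(x$regions))),
                    collapse = " ")))
  invisible(x)
}

## ---- structured grid -> solid mesh --------------------------------------

## surf: function(ti, sj) -> 3D point matrix for vectors ti, sj in [0,1]
## (evaluated on the tensor grid). collapse_i1: first i-row is a single
## point. edge_map: names of boundaries -> set names, e.g.
## list(jmin = "attachment_edge", jmax = "symmetry_plane",
##      imax = "free_edge").
grid_midsurface <- function(surf, nt, ns) {
  if (is.array(surf)) {
    stopifnot(dim(surf)[1] == nt, dim(surf)[2] == ns)
    return(surf)
  }
  ti <- seq(0, 1, length.out = nt)
  sj <- seq(0, 1, length.out = ns)
  P <- array(0, c(nt, ns, 3))
  for (i in seq_len(nt)) {
    P[i, , ] <- surf(rep(ti[i], ns), sj)
  }
  P
}

## finite-difference tangents along i and j on a grid
grid_tangents <- function(P) {
  nt <- dim(P)[1]; ns <- dim(P)[2]
  dPi <- array(0, dim(P)); dPj <- array(0, dim(P))
  if (nt > 2L) dPi[2:(nt - 1), , ] <- (P[3:nt, , , drop = FALSE] -
                                         P[1:(nt - 2), , , drop = FALSE]) / 2
  dPi[1, , ] <- P[2, , ] - P[1, , ]
  dPi[nt, , ] <- P[nt, , ] - P[nt - 1, , ]
  if (ns > 2L) dPj[, 2:(ns - 1), ] <- (P[, 3:ns, , drop = FALSE] -
                                         P[, 1:(ns - 2), , drop = FALSE]) / 2
  dPj[, 1, ] <- P[, 2, ] - P[, 1, ]
  dPj[, ns, ] <- P[, ns, ] - P[, ns - 1, ]
  list(di = dPi, dj = dPj)
}

grid_normals <- function(P) {
  tg <- grid_tangents(P)
  n <- array(0, dim(P))
  n[, , 1] <- tg$di[, , 2] * tg$dj[, , 3] - tg$di[, , 3] * tg$dj[, , 2]
  n[, , 2] <- tg$di[, , 3] * tg$dj[, , 1] - tg$di[, , 1] * tg$dj[, , 3]
  n[, , 3] <- tg$di[, , 1] * tg$dj[, , 2] - tg$di[, , 2] * tg$dj[, , 1]
  len <- sqrt(n[, , 1]^2 + n[, , 2]^2 + n[, , 3]^2)
  bad <- len < 1e-12
  len[bad] <- 1
  for (d in 1:3) n[, , d] <- n[, , d] / len
  ## collapsed / degenerate rows inherit the nearest valid normal; a fully
  ## collapsed first row (fan center) gets one consistent averaged normal
  if (any(bad)) {
    nt <- dim(P)[1]
    if (all(bad[1, ])) {
      avg <- colMeans(matrix(n[2, , ], ncol = 3))
      avg <- avg / sqrt(sum(avg^2))
      for (d in 1:3) n[1, , d] <- avg[d]
      bad[1, ] <- FALSE
    }
    idx <- which(bad, arr.ind = TRUE)
    for (r in seq_len(nrow(idx))) {
      i <- idx[r, 1]; j <- idx[r, 2]
      i2 <- if (i < nt) i + 1L else i - 1L
      n[i, j, ] <- n[i2, j, ]
    }
  }
  n
}

## Smoothing of a unit direction field over a surface grid by
## Gaussian-weighted averaging in physical distance (renormalized), so the
## smoothing length is independent of grid resolution.
smooth_directors <- function(n, P, sigma = 1.5) {
  if (sigma <= 0) return(n)
  nt <- dim(n)[1]; ns <- dim(n)[2]
  pts <- cbind(as.vector(P[, , 1]), as.vector(P[, , 2]),
               as.vector(P[, , 3]))
  nv <- cbind(as.vector(n[, , 1]), as.vector(n[, , 2]),
              as.vector(n[, , 3]))
  d2 <- outer(rowSums(pts^2), rowSums(pts^2), "+") - 2 * tcrossprod(pts)
  w <- exp(-pmax(d2, 0) / (2 * sigma^2))
  sm <- w %*% nv
  len <- sqrt(rowSums(sm^2))
  len[len < 1e-12] <- 1
  sm <- sm / len
  array(sm, c(nt, ns, 3))
}

## Build a solid hexahedral mesh from a parametric mid-surface.
## order 1: grid (nt x ns), nl layers of hex8.
## order 2: serendipity 20-node bricks on a doubled grid.
build_solid_mesh <- function(surf, nt, ns, thickness, n_layers = 2L,
                             order = 2L, collapse_i1 = TRUE,
                             edge_map = list(jmin = "attachment_edge",
                                             jmax = "symmetry_plane",
                                             imax = "free_edge"),
                             meta = list(), smooth_dirs = 1.5) {
  order <- as.integer(order)
  if (order == 2L) {
    nt_f <- 2L * nt - 1L; ns_f <- 2L * ns - 1L; nl_f <- 2L * n_layers
  } else {
    nt_f <- nt; ns_f <- ns; nl_f <- n_layers
  }
  P <- grid_midsurface(surf, nt_f, ns_f)
  ## orient the grid so normals point toward +z (arterial side on top)
  nrm <- grid_normals(P)
  if (mean(nrm[, , 3]) < 0) {
    P <- P[, ns_f:1, , drop = FALSE]
    nrm <- grid_normals(P)
    edge_map <- stats::setNames(edge_map,
      vapply(names(edge_map), function(nm) {
        switch(nm, jmin = "jmax", jmax = "jmin", nm)
      }, character(1)))
  }
  ## extrusion directors: the normal field smoothed over a physical length
  ## scale, so offsets vary slowly and cannot fold across surface creases
  ## (the averaged-director treatment of folded shells)
  nrm <- smooth_directors(nrm, P, sigma = smooth_dirs)
  ## directors on the symmetry boundary must lie in the plane x = 0 so the
  ## extruded boundary nodes stay exactly on it (mirror compatibility)
  sym_b <- names(edge_map)[vapply(edge_map, identical, logical(1),
                                  "symmetry_plane")]
  if (length(sym_b)) {
    idx <- switch(sym_b, imin = cbind(1L, seq_len(ns_f)),
                  imax = cbind(nt_f, seq_len(ns_f)),
                  jmin = cbind(seq_len(nt_f), 1L),
                  jmax = cbind(seq_len(nt_f), ns_f))
    for (r in seq_len(nrow(idx))) {
      v <- nrm[idx[r, 1], idx[r, 2], ]
      v[1] <- 0
      nv <- sqrt(sum(v^2))
      if (nv > 1e-12) nrm[idx[r, 1], idx[r, 2], ] <- v / nv
    }
  }

  nsheet <- nl_f + 1L
  zeta <- seq(-0.5, 0.5, length.out = nsheet)
  ## node ids on the fine grid; collapsed first row maps to a single node
  ## per sheet; for order 2 only corner/edge nodes exist
  used <- array(TRUE, c(nt_f, ns_f, nsheet))
  if (order == 2L) {
    for (i in seq_len(nt_f)) for (j in seq_len(ns_f)) for (k in seq_len(nsheet)) {
      n_even <- (i %% 2L == 0L) + (j %% 2L == 0L) + (k %% 2L == 0L)
      if (n_even > 1L) used[i, j, k] <- FALSE
    }
  }
  id <- array(NA_integer_, c(nt_f, ns_f, nsheet))
  coords <- matrix(0, 0, 3)
  nid <- 0L
  node_list <- vector("list", nt_f * nsheet)
  ptr <- 0L
  for (k in seq_len(nsheet)) {
    for (i in seq_len(nt_f)) {
      if (collapse_i1 && i == 1L) {
        ## single node for the whole collapsed row
        if (!any(used[1L, , k])) next
        nid <- nid + 1L
        id[1L, used[1L, , k], k] <- nid
        pos <- P[1L, 1L, ] + zeta[k] * thickness * nrm[1L, 1L, ]
        ptr <- ptr + 1L; node_list[[ptr]] <- pos
        next
      }
      for (j in seq_len(ns_f)) {
        if (!used[i, j, k]) next
        nid <- nid + 1L
        id[i, j, k] <- nid
        pos <- P[i, j, ] + zeta[k] * thickness * nrm[i, j, ]
        ptr <- ptr + 1L; node_list[[ptr]] <- pos
      }
    }
  }
  coords <- do.call(rbind, node_list[seq_len(ptr)])

  ## subparametric quadratic bricks: midside nodes at edge midpoints, so
  ## element validity matches the straight-edged linear mesh (curved
  ## boundaries are approximated piecewise-linearly per edge)
  if (order == 2L) {
    for (k in seq_len(nsheet)) for (i in seq_len(nt_f)) for (j in seq_len(ns_f)) {
      nd <- id[i, j, k]
      if (is.na(nd)) next
      ie <- i %% 2L == 0L; je <- j %% 2L == 0L; ke <- k %% 2L == 0L
      if (ie + je + ke != 1L) next
      if (ie) {
        a <- id[i - 1L, j, k]; b <- id[i + 1L, j, k]
      } else if (je) {
        a <- id[i, j - 1L, k]; b <- id[i, j + 1L, k]
      } else {
        a <- id[i, j, k - 1L]; b <- id[i, j, k + 1L]
      }
      coords[nd, ] <- (coords[a, ] + coords[b, ]) / 2
    }
  }

  ## connectivity
  nel_i <- nt - 1L; nel_j <- ns - 1L; nel_k <- n_layers
  conn <- list(); press <- list(); ecount <- 0L
  cell_ij <- matrix(0L, nel_i * nel_j * nel_k, 2)
  for (kk in seq_len(nel_k)) for (ii in seq_len(nel_i)) for (jj in seq_len(nel_j)) {
    if (order == 1L) {
      i0 <- ii; j0 <- jj; k0 <- kk
      n1 <- id[i0, j0, k0];     n2 <- id[i0 + 1L, j0, k0]
      n3 <- id[i0 + 1L, j0 + 1L, k0]; n4 <- id[i0, j0 + 1L, k0]
      n5 <- id[i0, j0, k0 + 1L]; n6 <- id[i0 + 1L, j0, k0 + 1L]
      n7 <- id[i0 + 1L, j0 + 1L, k0 + 1L]; n8 <- id[i0, j0 + 1L, k0 + 1L]
      nodes <- c(n1, n2, n3, n4, n5, n6, n7, n8)
      if (length(unique(nodes)) < 5L) next  ## fully degenerate sliver
      ecount <- ecount + 1L
      conn[[ecount]] <- nodes
      cell_ij[ecount, ] <- c(ii, jj)
      if (kk == nel_k) press[[length(press) + 1L]] <-
          list(elem = ecount, nodes = c(n5, n6, n7, n8))
    } else {
      i0 <- 2L * ii - 1L; j0 <- 2L * jj - 1L; k0 <- 2L * kk - 1L
      cn <- function(di, dj, dk) id[i0 + di, j0 + dj, k0 + dk]
      corners <- c(cn(0, 0, 0), cn(2, 0, 0), cn(2, 2, 0), cn(0, 2, 0),
                   cn(0, 0, 2), cn(2, 0, 2), cn(2, 2, 2), cn(0, 2, 2))
      mids <- c(cn(1, 0, 0), cn(2, 1, 0), cn(1, 2, 0), cn(0, 1, 0),
                cn(1, 0, 2), cn(2, 1, 2), cn(1, 2, 2), cn(0, 1, 2),
                cn(0, 0, 1), cn(2, 0, 1), cn(2, 2, 1), cn(0, 2, 1))
      nodes <- c(corners, mids)
      if (length(unique(corners)) < 5L) next
      ecount <- ecount + 1L
      conn[[ecount]] <- nodes
      cell_ij[ecount, ] <- c(ii, jj)
      if (kk == nel_k) press[[length(press) + 1L]] <-
          list(elem = ecount,
               nodes = c(cn(0, 0, 2), cn(2, 0, 2), cn(2, 2, 2), cn(0, 2, 2),
                         cn(1, 0, 2), cn(2, 1, 2), cn(1, 2, 2), cn(0, 1, 2)))
    }
  }
  elems <- do.call(rbind, conn)
  cell_ij <- cell_ij[seq_len(ecount), , drop = FALSE]

  ## node sets
  grab <- function(ifix = NULL, jfix = NULL, kfix = NULL) {
    ii <- ifix %||% seq_len(nt_f); jj <- jfix %||% seq_len(ns_f)
    kk <- kfix %||% seq_len(nsheet)
    v <- id[ii, jj, kk]
    sort(unique(v[!is.na(v)]))
  }
  sets <- list()
  for (nm in names(edge_map)) {
    sets[[edge_map[[nm]]]] <- switch(nm,
      imin = grab(ifix = 1L),
      imax = grab(ifix = nt_f),
      jmin = grab(jfix = 1L),
      jmax = grab(jfix = ns_f))
  }
  sets$arterial_surface <- grab(kfix = nsheet)
  sets$ventricular_surface <- grab(kfix = 1L)

  ## per-element reference frames from mid-surface tangents at cell centers
  tg <- grid_tangents(P)
  v1m <- matrix(0, ecount, 3); v2m <- matrix(0, ecount, 3)
  step_f <- if (order == 2L) 2L else 1L
  for (e in seq_len(ecount)) {
    ii <- cell_ij[e, 1]; jj <- cell_ij[e, 2]
    ic <- step_f * (ii - 1L) + 1L; jc <- step_f * (jj - 1L) + 1L
    i2 <- min(ic + step_f, nt_f); j2 <- min(jc + step_f, ns_f)
    dj <- (tg$dj[ic, jc, ] + tg$dj[i2, jc, ] + tg$dj[ic, j2, ] +
             tg$dj[i2, j2, ]) / 4
    di <- (tg$di[ic, jc, ] + tg$di[i2, jc, ] + tg$di[ic, j2, ] +
             tg$di[i2, j2, ]) / 4
    a <- dj / sqrt(sum(dj * dj))
    b <- di - sum(di * a) * a
    b <- b / sqrt(sum(b * b))
    v1m[e, ] <- a; v2m[e, ] <- b
  }

  meta$grid <- list(nt = nt, ns = ns, n_layers = n_layers, order = order,
                    surface_fn = surf, cell_ij = cell_ij,
                    mid_grid = P, id_grid = id, nsheet = nsheet)
  meta$edge_map <- edge_map
  meta$thickness <- thickness
  leaflet_mesh(coords, elems, order, sets, press,
               regions = factor(rep("other", ecount),
                                levels = c("belly", "commissure", "tip", "other")),
               frames = list(v1 = v1m, v2 = v2m), meta = meta)
}

## ---- region labelling ---------------------------------------------------

## Label belly / commissure / tip / other element regions from surface
## distances: commissure = within frac_comm of the span from the commissure
## corner; tip = within frac_tip of the span from the free-edge midpoint
## (the tip); belly = within frac_belly of the symmetry-plane midline.
label_regions <- function(mesh, commissure_point, tip_point, belly_curve,
                          frac_comm = 0.15, frac_tip = 0.10,
                          frac_belly = 0.35) {
  cent <- element_centroids(mesh)
  d_comm <- sqrt(colSums((t(cent) - commissure_point)^2))
  d_tip <- sqrt(colSums((t(cent) - tip_point)^2))
  ## distance to the symmetry-plane midline polyline
  d_belly <- vapply(seq_len(nrow(cent)), function(e) {
    min(sqrt(colSums((t(belly_curve) - cent[e, ])^2)))
  }, numeric(1))
  span <- max(d_comm)
  reg <- rep("other", nrow(cent))
  reg[d_belly < frac_belly * max(d_belly)] <- "belly"
  reg[d_tip < frac_tip * span] <- "tip"
  reg[d_comm < frac_comm * span] <- "commissure"
  mesh$regions <- factor(reg, levels = c("belly", "commissure", "tip", "other"))
  mesh$meta$region_fracs <- c(commissure = frac_comm, tip = frac_tip,
                              belly = frac_belly)
  mesh
}

#' Element centroids of a leaflet mesh
#' @param mesh `leaflet_mesh`.
#' @return matrix (n_elems x 3).
#' @export
element_centroids <- function(mesh) {
  nc <- if (mesh$order == 1L) 8L else 8L  ## corners suffice
  t(apply(mesh$elems[, seq_len(nc), drop = FALSE], 1, function(en) {
    colMeans(mesh$nodes[en, , drop = FALSE])
  }))
}

#' Validate the geometric invariants of a leaflet mesh
#'
#' Checks that every node lies within the valve cylinder (radius R +
#' thickness), that the per-element frames are orthonormal and tangent to
#' the mid-surface, and that element Jacobians are positive at all
#' integration points.
#'
#' @param mesh `leaflet_mesh`. @param tol tolerance.
#' @return `TRUE` invisibly; stops on violation.
#' @export
validate_mesh <- function(mesh, tol = 1e-8) {
  R <- mesh$meta$params$R
  th <- mesh$meta$thickness
  if (!is.null(R)) {
    rad <- sqrt(mesh$nodes[, 1]^2 + mesh$nodes[, 2]^2)
    if (any(rad > R + th + 1e-6)) stop("node outside valve cylinder")
  }
  v1 <- mesh$frames$v1; v2 <- mesh$frames$v2
  if (any(abs(rowSums(v1 * v1) - 1) > 1e-8) ||
      any(abs(rowSums(v2 * v2) - 1) > 1e-8) ||
      any(abs(rowSums(v1 * v2)) > 1e-8)) {
    stop("element frames not orthonormal")
  }
  jmin <- min_jacobian(mesh)
  if (jmin <= 0) stop(sprintf("non-positive element Jacobian (min %.3g)", jmin))
  invisible(TRUE)
}

## minimum Jacobian determinant over all elements/integration points
min_jacobian <- function(mesh) {
  sh <- shape_library(mesh$order)
  jmin <- Inf
  for (e in seq_len(nrow(mesh$elems))) {
    xe <- mesh$nodes[mesh$elems[e, ], , drop = FALSE]
    for (g in seq_along(sh$w)) {
      J <- t(sh$dN[[g]]) %*% xe
      jmin <- min(jmin, det3(t(J)))
    }
  }
  jmin
}

## Remove degenerate sliver elements (integration-point Jacobian at or
## below jtol). Where a surface fold tightens below the half-thickness --
## the coaptation fold near the leaflet apex -- the offset sheets of the
## few cells resolving it fold over; those near-zero-volume slivers are
## dropped, as mesh-cleanup practice, and dangling nodes are removed.
prune_degenerate_elements <- function(mesh, jtol = 1e-5) {
  sh <- shape_library(mesh$order)
  nel <- nrow(mesh$elems)
  jmin <- numeric(nel)
  for (e in seq_len(nel)) {
    xe <- mesh$nodes[mesh$elems[e, ], , drop = FALSE]
    jmin[e] <- min(vapply(seq_along(sh$w), function(g) {
      det3(t(sh$dN[[g]]) %*% xe)
    }, numeric(1)))
  }
  drop <- jmin <= jtol
  if (!any(drop)) return(mesh)
  keep <- which(!drop)
  used <- sort(unique(as.vector(mesh$elems[keep, , drop = FALSE])))
  remap <- integer(nrow(mesh$nodes))
  remap[used] <- seq_along(used)
  m <- mesh
  m$nodes <- mesh$nodes[used, , drop = FALSE]
  m$elems <- matrix(remap[mesh$elems[keep, , drop = FALSE]],
                    nrow = length(keep))
  m$sets <- lapply(mesh$sets, function(s) sort(remap[intersect(s, used)]))
  m$regions <- mesh$regions[keep]
  m$frames$v1 <- mesh$frames$v1[keep, , drop = FALSE]
  m$frames$v2 <- mesh$frames$v2[keep, , drop = FALSE]
  el_remap <- integer(nel); el_remap[keep] <- seq_along(keep)
  m$pressure_faces <- Filter(Negate(is.null), lapply(mesh$pressure_faces,
    function(fc) {
      if (drop[fc$elem] || !all(fc$nodes %in% used)) return(NULL)
      list(elem = el_remap[fc$elem], nodes = remap[fc$nodes])
    }))
  m$meta$grid$cell_ij <- mesh$meta$grid$cell_ij[keep, , drop = FALSE]
  id <- mesh$meta$grid$id_grid
  id[] <- ifelse(!is.na(id) & id %in% used, remap[ifelse(is.na(id), 1L, id)],
                 NA_integer_)
  m$meta$grid$id_grid <- id
  m$meta$pruned_elements <- sum(drop)
  m
}

#' Mirror a half-leaflet mesh across the symmetry plane
#'
#' Reflects nodes across x = 0 (element connectivity is reordered to keep
#' Jacobians positive). Used to assemble full leaflets for visualization and
#' orifice-area computation.
#'
#' @param mesh `leaflet_mesh`.
#' @return mirrored `leaflet_mesh` (sets preserved).
#' @export
mirror_mesh <- function(mesh) {
  m <- mesh
  m$nodes[, 1] <- -m$nodes[, 1]
  if (mesh$order == 1L) {
    perm <- c(4, 3, 2, 1, 8, 7, 6, 5)
  } else {
    perm <- c(4, 3, 2, 1, 8, 7, 6, 5, 11, 10, 9, 12, 15, 14, 13, 16,
              20, 19, 18, 17)
  }
  m$elems <- m$elems[, perm, drop = FALSE]
  m$frames$v1[, 1] <- -m$frames$v1[, 1]
  m$frames$v2[, 1] <- -m$frames$v2[, 1]
  ## restore outward orientation of the pressure faces (mirroring is an
  ## improper transform)
  fperm4 <- c(1, 4, 3, 2)
  fperm8 <- c(1, 4, 3, 2, 8, 7, 6, 5)
  m$pressure_faces <- lapply(m$pressure_faces, function(fc) {
    fc$nodes <- fc$nodes[if (length(fc$nodes) == 4L) fperm4 else fperm8]
    fc
  })
  if (!is.null(m$meta$grid$mid_grid)) {
    m$meta$grid$mid_grid[, , 1] <- -m$meta$grid$mid_grid[, , 1]
  }
  if (!is.null(m$meta$fe_env)) m$meta$fe_env <- new.env(parent = emptyenv())
  m
}
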