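## Quasi-static, geometrically nonlinear finite elements.
##
## Total-Lagrangian formulation on 8- or 20-node isoparametric hexahedra.
## The constitutive law returns Cauchy stress sigma(F); internal forces use
## the first Piola stress P = J sigma F^-T, and the consistent (generally
## unsymmetric) tangent dP/dF is computed by directed numerical
## perturbation of F, vectorized across all integration points. Pressure is
## a follower load on the arterial surface; inter-leaflet contact is a
## nodal penalty (optionally augmented-Lagrange) against the rigid planes
## y = tan(30 deg) |x|.

## ---- shape functions -----------------------------------------------------

gauss1d <- function(n) {
  if (n == 2L) list(x = c(-1, 1) / sqrt(3), w = c(1, 1))
  else list(x = c(-sqrt(3 / 5), 0, sqrt(3 / 5)), w = c(5, 8, 5) / 9)
}

## trilinear (8-node) and serendipity (20-node) brick shape functions
shape_hex <- function(xi, order) {
  x <- xi[1]; y <- xi[2]; z <- xi[3]
  s <- matrix(c(-1, -1, -1,  1, -1, -1,  1, 1, -1, -1, 1, -1,
                -1, -1, 1,   1, -1, 1,   1, 1, 1,  -1, 1, 1),
              8, 3, byrow = TRUE)
  if (order == 1L) {
    N <- numeric(8); dN <- matrix(0, 8, 3)
    for (a in 1:8) {
      sx <- s[a, 1]; sy <- s[a, 2]; sz <- s[a, 3]
      N[a] <- (1 + sx * x) * (1 + sy * y) * (1 + sz * z) / 8
      dN[a, ] <- c(sx * (1 + sy * y) * (1 + sz * z),
                   sy * (1 + sx * x) * (1 + sz * z),
                   sz * (1 + sx * x) * (1 + sy * y)) / 8
    }
    return(list(N = N, dN = dN))
  }
  N <- numeric(20); dN <- matrix(0, 20, 3)
  for (a in 1:8) {
    sx <- s[a, 1]; sy <- s[a, 2]; sz <- s[a, 3]
    f <- (1 + sx * x) * (1 + sy * y) * (1 + sz * z) / 8
    g <- sx * x + sy * y + sz * z - 2
    N[a] <- f * g
    dN[a, 1] <- sx * (1 + sy * y) * (1 + sz * z) * g / 8 + f * sx
    dN[a, 2] <- sy * (1 + sx * x) * (1 + sz * z) * g / 8 + f * sy
    dN[a, 3] <- sz * (1 + sx * x) * (1 + sy * y) * g / 8 + f * sz
  }
  ## midside nodes: 9-12 bottom ring, 13-16 top ring, 17-20 verticals
  mid <- list(
    c(0, -1, -1), c(1, 0, -1), c(0, 1, -1), c(-1, 0, -1),
    c(0, -1, 1),  c(1, 0, 1),  c(0, 1, 1),  c(-1, 0, 1),
    c(-1, -1, 0), c(1, -1, 0), c(1, 1, 0),  c(-1, 1, 0))
  for (m in seq_along(mid)) {
    a <- 8L + m
    sx <- mid[[m]][1]; sy <- mid[[m]][2]; sz <- mid[[m]][3]
    if (sx == 0) {
      N[a] <- (1 - x^2) * (1 + sy * y) * (1 + sz * z) / 4
      dN[a, ] <- c(-2 * x * (1 + sy * y) * (1 + sz * z),
                   sy * (1 - x^2) * (1 + sz * z),
                   sz * (1 - x^2) * (1 + sy * y)) / 4
    } else if (sy == 0) {
      N[a] <- (1 - y^2) * (1 + sx * x) * (1 + sz * z) / 4
      dN[a, ] <- c(sx * (1 - y^2) * (1 + sz * z),
                   -2 * y * (1 + sx * x) * (1 + sz * z),
                   sz * (1 - y^2) * (1 + sx * x)) / 4
    } else {
      N[a] <- (1 - z^2) * (1 + sx * x) * (1 + sy * y) / 4
      dN[a, ] <- c(sx * (1 - z^2) * (1 + sy * y),
                   sy * (1 - z^2) * (1 + sx * x),
                   -2 * z * (1 + sx * x) * (1 + sy * y)) / 4
    }
  }
  list(N = N, dN = dN)
}

## integration rule + tabulated shape functions for a brick of given order.
## The 20-node brick uses the 2x2x2 reduced rule (the standard scheme for
## quadratic bricks in soft-tissue work; full 3x3x3 available via `full`).
shape_library <- function(order, full = FALSE) {
  g <- gauss1d(if (order == 1L || !full) 2L else 3L)
  gp <- list(); w <- c(); N <- list(); dN <- list()
  for (k in seq_along(g$x)) for (j in seq_along(g$x)) for (i in seq_along(g$x)) {
    xi <- c(g$x[i], g$x[j], g$x[k])
    sh <- shape_hex(xi, order)
    gp[[length(gp) + 1L]] <- xi
    w <- c(w, g$w[i] * g$w[j] * g$w[k])
    N[[length(N) + 1L]] <- sh$N
    dN[[length(dN) + 1L]] <- sh$dN
  }
  list(gp = gp, w = w, N = N, dN = dN,
       nnode = if (order == 1L) 8L else 20L)
}

## quad face shape functions (4- or 8-node serendipity)
shape_quad <- function(xi, nnode) {
  x <- xi[1]; y <- xi[2]
  s <- matrix(c(-1, -1, 1, -1, 1, 1, -1, 1), 4, 2, byrow = TRUE)
  if (nnode == 4L) {
    N <- numeric(4); dN <- matrix(0, 4, 2)
    for (a in 1:4) {
      N[a] <- (1 + s[a, 1] * x) * (1 + s[a, 2] * y) / 4
      dN[a, ] <- c(s[a, 1] * (1 + s[a, 2] * y),
                   s[a, 2] * (1 + s[a, 1] * x)) / 4
    }
    return(list(N = N, dN = dN))
  }
  N <- numeric(8); dN <- matrix(0, 8, 2)
  for (a in 1:4) {
    sx <- s[a, 1]; sy <- s[a, 2]
    N[a] <- (1 + sx * x) * (1 + sy * y) * (sx * x + sy * y - 1) / 4
    dN[a, 1] <- sx * (1 + sy * y) * (2 * sx * x + sy * y) / 4
    dN[a, 2] <- sy * (1 + sx * x) * (sx * x + 2 * sy * y) / 4
  }
  mids <- list(c(0, -1), c(1, 0), c(0, 1), c(-1, 0))
  for (m in 1:4) {
    a <- 4L + m; sx <- mids[[m]][1]; sy <- mids[[m]][2]
    if (sx == 0) {
      N[a] <- (1 - x^2) * (1 + sy * y) / 2
      dN[a, ] <- c(-x * (1 + sy * y), sy * (1 - x^2) / 2)
    } else {
      N[a] <- (1 - y^2) * (1 + sx * x) / 2
      dN[a, ] <- c(sx * (1 - y^2) / 2, -y * (1 + sx * x))
    }
  }
  list(N = N, dN = dN)
}

quad_library <- function(nnode) {
  g <- gauss1d(if (nnode == 4L) 2L else 3L)
  out <- list()
  for (j in seq_along(g$x)) for (i in seq_along(g$x)) {
    sh <- shape_quad(c(g$x[i], g$x[j]), nnode)
    out[[length(out) + 1L]] <- list(N = sh$N, dN = sh$dN,
                                    w = g$w[i] * g$w[j])
  }
  out
}

## ---- precomputation ------------------------------------------------------

fe_precompute <- function(mesh) {
  cache <- mesh$meta$fe_env
  if (!is.null(cache) && !is.null(cache$pre)) return(cache$pre)
  sh <- shape_library(mesh$order)
  nel <- nrow(mesh$elems); nnode <- sh$nnode; ngp <- length(sh$w)
  nn <- nrow(mesh$nodes); ndof <- 3L * nn
  conn <- mesh$elems
  dofmap <- matrix(0L, nel, 3L * nnode)
  for (a in seq_len(nnode)) {
    dofmap[, 3L * (a - 1L) + 1L] <- 3L * (conn[, a] - 1L) + 1L
    dofmap[, 3L * (a - 1L) + 2L] <- 3L * (conn[, a] - 1L) + 2L
    dofmap[, 3L * (a - 1L) + 3L] <- 3L * (conn[, a] - 1L) + 3L
  }
  X <- array(0, c(nel, nnode, 3))
  for (a in seq_len(nnode)) X[, a, ] <- mesh$nodes[conn[, a], ]

  dNdX <- vector("list", ngp)
  wdet <- matrix(0, nel, ngp)
  Bm <- vector("list", nel)
  for (e in seq_len(nel)) Bm[[e]] <- vector("list", ngp)
  for (g in seq_len(ngp)) {
    dNg <- sh$dN[[g]]
    arr <- array(0, c(nel, nnode, 3))
    for (e in seq_len(nel)) {
      J <- t(dNg) %*% X[e, , ]   ## 3x3, J[r, i] = dX_i / dxi_r
      dj <- det3(J)
      if (dj <= 0) stop(sprintf("non-positive reference Jacobian (elem %d)", e))
      dn <- dNg %*% t(solve(J))  ## nnode x 3 = dN/dX
      arr[e, , ] <- dn
      wdet[e, g] <- sh$w[g] * dj
      Bm[[e]][[g]] <- kronecker(t(dn), diag(3))   ## 9 x 3nnode
    }
    dNdX[[g]] <- arr
  }

  ## sparse triplet pattern
  nd <- 3L * nnode
  ii <- matrix(0L, nel, nd * nd); jj <- matrix(0L, nel, nd * nd)
  for (e in seq_len(nel)) {
    d <- dofmap[e, ]
    ii[e, ] <- rep(d, times = nd)
    jj[e, ] <- rep(d, each = nd)
  }

  ## per-point (element-major) reference fiber basis
  idx_e <- rep(seq_len(nel), each = ngp)
  basis <- list(v1 = mesh$frames$v1[idx_e, , drop = FALSE],
                v2 = mesh$frames$v2[idx_e, , drop = FALSE])

  ## lumped nodal volumes (for contact tributary weights)
  vol_n <- numeric(nn)
  for (e in seq_len(nel)) {
    v <- sum(wdet[e, ])
    vol_n[conn[e, ]] <- vol_n[conn[e, ]] + v / nnode
  }

  pre <- list(sh = sh, nel = nel, nnode = nnode, ngp = ngp, nn = nn,
              ndof = ndof, conn = conn, dofmap = dofmap, dNdX = dNdX,
              wdet = wdet, B = Bm, trip_i = as.vector(t(ii)),
              trip_j = as.vector(t(jj)), basis = basis, idx_e = idx_e,
              vol_n = vol_n,
              g0 = pmin(contact_gap(mesh$nodes), 0),
              qlib = quad_library(if (mesh$order == 1L) 4L else 8L))
  if (is.null(cache)) {
    cache <- new.env(parent = emptyenv())
    ## note: mesh is modified by reference via the environment in meta only
  }
  cache$pre <- pre
  pre
}

## attach a cache environment to a mesh (returns mesh)
with_fe_cache <- function(mesh) {
  if (is.null(mesh$meta$fe_env)) mesh$meta$fe_env <- new.env(parent = emptyenv())
  mesh
}

## deformation gradients at all integration points (element-major)
compute_F_all <- function(pre, xcur) {
  nel <- pre$nel; ngp <- pre$ngp; nnode <- pre$nnode
  xe <- array(0, c(nel, nnode, 3))
  for (a in seq_len(nnode)) xe[, a, ] <- xcur[pre$conn[, a], ]
  Fall <- array(0, c(nel * ngp, 3, 3))
  for (g in seq_len(ngp)) {
    dn <- pre$dNdX[[g]]
    idx <- (seq_len(nel) - 1L) * ngp + g
    for (i in 1:3) {
      xei <- matrix(xe[, , i], nel, nnode)
      for (J in 1:3) {
        Fall[idx, i, J] <- rowSums(xei * matrix(dn[, , J], nel, nnode))
      }
    }
  }
  Fall
}

## inverse of an n x 3 x 3 array (adjugate / det)
inv3_arr <- function(a, dets = NULL) {
  d <- dets %||% det3_arr(a)
  out <- array(0, dim(a))
  out[, 1, 1] <- (a[, 2, 2] * a[, 3, 3] - a[, 2, 3] * a[, 3, 2]) / d
  out[, 1, 2] <- (a[, 1, 3] * a[, 3, 2] - a[, 1, 2] * a[, 3, 3]) / d
  out[, 1, 3] <- (a[, 1, 2] * a[, 2, 3] - a[, 1, 3] * a[, 2, 2]) / d
  out[, 2, 1] <- (a[, 2, 3] * a[, 3, 1] - a[, 2, 1] * a[, 3, 3]) / d
  out[, 2, 2] <- (a[, 1, 1] * a[, 3, 3] - a[, 1, 3] * a[, 3, 1]) / d
  out[, 2, 3] <- (a[, 1, 3] * a[, 2, 1] - a[, 1, 1] * a[, 2, 3]) / d
  out[, 3, 1] <- (a[, 2, 1] * a[, 3, 2] - a[, 2, 2] * a[, 3, 1]) / d
  out[, 3, 2] <- (a[, 1, 2] * a[, 3, 1] - a[, 1, 1] * a[, 3, 2]) / d
  out[, 3, 3] <- (a[, 1, 1] * a[, 2, 2] - a[, 1, 2] * a[, 2, 1]) / d
  out
}

## first Piola stress from Cauchy: P = J sigma F^-T
piola_from_cauchy <- function(Fall, sig) {
  J <- det3_arr(Fall)
  Finv <- inv3_arr(Fall, J)
  P <- matmul3_arr(sig, aperm(Finv, c(1, 3, 2)))
  for (i in 1:3) for (k in 1:3) P[, i, k] <- P[, i, k] * J
  P
}

## internal force vector; stress_fn(Fall) -> npt x 3 x 3 Cauchy
internal_force <- function(pre, Fall, sig) {
  P <- piola_from_cauchy(Fall, sig)
  nel <- pre$nel; ngp <- pre$ngp; nnode <- pre$nnode
  contrib <- matrix(0, nel, 3L * nnode)
  for (g in seq_len(ngp)) {
    idx <- (seq_len(nel) - 1L) * ngp + g
    W <- pre$wdet[, g]
    dn <- pre$dNdX[[g]]
    for (a in seq_len(nnode)) {
      for (i in 1:3) {
        contrib[, 3L * (a - 1L) + i] <- contrib[, 3L * (a - 1L) + i] +
          W * (P[idx, i, 1] * dn[, a, 1] + P[idx, i, 2] * dn[, a, 2] +
                 P[idx, i, 3] * dn[, a, 3])
      }
    }
  }
  f <- numeric(pre$ndof)
  agg <- rowsum(as.vector(contrib), group = as.vector(pre$dofmap))
  f[as.integer(rownames(agg))] <- agg
  f
}

## consistent tangent by directed perturbation of F (9 vectorized
## constitutive calls); returns sparse unsymmetric matrix
tangent_matrix <- function(pre, Fall, sig, stress_fn, h = 1e-7) {
  npt <- dim(Fall)[1]
  P0 <- piola_from_cauchy(Fall, sig)
  A <- array(0, c(npt, 9, 9))   ## [(iJ), (kL)] with idx 3*(J-1)+i
  for (kL in 1:9) {
    k <- (kL - 1L) %% 3L + 1L
    L <- (kL - 1L) %/% 3L + 1L
    Fp <- Fall
    Fp[, k, L] <- Fp[, k, L] + h
    Pp <- piola_from_cauchy(Fp, stress_fn(Fp))
    for (iJ in 1:9) {
      i <- (iJ - 1L) %% 3L + 1L
      J <- (iJ - 1L) %/% 3L + 1L
      A[, iJ, kL] <- (Pp[, i, J] - P0[, i, J]) / h
    }
  }
  nel <- pre$nel; ngp <- pre$ngp; nd <- 3L * pre$nnode
  Kx <- numeric(nel * nd * nd)
  pos <- 0L
  for (e in seq_len(nel)) {
    Ke <- matrix(0, nd, nd)
    for (g in seq_len(ngp)) {
      pt <- (e - 1L) * ngp + g
      B <- pre$B[[e]][[g]]
      Ke <- Ke + pre$wdet[e, g] * crossprod(B, A[pt, , ] %*% B)
    }
    Kx[pos + seq_len(nd * nd)] <- Ke   ## column-major = rep(d,times) rows
    pos <- pos + nd * nd
  }
  Matrix::sparseMatrix(i = pre$trip_i, j = pre$trip_j, x = Kx,
                       dims = c(pre$ndof, pre$ndof))
}

## ---- follower pressure ---------------------------------------------------

## nodal forces of pressure p (kPa) on the given faces in configuration
## xcur; face normals (from node ordering) point outward, traction = -p n.
pressure_forces <- function(pre, mesh, xcur, p) {
  f <- numeric(pre$ndof)
  if (p == 0) return(f)
  for (fc in mesh$pressure_faces) {
    nodes <- fc$nodes
    xy <- xcur[nodes, , drop = FALSE]
    ff <- face_force(xy, pre$qlib, p)
    dofs <- rep(3L * (nodes - 1L), each = 3L) + rep(1:3, length(nodes))
    f[dofs] <- f[dofs] + as.vector(t(ff))
  }
  f
}

face_force <- function(xy, qlib, p) {
  nn <- nrow(xy)
  ff <- matrix(0, nn, 3)
  for (q in qlib) {
    tx <- colSums(q$dN[, 1] * xy)
    ty <- colSums(q$dN[, 2] * xy)
    nrm <- c(tx[2] * ty[3] - tx[3] * ty[2],
             tx[3] * ty[1] - tx[1] * ty[3],
             tx[1] * ty[2] - tx[2] * ty[1])
    ff <- ff - p * q$w * outer(q$N, nrm)
  }
  ff
}

## follower-load stiffness by per-face numerical differentiation
pressure_stiffness <- function(pre, mesh, xcur, p, h = 1e-6) {
  if (p == 0) return(NULL)
  ti <- c(); tj <- c(); tx <- c()
  for (fc in mesh$pressure_faces) {
    nodes <- fc$nodes
    xy <- xcur[nodes, , drop = FALSE]
    f0 <- as.vector(t(face_force(xy, pre$qlib, p)))
    nd <- 3L * length(nodes)
    Kf <- matrix(0, nd, nd)
    for (d in seq_len(nd)) {
      a <- (d - 1L) %/% 3L + 1L; i <- (d - 1L) %% 3L + 1L
      xp <- xy; xp[a, i] <- xp[a, i] + h
      Kf[, d] <- (as.vector(t(face_force(xp, pre$qlib, p))) - f0) / h
    }
    dofs <- rep(3L * (nodes - 1L), each = 3L) + rep(1:3, length(nodes))
    ti <- c(ti, rep(dofs, times = nd))
    tj <- c(tj, rep(dofs, each = nd))
    tx <- c(tx, as.vector(Kf))
  }
  Matrix::sparseMatrix(i = ti, j = tj, x = tx,
                       dims = c(pre$ndof, pre$ndof))
}

## ---- contact -------------------------------------------------------------

## gap to the inter-leaflet planes: g = y - tan(30) |x| (admissible g >= 0)
contact_gap <- function(xy, tanb = tan(pi / 6)) {
  xy[, 2] - tanb * abs(xy[, 1])
}

## forces + stiffness triplets of the nodal penalty; lambda = AL
## multipliers. g0 is the reference-gap allowance: nodes of the extruded
## coaptation sheet that start at (or half a thickness inside) the plane
## are not penalized for their as-built interpenetration, only for moving
## further in.
contact_forces <- function(pre, xcur, k_pen, lambda = NULL,
                           tanb = tan(pi / 6), g0 = NULL, g_reg = 0.02) {
  g <- contact_gap(xcur, tanb)
  if (!is.null(g0)) g <- g - g0
  w <- pre$vol_n
  if (is.null(lambda)) lambda <- numeric(pre$nn)
  ## C1-regularized penalty: the normal traction grows quadratically from
  ## zero over the first g_reg of penetration (no active-set slope jump),
  ## then linearly with stiffness k_pen
  pen <- pmax(0, -g)
  fpen <- ifelse(pen <= 0, 0,
                 ifelse(pen < g_reg, k_pen * pen^2 / (2 * g_reg),
                        k_pen * (pen - g_reg / 2)))
  dfpen <- ifelse(pen <= 0, 0,
                  ifelse(pen < g_reg, k_pen * pen / g_reg, k_pen))
  tn <- pmax(0, lambda + fpen)        ## normal traction (per weight)
  act <- which(tn > 0)
  f <- numeric(pre$ndof)
  ti <- integer(0); tj <- integer(0); tx <- numeric(0)
  if (length(act)) {
    sg <- sign(xcur[act, 1])
    ## gradient of g wrt (x, y): (-tanb*sign(x), 1)
    f[3L * (act - 1L) + 1L] <- -tanb * sg * w[act] * tn[act]
    f[3L * (act - 1L) + 2L] <- w[act] * tn[act]
    ## stiffness dfpen w grad g grad g^T
    for (comp in list(c(1L, 1L), c(1L, 2L), c(2L, 1L), c(2L, 2L))) {
      gi <- ifelse(comp[1] == 1L, -tanb * sg, 1)
      gj <- ifelse(comp[2] == 1L, -tanb * sg, 1)
      ti <- c(ti, 3L * (act - 1L) + comp[1])
      tj <- c(tj, 3L * (act - 1L) + comp[2])
      tx <- c(tx, dfpen[act] * w[act] * gi * gj)
    }
  }
  K <- if (length(ti)) {
    Matrix::sparseMatrix(i = ti, j = tj, x = tx,
                         dims = c(pre$ndof, pre$ndof))
  } else NULL
  list(f = f, K = K, gap = g, traction = tn)
}

## ---- boundary conditions / settings -------------------------------------

#' Boundary conditions for a leaflet solve
#'
#' @param pressure follower pressure magnitude on the arterial surface, kPa.
#' @param contact enable frictionless contact against the inter-leaflet
#'   planes `y = tan(30 deg) |x|`.
#' @param fix_attachment fix all translations of the attachment edge.
#' @param symmetry enforce zero normal (x) displacement on the symmetry
#'   plane set.
#' @return object of class `boundary_conditions`.
#' @export
boundary_conditions <- function(pressure = 0, contact = TRUE,
                                fix_attachment = TRUE, symmetry = TRUE) {
  if (pressure < 0) stop("pressure must be nonnegative")
  structure(list(pressure = pressure, contact = contact,
                 fix_attachment = fix_attachment, symmetry = symmetry),
            class = "boundary_conditions")
}

#' Nonlinear solver settings
#'
#' @param newton_tol relative residual tolerance.
#' @param max_iter Newton iterations per load increment.
#' @param load_increments number of increments to the target pressure
#'   (`NULL` = one per 2 kPa).
#' @param penalty_stiffness contact penalty per tributary area
#'   (kPa/mm; `NULL` = `1e3 * G * phi_ecm / thickness`).
#' @param contact_method `"penalty"` or `"augmented"` (augmented-Lagrange
#'   multiplier updates until penetrations fall below `penetration_tol`).
#' @param penetration_tol admissible plane penetration, mm.
#' @param max_bisect automatic load-increment bisection depth on
#'   non-convergence.
#' @param unsymmetric keep the full unsymmetric tangent (default TRUE; if
#'   FALSE the tangent is symmetrized, which typically slows convergence of
#'   follower-pressure problems).
#' @param step_cap trust-region cap on the largest nodal displacement per
#'   Newton iteration, mm.
#' @return object of class `solver_settings`.
#' @export
solver_settings <- function(newton_tol = 1e-6, max_iter = 60L,
                            load_increments = NULL,
                            penalty_stiffness = NULL,
                            contact_method = c("penalty", "augmented"),
                            penetration_tol = 1e-3,
                            max_bisect = 4L,
                            unsymmetric = TRUE,
                            step_cap = 1) {
  if (newton_tol <= 0 || penetration_tol <= 0) stop("tolerances must be positive")
  structure(list(newton_tol = newton_tol, max_iter = as.integer(max_iter),
                 load_increments = load_increments,
                 penalty_stiffness = penalty_stiffness,
                 contact_method = match.arg(contact_method),
                 penetration_tol = penetration_tol,
                 max_bisect = as.integer(max_bisect),
                 unsymmetric = unsymmetric, step_cap = step_cap),
            class = "solver_settings")
}

## constrained dof indices from bcs
fixed_dofs <- function(mesh, bcs) {
  fx <- integer(0)
  if (bcs$fix_attachment && !is.null(mesh$sets$attachment_edge)) {
    na <- mesh$sets$attachment_edge
    fx <- c(fx, 3L * (na - 1L) + 1L, 3L * (na - 1L) + 2L, 3L * (na - 1L) + 3L)
  }
  if (bcs$symmetry && !is.null(mesh$sets$symmetry_plane)) {
    ns <- mesh$sets$symmetry_plane
    fx <- c(fx, 3L * (ns - 1L) + 1L)
  }
  sort(unique(fx))
}

## ---- static solve --------------------------------------------------------

#' Solve the quasi-static equilibrium of a pressure-loaded leaflet
#'
#' Total-Lagrangian Newton iteration with follower pressure, nodal plane
#' contact, and automatic load-increment bisection on non-convergence.
#'
#' @param mesh `leaflet_mesh`.
#' @param field tissue state field from [tissue_field()] (or `NULL` for the
#'   virgin initial state).
#' @param params `material_params`. @param bcs `boundary_conditions`.
#' @param settings `solver_settings`.
#' @param funcs `sf_response_functions`.
#' @param u0 optional initial displacement guess (n_nodes x 3).
#' @return object of class `fe_solution`: displacements `u`, per-point
#'   deformation gradients `F`, Cauchy stresses `sigma`, per-direction
#'   detail (`lam`, `eps`), reactions, convergence log, contact gaps.
#' @export
solve_static <- function(mesh, field = NULL, params = material_params(),
                         bcs = boundary_conditions(),
                         settings = solver_settings(),
                         funcs = sf_response_functions(params),
                         u0 = NULL) {
  mesh <- with_fe_cache(mesh)
  pre <- fe_precompute(mesh)
  if (is.null(field)) field <- tissue_field(mesh, params)
  state <- field$state; rate <- field$rate
  basis <- pre$basis
  stress_fn <- function(Fa) cauchy_stress_field(Fa, state, params, funcs,
                                                basis = basis, rate = rate)
  k_pen <- settings$penalty_stiffness %||%
    (1e3 * params$G * params$phi_ecm / (mesh$meta$thickness %||% 0.6))
  fx <- fixed_dofs(mesh, bcs)
  free <- setdiff(seq_len(pre$ndof), fx)
  u <- if (is.null(u0)) matrix(0, pre$nn, 3) else u0
  lambda <- numeric(pre$nn)

  n_inc <- settings$load_increments %||% max(1L, ceiling(bcs$pressure / 2))
  targets <- if (bcs$pressure > 0) {
    seq(bcs$pressure / n_inc, bcs$pressure, length.out = n_inc)
  } else 0
  log <- list()

  solve_increment <- function(u, p, depth) {
    res <- newton_solve(mesh, pre, stress_fn, u, p, bcs, settings, free,
                        k_pen, lambda)
    if (!res$converged) {
      ## dynamic-relaxation continuation through snap-through, then a
      ## Newton polish (the converged state carries no residual pseudo-
      ## dynamic forces, so the stabilization energy of the reported
      ## solution is zero)
      u_dr <- dynamic_relaxation(mesh, pre, stress_fn, u, p, bcs, free,
                                 k_pen, lambda)
      res <- newton_solve(mesh, pre, stress_fn, u_dr, p, bcs, settings,
                          free, k_pen, lambda)
    }
    if (!res$converged && depth < settings$max_bisect) {
      p_prev <- attr(u, "pressure") %||% 0
      mid <- (p_prev + p) / 2
      u1 <- solve_increment(u, mid, depth + 1L)
      attr(u1, "pressure") <- mid
      res <- newton_solve(mesh, pre, stress_fn, u1, p, bcs, settings, free,
                          k_pen, lambda)
    }
    if (!res$converged) {
      stop(structure(class = c("fe_nonconvergence", "error", "condition"),
                     list(message = sprintf(
                       "Newton failed at p = %.3g kPa (residual %.3g)",
                       p, res$resnorm), call = sys.call(-1),
                       last_u = res$u, pressure = p)))
    }
    log[[length(log) + 1L]] <<- data.frame(pressure = p, iters = res$iters,
                                           resnorm = res$resnorm)
    attr(res$u, "pressure") <- p
    res$u
  }

  for (p in targets) {
    u <- solve_increment(u, p, 0L)
    if (bcs$contact && settings$contact_method == "augmented") {
      for (al in 1:10) {
        xcur <- mesh$nodes + u
        g <- contact_gap(xcur) - pre$g0
        pen <- pmax(-g, 0)
        if (max(pen) <= settings$penetration_tol) break
        lambda <- pmax(0, lambda - k_pen * g)
        u <- solve_increment(u, p, 0L)
      }
    }
  }

  ## final fields
  xcur <- mesh$nodes + u
  Fall <- compute_F_all(pre, xcur)
  det_out <- cauchy_stress_field(Fall, state, params, funcs,
                                 basis = basis, rate = rate, detail = TRUE)
  fint <- internal_force(pre, Fall, det_out$sigma)
  fext <- pressure_forces(pre, mesh, xcur, bcs$pressure)
  fcon <- if (bcs$contact) contact_forces(pre, xcur, k_pen, lambda,
                                          g0 = pre$g0)$f else
    numeric(pre$ndof)
  Rfull <- fint - fext - fcon
  reactions <- matrix(0, pre$nn, 3)
  reactions[cbind((fx - 1L) %/% 3L + 1L, (fx - 1L) %% 3L + 1L)] <- Rfull[fx]
  gaps <- if (bcs$contact) contact_gap(xcur) - pre$g0 else rep(Inf, pre$nn)

  structure(list(mesh = mesh, u = u, x = xcur, F = Fall,
                 sigma = det_out$sigma, lam = det_out$lam,
                 eps = det_out$eps, J = det_out$J,
                 reactions = reactions, pressure = bcs$pressure,
                 f_ext = fext, residual = Rfull, free_dofs = free,
                 gaps = gaps, stabilization_energy = 0,
                 log = do.call(rbind, log), idx_e = pre$idx_e),
            class = "fe_solution")
}

## Dynamic relaxation: explicit pseudo-dynamic stepping with kinetic
## damping (velocities are zeroed whenever the kinetic energy peaks).
## Robust continuation through snap-through motions that defeat Newton;
## the result is polished by a Newton solve. Nodal pseudo-masses are
## rebuilt from the current tangent row sums so a unit pseudo-time step is
## stable.
dynamic_relaxation <- function(mesh, pre, stress_fn, u, p, bcs, free,
                               k_pen, lambda, max_steps = 4000L,
                               tol = 5e-3, mass_refresh = 250L) {
  uv <- as.vector(t(as.matrix(u)))
  v <- numeric(pre$ndof)
  mass <- NULL
  ke_prev <- 0
  refnorm <- NULL
  valid_state <- function(uv2) {
    x2 <- mesh$nodes + matrix(uv2, pre$nn, 3, byrow = TRUE)
    F2 <- compute_F_all(pre, x2)
    if (any(det3_arr(F2) <= 0.01)) return(FALSE)
    s2 <- try(stress_fn(F2), silent = TRUE)
    if (inherits(s2, "try-error") || any(!is.finite(s2))) return(FALSE)
    max(abs(s2)) < 1e5   ## reject runaway exponential fiber stresses
  }
  for (s in seq_len(max_steps)) {
    xcur <- mesh$nodes + matrix(uv, pre$nn, 3, byrow = TRUE)
    Fall <- compute_F_all(pre, xcur)
    sig <- stress_fn(Fall)
    fint <- internal_force(pre, Fall, sig)
    fext <- pressure_forces(pre, mesh, xcur, p)
    con <- if (bcs$contact) contact_forces(pre, xcur, k_pen, lambda,
                                           g0 = pre$g0) else NULL
    R <- fext + (if (is.null(con)) 0 else con$f) - fint
    rn <- sqrt(sum(R[free]^2))
    if (is.null(refnorm)) refnorm <- max(rn, sqrt(sum(fext[free]^2)), 1e-8)
    if (rn < tol * refnorm) break
    if (is.null(mass) || s %% mass_refresh == 0L) {
      K <- tangent_matrix(pre, Fall, sig, stress_fn)
      mass <- 1.2 * Matrix::rowSums(abs(K)) + 1e-9
    }
    v[free] <- v[free] + (R[free] / mass[free])
    vmax <- max(abs(v))
    if (vmax > 0.2) v <- v * (0.2 / vmax)   ## displacement cap per step
    ke <- sum(mass[free] * v[free]^2)
    if (ke < ke_prev) {
      v[] <- 0            ## kinetic damping at the energy peak
      ke_prev <- 0
      next
    }
    ke_prev <- ke
    if (valid_state(uv + v)) {
      uv <- uv + v
    } else {
      v[] <- 0            ## rejected trial: restart from rest, slower
      ke_prev <- 0
      mass <- mass * 1.5
    }
  }
  matrix(uv, pre$nn, 3, byrow = TRUE)
}

## single Newton loop at fixed pressure; stab > 0 adds anchoring springs
## of stiffness stab * vol_n at the configuration u_anchor
newton_solve <- function(mesh, pre, stress_fn, u, p, bcs, settings, free,
                         k_pen, lambda, stab = 0, u_anchor = NULL) {
  u <- as.matrix(u)
  uv <- as.vector(t(u))
  ua <- if (stab > 0) as.vector(t(as.matrix(u_anchor))) else NULL
  wstab <- if (stab > 0) stab * rep(pre$vol_n, each = 3L) else NULL
  refnorm <- NULL
  resnorm <- Inf
  for (it in seq_len(settings$max_iter)) {
    xcur <- mesh$nodes + matrix(uv, pre$nn, 3, byrow = TRUE)
    Fall <- try(compute_F_all(pre, xcur), silent = TRUE)
    sig <- try(stress_fn(Fall), silent = TRUE)
    if (inherits(sig, "try-error")) {
      return(list(converged = FALSE, u = u, iters = it, resnorm = Inf))
    }
    fint <- internal_force(pre, Fall, sig)
    fext <- pressure_forces(pre, mesh, xcur, p)
    con <- if (bcs$contact) contact_forces(pre, xcur, k_pen, lambda,
                                           g0 = pre$g0) else NULL
    R <- fint - fext - (if (is.null(con)) 0 else con$f)
    if (stab > 0) R <- R + wstab * (uv - ua)
    resnorm <- sqrt(sum(R[free]^2))
    if (!is.finite(resnorm)) {
      return(list(converged = FALSE, u = matrix(uv, pre$nn, 3, byrow = TRUE),
                  iters = it, resnorm = Inf))
    }
    if (is.null(refnorm)) {
      refnorm <- max(sqrt(sum(fext[free]^2)),
                     if (!is.null(con)) sqrt(sum(con$f[free]^2)) else 0,
                     resnorm, 1e-8)
    }
    if (resnorm <= settings$newton_tol * refnorm || resnorm < 1e-12) {
      return(list(converged = TRUE,
                  u = matrix(uv, pre$nn, 3, byrow = TRUE),
                  iters = it, resnorm = resnorm))
    }
    K <- tangent_matrix(pre, Fall, sig, stress_fn)
    if (!settings$unsymmetric) K <- (K + Matrix::t(K)) / 2
    Kp <- pressure_stiffness(pre, mesh, xcur, p)
    if (!is.null(Kp)) K <- K - Kp
    if (!is.null(con) && !is.null(con$K)) K <- K + con$K
    if (stab > 0) K <- K + Matrix::Diagonal(pre$ndof, wstab)
    du <- numeric(pre$ndof)
    sol <- try(Matrix::solve(K[free, free, drop = FALSE], -R[free]),
               silent = TRUE)
    if (inherits(sol, "try-error")) {
      return(list(converged = FALSE, u = matrix(uv, pre$nn, 3, byrow = TRUE),
                  iters = it, resnorm = resnorm))
    }
    du[free] <- as.numeric(sol)
    ## trust-region cap: thin unstressed leaflets have near-singular
    ## transverse stiffness, so raw Newton steps can be enormous
    dumax <- max(abs(du))
    if (dumax > settings$step_cap) du <- du * (settings$step_cap / dumax)
    ## backtrack only on invalid trial states (element inversion or
    ## non-finite stress); monotone residual descent is not enforced --
    ## soft thin structures traverse non-monotone residual paths
    step <- 1
    for (ls in 1:10) {
      uv_try <- uv + step * du
      xt <- mesh$nodes + matrix(uv_try, pre$nn, 3, byrow = TRUE)
      Ft <- compute_F_all(pre, xt)
      if (any(det3_arr(Ft) <= 0.02)) { step <- step / 2; next }
      st <- try(stress_fn(Ft), silent = TRUE)
      if (inherits(st, "try-error") || any(!is.finite(st)) ||
          max(abs(st)) > 1e6) {
        step <- step / 2; next
      }
      break
    }
    uv <- uv + step * du
  }
  list(converged = FALSE, u = matrix(uv, pre$nn, 3, byrow = TRUE),
       iters = settings$max_iter, resnorm = resnorm)
}

#' Equilibrium at zero external pressure (retraction / compaction state)
#'
#' Solves the unloaded configuration with the current (possibly compacted)
#' tissue state; captures leaflet retraction.
#'
#' @inheritParams solve_static
#' @return `fe_solution`.
#' @export
unloaded_configuration <- function(mesh, field = NULL,
                                   params = material_params(),
                                   settings = solver_settings(),
                                   funcs = sf_response_functions(params),
                                   u0 = NULL, contact = TRUE) {
  solve_static(mesh, field, params,
               bcs = boundary_conditions(pressure = 0, contact = contact),
               settings = settings, funcs = funcs, u0 = u0)
}

#' Tissue state field over the integration points of a mesh
#'
#' @param mesh `leaflet_mesh`. @param params `material_params`.
#' @param fibers `fiber_directions`.
#' @param prealign_kappa optional collagen pre-alignment concentration.
#' @return list with `state` (multi-point `tissue_state`), `rate`
#'   (npt x N strain-rate surrogate, initially 0), `npt`.
#' @export
tissue_field <- function(mesh, params = material_params(),
                         fibers = fiber_directions(),
                         prealign_kappa = NULL) {
  mesh <- with_fe_cache(mesh)
  pre <- fe_precompute(mesh)
  npt <- pre$nel * pre$ngp
  list(state = tissue_state(fibers, params, npoints = npt,
                            prealign_kappa = prealign_kappa),
       rate = matrix(0, npt, fibers$N), npt = npt)
}

#' @export
print.fe_solution <- function(x, ...) {
  cat(sprintf("<fe_solution> p = %.3g kPa, max |u| = %.4g mm, %d points\n",
              x$pressure, max(abs(x$u)), dim(x$F)[1]))
  invisible(x)
}
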