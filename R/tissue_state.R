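## Tissue state: per-material-point stress-fiber and collagen composition.

#' Tissue state at one or more material points
#'
#' Holds, per material point, the stress-fiber volume fraction per direction
#' (`phi_sf`), the free actin monomer fraction (`phi_mon`), the collagen
#' volume fraction per direction (`phi_cf`), and the collagen growth stretch
#' per direction (`lam_g`). Two conservation constraints hold at all times:
#' `phi_mon + mean(phi_sf) = phi_a` (actin balance) and
#' `sum(phi_cf) = phi_cf_total` (collagen balance).
#'
#' The initial state is stress-free: no polymerized stress fibers, all actin
#' as monomer, isotropic collagen (`phi_cf / N` per direction), and unit
#' growth stretches. A circumferentially pre-aligned initial collagen
#' distribution can be requested through `prealign_kappa`, which shapes
#' `phi_cf^i` proportional to `exp(kappa * cos(2 gamma_i))` (a von
#' Mises-shaped distribution on the half-circle), renormalized so the total
#' collagen fraction is unchanged.
#'
#' @param fibers `fiber_directions` object.
#' @param params `material_params` object.
#' @param npoints number of material points carried by this state.
#' @param prealign_kappa optional concentration parameter (> 0) of the
#'   pre-aligned initial collagen distribution; `NULL` for isotropic.
#' @return object of class `tissue_state`.
#' @export
tissue_state <- function(fibers = fiber_directions(),
                         params = material_params(),
                         npoints = 1L,
                         prealign_kappa = NULL) {
  N <- fibers$N
  npoints <- as.integer(npoints)
  phi_dir <- rep(params$phi_cf / N, N)
  if (!is.null(prealign_kappa)) {
    w <- exp(prealign_kappa * cos(2 * fibers$gamma))
    phi_dir <- params$phi_cf * w / sum(w)
  }
  structure(list(
    fibers = fibers,
    phi_sf = matrix(0, npoints, N),
    phi_mon = rep(params$phi_a, npoints),
    phi_cf = matrix(phi_dir, npoints, N, byrow = TRUE),
    lam_g = matrix(1, npoints, N),
    phi_a = params$phi_a,
    phi_cf_total = params$phi_cf
  ), class = "tissue_state")
}

#' Verify the conservation invariants of a tissue state
#'
#' @param state `tissue_state`.
#' @param tol absolute tolerance on the two conservation sums.
#' @return `TRUE` invisibly; stops with a message if an invariant fails.
#' @export
validate_tissue_state <- function(state, tol = 1e-10) {
  actin <- state$phi_mon + rowMeans(state$phi_sf)
  if (any(abs(actin - state$phi_a) > tol)) {
    stop("actin conservation violated: phi_mon + mean(phi_sf) != phi_a")
  }
  if (any(abs(rowSums(state$phi_cf) - state$phi_cf_total) > tol)) {
    stop("collagen conservation violated: sum(phi_cf) != phi_cf_total")
  }
  if (any(state$phi_sf < -tol) || any(state$phi_cf < -tol) ||
      any(state$phi_mon < -tol)) {
    stop("negative volume fraction in tissue state")
  }
  if (any(state$lam_g <= 0)) stop("non-positive collagen growth stretch")
  invisible(TRUE)
}

#' @export
print.tissue_state <- function(x, ...) {
  cat(sprintf("<tissue_state> %d point(s), %d directions\n",
              nrow(x$phi_sf), x$fibers$N))
  cat(sprintf("  mean phi_sf = %.4g, phi_mon = %.4g, sum phi_cf = %.4g, mean lam_g = %.4g\n",
              mean(x$phi_sf), mean(x$phi_mon), mean(rowSums(x$phi_cf)),
              mean(x$lam_g)))
  invisible(x)
}

## subset a multi-point state (used by the FE driver)
state_subset <- function(state, idx) {
  s <- state
  s$phi_sf <- state$phi_sf[idx, , drop = FALSE]
  s$phi_mon <- state$phi_mon[idx]
  s$phi_cf <- state$phi_cf[idx, , drop = FALSE]
  s$lam_g <- state$lam_g[idx, , drop = FALSE]
  s
}
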