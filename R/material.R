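## Material parameters and fiber-direction sets.
##
## Internal unit system: mm / s / kPa (so forces come out in mN). Parameters
## quoted in other units at the interface (G in MPa, k1_sf per Pa) are
## converted here, once, at construction.

#' In-plane fiber direction set
#'
#' The stress fibers and collagen fibers share `N` equally spaced directions
#' in the leaflet plane spanned by the local circumferential vector `v1` and
#' radial vector `v2`. Direction `i` makes angle
#' `gamma_i = (i - 1) * pi / N` with the circumferential axis.
#'
#' @param N number of directions (default 30).
#' @return object of class `fiber_directions` with fields `N`, `gamma`
#'   (radians in `[0, pi)`), and `e0` (`N x 2` matrix of in-plane unit
#'   components on `(v1, v2)`).
#' @export
fiber_directions <- function(N = 30L) {
  N <- as.integer(N)
  if (N < 2L) stop("need at least 2 fiber directions")
  gamma <- (seq_len(N) - 1L) * pi / N
  structure(list(N = N, gamma = gamma,
                 e0 = cbind(cos(gamma), sin(gamma))),
            class = "fiber_directions")
}

#' @export
print.fiber_directions <- function(x, ...) {
  cat(sprintf("<fiber_directions> N = %d, gamma in [0, %.4f) rad\n",
              x$N, pi))
  invisible(x)
}

#' Tissue material parameters
#'
#' Constructs the full parameter set of the constitutive model with the
#' baseline values of the study: a contractile stress-fiber population
#' (total actin fraction `phi_a`), tension-only exponential collagen fibers
#' (`phi_cf`, `k1_cf`, `k2_cf`), and a compressible neo-Hookean non-fibrous
#' matrix (`phi_ecm`, `G`, `nu`). The ECM bulk modulus is recomputed as
#' `kappa_ecm = 2 G (1 + nu) / (3 (1 - 2 nu))` unless overridden.
#'
#' @param phi_a total actin volume fraction.
#' @param eps0 active-response strain scale (dimensionless).
#' @param eps1 passive-response scale (printed as kPa in the source table;
#'   treated as the opaque scale of the passive hardening factor).
#' @param kappa_v strain-rate constant, s.
#' @param sigma_max maximum stress-fiber stress, kPa.
#' @param k0_sf,k1_sf,kd_sf stress-fiber kinetic rates; `k0_sf`, `kd_sf` in
#'   1/s, `k1_sf` in 1/(s Pa).
#' @param tau_sf stress-fiber remodeling time constant, s.
#' @param phi_cf total collagen volume fraction.
#' @param k1_cf collagen stiffness, kPa. @param k2_cf collagen exponent.
#' @param tau_lambda compaction time constant, s.
#' @param tau_cf collagen turnover time constant, s.
#' @param eps_deg strain scale of the strain-dependent collagen degradation
#'   law (dimensionless).
#' @param phi_ecm non-fibrous ECM volume fraction.
#' @param nu ECM Poisson ratio. @param G_MPa ECM shear modulus in MPa.
#' @param kappa_ecm optional bulk-modulus override, kPa.
#' @return object of class `material_params`; all stresses in kPa, times in s.
#' @export
material_params <- function(phi_a = 0.05,
                            eps0 = 0.12,
                            eps1 = 0.17,
                            kappa_v = 50,
                            sigma_max = 40,
                            k0_sf = 1.5e-6,
                            k1_sf = 0.7,
                            kd_sf = 1.0e-3,
                            tau_sf = 5 * 60,
                            phi_cf = 0.5,
                            k1_cf = 33.01,
                            k2_cf = 11.74,
                            tau_lambda = 3600,
                            tau_cf = 12 * 3600,
                            eps_deg = 0.05,
                            phi_ecm = 0.45,
                            nu = 0.3,
                            G_MPa = 1.0e-3,
                            kappa_ecm = NULL) {
  for (f in c(phi_a, phi_cf, phi_ecm)) {
    if (f < 0 || f > 1) stop("volume fractions must lie in [0, 1]")
  }
  if (phi_a + phi_cf + phi_ecm > 1 + 1e-9) {
    stop("phi_a + phi_cf + phi_ecm exceeds 1")
  }
  G <- G_MPa * 1000  ## kPa
  if (is.null(kappa_ecm)) kappa_ecm <- 2 * G * (1 + nu) / (3 * (1 - 2 * nu))
  structure(list(
    phi_a = phi_a, eps0 = eps0, eps1 = eps1, kappa_v = kappa_v,
    sigma_max = sigma_max,
    k0_sf = k0_sf, k1_sf = k1_sf, kd_sf = kd_sf, tau_sf = tau_sf,
    phi_cf = phi_cf, k1_cf = k1_cf, k2_cf = k2_cf,
    tau_lambda = tau_lambda, tau_cf = tau_cf, eps_deg = eps_deg,
    phi_ecm = phi_ecm, nu = nu, G = G, kappa_ecm = kappa_ecm
  ), class = "material_params")
}

#' @export
print.material_params <- function(x, ...) {
  cat("<material_params> (kPa, mm, s)\n")
  cat(sprintf("  stress fibers: phi_a=%.3g sigma_max=%.3g kPa tau_sf=%.3g s\n",
              x$phi_a, x$sigma_max, x$tau_sf))
  cat(sprintf("  collagen:      phi_cf=%.3g k1=%.4g kPa k2=%.4g tau_lambda=%.3g s tau_cf=%.3g s\n",
              x$phi_cf, x$k1_cf, x$k2_cf, x$tau_lambda, x$tau_cf))
  cat(sprintf("  ECM:           phi_ecm=%.3g G=%.3g kPa nu=%.3g kappa=%.4g kPa\n",
              x$phi_ecm, x$G, x$nu, x$kappa_ecm))
  invisible(x)
}

#' Named parameter variation presets
#'
#' The systematic variations of the design study: reduced cell contractility
#' (`sigma_max` 40 -> 20 kPa) and collagen stiffened by 10%
#' (`k1_cf` 33.01 -> 36.31 kPa, `k2_cf` 11.74 -> 12.91). Geometric variants
#' (coaptation height, leaflet thickness) are applied on the geometry side.
#'
#' @param name one of `"baseline"`, `"contractility-"`, `"stiffness+10"`.
#' @param base `material_params` object to modify.
#' @return `material_params` object.
#' @export
material_variant <- function(name = c("baseline", "contractility-", "stiffness+10"),
                             base = material_params()) {
  name <- match.arg(name)
  switch(name,
         "baseline" = base,
         "contractility-" = { base$sigma_max <- 20; base },
         "stiffness+10" = { base$k1_cf <- 36.31; base$k2_cf <- 12.91; base })
}
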