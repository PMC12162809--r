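## Stress-fiber response functions and the collagen degradation law.
##
## The framework treats these as an injected strategy: every operation that
## needs them takes a `sf_response_functions` object, so any admissible set
## of forms can be substituted. The shipped defaults are:
##
##   f_eps_a(e)  = exp(-(e / eps0)^2)            active actomyosin factor,
##                                               bounded in [0,1], maximal at
##                                               the strain of peak contraction
##                                               (e = 0);
##   f_eps_p(e)  = (max(e, 0) / eps1)^2          passive strain hardening,
##                                               tension-only, monotone;
##   f_rate(ed)  = 1 / (1 + (kappa_v * ed)^2)    strain-rate factor, bounded
##                                               in (0, 1], even, decreasing
##                                               in |rate| (fast stretching
##                                               suppresses fiber stress and
##                                               mechano-driven polymerization);
##   f_deg(e)    = (2 / tau_cf) / (1 + exp(e / eps_deg))
##                                               collagen degradation rate,
##                                               strictly decreasing in fiber
##                                               strain, bounded in
##                                               (0, 2 / tau_cf).

#' Stress-fiber response-function strategy
#'
#' Bundles the three factors of the stress-fiber stress law
#' `sigma_sf = sigma_max * (f_eps_a(eps) + f_eps_p(eps)) * f_rate(rate)`
#' together with the strain-dependent collagen degradation rate. Custom
#' forms may be supplied; each must be vectorized over its argument.
#'
#' @param params `material_params` supplying the scales `eps0`, `eps1`,
#'   `kappa_v`, `tau_cf`, `eps_deg`.
#' @param f_eps_a,f_eps_p,f_rate,f_deg optional replacement functions.
#' @return object of class `sf_response_functions`.
#' @export
sf_response_functions <- function(params = material_params(),
                                  f_eps_a = NULL, f_eps_p = NULL,
                                  f_rate = NULL, f_deg = NULL) {
  eps0 <- params$eps0; eps1 <- params$eps1
  kv <- params$kappa_v; tcf <- params$tau_cf; ed <- params$eps_deg
  structure(list(
    f_eps_a = f_eps_a %||% function(eps) exp(-(eps / eps0)^2),
    f_eps_p = f_eps_p %||% function(eps) (pmax(eps, 0) / eps1)^2,
    f_rate = f_rate %||% function(rate) 1 / (1 + (kv * rate)^2),
    f_deg = f_deg %||% function(eps) (2 / tcf) / (1 + exp(eps / ed))
  ), class = "sf_response_functions")
}

#' @export
print.sf_response_functions <- function(x, ...) {
  cat("<sf_response_functions> f_eps_a, f_eps_p, f_rate, f_deg\n")
  invisible(x)
}
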