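## Fiber-level constitutive and remodeling model.
##
## Total Cauchy stress = stress fibers + collagen fibers + non-fibrous ECM.
## Both fiber families act along N shared in-plane directions; stress fibers
## contribute (1/N) sum_i phi_sf^i sigma_sf^i e_f^i (x) e_f^i, collagen
## contributes sum_i phi_cf^i sigma_cf^i e_f^i (x) e_f^i with tension-only
## exponential fibers evaluated at the elastic stretch lam_e = lam_f / lam_g,
## and the ECM is a compressible neo-Hookean matrix. All remodeling laws are
## linear relaxations integrated exactly (exponential updates) except the
## collagen turnover, which is an explicit Euler step with exact conservation.

#' Scalar stress-fiber stress
#'
#' `sigma_sf = sigma_max * (f_eps_a(eps) + f_eps_p(eps)) * f_rate(rate)`.
#'
#' @param eps Green--Lagrange fiber strain (vectorized).
#' @param rate fiber strain rate, 1/s (vectorized).
#' @param params `material_params`. @param funcs `sf_response_functions`.
#' @return stress in kPa.
#' @export
stress_fiber_stress <- function(eps, rate = 0, params = material_params(),
                                funcs = sf_response_functions(params)) {
  params$sigma_max * (funcs$f_eps_a(eps) + funcs$f_eps_p(eps)) *
    funcs$f_rate(rate)
}

#' Scalar collagen fiber stress
#'
#' Tension-only exponential fiber:
#' `sigma_cf = k1 * lam^2 * (exp(k2 * (lam^2 - 1)) - 1)` for elastic stretch
#' `lam > 1`, zero otherwise.
#'
#' @param lam_e elastic fiber stretch (vectorized, > 0).
#' @param params `material_params`.
#' @return stress in kPa.
#' @export
collagen_fiber_stress <- function(lam_e, params = material_params()) {
  if (any(lam_e <= 0)) stop("elastic stretch must be positive")
  l2 <- lam_e^2
  out <- params$k1_cf * l2 * expm1(params$k2_cf * (l2 - 1))
  out[lam_e <= 1] <- 0
  out
}

#' Non-fibrous ECM Cauchy stress
#'
#' Compressible neo-Hookean matrix scaled by its volume fraction:
#' `sigma_ecm = phi_ecm * (kappa * ln(J)/J * I + G/J * (B - J^(2/3) I))`.
#'
#' @param F deformation gradient (3x3 matrix).
#' @param params `material_params`.
#' @return 3x3 Cauchy stress, kPa.
#' @export
ecm_stress <- function(F, params = material_params()) {
  J <- det3(F)
  if (J <= 0) stop("non-positive Jacobian")
  B <- F %*% t(F)
  params$phi_ecm * (params$kappa_ecm * log(J) / J * diag(3) +
                      params$G / J * (B - J^(2 / 3) * diag(3)))
}

## ---- vectorized field kernel -------------------------------------------

## Cauchy stress at many material points.
##   F:      npt x 3 x 3 array (or a single 3x3 matrix)
##   state:  tissue_state with npt rows
##   basis:  list(v1 = npt x 3, v2 = npt x 3) reference in-plane unit vectors
##   rate:   npt x N strain-rate surrogate (default 0)
## Returns npt x 3 x 3 array; with detail = TRUE also per-direction stretch,
## strain and fiber stresses.
cauchy_stress_field <- function(F, state, params, funcs,
                                basis = NULL, rate = NULL, detail = FALSE) {
  if (is.matrix(F)) F <- array(F, c(1, 3, 3))
  npt <- dim(F)[1]
  N <- state$fibers$N
  gamma <- state$fibers$gamma
  if (is.null(basis)) {
    basis <- list(v1 = matrix(rep(c(1, 0, 0), each = npt), npt, 3),
                  v2 = matrix(rep(c(0, 1, 0), each = npt), npt, 3))
  }
  if (is.null(rate)) rate <- matrix(0, npt, N)
  if (is.vector(rate)) rate <- matrix(rate, npt, N, byrow = npt == 1L)

  sig <- array(0, c(npt, 3, 3))
  if (detail) {
    lam_all <- eps_all <- ssf_all <- scf_all <- matrix(0, npt, N)
  }
  smax <- params$sigma_max
  for (i in seq_len(N)) {
    cg <- cos(gamma[i]); sg <- sin(gamma[i])
    e0 <- cg * basis$v1 + sg * basis$v2
    f1 <- F[, 1, 1] * e0[, 1] + F[, 1, 2] * e0[, 2] + F[, 1, 3] * e0[, 3]
    f2 <- F[, 2, 1] * e0[, 1] + F[, 2, 2] * e0[, 2] + F[, 2, 3] * e0[, 3]
    f3 <- F[, 3, 1] * e0[, 1] + F[, 3, 2] * e0[, 2] + F[, 3, 3] * e0[, 3]
    lam2 <- f1 * f1 + f2 * f2 + f3 * f3
    lam <- sqrt(lam2)
    eps <- 0.5 * (lam2 - 1)
    ssf <- smax * (funcs$f_eps_a(eps) + funcs$f_eps_p(eps)) *
      funcs$f_rate(rate[, i])
    lam_e <- lam / state$lam_g[, i]
    l2e <- lam_e^2
    scf <- params$k1_cf * l2e * expm1(params$k2_cf * (l2e - 1))
    scf[lam_e <= 1] <- 0
    w <- state$phi_sf[, i] * ssf / N + state$phi_cf[, i] * scf
    ## unit pushed-forward direction
    h1 <- f1 / lam; h2 <- f2 / lam; h3 <- f3 / lam
    sig[, 1, 1] <- sig[, 1, 1] + w * h1 * h1
    sig[, 2, 2] <- sig[, 2, 2] + w * h2 * h2
    sig[, 3, 3] <- sig[, 3, 3] + w * h3 * h3
    sig[, 1, 2] <- sig[, 1, 2] + w * h1 * h2
    sig[, 1, 3] <- sig[, 1, 3] + w * h1 * h3
    sig[, 2, 3] <- sig[, 2, 3] + w * h2 * h3
    if (detail) {
      lam_all[, i] <- lam; eps_all[, i] <- eps
      ssf_all[, i] <- ssf; scf_all[, i] <- scf
    }
  }
  sig[, 2, 1] <- sig[, 1, 2]; sig[, 3, 1] <- sig[, 1, 3]
  sig[, 3, 2] <- sig[, 2, 3]

  ## ECM
  J <- det3_arr(F)
  if (any(J <= 0)) stop("non-positive Jacobian in stress evaluation")
  B <- matmul3_arr(F, t3_arr(F))
  cvol <- params$phi_ecm * params$kappa_ecm * log(J) / J
  gj <- params$phi_ecm * params$G / J
  j23 <- J^(2 / 3)
  for (d in 1:3) sig[, d, d] <- sig[, d, d] + cvol + gj * (B[, d, d] - j23)
  sig[, 1, 2] <- sig[, 1, 2] + gj * B[, 1, 2]
  sig[, 2, 1] <- sig[, 2, 1] + gj * B[, 2, 1]
  sig[, 1, 3] <- sig[, 1, 3] + gj * B[, 1, 3]
  sig[, 3, 1] <- sig[, 3, 1] + gj * B[, 3, 1]
  sig[, 2, 3] <- sig[, 2, 3] + gj * B[, 2, 3]
  sig[, 3, 2] <- sig[, 3, 2] + gj * B[, 3, 2]

  if (detail) {
    list(sigma = sig, lam = lam_all, eps = eps_all,
         sig_sf = ssf_all, sig_cf = scf_all, J = J)
  } else {
    sig
  }
}

## ---- material-point wrappers -------------------------------------------

#' Kinematic quantities of a deformation gradient at a material point
#'
#' @param F 3x3 deformation gradient.
#' @param fibers `fiber_directions`.
#' @param v1,v2 reference in-plane unit vectors (default global x / y axes).
#' @return list with `F`, `B`, `J`, per-direction fiber stretch `lam` and
#'   Green--Lagrange fiber strain `eps`.
#' @export
deformation_point <- function(F, fibers = fiber_directions(),
                              v1 = c(1, 0, 0), v2 = c(0, 1, 0)) {
  J <- det3(F)
  if (J <= 0) stop("deformation gradient must have positive determinant")
  e0 <- outer(cos(fibers$gamma), v1) + outer(sin(fibers$gamma), v2)
  fe <- e0 %*% t(F)
  lam <- sqrt(rowSums(fe * fe))
  list(F = F, B = F %*% t(F), J = J, lam = lam, eps = 0.5 * (lam^2 - 1))
}

#' Stress-fiber Cauchy stress tensor
#'
#' `(1/N) sum_i phi_sf^i sigma_sf^i e_f^i (x) e_f^i` with current directions
#' obtained by pushing the reference directions through `F` and normalizing.
#'
#' @param state single-point `tissue_state`.
#' @param F 3x3 deformation gradient.
#' @param params,funcs material parameters and response strategy.
#' @param rate per-direction strain-rate surrogate (scalar or length-N).
#' @param v1,v2 reference in-plane basis.
#' @return 3x3 Cauchy stress, kPa.
#' @export
stress_fiber_tensor <- function(state, F, params = material_params(),
                                funcs = sf_response_functions(params),
                                rate = 0, v1 = c(1, 0, 0), v2 = c(0, 1, 0)) {
  p0 <- params
  p0$phi_cf <- 0; p0$phi_ecm <- 0; p0$G <- 0; p0$kappa_ecm <- 0
  st <- state
  st$phi_cf <- matrix(0, 1, state$fibers$N)
  basis <- list(v1 = matrix(v1, 1, 3), v2 = matrix(v2, 1, 3))
  cauchy_stress_field(F, st, p0, funcs, basis = basis,
                      rate = matrix(rate, 1, state$fibers$N))[1, , ]
}

#' Total Cauchy stress at a material point
#'
#' Sum of the stress-fiber, collagen and ECM contributions.
#'
#' @inheritParams stress_fiber_tensor
#' @return 3x3 Cauchy stress, kPa.
#' @export
total_stress <- function(F, state, params = material_params(),
                         funcs = sf_response_functions(params),
                         rate = 0, v1 = c(1, 0, 0), v2 = c(0, 1, 0)) {
  basis <- list(v1 = matrix(v1, 1, 3), v2 = matrix(v2, 1, 3))
  cauchy_stress_field(F, state, params, funcs, basis = basis,
                      rate = matrix(rate, 1, state$fibers$N))[1, , ]
}

## ---- remodeling laws ----------------------------------------------------

#' Preferred (equilibrium) stress-fiber fractions under cyclic loading
#'
#' Analytical equilibrium of the stress-fiber kinetics under a cyclic
#' stimulus described by the loaded and unloaded fiber strains and the cycle
#' period: with a triangular-wave strain path the strain-rate surrogate is
#' `rate = 2 (eps_loaded - eps_unloaded) / period`, the cycle-averaged
#' polymerization coefficient is
#' `c_i = k0 + k1 * sigma_max * mean(f_eps_a) * f_rate(rate_i)`, and the
#' stationary fractions solve the kinetics jointly with actin conservation:
#' `phi_mon* = phi_a / (1 + mean(c_i / kd))`, `phi_sf_p^i = c_i/kd phi_mon*`.
#'
#' @param eps_loaded,eps_unloaded per-direction Green--Lagrange strains
#'   (vectors of length N, or npt x N matrices).
#' @param period cycle period, s (> 0).
#' @param params,funcs material parameters and response strategy.
#' @return preferred fractions, same shape as `eps_loaded`; attribute
#'   `"phi_mon"` carries the stationary monomer fraction.
#' @export
preferred_sf_fraction <- function(eps_loaded, eps_unloaded, period = 0.85,
                                  params = material_params(),
                                  funcs = sf_response_functions(params)) {
  if (period <= 0) stop("cycle period must be positive")
  vec_in <- !is.matrix(eps_loaded)
  if (vec_in) {
    eps_loaded <- matrix(eps_loaded, 1)
    eps_unloaded <- matrix(eps_unloaded, 1)
  }
  rate <- 2 * (eps_loaded - eps_unloaded) / period
  fbar <- 0.5 * (funcs$f_eps_a(eps_loaded) + funcs$f_eps_a(eps_unloaded)) *
    funcs$f_rate(rate)
  ## k1_sf is per Pa; sigma_max is kPa
  cc <- params$k0_sf + params$k1_sf * (params$sigma_max * 1000) * fbar
  ratio <- cc / params$kd_sf
  phi_mon_eq <- params$phi_a / (1 + rowMeans(ratio))
  out <- ratio * phi_mon_eq
  if (vec_in) {
    out <- drop(out)
    phi_mon_eq <- drop(phi_mon_eq)
  }
  attr(out, "phi_mon") <- phi_mon_eq
  attr(out, "rate") <- if (vec_in) drop(rate) else rate
  out
}

#' Relax stress-fiber fractions toward their preferred values
#'
#' Exact exponential integration of the linear relaxation
#' `d(phi_sf)/dt = (phi_sf_p - phi_sf) / tau_sf`; the monomer fraction is
#' recomputed from actin conservation after the step.
#'
#' @param state `tissue_state`. @param phi_p preferred fractions (npt x N).
#' @param dt time step, s. @param params `material_params`.
#' @return updated `tissue_state`.
#' @export
update_stress_fibers <- function(state, phi_p, dt, params = material_params()) {
  if (dt <= 0) stop("dt must be positive")
  if (!is.matrix(phi_p)) phi_p <- matrix(phi_p, nrow(state$phi_sf),
                                         state$fibers$N, byrow = TRUE)
  a <- exp(-dt / params$tau_sf)
  phi <- phi_p + (state$phi_sf - phi_p) * a
  if (any(phi < 0)) {
    warning("negative stress-fiber fraction clamped to 0")
    phi[phi < 0] <- 0
  }
  state$phi_sf <- phi
  state$phi_mon <- state$phi_a - rowMeans(phi)
  state
}

#' Preferred collagen growth stretch from the stress balance
#'
#' Cells compact collagen until the collagen fiber stress balances the
#' stress-fiber stress. Given the total fiber stretch `lam_cf` and the
#' balance target `sigma_target = sigma_sf`, returns `lam_g_p` solving
#' `sigma_cf(lam_cf / lam_g_p) = sigma_target` by safeguarded bisection on
#' the bracket `[1e-2, lam_cf * (1 + 1e-6)]`. For `sigma_target = 0` the
#' stress-free compaction limit `lam_g_p = lam_cf` is returned. If the
#' target is unreachable within the bracket the bracket endpoint is returned
#' and flagged.
#'
#' @param lam_cf total collagen fiber stretch (vectorized).
#' @param sigma_target balance stress, kPa (vectorized, >= 0).
#' @param params `material_params`.
#' @param iter bisection iterations (the bracket halves each time).
#' @return numeric vector `lam_g_p` with logical attribute `"bracket_failed"`.
#' @export
preferred_growth_stretch <- function(lam_cf, sigma_target,
                                     params = material_params(),
                                     iter = 100L) {
  if (any(sigma_target < 0)) stop("sigma_target must be nonnegative")
  n <- max(length(lam_cf), length(sigma_target))
  lam_cf <- rep_len(lam_cf, n)
  sigma_target <- rep_len(sigma_target, n)
  lo <- rep(1e-2, n)
  hi <- lam_cf * (1 + 1e-6)
  out <- lam_cf
  failed <- logical(n)
  active <- sigma_target > 0
  if (any(active)) {
    ## residual g(lam_g) = sigma_cf(lam_cf/lam_g) - target, decreasing in lam_g
    g_lo <- collagen_fiber_stress(lam_cf[active] / lo[active], params) -
      sigma_target[active]
    failed[active] <- g_lo < 0
    idx <- which(active & !failed)
    if (length(idx)) {
      a <- lo[idx]; b <- hi[idx]
      lamc <- lam_cf[idx]; tgt <- sigma_target[idx]
      for (k in seq_len(iter)) {
        m <- 0.5 * (a + b)
        gm <- collagen_fiber_stress(lamc / m, params) - tgt
        pos <- gm >= 0
        a[pos] <- m[pos]
        b[!pos] <- m[!pos]
      }
      out[idx] <- 0.5 * (a + b)
    }
    out[active & failed] <- lo[active & failed]
  }
  attr(out, "bracket_failed") <- failed
  out
}

#' Relax collagen growth stretches toward their preferred values
#'
#' Exact exponential integration of
#' `d(lam_g)/dt = (lam_g_p - lam_g) / tau_lambda`.
#'
#' @param state `tissue_state`. @param lam_gp preferred growth stretches.
#' @param dt time step, s. @param params `material_params`.
#' @return updated `tissue_state`.
#' @export
update_collagen_growth <- function(state, lam_gp, dt,
                                   params = material_params()) {
  if (dt <= 0) stop("dt must be positive")
  if (!is.matrix(lam_gp)) lam_gp <- matrix(lam_gp, nrow(state$lam_g),
                                           state$fibers$N, byrow = TRUE)
  a <- exp(-dt / params$tau_lambda)
  state$lam_g <- lam_gp + (state$lam_g - lam_gp) * a
  state
}

#' Strain-dependent collagen turnover
#'
#' Per-direction degradation at a rate that decreases with fiber strain
#' (`f_deg` of the response strategy), balanced by isotropic deposition of
#' exactly the degraded amount, so the total collagen fraction is conserved
#' to machine precision. Explicit Euler step.
#'
#' @param state `tissue_state`.
#' @param eps per-direction Green--Lagrange strain (npt x N or length N).
#' @param dt time step, s.
#' @param params,funcs material parameters and response strategy.
#' @return updated `tissue_state`.
#' @export
collagen_turnover <- function(state, eps, dt, params = material_params(),
                              funcs = sf_response_functions(params)) {
  if (dt <= 0) stop("dt must be positive")
  if (!is.matrix(eps)) eps <- matrix(eps, nrow(state$phi_cf),
                                     state$fibers$N, byrow = TRUE)
  r <- funcs$f_deg(eps)
  frac <- pmin(r * dt, 1)  ## explicit Euler, clamped for stability
  deg <- state$phi_cf * frac
  dep <- rowSums(deg) / state$fibers$N
  phi <- state$phi_cf - deg + dep
  ## exact conservation (guards rounding)
  phi <- phi * (state$phi_cf_total / rowSums(phi))
  state$phi_cf <- phi
  state
}

## one full remodeling update shared by the material-point driver and the
## FE remodeling driver; eps_l/eps_u/lam_l are npt x N, period in s.
## lam_g_rate_cap (per hour) is a move limit on the growth stretch: the
## staggered coupling evaluates the compaction balance at frozen strain, so
## unlimited relaxation overshoots the self-consistent state and rings;
## the limiter is inactive near equilibrium and does not move fixed points.
remodel_step <- function(state, eps_l, eps_u, lam_l, dt, period,
                         params, funcs, turnover = TRUE,
                         lam_g_rate_cap = 0.01) {
  phi_p <- preferred_sf_fraction(eps_l, eps_u, period, params, funcs)
  rate <- attr(phi_p, "rate")
  state <- update_stress_fibers(state, phi_p, dt, params)
  sig_sf <- params$sigma_max *
    (funcs$f_eps_a(eps_l) + funcs$f_eps_p(eps_l)) * funcs$f_rate(rate)
  lam_e <- lam_l / state$lam_g
  sig_cf <- collagen_fiber_stress(lam_e, params)
  ## cells compact only where collagen stress is below stress-fiber stress
  compact <- sig_cf < sig_sf
  lam_gp <- state$lam_g
  if (any(compact)) {
    lam_gp[compact] <- preferred_growth_stretch(lam_l[compact],
                                                sig_sf[compact], params)
  }
  lam_old <- state$lam_g
  state <- update_collagen_growth(state, lam_gp, dt, params)
  if (is.finite(lam_g_rate_cap)) {
    cap <- lam_g_rate_cap * dt / 3600
    state$lam_g <- lam_old + pmin(pmax(state$lam_g - lam_old, -cap), cap)
  }
  if (turnover) state <- collagen_turnover(state, eps_l, dt, params, funcs)
  attr(state, "rate") <- matrix(rate, nrow(state$phi_sf))
  attr(state, "compacting") <- compact
  state
}

#' Material-point remodeling driver under prescribed cyclic deformation
#'
#' Advances a tissue state through the remodeling equations using the
#' cyclic approximation: each history entry provides the loaded and
#' unloaded deformation gradients of the cycle at that time; per-direction
#' strains, the triangular-wave strain-rate surrogate, and the analytic
#' preferred stress-fiber fractions are evaluated from them, and the state
#' relaxes accordingly between entries.
#'
#' @param F_history list of entries `list(time, F_loaded, F_unloaded)` with
#'   strictly increasing times (s).
#' @param params,funcs material parameters and response strategy.
#' @param fibers `fiber_directions`.
#' @param period cycle period, s.
#' @param state optional initial `tissue_state` (default: isotropic).
#' @param turnover logical; include collagen turnover.
#' @return list with `state` (final), `trajectory` (data frame: time,
#'   mean/max state measures, order parameters, max step change) and
#'   `states` (list of intermediate states).
#' @export
simulate_material_point <- function(F_history, params = material_params(),
                                    funcs = sf_response_functions(params),
                                    fibers = fiber_directions(),
                                    period = 0.85, state = NULL,
                                    turnover = TRUE) {
  times <- vapply(F_history, function(e) e$time, numeric(1))
  if (any(diff(times) <= 0)) stop("history times must be strictly increasing")
  if (is.null(state)) state <- tissue_state(fibers, params, npoints = 1L)
  dts <- diff(times)
  if (length(dts) && max(dts) > min(params$tau_sf, params$tau_lambda) / 2) {
    warning("remodeling step exceeds min(tau_sf, tau_lambda)/2; ",
            "trajectory accuracy may suffer")
  }
  gamma <- fibers$gamma
  rec <- vector("list", length(F_history))
  states <- vector("list", length(F_history))
  prev <- NULL
  for (k in seq_along(F_history)) {
    ent <- F_history[[k]]
    dl <- deformation_point(ent$F_loaded, fibers)
    du <- deformation_point(ent$F_unloaded, fibers)
    if (k > 1L) {
      state <- remodel_step(state,
                            matrix(dl$eps, 1), matrix(du$eps, 1),
                            matrix(dl$lam, 1),
                            dt = times[k] - times[k - 1L],
                            period = period, params = params, funcs = funcs,
                            turnover = turnover)
    }
    ssum <- function(phi) {
      tot <- sum(phi)
      if (tot <= 0) return(0)
      sum(phi * cos(2 * gamma)) / tot
    }
    delta <- if (is.null(prev)) NA_real_ else {
      max(abs(state$phi_sf - prev$phi_sf), abs(state$lam_g - prev$lam_g),
          abs(state$phi_cf - prev$phi_cf))
    }
    rec[[k]] <- data.frame(
      time = times[k],
      phi_mon = state$phi_mon,
      mean_phi_sf = mean(state$phi_sf),
      mean_lam_g = mean(state$lam_g),
      S_sf = ssum(state$phi_sf[1, ]),
      S_cf = ssum(state$phi_cf[1, ]),
      step_change = delta
    )
    states[[k]] <- state
    prev <- state
  }
  list(state = state, trajectory = do.call(rbind, rec), states = states)
}
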