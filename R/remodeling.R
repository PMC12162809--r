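## Staggered mechano-remodeling driver: alternate loaded/unloaded static
## solves at fixed tissue state, evaluate the cyclic stimulus per
## integration point, advance the remodeling state, repeat to equilibrium.

#' Loading / remodeling protocol
#'
#' @param condition `"pulmonary"` (2 kPa diastolic) or `"aortic"` (10 kPa,
#'   reached through a 2,4,6,8,10 kPa ramp over the first remodeling
#'   steps).
#' @param diastolic_pressure override of the plateau pressure, kPa.
#' @param ramp override of the per-step ramp pressures, kPa (must end at
#'   the plateau).
#' @param period loading cycle period, s.
#' @param remodel_step remodeling time step, hours.
#' @param max_duration maximum simulated time, days.
#' @param equilibrium_tol relative change threshold for equilibrium.
#' @param equilibrium_window trailing window for the equilibrium check,
#'   hours.
#' @return object of class `protocol`.
#' @export
protocol <- function(condition = c("pulmonary", "aortic"),
                     diastolic_pressure = NULL, ramp = NULL,
                     period = 0.85, remodel_step = 0.5,
                     max_duration = 60, equilibrium_tol = 1e-3,
                     equilibrium_window = 24) {
  condition <- match.arg(condition)
  dp <- diastolic_pressure %||% if (condition == "pulmonary") 2 else 10
  ramp <- ramp %||% if (condition == "aortic") seq(2, dp, by = 2) else dp
  if (abs(ramp[length(ramp)] - dp) > 1e-12) {
    stop("ramp must end at the diastolic pressure")
  }
  if (period <= 0) stop("period must be positive")
  structure(list(condition = condition, diastolic_pressure = dp,
                 ramp = ramp, period = period,
                 remodel_step = remodel_step,
                 max_duration = max_duration,
                 equilibrium_tol = equilibrium_tol,
                 equilibrium_window = equilibrium_window),
            class = "protocol")
}

#' Pressure applied at a given remodeling step
#' @param prot `protocol`. @param step step index (1-based).
#' @return pressure, kPa.
#' @export
protocol_pressure <- function(prot, step) {
  if (step <= length(prot$ramp)) prot$ramp[step] else prot$diastolic_pressure
}

#' Run the coupled mechanics--remodeling loop on a leaflet
#'
#' Each remodeling step solves the loaded (diastolic) and unloaded
#' equilibria at the current tissue state, evaluates per-point loaded and
#' unloaded fiber strains and the triangular-wave strain-rate surrogate,
#' advances stress-fiber fractions, collagen growth stretches and collagen
#' turnover by `remodel_step`, and records valve metrics. The loop stops at
#' equilibrium (trailing-window relative change of ROA and belly length
#' below tolerance) or at `max_duration`.
#'
#' @param mesh `leaflet_mesh`.
#' @param params `material_params`. @param prot `protocol`.
#' @param settings `solver_settings`. @param funcs response strategy.
#' @param fibers `fiber_directions`.
#' @param prealign_kappa optional initial collagen pre-alignment.
#' @param turnover include collagen turnover (default TRUE).
#' @param snapshot_dir optional directory for per-step VTU snapshots.
#' @param snapshot_every snapshot cadence in steps.
#' @return object of class `remodeling_history`: `history` data frame (one
#'   row per step), final `state`, final `loaded`/`unloaded` solutions,
#'   `equilibrium` flag.
#' @export
run_remodeling <- function(mesh, params = material_params(),
                           prot = protocol(), settings = solver_settings(),
                           funcs = sf_response_functions(params),
                           fibers = fiber_directions(),
                           prealign_kappa = NULL, turnover = TRUE,
                           snapshot_dir = NULL, snapshot_every = 10L) {
  field <- tissue_field(mesh, params, fibers, prealign_kappa)
  dt <- prot$remodel_step * 3600
  nsteps <- max(1L, ceiling(prot$max_duration * 24 / prot$remodel_step))
  gamma <- fibers$gamma
  u_l <- NULL; u_u <- NULL
  rows <- vector("list", nsteps)
  loaded <- unloaded <- NULL
  equilibrium <- FALSE
  ref_lengths <- profile_lengths(mesh)
  for (k in seq_len(nsteps)) {
    p_k <- protocol_pressure(prot, k)
    loaded <- tryCatch(
      solve_static(mesh, field, params,
                   bcs = boundary_conditions(pressure = p_k),
                   settings = settings, funcs = funcs, u0 = u_l),
      fe_nonconvergence = function(e) {
        stop(structure(class = c("remodeling_error", "error", "condition"),
                       list(message = sprintf("step %d (loaded, p=%.3g kPa): %s",
                                              k, p_k, conditionMessage(e)),
                            call = NULL, step = k,
                            history = do.call(rbind, rows[seq_len(k - 1L)]))))
      })
    unloaded <- tryCatch(
      unloaded_configuration(mesh, field, params, settings, funcs, u0 = u_u),
      fe_nonconvergence = function(e) {
        stop(structure(class = c("remodeling_error", "error", "condition"),
                       list(message = sprintf("step %d (unloaded): %s", k,
                                              conditionMessage(e)),
                            call = NULL, step = k,
                            history = do.call(rbind, rows[seq_len(k - 1L)]))))
      })
    u_l <- loaded$u; u_u <- unloaded$u

    ## advance the tissue state from the cyclic stimulus. The stress-fiber
    ## relaxation is under-relaxed to the staggered step scale: with
    ## tau_sf (5 min) far below any remodeling step, the exact update is a
    ## raw fixed-point iteration of the stimulus <-> fraction map, which
    ## rings; an effective time constant of twice the step damps it
    ## without moving fixed points (for dt <= tau_sf it is the exact
    ## integrator again).
    params_eff <- params
    params_eff$tau_sf <- max(params$tau_sf, 2 * dt)
    st <- remodel_step(field$state, loaded$eps, unloaded$eps, loaded$lam,
                       dt = dt, period = prot$period, params = params_eff,
                       funcs = funcs, turnover = turnover)
    field$state <- st
    field$rate <- attr(st, "rate")

    ## metrics
    lln <- profile_lengths(loaded)
    uln <- profile_lengths(unloaded)
    comp <- directional_compaction(unloaded)
    roa <- as.numeric(regurgitant_orifice_area(loaded))
    fs <- field_summaries(loaded)
    phi_cf_tot <- colSums(st$phi_cf)
    phi_sf_tot <- colSums(st$phi_sf)
    rows[[k]] <- data.frame(
      step = k, time_h = k * prot$remodel_step, pressure = p_k,
      roa = roa,
      belly_length_loaded = lln[["belly_profile_length"]],
      free_edge_length_loaded = lln[["free_edge_length"]],
      belly_length_unloaded = uln[["belly_profile_length"]],
      free_edge_length_unloaded = uln[["free_edge_length"]],
      compaction_circ = comp[["circumferential"]],
      compaction_rad = comp[["radial"]],
      peak_vm_global = fs$peak_von_mises[fs$region == "global"],
      peak_vm_commissure = fs$peak_von_mises[fs$region == "commissure"],
      peak_vm_belly = fs$peak_von_mises[fs$region == "belly"],
      peak_vm_tip = fs$peak_von_mises[fs$region == "tip"],
      S_cf = order_parameter(phi_cf_tot, fibers),
      S_sf = if (sum(phi_sf_tot) > 0) order_parameter(phi_sf_tot, fibers)
             else 0
    )
    if (!is.null(snapshot_dir) && k %% snapshot_every == 0L) {
      export_solution(loaded, file.path(snapshot_dir,
                                        sprintf("step_%04d.vtu", k)))
    }
    hist_so_far <- do.call(rbind, rows[seq_len(k)])
    if (k > length(prot$ramp) &&
        check_equilibrium(hist_so_far, tol = prot$equilibrium_tol,
                          window = prot$equilibrium_window)) {
      equilibrium <- TRUE
      rows <- rows[seq_len(k)]
      break
    }
  }
  history <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  structure(list(history = history, state = field$state, field = field,
                 loaded = loaded, unloaded = unloaded, mesh = mesh,
                 protocol = prot, equilibrium = equilibrium,
                 ref_lengths = ref_lengths),
            class = "remodeling_history")
}

#' Equilibrium detection on a remodeling history
#'
#' TRUE when the relative change of both the regurgitant orifice area and
#' the unloaded belly-profile length over the trailing window falls below
#' `tol`. ROA changes are measured relative to `max(mean ROA, 1 mm^2)` so
#' a closed valve (ROA = 0) does not block detection.
#'
#' @param history data frame with columns `time_h`, `roa`,
#'   `belly_length_unloaded`.
#' @param tol relative change threshold.
#' @param window trailing window, hours.
#' @return logical.
#' @export
check_equilibrium <- function(history, tol = 1e-3, window = 24) {
  if (nrow(history) < 2L) return(FALSE)
  t_end <- history$time_h[nrow(history)]
  win <- history[history$time_h > t_end - window, , drop = FALSE]
  if (nrow(win) < 2L) return(FALSE)
  if (history$time_h[2] - history$time_h[1] > 0 &&
      t_end < window) return(FALSE)  ## not enough elapsed time yet
  rel <- function(v, floor_) (max(v) - min(v)) / max(mean(abs(v)), floor_)
  rel(win$roa, 1) < tol && rel(win$belly_length_unloaded, 1) < tol
}

#' @export
print.remodeling_history <- function(x, ...) {
  h <- x$history
  n <- nrow(h)
  cat(sprintf("<remodeling_history> %s, %d steps (%.3g days), %s\n",
              x$protocol$condition, n, h$time_h[n] / 24,
              if (x$equilibrium) "equilibrated" else "max duration reached"))
  cat(sprintf("  final: ROA %.3g mm^2, belly %.4g mm (unloaded), S_cf %.3f\n",
              h$roa[n], h$belly_length_unloaded[n], h$S_cf[n]))
  invisible(x)
}
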