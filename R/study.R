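## Configuration-driven design study: geometry grids x pressure conditions
## x parameter variations, with per-cell fault tolerance, cost ranking,
## fixture generation and YAML config I/O.

#' Study configuration
#'
#' @param designs design families to evaluate (subset of `c(1, 2)`).
#' @param codes optional subset of two-letter geometry codes.
#' @param conditions subset of `c("pulmonary", "aortic")`.
#' @param variation one of `"baseline"`, `"coaptation+"`,
#'   `"contractility-"`, `"stiffness+10"`, `"thin"`, `"thick"`: the
#'   systematic parameter variations of the study (H 16.31 mm /
#'   tip extension 2.01 mm; sigma_max 20 kPa; k1 36.31 kPa with k2 12.91;
#'   thickness 0.4 mm; thickness 0.8 mm).
#' @param n_profile,n_span,n_layers,order mesh resolution and element
#'   order.
#' @param remodel_step,max_duration protocol overrides (hours / days).
#' @param settings `solver_settings`.
#' @param out_dir optional output directory (CSV + VTU snapshots).
#' @param material_overrides named list applied to `material_params()`.
#' @return object of class `study_config`.
#' @export
study_config <- function(designs = c(1L, 2L), codes = NULL,
                         conditions = c("pulmonary", "aortic"),
                         variation = "baseline",
                         n_profile = 14L, n_span = 14L, n_layers = 2L,
                         order = 2L, remodel_step = 0.5, max_duration = 60,
                         settings = solver_settings(), out_dir = NULL,
                         material_overrides = list()) {
  variation <- match.arg(variation,
                         c("baseline", "coaptation+", "contractility-",
                           "stiffness+10", "thin", "thick"))
  conditions <- match.arg(conditions, c("pulmonary", "aortic"),
                          several.ok = TRUE)
  bad <- setdiff(names(material_overrides),
                 names(formals(material_params)))
  if (length(bad)) stop("unknown material parameter(s): ",
                        paste(bad, collapse = ", "))
  structure(list(designs = designs, codes = codes, conditions = conditions,
                 variation = variation, n_profile = n_profile,
                 n_span = n_span, n_layers = n_layers, order = order,
                 remodel_step = remodel_step, max_duration = max_duration,
                 settings = settings, out_dir = out_dir,
                 material_overrides = material_overrides),
            class = "study_config")
}

## geometry/material adjustments of a named variation
apply_variation <- function(variation, params_geo, params_mat) {
  switch(variation,
    "baseline" = NULL,
    "coaptation+" = {
      if (inherits(params_geo, "design1_params")) {
        params_geo$tip_extension <- 2.01
      } else {
        params_geo$H <- 16.31
      }
    },
    "contractility-" = params_mat$sigma_max <- 20,
    "stiffness+10" = {
      params_mat$k1_cf <- 36.31; params_mat$k2_cf <- 12.91
    },
    "thin" = params_geo$thickness <- 0.4,
    "thick" = params_geo$thickness <- 0.8)
  list(geo = params_geo, mat = params_mat)
}

## stable hash of a configuration cell (provenance)
config_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, version = 2)
  unname(tools::md5sum(f))
}

#' Run the design-of-experiments study
#'
#' Executes geometry generation, remodeling and metric extraction for
#' every (design, geometry code, condition) cell of the configured grid.
#' Cells whose mechanics fail to converge are recorded as structured
#' non-convergence outcomes rather than aborting the batch. Cost
#' components (peak stress, ROA; targets 0) are appended per
#' (design, condition) batch.
#'
#' @param config `study_config`.
#' @return object of class `study_result`: data frame `results` (one row
#'   per cell) and the `config`.
#' @export
run_study <- function(config = study_config()) {
  rows <- list()
  for (design in config$designs) {
    grid <- enumerate_design_grid(design)
    if (!is.null(config$codes)) {
      grid <- Filter(function(e) e$code %in% config$codes, grid)
    }
    for (entry in grid) {
      var <- apply_variation(config$variation, entry$params,
                             do.call(material_params,
                                     config$material_overrides))
      mesh <- build_leaflet(list(code = entry$code, params = var$geo),
                            n_profile = config$n_profile,
                            n_span = config$n_span,
                            n_layers = config$n_layers,
                            order = config$order)
      for (cond in config$conditions) {
        prot <- protocol(cond, remodel_step = config$remodel_step,
                         max_duration = config$max_duration)
        cell_id <- sprintf("design%d_%s_%s_%s", design, entry$code, cond,
                           config$variation)
        hash <- config_hash(list(design = design, code = entry$code,
                                 cond = cond, var = config$variation,
                                 geo = var$geo, mat = var$mat,
                                 prot = prot,
                                 mesh = c(config$n_profile, config$n_span,
                                          config$n_layers, config$order)))
        res <- tryCatch(
          run_remodeling(mesh, var$mat, prot, config$settings,
                         snapshot_dir = config$out_dir),
          remodeling_error = function(e) e)
        if (inherits(res, "remodeling_error")) {
          rows[[cell_id]] <- data.frame(
            design = design, code = entry$code, condition = cond,
            variation = config$variation, converged = FALSE,
            failed_step = res$step, message = conditionMessage(res),
            roa = NA_real_, belly_length_unloaded = NA_real_,
            free_edge_length_unloaded = NA_real_,
            compaction_circ = NA_real_, compaction_rad = NA_real_,
            peak_stress = NA_real_, peak_vm_commissure = NA_real_,
            S_cf = NA_real_, S_sf = NA_real_, equilibrium = FALSE,
            steps = NA_integer_, config_hash = hash)
          next
        }
        h <- res$history[nrow(res$history), ]
        rows[[cell_id]] <- data.frame(
          design = design, code = entry$code, condition = cond,
          variation = config$variation, converged = TRUE,
          failed_step = NA_integer_, message = "",
          roa = h$roa,
          belly_length_unloaded = h$belly_length_unloaded,
          free_edge_length_unloaded = h$free_edge_length_unloaded,
          compaction_circ = h$compaction_circ,
          compaction_rad = h$compaction_rad,
          peak_stress = h$peak_vm_global,
          peak_vm_commissure = h$peak_vm_commissure,
          S_cf = h$S_cf, S_sf = h$S_sf,
          equilibrium = res$equilibrium, steps = nrow(res$history),
          config_hash = hash)
        if (!is.null(config$out_dir)) {
          utils::write.csv(res$history,
                           file.path(config$out_dir,
                                     paste0(cell_id, "_history.csv")),
                           row.names = FALSE)
        }
      }
    }
  }
  results <- do.call(rbind, rows)
  rownames(results) <- NULL
  ## cost per (design, condition) batch over converged cells
  results$C_tot <- NA_real_
  for (d in unique(results$design)) for (cc in unique(results$condition)) {
    sel <- which(results$design == d & results$condition == cc &
                   results$converged)
    if (length(sel) >= 2L) {
      batch <- results[sel, c("peak_stress", "roa")]
      cb <- tryCatch(cost_evaluate(batch, cost_spec(
        targets = c(peak_stress = 0, roa = 0))), warning = function(w) NULL,
        error = function(e) NULL)
      if (!is.null(cb)) results$C_tot[sel] <- cb$C_tot
    }
  }
  if (!is.null(config$out_dir)) {
    utils::write.csv(results, file.path(config$out_dir, "study_results.csv"),
                     row.names = FALSE)
  }
  structure(list(results = results, config = config),
            class = "study_result")
}

#' @export
print.study_result <- function(x, ...) {
  r <- x$results
  cat(sprintf("<study_result> %d cells (%d converged), variation %s\n",
              nrow(r), sum(r$converged), x$config$variation))
  ok <- r[r$converged & !is.na(r$C_tot), ]
  if (nrow(ok)) {
    ok <- ok[order(ok$C_tot), ]
    cat("  best designs by cost:\n")
    print(utils::head(ok[, c("design", "code", "condition", "roa",
                             "peak_stress", "C_tot")], 5))
  }
  invisible(x)
}

## ---- fixtures ------------------------------------------------------------

## rectangular block mesh (flat mid-surface), used by patch/strip fixtures
block_mesh <- function(lx = 1, ly = 1, thickness = 0.5, nx = 1L, ny = 1L,
                       n_layers = 1L, order = 1L, distort = 0) {
  surf <- function(ti, sj) {
    pts <- cbind(ti * lx, sj * ly, 0)
    if (distort > 0) {
      ## deterministic interior warp (keeps the boundary planar)
      b <- ti * (1 - ti) * sj * (1 - sj)
      pts[, 1] <- pts[, 1] + distort * lx * b * sin(3 * sj)
      pts[, 2] <- pts[, 2] + distort * ly * b * cos(2 * ti)
    }
    pts
  }
  mesh <- build_solid_mesh(surf, nt = nx + 1L, ns = ny + 1L,
                           thickness = thickness, n_layers = n_layers,
                           order = order, collapse_i1 = FALSE,
                           edge_map = list(imin = "attachment_edge",
                                           jmin = "symmetry_plane",
                                           imax = "free_edge"),
                           meta = list(design = "block",
                                       params = list(R = NULL)),
                           smooth_dirs = 0)
  mesh$regions <- factor(rep("belly", nrow(mesh$elems)),
                         levels = c("belly", "commissure", "tip", "other"))
  with_fe_cache(mesh)
}

#' Deterministic test fixtures
#'
#' `"patch"`: a distorted two-element brick patch; `"strip"`: a clamped
#' rectangular strip (10 x 5 x 0.6 mm by default) for pressure loading;
#' `"point_histories"`: prescribed deformation-gradient cycles (uniaxial,
#' equibiaxial, or cyclic loaded/unloaded pairs at the 0.85 s period) for
#' material-point tests. All fixtures are reproducible (no RNG).
#'
#' @param kind fixture kind.
#' @param ... overrides: block dimensions / element counts for meshes;
#'   `stretch`, `n_steps`, `dt`, `period`, `mode` for histories.
#' @return a `leaflet_mesh` or a list of history entries.
#' @export
make_fixtures <- function(kind = c("patch", "strip", "point_histories"),
                          ...) {
  kind <- match.arg(kind)
  args <- list(...)
  if (kind == "patch") {
    do.call(block_mesh, utils::modifyList(
      list(lx = 2, ly = 1, thickness = 1, nx = 2L, ny = 1L,
           n_layers = 1L, order = 1L, distort = 0.15), args))
  } else if (kind == "strip") {
    do.call(block_mesh, utils::modifyList(
      list(lx = 10, ly = 5, thickness = 0.6, nx = 5L, ny = 3L,
           n_layers = 1L, order = 1L), args))
  } else {
    stretch <- args$stretch %||% 1.05
    n_steps <- args$n_steps %||% 20L
    dt <- args$dt %||% 1800
    mode <- args$mode %||% "cyclic"
    Fl <- switch(mode,
                 uniaxial = diag(c(stretch, 1, 1)),
                 equibiaxial = diag(c(stretch, stretch, 1)),
                 cyclic = diag(c(stretch, stretch, 1)))
    Fu <- if (mode == "cyclic") diag(3) else Fl
    lapply(seq_len(n_steps), function(k) {
      list(time = (k - 1L) * dt, F_loaded = Fl, F_unloaded = Fu)
    })
  }
}

## ---- YAML config I/O -----------------------------------------------------

#' Read a study configuration from YAML
#'
#' Top-level keys mirror [study_config()] arguments; `material` is a named
#' block of `material_params()` overrides and `solver` of
#' [solver_settings()] arguments.
#'
#' @param file YAML path.
#' @return `study_config`.
#' @export
read_study_config <- function(file) {
  y <- yaml::read_yaml(file)
  settings <- do.call(solver_settings, y$solver %||% list())
  args <- y[setdiff(names(y), c("solver", "material"))]
  args$settings <- settings
  args$material_overrides <- y$material %||% list()
  do.call(study_config, args)
}

#' Write a study configuration to YAML
#' @param config `study_config`. @param file output path.
#' @return file path, invisibly.
#' @export
write_study_config <- function(config, file) {
  y <- config[setdiff(names(config), c("settings", "material_overrides"))]
  y$solver <- config$settings[names(config$settings) != "contact_method"]
  y$solver$contact_method <- config$settings$contact_method
  y$material <- config$material_overrides
  yaml::write_yaml(y, file)
  invisible(file)
}
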