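## Design-of-experiments grids: nine geometries per design family.

#' Enumerate the nine-geometry design grid of a leaflet family
#'
#' Three levels per shape parameter, fully crossed. Two-letter codes: the
#' first letter encodes the attachment-edge level, the second the
#' belly-curvature level.
#'
#' Design 1: attachment `N`/`M`/`W` (narrow to wide commissures,
#' `D11 = 0, 0.5, 1`) crossed with belly `s`/`m`/`c` (straight to curved,
#' the guiding point sagging 0 / 2.5 / 5 mm below the straight chord).
#' Design 2: attachment `L`/`M`/`H` (`D21 = 2.8, 3.4, 4.0`) crossed with
#' belly `l`/`m`/`h` (`D22 = 2.4, 1.9, 1.4`; smaller D22 = more curved
#' belly).
#'
#' @param design 1 or 2.
#' @param attachment_levels,belly_levels optional numeric length-3
#'   overrides of the parameter levels (Design 1 belly levels are sag
#'   values below the chord, mm).
#' @param R,H,thickness shared geometry parameters.
#' @return list of 9 entries `list(code, params)`, attachment level
#'   varying slowest.
#' @export
enumerate_design_grid <- function(design = 1L,
                                  attachment_levels = NULL,
                                  belly_levels = NULL,
                                  R = 11.5, H = 14.3, thickness = 0.6) {
  design <- as.integer(design)
  if (design == 1L) {
    att <- attachment_levels %||% c(0, 0.5, 1)
    bel <- belly_levels %||% c(0, 2.5, 5)
    att_code <- c("N", "M", "W"); bel_code <- c("s", "m", "c")
  } else if (design == 2L) {
    att <- attachment_levels %||% c(2.8, 3.4, 4.0)
    bel <- belly_levels %||% c(2.4, 1.9, 1.4)
    att_code <- c("L", "M", "H"); bel_code <- c("l", "m", "h")
  } else stop("design must be 1 or 2")
  if (length(att) != 3L || length(bel) != 3L) {
    stop("exactly 3 levels per parameter are required")
  }
  out <- list()
  for (a in 1:3) for (b in 1:3) {
    code <- paste0(att_code[a], bel_code[b])
    params <- if (design == 1L) {
      p <- design1_params(R = R, H = H, D11 = att[a], thickness = thickness)
      p$D12 <- design1_chord_d12(p) - bel[b]
      p
    } else {
      design2_params(R = R, H = H, D21 = att[a], D22 = bel[b],
                     thickness = thickness)
    }
    out[[length(out) + 1L]] <- list(code = code, params = params)
  }
  out
}

#' Build the leaflet mesh for any grid entry
#'
#' @param entry an element of [enumerate_design_grid()] output, or a bare
#'   `design1_params` / `design2_params` object.
#' @param ... passed to the design-specific builder (sampling, order, ...).
#' @return `leaflet_mesh`.
#' @export
build_leaflet <- function(entry, ...) {
  params <- if (!is.null(entry$params)) entry$params else entry
  mesh <- if (inherits(params, "design1_params")) {
    build_design1_leaflet(params, ...)
  } else if (inherits(params, "design2_params")) {
    build_design2_leaflet(params, ...)
  } else stop("not a design parameter object")
  mesh$meta$code <- entry$code %||% NA_character_
  mesh
}
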