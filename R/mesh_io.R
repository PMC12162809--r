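## Mesh and field export: XML VTK unstructured grids (VTU, ascii) and
## Abaqus-dialect .inp decks. Thin serializers; numerics live elsewhere.

## VTK cell types: 12 = hexahedron, 25 = quadratic hexahedron
vtk_cell_type <- function(order) if (order == 1L) 12L else 25L

#' Export a leaflet mesh (with optional fields) to VTU or Abaqus .inp
#'
#' VTU files carry optional point data (e.g. displacements) and cell data
#' (e.g. region labels, per-element stress summaries). The .inp deck writes
#' NODE/ELEMENT blocks with C3D8/C3D20 connectivity ordering plus one NSET
#' per named node set and one ELSET per (non-empty) region.
#'
#' @param mesh `leaflet_mesh`.
#' @param file output path.
#' @param format `"vtu"` or `"inp"` (default from the file extension).
#' @param point_data named list of per-node vectors/matrices.
#' @param cell_data named list of per-element vectors.
#' @return the file path, invisibly.
#' @export
export_mesh <- function(mesh, file, format = NULL,
                        point_data = list(), cell_data = list()) {
  format <- format %||% tolower(tools::file_ext(file))
  switch(format,
         vtu = write_vtu(mesh, file, point_data, cell_data),
         inp = write_inp(mesh, file),
         stop("unsupported mesh format: ", format))
  invisible(file)
}

write_vtu <- function(mesh, file, point_data = list(), cell_data = list()) {
  nn <- nrow(mesh$nodes); nel <- nrow(mesh$elems)
  nne <- ncol(mesh$elems)
  con <- file(file, "w")
  on.exit(close(con))
  w <- function(...) cat(..., "\n", sep = "", file = con)
  num <- function(x) paste(format(x, digits = 17, trim = TRUE,
                                  scientific = FALSE), collapse = " ")
  w('<?xml version="1.0"?>')
  w('<VTKFile type="UnstructuredGrid" version="0.1" byte_order="LittleEndian">')
  w('<UnstructuredGrid>')
  w(sprintf('<Piece NumberOfPoints="%d" NumberOfCells="%d">', nn, nel))
  w('<Points><DataArray type="Float64" NumberOfComponents="3" format="ascii">')
  for (i in seq_len(nn)) w(num(mesh$nodes[i, ]))
  w('</DataArray></Points>')
  w('<Cells>')
  w('<DataArray type="Int64" Name="connectivity" format="ascii">')
  for (e in seq_len(nel)) w(paste(mesh$elems[e, ] - 1L, collapse = " "))
  w('</DataArray>')
  w('<DataArray type="Int64" Name="offsets" format="ascii">')
  w(paste(seq_len(nel) * nne, collapse = " "))
  w('</DataArray>')
  w('<DataArray type="UInt8" Name="types" format="ascii">')
  w(paste(rep(vtk_cell_type(mesh$order), nel), collapse = " "))
  w('</DataArray>')
  w('</Cells>')
  if (length(point_data)) {
    w('<PointData>')
    for (nm in names(point_data)) {
      v <- point_data[[nm]]
      nc <- if (is.matrix(v)) ncol(v) else 1L
      w(sprintf('<DataArray type="Float64" Name="%s" NumberOfComponents="%d" format="ascii">',
                nm, nc))
      if (is.matrix(v)) for (i in seq_len(nrow(v))) w(num(v[i, ]))
      else w(num(v))
      w('</DataArray>')
    }
    w('</PointData>')
  }
  if (length(cell_data)) {
    w('<CellData>')
    for (nm in names(cell_data)) {
      v <- as.numeric(cell_data[[nm]])
      w(sprintf('<DataArray type="Float64" Name="%s" format="ascii">', nm))
      w(num(v))
      w('</DataArray>')
    }
    w('</CellData>')
  }
  w('</Piece></UnstructuredGrid></VTKFile>')
}

#' Read node coordinates and connectivity back from a VTU file
#'
#' Minimal reader for round-trip verification of [export_mesh()] output.
#'
#' @param file VTU path.
#' @return list with `nodes` (n x 3) and `elems` (1-based connectivity).
#' @export
read_vtu <- function(file) {
  doc <- xml2::read_xml(file)
  piece <- xml2::xml_find_first(doc, ".//Piece")
  nn <- as.integer(xml2::xml_attr(piece, "NumberOfPoints"))
  nel <- as.integer(xml2::xml_attr(piece, "NumberOfCells"))
  pts <- xml2::xml_text(xml2::xml_find_first(doc, ".//Points/DataArray"))
  nodes <- matrix(as.numeric(strsplit(trimws(pts), "\\s+")[[1]]),
                  ncol = 3, byrow = TRUE)
  conn_node <- xml2::xml_find_first(doc,
    ".//Cells/DataArray[@Name='connectivity']")
  conn <- as.integer(strsplit(trimws(xml2::xml_text(conn_node)), "\\s+")[[1]])
  elems <- matrix(conn + 1L, nrow = nel, byrow = TRUE)
  stopifnot(nrow(nodes) == nn)
  list(nodes = nodes, elems = elems)
}

write_inp <- function(mesh, file) {
  con <- file(file, "w")
  on.exit(close(con))
  w <- function(...) cat(..., "\n", sep = "", file = con)
  w("*HEADING")
  w(sprintf("** leaflet mesh (%s), %d nodes, %d elements",
            mesh$meta$design %||% "generic", nrow(mesh$nodes),
            nrow(mesh$elems)))
  w("*NODE")
  for (i in seq_len(nrow(mesh$nodes))) {
    w(sprintf("%d, %.10g, %.10g, %.10g", i, mesh$nodes[i, 1],
              mesh$nodes[i, 2], mesh$nodes[i, 3]))
  }
  etype <- if (mesh$order == 1L) "C3D8" else "C3D20"
  w(sprintf("*ELEMENT, TYPE=%s", etype))
  for (e in seq_len(nrow(mesh$elems))) {
    ids <- mesh$elems[e, ]
    ## Abaqus limits 16 entries per line
    line <- paste(c(e, ids), collapse = ", ")
    if (length(ids) > 15L) {
      w(paste(c(e, ids[1:15]), collapse = ", "), ",")
      w(paste(ids[16:length(ids)], collapse = ", "))
    } else {
      w(line)
    }
  }
  for (nm in names(mesh$sets)) {
    ids <- mesh$sets[[nm]]
    if (!length(ids)) next
    w(sprintf("*NSET, NSET=%s", toupper(nm)))
    for (chunk in split(ids, ceiling(seq_along(ids) / 16))) {
      w(paste(chunk, collapse = ", "))
    }
  }
  if (!is.null(mesh$regions)) {
    for (lv in levels(mesh$regions)) {
      ids <- which(mesh$regions == lv)
      if (!length(ids)) next
      w(sprintf("*ELSET, ELSET=REGION_%s", toupper(lv)))
      for (chunk in split(ids, ceiling(seq_along(ids) / 16))) {
        w(paste(chunk, collapse = ", "))
      }
    }
  }
}

#' Write an FE solution snapshot to VTU
#'
#' Deformed coordinates with displacement point data and per-element von
#' Mises stress / region cell data.
#'
#' @param sol `fe_solution`. @param file output path.
#' @return file path, invisibly.
#' @export
export_solution <- function(sol, file) {
  mesh <- sol$mesh
  vm <- von_mises(sol$sigma)
  ## per-element max over integration points
  vm_el <- tapply(vm, sol$idx_e, max)
  export_mesh(mesh, file, format = "vtu",
              point_data = list(displacement = sol$u),
              cell_data = list(von_mises_max = as.numeric(vm_el),
                               region = as.integer(mesh$regions)))
}
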