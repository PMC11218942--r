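# VTK unstructured-grid I/O (tetrahedra, cell type 10) in two flavours:
# legacy ASCII .vtk and XML ASCII .vtu. Fields travel as point-data arrays
# "pressure" (scalar) and "velocity" (3-vector); cap labels as the integer
# cell-data array "cap_id" on boundary triangle cells (type 5):
# 0 = wall, 1 = inlet, 2 = outlet_left, 3 = outlet_right.

.cap_levels <- c(inlet = 1L, outlet_left = 2L, outlet_right = 3L)

# assemble the cell block: tets first, then boundary triangles with cap ids
.vtk_cells <- function(mesh) {
  surf <- extract_surface(mesh)
  ntet <- nrow(mesh$tets)
  tri <- surf$triangles
  cap_id <- rep(0L, nrow(tri))
  if (length(mesh$cap_faces)) {
    tkey <- .face_key(tri)
    for (nm in names(mesh$cap_faces)) {
      k <- .face_key(mesh$cap_faces[[nm]])
      cap_id[tkey %in% k] <- .cap_levels[[nm]]
    }
  }
  list(tets = mesh$tets, tris = tri, cap_id = cap_id, ntet = ntet)
}

.vtk_split_cells <- function(conn_list, types, cap_id) {
  is_tet <- types == 10L
  is_tri <- types == 5L
  tets <- do.call(rbind, conn_list[is_tet])
  cap_faces <- list()
  if (any(is_tri) && !is.null(cap_id)) {
    tris <- do.call(rbind, conn_list[is_tri])
    cap_tri <- cap_id[is_tri]
    for (nm in names(.cap_levels)) {
      sel <- cap_tri == .cap_levels[[nm]]
      if (any(sel)) cap_faces[[nm]] <- tris[sel, , drop = FALSE]
    }
  }
  list(tets = tets, cap_faces = cap_faces)
}

#' Write a volume mesh (plus optional fields) to VTK
#'
#' Format is chosen from the file extension: `.vtu` (XML ASCII) or `.vtk`
#' (legacy ASCII).
#'
#' @param mesh a `volume_mesh`.
#' @param path output file path ending in `.vtu` or `.vtk`.
#' @param fields optional `field_set` aligned with the mesh.
#' @return `path`, invisibly.
#' @export
write_mesh_vtk <- function(mesh, path, fields = NULL) {
  if (grepl("\\.vtu$", path)) .write_vtu(mesh, path, fields)
  else if (grepl("\\.vtk$", path)) .write_vtk_legacy(mesh, path, fields)
  else stop("unsupported mesh extension (use .vtu or .vtk): ", path)
  invisible(path)
}

.fmt3 <- function(m) sprintf("%.17g %.17g %.17g", m[, 1], m[, 2], m[, 3])

.write_vtk_legacy <- function(mesh, path, fields) {
  cb <- .vtk_cells(mesh)
  ncell <- cb$ntet + nrow(cb$tris)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "hemomesh unstructured grid",
               "ASCII", "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", nrow(mesh$nodes))), con)
  writeLines(.fmt3(mesh$nodes), con)
  writeLines(sprintf("CELLS %d %d", ncell, 5L * cb$ntet + 4L * nrow(cb$tris)), con)
  t0 <- cb$tets - 1L
  writeLines(sprintf("4 %d %d %d %d", t0[, 1], t0[, 2], t0[, 3], t0[, 4]), con)
  if (nrow(cb$tris)) {
    tr0 <- cb$tris - 1L
    writeLines(sprintf("3 %d %d %d", tr0[, 1], tr0[, 2], tr0[, 3]), con)
  }
  writeLines(sprintf("CELL_TYPES %d", ncell), con)
  writeLines(as.character(c(rep(10L, cb$ntet), rep(5L, nrow(cb$tris)))), con)
  writeLines(sprintf("CELL_DATA %d", ncell), con)
  writeLines(c("SCALARS cap_id int 1", "LOOKUP_TABLE default"), con)
  writeLines(as.character(c(rep(0L, cb$ntet), cb$cap_id)), con)
  if (!is.null(fields)) {
    writeLines(sprintf("POINT_DATA %d", nrow(mesh$nodes)), con)
    writeLines(c("SCALARS pressure double 1", "LOOKUP_TABLE default"), con)
    writeLines(sprintf("%.17g", fields$pressure), con)
    writeLines("VECTORS velocity double", con)
    writeLines(.fmt3(fields$velocity), con)
  }
}

.write_vtu <- function(mesh, path, fields) {
  cb <- .vtk_cells(mesh)
  ncell <- cb$ntet + nrow(cb$tris)
  conn <- c(t(cb$tets - 1L), t(cb$tris - 1L))
  offs <- cumsum(c(rep(4L, cb$ntet), rep(3L, nrow(cb$tris))))
  types <- c(rep(10L, cb$ntet), rep(5L, nrow(cb$tris)))
  da <- function(name, type, ncomp, values) {
    c(sprintf('<DataArray type="%s" Name="%s" NumberOfComponents="%d" format="ascii">',
              type, name, ncomp),
      paste(values, collapse = " "), "</DataArray>")
  }
  lines <- c(
    '<?xml version="1.0"?>',
    '<VTKFile type="UnstructuredGrid" version="0.1" byte_order="LittleEndian">',
    "<UnstructuredGrid>",
    sprintf('<Piece NumberOfPoints="%d" NumberOfCells="%d">', nrow(mesh$nodes), ncell),
    "<Points>",
    da("Points", "Float64", 3L, .fmt3(mesh$nodes)),
    "</Points>", "<Cells>",
    da("connectivity", "Int64", 1L, conn),
    da("offsets", "Int64", 1L, offs),
    da("types", "UInt8", 1L, types),
    "</Cells>",
    "<CellData>",
    da("cap_id", "Int32", 1L, c(rep(0L, cb$ntet), cb$cap_id)),
    "</CellData>")
  if (!is.null(fields)) {
    lines <- c(lines, "<PointData>",
               da("pressure", "Float64", 1L, sprintf("%.17g", fields$pressure)),
               da("velocity", "Float64", 3L, .fmt3(fields$velocity)),
               "</PointData>")
  }
  lines <- c(lines, "</Piece>", "</UnstructuredGrid>", "</VTKFile>")
  writeLines(lines, path)
}

#' Read a volume mesh (plus fields if present) from VTK
#'
#' @param path `.vtu` or `.vtk` file written by [write_mesh_vtk()] (or any
#'   ASCII file restricted to tet cells, optional boundary triangles with a
#'   `cap_id` cell array, and the `pressure`/`velocity` point arrays).
#' @param validate run [validate_mesh()] on the result.
#' @return list with `mesh` (`volume_mesh`) and `fields` (`field_set` or NULL).
#' @export
read_mesh_vtk <- function(path, validate = TRUE) {
  if (grepl("\\.vtu$", path)) .read_vtu(path, validate)
  else if (grepl("\\.vtk$", path)) .read_vtk_legacy(path, validate)
  else stop("unsupported mesh extension (use .vtu or .vtk): ", path)
}

.read_vtk_legacy <- function(path, validate) {
  lines <- readLines(path)
  toks <- function(s) strsplit(trimws(s), "\\s+")[[1]]
  ip <- grep("^POINTS", lines)[1]
  npt <- as.integer(toks(lines[ip])[2])
  num <- scan(text = lines[(ip + 1):length(lines)], what = double(),
              n = 3L * npt, quiet = TRUE)
  nodes <- matrix(num, ncol = 3L, byrow = TRUE)
  ic <- grep("^CELLS", lines)[1]
  ncell <- as.integer(toks(lines[ic])[2])
  conn_list <- vector("list", ncell)
  for (i in seq_len(ncell)) {
    v <- as.integer(toks(lines[ic + i]))
    conn_list[[i]] <- v[-1] + 1L
  }
  it <- grep("^CELL_TYPES", lines)[1]
  types <- scan(text = lines[(it + 1):length(lines)], what = integer(),
                n = ncell, quiet = TRUE)
  cap_id <- NULL
  icd <- grep("^CELL_DATA", lines)
  if (length(icd)) {
    j <- grep("^SCALARS cap_id", lines)
    if (length(j)) cap_id <- scan(text = lines[(j[1] + 2):length(lines)],
                                  what = integer(), n = ncell, quiet = TRUE)
  }
  fields <- NULL
  ipd <- grep("^POINT_DATA", lines)
  if (length(ipd)) {
    jp <- grep("^SCALARS pressure", lines)
    jv <- grep("^VECTORS velocity", lines)
    if (length(jp) && length(jv)) {
      p <- scan(text = lines[(jp[1] + 2):length(lines)], what = double(),
                n = npt, quiet = TRUE)
      v <- scan(text = lines[(jv[1] + 1):length(lines)], what = double(),
                n = 3L * npt, quiet = TRUE)
      fields <- field_set(p, matrix(v, ncol = 3L, byrow = TRUE))
    }
  }
  sp <- .vtk_split_cells(conn_list, types, cap_id)
  list(mesh = volume_mesh(nodes, sp$tets, sp$cap_faces, validate = validate),
       fields = fields)
}

.read_vtu <- function(path, validate) {
  doc <- xml2::read_xml(path)
  arr <- function(xpath) {
    nd <- xml2::xml_find_first(doc, xpath)
    if (inherits(nd, "xml_missing")) return(NULL)
    scan(text = xml2::xml_text(nd), what = double(), quiet = TRUE)
  }
  pts <- arr("//Points/DataArray[@Name='Points']")
  nodes <- matrix(pts, ncol = 3L, byrow = TRUE)
  conn <- as.integer(arr("//Cells/DataArray[@Name='connectivity']")) + 1L
  offs <- as.integer(arr("//Cells/DataArray[@Name='offsets']"))
  types <- as.integer(arr("//Cells/DataArray[@Name='types']"))
  starts <- c(1L, head(offs, -1L) + 1L)
  conn_list <- Map(function(s, e) conn[s:e], starts, offs)
  cap_id <- arr("//CellData/DataArray[@Name='cap_id']")
  if (!is.null(cap_id)) cap_id <- as.integer(cap_id)
  p <- arr("//PointData/DataArray[@Name='pressure']")
  v <- arr("//PointData/DataArray[@Name='velocity']")
  fields <- if (!is.null(p) && !is.null(v))
    field_set(p, matrix(v, ncol = 3L, byrow = TRUE)) else NULL
  sp <- .vtk_split_cells(conn_list, types, cap_id)
  list(mesh = volume_mesh(nodes, sp$tets, sp$cap_faces, validate = validate),
       fields = fields)
}
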