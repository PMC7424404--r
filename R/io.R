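#' Write a labeled tetrahedral mesh as ASCII VTU
#'
#' Writes an XML VTK unstructured-grid file with the tissue label as element
#' data and (optionally) a per-node displacement field.
#'
#' @param mesh a [tet_mesh()]
#' @param path output file path (.vtu)
#' @param displacement optional n x 3 matrix written as a point-data vector
#'   field named \code{"displacement"}
#' @return \code{path}, invisibly
#' @export
write_vtu <- function(mesh, path, displacement = NULL) {
  n <- nrow(mesh$nodes); m <- nrow(mesh$elems)
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) cat(..., "\n", sep = "", file = con)
  num <- function(x) paste(format(x, digits = 12, trim = TRUE, scientific = FALSE),
                           collapse = " ")
  w('<?xml version="1.0"?>')
  w('<VTKFile type="UnstructuredGrid" version="0.1" byte_order="LittleEndian">')
  w('<UnstructuredGrid>')
  w(sprintf('<Piece NumberOfPoints="%d" NumberOfCells="%d">', n, m))
  w('<Points><DataArray type="Float64" NumberOfComponents="3" format="ascii">')
  w(paste(apply(mesh$nodes, 1, num), collapse = "\n"))
  w('</DataArray></Points>')
  w('<Cells>')
  w('<DataArray type="Int32" Name="connectivity" format="ascii">')
  w(paste(apply(mesh$elems - 1L, 1, paste, collapse = " "), collapse = "\n"))
  w('</DataArray>')
  w('<DataArray type="Int32" Name="offsets" format="ascii">')
  w(paste(seq_len(m) * 4L, collapse = " "))
  w('</DataArray>')
  w('<DataArray type="UInt8" Name="types" format="ascii">')
  w(paste(rep(10L, m), collapse = " "))
  w('</DataArray>')
  w('</Cells>')
  w('<CellData Scalars="tissue">')
  w('<DataArray type="Int32" Name="tissue" format="ascii">')
  w(paste(ifelse(mesh$labels == "bone", 1L, 2L), collapse = " "))
  w('</DataArray>')
  w('</CellData>')
  if (!is.null(displacement)) {
    stopifnot(nrow(displacement) == n)
    w('<PointData Vectors="displacement">')
    w('<DataArray type="Float64" Name="displacement" NumberOfComponents="3" format="ascii">')
    w(paste(apply(displacement, 1, num), collapse = "\n"))
    w('</DataArray>')
    w('</PointData>')
  }
  w('</Piece>')
  w('</UnstructuredGrid>')
  w('</VTKFile>')
  invisible(path)
}

#' Write a triangulated surface as ASCII STL
#' @param surface a [tri_surface()]
#' @param path output path (.stl)
#' @param name solid name
#' @return \code{path}, invisibly
#' @export
write_stl <- function(surface, path, name = "surface") {
  cr <- .tri_cross(surface)
  nrm <- cr / pmax(sqrt(rowSums(cr^2)), .Machine$double.eps)
  v <- surface$vertices; f <- surface$faces
  fmt <- function(p) sprintf("%.9g %.9g %.9g", p[, 1], p[, 2], p[, 3])
  lines <- c(
    paste("solid", name),
    as.vector(rbind(
      paste("  facet normal", fmt(nrm)),
      "    outer loop",
      paste("      vertex", fmt(v[f[, 1], , drop = FALSE])),
      paste("      vertex", fmt(v[f[, 2], , drop = FALSE])),
      paste("      vertex", fmt(v[f[, 3], , drop = FALSE])),
      "    endloop",
      "  endfacet")),
    paste("endsolid", name))
  writeLines(lines, path)
  invisible(path)
}

#' Read an ASCII STL surface
#'
#' Vertices are merged exactly (bitwise identical coordinates).
#'
#' @param path STL file path
#' @return a [tri_surface()]
#' @export
read_stl <- function(path) {
  txt <- readLines(path)
  vx <- grep("^\\s*vertex", txt, value = TRUE)
  if (!length(vx)) stop("no vertices found in ", path)
  coords <- do.call(rbind, lapply(strsplit(trimws(vx), "\\s+"), function(p) {
    as.numeric(p[2:4])
  }))
  key <- paste(coords[, 1], coords[, 2], coords[, 3], sep = "_")
  uk <- !duplicated(key)
  verts <- coords[uk, , drop = FALSE]
  idx <- match(key, key[uk])
  tri_surface(verts, matrix(idx, ncol = 3, byrow = TRUE))
}

#' Write a cohort table as CSV
#'
#' Columns: patient_id, age_CT, age_SAC, V_CT, spring_ant, spring_post,
#' OP_IO, OP_FU1, OP_FU2 (measured openings, mm).
#'
#' @param cohort list of cohort records from [generate_cohort()]
#' @param path output CSV path
#' @return \code{path}, invisibly
#' @export
write_cohort_csv <- function(cohort, path) {
  df <- cohort_table(cohort)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Flatten a cohort into a data frame
#' @param cohort list of cohort records
#' @return data.frame, one row per patient
#' @export
cohort_table <- function(cohort) {
  do.call(rbind, lapply(cohort, function(r) {
    data.frame(patient_id = r$patient_id,
               age_CT = r$age_CT_months,
               age_SAC = r$age_SAC_months,
               V_CT = r$V_CT_mm3,
               spring_ant = r$spring_models[1],
               spring_post = r$spring_models[2],
               OP_IO = r$measured_openings$mm[1],
               OP_FU1 = r$measured_openings$mm[2],
               OP_FU2 = r$measured_openings$mm[3],
               stringsAsFactors = FALSE)
  }))
}
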