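#' Read and write medial surfaces as VTK polydata
#'
#' Surfaces travel as VTK polydata in world-mm coordinates, with the
#' radius and any derived maps (e.g. "fa_mean", "rate", "plateau_age",
#' "sig_model") stored as named per-vertex scalar arrays. Both the legacy
#' ASCII format (`.vtk`) and the XML format with ASCII-encoded arrays
#' (`.vtp`) are supported; the format is chosen from the file extension.
#'
#' @param surface a [medial_surface()].
#' @param path file path ending in `.vtk` or `.vtp`.
#' @param arrays named list of per-vertex numeric vectors written as
#'   additional point-data arrays (besides "radius"). NA values are
#'   written as NaN.
#' @return `write_surface_vtk` returns `path` invisibly;
#'   `read_surface_vtk` returns a list with the `surface` and a named list
#'   `arrays` of any extra point-data fields found.
#' @export
write_surface_vtk <- function(surface, path, arrays = list()) {
  stopifnot(inherits(surface, "medial_surface"))
  arrays <- c(list(radius = surface$radius), arrays)
  ext <- tolower(tools::file_ext(path))
  if (ext == "vtp") {
    .write_vtp(surface, path, arrays)
  } else {
    .write_vtk_legacy(surface, path, arrays)
  }
  invisible(path)
}

#' @rdname write_surface_vtk
#' @param tract_name,hemisphere metadata attached to the surface on read.
#' @export
read_surface_vtk <- function(path, tract_name = "tract",
                             hemisphere = "midline") {
  ext <- tolower(tools::file_ext(path))
  got <- if (ext == "vtp") .read_vtp(path) else .read_vtk_legacy(path)
  if (is.null(got$arrays$radius))
    stop("VTK file carries no 'radius' point array")
  surf <- medial_surface(got$points, got$polys, got$arrays$radius,
                         tract_name = tract_name, hemisphere = hemisphere)
  list(surface = surf,
       arrays = got$arrays[setdiff(names(got$arrays), "radius")])
}

.fmt_num <- function(x) {
  x <- ifelse(is.na(x), NaN, x)
  format(x, digits = 10, trim = TRUE, scientific = FALSE, nsmall = 0)
}

.write_vtk_legacy <- function(surface, path, arrays) {
  con <- file(path, "w")
  on.exit(close(con))
  v <- surface$vertices
  tr <- surface$triangles
  writeLines(c("# vtk DataFile Version 3.0",
               sprintf("tractmat medial surface %s", surface$tract_name),
               "ASCII",
               "DATASET POLYDATA",
               sprintf("POINTS %d float", nrow(v))), con)
  writeLines(apply(v, 1, function(p) paste(.fmt_num(p), collapse = " ")),
             con)
  writeLines(sprintf("POLYGONS %d %d", nrow(tr), 4L * nrow(tr)), con)
  writeLines(apply(tr, 1, function(t)
    paste(c(3L, t - 1L), collapse = " ")), con)
  writeLines(sprintf("POINT_DATA %d", nrow(v)), con)
  for (nm in names(arrays)) {
    writeLines(c(sprintf("SCALARS %s float 1", nm),
                 "LOOKUP_TABLE default"), con)
    writeLines(.fmt_num(arrays[[nm]]), con)
  }
}

.read_vtk_legacy <- function(path) {
  ln <- readLines(path, warn = FALSE)
  toks <- function(s) strsplit(trimws(s), "\\s+")[[1]]
  i <- grep("^POINTS", ln)[1]
  if (is.na(i)) stop("not a VTK polydata file: no POINTS section")
  np <- as.integer(toks(ln[i])[2])
  nums <- function(from, count) {
    vals <- numeric(0)
    j <- from
    while (length(vals) < count) {
      vals <- c(vals, as.numeric(toks(ln[j])))
      j <- j + 1
    }
    list(vals = vals[seq_len(count)], nxt = j)
  }
  pts <- nums(i + 1, 3L * np)
  points <- matrix(pts$vals, ncol = 3, byrow = TRUE)
  ip <- grep("^POLYGONS", ln)[1]
  hp <- toks(ln[ip])
  ncell <- as.integer(hp[2]); ntot <- as.integer(hp[3])
  cl <- nums(ip + 1, ntot)
  cells <- cl$vals
  polys <- matrix(NA_integer_, ncell, 3)
  pos <- 1
  for (k in seq_len(ncell)) {
    sz <- cells[pos]
    if (sz != 3) stop("only triangle polydata supported")
    polys[k, ] <- as.integer(cells[pos + 1:3]) + 1L
    pos <- pos + sz + 1
  }
  arrays <- list()
  for (is in grep("^SCALARS", ln)) {
    nm <- toks(ln[is])[2]
    start <- is + 1
    if (grepl("^LOOKUP_TABLE", ln[start])) start <- start + 1
    arrays[[nm]] <- nums(start, np)$vals
  }
  list(points = points, polys = polys, arrays = arrays)
}

.write_vtp <- function(surface, path, arrays) {
  v <- surface$vertices
  tr <- surface$triangles
  da <- function(name, vals, comps) {
    sprintf(
      '<DataArray type="Float64" Name="%s" NumberOfComponents="%d" format="ascii">\n%s\n</DataArray>',
      name, comps, paste(.fmt_num(vals), collapse = " "))
  }
  dai <- function(name, vals) {
    sprintf(
      '<DataArray type="Int64" Name="%s" format="ascii">\n%s\n</DataArray>',
      name, paste(vals, collapse = " "))
  }
  pd <- paste(vapply(names(arrays), function(nm)
    da(nm, arrays[[nm]], 1L), ""), collapse = "\n")
  xml <- sprintf(
    '<?xml version="1.0"?>
<VTKFile type="PolyData" version="1.0" byte_order="LittleEndian">
<PolyData>
<Piece NumberOfPoints="%d" NumberOfVerts="0" NumberOfLines="0" NumberOfStrips="0" NumberOfPolys="%d">
<Points>
%s
</Points>
<PointData>
%s
</PointData>
<Polys>
%s
%s
</Polys>
</Piece>
</PolyData>
</VTKFile>',
    nrow(v), nrow(tr),
    da("Points", as.vector(t(v)), 3L),
    pd,
    dai("connectivity", as.vector(t(tr)) - 1L),
    dai("offsets", 3L * seq_len(nrow(tr))))
  writeLines(xml, path)
  invisible(path)
}

.read_vtp <- function(path) {
  doc <- xml2::read_xml(path)
  piece <- xml2::xml_find_first(doc, ".//Piece")
  get_num <- function(node) as.numeric(strsplit(trimws(xml2::xml_text(node)),
                                                "\\s+")[[1]])
  pts_node <- xml2::xml_find_first(piece, "./Points/DataArray")
  points <- matrix(get_num(pts_node), ncol = 3, byrow = TRUE)
  conn <- get_num(xml2::xml_find_first(
    piece, "./Polys/DataArray[@Name='connectivity']"))
  offs <- get_num(xml2::xml_find_first(
    piece, "./Polys/DataArray[@Name='offsets']"))
  if (any(diff(c(0, offs)) != 3)) stop("only triangle polydata supported")
  polys <- matrix(as.integer(conn), ncol = 3, byrow = TRUE) + 1L
  arrays <- list()
  for (nd in xml2::xml_find_all(piece, "./PointData/DataArray")) {
    arrays[[xml2::xml_attr(nd, "Name")]] <- get_num(nd)
  }
  list(points = points, polys = polys, arrays = arrays)
}
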