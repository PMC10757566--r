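# VTK XML PolyData (.vtp, ASCII) reader/writer for labeled WSS
# surfaces. Point-data arrays: "region" (Int32) and "WSS_t<k>"
# (Float64, 3 components, k = 0-based time index); field-data array
# "times" holds the sample times. Numbers are written with 17
# significant digits so a write/read round trip is bitwise exact.

fmt_dbl <- function(x) paste(sprintf("%.17g", x), collapse = " ")
fmt_int <- function(x) paste(format(x, scientific = FALSE, trim = TRUE),
                             collapse = " ")

#' Write a surface field as VTK XML PolyData
#'
#' @param field a [tri_surface_field()].
#' @param path output file path (conventionally `.vtp`).
#' @return `path`, invisibly.
#' @seealso [read_surface_field()]
#' @export
write_surface_field <- function(field, path) {
  stopifnot(inherits(field, "tri_surface_field"))
  nt <- length(field$times)
  wss_arrays <- vapply(seq_len(nt), function(k) {
    sprintf(
      '        <DataArray type="Float64" Name="WSS_t%d" NumberOfComponents="3" format="ascii">%s</DataArray>',
      k - 1L, fmt_dbl(as.vector(t(field$wss[, , k]))))
  }, character(1))
  lines <- c(
    '<?xml version="1.0"?>',
    '<VTKFile type="PolyData" version="1.0" byte_order="LittleEndian" LengthUnit="cm">',
    '  <PolyData>',
    '    <FieldData>',
    sprintf('      <DataArray type="Float64" Name="times" format="ascii">%s</DataArray>',
            fmt_dbl(field$times)),
    '    </FieldData>',
    sprintf('    <Piece NumberOfPoints="%d" NumberOfVerts="0" NumberOfLines="0" NumberOfStrips="0" NumberOfPolys="%d">',
            nrow(field$points), nrow(field$triangles)),
    '      <PointData>',
    sprintf('        <DataArray type="Int32" Name="region" format="ascii">%s</DataArray>',
            fmt_int(field$region)),
    wss_arrays,
    '      </PointData>',
    '      <CellData/>',
    '      <Points>',
    sprintf('        <DataArray type="Float64" Name="Points" NumberOfComponents="3" format="ascii">%s</DataArray>',
            fmt_dbl(as.vector(t(field$points)))),
    '      </Points>',
    '      <Polys>',
    sprintf('        <DataArray type="Int64" Name="connectivity" format="ascii">%s</DataArray>',
            fmt_int(as.vector(t(field$triangles)) - 1L)),
    sprintf('        <DataArray type="Int64" Name="offsets" format="ascii">%s</DataArray>',
            fmt_int(seq_len(nrow(field$triangles)) * 3L)),
    '      </Polys>',
    '    </Piece>',
    '  </PolyData>',
    '</VTKFile>')
  writeLines(lines, path)
  invisible(path)
}

vtp_numbers <- function(node) {
  as.numeric(strsplit(trimws(xml2::xml_text(node)), "\\s+")[[1L]])
}

vtp_point_array <- function(piece, name, path) {
  node <- xml2::xml_find_first(
    piece, sprintf("./PointData/DataArray[@Name='%s']", name))
  if (inherits(node, "xml_missing")) {
    stop(sprintf("format error in %s: missing point-data array \"%s\"",
                 path, name), call. = FALSE)
  }
  node
}

#' Read a surface field from VTK XML PolyData
#'
#' Reads the `.vtp` convention written by [write_surface_field()]:
#' triangle cells only, point-data arrays `region` and
#' `WSS_t0 ... WSS_t<k>`, field-data array `times`. A missing
#' `LengthUnit` declaration is assumed to be cm, with a warning.
#'
#' @param path path to a `.vtp` file.
#' @return A [tri_surface_field()].
#' @export
read_surface_field <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  if (is.na(xml2::xml_attr(doc, "LengthUnit"))) {
    warning("no LengthUnit declared in ", path, "; assuming cm",
            call. = FALSE)
  }
  piece <- xml2::xml_find_first(doc, ".//Piece")
  if (inherits(piece, "xml_missing")) {
    stop("format error: no <Piece> element in ", path, call. = FALSE)
  }
  pts_node <- xml2::xml_find_first(piece, "./Points/DataArray")
  if (inherits(pts_node, "xml_missing")) {
    stop("format error: missing Points array in ", path, call. = FALSE)
  }
  points <- matrix(vtp_numbers(pts_node), ncol = 3L, byrow = TRUE)
  conn <- xml2::xml_find_first(piece,
                               "./Polys/DataArray[@Name='connectivity']")
  offs <- xml2::xml_find_first(piece, "./Polys/DataArray[@Name='offsets']")
  if (inherits(conn, "xml_missing") || inherits(offs, "xml_missing")) {
    stop("format error: missing Polys connectivity/offsets in ", path,
         call. = FALSE)
  }
  offsets <- vtp_numbers(offs)
  if (length(offsets) > 0L && any(diff(c(0, offsets)) != 3)) {
    stop("unsupported format: ", path,
         " contains non-triangle cells (mixed cell sizes)", call. = FALSE)
  }
  triangles <- matrix(as.integer(vtp_numbers(conn)) + 1L, ncol = 3L,
                      byrow = TRUE)
  region <- as.integer(vtp_numbers(vtp_point_array(piece, "region", path)))
  times_node <- xml2::xml_find_first(
    doc, ".//FieldData/DataArray[@Name='times']")
  if (inherits(times_node, "xml_missing")) {
    stop("format error in ", path,
         ": missing field-data array \"times\"", call. = FALSE)
  }
  times <- vtp_numbers(times_node)
  n <- nrow(points)
  wss <- array(0, dim = c(n, 3L, length(times)))
  for (k in seq_along(times)) {
    nm <- sprintf("WSS_t%d", k - 1L)
    vals <- vtp_numbers(vtp_point_array(piece, nm, path))
    wss[, , k] <- matrix(vals, ncol = 3L, byrow = TRUE)
  }
  tri_surface_field(points, triangles, region, times, wss)
}

#' Write a surface field as one .vtp per time step plus a manifest
#'
#' The common CFD-export dialect: a directory of per-timestep
#' PolyData files, each carrying a single 3-component `WSS` array and
#' the `region` labels, plus a `manifest.csv` listing `file,time_s`.
#'
#' @param field a [tri_surface_field()].
#' @param dir output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_surface_series <- function(field, dir) {
  stopifnot(inherits(field, "tri_surface_field"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- sprintf("step_%04d.vtp", seq_along(field$times) - 1L)
  for (k in seq_along(field$times)) {
    snap <- field
    # single-time file: one WSS array named plainly "WSS"
    lines <- c(
      '<?xml version="1.0"?>',
      '<VTKFile type="PolyData" version="1.0" byte_order="LittleEndian" LengthUnit="cm">',
      '  <PolyData>',
      sprintf('    <Piece NumberOfPoints="%d" NumberOfVerts="0" NumberOfLines="0" NumberOfStrips="0" NumberOfPolys="%d">',
              nrow(snap$points), nrow(snap$triangles)),
      '      <PointData>',
      sprintf('        <DataArray type="Int32" Name="region" format="ascii">%s</DataArray>',
              fmt_int(snap$region)),
      sprintf('        <DataArray type="Float64" Name="WSS" NumberOfComponents="3" format="ascii">%s</DataArray>',
              fmt_dbl(as.vector(t(snap$wss[, , k])))),
      '      </PointData>',
      '      <Points>',
      sprintf('        <DataArray type="Float64" Name="Points" NumberOfComponents="3" format="ascii">%s</DataArray>',
              fmt_dbl(as.vector(t(snap$points)))),
      '      </Points>',
      '      <Polys>',
      sprintf('        <DataArray type="Int64" Name="connectivity" format="ascii">%s</DataArray>',
              fmt_int(as.vector(t(snap$triangles)) - 1L)),
      sprintf('        <DataArray type="Int64" Name="offsets" format="ascii">%s</DataArray>',
              fmt_int(seq_len(nrow(snap$triangles)) * 3L)),
      '      </Polys>',
      '    </Piece>',
      '  </PolyData>',
      '</VTKFile>')
    writeLines(lines, file.path(dir, files[k]))
  }
  manifest <- file.path(dir, "manifest.csv")
  utils::write.csv(data.frame(file = files,
                              time_s = sprintf("%.17g", field$times)),
                   manifest, row.names = FALSE, quote = FALSE)
  invisible(manifest)
}

#' Read a per-timestep .vtp series into one surface field
#'
#' @param dir directory containing the series and its manifest.
#' @param manifest manifest file name within `dir`.
#' @return A [tri_surface_field()].
#' @export
read_surface_series <- function(dir, manifest = "manifest.csv") {
  man_path <- file.path(dir, manifest)
  if (!file.exists(man_path)) {
    stop("format error: missing manifest ", man_path, call. = FALSE)
  }
  man <- utils::read.csv(man_path, stringsAsFactors = FALSE)
  if (!all(c("file", "time_s") %in% names(man))) {
    stop("format error: manifest must have columns file, time_s",
         call. = FALSE)
  }
  ord <- order(man$time_s)
  man <- man[ord, ]
  times <- as.numeric(man$time_s)
  points <- triangles <- region <- NULL
  wss <- NULL
  for (k in seq_len(nrow(man))) {
    path <- file.path(dir, man$file[k])
    doc <- xml2::read_xml(path)
    xml2::xml_ns_strip(doc)
    piece <- xml2::xml_find_first(doc, ".//Piece")
    pts <- matrix(vtp_numbers(
      xml2::xml_find_first(piece, "./Points/DataArray")), ncol = 3L,
      byrow = TRUE)
    conn <- as.integer(vtp_numbers(xml2::xml_find_first(
      piece, "./Polys/DataArray[@Name='connectivity']"))) + 1L
    reg <- as.integer(vtp_numbers(vtp_point_array(piece, "region", path)))
    w <- matrix(vtp_numbers(vtp_point_array(piece, "WSS", path)),
                ncol = 3L, byrow = TRUE)
    if (k == 1L) {
      points <- pts
      triangles <- matrix(conn, ncol = 3L, byrow = TRUE)
      region <- reg
      wss <- array(0, dim = c(nrow(pts), 3L, nrow(man)))
    } else if (!identical(dim(pts), dim(points))) {
      stop("format error: inconsistent point counts across series steps",
           call. = FALSE)
    }
    wss[, , k] <- w
  }
  tri_surface_field(points, triangles, region, times, wss)
}
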