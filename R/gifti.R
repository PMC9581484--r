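# Minimal GIFTI reader/writer built on xml2.
#
# Covers surface geometry (.surf.gii: POINTSET + TRIANGLE), per-vertex
# metrics (.func.gii / .shape.gii) and label files (.label.gii with a
# LabelTable).  Encodings handled: ASCII, Base64Binary and
# GZipBase64Binary, little-endian, row- or column-major.  The writer emits
# Base64Binary little-endian row-major.

#' Triangulated cortical surface
#'
#' @param vertices n x 3 matrix of world coordinates (mm).
#' @param triangles m x 3 integer matrix of 1-based vertex indices.
#' @param hemisphere `"left"`, `"right"` or `"both"`.
#' @return an object of class `surface_mesh`.
#' @export
surface_mesh <- function(vertices, triangles, hemisphere = "left") {
  vertices <- as.matrix(vertices)
  triangles <- matrix(as.integer(as.matrix(triangles)), ncol = 3)
  assert_that(ncol(vertices) == 3, "vertices must be n x 3")
  nv <- nrow(vertices)
  assert_that(all(triangles >= 1L) && all(triangles <= nv),
              "triangle index out of range (1..%d)", nv,
              class = "bxs_format_error")
  degen <- triangles[, 1] == triangles[, 2] | triangles[, 1] == triangles[, 3] |
    triangles[, 2] == triangles[, 3]
  assert_that(!any(degen), "%d degenerate triangle(s) with repeated vertices",
              sum(degen), class = "bxs_format_error")
  structure(list(vertices = vertices, triangles = triangles,
                 hemisphere = hemisphere),
            class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("<surface_mesh> %d vertices, %d triangles (%s)\n",
              nrow(x$vertices), nrow(x$triangles), x$hemisphere))
  invisible(x)
}

gii_decode <- function(node, ns_prefix = "") {
  enc <- xml2::xml_attr(node, "Encoding")
  dt <- xml2::xml_attr(node, "DataType")
  ndim <- as.integer(xml2::xml_attr(node, "Dimensionality"))
  dims <- vapply(seq_len(ndim) - 1L, function(d) {
    as.integer(xml2::xml_attr(node, paste0("Dim", d)))
  }, integer(1))
  order <- xml2::xml_attr(node, "ArrayIndexingOrder") %||% "RowMajorOrder"
  txt <- xml2::xml_text(xml2::xml_find_first(node, paste0(".//", ns_prefix, "Data")))
  n <- prod(dims)
  if (identical(enc, "ASCII")) {
    vals <- scan(text = txt, quiet = TRUE)
  } else {
    raw <- jsonlite::base64_dec(gsub("[[:space:]]", "", txt))
    if (identical(enc, "GZipBase64Binary")) raw <- memDecompress(raw, "gzip")
    vals <- switch(dt,
      NIFTI_TYPE_FLOAT32 = readBin(raw, "double", n, 4L, endian = "little"),
      NIFTI_TYPE_FLOAT64 = readBin(raw, "double", n, 8L, endian = "little"),
      NIFTI_TYPE_INT32 = readBin(raw, "integer", n, 4L, endian = "little"),
      NIFTI_TYPE_UINT8 = readBin(raw, "integer", n, 1L, signed = FALSE,
                                 endian = "little"),
      stop_bxs("unsupported GIFTI DataType %s", dt, class = "bxs_format_error"))
  }
  assert_that(length(vals) == n, "GIFTI data length mismatch",
              class = "bxs_format_error")
  if (length(dims) == 2L) {
    if (identical(order, "RowMajorOrder")) {
      matrix(vals, nrow = dims[1], byrow = TRUE)
    } else {
      matrix(vals, nrow = dims[1])
    }
  } else {
    vals
  }
}

gii_arrays <- function(path) {
  assert_that(file.exists(path), "no such file: %s", path,
              class = "bxs_format_error")
  doc <- xml2::read_xml(path)
  nodes <- xml2::xml_find_all(doc, "//DataArray")
  ns_prefix <- ""
  if (length(nodes) == 0L) {
    # file declares a default namespace; xml2 maps it to d1
    nodes <- xml2::xml_find_all(doc, "//d1:DataArray")
    ns_prefix <- "d1:"
  }
  assert_that(length(nodes) > 0, "no DataArray elements in %s", path,
              class = "bxs_format_error")
  list(doc = doc, nodes = nodes, ns_prefix = ns_prefix,
       intents = vapply(nodes, function(n) xml2::xml_attr(n, "Intent"), ""))
}

#' Read a GIFTI surface
#'
#' @param path a `.surf.gii` file holding a POINTSET and a TRIANGLE array.
#' @param hemisphere hemisphere tag attached to the mesh.
#' @return a [surface_mesh].
#' @export
read_surface <- function(path, hemisphere = "left") {
  g <- gii_arrays(path)
  ip <- which(g$intents == "NIFTI_INTENT_POINTSET")
  it <- which(g$intents == "NIFTI_INTENT_TRIANGLE")
  assert_that(length(ip) == 1L && length(it) == 1L,
              "%s must contain one POINTSET and one TRIANGLE array", path,
              class = "bxs_format_error")
  verts <- gii_decode(g$nodes[[ip]], g$ns_prefix)
  tris <- gii_decode(g$nodes[[it]], g$ns_prefix)
  # GIFTI triangle indices are 0-based
  surface_mesh(verts, tris + 1L, hemisphere = hemisphere)
}

gii_skeleton <- function() {
  xml2::read_xml(paste0(
    '<?xml version="1.0" encoding="UTF-8"?>\n',
    '<GIFTI xmlns:xsi="http://www.w3.org/2001/XMLSchema-instance" ',
    'Version="1.0" NumberOfDataArrays="0"/>'))
}

gii_add_array <- function(doc, values, intent, datatype) {
  root <- xml2::xml_root(doc)
  dims <- if (is.matrix(values)) dim(values) else length(values)
  da <- xml2::xml_add_child(root, "DataArray",
    Intent = intent, DataType = datatype,
    ArrayIndexingOrder = "RowMajorOrder",
    Dimensionality = as.character(length(dims)),
    Encoding = "Base64Binary", Endian = "LittleEndian",
    ExternalFileName = "", ExternalFileOffset = "")
  for (i in seq_along(dims)) {
    xml2::xml_attr(da, paste0("Dim", i - 1L)) <- as.character(dims[i])
  }
  flat <- if (is.matrix(values)) as.vector(t(values)) else values
  raw <- switch(datatype,
    NIFTI_TYPE_FLOAT32 = writeBin(as.double(flat), raw(), 4L, endian = "little"),
    NIFTI_TYPE_INT32 = writeBin(as.integer(flat), raw(), 4L, endian = "little"),
    stop_bxs("unsupported write DataType %s", datatype))
  xml2::xml_add_child(da, "Data", jsonlite::base64_enc(raw))
  n <- as.integer(xml2::xml_attr(root, "NumberOfDataArrays")) + 1L
  xml2::xml_attr(root, "NumberOfDataArrays") <- as.character(n)
  invisible(doc)
}

#' Write a GIFTI surface
#' @param mesh a [surface_mesh].
#' @param path output `.surf.gii` path.
#' @return `path`, invisibly.
#' @export
write_surface <- function(mesh, path) {
  doc <- gii_skeleton()
  gii_add_array(doc, mesh$vertices, "NIFTI_INTENT_POINTSET", "NIFTI_TYPE_FLOAT32")
  gii_add_array(doc, mesh$triangles - 1L, "NIFTI_INTENT_TRIANGLE", "NIFTI_TYPE_INT32")
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Read / write a per-vertex metric (.func.gii / .shape.gii)
#'
#' @param path a GIFTI metric file with one data array per map.
#' @return for the reader, a numeric matrix (vertices x maps).
#' @export
read_surface_metric <- function(path) {
  g <- gii_arrays(path)
  cols <- lapply(g$nodes, gii_decode, ns_prefix = g$ns_prefix)
  do.call(cbind, lapply(cols, as.numeric))
}

#' @rdname read_surface_metric
#' @param values numeric vector or matrix (vertices x maps).
#' @export
write_surface_metric <- function(values, path) {
  values <- as.matrix(values)
  doc <- gii_skeleton()
  for (j in seq_len(ncol(values))) {
    gii_add_array(doc, values[, j], "NIFTI_INTENT_NONE", "NIFTI_TYPE_FLOAT32")
  }
  xml2::write_xml(doc, path)
  invisible(path)
}
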