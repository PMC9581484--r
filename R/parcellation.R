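#' Cortical parcellation
#'
#' Per-vertex integer parcel labels plus an id -> name table, an optional
#' id -> cortical-system map, and a set of excluded parcel ids.  Excluded
#' parcels (e.g. an insula analogue that the tract set represents poorly)
#' stay in the object — their vertices are flagged, never dropped — and are
#' omitted from parcel-level divergence summaries.
#'
#' @param labels integer vector, one parcel id per vertex (0 = unlabeled).
#' @param names named character vector mapping parcel id to parcel name.
#' @param systems optional named character vector mapping parcel id to a
#'   cortical-system name.
#' @param exclusions integer vector of parcel ids to exclude from summaries.
#' @return an object of class `parcellation`.
#' @export
parcellation <- function(labels, names, systems = NULL, exclusions = integer()) {
  labels <- as.integer(labels)
  ids <- sort(unique(labels[labels != 0L]))
  known <- as.integer(base::names(names))
  missing <- setdiff(ids, known)
  assert_that(length(missing) == 0L,
              "label id(s) absent from the name table: %s",
              paste(missing, collapse = ", "), class = "bxs_format_error")
  structure(list(labels = labels, names = names, systems = systems,
                 exclusions = as.integer(exclusions)),
            class = "parcellation")
}

#' @export
print.parcellation <- function(x, ...) {
  cat(sprintf("<parcellation> %d vertices, %d parcels (%d excluded)\n",
              length(x$labels), length(unique(x$labels[x$labels != 0])),
              length(x$exclusions)))
  invisible(x)
}

#' Ids of parcels that enter summaries (labeled, not excluded)
#' @param parc a [parcellation].
#' @export
included_parcels <- function(parc) {
  setdiff(sort(unique(parc$labels[parc$labels != 0L])), parc$exclusions)
}

#' Per-vertex flag: does this vertex participate in parcel summaries?
#' @param parc a [parcellation].
#' @export
vertex_included <- function(parc) {
  parc$labels != 0L & !(parc$labels %in% parc$exclusions)
}

#' Read a parcellation from a label file plus a TSV name table
#'
#' The label file is either a GIFTI `.label.gii`/`.func.gii` (first data
#' array = per-vertex ids) or a single-column text file of ids.  The name
#' table is TSV with columns `id`, `name` and optionally `system`.
#'
#' @param path label file.
#' @param name_table path to the TSV name table.
#' @param exclusions integer ids to exclude from summaries.
#' @return a [parcellation].
#' @export
read_parcellation <- function(path, name_table, exclusions = integer()) {
  if (grepl("\\.gii$", path)) {
    labels <- as.integer(read_surface_metric(path)[, 1])
  } else {
    labels <- as.integer(scan(path, quiet = TRUE))
  }
  tab <- utils::read.delim(name_table, sep = "\t", stringsAsFactors = FALSE)
  assert_that(all(c("id", "name") %in% names(tab)),
              "name table must have 'id' and 'name' columns",
              class = "bxs_format_error")
  nm <- stats::setNames(as.character(tab$name), tab$id)
  sys <- if ("system" %in% names(tab)) {
    stats::setNames(as.character(tab$system), tab$id)
  }
  parcellation(labels, nm, systems = sys, exclusions = exclusions)
}

#' Icosphere mesh (subdivided icosahedron projected to a sphere)
#'
#' Subdivision level `k` gives `10 * 4^k + 2` vertices and `20 * 4^k`
#' triangles (k = 2: 162 vertices; k = 3: 642; k = 5: 10242, the working
#' per-hemisphere resolution for cortical meshes in this package).
#'
#' @param subdiv number of 4-to-1 triangle subdivisions.
#' @param radius sphere radius in mm.
#' @param center sphere centre in mm.
#' @param hemisphere tag for the resulting [surface_mesh].
#' @export
icosphere <- function(subdiv = 3, radius = 1, center = c(0, 0, 0),
                      hemisphere = "left") {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdiv)) {
    midcache <- new.env(hash = TRUE)
    nv <- nrow(v)
    newf <- matrix(0L, nrow = 4 * nrow(f), ncol = 3)
    midpoint <- function(a, b) {
      key <- paste(min(a, b), max(a, b))
      hit <- midcache[[key]]
      if (!is.null(hit)) return(hit)
      m <- normalize_vec(colMeans(v[c(a, b), ]))
      v <<- rbind(v, m)
      idx <- nrow(v)
      midcache[[key]] <- idx
      idx
    }
    for (i in seq_len(nrow(f))) {
      a <- f[i, 1]; b <- f[i, 2]; c3 <- f[i, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, c3); ca <- midpoint(c3, a)
      newf[(4 * i - 3):(4 * i), ] <- rbind(
        c(a, ab, ca), c(b, bc, ab), c(c3, ca, bc), c(ab, bc, ca))
    }
    f <- newf
  }
  verts <- sweep(v * radius, 2, center, `+`)
  surface_mesh(verts, f, hemisphere = hemisphere)
}

#' Planar grid-shell mesh on a face of a volume
#'
#' Builds a regular triangulated grid of vertices sitting at the voxel
#' centres of one boundary slab of `vol` — the phantom analogue of a
#' white-gray-boundary sheet at a bundle's cortical end.
#'
#' @param vol a [volume_grid] defining the grid geometry.
#' @param face one of `"x-"`, `"x+"`, `"y-"`, `"y+"`, `"z-"`, `"z+"`.
#' @param hemisphere tag for the mesh.
#' @export
grid_shell_mesh <- function(vol, face = "x-", hemisphere = "left") {
  shp <- grid_shape(vol)
  ax <- match(substr(face, 1, 1), c("x", "y", "z"))
  lev <- if (substr(face, 2, 2) == "-") 0 else shp[ax] - 1
  other <- setdiff(1:3, ax)
  n1 <- shp[other[1]]; n2 <- shp[other[2]]
  idx <- as.matrix(expand.grid(a = 0:(n1 - 1), b = 0:(n2 - 1)))
  ijk <- matrix(0, nrow(idx), 3)
  ijk[, ax] <- lev
  ijk[, other[1]] <- idx[, 1]
  ijk[, other[2]] <- idx[, 2]
  verts <- voxel_to_world(vol, ijk)
  vid <- function(a, b) (b - 1L) * n1 + a
  tris <- NULL
  for (b in seq_len(n2 - 1)) {
    a <- seq_len(n1 - 1)
    tris <- rbind(tris,
                  cbind(vid(a, b), vid(a + 1L, b), vid(a, b + 1L)),
                  cbind(vid(a + 1L, b), vid(a + 1L, b + 1L), vid(a, b + 1L)))
  }
  surface_mesh(verts, tris, hemisphere = hemisphere)
}
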