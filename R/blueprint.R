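# Connectivity blueprints: (cortical vertices x tracts) matrices whose
# normalized rows are connection-likelihood distributions over tracts.

#' Connectivity blueprint
#'
#' @param matrix numeric matrix, rows = vertices (or parcels), columns =
#'   tracts in library order.
#' @param tracts tract names, one per column.
#' @param normalized are rows probability distributions?
#' @param valid logical per-row flag; rows with zero support (e.g. a
#'   medial-wall analogue) are flagged invalid and excluded from divergence
#'   analyses rather than padded with a pseudo-uniform row.
#' @export
connectivity_blueprint <- function(matrix, tracts = colnames(matrix),
                                   normalized = FALSE, valid = NULL) {
  matrix <- as.matrix(matrix)
  assert_that(!is.null(tracts) && length(tracts) == ncol(matrix),
              "tract names must match blueprint columns")
  assert_that(all(matrix >= 0), "blueprint entries must be nonnegative")
  if (is.null(valid)) valid <- rowSums(matrix) > 0
  if (normalized) {
    rs <- rowSums(matrix[valid, , drop = FALSE])
    assert_that(length(rs) == 0 || max(abs(rs - 1)) < 1e-9,
                "normalized blueprint rows must sum to 1 (max dev %g)",
                if (length(rs)) max(abs(rs - 1)) else 0)
  }
  colnames(matrix) <- tracts
  structure(list(matrix = matrix, tracts = tracts, normalized = normalized,
                 valid = valid),
            class = "connectivity_blueprint")
}

#' @export
print.connectivity_blueprint <- function(x, ...) {
  cat(sprintf("<connectivity_blueprint> %d vertices x %d tracts%s, %d invalid row(s)\n",
              nrow(x$matrix), ncol(x$matrix),
              if (x$normalized) " (normalized)" else "",
              sum(!x$valid)))
  invisible(x)
}

#' Surface-to-volume connectivity from vertex-seeded tractography
#'
#' Seeds `samples_per_vertex` streamlines from each mesh vertex (the
#' white-gray-boundary analogue) and records per-vertex visitation counts
#' over the voxels of `brain_mask` (a whole-brain mask, ventricles
#' removed).  The result feeds [build_blueprint()].
#'
#' @param field a [fiber_field].
#' @param mesh a [surface_mesh] whose vertices lie in the field's grid.
#' @param params a [tracking_params].
#' @param samples_per_vertex streamlines seeded per vertex (the working
#'   default at full scale is 1000; tests use far fewer).
#' @param brain_mask optional binary [volume_grid]; defaults to the whole
#'   grid.
#' @return list with `counts` (vertices x voxels-in-mask matrix),
#'   `voxel_index` (linear indices of mask voxels), `samples_per_vertex`.
#' @export
surface_connectivity <- function(field, mesh, params = tracking_params(),
                                 samples_per_vertex = 50, brain_mask = NULL) {
  shape <- dim(field$fractions)[1:3]
  if (is.null(brain_mask)) {
    brain_mask <- volume_grid(array(1L, shape), field$affine)
  }
  keep_lin <- which(brain_mask$values != 0)
  col_of <- integer(prod(shape))
  col_of[keep_lin] <- seq_along(keep_lin)
  nv <- nrow(mesh$vertices)
  counts <- matrix(0, nv, length(keep_lin))
  inv_affine <- solve(field$affine)
  with_seed_bxs(params$seed, {
    for (v in seq_len(nv)) {
      for (s in seq_len(samples_per_vertex)) {
        sl <- propagate_streamline(field, mesh$vertices[v, ], params)
        if (sl$rejected) next
        vox <- floor(t(inv_affine %*% rbind(t(sl$points), 1))[, 1:3,
                                                              drop = FALSE] + 1e-9)
        keep <- vox[, 1] >= 0 & vox[, 1] < shape[1] &
          vox[, 2] >= 0 & vox[, 2] < shape[2] &
          vox[, 3] >= 0 & vox[, 3] < shape[3]
        vox <- vox[keep, , drop = FALSE]
        if (nrow(vox) == 0L) next
        lin <- unique(1 + vox[, 1] + shape[1] * (vox[, 2] + shape[2] * vox[, 3]))
        cols <- col_of[lin]
        cols <- cols[cols > 0]
        counts[v, cols] <- counts[v, cols] + 1
      }
    }
  })
  list(counts = counts, voxel_index = keep_lin,
       samples_per_vertex = samples_per_vertex)
}

#' Build a connectivity blueprint from surface connectivity and tract maps
#'
#' Entry `(i, k)` is the inner product of vertex `i`'s voxel visitation
#' profile with tract `k`'s path density map over the shared voxel space —
#' the product of the (cortex x whole-brain) connectivity matrix with the
#' vectorised tract matrix.  The output is raw; normalize with
#' [normalize_rows()].
#'
#' @param surface_conn result of [surface_connectivity()].
#' @param tract_maps named list of normalized [path_density_map]s on the
#'   same voxel grid the surface connectivity was computed in.
#' @return an unnormalized [connectivity_blueprint].
#' @export
build_blueprint <- function(surface_conn, tract_maps) {
  tracts <- names(tract_maps)
  assert_that(!is.null(tracts), "tract_maps must be a named list")
  nvox_total <- vapply(tract_maps, function(m) length(m$counts$values), 0)
  assert_that(length(unique(nvox_total)) == 1L,
              "tract maps disagree on voxel space", class = "bxs_grid_error")
  assert_that(max(surface_conn$voxel_index) <= nvox_total[1],
              "surface connectivity voxel space does not match tract maps",
              class = "bxs_grid_error")
  tmat <- vapply(tract_maps,
                 function(m) as.vector(m$counts$values)[surface_conn$voxel_index],
                 numeric(length(surface_conn$voxel_index)))
  bp <- surface_conn$counts %*% tmat
  colnames(bp) <- tracts
  connectivity_blueprint(bp, tracts, normalized = FALSE)
}

#' Row-normalize a blueprint to connection-probability distributions
#'
#' Rows with support are divided by their sums; zero-support rows are left
#' untouched and flagged invalid.
#'
#' @param blueprint a [connectivity_blueprint].
#' @export
normalize_rows <- function(blueprint) {
  m <- blueprint$matrix
  rs <- rowSums(m)
  valid <- rs > 0
  m[valid, ] <- m[valid, , drop = FALSE] / rs[valid]
  connectivity_blueprint(m, blueprint$tracts, normalized = TRUE, valid = valid)
}

#' Group-average subject blueprints
#'
#' Subject blueprints are row-normalized first (so subjects with more
#' streamlines do not dominate), averaged element-wise, and the average is
#' re-normalized.  A row is valid in the group blueprint iff it is valid
#' in at least one subject.
#'
#' @param blueprints list of [connectivity_blueprint]s on identical vertex
#'   and tract spaces.
#' @return a normalized group [connectivity_blueprint].
#' @export
average_blueprints <- function(blueprints) {
  assert_that(length(blueprints) >= 1, "need at least one blueprint")
  dims <- vapply(blueprints, function(b) dim(b$matrix), c(0, 0))
  assert_that(all(dims[1, ] == dims[1, 1]) && all(dims[2, ] == dims[2, 1]),
              "blueprints disagree in shape", class = "bxs_grid_error")
  tracts <- blueprints[[1]]$tracts
  for (b in blueprints) {
    assert_that(identical(b$tracts, tracts), "blueprints disagree on tracts")
  }
  normed <- lapply(blueprints, function(b) if (b$normalized) b else normalize_rows(b))
  acc <- Reduce(`+`, lapply(normed, function(b) b$matrix))
  normalize_rows(connectivity_blueprint(acc / length(normed), tracts))
}
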