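#' Volumetric grid container
#'
#' A `volume_grid` couples a 3-D (scalar) or 4-D (vector / multi-volume)
#' value array with a 4x4 voxel-to-world affine (mm, RAS+).  Voxel indices
#' are 0-based in all world/voxel conversions; the value array itself is an
#' ordinary R array with 1-based subscripts.
#'
#' @param values numeric/integer/logical array, 3-D or 4-D.
#' @param affine 4x4 invertible voxel-to-world transform in mm.  Defaults to
#'   identity (1 mm isotropic, corner at the origin).
#' @return An object of class `volume_grid`.
#' @export
volume_grid <- function(values, affine = diag(4)) {
  if (is.logical(values)) values <- array(as.integer(values), dim = dim(values))
  nd <- length(dim(values))
  assert_that(nd %in% c(3L, 4L), "values must be a 3-D or 4-D array, got %d-D", nd)
  affine <- as.matrix(affine)
  assert_that(all(dim(affine) == c(4L, 4L)), "affine must be 4x4")
  det3 <- det(affine[1:3, 1:3])
  assert_that(is.finite(det3) && abs(det3) > 1e-12,
              "affine is not invertible (|det| = %g)", abs(det3),
              class = "bxs_format_error")
  structure(list(values = values, affine = affine), class = "volume_grid")
}

#' @export
print.volume_grid <- function(x, ...) {
  cat("<volume_grid> ", paste(dim(x$values), collapse = " x "),
      " | voxel size ", paste(signif(voxel_size(x), 3), collapse = " x "),
      " mm\n", sep = "")
  invisible(x)
}

#' @export
dim.volume_grid <- function(x) dim(x$values)

grid_shape <- function(vol) dim(vol$values)[1:3]

#' Voxel edge lengths in mm
#' @param vol a `volume_grid`.
#' @export
voxel_size <- function(vol) {
  sqrt(colSums(vol$affine[1:3, 1:3]^2))
}

#' Voxel volume in cubic millimetres
#' @param vol a `volume_grid`.
#' @export
voxel_volume <- function(vol) abs(det(vol$affine[1:3, 1:3]))

#' Convert between voxel (0-based) and world (mm) coordinates
#'
#' @param vol a `volume_grid`.
#' @param ijk matrix (n x 3) of 0-based voxel indices (possibly fractional).
#' @param xyz matrix (n x 3) of world coordinates in mm.
#' @return n x 3 matrix of coordinates in the other frame.
#' @export
voxel_to_world <- function(vol, ijk) {
  ijk <- rbind2cols(ijk)
  t(vol$affine %*% rbind(t(ijk), 1))[, 1:3, drop = FALSE]
}

#' @rdname voxel_to_world
#' @export
world_to_voxel <- function(vol, xyz) {
  xyz <- rbind2cols(xyz)
  t(solve(vol$affine) %*% rbind(t(xyz), 1))[, 1:3, drop = FALSE]
}

rbind2cols <- function(m) {
  if (is.null(dim(m))) m <- matrix(m, ncol = 3)
  m
}

# TRUE if two grids share shape and affine (exact-ish; affine to 1e-6 mm)
same_grid <- function(a, b) {
  identical(grid_shape(a), grid_shape(b)) &&
    max(abs(a$affine - b$affine)) < 1e-6
}

assert_same_grid <- function(a, b, what = "volumes") {
  assert_that(same_grid(a, b), "%s are not on the same grid (shape/affine mismatch)",
              what, class = "bxs_grid_error")
}

#' Indices (0-based, n x 3) of nonzero voxels of a mask volume
#' @param vol a `volume_grid` holding a binary mask.
#' @export
mask_voxels <- function(vol) {
  idx <- which(vol$values != 0, arr.ind = TRUE)
  if (length(idx) == 0L) return(matrix(numeric(0), ncol = 3))
  unname(idx[, 1:3, drop = FALSE] - 1)
}

mask_count <- function(vol) sum(vol$values != 0)
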