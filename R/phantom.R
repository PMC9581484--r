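# Synthetic phantoms: fiber-orientation fields with matching protocols and
# ground-truth masks, synthetic connectivity blueprints with controlled
# between-group divergence, and multi-shell DWI signals from known tensors.
# These are the package's only data source: every downstream module is
# exercised against them.

#' Per-voxel fiber orientation field
#'
#' Up to three unit orientation vectors per voxel with volume fractions,
#' ordered by descending fraction.  Voxels whose fractions sum to zero are
#' outside the tracking mask.
#'
#' @param orientations array `[nx, ny, nz, 3 fibers, 3 xyz]`.
#' @param fractions array `[nx, ny, nz, 3 fibers]`, each voxel summing to
#'   at most 1.
#' @param affine 4x4 voxel-to-world transform.
#' @return an object of class `fiber_field`.
#' @export
fiber_field <- function(orientations, fractions, affine = diag(4)) {
  assert_that(length(dim(orientations)) == 5L && dim(orientations)[5] == 3L,
              "orientations must be [nx,ny,nz,fibers,3]")
  assert_that(all(dim(fractions) == dim(orientations)[1:4]),
              "fractions must match orientations in shape")
  assert_that(all(fractions >= 0 & fractions <= 1), "fractions must lie in [0,1]")
  sums <- apply(fractions, 1:3, sum)
  assert_that(all(sums <= 1 + 1e-9),
              "per-voxel volume fractions exceed 1 (max %.3f)", max(sums),
              class = "bxs_spec_error")
  structure(list(orientations = orientations, fractions = fractions,
                 affine = as.matrix(affine)),
            class = "fiber_field")
}

#' @export
print.fiber_field <- function(x, ...) {
  shp <- dim(x$fractions)[1:3]
  cat(sprintf("<fiber_field> %s, %d voxels in mask\n",
              paste(shp, collapse = " x "),
              sum(apply(x$fractions, 1:3, sum) > 0)))
  invisible(x)
}

field_shape <- function(field) dim(x = field$fractions)[1:3]

# binary mask of voxels with any fiber
field_mask <- function(field) {
  volume_grid(array(as.integer(apply(field$fractions, 1:3, sum) > 0),
                    dim(field$fractions)[1:3]),
              field$affine)
}

#' Phantom specification
#'
#' @param shape 3 positive integers, the voxel grid.
#' @param bundles list of bundle descriptors; each a list with `kind`
#'   (`"straight"`, `"arc"` or `"crossing"`), a `fraction` (volume fraction
#'   given to the bundle in voxels it occupies, default 1 for a single
#'   bundle and 0.5 for each arm of a crossing), and geometry fields:
#'   `axis` (1..3) and `center` (the two in-plane 0-based voxel coordinates)
#'   plus `radius` for straight bundles; `radius`/`thickness` for arcs.
#' @param mesh `"grid-shell"` (a sheet at each end face of the first
#'   bundle) or `"icosphere"`.
#' @param noise reserved for orientation jitter (degrees, default 0).
#' @param seed RNG seed fixing all stochastic output.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(40L, 40L, 40L),
                         bundles = list(list(kind = "straight", axis = 1,
                                             center = c(20, 20), radius = 2,
                                             fraction = 1)),
                         mesh = "grid-shell", noise = 0, seed = 1L) {
  assert_that(length(shape) == 3L && all(shape >= 4), "shape must be 3 ints >= 4")
  structure(list(shape = as.integer(shape), bundles = bundles, mesh = mesh,
                 noise = noise, seed = seed),
            class = "phantom_spec")
}

bundle_voxels_straight <- function(shape, axis, center, radius) {
  other <- setdiff(1:3, axis)
  g <- as.matrix(expand.grid(i = 0:(shape[1] - 1), j = 0:(shape[2] - 1),
                             k = 0:(shape[3] - 1)))
  sel <- (g[, other[1]] - center[1])^2 + (g[, other[2]] - center[2])^2 <= radius^2
  g[sel, , drop = FALSE]
}

# quarter-arc in the xy-plane at slice z = center[3]; returns voxels and
# per-voxel tangent directions
bundle_voxels_arc <- function(shape, center, radius, thickness) {
  g <- as.matrix(expand.grid(i = 0:(shape[1] - 1), j = 0:(shape[2] - 1),
                             k = 0:(shape[3] - 1)))
  dx <- g[, 1] - center[1]; dy <- g[, 2] - center[2]
  r <- sqrt(dx^2 + dy^2)
  ang <- atan2(dy, dx)
  sel <- abs(r - radius) <= thickness & ang >= 0 & ang <= pi / 2 &
    abs(g[, 3] - center[3]) <= thickness
  vox <- g[sel, , drop = FALSE]
  tang <- cbind(-sin(ang[sel]), cos(ang[sel]), 0)
  list(vox = vox, tang = tang)
}

slab_mask <- function(shape, affine, voxels, axis, range) {
  m <- array(0L, shape)
  sel <- voxels[, axis] >= range[1] & voxels[, axis] <= range[2]
  sub <- voxels[sel, , drop = FALSE] + 1
  m[sub] <- 1L
  volume_grid(m, affine)
}

vox_to_mask <- function(shape, affine, voxels) {
  m <- array(0L, shape)
  m[voxels + 1] <- 1L
  volume_grid(m, affine)
}

#' Build a fiber phantom with protocols and ground truth
#'
#' For each bundle the phantom provides: the orientation field
#' contribution, a matching [tract_protocol] (seed slab at one end,
#' waypoint slab mid-course, stop slab at the far end, exclusion slab
#' off-course) and a ground-truth binary mask of bundle voxels.
#' `"crossing"` generates two straight bundles along axes 1 and 2 sharing
#' the grid centre, each carrying fraction 0.5 where they overlap.
#'
#' @param spec a [phantom_spec].
#' @return list with elements `field` ([fiber_field]), `protocols` (list of
#'   [tract_protocol]), `truth` (list of [volume_grid] masks), `spec`.
#' @export
make_fiber_phantom <- function(spec) {
  assert_that(inherits(spec, "phantom_spec"), "spec must be a phantom_spec")
  shape <- spec$shape
  affine <- diag(4)
  orient <- array(0, c(shape, 3, 3))
  frac <- array(0, c(shape, 3))
  protocols <- list()
  truth <- list()

  add_fiber <- function(vox, dirs, fraction) {
    # dirs: either one 3-vector or an n x 3 matrix of per-voxel directions
    if (is.null(dim(dirs))) dirs <- matrix(dirs, nrow(vox), 3, byrow = TRUE)
    for (r in seq_len(nrow(vox))) {
      i <- vox[r, 1] + 1; j <- vox[r, 2] + 1; k <- vox[r, 3] + 1
      slot <- which(frac[i, j, k, ] == 0)[1]
      assert_that(!is.na(slot) && sum(frac[i, j, k, ]) + fraction <= 1 + 1e-9,
                  "overlapping bundles exceed the per-voxel fraction budget",
                  class = "bxs_spec_error")
      orient[i, j, k, slot, ] <<- normalize_vec(dirs[r, ])
      frac[i, j, k, slot] <<- fraction
    }
  }

  expand_bundles <- function(bundles) {
    out <- list()
    for (b in bundles) {
      if (identical(b$kind, "crossing")) {
        ctr <- b$center %||% floor(shape / 2)
        rad <- b$radius %||% 2
        fr <- b$fraction %||% 0.5
        out <- c(out,
                 list(list(kind = "straight", axis = 1,
                           center = ctr[2:3], radius = rad, fraction = fr,
                           name = paste0(b$name %||% "crossing", "_x")),
                      list(kind = "straight", axis = 2,
                           center = ctr[c(1, 3)], radius = rad, fraction = fr,
                           name = paste0(b$name %||% "crossing", "_y"))))
      } else {
        out <- c(out, list(b))
      }
    }
    out
  }

  bundles <- expand_bundles(spec$bundles)
  for (bi in seq_along(bundles)) {
    b <- bundles[[bi]]
    nm <- b$name %||% paste0("bundle", bi)
    fr <- b$fraction %||% 1
    if (identical(b$kind, "straight")) {
      ax <- b$axis %||% 1
      vox <- bundle_voxels_straight(shape, ax, b$center, b$radius %||% 2)
      dir <- c(0, 0, 0); dir[ax] <- 1
      add_fiber(vox, dir, fr)
      n <- shape[ax]
      mid <- floor(n / 2)
      seed <- slab_mask(shape, affine, vox, ax, c(0, 1))
      way <- slab_mask(shape, affine, vox, ax, c(mid - 1, mid + 1))
      stopm <- slab_mask(shape, affine, vox, ax, c(n - 2, n - 1))
      # off-course slab: same extent, displaced laterally out of the bundle
      other <- setdiff(1:3, ax)[1]
      exc_vox <- vox
      off <- if (max(vox[, other]) + 3 * (b$radius %||% 2) < shape[other]) {
        3 * (b$radius %||% 2) + 1
      } else {
        -(3 * (b$radius %||% 2) + 1)
      }
      exc_vox[, other] <- pmin(pmax(exc_vox[, other] + off, 0), shape[other] - 1)
      exc <- vox_to_mask(shape, affine, exc_vox)
    } else if (identical(b$kind, "arc")) {
      ctr <- b$center %||% c(floor(shape[1] / 4), floor(shape[2] / 4),
                             floor(shape[3] / 2))
      arc <- bundle_voxels_arc(shape, ctr, b$radius %||% floor(shape[1] / 3),
                               b$thickness %||% 1.5)
      vox <- arc$vox
      add_fiber(vox, arc$tang, fr)
      ang <- atan2(vox[, 2] - ctr[2], vox[, 1] - ctr[1])
      seed <- vox_to_mask(shape, affine, vox[ang <= 0.12, , drop = FALSE])
      way <- vox_to_mask(shape, affine,
                         vox[abs(ang - pi / 4) <= 0.12, , drop = FALSE])
      stopm <- vox_to_mask(shape, affine,
                           vox[ang >= pi / 2 - 0.12, , drop = FALSE])
      exc_vox <- vox
      exc_vox[, 3] <- pmin(exc_vox[, 3] + 5, shape[3] - 1)
      exc <- vox_to_mask(shape, affine, exc_vox)
    } else {
      stop_bxs("unknown bundle kind '%s'", b$kind, class = "bxs_spec_error")
    }
    protocols[[nm]] <- tract_protocol(
      name = nm, abbreviation = nm, seed = seed, targets = list(way),
      exclusion = exc, stop = stopm)
    truth[[nm]] <- vox_to_mask(shape, affine, vox)
  }

  list(field = fiber_field(orient, frac, affine),
       protocols = protocols, truth = truth, spec = spec)
}

rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  x <- matrix(stats::rgamma(n * k, shape = rep(alpha, each = n)), nrow = n)
  x / rowSums(x)
}

#' Synthetic connectivity blueprints with controlled group divergence
#'
#' Each vertex `v` owns a Dirichlet-mean profile over tracts, shared across
#' groups so the ground-truth vertex correspondence is the identity.  A
#' group-specific profile is mixed into every vertex profile with weight
#' `group_shift` (convex mixing), so expected between-group divergence grows
#' monotonically with `group_shift` and is zero in expectation at
#' `group_shift = 0` (groups exchangeable).  Subject rows are then drawn
#' from a Dirichlet around the shifted profile.
#'
#' @param n_vertices vertices per blueprint.
#' @param n_tracts tract count (>= 2).
#' @param n_groups number of groups ("species"/"age" analogues).
#' @param group_shift mixing weight in `[0, 1]` toward the group profile.
#' @param n_subjects subjects per group.
#' @param concentration Dirichlet concentration for subject sampling around
#'   the vertex profile (larger = less subject noise).
#' @param seed RNG seed.
#' @return list with `groups` (list over groups of lists of subject
#'   matrices, rows normalized), `profiles` (vertex base profiles),
#'   `group_profiles`, `tracts` (tract names).
#' @export
make_synthetic_blueprints <- function(n_vertices, n_tracts, n_groups = 2,
                                      group_shift = 0, n_subjects = 10,
                                      concentration = 100, seed = 1L) {
  assert_that(n_tracts >= 2, "n_tracts must be >= 2", class = "bxs_spec_error")
  assert_that(group_shift >= 0 && group_shift <= 1,
              "group_shift must lie in [0, 1]", class = "bxs_spec_error")
  with_seed_bxs(seed, {
    base <- rdirichlet(n_vertices, rep(1, n_tracts))
    gprof <- rdirichlet(n_groups, rep(1, n_tracts))
    tracts <- paste0("tract", seq_len(n_tracts))
    groups <- lapply(seq_len(n_groups), function(g) {
      target <- (1 - group_shift) * base +
        group_shift * matrix(gprof[g, ], n_vertices, n_tracts, byrow = TRUE)
      lapply(seq_len(n_subjects), function(s) {
        # per-vertex Dirichlet draw around the shifted profile
        m <- matrix(stats::rgamma(n_vertices * n_tracts,
                                  shape = concentration * target),
                    n_vertices, n_tracts)
        m <- m / rowSums(m)
        colnames(m) <- tracts
        connectivity_blueprint(m, tracts, normalized = TRUE)
      })
    })
    list(groups = groups, profiles = base, group_profiles = gprof,
         tracts = tracts)
  })
}

#' Simulate multi-shell DWI signals from a tensor field
#'
#' Noise-free signal follows the single-tensor model
#' `S = S0 * exp(-b * g' D g)`; optional Gaussian (default) or Rician noise
#' at a stated SNR (`S0 / sigma`).  `snr = Inf` gives noise-free data.
#'
#' @param tensors array `[nx, ny, nz, 6]` of tensor components
#'   `(Dxx, Dyy, Dzz, Dxy, Dxz, Dyz)` in mm^2/s, or a single length-6
#'   vector recycled to every voxel of `shape`.
#' @param bvals vector of b-values (s/mm^2), e.g. `c(0, 400, 1000, 2600)`
#'   shells expanded over directions.
#' @param bvecs matrix (n x 3) of unit gradient directions, one per bval.
#' @param snr signal-to-noise ratio `S0 / sigma`; `Inf` for noise-free.
#' @param seed RNG seed.
#' @param s0 non-diffusion-weighted signal level.
#' @param shape grid shape when `tensors` is a single tensor.
#' @param noise `"gaussian"` or `"rician"`.
#' @return a [volume_grid] with a 4-D value array `[nx, ny, nz, n_volumes]`.
#' @export
make_dwi_phantom <- function(tensors, bvals, bvecs, snr = Inf, seed = 1L,
                             s0 = 100, shape = c(5L, 5L, 5L),
                             noise = c("gaussian", "rician")) {
  noise <- match.arg(noise)
  bvecs <- as.matrix(bvecs)
  assert_that(length(bvals) == nrow(bvecs), "one bvec per bval required")
  if (is.null(dim(tensors))) {
    tensors <- array(rep(tensors, each = prod(shape)), c(shape, 6))
  }
  shp <- dim(tensors)[1:3]
  nvox <- prod(shp)
  tm <- matrix(tensors, nvox, 6)
  # positive-definiteness of every voxel tensor
  for (r in seq_len(nvox)) {
    D <- tensor6_to_mat(tm[r, ])
    ev <- eigen(D, symmetric = TRUE, only.values = TRUE)$values
    assert_that(all(ev > 0), "non-positive-definite tensor at voxel %d", r,
                class = "bxs_spec_error")
  }
  # design: bvec quadratic form per volume
  q <- cbind(bvecs[, 1]^2, bvecs[, 2]^2, bvecs[, 3]^2,
             2 * bvecs[, 1] * bvecs[, 2], 2 * bvecs[, 1] * bvecs[, 3],
             2 * bvecs[, 2] * bvecs[, 3])
  expo <- tm %*% t(q * bvals)         # nvox x nvol, b * g'Dg
  sig <- s0 * exp(-expo)
  if (is.finite(snr)) {
    sigma <- s0 / snr
    sig <- with_seed_bxs(seed, {
      if (noise == "gaussian") {
        sig + stats::rnorm(length(sig), sd = sigma)
      } else {
        sqrt((sig + stats::rnorm(length(sig), sd = sigma))^2 +
               stats::rnorm(length(sig), sd = sigma)^2)
      }
    })
  }
  volume_grid(array(sig, c(shp, length(bvals))), diag(4))
}

tensor6_to_mat <- function(t6) {
  matrix(c(t6[1], t6[4], t6[5],
           t6[4], t6[2], t6[6],
           t6[5], t6[6], t6[3]), 3, 3)
}
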