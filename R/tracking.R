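# Probabilistic streamline tractography over a discrete fiber field,
# honoring seed / waypoint / exclusion / stop protocol semantics.

#' Tracking parameters
#'
#' Defaults follow the standardized cross-species tracking configuration:
#' 0.5 mm steps (a 0.2 mm preset suits small, macaque-like brains), an 80
#' degree curvature threshold between successive steps, at most 2000 steps
#' per direction, and subsidiary fibers considered above a 1% volume
#' fraction.
#'
#' @param step_size_mm step length in mm.
#' @param curvature_deg maximum turning angle per step, degrees, in (0, 180].
#' @param max_steps maximum steps per direction.
#' @param fib_threshold volume-fraction threshold for subsidiary fibers.
#' @param samples streamlines per protocol run (cycled over seed voxels).
#' @param seed RNG seed.
#' @export
tracking_params <- function(step_size_mm = 0.5, curvature_deg = 80,
                            max_steps = 2000, fib_threshold = 0.01,
                            samples = 1000, seed = 1L) {
  assert_that(step_size_mm > 0, "step size must be positive")
  assert_that(curvature_deg > 0 && curvature_deg <= 180,
              "curvature threshold must lie in (0, 180] degrees")
  structure(list(step_size_mm = step_size_mm, curvature_deg = curvature_deg,
                 max_steps = max_steps, fib_threshold = fib_threshold,
                 samples = samples, seed = seed),
            class = "tracking_params")
}

#' Macaque-style preset (0.2 mm steps)
#' @param ... overrides passed to [tracking_params()].
#' @export
tracking_params_macaque <- function(...) tracking_params(step_size_mm = 0.2, ...)

# sample one fiber direction at a 0-based voxel (probability proportional
# to volume fraction).  Returns NULL when no fiber clears the threshold.
# Orientations are treated as directed; the caller applies the run sign.
sample_fiber <- function(field, vox, fib_threshold) {
  i <- vox[1] + 1L; j <- vox[2] + 1L; k <- vox[3] + 1L
  fr <- field$fractions[i, j, k, ]
  ok <- which(fr >= fib_threshold & fr > 0)
  if (length(ok) == 0L) return(NULL)
  pick <- if (length(ok) == 1L) ok else sample(ok, 1L, prob = fr[ok])
  field$orientations[i, j, k, pick, ]
}

# locally dominant fiber (largest fraction), or NULL outside the mask
dominant_fiber <- function(field, vox, fib_threshold) {
  i <- vox[1] + 1L; j <- vox[2] + 1L; k <- vox[3] + 1L
  fr <- field$fractions[i, j, k, ]
  ok <- which(fr >= fib_threshold & fr > 0)
  if (length(ok) == 0L) return(NULL)
  field$orientations[i, j, k, ok[which.max(fr[ok])], ]
}

in_grid <- function(vox, shape) {
  all(vox >= 0) && all(vox < shape)
}

# track one sense (run_sign = +1 / -1) from pos0; the run sign, fixed at
# the seed, is applied to every sampled orientation, so a genuine turn
# sharper than the curvature threshold terminates the streamline (the
# field is assumed sign-consistent along bundles, which the phantoms
# guarantee).  Returns positions (excluding pos0) and a termination reason.
track_one_direction <- function(field, pos0, run_sign, heading, params,
                                inv_affine, shape, stop_vals) {
  cos_thr <- cos(params$curvature_deg * pi / 180)
  pts <- matrix(NA_real_, params$max_steps, 3)
  pos <- pos0
  reason <- "max_steps"
  n <- 0L
  for (s in seq_len(params$max_steps)) {
    vox <- floor((inv_affine %*% c(pos, 1))[1:3] + 1e-9)
    if (!in_grid(vox, shape)) { reason <- "mask_exit"; break }
    if (!is.null(stop_vals) && stop_vals[vox[1] + 1, vox[2] + 1, vox[3] + 1] != 0) {
      reason <- "stop"; break
    }
    d <- sample_fiber(field, vox, params$fib_threshold)
    if (is.null(d)) { reason <- "mask_exit"; break }
    d <- run_sign * d
    if (sum(d * heading) < cos_thr) { reason <- "curvature"; break }
    new_pos <- pos + params$step_size_mm * d
    new_vox <- floor((inv_affine %*% c(new_pos, 1))[1:3] + 1e-9)
    if (!in_grid(new_vox, shape)) { reason <- "mask_exit"; break }
    pos <- new_pos
    heading <- d
    n <- n + 1L
    pts[n, ] <- pos
  }
  list(points = pts[seq_len(n), , drop = FALSE], reason = reason)
}

#' Propagate one streamline from a seed point
#'
#' Both directions from the seed are tracked and concatenated.  At each
#' step one fiber is sampled among those above the volume-fraction
#' threshold with probability proportional to its fraction; the run's
#' sign (chosen at the seed: the locally dominant fiber for the forward
#' run, its negation for the backward run) is applied to the sampled
#' orientation, so sign alignment with the heading is fixed per run and a
#' genuine turn sharper than the curvature threshold terminates tracking.
#' Propagation also terminates on tracking-mask exit, stop-mask entry or
#' the step cap.
#'
#' @param field a [fiber_field].
#' @param seed_point world coordinates (mm) of the seed.
#' @param params a [tracking_params].
#' @param stop_mask optional binary [volume_grid].
#' @return list with `points` (n x 3 polyline including the seed),
#'   `reasons` (termination reason per direction), `rejected` (TRUE when
#'   the seed fell outside the tracking mask).
#' @export
propagate_streamline <- function(field, seed_point, params = tracking_params(),
                                 stop_mask = NULL) {
  shape <- dim(field$fractions)[1:3]
  inv_affine <- solve(field$affine)
  vox <- floor((inv_affine %*% c(seed_point, 1))[1:3] + 1e-9)
  if (!in_grid(vox, shape)) {
    return(list(points = matrix(seed_point, 1), reasons = character(),
                rejected = TRUE))
  }
  d0 <- dominant_fiber(field, vox, params$fib_threshold)
  if (is.null(d0)) {
    return(list(points = matrix(seed_point, 1), reasons = character(),
                rejected = TRUE))
  }
  stop_vals <- if (!is.null(stop_mask)) stop_mask$values
  fwd <- track_one_direction(field, seed_point, +1, d0, params, inv_affine,
                             shape, stop_vals)
  bwd <- track_one_direction(field, seed_point, -1, -d0, params, inv_affine,
                             shape, stop_vals)
  pts <- rbind(bwd$points[rev(seq_len(nrow(bwd$points))), , drop = FALSE],
               matrix(seed_point, 1),
               fwd$points)
  list(points = pts, reasons = c(backward = bwd$reason, forward = fwd$reason),
       rejected = FALSE)
}

#' Path density map
#'
#' Visitation volume for one tract.  Each valid streamline contributes at
#' most one count per voxel (binary visitation), so the normalized map —
#' counts divided by the number of valid streamlines — reads as a
#' per-voxel visitation probability, which is what the downstream 0.1%
#' thresholds assume.
#'
#' @param counts a [volume_grid] of visitation counts.
#' @param n_valid number of valid streamlines.
#' @param normalized has `counts` been divided by `n_valid`?
#' @param empty TRUE when the run produced zero valid streamlines.
#' @param log named counts (valid/invalid/rejected) from the generating run.
#' @export
path_density_map <- function(counts, n_valid, normalized = FALSE,
                             empty = n_valid == 0, log = NULL) {
  structure(list(counts = counts, n_valid = n_valid, normalized = normalized,
                 empty = empty, log = log),
            class = "path_density_map")
}

#' @export
print.path_density_map <- function(x, ...) {
  cat(sprintf("<path_density_map> %s, %d valid streamline(s)%s%s\n",
              paste(grid_shape(x$counts), collapse = " x "), x$n_valid,
              if (x$normalized) ", normalized" else "",
              if (x$empty) ", EMPTY" else ""))
  invisible(x)
}

#' Normalize a path density map by its valid-streamline count
#' @param pdm a [path_density_map].
#' @export
normalize_density <- function(pdm) {
  if (pdm$normalized) return(pdm)
  vals <- if (pdm$n_valid > 0) pdm$counts$values / pdm$n_valid else
    pdm$counts$values * 0
  path_density_map(volume_grid(vals + 0.0, pdm$counts$affine), pdm$n_valid,
                   normalized = TRUE, empty = pdm$empty, log = pdm$log)
}

run_protocol_once <- function(field, seed_mask, targets, exclusion, stop_mask,
                              params) {
  shape <- dim(field$fractions)[1:3]
  seeds <- mask_voxels(seed_mask)
  assert_that(nrow(seeds) > 0, "seed mask is empty", class = "bxs_protocol_error")
  counts <- array(0, shape)
  target_vals <- lapply(targets, function(t) t$values)
  exc_vals <- if (!is.null(exclusion)) exclusion$values
  n_valid <- 0L; n_invalid <- 0L; n_rejected <- 0L
  inv_affine <- solve(field$affine)
  for (s in seq_len(params$samples)) {
    sv <- seeds[((s - 1L) %% nrow(seeds)) + 1L, ]
    # jittered start point inside the seed voxel
    p0 <- (field$affine %*% c(sv + stats::runif(3), 1))[1:3]
    sl <- propagate_streamline(field, p0, params, stop_mask = stop_mask)
    if (sl$rejected) { n_rejected <- n_rejected + 1L; next }
    vox <- floor(t(inv_affine %*% rbind(t(sl$points), 1))[, 1:3, drop = FALSE] + 1e-9)
    keep <- vox[, 1] >= 0 & vox[, 1] < shape[1] &
      vox[, 2] >= 0 & vox[, 2] < shape[2] &
      vox[, 3] >= 0 & vox[, 3] < shape[3]
    vox <- vox[keep, , drop = FALSE]
    if (nrow(vox) == 0L) { n_invalid <- n_invalid + 1L; next }
    lin <- unique(1 + vox[, 1] + shape[1] * (vox[, 2] + shape[2] * vox[, 3]))
    if (!is.null(exc_vals) && any(exc_vals[lin] != 0)) {
      n_invalid <- n_invalid + 1L; next
    }
    hit_all <- all(vapply(target_vals, function(tv) any(tv[lin] != 0), TRUE))
    if (!hit_all) { n_invalid <- n_invalid + 1L; next }
    counts[lin] <- counts[lin] + 1
    n_valid <- n_valid + 1L
  }
  path_density_map(volume_grid(counts, field$affine), n_valid,
                   log = c(valid = n_valid, invalid = n_invalid,
                           rejected = n_rejected))
}

#' Run a tract protocol and return its normalized path density map
#'
#' Streamlines are seeded across all seed voxels (cycled, with uniform
#' jitter inside each voxel).  A streamline is valid iff it visits every
#' waypoint mask (in any order); any exclusion-mask visit discards it;
#' stop masks truncate propagation.  Valid streamlines are counted once
#' per visited voxel and the map is normalized by the number of valid
#' streamlines.  With `reverse_seeding`, the protocol is rerun with the
#' seed and target roles exchanged and the two normalized distributions
#' are added together.
#'
#' A run with zero valid streamlines returns an all-zero map with
#' `empty = TRUE` rather than failing silently.
#'
#' @param field a [fiber_field].
#' @param protocol a [tract_protocol] on the field's grid.
#' @param params a [tracking_params].
#' @return a normalized [path_density_map].
#' @export
run_protocol <- function(field, protocol, params = tracking_params()) {
  assert_same_grid(field_mask(field), protocol$seed, "field and protocol")
  with_seed_bxs(params$seed, {
    fwd <- normalize_density(run_protocol_once(
      field, protocol$seed, protocol$targets, protocol$exclusion,
      protocol$stop, params))
    if (!protocol$reverse_seeding) return(fwd)
    assert_that(length(protocol$targets) > 0,
                "reverse seeding requires at least one target",
                class = "bxs_protocol_error")
    # seed from the union of the target masks; old seed becomes the waypoint
    tvals <- Reduce(`+`, lapply(protocol$targets, function(t) t$values))
    rev_seed <- volume_grid(array(as.integer(tvals != 0), dim(tvals)),
                            protocol$seed$affine)
    rev <- normalize_density(run_protocol_once(
      field, rev_seed, list(protocol$seed), protocol$exclusion,
      protocol$stop, params))
    path_density_map(
      volume_grid(fwd$counts$values + rev$counts$values, fwd$counts$affine),
      n_valid = fwd$n_valid + rev$n_valid, normalized = TRUE,
      empty = fwd$empty && rev$empty,
      log = fwd$log + rev$log)
  })
}
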