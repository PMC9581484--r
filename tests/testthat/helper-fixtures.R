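# Shared fixture builders.  Everything is generated in code at test time;
# nothing is read from disk except files the tests themselves write.

# single-column straight bundle along x: every streamline shares one voxel
# column, so normalized density in bundle voxels is exactly 1
straight_phantom <- function(nx = 30, seed = 7) {
  spec <- phantom_spec(
    shape = c(nx, 12L, 12L),
    bundles = list(list(kind = "straight", axis = 1, center = c(6, 6),
                        radius = 0.5, fraction = 1)),
    seed = seed)
  make_fiber_phantom(spec)
}

# thicker bundle for atlas / multi-subject tests
wide_phantom <- function(nx = 24, radius = 1.5, seed = 7) {
  spec <- phantom_spec(
    shape = c(nx, 12L, 12L),
    bundles = list(list(kind = "straight", axis = 1, center = c(6, 6),
                        radius = radius, fraction = 1)),
    seed = seed)
  make_fiber_phantom(spec)
}

fast_params <- function(samples = 60, seed = 1, ...) {
  tracking_params(samples = samples, seed = seed, ...)
}

# random normalized blueprint with all-valid rows
random_blueprint <- function(nv, nt, seed = 1) {
  withr::with_seed(seed, {
    m <- matrix(stats::rgamma(nv * nt, 1), nv, nt)
    m <- m / rowSums(m)
    connectivity_blueprint(m, paste0("t", seq_len(nt)), normalized = TRUE)
  })
}

# independent brute-force oracle for the two-term symmetric KL sum
oracle_symmetric_kl <- function(p, q, floor = 1e-6) {
  p <- p + floor; p <- p / sum(p)
  q <- q + floor; q <- q / sum(q)
  s <- 0
  for (k in seq_along(p)) {
    s <- s + p[k] * log2(p[k] / q[k]) + q[k] * log2(q[k] / p[k])
  }
  unname(s)
}

# per-subject map list (single tract named "b") from a density map
subject_maps <- function(pdm) list(b = pdm)
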