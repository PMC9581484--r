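# Synthetic ground-truth generators.

test_that("straight bundle voxels carry the bundle orientation", {
  ph <- straight_phantom(nx = 20)
  tv <- which(ph$truth[[1]]$values == 1, arr.ind = TRUE)
  for (r in seq_len(nrow(tv))) {
    o <- ph$field$orientations[tv[r, 1], tv[r, 2], tv[r, 3], 1, ]
    expect_equal(o, c(1, 0, 0))
    expect_equal(ph$field$fractions[tv[r, 1], tv[r, 2], tv[r, 3], 1], 1)
  }
  # protocol masks live on the bundle: seed at one end, waypoint mid,
  # stop at the far end
  p <- ph$protocols[[1]]
  expect_gt(mask_count(p$seed), 0)
  expect_gt(mask_count(p$targets[[1]]), 0)
  expect_gt(mask_count(p$stop), 0)
  expect_identical(sum(p$seed$values * ph$truth[[1]]$values),
                   sum(p$seed$values))
})

test_that("90-degree crossing voxels carry two fibers at 0.5/0.5", {
  spec <- phantom_spec(shape = c(20, 20, 8),
                       bundles = list(list(kind = "crossing",
                                           center = c(10, 10, 4),
                                           radius = 1, fraction = 0.5)))
  ph <- make_fiber_phantom(spec)
  both <- ph$truth[[1]]$values * ph$truth[[2]]$values
  expect_gt(sum(both), 0)
  ix <- which(both == 1, arr.ind = TRUE)[1, ]
  fr <- ph$field$fractions[ix[1], ix[2], ix[3], ]
  expect_equal(sort(fr[fr > 0]), c(0.5, 0.5))
  o1 <- ph$field$orientations[ix[1], ix[2], ix[3], 1, ]
  o2 <- ph$field$orientations[ix[1], ix[2], ix[3], 2, ]
  expect_equal(abs(sum(o1 * o2)), 0)              # orthogonal
})

test_that("overlapping bundles beyond the fraction budget are rejected", {
  spec <- phantom_spec(shape = c(16, 10, 10),
                       bundles = list(
                         list(kind = "straight", axis = 1, center = c(5, 5),
                              radius = 1, fraction = 0.8),
                         list(kind = "straight", axis = 2, center = c(5, 5),
                              radius = 1, fraction = 0.8)))
  expect_error(make_fiber_phantom(spec), "fraction budget",
               class = "bxs_spec_error")
})

test_that("phantom generation is seed-deterministic", {
  a <- make_fiber_phantom(phantom_spec(shape = c(16, 8, 8), seed = 3,
    bundles = list(list(kind = "straight", axis = 1, center = c(4, 4),
                        radius = 1, fraction = 1))))
  b <- make_fiber_phantom(phantom_spec(shape = c(16, 8, 8), seed = 3,
    bundles = list(list(kind = "straight", axis = 1, center = c(4, 4),
                        radius = 1, fraction = 1))))
  expect_identical(a$field$orientations, b$field$orientations)
  expect_identical(a$field$fractions, b$field$fractions)
})

test_that("synthetic blueprint rows are probability vectors, identity truth", {
  res <- make_synthetic_blueprints(30, 6, n_groups = 2, group_shift = 0.3,
                                   n_subjects = 4, seed = 2)
  for (g in res$groups) {
    for (bp in g) {
      expect_lt(max(abs(rowSums(bp$matrix) - 1)), 1e-9)
      expect_true(all(bp$matrix >= 0))
    }
  }
  expect_error(make_synthetic_blueprints(10, 1, n_subjects = 2),
               "n_tracts", class = "bxs_spec_error")
  # fixed seed -> reproducible matrices
  res2 <- make_synthetic_blueprints(30, 6, n_groups = 2, group_shift = 0.3,
                                    n_subjects = 4, seed = 2)
  expect_identical(res$groups[[1]][[1]]$matrix, res2$groups[[1]][[1]]$matrix)
})

test_that("group_shift = 0 makes within- and between-group divergence equal", {
  # groups are exchangeable at shift 0: compare mean divergence between
  # group averages across two disjoint splits of one group vs across groups
  res <- make_synthetic_blueprints(40, 6, n_groups = 2, group_shift = 0,
                                   n_subjects = 8, concentration = 50,
                                   seed = 9)
  within <- mean(min_divergence_map(divergence_matrix(
    average_blueprints(res$groups[[1]][1:4]),
    average_blueprints(res$groups[[1]][5:8])))$value)
  between <- mean(min_divergence_map(divergence_matrix(
    average_blueprints(res$groups[[1]][1:4]),
    average_blueprints(res$groups[[2]][1:4])))$value)
  expect_lt(abs(within - between) / within, 0.5)   # same order, noise only
})

test_that("one-hot rows on different tracts give the maximal divergence", {
  m <- rbind(c(1, 0, 0), c(0, 1, 0), c(0.4, 0.3, 0.3))
  bp <- connectivity_blueprint(m, paste0("t", 1:3), normalized = TRUE)
  D <- divergence_matrix(bp, bp)$D
  off <- D[upper.tri(D) | lower.tri(D)]
  expect_equal(max(off), D[1, 2])
  expect_equal(D[1, 2], oracle_symmetric_kl(m[1, ], m[2, ]), tolerance = 1e-9)
})

test_that("DWI phantom follows the closed-form tensor signal", {
  iso <- c(1e-3, 1e-3, 1e-3, 0, 0, 0)
  bv <- rbind(c(0, 0, 0), c(1, 0, 0), c(0.6, 0.8, 0))
  dwi <- make_dwi_phantom(iso, c(0, 1000, 1000), bv, snr = Inf,
                          shape = c(2, 2, 2), s0 = 100)
  # isotropic: S/S0 = exp(-b d) for any direction
  expect_equal(dwi$values[1, 1, 1, 2] / dwi$values[1, 1, 1, 1],
               exp(-1000 * 1e-3), tolerance = 1e-12)
  expect_equal(dwi$values[1, 1, 1, 3], dwi$values[1, 1, 1, 2])

  # prolate tensor, gradient perpendicular to the principal axis:
  # attenuation governed by the radial diffusivity only
  pro <- c(1.7e-3, 2e-4, 2e-4, 0, 0, 0)
  bv2 <- rbind(c(0, 0, 0), c(0, 1, 0), c(0, 0.6, 0.8))
  dwi2 <- make_dwi_phantom(pro, c(0, 1000, 1000), bv2, snr = Inf,
                           shape = c(2, 2, 2), s0 = 50)
  expect_equal(dwi2$values[2, 1, 1, 2] / dwi2$values[2, 1, 1, 1],
               exp(-1000 * 2e-4), tolerance = 1e-12)
  expect_equal(dwi2$values[2, 1, 1, 3] / dwi2$values[2, 1, 1, 1],
               exp(-1000 * 2e-4), tolerance = 1e-12)

  # snr = Inf is noise-free and deterministic; finite snr is seeded
  n1 <- make_dwi_phantom(iso, c(0, 1000), bv[1:2, ], snr = 20, seed = 4,
                         shape = c(2, 2, 2))
  n2 <- make_dwi_phantom(iso, c(0, 1000), bv[1:2, ], snr = 20, seed = 4,
                         shape = c(2, 2, 2))
  expect_identical(n1$values, n2$values)

  # non-positive-definite tensor rejected
  expect_error(make_dwi_phantom(c(-1e-3, 1e-3, 1e-3, 0, 0, 0),
                                c(0, 1000), bv[1:2, ], shape = c(1, 1, 1)),
               "positive-definite", class = "bxs_spec_error")
})
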