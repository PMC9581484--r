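# Symmetric KL divergence and derived maps.

test_that("symmetric_kl: hand cases and the independent oracle", {
  expect_equal(symmetric_kl(c(0.5, 0.5), c(0.5, 0.5)), 0, tolerance = 1e-12)
  # closed-form hand evaluation: (0.75,0.25) vs (0.25,0.75) = log2 3
  expect_equal(symmetric_kl(c(0.75, 0.25), c(0.25, 0.75)), log2(3),
               tolerance = 1e-4)
  expect_error(symmetric_kl(c(0.5, 0.5), c(1, 0, 0)), "length")
  expect_error(symmetric_kl(c(-0.1, 1.1), c(0.5, 0.5)), "nonnegative")
  # oracle equivalence on random distribution pairs
  withr::with_seed(42, {
    for (rep in 1:200) {
      k <- sample(2:12, 1)
      p <- rgamma(k, 1); p <- p / sum(p)
      q <- rgamma(k, 1); q <- q / sum(q)
      expect_equal(symmetric_kl(p, q), oracle_symmetric_kl(p, q),
                   tolerance = 1e-12)
    }
  })
})

test_that("symmetric_kl properties: nonneg, symmetric, identity", {
  withr::with_seed(7, {
    for (rep in 1:50) {
      k <- sample(2:8, 1)
      p <- rgamma(k, 1); p <- p / sum(p)
      q <- rgamma(k, 1); q <- q / sum(q)
      d <- symmetric_kl(p, q)
      expect_gte(d, 0)
      expect_equal(d, symmetric_kl(q, p), tolerance = 1e-12)
      expect_equal(symmetric_kl(p, p), 0, tolerance = 1e-12)
      if (max(abs(p - q)) > 1e-6) expect_gt(d, 0)
    }
  })
})

test_that("divergence_matrix matches the oracle loop and transposes", {
  N <- random_blueprint(6, 4, seed = 1)
  A <- random_blueprint(5, 4, seed = 2)
  dm <- divergence_matrix(N, A)
  for (i in 1:6) for (j in 1:5) {
    expect_equal(dm$D[i, j],
                 oracle_symmetric_kl(N$matrix[i, ], A$matrix[j, ]),
                 tolerance = 1e-9)
  }
  # swapping the blueprints transposes D
  dm2 <- divergence_matrix(A, N)
  expect_equal(dm2$D, t(dm$D), tolerance = 1e-12)
  # N = A -> zero diagonal
  dm3 <- divergence_matrix(N, N)
  expect_equal(unname(diag(dm3$D)), rep(0, 6), tolerance = 1e-9)
  # tract mismatch -> error
  B <- connectivity_blueprint(A$matrix, paste0("x", 1:4), normalized = TRUE)
  expect_error(divergence_matrix(N, B), class = "bxs_grid_error")
})

test_that("invalid rows are masked through the matrix and the min map", {
  m <- rbind(c(0.5, 0.5), c(0, 0), c(0.2, 0.8))
  bp <- normalize_rows(connectivity_blueprint(m, c("a", "b")))
  dm <- divergence_matrix(bp, bp)
  expect_true(all(is.na(dm$D[2, ])))
  expect_true(all(is.na(dm$D[, 2])))
  mm <- min_divergence_map(dm)
  expect_true(is.na(mm$value[2]))
  expect_identical(mm$argmin[1], 1L)
})

test_that("min_divergence_map recovers permutations, ties break low", {
  # hand 2x3 matrix: min/argmin by inspection
  D <- rbind(c(0.3, 0.1, 0.7), c(0.2, 0.2, 0.9))
  mm <- min_divergence_map(D)
  expect_equal(mm$value, c(0.1, 0.2))
  expect_identical(mm$argmin, c(2L, 1L))          # tie in row 2 -> lowest index
  # column-permuted copy with distinct rows -> argmin recovers the
  # permutation, map is all zeros
  bp <- random_blueprint(20, 6, seed = 9)
  withr::with_seed(10, perm <- sample(20))
  bp_p <- connectivity_blueprint(bp$matrix[perm, ], bp$tracts,
                                 normalized = TRUE)
  mm2 <- min_divergence_map(divergence_matrix(bp_p, bp))
  expect_identical(mm2$argmin, perm)
  expect_equal(mm2$value, rep(0, 20), tolerance = 1e-9)
})

test_that("parcellated divergence equals the brute-force median oracle", {
  withr::with_seed(11, {
    D <- matrix(runif(400), 20, 20)
  })
  dm <- structure(list(D = D, row_valid = rep(TRUE, 20),
                       col_valid = rep(TRUE, 20), floor = 1e-6),
                  class = "divergence_matrix")
  lab <- rep(1:4, each = 5)
  nm <- stats::setNames(paste0("p", 1:4), 1:4)
  parc <- parcellation(lab, nm)
  pd <- parcellate_divergence(dm, parc, parc)
  for (a in 1:4) for (b in 1:4) {
    expect_equal(pd$D[a, b],
                 stats::median(D[lab == a, lab == b]))   # midpoint convention
  }
  # one-vertex parcels: parcellation is the identity
  parc1 <- parcellation(1:20, stats::setNames(paste0("v", 1:20), 1:20))
  pd1 <- parcellate_divergence(dm, parc1, parc1)
  expect_equal(unname(pd1$D), unname(D))
  # single parcel each side: the global median
  parcg <- parcellation(rep(1L, 20), c(`1` = "all"))
  expect_equal(unname(parcellate_divergence(dm, parcg, parcg)$D[1, 1]),
               stats::median(D))
  # excluded parcels never enter the result
  parc_ex <- parcellation(lab, nm, exclusions = 2L)
  pd_ex <- parcellate_divergence(dm, parc_ex, parc_ex)
  expect_identical(dim(pd_ex$D), c(3L, 3L))
  expect_false("p2" %in% rownames(pd_ex$D))
  # diagonal extraction requires identical schemes
  expect_equal(unname(corresponding_parcel_divergence(pd)),
               unname(diag(pd$D)))
  pd_mism <- parcellate_divergence(dm, parc, parc_ex)
  expect_error(corresponding_parcel_divergence(pd_mism),
               class = "bxs_spec_error")
})

test_that("joint and xor map algebra reproduce the printed formulas", {
  mk <- function(v) structure(list(value = v, argmin = NULL, scaled = TRUE),
                              class = "divergence_map")
  one <- mk(1); zero <- mk(0); half <- mk(0.5)
  expect_equal(joint_divergence(one, one)$value, 1)
  expect_equal(xor_divergence(one, one)$value, 0)
  expect_equal(joint_divergence(one, zero)$value, 0)
  expect_equal(xor_divergence(one, zero)$value, 1)
  expect_equal(joint_divergence(half, half)$value, 0.25)
  expect_equal(xor_divergence(half, half)$value, 0.5)
  # random maps vs the formula oracle, element-wise
  withr::with_seed(12, {
    b <- runif(50); c2 <- runif(50)
  })
  jb <- joint_divergence(mk(b), mk(c2))$value
  xb <- xor_divergence(mk(b), mk(c2))$value
  expect_equal(jb, b * c2)
  expect_equal(xb, b + c2 - 2 * b * c2)
  expect_true(all(jb >= 0 & jb <= 1 & xb >= 0 & xb <= 1))
  # unrescaled inputs are refused (explicit state machine)
  raw_map <- structure(list(value = b, argmin = NULL, scaled = FALSE),
                       class = "divergence_map")
  expect_error(joint_divergence(raw_map, mk(c2)), "rescale",
               class = "bxs_state_error")
  # rescale_map maps to [0,1] with min 0 and max 1
  rs <- rescale_map(structure(list(value = c(2, 4, 3), argmin = NULL,
                                   scaled = FALSE), class = "divergence_map"))
  expect_equal(rs$value, c(0, 1, 0.5))
})

test_that("entropy_map: uniform, one-hot, and hand case", {
  m <- rbind(rep(1 / 8, 8),
             c(1, rep(0, 7)),
             c(0.5, 0.25, 0.25, rep(0, 5)))
  bp <- connectivity_blueprint(m, paste0("t", 1:8), normalized = TRUE)
  h <- entropy_map(bp)
  expect_equal(unname(h), c(3, 0, 1.5), tolerance = 1e-12)
})

test_that("bootstrap divergence: identical subjects give zero variance", {
  bp <- random_blueprint(15, 5, seed = 3)
  ga <- list(bp, bp, bp)
  gb <- list(bp, bp)
  res <- bootstrap_divergence(ga, gb, size_a = 3, size_b = 2, n_iter = 10,
                              seed = 5)
  expect_equal(res$variance, rep(0, 15))
  expect_equal(res$mean, rep(0, 15), tolerance = 1e-9)
  # fixed seed -> bit-identical reruns
  res2 <- bootstrap_divergence(ga, gb, size_a = 3, size_b = 2, n_iter = 10,
                               seed = 5)
  expect_identical(res$mean, res2$mean)
  expect_error(bootstrap_divergence(list(), gb), class = "bxs_spec_error")
})

test_that("bootstrap divergence grows with phantom group shift", {
  sizes <- c(8, 8)
  shift_means <- sapply(c(0, 0.3), function(sh) {
    res <- make_synthetic_blueprints(25, 6, n_groups = 2, group_shift = sh,
                                     n_subjects = 8, concentration = 80,
                                     seed = 17)
    bt <- bootstrap_divergence(res$groups[[1]], res$groups[[2]],
                               size_a = sizes[1], size_b = sizes[2],
                               n_iter = 15, seed = 19)
    mean(bt$mean)
  })
  expect_gt(shift_means[2], shift_means[1])
})
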