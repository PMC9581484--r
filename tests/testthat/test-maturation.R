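# Tensor fitting, tract medians, and the age GLM.

dirs_12 <- function() {
  # 12 well-spread unit directions (icosahedron vertices)
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
             c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
             c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v / sqrt(rowSums(v^2))
}

test_that("noise-free DTI fit recovers the generating tensor", {
  g <- rbind(c(0, 0, 0), dirs_12())
  bvals <- c(0, rep(1000, 12))
  iso <- c(1e-3, 1e-3, 1e-3, 0, 0, 0)
  dwi <- make_dwi_phantom(iso, bvals, g, snr = Inf, shape = c(2, 2, 2))
  fit <- fit_dti(dwi, bvals, g)
  expect_equal(fit$fa$values[1, 1, 1], 0, tolerance = 1e-8)
  expect_equal(fit$md$values[1, 1, 1], 1e-3, tolerance = 1e-10)

  pro <- c(1.7e-3, 2e-4, 2e-4, 0, 0, 0)
  dwi2 <- make_dwi_phantom(pro, bvals, g, snr = Inf, shape = c(2, 2, 2))
  fit2 <- fit_dti(dwi2, bvals, g)
  ev <- c(1.7e-3, 2e-4, 2e-4)
  fa_true <- sqrt(1.5 * sum((ev - mean(ev))^2)) / sqrt(sum(ev^2))
  expect_equal(fit2$fa$values[1, 1, 1], fa_true, tolerance = 1e-8)
  expect_equal(fit2$md$values[1, 1, 1], mean(ev), tolerance = 1e-10)
  # fitted tensor equals the generating tensor within 1e-8
  expect_lt(max(abs(matrix(fit2$tensor$values, 8, 6)[1, ] - pro)), 1e-8)
  expect_true(all(fit2$physical$values == 1))
  # a rotated (off-diagonal) tensor also round-trips
  R <- qr.Q(qr(matrix(c(1, 2, 0, 0, 1, 1, 1, 0, 1), 3)))
  Dm <- R %*% diag(ev) %*% t(R)
  rot <- c(Dm[1, 1], Dm[2, 2], Dm[3, 3], Dm[1, 2], Dm[1, 3], Dm[2, 3])
  dwi3 <- make_dwi_phantom(rot, bvals, g, snr = Inf, shape = c(2, 2, 2))
  fit3 <- fit_dti(dwi3, bvals, g)
  expect_lt(max(abs(matrix(fit3$tensor$values, 8, 6)[1, ] - rot)), 1e-8)
  expect_equal(fit3$fa$values[1, 1, 1], fa_true, tolerance = 1e-8)
})

test_that("the fit uses only the b=0 and inner-shell volumes", {
  g <- rbind(c(0, 0, 0), dirs_12(), dirs_12())
  bvals <- c(0, rep(1000, 12), rep(2600, 12))
  pro <- c(1.5e-3, 3e-4, 3e-4, 0, 0, 0)
  dwi <- make_dwi_phantom(pro, bvals, g, snr = Inf, shape = c(1, 2, 2))
  # corrupt the outer shell: must not affect the fit
  vals <- dwi$values
  vals[, , , 14:25] <- vals[, , , 14:25] * 10
  fit <- fit_dti(volume_grid(vals, dwi$affine), bvals, g)
  expect_lt(max(abs(matrix(fit$tensor$values, 4, 6)[1, ] - pro)), 1e-8)
  # FA in [0,1] and MD = mean eigenvalue
  expect_true(all(fit$fa$values >= 0 & fit$fa$values <= 1))
})

test_that("insufficient directions are refused", {
  g <- rbind(c(0, 0, 0), diag(3))
  bvals <- c(0, rep(1000, 3))
  dwi <- make_dwi_phantom(c(1e-3, 1e-3, 1e-3, 0, 0, 0), bvals, g,
                          shape = c(1, 1, 2))
  expect_error(fit_dti(dwi, bvals, g), "6 unique", class = "bxs_spec_error")
})

test_that("tract medians and volumes come from thresholded atlas ROIs", {
  v <- array(0, c(5, 5, 5))
  v[1:5, 1, 1] <- 1:5
  atlas_vals <- array(0, c(5, 5, 5))
  atlas_vals[1:5, 1, 1] <- c(100, 100, 50, 40, 20)  # 30% cut keeps 4 voxels
  atl <- population_atlas(list(tr = volume_grid(atlas_vals)), 10, 0.001)
  res <- tract_median_metric(volume_grid(v), atl, population_threshold = 30)
  expect_equal(res$median, stats::median(c(1, 2, 3, 4)))
  expect_equal(res$volume_mm3, 4)                   # 1 mm^3 voxels
  # constant metric in mask
  res2 <- tract_median_metric(volume_grid(array(0.4, c(5, 5, 5))), atl)
  expect_equal(res2$median, 0.4)
  # empty mask -> missing value
  atl0 <- population_atlas(list(tr = volume_grid(array(0, c(5, 5, 5)))), 10,
                           0.001)
  expect_true(is.na(tract_median_metric(volume_grid(v), atl0)$median))
  # random volume vs brute-force median oracle
  withr::with_seed(6, {
    rv <- array(runif(125), c(5, 5, 5))
    ra <- array(runif(125, 0, 100), c(5, 5, 5))
  })
  atlr <- population_atlas(list(tr = volume_grid(ra)), 10, 0.001)
  resr <- tract_median_metric(volume_grid(rv), atlr)
  expect_equal(resr$median, stats::median(rv[ra >= 30]))
})

test_that("the age GLM recovers a planted beta within 2 SE", {
  sim <- simulate_maturation_cohort(
    n_subjects = 200,
    betas = c(proj = 0.004),
    noise_sd = 0.01, seed = 41)
  res <- fit_maturation_glm(sim$metrics, sim$age_weeks, sim$confounds)
  expect_lt(abs(res$beta_age - 0.004), 2 * res$se)
  expect_true(res$significant)                       # strong planted effect
})

test_that("planted projection > limbic beta ordering is reproduced", {
  betas <- c(proj1 = 0.006, proj2 = 0.005, limbic1 = 0.001, limbic2 = 0.0015)
  sim <- simulate_maturation_cohort(n_subjects = 150, betas = betas,
                                    noise_sd = 0.01, seed = 43)
  res <- fit_maturation_glm(sim$metrics, sim$age_weeks, sim$confounds)
  b <- stats::setNames(res$beta_age, res$tract)
  expect_gt(min(b[c("proj1", "proj2")]), max(b[c("limbic1", "limbic2")]))
})

test_that("Bonferroni flag matches the family rule and collinearity errors", {
  sim <- simulate_maturation_cohort(n_subjects = 60,
                                    betas = c(a = 0, b = 0, c = 0),
                                    noise_sd = 0.02, seed = 47)
  res <- fit_maturation_glm(sim$metrics, sim$age_weeks, sim$confounds)
  expect_identical(res$significant, res$p < 0.05 / 3)
  expect_equal(attr(res, "family")$n_tests, 3)
  # confound perfectly collinear with age -> explicit rank-deficiency error
  conf <- sim$confounds
  conf$age_copy <- sim$age_weeks
  expect_error(fit_maturation_glm(sim$metrics, sim$age_weeks, conf),
               "collinear", class = "bxs_design_error")
})

test_that("Bonferroni controls family-wise error in a null simulation", {
  # scaled-down version of the 42-test null check: 12 tracts, 60 reps
  n_rep <- 60; n_tests <- 12; n <- 40
  fwe <- withr::with_seed(51, {
    hits <- 0
    for (r in seq_len(n_rep)) {
      age <- runif(n, 37, 45)
      p <- sapply(seq_len(n_tests), function(t) {
        y <- rnorm(n)
        summary(stats::lm(y ~ age))$coefficients["age", "Pr(>|t|)"]
      })
      if (any(p < 0.05 / n_tests)) hits <- hits + 1
    }
    hits / n_rep
  })
  # binomial(60, 0.05) upper tail: allow generous slack
  expect_lte(fwe, 0.15)
})

test_that("qc_score averages z-scored SNR and CNR", {
  snr <- c(10, 20, 30); cnr <- c(1, 2, 3)
  q <- qc_score(snr, cnr)
  expect_equal(q, (scale(snr)[, 1] + scale(cnr)[, 1]) / 2)
  expect_equal(mean(q), 0, tolerance = 1e-12)
})
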