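# Tract microstructure and its maturation with age: diffusion tensor
# fitting (log-linear least squares on the b = 1000 shell), tract-median
# metric extraction over population-atlas ROIs, and per-tract GLMs of
# metric against age with Bonferroni correction across the tract family.

#' Fit the diffusion tensor model voxel-wise
#'
#' Log-linear least squares of `log S = log S0 - b g' D g`, restricted to
#' the `b = 0` and `b = shell` volumes (the tensor model is only fitted to
#' the inner shell plus non-diffusion-weighted volumes).  FA and MD follow
#' the standard eigenvalue closed forms; fits with any nonpositive
#' eigenvalue are reported with `physical = FALSE` rather than clipped.
#'
#' @param dwi a [volume_grid] with a 4-D signal array.
#' @param bvals,bvecs acquisition table (one bval and unit bvec per volume).
#' @param shell b-value of the shell used for fitting (default 1000); b
#'   values within `shell_tol` are included.
#' @param shell_tol half-width for shell membership (default 50).
#' @return list of [volume_grid]s: `fa`, `md` (mm^2/s), `tensor` (4-D,
#'   6 components `Dxx, Dyy, Dzz, Dxy, Dxz, Dyz`), `physical` (1 = all
#'   eigenvalues positive).
#' @export
fit_dti <- function(dwi, bvals, bvecs, shell = 1000, shell_tol = 50) {
  bvecs <- as.matrix(bvecs)
  use <- bvals <= shell_tol | abs(bvals - shell) <= shell_tol
  nb0 <- sum(bvals <= shell_tol)
  ndir <- length(unique(apply(round(bvecs[abs(bvals - shell) <= shell_tol, ,
                                          drop = FALSE], 6), 1, paste,
                              collapse = ",")))
  assert_that(nb0 >= 1 && ndir >= 6,
              paste0("tensor fit needs >= 1 b=0 and >= 6 unique directions ",
                     "at b = %g (have %d and %d)"), shell, nb0, ndir,
              class = "bxs_spec_error")
  b <- bvals[use]; g <- bvecs[use, , drop = FALSE]
  X <- cbind(1, -b * cbind(g[, 1]^2, g[, 2]^2, g[, 3]^2,
                           2 * g[, 1] * g[, 2], 2 * g[, 1] * g[, 3],
                           2 * g[, 2] * g[, 3]))
  shp <- dim(dwi$values)[1:3]
  nvox <- prod(shp)
  sig <- matrix(dwi$values, nvox)[, use, drop = FALSE]
  sig[sig <= 0] <- .Machine$double.eps
  # one least-squares solve for all voxels at once
  beta <- t(qr.coef(qr(X), t(log(sig))))      # nvox x 7
  fa <- md <- numeric(nvox)
  phys <- integer(nvox)
  for (v in seq_len(nvox)) {
    D <- tensor6_to_mat(beta[v, 2:7])
    ev <- eigen(D, symmetric = TRUE, only.values = TRUE)$values
    md[v] <- mean(ev)
    denom <- sqrt(sum(ev^2))
    fa[v] <- if (denom == 0) 0 else
      sqrt(1.5 * sum((ev - mean(ev))^2)) / denom
    phys[v] <- as.integer(all(ev > 0))
  }
  list(fa = volume_grid(array(fa, shp), dwi$affine),
       md = volume_grid(array(md, shp), dwi$affine),
       tensor = volume_grid(array(beta[, 2:7], c(shp, 6)), dwi$affine),
       physical = volume_grid(array(phys, shp), dwi$affine))
}

#' Tract-median metric over atlas ROIs
#'
#' Each tract's atlas is thresholded at `population_threshold` percent and
#' binarized; the metric's median over the ROI is returned together with
#' the tract volume (suprathreshold voxel count times voxel volume, mm^3)
#' used downstream as a confound.
#'
#' @param metric a [volume_grid] (e.g. FA or MD) on the atlas grid.
#' @param atlas a [population_atlas].
#' @param population_threshold population percentage cut (default 30).
#' @return data.frame with `tract`, `median`, `volume_mm3`, `n_voxels`.
#' @export
tract_median_metric <- function(metric, atlas, population_threshold = 30) {
  vv <- voxel_volume(atlas$percent[[1]])
  rows <- lapply(names(atlas$percent), function(tr) {
    av <- atlas$percent[[tr]]
    assert_same_grid(metric, av, "metric and atlas")
    sel <- av$values >= population_threshold
    data.frame(tract = tr,
               median = median_or_na(metric$values[sel]),
               volume_mm3 = sum(sel) * vv,
               n_voxels = sum(sel))
  })
  do.call(rbind, rows)
}

#' Quality-control score from SNR and CNR
#'
#' The z-score average of per-subject signal-to-noise and
#' contrast-to-noise ratios (z-scored across the cohort).
#'
#' @param snr,cnr numeric vectors across subjects.
#' @export
qc_score <- function(snr, cnr) {
  (scale(snr)[, 1] + scale(cnr)[, 1]) / 2
}

#' Per-tract GLM of tract metric against age with confounds
#'
#' One ordinary-least-squares model per tract (per metric): metric ~ age +
#' confounds.  Confound columns conventionally hold birth weight (g), head
#' circumference at scan (cm), tract volume (mm^3) and a QC score.  The
#' age coefficient, its standard error and two-sided p-value are reported,
#' with Bonferroni significance across the tract family (alpha divided by
#' the number of tracts in the metric's family).
#'
#' @param metrics data.frame with columns `subject`, `tract`, `value`.
#' @param age_weeks named or ordered numeric vector, one age per subject.
#' @param confounds optional data.frame (one row per subject) of confound
#'   regressors.
#' @param alpha family-wise error rate (default 0.05).
#' @return data.frame, one row per tract: `tract`, `beta_age`, `se`,
#'   `p`, `p_bonferroni`, `significant`, plus one `beta_<confound>` column
#'   per confound.
#' @export
fit_maturation_glm <- function(metrics, age_weeks, confounds = NULL,
                               alpha = 0.05) {
  tracts <- unique(metrics$tract)
  n_family <- length(tracts)
  subjects <- unique(metrics$subject)
  assert_that(length(age_weeks) == length(subjects),
              "one age per subject required")
  rows <- lapply(tracts, function(tr) {
    sub <- metrics[metrics$tract == tr, ]
    sub <- sub[match(subjects, sub$subject), ]
    X <- cbind(age = age_weeks)
    if (!is.null(confounds)) X <- cbind(X, as.matrix(confounds))
    df <- data.frame(value = sub$value, X)
    fit <- stats::lm(value ~ ., data = df)
    cf <- stats::coef(fit)
    if (anyNA(cf)) {
      bad <- names(cf)[is.na(cf)]
      stop_bxs("rank-deficient design for tract %s: collinear column(s) %s",
               tr, paste(bad, collapse = ", "), class = "bxs_design_error")
    }
    sm <- summary(fit)$coefficients
    out <- data.frame(tract = tr,
                      beta_age = sm["age", "Estimate"],
                      se = sm["age", "Std. Error"],
                      p = sm["age", "Pr(>|t|)"])
    if (!is.null(confounds)) {
      for (cn in colnames(confounds)) {
        out[[paste0("beta_", cn)]] <- sm[cn, "Estimate"]
      }
    }
    out
  })
  res <- do.call(rbind, rows)
  res$p_bonferroni <- pmin(res$p * n_family, 1)
  res$significant <- res$p < alpha / n_family
  attr(res, "family") <- list(n_tests = n_family, alpha = alpha)
  res
}

#' Simulate a maturation cohort with planted age effects
#'
#' Generates per-subject tract metrics `value = intercept + beta * age +
#' confound effects + noise` for parameter-recovery tests: tract families
#' can be given different planted slopes (e.g. faster "projection-like"
#' and slower "limbic-like" maturation).
#'
#' @param n_subjects cohort size.
#' @param betas named numeric vector of planted age slopes per tract.
#' @param age_range weeks, uniform (default the 37-45 week window).
#' @param intercept baseline metric value.
#' @param noise_sd residual SD.
#' @param seed RNG seed.
#' @return list with `metrics` (data.frame subject/tract/value),
#'   `age_weeks`, `confounds`.
#' @export
simulate_maturation_cohort <- function(n_subjects = 200, betas,
                                       age_range = c(37, 45),
                                       intercept = 0.2, noise_sd = 0.01,
                                       seed = 1L) {
  with_seed_bxs(seed, {
    age <- stats::runif(n_subjects, age_range[1], age_range[2])
    confounds <- data.frame(
      birth_weight_g = stats::rnorm(n_subjects, 3200, 400),
      head_circ_cm = stats::rnorm(n_subjects, 35, 1.2),
      tract_volume_mm3 = stats::rnorm(n_subjects, 5000, 500),
      qc = stats::rnorm(n_subjects))
    rows <- lapply(names(betas), function(tr) {
      data.frame(subject = seq_len(n_subjects), tract = tr,
                 value = intercept + betas[[tr]] * age +
                   1e-5 * confounds$birth_weight_g +
                   stats::rnorm(n_subjects, sd = noise_sd))
    })
    list(metrics = do.call(rbind, rows), age_weeks = age,
         confounds = confounds)
  })
}
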