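# Population tract atlases and reproducibility statistics.

#' Population tract atlas
#'
#' Per-tract volumes of population percentages: the percentage of subjects
#' whose normalized path density reached the binarization threshold at each
#' voxel (path density maps binarized, then averaged across subjects).
#'
#' @param percent named list of [volume_grid]s with values in `[0, 100]`.
#' @param n_subjects subjects entering the average.
#' @param binarize_threshold normalized-density threshold used (fraction of
#'   valid streamlines; 0.001 is the 0.1% default).
#' @export
population_atlas <- function(percent, n_subjects, binarize_threshold) {
  structure(list(percent = percent, n_subjects = n_subjects,
                 binarize_threshold = binarize_threshold),
            class = "population_atlas")
}

#' @export
print.population_atlas <- function(x, ...) {
  cat(sprintf("<population_atlas> %d tract(s), %d subject(s), threshold %g\n",
              length(x$percent), x$n_subjects, x$binarize_threshold))
  invisible(x)
}

#' Build a population atlas from per-subject density maps
#'
#' @param density_maps list over subjects; each element a named list of
#'   normalized [path_density_map]s (one per tract), all on one grid.
#' @param binarize_threshold normalized density at or above which a voxel
#'   counts as visited for a subject (default 0.001, i.e. 0.1%).
#' @return a [population_atlas].
#' @export
build_atlas <- function(density_maps, binarize_threshold = 0.001) {
  assert_that(length(density_maps) >= 1, "need at least one subject")
  tracts <- names(density_maps[[1]])
  ref <- density_maps[[1]][[1]]$counts
  n <- length(density_maps)
  percent <- lapply(tracts, function(tr) {
    acc <- array(0, grid_shape(ref))
    for (subj in density_maps) {
      pdm <- subj[[tr]]
      assert_that(isTRUE(pdm$normalized),
                  "density maps must be normalized before atlas building")
      assert_same_grid(pdm$counts, ref, "subject maps")
      acc <- acc + (pdm$counts$values >= binarize_threshold)
    }
    volume_grid(100 * acc / n, ref$affine)
  })
  names(percent) <- tracts
  population_atlas(percent, n, binarize_threshold)
}

#' Correlate two atlases tract by tract
#'
#' Each tract is thresholded at `population_threshold` percent in either
#' atlas; Pearson's r is computed over the union of suprathreshold voxels.
#' A tract whose union support is empty (or constant) yields `NA`.
#'
#' @param atlas_a,atlas_b [population_atlas] objects on one grid with the
#'   same tract set.
#' @param population_threshold population percentage cut (default 30).
#' @return list with `per_tract` (named numeric), `mean`, `sd`.
#' @export
atlas_similarity <- function(atlas_a, atlas_b, population_threshold = 30) {
  tracts <- names(atlas_a$percent)
  assert_that(setequal(tracts, names(atlas_b$percent)),
              "atlases have different tract sets")
  r <- vapply(tracts, function(tr) {
    va <- atlas_a$percent[[tr]]; vb <- atlas_b$percent[[tr]]
    assert_same_grid(va, vb, "atlases")
    sel <- va$values >= population_threshold | vb$values >= population_threshold
    if (!any(sel)) return(NA_real_)
    a <- va$values[sel]; b <- vb$values[sel]
    if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
    stats::cor(a, b)
  }, numeric(1))
  list(per_tract = r, mean = mean(r, na.rm = TRUE), sd = stats::sd(r, na.rm = TRUE))
}

threshold_binarize <- function(pdm, threshold) {
  as.numeric(pdm$counts$values >= threshold)
}

pair_mean_correlation <- function(maps_i, maps_j, threshold) {
  tracts <- names(maps_i)
  rs <- vapply(tracts, function(tr) {
    a <- maps_i[[tr]]$counts$values
    b <- maps_j[[tr]]$counts$values
    sel <- a >= threshold | b >= threshold
    if (!any(sel)) return(NA_real_)
    av <- a[sel]; bv <- b[sel]
    if (stats::sd(av) == 0 || stats::sd(bv) == 0) return(NA_real_)
    stats::cor(av, bv)
  }, numeric(1))
  mean(rs, na.rm = TRUE)
}

#' Intersubject variability of tract maps, within or across groups
#'
#' Within one group, every unordered subject pair — `n(n-1)/2` pairs — is
#' correlated (Pearson, over the union of voxels at or above `threshold`),
#' and the correlations are averaged across tracts for each pair.  Across
#' two groups, the same number of cross pairs is drawn at random (without
#' replacement among distinct cross pairs) so both designs contribute the
#' same number of data points; n = 22 within-group gives the reference 231
#' pairs.
#'
#' @param group_a list over subjects; each a named list of normalized
#'   [path_density_map]s.
#' @param group_b optional second group; when given, the across-group
#'   design is used.
#' @param threshold normalized-density threshold (default 0.001).
#' @param n_pairs number of across-group pairs; defaults to
#'   `n_a * (n_a - 1) / 2` to match the within-group count.
#' @param seed RNG seed for across-group pair sampling.
#' @return list with `pairs` (two-column matrix of subject indices) and
#'   `values` (per-pair tract-averaged correlations).
#' @export
intersubject_variability <- function(group_a, group_b = NULL,
                                     threshold = 0.001, n_pairs = NULL,
                                     seed = 1L) {
  n_a <- length(group_a)
  assert_that(n_a >= 2, "need at least two subjects", class = "bxs_spec_error")
  if (is.null(group_b)) {
    pairs <- t(utils::combn(n_a, 2))
    vals <- apply(pairs, 1, function(p) {
      pair_mean_correlation(group_a[[p[1]]], group_a[[p[2]]], threshold)
    })
    return(list(pairs = pairs, values = vals))
  }
  n_b <- length(group_b)
  assert_that(n_b >= 2, "need at least two subjects per group",
              class = "bxs_spec_error")
  if (is.null(n_pairs)) n_pairs <- n_a * (n_a - 1) / 2
  all_pairs <- as.matrix(expand.grid(a = seq_len(n_a), b = seq_len(n_b)))
  assert_that(n_pairs <= nrow(all_pairs),
              "requested %d cross pairs but only %d exist", n_pairs,
              nrow(all_pairs))
  pairs <- with_seed_bxs(seed,
    all_pairs[sample(nrow(all_pairs), n_pairs), , drop = FALSE])
  vals <- apply(pairs, 1, function(p) {
    pair_mean_correlation(group_a[[p[1]]], group_b[[p[2]]], threshold)
  })
  list(pairs = pairs, values = vals)
}
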