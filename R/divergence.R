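# Symmetric Kullback-Leibler divergence between connectivity patterns and
# every map built from it: dense and parcellated divergence matrices,
# minimum-divergence maps, joint / exclusive-OR ontogeny-phylogeny map
# algebra, row entropy, and bootstrap dispersion.

#' Symmetric KL divergence between two tract-probability rows (bits)
#'
#' `D(p, q) = sum_k p_k log2(p_k / q_k) + sum_k q_k log2(q_k / p_k)`.
#' Zeros are handled by adding a small floor to every entry and
#' re-normalizing both rows, so the divergence is finite, zero iff the
#' (floored) rows coincide, and symmetric.
#'
#' @param p,q nonnegative vectors of equal length summing to 1.
#' @param floor positive constant added to all entries before
#'   re-normalization (default 1e-6).
#' @return divergence in bits.
#' @export
symmetric_kl <- function(p, q, floor = 1e-6) {
  assert_that(length(p) == length(q), "p and q differ in length")
  assert_that(all(p >= 0) && all(q >= 0), "probabilities must be nonnegative")
  assert_that(floor > 0, "floor must be positive")
  p <- (p + floor) / sum(p + floor)
  q <- (q + floor) / sum(q + floor)
  sum(p * log2(p / q)) + sum(q * log2(q / p))
}

floor_normalize <- function(m, floor) {
  m <- m + floor
  m / rowSums(m)
}

#' Pairwise symmetric KL divergence between two blueprints
#'
#' Row `i`, column `j` holds the symmetric KL divergence (bits) between
#' row `i` of `N` and row `j` of `A`.  Rows flagged invalid in either
#' blueprint are masked (`NA`).  Swapping the two blueprints transposes
#' the result.
#'
#' @param N,A normalized [connectivity_blueprint]s over the same ordered
#'   tract set.
#' @param floor zero-handling floor, as in [symmetric_kl()].
#' @return an object of class `divergence_matrix` with fields `D`
#'   (matrix, bits), `row_valid`, `col_valid`, `floor`.
#' @export
divergence_matrix <- function(N, A, floor = 1e-6) {
  assert_that(identical(N$tracts, A$tracts),
              "blueprints disagree on tract names/order",
              class = "bxs_grid_error")
  assert_that(N$normalized && A$normalized,
              "blueprints must be row-normalized")
  Pm <- floor_normalize(N$matrix, floor)
  Qm <- floor_normalize(A$matrix, floor)
  lP <- log2(Pm); lQ <- log2(Qm)
  hP <- rowSums(Pm * lP)             # sum_k p log2 p
  hQ <- rowSums(Qm * lQ)
  # D_ij = hP_i - sum_k P_ik lQ_jk + hQ_j - sum_k Q_jk lP_ik
  D <- outer(hP, hQ, `+`) - Pm %*% t(lQ) - lP %*% t(Qm)
  D[D < 0] <- 0                      # clamp tiny negative round-off
  D[!N$valid, ] <- NA_real_
  D[, !A$valid] <- NA_real_
  structure(list(D = D, row_valid = N$valid, col_valid = A$valid,
                 floor = floor),
            class = "divergence_matrix")
}

#' @export
print.divergence_matrix <- function(x, ...) {
  cat(sprintf("<divergence_matrix> %d x %d (bits), floor %g\n",
              nrow(x$D), ncol(x$D), x$floor))
  invisible(x)
}

#' Minimum-divergence map
#'
#' For each row (vertex of the non-reference brain) the minimum divergence
#' over valid columns of the reference brain and its argmin — the best
#' matching connectivity profile.  Ties break to the lowest column index.
#'
#' @param dmat a `divergence_matrix` (or plain matrix).
#' @param axis 1 to minimize over columns for each row (default), 2 for
#'   the transposed reading.
#' @return an object of class `divergence_map`: fields `value` (bits,
#'   `NA` for fully-masked rows), `argmin` (index into the other brain),
#'   `scaled` (FALSE; see [rescale_map()]).
#' @export
min_divergence_map <- function(dmat, axis = 1) {
  D <- if (inherits(dmat, "divergence_matrix")) dmat$D else as.matrix(dmat)
  if (axis == 2) D <- t(D)
  n <- nrow(D)
  value <- rep(NA_real_, n)
  argmin <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    row <- D[i, ]
    ok <- which(!is.na(row))
    if (length(ok) == 0L) next
    j <- ok[which.min(row[ok])]      # which.min takes the first = lowest index
    value[i] <- row[j]
    argmin[i] <- j
  }
  structure(list(value = value, argmin = argmin, scaled = FALSE),
            class = "divergence_map")
}

#' @export
print.divergence_map <- function(x, ...) {
  cat(sprintf("<divergence_map> %d vertices, median %.3g%s\n",
              length(x$value), stats::median(x$value, na.rm = TRUE),
              if (x$scaled) " (rescaled to [0,1])" else " bits"))
  invisible(x)
}

#' Summary statistics of a divergence map
#'
#' Both whole-brain summaries in use are provided: mean with SD, and
#' median with median absolute deviation; callers choose.
#'
#' @param map a `divergence_map`.
#' @export
summarize_divergence <- function(map) {
  v <- map$value[!is.na(map$value)]
  list(mean = mean(v), sd = stats::sd(v),
       median = stats::median(v), mad = stats::mad(v))
}

#' Parcellate a divergence matrix (parcel-wise median)
#'
#' Entry `(P, Q)` is the median of `D` over vertex pairs `(i in P, j in
#' Q)`.  Parcels listed in each parcellation's exclusion set (insula
#' analogues and similar) never enter the result.  Medians over even
#' counts use the midpoint convention.
#'
#' @param dmat a `divergence_matrix`.
#' @param parc_rows,parc_cols [parcellation]s for the row and column
#'   vertex spaces.
#' @return list with `D` (parcels x parcels matrix), `row_parcels`,
#'   `col_parcels` (ids), plus name vectors when available.
#' @export
parcellate_divergence <- function(dmat, parc_rows, parc_cols) {
  D <- dmat$D
  rp <- included_parcels(parc_rows)
  cp <- included_parcels(parc_cols)
  out <- matrix(NA_real_, length(rp), length(cp),
                dimnames = list(parc_rows$names[as.character(rp)],
                                parc_cols$names[as.character(cp)]))
  for (a in seq_along(rp)) {
    ri <- which(parc_rows$labels == rp[a])
    for (b in seq_along(cp)) {
      ci <- which(parc_cols$labels == cp[b])
      vals <- D[ri, ci]
      vals <- vals[!is.na(vals)]
      out[a, b] <- median_or_na(vals)
    }
  }
  list(D = out, row_parcels = rp, col_parcels = cp)
}

#' Divergence between corresponding parcels
#'
#' The diagonal of a parcellated divergence matrix; requires the same
#' parcellation scheme on both axes (used when both brains share an atlas,
#' e.g. age-group comparisons).
#'
#' @param parc_div result of [parcellate_divergence()].
#' @return named numeric vector of per-parcel divergences.
#' @export
corresponding_parcel_divergence <- function(parc_div) {
  assert_that(identical(parc_div$row_parcels, parc_div$col_parcels),
              "diagonal requires identical parcel schemes on both axes",
              class = "bxs_spec_error")
  stats::setNames(diag(parc_div$D), rownames(parc_div$D))
}

#' Min-max rescale a divergence map to [0, 1]
#'
#' Joint/XOR map algebra is only meaningful on `[0, 1]`, so maps must be
#' rescaled (over valid vertices) before combination; the `scaled` flag
#' enforces this explicitly.
#'
#' @param map a `divergence_map`.
#' @export
rescale_map <- function(map) {
  v <- map$value
  rng <- range(v, na.rm = TRUE)
  span <- rng[2] - rng[1]
  v <- if (span == 0) ifelse(is.na(v), NA_real_, 0) else (v - rng[1]) / span
  structure(list(value = v, argmin = map$argmin, scaled = TRUE),
            class = "divergence_map")
}

assert_scaled <- function(map, what) {
  assert_that(inherits(map, "divergence_map") && isTRUE(map$scaled),
              "%s requires maps rescaled to [0,1]; call rescale_map() first",
              what, class = "bxs_state_error")
}

#' Joint and exclusive-OR combination of two rescaled divergence maps
#'
#' With both maps on `[0, 1]`, the joint map is the element-wise product
#' `B * C` (large where divergence is high on both dimensions, e.g.
#' ontogeny and phylogeny) and the exclusive-OR map is
#' `B + C - 2 * B * C` (union minus intersection: high on exactly one
#' dimension).
#'
#' @param map_b,map_c rescaled `divergence_map`s (see [rescale_map()]).
#' @return a `divergence_map` on `[0, 1]`.
#' @export
joint_divergence <- function(map_b, map_c) {
  assert_scaled(map_b, "joint_divergence"); assert_scaled(map_c, "joint_divergence")
  structure(list(value = map_b$value * map_c$value, argmin = NULL,
                 scaled = TRUE),
            class = "divergence_map")
}

#' @rdname joint_divergence
#' @export
xor_divergence <- function(map_b, map_c) {
  assert_scaled(map_b, "xor_divergence"); assert_scaled(map_c, "xor_divergence")
  b <- map_b$value; c2 <- map_c$value
  structure(list(value = b + c2 - 2 * b * c2, argmin = NULL, scaled = TRUE),
            class = "divergence_map")
}

#' Per-vertex Shannon entropy of a blueprint (bits)
#'
#' Complexity of each vertex's connection pattern: entropy of its
#' normalized row, base 2; zero entries contribute 0 by convention.
#' Invalid rows give `NA`.
#'
#' @param blueprint a normalized [connectivity_blueprint].
#' @export
entropy_map <- function(blueprint) {
  assert_that(blueprint$normalized, "blueprint must be normalized")
  m <- blueprint$matrix
  h <- apply(m, 1, function(r) {
    r <- r[r > 0]
    -sum(r * log2(r))
  })
  h[!blueprint$valid] <- NA_real_
  h
}

#' Bootstrap dispersion of minimum-divergence maps
#'
#' Each iteration subsamples both groups with replacement at the stated
#' sizes, group-averages the subsampled blueprints, and computes the
#' min-divergence map of the first group relative to the second.  Returns
#' the per-vertex mean and variance across iterations (the reference
#' design resamples 100 iterations at sizes 20/20/4 for the three
#' cohorts).
#'
#' @param group_a,group_b lists of subject [connectivity_blueprint]s.
#' @param size_a,size_b subsample sizes (with replacement).
#' @param n_iter bootstrap iterations (default 100).
#' @param floor KL floor.
#' @param seed RNG seed.
#' @return list with `mean`, `variance` (per-vertex), `n_iter`, `sizes`.
#' @export
bootstrap_divergence <- function(group_a, group_b, size_a = 20, size_b = 20,
                                 n_iter = 100, floor = 1e-6, seed = 1L) {
  assert_that(length(group_a) >= 1 && length(group_b) >= 1,
              "empty group", class = "bxs_spec_error")
  nv <- nrow(group_a[[1]]$matrix)
  with_seed_bxs(seed, {
    acc <- matrix(NA_real_, n_iter, nv)
    for (it in seq_len(n_iter)) {
      sa <- sample(length(group_a), size_a, replace = TRUE)
      sb <- sample(length(group_b), size_b, replace = TRUE)
      ga <- average_blueprints(group_a[sa])
      gb <- average_blueprints(group_b[sb])
      acc[it, ] <- min_divergence_map(divergence_matrix(ga, gb, floor))$value
    }
    list(mean = colMeans(acc), variance = apply(acc, 2, stats::var),
         n_iter = n_iter, sizes = c(size_a, size_b))
  })
}
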