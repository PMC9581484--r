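# Spectral embedding of inverse-divergence similarity: joint
# low-dimensional map of parcels from two brains, used to translate
# atlases across brains.

#' Similarity from a parcel divergence matrix
#'
#' The default transform is the inverse `1 / (D + eps)`: strictly
#' decreasing in divergence, with `eps` guarding exact-zero self pairs.
#' A Gaussian kernel `exp(-D / scale)` is also exposed since the choice is
#' a configuration, not a fixed fact.
#'
#' @param D nonnegative matrix of parcel divergences.
#' @param mode `"inverse"` (default) or `"gaussian"`.
#' @param eps additive guard for the inverse transform.
#' @param scale kernel scale for the Gaussian transform (defaults to the
#'   median of `D`).
#' @export
similarity_from_divergence <- function(D, mode = c("inverse", "gaussian"),
                                       eps = 1e-6, scale = NULL) {
  mode <- match.arg(mode)
  D <- as.matrix(D)
  assert_that(all(is.na(D) | D >= 0), "divergences must be nonnegative")
  if (mode == "inverse") {
    1 / (D + eps)
  } else {
    if (is.null(scale)) scale <- stats::median(D, na.rm = TRUE)
    exp(-D / scale)
  }
}

# connected components of the positive-similarity graph (off-diagonal)
graph_components <- function(W) {
  n <- nrow(W)
  comp <- rep(0L, n)
  cur <- 0L
  adj <- (W > 0) & !diag(TRUE, n)
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      nb <- which(adj[v, ] & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

#' Spectral embedding of a joint similarity matrix
#'
#' Both brains' parcels enter one similarity graph; coordinates come from
#' the leading nontrivial eigenvectors of the normalized (random-walk)
#' graph Laplacian — the spectral-reordering family.  Each mode's sign is
#' canonicalized so its first nonzero loading is positive, making the
#' embedding deterministic.
#'
#' @param similarity symmetric nonnegative matrix over the union of
#'   parcels of the two brains.
#' @param n_modes number of embedding modes (default 2).
#' @param brain optional character tag per parcel (brain of origin).
#' @param laplacian `"randomwalk"` (default) or `"unnormalized"`.
#' @return an object of class `embedding_result`: `coords` (parcels x
#'   modes), `eigenvalues` (the corresponding Laplacian eigenvalues),
#'   `brain`, `laplacian`.
#' @export
spectral_embed <- function(similarity, n_modes = 2, brain = NULL,
                           laplacian = c("randomwalk", "unnormalized")) {
  laplacian <- match.arg(laplacian)
  W <- as.matrix(similarity)
  assert_that(isTRUE(all.equal(unname(W), unname(t(W)), tolerance = 1e-8)),
              "similarity must be symmetric")
  assert_that(all(W >= 0), "similarity must be nonnegative")
  n <- nrow(W)
  comp <- graph_components(W)
  assert_that(max(comp) == 1L,
              "similarity graph is disconnected (%d components; sizes %s)",
              max(comp), paste(tabulate(comp), collapse = ", "),
              class = "bxs_spec_error")
  deg <- rowSums(W)
  if (laplacian == "randomwalk") {
    # random-walk eigenvectors via the symmetric normalization
    dh <- 1 / sqrt(deg)
    S <- W * (dh %o% dh)
    es <- eigen(S, symmetric = TRUE)
    # eigenvalues of L_rw are 1 - eigenvalues of S, ascending from 0
    ord <- order(1 - es$values)
    lam <- (1 - es$values)[ord][2:(n_modes + 1)]
    U <- es$vectors[, ord[2:(n_modes + 1)], drop = FALSE] * dh
    # diffusion-map scaling: weight each mode by its operator eigenvalue
    # (1 - Laplacian eigenvalue), so a flat (degenerate) spectrum collapses
    # all parcels to the origin instead of picking arbitrary axes
    U <- sweep(U, 2, 1 - lam, `*`)
  } else {
    L <- diag(deg) - W
    es <- eigen(L, symmetric = TRUE)
    ord <- order(es$values)
    lam <- es$values[ord][2:(n_modes + 1)]
    U <- es$vectors[, ord[2:(n_modes + 1)], drop = FALSE]
  }
  for (m in seq_len(ncol(U))) {
    nz <- which(abs(U[, m]) > 1e-12)
    if (length(nz) > 0 && U[nz[1], m] < 0) U[, m] <- -U[, m]
  }
  rownames(U) <- rownames(W)
  structure(list(coords = U, eigenvalues = lam, brain = brain,
                 laplacian = laplacian),
            class = "embedding_result")
}

#' @export
print.embedding_result <- function(x, ...) {
  cat(sprintf("<embedding_result> %d parcels in %d modes (%s Laplacian)\n",
              nrow(x$coords), ncol(x$coords), x$laplacian))
  invisible(x)
}

#' Per-system centres of gravity in embedded space
#'
#' The coordinate-wise median of parcel coordinates for each
#' anatomofunctional cortical system, per brain when a brain tag is
#' present.
#'
#' @param emb an `embedding_result`.
#' @param systems character vector, one system name per parcel.
#' @return data.frame with `system`, optional `brain`, and one column per
#'   mode; systems with no parcels are absent.
#' @export
system_centers <- function(emb, systems) {
  assert_that(length(systems) == nrow(emb$coords),
              "one system label per parcel required")
  brain <- emb$brain %||% rep("all", nrow(emb$coords))
  key <- interaction(systems, brain, drop = TRUE)
  rows <- lapply(levels(key), function(k) {
    sel <- key == k
    ctr <- apply(emb$coords[sel, , drop = FALSE], 2, stats::median)
    data.frame(system = systems[sel][1], brain = brain[sel][1],
               t(ctr), check.names = FALSE)
  })
  out <- do.call(rbind, rows)
  names(out)[-(1:2)] <- paste0("mode", seq_len(ncol(emb$coords)))
  out
}
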