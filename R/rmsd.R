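# Rigid-body superposition (Kabsch) and conformer-ensemble diversity
# statistics.

#' Optimal rigid superposition of two paired point sets
#'
#' Kabsch algorithm: finds the proper rotation (determinant +1) and
#' translation that minimize the RMSD between `coords_a` (moved) and
#' `coords_b` (fixed), with point correspondence given by row index.
#' Reflections are never returned. When one point set is wholly degenerate
#' (all points coincident) the rotation is the identity and the RMSD is
#' computed after centroid alignment.
#'
#' @param coords_a,coords_b n x 3 numeric matrices, n >= 1.
#' @return list with `rotation` (3 x 3), `translation` (length 3) such that
#'   `coords_a %*% t(rotation)` + translation superposes onto `coords_b`,
#'   and `rmsd` (A).
#' @export
superpose <- function(coords_a, coords_b) {
  a <- as.matrix(coords_a); b <- as.matrix(coords_b)
  stopifnot(ncol(a) == 3L, ncol(b) == 3L, nrow(a) == nrow(b), nrow(a) >= 1L)
  ca <- colMeans(a); cb <- colMeans(b)
  ac <- sweep(a, 2, ca); bc <- sweep(b, 2, cb)
  if (sum(ac^2) < 1e-24 || sum(bc^2) < 1e-24) {
    rot <- diag(3)
  } else {
    h <- crossprod(ac, bc)                 # 3x3 covariance
    sv <- svd(h)
    d <- sign(det(sv$v %*% t(sv$u)))
    rot <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  }
  moved <- ac %*% t(rot)
  rmsd <- sqrt(mean(rowSums((moved - bc)^2)))
  translation <- as.numeric(cb - rot %*% ca)
  list(rotation = rot, translation = translation, rmsd = rmsd)
}

#' RMSD of each conformer to the ground-truth conformation
#'
#' For conformer i, RMSD_i = sqrt(mean_j(delta_j^2)) where delta_j is the
#' distance between atom j and the corresponding ground-truth atom after
#' optimal rigid superposition. Atom correspondence is by index.
#'
#' @param ensemble a [conformer_ensemble()] with `ground_truth` set.
#' @param heavy_only if `TRUE` (default) only non-hydrogen atoms enter the
#'   superposition and the RMSD; if `FALSE` all atoms are used.
#' @param per_atom if `TRUE`, also return the per-atom deviations.
#' @return list with `per_conformer_rmsd` (length N), `atom_count_used`,
#'   and, when requested, `per_atom_deviations` (N x M matrix).
#' @export
rmsd_to_ground_truth <- function(ensemble, heavy_only = TRUE,
                                 per_atom = FALSE) {
  if (is.null(ensemble$ground_truth)) {
    stop("ensemble for compound ", ensemble$molecule$compound_id,
         " has no ground-truth conformation")
  }
  idx <- if (heavy_only) heavy_atoms(ensemble$molecule) else
    seq_along(ensemble$molecule$elements)
  gt <- ensemble$ground_truth[idx, , drop = FALSE]
  n <- length(ensemble$conformers)
  rmsds <- numeric(n)
  devs <- if (per_atom) matrix(NA_real_, n, length(idx)) else NULL
  for (i in seq_len(n)) {
    a <- ensemble$conformers[[i]]$coords[idx, , drop = FALSE]
    fit <- superpose(a, gt)
    rmsds[i] <- fit$rmsd
    if (per_atom) {
      moved <- sweep(a %*% t(fit$rotation), 2, fit$translation, `+`)
      devs[i, ] <- sqrt(rowSums((moved - gt)^2))
    }
  }
  out <- list(per_conformer_rmsd = rmsds, atom_count_used = length(idx))
  if (per_atom) out$per_atom_deviations <- devs
  out
}

#' Pairwise conformational diversity of an ensemble
#'
#' Exhaustive superposed RMSD over all C(N,2) conformer pairs; reports the
#' maximum and mean. With fewer than two conformers the statistics are
#' absent (`NULL`).
#'
#' @param ensemble a [conformer_ensemble()].
#' @param heavy_only include only heavy atoms; default `FALSE` (all atoms,
#'   hydrogens included).
#' @return list with `max_pairwise_rmsd`, `mean_pairwise_rmsd` (possibly
#'   `NULL`) and `n_conformers`.
#' @export
pairwise_diversity <- function(ensemble, heavy_only = FALSE) {
  n <- length(ensemble$conformers)
  if (n < 2L) {
    return(list(max_pairwise_rmsd = NULL, mean_pairwise_rmsd = NULL,
                n_conformers = n))
  }
  idx <- if (heavy_only) heavy_atoms(ensemble$molecule) else
    seq_along(ensemble$molecule$elements)
  coords <- lapply(ensemble$conformers,
                   function(cf) cf$coords[idx, , drop = FALSE])
  vals <- numeric(0)
  for (i in seq_len(n - 1L)) {
    for (j in seq((i + 1L), n)) {
      vals <- c(vals, superpose(coords[[i]], coords[[j]])$rmsd)
    }
  }
  list(max_pairwise_rmsd = max(vals), mean_pairwise_rmsd = mean(vals),
       n_conformers = n)
}
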