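# GROMOS-style (Daura) conformational clustering of trajectory frames.

#' Optimal-superposition RMSD between two coordinate sets (Kabsch)
#'
#' Centers both sets, finds the optimal rotation by singular value
#' decomposition of the covariance (with the determinant correction that
#' excludes reflections), and returns the root-mean-square deviation.
#'
#' @param a,b n x 3 coordinate matrices (same n >= 3).
#' @return RMSD in the coordinate units.
#' @export
kabsch_rmsd <- function(a, b) {
  stopifnot(nrow(a) == nrow(b), ncol(a) == 3, ncol(b) == 3, nrow(a) >= 3)
  a <- sweep(a, 2, colMeans(a))
  b <- sweep(b, 2, colMeans(b))
  s <- svd(t(b) %*% a)
  d <- sign(det(s$u %*% t(s$v)))
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  sqrt(mean(rowSums((a - b %*% R)^2)))
}

#' Cluster trajectory frames by the GROMOS (Daura) algorithm
#'
#' Frames are superposed pairwise on the fit selection by optimal rigid-body
#' fitting ([kabsch_rmsd()]) and their RMSD matrix computed. The algorithm
#' then repeatedly extracts the frame with the largest number of neighbors
#' within the cutoff as a cluster centroid together with its neighbors,
#' until no frames remain. Ties are broken by the lowest frame index, which
#' makes the partition deterministic.
#'
#' @param traj A `synthetic_traj` (>= 1 frame).
#' @param cutoff RMSD cutoff in nm (GROMOS convention; default 0.3 nm).
#'   Coordinates are Angstrom internally and converted.
#' @param fit_selection Integer atom indices used for superposition and
#'   RMSD; default all dye atoms (the probe's BODIPY core and phenyldiene
#'   tail markers).
#' @return Object of class `cluster_result`: `clusters` (list of integer
#'   frame vectors), `centroids`, `sizes`, `assignment` (per-frame cluster
#'   id), `cutoff`, `rmsd` (full matrix, nm).
#' @export
cluster_conformers <- function(traj, cutoff = 0.3, fit_selection = NULL) {
  F <- n_frames(traj)
  if (F < 1) stop("empty trajectory")
  if (is.null(fit_selection)) {
    fit_selection <- select_atoms(traj, species = "DYE")
    if (!length(fit_selection)) fit_selection <- seq_len(nrow(traj$topology))
  }
  if (length(fit_selection) < 3) {
    stop("fit selection needs at least 3 atoms for rigid-body superposition")
  }
  D <- matrix(0, F, F)
  if (F > 1) {
    for (i in seq_len(F - 1)) {
      for (j in (i + 1):F) {
        d <- kabsch_rmsd(traj$coords[fit_selection, , i],
                         traj$coords[fit_selection, , j])
        D[i, j] <- d
        D[j, i] <- d
      }
    }
  }
  D <- D / 10   # Angstrom -> nm
  adj <- D <= cutoff
  alive <- rep(TRUE, F)
  clusters <- list(); centroids <- integer(); extraction_counts <- integer()
  while (any(alive)) {
    nb <- rowSums(adj[, alive, drop = FALSE]) * alive
    c0 <- which.max(nb)   # ties -> lowest index
    members <- which(alive & adj[c0, ])
    clusters[[length(clusters) + 1]] <- members
    centroids <- c(centroids, c0)
    extraction_counts <- c(extraction_counts, nb[c0])
    alive[members] <- FALSE
  }
  assignment <- integer(F)
  for (k in seq_along(clusters)) assignment[clusters[[k]]] <- k
  structure(list(clusters = clusters, centroids = centroids,
                 sizes = lengths(clusters), assignment = assignment,
                 extraction_counts = extraction_counts,
                 cutoff = cutoff, rmsd = D,
                 fit_selection = fit_selection),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("cluster_result: %d clusters from %d frames (RMSD cutoff %.2f nm)\n",
              length(x$clusters), length(x$assignment), x$cutoff))
  cat("  sizes:", paste(x$sizes, collapse = " "), "\n")
  cat("  centroids (frame):", paste(x$centroids, collapse = " "), "\n")
  invisible(x)
}
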