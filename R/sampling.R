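# Seeded frame sampling: uniform hard-core placement plus Metropolis Monte
# Carlo for the dye-cardiolipin lateral attraction.

#' Sample a synthetic trajectory from a bilayer configuration
#'
#' Frames are statistically independent snapshots. Per frame, lipids are
#' placed laterally at random subject to the hard-core minimum distance;
#' cardiolipin molecules in the dye-containing leaflet are then resampled by
#' Metropolis Monte Carlo under a square attraction well of depth
#' `-epsilon` (kT units) within radius `r0` of the dye center, using
#' periodic minimum image in the membrane plane. Marker depths are drawn
#' from the per-group Gaussians of the configuration's depth model. With
#' `epsilon = 0` the placement is uniform (beyond the hard core). A fixed
#' seed reproduces the trajectory bit-identically.
#'
#' @param config A [build_bilayer()] configuration.
#' @param n_frames Number of frames (>= 1).
#' @param epsilon Well depth in kT units (>= 0).
#' @param r0 Well radius in Angstrom; must not exceed half the smaller
#'   lateral box edge (minimum image).
#' @param seed Integer RNG seed.
#' @param n_sweeps Monte Carlo sweeps over the cardiolipin molecules per
#'   frame (independence proposals; the stationary distribution is the
#'   Boltzmann weight of the well energy).
#' @return A [synthetic_traj()].
#' @examples
#' cfg <- build_bilayer(n_per_leaflet = 20, seed = 1)
#' trj <- sample_frames(cfg, n_frames = 5, epsilon = 1, r0 = 7, seed = 1)
#' @export
sample_frames <- function(config, n_frames, epsilon = 0, r0 = 7, seed = 1L,
                          n_sweeps = 25L) {
  stopifnot(inherits(config, "bilayer_config"))
  if (n_frames < 1) stop("n_frames must be >= 1")
  if (epsilon < 0) stop("affinity well depth epsilon must be >= 0")
  if (r0 > min(config$box[1:2]) / 2) {
    stop("well radius r0 = ", r0, " A exceeds half the lateral box (",
         min(config$box[1:2]) / 2, " A): minimum image violated")
  }
  mols <- config$molecules
  box <- config$box
  top <- config$topology
  dye_mol <- which(mols$is_dye)
  has_dye <- length(dye_mol) > 0
  dleaf <- if (has_dye) mols$leaflet[dye_mol[1]] else "upper"
  leaf_idx <- which(mols$leaflet == dleaf)
  cl_idx <- leaf_idx[mols$is_cl[leaf_idx]]
  center <- box[1:2] / 2   # dye is pinned here by .place_all

  set.seed(seed)
  coords <- array(NA_real_, dim = c(nrow(top), 3, n_frames))
  for (f in seq_len(n_frames)) {
    pos <- .place_all(config)
    if (epsilon > 0 && has_dye && length(cl_idx)) {
      pos <- .mc_cl_resample(pos, cl_idx, leaf_idx, center, box,
                             config$min_dist, epsilon, r0, n_sweeps)
    }
    coords[, , f] <- .frame_coords(config, pos)
  }
  synthetic_traj(top, coords, box, seed = seed,
                 affinity = list(epsilon = epsilon, r0 = r0),
                 depth_model = config$depth_model)
}

# Metropolis resampling of cardiolipin lateral positions in the dye leaflet.
# Energy (kT units): -epsilon per CL molecule within r0 of the dye center.
.mc_cl_resample <- function(pos, cl_idx, leaf_idx, center, box, min_dist,
                            epsilon, r0, n_sweeps) {
  for (s in seq_len(n_sweeps)) {
    for (i in cl_idx) {
      p_new <- stats::runif(2) * box[1:2]
      others <- setdiff(leaf_idx, i)
      if (any(lateral_dist(p_new, pos[others, , drop = FALSE], box) <
                min_dist)) next
      d_old <- lateral_dist(pos[i, ], matrix(center, 1), box)
      d_new <- lateral_dist(p_new, matrix(center, 1), box)
      dE <- -epsilon * ((d_new < r0) - (d_old < r0))
      if (dE <= 0 || stats::runif(1) < exp(-dE)) pos[i, ] <- p_new
    }
  }
  pos
}

#' Lateral dye-to-marker distances, per frame
#'
#' Minimum-image in-plane distances between the dye's TPP phosphorus and all
#' markers of a species in the dye-containing leaflet. Convenience used for
#' affinity diagnostics.
#'
#' @param traj A `synthetic_traj` containing a dye.
#' @param species Lipid species label (e.g. "TLCL").
#' @param marker Marker name on the lipid (default "P").
#' @return data.frame with columns `frame` and `dist` (Angstrom).
#' @export
dye_distances <- function(traj, species, marker = "P") {
  dleaf <- dye_leaflet(traj)
  a <- select_atoms(traj, species = "DYE", name = "PTPP")
  b <- select_atoms(traj, species = species, name = marker, leaflet = dleaf)
  if (!length(b)) stop("no markers for species ", species)
  F <- n_frames(traj)
  out <- vector("list", F)
  for (f in seq_len(F)) {
    q <- traj$coords[b, 1:2, f, drop = FALSE]
    dim(q) <- dim(q)[1:2]
    d <- lateral_dist(traj$coords[a, 1:2, f], q, traj$box)
    out[[f]] <- data.frame(frame = f, dist = d)
  }
  do.call(rbind, out)
}
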