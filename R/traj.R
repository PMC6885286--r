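# Trajectory container and atom selection.

#' Construct a synthetic trajectory object
#'
#' A trajectory is a fixed topology (one row per marker particle) plus a
#' `n_atoms x 3 x n_frames` coordinate array in Angstrom and an orthorhombic
#' box. All analysis functions in the package consume this container, so
#' trajectories read from GRO/PDB/XYZ files and trajectories produced by the
#' generator are interchangeable.
#'
#' @param topology data.frame with columns `name`, `group`, `species`,
#'   `resname`, `resid`, `leaflet` ("upper"/"lower"), `mass` (amu).
#' @param coords Numeric array `n_atoms x 3 x n_frames` (Angstrom), or an
#'   `n_atoms x 3` matrix for a single frame.
#' @param box Numeric length-3: Lx, Ly, Lz in Angstrom.
#' @param seed,affinity,depth_model Optional provenance of the generator.
#' @return Object of class `synthetic_traj`.
#' @export
synthetic_traj <- function(topology, coords, box, seed = NULL,
                           affinity = NULL, depth_model = NULL) {
  req <- c("name", "group", "species", "resname", "resid", "leaflet", "mass")
  miss <- setdiff(req, names(topology))
  if (length(miss)) {
    stop("topology lacks columns: ", paste(miss, collapse = ", "))
  }
  if (is.matrix(coords)) {
    coords <- array(coords, dim = c(nrow(coords), 3, 1))
  }
  stopifnot(length(dim(coords)) == 3, dim(coords)[2] == 3,
            dim(coords)[1] == nrow(topology), length(box) == 3)
  structure(
    list(topology = topology, coords = coords, box = as.numeric(box),
         seed = seed, affinity = affinity, depth_model = depth_model),
    class = "synthetic_traj"
  )
}

#' Number of frames in a trajectory
#' @param traj A `synthetic_traj`.
#' @return Integer frame count.
#' @export
n_frames <- function(traj) dim(traj$coords)[3]

#' @export
print.synthetic_traj <- function(x, ...) {
  cat(sprintf("synthetic_traj: %d atoms, %d frames, box %.1f x %.1f x %.1f A\n",
              nrow(x$topology), n_frames(x), x$box[1], x$box[2], x$box[3]))
  cat("  species:", paste(unique(x$topology$species), collapse = " "), "\n")
  invisible(x)
}

#' Select atoms of a trajectory
#'
#' Filters the topology by any combination of group, species, marker name,
#' and leaflet; `NULL` means no constraint on that field.
#'
#' @param traj A `synthetic_traj`.
#' @param group,species,name,leaflet Character vectors of admissible values
#'   or `NULL`.
#' @return Integer vector of atom indices (possibly empty).
#' @export
select_atoms <- function(traj, group = NULL, species = NULL, name = NULL,
                         leaflet = NULL) {
  top <- traj$topology
  keep <- rep(TRUE, nrow(top))
  if (!is.null(group))   keep <- keep & top$group %in% group
  if (!is.null(species)) keep <- keep & top$species %in% species
  if (!is.null(name))    keep <- keep & top$name %in% name
  if (!is.null(leaflet)) keep <- keep & top$leaflet %in% leaflet
  which(keep)
}

#' Leaflet containing the dye
#' @param traj A `synthetic_traj`.
#' @return "upper" or "lower".
#' @export
dye_leaflet <- function(traj) {
  i <- select_atoms(traj, species = "DYE")
  if (!length(i)) stop("trajectory contains no dye (species 'DYE')")
  unique(traj$topology$leaflet[i])[1]
}

# Per-frame bilayer midplane: mean z of all phosphate-equivalent lipid
# markers (name "P", species != DYE). Returns vector of length n_frames.
midplane_z <- function(traj) {
  idx <- select_atoms(traj, name = "P")
  idx <- idx[traj$topology$species[idx] != "DYE"]
  if (!length(idx)) stop("no phosphate markers to define the midplane")
  apply(traj$coords[idx, 3, , drop = FALSE], 3, mean)
}
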