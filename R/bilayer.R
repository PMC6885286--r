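# Coarse bilayer construction: composition apportionment, marker topology,
# and seeded lateral placement with a hard-core exclusion.

#' Default depth model for the coarse generator
#'
#' Gaussian means (Angstrom, bilayer midplane at z = 0, per leaflet the mean
#' applies with the leaflet sign) and a common standard deviation for each
#' marker group. The defaults put phosphate/TPP markers in the headgroup
#' band near |z| = 18, acyl diene carbons near |z| = 8, the probe linker in
#' between, and the C9/C13 hydroperoxide bands at |z| = 9 and 13: the C9
#' band therefore co-localizes more closely with the probe's oxidizable
#' diene than the C13 band does. All values are configuration, not
#' constants.
#'
#' @param sigma Common Gaussian sigma in Angstrom.
#' @return List with elements `means` (named numeric) and `sigma`.
#' @export
default_depth_model <- function(sigma = 3) {
  list(
    means = c(headgroup = 18, CL_glycerol = 16, CL_diene = 8,
              CL_peroxide_9 = 9, CL_peroxide_13 = 13,
              TPP = 18, linker = 14, dye_diene = 8, PDT = 8),
    sigma = sigma
  )
}

# group label for a marker name within a lipid species
.marker_group <- function(name) {
  switch(name,
         P  = "headgroup",
         C2 = "CL_glycerol",
         CC = "CL_diene",
         OO = "CL_peroxide",
         stop("unknown lipid marker name: ", name))
}

# nominal marker masses (amu) used by mass-weighted density profiles
.marker_mass <- c(P = 94.97, C2 = 13.02, CC = 48.04, OO = 34.01,
                  PTPP = 30.97, LK1 = 42.0, LK2 = 42.0,
                  DC1 = 24.02, DC2 = 24.02, PDT = 115.2)

# dye marker table: name, group, lateral offset (Angstrom) along the
# per-frame orientation unit vector; PTPP sits at the dye center.
.dye_markers <- function() {
  data.frame(
    name  = c("PTPP", "LK1", "LK2", "DC1", "DC2", "PDT"),
    group = c("TPP", "linker", "linker", "dye_diene", "dye_diene", "PDT"),
    off   = c(0, 3, 5, 7, 9, 8),
    stringsAsFactors = FALSE
  )
}

# Resolve the depth-model mean for one topology row.
.zmean_for <- function(group, peroxide_position, means) {
  if (group == "CL_peroxide") {
    key <- paste0("CL_peroxide_", peroxide_position)
  } else {
    key <- group
  }
  if (!key %in% names(means)) stop("depth model lacks a mean for ", key)
  unname(means[key])
}

#' Build a coarse bilayer configuration
#'
#' Apportions the composition onto `n_per_leaflet` lipids per leaflet by the
#' largest-remainder method, builds a marker-level topology (one particle
#' per marker site), places lipids laterally at random with a hard-core
#' minimum distance, and inserts the dye into the upper leaflet at the box
#' center. When `oxidized` is 9 or 13, the cardiolipin population is
#' replaced by the four mono-hydroperoxide variants of that position in
#' equal proportion.
#'
#' @param comp A [composition_spec()]; default [default_composition()].
#' @param n_per_leaflet Lipids per leaflet (>= 1).
#' @param seed Integer seed for the placement RNG.
#' @param oxidized Optional peroxide position (9 or 13).
#' @param area_per_lipid Lateral area per lipid in Angstrom^2 (sets the box).
#' @param lz Box extent along the normal (Angstrom).
#' @param min_dist Hard-core lateral minimum distance between molecules
#'   (Angstrom).
#' @param depth_model Depth model, see [default_depth_model()].
#' @param dye Logical; include the probe molecule (default TRUE).
#' @return Object of class `bilayer_config`: topology, molecule table, one
#'   placed frame, box, counts.
#' @examples
#' cfg <- build_bilayer(n_per_leaflet = 43, seed = 1)
#' cfg$counts
#' @export
build_bilayer <- function(comp = default_composition(), n_per_leaflet,
                          seed = 1L, oxidized = NULL, area_per_lipid = 65,
                          lz = 80, min_dist = 4,
                          depth_model = default_depth_model(), dye = TRUE) {
  stopifnot(inherits(comp, "composition_spec"))
  counts <- apportion_largest_remainder(comp$ratio, n_per_leaflet)
  names(counts) <- vapply(comp$species, `[[`, "", "name")

  # species roster actually placed (oxidized membranes swap TLCL for the
  # four same-position hydroperoxide variants in equal proportion)
  roster <- list()   # list of (spec, count)
  for (i in seq_along(comp$species)) {
    sp <- comp$species[[i]]
    if (!is.null(oxidized) && identical(sp$name, "TLCL")) {
      stopifnot(oxidized %in% c(9L, 13L))
      vars <- enumerate_oxidized_cl(position = oxidized)
      sub <- apportion_largest_remainder(rep(1, 4), counts[i])
      for (v in seq_len(4)) {
        if (sub[v] > 0) {
          roster[[length(roster) + 1]] <-
            list(spec = oxidized_cl_spec(vars[v, ]), count = sub[v])
        }
      }
    } else if (counts[i] > 0) {
      roster[[length(roster) + 1]] <- list(spec = sp, count = counts[i])
    }
  }

  L <- sqrt(n_per_leaflet * area_per_lipid)
  box <- c(L, L, lz)

  # molecule and atom tables, both leaflets
  mol_rows <- list(); atom_rows <- list()
  mol_id <- 0L
  for (leaf in c("upper", "lower")) {
    for (entry in roster) {
      sp <- entry$spec
      resname <- if (!is.null(sp$resname)) sp$resname else sp$name
      is_cl <- "C2" %in% sp$marker_atoms
      ppos <- if (!is.null(sp$peroxide_position)) sp$peroxide_position else NA
      for (m in seq_len(entry$count)) {
        mol_id <- mol_id + 1L
        mol_rows[[mol_id]] <- data.frame(
          mol = mol_id, species = sp$name, resname = resname,
          leaflet = leaf, is_cl = is_cl, is_dye = FALSE,
          stringsAsFactors = FALSE)
        atom_rows[[length(atom_rows) + 1]] <- data.frame(
          name = sp$marker_atoms,
          group = vapply(sp$marker_atoms, .marker_group, ""),
          species = sp$name, resname = resname, resid = mol_id,
          leaflet = leaf, mol = mol_id,
          mass = unname(.marker_mass[sp$marker_atoms]),
          dye_off = 0, peroxide_position = ppos,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (dye) {
    mol_id <- mol_id + 1L
    dm <- .dye_markers()
    mol_rows[[mol_id]] <- data.frame(
      mol = mol_id, species = "DYE", resname = "DYE", leaflet = "upper",
      is_cl = FALSE, is_dye = TRUE, stringsAsFactors = FALSE)
    atom_rows[[length(atom_rows) + 1]] <- data.frame(
      name = dm$name, group = dm$group, species = "DYE", resname = "DYE",
      resid = mol_id, leaflet = "upper", mol = mol_id,
      mass = unname(.marker_mass[dm$name]), dye_off = dm$off,
      peroxide_position = NA, stringsAsFactors = FALSE)
  }
  molecules <- do.call(rbind, mol_rows)
  topology <- do.call(rbind, atom_rows)
  rownames(topology) <- NULL

  topology$zmean <- mapply(.zmean_for, topology$group,
                           topology$peroxide_position,
                           MoreArgs = list(means = depth_model$means))
  topology$zmean[topology$group == "CL_peroxide" &
                   is.na(topology$peroxide_position)] <- NA

  cfg <- structure(
    list(topology = topology, molecules = molecules, box = box,
         counts = counts, composition = comp, oxidized = oxidized,
         min_dist = min_dist, depth_model = depth_model, seed = seed),
    class = "bilayer_config"
  )
  set.seed(seed)
  cfg$xyz <- .frame_coords(cfg, .place_all(cfg))
  cfg
}

#' @export
print.bilayer_config <- function(x, ...) {
  cat(sprintf("bilayer_config: %d molecules (%d per leaflet), box %.1f x %.1f x %.1f A\n",
              nrow(x$molecules), sum(x$counts), x$box[1], x$box[2], x$box[3]))
  print(x$counts)
  invisible(x)
}

# Random non-overlapping lateral placement of all molecules (both leaflets).
# Dye molecules are pinned at the box center. Returns n_mol x 2 matrix.
.place_all <- function(cfg) {
  mols <- cfg$molecules
  box <- cfg$box
  pos <- matrix(NA_real_, nrow(mols), 2)
  for (leaf in c("upper", "lower")) {
    idx <- which(mols$leaflet == leaf)
    # dye first, pinned at the center
    dye_i <- idx[mols$is_dye[idx]]
    if (length(dye_i)) pos[dye_i, ] <- rep(box[1:2] / 2, each = length(dye_i))
    placed <- matrix(pos[dye_i, ], ncol = 2)
    for (i in idx[!mols$is_dye[idx]]) {
      ok <- FALSE
      for (try in seq_len(5000)) {
        p <- stats::runif(2) * box[1:2]
        if (nrow(placed) == 0 ||
            all(lateral_dist(p, placed, box) >= cfg$min_dist)) {
          ok <- TRUE; break
        }
      }
      if (!ok) stop("could not place molecule ", i,
                    ": leaflet too crowded for min_dist = ", cfg$min_dist)
      pos[i, ] <- p
      placed <- rbind(placed, p)
    }
  }
  pos
}

# Assemble atom coordinates for one frame from molecule lateral positions.
# Draws marker depths from the per-group Gaussians and a random dye
# orientation. Consumes RNG.
.frame_coords <- function(cfg, molpos) {
  top <- cfg$topology
  n <- nrow(top)
  xyz <- matrix(0, n, 3)
  xyz[, 1:2] <- molpos[top$mol, , drop = FALSE]
  dye_atoms <- which(top$species == "DYE")
  if (length(dye_atoms)) {
    theta <- stats::runif(1, 0, 2 * pi)
    u <- c(cos(theta), sin(theta))
    off <- top$dye_off[dye_atoms]
    xyz[dye_atoms, 1] <- xyz[dye_atoms, 1] + off * u[1]
    xyz[dye_atoms, 2] <- xyz[dye_atoms, 2] + off * u[2]
  }
  sign <- ifelse(top$leaflet == "upper", 1, -1)
  xyz[, 3] <- sign * stats::rnorm(n, mean = top$zmean,
                                  sd = cfg$depth_model$sigma)
  # wrap lateral coordinates into the box
  xyz[, 1] <- xyz[, 1] %% cfg$box[1]
  xyz[, 2] <- xyz[, 2] %% cfg$box[2]
  xyz
}
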