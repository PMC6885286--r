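# Depth density profiles along the bilayer normal and their overlap.

# amu per Angstrom^3 -> g per cm^3; also (1/A^3) -> mol/cm^3
.AMU_PER_A3_TO_G_CM3 <- 1.66053907

#' Depth density profile along the bilayer normal
#'
#' Histograms the z coordinates of a marker selection, centered on the
#' per-frame bilayer midplane (mean z of all lipid phosphate markers),
#' averages over frames and divides by the slab volume. Unit modes follow
#' the display convention of putting minority components on a comparable
#' scale: `"mass"` is g/cm^3, `"mass_x10"` the same density expressed in
#' units of 10 (value multiplied by 10), `"molar_x10"` molar density
#' (mol/cm^3) times 10, `"number"` the raw per-Angstrom^3 number density.
#'
#' @param traj A `synthetic_traj`.
#' @param group,species,name,leaflet Selection (see [select_atoms()]).
#' @param bin Bin width along z in Angstrom (> 0).
#' @param units_mode One of "mass", "mass_x10", "molar_x10", "number".
#' @param frames Optional integer frame subset (default all).
#' @return Object of class `density_profile`: `z` (bin centers), `edges`,
#'   `values` (scaled), `raw` (amu/A^3 for mass modes, 1/A^3 otherwise),
#'   `units_mode`, `group` label.
#' @export
depth_density_profile <- function(traj, group = NULL, species = NULL,
                                  name = NULL, leaflet = NULL, bin = 1,
                                  units_mode = c("mass", "mass_x10",
                                                 "molar_x10", "number"),
                                  frames = NULL) {
  units_mode <- match.arg(units_mode)
  stopifnot(bin > 0)
  if (is.null(frames)) frames <- seq_len(n_frames(traj))
  if (!length(frames)) stop("zero frames selected")
  idx <- select_atoms(traj, group = group, species = species, name = name,
                      leaflet = leaflet)
  half <- traj$box[3] / 2
  edges <- seq(-half, half, by = bin)
  if (edges[length(edges)] < half) edges <- c(edges, edges[length(edges)] + bin)
  centers <- (edges[-1] + edges[-length(edges)]) / 2
  label <- paste(c(group, species, name), collapse = "/")
  if (!length(idx)) {
    warning("empty selection '", label, "': returning an all-zero profile")
    vals <- numeric(length(centers))
    return(structure(list(z = centers, edges = edges, values = vals,
                          raw = vals, units_mode = units_mode,
                          group = label, bin = bin),
                     class = "density_profile"))
  }
  mid <- midplane_z(traj)
  mass_weight <- units_mode %in% c("mass", "mass_x10")
  w <- if (mass_weight) traj$topology$mass[idx] else rep(1, length(idx))
  acc <- numeric(length(centers))
  for (f in frames) {
    z <- traj$coords[idx, 3, f] - mid[f]
    bi <- findInterval(z, edges, rightmost.closed = TRUE)
    ok <- bi >= 1 & bi <= length(centers)
    if (any(ok)) {
      tmp <- rowsum(w[ok], bi[ok])
      acc[as.integer(rownames(tmp))] <- acc[as.integer(rownames(tmp))] +
        as.numeric(tmp)
    }
  }
  slab <- traj$box[1] * traj$box[2] * bin
  raw <- acc / (length(frames) * slab)   # amu/A^3 or 1/A^3
  values <- switch(units_mode,
                   mass = raw * .AMU_PER_A3_TO_G_CM3,
                   mass_x10 = raw * .AMU_PER_A3_TO_G_CM3 * 10,
                   molar_x10 = raw * .AMU_PER_A3_TO_G_CM3 * 10,
                   number = raw)
  structure(list(z = centers, edges = edges, values = values, raw = raw,
                 units_mode = units_mode, group = label, bin = bin),
            class = "density_profile")
}

#' @export
print.density_profile <- function(x, ...) {
  pk <- x$z[which.max(x$values)]
  cat(sprintf("density_profile '%s' (%s): %d bins of %g A, peak at z = %g A\n",
              x$group, x$units_mode, length(x$z), x$bin, pk))
  invisible(x)
}

#' @export
plot.density_profile <- function(x, ...) {
  graphics::plot(x$z, x$values, type = "l",
                 xlab = "z (Angstrom, midplane 0)",
                 ylab = paste0("density (", x$units_mode, ")"),
                 main = x$group, ...)
  invisible(x)
}

#' Depth of the profile maximum
#'
#' @param profile A `density_profile`.
#' @param absolute Return |z| of the peak (default TRUE; profiles of a
#'   symmetric bilayer peak in both leaflets).
#' @return z (or |z|) of the highest bin, Angstrom.
#' @export
profile_peak_depth <- function(profile, absolute = TRUE) {
  z <- profile$z[which.max(profile$values)]
  if (absolute) abs(z) else z
}

#' Overlap coefficient of two depth profiles
#'
#' Profiles are normalized to unit sum over the common bins, and the overlap
#' is the summed bin-wise minimum: 1 for identical shapes, 0 for disjoint
#' supports, symmetric in its arguments. Used to compare the probe's
#' oxidizable-diene depth band with the cardiolipin hydroperoxide bands.
#'
#' @param p1,p2 `density_profile` objects on identical bins.
#' @return Overlap coefficient in [0, 1].
#' @export
profile_overlap <- function(p1, p2) {
  if (length(p1$z) != length(p2$z) || any(abs(p1$z - p2$z) > 1e-9)) {
    stop("profiles are binned on different grids")
  }
  s1 <- sum(p1$values); s2 <- sum(p2$values)
  if (s1 <= 0 || s2 <= 0) return(0)
  sum(pmin(p1$values / s1, p2$values / s2))
}
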