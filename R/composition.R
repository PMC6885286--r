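# Lipid species, membrane composition, and oxidized-cardiolipin enumeration.

#' Describe a lipid species
#'
#' A lipid is reduced to the marker sites the coarse generator and the
#' analysis code care about: a phosphate-equivalent position, and for
#' cardiolipin additionally the central (C2) glycerol carbon, the acyl
#' double-bond carbons, and -- for oxidized variants -- the peroxide site.
#'
#' @param name Species label, e.g. "PLPC".
#' @param headgroup_charge Integer net charge of the headgroup in elementary
#'   charges (cardiolipin: -2; zwitterionic species: 0).
#' @param marker_atoms Character vector of marker-site names; must be
#'   non-empty. Conventional names: "P" (phosphate-equivalent), "C2"
#'   (central glycerol carbon), "CC" (acyl diene carbons), "OO" (peroxide).
#' @return An object of class `lipid_spec`.
#' @export
lipid_spec <- function(name, headgroup_charge, marker_atoms) {
  stopifnot(is.character(name), length(name) == 1L)
  if (length(marker_atoms) == 0L) {
    stop("marker_atoms must be non-empty for species ", name)
  }
  structure(
    list(name = name,
         headgroup_charge = as.integer(headgroup_charge),
         marker_atoms = as.character(marker_atoms)),
    class = "lipid_spec"
  )
}

#' Built-in lipid species table
#'
#' The four species of the model inner-mitochondrial-membrane mixture.
#' SLPE is treated as the ethanolamine (PE) species its abbreviation
#' implies; both full name and abbreviation are stored.
#'
#' @return Named list of `lipid_spec` objects.
#' @export
builtin_lipids <- function() {
  list(
    PLPC = lipid_spec("PLPC", 0L, "P"),
    SLPE = lipid_spec("SLPE", 0L, "P"),
    POPC = lipid_spec("POPC", 0L, "P"),
    TLCL = lipid_spec("TLCL", -2L, c("P", "C2", "CC"))
  )
}

#' Model membrane composition
#'
#' @param species Character vector of species names or list of
#'   [lipid_spec()] objects.
#' @param ratio Non-negative numeric mixing ratio, same length as `species`,
#'   with a positive sum.
#' @return An object of class `composition_spec`.
#' @export
composition_spec <- function(species, ratio) {
  if (is.character(species)) {
    lib <- builtin_lipids()
    unknown <- setdiff(species, names(lib))
    if (length(unknown)) {
      stop("unknown lipid species: ", paste(unknown, collapse = ", "))
    }
    species <- lib[species]
  }
  stopifnot(length(species) == length(ratio), all(ratio >= 0), sum(ratio) > 0)
  structure(
    list(species = species, ratio = as.numeric(ratio)),
    class = "composition_spec"
  )
}

#' Default membrane composition: PLPC:SLPE:POPC:TLCL = 7:21:7:8
#'
#' The mixture mimics the phospholipid make-up of the inner mitochondrial
#' membrane: two cholines (PLPC, POPC), one ethanolamine (SLPE), and
#' tetralinoleoyl cardiolipin (TLCL).
#'
#' @return A `composition_spec`.
#' @export
default_composition <- function() {
  composition_spec(c("PLPC", "SLPE", "POPC", "TLCL"), c(7, 21, 7, 8))
}

#' @export
print.composition_spec <- function(x, ...) {
  cat("Membrane composition:\n")
  for (i in seq_along(x$species)) {
    cat(sprintf("  %-6s ratio %g  charge %+d\n",
                x$species[[i]]$name, x$ratio[i],
                x$species[[i]]$headgroup_charge))
  }
  invisible(x)
}

#' Enumerate mono-hydroperoxy cardiolipin variants
#'
#' Linoleate autoxidation yields four positional/geometric hydroperoxide
#' isomers -- 13-EE, 13-ZE, 9-EE and 9-EZ conjugated-diene hydroperoxides.
#' Cardiolipin can carry the oxidized chain on either its glycero-1-acid or
#' glycero-2-acid half, so exactly eight distinct mono-peroxidized species
#' exist. Ordering is deterministic: peroxide position ascending, geometry
#' lexical, glycerol acid ascending.
#'
#' @param position Optional filter, 9 or 13.
#' @return A data.frame with columns `position`, `geometry`,
#'   `glycerol_acid`, `label`, and `resname` (a fixed 4-character residue
#'   code used by the structure writers).
#' @examples
#' enumerate_oxidized_cl()            # all 8
#' enumerate_oxidized_cl(position = 9)  # the 4 C9 hydroperoxides
#' @export
enumerate_oxidized_cl <- function(position = NULL) {
  hp <- data.frame(
    position = c(9L, 9L, 13L, 13L),
    geometry = c("EE", "EZ", "EE", "ZE"),
    stringsAsFactors = FALSE
  )
  out <- merge(hp, data.frame(glycerol_acid = c(1L, 2L)), by = NULL)
  out <- out[order(out$position, out$geometry, out$glycerol_acid), ]
  rownames(out) <- NULL
  out$label <- sprintf("CL-%d%s-sn%d", out$position, out$geometry,
                       out$glycerol_acid)
  # residue codes must fit 4 characters: position 13 is encoded "T"
  pos_code <- ifelse(out$position == 13L, "T", "9")
  out$resname <- paste0(pos_code, out$geometry, out$glycerol_acid)
  if (!is.null(position)) {
    stopifnot(position %in% c(9L, 13L))
    out <- out[out$position == position, ]
    rownames(out) <- NULL
  }
  out
}

# lipid_spec for an oxidized-CL variant row (as returned by
# enumerate_oxidized_cl): cardiolipin markers plus the peroxide site.
oxidized_cl_spec <- function(variant_row) {
  sp <- lipid_spec(variant_row$label, -2L, c("P", "C2", "CC", "OO"))
  sp$resname <- variant_row$resname
  sp$peroxide_position <- variant_row$position
  sp
}

#' Apportion a mixing ratio onto an integer count (largest remainder)
#'
#' Hamilton/largest-remainder apportionment: each species gets the floor of
#' its exact quota; remaining seats go to the largest fractional remainders
#' (ties broken by species order). Exact when `n` is a multiple of the
#' ratio sum.
#'
#' @param ratio Non-negative numeric vector with positive sum.
#' @param n Total integer count to distribute (>= 1).
#' @return Integer vector summing to `n`.
#' @examples
#' apportion_largest_remainder(c(7, 21, 7, 8), 43)
#' @export
apportion_largest_remainder <- function(ratio, n) {
  stopifnot(all(ratio >= 0), sum(ratio) > 0)
  n <- as.integer(n)
  if (is.na(n) || n < 1) {
    stop("cannot apportion a composition onto n = ", n,
         " lipids; need n >= 1")
  }
  quota <- n * ratio / sum(ratio)
  counts <- floor(quota)
  left <- n - sum(counts)
  if (left > 0) {
    frac <- quota - counts
    take <- order(-frac, seq_along(frac))[seq_len(left)]
    counts[take] <- counts[take] + 1
  }
  as.integer(counts)
}
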