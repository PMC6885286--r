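# Dye-aligned lateral occupancy maps and lateral radial distribution
# functions, restricted to the dye-containing leaflet.

# Alignment transform for one frame: translation of the dye reference point
# to the origin and rotation about the normal putting the planar projection
# of the (PDT tail centroid -> TPP centroid) vector along +Y. Returns NULL
# when the planar projection is degenerate.
.frame_alignment <- function(traj, f, ref = c("midpoint", "TPP"),
                             min_proj = 1e-6) {
  ref <- match.arg(ref)
  tpp <- select_atoms(traj, species = "DYE", group = "TPP")
  pdt <- select_atoms(traj, species = "DYE", group = "PDT")
  if (!length(tpp) || !length(pdt)) stop("dye sites (TPP, PDT) not present")
  ctpp <- c(mean(traj$coords[tpp, 1, f]), mean(traj$coords[tpp, 2, f]))
  cpdt <- c(mean(traj$coords[pdt, 1, f]), mean(traj$coords[pdt, 2, f]))
  v <- c(min_image(ctpp[1] - cpdt[1], traj$box[1]),
         min_image(ctpp[2] - cpdt[2], traj$box[2]))
  if (sqrt(sum(v^2)) < min_proj) return(NULL)
  beta <- pi / 2 - atan2(v[2], v[1])
  R <- matrix(c(cos(beta), sin(beta), -sin(beta), cos(beta)), 2, 2)
  origin <- if (ref == "midpoint") (ctpp + cpdt) / 2 else ctpp
  list(origin = origin, R = R)
}

#' Dye-aligned lateral occupancy map
#'
#' Per frame, all lateral positions in the dye-containing leaflet are
#' expressed relative to the dye reference point (minimum image), rotated so
#' the planar projection of the phenyldiene-to-TPP vector points along +Y,
#' and accumulated on a square grid. Values are time-averaged areal
#' concentrations (markers per Angstrom^2); the occupancy mask flags cells
#' whose concentration exceeds half the species' bulk concentration in the
#' leaflet. Frames with a degenerate alignment vector are skipped and
#' counted.
#'
#' @param traj A `synthetic_traj` with a dye.
#' @param species Character vector of species to map.
#' @param grid_step Cell edge in Angstrom (> 0).
#' @param marker Marker name locating each lipid (default "P").
#' @param ref Dye reference point: "midpoint" of the PDT and TPP centroids
#'   (default) or "TPP".
#' @return Named list (per species) of class `lateral_map`: `x`, `y` cell
#'   centers, `values`, `mask`, `bulk`, `n_frames_used`, `n_skipped`.
#' @export
lateral_map <- function(traj, species, grid_step = 2, marker = "P",
                        ref = "midpoint") {
  stopifnot(grid_step > 0)
  dleaf <- dye_leaflet(traj)
  L <- min(traj$box[1:2])
  half <- L / 2
  nb <- max(1L, floor(L / grid_step))
  edges <- seq(-half, half, length.out = nb + 1)
  centers <- (edges[-1] + edges[-length(edges)]) / 2
  F <- n_frames(traj)
  area_cell <- diff(edges)[1]^2
  sel <- lapply(species, function(sp)
    select_atoms(traj, species = sp, name = marker, leaflet = dleaf))
  names(sel) <- species
  counts <- lapply(species, function(sp) matrix(0, nb, nb))
  names(counts) <- species
  used <- 0L; skipped <- 0L
  for (f in seq_len(F)) {
    al <- .frame_alignment(traj, f, ref = ref)
    if (is.null(al)) { skipped <- skipped + 1L; next }
    used <- used + 1L
    for (sp in species) {
      idx <- sel[[sp]]
      if (!length(idx)) next
      dx <- min_image(traj$coords[idx, 1, f] - al$origin[1], traj$box[1])
      dy <- min_image(traj$coords[idx, 2, f] - al$origin[2], traj$box[2])
      p <- cbind(dx, dy) %*% t(al$R)
      bx <- findInterval(p[, 1], edges, rightmost.closed = TRUE)
      by <- findInterval(p[, 2], edges, rightmost.closed = TRUE)
      ok <- bx >= 1 & bx <= nb & by >= 1 & by <= nb
      for (q in which(ok)) {
        counts[[sp]][bx[q], by[q]] <- counts[[sp]][bx[q], by[q]] + 1
      }
    }
  }
  if (used == 0L) stop("all frames had degenerate alignment vectors")
  out <- lapply(species, function(sp) {
    vals <- counts[[sp]] / (used * area_cell)
    bulk <- length(sel[[sp]]) / (traj$box[1] * traj$box[2])
    structure(list(x = centers, y = centers, values = vals,
                   mask = vals > 0.5 * bulk, bulk = bulk,
                   species = sp, n_frames_used = used,
                   n_skipped = skipped, grid_step = diff(edges)[1]),
              class = "lateral_map")
  })
  names(out) <- species
  out
}

#' @export
print.lateral_map <- function(x, ...) {
  cat(sprintf("lateral_map %s: %dx%d cells of %.2f A, bulk %.4g /A^2, %d/%d cells occupied\n",
              x$species, length(x$x), length(x$y), x$grid_step, x$bulk,
              sum(x$mask), length(x$mask)))
  invisible(x)
}

#' Lateral radial distribution function around the dye
#'
#' Default lateral-2D mode: in-plane minimum-image distances between the
#' dye's TPP phosphorus and a lipid marker within the dye-containing
#' leaflet, binned and normalized by the ideal-gas annulus expectation
#' `n_B / Area * pi (r2^2 - r1^2)` per frame, so g(r) tends to 1 at large r
#' for unstructured placement. Per-bin Monte Carlo standard errors are
#' estimated from the frame-to-frame spread. A 3D mode (spherical shells,
#' lateral minimum image) is also available.
#'
#' @param traj A `synthetic_traj` with a dye.
#' @param species Partner species (e.g. "TLCL", "SLPE").
#' @param marker Partner marker name; default "C2" for cardiolipin species
#'   if present, else "P".
#' @param bin Radial bin width in Angstrom.
#' @param mode "lateral" (default) or "3d".
#' @param r_max Maximum radius; default half the smaller lateral box edge.
#' @return Object of class `rdf_result`: `r` (bin centers), `g`, `se`,
#'   `counts`, `pair`, `mode`.
#' @export
radial_distribution <- function(traj, species, marker = NULL, bin = 0.5,
                                mode = c("lateral", "3d"), r_max = NULL) {
  mode <- match.arg(mode)
  stopifnot(bin > 0)
  dleaf <- dye_leaflet(traj)
  if (is.null(marker)) {
    has_c2 <- length(select_atoms(traj, species = species, name = "C2")) > 0
    marker <- if (has_c2) "C2" else "P"
  }
  a <- select_atoms(traj, species = "DYE", name = "PTPP")
  b <- select_atoms(traj, species = species, name = marker, leaflet = dleaf)
  if (length(a) != 1) stop("expected exactly one TPP phosphorus marker")
  if (length(b) < 1) stop("no partner markers for species ", species,
                          " marker ", marker)
  if (is.null(r_max)) r_max <- min(traj$box[1:2]) / 2
  edges <- seq(0, r_max, by = bin)
  if (edges[length(edges)] < r_max) edges <- c(edges, r_max)
  nbin <- length(edges) - 1
  centers <- (edges[-1] + edges[-length(edges)]) / 2
  F <- n_frames(traj)
  area <- traj$box[1] * traj$box[2]
  gmat <- matrix(0, F, nbin)
  counts <- numeric(nbin)
  for (f in seq_len(F)) {
    q <- traj$coords[b, , f, drop = FALSE]
    dim(q) <- dim(q)[1:2]
    dx <- min_image(q[, 1] - traj$coords[a, 1, f], traj$box[1])
    dy <- min_image(q[, 2] - traj$coords[a, 2, f], traj$box[2])
    if (mode == "lateral") {
      d <- sqrt(dx^2 + dy^2)
      expct <- length(b) / area * pi * (edges[-1]^2 - edges[-nbin - 1]^2)
    } else {
      dz <- q[, 3] - traj$coords[a, 3, f]
      d <- sqrt(dx^2 + dy^2 + dz^2)
      vol <- area * traj$box[3]
      expct <- length(b) / vol * 4 / 3 * pi *
        (edges[-1]^3 - edges[-nbin - 1]^3)
    }
    h <- graphics::hist(d[d < r_max], breaks = edges, plot = FALSE)$counts
    counts <- counts + h
    gmat[f, ] <- h / expct
  }
  g <- colMeans(gmat)
  se <- apply(gmat, 2, stats::sd) / sqrt(F)
  structure(list(r = centers, g = g, se = se, counts = counts,
                 pair = c("TPP-P", paste0(species, "-", marker)),
                 mode = mode, bin = bin, n_frames = F),
            class = "rdf_result")
}

#' @export
print.rdf_result <- function(x, ...) {
  pk <- x$r[which.max(x$g)]
  cat(sprintf("rdf_result %s vs %s (%s): peak g = %.2f at r = %.2f A over %d frames\n",
              x$pair[1], x$pair[2], x$mode, max(x$g), pk, x$n_frames))
  invisible(x)
}

#' @export
plot.rdf_result <- function(x, ...) {
  graphics::plot(x$r, x$g, type = "l", xlab = "r (Angstrom)", ylab = "g(r)",
                 main = paste(x$pair, collapse = " vs "), ...)
  graphics::abline(h = 1, lty = 3)
  invisible(x)
}

#' First-shell maximum of an RDF
#'
#' @param rdf An `rdf_result`.
#' @param r_shell Upper radius of the first shell (Angstrom).
#' @return Maximum g(r) for r <= r_shell.
#' @export
rdf_first_shell_max <- function(rdf, r_shell) {
  sel <- rdf$r <= r_shell
  if (!any(sel)) stop("no bins within r_shell")
  max(rdf$g[sel])
}
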