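# Periodic dihedral energy model, least-squares fitting of torsion terms to
# a reference potential-energy surface, and the thermal flexibility range.

#' A periodic dihedral term k * (1 + cos(n*phi - delta))
#'
#' Phases are conventionally restricted to 0 or 180 degrees; a 180-degree
#' phase is equivalent to a sign flip of `k` at phase 0, which is how the
#' linear fit represents it. Signed `k` is therefore permitted.
#'
#' @param k Force constant, kcal/mol (may be negative when delta = 0 encodes
#'   a 180-degree phase).
#' @param n Multiplicity, one of 1, 2, 3, 4, 6.
#' @param delta Phase in degrees (default 0).
#' @return Object of class `dihedral_term`.
#' @export
dihedral_term <- function(k, n, delta = 0) {
  if (!n %in% c(1, 2, 3, 4, 6)) {
    stop("multiplicity n must be one of 1, 2, 3, 4, 6; got ", n)
  }
  structure(list(k = as.numeric(k), n = as.integer(n),
                 delta = as.numeric(delta)),
            class = "dihedral_term")
}

#' Evaluate a periodic dihedral energy
#'
#' E(phi) = sum_i k_i * (1 + cos(n_i * phi - delta_i)), angles in degrees,
#' energy in kcal/mol. An empty term list gives identically zero.
#'
#' @param angle Numeric vector of dihedral angles in degrees.
#' @param terms List of [dihedral_term()] objects (possibly empty).
#' @return Numeric vector of energies.
#' @examples
#' dihedral_energy(c(0, 180), list(dihedral_term(1, 1)))
#' @export
dihedral_energy <- function(angle, terms) {
  e <- numeric(length(angle))
  for (t in terms) {
    e <- e + t$k * (1 + cos((t$n * angle - t$delta) * pi / 180))
  }
  e
}

#' Torsion potential-energy surface
#'
#' @param angles Strictly increasing angle grid in degrees.
#' @param energies Energies in kcal/mol; normalized so that the minimum is 0
#'   unless `normalize = FALSE`.
#' @param label Bond identity label (e.g. "C14-C15").
#' @param normalize Re-zero to the minimum (default TRUE).
#' @return Object of class `torsion_pes`.
#' @export
torsion_pes <- function(angles, energies, label = "", normalize = TRUE) {
  stopifnot(length(angles) == length(energies), !anyNA(energies))
  if (any(diff(angles) <= 0)) stop("PES angles must be strictly increasing")
  if (normalize) energies <- energies - min(energies)
  structure(list(angles = as.numeric(angles),
                 energies = as.numeric(energies),
                 label = label),
            class = "torsion_pes")
}

#' @export
print.torsion_pes <- function(x, ...) {
  cat(sprintf("torsion_pes '%s': %d points over [%g, %g] deg, barrier %.3f kcal/mol\n",
              x$label, length(x$angles), min(x$angles), max(x$angles),
              max(x$energies)))
  invisible(x)
}

#' Read/write a PES as a two-column CSV (angle_deg, energy_kcal_mol)
#'
#' The on-disk table is the interchange format for reference torsion
#' profiles (e.g. tabulated quantum-chemical scans).
#'
#' @param path CSV file path.
#' @param label Label for the PES read.
#' @return [torsion_pes()] for `read_pes`; `path` invisibly for `write_pes`.
#' @export
read_pes <- function(path, label = basename(path)) {
  d <- utils::read.csv(path)
  if (ncol(d) < 2) stop(path, ": expected columns angle_deg, energy_kcal_mol")
  torsion_pes(d[[1]], d[[2]], label = label)
}

#' @rdname read_pes
#' @param pes A `torsion_pes` to write.
#' @export
write_pes <- function(pes, path) {
  utils::write.csv(
    data.frame(angle_deg = pes$angles, energy_kcal_mol = pes$energies),
    path, row.names = FALSE)
  invisible(path)
}

#' Fit periodic dihedral terms to a reference PES
#'
#' Linear least squares of the cosine amplitudes: with phases fixed at 0
#' degrees (a 180-degree phase is a negative amplitude), E(phi) =
#' c0 + sum_n k_n cos(n phi) is linear in (c0, k_n). When a background
#' molecule is supplied, its relaxed-scan profile with the fitted torsion
#' zeroed is subtracted from the reference before fitting, so the terms
#' absorb only the residual torsional energy.
#'
#' @param ref Reference [torsion_pes()].
#' @param multiplicities Integer multiplicities to fit (default 1:3).
#' @param base Optional background: either a `torsion_pes` on the same grid
#'   or a list `list(mol = <toy_molecule>, dihedral = <atom quadruple>)`
#'   whose relaxed scan (with the scanned torsion's terms removed) is
#'   computed on `ref$angles`.
#' @return List of class `dihedral_fit`: `terms` (list of
#'   [dihedral_term()]), `offset`, `rmse`, `fitted` (a `torsion_pes` of the
#'   model evaluated on the grid).
#' @examples
#' tr <- list(dihedral_term(1.2, 1), dihedral_term(0.8, 2, 180),
#'            dihedral_term(0.5, 3))
#' grid <- seq(-180, 170, by = 10)
#' fit <- fit_dihedral_terms(torsion_pes(grid, dihedral_energy(grid, tr)))
#' sapply(fit$terms, `[[`, "k")
#' @export
fit_dihedral_terms <- function(ref, multiplicities = c(1, 2, 3),
                               base = NULL) {
  stopifnot(inherits(ref, "torsion_pes"))
  m <- sort(unique(as.integer(multiplicities)))
  need <- 2 * length(m) + 1
  if (length(ref$angles) < need) {
    stop("underdetermined fit: ", length(ref$angles), " points for ",
         length(m), " multiplicities; need at least ", need)
  }
  y <- ref$energies
  if (!is.null(base)) {
    bg <- if (inherits(base, "torsion_pes")) {
      base
    } else {
      mol0 <- base$mol
      mol0$torsions <- lapply(mol0$torsions, function(tr) {
        if (identical(sort(tr$atoms[2:3]), sort(base$dihedral[2:3]))) {
          tr$terms <- list()
        }
        tr
      })
      relaxed_scan(mol0, base$dihedral, ref$angles)
    }
    if (length(bg$angles) != length(ref$angles) ||
        any(abs(bg$angles - ref$angles) > 1e-9)) {
      stop("background PES grid does not match the reference grid")
    }
    y <- y - bg$energies
  }
  phi <- ref$angles * pi / 180
  X <- cbind(1, vapply(m, function(n) cos(n * phi), numeric(length(phi))))
  coef <- stats::lm.fit(X, y)$coefficients
  coef[is.na(coef)] <- 0
  terms <- lapply(seq_along(m),
                  function(i) dihedral_term(coef[i + 1], m[i]))
  pred <- as.numeric(X %*% coef)
  rmse <- sqrt(mean((y - pred)^2))
  structure(
    list(terms = terms, offset = unname(coef[1]), rmse = rmse,
         multiplicities = m,
         fitted = torsion_pes(ref$angles,
                              dihedral_energy(ref$angles, terms),
                              label = paste0(ref$label, " (fit)"))),
    class = "dihedral_fit")
}

#' @export
print.dihedral_fit <- function(x, ...) {
  cat("dihedral fit (phases fixed at 0 deg; signed amplitudes):\n")
  for (t in x$terms) {
    cat(sprintf("  k = %+.6f kcal/mol  n = %d\n", t$k, t$n))
  }
  cat(sprintf("  offset %.6f, RMSE %.3g kcal/mol\n", x$offset, x$rmse))
  invisible(x)
}

#' Thermal flexibility range of a torsion
#'
#' Width in degrees of the contiguous angular interval around the global
#' PES minimum within which the energy stays at or below a thermal
#' threshold (default 2 kT at 310 K). Crossings are located by linear
#' interpolation between grid points; grids covering a full period are
#' treated periodically.
#'
#' @param pes A normalized [torsion_pes()] (minimum 0).
#' @param threshold Energy threshold in kcal/mol; default `2 * kT(temperature)`.
#' @param temperature Temperature in K used for the default threshold.
#' @return Width in degrees (<= 360).
#' @examples
#' grid <- seq(-180, 179, by = 1)
#' pes <- torsion_pes(grid, 1 - cos(grid * pi / 180))
#' flexibility_range(pes, threshold = 1)   # 180 degrees
#' @export
flexibility_range <- function(pes, threshold = NULL, temperature = 310) {
  stopifnot(inherits(pes, "torsion_pes"))
  if (is.null(threshold)) threshold <- 2 * kT(temperature)
  if (threshold <= 0) stop("flexibility threshold must be positive")
  a <- pes$angles
  e <- pes$energies - min(pes$energies)
  step <- stats::median(diff(a))
  span <- max(a) - min(a)
  periodic <- (360 - span) <= 2 * step + 1e-9
  if (periodic) {
    a <- c(a - 360, a, a + 360)
    e <- rep(e, 3)
    imin <- length(pes$angles) + which.min(pes$energies)
  } else {
    imin <- which.min(e)
  }
  # march right from the minimum to the first upward crossing
  right <- a[length(a)]
  if (imin < length(a)) {
    for (i in imin:(length(a) - 1)) {
      if (e[i] <= threshold && e[i + 1] > threshold) {
        right <- a[i] + (threshold - e[i]) / (e[i + 1] - e[i]) *
          (a[i + 1] - a[i])
        break
      }
    }
  }
  left <- a[1]
  if (imin > 1) {
    for (i in imin:2) {
      if (e[i] <= threshold && e[i - 1] > threshold) {
        left <- a[i] - (threshold - e[i]) / (e[i - 1] - e[i]) *
          (a[i] - a[i - 1])
        break
      }
    }
  }
  min(right - left, 360)
}
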