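# Toy molecular mechanics: a minimal CHARMM-like energy function (harmonic
# bonds and angles, periodic torsions, 1-4 Lennard-Jones and Coulomb pairs)
# sufficient to exercise relaxed torsion scanning against a brute-force
# oracle. Not a general force-field engine.

.COULOMB_KCAL <- 332.0636  # kcal/mol * Angstrom / e^2

#' Construct a toy molecule
#'
#' @param atoms data.frame with columns `name` and `charge` (e).
#' @param xyz Initial coordinates, n x 3 matrix (Angstrom).
#' @param bonds data.frame `i, j, r0, k` (Angstrom, kcal/mol/A^2; energy
#'   k*(r - r0)^2, CHARMM convention).
#' @param angles data.frame `i, j, k, theta0, ktheta` (degrees,
#'   kcal/mol/rad^2; energy ktheta*(theta - theta0)^2).
#' @param torsions List of `list(atoms = c(i,j,k,l), terms = list of
#'   dihedral_term)`.
#' @param pairs14 data.frame `i, j, eps, rmin` for 1-4 Lennard-Jones
#'   (CHARMM form eps*((rmin/r)^12 - 2*(rmin/r)^6)) plus Coulomb from the
#'   atomic charges.
#' @return Object of class `toy_molecule`.
#' @export
toy_molecule <- function(atoms, xyz, bonds, angles = NULL, torsions = list(),
                         pairs14 = NULL) {
  n <- nrow(atoms)
  stopifnot(is.matrix(xyz), nrow(xyz) == n, ncol(xyz) == 3)
  # connectivity must form a single connected graph
  if (nrow(bonds) > 0) {
    comp <- seq_len(n)
    repeat {
      changed <- FALSE
      for (b in seq_len(nrow(bonds))) {
        ci <- comp[bonds$i[b]]; cj <- comp[bonds$j[b]]
        if (ci != cj) { comp[comp == max(ci, cj)] <- min(ci, cj); changed <- TRUE }
      }
      if (!changed) break
    }
    if (length(unique(comp)) != 1) {
      stop("toy molecule connectivity is not a single connected graph")
    }
  }
  structure(list(atoms = atoms, xyz = xyz, bonds = bonds, angles = angles,
                 torsions = torsions, pairs14 = pairs14),
            class = "toy_molecule")
}

#' Measure a dihedral angle (IUPAC sign convention)
#'
#' @param xyz n x 3 coordinate matrix (Angstrom).
#' @param idx Atom quadruple (i, j, k, l).
#' @return Angle in degrees in [-180, 180).
#' @export
measure_dihedral <- function(xyz, idx) {
  p <- xyz[idx, , drop = FALSE]
  b1 <- p[2, ] - p[1, ]; b2 <- p[3, ] - p[2, ]; b3 <- p[4, ] - p[3, ]
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m <- c(b2[2] * n1[3] - b2[3] * n1[2],
         b2[3] * n1[1] - b2[1] * n1[3],
         b2[1] * n1[2] - b2[2] * n1[1]) / sqrt(sum(b2^2))
  wrap_angle(atan2(sum(m * n2), sum(n1 * n2)) * 180 / pi)
}

# Rotate the l-side of bond j-k so the dihedral (i,j,k,l) equals `target`
# degrees. Returns the new coordinate matrix.
set_dihedral <- function(mol, idx, target, xyz = mol$xyz) {
  cur <- measure_dihedral(xyz, idx)
  delta <- (target - cur) * pi / 180
  if (abs(delta) < 1e-14) return(xyz)
  j <- idx[2]; k <- idx[3]
  # atoms on the k-side of bond j-k (BFS excluding the j-k edge)
  adj <- vector("list", nrow(xyz))
  for (b in seq_len(nrow(mol$bonds))) {
    bi <- mol$bonds$i[b]; bj <- mol$bonds$j[b]
    if ((bi == j && bj == k) || (bi == k && bj == j)) next
    adj[[bi]] <- c(adj[[bi]], bj); adj[[bj]] <- c(adj[[bj]], bi)
  }
  side <- k; queue <- k; seen <- rep(FALSE, nrow(xyz)); seen[c(j, k)] <- TRUE
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    for (w in adj[[v]]) {
      if (!seen[w]) { seen[w] <- TRUE; side <- c(side, w); queue <- c(queue, w) }
    }
  }
  axis <- xyz[k, ] - xyz[j, ]
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, axis[3], -axis[2],
                -axis[3], 0, axis[1],
                axis[2], -axis[1], 0), 3, 3)
  R <- diag(3) + sin(delta) * K + (1 - cos(delta)) * (K %*% K)
  rot <- setdiff(side, k)
  if (length(rot)) {
    xyz[rot, ] <- sweep(sweep(xyz[rot, , drop = FALSE], 2, xyz[k, ]) %*% t(R),
                        2, xyz[k, ], `+`)
  }
  xyz
}

#' Mechanical energy of a toy molecule
#'
#' @param mol A [toy_molecule()].
#' @param xyz Coordinates (defaults to the molecule's own).
#' @return Energy in kcal/mol.
#' @export
toy_energy <- function(mol, xyz = mol$xyz) {
  e <- 0
  b <- mol$bonds
  if (!is.null(b) && nrow(b)) {
    d <- xyz[b$i, , drop = FALSE] - xyz[b$j, , drop = FALSE]
    r <- sqrt(rowSums(d^2))
    e <- e + sum(b$k * (r - b$r0)^2)
  }
  a <- mol$angles
  if (!is.null(a) && nrow(a)) {
    for (q in seq_len(nrow(a))) {
      v1 <- xyz[a$i[q], ] - xyz[a$j[q], ]
      v2 <- xyz[a$k[q], ] - xyz[a$j[q], ]
      ct <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
      th <- acos(pmin(1, pmax(-1, ct)))
      e <- e + a$ktheta[q] * (th - a$theta0[q] * pi / 180)^2
    }
  }
  for (tr in mol$torsions) {
    e <- e + dihedral_energy(measure_dihedral(xyz, tr$atoms), tr$terms)
  }
  p <- mol$pairs14
  if (!is.null(p) && nrow(p)) {
    d <- xyz[p$i, , drop = FALSE] - xyz[p$j, , drop = FALSE]
    r <- sqrt(rowSums(d^2))
    sr <- (p$rmin / r)
    qq <- mol$atoms$charge[p$i] * mol$atoms$charge[p$j]
    e <- e + sum(p$eps * (sr^12 - 2 * sr^6) + .COULOMB_KCAL * qq / r)
  }
  e
}

#' Build a butane-like 4-site chain molecule
#'
#' Constructs a minimal torsion test system: four sites in a chain with
#' harmonic bonds and angles, one periodic torsion on the 1-2-3-4 quadruple,
#' and a 1-4 Lennard-Jones/Coulomb pair. Coordinates are generated from
#' internal coordinates (bond length, bend angle, initial dihedral).
#'
#' @param phi0 Initial dihedral in degrees.
#' @param torsion_terms List of [dihedral_term()] for the 1-2-3-4 torsion.
#' @param r0,theta0 Equilibrium bond length (Angstrom) and angle (degrees).
#' @param kb,ktheta Bond and angle force constants (kcal/mol/A^2,
#'   kcal/mol/rad^2).
#' @param eps14,rmin14 1-4 Lennard-Jones parameters (kcal/mol, Angstrom);
#'   `eps14 = 0` disables the pair.
#' @param charges Length-4 partial charges (e).
#' @return A [toy_molecule()].
#' @export
chain_molecule <- function(phi0 = 60,
                           torsion_terms = list(dihedral_term(1.4, 3),
                                                dihedral_term(0.3, 1)),
                           r0 = 1.54, theta0 = 111, kb = 300, ktheta = 60,
                           eps14 = 0.1, rmin14 = 4.0,
                           charges = c(0.05, -0.05, -0.05, 0.05)) {
  th <- theta0 * pi / 180
  p1 <- c(0, 0, 0); p2 <- c(r0, 0, 0)
  p3 <- p2 + r0 * c(-cos(th), sin(th), 0)
  b2u <- (p3 - p2) / r0
  n <- c(0, 0, 1)
  m <- c(b2u[2] * n[3] - b2u[3] * n[2],
         b2u[3] * n[1] - b2u[1] * n[3],
         b2u[1] * n[2] - b2u[2] * n[1])
  phir <- phi0 * pi / 180
  p4 <- p3 + r0 * (-cos(th) * b2u + sin(th) * (cos(phir) * (-m) +
                                                 sin(phir) * n))
  pairs <- if (eps14 > 0) {
    data.frame(i = 1, j = 4, eps = eps14, rmin = rmin14)
  } else NULL
  toy_molecule(
    atoms = data.frame(name = c("C1", "C2", "C3", "C4"), charge = charges),
    xyz = rbind(p1, p2, p3, p4),
    bonds = data.frame(i = 1:3, j = 2:4, r0 = r0, k = kb),
    angles = data.frame(i = 1:2, j = 2:3, k = 3:4, theta0 = theta0,
                        ktheta = ktheta),
    torsions = list(list(atoms = 1:4, terms = torsion_terms)),
    pairs14 = pairs
  )
}

#' Relaxed torsion scan of a toy molecule
#'
#' For each grid angle the scanned dihedral is driven to the target and held
#' by a stiff harmonic restraint while all remaining degrees of freedom are
#' minimized (BFGS followed by damped Newton polishing on a numerical
#' Hessian); the mechanical energy is then recorded without the restraint
#' term, and the profile is re-zeroed to its minimum. Geometry continues
#' from the previous grid point.
#'
#' @param mol A [toy_molecule()].
#' @param dihedral Atom quadruple of the scanned torsion.
#' @param grid Angles in degrees (non-empty).
#' @param restraint_k Restraint stiffness, kcal/mol/rad^2.
#' @param tol Convergence threshold on the max absolute gradient of the
#'   restrained energy, kcal/mol/Angstrom.
#' @param normalize Re-zero the profile to its minimum (default TRUE).
#' @return A [torsion_pes()] over `grid`.
#' @export
relaxed_scan <- function(mol, dihedral, grid, restraint_k = 1000,
                         tol = 1e-6, normalize = TRUE) {
  stopifnot(length(grid) >= 1, length(dihedral) == 4,
            all(dihedral <= nrow(mol$xyz)))
  ord <- order(grid)
  energies <- numeric(length(grid))
  xyz <- mol$xyz
  for (gi in ord) {
    a <- grid[gi]
    a_rad <- a * pi / 180
    xyz <- set_dihedral(mol, dihedral, a, xyz)
    f <- function(x) {
      m <- matrix(x, ncol = 3)
      phi <- measure_dihedral(m, dihedral) * pi / 180
      toy_energy(mol, m) + restraint_k * wrap_rad(phi - a_rad)^2
    }
    opt <- stats::optim(as.numeric(xyz), f, method = "BFGS",
                        control = list(maxit = 1000, reltol = 1e-15))
    x <- opt$par
    # damped Newton polish on the numerical Hessian (pseudo-inverse over
    # the non-degenerate modes; rigid-body modes are flat and dropped)
    for (it in seq_len(12)) {
      g <- num_grad(f, x)
      if (max(abs(g)) < tol) break
      H <- num_hess(f, x)
      ed <- eigen(H, symmetric = TRUE)
      keep <- ed$values > 1e-4 * max(abs(ed$values))
      step <- -ed$vectors[, keep, drop = FALSE] %*%
        ((t(ed$vectors[, keep, drop = FALSE]) %*% g) / ed$values[keep])
      lam <- 1
      f0 <- f(x)
      while (lam > 1e-6 && f(x + lam * step) > f0) lam <- lam / 2
      x <- x + lam * as.numeric(step)
    }
    g <- num_grad(f, x)
    if (max(abs(g)) > tol) {
      stop(sprintf(
        "relaxed scan: minimization did not converge at angle %g deg (max |gradient| %.3e kcal/mol/A)",
        a, max(abs(g))))
    }
    xyz <- matrix(x, ncol = 3)
    # the restraint leaves a residual offset of order slope/restraint_k in
    # the scanned angle; snap it back exactly before recording the energy
    xyz <- set_dihedral(mol, dihedral, a, xyz)
    energies[gi] <- toy_energy(mol, xyz)
  }
  if (any(duplicated(grid))) stop("scan grid contains duplicate angles")
  torsion_pes(grid[ord], energies[ord],
              label = paste(dihedral, collapse = "-"),
              normalize = normalize)
}
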