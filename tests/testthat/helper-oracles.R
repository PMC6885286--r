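# Independent oracles and fixture builders used across the test files.
# Oracles are deliberately written against first principles (brute force,
# closed forms, direct counting), not by calling the code paths they check.

# ---- toy molecule used for scan-oracle equivalence ------------------------
# Stiff bonds so the fixed-bond brute-force oracle is valid to < 1e-4
# kcal/mol, soft angles and a gentle 1-4 LJ so relaxation still moves the
# profile by ~1 kcal/mol.
scan_test_molecule <- function(phi0 = 60) {
  chain_molecule(phi0, kb = 60000, ktheta = 30, eps14 = 0.1, rmin14 = 3.5,
                 charges = rep(0, 4))
}

# Brute-force relaxed-scan oracle: dense 2D grid over the two bend angles at
# fixed equilibrium bond lengths; 1-4 distance evaluated from the internal
# geometry in closed form.
brute_force_scan <- function(mol, grid, half_width = 10, step = 0.05) {
  r0 <- mol$bonds$r0[1]; kth <- mol$angles$ktheta[1]
  th0 <- mol$angles$theta0[1]
  terms <- mol$torsions[[1]]$terms
  eps <- mol$pairs14$eps; rmin <- mol$pairs14$rmin
  qq <- mol$atoms$charge[1] * mol$atoms$charge[4]
  th_grid <- (th0 + seq(-half_width, half_width, by = step)) * pi / 180
  th0r <- th0 * pi / 180
  e_out <- numeric(length(grid))
  for (gi in seq_along(grid)) {
    phir <- grid[gi] * pi / 180
    best <- Inf
    for (t1 in th_grid) {
      p3 <- c(r0 - r0 * cos(t1), r0 * sin(t1), 0)
      b2u <- (p3 - c(r0, 0, 0)) / r0
      m <- c(b2u[2], -b2u[1], 0)
      dirv <- outer(-cos(th_grid), b2u) +
        outer(sin(th_grid) * cos(phir), -m) +
        outer(sin(th_grid) * sin(phir), c(0, 0, 1))
      p4 <- matrix(p3, length(th_grid), 3, byrow = TRUE) + r0 * dirv
      r14 <- sqrt(rowSums(p4^2))
      sr <- rmin / r14
      e <- kth * ((t1 - th0r)^2 + (th_grid - th0r)^2) +
        eps * (sr^12 - 2 * sr^6) + 332.0636 * qq / r14
      best <- min(best, min(e))
    }
    e_out[gi] <- best + dihedral_energy(grid[gi], terms)
  }
  e_out - min(e_out)
}

# Brute-force largest-remainder oracle: enumerate every integer vector
# summing to n and pick the one minimising max_i |count_i - quota_i|
# lexicographically (the largest-remainder optimum for the L-inf criterion),
# tie-broken toward the Hamilton solution ordering. Only usable for tiny
# problems; here 4 species.
brute_force_apportion <- function(ratio, n) {
  quota <- n * ratio / sum(ratio)
  k <- length(ratio)
  best <- NULL; best_dev <- Inf
  lo <- pmax(0, floor(quota) - 1); hi <- floor(quota) + 1
  grid <- expand.grid(lapply(seq_len(k), function(i) lo[i]:hi[i]))
  grid <- grid[rowSums(grid) == n, , drop = FALSE]
  for (r in seq_len(nrow(grid))) {
    cand <- as.numeric(grid[r, ])
    dev <- sum(abs(cand - quota))
    if (dev < best_dev - 1e-12) { best_dev <- dev; best <- cand }
  }
  as.integer(best)
}

# Brute-force Daura clustering oracle: distance matrix via bio3d's
# independent fitted RMSD, neighbour counts recomputed from scratch at every
# extraction.
brute_force_daura <- function(coords, cutoff_nm) {
  F <- dim(coords)[3]
  v <- function(f) as.numeric(t(coords[, , f]))
  D <- matrix(0, F, F)
  for (i in seq_len(F)) for (j in seq_len(F)) {
    if (i < j) {
      D[i, j] <- D[j, i] <-
        suppressWarnings(bio3d::rmsd(v(i), matrix(v(j), nrow = 1),
                                     fit = TRUE)) / 10
    }
  }
  remaining <- seq_len(F)
  clusters <- list(); centroids <- integer()
  while (length(remaining)) {
    counts <- vapply(remaining, function(i)
      sum(D[i, remaining] <= cutoff_nm), 0L)
    c0 <- remaining[which.max(counts)]
    members <- remaining[D[c0, remaining] <= cutoff_nm]
    clusters[[length(clusters) + 1]] <- sort(members)
    centroids <- c(centroids, c0)
    remaining <- setdiff(remaining, members)
  }
  list(clusters = clusters, centroids = centroids)
}

# ---- hand-built planar trajectory fixtures --------------------------------
# Topology: one dye (6 markers) plus n_b lipids of `species` carrying a "P"
# marker and (optionally) a "C2" marker at the same lateral position.
make_test_topology <- function(n_b, species = "TLCL", with_c2 = TRUE) {
  dye <- data.frame(
    name = c("PTPP", "LK1", "LK2", "DC1", "DC2", "PDT"),
    group = c("TPP", "linker", "linker", "dye_diene", "dye_diene", "PDT"),
    species = "DYE", resname = "DYE", resid = n_b + 1, leaflet = "upper",
    mass = 1, stringsAsFactors = FALSE)
  per <- if (with_c2) c("P", "C2") else "P"
  grp <- if (with_c2) c("headgroup", "CL_glycerol") else "headgroup"
  lip <- do.call(rbind, lapply(seq_len(n_b), function(i)
    data.frame(name = per, group = grp, species = species,
               resname = substr(species, 1, 4), resid = i,
               leaflet = "upper", mass = 1, stringsAsFactors = FALSE)))
  rbind(lip, dye)
}

# Build a synthetic_traj from per-frame lipid lateral positions (list of
# n_b x 2 matrices), a fixed dye centre, and per-frame dye orientation.
make_planar_traj <- function(b_xy, box, dye_center = box[1:2] / 2,
                             dye_theta = rep(0, length(b_xy)),
                             species = "TLCL", with_c2 = TRUE,
                             z_lipid = 15, z_dye = c(18, 14, 14, 8, 8, 8)) {
  n_b <- nrow(b_xy[[1]])
  top <- make_test_topology(n_b, species, with_c2)
  offs <- c(0, 3, 5, 7, 9, 8)
  F <- length(b_xy)
  per <- if (with_c2) 2 else 1
  coords <- array(0, dim = c(nrow(top), 3, F))
  for (f in seq_len(F)) {
    u <- c(cos(dye_theta[f]), sin(dye_theta[f]))
    lx <- b_xy[[f]][rep(seq_len(n_b), each = per), , drop = FALSE]
    coords[seq_len(n_b * per), 1:2, f] <- lx
    coords[seq_len(n_b * per), 3, f] <- z_lipid
    di <- n_b * per + seq_len(6)
    coords[di, 1, f] <- dye_center[1] + offs * u[1]
    coords[di, 2, f] <- dye_center[2] + offs * u[2]
    coords[di, 3, f] <- z_dye
  }
  synthetic_traj(top, coords, box)
}

# Small default bilayer shared by several analysis tests (built once).
shared_bilayer <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- build_bilayer(n_per_leaflet = 43, seed = 101)
    cache
  }
})
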