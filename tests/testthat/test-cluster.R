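# Fixtures: trajectories over the 6 dye markers with controlled conformations.
dye_conformer_traj <- function(ref_list, assignment, noise = 0, seed = 1) {
  set.seed(seed)
  F <- length(assignment)
  top <- make_test_topology(1)[3:8, ]   # the six dye rows
  top$resid <- 1
  coords <- array(0, dim = c(6, 3, F))
  for (f in seq_len(F)) {
    coords[, , f] <- ref_list[[assignment[f]]] +
      matrix(rnorm(18, 0, noise), 6, 3)
  }
  synthetic_traj(top, coords, box = c(50, 50, 50))
}

ref_a <- matrix(c(0, 0, 0,  3, 0, 0,  5, 0, 0,  7, 1, 0,  9, 2, 1,  8, 3, 2),
                6, 3, byrow = TRUE)
ref_b <- matrix(c(0, 0, 0,  0, 3, 0,  0, 5, 2,  2, 6, 4,  4, 6, 6,  6, 5, 7),
                6, 3, byrow = TRUE) * 3   # ~0.92 nm from ref_a after fitting

test_that("identical frames collapse to one cluster with frame 1 centroid", {
  trj <- dye_conformer_traj(list(ref_a), rep(1, 8), noise = 0)
  cl <- cluster_conformers(trj, cutoff = 0.3)
  expect_equal(length(cl$clusters), 1)
  expect_equal(cl$centroids, 1L)
  expect_equal(sort(cl$clusters[[1]]), 1:8)
})

test_that("two well-separated conformer groups give exactly two clusters", {
  # inter-group RMSD about 3x the cutoff, intra-group about 0.1x
  assign <- rep(c(1, 2), c(12, 8))
  trj <- dye_conformer_traj(list(ref_a, ref_b), assign, noise = 0.1,
                            seed = 7)
  rms_ab <- kabsch_rmsd(ref_a, ref_b) / 10
  expect_gt(rms_ab, 0.6)   # nm, comfortably above the 0.3 nm cutoff
  cl <- cluster_conformers(trj, cutoff = 0.3)
  expect_equal(length(cl$clusters), 2)
  expect_equal(sort(cl$clusters[[1]]), 1:12)   # larger group first
  expect_equal(sort(cl$clusters[[2]]), 13:20)
  # membership equals the brute-force neighbour-count oracle
  oracle <- brute_force_daura(trj$coords, 0.3)
  expect_equal(lapply(cl$clusters, sort), oracle$clusters)
  expect_equal(cl$centroids, oracle$centroids)
})

test_that("Daura output equals the brute-force oracle on mixed fixtures", {
  refs <- list(ref_a, ref_b, (ref_a + ref_b) / 2)
  set.seed(23)
  assign <- sample(1:3, 50, replace = TRUE)
  trj <- dye_conformer_traj(refs, assign, noise = 0.35, seed = 23)
  cl <- cluster_conformers(trj, cutoff = 0.3)
  oracle <- brute_force_daura(trj$coords, 0.3)
  expect_equal(lapply(cl$clusters, sort), oracle$clusters)
  expect_equal(cl$centroids, oracle$centroids)
  # partition covers every frame exactly once
  expect_equal(sort(unlist(cl$clusters)), 1:50)
  expect_equal(sum(cl$sizes), 50)
  # centroids are members of their clusters
  for (k in seq_along(cl$clusters)) {
    expect_true(cl$centroids[k] %in% cl$clusters[[k]])
  }
  # extraction-order neighbour counts are non-increasing
  expect_true(all(diff(cl$extraction_counts) <= 0))
})

test_that("a cutoff above the RMSD range yields a single cluster", {
  assign <- rep(c(1, 2), 5)
  trj <- dye_conformer_traj(list(ref_a, ref_b), assign, noise = 0.2,
                            seed = 11)
  cl <- cluster_conformers(trj, cutoff = max(trj$coords) )  # huge cutoff
  expect_equal(length(cl$clusters), 1)
  expect_equal(sum(cl$sizes), 10)
})

test_that("kabsch_rmsd agrees with bio3d's fitted RMSD", {
  set.seed(5)
  for (rep in 1:6) {
    a <- matrix(rnorm(18), 6, 3)
    b <- matrix(rnorm(18), 6, 3)
    mine <- kabsch_rmsd(a, b)
    ref <- suppressWarnings(
      bio3d::rmsd(as.numeric(t(a)), matrix(as.numeric(t(b)), nrow = 1),
                  fit = TRUE))
    expect_equal(mine, ref, tolerance = 1e-3)  # bio3d rounds to 3 decimals
  }
  # exactly zero for a rotated-plus-translated copy
  a <- matrix(rnorm(18), 6, 3)
  th <- 0.8
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  expect_lt(kabsch_rmsd(a, a %*% R + 2), 1e-9)
})
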