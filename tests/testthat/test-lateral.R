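test_that("maps are invariant under a rigid in-plane rotation of the frame", {
  set.seed(41)
  box <- c(40, 40, 60)
  ctr <- box[1:2] / 2
  n_b <- 12
  # keep lipids inside the inscribed circle so rotation cannot move any
  # point across the square map boundary between the two frames
  rr <- sqrt(runif(n_b)) * 17
  aa <- runif(n_b, 0, 2 * pi)
  xy1 <- cbind(ctr[1] + rr * cos(aa), ctr[2] + rr * sin(aa))
  alpha <- 1.1
  R <- matrix(c(cos(alpha), sin(alpha), -sin(alpha), cos(alpha)), 2, 2)
  xy2 <- sweep(sweep(xy1, 2, ctr) %*% t(R), 2, ctr, `+`)
  xy2[, 1] <- xy2[, 1] %% box[1]; xy2[, 2] <- xy2[, 2] %% box[2]
  t1 <- make_planar_traj(list(xy1), box, dye_center = ctr, dye_theta = 0)
  t12 <- make_planar_traj(list(xy1, xy2), box, dye_center = ctr,
                          dye_theta = c(0, alpha))
  m1 <- lateral_map(t1, "TLCL", grid_step = 2)$TLCL
  m12 <- lateral_map(t12, "TLCL", grid_step = 2)$TLCL
  expect_equal(m12$values, m1$values, tolerance = 1e-12)
  expect_equal(m12$n_frames_used, 2)
})

test_that("a cardiolipin ring maps to an occupancy annulus (binning oracle)", {
  box <- c(40, 40, 60)
  ctr <- box[1:2] / 2
  radius <- 10
  ang <- seq(0, 2 * pi, length.out = 25)[-25]
  frames <- lapply(c(0, pi / 7, pi / 3), function(rot)
    cbind(ctr[1] + radius * cos(ang + rot), ctr[2] + radius * sin(ang + rot)))
  trj <- make_planar_traj(frames, box, dye_center = ctr,
                          dye_theta = rep(pi / 2, 3))
  m <- lateral_map(trj, "TLCL", grid_step = 2, ref = "TPP")$TLCL
  # occupied cells all lie in an annulus around the ring radius
  occ <- which(m$mask, arr.ind = TRUE)
  r_occ <- sqrt(m$x[occ[, 1]]^2 + m$y[occ[, 2]]^2)
  expect_true(all(abs(r_occ - radius) < 2 * sqrt(2)))
  expect_gt(nrow(occ), 0)
  # direct binning oracle: same transform computed independently
  edges <- seq(-min(box[1:2]) / 2, min(box[1:2]) / 2,
               length.out = length(m$x) + 1)
  oracle <- matrix(0, length(m$x), length(m$y))
  thetas <- rep(pi / 2, 3)
  for (f in 1:3) {
    # TPP sits at the dye centre; PDT->TPP projection points along -u(theta)
    v <- -c(cos(thetas[f]), sin(thetas[f]))
    beta <- pi / 2 - atan2(v[2], v[1])
    Rb <- matrix(c(cos(beta), sin(beta), -sin(beta), cos(beta)), 2, 2)
    rel <- sweep(frames[[f]], 2, ctr)
    rel <- rel - sweep(matrix(0, nrow(rel), 2), 1, 0)  # already min-image safe
    rot <- rel %*% t(Rb)
    bx <- findInterval(rot[, 1], edges, rightmost.closed = TRUE)
    by <- findInterval(rot[, 2], edges, rightmost.closed = TRUE)
    for (q in seq_along(bx)) oracle[bx[q], by[q]] <- oracle[bx[q], by[q]] + 1
  }
  counts <- m$values * m$n_frames_used * diff(edges)[1]^2
  expect_equal(counts, oracle, tolerance = 1e-9)
})

test_that("a uniform species exceeds half its bulk concentration everywhere", {
  box <- c(40, 40, 60)
  ctr <- box[1:2] / 2
  g <- expand.grid(x = seq(1, 39, by = 2), y = seq(1, 39, by = 2))
  trj <- make_planar_traj(list(as.matrix(g)), box, dye_center = ctr,
                          dye_theta = 0)
  m <- lateral_map(trj, "TLCL", grid_step = 2, ref = "TPP")$TLCL
  expect_true(all(m$mask))
})

test_that("the alignment transform is an isometry of lateral distances", {
  cfg <- shared_bilayer()
  trj <- sample_frames(cfg, n_frames = 3, epsilon = 1, seed = 6)
  al <- mitoprobe:::.frame_alignment(trj, 2)
  expect_false(is.null(al))
  expect_equal(t(al$R) %*% al$R, diag(2), tolerance = 1e-12)
  set.seed(8)
  p <- matrix(runif(20, 0, 40), 10, 2)
  q <- p %*% t(al$R)
  expect_equal(as.numeric(dist(q)), as.numeric(dist(p)), tolerance = 1e-9)
})

test_that("uniform placement gives g(r) of 1 beyond the exclusion radius", {
  cfg <- shared_bilayer()
  trj <- sample_frames(cfg, n_frames = 200, epsilon = 0, seed = 17)
  rdf <- radial_distribution(trj, "TLCL", bin = 1)
  sel <- rdf$r > 6 & rdf$r < 20
  expect_lt(mean(abs(rdf$g[sel] - 1)), 3 * mean(rdf$se[sel]))
})

test_that("lattice partners produce peaks matching brute-force pair counts", {
  box <- c(40, 40, 60)
  ctr <- box[1:2] / 2
  lat <- expand.grid(x = ctr[1] + (-2:2) * 8, y = ctr[2] + (-2:2) * 8)
  lat <- as.matrix(lat[!(lat$x == ctr[1] & lat$y == ctr[2]), ])
  trj <- make_planar_traj(list(lat), box, dye_center = ctr, dye_theta = 0.3)
  rdf <- radial_distribution(trj, "TLCL", bin = 0.5)
  # brute-force oracle: histogram of minimum-image distances to the centre
  dx <- lat[, 1] - ctr[1]; dy <- lat[, 2] - ctr[2]
  dx <- dx - box[1] * round(dx / box[1]); dy <- dy - box[2] * round(dy / box[2])
  d <- sqrt(dx^2 + dy^2)
  edges <- c(rdf$r - 0.25, max(rdf$r) + 0.25)
  oracle <- hist(d[d < 20], breaks = seq(0, 20, by = 0.5),
                 plot = FALSE)$counts
  expect_equal(rdf$counts[seq_along(oracle)], oracle)
  # peaks at the lattice spacings 8 and 8*sqrt(2)
  peaks <- rdf$r[rdf$g > 0]
  expect_true(any(abs(peaks - 8) <= 0.25 + 1e-9))
  expect_true(any(abs(peaks - 8 * sqrt(2)) <= 0.25 + 1e-9))
})

test_that("the attraction well shows up as a first-shell RDF peak", {
  cfg <- shared_bilayer()
  trj <- sample_frames(cfg, n_frames = 150, epsilon = 2, r0 = 7, seed = 19)
  rdf <- radial_distribution(trj, "TLCL", bin = 0.5)
  expect_lte(rdf$r[which.max(rdf$g)], 7.5)
  expect_gt(rdf_first_shell_max(rdf, 7), 1.5)
})
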