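test_that("depth profile equals a direct-count histogram oracle", {
  set.seed(12)
  n <- 1000
  box <- c(50, 50, 80)
  top <- data.frame(name = "P", group = "headgroup", species = "POPC",
                    resname = "POPC", resid = seq_len(n),
                    leaflet = rep(c("upper", "lower"), each = n / 2),
                    mass = 94.97, stringsAsFactors = FALSE)
  z <- c(rnorm(n / 2, 15, 3), rnorm(n / 2, -15, 3))
  coords <- array(0, dim = c(n, 3, 2))
  for (f in 1:2) {
    coords[, 1, f] <- runif(n, 0, box[1])
    coords[, 2, f] <- runif(n, 0, box[2])
    coords[, 3, f] <- z + rnorm(n, 0, 0.5)
  }
  trj <- synthetic_traj(top, coords, box)
  prof <- depth_density_profile(trj, group = "headgroup", bin = 1,
                                units_mode = "number")
  # oracle: direct counting with the same midplane convention
  oracle <- numeric(length(prof$z))
  for (f in 1:2) {
    zc <- coords[, 3, f] - mean(coords[, 3, f])
    bi <- findInterval(zc, prof$edges, rightmost.closed = TRUE)
    for (b in bi[bi >= 1 & bi <= length(oracle)]) {
      oracle[b] <- oracle[b] + 1
    }
  }
  oracle <- oracle / (2 * box[1] * box[2] * 1)
  expect_equal(prof$raw, oracle, tolerance = 1e-12)
  # mass conservation: integral x area recovers the group mass per frame
  pm <- depth_density_profile(trj, group = "headgroup", bin = 1,
                              units_mode = "mass")
  expect_equal(sum(pm$raw) * 1 * box[1] * box[2], n * 94.97,
               tolerance = 1e-9)
})

test_that("empty selections warn and return a zero profile", {
  cfg <- shared_bilayer()
  trj <- sample_frames(cfg, n_frames = 3, epsilon = 0, seed = 2)
  expect_warning(p <- depth_density_profile(trj, group = "no_such_group"),
                 "empty selection")
  expect_true(all(p$values == 0))
  expect_error(depth_density_profile(trj, group = "TPP", frames = integer(0)),
               "zero frames")
})

test_that("TPP sits in the headgroup band, the dye diene among acyl chains", {
  cfg <- shared_bilayer()
  trj <- sample_frames(cfg, n_frames = 80, epsilon = 0, seed = 3)
  p_tpp <- depth_density_profile(trj, group = "TPP", units_mode = "molar_x10")
  p_diene <- depth_density_profile(trj, group = "dye_diene",
                                   units_mode = "molar_x10")
  expect_gt(profile_peak_depth(p_tpp), profile_peak_depth(p_diene))
})

test_that("profile overlap obeys identity, disjointness, symmetry, bounds", {
  z <- seq(-30.5, 30.5, by = 1)
  mkprof <- function(vals) structure(list(z = z, values = vals),
                                     class = "density_profile")
  g1 <- mkprof(dnorm(z, 10, 3))
  expect_equal(profile_overlap(g1, g1), 1, tolerance = 1e-12)
  d1 <- mkprof(ifelse(z < 0, 1, 0)); d2 <- mkprof(ifelse(z >= 0, 1, 0))
  expect_equal(profile_overlap(d1, d2), 0)
  g2 <- mkprof(dnorm(z, 16, 3))
  expect_equal(profile_overlap(g1, g2), profile_overlap(g2, g1))
  ov <- profile_overlap(g1, g2)
  expect_gte(ov, 0); expect_lte(ov, 1)
  expect_error(profile_overlap(g1, structure(list(z = z + 0.5,
                                                  values = g1$values),
                                             class = "density_profile")),
               "different grids")
})

test_that("binned Gaussian overlap matches the closed form 2*Phi(-d/(2s))", {
  z <- seq(-40.25, 40.25, by = 0.5)
  mkprof <- function(mu) structure(list(z = z, values = dnorm(z, mu, 3)),
                                   class = "density_profile")
  for (delta in c(1, 3, 6, 10)) {
    got <- profile_overlap(mkprof(0), mkprof(delta))
    expect_lt(abs(got - 2 * pnorm(-delta / (2 * 3))), 2e-3)
  }
})

test_that("C9 hydroperoxide band overlaps the probe diene more than C13", {
  ov <- numeric(2); names(ov) <- c("9", "13")
  for (pos in c(9L, 13L)) {
    cfg <- build_bilayer(n_per_leaflet = 43, seed = 31, oxidized = pos)
    trj <- sample_frames(cfg, n_frames = 60, epsilon = 2, seed = 32)
    pd <- depth_density_profile(trj, group = "dye_diene")
    po <- depth_density_profile(trj, group = "CL_peroxide")
    ov[as.character(pos)] <- profile_overlap(pd, po)
  }
  expect_gt(ov["9"], ov["13"])
})
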