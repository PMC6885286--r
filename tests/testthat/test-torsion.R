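test_that("periodic dihedral energy matches its defining sum", {
  expect_equal(dihedral_energy(c(-123, 0, 77), list()), c(0, 0, 0))
  t1 <- list(dihedral_term(1, 1))
  expect_equal(dihedral_energy(0, t1), 2)
  expect_equal(dihedral_energy(180, t1), 0)
  # random term set vs independent term-by-term summation on a 1-degree grid
  set.seed(14)
  grid <- seq(-180, 179, by = 1)
  for (rep in 1:5) {
    ns <- sample(c(1, 2, 3, 4, 6), 3)
    ks <- round(runif(3, -2, 2), 3)
    ds <- sample(c(0, 180), 3, replace = TRUE)
    terms <- Map(dihedral_term, ks, ns, ds)
    manual <- Reduce(`+`, lapply(seq_len(3), function(i)
      ks[i] * (1 + cos((ns[i] * grid - ds[i]) * pi / 180))))
    expect_lt(max(abs(dihedral_energy(grid, terms) - manual)), 1e-12)
    # periodicity to 1e-12
    expect_lt(max(abs(dihedral_energy(grid + 360, terms) -
                        dihedral_energy(grid, terms))), 1e-12)
  }
  expect_error(dihedral_term(1, 5), "multiplicity")
})

test_that("least-squares fit recovers generating terms and is idempotent", {
  truth <- list(dihedral_term(1.2, 1), dihedral_term(0.8, 2, 180),
                dihedral_term(0.5, 3))
  grid <- seq(-180, 170, by = 10)
  ref <- torsion_pes(grid, dihedral_energy(grid, truth) + 2.7,
                     normalize = FALSE)
  fit <- fit_dihedral_terms(ref)
  k <- vapply(fit$terms, `[[`, 0, "k")
  # 180-degree phase is a signed amplitude at phase 0
  expect_lt(max(abs(k - c(1.2, -0.8, 0.5))), 1e-6)
  expect_lt(fit$rmse, 1e-9)
  # idempotence: fitting the fitted PES returns the same terms
  fit2 <- fit_dihedral_terms(fit$fitted)
  expect_lt(max(abs(vapply(fit2$terms, `[[`, 0, "k") - k)), 1e-9)
  # flat reference gives all-zero amplitudes
  flat <- fit_dihedral_terms(torsion_pes(grid, rep(0, length(grid))))
  expect_lt(max(abs(vapply(flat$terms, `[[`, 0, "k"))), 1e-9)
  # underdetermined grid is refused with the required point count
  expect_error(fit_dihedral_terms(torsion_pes(c(0, 60, 120), c(0, 1, 2))),
               "at least 7")
})

test_that("fit under Gaussian noise keeps RMSE near the noise level", {
  truth <- list(dihedral_term(1.2, 1), dihedral_term(-0.8, 2),
                dihedral_term(0.5, 3))
  grid <- seq(-180, 170, by = 10)
  clean <- dihedral_energy(grid, truth)
  set.seed(99)
  rmses <- replicate(100, {
    noisy <- clean + rnorm(length(grid), 0, 0.05)
    fit_dihedral_terms(torsion_pes(grid, noisy, normalize = FALSE))$rmse
  })
  # expected residual sd is sigma * sqrt(1 - p/n); stay within 10%
  expect_lt(mean(rmses), 0.05 * 1.1)
  expect_gt(mean(rmses), 0.05 * 0.7)
})

test_that("background subtraction isolates the torsional part", {
  truth <- list(dihedral_term(0.9, 2))
  grid <- seq(-180, 170, by = 15)
  bg <- torsion_pes(grid, 0.3 * (1 + cos(grid * pi / 180)),
                    normalize = FALSE)
  ref <- torsion_pes(grid, dihedral_energy(grid, truth) + bg$energies,
                     normalize = FALSE)
  fit <- fit_dihedral_terms(ref, multiplicities = 2, base = bg)
  expect_lt(abs(fit$terms[[1]]$k - 0.9), 1e-9)
})

test_that("flexibility range matches closed form, limits and a dense oracle", {
  grid <- seq(-180, 179, by = 1)
  # cosine well with amplitude = threshold: E <= a exactly where cos >= 0
  a <- 0.7
  pes <- torsion_pes(grid, a * (1 - cos((grid - 20) * pi / 180)))
  expect_equal(flexibility_range(pes, threshold = a), 180, tolerance = 1e-3)
  # threshold -> 0+ collapses the range on a strict single-minimum PES
  expect_lt(flexibility_range(pes, threshold = 1e-9), 0.01)
  # default threshold is 2 kT at 310 K
  expect_equal(kT(310), 0.0019872041 * 310)
  # brute-force dense-grid oracle on an arbitrary tabulated PES
  set.seed(4)
  for (rep in 1:4) {
    terms <- list(dihedral_term(runif(1, 0.5, 2), 1),
                  dihedral_term(runif(1, -1, 1), 2),
                  dihedral_term(runif(1, -0.8, 0.8), 3))
    g <- seq(-180, 177.5, by = 2.5)
    pes <- torsion_pes(g, dihedral_energy(g, terms))
    thr <- 2 * kT(310)
    got <- flexibility_range(pes, threshold = thr)
    # oracle: 0.01-degree linear interpolation, contiguous region about min
    dense_x <- seq(-540, 540, by = 0.01)
    dense_e <- approx(c(g - 360, g, g + 360), rep(pes$energies, 3),
                      xout = dense_x)$y
    imin <- which.min(abs(dense_x - g[which.min(pes$energies)]))
    lo <- imin; while (lo > 1 && dense_e[lo - 1] <= thr) lo <- lo - 1
    hi <- imin; while (hi < length(dense_x) && dense_e[hi + 1] <= thr) hi <- hi + 1
    oracle <- min(dense_x[hi] - dense_x[lo], 360)
    expect_lt(abs(got - oracle), 0.1)
  }
  # monotone non-decreasing in the threshold
  g <- seq(-180, 170, by = 10)
  pes <- torsion_pes(g, dihedral_energy(g, list(dihedral_term(1.5, 3))))
  thr <- seq(0.1, 3.5, by = 0.2)
  widths <- vapply(thr, function(t) flexibility_range(pes, threshold = t), 0)
  expect_true(all(diff(widths) >= -1e-9))
  expect_error(flexibility_range(pes, threshold = 0), "positive")
})

test_that("PES CSV round-trips through read_pes/write_pes", {
  g <- seq(-180, 170, by = 10)
  pes <- torsion_pes(g, dihedral_energy(g, list(dihedral_term(1.1, 2))))
  f <- tempfile(fileext = ".csv")
  write_pes(pes, f)
  rt <- read_pes(f)
  expect_equal(rt$angles, pes$angles)
  expect_equal(rt$energies, pes$energies, tolerance = 1e-12)
})
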