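test_that("Beer-Lambert inversion reproduces the defining arithmetic", {
  tr <- absorbance_trace(c(0, 5), c(0, 0.0274))
  expect_equal(diene_concentration(tr), c(0, 1))   # uM
  # 1 M at 1 cm absorbs epsilon units
  p <- beer_lambert_params()
  expect_equal(absorbance_from_concentration(1e6, p), 27400)
  # null trace
  tr0 <- absorbance_trace(seq(0, 50, 5), rep(0.12, 11))
  expect_true(all(diene_concentration(tr0) == 0))
  # linearity: doubling dA doubles c exactly
  tr2 <- absorbance_trace(c(0, 5), c(0, 0.0548))
  expect_equal(diene_concentration(tr2)[2], 2 * diene_concentration(tr)[2])
  expect_error(beer_lambert_params(epsilon = -1), "positive")
  expect_error(beer_lambert_params(path = 0), "positive")
  expect_error(absorbance_trace(c(0, 5, 5), c(0, 0, 0)), "increasing")
})

test_that("concentration -> absorbance -> concentration is the identity", {
  t <- seq(0, 50, by = 5)
  conc <- 0.4 * t
  p <- beer_lambert_params()
  tr <- absorbance_trace(t, absorbance_from_concentration(conc, p, a0 = 0.03))
  back <- diene_concentration(tr, p)
  expect_lt(max(abs(back - conc)), 1e-12)
})

test_that("oxidized fraction divides element-wise, flags inconsistency", {
  expect_equal(oxidized_fraction(20, 100), 0.2)
  expect_equal(oxidized_fraction(0, 100), 0)
  expect_equal(oxidized_fraction(20, 100, per_chain = TRUE), 0.05)
  set.seed(6)
  d <- runif(11, 0, 30)
  expect_equal(oxidized_fraction(d, 87.3), d / 87.3)
  expect_warning(f <- oxidized_fraction(150, 100), "exceeds 1")
  expect_equal(f, 1.5)   # uncapped
  expect_error(oxidized_fraction(1, 0), "positive")
})

test_that("segment rates recover exact lines and inhibition ratios", {
  t <- seq(0, 50, by = 5)
  rs <- rate_segments(t, 0.4 * t, NULL)
  expect_equal(nrow(rs$segments), 1)
  expect_equal(rs$segments$slope, 0.4, tolerance = 1e-12)
  # full inhibition after an antioxidant-like addition
  tr <- simulate_oxidation_trace(duration_min = 60, rate_uM_per_min = 0.4,
                                 addition = list(time = 30, label = "TBHQ",
                                                 rate_after = 0))
  conc <- diene_concentration(tr)
  rs <- rate_segments(tr$time, conc, tr$annotations)
  expect_equal(rs$ratios$slope_before, 0.4, tolerance = 1e-9)
  expect_equal(rs$ratios$ratio, 0, tolerance = 1e-9)
  # sparse segment is skipped with a warning
  expect_warning(
    rs2 <- rate_segments(c(0, 5, 10), c(0, 2, 4),
                         data.frame(time = 12, label = "late")),
    "fewer than 2")
  expect_true(is.na(rs2$segments$slope[2]))
})

test_that("noisy slopes land within three standard errors of the truth", {
  slopes <- ses <- numeric(100)
  t <- seq(0, 50, by = 5)
  set.seed(77)
  for (i in 1:100) {
    tr <- simulate_oxidation_trace(noise_sd = 0.003)
    conc <- diene_concentration(tr)
    fit <- stats::lm(conc ~ t)
    slopes[i] <- coef(fit)[2]
    ses[i] <- summary(fit)$coefficients[2, 2]
  }
  expect_gt(mean(abs(slopes - 0.4) <= 3 * ses), 0.95)
  expect_lt(abs(mean(slopes) - 0.4), 3 * sd(slopes) / 10)
})

test_that("CSV input round-trips through read_absorbance_csv", {
  t <- seq(0, 30, by = 5)
  tr <- simulate_oxidation_trace(duration_min = 30)
  f <- tempfile(fileext = ".csv")
  utils::write.csv(data.frame(time_min = tr$time, a234 = tr$a234), f,
                   row.names = FALSE)
  fa <- tempfile(fileext = ".csv")
  utils::write.csv(data.frame(time_min = 15, label = "SkQ1"), fa,
                   row.names = FALSE)
  rt <- read_absorbance_csv(f, fa)
  expect_equal(rt$a234, tr$a234)
  expect_equal(rt$annotations$label, "SkQ1")
  expect_error(read_absorbance_csv(fa), "time_min")
})
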