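test_that("XIC extraction sums centroids inside the ppm window only", {
  times <- seq(9.5, 10.5, by = 1 / 30)
  mz0 <- 200
  ions <- data.frame(mz = c(mz0 * (1 + 4e-6), mz0 * (1 + 6e-6), 150),
                     apex_rt = 10, sigma = 0.05,
                     height = c(1e5, 2e5, 3e5))
  ch <- make_channel(times, ions)
  x <- extract_xic(ch, mz0, tol_ppm = 5, rt_window = c(9.5, 10.5))
  # only the +4 ppm centroid contributes; +6 ppm is outside the window
  expect_equal(max(x$intensities), 1e5, tolerance = 1e-9)
  expect_length(x$times, length(times))
  # a channel with nothing in tolerance anywhere gives all zeros
  x0 <- extract_xic(ch, 300, tol_ppm = 5, rt_window = c(9.5, 10.5))
  expect_true(all(x0$intensities == 0))
  expect_error(extract_xic(ch, mz0, 5, c(20, 21)), "empty window")
})

test_that("XIC of a simulated Gaussian recovers apex and area", {
  sim <- sim_single("C9H7O4", seed = 7)
  x <- extract_xic(sim$run$ms1, monoisotopic_mz(chem_formula("C9H7O4", charge = -1)),
                   5, c(1.5, 2.5))
  apex <- x$times[which.max(x$intensities)]
  # apex within one MS1 scan interval (2 s) of the planted 2.0 min
  expect_lt(abs(apex - 2.0), 2 / 60 + 1e-9)
  # trapezoidal area vs the closed-form generating Gaussian, within 5%
  trapz <- sum(diff(x$times) *
                 (x$intensities[-1] + x$intensities[-length(x$intensities)]) / 2)
  exact <- 1e6 * 0.05 * sqrt(2 * pi)
  expect_lt(abs(trapz - exact) / exact, 0.05)
})

test_that("normalization scales the apex to one and is idempotent", {
  x <- xic_from_curve(1:10, gauss_curve(1:10, 5, 2, 2e6))
  n1 <- normalize_xic(x)
  expect_equal(max(n1$intensities), 1)
  expect_equal(normalize_xic(n1)$intensities, n1$intensities)
  expect_equal(n1$intensities * 2e6, x$intensities)
  z <- xic_from_curve(1:10, rep(0, 10))
  expect_error(normalize_xic(z), "cannot normalize zero trace")
})

test_that("area between identical traces is zero and the metric is symmetric", {
  t <- seq(0, 2, by = 0.01)
  a <- xic_from_curve(t, gauss_curve(t, 1, 0.2))
  b <- xic_from_curve(t, gauss_curve(t, 1.3, 0.25, 5e5))
  expect_identical(area_between(a, a, c(0, 2))$area, 0)
  expect_lt(abs(area_between(a, b, c(0, 2))$area -
                  area_between(b, a, c(0, 2))$area), 1e-12)
  # normalization first: uniform scaling of either input changes nothing
  b2 <- xic_from_curve(t, gauss_curve(t, 1.3, 0.25, 5e5) * 37.5)
  expect_equal(area_between(a, b2, c(0, 2))$area,
               area_between(a, b, c(0, 2))$area)
  expect_error(area_between(a, b, c(1, 1)), "degenerate window")
})

test_that("opposed unit steps give area exactly one", {
  d <- 1e-9
  a <- xic_from_curve(c(0, 1, 1 + d, 2), c(1, 1, 0, 0))
  b <- xic_from_curve(c(0, 1, 1 + d, 2), c(0, 0, 1, 1))
  expect_equal(area_between(a, b, c(0, 2))$area, 1, tolerance = 1e-9)
})

test_that("area grows with apex separation and 3-sigma decoys are rejected", {
  t <- seq(1.0, 3.0, by = 0.01)
  sigma <- 0.05
  ref <- xic_from_curve(t, gauss_curve(t, 1.8, sigma))
  areas <- vapply(seq(0, 4, by = 0.5), function(k) {
    shifted <- xic_from_curve(t, gauss_curve(t, 1.8 + k * sigma, sigma))
    area_between(ref, shifted, c(1.5, 2.5))$area
  }, numeric(1))
  expect_true(all(diff(areas) > 0))
  cmp <- area_between(ref, xic_from_curve(t, gauss_curve(t, 1.8 + 3 * sigma,
                                                         sigma)),
                      c(1.5, 2.5))
  expect_gt(cmp$area, 0.15)
  expect_false(cmp$passed)
})

test_that("fragment candidates come from the apex AIF scans, filtered and de-isotoped", {
  sim <- sim_aspirin(seed = 3)
  cfg <- run_config()
  cand <- candidate_fragment_mzs(sim$run, 179.0350, 2.0, cfg)
  # the true fragment masses and the decoy are all offered as candidates;
  # the shape filter decides later
  expect_true(any(abs(cand - 93.0346) < 0.002))
  expect_true(any(abs(cand - 77.0146) < 0.002))
  expect_true(any(abs(cand - 137.0244) < 0.002))
  # nothing above the precursor mass, and not the precursor itself
  expect_true(all(cand <= 179.0350 * (1 + cfg$xic_tol_ppm * 1e-6)))
  expect_false(any(abs(cand - 179.0350) < 0.001))
  # isotopologue satellites of the fragments are removed
  expect_false(any(abs(cand - 94.0380) < 0.005))
  # low-intensity centroids are excluded
  cfg_hi <- run_config(min_fragment_intensity = 1e9)
  expect_length(candidate_fragment_mzs(sim$run, 179.0350, 2.0, cfg_hi), 0)
  expect_error(candidate_fragment_mzs(sim$run, 179.0350, 10, cfg),
               "empty window")
})
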