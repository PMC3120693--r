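test_that("fano is variance over mean with the n-1 denominator", {
  x <- c(1, 2, 3, 4)
  expect_equal(fano(x), var(x) / mean(x))
  expect_equal(fano(rep(5, 10)), 0)
  expect_error(fano(3), "at least two")
  expect_error(fano(c(0, 0)), "mean <= 0")
  set.seed(9)
  expect_equal(fano(rpois(1e5, 10)), 1, tolerance = 0.05)
  # Fano scales linearly under multiplication (the calibration identity)
  set.seed(10)
  y <- rpois(1000, 7)
  expect_equal(fano(53 * y), 53 * fano(y))
})

test_that("summary-form Fano factors reproduce the measured table", {
  m <- measured_gfp_summary()
  expect_identical(nrow(m), 5L)
  expect_equal(fano_from_summary(1841.54, 2414.88), 3166.7, tolerance = 1e-4)
  expect_equal(m$fano, c(3166.72, 2754.85, 4549.43, 15200.89, 47909.94),
               tolerance = 2e-4)
})

test_that("relative means normalise by the largest mean", {
  m <- measured_gfp_summary()
  expect_equal(round(relative_means(m$mean), 2), c(0.01, 0.02, 0.07, 0.32, 1))
  expect_equal(max(relative_means(m$mean)), 1)
  expect_equal(relative_means(42), 1)
  expect_error(relative_means(numeric(0)), "no means")
  # permutation equivariance
  p <- c(3, 1, 5, 2, 4)
  expect_equal(relative_means(m$mean[p]), relative_means(m$mean)[p])
})

test_that("binned distributions are proper probability vectors", {
  b <- bin_distribution(rep(2, 10), bins = c(0, 1, 3, 5))
  expect_equal(b$probability, c(0, 1, 0))
  set.seed(4)
  x <- runif(2000, 0, 30)
  b2 <- bin_distribution(x, bins = 30)
  expect_equal(sum(b2$probability), 1)
  expect_true(all(abs(b2$probability - 1 / 30) < 0.02))
  expect_error(bin_distribution(c(10, 11), bins = c(0, 1)), "outside")
  # last bin is closed: the maximum is counted
  b3 <- bin_distribution(c(0, 1), bins = c(0, 0.5, 1))
  expect_equal(b3$probability, c(0.5, 0.5))
})

test_that("fit distance D is a squared-difference sum", {
  expect_equal(fit_distance_D(1:5, 1:5), 0)
  expect_equal(fit_distance_D(rep(1, 5), rep(0, 5)), 5)
  e <- c(3, 1, 4, 1, 5); m <- c(2, 7, 1, 8, 2)
  p <- c(5, 3, 1, 2, 4)
  expect_equal(fit_distance_D(e[p], m[p]), fit_distance_D(e, m))
  expect_error(fit_distance_D(1:4, 1:5), "equal length")
  # moving any single model value away from its measurement increases D
  m2 <- m; m2[3] <- m2[3] - 1
  expect_gt(fit_distance_D(e, m2), fit_distance_D(e, m))
})

test_that("calibration factor phi links fluorescence to molecules", {
  model <- c(10, 20, 30)
  expect_equal(calibration_factor(2 * model, model), 2)
  m <- measured_gfp_summary()
  oracle <- vapply(tet_conditions()$k1, function(k1)
    steady_state_oracle(model_params(k1))[["mean_protein"]], numeric(1))
  phi <- calibration_factor(m$mean, oracle)
  expect_gt(phi, 50); expect_lt(phi, 56)
  ratios <- calibration_ratios(m$mean, oracle)
  expect_true(all(ratios > 51.5 & ratios < 55))
  expect_lt(sd(ratios) / mean(ratios), 0.05)
  expect_error(calibration_factor(c(-1, 1), c(1, 1)), "positive")
})

test_that("condition summaries carry the measurement-table columns", {
  set.seed(2)
  s <- summarize_conditions(list(
    summarize_population(rpois(100, 50), condition = "a"),
    summarize_population(rpois(100, 100), condition = "b")))
  expect_identical(names(s), c("condition", "n_cells", "mean", "sd",
                               "fano", "relative_mean"))
  expect_equal(max(s$relative_mean), 1)
  expect_equal(s$fano, s$sd^2 / s$mean)
})
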