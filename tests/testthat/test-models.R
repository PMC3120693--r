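test_that("build_model assembles the four delayed reactions", {
  sys <- build_model(model_params(2.8e-2, variant = 1))
  expect_identical(sys$species, c("Pro", "RBS", "P"))
  expect_identical(unname(sys$initial_counts), c(1L, 0L, 0L))
  expect_equal(length(sys$reactions), 4L)
  r1 <- sys$reactions[[1]]
  expect_equal(r1$rate, 2.8e-2)
  pro <- r1$products[[which(vapply(r1$products, function(p) p$species,
                                   "") == "Pro")]]
  expect_identical(pro$delay$kind, "constant")
  expect_equal(pro$delay$mean, 19)
  rbs <- r1$products[[which(vapply(r1$products, function(p) p$species,
                                   "") == "RBS")]]
  expect_equal(rbs$delay$mean, 2)
  # translation delays the protein by tau3
  r2 <- sys$reactions[[2]]
  expect_equal(r2$rate, 0.19)
  pdel <- r2$products[[which(vapply(r2$products, function(p) p$species,
                                    "") == "P")]]
  expect_equal(pdel$delay$mean, 420)
  expect_equal(sys$reactions[[3]]$rate, 0.004)
  expect_equal(sys$reactions[[4]]$rate, 2e-4)
  # gamma open-complex delay in variant 2
  sys2 <- build_model(model_params(2.8e-2, variant = 2, tau1_sd = 400))
  pro2 <- sys2$reactions[[1]]$products[[1]]
  expect_identical(pro2$delay$kind, "gamma")
  expect_equal(pro2$delay$mean, 19)
  expect_equal(pro2$delay$sd, 400)
  expect_error(model_params(0), "positive")
  expect_error(model_params(1e-3, variant = 2, tau1_sd = 0), "tau1_sd")
})

test_that("steady-state oracle closed form and its limits", {
  o <- steady_state_oracle(model_params(2.8e-2))
  expect_equal(o[["mean_rna"]], (1 / (1 / 2.8e-2 + 19)) / 0.004)
  expect_equal(o[["mean_rna"]], 4.569, tolerance = 1e-3)
  expect_equal(o[["mean_protein"]], 4.341e3, tolerance = 1e-3)
  # doubling k2 doubles protein, leaves RNA unchanged
  o2 <- steady_state_oracle(model_params(2.8e-2, k2 = 0.38))
  expect_equal(o2[["mean_rna"]], o[["mean_rna"]])
  expect_equal(o2[["mean_protein"]], 2 * o[["mean_protein"]])
  # initiation rate -> 0 sends both means to 0
  o3 <- steady_state_oracle(model_params(1e-9))
  expect_lt(o3[["mean_protein"]], 1e-2)
})

test_that("oracle matches a long time-averaged variant-1 simulation", {
  p <- model_params(6.5e-3, variant = 1)
  sys <- build_model(p)
  res <- run_simulation(sys, 2e5, seed = 5, sampling = 100)
  keep <- res$series$time > 25000
  o <- steady_state_oracle(p)
  rna_bar <- mean(res$series$RBS[keep])
  prot_bar <- mean(res$series$P[keep])
  expect_equal(rna_bar, o[["mean_rna"]], tolerance = 0.15)
  expect_equal(prot_bar, o[["mean_protein"]], tolerance = 0.1)
})

test_that("populations are reproducible and sampled per cell", {
  p <- model_params(1.4e-3, variant = 2, tau1_sd = 400)
  a <- simulate_population(p, 20, t_sample = 5000, master_seed = 10)
  b <- simulate_population(p, 20, t_sample = 5000, master_seed = 10)
  expect_identical(a, b)
  expect_identical(nrow(a), 20L)
  expect_true(all(a$rna >= 0) && all(a$protein >= 0))
  empty <- simulate_population(p, 0, master_seed = 1)
  expect_identical(nrow(empty), 0L)
  # distinct master seeds decorrelate the population
  c3 <- simulate_population(p, 20, t_sample = 5000, master_seed = 11)
  expect_false(identical(a$protein, c3$protein))
})

test_that("variant 1 and 2 share mean expression at equal k1", {
  # same mean open-complex duration => same initiation rate => same means
  n <- 250
  p1 <- model_params(2.8e-2, variant = 1)
  p2 <- model_params(2.8e-2, variant = 2, tau1_sd = 400)
  a <- simulate_population(p1, n, master_seed = 21)
  b <- simulate_population(p2, n, master_seed = 22)
  se <- sqrt(var(a$protein) / n + var(b$protein) / n)
  expect_lt(abs(mean(a$protein) - mean(b$protein)), 3 * se)
  # and the variant-1 mean agrees with the closed form
  o <- steady_state_oracle(p1)
  expect_lt(abs(mean(a$protein) - o[["mean_protein"]]),
            3 * sd(a$protein) / sqrt(n))
})
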