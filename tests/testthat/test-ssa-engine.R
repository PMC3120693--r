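# small systems with analytic behaviour used as engine oracles
birth_death <- function(lambda = 10, mu = 1)
  reaction_system(list(reaction(lambda, NULL, list(product("X"))),
                       reaction(mu, c(X = 1))), c(X = 0))

delayed_birth <- function(lambda = 1, tau = 5)
  reaction_system(list(reaction(lambda, NULL,
                                list(product("X", delay = delay_constant(tau))))),
                  c(X = 0))

test_that("waiting times of a single source reaction are exponential", {
  sys <- reaction_system(list(reaction(2, NULL, list(product("X")))),
                         c(X = 0))
  # X(t_stop) counts Poisson(lambda * t) events; the mean inter-event time
  # over many events estimates 1/lambda
  res <- run_simulation(sys, 5000, seed = 11)
  expect_equal(5000 / res$final_counts[["X"]], 1 / 2, tolerance = 0.05)
})

test_that("t_stop = 0 and negative t_stop behave as specified", {
  sys <- birth_death()
  res <- run_simulation(sys, 0, seed = 1)
  expect_identical(res$final_counts, sys$initial_counts)
  expect_identical(res$n_events, 0L)
  expect_error(run_simulation(sys, -1), "non-negative")
})

test_that("delayed pure birth matches the Poisson mean lambda*(t - tau)", {
  sys <- delayed_birth(lambda = 1, tau = 5)
  set.seed(202)
  n <- 2000
  x <- vapply(seq_len(n), function(i)
    run_simulation(sys, 10)$final_counts[["X"]], numeric(1))
  # E[X(10)] = 1 * (10 - 5) = 5, MC SE = sqrt(5/n)
  expect_equal(mean(x), 5, tolerance = 3 * sqrt(5 / n) / 5)
})

test_that("zero-delay birth-death is stationary Poisson (chi-squared fit)", {
  sys <- birth_death(lambda = 10, mu = 1)
  # sample well past relaxation (1/mu = 1 s) every 2 s for independence
  res <- run_simulation(sys, 2.1e4, seed = 7, sampling = 2)
  x <- res$series$X[res$series$time > 50]
  expect_gte(length(x), 1e4)
  expect_equal(mean(x), 10, tolerance = 0.05)
  expect_equal(fano(x), 1, tolerance = 0.1)
  counts <- table(factor(x, levels = 0:max(x)))
  p <- dpois(0:max(x), 10)
  p[length(p)] <- 1 - ppois(max(x) - 1, 10)   # fold the tail in
  keep <- p * length(x) >= 5
  chi <- suppressWarnings(chisq.test(
    c(counts[keep], sum(counts[!keep])),
    p = c(p[keep], sum(p[!keep])), rescale.p = TRUE))
  expect_gt(chi$p.value, 0.01)
})

test_that("promoter conservation: free + pending count is constant", {
  p <- model_params(2.8e-2, variant = 2, tau1_sd = 400)
  sys <- build_model(p)
  for (seed in 1:5) {
    res <- run_simulation(sys, 5000, seed = seed)
    expect_identical(res$final_counts[["Pro"]] + res$pending_counts[["Pro"]],
                     1L)
  }
})

test_that("identical seeds give identical event sequences", {
  sys <- build_model(model_params(6.5e-3, variant = 2, tau1_sd = 400))
  a <- run_simulation(sys, 10000, seed = 99, sampling = 100)
  b <- run_simulation(sys, 10000, seed = 99, sampling = 100)
  expect_identical(a$final_counts, b$final_counts)
  expect_identical(a$series, b$series)
  expect_identical(a$n_events, b$n_events)
})

test_that("waitlist semantics: release precedes a later candidate reaction", {
  # one pending release, no reactions possible -> pure release mode
  sys <- reaction_system(list(reaction(1, c(A = 1),
                                       list(product("B", delay = delay_constant(3))))),
                         c(A = 1, B = 0))
  res <- run_simulation(sys, 10, seed = 1)
  expect_identical(res$final_counts[["B"]], 1L)   # release at ~t_fire + 3
  expect_identical(res$final_counts[["A"]], 0L)
  # release scheduled after t_stop stays pending
  sys2 <- reaction_system(list(reaction(100, c(A = 1),
                                        list(product("B", delay = delay_constant(50))))),
                          c(A = 1, B = 0))
  res2 <- run_simulation(sys2, 1, seed = 1)
  expect_identical(res2$final_counts[["B"]], 0L)
  expect_identical(res2$pending_counts[["B"]], 1L)
})

test_that("stepwise reference engine: tie and FIFO rules", {
  sys <- reaction_system(list(reaction(1e-9, c(A = 1))), c(A = 1))
  st <- sim_state(sys)
  # two pending releases at the same time: FIFO by insertion order
  st$waitlist <- data.frame(time = c(2, 2), seq = c(1L, 2L),
                            species = c("A", "A"), count = c(1L, 3L))
  st2 <- advance_one_event(st, sys, t_stop = 10)
  expect_equal(st2$t, 2)
  expect_identical(st2$counts[["A"]], 2L)         # first-inserted released
  st3 <- advance_one_event(st2, sys, t_stop = 10)
  expect_identical(st3$counts[["A"]], 5L)
  # zero propensity + empty waitlist terminates at t_stop
  empty <- sim_state(reaction_system(list(reaction(1, c(Z = 1))), c(Z = 0)))
  done <- advance_one_event(empty, reaction_system(list(reaction(1, c(Z = 1))),
                                                   c(Z = 0)), t_stop = 7)
  expect_equal(done$t, 7)
  expect_identical(done$status, "done")
})

test_that("compiled and reference engines agree in distribution", {
  sys <- delayed_birth(lambda = 2, tau = 1)
  set.seed(31)
  xc <- vapply(1:300, function(i)
    run_simulation(sys, 5, engine = "cpp")$final_counts[["X"]], numeric(1))
  xr <- vapply(1:300, function(i)
    run_simulation(sys, 5, engine = "r")$final_counts[["X"]], numeric(1))
  # both estimate E[X(5)] = 2 * 4 = 8
  expect_equal(mean(xc), 8, tolerance = 0.1)
  expect_equal(mean(xr), 8, tolerance = 0.1)
  expect_gt(suppressWarnings(ks.test(xc, xr))$p.value, 0.01)
})
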