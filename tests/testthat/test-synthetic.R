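clean_config <- function(...) {
  generator_config(photons_per_au = 0, read_noise_sd = 0,
                   hot_pixel_rate = 0, floor = 0, bg_slope = 0,
                   bg_intercept = 0, ...)
}

test_that("scene generation is reproducible and ground-truthed", {
  cfg <- generator_config(n_cells = 10, seed = 3)
  a <- synthetic_scene(cfg)
  b <- synthetic_scene(cfg)
  expect_identical(a$truth, b$truth)
  expect_identical(nrow(a$truth), 10L)
  expect_true(all(a$truth$center_slice > 1 &
                    a$truth$center_slice < cfg$n_slices))
  expect_error(generator_config(cluster_fraction = 2), "cluster_fraction")
  expect_error(generator_config(n_slices = 2), "n_slices")
})

test_that("rendered stacks conserve the fluorescence-per-protein factor", {
  cfg <- clean_config(n_cells = 1, img_size = c(96, 96), seed = 6)
  sc <- render_stack(synthetic_scene(cfg, protein_counts = 1500L,
                                     rna_counts = 0L), noise = FALSE)
  integral <- sum(sc$stack)
  expect_equal(integral / 1500, cfg$phi, tolerance = 0.02)
  # empty scene renders background only
  cfg0 <- generator_config(n_cells = 0, seed = 1, img_size = c(64, 64))
  sc0 <- render_stack(synthetic_scene(cfg0, protein_counts = integer(0),
                                      rna_counts = integer(0)), noise = FALSE)
  expect_equal(unique(round(as.vector(sc0$stack), 6)), cfg0$floor)
})

test_that("fully clustered pairs touch as one connected component", {
  cfg <- clean_config(n_cells = 2, cluster_fraction = 1,
                      img_size = c(96, 96), seed = 2)
  sc <- render_stack(synthetic_scene(cfg, protein_counts = c(1000L, 1000L),
                                     rna_counts = c(0L, 0L)), noise = FALSE)
  fg <- sc$stack[, , sc$truth$center_slice[1]] > 1 |
    sc$stack[, , sc$truth$center_slice[2]] > 1
  lab <- tetnoise:::label_components(fg)
  expect_identical(max(lab), 1L)
  expect_true(sc$truth$clustered[2])
})

test_that("spot images encode RNA counts as intensity multiples", {
  cfg <- clean_config(n_cells = 1, img_size = c(64, 64), seed = 8,
                      ms2_background = 0)
  sc <- synthetic_scene(cfg, protein_counts = 0L, rna_counts = 4L)
  sc <- render_spot_image(sc, spots_per_rna = "one_spot", noise = FALSE)
  expect_identical(nrow(sc$spot_truth), 1L)
  expect_equal(sum(sc$spot_image), 4 * cfg$unit_intensity, tolerance = 0.02)
  # zero RNA everywhere: nothing above the diffuse cell level
  cfg2 <- generator_config(n_cells = 3, seed = 9, img_size = c(96, 96))
  sc2 <- render_spot_image(synthetic_scene(cfg2,
                                           rna_counts = c(0L, 0L, 0L)),
                           noise = FALSE)
  expect_identical(nrow(sc2$spot_truth), 0L)
  expect_lte(max(sc2$spot_image), cfg2$floor + cfg2$ms2_background + 1e-9)
  # spots-per-cell bookkeeping matches the rendered truth
  sc3 <- synthetic_scene(generator_config(n_cells = 5, seed = 10,
                                          img_size = c(128, 128)),
                         rna_counts = c(1L, 2L, 0L, 3L, 2L))
  sc3 <- render_spot_image(sc3, spots_per_rna = "singles", noise = FALSE)
  agg <- tapply(sc3$spot_truth$rna, sc3$spot_truth$cell_id, sum)
  expect_equal(as.vector(agg[as.character(c(1, 2, 4, 5))]), c(1, 2, 3, 2))
})

test_that("population fluorescence tables decompose exactly", {
  p <- model_params(6.5e-3, variant = 1)
  pop <- simulate_population(p, 40, t_sample = 4000, master_seed = 5)
  cfg <- clean_config(phi = 53)
  tab <- generate_population_counts(pop, cfg, noise_cv = 0)
  expect_equal(tab$fluorescence, 53 * tab$protein)   # zero background
  cfg2 <- generator_config(phi = 53)
  tab2 <- generate_population_counts(pop, cfg2, noise_cv = 0)
  expect_equal(tab2$fluorescence, tab2$signal + tab2$background)
  expect_equal(tab2$background,
               cfg2$bg_slope * tab2$area + cfg2$bg_intercept)
  # reproducible for a fixed generator seed
  tab3 <- generate_population_counts(pop, cfg2, noise_cv = 0.05)
  tab4 <- generate_population_counts(pop, cfg2, noise_cv = 0.05)
  expect_identical(tab3, tab4)
  # Fano scales by phi when fluorescence is a pure rescaling
  expect_equal(fano(tab$fluorescence), 53 * fano(tab$protein))
})
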