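test_that("2x2 lower-median filter removes hot pixels and keeps flats", {
  flat <- matrix(7, 10, 10)
  expect_equal(median_filter_2x2(flat), flat)
  hot <- flat
  hot[5, 5] <- 1e6
  expect_equal(median_filter_2x2(hot), flat)
  # lower-median convention: 2nd-smallest of the 2x2 block
  m <- matrix(c(1, 3, 2, 4), 2, 2)
  out <- median_filter_2x2(m)
  expect_equal(out[1, 1], 2)   # block {1,3,2,4} -> 2
})

test_that("preprocess_stack filters slices and sums them", {
  stack <- array(3, c(8, 8, 4))
  pre <- preprocess_stack(stack)
  expect_equal(pre$filtered, stack)
  expect_equal(pre$i_sum, matrix(12, 8, 8))
  expect_error(preprocess_stack(array(1, c(4, 4))), "slices")
})

make_scene <- function(positions, protein = NULL, n_slices = 5, seed = 1) {
  cfg <- generator_config(n_cells = nrow(positions), img_size = c(128, 128),
                          n_slices = n_slices, seed = seed)
  if (is.null(protein)) protein <- rep(2000L, nrow(positions))
  synthetic_scene(cfg, protein_counts = protein,
                  rna_counts = rep(0L, nrow(positions)),
                  positions = positions)
}

test_that("segmentation finds separated rods and drops border objects", {
  pos <- data.frame(cx = c(30, 64, 100), cy = c(30, 90, 40),
                    theta = c(0, 1, 2), length = 18, width = 6)
  sc <- render_stack(make_scene(pos))
  mask <- segment_cells(preprocess_stack(sc$stack)$i_sum)
  expect_identical(mask$n_cells, 3L)
  hits <- mask$labels[cbind(round(pos$cx), round(pos$cy))]
  expect_setequal(hits, 1:3)
  # same scene plus a border-touching rod: still exactly 3 cells
  pos2 <- rbind(pos, data.frame(cx = 2, cy = 64, theta = 0.2,
                                length = 18, width = 6))
  sc2 <- render_stack(make_scene(pos2))
  mask2 <- segment_cells(preprocess_stack(sc2$stack)$i_sum)
  expect_identical(mask2$n_cells, 3L)
  expect_error(segment_cells(matrix(5, 10, 10)), "constant")
})

test_that("touching V-shaped pairs are detected as clusters and split", {
  # three isolated rods plus one rod grown against a neighbour: the
  # merged pair is non-convex, is flagged as a cluster and splits back
  # into two cells
  cfg <- generator_config(n_cells = 4, cluster_fraction = 0.25,
                          img_size = c(160, 160), seed = 2)
  sc <- render_stack(synthetic_scene(
    cfg, protein_counts = c(2000L, 2100L, 1900L, 2200L),
    rna_counts = rep(0L, 4)))
  expect_true(sc$truth$clustered[4])
  mask <- segment_cells(preprocess_stack(sc$stack)$i_sum)
  expect_identical(mask$n_cells, 4L)
  hits <- mask$labels[cbind(round(sc$truth$cx), round(sc$truth$cy))]
  expect_setequal(hits, 1:4)
})

test_that("measure_cell picks the brightest interior slice", {
  lab <- matrix(0L, 6, 6)
  lab[2:4, 2:4] <- 1L
  mk <- function(totals) {
    stack <- array(0, c(6, 6, length(totals)))
    for (s in seq_along(totals)) stack[2:4, 2:4, s] <- totals[s] / 9
    stack
  }
  r <- measure_cell(mk(c(1, 5, 3)), lab, 1L)
  expect_identical(r$chosen_slice, 2L)
  expect_equal(r$total_intensity, 5)
  expect_false(r$flag_discarded_slice)
  # argmax at the first slice: flagged for discarding
  r2 <- measure_cell(mk(c(9, 1, 1)), lab, 1L)
  expect_identical(r2$chosen_slice, 1L)
  expect_true(r2$flag_discarded_slice)
  # all tied: lowest interior slice wins
  r3 <- measure_cell(mk(c(4, 4, 4, 4)), lab, 1L)
  expect_identical(r3$chosen_slice, 2L)
  expect_false(r3$flag_discarded_slice)
  expect_error(measure_cell(mk(1:3), lab, 9L), "not present")
})

fake_records <- function(intensity, area) {
  data.frame(label = seq_along(intensity), area = area,
             chosen_slice = 2L, total_intensity = intensity,
             flag_discarded_slice = FALSE,
             flag_outlier_intensity = FALSE, flag_outlier_area = FALSE,
             corrected_intensity = NA_real_)
}

test_that("outlier filters follow the floor(0.025 n) and median-area rules", {
  # n = 40: exactly one intensity outlier
  r <- fake_records(c(rep(100, 39), 1e6), rep(10, 40))
  out <- remove_outliers(r)
  expect_identical(sum(out$flag_outlier_intensity), 1L)
  expect_true(out$flag_outlier_intensity[40])
  # n = 39: floor(0.975) = 0 outliers
  r2 <- fake_records(c(rep(100, 38), 1e6), rep(10, 39))
  expect_identical(sum(remove_outliers(r2)$flag_outlier_intensity), 0L)
  # area rule: median 11, bounds (5.5, 16.5)
  r3 <- fake_records(rep(100, 4), c(8, 10, 12, 100))
  out3 <- remove_outliers(r3)
  expect_identical(which(out3$flag_outlier_area), 4L)
  # idempotent on an already-clean set
  out4 <- remove_outliers(out3[!out3$flag_outlier_area, ])
  expect_identical(sum(out4$flag_outlier_area), 0L)
  # never flags more than floor(0.025 n) by intensity
  set.seed(8)
  r5 <- fake_records(runif(200, 50, 150), rep(10, 200))
  expect_lte(sum(remove_outliers(r5)$flag_outlier_intensity), 5L)
})

test_that("background model fits and subtracts a linear size trend", {
  area <- c(5, 10, 15, 20, 30)
  m <- fit_background(area, 2 * area + 5)
  expect_equal(m$slope, 2)
  expect_equal(m$intercept, 5)
  # shifting all autofluorescence shifts only the intercept
  m2 <- fit_background(area, 2 * area + 5 + 10)
  expect_equal(m2$slope, 2)
  expect_equal(m2$intercept, 15)
  expect_error(fit_background(rep(7, 5), 1:5), "distinct areas")
  # noisy recovery within 3 SE
  set.seed(5)
  a <- runif(200, 50, 300)
  y <- 1.7 * a + 40 + rnorm(200, sd = 20)
  fit <- fit_background(a, y)
  se <- summary(lm(y ~ a))$coefficients[, 2]
  expect_lt(abs(fit$slope - 1.7), 3 * se[2])
  expect_lt(abs(fit$intercept - 40), 3 * se[1])

  recs <- fake_records(c(100, 20), c(10, 10))
  out <- subtract_background(recs, m)
  expect_equal(out$corrected_intensity, c(100 - 25, 20 - 25))
  zero <- structure(list(slope = 0, intercept = 0),
                    class = "background_model")
  expect_equal(subtract_background(recs, zero)$corrected_intensity,
               recs$total_intensity)
})

test_that("RNA counting recovers spot multiplicities", {
  cfg <- generator_config(n_cells = 6, img_size = c(160, 160), seed = 11)
  sc <- synthetic_scene(cfg, rna_counts = c(0L, 3L, 0L, 5L, 1L, 2L))
  sc <- render_spot_image(sc, spots_per_rna = "one_spot", noise = FALSE)
  res <- count_rna(sc$spot_image, unit_intensity = cfg$unit_intensity)
  img <- tetnoise:::despike(sc$spot_image)
  bw <- EBImage::opening(EBImage::Image((img > mean(img)) * 1),
                         EBImage::makeBrush(5, "disc")) > 0.5
  lab <- tetnoise:::label_components(bw)
  lab_at <- lab[cbind(round(sc$truth$cx), round(sc$truth$cy))]
  got <- res$per_cell$rna_count[lab_at]
  expect_equal(got[sc$truth$rna == 0], c(0L, 0L))
  # one_spot mode: each expressing cell carries one spot of rna x unit
  expressing <- sc$truth$rna > 0
  expect_equal(got[expressing], sc$truth$rna[expressing], tolerance = 0.26)
  expect_identical(nrow(res$spots), sum(expressing))
})

test_that("TIFF round trip is lossless and masks are writable", {
  set.seed(3)
  stack <- array(runif(32 * 32 * 3, 0, 5e4), c(32, 32, 3))
  path <- withr::local_tempfile(fileext = ".tif")
  write_stack_tiff(stack, path)
  expect_equal(read_stack_tiff(path), stack, tolerance = 1e-6)
  lab <- matrix(0L, 8, 8); lab[3:5, 3:5] <- 2L
  p2 <- withr::local_tempfile(fileext = ".png")
  write_mask_image(lab, p2)
  expect_true(file.exists(p2))
})
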