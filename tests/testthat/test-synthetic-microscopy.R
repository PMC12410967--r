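# The synthetic-microscopy generator: placement, strain placement laws,
# rendering, noise model and file round trips.

test_that("configuration invariants are enforced", {
  expect_error(sim_config(p_obvious = 1.2), "\\[0, 1\\]")
  expect_error(sim_config(p_predivision = -0.1), "\\[0, 1\\]")
  expect_error(sim_config(length_mean_um = 0.5, width_um = 0.8),
               "exceed width_um")
  expect_error(sim_config(n_cells = 500, field_size_px = c(128, 128)),
               "field too small")
  expect_error(sim_config(pixel_size_um = 0), "positive")
})

test_that("zero cells requested yields an empty field", {
  cfg <- sim_config(n_cells = 0, field_size_px = c(64, 64))
  f <- simulate_field(cfg)
  expect_length(f$cells, 0)
  expect_equal(nrow(f$truth), 0)
  expect_true(all(f$mask == 0L))
})

test_that("sampled cells are pairwise disjoint with clearance", {
  cfg <- sim_config(n_cells = 50, seed = 1)
  set.seed(cfg$seed)
  cells <- sample_cells(cfg)
  expect_length(cells, 50)
  # pairwise mask intersection is empty: no pixel is claimed twice
  all_px <- do.call(rbind, lapply(cells, `[[`, "pixels"))
  keys <- all_px[, 1] * 10000 + all_px[, 2]
  expect_equal(anyDuplicated(keys), 0L)
})

test_that("placement failure names the densest achievable count", {
  cfg <- sim_config(n_cells = 16, field_size_px = c(150, 150),
                    length_mean_um = 3, seed = 5)
  set.seed(5)
  expect_error(sample_cells(cfg, max_attempts = 20L),
               "densest achievable count")
})

test_that("identical config and seed reproduce the field bit for bit", {
  cfg <- sim_config(n_cells = 8, field_size_px = c(256, 256), seed = 11)
  f1 <- simulate_field(cfg)
  f2 <- simulate_field(cfg)
  expect_identical(f1$image, f2$image)
  expect_identical(f1$mask, f2$mask)
  expect_identical(f1$truth, f2$truth)
})

test_that("wildtype sites are polar; flhF-null sites are uniform", {
  cfg <- quiet_config(n_cells = 1, field_size_px = c(128, 128),
                      p_obvious = 1, p_predivision = 0, seed = 3)
  set.seed(3)
  cell <- sample_cells(cfg)[[1]]
  cells <- clone_cells(cell, 2000)
  set.seed(31)
  tr_wt <- place_structures(cells, cfg)
  expect_true(all(tr_wt$cluster_s <= 0.10 | tr_wt$cluster_s >= 0.90))

  cfg_f <- quiet_config(n_cells = 1, field_size_px = c(128, 128),
                        strain_model = "flhF_null", p_obvious = 1,
                        p_predivision = 0, seed = 3)
  set.seed(32)
  tr_f <- place_structures(clone_cells(cell, 10000), cfg_f)
  ks <- suppressWarnings(stats::ks.test(tr_f$cluster_s, "punif"))
  expect_gt(ks$p.value, 0.01)
  # Uniform(0,1) puts mass 1/2 on [0.25, 0.75]
  mid <- mean(tr_f$cluster_s >= 0.25 & tr_f$cluster_s <= 0.75)
  expect_lt(abs(mid - 0.5), 3 * sqrt(0.25 / 10000))
})

test_that("cluster and flagellar sites coincide exactly by construction", {
  cfg <- sim_config(n_cells = 30, p_obvious = 1, seed = 7)
  set.seed(7)
  cells <- sample_cells(cfg)
  tr <- place_structures(cells, cfg)
  both <- tr$has_obvious_cluster & tr$has_flagellum
  expect_gt(sum(both), 0)
  d <- sqrt((tr$cluster_row - tr$flagellum_row)^2 +
            (tr$cluster_col - tr$flagellum_col)^2)[both]
  expect_true(all(d == 0))
})

test_that("pre-division cells carry structures at both poles", {
  cfg <- sim_config(n_cells = 20, p_obvious = 1, p_predivision = 1,
                    seed = 13)
  set.seed(13)
  cells <- sample_cells(cfg)
  tr <- place_structures(cells, cfg)
  expect_true(all(tr$bipolar))
  # the two sites sit in opposite polar caps for the wildtype model
  s_lo <- pmin(tr$cluster_s, tr$cluster2_s)
  s_hi <- pmax(tr$cluster_s, tr$cluster2_s)
  expect_true(all(s_lo <= 0.10 & s_hi >= 0.90))
})

test_that("delta rendering puts the channel maximum at the planted site", {
  cfg <- quiet_config(n_cells = 1, field_size_px = c(128, 128),
                      p_obvious = 1, p_predivision = 0, seed = 2)
  f <- simulate_field(cfg)
  ch1 <- f$image[, , 1]
  amax <- which(ch1 == max(ch1), arr.ind = TRUE)
  expect_true(any(amax[, 1] == f$truth$cluster_row &
                  amax[, 2] == f$truth$cluster_col))
})

test_that("PSF convolution conserves total intensity pre-noise", {
  cfg <- quiet_config(n_cells = 10, field_size_px = c(256, 256), seed = 17)
  f <- simulate_field(cfg)  # sharp, noise-free, integer-exact signal
  for (ch in 1:3) {
    sharp <- f$image[, , ch] - cfg$background_level
    blurred <- psf_blur(sharp, 1.3)
    expect_lt(abs(sum(blurred) - sum(sharp)) / sum(sharp), 0.001)
  }
})

test_that("reporter channel intensity is proportional to the latent level", {
  # high gain keeps 16-bit quantization (+-0.5 count) well below 1%
  cfg <- sim_config(n_cells = 12, field_size_px = c(384, 384),
                    gaussian_sd = 0, poisson_scale = 0, seed = 19,
                    reporter_cv = 0.5, reporter_gain = 500)
  f <- simulate_field(cfg)
  ch3 <- f$image[, , 3] - cfg$background_level
  # interior mean (mask eroded clear of the PSF edge) over the latent level
  # is the gain, constant across cells
  brush <- EBImage::makeBrush(9, "disc")  # erosion radius 4 px ~ 3 sigma
  ratios <- vapply(f$cells, function(cell) {
    bin <- matrix(0L, nrow(f$mask), ncol(f$mask))
    bin[cell$pixels] <- 1L
    interior <- which(EBImage::erode(bin, brush) > 0, arr.ind = TRUE)
    tr <- f$truth[f$truth$cell_id == cell$cell_id, ]
    mean(ch3[interior]) / tr$reporter_level
  }, numeric(1))
  expect_lt(diff(range(ratios)) / mean(ratios), 0.01)
  expect_equal(mean(ratios), cfg$reporter_gain, tolerance = 0.01)
})

test_that("saturating amplitudes are clipped with a warning and count", {
  cfg <- sim_config(n_cells = 5, field_size_px = c(128, 128),
                    focus_amplitude = 5e6, p_obvious = 1, seed = 23)
  expect_warning(f <- simulate_field(cfg), "clipped")
  expect_gt(f$n_clipped, 0)
  expect_true(all(f$image <= 65535L))
})

test_that("fields round-trip through 16-bit TIFF + CSV exactly", {
  cfg <- sim_config(n_cells = 5, field_size_px = c(128, 128), seed = 29)
  f <- simulate_field(cfg)
  dir <- withr::local_tempdir()
  write_field(f, dir, "field_1")
  back <- read_field(dir, "field_1")
  expect_identical(back$image, f$image)
  expect_identical(back$mask, f$mask)
  expect_equal(back$truth$cluster_s, f$truth$cluster_s)
  expect_equal(back$truth$reporter_level, f$truth$reporter_level)
})
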