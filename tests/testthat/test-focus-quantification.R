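# Focus detection, the 3x3 intensity rule and obvious-cluster calls.

test_that("constant cells give the constant mean and a deterministic center", {
  img <- matrix(7, 60, 60)
  cell <- make_cell(2, 0.8, dim_px = c(60, 60), center = c(30, 30))
  f <- detect_focus(img, cell)
  expect_equal(f$intensity_3x3, 7)
  # lexicographic tie-break: the first mask pixel in (row, col) order
  first <- cell$pixels[order(cell$pixels[, 1], cell$pixels[, 2]), ][1, ]
  expect_equal(c(f$row, f$col), unname(first))
})

test_that("the 3x3 mean of the digits 1..9 around the maximum is 5", {
  img <- matrix(0, 30, 30)
  img[14:16, 14:16] <- matrix(c(1, 2, 3, 4, 9, 5, 6, 7, 8), 3, 3)
  mask <- as.matrix(expand.grid(row = 13:17, col = 13:17))  # 25 px blob
  cell <- fit_axis(mask, PX)
  f <- detect_focus(img, cell)
  expect_equal(c(f$row, f$col), c(15, 15))
  expect_equal(f$intensity_3x3, 5)
})

test_that("the 3x3 rule equals a brute-force window mean, edges included", {
  set.seed(8)
  brute <- function(img, r, c) {
    acc <- c()
    for (dr in -1:1) for (dc in -1:1) {
      rr <- r + dr; cc <- c + dc
      if (rr >= 1 && rr <= nrow(img) && cc >= 1 && cc <= ncol(img)) {
        acc <- c(acc, img[rr, cc])
      }
    }
    mean(acc)
  }
  for (i in 1:50) {
    img <- matrix(stats::runif(15 * 17), 15, 17)
    r <- sample(15, 1); c <- sample(17, 1)
    expect_equal(poleloc:::mean_3x3(img, r, c), brute(img, r, c),
                 tolerance = 1e-14)
  }
})

test_that("planted foci are recovered within one pixel on noiseless fields", {
  cfg <- sim_config(n_cells = 20, gaussian_sd = 0, poisson_scale = 0,
                    p_obvious = 1, p_predivision = 0, seed = 41)
  f <- simulate_field(cfg)
  a <- analyze_field(f$image, f$mask, run_config())
  foci <- a$foci[a$foci$channel == "cluster" & a$foci$rank == 1L, ]
  m <- merge(foci, f$truth, by = "cell_id")
  err <- sqrt((m$row - m$cluster_row)^2 + (m$col - m$cluster_col)^2)
  expect_true(all(err <= 1))
  expect_true(all(m$obvious))  # 100% recall at this amplitude
})

test_that("obvious calls follow the dual SNR + contrast criterion", {
  f <- data.frame(cell_id = 1:3, intensity_3x3 = c(500, 105, 400),
                  cell_median = c(100, 100, 300),
                  snr = c(5, 1.05, 4 / 3))
  out <- call_obvious(f, threshold_snr = 2, min_abs = 15)
  expect_equal(out$obvious, c(TRUE, FALSE, FALSE))
  # absolute contrast can veto a high-SNR call in a near-zero-median cell
  dim_cell <- data.frame(cell_id = 4, intensity_3x3 = 4, cell_median = 1,
                         snr = 4)
  expect_false(call_obvious(dim_cell, 2, 15)$obvious)
  bad <- data.frame(cell_id = 5, intensity_3x3 = NaN, cell_median = 1,
                    snr = NaN)
  expect_error(call_obvious(bad), "non-finite")
})

test_that("raising the SNR threshold never increases obvious calls", {
  cfg <- sim_config(n_cells = 40, p_obvious = 0.7, seed = 43)
  f <- simulate_field(cfg)
  geo <- mask_geometries(f$mask, cfg$pixel_size_um)
  counts <- vapply(c(1, 1.5, 2, 3, 5), function(thr) {
    foci <- detect_foci(f$image[, , 1], geo$cells, threshold_snr = thr,
                        min_abs = 15, second_pass = FALSE)
    sum(foci$obvious)
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("fields without planted clusters yield few false positives", {
  cfg <- sim_config(n_cells = 50, p_obvious = 0, seed = 47)
  fields <- simulate_fields(cfg, 2)
  a <- analyze_fields(fields, run_config())
  expect_lt(mean(a$cells$obvious_cluster), 0.05)
})

test_that("pre-division cells yield a second focus at the opposite pole", {
  cfg <- sim_config(n_cells = 15, p_obvious = 1, p_predivision = 1,
                    seed = 53)
  f <- simulate_field(cfg)
  a <- analyze_field(f$image, f$mask, run_config())
  foci <- a$foci[a$foci$channel == "cluster", ]
  second <- foci[foci$rank == 2L, ]
  expect_gt(nrow(second), 10)  # nearly all bipolar cells
  both <- merge(foci[foci$rank == 1L, ], second, by = "cell_id")
  # the two foci straddle the midline
  expect_true(all((both$axial_s.x - 0.5) * (both$axial_s.y - 0.5) < 0))
})

test_that("focus centers always lie inside the cell mask", {
  cfg <- sim_config(n_cells = 30, seed = 59)
  f <- simulate_field(cfg)
  a <- analyze_field(f$image, f$mask, run_config())
  foci <- a$foci
  inside <- f$mask[cbind(foci$row, foci$col)] == foci$cell_id
  expect_true(all(inside))
  expect_true(all(foci$snr >= 0))
})
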