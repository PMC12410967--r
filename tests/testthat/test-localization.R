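# Axial zone classification and cluster-flagellum colocalization.

test_that("zone boundaries follow the stated partition and ownership", {
  expect_equal(as.character(classify_zone(0.05)), "precise_polar")
  expect_equal(as.character(classify_zone(0.50)), "mid_cell")
  expect_equal(as.character(classify_zone(0.20)), "near_polar")
  expect_equal(as.character(classify_zone(0.97)), "precise_polar")
  # boundary ownership: each boundary belongs to its own side's zone
  expect_equal(as.character(classify_zone(c(0.10, 0.25, 0.75, 0.90))),
               c("precise_polar", "mid_cell", "mid_cell", "precise_polar"))
  expect_error(classify_zone(1.2), "\\[0, 1\\]")
  expect_error(classify_zone(-0.01), "\\[0, 1\\]")
  expect_error(classify_zone(NA_real_), "\\[0, 1\\]")
})

test_that("every axial fraction receives exactly one zone", {
  s <- seq(0, 1, by = 1e-4)
  z <- classify_zone(s)
  expect_false(anyNA(z))
  expect_equal(length(z), length(s))
  # interval measures of the partition
  p <- as.numeric(table(z)) / length(s)
  expect_equal(p, c(0.2, 0.3, 0.5), tolerance = 1e-3)
})

test_that("zone proportions count foci per the partition", {
  zp <- zone_proportions(c(0.02, 0.97, 0.5, 0.2))
  expect_equal(unname(zp$proportions), c(0.5, 0.25, 0.25))
  expect_equal(sum(zp$proportions), 1)

  degenerate <- zone_proportions(rep(0, 5))
  expect_equal(unname(degenerate$proportions), c(1, 0, 0))

  empty <- zone_proportions(numeric(0))
  expect_true(empty$empty)
  expect_equal(empty$n, 0L)

  # data.frame input restricted to obvious foci
  df <- data.frame(axial_s = c(0.05, 0.5), obvious = c(TRUE, FALSE))
  expect_equal(zone_proportions(df)$n, 1L)
})

test_that("uniform placement hits the (0.2, 0.3, 0.5) zone measures", {
  set.seed(61)
  s <- stats::runif(10000)
  zp <- zone_proportions(s)
  expected <- c(0.2, 0.3, 0.5)
  for (i in 1:3) {
    sd_i <- sqrt(expected[i] * (1 - expected[i]) / 10000)
    expect_lt(abs(zp$proportions[i] - expected[i]), 3 * sd_i)
  }
})

test_that("colocalization distance, pole agreement and threshold", {
  cell <- make_cell(L_um = 4, d_um = 1)
  mk <- function(p) data.frame(cell_id = 1L, row = p[1], col = p[2])
  same <- colocalize(mk(cell$tip0 + c(0, 3)), mk(cell$tip0 + c(0, 3)), cell)
  expect_equal(same$distance_um, 0)
  expect_true(same$colocalized)
  expect_true(same$same_pole)

  opp <- colocalize(mk(round(cell$tip0 + 0.5 * cell$axis)),
                    mk(round(cell$tip1 - 0.5 * cell$axis)), cell)
  expect_equal(opp$distance_um, 4, tolerance = 0.1)
  expect_false(opp$colocalized)
  expect_false(opp$same_pole)

  # symmetric in its two focus arguments
  a <- mk(round(cell$centroid)); b <- mk(round(cell$tip0 + 2 * cell$axis))
  expect_equal(colocalize(a, b, cell)$distance_um,
               colocalize(b, a, cell)$distance_um)

  # missing focus: not evaluable, no crash
  ne <- colocalize(NULL, a, cell)
  expect_false(ne$evaluable)
  expect_true(is.na(ne$colocalized))
})

test_that("colocalization distance is invariant under field rotation", {
  cell <- make_cell(L_um = 3, d_um = 0.8, angle = 0.4)
  mk <- function(p) data.frame(cell_id = 1L, row = p[1], col = p[2])
  p1 <- round(cell$tip0 + 2 * cell$axis)
  p2 <- round(cell$tip1 - 1 * cell$axis)
  d0 <- colocalize(mk(p1), mk(p2), cell)$distance_um
  # rotate everything by 90 degrees: (r, c) -> (c, 201 - r)
  rot <- function(p) c(p[2], 201 - p[1])
  cell_r <- fit_axis(t(apply(cell$pixels, 1, rot)), PX)
  d90 <- colocalize(mk(rot(p1)), mk(rot(p2)), cell_r)$distance_um
  expect_equal(d0, d90, tolerance = 1e-10)
})

test_that("flhF-null-like fields dissociate placement from pairing", {
  cfg_wt <- sim_config(n_cells = 40, strain_model = "wildtype", seed = 67)
  cfg_ff <- sim_config(n_cells = 40, strain_model = "flhF_null", seed = 167)
  a_wt <- analyze_fields(simulate_fields(cfg_wt, 2), run_config())
  a_ff <- analyze_fields(simulate_fields(cfg_ff, 2), run_config())
  s_wt <- summarize_strains(a_wt)
  s_ff <- summarize_strains(a_ff)
  frac_precise <- function(s) {
    s$zone_precise_polar /
      (s$zone_precise_polar + s$zone_near_polar + s$zone_mid_cell)
  }
  # pairing persists while precise-polar placement collapses
  expect_gt(s_ff$coloc_rate, 0.95)
  expect_equal(s_wt$coloc_rate, 1)
  expect_lt(frac_precise(s_ff), frac_precise(s_wt) - 0.3)
})
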