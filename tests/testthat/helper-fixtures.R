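# Shared fixtures: digitized spherocylinder masks, small quiet configs and
# an independent enumeration oracle for the two-sided exact test.

PX <- 0.065  # um/px used throughout the tests

# pixel footprint of a spherocylinder placed in a blank field
make_mask <- function(L_um, d_um, angle = 0, dim_px = c(200, 200),
                      center = c(100, 100), px = PX) {
  poleloc:::spherocylinder_pixels(center, angle, L_um / px, d_um / px,
                                  dim_px)
}

# a fitted cell on a synthetic footprint
make_cell <- function(L_um = 4, d_um = 1, angle = 0, dim_px = c(200, 200),
                      center = c(100, 100), px = PX, cell_id = 1L) {
  fit_axis(make_mask(L_um, d_um, angle, dim_px, center, px), px,
           cell_id = cell_id)
}

# noise-free, blur-free simulator settings (delta rendering)
quiet_config <- function(...) {
  sim_config(psf_sigma_px = 0, gaussian_sd = 0, poisson_scale = 0, ...)
}

# two-sided Fisher p by exhaustive enumeration of the hypergeometric
# distribution (all tables with the observed margins whose probability does
# not exceed the observed table's)
fisher_p_enum <- function(k1, n1, k2, n2) {
  m <- k1 + k2
  lo <- max(0, m - n2)
  hi <- min(n1, m)
  pr <- stats::dhyper(lo:hi, n1, n2, m)
  obs <- stats::dhyper(k1, n1, n2, m)
  sum(pr[pr <= obs * (1 + 1e-7)])
}

# clone one footprint into n independent cells (placement-free truth draws)
clone_cells <- function(cell, n) {
  cells <- rep(list(cell), n)
  for (i in seq_len(n)) cells[[i]]$cell_id <- i
  cells
}
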