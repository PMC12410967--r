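# Synthetic multi-channel fluorescence fields of spherocylindrical bacteria.
# Channel 1: cytoplasmic baseline + receptor-cluster focus impulses.
# Channel 2: flagellar-base focus impulses.
# Channel 3: per-cell uniform diffuse-reporter signal.

# pixels whose center lies within d/2 (+ extra) of the cell's axis segment
spherocylinder_pixels <- function(center, angle, L_px, d_px, dim_px,
                                  extra = 0) {
  r <- d_px / 2 + extra
  h <- max((L_px - d_px) / 2, 0)
  v <- c(cos(angle), sin(angle))
  a0 <- center - h * v
  a1 <- center + h * v
  rows <- max(1L, floor(min(a0[1], a1[1]) - r)):
    min(dim_px[1], ceiling(max(a0[1], a1[1]) + r))
  cols <- max(1L, floor(min(a0[2], a1[2]) - r)):
    min(dim_px[2], ceiling(max(a0[2], a1[2]) + r))
  rr <- rep(rows, times = length(cols))
  cc <- rep(cols, each = length(rows))
  w <- a1 - a0
  L2 <- sum(w^2)
  t <- if (L2 == 0) 0 else
    clamp01(((rr - a0[1]) * w[1] + (cc - a0[2]) * w[2]) / L2)
  keep <- (rr - (a0[1] + t * w[1]))^2 + (cc - (a0[2] + t * w[2]))^2 <= r^2
  cbind(row = rr[keep], col = cc[keep])
}

# lognormal cell length in um, truncated at >= width; pre-division cells
# draw from the upper quartile (they are the long, large-aspect-ratio cells)
draw_length <- function(cfg, bipolar) {
  sdlog <- sqrt(log(1 + (cfg$length_sd_um / cfg$length_mean_um)^2))
  meanlog <- log(cfg$length_mean_um) - sdlog^2 / 2
  lo <- if (bipolar) stats::qlnorm(0.75, meanlog, sdlog) else cfg$width_um
  for (i in 1:1000) {
    L <- stats::rlnorm(1, meanlog, sdlog)
    if (L >= lo && L >= cfg$width_um) return(L)
  }
  stop("could not draw a cell length above ", signif(lo, 3), " um")
}

#' Place non-overlapping spherocylindrical cells in a field
#'
#' Rejection-samples random positions and orientations until all requested
#' cells fit with at least 2 px clearance between footprints. Consumes the
#' current RNG stream; [simulate_field()] seeds it from the config.
#'
#' @param config a [sim_config()].
#' @param max_attempts placement attempts per cell before giving up.
#' @return list of \code{cell_geometry} objects (true geometry, exact
#'   lengths/poles), each with an extra \code{bipolar} flag.
#' @export
sample_cells <- function(config, max_attempts = 2000L) {
  validate_sim_config(config)
  dim_px <- config$field_size_px
  px <- config$pixel_size_um
  d_px <- config$width_um / px
  clearance <- 2
  occ <- matrix(FALSE, dim_px[1], dim_px[2])
  cells <- vector("list", config$n_cells)

  for (i in seq_len(config$n_cells)) {
    bipolar <- stats::runif(1) < config$p_predivision
    L_um <- draw_length(config, bipolar)
    L_px <- L_um / px
    margin <- L_px / 2 + clearance + 2
    if (2 * margin >= min(dim_px)) {
      stop(sprintf("cell of length %.2f um does not fit the field", L_um))
    }
    placed <- FALSE
    for (att in seq_len(max_attempts)) {
      ctr <- c(stats::runif(1, margin, dim_px[1] - margin),
               stats::runif(1, margin, dim_px[2] - margin))
      ang <- stats::runif(1, 0, pi)
      clear_px <- spherocylinder_pixels(ctr, ang, L_px, d_px, dim_px,
                                        extra = clearance)
      if (any(occ[clear_px])) next
      fp <- spherocylinder_pixels(ctr, ang, L_px, d_px, dim_px)
      occ[fp] <- TRUE
      v <- c(cos(ang), sin(ang))
      tip_a <- ctr - L_px / 2 * v
      tip_b <- ctr + L_px / 2 * v
      if (tip_b[1] < tip_a[1] ||
          (tip_b[1] == tip_a[1] && tip_b[2] < tip_a[2])) {
        tmp <- tip_a; tip_a <- tip_b; tip_b <- tmp
      }
      axis_dir <- (tip_b - tip_a) / sqrt(sum((tip_b - tip_a)^2))
      cells[[i]] <- structure(list(
        cell_id = i,
        pixels = fp,
        n_pixels = nrow(fp),
        centroid = ctr,
        axis = axis_dir,
        angle_deg = atan2(axis_dir[2], axis_dir[1]) * 180 / pi,
        length_um = L_um,
        width_um = config$width_um,
        tip0 = tip_a,
        tip1 = tip_b,
        pole0 = tip_a + d_px / 2 * axis_dir,
        pole1 = tip_b - d_px / 2 * axis_dir,
        volume_um3 = spherocylinder_volume(L_um, config$width_um),
        pixel_size_um = px,
        bipolar = bipolar
      ), class = "cell_geometry")
      placed <- TRUE
      break
    }
    if (!placed) {
      stop(sprintf(
        "placement failed for cell %d after %d attempts; densest achievable count in this field: %d",
        i, max_attempts, i - 1L))
    }
  }
  cells
}

# axial fraction -> nearest footprint pixel (foci must land inside the mask)
site_pixel <- function(cell, s) {
  p <- cell$tip0 + s * (cell$tip1 - cell$tip0)
  rp <- round(p)
  fp <- cell$pixels
  hit <- fp[, 1] == rp[1] & fp[, 2] == rp[2]
  if (any(hit)) return(c(rp[1], rp[2]))
  d2 <- (fp[, 1] - p[1])^2 + (fp[, 2] - p[2])^2
  as.numeric(fp[which.min(d2), ])
}

# one axial site per the strain's placement law; polar sites live in the
# outer 10% of the length, with the pole chosen at random
sample_axial_site <- function(strain) {
  if (strain == "flhF_null") return(stats::runif(1))
  s <- stats::runif(1, 0, 0.10)
  if (stats::runif(1) < 0.5) s else 1 - s
}

#' Plant foci and reporter levels in sampled cells
#'
#' Applies the strain model: wildtype and motor-null cells receive their
#' focus site in a polar cap (axial fraction in [0, 0.10] or [0.90, 1]);
#' flhF-null cells draw the site uniformly along the axis. With probability
#' \code{p_obvious} the site carries a detectable receptor cluster. Strains
#' with motors also carry a flagellar base at the identical site (true
#' cluster-flagellum distance is exactly zero by construction). Pre-division
#' (bipolar) cells receive a second site: mirrored to the opposite pole for
#' polar strains, an independent uniform draw for flhF-null.
#'
#' @param cells list from [sample_cells()].
#' @param config a [sim_config()].
#' @return ground-truth data.frame, one row per cell; absent structures are
#'   NA.
#' @export
place_structures <- function(cells, config) {
  n <- length(cells)
  na <- rep(NA_real_, n)
  out <- list(cell_id = integer(n), strain = character(n),
              bipolar = logical(n), length_um = numeric(n),
              width_um = numeric(n), volume_um3 = numeric(n),
              has_obvious_cluster = logical(n),
              cluster_s = na, cluster_row = na, cluster_col = na,
              cluster2_s = na, cluster2_row = na, cluster2_col = na,
              has_flagellum = logical(n),
              flagellum_row = na, flagellum_col = na,
              flagellum2_row = na, flagellum2_col = na,
              reporter_level = numeric(n))
  sdlog <- sqrt(log(1 + config$reporter_cv^2))
  meanlog <- log(config$reporter_mean) - sdlog^2 / 2
  for (i in seq_len(n)) {
    cell <- cells[[i]]
    strain <- if (config$strain_model == "mixed") {
      sample(c("wildtype", "flhF_null", "motor_null"), 1)
    } else config$strain_model
    has_cluster <- stats::runif(1) < config$p_obvious
    s1 <- sample_axial_site(strain)
    bip <- isTRUE(cell$bipolar)
    s2 <- if (bip) {
      if (strain == "flhF_null") stats::runif(1)
      else if (s1 <= 0.5) 1 - stats::runif(1, 0, 0.10)
      else stats::runif(1, 0, 0.10)
    } else NA_real_
    p1 <- site_pixel(cell, s1)
    p2 <- if (bip) site_pixel(cell, s2) else c(NA_real_, NA_real_)
    has_flag <- strain != "motor_null"
    out$cell_id[i] <- cell$cell_id
    out$strain[i] <- strain
    out$bipolar[i] <- bip
    out$length_um[i] <- cell$length_um
    out$width_um[i] <- cell$width_um
    out$volume_um3[i] <- cell$volume_um3
    out$has_obvious_cluster[i] <- has_cluster
    if (has_cluster) {
      out$cluster_s[i] <- s1
      out$cluster_row[i] <- p1[1]; out$cluster_col[i] <- p1[2]
      if (bip) {
        out$cluster2_s[i] <- s2
        out$cluster2_row[i] <- p2[1]; out$cluster2_col[i] <- p2[2]
      }
    }
    out$has_flagellum[i] <- has_flag
    if (has_flag) {
      out$flagellum_row[i] <- p1[1]; out$flagellum_col[i] <- p1[2]
      if (bip) {
        out$flagellum2_row[i] <- p2[1]; out$flagellum2_col[i] <- p2[2]
      }
    }
    out$reporter_level[i] <- stats::rlnorm(1, meanlog, sdlog)
  }
  as.data.frame(out, stringsAsFactors = FALSE)
}

gaussian_kernel <- function(sigma) {
  half <- ceiling(4 * sigma)
  g <- stats::dnorm(-half:half, sd = sigma)
  k <- outer(g, g)
  k / sum(k)
}

#' Gaussian PSF convolution of one channel
#'
#' Convolution with a normalized Gaussian kernel (support 4 sigma) under a
#' circular boundary, which conserves total intensity exactly up to
#' floating-point error; this is the blur applied by [render_field()]
#' before the noise model and 16-bit quantization.
#'
#' @param channel numeric matrix.
#' @param sigma_px PSF standard deviation in pixels; 0 returns the input.
#' @return blurred matrix.
#' @export
psf_blur <- function(channel, sigma_px) {
  if (sigma_px < 0) stop("sigma_px must be non-negative")
  if (sigma_px == 0) return(channel)
  EBImage::filter2(channel, gaussian_kernel(sigma_px),
                   boundary = "circular")
}

#' Render a multi-channel image from cells and ground truth
#'
#' Foci are rendered as single-pixel impulses (receptor clusters are
#' sub-diffraction, so the PSF sets the spot size), the reporter as a
#' uniform per-cell interior intensity, and the cluster channel additionally
#' carries a cytoplasmic baseline. Each channel is convolved with a Gaussian
#' PSF (circular boundary, so total intensity is conserved), then Poisson
#' shot noise is applied, and the constant camera background plus Gaussian
#' read noise are added. Output is clipped to the 16-bit range; clipped
#' pixels are counted and reported via a warning.
#'
#' @param cells list from [sample_cells()].
#' @param truth data.frame from [place_structures()].
#' @param config a [sim_config()].
#' @return list with \code{image} (integer rows x cols x 3 array, counts),
#'   \code{mask} (integer-labeled matrix of pre-blur footprints) and
#'   \code{n_clipped}.
#' @export
render_field <- function(cells, truth, config) {
  dim_px <- config$field_size_px
  img <- array(0, c(dim_px[1], dim_px[2], 3L))
  mask <- matrix(0L, dim_px[1], dim_px[2])
  for (cell in cells) {
    tr <- truth[truth$cell_id == cell$cell_id, ]
    mask[cell$pixels] <- cell$cell_id
    ch1 <- img[, , 1]; ch1[cell$pixels] <- ch1[cell$pixels] +
      config$cytoplasm_level
    ch3 <- img[, , 3]; ch3[cell$pixels] <- ch3[cell$pixels] +
      config$reporter_gain * tr$reporter_level
    img[, , 1] <- ch1
    img[, , 3] <- ch3
    add_impulse <- function(ch, r, c, a) {
      if (!is.na(r)) img[r, c, ch] <<- img[r, c, ch] + a
    }
    add_impulse(1, tr$cluster_row, tr$cluster_col, config$focus_amplitude)
    add_impulse(1, tr$cluster2_row, tr$cluster2_col, config$focus_amplitude)
    add_impulse(2, tr$flagellum_row, tr$flagellum_col, config$focus_amplitude)
    add_impulse(2, tr$flagellum2_row, tr$flagellum2_col,
                config$focus_amplitude)
  }
  if (config$psf_sigma_px > 0) {
    for (ch in 1:3) {
      img[, , ch] <- psf_blur(img[, , ch], config$psf_sigma_px)
    }
  }
  npx <- prod(dim_px)
  for (ch in 1:3) {
    x <- pmax(img[, , ch], 0)
    if (config$poisson_scale > 0) {
      x <- stats::rpois(npx, x * config$poisson_scale) / config$poisson_scale
    }
    x <- x + config$background_level
    if (config$gaussian_sd > 0) {
      x <- x + stats::rnorm(npx, 0, config$gaussian_sd)
    }
    img[, , ch] <- x
  }
  n_clipped <- sum(img > 65535 | img < 0)
  if (n_clipped > 0) {
    warning(sprintf("%d pixel values clipped to the 16-bit range", n_clipped))
  }
  img <- round(pmin(pmax(img, 0), 65535))
  storage.mode(img) <- "integer"
  list(image = img, mask = mask, n_clipped = n_clipped)
}

#' Simulate one field (cells, ground truth, rendered image)
#'
#' Seeds the RNG from \code{config$seed}, then runs [sample_cells()],
#' [place_structures()] and [render_field()]. Identical configs give
#' bit-identical output.
#'
#' @param config a [sim_config()].
#' @return list with \code{image}, \code{mask}, \code{truth}, \code{cells},
#'   \code{n_clipped}, \code{config}.
#' @export
#' @examples
#' f <- simulate_field(sim_config(n_cells = 3, field_size_px = c(128, 128)))
#' dim(f$image)
simulate_field <- function(config) {
  set.seed(config$seed)
  cells <- sample_cells(config)
  truth <- place_structures(cells, config)
  rf <- render_field(cells, truth, config)
  list(image = rf$image, mask = rf$mask, truth = truth, cells = cells,
       n_clipped = rf$n_clipped, config = config)
}

#' Simulate several independent fields
#'
#' Field k uses seed \code{config$seed + k - 1}; truth tables gain a
#' \code{field} column.
#'
#' @param config a [sim_config()].
#' @param n_fields number of fields.
#' @return list of [simulate_field()] results.
#' @export
simulate_fields <- function(config, n_fields) {
  lapply(seq_len(n_fields), function(k) {
    cfg <- config
    cfg$seed <- config$seed + k - 1L
    f <- simulate_field(cfg)
    if (nrow(f$truth)) f$truth$field <- k else f$truth$field <- integer(0)
    f$field <- k
    f
  })
}

#' Write / read a simulated field as 16-bit TIFFs + truth CSV
#'
#' \code{write_field} writes \code{<prefix>_img.tif} (multi-channel 16-bit),
#' \code{<prefix>_mask.tif} (integer-labeled) and \code{<prefix>_truth.csv}
#' into \code{dir}; \code{read_field} reads them back (exactly — 16-bit
#' values round-trip losslessly).
#'
#' @param field a [simulate_field()] result (or any list with image, mask,
#'   truth).
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix, e.g. \code{"field_1"}.
#' @return \code{write_field}: the prefix path, invisibly.
#'   \code{read_field}: list with \code{image}, \code{mask}, \code{truth}
#'   (NULL if no CSV).
#' @export
write_field <- function(field, dir, prefix = "field_1") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  base <- file.path(dir, prefix)
  tiff::writeTIFF(field$image / 65535, paste0(base, "_img.tif"),
                  bits.per.sample = 16L)
  tiff::writeTIFF(field$mask / 65535, paste0(base, "_mask.tif"),
                  bits.per.sample = 16L)
  if (!is.null(field$truth)) {
    utils::write.csv(field$truth, paste0(base, "_truth.csv"),
                     row.names = FALSE)
  }
  invisible(base)
}

#' @rdname write_field
#' @export
read_field <- function(dir, prefix = "field_1") {
  base <- file.path(dir, prefix)
  img <- round(tiff::readTIFF(paste0(base, "_img.tif")) * 65535)
  storage.mode(img) <- "integer"
  mask <- round(tiff::readTIFF(paste0(base, "_mask.tif")) * 65535)
  storage.mode(mask) <- "integer"
  truth_path <- paste0(base, "_truth.csv")
  truth <- if (file.exists(truth_path)) {
    utils::read.csv(truth_path)
  } else NULL
  list(image = img, mask = mask, truth = truth)
}
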