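#' Spherocylinder volume
#'
#' Volume of a solid spherocylinder (cylinder with hemispherical caps): the
#' short-axis length \code{d} is the sphere diameter and the long-axis length
#' \code{L} is the cylinder height plus the sphere diameter, so
#' \deqn{V = \pi d^3/6 + (\pi d^2/4)(L - d).}
#' This is the cell-shape model used to normalize single-cell fluorescence
#' by volume.
#'
#' @param length_L long-axis length, um (vectorized).
#' @param width_d short-axis length (diameter), um (vectorized).
#' @return volume in um^3.
#' @export
#' @examples
#' spherocylinder_volume(1, 1)   # sphere: pi/6
#' spherocylinder_volume(3, 1)   # 2*pi/3
spherocylinder_volume <- function(length_L, width_d) {
  if (any(!is.finite(length_L)) || any(!is.finite(width_d))) {
    stop("non-finite input")
  }
  if (any(length_L <= 0) || any(width_d <= 0)) {
    stop("length_L and width_d must be positive")
  }
  if (any(length_L < width_d)) {
    stop("long axis shorter than short axis")
  }
  pi * width_d^3 / 6 + pi * width_d^2 / 4 * (length_L - width_d)
}

#' Fit the long axis and spherocylinder geometry of one segmented cell
#'
#' The cell's long axis is the principal eigenvector of the pixel-coordinate
#' covariance; the long- and short-axis lengths are the peak-to-peak extents
#' of the pixel projections on the principal and orthogonal axes (+1 px for
#' pixel width), scaled by the pixel size. The two axis "tips" are the
#' outermost points of the cell along the axis; the poles (hemisphere
#' centers) sit \code{d/2} inside each tip. By convention \code{tip0} is the
#' tip with the smaller (row, col) lexicographic coordinate, which fixes the
#' orientation of the axial coordinate (see [axial_fraction()]).
#'
#' @param pixels two-column matrix of (row, col) pixel coordinates of a
#'   single connected mask component (at least 20 pixels).
#' @param pixel_size_um pixel size, um/px.
#' @param cell_id optional integer label carried through to outputs.
#' @return an object of class \code{cell_geometry}: list with fields
#'   \code{cell_id}, \code{pixels}, \code{n_pixels}, \code{centroid},
#'   \code{axis} (unit vector tip0 -> tip1), \code{angle_deg},
#'   \code{length_um}, \code{width_um}, \code{tip0}, \code{tip1},
#'   \code{pole0}, \code{pole1} (px coords), \code{volume_um3},
#'   \code{pixel_size_um}.
#' @export
fit_axis <- function(pixels, pixel_size_um, cell_id = NA_integer_) {
  pixels <- as.matrix(pixels)
  if (ncol(pixels) != 2L) stop("pixels must be a (row, col) matrix")
  n <- nrow(pixels)
  if (n < 20L) stop("cell has fewer than 20 pixels")
  if (!single_component(pixels)) stop("cell mask is not a single connected component")

  ctr <- colMeans(pixels)
  cen <- sweep(pixels, 2, ctr)
  cv <- crossprod(cen) / n
  eg <- eigen(cv, symmetric = TRUE)
  u <- eg$vectors[, 1]
  w <- eg$vectors[, 2]

  tu <- cen %*% u
  tw <- cen %*% w
  L_px <- diff(range(tu)) + 1
  d_px <- diff(range(tw)) + 1
  if (L_px < d_px) {  # eigenvalue near-ties can swap axes for discs
    tmp <- u; u <- w; w <- tmp
    tmp <- tu; tu <- tw; tw <- tmp
    tmp <- L_px; L_px <- d_px; d_px <- tmp
  }

  tip_a <- ctr + (min(tu) - 0.5) * u
  tip_b <- ctr + (max(tu) + 0.5) * u
  # orientation convention: tip0 has the smaller (row, col) lexicographically
  if (tip_b[1] < tip_a[1] ||
      (tip_b[1] == tip_a[1] && tip_b[2] < tip_a[2])) {
    tmp <- tip_a; tip_a <- tip_b; tip_b <- tmp
  }
  axis_dir <- (tip_b - tip_a) / sqrt(sum((tip_b - tip_a)^2))

  length_um <- L_px * pixel_size_um
  width_um <- d_px * pixel_size_um
  pole0 <- tip_a + d_px / 2 * axis_dir
  pole1 <- tip_b - d_px / 2 * axis_dir

  structure(list(
    cell_id = cell_id,
    pixels = pixels,
    n_pixels = n,
    centroid = ctr,
    axis = axis_dir,
    angle_deg = atan2(axis_dir[2], axis_dir[1]) * 180 / pi,
    length_um = length_um,
    width_um = width_um,
    tip0 = tip_a,
    tip1 = tip_b,
    pole0 = pole0,
    pole1 = pole1,
    volume_um3 = spherocylinder_volume(length_um, width_um),
    pixel_size_um = pixel_size_um
  ), class = "cell_geometry")
}

# connected-component check on the pixel set (EBImage labeling over the
# bounding box)
single_component <- function(pixels) {
  r0 <- min(pixels[, 1]); c0 <- min(pixels[, 2])
  m <- matrix(0L, max(pixels[, 1]) - r0 + 1L, max(pixels[, 2]) - c0 + 1L)
  m[cbind(pixels[, 1] - r0 + 1L, pixels[, 2] - c0 + 1L)] <- 1L
  max(EBImage::bwlabel(m)) == 1
}

#' @export
print.cell_geometry <- function(x, ...) {
  cat(sprintf(
    "<cell_geometry> id %s: L = %.2f um, d = %.2f um, V = %.3f um^3, %d px, angle %.1f deg\n",
    x$cell_id, x$length_um, x$width_um, x$volume_um3, x$n_pixels,
    x$angle_deg))
  invisible(x)
}

#' Axial fraction of a point within a cell
#'
#' Normalized position along the cell's long axis: 0 at \code{tip0}, 1 at
#' \code{tip1} (tip-to-tip, i.e. over the full length L including the
#' hemispherical caps). Points projecting beyond a tip — as a PSF-blurred
#' spot maximum can — are clamped to \[0, 1\].
#'
#' @param point numeric length-2 (row, col), or an n x 2 matrix of points.
#' @param cell a [fit_axis()] \code{cell_geometry}.
#' @return axial fraction(s) in \[0, 1\].
#' @export
axial_fraction <- function(point, cell) {
  stopifnot(inherits(cell, "cell_geometry"))
  L_px <- cell$length_um / cell$pixel_size_um
  if (L_px <= 0) stop("degenerate cell: zero length")
  p <- if (is.matrix(point)) point else matrix(point, ncol = 2)
  s <- ((p[, 1] - cell$tip0[1]) * cell$axis[1] +
        (p[, 2] - cell$tip0[2]) * cell$axis[2]) / L_px
  clamp01(as.numeric(s))
}

#' Extract cell geometries from an integer-labeled mask
#'
#' Runs [fit_axis()] on every positive label of the mask. Cells that fail
#' the geometry preconditions (fewer than 20 pixels, disconnected) are
#' excluded and reported rather than aborting the field.
#'
#' @param mask integer matrix; 0 = background, positive integers = cell
#'   labels.
#' @param pixel_size_um pixel size, um/px.
#' @return list with \code{cells} (named list of \code{cell_geometry}) and
#'   \code{excluded} (data.frame of cell_id + reason).
#' @export
mask_geometries <- function(mask, pixel_size_um) {
  ids <- sort(unique(as.integer(mask[mask > 0])))
  cells <- list()
  excl <- list()
  for (id in ids) {
    px <- which(mask == id, arr.ind = TRUE)
    colnames(px) <- c("row", "col")
    g <- tryCatch(fit_axis(px, pixel_size_um, cell_id = id),
                  error = function(e) conditionMessage(e))
    if (inherits(g, "cell_geometry")) {
      cells[[as.character(id)]] <- g
    } else {
      excl[[length(excl) + 1L]] <- data.frame(cell_id = id, reason = g)
    }
  }
  excluded <- if (length(excl)) do.call(rbind, excl) else
    data.frame(cell_id = integer(), reason = character())
  list(cells = cells, excluded = excluded)
}

#' Tabulate a list of cell geometries
#'
#' @param cells list of \code{cell_geometry} objects.
#' @return data.frame with one row per cell (id, n_pixels, L, d, angle,
#'   volume, tip and pole coordinates).
#' @export
geometry_table <- function(cells) {
  if (!length(cells)) {
    return(data.frame(cell_id = integer(), n_pixels = integer(),
                      length_um = numeric(), width_um = numeric(),
                      angle_deg = numeric(), volume_um3 = numeric(),
                      tip0_row = numeric(), tip0_col = numeric(),
                      tip1_row = numeric(), tip1_col = numeric()))
  }
  do.call(rbind, lapply(cells, function(g) data.frame(
    cell_id = g$cell_id, n_pixels = g$n_pixels,
    length_um = g$length_um, width_um = g$width_um,
    angle_deg = g$angle_deg, volume_um3 = g$volume_um3,
    tip0_row = g$tip0[1], tip0_col = g$tip0[2],
    tip1_row = g$tip1[1], tip1_col = g$tip1[2],
    row.names = NULL)))
}
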