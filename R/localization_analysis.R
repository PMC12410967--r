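# Three-zone axial classification and cluster-flagellum colocalization.
# The cell length is partitioned into: two precise-polar caps of 10% each,
# a central mid-cell domain of 50%, and the remaining 15% on each side as
# near-polar.

zone_levels <- c("precise_polar", "near_polar", "mid_cell")

#' Classify an axial fraction into the three-zone partition
#'
#' Zones over the axial fraction s: precise-polar for s in [0, 0.10] or
#' [0.90, 1]; mid-cell for s in [0.25, 0.75]; near-polar otherwise.
#' Boundary ownership is fixed so each boundary belongs to the zone nearer
#' its own side's extreme (0.10/0.90 are precise-polar, 0.25/0.75 are
#' mid-cell); boundary hits are measure-zero in practice but must be
#' deterministic.
#'
#' @param axial_s numeric vector of axial fractions in \[0, 1\].
#' @return factor with levels precise_polar, near_polar, mid_cell.
#' @export
#' @examples
#' classify_zone(c(0.05, 0.2, 0.5, 0.97))
classify_zone <- function(axial_s) {
  if (any(!is.finite(axial_s)) || any(axial_s < 0) || any(axial_s > 1)) {
    stop("axial_s must lie in [0, 1]")
  }
  z <- ifelse(axial_s <= 0.10 | axial_s >= 0.90, "precise_polar",
              ifelse(axial_s >= 0.25 & axial_s <= 0.75, "mid_cell",
                     "near_polar"))
  factor(z, levels = zone_levels)
}

#' Zone counts and proportions of a set of foci
#'
#' @param foci either a numeric vector of axial fractions or a data.frame
#'   with an \code{axial_s} column (conventionally restricted to obvious
#'   foci; rows with \code{obvious == FALSE} are dropped when present).
#' @return list with \code{counts}, \code{proportions} (both named
#'   precise_polar / near_polar / mid_cell), \code{n} and \code{empty}.
#' @export
zone_proportions <- function(foci) {
  s <- if (is.data.frame(foci)) {
    if ("obvious" %in% names(foci)) foci <- foci[foci$obvious, , drop = FALSE]
    foci$axial_s
  } else foci
  if (!length(s)) {
    counts <- stats::setNames(rep(0L, 3), zone_levels)
    return(list(counts = counts,
                proportions = stats::setNames(rep(NA_real_, 3), zone_levels),
                n = 0L, empty = TRUE))
  }
  counts <- table(classify_zone(s))
  list(counts = stats::setNames(as.integer(counts), names(counts)),
       proportions = stats::setNames(as.numeric(counts) / length(s),
                                     names(counts)),
       n = length(s), empty = FALSE)
}

#' Cluster-flagellum colocalization of one cell
#'
#' Distance-based: the two foci colocalize when their centers are within
#' \code{threshold_um} (default 0.5 um, roughly the PSF scale below which
#' two blurred point sources merge visually). Distance-based rather than
#' pole-based, so that non-polar (flhF-null-like) foci can still be scored
#' as colocalized; whether both foci sit nearest the same cell tip is
#' reported separately as \code{same_pole}.
#'
#' @param cluster,flagellum one-row focus data.frames from
#'   [detect_focus()], or NULL / zero-row when the focus is missing (the
#'   result is then flagged not evaluable).
#' @param cell the \code{cell_geometry} both foci belong to.
#' @param threshold_um colocalization distance threshold, um.
#' @return one-row data.frame: cell_id, distance_um, same_pole,
#'   colocalized, evaluable.
#' @export
colocalize <- function(cluster, flagellum, cell, threshold_um = 0.5) {
  stopifnot(inherits(cell, "cell_geometry"))
  missing_focus <- function(f) is.null(f) || !nrow(f)
  if (missing_focus(cluster) || missing_focus(flagellum)) {
    return(data.frame(cell_id = cell$cell_id, distance_um = NA_real_,
                      same_pole = NA, colocalized = NA, evaluable = FALSE))
  }
  p1 <- c(cluster$row[1], cluster$col[1])
  p2 <- c(flagellum$row[1], flagellum$col[1])
  dist_um <- sqrt(sum((p1 - p2)^2)) * cell$pixel_size_um
  nearest_tip <- function(p) {
    d0 <- sum((p - cell$tip0)^2)
    d1 <- sum((p - cell$tip1)^2)
    if (d0 <= d1) 0L else 1L
  }
  data.frame(cell_id = cell$cell_id,
             distance_um = dist_um,
             same_pole = nearest_tip(p1) == nearest_tip(p2),
             colocalized = dist_um <= threshold_um,
             evaluable = TRUE)
}

#' Colocalization across a field
#'
#' Pairs each cell's rank-1 obvious cluster focus with the nearest obvious
#' flagellum focus of that cell (any rank): pre-division cells carry both
#' structures at both poles, and the two channels' global maxima need not
#' pick the same pole. Cells missing either focus are reported as not
#' evaluable and excluded from the rate.
#'
#' @param cluster_foci,flagellum_foci data.frames from [detect_foci()].
#' @param cells list of \code{cell_geometry}.
#' @param threshold_um distance threshold, um.
#' @return list with \code{per_cell} (data.frame) and \code{rate}
#'   (fraction colocalized among evaluable cells; NA if none evaluable).
#' @export
colocalization_summary <- function(cluster_foci, flagellum_foci, cells,
                                   threshold_um = 0.5) {
  pick <- function(foci, id, near = NULL) {
    f <- foci[foci$cell_id == id & foci$obvious, , drop = FALSE]
    if (!nrow(f)) return(NULL)
    if (is.null(near)) return(f[f$rank == 1L, , drop = FALSE][1, , drop = FALSE])
    d2 <- (f$row - near$row[1])^2 + (f$col - near$col[1])^2
    f[which.min(d2), , drop = FALSE]
  }
  rows <- lapply(cells, function(cell) {
    cl <- pick(cluster_foci, cell$cell_id)
    colocalize(cl, pick(flagellum_foci, cell$cell_id, near = cl),
               cell, threshold_um)
  })
  per_cell <- if (length(rows)) do.call(rbind, rows) else
    data.frame(cell_id = integer(), distance_um = numeric(),
               same_pole = logical(), colocalized = logical(),
               evaluable = logical())
  ev <- per_cell[per_cell$evaluable, , drop = FALSE]
  list(per_cell = per_cell,
       rate = if (nrow(ev)) mean(ev$colocalized) else NA_real_,
       n_evaluable = nrow(ev))
}
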