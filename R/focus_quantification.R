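# Focus detection and the 3x3-pixel intensity rule: the intensity maximum
# inside the cell mask is taken as the focus center and the final focus
# intensity is the mean of the 3x3 pixel matrix around it.

# mean of the 3x3 window centered at (r, c); windows at the image border
# average only the available pixels (no padding is invented)
mean_3x3 <- function(img, r, c) {
  rows <- max(1L, r - 1L):min(nrow(img), r + 1L)
  cols <- max(1L, c - 1L):min(ncol(img), c + 1L)
  mean(img[rows, cols, drop = FALSE])
}

#' Detect the brightest focus of one cell in one channel
#'
#' The focus center is the argmax of the channel over the cell's mask (ties
#' broken deterministically by the smallest (row, col) lexicographic
#' coordinate); its intensity is the mean over the 3x3 window centered
#' there, clipped at the image border. The SNR is that 3x3 mean divided by
#' the median intensity over the cell mask.
#'
#' @param image_channel numeric matrix, one fluorescence channel.
#' @param cell a \code{cell_geometry}.
#' @param channel label carried into the output ("cluster" or "flagellum").
#' @param pixels optional subset of the cell's pixels to search (used for
#'   the second, opposite-half pass on pre-division cells); SNR is always
#'   computed against the whole-cell median.
#' @return one-row data.frame: cell_id, channel, row, col, intensity_3x3,
#'   cell_median, snr, axial_s, edge_window.
#' @export
detect_focus <- function(image_channel, cell, channel = "cluster",
                         pixels = NULL) {
  stopifnot(inherits(cell, "cell_geometry"))
  if (cell$n_pixels < 20L) stop("cell has fewer than 20 pixels")
  search <- if (is.null(pixels)) cell$pixels else pixels
  ord <- order(search[, 1], search[, 2])
  search <- search[ord, , drop = FALSE]
  vals <- image_channel[search]
  i <- which.max(vals)  # first max in lexicographic order
  ctr <- as.integer(search[i, ])
  cell_median <- stats::median(image_channel[cell$pixels])
  i3 <- mean_3x3(image_channel, ctr[1], ctr[2])
  edge <- ctr[1] == 1L || ctr[2] == 1L ||
    ctr[1] == nrow(image_channel) || ctr[2] == ncol(image_channel)
  data.frame(
    cell_id = cell$cell_id,
    channel = channel,
    row = ctr[1],
    col = ctr[2],
    intensity_3x3 = i3,
    cell_median = cell_median,
    snr = if (cell_median > 0) i3 / cell_median else Inf,
    axial_s = axial_fraction(c(ctr[1], ctr[2]), cell),
    edge_window = edge
  )
}

#' Call "obvious" foci
#'
#' A focus counts as an obvious cluster when both its SNR (3x3 mean over
#' cell median) reaches \code{threshold_snr} and its absolute contrast
#' (3x3 mean minus cell median) reaches \code{min_abs} counts. The dual
#' criterion makes the qualitative notion of an "obvious" focus explicit
#' and is robust both to dim cells (SNR) and to near-zero medians
#' (absolute contrast).
#'
#' @param foci data.frame from [detect_focus()] (any number of rows).
#' @param threshold_snr SNR ratio threshold (default 2).
#' @param min_abs absolute contrast threshold in counts; conventionally
#'   3x the image noise SD (see [estimate_noise_sd()]).
#' @return the input with a logical \code{obvious} column.
#' @export
call_obvious <- function(foci, threshold_snr = 2, min_abs = 0) {
  if (!nrow(foci)) {
    foci$obvious <- logical(0)
    return(foci)
  }
  if (any(!is.finite(foci$intensity_3x3)) || any(!is.finite(foci$cell_median))) {
    stop("non-finite focus intensities")
  }
  if (!is.finite(threshold_snr) || !is.finite(min_abs)) {
    stop("non-finite thresholds")
  }
  foci$obvious <- foci$snr >= threshold_snr &
    (foci$intensity_3x3 - foci$cell_median) >= min_abs
  foci
}

#' Estimate the image noise SD from extracellular pixels
#'
#' Robust (MAD-based) SD of pixels outside a 3 px dilation of all cell
#' footprints; used to set the default absolute-contrast threshold for
#' obvious-cluster calls.
#'
#' @param image_channel numeric matrix.
#' @param mask integer-labeled cell mask.
#' @param dilate_px dilation radius separating cells from background.
#' @return noise SD in counts.
#' @export
estimate_noise_sd <- function(image_channel, mask, dilate_px = 3L) {
  bg <- background_pixels(image_channel, mask, dilate_px)
  stats::mad(bg)
}

#' Detect and score foci for every cell in a field
#'
#' One focus per cell per channel (global argmax). Pre-division cells with
#' foci at both poles are handled by a second pass: the axial half of the
#' mask not containing the first focus is searched for its own maximum,
#' which is kept only when it independently passes the obvious criterion
#' (rank 2 in the output).
#'
#' @param image_channel numeric matrix.
#' @param cells list of \code{cell_geometry}.
#' @param channel label ("cluster" or "flagellum").
#' @param threshold_snr,min_abs thresholds for [call_obvious()].
#' @param second_pass search the opposite mask half for a second (bipolar)
#'   focus?
#' @return data.frame of foci with \code{obvious} and \code{rank} columns.
#' @export
detect_foci <- function(image_channel, cells, channel = "cluster",
                        threshold_snr = 2, min_abs = 0,
                        second_pass = TRUE) {
  out <- list()
  for (cell in cells) {
    f1 <- detect_focus(image_channel, cell, channel)
    f1 <- call_obvious(f1, threshold_snr, min_abs)
    f1$rank <- 1L
    out[[length(out) + 1L]] <- f1
    if (second_pass && f1$obvious) {
      s_px <- axial_fraction(cell$pixels, cell)
      other <- if (f1$axial_s <= 0.5) cell$pixels[s_px > 0.5, , drop = FALSE]
               else cell$pixels[s_px <= 0.5, , drop = FALSE]
      if (nrow(other) >= 9L) {
        f2 <- detect_focus(image_channel, cell, channel, pixels = other)
        f2 <- call_obvious(f2, threshold_snr, min_abs)
        if (f2$obvious) {
          f2$rank <- 2L
          out[[length(out) + 1L]] <- f2
        }
      }
    }
  }
  if (!length(out)) {
    return(data.frame(cell_id = integer(), channel = character(),
                      row = integer(), col = integer(),
                      intensity_3x3 = numeric(), cell_median = numeric(),
                      snr = numeric(), axial_s = numeric(),
                      edge_window = logical(), obvious = logical(),
                      rank = integer()))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
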