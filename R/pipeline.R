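# Orchestration: field analysis (geometry -> foci -> localization ->
# reporter), strain-level aggregation, and the file-based simulate/analyze
# entry points behind the command-line interface.

#' Analysis configuration
#'
#' @param pixel_size_um physical pixel size, um/px.
#' @param channels named integer vector mapping channel roles to image
#'   planes; roles \code{cluster} and \code{reporter} are required for the
#'   respective analyses, \code{flagellum} is optional.
#' @param threshold_snr SNR threshold for obvious-cluster calls.
#' @param min_abs absolute contrast threshold in counts; \code{NULL}
#'   (default) means 3x the estimated image noise SD.
#' @param coloc_threshold_um colocalization distance threshold, um.
#' @param reference_strain strain name used as reference in comparisons.
#' @param seed integer seed recorded in outputs (and used by any seeded
#'   downstream statistics).
#' @return object of class \code{run_config}.
#' @export
run_config <- function(pixel_size_um = 0.065,
                       channels = c(cluster = 1L, flagellum = 2L,
                                    reporter = 3L),
                       threshold_snr = 2,
                       min_abs = NULL,
                       coloc_threshold_um = 0.5,
                       reference_strain = "wildtype",
                       seed = 1L) {
  if (pixel_size_um <= 0) stop("pixel_size_um must be positive")
  if (is.null(names(channels)) || !"cluster" %in% names(channels)) {
    stop("channels must be a named vector including at least 'cluster'")
  }
  structure(list(pixel_size_um = pixel_size_um,
                 channels = channels,
                 threshold_snr = threshold_snr,
                 min_abs = min_abs,
                 coloc_threshold_um = coloc_threshold_um,
                 reference_strain = reference_strain,
                 seed = as.integer(seed)),
            class = "run_config")
}

get_channel <- function(image, channels, role) {
  if (!role %in% names(channels)) return(NULL)
  idx <- channels[[role]]
  if (length(dim(image)) == 2L) {
    if (idx != 1L) stop(sprintf("channel '%s' maps to plane %d but the image has a single plane", role, idx))
    return(image)
  }
  if (idx > dim(image)[3]) {
    stop(sprintf("channel '%s' maps to plane %d but the image has %d planes",
                 role, idx, dim(image)[3]))
  }
  image[, , idx]
}

#' Analyze one field (image + labeled mask)
#'
#' Extracts per-cell geometry from the mask, detects and scores foci in the
#' cluster (and, when mapped, flagellum) channel, classifies axial zones,
#' scores cluster-flagellum colocalization, and quantifies the
#' volume-normalized reporter signal. When a ground-truth table is supplied
#' its \code{strain} column is joined onto every output.
#'
#' @param image integer/numeric array (rows x cols x channels) or matrix.
#' @param mask integer-labeled cell mask, same spatial dimensions.
#' @param config a [run_config()].
#' @param truth optional ground-truth data.frame (simulator output) with
#'   \code{cell_id} and \code{strain} columns.
#' @return list of class \code{field_analysis}: \code{cells},
#'   \code{foci}, \code{coloc}, \code{reporter} (data.frames),
#'   \code{excluded}, \code{background}, \code{noise_sd}, \code{min_abs},
#'   \code{config}.
#' @export
analyze_field <- function(image, mask, config = run_config(), truth = NULL) {
  sp_img <- if (length(dim(image)) == 3L) dim(image)[1:2] else dim(image)
  if (!identical(as.integer(sp_img), as.integer(dim(mask)))) {
    stop(sprintf("image/mask shape mismatch: image %s vs mask %s",
                 paste(sp_img, collapse = "x"),
                 paste(dim(mask), collapse = "x")))
  }
  geo <- mask_geometries(mask, config$pixel_size_um)
  cells <- geo$cells
  ch_cluster <- get_channel(image, config$channels, "cluster")
  ch_flag <- get_channel(image, config$channels, "flagellum")
  ch_rep <- get_channel(image, config$channels, "reporter")

  noise_sd <- estimate_noise_sd(ch_cluster, mask)
  min_abs <- config$min_abs %||% (3 * noise_sd)

  foci_cluster <- detect_foci(ch_cluster, cells, channel = "cluster",
                              threshold_snr = config$threshold_snr,
                              min_abs = min_abs)
  foci_flag <- if (!is.null(ch_flag)) {
    detect_foci(ch_flag, cells, channel = "flagellum",
                threshold_snr = config$threshold_snr, min_abs = min_abs)
  } else NULL
  foci <- rbind(foci_cluster, foci_flag)

  coloc <- if (!is.null(foci_flag)) {
    colocalization_summary(foci_cluster, foci_flag, cells,
                           config$coloc_threshold_um)
  } else list(per_cell = NULL, rate = NA_real_, n_evaluable = 0L)

  background <- NA_real_
  reporter <- NULL
  if (!is.null(ch_rep) && length(cells)) {
    background <- estimate_background(ch_rep, mask)
    reporter <- measure_cells(ch_rep, cells, background)
  }

  cell_tab <- geometry_table(cells)
  if (nrow(cell_tab)) {
    obv <- foci_cluster[foci_cluster$rank == 1L, c("cell_id", "obvious")]
    cell_tab$obvious_cluster <- obv$obvious[match(cell_tab$cell_id,
                                                  obv$cell_id)]
  }
  out <- list(cells = cell_tab, foci = foci, coloc = coloc$per_cell,
              coloc_rate = coloc$rate, reporter = reporter,
              excluded = geo$excluded, background = background,
              noise_sd = noise_sd, min_abs = min_abs, config = config)
  if (!is.null(truth) && nrow(truth)) {
    add_strain <- function(df) {
      if (is.null(df) || !nrow(df)) return(df)
      df$strain <- truth$strain[match(df$cell_id, truth$cell_id)]
      df
    }
    out$cells <- add_strain(out$cells)
    out$foci <- add_strain(out$foci)
    out$coloc <- add_strain(out$coloc)
    out$reporter <- add_strain(out$reporter)
  }
  class(out) <- "field_analysis"
  out
}

#' Analyze several fields and pool the per-cell tables
#'
#' @param fields list of fields, each a list with \code{image}, \code{mask}
#'   and optionally \code{truth} (as from [simulate_fields()] or
#'   [read_field()]).
#' @param config a [run_config()].
#' @return list of pooled data.frames (\code{cells}, \code{foci},
#'   \code{coloc}, \code{reporter}, \code{excluded}) with a \code{field}
#'   column, plus per-field \code{background}/\code{noise_sd} vectors.
#' @export
analyze_fields <- function(fields, config = run_config()) {
  pooled <- list(cells = list(), foci = list(), coloc = list(),
                 reporter = list(), excluded = list())
  background <- noise_sd <- numeric(length(fields))
  for (k in seq_along(fields)) {
    f <- fields[[k]]
    a <- analyze_field(f$image, f$mask, config, truth = f$truth)
    for (nm in names(pooled)) {
      df <- a[[nm]]
      if (!is.null(df) && nrow(df)) {
        df$field <- k
        pooled[[nm]][[length(pooled[[nm]]) + 1L]] <- df
      }
    }
    background[k] <- a$background
    noise_sd[k] <- a$noise_sd
  }
  res <- lapply(pooled, function(lst) {
    if (length(lst)) do.call(rbind, lst) else NULL
  })
  res$background <- background
  res$noise_sd <- noise_sd
  res$config <- config
  res
}

#' Strain-level summary of a pooled analysis
#'
#' For each strain: cells examined, cells with an obvious cluster
#' (proportion + Wilson 95% CI), zone counts of obvious cluster foci, and
#' the colocalization rate among evaluable cells.
#'
#' @param analysis pooled tables from [analyze_fields()] (or a compatible
#'   list with \code{cells}, \code{foci}, \code{coloc}).
#' @return data.frame, one row per strain.
#' @export
summarize_strains <- function(analysis) {
  cells <- analysis$cells
  if (is.null(cells) || !nrow(cells)) {
    warning("no cells to summarize")
    return(data.frame(strain = character(), n = integer(), k = integer(),
                      proportion = numeric(), percent = numeric(),
                      ci_lower = numeric(), ci_upper = numeric(),
                      zone_precise_polar = integer(),
                      zone_near_polar = integer(),
                      zone_mid_cell = integer(),
                      coloc_rate = numeric(), n_evaluable = integer()))
  }
  if (is.null(cells$strain)) cells$strain <- "all"
  foci <- analysis$foci
  if (!is.null(foci) && is.null(foci$strain)) foci$strain <- "all"
  coloc <- analysis$coloc
  if (!is.null(coloc) && is.null(coloc$strain)) coloc$strain <- "all"

  rows <- lapply(split(cells, cells$strain), function(cs) {
    st <- cs$strain[1]
    n <- nrow(cs)
    k <- sum(cs$obvious_cluster, na.rm = TRUE)
    ps <- proportion_summary(k, n)
    fs <- if (!is.null(foci)) {
      foci[foci$strain == st & foci$channel == "cluster" & foci$obvious &
             foci$rank == 1L, , drop = FALSE]
    } else NULL
    zp <- zone_proportions(if (is.null(fs)) numeric(0) else fs$axial_s)
    cl <- if (!is.null(coloc)) {
      coloc[coloc$strain == st & coloc$evaluable, , drop = FALSE]
    } else NULL
    data.frame(strain = st, n = n, k = k,
               proportion = ps$proportion, percent = ps$percent,
               ci_lower = ps$ci_lower, ci_upper = ps$ci_upper,
               zone_precise_polar = zp$counts[["precise_polar"]],
               zone_near_polar = zp$counts[["near_polar"]],
               zone_mid_cell = zp$counts[["mid_cell"]],
               coloc_rate = if (!is.null(cl) && nrow(cl)) mean(cl$colocalized)
                            else NA_real_,
               n_evaluable = if (!is.null(cl)) nrow(cl) else 0L)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Pairwise comparison of strain proportions against a reference
#'
#' One row per non-reference strain: Fisher's exact p-value for the
#' obvious-cluster proportion against the reference strain, the
#' significance label, and the change in the proportion in both conventions
#' (percentage points and relative percent).
#'
#' @param summary data.frame from [summarize_strains()].
#' @param reference reference strain name.
#' @return data.frame of pairwise comparisons.
#' @export
compare_strains <- function(summary, reference) {
  if (!reference %in% summary$strain) {
    stop(sprintf("unknown reference strain '%s'; available: %s", reference,
                 paste(summary$strain, collapse = ", ")))
  }
  ref <- summary[summary$strain == reference, ][1, ]
  others <- summary[summary$strain != reference, , drop = FALSE]
  if (!nrow(others)) {
    warning("only the reference strain present; nothing to compare")
    return(data.frame(strain = character(), reference = character(),
                      percent = numeric(), reference_percent = numeric(),
                      delta_pp = numeric(), delta_relative_percent = numeric(),
                      p_value = numeric(), p_ztest = numeric(),
                      label = character()))
  }
  rows <- lapply(seq_len(nrow(others)), function(i) {
    s <- others[i, ]
    cmp <- compare_two_proportions(s$k, s$n, ref$k, ref$n)
    pc <- percent_change(s$proportion, ref$proportion)
    data.frame(strain = s$strain, reference = reference,
               percent = s$percent, reference_percent = ref$percent,
               delta_pp = pc$absolute_pp,
               delta_relative_percent = pc$relative_percent,
               p_value = cmp$p_value, p_ztest = cmp$p_ztest,
               label = cmp$label)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Simulate fields and write them to disk
#'
#' Writes \code{field_<k>_img.tif}, \code{field_<k>_mask.tif},
#' \code{field_<k>_truth.csv} and \code{sim_config.yaml} to \code{out_dir}.
#'
#' @param config a [sim_config()].
#' @param out_dir output directory.
#' @param n_fields number of fields.
#' @return the field list, invisibly.
#' @export
run_simulation <- function(config, out_dir, n_fields = 1L) {
  fields <- simulate_fields(config, n_fields)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  for (k in seq_along(fields)) {
    write_field(fields[[k]], out_dir, sprintf("field_%d", k))
  }
  write_sim_config(config, file.path(out_dir, "sim_config.yaml"))
  invisible(fields)
}

#' Run the full analysis on a directory of fields
#'
#' Reads every \code{field_*_img.tif} / \code{field_*_mask.tif} pair (plus
#' truth CSVs when present), analyzes them, and writes per-cell CSV tables,
#' a strain summary + comparison (CSV and JSON) and a run log recording the
#' package version, seed and every threshold used.
#'
#' @param input_dir directory with fields (as written by
#'   [run_simulation()]).
#' @param out_dir output directory.
#' @param config a [run_config()].
#' @return list with the pooled analysis, \code{summary} and
#'   \code{comparison} data.frames, invisibly.
#' @export
run_analysis <- function(input_dir, out_dir, config = run_config()) {
  imgs <- sort(list.files(input_dir, pattern = "^field_.*_img\\.tif$"))
  if (!length(imgs)) stop("no field_*_img.tif files found in ", input_dir)
  prefixes <- sub("_img\\.tif$", "", imgs)
  fields <- lapply(prefixes, function(p) read_field(input_dir, p))
  analysis <- analyze_fields(fields, config)
  summary <- summarize_strains(analysis)
  comparison <- if (nrow(summary) > 1 &&
                    config$reference_strain %in% summary$strain) {
    compare_strains(summary, config$reference_strain)
  } else NULL

  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  wr <- function(df, name) {
    if (!is.null(df) && nrow(df)) {
      utils::write.csv(df, file.path(out_dir, name), row.names = FALSE)
    }
  }
  wr(analysis$cells, "cells.csv")
  wr(analysis$foci, "foci.csv")
  wr(analysis$coloc, "colocalization.csv")
  wr(analysis$reporter, "reporter.csv")
  wr(summary, "strain_summary.csv")
  wr(comparison, "strain_comparison.csv")

  summary_json <- list(
    package_version = as.character(utils::packageVersion("poleloc")),
    seed = config$seed,
    thresholds = list(snr = config$threshold_snr,
                      min_abs = config$min_abs %||% "3 x noise SD (per field)",
                      coloc_um = config$coloc_threshold_um,
                      zone_boundaries = c(0.10, 0.25, 0.75, 0.90)),
    background = analysis$background,
    noise_sd = analysis$noise_sd,
    strains = summary,
    comparison = comparison
  )
  jsonlite::write_json(summary_json, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  log_lines <- c(
    sprintf("poleloc %s", utils::packageVersion("poleloc")),
    sprintf("run at %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
    sprintf("input: %s (%d fields)", input_dir, length(fields)),
    sprintf("pixel size: %g um/px", config$pixel_size_um),
    sprintf("seed: %d", config$seed),
    sprintf("threshold_snr: %g", config$threshold_snr),
    sprintf("min_abs: %s", if (is.null(config$min_abs))
      "auto (3 x noise SD)" else as.character(config$min_abs)),
    sprintf("coloc threshold: %g um", config$coloc_threshold_um),
    "zone boundaries (axial fraction): 0.10 / 0.25 / 0.75 / 0.90"
  )
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))

  if (is.null(analysis$cells) || !nrow(analysis$cells)) {
    warning("no cells found in any field; summary is empty")
  }
  invisible(list(analysis = analysis, summary = summary,
                 comparison = comparison))
}
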