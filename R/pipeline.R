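#' Run the full polarity analysis on one cell
#'
#' Detects the cell once on the detection channel, then per channel:
#' background correction and mean normalization, charge decomposition,
#' charge centers, normalized dipole moment, constriction and signal
#' summary; per channel pair: distance and angle between positive charge
#' centers and the voxel Pearson correlation.  When a DAPI channel is
#' named, the nucleus position metric `d_nucleus` is computed from its
#' negative charge center.
#'
#' @param record a [cell_record()].
#' @param detection detection channel label or `"sum"` (default).
#' @param dapi optional label of the nuclear-stain channel.
#' @param config a [normalization_config()].
#' @param n_bins Otsu histogram bins.
#' @return An object of class `cell_analysis`: fields `cell_id`, `mask`,
#'   `geometry`, `channels` (per channel: `corrected`, `field`, `dipole`,
#'   `constriction`, `summary`), `d_nucleus`, and two flat data.frames
#'   `channel_table` (one row per channel) and `pair_table` (one row per
#'   unordered channel pair).
#' @export
analyze_cell <- function(record, detection = "sum", dapi = NULL,
                         config = normalization_config(), n_bins = 256L) {
  stopifnot(inherits(record, "cell_record"))
  if (!is.null(dapi) && !dapi %in% names(record$channels))
    stop("DAPI channel '", dapi, "' not present", call. = FALSE)
  mask <- detect_cell(record, detection = detection, n_bins = n_bins)
  geometry <- cell_geometry(mask)
  channels <- lapply(record$channels, function(st) {
    corrected <- background_correct_and_normalize(
      st, mask, clamp_negative = config$clamp_negative)
    field <- compute_charges(corrected)
    dipole <- normalize_dipole(field, geometry, config = config)
    cons <- if (!dipole$degenerate)
      constriction(field, dipole$R_plus, dipole$R_minus, geometry$d_max)
    else NULL
    list(corrected = corrected, field = field, dipole = dipole,
         constriction = cons, summary = channel_summary(corrected, field))
  })
  d_nucleus <- NA_real_
  if (!is.null(dapi) && !channels[[dapi]]$dipole$degenerate)
    d_nucleus <- nucleus_position(channels[[dapi]]$dipole, geometry$M,
                                  geometry$d_max)
  channel_table <- do.call(rbind, lapply(names(channels), function(nm) {
    ch <- channels[[nm]]
    dp <- ch$dipole
    cs <- ch$constriction
    data.frame(
      cell_id = record$cell_id, channel = nm,
      P_n = dp$P_n, q_n1 = dp$q_n1, R_n1 = dp$R_n1, P_raw = dp$P_raw,
      q_plus = dp$q_plus, degenerate = dp$degenerate,
      Rp_z = dp$R_plus[["z"]], Rp_y = dp$R_plus[["y"]], Rp_x = dp$R_plus[["x"]],
      Rm_z = dp$R_minus[["z"]], Rm_y = dp$R_minus[["y"]], Rm_x = dp$R_minus[["x"]],
      M_z = geometry$M[["z"]], M_y = geometry$M[["y"]], M_x = geometry$M[["x"]],
      d_max = geometry$d_max, cell_volume = geometry$volume,
      n_cell_voxels = geometry$n_cell_voxels,
      amount = ch$summary$amount, signal_volume = ch$summary$signal_volume,
      spread_plus = if (is.null(cs)) NA_real_ else cs$spread_plus,
      spread_minus = if (is.null(cs)) NA_real_ else cs$spread_minus,
      spread_plus_norm = if (is.null(cs)) NA_real_ else cs$spread_plus_norm,
      spread_minus_norm = if (is.null(cs)) NA_real_ else cs$spread_minus_norm,
      d_nucleus = if (!is.null(dapi) && nm == dapi) d_nucleus else NA_real_,
      stringsAsFactors = FALSE)
  }))
  pair_table <- NULL
  nms <- names(channels)
  if (length(nms) >= 2L) {
    prs <- t(combn(nms, 2L))
    pair_table <- do.call(rbind, lapply(seq_len(nrow(prs)), function(i) {
      a <- prs[i, 1L]; b <- prs[i, 2L]
      pg <- pair_geometry(channels[[a]]$dipole, channels[[b]]$dipole,
                          geometry$M)
      pv <- pearson_voxels(channels[[a]]$corrected, channels[[b]]$corrected)
      data.frame(cell_id = record$cell_id, channel_a = a, channel_b = b,
                 d = pg$d, alpha = pg$alpha, angle_defined = pg$angle_defined,
                 r_pearson = pv$r, p_pearson = pv$p, n_voxels = pv$n,
                 stringsAsFactors = FALSE)
    }))
  }
  rownames(channel_table) <- NULL
  if (!is.null(pair_table)) rownames(pair_table) <- NULL
  structure(list(cell_id = record$cell_id, mask = mask, geometry = geometry,
                 channels = channels, d_nucleus = d_nucleus,
                 channel_table = channel_table, pair_table = pair_table),
            class = "cell_analysis")
}

#' @export
print.cell_analysis <- function(x, ...) {
  cat(sprintf("<cell_analysis> '%s': %d channel(s), %d cell voxels, d_max = %.4g\n",
              x$cell_id, length(x$channels), x$geometry$n_cell_voxels,
              x$geometry$d_max))
  pn <- vapply(x$channels, function(ch) ch$dipole$P_n, numeric(1))
  cat("  P_n:", paste(sprintf("%s = %.4g", names(pn), pn), collapse = ", "), "\n")
  invisible(x)
}

#' Read a batch manifest
#'
#' A manifest is a TSV table with columns `cell_id`, `channel` and `path`
#' (one row per channel of each cell).
#'
#' @param path manifest path.
#' @return A data.frame.
#' @export
read_manifest <- function(path) {
  m <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("cell_id", "channel", "path")
  if (!all(need %in% names(m)))
    stop("manifest must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  m
}

#' Batch-process a manifest of single-cell TIFF sets
#'
#' Every cell in the manifest is assembled and analyzed; failures are
#' logged per cell and the run continues.  Optionally writes the two result
#' tables and a log to an output directory.
#'
#' @param manifest data.frame with columns `cell_id`, `channel`, `path`
#'   (see [read_manifest()]), or a path to such a TSV.
#' @param spacing,bit_depth acquisition geometry, shared by all cells.
#' @param detection,dapi,config,n_bins forwarded to [analyze_cell()].
#' @param out_dir optional output directory for `channels.<format>`,
#'   `pairs.<format>` and `run.log`.
#' @param format output table format (`"tsv"`, `"csv"` or `"json"`).
#' @param verbose emit one status message per cell.
#' @return list with `channels` and `pairs` (row-bound per-cell tables) and
#'   `errors` (data.frame of per-cell failures).
#' @export
run_batch <- function(manifest, spacing, bit_depth, detection = "sum",
                      dapi = NULL, config = normalization_config(),
                      n_bins = 256L, out_dir = NULL,
                      format = c("tsv", "csv", "json"), verbose = TRUE) {
  format <- match.arg(format)
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  need <- c("cell_id", "channel", "path")
  if (!is.data.frame(manifest) || !all(need %in% names(manifest)) ||
      nrow(manifest) == 0L)
    stop("manifest must be a non-empty data.frame with columns ",
         paste(need, collapse = ", "), call. = FALSE)
  log_lines <- character(0)
  say <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, line)
    if (verbose) message(line)
  }
  cells <- unique(manifest$cell_id)
  chan_tabs <- list(); pair_tabs <- list(); errors <- list()
  for (cid in cells) {
    rows <- manifest[manifest$cell_id == cid, ]
    res <- tryCatch({
      paths <- setNames(rows$path, rows$channel)
      rec <- assemble_cell(paths, spacing = spacing, bit_depth = bit_depth,
                           cell_id = cid)
      analyze_cell(rec, detection = detection, dapi = dapi, config = config,
                   n_bins = n_bins)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errors[[cid]] <- data.frame(cell_id = cid,
                                  message = conditionMessage(res),
                                  stringsAsFactors = FALSE)
      say("cell %s: ERROR - %s", cid, conditionMessage(res))
    } else {
      chan_tabs[[cid]] <- res$channel_table
      pair_tabs[[cid]] <- res$pair_table
      say("cell %s: ok (%d channels, %d cell voxels)", cid,
          length(res$channels), res$geometry$n_cell_voxels)
    }
  }
  out <- list(
    channels = if (length(chan_tabs)) do.call(rbind, unname(chan_tabs)) else NULL,
    pairs = if (length(pair_tabs)) do.call(rbind, unname(pair_tabs)) else NULL,
    errors = if (length(errors)) do.call(rbind, unname(errors))
             else data.frame(cell_id = character(0), message = character(0)))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!is.null(out$channels))
      write_results(out$channels, file.path(out_dir, paste0("channels.", format)),
                    format)
    if (!is.null(out$pairs))
      write_results(out$pairs, file.path(out_dir, paste0("pairs.", format)),
                    format)
    writeLines(log_lines, file.path(out_dir, "run.log"))
  }
  out
}

#' Compare a per-cell metric between two groups
#'
#' Two-sided Wilcoxon rank-sum comparison of one column of two result
#' tables (e.g. `P_n` of a young versus an old population), with group
#' medians and the common-language effect size.
#'
#' @param table_a,table_b data.frames both containing `metric`.
#' @param metric column name to compare.
#' @return list with `metric`, `median_a`, `median_b`, `n_a`, `n_b` and
#'   `test` (a [ranksum()] result).
#' @export
compare_groups <- function(table_a, table_b, metric) {
  for (tb in list(table_a, table_b))
    if (!metric %in% names(tb))
      stop("column '", metric, "' missing from a table", call. = FALSE)
  x <- table_a[[metric]]; x <- x[is.finite(x)]
  y <- table_b[[metric]]; y <- y[is.finite(y)]
  rs <- ranksum(x, y)
  list(metric = metric, median_a = median(x), median_b = median(y),
       n_a = length(x), n_b = length(y), test = rs)
}
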