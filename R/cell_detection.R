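#' Otsu threshold of an intensity sample
#'
#' Histogram-based Otsu threshold: intensities are binned into `n_bins`
#' equal-width bins over their range and the inter-bin cut maximizing the
#' between-class variance is selected.  The returned value is the upper edge
#' of the chosen bin, so `x > otsu_threshold(x)` splits the sample into the
#' two classes.  When several cuts maximize the criterion exactly (a plateau
#' across an empty histogram gap), the middle cut of the plateau is
#' returned, as in common Otsu implementations.
#'
#' @param x numeric vector (or array) of intensities with at least two
#'   distinct values.
#' @param n_bins number of histogram bins (default 256).
#' @return The threshold, a scalar strictly between `min(x)` and `max(x)`.
#' @examples
#' otsu_threshold(c(rep(10, 50), rep(200, 50)))
#' @export
otsu_threshold <- function(x, n_bins = 256L) {
  x <- as.numeric(x)
  x <- x[is.finite(x)]
  if (length(x) < 2L) stop("need at least 2 intensity values", call. = FALSE)
  mn <- min(x); mx <- max(x)
  if (mx <= mn)
    stop("constant intensities: no cell/background bimodality to threshold",
         call. = FALSE)
  n_bins <- as.integer(n_bins)
  if (n_bins < 2L) stop("`n_bins` must be >= 2", call. = FALSE)
  bin <- pmin(floor((x - mn) / (mx - mn) * n_bins) + 1L, n_bins)
  counts <- as.numeric(tabulate(bin, n_bins))
  mids <- mn + (seq_len(n_bins) - 0.5) * (mx - mn) / n_bins
  w0 <- cumsum(counts)
  m0 <- cumsum(counts * mids)
  n <- w0[n_bins]; m <- m0[n_bins]
  t <- seq_len(n_bins - 1L)
  w1 <- n - w0[t]
  valid <- w0[t] > 0 & w1 > 0
  bcv <- rep(-Inf, n_bins - 1L)
  mu0 <- m0[t][valid] / w0[t][valid]
  mu1 <- (m - m0[t][valid]) / w1[valid]
  bcv[valid] <- w0[t][valid] * w1[valid] * (mu0 - mu1)^2
  best <- mean(which(bcv == max(bcv)))
  mn + best * (mx - mn) / n_bins
}

#' Detect the cell mask of a single-cell crop
#'
#' The detection image (one channel, or the voxel-wise sum of all channels)
#' is Otsu-thresholded; the largest 26-connected above-threshold component
#' is kept, fully enclosed holes are filled, and the resulting boolean mask
#' is shared by all channels of the cell.
#'
#' @param record a [cell_record()].
#' @param detection a channel label, or `"sum"` (default) to detect on the
#'   sum of all channels.
#' @param n_bins histogram bins for [otsu_threshold()].
#' @return An object of class `cell_mask` with fields `mask` (logical
#'   array), `n_cell_voxels`, `detection_channel`, `threshold` and
#'   `spacing`.
#' @export
detect_cell <- function(record, detection = "sum", n_bins = 256L) {
  stopifnot(inherits(record, "cell_record"))
  if (identical(detection, "sum")) {
    img <- Reduce(`+`, lapply(record$channels, `[[`, "voxels"))
  } else {
    if (!detection %in% names(record$channels))
      stop("detection channel '", detection, "' not present", call. = FALSE)
    img <- record$channels[[detection]]$voxels
  }
  thr <- otsu_threshold(img, n_bins = n_bins)
  fg <- img > thr
  if (!any(fg))
    stop("no above-threshold voxels: cell not detectable", call. = FALSE)
  lc <- .label_components(fg, connectivity = 26L)
  keep <- which.max(lc$sizes)
  if (lc$n > 1L) {
    discarded <- sum(lc$sizes) - lc$sizes[keep]
    if (discarded >= max(8, 0.01 * lc$sizes[keep]))
      warning(sprintf(paste0("cell '%s': %d above-threshold component(s) ",
                             "(%d voxels) discarded, largest kept"),
                      record$cell_id, lc$n - 1L, discarded), call. = FALSE)
  }
  m <- .fill_holes(lc$labels == keep)
  structure(list(mask = m,
                 n_cell_voxels = sum(m),
                 detection_channel = if (identical(detection, "sum")) "sum" else detection,
                 threshold = thr,
                 spacing = record$channels[[1L]]$spacing),
            class = "cell_mask")
}

#' @export
print.cell_mask <- function(x, ...) {
  cat(sprintf("<cell_mask> %d cell voxels (detection: %s, Otsu threshold %.4g)\n",
              x$n_cell_voxels, x$detection_channel, x$threshold))
  invisible(x)
}

#' Background-correct a channel and normalize to unit mean cell intensity
#'
#' The mean background-voxel intensity is subtracted from every cell voxel;
#' negative residuals are clamped to zero (intensities are photon counts) by
#' default; the result is divided by its mean over the cell so that the mean
#' cell-voxel intensity is exactly 1.  Downstream operations ignore voxels
#' outside the mask.
#'
#' @param stack an [image_stack()].
#' @param mask a [detect_cell()] mask congruent with `stack`.
#' @param clamp_negative clamp negative background-corrected intensities to
#'   zero before normalization (default `TRUE`).
#' @return An object of class `corrected_channel` with fields `values`
#'   (dimensionless intensities, mean 1 over the mask), `mask`, `spacing`,
#'   `bit_depth`, `channel`, `mean_raw_cell_intensity`,
#'   `mean_background_intensity` and `mean_corrected_intensity` (the
#'   normalizer, in raw intensity units).
#' @export
background_correct_and_normalize <- function(stack, mask, clamp_negative = TRUE) {
  stopifnot(inherits(stack, "image_stack"), inherits(mask, "cell_mask"))
  if (!identical(dim(stack$voxels), dim(mask$mask)))
    stop("mask and stack are not congruent", call. = FALSE)
  v <- stack$voxels
  m <- mask$mask
  mean_cell_raw <- mean(v[m])
  mean_bg <- if (all(m)) 0 else mean(v[!m])
  if (mean_cell_raw <= mean_bg)
    stop(sprintf(paste0("channel '%s': mean cell intensity (%.4g) does not ",
                        "exceed mean background (%.4g) - no signal"),
                 stack$channel, mean_cell_raw, mean_bg), call. = FALSE)
  corr <- v - mean_bg
  if (clamp_negative) corr[corr < 0] <- 0
  mu <- mean(corr[m])
  structure(list(values = corr / mu,
                 mask = mask,
                 spacing = stack$spacing,
                 bit_depth = stack$bit_depth,
                 channel = stack$channel,
                 mean_raw_cell_intensity = mean_cell_raw,
                 mean_background_intensity = mean_bg,
                 mean_corrected_intensity = mu),
            class = "corrected_channel")
}

#' @export
print.corrected_channel <- function(x, ...) {
  cat(sprintf(paste0("<corrected_channel> '%s': mean background %.4g ",
                     "subtracted, cell mean normalized to 1 (raw cell mean %.4g)\n"),
              x$channel, x$mean_background_intensity, x$mean_raw_cell_intensity))
  invisible(x)
}
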