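#' Construct a single-channel 3D image stack
#'
#' The elementary container of the package: one fluorescence channel of one
#' cell as a 3D voxel grid with physical voxel spacing and acquisition bit
#' depth.  A 2D image is represented as a stack with a single z-layer.
#'
#' @param voxels numeric array of non-negative intensities in `(z, y, x)`
#'   order, or a matrix `(y, x)` which is promoted to a one-layer stack.
#' @param spacing physical voxel size per axis as a `(z, y, x)` triple (one
#'   common length unit, e.g. nm); a scalar is recycled to all three axes.
#' @param bit_depth integer acquisition bit depth (e.g. 8, 12, 16); all
#'   intensities must lie in `[0, 2^bit_depth - 1]`.
#' @param channel channel label.
#' @return An object of class `image_stack` with fields `voxels`, `spacing`,
#'   `bit_depth` and `channel`.
#' @examples
#' s <- image_stack(array(10, c(2, 4, 4)), spacing = c(300, 100, 100),
#'                  bit_depth = 16, channel = "Cdc42")
#' dim(s$voxels)
#' @export
image_stack <- function(voxels, spacing, bit_depth, channel = "channel1") {
  if (is.matrix(voxels)) voxels <- array(voxels, c(1L, dim(voxels)))
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stop("`voxels` must be a (z, y, x) array or a (y, x) matrix", call. = FALSE)
  storage.mode(voxels) <- "double"
  if (any(!is.finite(voxels))) stop("non-finite voxel intensities", call. = FALSE)
  if (any(voxels < 0)) stop("negative voxel intensities", call. = FALSE)
  bit_depth <- as.integer(bit_depth)
  if (is.na(bit_depth) || bit_depth < 1L || bit_depth > 32L)
    stop("`bit_depth` must be an integer in [1, 32]", call. = FALSE)
  maxdn <- 2^bit_depth - 1
  if (max(voxels) > maxdn) {
    stop(sprintf("intensity %.6g exceeds 2^%d - 1 = %.0f declared by `bit_depth`",
                 max(voxels), bit_depth, maxdn), call. = FALSE)
  }
  structure(list(voxels = voxels,
                 spacing = .check_spacing(spacing),
                 bit_depth = bit_depth,
                 channel = as.character(channel)),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<image_stack> channel '%s': %d z-layer(s) of %d x %d voxels\n",
              x$channel, d[1], d[2], d[3]))
  cat(sprintf("  spacing (z,y,x): %s; bit depth: %d; intensity range [%.4g, %.4g]\n",
              paste(signif(x$spacing, 6), collapse = " x "), x$bit_depth,
              min(x$voxels), max(x$voxels)))
  invisible(x)
}

#' Read a single- or multi-page grayscale TIFF into an image stack
#'
#' Multi-page files become z-ordered layers; a single page becomes a
#' one-layer stack.  Integer sample values are preserved bit-exactly.
#' Spacing and bit depth are supplied by the caller: TIFF metadata dialects
#' are unreliable and are treated as advisory only.
#'
#' @param path path to a grayscale baseline TIFF (one channel per file).
#' @inheritParams image_stack
#' @param channel channel label; defaults to the file name without extension.
#' @return An [image_stack()].
#' @export
read_tiff_stack <- function(path, spacing, bit_depth, channel = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = TRUE),
                    error = function(e) stop("unreadable TIFF '", path, "': ",
                                             conditionMessage(e), call. = FALSE))
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) == 0L) stop("TIFF contains no pages: ", path, call. = FALSE)
  if (any(vapply(pages, function(p) length(dim(p)) != 2L, logical(1))))
    stop("multi-sample (non-grayscale) TIFF not supported: ", path, call. = FALSE)
  d1 <- dim(pages[[1L]])
  same <- vapply(pages, function(p) identical(dim(p), d1), logical(1))
  if (!all(same))
    stop("page shape mismatch across z in '", path, "' (page ",
         which(!same)[1L], ")", call. = FALSE)
  arr <- array(0, c(length(pages), d1[1L], d1[2L]))
  for (z in seq_along(pages)) arr[z, , ] <- pages[[z]]
  if (is.null(channel)) channel <- sub("\\.[^.]*$", "", basename(path))
  image_stack(arr, spacing = spacing, bit_depth = bit_depth, channel = channel)
}

#' Write an image stack as a multi-page grayscale TIFF
#'
#' Intensities are rounded to integers and stored in an 8-bit container when
#' `bit_depth <= 8`, else in a 16-bit container, so that integer-valued
#' stacks round-trip exactly through [read_tiff_stack()].
#'
#' @param stack an [image_stack()] with `bit_depth <= 16`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tiff_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  if (stack$bit_depth > 16L)
    stop("TIFF writing supports bit depths up to 16", call. = FALSE)
  bits <- if (stack$bit_depth <= 8L) 8L else 16L
  denom <- 2^bits - 1
  pages <- lapply(seq_len(dim(stack$voxels)[1L]), function(z)
    round(stack$voxels[z, , ]) / denom)
  tiff::writeTIFF(pages, path, bits.per.sample = bits)
  invisible(path)
}

#' Bundle congruent channels of one cell
#'
#' All channels of one cell must share identical voxel dimensions and
#' spacing; the cell mask computed on the detection channel is shared across
#' them.
#'
#' @param channels named list of [image_stack()] objects (names are channel
#'   labels; unnamed lists take the stacks' own channel labels).
#' @param cell_id cell identifier.
#' @return An object of class `cell_record`.
#' @export
cell_record <- function(channels, cell_id = "cell") {
  if (!is.list(channels) || length(channels) == 0L)
    stop("`channels` must be a non-empty list of image stacks", call. = FALSE)
  ok <- vapply(channels, inherits, logical(1), what = "image_stack")
  if (!all(ok)) stop("all channels must be image_stack objects", call. = FALSE)
  if (is.null(names(channels)) || any(!nzchar(names(channels))))
    names(channels) <- vapply(channels, `[[`, character(1), "channel")
  if (anyDuplicated(names(channels)))
    stop("duplicated channel names", call. = FALSE)
  ref <- channels[[1L]]
  for (nm in names(channels)) {
    ch <- channels[[nm]]
    if (!identical(dim(ch$voxels), dim(ref$voxels)))
      stop(sprintf("channel '%s' has dimensions %s, expected %s", nm,
                   paste(dim(ch$voxels), collapse = "x"),
                   paste(dim(ref$voxels), collapse = "x")), call. = FALSE)
    if (!isTRUE(all.equal(ch$spacing, ref$spacing)))
      stop(sprintf("channel '%s' has a different voxel spacing", nm),
           call. = FALSE)
  }
  structure(list(cell_id = as.character(cell_id), channels = channels),
            class = "cell_record")
}

#' @export
print.cell_record <- function(x, ...) {
  cat(sprintf("<cell_record> '%s': %d channel(s) [%s], %s voxels\n",
              x$cell_id, length(x$channels),
              paste(names(x$channels), collapse = ", "),
              paste(dim(x$channels[[1L]]$voxels), collapse = "x")))
  invisible(x)
}

#' Load all channels of one cell from per-channel TIFF files
#'
#' @param paths named character vector of TIFF paths, one per channel; names
#'   are the channel labels.
#' @inheritParams image_stack
#' @param cell_id cell identifier.
#' @return A [cell_record()]; channels are congruence-checked on assembly.
#' @export
assemble_cell <- function(paths, spacing, bit_depth, cell_id = "cell") {
  paths <- unlist(paths)
  if (length(paths) == 0L) stop("no channel paths given", call. = FALSE)
  if (is.null(names(paths)) || any(!nzchar(names(paths))))
    stop("`paths` must be named by channel", call. = FALSE)
  channels <- lapply(names(paths), function(nm)
    read_tiff_stack(paths[[nm]], spacing = spacing, bit_depth = bit_depth,
                    channel = nm))
  names(channels) <- names(paths)
  cell_record(channels, cell_id = cell_id)
}

#' Write a per-cell result table
#'
#' Floating point values are written at full double precision (15
#' significant digits) so that tables round-trip through [read_results()].
#'
#' @param records a data.frame of result rows (may have zero rows).
#' @param path output path.
#' @param format one of `"tsv"`, `"csv"`, `"json"`.
#' @return `path`, invisibly.
#' @export
write_results <- function(records, path, format = c("tsv", "csv", "json")) {
  format <- match.arg(format)
  if (!is.data.frame(records))
    stop("`records` must be a data.frame", call. = FALSE)
  switch(format,
    tsv = write.table(records, path, sep = "\t", quote = FALSE,
                      row.names = FALSE, na = "NA"),
    csv = write.csv(records, path, row.names = FALSE, na = "NA"),
    json = jsonlite::write_json(records, path, dataframe = "rows",
                                digits = NA, na = "null"))
  invisible(path)
}

#' Read back a result table written by [write_results()]
#'
#' @param path input path.
#' @param format one of `"tsv"`, `"csv"`, `"json"`; guessed from the file
#'   extension when missing.
#' @return A data.frame.
#' @export
read_results <- function(path, format = NULL) {
  if (is.null(format)) {
    ext <- tolower(sub(".*\\.", "", path))
    format <- if (ext %in% c("tsv", "csv", "json")) ext else "tsv"
  }
  switch(format,
    tsv = read.delim(path, check.names = FALSE),
    csv = read.csv(path, check.names = FALSE),
    json = as.data.frame(jsonlite::fromJSON(path)),
    stop("unknown format: ", format, call. = FALSE))
}
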