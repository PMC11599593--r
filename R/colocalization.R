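#' Voxel-intensity Pearson correlation of two channels
#'
#' Standard Pearson correlation of paired voxel intensities over the shared
#' cell mask: 1 is a perfect match of the two distributions, 0 random, -1 a
#' perfect mismatch.  Pearson correlation is affine-invariant, so the
#' background-corrected mean-normalized values give the same `r` as the raw
#' intensities within the mask.
#'
#' @param a,b [background_correct_and_normalize()] results for two channels
#'   of the same cell.
#' @param mask optional [detect_cell()] mask; defaults to the channels'
#'   shared mask.
#' @return list with `r`, two-sided `p` (defined for `n >= 3`), `n` (voxel
#'   count) and `flagged` (`TRUE` with `r = NA` when either channel has
#'   zero variance over the mask).
#' @export
pearson_voxels <- function(a, b, mask = NULL) {
  stopifnot(inherits(a, "corrected_channel"), inherits(b, "corrected_channel"))
  if (is.null(mask)) mask <- a$mask
  if (!identical(dim(a$values), dim(b$values)) ||
      !identical(dim(a$values), dim(mask$mask)))
    stop("channels and mask are not congruent", call. = FALSE)
  m <- mask$mask
  x <- a$values[m]
  y <- b$values[m]
  n <- length(x)
  if (n < 3L || sd(x) == 0 || sd(y) == 0)
    return(list(r = NA_real_, p = NA_real_, n = n, flagged = TRUE))
  ct <- cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, n = n, flagged = FALSE)
}

#' Per-cell table of pairwise channel correlations
#'
#' One Pearson `r` per cell and channel pair, computed over each cell's own
#' mask; degenerate (zero-variance) channels propagate as `NA` rather than
#' dropping the cell.
#'
#' @param cells list of [analyze_cell()] results.
#' @param pairs optional 2-column character matrix of channel pairs; by
#'   default all unordered pairs of the first cell's channels.
#' @return data.frame with columns `cell_id`, `channel_a`, `channel_b`,
#'   `pair` (`"a|b"`), `r`, `p`, `n`.
#' @export
pairwise_correlation_table <- function(cells, pairs = NULL) {
  if (length(cells) == 0L) stop("need at least one cell", call. = FALSE)
  stopifnot(all(vapply(cells, inherits, logical(1), what = "cell_analysis")))
  if (is.null(pairs)) {
    chs <- names(cells[[1L]]$channels)
    if (length(chs) < 2L) stop("need at least two channels", call. = FALSE)
    pairs <- t(combn(chs, 2L))
  }
  pairs <- as.matrix(pairs)
  rows <- lapply(cells, function(cell) {
    do.call(rbind, lapply(seq_len(nrow(pairs)), function(i) {
      ca <- pairs[i, 1L]; cb <- pairs[i, 2L]
      pv <- pearson_voxels(cell$channels[[ca]]$corrected,
                           cell$channels[[cb]]$corrected)
      data.frame(cell_id = cell$cell_id, channel_a = ca, channel_b = cb,
                 pair = paste(ca, cb, sep = "|"),
                 r = pv$r, p = pv$p, n = pv$n,
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Correlation of colocalization correlations across a cell population
#'
#' Takes the per-cell table of pairwise channel correlations and correlates
#' the pair-columns with each other across cells: the resulting symmetric,
#' unit-diagonal matrix describes how the colocalizations themselves covary
#' over the population (a second-order view of the protein network).  When
#' a second population is given, the element-wise difference of the two
#' matrices is also returned.  Missing per-cell values are handled
#' pairwise-complete so that a degenerate channel in a few cells does not
#' void the population matrix.
#'
#' @param table a [pairwise_correlation_table()] result (needs columns
#'   `cell_id`, `pair`, `r`) for population A.
#' @param table_b optional second population.
#' @param min_cells minimum cells per population (default 3).
#' @return list with `r` (and `p`, per-entry two-sided tests), plus `r_b`,
#'   `p_b` and `difference = r - r_b` when `table_b` is given.
#' @export
correlation_of_correlations <- function(table, table_b = NULL, min_cells = 3L) {
  mat_a <- .pair_r_matrix(table, min_cells)
  res <- .cor_of_cols(mat_a)
  out <- list(r = res$r, p = res$p, n_cells = nrow(mat_a))
  if (!is.null(table_b)) {
    mat_b <- .pair_r_matrix(table_b, min_cells)
    if (!identical(colnames(mat_a), colnames(mat_b)))
      stop("the two populations have different channel pairs", call. = FALSE)
    res_b <- .cor_of_cols(mat_b)
    out$r_b <- res_b$r
    out$p_b <- res_b$p
    out$n_cells_b <- nrow(mat_b)
    out$difference <- res$r - res_b$r
  }
  out
}

## long (cell_id, pair, r) -> cells x pairs matrix
.pair_r_matrix <- function(table, min_cells) {
  stopifnot(is.data.frame(table),
            all(c("cell_id", "pair", "r") %in% names(table)))
  cells <- unique(table$cell_id)
  prs <- unique(table$pair)
  if (length(cells) < min_cells)
    stop("need at least ", min_cells, " cells per population", call. = FALSE)
  m <- matrix(NA_real_, length(cells), length(prs),
              dimnames = list(cells, prs))
  m[cbind(match(table$cell_id, cells), match(table$pair, prs))] <- table$r
  m
}

## column-pair Pearson correlations, pairwise-complete, with p-values
.cor_of_cols <- function(m) {
  k <- ncol(m)
  r <- diag(1, k)
  p <- matrix(NA_real_, k, k)
  dimnames(r) <- dimnames(p) <- list(colnames(m), colnames(m))
  diag(p) <- 0
  for (i in seq_len(k - 1L)) for (j in seq.int(i + 1L, k)) {
    ok <- complete.cases(m[, c(i, j)])
    if (sum(ok) >= 3L && sd(m[ok, i]) > 0 && sd(m[ok, j]) > 0) {
      ct <- cor.test(m[ok, i], m[ok, j])
      r[i, j] <- r[j, i] <- unname(ct$estimate)
      p[i, j] <- p[j, i] <- ct$p.value
    } else {
      r[i, j] <- r[j, i] <- NA_real_
    }
  }
  list(r = r, p = p)
}
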