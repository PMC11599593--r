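## Independent brute-force oracles and small fixture builders shared by the
## suite.  Oracles deliberately use first-principles loops, not the package's
## vectorized code paths.

## Otsu oracle: for every candidate inter-bin cut, compute the between-class
## variance directly from the raw values assigned to each side.
naive_otsu <- function(x, n_bins = 256L) {
  mn <- min(x); mx <- max(x)
  edges <- mn + seq_len(n_bins - 1L) / n_bins * (mx - mn)
  bcvs <- rep(-Inf, length(edges))
  for (k in seq_along(edges)) {
    lo <- x[x <= edges[k]]; hi <- x[x > edges[k]]
    if (length(lo) == 0L || length(hi) == 0L) next
    w0 <- length(lo) / length(x); w1 <- 1 - w0
    bcvs[k] <- w0 * w1 * (mean(lo) - mean(hi))^2
  }
  ## midpoint of the maximizing plateau, as in the package implementation
  mean(edges[bcvs >= max(bcvs) * (1 - 1e-12)])
}

## Mann-Whitney statistics by direct pair counting (ties count 1/2)
brute_pair_counts <- function(x, y) {
  u1 <- 0
  for (xi in x) for (yj in y) {
    if (xi < yj) u1 <- u1 + 1
    else if (xi == yj) u1 <- u1 + 0.5
  }
  list(U1 = u1, U2 = length(x) * length(y) - u1)
}

brute_cles <- function(x, y) {
  pc <- brute_pair_counts(x, y)
  min(pc$U1, pc$U2) / (length(x) * length(y))
}

## exhaustive pairwise max distance between mask voxel centers
brute_diameter <- function(mask_arr, spacing) {
  idx <- which(mask_arr)
  ai <- arrayInd(idx, dim(mask_arr))
  P <- sweep(ai - 1, 2, spacing, `*`)
  best <- 0
  n <- nrow(P)
  for (i in seq_len(n)) for (j in seq_len(n))
    best <- max(best, sum((P[i, ] - P[j, ])^2))
  sqrt(best)
}

## a small noise-free two-level spherical cell record (fast fixture)
small_sphere_record <- function(radius_vox = 6, fg = 200, bg = 10,
                                spacing = c(100, 100, 100), bit_depth = 16,
                                dims = NULL, center_vox = NULL,
                                channel = "signal") {
  if (is.null(dims)) dims <- rep(2L * radius_vox + 5L, 3L)
  if (is.null(center_vox)) center_vox <- (dims + 1) / 2
  arr <- array(bg, dims)
  g <- as.matrix(expand.grid(z = seq_len(dims[1]), y = seq_len(dims[2]),
                             x = seq_len(dims[3])))
  inside <- rowSums(sweep(g, 2, center_vox)^2) <= radius_vox^2
  arr[g[inside, , drop = FALSE]] <- fg
  list(record = cell_record(list(image_stack(arr, spacing, bit_depth,
                                             channel = channel))),
       mask = array(inside, dims))
}

## circular shift of a (z,y,x) array: a rigid translation of the whole
## frame, background included
circshift3 <- function(a, s) {
  d <- dim(a)
  iz <- ((seq_len(d[1]) - 1 - s[1]) %% d[1]) + 1
  iy <- ((seq_len(d[2]) - 1 - s[2]) %% d[2]) + 1
  ix <- ((seq_len(d[3]) - 1 - s[3]) %% d[3]) + 1
  a[iz, iy, ix, drop = FALSE]
}

## 90-degree rotation about the z axis (swap y/x, reverse one)
rot90_z <- function(a) {
  b <- aperm(a, c(1L, 3L, 2L))
  b[, rev(seq_len(dim(b)[2])), , drop = FALSE]
}

## re-wrap an array as a single-channel record with given metadata
as_record <- function(voxels, spacing, bit_depth = 16, channel = "signal",
                      cell_id = "cell") {
  cell_record(list(image_stack(voxels, spacing, bit_depth, channel = channel)),
              cell_id = cell_id)
}

## multiply intensities of a record without re-validating the bit range
## (used by scale-invariance checks, where bit depth is held fixed)
scale_record <- function(record, factor) {
  for (nm in names(record$channels))
    record$channels[[nm]]$voxels <- record$channels[[nm]]$voxels * factor
  record
}
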