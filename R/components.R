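## 3D connected-component labelling and hole filling on logical voxel grids.
## Components are found by building the voxel-adjacency edge list with
## vectorized index shifts and delegating the union-find to igraph; this
## keeps million-voxel crops tractable in pure R.

## half-space neighbour offsets (each unordered pair counted once)
.half_offsets <- function(connectivity) {
  if (connectivity == 6L) {
    matrix(c(1L, 0L, 0L,
             0L, 1L, 0L,
             0L, 0L, 1L), ncol = 3L, byrow = TRUE)
  } else if (connectivity == 26L) {
    g <- as.matrix(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1))
    keep <- g[, 1L] > 0L |
      (g[, 1L] == 0L & g[, 2L] > 0L) |
      (g[, 1L] == 0L & g[, 2L] == 0L & g[, 3L] > 0L)
    unname(g[keep, , drop = FALSE])
  } else stop("connectivity must be 6 or 26", call. = FALSE)
}

## label connected TRUE-components; returns list(labels = integer array
## (0 = background), n = component count, sizes = voxel counts)
.label_components <- function(mask, connectivity = 26L) {
  dims <- dim(mask)
  idx <- which(mask)
  n <- length(idx)
  lab <- integer(length(mask))
  if (n == 0L) return(list(labels = array(lab, dims), n = 0L, sizes = integer(0)))
  id <- integer(length(mask))
  id[idx] <- seq_len(n)
  ai <- arrayInd(idx, dims)
  offs <- .half_offsets(connectivity)
  strides <- c(1L, dims[1L], dims[1L] * dims[2L])
  edges <- vector("list", nrow(offs))
  for (r in seq_len(nrow(offs))) {
    o <- offs[r, ]
    ok <- ai[, 1L] + o[1L] >= 1L & ai[, 1L] + o[1L] <= dims[1L] &
          ai[, 2L] + o[2L] >= 1L & ai[, 2L] + o[2L] <= dims[2L] &
          ai[, 3L] + o[3L] >= 1L & ai[, 3L] + o[3L] <= dims[3L]
    src <- idx[ok]
    nb <- src + sum(o * strides)
    inm <- mask[nb]
    if (any(inm)) edges[[r]] <- rbind(id[src[inm]], id[nb[inm]])
  }
  edges <- do.call(cbind, edges)
  if (is.null(edges)) {
    comp <- seq_len(n)
    ncomp <- n
  } else {
    g <- igraph::make_graph(as.vector(edges), n = n, directed = FALSE)
    cc <- igraph::components(g)
    comp <- cc$membership
    ncomp <- cc$no
  }
  lab[idx] <- comp
  list(labels = array(lab, dims), n = ncomp, sizes = tabulate(comp, ncomp))
}

## fill background cavities fully enclosed by the mask (background taken
## 6-connected, the complement of 26-connected foreground)
.fill_holes <- function(mask) {
  bg <- !mask
  if (!any(bg)) return(mask)
  lb <- .label_components(bg, connectivity = 6L)
  dims <- dim(mask)
  border <- array(FALSE, dims)
  border[c(1L, dims[1L]), , ] <- TRUE
  border[, c(1L, dims[2L]), ] <- TRUE
  border[, , c(1L, dims[3L])] <- TRUE
  outside <- logical(lb$n)
  outside[unique(lb$labels[border & bg])] <- TRUE
  out <- mask
  bgidx <- which(bg)
  out[bgidx] <- !outside[lb$labels[bgidx]]
  out
}

## voxels of `mask` with at least one 6-neighbour outside the mask (or on
## the array border)
.surface_voxels <- function(mask) {
  dims <- dim(mask)
  inner <- mask
  shifts <- rbind(c(1L, 0L, 0L), c(-1L, 0L, 0L), c(0L, 1L, 0L),
                  c(0L, -1L, 0L), c(0L, 0L, 1L), c(0L, 0L, -1L))
  for (r in seq_len(nrow(shifts))) {
    inner <- inner & .shift_logical(mask, shifts[r, ])
    if (!any(inner)) break
  }
  mask & !inner
}

## shift a logical array by (dz, dy, dx), filling with FALSE
.shift_logical <- function(m, d) {
  dims <- dim(m)
  out <- array(FALSE, dims)
  src <- dst <- vector("list", 3L)
  for (a in 1:3) {
    if (d[a] >= 0L) {
      src[[a]] <- seq_len(dims[a] - d[a])
      dst[[a]] <- src[[a]] + d[a]
    } else {
      src[[a]] <- seq.int(1L - d[a], dims[a])
      dst[[a]] <- src[[a]] + d[a]
    }
    if (length(src[[a]]) == 0L) return(out)
  }
  out[dst[[1L]], dst[[2L]], dst[[3L]]] <- m[src[[1L]], src[[2L]], src[[3L]]]
  out
}
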