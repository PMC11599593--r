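#' Vectors from the cell center to the charge centers
#'
#' @param M cell centroid (physical `(z, y, x)`).
#' @param R_plus,R_minus charge-center coordinates.
#' @return list with `MR_plus` and `MR_minus`, physical vectors.
#' @export
center_vectors <- function(M, R_plus, R_minus) {
  list(MR_plus = R_plus - M, MR_minus = R_minus - M)
}

#' Distance and angle between the positive charge centers of two channels
#'
#' `d` is the Euclidean distance between the positive charge centers; the
#' angle `alpha` (degrees, in `[0, 180]`) is measured between the lines from
#' the cell center `M` to each positive charge center.  Two polar signals on
#' opposite sides of the cell give a large `d` and `alpha` near 180; two
#' apolar signals collapse both centers near `M`, giving a small `d`.  If a
#' center coincides with `M` the angle is undefined (`NA`, flagged) while
#' `d` is still reported.
#'
#' @param result_a,result_b [normalize_dipole()] results for the two
#'   channels (same cell, same mask).
#' @param M cell centroid.
#' @return An object of class `pair_geometry` with `d`, `alpha`,
#'   `angle_defined` and the channel results' degenerate flags propagated
#'   as `NA` entries.
#' @export
pair_geometry <- function(result_a, result_b, M) {
  stopifnot(inherits(result_a, "dipole_result"),
            inherits(result_b, "dipole_result"))
  if (result_a$degenerate || result_b$degenerate) {
    return(structure(list(d = NA_real_, alpha = NA_real_,
                          angle_defined = FALSE), class = "pair_geometry"))
  }
  d <- .vnorm(result_a$R_plus - result_b$R_plus)
  va <- result_a$R_plus - M
  vb <- result_b$R_plus - M
  na <- .vnorm(va); nb <- .vnorm(vb)
  if (na == 0 || nb == 0) {
    return(structure(list(d = d, alpha = NA_real_, angle_defined = FALSE),
                     class = "pair_geometry"))
  }
  cosv <- min(1, max(-1, sum(va * vb) / (na * nb)))
  structure(list(d = d, alpha = acos(cosv) * 180 / pi, angle_defined = TRUE),
            class = "pair_geometry")
}

#' Nucleus position as a percentage of the maximal cell diameter
#'
#' Uses the negative charge center of the nuclear-stain (DAPI) channel:
#' `R_minus` of DAPI sits in the cytoplasm opposite the nucleus and is not
#' perturbed by the uneven DAPI intensity of hetero- versus euchromatin,
#' unlike the positive center inside the nucleus.
#'
#' @param dapi_result [normalize_dipole()] result of the DAPI channel.
#' @param M cell centroid.
#' @param d_max maximal cell diameter (> 0).
#' @return `d_nucleus = 100 * |M - R_minus| / d_max` (percent).
#' @export
nucleus_position <- function(dapi_result, M, d_max) {
  stopifnot(inherits(dapi_result, "dipole_result"))
  if (d_max <= 0) stop("d_max must be > 0", call. = FALSE)
  if (dapi_result$degenerate)
    stop("DAPI channel is degenerate: R_minus undefined", call. = FALSE)
  100 * .vnorm(M - dapi_result$R_minus) / d_max
}

#' Constriction of the charge centers
#'
#' Quantifies how tightly the charge of each sign clusters around its
#' center, as the charge-weighted RMS distance about `R_plus`
#' (respectively `R_minus`); zero when all charge of that sign sits in a
#' single voxel.  Normalized variants divide by `d_max`.
#'
#' @param field a [compute_charges()] result with `q_plus > 0`.
#' @param R_plus,R_minus charge-center coordinates.
#' @param d_max maximal cell diameter for the normalized spreads.
#' @return An object of class `constriction_result` with `spread_plus`,
#'   `spread_minus` (physical units) and `spread_plus_norm`,
#'   `spread_minus_norm`.
#' @export
constriction <- function(field, R_plus, R_minus, d_max) {
  stopifnot(inherits(field, "charge_field"))
  if (field$q_plus <= 0)
    stop("q_plus = 0: constriction undefined for a uniform channel",
         call. = FALSE)
  dims <- dim(field$q)
  rms <- function(idx, w, center) {
    cc <- .phys_coords(idx, dims, field$spacing)
    d2 <- (cc[, 1L] - center[1L])^2 + (cc[, 2L] - center[2L])^2 +
      (cc[, 3L] - center[3L])^2
    sqrt(sum(w * d2) / sum(w))
  }
  ip <- which(field$q > 0)
  im <- which(field$q < 0)
  sp <- rms(ip, field$q[ip], R_plus)
  sm <- rms(im, -field$q[im], R_minus)
  structure(list(spread_plus = sp, spread_minus = sm,
                 spread_plus_norm = sp / d_max,
                 spread_minus_norm = sm / d_max),
            class = "constriction_result")
}

#' Amount and spatial volume of the signal in one channel
#'
#' `amount` is the total background-corrected raw intensity over the cell
#' (intensity units); `signal_volume` is the volume occupied by
#' above-average (positively charged) voxels, consistent with the charge
#' decomposition, and is at most the cell volume.
#'
#' @param corrected a [background_correct_and_normalize()] result.
#' @param field the matching [compute_charges()] result.
#' @return An object of class `channel_summary` with `amount`,
#'   `signal_volume` and `cell_volume`.
#' @export
channel_summary <- function(corrected, field) {
  stopifnot(inherits(corrected, "corrected_channel"),
            inherits(field, "charge_field"))
  n <- corrected$mask$n_cell_voxels
  voxvol <- prod(corrected$spacing)
  structure(list(amount = corrected$mean_corrected_intensity * n,
                 signal_volume = sum(field$q > 0) * voxvol,
                 cell_volume = n * voxvol),
            class = "channel_summary")
}
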