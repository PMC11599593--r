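#' Point-charge validation scenario on an artificial sphere
#'
#' The pipeline's validation harness: a spherical cell of known radius with
#' point charges at known positions.  The dipole moment of the point set has
#' a closed form ([analytic_dipole()]), and the rendered image
#' ([render_scenario()]) run through the full pipeline must reproduce it.
#'
#' @param charges data.frame or matrix with columns `z`, `y`, `x`
#'   (physical coordinates relative to the sphere center) and `magnitude`
#'   (signed charge).  Magnitudes should sum to zero, as they do for the
#'   charge field the pipeline extracts from an image; an empty set is the
#'   explicit uniform case.
#' @param sphere_radius sphere radius in physical units (default 5000 nm).
#' @param spacing voxel size `(z, y, x)` for rendering (default 100 nm
#'   isotropic).
#' @param bit_depth rendering bit depth (default 16).
#' @return An object of class `charge_scenario`.
#' @examples
#' sc <- charge_scenario(data.frame(z = 0, y = 0, x = c(5000, -5000),
#'                                  magnitude = c(1, -1)))
#' analytic_dipole(sc)$d_vec
#' @export
charge_scenario <- function(charges, sphere_radius = 5000,
                            spacing = c(100, 100, 100), bit_depth = 16L) {
  charges <- as.data.frame(charges)
  if (nrow(charges) > 0) {
    stopifnot(all(c("z", "y", "x", "magnitude") %in% names(charges)))
    rad <- sqrt(charges$z^2 + charges$y^2 + charges$x^2)
    if (any(rad > sphere_radius * (1 + 1e-9)))
      stop("charge positions must lie within the sphere", call. = FALSE)
    if (any(charges$magnitude == 0))
      stop("zero-magnitude charges are not allowed", call. = FALSE)
    if (abs(sum(charges$magnitude)) > 1e-9 * sum(abs(charges$magnitude)))
      warning("charge magnitudes do not sum to zero; the rendered image ",
              "redistributes the excess over the whole cell", call. = FALSE)
    has_pos <- any(charges$magnitude > 0)
    has_neg <- any(charges$magnitude < 0)
    if (!(has_pos && has_neg))
      stop("need at least one positive and one negative charge ",
           "(or an empty set for the uniform case)", call. = FALSE)
  }
  structure(list(charges = charges,
                 sphere_radius = sphere_radius,
                 spacing = .check_spacing(spacing),
                 bit_depth = as.integer(bit_depth)),
            class = "charge_scenario")
}

#' Closed-form dipole moment of a point-charge scenario
#'
#' Charge-weighted means of the positive and negative point charges and the
#' resulting dipole, computed directly from the point list with no
#' voxelization: the independent oracle against which the image pipeline is
#' validated.
#'
#' @param scenario a [charge_scenario()].
#' @return list with `R_plus`, `R_minus` (physical `(z, y, x)`, relative to
#'   the sphere center), `d_vec`, `P_raw` and `q_plus`; all-`NA` centers
#'   with `P_raw = 0` for the uniform case.
#' @export
analytic_dipole <- function(scenario) {
  stopifnot(inherits(scenario, "charge_scenario"))
  ch <- scenario$charges
  nav <- c(z = NA_real_, y = NA_real_, x = NA_real_)
  if (nrow(ch) == 0L)
    return(list(R_plus = nav, R_minus = nav, d_vec = nav, P_raw = 0,
                q_plus = 0))
  pos <- ch$magnitude > 0
  P <- as.matrix(ch[, c("z", "y", "x")])
  wp <- ch$magnitude[pos]
  wm <- -ch$magnitude[!pos]
  R_plus <- setNames(colSums(P[pos, , drop = FALSE] * wp) / sum(wp),
                     c("z", "y", "x"))
  R_minus <- setNames(colSums(P[!pos, , drop = FALSE] * wm) / sum(wm),
                      c("z", "y", "x"))
  d_vec <- R_plus - R_minus
  list(R_plus = R_plus, R_minus = R_minus, d_vec = d_vec,
       P_raw = sum(wp) * .vnorm(d_vec), q_plus = sum(wp))
}

#' Render a point-charge scenario as a synthetic cell image
#'
#' A digitized sphere of uniform base intensity on a dark background, with
#' each point charge deposited as a narrow Gaussian intensity increment
#' (positive charges) or decrement (negative charges).  Each charge's
#' kernel is restricted to in-sphere voxels and renormalized so its
#' deposited mass matches the scenario magnitude; the kernel is kept narrow
#' (default `sigma = 0.75` voxels) because a wide kernel centred on a
#' surface charge loses its outward half to the cell boundary and biases
#' the rendered charge center inward by about `0.8 * sigma`.  Intensities
#' are left as floating point: quantization is a property of file export
#' ([write_tiff_stack()]), not of the validation geometry.
#'
#' @param scenario a [charge_scenario()]; the spacing must resolve the
#'   sphere with at least 20 voxels across its diameter.
#' @param base_fraction base (pedestal) cell intensity as a fraction of the
#'   dynamic range (default 0.3).
#' @param background_fraction background intensity fraction (default 0.02).
#' @param kernel_sigma_vox Gaussian deposition width in voxels.
#' @param cell_id identifier of the returned record.
#' @return A single-channel [cell_record()]; the generating truth
#'   ([analytic_dipole()] plus the scenario and the sphere-center
#'   coordinate `center` of the rendered grid) is attached as attribute
#'   `"truth"`.
#' @export
render_scenario <- function(scenario, base_fraction = 0.3,
                            background_fraction = 0.02,
                            kernel_sigma_vox = 0.75, cell_id = "scenario") {
  stopifnot(inherits(scenario, "charge_scenario"))
  sp <- scenario$spacing
  if (any(2 * scenario$sphere_radius / sp < 20))
    stop("spacing too coarse: need >= 20 voxels across the sphere",
         call. = FALSE)
  margin <- 3L
  rvox <- ceiling(scenario$sphere_radius / sp)
  dims <- 2L * (rvox + margin) + 1L
  center <- (rvox + margin) * sp  # physical (z,y,x) of the sphere center
  idx <- seq_len(prod(dims))
  cc <- .phys_coords(idx, dims, sp)
  inside <- (cc[, 1L] - center[1L])^2 + (cc[, 2L] - center[2L])^2 +
    (cc[, 3L] - center[3L])^2 <= scenario$sphere_radius^2
  mask <- array(inside, dims)
  D <- array(0, dims)
  ch <- scenario$charges
  sig <- kernel_sigma_vox * sp  # physical per-axis sigma
  halfw <- ceiling(3 * kernel_sigma_vox)
  for (i in seq_len(nrow(ch))) {
    p <- center + c(ch$z[i], ch$y[i], ch$x[i])
    ivox <- round(p / sp) + 1  # nearest voxel (1-based)
    rz <- max(1, ivox[1] - halfw):min(dims[1], ivox[1] + halfw)
    ry <- max(1, ivox[2] - halfw):min(dims[2], ivox[2] + halfw)
    rx <- max(1, ivox[3] - halfw):min(dims[3], ivox[3] + halfw)
    g <- expand.grid(z = rz, y = ry, x = rx)
    pz <- (g$z - 1) * sp[1]; py <- (g$y - 1) * sp[2]; px <- (g$x - 1) * sp[3]
    w <- exp(-((pz - p[1])^2 / sig[1]^2 +
               (py - p[2])^2 / sig[2]^2 +
               (px - p[3])^2 / sig[3]^2) / 2)
    lin <- g$z + (g$y - 1) * dims[1] + (g$x - 1) * dims[1] * dims[2]
    keep <- mask[lin] & w > 0
    if (!any(keep))
      stop("charge ", i, " falls outside the rendered sphere", call. = FALSE)
    w <- w[keep] / sum(w[keep])
    D[lin[keep]] <- D[lin[keep]] + ch$magnitude[i] * w
  }
  maxdn <- 2^scenario$bit_depth - 1
  base <- base_fraction * maxdn
  bg <- background_fraction * maxdn
  vox <- array(bg, dims)
  amp <- if (any(D != 0)) 0.25 * base / max(abs(D)) else 0
  vox[mask] <- base + amp * D[mask]
  truth <- c(analytic_dipole(scenario),
             list(scenario = scenario, center = center, mask = mask))
  rec <- cell_record(list(signal = image_stack(vox, sp, scenario$bit_depth,
                                               channel = "signal")),
                     cell_id = cell_id)
  attr(rec, "truth") <- truth
  rec
}

#' Specification of a synthetic fluorescent cell
#'
#' Describes a spherical or ellipsoidal cell body carrying one of four
#' signal models on a uniform pedestal: `uniform` (apolar), `gaussian_blob`
#' (a polar cap displaced from the cell center), `two_opposite_blobs` (two
#' equal poles, visually apolar) and `ring` (a spherical shell).  Noise
#' follows a Poisson-Gaussian camera model parameterized by the
#' signal-to-noise ratio at the mean cell intensity, and an optional
#' fraction of the brightest cell voxels can be saturation-clipped.
#'
#' @param shape `"sphere"` or `"ellipsoid"`.
#' @param radius sphere radius (physical units; default 5000 nm).
#' @param semiaxes ellipsoid semi-axes `(z, y, x)`; required for
#'   `shape = "ellipsoid"`.
#' @param signal_model one of `"gaussian_blob"`, `"uniform"`,
#'   `"two_opposite_blobs"`, `"ring"`.
#' @param offset blob center displacement as a fraction of the cell radius
#'   along `direction`, in `[0, 1)`.
#' @param width blob (or shell) Gaussian width as a fraction of the radius
#'   (default 0.35, a broad polar cap occupying roughly one cell pole).
#' @param direction unit `(z, y, x)` direction of blob displacement.
#' @param snr signal-to-noise ratio at the mean cell intensity (`Inf` for
#'   noise-free).
#' @param brightness mean cell intensity as a fraction of the dynamic
#'   range; the default 0.15 leaves headroom so that doubling the exposure
#'   keeps even the blob peak below saturation (clipping is controlled
#'   separately through `saturation_fraction`).
#' @param saturation_fraction fraction of cell voxels clipped at the top of
#'   the dynamic range.
#' @param background_fraction background intensity as a fraction of the
#'   mean cell intensity, so that `brightness` emulates exposure or laser
#'   power scaling of the whole image (cell and background glow together).
#' @param spacing voxel size `(z, y, x)`; the default 200 nm laterally with
#'   400 nm z-steps mimics widefield stacks of small round cells.
#' @param bit_depth acquisition bit depth.
#' @param seed RNG seed; a fixed seed makes [make_cell()] bit-identical.
#' @return An object of class `synthetic_cell_spec`.
#' @export
synthetic_cell_spec <- function(shape = c("sphere", "ellipsoid"),
                                radius = 5000, semiaxes = NULL,
                                signal_model = c("gaussian_blob", "uniform",
                                                 "two_opposite_blobs", "ring"),
                                offset = 0.5, width = 0.35,
                                direction = c(0, 0, 1),
                                snr = 20, brightness = 0.15,
                                saturation_fraction = 0,
                                background_fraction = 0.03,
                                spacing = c(400, 200, 200),
                                bit_depth = 16L, seed = 0L) {
  shape <- match.arg(shape)
  signal_model <- match.arg(signal_model)
  if (shape == "ellipsoid") {
    if (is.null(semiaxes) || length(semiaxes) != 3L || any(semiaxes <= 0))
      stop("`semiaxes` must be a positive (z, y, x) triple", call. = FALSE)
  } else {
    if (radius <= 0) stop("`radius` must be > 0", call. = FALSE)
    semiaxes <- rep(radius, 3L)
  }
  if (offset < 0 || offset >= 1)
    stop("`offset` must be in [0, 1)", call. = FALSE)
  if (width <= 0) stop("`width` must be > 0", call. = FALSE)
  if (!is.finite(snr) && !is.infinite(snr)) stop("bad `snr`", call. = FALSE)
  if (snr <= 0) stop("`snr` must be > 0", call. = FALSE)
  if (saturation_fraction < 0 || saturation_fraction >= 1)
    stop("`saturation_fraction` must be in [0, 1)", call. = FALSE)
  if (brightness <= 0 || brightness > 1)
    stop("`brightness` must be in (0, 1]", call. = FALSE)
  nd <- .vnorm(direction)
  if (nd == 0) stop("`direction` must be non-zero", call. = FALSE)
  structure(list(shape = shape, radius = radius,
                 semiaxes = as.numeric(semiaxes),
                 signal_model = signal_model, offset = offset, width = width,
                 direction = direction / nd,
                 snr = snr, brightness = brightness,
                 saturation_fraction = saturation_fraction,
                 background_fraction = background_fraction,
                 spacing = .check_spacing(spacing),
                 bit_depth = as.integer(bit_depth),
                 seed = as.integer(seed)),
            class = "synthetic_cell_spec")
}

#' Generate a synthetic cell image from a specification
#'
#' Deterministic given the spec's seed.  The expected image is built first
#' (pedestal 1 plus the signal model's fixed-mass contribution on the cell;
#' constant background), scaled so the mean cell intensity is `brightness`
#' of the dynamic range;
#' Poisson shot noise plus Gaussian read noise (sd 3 photons) is applied at
#' a photon gain chosen so the SNR at the mean cell intensity matches the
#' spec; saturation clipping is applied last.
#'
#' @param spec a [synthetic_cell_spec()].
#' @param cell_id identifier of the returned record.
#' @param channel channel label.
#' @return A single-channel [cell_record()] with the generating spec and
#'   true cell mask attached as attribute `"truth"`.
#' @export
make_cell <- function(spec, cell_id = "synthetic", channel = "signal") {
  stopifnot(inherits(spec, "synthetic_cell_spec"))
  sp <- spec$spacing
  margin <- 3L
  rvox <- ceiling(spec$semiaxes / sp)
  dims <- 2L * (rvox + margin) + 1L
  center <- (rvox + margin) * sp
  idx <- seq_len(prod(dims))
  cc <- .phys_coords(idx, dims, sp)
  dz <- cc[, 1L] - center[1L]
  dy <- cc[, 2L] - center[2L]
  dx <- cc[, 3L] - center[3L]
  inside <- (dz / spec$semiaxes[1L])^2 + (dy / spec$semiaxes[2L])^2 +
    (dx / spec$semiaxes[3L])^2 <= 1
  mask <- array(inside, dims)
  ## radius of the cell along the blob direction (== radius for a sphere)
  u <- spec$direction
  r_dir <- 1 / sqrt(sum((u / spec$semiaxes)^2))
  r_ref <- min(spec$semiaxes)
  wid <- spec$width * r_ref
  blob <- function(center_off) {
    b <- center_off
    exp(-((dz - b[1L])^2 + (dy - b[2L])^2 + (dx - b[3L])^2) / (2 * wid^2))
  }
  ## each structured component carries a fixed signal mass: the biomolecule
  ## cannot leave the cell, so the envelope is truncated at the boundary and
  ## renormalized (mean contribution over the cell held constant); without
  ## this, a displaced cap sheds mass through the membrane and its measured
  ## polarity reflects the leak rather than the displacement
  fixed_mass <- function(g, mass) mass * g / mean(g[inside])
  S <- rep(1, length(idx))  # pedestal
  S <- S + switch(spec$signal_model,
    uniform = 0,
    gaussian_blob = fixed_mass(blob(spec$offset * r_dir * u), 0.5),
    two_opposite_blobs = fixed_mass(blob(spec$offset * r_dir * u), 0.25) +
      fixed_mass(blob(-spec$offset * r_dir * u), 0.25),
    ring = {
      rho <- sqrt(dz^2 + dy^2 + dx^2)
      fixed_mass(exp(-(rho - 0.65 * r_ref)^2 / (2 * (0.15 * r_ref)^2)), 0.5)
    })
  maxdn <- 2^spec$bit_depth - 1
  mean_cell <- spec$brightness * maxdn
  I_exp <- rep(spec$background_fraction * mean_cell, length(idx))
  I_exp[inside] <- S[inside] * (mean_cell / mean(S[inside]))
  vox <- .with_seed(spec$seed, {
    if (is.finite(spec$snr)) {
      read_sd <- 3
      s <- spec$snr
      lambda_mean <- (s^2 + s * sqrt(s^2 + 4 * read_sd^2)) / 2
      eta <- lambda_mean / mean(I_exp[inside])  # photons per intensity unit
      photons <- rpois(length(I_exp), I_exp * eta) + rnorm(length(I_exp), 0, read_sd)
      pmax(photons / eta, 0)
    } else I_exp
  })
  if (spec$saturation_fraction > 0) {
    qv <- quantile(vox[inside], 1 - spec$saturation_fraction, names = FALSE)
    vox <- pmin(vox * (maxdn / qv), maxdn)
  } else {
    vox <- pmin(vox, maxdn)
  }
  rec <- cell_record(list(image_stack(array(vox, dims), sp, spec$bit_depth,
                                      channel = channel)),
                     cell_id = cell_id)
  names(rec$channels) <- channel
  attr(rec, "truth") <- list(spec = spec, mask = mask, center = center)
  rec
}
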