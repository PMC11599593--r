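## a corrected channel with prescribed values on a cuboid cell, built
## without the detection path so charge arithmetic can be tested in isolation
corrected_fixture <- function(values_by_voxel, dims = c(3, 8, 8),
                              spacing = c(100, 100, 100), bit_depth = 16) {
  arr <- array(10, dims)
  m <- array(FALSE, dims)
  m[2, 2:7, 2:7] <- TRUE
  idx <- which(m)
  stopifnot(length(values_by_voxel) %in% c(1L, length(idx)))
  raw <- 100 * values_by_voxel + 10
  arr[idx] <- raw
  mask <- structure(list(mask = m, n_cell_voxels = length(idx),
                         detection_channel = "fix", threshold = 20,
                         spacing = spacing), class = "cell_mask")
  background_correct_and_normalize(image_stack(arr, spacing, bit_depth), mask)
}

test_that("charges are intensity deviations from the cell mean and conserve", {
  n <- 36L
  cc <- corrected_fixture(rep(c(0.5, 1.5), n / 2))
  f <- compute_charges(cc)
  qs <- f$q[cc$mask$mask]
  expect_equal(sort(unique(round(qs, 9))), c(-0.5, 0.5))
  expect_equal(f$q_plus, 0.5 * n / 2)
  expect_lt(abs(f$q_plus + f$q_minus), 1e-9)

  ## three-level {0, 1, 2} -> charges {-1, 0, 1}, q_plus = N/3
  cc <- corrected_fixture(rep(c(0, 1, 2), n / 3))
  f <- compute_charges(cc)
  expect_equal(sort(unique(round(f$q[cc$mask$mask], 9))), c(-1, 0, 1))
  expect_equal(f$q_plus, n / 3)

  ## uniform signal: all charges zero, centers undefined
  cc <- corrected_fixture(1)
  f <- compute_charges(cc)
  expect_identical(f$q_plus, 0)
  expect_error(charge_centers(f), "undefined")
})

test_that("charge centers are charge-weighted means in physical coordinates", {
  dims <- c(3, 8, 8)
  base <- rep(1, 36)
  ## +1 net charge at two voxels along x, equal weights -> midpoint
  cc <- corrected_fixture(base)
  ## build the field directly: charges +1 at x-index 2 and 7 of the cell
  ## row y=2, balanced by -2 at one voxel
  q <- array(0, dims)
  q[2, 2, 2] <- 1; q[2, 2, 7] <- 1; q[2, 5, 4] <- -2
  f <- structure(list(q = q, q_plus = 2, q_minus = -2, mask = cc$mask,
                      spacing = cc$spacing, bit_depth = 16, channel = "fix"),
                 class = "charge_field")
  ctr <- charge_centers(f)
  expect_equal(unname(ctr$R_plus), c(100, 100, (100 + 600) / 2))
  expect_equal(unname(ctr$R_minus), c(100, 400, 300))

  ## weights +1, +3 at x = 0 and x = 400 -> weighted mean at x = 300
  q <- array(0, dims)
  q[2, 2, 1] <- 1; q[2, 2, 5] <- 3; q[2, 5, 4] <- -4
  f$q <- q; f$q_plus <- 4; f$q_minus <- -4
  ctr <- charge_centers(f)
  expect_equal(unname(ctr$R_plus[["x"]]), 300)

  rd <- raw_dipole(c(0, 0, 3), c(0, 0, 0), 2)
  expect_equal(rd$P_raw, 6)
  expect_equal(raw_dipole(c(1, 2, 3), c(1, 2, 3), 5)$P_raw, 0)
})

test_that("max diameter and cell center match brute-force geometry", {
  sp <- c(100, 100, 100)
  mk <- function(m) structure(list(mask = m, n_cell_voxels = sum(m),
                                   detection_channel = "x", threshold = 0,
                                   spacing = sp), class = "cell_mask")
  ## single voxel
  m <- array(FALSE, c(3, 3, 3)); m[2, 2, 2] <- TRUE
  expect_identical(max_diameter(mk(m)), 0)
  ## 1x1x11 rod at 100 nm spacing -> 1000 nm end to end
  m <- array(FALSE, c(3, 3, 13)); m[2, 2, 2:12] <- TRUE
  expect_equal(max_diameter(mk(m)), 1000)
  expect_equal(unname(cell_center(mk(m))), c(100, 100, 600))
  ## L-shaped mask: centroid equals the brute-force coordinate mean and
  ## diameter the exhaustive pairwise maximum
  m <- array(FALSE, c(4, 10, 10))
  m[2:3, 2:9, 2:3] <- TRUE
  m[2:3, 8:9, 2:8] <- TRUE
  expect_equal(max_diameter(mk(m)), brute_diameter(m, sp))
  idx <- which(m); ai <- arrayInd(idx, dim(m))
  expect_equal(unname(cell_center(mk(m))), colMeans((ai - 1) * 100))
  ## anisotropic spacing is honoured
  spz <- c(300, 100, 100)
  mz <- array(FALSE, c(7, 3, 3)); mz[1:7, 2, 2] <- TRUE
  mkz <- mk(mz); mkz$spacing <- spz
  expect_equal(max_diameter(mkz), 1800)
})

test_that("support-sampled diameter agrees with exhaustive search", {
  ## digitized sphere large enough to trigger the direction-sampled path
  fx <- small_sphere_record(radius_vox = 9)
  mask <- detect_cell(fx$record)
  exact <- max_diameter(mask, exact_limit = 1e6)
  fast <- max_diameter(mask, exact_limit = 10)
  expect_lte(fast, exact)
  expect_lt(exact - fast, 0.005 * exact)
})

test_that("P_n assembles from its normalized factors", {
  ## hand arithmetic: q_plus/N = 0.13107, 16 bit, R_n1 = 0.5
  dims <- c(3, 8, 8)
  cc <- corrected_fixture(rep(1, 36))
  geom <- structure(list(M = c(z = 100, y = 450, x = 450), d_max = 800,
                         volume = 36e6, n_cell_voxels = 36L),
                    class = "cell_geometry")
  q <- array(0, dims)
  ## one +q voxel and one -q voxel 400 nm apart -> |d| = 400, R_n1 = 0.5
  q[2, 2, 2] <- 36 * 0.13107; q[2, 2, 6] <- -36 * 0.13107
  f <- structure(list(q = q, q_plus = 36 * 0.13107, q_minus = -36 * 0.13107,
                      mask = cc$mask, spacing = cc$spacing, bit_depth = 16L,
                      channel = "fix"), class = "charge_field")
  dp <- normalize_dipole(f, geom)
  expect_equal(dp$R_n1, 0.5)
  expect_equal(dp$q_n1, 0.13107 / 65535)
  expect_equal(dp$P_n, 1.0e-06) # 0.13107/65535 * 0.5 exactly
  ## alternate normalization options factorize consistently
  dp2 <- normalize_dipole(f, geom, normalization_config(charge = "mean_per_voxel"))
  expect_equal(dp2$q_n1, 0.13107)
  expect_equal(dp2$P_n, dp$P_n * 65535)
  dp3 <- normalize_dipole(f, geom, normalization_config(distance = "raw"))
  expect_equal(dp3$R_n1, 400)
  ## degenerate uniform channel: P_n defined as 0
  f0 <- compute_charges(cc)
  d0 <- normalize_dipole(f0, geom)
  expect_true(d0$degenerate)
  expect_identical(d0$P_n, 0)
})

test_that("P_n is invariant to translation, scaling and 90-degree rotation", {
  spec <- synthetic_cell_spec(signal_model = "gaussian_blob", offset = 0.5,
                              snr = 20, spacing = c(200, 200, 200), seed = 42)
  rec <- make_cell(spec)
  p0 <- analyze_cell(rec)$channels$signal$dipole$P_n
  v0 <- rec$channels[[1]]$voxels

  ## translation: circular shift of the whole frame
  for (s in list(c(1, 2, -2), c(0, -3, 1))) {
    rec_t <- as_record(circshift3(v0, s), spacing = 200)
    pt <- analyze_cell(rec_t)$channels$signal$dipole$P_n
    expect_lt(abs(pt - p0) / p0, 1e-9)
  }
  ## intensity scaling
  for (c in c(0.5, 2, 10)) {
    pc <- analyze_cell(scale_record(rec, c))$channels$signal$dipole$P_n
    expect_lt(abs(pc - p0) / p0, 1e-9)
  }
  ## 90-degree rotation about z (isotropic spacing)
  pr <- analyze_cell(as_record(rot90_z(v0), spacing = 200))$channels$signal$dipole$P_n
  expect_lt(abs(pr - p0) / p0, 1e-9)
})

test_that("P_n increases strictly with blob displacement", {
  offs <- seq(0, 0.8, by = 0.2)
  pn <- vapply(offs, function(o) {
    spec <- synthetic_cell_spec(signal_model = "gaussian_blob", offset = o,
                                snr = Inf, radius = 3000,
                                spacing = c(300, 200, 200), seed = 0)
    analyze_cell(make_cell(spec))$channels$signal$dipole$P_n
  }, numeric(1))
  expect_lt(abs(pn[1]), 1e-12) # centred blob on a symmetric grid
  expect_true(all(diff(pn) > 0))
})
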