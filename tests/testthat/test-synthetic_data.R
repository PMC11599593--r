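test_that("analytic dipole matches hand vector arithmetic", {
  ## antipodal unit charges on the 5000 nm sphere
  sc <- charge_scenario(data.frame(z = 0, y = 0, x = c(5000, -5000),
                                   magnitude = c(1, -1)))
  a <- analytic_dipole(sc)
  expect_equal(unname(a$d_vec), c(0, 0, 10000))
  expect_equal(a$P_raw, 10000)
  ## three charges: R+ = (0,0,2000), R- = (0,-3000,0)
  sc <- charge_scenario(data.frame(z = 0, y = c(0, 0, -3000),
                                   x = c(0, 4000, 0),
                                   magnitude = c(1, 1, -2)))
  a <- analytic_dipole(sc)
  expect_equal(unname(a$R_plus), c(0, 0, 2000))
  expect_equal(unname(a$R_minus), c(0, -3000, 0))
  expect_equal(sqrt(sum(a$d_vec^2)), sqrt(2000^2 + 3000^2))
  ## the uniform case has zero dipole
  a0 <- analytic_dipole(charge_scenario(data.frame()))
  expect_equal(a0$P_raw, 0)
  ## charge positions outside the sphere are rejected
  expect_error(charge_scenario(data.frame(z = 0, y = 0, x = c(6000, -1000),
                                          magnitude = c(1, -1))),
               "within the sphere")
})

test_that("rendered scenarios reproduce the analytic dipole through the pipeline", {
  ## coarse rendering (250 nm) keeps the unit test fast; interior charges
  ## avoid the surface-truncation regime, which the acceptance suite covers
  ## at fine spacing
  run <- function(df) {
    sc <- charge_scenario(df, spacing = c(250, 250, 250))
    rec <- render_scenario(sc)
    truth <- attr(rec, "truth")
    dp <- analyze_cell(rec)$channels$signal$dipole
    list(truth = truth, dp = dp)
  }
  r <- run(data.frame(z = 0, y = 0, x = c(3500, -3500), magnitude = c(1, -1)))
  expect_equal(unname(r$dp$R_plus - r$truth$center), unname(r$truth$R_plus),
               tolerance = 1e-6)
  expect_lt(abs(sqrt(sum(r$dp$d_vec^2)) - 7000) / 7000, 0.02)
  ## three-charge scenario: centers within one voxel of analytic
  r <- run(data.frame(z = 0, y = c(0, 0, -3000), x = c(0, 4000, 0),
                      magnitude = c(1, 1, -2)))
  expect_lt(sqrt(sum((r$dp$R_plus - r$truth$center - r$truth$R_plus)^2)), 250)
  expect_lt(sqrt(sum((r$dp$R_minus - r$truth$center - r$truth$R_minus)^2)), 250)
  ## zero-charge scenario: P_n = 0
  rec0 <- render_scenario(charge_scenario(data.frame(),
                                          spacing = c(250, 250, 250)))
  expect_identical(analyze_cell(rec0)$channels$signal$dipole$P_n, 0)
})

test_that("synthetic cells are deterministic and respect their spec", {
  spec <- synthetic_cell_spec(signal_model = "gaussian_blob", offset = 0.6,
                              radius = 3000, spacing = c(300, 200, 200),
                              snr = 15, seed = 9)
  a <- make_cell(spec); b <- make_cell(spec)
  expect_identical(a$channels[[1]]$voxels, b$channels[[1]]$voxels)
  ## a different seed changes the noise realization
  spec2 <- synthetic_cell_spec(signal_model = "gaussian_blob", offset = 0.6,
                               radius = 3000, spacing = c(300, 200, 200),
                               snr = 15, seed = 10)
  expect_false(identical(a$channels[[1]]$voxels, make_cell(spec2)$channels[[1]]$voxels))
  ## displaced blob is more polar than a nearly centred one
  pn <- function(o, snr) {
    s <- synthetic_cell_spec(signal_model = "gaussian_blob", offset = o,
                             radius = 3000, spacing = c(300, 200, 200),
                             snr = snr, seed = 3)
    analyze_cell(make_cell(s))$channels$signal$dipole$P_n
  }
  expect_gt(pn(0.6, Inf), pn(0.1, Inf))
  ## uniform cell at infinite SNR is exactly apolar
  su <- synthetic_cell_spec(signal_model = "uniform", radius = 3000,
                            spacing = c(300, 200, 200), snr = Inf)
  expect_identical(analyze_cell(make_cell(su))$channels$signal$dipole$P_n, 0)
  ## spec validation
  expect_error(synthetic_cell_spec(offset = 1.2), "offset")
  expect_error(synthetic_cell_spec(snr = -2), "snr")
  expect_error(synthetic_cell_spec(shape = "ellipsoid"), "semiaxes")
})

test_that("ellipsoid, two-blob and ring models produce the expected symmetry", {
  ## two opposite blobs: visually apolar, P_n near zero but d large would
  ## need two channels; here the single channel has symmetric charge
  s2 <- synthetic_cell_spec(signal_model = "two_opposite_blobs", offset = 0.6,
                            radius = 3000, spacing = c(300, 200, 200),
                            snr = Inf)
  p2 <- analyze_cell(make_cell(s2))$channels$signal$dipole$P_n
  s1 <- synthetic_cell_spec(signal_model = "gaussian_blob", offset = 0.6,
                            radius = 3000, spacing = c(300, 200, 200),
                            snr = Inf)
  p1 <- analyze_cell(make_cell(s1))$channels$signal$dipole$P_n
  expect_lt(p2, 0.05 * p1)
  ## ring: radially symmetric, also apolar
  sr <- synthetic_cell_spec(signal_model = "ring", radius = 3000,
                            spacing = c(300, 200, 200), snr = Inf)
  expect_lt(analyze_cell(make_cell(sr))$channels$signal$dipole$P_n, 0.05 * p1)
  ## ellipsoid mask has the requested aspect ratio
  se <- synthetic_cell_spec(shape = "ellipsoid", semiaxes = c(2000, 3000, 4000),
                            signal_model = "uniform", snr = Inf,
                            spacing = c(200, 200, 200))
  rec <- make_cell(se)
  an <- analyze_cell(rec)
  expect_equal(an$geometry$d_max, 8000, tolerance = 0.05)
})

test_that("brightness rescaling leaves P_n unchanged and saturation is applied", {
  base <- synthetic_cell_spec(signal_model = "gaussian_blob", offset = 0.5,
                              radius = 3000, spacing = c(300, 200, 200),
                              snr = Inf, brightness = 0.15)
  p0 <- analyze_cell(make_cell(base))$channels$signal$dipole$P_n
  for (b in c(0.075, 0.3)) {
    s <- synthetic_cell_spec(signal_model = "gaussian_blob", offset = 0.5,
                             radius = 3000, spacing = c(300, 200, 200),
                             snr = Inf, brightness = b)
    p <- analyze_cell(make_cell(s))$channels$signal$dipole$P_n
    expect_lt(abs(p - p0) / p0, 1e-9)
  }
  ## saturation clips the requested fraction of cell voxels to the top
  ssat <- synthetic_cell_spec(signal_model = "gaussian_blob", offset = 0.5,
                              radius = 3000, spacing = c(300, 200, 200),
                              snr = 20, saturation_fraction = 0.02, seed = 5)
  rec <- make_cell(ssat)
  truth <- attr(rec, "truth")
  vox <- rec$channels[[1]]$voxels
  frac <- mean(vox[truth$mask] >= 65535 - 1e-6)
  expect_equal(frac, 0.02, tolerance = 0.25)
})
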