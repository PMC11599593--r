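# dipolarity

Continuous, landmark-free quantification of the spatial polarity of a
fluorescent signal in single-cell 3D image stacks, for cell biologists who
need more than a visual polar/apolar call — e.g. for isotropic cells such
as hematopoietic stem cells, where there is no morphological feature to
anchor an angle or region measurement.

## The measure

The package transfers the molecular dipole moment to fluorescence images.
After Otsu-based cell detection, background subtraction and normalization
of the cell's mean voxel intensity to 1, each voxel carries a charge

```
q(v) = I_corr(v) / mean(I_corr) − 1
```

(positive above the cell average, negative below, summing to zero).  With
the charge-weighted centers `R+` and `R−` and the total positive charge
`q+`, the dipole moment is `P = q+ · |R+ − R−|`, computed jointly across
all z-layers, and reported in normalized, dimensionless form

```
P_n = q_n1 · R_n1,   R_n1 = |R+ − R−| / d_max,
                     q_n1 = (q+ / N_cell) / (2^bitdepth − 1)
```

with `d_max` the maximal diameter of the cell mask.  `P_n` is zero for an
even distribution, grows continuously with asymmetric clustering, and is
invariant to global intensity scaling, translation and rotation.  Derived
outputs per cell: signal amount and volume, vectors from the cell center
`M` to the charge centers, distances `d` and angles `α` between the
positive charge centers of different channels, a nucleus-position metric
`d_nucleus = 100·|M − R−(DAPI)|/d_max`, charge constriction (charge-
weighted RMS spread about each center), voxel-level Pearson colocalization
and correlation-of-correlations matrices across cell populations, plus
two-sided Wilcoxon rank-sum comparisons with the common-language effect
size `f = min(U1, U2) / (n1·n2)`.

## Worked example

Simulate a cell with a polar cap displaced 60% of the radius towards one
pole, analyze it, and compare a polar against an apolar population:

```r
library(dipolarity)

spec <- synthetic_cell_spec(signal_model = "gaussian_blob", offset = 0.6,
                            seed = 1)
cell <- make_cell(spec, cell_id = "demo")
analyze_cell(cell)
#> <cell_analysis> 'demo': 1 channel(s), 32705 cell voxels, d_max = 1e+04
#>   P_n: signal = 1.237e-06

an <- analyze_cell(cell)
an$channels$signal$dipole
#> <dipole_result> P_n = 1.23715e-06 (q_n1 = 3.02401e-06, R_n1 = 0.409108, |d| = 4091.08)
```

The charge centers sit 4091 nm apart in a cell of maximal diameter
10000 nm (`R_n1 = 0.41`), and the normalized charge puts `P_n` at
1.24e-06 — polar cells land around 1e-06 under the default normalization,
apolar cells orders of magnitude lower:

```r
polar  <- sapply(1:15, function(i) analyze_cell(make_cell(
  synthetic_cell_spec(signal_model = "gaussian_blob", offset = 0.6,
                      seed = i)))$channels$signal$dipole$P_n)
apolar <- sapply(1:15, function(i) analyze_cell(make_cell(
  synthetic_cell_spec(signal_model = "uniform",
                      seed = 100 + i)))$channels$signal$dipole$P_n)
ranksum(polar, apolar)
#> <ranksum_result> n1 = 15, n2 = 15: U = (0.0, 225.0), p = 3.392e-06 (normal_approx), CLES f = 0
median(polar); median(apolar)
#> [1] 1.24e-06
#> [1] 1.02e-09
```

Complete separation: every polar cell scores above every apolar cell
(`U_min = 0`, CLES 0).

Real data enter through per-channel TIFF files listed in a TSV manifest
(`cell_id`, `channel`, `path`):

```r
res <- run_batch("manifest.tsv", spacing = c(300, 100, 100), bit_depth = 16,
                 dapi = "DAPI", out_dir = "results", format = "tsv")
compare_groups(res_young$channels, res_old$channels, "P_n")
```

A thin command-line front-end with `analyze`, `compare` and `simulate`
subcommands is installed at `inst/cli/dipolarity.R`.

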