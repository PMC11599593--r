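---
title: "Quantifying single-cell polarity with a normalized dipole moment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying single-cell polarity with a normalized dipole moment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dipolarity)
```

## The measurement problem

Many biomolecules function through *where* they sit in a cell. Polarity --
the asymmetric clustering of a component within the cell volume -- is
usually scored visually and binarily (polar / apolar), which is subjective
and discards the continuum of intermediate states.  For isotropic, nearly
spherical cells such as hematopoietic stem cells there is no morphological
landmark (no leading edge, no apical surface) to anchor an angle- or
region-based measurement, so a landmark-free, continuous statistic is
needed.

`dipolarity` treats the fluorescence distribution of one channel inside one
cell the way physical chemistry treats charge in a molecule.  After
background correction, voxel intensities are normalized so their mean over
the cell is 1; the deviation of each voxel from that mean is its *charge*

$$q(v) = \frac{I_\mathrm{corr}(v)}{\bar I_\mathrm{corr}} - 1 ,$$

positive where the signal is denser than average, negative where it is
sparser, summing to zero by construction.  The charge-weighted barycenters
of the positive and negative charges, $R_+$ and $R_-$, and the total
positive charge $q_+$ give the dipole moment
$P = q_+ \,\lvert R_+ - R_-\rvert$, computed jointly over all z-layers.
An even distribution has coincident centers and $P = 0$; a signal piled at
one pole has well-separated centers and a large $P$.

Because cells, unlike molecules of one species, differ in size, signal
amount and camera settings, $P$ is reported in normalized form

$$P_n = q_{n1} \cdot R_{n1}, \qquad
  R_{n1} = \frac{\lvert R_+ - R_-\rvert}{d_\mathrm{max}}, \qquad
  q_{n1} = \frac{q_+ / N_\mathrm{cell}}{2^{\mathrm{bit\ depth}} - 1},$$

with $d_\mathrm{max}$ the maximal diameter of the detected cell mask and
$N_\mathrm{cell}$ its voxel count.  $R_{n1}\in[0,1]$; $P_n$ is
dimensionless, invariant to global intensity scaling, translation and
rotation, and comparable across cells.  Under these defaults $P_n$ for
polar cells lands around $10^{-6}$; its absolute scale is arbitrary and
depends on the normalization option chosen, so only like-normalized values
should be compared.  Two distance options (`max_diameter`, `raw`) and three
charge options (`bitdepth_cellsize`, `mean_per_voxel`, `raw`) are exposed in
`normalization_config()`; the factors are always reported separately so
alternative normalizations can be compared after the fact.

## Pipeline

1. **Cell detection** (`detect_cell`).  Otsu's threshold is computed on a
   256-bin histogram of the full crop, on a designated channel or on the
   voxel-wise sum of all channels (the default, so that every channel of a
   cell shares one mask, one center $M$ and one $d_\mathrm{max}$ -- the
   inter-channel distances and angles require a common frame).  The largest
   26-connected above-threshold component is kept, enclosed holes are
   filled.  Debris smaller than the cell is discarded with a warning.
   When the between-class variance has an exact plateau (an empty histogram
   gap between background and cell), the middle cut of the plateau is used.
2. **Background correction and normalization**
   (`background_correct_and_normalize`).  The mean background-voxel
   intensity is subtracted; negative residuals are clamped to zero by
   default (intensities are photon counts; the clamp is configurable); the
   result is divided by its mean over the cell.
3. **Charges, centers, dipole** (`compute_charges`, `charge_centers`,
   `normalize_dipole`).
4. **Derived geometry** (`pair_geometry`, `nucleus_position`,
   `constriction`, `channel_summary`) and **colocalization**
   (`pearson_voxels`, `correlation_of_correlations`).

`analyze_cell()` runs all of this for one multichannel cell;
`run_batch()` maps it over a TSV manifest with per-cell error isolation.

### Numerical choices

* Axis order is `(z, y, x)` everywhere; voxel positions are voxel centers
  at `(index - 1) * spacing`, with per-axis physical spacing so anisotropic
  z-steps are handled in physical units.
* A 2D image is a one-layer stack; 26-connectivity degrades to
  8-connectivity there.
* $d_\mathrm{max}$ is the maximum pairwise distance between surface-voxel
  centers.  Small surfaces are solved exhaustively; beyond 4000 surface
  voxels support-point sampling over 1024 Fibonacci directions is used,
  whose relative underestimate is bounded by $1-\cos\theta$ of the angular
  mesh (about 0.2%), below one voxel diagonal at practical resolutions.
* A perfectly uniform channel ($q_+ = 0$) is reported as $P_n = 0$ with a
  `degenerate` flag rather than `NaN`: the polarity of an even distribution
  is zero, and population statistics should not lose such cells.
* Degenerate pair angles (a charge center coinciding with $M$) are flagged
  `NA`; the distance is still reported.
* The angle $\alpha$ is unsigned, in $[0, 180]$ degrees; its cosine is
  clipped to $[-1, 1]$ before `acos`.

## Group statistics

Populations are compared with the two-sided Wilcoxon rank-sum test:
$U_1 = n_1 n_2 + n_1(n_1+1)/2 - R_1$ from the rank sum $R_1$ (midranks for
ties), exact null distribution when $\min(n_1,n_2) \le 8$ without ties,
otherwise the tie- and continuity-corrected normal approximation -- the
regime actually exercised by per-cell metrics with hundreds of cells.  The
common-language effect size $f = \min(U_1,U_2)/(n_1 n_2)$ (the folded
ROC-AUC) is reported alongside, with the directional variant
$\mathrm{auc} = P(x > y) + \tfrac12 P(x = y)$ under a separate name since
$f$ deliberately drops direction.  Pearson and Spearman correlations of
per-cell metrics delegate to `stats::cor.test`.

## The validation harness

The package ships its own ground-truth machinery rather than relying on
expert-scored images.

**Analytic point-charge oracle.**  `charge_scenario()` places point charges
inside a 5000 nm sphere; `analytic_dipole()` computes $R_+$, $R_-$ and the
dipole in closed form from the point list.  `render_scenario()` digitizes
the sphere (uniform pedestal at 30% of the dynamic range over a 2%
background) and deposits each charge as a narrow Gaussian intensity
increment or decrement, and the full image pipeline must recover the
analytic answer.  Two rendering decisions matter:

* *Kernel width.*  Each charge is deposited with a Gaussian kernel of
  $\sigma = 0.75$ voxels, mass-renormalized over in-sphere voxels.  A wide
  kernel centred on a *surface* charge loses its outward half to the cell
  boundary, biasing the rendered center inward by roughly $0.8\sigma$; at
  $\sigma = 2$ voxels and 100 nm spacing that is a 3% error on the
  antipodal charge separation, larger than the discrepancy being measured.
  At $\sigma = 0.75$ the bias stays near 1%, and interior charges are
  recovered to machine precision (a symmetric discrete kernel centred on a
  voxel has that voxel as its exact barycenter).
* *No quantization.*  Rendered intensities stay floating point;
  quantization is a property of file export (`write_tiff_stack`), not of
  the validation geometry.  Rounding a smooth bump onto a deep pedestal
  would add a spatially correlated residual charge comparable to the bump
  itself.

At 100 nm spacing the pipeline reproduces $\lvert d\rvert$ within 2% (the
antipodal worst case; interior scenarios are essentially exact) and the
dipole direction within a small fraction of a degree.

**Synthetic cells.**  `make_cell()` renders spherical or ellipsoidal cells
carrying one of four signal models on a unit pedestal: `uniform` (apolar),
`gaussian_blob` (a polar cap at `offset` $\times$ radius along a
direction), `two_opposite_blobs` (two equal poles -- visually apolar) and
`ring` (a shell).  Key design decisions:

* *Fixed-mass caps.*  Each structured component deposits a fixed total
  signal mass inside the cell: its Gaussian envelope is truncated at the
  membrane and renormalized, because the biomolecule cannot leave the
  cell.  A fixed-amplitude cap would shed mass through the boundary as it
  is displaced, so that the measured polarity of large displacements
  reflects the leak rather than the position -- with conserved mass, $P_n$
  grows strictly with displacement over the whole 0--0.8 radius range at
  the natural cap width of $0.35 r$.
* *Camera model.*  Poisson shot noise plus Gaussian read noise (sd 3
  photons), with the photon gain chosen so the SNR at the mean cell
  intensity matches the requested value; `snr = Inf` is noise-free.
  Saturation is applied last: with `saturation_fraction` $= f$, exposure is
  scaled so the brightest $f$ of cell voxels clip at the top of the dynamic
  range.  The defaults -- 5000 nm radius, 200 nm lateral / 400 nm axial
  spacing, 16 bit, SNR 20, mean cell intensity at 15% of range with
  background at 3% of the cell mean -- mimic widefield stacks of small
  round cells; brightness enters as exposure scaling of cell and background
  together, leaving headroom so doubled exposure does not clip the cap
  peak.
* All randomness flows through the spec's single seed; a fixed spec is
  bit-reproducible.

What these emulations deliberately omit: optical blur (the PSF), bleed-
through between channels, autofluorescence texture, irregular cell shapes
and touching cells.  Passing the harness therefore demonstrates
correctness of the *measure* and its invariances on resolvable geometry,
not segmentation robustness on hard real-world images -- single-cell crops
of reasonable quality remain the intended input.

## Validation summary

The test-suite and `scripts/acceptance.R` recompute, from scratch: the
analytic-oracle agreement on five sphere scenarios at 100 nm; the zero
limit for uniform cells; invariance of $P_n$ under intensity scaling
(0.5--10$\times$), in-frame translation, axis-aligned and arbitrary-angle
rotation; strict monotonicity of $P_n$ in cap displacement (noise-free
single cells, and medians of 30-cell populations at SNR 10); separation of
30 polar versus 30 apolar cells (rank-sum $p$, CLES, quartile gap); charge
conservation on random cells; exact agreement of $U$ and CLES with a
pair-counting oracle plus the empirical type-I error at the nominal level;
the colocalization limiting contracts; and the stability of the population
median under SNR halving and 1% saturation.  Problem sizes (30 cells per
condition, 100 nm oracle rendering, 10,000 null simulations) were chosen so
each property is measured with comfortable statistical margin on a single
CPU.

## Known limitations

* Cropping single cells out of wide fields is upstream of this package;
  the detector assumes one dominant cell per crop.
* The $q_{n1}$ charge normalization makes $P_n$'s absolute magnitude
  convention-dependent; compare only like-normalized values, and prefer
  reporting the factorized $(q_{n1}, R_{n1})$ alongside $P_n$.
* Low-contrast images compress the charge field and can understate
  polarity; the normalized distance $R_{n1}$ alone is the more robust
  comparator there.
* Coarse axial sampling weakens the z-component of the dipole and widens
  the spread of $P_n$ across cells; with tens of cells per group the effect
  on group comparisons is minor.
* Filamentous, multi-level structures (e.g. microtubule networks) can be
  polar per z-level yet apolar in aggregate; a 3D summary statistic cannot
  resolve that by construction.
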