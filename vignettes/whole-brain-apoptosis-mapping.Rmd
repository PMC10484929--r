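---
title: "Whole-brain volume-fraction mapping of apoptotic cells: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Whole-brain volume-fraction mapping of apoptotic cells: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

brainfrac quantifies punctate immunostaining — typically cleaved caspase-3,
the executioner-caspase fragment marking apoptotic cells — in light-sheet
stacks of cleared perinatal mouse brains, and reports per-region *volume
fractions*: positive voxels divided by total voxels in each anatomical
region, as a percentage. This vignette explains the underlying models, the
parameters that matter, what the synthetic phantoms do and do not emulate,
and the design choices made where more than one reasonable option existed.

## The measurement model

The 3D analysis chain treats an acquired antibody-channel stack as

$$I(v) \;=\; B(v) \;+\; \sum_k A\, e^{-\|v - c_k\|^2 / 2\sigma_b^2} \;+\; \varepsilon(v),$$

a smooth background $B$, bright somata approximated by isotropic Gaussian
blobs of amplitude $A$ at centers $c_k$, and additive noise $\varepsilon$.
Quantification proceeds in four steps, each exposed as its own function:

1. **Brain masking** (`brain_mask()`). The autofluorescence channel is
   Gaussian-blurred slicewise ($\sigma_{xy} = 10$ voxels) and thresholded at
   a user-defined level; the largest 3D connected component is kept. The
   threshold is deliberately not defaulted — it depends on the acquisition —
   but an Otsu fallback is available as an explicit opt-in.
2. **Noise estimation** (`estimate_noise_sigma()`). The noise scale is half
   the spread between the 16th and 84th percentiles of the *raw* voxel
   values inside the mask — the percentile pair that brackets $\pm 1\sigma$
   of a Gaussian. Percentiles interpolate linearly between order statistics.
   This estimator is robust to the sparse bright blobs but *not* to strong
   smooth intensity structure inside the brain; see the phantom design
   below.
3. **Band-pass** (`bandpass()`). A difference-of-Gaussians,
   $G_{\sigma=1} \ast (I - G_{\sigma=6} \ast I)$, applied slicewise in the
   imaging plane. The high-pass removes the smooth background (a constant
   image maps exactly to zero); the low-pass suppresses single-voxel noise.
   All sigmas are in-plane only: the z step (3.5 µm) differs from the xy
   pitch, so filtering stays within acquisition planes.
4. **Classification and fractions** (`classify_positive()`,
   `regional_volume_fraction()`). A voxel is positive when its filtered
   value exceeds $k \cdot \hat\sigma_{\text{noise}}$ (default $k = 2$;
   one-sided, bright). Fractions are reported per atlas region plus a
   whole-brain row defined as the union of the regions, so the whole-brain
   positive count is exactly the sum over regions.

Two conventions deserve a note because the alternatives are also
defensible. The threshold is applied to the *signed* filtered value (bright
objects only), not its absolute value. And the noise sigma is computed on
the raw image before filtering, following the order of the processing
steps; a `sigma_on_filtered` flag exists for sensitivity analysis.

## Atlas reconstruction from sparse annotations

Regional anatomy enters as manual outlines of each region on a sparse
subset of planes (typically 50 horizontal slices, with an optional coronal
group overriding inside its slab — mirroring a two-stage annotation where
cortical subdivisions are drawn separately). `interpolate_atlas()`
reconstructs the dense label volume by *shape-based interpolation*: each
annotated region on each annotated plane is converted to a signed Euclidean
distance map (negative inside); distances are interpolated linearly between
consecutive annotated planes; a voxel takes the region whose interpolated
distance is most negative, ties going to the lower region id, and label 0
(outside brain) where no distance is negative.

This scheme was chosen over nearest-plane label copying because it produces
smooth boundaries and is analytically testable: for concentric circles the
signed distance is linear in the radius, so a circle interpolated halfway
between radii 10 and 20 must have radius 15 — one of the unit tests. Two
properties are guaranteed by construction and verified in tests: the
labels partition the in-brain volume (each voxel exactly one label), and
interpolating a dense atlas's own planes at full density returns the atlas
unchanged.

## Landmark registration

Stacks are aligned by a two-landmark rule: each brain carries a line drawn
between two recognizable landmarks, and the pose is read off that line —
rotation about z from its in-plane direction, isotropic scale from its
in-plane length, translation from its first endpoint. Brains are assumed
flat-landed (no tilt about x or y), so z is handled by translation only.
Whether z should be stretched by the same in-plane factor is not determined
by the two-landmark construction; the package applies the same factor by
default and exposes `scale_z = FALSE` as the alternative. Intensities are
resampled trilinearly, label volumes with nearest-neighbour interpolation;
coordinates are 0-based voxel centers.

## The 2D cell detector

`detect_cells()` reimplements a standard "general cell counter"
parameterization for confocal slices: optional median filter; Gaussian
high-pass with $\sigma = 8\,\mu m$ (converted to pixels at 0.645 µm/px);
local mean threshold over a disk of radius 25 px with offset $-30$;
8-connected components; area filter 15–140 µm²; circularity filter
$4\pi A / P^2 \in [0.1, 1]$; minimum-distance suppression at 1 µm.

Three conventions are worth stating plainly:

* **Offset sign.** A pixel is foreground iff
  `value > local_mean - offset`; the default offset of $-30$ therefore
  demands the pixel to exceed its local mean *by* 30 units. This matches
  the common "Mean" auto-local-threshold convention. A consequence is that
  a perfectly uniform (even saturated) channel contains no foreground —
  there is no local contrast to detect.
* **Perimeter estimator.** Circularity uses a Moore-contour trace with
  corner-corrected step weights (0.948 per axial, 1.340 per diagonal step).
  Naive pixel-edge counting overestimates the perimeter of digitized disks
  by up to a factor $4/\pi$ and would push genuine disks below common
  circularity cutoffs; with the corrected estimator a digitized disk scores
  $\geq 0.85$ (clipped at 1) and a 1×40 px line scores below 0.1.
* **Suppression rule.** When two accepted detections fall closer than the
  minimum distance, the larger area survives; ties break by lower (row,
  column) centroid, making detection deterministic.

Laminar assignment bins detected centroids into half-open row bands
$[b_i, b_{i+1})$ between externally supplied layer boundaries (layer
delineation from a nuclear stain is an *input*, not something the package
infers), with an explicit "outside" sentinel. Marker colocalization calls a
cell positive for a marker when at least half its pixels (configurable)
pass the same local-mean rule on the marker channel; the true overlap
criterion used in manual co-expression counting is unknowable, so this
threshold is exposed rather than claimed faithful.

## Statistics

Group comparisons use the two-tailed Mann–Whitney U test with the *exact*
small-sample null: for tie-free samples with $n_1 + n_2 \le 25$ the null
distribution of $U$ is enumerated by the standard counting recursion
(equivalently, partitions of $u$ into at most $n_1$ parts each $\le n_2$),
and the two-sided p-value is $2\min(P(U \le u), P(U \ge u))$ capped at 1.
This convention reproduces the printed p-values of the motivating study
exactly (e.g. $U = 4$ at $n = 6, 10$ gives $24/8008 = 3.00\times10^{-3}$),
and the smallest attainable p-value is $2/\binom{n_1+n_2}{n_1}$. Ties or
larger samples switch to a tie-corrected normal approximation, flagged in
the output — the approximation is never silently substituted for the exact
test.

Three paired conditions are compared with the Friedman test
($\chi^2 = \frac{12}{nk(k+1)}\sum_j R_j^2 - 3n(k+1)$ on within-row ranks)
followed by Dunn's post-hoc: $z = |\bar R_i - \bar R_j| / \sqrt{k(k+1)/6n}$
with Bonferroni adjustment over all $k(k-1)/2$ pairs. Normality checking
delegates to the standard Shapiro–Wilk implementation. Summaries follow the
field's reporting style: median [IQR] by default (type-7 quantiles),
mean (s.d.) for histological counts.

No multiple-testing correction is applied across regions by default — the
per-region raw p-values are the primary output, matching how such regional
screens are reported — but `run_config(fdr = TRUE)` adds
Benjamini–Hochberg adjusted values.

## The synthetic phantoms: what they emulate, and what not

Because raw whole-brain images of this kind are not publicly deposited, the
package ships a generator whose defaults *are* the study conditions, and
every end-to-end claim is made against its known ground truth.

The 3D phantom is an ellipsoidal "brain" (semi-axes 52 × 56 × 40 voxels in
a 128 × 128 × 96 grid at 5 × 5 × 3.5 µm) partitioned into the seven
perinatal regions — myelencephalon, metencephalon/midbrain, diencephalon,
hippocampus, neocortex, striatum, cerebellum — as anterior–posterior bands
plus a central core ball standing in for the hippocampus. The exact
geometry is a free design choice; what matters is that regions are
connected, non-empty, and span a realistic range of sizes (from ~4% to
~20% of the brain). Positivity ground truth is defined at the blob
half-maximum: a voxel is truly positive when the noise-free blob signal
exceeds $A/2$, which makes the truth mask unambiguous and countable. Blobs
($\sigma_b = 2$ voxels) are planted wholly inside their region without
overlap until the planted count reaches the requested regional fraction to
within half a blob volume; requesting an unreachable fraction is an error
naming the region.

Two generator defaults encode method assumptions rather than arbitrary
taste, and were fixed by analysis before the acceptance runs:

* **The antibody channel background is dim** (level 20 vs noise sigma 8).
  The percentile noise estimator and the 2σ threshold assume the raw
  in-brain intensity distribution is noise-dominated; that is realistic for
  a far-red antibody channel in cleared tissue, where nonspecific signal is
  low and the bright anatomical signal lives in the separate
  autofluorescence channel (level 120, used only for masking behind a σ=10
  blur). A bright antibody-channel background with a sharp tissue edge
  would leave a high-pass residual halo of order half the edge height at
  the brain surface — a genuine property of difference-of-Gaussians
  thresholding, not an artifact of this implementation.
* **Blob amplitude 45 ≈ 5.6 × noise sigma.** The classifier measures the
  area inside its $2\hat\sigma$ contour, the truth is the half-maximum
  contour; these coincide only at a particular contrast. From the 2D
  transfer factors of the band-pass ($\sigma_b^2/(\sigma_b^2+\sigma^2)$ per
  Gaussian stage), the filtered center-slice blob peak is ≈ 0.70 A and the
  filtered value at the half-maximum radius ≈ 0.37 A; with $A = 45$ and
  $\hat\sigma \approx 8$ the $2\hat\sigma$ threshold (≈ 16) sits near that
  contour, and summing the per-slice threshold areas over the blob's z
  extent gives a measured-to-true volume ratio close to 1. Measured
  whole-brain medians on seeded cohorts land within ~±15% of truth.

Known, deliberate simplifications: no point-spread anisotropy, stripe
artifacts, vignetting, or intensity falloff with depth; no nuclei
rendering for the nuclear-stain channel; per-animal variability is a
single multiplicative lognormal jitter of the regional fractions
($\sigma_{\log} = 0.15$ by default, right-skewed and positive like real
fraction data). Passing the recovery tests therefore demonstrates that the
*chain is implemented correctly and is unbiased at calibrated contrast*;
it does not certify performance on real stacks with structured
backgrounds, where the user-set mask threshold and the dim-background
assumption must be judged against the data.

Residual measurement biases visible on phantoms are worth knowing: regions
dominated by the ellipsoid rim read slightly high at low density (edge
residuals), and small dense regions read low (each blob raises its own
local mean, shrinking the threshold contour). Whole-brain medians stay
within the 25% recovery band; group *ordering* is preserved in every
region with a planted effect.

The 2D phantom plants disk-shaped cells of known rasterized pixel area
(e.g. a radius-4 px disk is exactly 49 px ≈ 20.4 µm² at 0.645 µm/px) on a
noisy background, with marker-channel memberships and layer boundaries
supplied explicitly; planted cells closer than a minimum rim separation are
rejected so the truth stays unambiguous.

## Problem sizes and numerical choices

The shipped test suite exercises unit properties on a reduced 64 × 64 × 48
phantom and runs the full-size 128 × 128 × 96 cohort analysis (6 control
vs 10 treated animals) end to end, including 20 seeded effect cohorts for
the power property and 12 seeded no-effect cohorts for specificity; these
sizes keep a complete run comfortably on a single core while leaving the
statistics at the study's own sample sizes. Gaussian kernels are truncated
at 4σ and renormalised (row-wise) so constants are preserved exactly at
image borders — the property the DC-removal contract of the band-pass
relies on. Percentiles are type-7 (linear interpolation); connected
components are 8-connected in 2D and 6-connected in 3D; all randomness
flows from explicit seeds through a local RNG that never touches the
caller's state.

## Limitations

* The registration model is deliberately minimal (rotation about z,
  isotropic scale, translation): no tilt, no affine or elastic refinement.
  It is exact on its defining landmarks and is not intended to correct
  mounting tilt.
* Exact Mann–Whitney enumeration with ties is out of scope; ties trigger
  the flagged normal approximation.
* The Friedman/Dunn layer requires complete blocks. Real designs sometimes
  report unequal group sizes for "paired" conditions; such data must be
  reduced to complete rows (or analysed elsewhere) before entering
  `friedman_dunn()`.
* Whole-brain totals are defined as the union of atlas regions; masked
  voxels outside every region do not contribute.
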