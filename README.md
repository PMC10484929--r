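# brainfrac

Whole-brain quantification of apoptotic (cleaved caspase-3 positive) cells
in light-sheet stacks of cleared perinatal mouse brains — and everything
needed to validate that quantification end to end on synthetic data with
known ground truth.

Anesthetic exposure during the brain growth spurt increases programmed cell
death, and the effect is anatomically heterogeneous: whole-brain screens
report regional volume fractions of cleaved caspase-3 staining and compare
small groups of animals per region. This package implements that analysis
chain for R users:

* **Landmark registration** — a pose (rotation about z, isotropic scale,
  translation) read off a line drawn between two landmarks;
  `pose_from_landmarks()`, `apply_pose()`.
* **Atlas reconstruction** — a dense 7-region label volume interpolated
  from sparse per-slice manual annotations via signed-distance maps;
  `interpolate_atlas()`.
* **Voxel classification** — brain masking on a blurred autofluorescence
  channel, noise sigma from the 16th/84th in-brain percentiles
  (half the spread brackets ±1σ), difference-of-Gaussians band-pass
  (σ_hp = 6, σ_lp = 1 voxels, slicewise), threshold at 2·σ_noise;
  `quantify_stack()`.
* **Volume fractions** — per region, `fraction = 100 · positive/total` %,
  plus a whole-brain row; `regional_volume_fraction()`.
* **2D cell detection** — Gaussian high-pass (8 µm), local-mean disk
  threshold (radius 25 px, offset −30), 8-connected components, area
  (15–140 µm²) and circularity (0.1–1.0) filters, laminar assignment and
  marker colocalization; `detect_cells()`, `assign_layers()`,
  `colocalize()`.
* **Exact small-sample statistics** — two-tailed Mann–Whitney U with the
  null distribution enumerated exactly (p = 2·min tail, capped at 1),
  Friedman + Dunn–Bonferroni for three paired conditions, Shapiro–Wilk,
  median [IQR] / mean (s.d.) summaries; `mann_whitney_exact()`,
  `friedman_dunn()`.
* **Synthetic phantoms** — ellipsoidal 7-region brains with planted
  Gaussian blobs at known regional fractions, and 2D slices with
  disk cells of exactly known area; `phantom_spec_3d()`,
  `generate_brain_volume()`, `generate_group_experiment()`,
  `generate_cortex_slice()`.
* **Pipeline** — `run_end_to_end()` composes simulate → atlas → quantify →
  statistics into a deterministic, seeded report.

Arrays are (y, x, z) — row, column, slice — with physical spacing in µm
(default 5 × 5 × 3.5). See the vignette
(`vignettes/whole-brain-apoptosis-mapping.Rmd`) for the models, parameter
semantics and design rationale.

## Worked example

Simulate a two-group cohort at the study's sample sizes (6 controls vs 10
treated, whole-brain truth fractions 0.5% vs 1.6%, a 3.7× effect in the
neocortex-like region), run the full chain, and test each region:

```r
library(brainfrac)

ctrl <- phantom_spec_3d(
  region_fractions = setNames(rep(0.005, 7), as.character(1:7)))
trt_fr <- setNames(rep(0.016, 7), as.character(1:7))
trt_fr["5"] <- 0.005 * 3.7
trt <- phantom_spec_3d(region_fractions = trt_fr)

report <- run_end_to_end(run_config(ctrl, trt, n_control = 6, n_treated = 10,
                                    seed = 42, atlas_source = "interpolated"))
report
#> <run_report>
#>   whole brain, control: 0.634 [0.586-0.693] % (n = 6)
#>   whole brain, treated: 1.69 [1.61-1.75] % (n = 10)
#>   per-region two-tailed exact Mann-Whitney:
#>  region_id            region_name  U            p method
#>          1         myelencephalon 60 0.0002497502  exact
#>          2 metencephalon/midbrain 60 0.0002497502  exact
#>          3           diencephalon 60 0.0002497502  exact
#>          4            hippocampus 60 0.0002497502  exact
#>          5              neocortex 60 0.0002497502  exact
#>          6               striatum 60 0.0002497502  exact
#>          7             cerebellum 60 0.0002497502  exact
#>          0            whole brain 60 0.0002497502  exact
```

Reading this: the measured whole-brain medians (0.63% and 1.69%) recover
the planted group levels (0.5% and 1.6%, modestly inflated by the bright
rim residuals discussed in the vignette); every region shows complete
group separation
(U = 60 is the maximum at n = 6, 10), so each exact p-value is the smallest
attainable, 2/choose(16, 6) ≈ 2.5 × 10⁻⁴. With the weaker effects of real
data, intermediate U values arise; e.g. `mw_exact_p(4, 6, 10)` returns
24/8008 ≈ 3.00 × 10⁻³.

A thin command-line wrapper over the same functions is installed at
`inst/cli/brainfrac.R` (subcommands `simulate`, `register`, `build-atlas`,
`quantify`, `stats`).

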