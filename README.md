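# vesicoloc

Object-based co-localization of the gut hormones **INSL5, GLP-1 and PYY** in
secretory vesicles of colonic enteroendocrine L-cells, from three-channel 3D
fluorescence z-stacks. The package is aimed at microscopists and
quantitative biologists who need to decide, vesicle by vesicle, whether
several immunolabelled peptides are stored together — a question that
volume-overlap co-localization measures answer badly, because the
single-colour rim voxels of a genuinely co-labelled vesicle are counted as
single-labelled signal.

## The method

For each cell the pipeline runs:

1. **Detection**, per channel, in two modes: *bright* spots from a
   three-class histogram split (top Otsu class), *dim* spots from two-class
   Otsu binarization keeping 26-connected components with voxel count
   12 < np < 250. Candidates from all channels are pooled and duplicates
   (within 2 pixels) removed, brighter candidate wins.
2. **Sub-pixel localization**: per channel, bounded Levenberg–Marquardt
   fits of anisotropic 3D Gaussians (joint mixture fits where windows
   overlap). Insignificant fits (amplitude ≤ 5 × residual sd — i.e. no real
   spot in that channel's window) fall back to the window centroid.
3. **Chromatic registration**: channels are translated so their mean
   vesicle positions (over spots converged in every channel) coincide.
4. **Separation prefilter**: the three channel positions of a vesicle must
   lie pairwise within 200 nm, else the vesicle is excluded.
5. **Classification**: per channel, the mean normalized intensity in a
   150 nm sphere minus image background; calls are positive (> 0.05 of the
   channel maximum), negative (< 0.02) or indeterminate (dead band).
   Categories: single / double / triple / indeterminate.
6. **Sizing**: 1D Gaussian fits to x-axis line profiles; apparent size σ
   (and FWHM = 2√(2 ln 2) σ), fits kept only when R² > 0.75; distribution
   summarized as median with bootstrap 95% CI.

A synthetic-stack generator (`sample_vesicle_field()`, `render_stack()`)
renders ground-truth vesicle fields as PSF-blurred Gaussians with
shot-dominated noise and per-channel chromatic shifts, so every stage is
testable against known truth. Companion assay statistics implement
protein-normalized secretion fold changes, Dunn post-hoc tests against
control, inter-hormone Pearson correlations, qPCR relative expression
(2^ΔCT, undetermined CT → 40, ratio paired t-test) and calcium fold
responses with a Wilcoxon signed-rank cohort test.

## Worked example

```r
library(vesicoloc)

cfg   <- imaging_config(shape_voxels = c(16, 128, 128), seed = 7)
truth <- sample_vesicle_field(60,
           category_fractions(triple = 0.9, double = 0.05, single = 0.05),
           cfg, rng_seed = 7)
cell  <- render_stack(truth, cfg)
res   <- analyze_cell(cell, cell_id = "1.01")
res$summary
#>  cell_id n_detected n_prefilter_pass n_single n_double n_triple n_indeterminate
#>     1.01         61               60        5        1       54               0
#>  pct_single pct_double pct_triple
#>    8.333333   1.666667         90
```

The generator drew 53 triple, 2 double and 5 single vesicles for this seed;
the pipeline detects 61 candidate spots, passes 60 through the 200 nm
separation prefilter, and classifies 90% of the determinate vesicles as
containing all three peptides — recovering the simulated co-storage
fraction. `res$records` holds the per-vesicle positions (nm), normalized
intensities and calls; `write_results()` exports them as CSV + JSON, and
`write_stack()` / `read_stack()` round-trip stacks as float TIFF with an
OME companion metadata file.

A thin CLI over the same functions is in `inst/cli/vesicoloc.R`
(`simulate`, `analyze`, `secretion-stats` subcommands).

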