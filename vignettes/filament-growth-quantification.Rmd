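---
title: "Quantifying filamentous cyanobacteria growth in microcapillary strips"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying filamentous cyanobacteria growth in microcapillary strips}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(filatrack)
```

## The measurement model

*Oscillatoria*-type cyanobacteria grow as trichomes — chains of
disk-shaped cells — that elongate exclusively by adding new cells at one
or both tips (apical growth). Inside a sealed fluoropolymer microcapillary
lane (~206 µm bore) a filament cannot glide or entangle, so a weekly
micrograph series of a fixed field of view observes the *same* filament
repeatedly. Growth quantification then reduces to three steps:

1. measure the projected area `A_filament(t)` of each filament,
2. convert area to a cell count with a per-cell area calibration,
   `n_cells(t) = A_filament(t) / A_cell`,
3. convert counts to lengths, `L_filament(t) = n_cells(t) * L_cell`.

The calibration constants come from SEM morphometry of individual cells:
mean length `L_cell = 1.8 ± 0.4` µm (along the filament axis), mean width
`W_cell = 3.9 ± 0.7` µm, and mean projected area
`A_cell = 6.844 ± 2.194` µm² (n = 56 cells).

A point worth stressing: `A_cell` (6.844) is *not* `L_cell x W_cell`
(7.02). The measured mean of the per-cell length x width products is
smaller than the product of the means, implying negative covariance
between a cell's length and width. `measure_cells()` therefore computes
`A_cell` as the mean of per-cell products when raw measurements are
available, and the package default `oscillatoria_morphometry()` carries
the measured 6.844 µm² — never the 7.02 µm² product. Cell counts are kept
fractional throughout; rounding happens only at report serialization
(counts to 1–2 decimals, lengths to 1 decimal).

## Imaging: lane detection and segmentation

Lanes are found from the smoothed cross-lane mean-intensity profile:
capillary interiors are bright, walls dark. Bands above the midpoint
threshold become lane ROIs. A dense dark filament can drag part of a
lane's profile below the midpoint and split its band in two, so bands
separated by a gap whose profile stays well above the wall level (walls
sit at the global minimum) are re-merged before the `n_lanes` widest
bands are kept. If profile contrast is below 0.05 the image is
partitioned into equal bands instead (uniform images carry no lane
information).

Within a lane ROI, foreground is "darker than an Otsu threshold"
(filaments absorb light; polarity is configurable). Otsu's criterion has
a known failure mode that matters here: when foreground occupies well
under ~1% of the ROI, splitting the *background noise distribution* can
yield a higher between-class variance than the true foreground/background
split. `segment_filaments()` therefore validates the Otsu result (the
class means must differ by at least `min_contrast`, default 0.15) and
falls back to a robust background model — threshold = median − 6 × MAD of
the ROI — which handles both nearly-empty lanes (no pixels qualify) and
lanes with a single small filament. Components are labeled with
8-connectivity (compiled two-pass union-find, tested against a pure-R
flood fill), filtered at `min_cells = 3` cell-equivalents (~20.5 µm², a
debris gate), and flagged when they touch the lateral image border
(truncated area would bias Eq. 1); flagged observations are kept but
excluded from growth statistics. Touching filaments are not split — the
synthetic generator enforces a 5 µm gap, and a component exceeding 150
cell-equivalents triggers a warning as a possible overlap.

Micrograph pixel size is not standardized (the microscope magnification
is configuration, not data), so `pixel_size_um` is a required parameter
everywhere an image enters the pipeline.

## Tracking

Filaments in sealed capillaries are effectively static and only grow.
Between consecutive timepoints, observations within the same lane are
matched by a globally optimal one-to-one assignment (Hungarian algorithm,
via `clue::solve_LSAP`) minimizing summed centroid distance, subject to a
displacement gate (`max_centroid_shift_um = 20`; apical growth moves a
centroid by at most ~half the added length, ~7 µm per week at the largest
observed increments) and a shrinkage gate
(`max_relative_shrinkage = 0.1`; filaments never lose appreciable area,
so a >10% decrease indicates a mismatch). Distance ties are broken by
smaller area difference, then by along-lane position, keeping matching
deterministic. Tracks chain consecutive links only — a filament missed at
one timepoint ends its track, mirroring a manual protocol of continuous
weekly relocation. Weekly increments are differences of consecutive
fractional cell counts; they may be slightly negative under measurement
noise, and they are clipped to zero only in the hormogonium analysis
(biological growth cannot be negative; noise can).

## Growth statistics

Filaments are grouped by initial cell number into 0–50, 50–100, and
100–150. The bins are half-open at 50 and 100 and closed at 150; the
boundary membership is a package decision (the grouping's source never
states it), and counts above 150 are excluded with a warning unless the
top bin is extended. The rate of increase of population dN/dt is the OLS
slope of the *group-mean* cell number against time. Fitting on group
means (rather than pooled per-filament points) is adopted because the
packaged reference growth curves reproduce all three published slopes
under that convention; a per-filament-slope alternative is available via
`fit = "per_filament"`. The normalized rate divides the slope by the mean
over timepoints of the group-mean cell number — the natural reading of
"rate normalized to population size" when N is otherwise undefined.

Group comparisons per weekly interval use single-factor ANOVA and
pairwise two-tailed Student t-tests with pooled variance at alpha = 0.05,
with no multiple-testing correction by default (a Bonferroni flag
exists). Significance letters are maximal cliques of the
non-significance graph, so groups sharing no letter differ at p < 0.05.

Very short filaments that do not grow are flagged "hormogonium-like":
initial count at or below 28 cells (~50 µm, the upper end of the
plausible hormogonium size range of ~6–28 cells) and total clipped
increment below one cell over the experiment.

## The synthetic generator: what it emulates, and what it does not

`make_paper_like_experiment()` builds the reference design: 20 filaments
(7/7/6 across the three size groups, initial sizes uniform on 20–45,
55–95, 105–145 cells), one filament per 206 µm lane, 2 strips x 10
lanes, observed at days 0, 7, 14, 21, 28. Per week each filament adds
`round(X)` cells, X ~ Normal(mean, sd) truncated at zero with
group/week-specific parameters from the default growth schedule; the
increment is split between the two tips by a fair coin per cell.
Truncated-normal increments (rather than Poisson) honor the schedule's
printed SDs; rounding makes ground-truth counts whole cells, while
measured counts stay fractional. Ground-truth area is *defined* as
`count x A_cell` — the calibration identity is exact in the stated world.

Rendering choices, and why:

- **Effective width.** A rectangle of `L_cell x W_cell` has area 7.02 µm²
  per cell, but the calibration area is 6.844 µm². Filaments are rendered
  with the area-consistent width `A_cell / L_cell ≈ 3.80` µm, so that
  rendered area matches ground-truth area (real cells are disks, not
  rectangles; their projected area is smaller than the bounding box).
  Rendering at `W_cell` would bias every recovered count by +2.6% — about
  3 cells on a 110-cell filament — and no segmentation could undo it.
- **Pixel grid.** The default render pixel size is 0.2 µm/px: one cell is
  then exactly 9 px long and the effective width rasterizes to 19 px, so
  one cell covers 171 px = 6.84 µm², within 0.07% of `A_cell`. Filament
  anchors are snapped to the pixel grid. Without snapping, a half-pixel
  row misalignment across a 110-cell filament costs up to ~6 cells of
  area — sub-pixel rasterization error, not a property of the method
  under test. (The imaging module's own default for real images remains
  0.25 µm/px.)
- **Optics.** Lane interior renders at intensity 0.85, walls 0.3,
  filaments 0.35, with optional 1-px darker cross-wall lines every cell
  length; then Gaussian PSF blur (default sigma 1 px) and additive
  Gaussian noise (default sigma 0.05), clipped to [0, 1]. "Noise-free"
  (`noise_free()`) disables blur, noise, and texture, making the
  rasterized mask exact.

Not emulated: filament curvature, gliding motility, breakage and
merging, sheaths, granule texture, diffraction, uneven illumination, and
overlap of filaments. A green synthetic test therefore establishes that
segmentation, calibration, tracking, and statistics are internally
consistent and unbiased under the stated world — not that segmentation
is robust to every optical artifact of real micrographs.

## Numerical conventions

- Pixel coordinates are 0-based, row-major, origin top-left; ROI and bbox
  intervals are half-open.
- Report rounding is half-up (`round_half_up`), matching the
  accumulate-then-round convention of the simulator, not R's
  round-half-even.
- OLS is closed-form (`Sxy/Sxx`); r² is defined as 0 for a constant
  response. Degenerate inputs error: fewer than two distinct times, zero
  within-group variance with separated means (F undefined), zero
  population size in normalization.
- All stochastic stages derive from a single integer seed; identical
  seeds reproduce every artifact bit-for-bit.

## Known limitations

- The published per-filament raw data are not deposited, so per-filament
  SDs, box-plot medians, and the per-filament scatter cannot be
  reproduced; only group means, slopes, and derived quantities are
  checked against printed values, and distributional claims are covered
  by seeded property tests.
- The published count/length table carries internal rounding
  inconsistencies (lengths were computed from unrounded means, e.g.
  27.7 x 1.8 = 49.86 prints as 50.0); consistency tests allow the
  corresponding ±0.15 µm.
- Otsu-with-fallback thresholding assumes a unimodal bright background
  per lane; strong illumination gradients would need flat-field
  correction upstream.
- TIFF input is not supported in this environment (no TIFF codec among
  the available dependencies); PNG is used for image files, and all core
  functions accept in-memory matrices.
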