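# filatrack

Growth quantification of filamentous cyanobacteria in microcapillary
micrographs.

## The problem

Filamentous cyanobacteria such as *Oscillatoria* form toxic harmful algal
blooms (HABs), but their growth kinetics are hard to measure *in vitro*:
filaments entangle into aggregates, so classical cell counting and
biomass- or chlorophyll-based proxies are unreliable. Cultivating filament
suspensions in transparent, gas-permeable fluoropolymer (FEP)
microcapillary strips — 10 parallel lanes of ~206 µm bore — immobilizes
individual filaments so the *same* filament can be photographed week after
week and its growth measured at single-cell resolution.

`filatrack` implements the complete analysis for such experiments, for
microbiologists and water-quality researchers:

1. **Lane detection** — locate the capillary lanes in a strip micrograph
   from the cross-lane intensity profile.
2. **Segmentation** — threshold each lane (Otsu with a robust-background
   fallback), label 8-connected components, and measure each filament's
   projected area A_filament (µm²).
3. **Calibration** — convert areas to cell counts and lengths using
   SEM-derived cell morphometry:

   n_cells(t) = A_filament(t) / A_cell,
   L_filament(t) = n_cells(t) × L_cell,

   with defaults A_cell = 6.844 µm², L_cell = 1.8 µm, W_cell = 3.9 µm.
4. **Tracking** — re-identify each filament across weekly timepoints by
   position and size (optimal one-to-one assignment; filaments are static
   and only grow), and compute weekly cell increments.
5. **Growth statistics** — assign filaments to size groups by initial cell
   number (0–50, 50–100, 100–150), fit the rate of increase of population
   dN/dt by ordinary least squares on the group-mean growth curve,
   normalize it by population size, and compare groups by one-way ANOVA
   and pairwise Student t-tests with compact significance letters.
6. **Synthetic data** — generate micrograph series with exact ground truth
   (static filaments, apical cell addition following a group/week growth
   schedule, configurable PSF blur and sensor noise) for validation and
   parameter-recovery studies.

## Worked example

Fit the packaged reference growth tables (per-group mean cell numbers at
days 0–28):

```r
library(filatrack)
ft <- fit_paper_tables()
print(ft)
#> Group 0-50: dN/dt = 0.09 cells/day (r2 = 0.969), normalized 3.02e-03 /day
#> Group 50-100: dN/dt = 0.47 cells/day (r2 = 0.978), normalized 6.16e-03 /day
#> Group 100-150: dN/dt = 0.39 cells/day (r2 = 0.763), normalized 3.25e-03 /day
```

Small filaments grow at ~0.09 cells/day; filaments above 50 cells grow
4–5× faster. After normalizing dN/dt by population size, the *medium*
group (50–100 cells) has the highest per-cell growth rate — consistent
with very short filaments behaving like dormant dispersal hormogonia.

A fully synthetic end-to-end run (simulate → render → segment → track →
quantify):

```r
exp <- make_paper_like_experiment(seed = 42, noise = noise_params())
obs <- segment_experiment(exp)          # renders + segments 10 micrographs
tracks <- build_tracks(obs)             # 20 complete weekly tracks
summaries <- summarize_groups(tracks)
sapply(summaries, `[[`, "slope")        # recovered dN/dt per size group
```

Or from the command line, writing all CSV/JSON artifacts:

```sh
Rscript inst/cli/filatrack.R run --seed 42 --out out/
Rscript inst/cli/filatrack.R fit-tables --out out/
```

## Layout

- `R/`, `src/` — implementation (R + a small Rcpp component labeler)
- `inst/extdata/` — packaged reference growth tables
- `vignettes/filament-growth-quantification.Rmd` — methods vignette
- `tests/testthat/` — unit, property, and acceptance tests
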