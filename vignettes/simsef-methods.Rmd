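---
title: "Scheduling and evaluating MS2 experiments on TIMS imaging data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scheduling and evaluating MS2 experiments on TIMS imaging data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(simsef)
```

## The problem

Mass spectrometry imaging acquires one mass spectrum per pixel of a tissue
section, but almost all public imaging datasets are MS1-only: without
fragmentation spectra (MS2), compound annotation has to rely on accurate
mass alone. On trapped ion mobility (TIMS) instruments each pixel's
spectrum is additionally resolved in the reduced-mobility dimension
(1/K0), and because the quadrupole can switch its isolation m/z within a
few milliseconds, several precursors can be fragmented *within a single
TIMS ramp* at one pixel — provided their mobility windows do not collide.

`simsef` plans such fragmentation experiments after the MS1 image has been
acquired: it is a *dataset-dependent* acquisition scheduler. Given the
detected feature list (every feature with its m/z, mobility window and
per-pixel intensities) and the per-pixel MS1 frame point clouds, it
decides in which pixels each precursor is fragmented, at which collision
energies, and writes per-spot precursor lists for the acquisition
software. After acquisition, it assigns the MS2 scans back to the image
features, merges replicates into consensus spectra and scores coverage
and spectral quality.

## The scheduling model

Let a feature $p$ have per-pixel intensities $I_p(x,y)$, maximum intensity
$I_p^{max}$, and a mobility window $w_p$. Scheduling proceeds greedily:

1. **Eligibility and priority.** Features with
   $I_p^{max} \ge$ `eligibility_min_intensity` (default 5000 a.u.) are
   eligible. They are visited in *ascending* order of area
   $A_p = \sum_{x,y} I_p(x,y)$: low-abundance precursors are detected in
   few pixels, so they get first pick of their best pixels. Ties break by
   ascending m/z, then feature id.
2. **Pixel walk.** For each feature and each collision energy the pixels
   are walked from most to least intense (row-major tie-break). A pixel is
   accepted iff all four checks pass:
   * **intensity** — $I_p(x,y)$ strictly exceeds both the absolute
     threshold (3000 a.u.) and the relative one (20 % of $I_p^{max}$);
   * **ramp feasibility** — after inserting $w_p$ into the pixel's already
     scheduled windows sorted by descending upper edge, every consecutive
     pair leaves at least the mobility gap equivalent to the quadrupole
     switch time. The TIMS ramp scans from high to low 1/K0 and is
     linearised, so a switch time $t_s$ maps to a gap
     $t_s \cdot (K_{max} - K_{min}) / t_{ramp}$ (1.65 ms with the default
     150 ms ramp over 0.65–1.75 Vs/cm² gives 0.0121 Vs/cm²);
   * **spatial distribution** — replicate events of the *same* collision
     energy must be at least `min_distance_px` apart (Euclidean, pixel
     units; default 20). Different energies are exempt, so a hotspot can
     host the same precursor at several energies;
   * **purity** — the expected isolation purity (below) must reach
     `min_purity` (default 0.8).
3. **Second pass.** Any (feature, energy) pair still short of its
   `n_spectra_per_ce` replicates is retried with identical checks, but
   candidate pixels that already hold a scheduled event are tried first.
   This concentrates the remaining events on pixels that will be consumed
   by MS2 anyway, preserving sample area.

The scheduler is fully deterministic: every ordering has an explicit
tie-break, so identical inputs produce byte-identical exported folders.

### Isolation purity

The quadrupole cannot isolate narrower than its isolation width (1.7 Da
default), so co-eluting ions within the window produce chimeric spectra.
The purity of isolating feature $p$ in pixel $(x,y)$ is estimated from the
MS1 frame: among all frame points inside the isolation m/z window and the
precursor's mobility window, the pure fraction is the summed intensity of
points within `purity_mz_tol_da` (0.01 Da) of the precursor m/z *or of its
first isotope positions* (spacing 1.0034 Da, `n_isotopes_pure` = 2),
divided by the total. Isotopes count as pure because they belong to the
same ion species and would otherwise make high purity unreachable for
most real ions whenever the isolation window reaches an isotope peak. An
empty isolation region scores 0, so nothing is scheduled on empty pixels.
Users who want strict monoisotopic purity can set `n_isotopes_pure = 1`.

### Mobility windows

Each precursor's extraction window is centred on its mobility apex with a
width equal to the detected mobilogram extent clamped to 0.02–0.04
Vs/cm², then shifted to lie within the ramp range with its width
preserved. The clamp keeps windows wide enough to capture the precursor
but narrow enough to multiplex many precursors per ramp.

## Choices where the design was open

* **Distance units.** Spatial thresholds are in pixel index units, not
  µm. With a uniform raster pitch the two are proportional, and the
  field states these thresholds in pixels.
* **Pixel intensity rule.** The absolute (3000 a.u.) and relative (20 %)
  thresholds combine with AND and compare strictly (`>`), while the
  5000 a.u. feature-eligibility threshold compares with `>=`. These are
  kept as two separate parameters rather than one, so the per-pixel rule
  and the eligibility rule can be tuned independently.
* **Scope of the minimum distance.** The distance constraint applies per
  (feature, collision energy), not globally across features; global
  crowding is indirectly limited by ramp capacity. There is no hard cap
  on precursors per pixel beyond ramp feasibility — the observed
  precursors-per-spot count is an outcome, not a parameter.
* **Second-pass semantics.** "Prefer already used pixels" is implemented
  purely as a candidate *ordering* change; all quality checks are
  identical in both passes, and the pass applies to any replicate
  shortfall, not only to fully unscheduled precursors.
* **Purity formula.** The intensity-fraction-with-isotopes definition
  above is this package's own operationalisation of "expected purity";
  tolerance, isotope spacing and isotope count are exposed as parameters
  so stricter definitions are configurable.

## Numerical and format choices

* **Exported folder.** One CSV per MS2 spot plus a master table, energy
  list, parameter dump and geometry file. Formatting is fixed — m/z and
  mobility window edges with 6 decimals, purity 3, collision energy 1 —
  so exports are byte-stable and write/read/write cycles are
  byte-identical. Six decimals on window edges (rather than the 4 used
  for mobilities in the feature CSV) matter: windows derived from
  4-decimal feature mobilities have at most 5 decimal places, so the
  folder carries exactly the scheduled windows and a post-hoc validation
  of a re-read folder reproduces every purity score bit for bit. With
  coarser rounding, a window edge can shift by 5e-5 Vs/cm² and flip a
  boundary frame point in or out of the isolation region.
* **Degenerate inputs.** Empty frames give purity 0 everywhere (nothing
  is scheduled); features may legitimately end with zero events and are
  reported as such in the per-feature summary; an empty schedule exports
  a header-only master file.
* **Consensus merging.** Replicate scans merge by single-linkage grouping
  on the globally sorted peak list — a gap larger than
  `max(15 ppm, 0.005 Da)` starts a new group, and a group spanning more
  than 3x the tolerance is broken to bound drift. Group m/z is the
  intensity-weighted mean, group intensity the member maximum, so even
  low-abundance replicates contribute signals the others lack. Operating
  on the globally sorted list makes the result independent of scan
  order. Across-energy consensus spectra are built from the per-energy
  consensus spectra (two-stage), keeping per-energy artefacts
  inspectable.
* **Similarity.** Replicate similarity uses the plain normalised dot
  product on greedily intensity-matched peaks; it is symmetric and
  scale-invariant. The "fraction of replicate pairs above 0.7" summary is
  computed per (feature, collision energy) group; groups with fewer than
  two scans form no pairs, and with no pairs at all the fraction is
  reported as missing rather than 0.

## The synthetic data generator

Real TIMS imaging raw data is vendor-binary and far too large for routine
testing, so the package ships a generator that emulates the *structure*
the scheduler depends on:

* features are Gaussian spatial blobs (hotspot plus low-intensity
  margins, truncated below the noise floor of 100 a.u.), with m/z drawn
  with a minimum pairwise separation, mobility apex affine in m/z plus
  noise, and window widths in 0.02–0.04 Vs/cm²;
* a configurable fraction (default 0.3) of features receives an isobaric
  interference partner within ±0.85 Da with overlapping mobility and
  overlapping spatial distribution — these are *not* listed as features
  and exist purely to give the purity filter true positives and
  negatives;
* frames contain one monoisotopic point per contributing species (with
  m/z jitter bounded well below the purity tolerance), an M+1 isotope
  point where intense enough, and uniform background points below the
  noise floor, kept away from every feature's isotope positions so that
  the label-based ground-truth purity is well defined;
* every point is labelled with its originating species, which yields an
  independent purity oracle: `purity_from_truth()` must agree with
  `purity_score()` to machine precision, and does in the test suite over
  a thousand randomised queries;
* simulated MS2 scans are deterministic per-feature fragment templates
  with a Gaussian collision-energy response, so replicate scans of one
  feature are identical by construction and all merging/QC contracts
  have known expected outcomes.

All randomness flows from the single seed in the spec; the same spec
generates byte-identical datasets.

What the generator does *not* emulate — full isotope envelopes, matrix
cluster chemistry, detector saturation, mobility peak shapes, spatially
correlated noise — bounds what passing tests show: they demonstrate the
correctness of the scheduling and evaluation logic under the stated data
model, not instrument-level performance on real tissue.

## Problem sizes and test design

The constraint validator `validate_schedule()` is an independent oracle:
it re-checks every scheduled event against all four constraints with its
own pairwise logic. The test suite runs it over 50 randomised synthetic
datasets (rasters up to 24 x 24 pixels, up to 20 features, randomised
parameters) and asserts zero violations, plus hand-corrupted schedules
that must yield exactly the injected violations. Parameter-trend checks
(relaxing purity 0.8 to 0.6 or distance 20 to 5 pixels never reduces the
event count) use a fixed-seed 40 x 40 dataset with 60 features and the
full default parameter set. These sizes keep the whole suite under a
minute while still exercising every constraint interaction; the scheduler
itself is O(features x energies x pixels) with purity caching and runs
full-raster datasets of realistic size in minutes.

## Known limitations

* Greedy scheduling is not globally optimal; a precursor scheduled early
  can block a ramp slot a later precursor needed. The ascending-area
  priority is a heuristic that protects rare compounds, not an optimum.
* Purity is *expected* purity from the MS1 frame; isomers sharing m/z
  and mobility are invisible to it, so chimeric spectra from unresolved
  isomers remain possible and should be flagged downstream via the
  intra-feature similarity report.
* Vendor raw formats are out of scope; the package consumes and produces
  plain CSV/MGF interchange files.
* MS2 input is MGF; the spot/energy/mobility metadata travel in the
  TITLE line as `spot=... ce=... mob=low-high`.
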