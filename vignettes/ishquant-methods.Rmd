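---
title: "Quantifying single-pair probe ISH: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying single-pair probe ISH: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ishquant)
```

## The assay and its computational problem

Single-pair probe in situ hybridization (the BaseScope-style assay)
detects individual transcripts as discrete chromogenic/fluorescent dots:
one pair of 18-25 nt anti-sense oligos — one spanning an exon-exon
junction, the other hybridizing immediately adjacent — seeds enzymatic
amplification, and each resulting dot approximates one mRNA molecule.
Because the probe footprint is only ~40-50 nt, the assay resolves targets
that are too short for conventional multi-pair probe sets, most notably
alternative splice junctions. The measurement is *semi-quantitative*:
what can be counted on a section are dots, the nuclei they surround, and
their ratios.

`ishquant` implements the full computational side of such an experiment:

1. **Probe design** (`enumerate_junctions()`, `design_probes()`,
   `check_specificity()`): enumerate junctions of a multi-isoform gene
   model, place junction-spanning + adjacent oligo pairs, and screen the
   spanning oligo against all isoforms.
2. **Simulation** (`simulate_field()`, `simulate_negative_control()`):
   two-channel synthetic fields with exact ground truth, so every later
   stage can be tested without real data.
3. **Quantification** (`segment_nuclei()`, `calibrate()`,
   `detect_dots()`, `assign_dots()`, `quantify_region()`,
   `run_pipeline()`): negative-control-calibrated dot detection,
   closest-nucleus assignment, and the three region metrics — dots/area,
   percent positive cells, and dots per positive cell.
4. **Statistics** (`anova_oneway()`, `anova_from_summary()`,
   `tukey_hsd()`, `anova_twoway()`, `relative_abundance()`): the ANOVA /
   Tukey layer, computable either from raw replicates or directly from
   printed mean ± SEM (n) summaries, and relative isoform abundance from
   paired counts.

## Probe design

A placement is valid when the spanning oligo covers the junction with at
least `min_overhang` bases in each exon, both oligos are 18-25 nt, the
adjacent oligo abuts the spanning oligo with zero gap and zero overlap
(either upstream or downstream), and each oligo's GC fraction lies in
`gc_range`. All valid placements are enumerated deterministically
(ordered by spanning-oligo start, length, side, adjacent length).

Open choices and how they were fixed:

* **`min_overhang = 4` nt.** Vendor documentation does not state the
  minimum junction overhang. Below a handful of bases a "spanning" oligo
  is effectively contained in one exon and cannot confer junction
  specificity; 4 nt is the smallest overhang that our exact-substring
  specificity screen can reward. Configurable.
* **GC bounds `[0.30, 0.70]`.** A generic oligo-design heuristic, not an
  assay constraint; overridable.
* **Junction marker.** Target sequences are reported with `/` at the
  junction; `-` is accepted on input. Table conventions differ between
  sources, so both are tolerated but one is canonical.
* **Junction offset.** Published probe sequences suggest the junction
  falls at variable positions within the spanning oligo; we do not guess
  a fixed offset but expose `junction_offset` for designs that pin it.
* **Strand.** Coordinates and sequences are recorded on the sense strand
  (0-based, half-open, transcript-relative, BED-compatible); the physical
  probes are the reverse complements.
* **Specificity = exact substring matching.** No thermodynamic mismatch
  model is attempted — there is no published hybridization energetics for
  this chemistry to calibrate one against. A probe is *specific* when its
  spanning oligo occurs in no isoform that lacks the targeted junction.
  Exon identifiers are treated as opaque labels throughout, since exon
  numbering conventions differ between references.

`example_gene_model()` provides a miniature four-isoform receptor model
(mutually exclusive juxtamembrane exons of 45/75 nt; a 48 nt cytoplasmic
exon that is included or skipped) whose junction contexts reproduce
published single-pair probe target sequences; filler regions are
synthetic. It is the shared fixture for the designer's documentation and
tests.

## The simulator: what it emulates, and what it does not

`simulate_field()` renders a nuclear channel (non-overlapping disks,
Gaussian-smoothed, plus read noise) and a signal channel (2-D Gaussian
dots plus read noise) with complete ground truth. The default parameters
describe a hippocampus-like section in which about one cell in five
expresses the target at a handful of transcripts per cell — the regime
for which this assay and pipeline were designed:

| parameter | default | rationale |
|---|---|---|
| `image_shape`, `pixel_size` | 640 × 640 px, 0.325 µm/px | ~0.043 mm² field at a typical 20× camera sampling |
| `n_nuclei` | 200 | tissue-like density (~4600 nuclei/mm²) with non-overlapping nuclei |
| `nucleus_radius` | 9-12 px | 6-8 µm diameter nuclei |
| `positive_fraction` | 0.2 | ~20 % of cells express the target |
| `dots_per_positive_cell` | Poisson, mean 5 | low-abundance transcript; `gamma-poisson` available for overdispersion |
| `dot_peak_intensity` | 1500 ± 200 over background 500 | SNR 30 at `background_noise_sd` 50 — amplified dots are bright |
| `psf_sigma` | 1.1 px | ~0.8 µm FWHM effective dot profile |
| `annulus` | [0.5, 1.8] × radius | perinuclear/cytoplasmic signal |
| `background_dot_rate` | 75 /mm² | ~1 false dot per 60 cells: the knockout-like floor (~1-2 % "positive" cells in control sections) |
| `clump_prob` | 0 | clump artifacts off unless requested |
| `min_dot_separation_px` | 7 | component-resolvability limit (below) |
| `bit_depth` | 16 | dots clip, never wrap |

Three structural choices deserve explanation:

* **Dots are 2-D Gaussians.** Nothing is published about the dot profile;
  a Gaussian PSF is the standard idealization for diffraction-limited
  puncta.
* **Territory constraint.** An owned dot must lie in its cell's annulus
  *and* its owner must be the nearest nucleus by boundary distance
  (distance to centre minus radius — an additively weighted Voronoi
  tessellation). In space-filling tissue the cytoplasm hosting a
  transcript belongs to the nearest cell; without this constraint the
  generator would place "cell A's" transcripts inside cell B, which no
  proximity-based assignment (including the one being tested) could ever
  attribute correctly.
* **Minimum dot separation (7 px).** Two ideal dots closer than roughly
  three PSF sigmas render as a *single* above-threshold component: the
  summed Gaussian tails (of a pair, or of several dots in a cluster)
  exceed the detection threshold at the saddle between them. Such
  coincidences are exactly what the explicit clump mechanism
  (`clump_prob`, which collapses a cell's dots onto one centre) is for,
  so by default the generator keeps distinct transcripts at resolvable
  spacing and models fusion deliberately rather than accidentally.
  Setting `min_dot_separation_px = 0` restores arbitrary overlap.

The simulator does **not** emulate optical sectioning or z-stacks,
chromatic aberration, tissue autofluorescence texture, uneven
illumination, or multiplexed channels. Passing tests on simulated fields
therefore demonstrate correctness of the *computational* pipeline under
idealized optics — not robustness to every artifact of real sections.
Clumps (enzymatic signal accumulation over abundant transcripts) are
simulated on request and addressed by the optional declumping watershed.

## Calibration, detection, assignment, metrics

**Calibration is anchored on the negative control.** The intensity
threshold is `mean + k_sigma × sd` (default `k_sigma = 3`) over all
pooled pixels of knockout-like signal channels, recorded with its inputs
for provenance; a background-quantile mode (e.g. 99.9th percentile) is
available. The published procedure states only that the threshold was
"based on background intensity" in control sections; mean + k·SD is the
simplest reproducible reading, and `calibrate()` refuses to run without a
negative control. Background statistics use whole images by default (the
alternative — statistics over detected-object pixels only — is not
implemented as a separate mode; the quantile mode covers heavy-tailed
backgrounds).

**Dot diameter** means equivalent-circle diameter `2·sqrt(area/π)`,
robust for near-circular puncta; the threshold defaults to the published
fixed 3 px, with a `wt-derived` mode
(`floor(wt_mean_dot_diameter × fraction)`) when wild-type images are
supplied.

**Detection** applies a 3 × 3 median prefilter (suppressing isolated
noise pixels that would otherwise bridge nearby dots into one component —
the same reasoning as speckle-removal smoothing in CellProfiler-style
pipelines), thresholds, labels components (8-connectivity by default),
and size-filters. Intensities are reported from the unfiltered image.
With `declump = TRUE`, components larger than `max_single_dot_area_px`
are split by a watershed on local intensity maxima and the fragments
re-tested.

**Assignment** minimizes the Euclidean distance from the dot centroid to
the nucleus *mask* (0 inside): signal is cytoplasmic and nucleus sizes
vary, so centroid-to-boundary is the better-behaved metric than
centroid-to-centroid. Dots farther than `max_distance_px` (default 30 px,
about one cell diameter) from every nucleus stay unassigned — an
unlimited radius would attach far-field background dots to cells. Exact
ties go to the lowest label. The production path searches only boundary
pixels of each nucleus (exact for filled masks — the nearest mask pixel
to an exterior point is always a boundary pixel); a brute-force
every-pixel search is kept as the reference implementation and the two
are required to agree in the test suite.

**Region metrics.** Dots/area uses *all* detected dots over the full
frame area (the alternative — normalizing to segmented-tissue area — is
not used; on full-frame simulated fields the two coincide). A cell is
positive with at least `positive_min_dots` assigned dots (default 1,
matching a labeled-nucleus count whose floor is set by the control
background; 2 gives stricter calls). The mean dots per positive cell is
computed over positive cells only; the histogram runs over bins
1..`histogram_max_bin` with an open-ended last bin. With zero nuclei the
cell-level metrics are reported as missing, never as 0.

## Statistics

`anova_oneway()` is the classical fixed-effects decomposition;
`anova_from_summary()` computes the identical quantities from
(mean, SEM, n) triples — the form figure captions print — via
`SS_between` from n-weighted means and pooled within-variance
`Σ(nᵢ−1)·(semᵢ·√nᵢ)² / Σ(nᵢ−1)`. The two routes agree to machine
precision, which the suite verifies through
`reconstruct_from_summary()`: a symmetric two-point construction with
exact sample mean and SD (even n: half at mean ± d with
`d = sd·√((n−1)/n)`; odd n: one value at the mean plus symmetric pairs at
mean ± sd). The construction is unit-tested against the target SD, not
assumed.

`tukey_hsd()` uses the Tukey-Kramer studentized-range statistic
`q = |Δ| / sqrt(MS_within/2 · (1/nₐ + 1/n_b))` (harmonic-mean correction
for unequal n; the balanced case reduces to the textbook form) with
adjusted p-values from R's studentized-range distribution (`ptukey`),
cross-checked in the tests against `TukeyHSD()` on reconstructed raw
data and against published critical values (q(0.05; 3, 9) = 3.95).
Near-1 adjusted p-values are the most sensitive to rounding of printed
inputs: around q ≈ 1 a half-ulp perturbation of a printed SEM moves the
adjusted p by several 10⁻³, which is why worked-example checks at that
end are framed as printing-precision consistency rather than exact
reproduction.

`anova_twoway()` fits `value ~ A * B` on a complete crossed design
(missing cells are refused — no imputation) and can run Tukey on factor A.
It exists for genotype × count-bin histogram comparisons; treating binned
counts as independent responses violates independence across bins, so
those p-values should be read descriptively. This caveat is flagged, not
"fixed", because the published analysis is specified that way. A constant
response returns F = 0 across all terms rather than 0/0.

`relative_abundance()` converts paired per-animal measurements (we
default to dots/area as the paired measurement, the choice the source
material leaves open) to per-animal percentages `100·a/(a+b)`,
excluding uninformative `a + b = 0` animals with a warning, and
summarizes mean ± SEM across animals.

## Numerical and interface choices

* Pixel coordinates are 1-based `(row, col)` in R matrix convention;
  transcript/probe coordinates are 0-based half-open.
* 8-connectivity for components (4 available); labelling is EBImage's
  `bwlabel` plus a union-find merge of diagonally touching labels.
* Watershed splitting of touching nuclei uses the distance transform with
  a 1 px depth tolerance (suppressing noise-induced oversplits).
* Exports are CSV (spreadsheet-compatible, portable), calibration and
  ground truth are JSON, images are 16-bit grayscale TIFF. Every CSV
  carries an MD5 configuration hash in a comment header; identical
  configurations produce byte-identical outputs.
* All randomness flows through a single integer seed; a fixed seed
  reproduces fields bit-identically.

## Verification scales

The test suite and the acceptance script exercise the pipeline at the
scale the workflow targets: 200-nucleus, 640 × 640 px fields; 20
independent seeds for end-to-end recovery (positive-cell percentage
within ±3 points, dots per positive cell within 15 % relative, on
average); 20 sparse fields (9 px dot spacing, mean 3 dots/cell) for
exact detection recall/precision and boundary-vs-brute-force assignment
agreement; pooled knockout-mode fields for the single-dot background
floor. Smaller 256 × 256 px, 30-nucleus fields back the unit tests.

## Known limitations

* Detection is threshold-and-components: two transcripts closer than the
  component-resolvability limit (~2-3 PSF sigmas under default optics)
  are counted as one unless declumping can separate their intensity
  maxima; perfectly coincident dots are irrecoverable by any method.
* The percent-positive metric inherits the background floor of the assay:
  with a positivity cutoff of one dot, control-level false dots make a
  small percentage of cells nominally positive. This matches the
  published workflow; raising `positive_min_dots` trades that floor for
  sensitivity.
* Specificity screening is exact matching on the modelled isoforms only —
  no genome-wide off-target search, no thermodynamics.
* 2-D only; quantification of overlapping cells in thick sections is out
  of scope.

## A worked end-to-end example

```{r, eval = FALSE}
library(ishquant)

wt <- simulate_field(sim_params(seed = 1))
ko <- simulate_negative_control(sim_params(seed = 1001))
run <- run_pipeline(default_config(), ko, list(wt = wt, ko = ko),
                    out_dir = "results")
run$summary

# statistics straight from printed summaries
sm <- group_summary(c("GAD2", "MAG", "other"),
                    mean = c(19.65, 6.73, 4.72),
                    sem  = c(3.39, 0.61, 0.23), n = c(4, 4, 4))
anova_from_summary(sm)
tukey_hsd(sm)
```
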