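---
title: "Population autocorrelation analysis of grid-cell activity in undersampled environments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population autocorrelation analysis of grid-cell activity in undersampled environments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gridpop)
```

## The problem

A grid cell fires whenever the animal crosses any vertex of a hexagonal
lattice tiling the environment. The lattice has three parameters: spacing
$\lambda$ (nearest-neighbour distance between field centers), orientation
$\theta$ (direction of one lattice axis, defined modulo $60^\circ$), and a
2D spatial phase. Cells within a *module* share $\lambda$ and $\theta$ and
differ only in phase.

In a large open arena the lattice is read off each cell's spatial
autocorrelogram: a ring of six peaks, $60^\circ$ apart, at radius
$\lambda$. On an annular (circular) track the animal samples only a thin
ring of the environment, so each cell's rate map contains only the fields
that happen to intersect the track — which fields those are depends on the
cell's phase. Individual autocorrelograms then show arbitrary subsets of
the six peaks and cannot be distinguished reliably from those of shuffled
surrogates.

The population autocorrelation resolves this. The autocorrelation of a
lattice is independent of its phase, so comodular cells have *identical*
expected autocorrelograms; on the track each cell expresses a different,
phase-dependent subset of the peak ring, and the elementwise **sum** of
the individual autocorrelograms restores the complete six-peak pattern.
The sum is deliberately unnormalized: a cell whose sampled fields express
more of the lattice contributes proportionally more. This is the core
statistic of the package, `population_autocorrelation()`.

## Models and procedures

### Idealized grid cells

`ideal_rate_map()` builds a cell's rate map as the sum of three 2D
sinusoidal gratings whose stripe directions are $\theta$,
$\theta+60^\circ$, $\theta+120^\circ$; the wavevectors (perpendicular to
the stripes, magnitude $4\pi/(\sqrt3\,\lambda)$) then generate a
real-space field lattice whose nearest-neighbour directions are $\theta$,
$\theta+60^\circ$, $\theta+120^\circ$ — so inferred orientations recover
the generative $\theta$ directly. The summed gratings span $[-1.5, 3]$ and
are rescaled affinely to $[0, \text{peak rate}]$; no thresholding or
rectification is applied, which keeps the fields smooth with maxima
exactly on the lattice. The peak rate is not constrained by the analysis
(every statistic downstream is either rate-normalized or
Pearson-normalized); the default of 10 Hz is a typical grid-cell peak
rate. Phases are drawn uniformly over the lattice unit-cell parallelogram,
which is the uniform distribution on the phase torus.

### Standard geometries

The reference environments are a circular arena of radius 75 cm and an
annular track with outer radius 75 cm and inner radius 60 cm (width
15 cm), both binned at 1 cm; bin $(i,j)$ covers the half-open square
$[\mathrm{origin}+i-1, \mathrm{origin}+i) \times [\cdot)$ and all
positions are in cm relative to the environment center. Track responses
are modelled as slices of the arena lattice (`slice_to_track()`).

### Rate-map estimation

`average_rate_map()` implements
$$\lambda(x) = \frac{\sum_i g((s_i - x)/\sigma)}{\int_0^T g((y(t)-x)/\sigma)\,dt},$$
with $g$ an unnormalized Gaussian ($\sigma$ = 3 cm by default; the
kernel's constant cancels between numerator and denominator). Positions
are accumulated on the 1-cm grid before smoothing; the time integral is a
Riemann sum over trajectory samples with $\Delta t$ the median
inter-sample interval; spike positions are linear interpolations of the
trajectory at spike times. Bins farther than 3 cm from every trajectory
sample are unvisited and set to 0. The test suite verifies conservation
($\sum_x \lambda(x)\,\mathrm{occ}(x) \approx N$), homogeneous-rate
recovery, and round-trip recovery of a generative map from Poisson spikes.

### Autocorrelogram windows

At every integer-bin lag the correlogram holds the Pearson correlation of
the map with its shifted copy over the window where the two copies
overlap. Two windows are supported:

* `zero_fill_pearson` (default): unvisited bins count as rate 0 and the
  window is the full bounding square. This is the behaviour implied by
  zeroing unvisited rates before correlating, and it reproduces a known
  geometric signature of annular tracks — the track mask alone contributes
  a central peak plus an outer ring at a lag equal to the track diameter.
* `masked_pearson`: only bins visited in both copies enter, and lags with
  fewer than 20 overlapping bins are invalid.

The zero-filled window is rectangular and therefore slightly anisotropic:
diagonal lags have smaller windows than axial lags of the same length. On
annular geometry this biases peak *positions* by a few centimeters and a
few degrees (the peak ring leans toward the diagonals), which is invisible
in gridness scoring but matters when reading off precise ring geometry.
The package therefore uses the default window for detection, scoring and
significance (where fidelity to the zeroed-unvisited-rate convention and
its track artifact is wanted), and the masked window for ring-resolved
measurements (`lattice_peaks_2d()` on track data), where it recovers ring
radii and directions essentially exactly in simulations. Both modes are
validated against a brute-force double-loop oracle to $10^{-9}$;
computation is FFT-based with summed-area tables for the window sums.

Lags with zero variance in either copy are flagged invalid rather than
NaN; population sums run over the valid inputs at each lag.

### Gridness and lattice inference

`radial_profile()` tabulates $M(r)$, the mean correlogram value on
concentric circles. `annulus_bounds()` takes $r_{\min}$ = the radius
minimizing $M$ over the search range and $r_{\max}$ = the radius
maximizing $M$ beyond $r_{\min}$, and extracts the annulus from
$r_{\min}$ to $r_{\max} + (r_{\max} - r_{\min})$. Two operational choices
deserve note:

* The search range stops at 60% of the correlogram half-extent by default,
  because on track data the track-diameter artifact ring would otherwise
  capture the argmax. The range is an explicit argument.
* A minimum/maximum pair only counts as "clear" if the rise
  $M(r_{\max}) - M(r_{\min})$ is at least 2% of $M(0)$. Six narrow peaks
  spread over a full circle leave a shallow bump in the azimuthal mean —
  on simulated 20-cell track populations the genuine second-ring bump is
  $\approx$ 2–4% of $M(0)$ — so a stricter criterion would discard real
  rings. Profiles failing the criterion fall back to the fixed annulus
  $r_{\min} = 25$, $r_{\max} = 40$ cm, flagged in the output.

On track populations $M(r)$ typically dips *beyond* the (obscured)
innermost ring, so this rule detects the **second** hexagonal ring —
radius $\sqrt3\,\lambda$, rotated $30^\circ$ — which is the expected and
correct reading for track recordings; the caller interprets the detected
ring via the $\sqrt3$/30° geometry, or uses `locate_ring()` /
`lattice_peaks_2d()` to address rings explicitly.

The gridness score evaluates the rotational autocorrelation of the
annulus (bilinear interpolation on the 1-cm lag grid, pairwise deletion
of samples leaving the valid region) at the five canonical angles:
$\min\{r(60^\circ), r(120^\circ)\} - \max\{r(30^\circ), r(90^\circ),
r(150^\circ)\}$, in $[-2, 2]$. Peak location iterates argmax over the
upper half-annulus, excluding $\pm35^\circ$ sectors (angular distance
modulo $180^\circ$, so exclusion wraps through the correlogram's point
symmetry) around previously found peaks, three times; peaks are bin-center
argmaxes (1-cm bins are two orders of magnitude below the spacing, so
subpixel refinement would add nothing), ties resolved by raster order.
Spacing is the mean radial distance to the three peaks; orientations are
their angles from the positive x-axis.

`lattice_peaks_2d()` complements the annulus route for ring-resolved
questions: it takes 2D local maxima (positive, valid, dominant within a
6-bin disc) and clusters their radii into rings wherever consecutive
sorted radii jump by more than 6 cm. This separates ring 2
($\sqrt3\lambda \approx 78$ cm for $\lambda = 45$) from ring 3
($2\lambda = 90$ cm), which blur together in $M(r)$.

### Field-shuffle null models

`shuffle_fields()` rebuilds a rate map with the same non-spatial
statistics: fields (8-connected components above a threshold fraction of
the map maximum, starting at 0) are placed uniformly at random in the same
environment, largest first, rejecting placements that overlap *or touch*
an already-placed field — touching fields would merge into one component
and break the conservation of field count and areas that makes the
surrogate exchangeable with the original. If any field exceeds the
area cap (1000 cm² in the arena, 500 cm² on the track) or a placement
cannot be found within 1000 uniform draws, the threshold rises by 1% of
the map maximum and the whole placement restarts. Finally the
subthreshold pixel values are assigned at random to the remaining empty
environment bins, so the control's value multiset equals the source's
exactly. Two implementation notes: the first threshold whose fields all
satisfy the area cap is found by bisection (component areas shrink
monotonically with threshold, so this is the same threshold the
step-by-step scan reaches, at a fraction of the detections), and repeated
shuffles of one map reuse a memoised detection ladder (`shuffle_plan()`).

For idealized cosine-sum maps the rate is positive almost everywhere, so
the zero-threshold detection sees one large connected region and the
threshold necessarily escalates (to roughly 50–80% of the maximum on the
track) before fields become separable and placeable; maps with compact,
well-separated fields — the situation for typical recorded cells — shuffle
at or near threshold 0.

`gridness_significance()` shuffles every cell's map per replicate, sums
the control autocorrelograms, scores them, and reports
$p = \#\{\text{control} \ge \text{observed}\}/n$ — the plain fraction,
so $p$ may be exactly 0; with the +1 correction the reported zeros would
become $1/(n+1)$, a documented difference. `joint_significance()` counts
simultaneous (inclusive) dominance of a pair of scores; this is one
defensible reading of a joint test over light/dark condition pairs, chosen
here because it is exact, assumption-free and conservative (its $p$ never
exceeds either marginal).

### Linearization

`linearize()` maps an annular-track session to 1D: position is the
cumulative signed angular distance from the start (clockwise positive by
convention, configurable) times a reference radius. With the outer radius
(75 cm) one lap is 471 cm; the track midline (67.5 cm, one lap 424 cm) is
an equally defensible convention — both appear in the literature for this
geometry — and is selected by `radius_convention`. Rates use the
spikes / (timestamps × Δt) book-keeping per 1-cm bin. A cell with
lap-stable (allocentric) fields repeats with period equal to the
circumference, so the 1D population autocorrelation peaks there;
`first_prominent_peak()` reads that lag off (first local maximum beyond
25 cm, dominant within ±10 bins, at least half the height of the tallest
such maximum — defaults chosen so the broad central peak and minor
side-structure are skipped without reference to any expected lag).

### Module partitioning and cross-environment tests

`cluster_modules()` z-scores each cell's spacing and three orientation
angles and applies average-linkage agglomerative clustering (the distance
between clusters is the mean Euclidean distance over all cross-pairs,
`hclust(method = "average")`, verified against an all-pairs brute force).
The tree is cut at the smallest number of clusters at which exactly the
requested number have two or more members; singletons at that cut are
outliers. The linear z-scoring of angles ignores their circularity
(modulo 60°) by design, matching the analysis convention this package
follows; a circular-aware embedding (cosine/sine of the 60°-period angle)
ships behind `cell_features(circular = TRUE)`, off by default.

`extract_annulus_vector()` and `pairwise_environment_correlations()`
compare each cell's activity across environments on a common annulus
(radii 60 and 75 cm by default — the track itself, i.e. the outer ring of
the arena), after subtracting each map's mean rate over visited annulus
bins to remove exploration bias. Same-cell coefficients are tested against
cross-cell controls with a right-tailed Mann–Whitney U test. A population
whose lattice undergoes a *common phase shift* between environments shows
same-cell correlations indistinguishable from cross-cell — spacing and
orientation can be preserved while the pairwise correlation finds nothing
— which is why the package treats the population autocorrelation and the
pairwise correlations as complementary: the former sees the lattice, the
latter the phase.

## The simulator and what passing tests mean

`make_module()`, `synth_trajectory()` and `spikes_from_rate()` emulate the
study conditions the analysis is validated on: 20 comodular cells
(optionally with normal variability in spacing and orientation, e.g.
sd 5 cm and 3°), smooth random-walk arena exploration or noisy angular
progression on the track with occasional direction reversals (probability
0.001 per 20-ms step by default), and inhomogeneous Poisson spiking with
piecewise-constant intensity per tracking interval (validated by
time-rescaling against Exp(1)). The simulator does **not** emulate:
non-Poisson firing (bursting, theta modulation), lattice distortions near
walls, head-direction or speed conditioning, tetrode noise, or
lap-by-lap field drift. Passing tests therefore demonstrate that the
analysis chain is correct and recovers known ground truth under idealized
conditions and realistic parameter variability — not that any particular
biological dataset will show the same effect sizes.

## Numerical choices and problem sizes

* FFT-based correlations match brute-force double loops to $10^{-9}$
  (asserted in the suite); correlograms are symmetrized with their point
  reflection, making the symmetry exact.
* Rotation resampling is bilinear on the 1-cm grid; samples touching an
  invalid or out-of-range bin are dropped pairwise.
* Variance guards: lags with window variance below $10^{-8}$ of scale,
  rotational correlations over fewer than 3 samples or with degenerate
  sd, and all-zero rate vectors are flagged invalid, never NaN.
* Deterministic tie-breaks everywhere (smallest radius for profile
  extrema, raster order for argmax peaks).
* All stochastic functions take an explicit integer seed and restore the
  caller's RNG state; child seeds are derived arithmetically, so
  `gridness_significance()` is bit-reproducible.
* Test-suite problem sizes: the discrimination experiment runs 100
  seeded repeats of 20-cell true vs field-shuffled track populations; the
  null-calibration experiment runs 200 significance tests with 100
  controls each on 4-cell compact-field populations in a 40-cm arena
  (a small module in a small environment — calibration of the permutation
  p-value depends only on exchangeability, not on geometry, so the small
  setting measures the same property at a fraction of the cost).

## Known limitations

* The inner track diameter bounds the largest usable spacing: beyond it
  the second ring collides with the track-diameter artifact (for a 65-cm
  module the second ring at ≈113 cm sits just inside the 120-cm inner
  diameter, and only the masked window separates them).
* The annulus detector assumes a single dominant ring in its search
  range; concentric multi-module populations should be partitioned first
  (`cluster_modules()`).
* The zero-filled window's mild diagonal bias (above) is inherent to the
  full-square convention, not to the implementation; use the masked mode
  when peak coordinates matter.
* Field shuffling preserves per-field value multisets but not field
  *shapes'* orientation (fields are translated, never rotated); strongly
  anisotropic fields therefore remain anisotropic in the same direction
  in controls.
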