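---
title: "Models and methods behind rcdscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind rcdscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`rcdscan` analyses binned EdU pull-down (EdU-seq) time courses from
synchronised early-S-phase cells to locate Replicon Cluster Domains
(RCDs), follow their growth, quantify the filling of the valleys between
them, and test for sequential ("domino") activation of neighbours. This
vignette records the models the package implements, the parameters that
matter, the numerical choices, and the design decisions taken where more
than one reasonable convention exists. Coordinates are 0-based half-open
everywhere (the native bedGraph convention); masked bins are an explicit
`NA` sentinel, never zero, so sums, percentiles and peak calls exclude
them.

## Background model and normalisation

The pull-down track is modelled per bin as signal plus scaled genomic
background, `P_i = S_i + r * C_i`, with the background sharing the
control's spatial distribution. Both tracks are first scaled to reads per
million over unmasked bins (genome-wide when a track list is supplied).

On the scatter of `y = log(P_i/C_i)` against `x = log(P_i + C_i)`
(natural logs; membership of the background set is invariant to the
base), no-signal bins form a horizontal band at height `log r` while
signal bins rise with coverage. `fit_breakpoint()` fits a two-segment
broken line — left segment horizontal at the mean of its y values, right
segment ordinary least squares — with the breakpoint `b` chosen by
exhaustive search over 200 candidate x-quantiles between the 5th and 95th
percentile, minimising the total squared error. No continuity constraint
ties the segments: the data decide. Only bins with `P > 0` and `C > 0`
enter (the logs must exist); fewer than 10 such bins is an error, and a
right-segment slope below 1e-3 in absolute value flags a degenerate
(no-signal) fit. The background set is `G = {i : x_i < b}`.

Two estimators of `r` are computed over G. The ratio of sums
`sum(P_G)/sum(C_G)` is exact when G is pure, but G always retains some
signal-carrying bins, which inflate it. The default estimator is
therefore the mode of the per-bin ratio distribution `P_j/C_j` over G,
found as the argmax of a Gaussian kernel density (Silverman's
rule-of-thumb bandwidth, 512 evaluation points spanning the ratio range).
At low Poisson counts the ratio distribution itself is right-skewed and
the mode sits below the mean ratio; on count-noise-free constructions
both estimators agree to within 2% (asserted in the tests). Bins with
`C = 0` are excluded from G and the subtraction there reduces to
`S_i = P_i`. Negative `S` values are retained throughout — display layers
may clamp at zero, the analysis never does.

## Ricker detection and the scale convention

The matched filter is the Ricker wavelet
`psi(t) ~ (1 - t^2/sigma^2) exp(-t^2 / 2 sigma^2)`. Its "peak width" W is
the lateral extent of the central positive lobe, i.e. the distance
between the zero crossings, so `sigma = W/2`; this single constant lives
in `ricker_sigma()`. Taps are sampled on the bin grid, truncated at
±4σ, and mean-subtracted *after* normalisation so they sum to zero
exactly: the response to a constant track is exactly zero away from the
chromosome ends despite truncation. Ends are zero-padded, a known edge
bias within about W of each end.

Cross-scale comparability is a genuine design choice. With unit-amplitude
taps, the called-peak response to any isolated bump increases
monotonically with W, so a width scan has no interior optimum and cannot
read off a feature scale. The package therefore defaults to the
unit-area convention (taps scaled by `bin_size/sigma`), under which the
centre response to a flat-topped feature of half-max width L is maximised
near `W = L`. This was validated by requiring that a scan over the
standard grid (100–800 kb in 50-kb steps, then 1000/1500/3000 kb)
recovers planted cluster widths: 500-kb clusters yield an optimum within
one grid step of 500 kb, and 300/800-kb variants shift the optimum
monotonically (these checks are in the test suite). Amplitude and energy
(L2) normalisations remain selectable; heights are always comparable
within one width regardless of the convention, which is all that
detection at a fixed 500 kb requires.

Peak calling takes strict positive local maxima; plateaus of equal values
yield one peak at the centre bin (leftmost of the two central bins for
even runs — the data are continuous, so plateaus essentially only arise
in constructed inputs). The cutoff for calling an early-domain peak an
RCD is the nearest-rank 70th percentile (the `ceiling(0.7 n)`-th order
statistic) of the wavelet peak heights in *late* timing domains, which
carry essentially background; nearest-rank makes "removes 70% of the
late peaks" exact whenever n is divisible by 10. A peak's extent is
`position ± W/2`, consistent with the zero-crossing width convention;
domain membership is decided by the peak position, and the replication
peak height is the maximum S over the unmasked extent bins.

## Width dynamics of isolated domains

Isolation: the summed S in the two 500-kb windows flanking the extent
must not exceed 25% of the summed S under the extent. The two flanks are
combined by default (a per-side variant is available); peaks whose
windows cross a chromosome end are excluded with a recorded reason.

Three width estimators are provided.

* `fit_optimal_wavelet()` scans 200–1200 kb in 25-kb steps and records
  the width maximising the convolved response within ±W/2 of the peak
  position, computed on a local slice so whole-genome convolution is
  never repeated per peak. A series is rejected if any timepoint's
  optimum lands on a grid end — such fits have run off the resolvable
  range.
* `fit_gaussian()` is a Nelder–Mead least-squares fit of
  `A exp(-(x-c)^2/2 sigma^2) + B` on the extent padded by 500 kb.
  Internally x is centred on the peak and scaled by W, y by its window
  maximum, so the default simplex behaves across scales; initial values
  are the peak position, `sigma = W/4`, the window maximum and zero
  baseline; relative tolerance 1e-10, at most 2000 iterations, one
  restart from a perturbed init on non-convergence.
  `FWHM = 2 sqrt(2 ln 2) sigma` exactly. Rejection applies the same
  200/1200-kb extremes to the FWHM.
* `fit_flat_topped_gaussian()` adds a plateau half-width h
  (`A exp(-max(|x-c|-h, 0)^2 / 2 sigma^2) + B`); its width at half
  maximum is `2h + FWHM`. With `h = 0` it reduces to the plain Gaussian.

The flat-topped width is the shape-appropriate growth measure: expanding
clusters produce plateau-like profiles, and the least-squares FWHM of a
plain Gaussian on a plateau of width L is biased low (about 0.65 L on a
rectangle), which distorts growth increments. On the synthetic
synchronous-entry cohort the flat-topped width grows by 2·v·Δt per
interval (90 kb at 1.5 kb/min and 30-min spacing) within 10%, which is
the package's kinetic calibration check.

Growth statistics are per-interval width deltas over accepted peaks:
mean, standard error, 95% CI, two-sided one-sample t against zero, and a
rate in kb/min (mean delta over the 30-min inter-pulse interval). A
zero-variance delta sample is flagged degenerate with p reported as 1
when the mean is also zero.

## Valleys

Valleys are defined from the *uncut* first-timepoint peak list: every
adjacent pair of wavelet peaks within one early domain bounds a valley
after trimming `fork_travel_trim()` = 1.5 kb/min × 120 min = 180 kb from
each internal edge, discounting what flanking forks could replicate over
the course. Pairs whose trimmed gap is empty are dropped. A valley is
tracked when each flank has a nearest-position match within ±100 kb at
every later timepoint, ties between equidistant candidates breaking
toward the higher wavelet peak. Because signal is not comparable across
timepoints, the valley mean and minimum S are expressed as percentages of
the mean flanking replication peak height (max S over each flank's
extent, per timepoint). Both percentages are invariant to global
rescaling of S, and the minimum can be negative: S is signed.

Per-valley filling rates default to the least-squares slope of the
percentage against the pulse midpoint times (25, 55, 85, 115 min), which
is robust to one noisy timepoint; a successive-difference mode is also
available. One caveat established on the simulations: at the first
timepoint, before valley initiation begins, the valley minimum is a pure
noise extreme divided by flank heights that are still rising steeply, so
its level is a reference rather than a filling measurement; the filling
assertion in the tests therefore requires strict monotone increase over
the later timepoints plus a significantly positive rate, not a
first-to-second comparison.

## Domino statistics

Groups are maximal runs of RCDs in one timing domain with successive
centre-to-centre distance below 1.6 Mbp (an edge-to-edge option exists).
For triples and quadruples, the height ranks along the chromosome
(1 = highest, ties broken by position with a warning) are canonicalised
to the lexicographic minimum of the sequence and its reversal — direction
along a chromosome is arbitrary — giving 3 and 12 classes whose
frequencies are compared with the uniform i.i.d. expectation (33.3% and
8.3%).

The adjacent-height similarity metric for a group of n heights is
`1 - (ADFA - ADFSV)/(MADFAP - ADFSV)` with ADFA the mean adjacent
absolute difference as laid out, ADFSV the same after sorting (equal to
`range/(n-1)`), and MADFAP the mean over all orderings, computed exactly
as the mean absolute difference over all unordered distinct pairs. It is
1 exactly on monotone distinct arrays, averages 0 over all orderings of
any fixed multiset (an affine identity, verified by brute-force
enumeration in the tests), is invariant to reversal and to affine height
transforms, and is undefined when `MADFAP = ADFSV` (constant arrays and
every n = 2 array). For n = 3 it is defined but bounded below at −0.5,
unable to separate random from anti-ordered — hence the weighted report
uses groups of four or more only. "Weighted" means each group's value
enters the reporting sample n−1 times (once per adjacency), giving larger
groups proportionally more weight; the once-per-group ("no-rep") sample
is reported alongside, both with one-sample t-tests against zero.

## The synthetic-data generator

The generator encodes an explicit kinetic model: each cell enters S phase
uniformly within an entry window (0–45 min by default, matching the
synchrony achievable after release); each cluster activates per cell with
its efficiency, at entry plus a non-negative draw around its mean
activation time; fired origins are a uniform subset of candidates evenly
spaced (with jitter) across the cluster width, initiating at activation
plus half-normal jitter; bidirectional forks extend at 1.5 kb/min and
merge on meeting; a pulse labels `replicated(t2) \ replicated(t1)`;
expected pull-down intensity is `read_depth` reads per labelled kb (mean
over cells) plus a uniform per-bin background, sampled Poisson per bin,
with the control an independent uniform Poisson track. All randomness
flows from R's RNG, so a single seed fixes the experiment.

Two generator behaviours deserve emphasis.

* **Activation spread is what keeps profiles solid.** If every cell
  activated a cluster at the same moment, interior forks would all
  terminate by mid-course and late pulses would label only the two
  advancing edges — a hollow twin-band profile that splits under any
  width fit. Real early-replication profiles stay filled and flat-topped
  because activation varies from cell to cell across the whole course,
  so the presets used for width dynamics draw activation times uniformly
  over the 130-min window. The `activation_dist` switch exposes both
  regimes.
* **The growth preset is a calibration instrument, not a portrait.** It
  uses synchronous entry, efficiency 1, dense clusters (10 origins, so
  intra-cluster fork travel of at most ~17 min clears before the first
  pulse starts) and a deterministic origin layout
  (`origin_candidate_factor = 1`). Those choices make the 2·v·Δt
  envelope oracle apply cleanly from the first interval; sparser or
  stochastic layouts add a fork-travel transient that suppresses
  first-interval growth, which is exactly the behaviour the staggered
  preset demonstrates deliberately via 0–45-min entry.

What the generator does **not** emulate: mappability and GC structure in
the background (the control profile is uniform), copy-number variation,
read-length and fragment-size effects, inter-cluster fork invasion
beyond simple geometry, checkpoint effects, or late-S completion.
Passing tests on this generator show the pipeline recovers the
parameters of this kinetic model from Poisson-sampled counts; they do
not certify performance on biases the generator omits.

Default problem sizes keep the full suite in the low minutes: 2 × 20 Mbp
at 50-kb bins for detection (14 planted clusters, 100 cells), a 60-Mbp
chromosome at 10-kb bins for dynamics (19 clusters, 300 cells), 2 ×
24 Mbp for valleys (20 valleys, 150 cells), and ~200 four-member groups
across 17 chromosomes for the domino presets (60 cells, one pulse — the
ordering statistic needs one height per RCD).

## Degenerate inputs and edge rules

Empty peak lists, empty valley sets and empty regions are legal
(functions return empty tables); all-zero tracks cannot be RPM-scaled;
fewer than 10 log-defined bins cannot anchor a breakpoint; fewer than 10
late peaks cannot calibrate a cutoff (the error suggests a fallback
percentile over all peaks); fewer than two accepted peaks or tracked
valleys cannot produce growth or filling statistics. Reads outside
declared chromosomes are rejected with a warning count. bedGraph
intervals must align to the declared grid (a short final interval is
accepted only at the chromosome end) and may not overlap; absent bins are
zero-filled, because absence in a genome-wide count track means zero
coverage, not missing data.

## Interfaces

The package's surface is its functions: `run_pipeline()` orchestrates
normalise → detect → dynamics → valleys → domino over a pulse series
with per-stage skipping and a determinism guarantee (same inputs, same
tables), `write_pipeline_tables()` and `write_rcd_bed()` export the
tabular reports, and `export_heatmap()` writes a multiscale matrix as
raw TSV plus an optional per-scale max-normalised image (display-only
rescaling; analysis always uses raw values). Every constant of the
analysis — 500-kb width, 70th percentile, 25% isolation ratio, 180-kb
trim, 100-kb tracking tolerance, 1.6-Mbp grouping distance, 1.5-kb/min
fork rate, pulse windows — is an explicit argument with these defaults.

## Known limitations

The Ricker scale convention was chosen for flat-topped features; very
sharp (sub-bin-scale) or strongly asymmetric peaks will be width-biased.
The late-domain cutoff assumes late domains carry mostly background
within the first pulse. Valley tracking by nearest peak position can
switch flanks in dense regions if a stronger peak appears within the
tolerance. The domino analysis reads population-level height order; it
cannot distinguish within-cell sequential activation from population
structure. The per-chromosome broken-line fit is available but the
default is genome-wide, which assumes one background ratio for the whole
library.
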