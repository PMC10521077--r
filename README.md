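# rcdscan

Detection and dynamics of **Replicon Cluster Domains (RCDs)** in early
replicating DNA, from binned EdU pull-down sequencing (EdU-seq) time
courses.

Eukaryotic genomes replicate from clusters of 2–10 origins that fire
near-synchronously and span roughly 400–800 kb. In synchronised early-S
cells pulsed with EdU at successive 30-minute windows, the nascent-DNA
signal resolves these clusters as discrete peaks inside early replication
timing domains. `rcdscan` implements the computational side of that
experiment for people analysing Repli-seq/EdU-seq tracks: it normalises
pull-down against input, locates the peaks at their characteristic scale,
follows their widths and the valleys between them across the time course,
and scores whether adjacent domains activate in sequence (the "domino"
model).

## What the package computes

**Background normalisation.** Pull-down and control counts are scaled to
reads per million (P_i, C_i). Assuming the pull-down contains scaled
genomic background, P_i = S_i + r C_i, the no-signal bin set
G = {i : log(P_i + C_i) < b} is isolated by fitting a two-segment broken
line to log(P_i/C_i) versus log(P_i + C_i) (horizontal left segment, OLS
right segment, breakpoint b by exhaustive SSE search). The scale factor is
estimated either as the ratio of sums over G
(r̂ = Σ_G P_i / Σ_G C_i) or, by default, as the mode of the per-bin
P_j/C_j ratio distribution over G, which resists the residual signal that
inflates the ratio of sums. The signal is S_i = P_i − r̂ C_i, negative
values retained.

**Multiscale Ricker detection.** S is convolved with Ricker ("Mexican
hat") kernels ψ(t) ∝ (1 − t²/σ²) exp(−t²/2σ²) whose peak width W — the
span of the central positive lobe — maps to σ = W/2. A width scan of the
called-peak heights locates the dominant feature scale (≈500 kb for
replicon clusters); detection then runs at 500 kb, with the peak-height
cutoff calibrated as the 70th nearest-rank percentile of wavelet peaks in
*late* timing domains, where peaks are essentially background. Surviving
early-domain peaks are the RCDs, each annotated with its replication peak
height (max S over the W/2 extent).

**Width dynamics.** Isolated RCDs (flanking signal ≤ 25% of under-peak
signal) are width-fitted per timepoint by an optimal-wavelet grid search
(200–1200 kb in 25-kb steps), by Nelder–Mead Gaussian least squares
(FWHM = 2√(2 ln 2) σ), or by a flat-topped Gaussian whose width at half
max suits the plateau-shaped profiles that expanding clusters produce.
Per-interval width deltas give growth rates in kb/min with one-sample
t-tests against zero; two outer forks at v kb/min predict 2vΔt ≈ 90 kb
per 30-min interval.

**Valley filling.** Adjacent wavelet peaks within one early domain define
a valley after trimming 180 kb (fork travel, 1.5 kb/min × 120 min) from
each internal edge. Valleys whose flanks persist within ±100 kb across
all four timepoints are tracked, and their mean and minimum S are
expressed as percentages of the mean flanking peak height — rising
minima indicate initiation inside the valley rather than fork spillover.

**Domino ordering.** RCDs within 1.6 Mbp of each other in one domain form
groups. Height-order permutation classes (canonical under chromosome
reversal: 3 classes for triples, 12 for quadruples) are tabulated against
the uniform i.i.d. expectation, and the adjacent-height similarity metric

    1 − (ADFA − ADFSV) / (MADFAP − ADFSV)

scores each group: 1 for perfect height order, 0 on average for random
order, negative for interleaved heights (ADFA = mean adjacent absolute
difference as laid out; ADFSV = the same after sorting = range/(n−1);
MADFAP = mean over all orderings = mean absolute difference over all
distinct pairs). For reporting, each group's value is recorded n−1 times
(weighted) and once (no-rep), each sample t-tested against zero.

**Synthetic data.** A kinetic simulator generates binned P/C tracks with
full ground truth: per-cell S-phase entry, stochastic cluster activation,
fired-origin subsets, bidirectional forks at 1.5 kb/min, 30-min EdU
pulses, and Poisson read sampling over a uniform background. Named
presets (`basic`, `growth`, `growth_staggered`, `valleys`,
`domino_null`, `domino_coupled`) pin down the scenarios used by the test
suite.

## Worked example

```r
library(rcdscan)

bm  <- make_benchmark_suite("basic")       # 2 x 20 Mbp, 500-kb clusters
sim <- simulate_edu_seq(bm$config, seed = 1)

norm <- background_normalize(sim$P[[1]], sim$C[[1]])
print(norm$fit)
#> <normalization_fit> b = 7.4967, |G| = 241 of 794 eligible bins
#>   r_cis = 0.4678, r_mode = 0.4151, chosen = mode

early <- domain_regions(bm$config$domains, "early")
late  <- domain_regions(bm$config$domains, "late")
scan_optimum(width_scan(norm$S, early))
#> [1] 5e+05                                 # 500 kb, the planted scale

conv <- lapply(norm$S, function(t) convolve_track(t, ricker_kernel(500e3, 50e3)))
cut  <- calibrate_cutoff(call_peaks(conv, late), 70)
rcds <- filter_rcds(call_peaks(conv, early), cut, norm$S, bm$config$domains)
nrow(rcds)
#> [1] 14                                    # all 14 planted clusters
rcd_stats(rcds, bm$config$domains)$mean_separation
#> [1] 1200000                               # the planted 1.2-Mbp spacing

groups <- form_groups(rcds)
adjacent_value_similarity(groups[[1]])
#> <adjacency_metric> n = 7: ADFA 402.9, ADFSV 191.2, MADFAP 481.6 -> value 0.2710
```

The normalisation report shows the ratio-of-sums estimate (0.468) pulled
above the ratio-mode estimate (0.415) by residual signal in G, the width
scan recovers the planted 500-kb cluster scale exactly, detection finds
every planted cluster at the planted spacing, and a seven-member group of
stochastic peak heights scores mildly positive on the similarity metric,
as expected when activation is random.

`run_pipeline()` chains all stages (normalise → detect → dynamics →
valleys → domino) over a four-pulse time course and
`write_pipeline_tables()` exports the TSV/BED reports.

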