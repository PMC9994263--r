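---
title: "Models and methods behind chorscar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind chorscar}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chorscar)
```

chorscar quantifies how histone H2A–H2B modifications traverse DNA
replication: how much of a mark arrives on nascent chromatin by parental
histone recycling, how fast steady state is restored, and how the mark
partitions between the two sister chromatids. This vignette explains the
models, the tunable parameters, the numerical choices, and what the
synthetic data generator does and does not emulate.

## Spike-in normalization (RRPM)

ChOR-seq chase timepoints are only comparable after correcting for
library size, immunoprecipitation efficiency and EdU-capture efficiency.
The correction uses exogenous spike-in chromatin (a second species, at a
nominal 0.05 % of total chromatin) and the EdU-purified ("clicked")
input as the reference. With all read totals as uniquely mapped,
deduplicated reads in millions, the raw factor per sample is

$$f = \frac{1}{\text{ChOR}_{spike}} \cdot
      \frac{\text{Input}_{spike}}{\text{Input}_{target}},$$

and within a time course all factors are rescaled by a common
$\alpha$ so the largest is exactly 1 (`downsampling_factors()`). The
factors are dimensionless and invariant to any common rescaling of
sequencing depth; the unit (millions) matters only for
`global_restoration_level()`, the $\alpha$-free factor multiplied by the
sample's target-genome reads in millions, which traces genome-wide
restoration over time. Downsampling is applied as multiplicative
scaling of signal rather than literal read subsampling: the two are
equivalent in expectation and scaling is deterministic.

## The restoration model

Per region, RRPM signal across chase time $t$ (hours) is fit to the
first-order form

$$y(t) = y_{max} - b\,e^{-kt},$$

where $y_{max}$ is the steady-state plateau, $k$ the restoration rate
and $b$ the amplitude still to be written after replication. Two derived
quantities summarise a fit: the nascent (recycled) fraction
$(y_{max}-b)/y_{max}$, i.e. the proportion of steady state present at
$t=0$, and $t_{90} = \ln(0.1\,y_{max}/b)/(-k)$, the time to reach 90 %
of the plateau (0 when $b \le 0.1\,y_{max}$, since the signal then
starts above 90 %).

`fit_first_order()` uses variable projection: for any candidate rate
$k$ the model is linear in $(y_{max}, b)$ and solved by least squares,
leaving a one-dimensional profile over $k$ that is scanned on a fixed
120-point logarithmic grid over $[10^{-3}, 50]\ \mathrm{h^{-1}}$ and
refined by golden-section search (tolerance $10^{-12}$ on $\log k$).
This makes the fit deterministic for given data — there is no random
restart — and recovers noiseless curves to better than $10^{-6}$.
Constraints $k>0$ and $0 \le b \le y_{max}$ are enforced by boundary
fall-backs in the linear step. Degenerate inputs are flagged rather than
silently fit: constant series return the plateau with `b = 0` and a
`degenerate-constant` flag, monotonically decreasing series raise an
error pointing to the unstable classification, and rates pinned at the
grid boundary are flagged `rate-at-bound`. Times are minutes at the I/O
surface and hours inside the model.

### Precision limits of the rate estimate

With the study's seven chase timepoints (0–8 h) and 10 % multiplicative
noise, the rate is intrinsically hard to pin down: the Cramér–Rao bound
of the three-parameter model gives a median best-achievable relative
error of $\hat{k}$ around 26 % for a single series and ~19 % for
curves averaged over two replicates, across true $t_{90}$ between 0.5
and 12 h. The package's estimator sits essentially on this bound (an
independent `nls` fit started at the truth does no better), and the test
suite asserts near-efficiency against the bound rather than an
unattainable absolute accuracy. The derived quantities are much better
behaved: the recycled fraction is typically recovered within 2–3
percentage points, and median $t_{90}$ estimates for fast
($k = 1.3\ \mathrm{h^{-1}}$) and slow ($k = 0.18\ \mathrm{h^{-1}}$)
marks land within the 2 h and 12 h envelopes expected for fast-restoring
ubiquitination marks and slow Polycomb methylation respectively.

## Restoration categories

The categorical view asks *when* a region stops gaining signal: a region
is restored at the earliest timepoint $X$ such that
$T(X+n)/T(X) < 1.5$ for every later timepoint. A $\ge$1.5-fold decrease
anywhere marks the region unstable (by default any later-vs-earlier
pair; a consecutive-only variant is available since the defining rule
does not specify), an all-zero series is excluded, and a zero value at
$X$ simply means "not restored at X" (the ratio is undefined). Labels
are computed per replicate and only regions with identical labels in
every replicate are kept — agreement is on labels, not on averaged
signal. The rule is scale invariant, so it is insensitive to residual
normalization error; it is, however, strict: at 10 % noise a
substantial minority of regions near a category boundary draw different
labels in the two replicates and are excluded, which mirrors the
behaviour of the published rule rather than a defect.
`restoration_summary()` reports, per stratum, the cumulative fraction
restored at each timepoint over the classifiable (non-excluded) regions,
with unstable counts carried separately.

## Interval operations

Coordinates are 0-based half-open (BED) everywhere; overlap means at
least one shared base pair, and the 500 bp merge distance is gap
(end-to-start) distance, both matching BEDtools defaults. Consensus
peaks concatenate and sort all replicate peaks, merge within the gap
distance, keep merged intervals overlapping at least one peak of
*every* replicate, and drop blacklist overlaps. Window parsing keeps
truncated terminal windows and flags them so signal can be
width-normalized. Quantile groupings (expression quartiles Q1–Q4 low to
high; intensity deciles D1–D10 with D1 highest) break ties by stable
rank order for determinism.

## Strand partition and fork directionality

The SCAR-seq chain is fixed, in this order: per-strand RPM in 1 kb
windows → uniform blur over the 30 neighbouring bins on each side
(truncated at chromosome ends; strands and chromosomes independent) →
input subtraction floored at zero → removal of windows below 0.3 RPM on
*both* strands → $\mathrm{Partition} = (F-R)/(F+R)$ → clipping at the
genome-wide 0.0001/0.9999 quantiles of the unmasked scores. OK-seq
fork directionality is $\mathrm{RFD} = (R-F)/(F+R)$ with no input
correction. Partition is antisymmetric under strand exchange, a
property the tests verify exactly end to end.

Two decisions here were genuinely open and deserve attention:

* **Input smoothing and scaling.** The input is blurred with the same
  kernel as the sample (toggleable), and by default rescaled to the
  sample's background level before subtraction, using the ratio of
  lower-quartile blurred window totals (`input_scale = "background"`).
  The rescaling matters: an RPM-normalized input necessarily sits
  *above* the RPM background of an enriched sample (enrichment
  compresses the background's share of the library), so unscaled
  subtraction over-subtracts, and with the zero floor this rectifies
  low-coverage windows to partition ±1 and biases partition magnitudes
  upward. Background-matched scaling removes the distortion; the lower
  quartile rather than the median is used because smoothing smears peak
  signal across many windows. Plain unscaled subtraction remains
  available (`input_scale = "none"`).
* **Orientation.** "Upstream/downstream" of an initiation zone follow
  genomic coordinate order. RFD rises from negative to positive through
  a zone, crossing zero at its center; a mark biased to the leading
  strand therefore shows positive partition downstream and negative
  upstream, and the adjusted partition (upstream values negated, each
  window assigned to its nearest zone center, coordinate-ties to the
  lower zone) makes positive values mean "leading" on both sides.

Zone edges are detected as the RFD minimum within 100 kb upstream and
maximum within 100 kb downstream of each center, ties broken toward the
center; zones without unmasked RFD in a search range are dropped with a
log message, and zones farther than 100 kb from any peak of the mark are
filtered out. Meta-profiles average unmasked partition per offset in a
200 kb window, replicates averaged after per-replicate profiles.

Asymmetry between two samples is a paired Wilcoxon signed-rank test
(normal approximation) over the common eligible windows: 25–75 kb from
the nearest zone center with input-corrected coverage above 0.6 RPM in
both samples, optionally intersected with a feature filter; fewer than
10 eligible windows is an error. Identical samples return $p = 1$. Note
that windows smoothed with a 61-bin kernel are serially correlated, so
when whole blurred tracks are compared the nominal p-values are
anti-conservative — a property of the published procedure itself; the
package's calibration tests therefore operate on independent
window-level values.

## The synthetic data generator

`sim_config()` + `simulate_genome()` build a deterministic, seeded toy
genome (default two 10 Mb chromosomes) carrying peaks of heterogeneous
widths with fast/medium/slow kinetic classes, genes, CpG islands,
enhancers, a blacklist, and initiation zones placed ≥ 200 kb from
chromosome ends with a piecewise-linear RFD ramp (plateau ±0.6, the
qualitative OK-seq shape). Default kinetic truths are
$(y_{max}, b, k) = (1, 0.7, k)$ with $k = 1.3, 0.5, 0.18\ \mathrm{h^{-1}}$,
i.e. 30 % recycling and $t_{90}$ of ≈1.5, 3.9 and 10.8 h — the regimes
of fast ubiquitination/variant marks versus slow Polycomb methylation.
Chase timepoints default to 0/15/30/60/120/180/480 min.

Read counts are simulated directly at the 1 kb window level (the
analysis consumes window counts; alignment is upstream of this package):
each window draws independent Poisson counts per strand. One unit of
unbiased, input-like background underlies every window; peak windows add
enriched mark-derived reads (default enrichment 3, as for broad
repressive domains) and only those enriched reads carry the strand
bias, $f_{fwd} = (1+\beta\,s(x))/2$ with $s(x)$ the normalized RFD ramp,
so background windows are strand-symmetric as in the assay. The matched
input is flat and unbiased. OK-seq counts follow the ramp directly.

ChOR time courses multiply each peak's analytic curve (scaled by a
log-normal peak intensity) by mean-one log-normal noise with CV 0.10 by
default — the noise model is a declared choice, the source material
being silent on replicate variability. The spike-in ledger is simulated
coherently with the signal: each sample's library size (default
2×10⁷ reads, matching the scale of real ChOR libraries whose read
ledgers are reported in millions) and IP efficiency drift log-normally,
the observed signal scales inversely with the sample's true spike-in
factor, and the ledger's Poisson read totals let the pipeline re-derive
the factors — so RRPM correction is both necessary and sufficient to
recover comparability. At `noise_cv = 0` all stochastic drift is
disabled and the table equals the analytic curve exactly. The
replication-dilution model is the simplest possible bookkeeping: each
daughter receives parental density × recycled fraction / 2, new
histones unmodified, so full symmetric recycling gives a parental :
per-daughter ratio of exactly 2.

What the generator does **not** emulate: sequence content, mappability,
duplicate reads, EdU click-chemistry efficiency, fragment-length
effects, locus-specific noise structure, or replication timing.
Passing tests therefore demonstrate the correctness of the analysis
arithmetic and its statistical behaviour under the declared noise
model, not robustness to every artifact of real sequencing data.

## Problem sizes and runtimes

The test and acceptance workloads use two 10 Mb chromosomes
(20,000 1 kb windows), 50–200 peaks, 6–10 initiation zones, 100–200
fitted time courses and 10⁷-scale simulated read depths — sizes chosen
so the complete suite runs in a couple of minutes on one core while
every statistical check retains enough data to be sharp (zone-level
standard errors, 1,000-instance oracle sweeps, 100-replicate null
calibrations).

## Known limitations

* The rate $\hat{k}$ from a 0–8 h course is noisy by design of the
  sampling grid (see the Cramér–Rao discussion); t90 and recycled
  fraction are the robust summaries.
* Quantile clipping bounds are estimated per sample, so two samples'
  clipped partitions are comparable only where both are interior to the
  bounds.
* The strict replicate-agreement rule discards many borderline regions
  at realistic noise; this is faithful to the published rule, and the
  excluded count is reported rather than hidden.
* Initiation zones are inputs (detected edges refine given centers);
  the package does not call zones de novo from OK-seq.
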