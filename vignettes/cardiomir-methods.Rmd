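---
title: "Methods: seed-site screening and cardiac trace analysis in cardiomiR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: seed-site screening and cardiac trace analysis in cardiomiR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cardiomiR)
```

cardiomiR bundles the computational analyses needed to ask which microRNAs
are positioned to regulate cardiac repolarization and to quantify the
electrophysiological consequences of manipulating them. This vignette
explains the models and procedures behind each module, the parameters that
matter, the numerical choices, and what the synthetic-data generators do
and do not emulate.

## 1. Canonical seed-site model

A miRNA represses an mRNA mainly through Watson–Crick pairing of its
*seed* — nucleotides 2–8 of the mature strand — with the 3' UTR. The three
canonical site types on the target strand are derived from the seed `s`
(5'→3', positions 2–8 of the miRNA):

* `7mer-m8` — reverse complement of `s` (pairs miRNA positions 2–8);
* `8mer` — the 7mer-m8 followed by a literal `A` opposite miRNA
  position 1;
* `7mer-A1` — reverse complement of `s[1..6]` (miRNA positions 2–7)
  followed by a literal `A`.

The `A` requirement is the standard canonical definition (an adenosine
opposite position 1 is recognized by Argonaute regardless of the miRNA's
first base), so the scanner demands a literal `A` in the UTR rather than
"any nucleotide".

**Counting convention.** A window matching the 8mer is *one* physical
site: the 7mer-m8 starting at the same offset and the 7mer-A1 starting one
base later are its internal windows and are suppressed. All remaining
7mer matches are reported, including mutually overlapping ones — the
screen counts binding sites, not disjoint footprints. For degenerate seeds
whose two 7mer strings coincide (e.g. poly-U), a matching window is
reported once, as 7mer-m8. `N` never matches, and DNA or RNA input yields
identical results. Coordinates are 0-based half-open on the supplied UTR;
when a gene has several transcript UTRs the longest is scanned (logged),
since isoform handling is otherwise underdetermined.

Scanning every (family, gene) pair gives the binding-site count matrix;
families are ranked by row sum (total site burden across the panel), ties
broken lexicographically so the ranking is deterministic. Expression
gating intersects the top-N most abundant miRNAs of two datasets
independently (N = 100 by default), with boundary ties broken by abundance
then id. Gene-level expression uses a strict threshold (TPM > 1 by
default). Conservation of sites is accepted as an optional *annotation*
and never computed: alignment-based conservation calls require a
multiz-style pipeline that is out of scope here, so the default scan
counts all canonical sites and says so.

## 2. Targetome statistics

**Enrichment.** For a target set against a term (disease or GO) within a
declared universe, the p-value is the hypergeometric upper tail
`P(X >= overlap)` — identical to the one-sided Fisher exact test for
over-representation, which is the conventional reading of "Fisher exact"
in gene-set enrichment. The per-term `contribution` (overlap / term size)
is the usual bubble-size quantity. The universe is a required argument
because results depend materially on it (all genes vs expressed genes vs
annotated genes); no silent default is defensible. Raw p-values are
reported by default (a 0.05 threshold on raw p is the convention this
screen follows); a Benjamini–Hochberg column is available and logged when
requested.

**DE filters.** "More than 30% expression change at FDR < 0.05" is exact
for upregulation (FC > 1.3). For downregulation two readings exist:
FC < 0.70 (the plain linear reading, default) or FC < 1/1.3 ≈ 0.769 (the
log-symmetric mirror). The choice is a logged argument; the two differ for
fold changes between 0.70 and 0.769. Reciprocal regulation (repressed
under a mimic, derepressed under an antimiR) is plain set intersection of
the two filtered sets.

**Fold-change shift.** Whether predicted targets are coherently shifted is
tested by a two-sided Wilcoxon rank-sum on log2 fold changes, targets vs
all other genes, with the Kolmogorov–Smirnov statistic reported alongside
as a shape check and the difference of group medians as effect size. The
rank-sum was chosen as primary because it is location-focused, robust to
the heavy tails of DE tables, and exactly invariant under adding a
constant to all log2FC values; a t-test would be needlessly sensitive to
outlying genes, and the KS statistic alone conflates location with shape.
An all-tied table carries no evidence and returns p = 1.

## 3. Optical AP analysis

Optical recordings (e.g. di-8-ANEPPS emission ratios) are dimensionless
and drift with photobleaching, so all AP features are defined relative to
a per-AP baseline and amplitude, making them invariant under positive
affine transforms of the signal.

* **Detection.** The signal is smoothed by a centered moving average
  (`smooth_ms`, default 20 ms), differentiated, and thresholded at half
  the maximal derivative; a candidate must also exceed 8 × the derivative
  MAD, which rejects flat noise-only traces. Each above-threshold run is
  collapsed to its derivative maximum and then *refined on the raw
  derivative* within half a smoothing window — smoothing flattens the
  upstroke's derivative and would otherwise bias detections early.
  Detections closer than `min_rr_ms` (250 ms) keep the steeper one.
* **Baseline and amplitude.** Baseline is the 10th percentile of the
  smoothed latter half of the preceding inter-AP segment (robust to
  bleaching and to repolarization tails); amplitude is the smoothed beat
  maximum minus baseline.
* **APD.** Onset ("takeoff") is the last raw-sample crossing of
  baseline + 10% of amplitude before the upstroke, interpolated between
  samples; the repolarization endpoint is the linearly interpolated
  crossing of baseline + (1 − level) × amplitude on the *smoothed*
  falling limb. Raw samples at the onset give sub-sample precision on the
  steep rising limb; smoothing on the slow falling limb suppresses noise
  without bias because a symmetric average preserves a locally linear
  segment. An AP whose repolarization does not complete before the next
  AP or the end of the trace is marked invalid and excluded (and counted).
* **Rate correction.** `cAPD90 = APD90 / sqrt(RR/1000)` with RR the
  interval from the *previous* upstroke — Bazett needs a preceding cycle
  length, so the first AP of a trace carries no cAPD90. A per-cell mean
  rate is a config alternative. Per-cell summaries are medians, which
  match how such distributions are usually reported and resist occasional
  mis-detections; `analyze_cell` flags cells with fewer than 3 valid APs.

Field potentials from multielectrode arrays are handled at the level the
practice dictates: FPD and beat interval are consumed as read out by
vendor software and Bazett-corrected (`cfpd`); `fpd_extract` is a clearly
flagged best-effort extractor (spike extremum → largest subsequent
excursion), not the primary path.

**IV curves.** Step currents are reduced to the signed peak (inward
currents such as the L-type calcium current) or the mean over a terminal
window (steady-state outward currents), normalized to capacitance
(pA/pF). Linear leak is fitted over a user-stated sub-threshold range
(logged — the appropriate range depends on the current under study) and
subtracted; drug-sensitive components are isolated by pointwise
control − drug subtraction on identical potential grids.

## 4. Tissue refractory period

The protocol pairs every regular pacing stimulus (S1, 0.5 Hz) with a
premature stimulus (S2) at a fixed interstimulus interval, held for a
20-s block; the interval decreases from 1000 ms towards 250 ms. The step
size is deliberately a *required* argument of `build_schedule`: it is a
protocol parameter the RP resolution depends on, and no silent default
would be honest.

A pair shows "two distinct contractions" when twitch detection finds a
peak attributable to each stimulus (within a 300-ms response latency) and
the valley between them drops below half the smaller peak (above the
local pre-stimulus baseline) — a fused broad twitch fails. Peaks count as
twitches when their prominence reaches 20% of the reference twitch (the
median S1-only twitch of the pre-protocol baseline period). A block is
classified by *strict majority* over its ~10 pairs: the protocol
classifies per block, and voting suppresses single-pair detection noise;
"last pair" or "any pair" rules would let one noisy window flip a block.
The RP is the longest interval whose block failed — the literal decision
rule, applied even to non-monotone block patterns rather than
interpolating, with censored sentinels (`below_min` / `above_max`) when
no or all blocks fail. The twitch smoothing window is 40 ms: the twitch
kernel peaks ~66 ms after the stimulus, so real twitches survive while
white-noise prominences are pushed to ~6 standard deviations below
threshold at 10% force noise.

## 5. Reporter quantification

Per-cell GFP/RFP ratio first, then the arm mean, then treated/control —
not the ratio of arm mean intensities — because single-cell ratios cancel
per-cell expression and size effects, and the normalized ratio is then
invariant to any per-channel rescaling applied to both arms. Dispersion is
the delta-method SE of a ratio of means. The default two-group test is
the rank-sum (intensity ratios are right-skewed); Welch's t is available.
Seed-mutated UTR arms run through the identical operation as the
specificity control and should return a normalized ratio near 1.

## 6. What the generators emulate — and what they do not

Every generator records its ground truth *before* noise is applied and is
bit-reproducible under `rng_seed` (seeds are applied without disturbing
the caller's RNG stream).

* **UTRs.** Random background at a set GC content with planted sites at
  non-overlapping positions. Background is rejection-sampled against the
  *whole* family pool — any window the scanner would report beyond the
  planted set is redrawn — so recovered counts equal planted counts
  exactly, making count recovery an exact test rather than a statistical
  one. Incompatible family pools (one family's site string inside
  another's) are rejected up front by `random_seed_families`, and
  infeasible plantings raise an explicit error. Real UTRs are not
  i.i.d. sequence: no dinucleotide structure, no conservation, no AU-rich
  context effects — so passing tests show correct *counting*, not
  biological site efficacy.
* **Expression.** Two abundance tables with an exactly planted top-N
  intersection on a smooth exponential abundance ladder. Real expression
  has ties, batch structure and heavy tails; the generator only
  guarantees the set identity the gate must recover.
* **AP traces.** Piecewise-linear beats (baseline → upstroke → plateau →
  linear repolarization) with analytic APD90 = upstroke + plateau +
  0.9 × repolarization, plus white noise and linear drift. Defaults
  (10 ms upstroke, 150 ms plateau, 250 ms repolarization, RR 640–1000 ms,
  ratio amplitude ~1) sit in the range of optical recordings from
  hiPSC-derived myocytes. Real APs have curved phase-3 repolarization and
  rate-dependent shape changes; the generator tests the measurement
  geometry, not AP biophysics (no ionic model).
* **Force traces.** Normalized double-exponential twitches (rise 40 ms,
  decay 120 ms, ~1 mN peak — typical of cultured human myocardial
  slices) under the binary response rule: S2 evokes a full twitch iff its
  interval exceeds the true RP, else a twitch scaled by
  `refractory_response_fraction` (0 by default — the decision rule in the
  field is itself binary; a graded mode exists for robustness studies).
  Real slices show graded restitution near the RP and beat-to-beat
  variability.
* **DE tables.** Targets `N(shift, sd)`, background `N(0, sd)`, FDR from
  Wald-style p-values BH-adjusted, so FDR tracks effect size. With zero
  shift, targets and background are exchangeable — the property the
  type-I-error calibration relies on.
* **Reporter cells.** Lognormal multiplicative cell-to-cell noise on both
  channels; the arm-mean bias it introduces cancels exactly in the
  normalized ratio. `cv = 0` is exact.

## 7. Problem sizes and numerical choices

The packaged tests and the acceptance script run at desk scale, chosen so
each check is statistically meaningful yet completes comfortably on one
CPU: 10^4 random (UTR, seed) pairs against the exhaustive scan oracle; 50
planted UTR sets of 20 genes; all hypergeometric tables with universes up
to 12 against a binomial-coefficient enumeration; 100 simulated cells for
APD recovery at 5% noise (tolerance: median error ≤ 2%); 100 force traces
per noise level for RP recovery (exact noiselessly, ≥ 95% at 10% noise);
1000 null and 300 shifted DE tables for the shift test's size and power;
300 cells per arm for reporter recovery. Thresholds crossings use linear
interpolation throughout for sub-sample resolution; ties in rankings are
broken lexicographically for determinism; degenerate inputs (empty terms,
all-tied tables, flat traces, censored RPs) return defined values or
explicit flags rather than errors wherever a defined value exists.

## 8. Known limitations

* The scanner is canonical-only: no 6mer, 3'-supplementary, or centered
  sites, and no context scoring — site counts are a prioritization
  heuristic, not an efficacy prediction.
* Conservation filtering relies on user-supplied annotations.
* `fpd_extract` is a heuristic convenience, not a validated FPD reader.
* The RP decision inherits the protocol's resolution (one schedule step)
  and the literal longest-failing-interval rule; no sub-step
  interpolation is attempted.
* Generators are statistical stand-ins; none of the packaged checks can
  validate biological conclusions about any particular miRNA.
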