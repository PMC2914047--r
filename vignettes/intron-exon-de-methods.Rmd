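---
title: "Methods: SAM with leave-one-out consensus on intron-exon two-color arrays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: SAM with leave-one-out consensus on intron-exon two-color arrays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope and model

`samloo` analyses two-color (Cy3/Cy5) oligoarray experiments on platforms
that interrogate, besides exons of protein-coding genes, long (>500 nt)
non-coding RNAs transcribed from intronic regions — in sense or antisense
orientation relative to the host gene — and from intergenic regions. The
scientific question it serves is a case-control contrast (e.g. patient
versus healthy bone-marrow cells) with very small groups (3-4 samples per
arm), where single-sample artifacts can dominate a significance list. The
pipeline therefore wraps a permutation-based differential-expression
statistic in a leave-one-out consensus: a transcript is reported only if
it passes the thresholds in the full dataset *and* in every dataset
formed by removing one sample.

## Preprocessing

Each hybridization carries one biological sample against a common pooled
reference. Per array and channel:

1. **Background subtraction.** net = max(fg − bg, floor), with
   `floor = 1` intensity unit so log2 stays defined. Clamping negative
   raw intensities is refused at read time — they indicate a corrupt
   export, not a dim probe.
2. **Expressed call.** A probe is expressed in a channel when
   fg > bg + k·spread, with `background_k = 2.6` by default
   (a one-sided normal call at roughly p < 0.005, the behaviour of
   feature-extraction "well above background" flags). Pixel-level
   statistics are not available downstream of feature extraction, so
   the call is a deterministic rule on the exported summaries, with k
   configurable.
3. **Dye correction.** M = log2(Cy5/Cy3) is regressed on
   A = ½·log2(Cy5·Cy3) by LOWESS (span 0.3, one robustifying
   iteration); the corrected per-channel log2 intensities are
   A ± (M − M̂)/2. The span default is a conventional middle ground: wide
   enough to ignore differential expression, narrow enough to track an
   intensity-dependent bias. Fits are refused below 10 probes.
4. **Quantile normalization** across samples (mean-of-sorted-columns
   target; ties receive the mean of their target quantiles), delegated
   to the standard limma implementation behind the package's function.
5. **Expressed-in-all filter.** Only probes expressed in every sample —
   in the channel carrying that sample — enter statistics. The filter is
   computed on the full sample set once; leave-one-out subsets reuse it,
   so all runs score the same probe universe.

## The SAM statistic

For probe *i*, d(i) = (x̄_patient − x̄_control) / (s(i) + s0), where s(i)
is the pooled scatter

s(i) = sqrt[(1/n1 + 1/n2) · (SS1 + SS2)/(n1 + n2 − 2)]

and s0 is the exchangeability ("fudge") factor that keeps low-variance
probes from dominating. s0 is chosen among the percentiles (0, 5, …, 100)
of s by minimizing the coefficient of variation of median |d| across
s-quantile bins, computed once on the observed labels and reused for all
permutations (standard practice; the permutation null must hold s0
fixed). Below 100 probes the estimate falls back to median(s).

The null is built from group-label permutations. With small designs the
distinct label assignments are few — C(8,4) = 70 for 4v4, C(7,3) = 35
for 3v4 — so when they fit within the permutation budget (default 500)
they are enumerated exhaustively; otherwise assignments are sampled
without replacement while the distinct count is at most five times the
request, with replacement beyond that. The expected order statistics
d̄(i) are means of the i-th smallest null d across permutations.

For a threshold delta, the upper cutoff is the smallest non-negative
observed order statistic with d(i) − d̄(i) ≥ delta, the lower cutoff the
largest non-positive one with d̄(i) − d(i) ≥ delta (cutoffs sit on their
respective sides of zero); probes at or beyond a cutoff are called. False
calls are counted per permutation beyond the same cutoffs and
summarized by the **median** (the canonical choice; a 90th-percentile
variant is a config switch), with the null proportion fixed at 1 —
conservative, and the only defensible choice without a reliable π0
estimate at these sample sizes. FDR = min(1, summary/n_called), defined
as 0 when nothing is called. The per-probe q-value is the minimum FDR
over a 200-point delta grid spanning 0 to max|d(i) − d̄(i)| at which the
probe is called; probes never called get q = 1. Reports print q at three
decimals, so "0.000" means below printable precision, not zero risk.

Fold changes are linear ratios 2^(x̄_patient − x̄_control) with
down-regulation written as the negative reciprocal (−4 means four-fold
down), the convention of the field's supplementary tables. The patient −
control orientation is fixed so signs are comparable across runs.

## Leave-one-out consensus

One dataset per sample is formed by removing that sample (patients and
controls alike; a group must keep ≥ 2 members, hence groups of ≥ 3).
The full dataset is included as a run by default so the reported
fold change and q per probe come from all samples. A probe survives iff
in **every** run q ≤ fdr_max, |FC| ≥ fc_min, and the direction is
identical. Direction consistency is enforced although not strictly
implied by thresholds alone: a sign flip under single-sample removal is
exactly the non-robustness the wrapper exists to remove. Defaults follow
the published analysis settings: fc_min 1.7 with fdr_max 0.01
(progenitor cells) or 0.05 (stromal cells); relaxed network-export lists
use 0.05/0.15. Per-run permutation seeds derive deterministically from
the master seed and the left-out sample id, so a consensus is
reproducible from one integer. The result keeps a per-run audit trace,
and both the full-data and the worst-run statistics per probe.

## Probe classification and locus reporting

Probes are classed against gene models: exon overlap on the same strand
(any shared base, conservatively) → coding; inside a span otherwise →
intronic, sense/antisense by strand match; outside all spans →
intergenic, named after the nearest gene on the chromosome (minimal
interval gap, ties to the lower start coordinate). On a real platform
the shipped annotation is authoritative and the classifier serves as a
consistency check; on synthetic data it defines truth. Consensus lists
are partitioned into coding/ncRNA × up/down counts, and loci
contributing both a significant ncRNA probe and a significant coding
probe yield concordance pairs (one per ncRNA probe, matched to the
locus's lowest-q coding probe), flagged concordant when directions
agree.

Displays mirror the field's signature heatmaps: per-probe z-scores
using the population SD ("standard deviations above/below the probe's
average"), with samples ordered by UPGMA (average linkage) on
1 − Pearson correlation; columns are pre-sorted by sample id so merge
ties resolve deterministically. Group homogeneity is summarized as the
mean patient×control correlation; two compartments are contrasted by a
rank-sum test on Fisher-z transformed pairwise correlations — the pairs
share samples, so this p-value is descriptive, not exact (the published
contrast named no statistic at all).

## qPCR validation

Relative expression is 2^−ΔΔCT: ΔCT = mean CT(target) − mean CT(HPRT-like
reference) over replicates (spread > 1 cycle is flagged), ΔΔCT subtracts
the arithmetic mean control ΔCT per gene, and amplification efficiency is
fixed at 2 — the assumption of the method; no efficiency calibration is
modelled. Controls evaluated against their own mean have geometric-mean
RQ 1 by construction. Array agreement is a sign comparison: mean patient
RQ versus 1 against the sign of the array fold change, with RQ converted
to the same signed convention for plots. Both per-patient and group-mean
summaries are emitted since bar-plot conventions differ.

# The synthetic-data generator

The generator is first-class, tested code: it emulates the study design
so every stage is testable with known truth and no downloads.

* **Architecture.** Non-overlapping three-exon gene spans on up to 8
  chromosomes; per locus a coding probe in the middle exon, optional
  intronic probes (sense/antisense) in the first intron, optional
  intergenic probes downstream (nearest-gene naming reproduces the
  platform's convention by construction).
* **Signal.** Per-probe log2 baseline ~ N(9, 1.5) (log-normal
  intensities); ~5% of probes near background (log2 3). Patients add the
  planted signed log2 effect; per-sample biological noise SD 0.3 and
  per-channel technical noise SD 0.15 (log2) — typical replicate scatter
  for spotted oligoarrays.
* **Rendering.** Sample on Cy5 against a common pooled reference on Cy3
  (the design is configurable; no dye swaps are assumed), smooth
  intensity-dependent Cy5 bias of amplitude 0.4·sin(A·π/4) log2 units,
  additive local background N(80, 20) truncated at 0 in both channels,
  with an independent draw recorded as the local background estimate.
* **Planted truth.** A configurable DE fraction with effects drawn from
  a pool of absolute log2 effect sizes; a concordance plan first plants
  coding+ncRNA pairs at shared loci (e.g. 7 down-down, 5 up-up,
  1 discordant). Planted effects are restricted to probes with baseline
  log2 ≥ 9: spike-ins must be quantifiable in both groups — planting a
  4-fold drop on a probe at the detection floor measures the expressed
  filter, not the statistic.
* **qPCR.** CT = intercept − log2 abundance + replicate jitter; the
  reference gene is never regulated. With zero jitter, 2^−ΔΔCT inverts
  exactly to the planted fold change — the generator and the analysis
  are inverse maps, which is the strongest cheap correctness check.

What the generator does **not** emulate: spatial artifacts, print-tip
effects, probe-sequence affinity differences, scanner saturation, and
correlated biological covariance across probes (noise is independent per
probe). Passing tests therefore demonstrate the statistics and plumbing
under the stated noise model, not robustness to structured artifacts in
real scans.

# Numerical and design choices

* Exhaustive permutation mode makes small-design results independent of
  the seed; sampled mode is seeded and reproducible.
* The delta grid (200 points) trades q-value resolution against runtime;
  q equals the grid minimum, so refining the grid can only lower q
  marginally.
* FDR uses median false counts and π0 = 1 (canonical); both the
  90th-percentile variant and a fixed s0 are config switches, because the
  original analyses of this kind rarely state which variant their SAM
  release used.
* Quantile-normalization ties take the mean of the tied target
  quantiles — stable and order-independent.
* Degenerate inputs fail loudly: negative intensities, single-sample
  normalization, groups below two members, constant columns in
  correlation clustering, empty post-filter matrices.
* Whether published per-probe q-values come from the full-data run or
  the worst leave-one-out run is generally unstated; the consensus
  result carries both (`q_value` from the full run, `worst_q` across
  runs).
* Counting is per probe, not per gene symbol: real designs carry several
  probes per locus, and collapsing them would discard the
  sense/antisense distinctions the platform exists to measure.

## Problem sizes used in the test suite

Unit tests run on instances up to a few hundred probes; the brute-force
oracle checks use ≤ 12 probes × ≤ 8 samples where all 70 label
assignments can be enumerated independently. End-to-end recovery checks
use ~10,000-probe simulations (the platform's scale) at 4v4 with 2% DE
at 4-fold, replicated over 20 seeds — small enough to run routinely,
large enough that q-value granularity matches production behaviour.

# Known limitations

* The expressed call assumes exported background summaries; platforms
  reporting pixel-level p-values can emulate them via `background_k`.
* π0 = 1 makes FDR conservative when many probes are truly changed.
* The rank-sum homogeneity comparison treats dependent correlations as
  independent observations; treat its p-value as descriptive.
* GEO validation mode bypasses preprocessing and trusts the deposited
  matrix; expressed flags in deposited data are approximated by
  missingness.
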