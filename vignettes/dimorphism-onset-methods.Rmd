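---
title: "Calling the onset of sexually dimorphic expression with a left-to-right HMM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling the onset of sexually dimorphic expression with a left-to-right HMM}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cascadeHMM)
```

## The problem

During mammalian sex determination the bipotential gonad commits to a
testicular or ovarian fate within roughly one day of development, and the
transcriptome reorganizes through ordered cascades of gene activation and
repression. Given expression profiles of XX and XY gonads sampled at a few
closely spaced developmental stages in two inbred strains, we want to decide,
per gene and strain, *whether* expression becomes sexually dimorphic,
*in which sex* it is higher, and — the interesting part — *when* dimorphism
starts. Per-stage tests alone are noisy: with three replicates per
sex/strain/stage cell, a single borderline stage can flip a call. The model
below borrows strength across adjacent stages instead.

## The model

Each gene × strain series is reduced to a sequence of $T$ symbols (default
$T = 6$ stages). At stage $t$ the **fold difference** is

$$\mathrm{FD}_t = \overline{\log_2 x}_{XY,t} - \overline{\log_2 x}_{XX,t},$$

tested with a pooled-variance two-sample t-test. The FD is **gated** to 0
when $p \ge 0.05$ or $|\mathrm{FD}_t| \le 0.3219$, then **quantized**:

| symbol | interval | meaning |
|---|---|---|
| `s`  | $|\mathrm{FD}| < 0.3219$ | similar expression |
| `m1` | $[0.3219, 0.585)$ | weak XY enrichment |
| `m2` | $[0.585, 1)$ | moderate XY enrichment |
| `m3` | $[1, \infty)$ | strong XY enrichment |
| `f1`–`f3` | mirrored negative bins | XX enrichment |

The edges are the $\log_2$ of 1.25-, 1.5- and 2-fold changes. Values exactly
on an edge fall in the larger-magnitude bin (a probability-zero event on real
data; fixed for reproducibility).

The sequences are modelled by a **left-to-right hidden Markov model** with
three states per stage — male-enriched ($M$), similar ($S$), female-enriched
($F$); $3T = 18$ states for $T = 6$ — and transitions only between adjacent
stages, so every admissible path visits exactly one state per stage and the
path space has size $3^T = 729$. The emission distribution over the seven
symbols is **tied across stages** (one $3 \times 7$ matrix), while each stage
step keeps its own $3 \times 3$ transition matrix, letting transition
pressure vary along the time course (cascades accelerate late) without
inflating the emission parameter count.

Initialization maps each symbol to its state class (`m*` → $M$, `s` → $S$,
`f*` → $F$), counts stage-1 classes and adjacent-stage class transitions,
adds a pseudocount of 1 to every admissible transition, and row-normalizes;
emissions start from a hand-chosen matrix in which each state gives 0.85 of
its mass to its own symbol class (within a class split 0.3/0.3/0.25 toward
the weaker grades) and the remainder uniformly to the other symbols, so all
probabilities are strictly positive. The exact numbers are a declared,
configurable convention (`emission_init()`); what matters is that each state
"means" its symbol class at the start, and training preserves that meaning.

Training is Baum-Welch for a fixed 200 iterations, pooling sequences from
both strains into one model; decoding is per gene per strain by Viterbi.
All lattice computations run in log space with log-sum-exp; Viterbi ties
break deterministically by the state order $M < S < F$. An exhaustive
enumeration decoder (`enumerate_paths_decode()`) evaluates all $3^T$ paths
and serves as an independent oracle for the Viterbi implementation in the
tests; the sum of its path probabilities must equal the forward likelihood,
which is checked to $10^{-10}$ relative error.

Decoded paths are written over $\{0, M, F\}$ (0 = similar): `0MMMMM` is a
gene that becomes male-enriched at stage 2 and stays so. Genes sharing a
path are clustered; enrichment calls require **strict persistence** (the
path stays in one dimorphic state through the final stage). Paths that
relapse to 0 are flagged rather than called — on the study's own data almost
all dimorphic genes persist, so this choice is nearly free, and it keeps
"onset" interpretable. Paths containing both $M$ and $F$ are reported as
`switch`. Onsets at stage 1 are flagged left-censored: dimorphism may
predate the sampled window.

## Upstream screen

Before the HMM, probes pass a funnel mirroring standard array practice:
quantile normalization (`limma::normalizeQuantiles`, ties averaged); a
detection filter (detection $p < 0.005$ in at least two replicates of some
sex × strain × stage cell); and a per-probe factorial OLS ANOVA with sex,
strain, categorical stage, all two-way interactions and the three-way
interaction, each term tested by a partial F-test under sum-to-zero
contrasts, BH-adjusted per term across probes. A probe passes when any
adjusted term p-value is below 0.05. We deliberately use plain OLS rather
than empirical-Bayes-moderated statistics: with at least three replicates
per cell the screen is only a gate, OLS keeps the package self-contained
and its null behaviour exactly characterizable (the suite verifies type-I
control on null simulations). Moderated tests would be slightly more
powerful at this sample size; the deviation is acknowledged here once.

## Downstream analytics

* **Mechanism**: for each enriched gene, expression changes from the stage
  before onset to the final stage are tested per sex (pooled t-test). A
  male-enriched gene rising by more than 0.32 log2 units ($p<0.05$) in XY is
  *activated in XY*; one falling below $-0.32$ in XX is *repressed in XX*;
  both is a *combination*; female-enriched genes mirror this.
* **Strain comparison**: onset stages of one class are cross-tabulated
  between strains over the union of called probes; each cell gets a
  one-sided hypergeometric over-representation p-value (flagged at
  $p<0.001$), and the modal onset offset summarizes the strain delay. The
  choice of universe (probes called in either strain) is a convention —
  the natural alternatives (all screened probes; probes called in both)
  change the p-values but not the modal offset, which is the quantity of
  interest.
* **Scatter classification**: first-vs-last-stage log2 changes per sex at a
  1.5-fold threshold assign genes to similarly-up/down, enrichment via
  activation, via repression, via both, or unchanged.
* **Robustness**: among genes with the same onset in both strains, an exact
  one-sided binomial test asks whether strain A's onset-stage |FD| exceeds
  strain B's more than half the time.
* **Candidate ranking**: genes in an eQTL interval are hard-gated on being
  expressed in XY gonads by mid-window, then tiered lexicographically on
  pathway-consistent dimorphism, expected-direction strain dimorphism, and
  variation within 10 kb of the TSS; a knocked-out
  abnormal-sex-determination phenotype promotes to tier 1 outright.
  Ties break alphabetically, making the ranking a deterministic total
  order. The tier rule is one explicit convention chosen from a
  qualitatively described funnel; the weights are configurable inputs, not
  fitted quantities.

## The synthetic-data generator

`simulate_timecourse()` emulates the study design: 2 strains × 2 sexes × 6
stages × 3 replicates (72 arrays), ~2,000 genes at desk scale, 20%
unexpressed background, 30% of expressed genes planted dimorphic, equal male/
female split, onset weights (0.05, 0.10, 0.20, 0.30, 0.35) over stages 2–6
(cascades grow over time), mechanism mix 0.7 activation / 0.2 repression /
0.1 both, planted |FD| of 1.0 log2 units, per-cell Gaussian noise with sd
0.25, and a 1-stage onset delay in strain B (genes delayed past the window
are simply not dimorphic in B). Baselines are uniform on 6–12 log2 units —
irrelevant to contrasts, realistic in range. Detection p-values are emitted
directly (≈0 for expressed, ≥0.5 for background genes) rather than modelled
from bead-level controls, since the pipeline only consumes the p-values.

Two generator choices deserve a note:

* **Ramp anchoring.** The planted fold difference rises linearly over
  `ramp_intervals` stages and plateaus; the default is 1, i.e. the full
  effect is present *at* the onset stage. A gentler ramp that reaches the
  full effect only a stage later would put half the effect at the nominal
  onset, and a power calculation at the study conditions (sd 0.25, n = 3)
  shows a 0.5-log2 difference survives the significance-and-magnitude gate
  only ~45% of the time — the truth table's "onset" would then not be the
  first *detectable* stage, making the generator internally inconsistent
  with its own labels. Setting `ramp_intervals = 2` restores the gentler
  shape for users who want it.
* **No re-normalization.** The generator's output emulates data *after*
  quantile normalization and log transformation; it contains no array-level
  technical effects. Re-running quantile normalization on it would equalize
  sample distributions that differ only by planted biology and thereby
  shrink real signal, so simulated runs are analysed with
  `normalize = FALSE`. On real arrays, normalization removes technical
  variation that dominates this effect and is the right first step.

What passing tests on this generator do **not** show: robustness to batch
and chip effects, probe cross-hybridization, cell-type composition shifts,
heteroskedastic noise, or correlated genes — none of which are simulated.
The generator validates the *inference machinery* (gating, quantization,
decoding, onset and mechanism recovery), not array preprocessing.

## Numerical choices and problem sizes

Fixed 200 EM iterations (no early stopping) keep runs reproducible; an
optional `tol` enables convergence stopping. The EM trace is checked
non-decreasing to $10^{-8}$. Degenerate inputs: constant probes get p = 1
for every screen term; zero-variance t-test cells give p = 1 when means are
equal, p = 0 otherwise; unreachable HMM states keep their previous
parameters during re-estimation rather than dividing by zero. Identical
sequences are collapsed to weighted unique rows inside Baum-Welch, which is
what makes full-scale training fast (a 2,000-gene run trains in seconds).
The test suite uses 2,000-gene simulations for the recovery checks, 500
sampled sequences for emission recovery and 200 random model/sequence pairs
for the decoding oracle; these sizes give sub-percent Monte-Carlo error on
the checked quantities while keeping the default test run under a minute.

## Known limitations

Per-stage contrasts use unmoderated pooled-variance t-tests; near the
gating threshold this can differ from moderated pipelines, shifting
borderline onsets by one stage. Onset resolution equals the sampling
interval: a sub-interval strain delay appears either as a one-stage offset
or as a fold-difference deficit at equal onset (which the binomial
robustness test is designed to catch). The candidate filter consumes
annotation flags as input; it does not query variant or phenotype
databases.
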