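---
title: "Identifying stable reference microRNAs in RT-qPCR panel data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying stable reference microRNAs in RT-qPCR panel data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirnorm)
```

## Why reference selection is a modelling problem

RT-qPCR reports every target relative to a reference, so the reference's own
biology enters every result. In dystrophin-deficient (DE50-MD) canine
skeletal muscle the textbook reference snRNA U6 is itself shifted by
genotype and declines with age; normalising to it manufactures spurious
target "effects" and masks real ones. `mirnorm` treats reference selection
as an estimation problem over a panel of candidates: score each candidate's
stability three independent ways, shortlist candidates that every method
ranks highly, combine the best few into a geometric-mean normalisation
factor, and validate the factor by showing that held-out candidates
normalised with it carry no residual structure.

This vignette documents the models, the defaults, the simulation design the
test suite relies on, and the numerical choices — the things a maintainer
would otherwise have to reverse-engineer from the code.

## The data model

A `cq_table` stores replicate-level quantification cycles keyed by
assay × sample × plate × replicate. Undetected wells (no amplification by
the run's ceiling) are a first-class flag (`NA`), never a sentinel like
Cq 40: the low-expression filter must distinguish "high Cq but detected"
from "undetectable", and a sentinel would silently conflate them. Companion
`sample_meta` rows carry dog, genotype (WT / DE50MD), muscle (VL, CRT, SEM,
TRI, DIA) and age (3–18 months); by design the four non-VL muscles exist
only as 18-month post-mortem samples (relax with `strict = FALSE`).

Relative quantities are `RQ(i, s) = E_i^(minCq_i − Cq(i, s))`, anchored so
every assay's most abundant sample has RQ 1. Efficiency defaults to 2.0
(perfect doubling) for every assay — panel efficiencies are rarely reported
and never were for this design — with per-assay overrides accepted. At
`E = 2`, `log2 RQ = minCq − Cq` exactly, which the tests use as an identity.

## Preprocessing

**Interplate calibration** comes in the two dialects panel workflows use.
The screening dialect uses a dedicated interplate calibrator reaction (IPC,
a fixed DNA template) on every plate: a plate's offset is its mean IPC Cq
minus the mean of the per-plate IPC means. Anchoring to the pooled mean
rather than a designated plate keeps the operation symmetric and
order-independent; offsets then sum to zero and recalibrating a calibrated
table is the identity. The individual-assay dialect re-measures a few
shared assays on one dedicated calibration plate and uses the mean paired
Cq difference per plate as the offset; here the natural anchor is the
calibration plate itself, so that dialect is anchored there instead.

**Replicate aggregation** averages numeric wells; a pair that disagrees by
more than 1 cycle is flagged (message + `qc_flags` attribute) but kept —
no replicate-agreement exclusion rule is applied, because none is part of
the workflow being modelled.

**Low-expression filtering** drops an assay only when *every* detected Cq
exceeds 32 *and* at least one sample is undetected. Both conditions matter:
high-but-consistent assays are quantifiable, and isolated dropout with low
Cq elsewhere indicates a technical failure, not absence.

**Missing-value policy** differs by role. Reference candidates must be
complete after filtering, so stability scoring uses `missing_policy =
"error"`; targets may genuinely drop out in some samples, so target
normalisation imputes undetected entries at the limit-of-detection Cq
(default 35) and logs it. Imputing a reference would quietly stabilise it,
which is exactly the artefact the workflow exists to avoid.

## The three stability scores

**geNorm.** Pairwise variation `V(j, k) = sd(log2(RQ_j / RQ_k))` (n−1
denominator, log base 2 — base only rescales all M equally), `M_j` the mean
over partners, iterative removal of the argmax-M candidate until the best
pair remains. Ties at removal break lexicographically so output is
deterministic; the final pair is reported at ranks 1–2 in lexicographic
order because the 2-panel M values are equal by construction. Scores are
each candidate's M *at its removal step*, matching the iterative definition
(reporting full-panel M instead would change scores but not the order of
removal). `V(n/n+1)` between successive geometric-mean factors of the top-n
candidates supports choosing the reference count.

**BestKeeper.** Runs on calibrated, aggregated *raw Cq*, never RQ. The
index is the per-sample geometric mean of candidate Cq; candidates are
ranked by descending Pearson r against it (ties: ascending SD, then id);
SD and CV% are reported alongside. Following the classic tool the index
includes the candidate itself, which flatters high-variance candidates (a
candidate's own variance contributes ~1/k of its covariance with the
index); `leave_one_out = TRUE` removes that bias and is the better choice
for small panels, but the self-inclusive form is the default because it is
the behaviour of the tool being modelled. A zero-variance candidate has no
defined r and is ranked after all defined ones, with a warning.

**NormFinder.** On log2 RQ, the additive model `y_is = α_i + β_s + ε_is`
with candidate-specific `var(ε_is) = σ_i²`. Naive per-candidate residual
variances `s_i²` from the two-way fit mix every candidate's noise, so they
are deconvolved through
`E[s_i²] = ((k−1)/k)² σ_i² + (1/k²) Σ_{i'≠i} σ_{i'}²`, which inverts in
closed form to `σ̂_i² = (k/(k−2)) (s_i² − S/(k(k−1)))`, `S = Σ s_i²`. The
closed form equals a brute-force solve of the k×k moment system (tested to
1e-9) and is undefined for k < 3, hence the panel-size precondition.
Negative estimates are floored at 0 before the square root and each
flooring is logged. The grouped variant estimates `σ̂²_ig` within each
group, centred intergroup differences
`d_ig = (ȳ_ig − ȳ_i·) − (ȳ_·g − ȳ_··)` (summing to zero over candidates in
each group), shrinks them by the empirical-Bayes factor
`γ̂²/(γ̂² + σ̂²_ig/n_g)` with
`γ̂² = max(0, mean(d²) − mean(σ̂²_ig/n_g))`, and scores
`(1/G) Σ_g (|d̃_ig| + sqrt(σ̂²_ig/n_g))`. The exact degrees-of-freedom
constants are fixed as written above and validated by parameter-recovery
simulation (injected σ² = 0.25 recovered with < 10% relative bias over 500
replicates), since the published description of the method names it without
formulas. Stability is reported in log2 units; published tables for this
workflow are therefore reproducible at rank level, not score level.

## Subsets, consensus and validation

Stability is scored on nine metadata-derived subsets — all samples, each
genotype, VL-only (overall and per genotype), and all 18-month samples
(overall and per genotype). Cardinalities are always computed from the
metadata predicates, never hard-coded; on the study design they realise
94 / 47 / 47 / 70 / 35 / 35 / 35 / 17 / 18. The "18-month" predicate is
`age == 18`, which includes the last longitudinal VL biopsies alongside the
post-mortem muscles; this is the reading consistent with the realised
group sizes (17 WT + 18 DE50-MD).

The consensus shortlist intersects each algorithm's top-k set (default
k = 11, the threshold used at the screening stage of this design) and
orders all candidates by mean rank. The top four become NF4, the per-sample
geometric mean of their RQs. Validation is deliberately within-dataset:
normalise a *held-out* weak candidate by NF4 and test for genotype
structure overall and per muscle × age stratum (Welch tests, Holm–Šídák).
A genuine reference factor leaves a stable held-out candidate flat (fold
change ≈ 1, nothing significant) while still exposing the injected
genotype/age structure of a U6-like candidate. `validate_reference` refuses
candidates that are part of the factor, since self-validation is circular.

Group comparisons use Welch's t on log2 values; fold changes are ratios of
geometric means (equivalently `2^Δmean(log2)`), reported in both
directions. The Holm–Šídák step-down is
`p_adj(i) = max_{j≤i} (1 − (1 − p(j))^(m−j+1))`, computed via
`expm1`/`log1p` so very small p-values do not underflow. Mixed-effects
modelling of the repeated-measures structure is intentionally out of scope;
per-stratum Welch tests are the supported inference, and the simulator's
shared dog effects exist precisely so that tests remain honest about that
correlation.

## The simulator and what passing tests mean

`simulate_study()` draws
`Cq = baseline − (genotype + age + muscle + candidate noise) − dog effect +
plate offset + well noise`, with all biological effects in log2 abundance
(1 log2 unit = 1 cycle at E = 2), wells above the detection ceiling
(default Cq 35) reported undetected, and everything deterministic under a
seed. Dog effects are shared across all of a dog's samples and all assays,
emulating repeated-measures correlation and sample-level input variation —
this is the component normalisation must remove, and the invariance tests
exploit it. Defaults: well noise 0.15 cycles (typical duplicate agreement),
plate offsets SD 0.5 cycles, dog effects SD 0.8 cycles. The between-dog and
between-plate components are plausible placeholders (no published variance
components exist for this design) and are labelled as such in `truth.json`.

The `panel9` preset reproduces the validation-stage design: 6 dogs per
genotype sampled in VL at 3–18 months, 3 per genotype post mortem in four
further muscles at 18 months, one DE50-MD 15-month and one WT 18-month VL
sample withheld (70 + 24 = 94 samples), and one post-mortem dog shared with
the longitudinal cohort to realise the study's 17 animals. Its ground
truth designates miR-191, let-7b, miR-125a and miR-15a stable (the latter
two carry the ±1.1-fold genotype shifts reported for their real
counterparts), gives snRNA-U6 a 1.8-fold genotype up-shift, an age decline
and large candidate noise, gives miR-29b an age trend with elevated noise,
and injects target effects of 3-fold down (miR-1-like), 2-fold down
(miR-133a-like), none (miR-206-like) and 2-fold up in VL / 4-fold up in
post-mortem muscles (miR-214-like fibromiR). The `screen87` preset
reproduces the screening stage (87 assays, 8 six-month VL samples, single
wells, two plates): 14 assays sit above the detection ceiling and must be
recovered exactly by the filter; the non-reference fillers are given the
larger biological spreads (0.5–1.0 log2) and occasional genotype shifts
expected of disease-responsive miRs, which is also what makes the designed
references separable with only eight samples. `null_panel` has nine
exchangeable candidates for type-I-error-style checks.

What passing tests show — and what they do not. The acceptance suite shows
that with 94 samples the workflow recovers a designed-stable quartet into
the top-4 consensus and pins the destabilised candidate at rank 9/9 for all
three algorithms in ≥95% of seeds, that the filter recovers the designed
absent set exactly, and that injected fold changes survive NF4
normalisation to within ±20%. It does not show robustness to features the
simulator omits: non-monotone age trajectories (the miR-29b-like candidate
gets a linear trend only), efficiency heterogeneity across assays,
correlated candidate noise (co-regulated miR families), or structured
dropout beyond a hard detection ceiling. With only 8 screening samples,
per-candidate variance estimates have ~50% sampling CV, so screening-stage
top-11 membership is expected to be *typical*, not certain — the same
caveat the original two-tier design handles by re-validating candidates on
the full sample set.

## Numerical and degenerate-input choices

- Ranks are always a permutation of 1..k; all tie-breaks are lexicographic
  on candidate id so every output is deterministic.
- geNorm on a panel of mutually proportional candidates has all M = 0 and
  degenerates to tie-break order; NormFinder floors negative variance
  estimates at 0; BestKeeper reports `r = NA` for zero-variance candidates.
- Shrinkage with both `γ̂² = 0` and zero within-group noise is defined as 0.
- The pipeline re-reads its own calibrated CSV before downstream stages so
  fresh and resumed runs operate on identical (formatted) numbers and
  produce bit-identical outputs under one seed.
- Problem sizes in the test suite: 100 random panels (k ≤ 6, n ≤ 12) per
  oracle check, 100 simulation seeds for recovery rates, 20 for the filter
  sweep, 200–500 replicates for bias checks.

## Known limitations

Vendor instrument exports and melt curves are not parsed (long/wide CSV
only); standard-curve efficiency estimation is not provided; linear mixed
models are delegated to dedicated tools; and agreement with the original
GUI/spreadsheet implementations of the three algorithms is at the level of
their published definitions, not bit-for-bit output.
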