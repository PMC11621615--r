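# mirnorm

Reference microRNA stability and normalisation for RT-qPCR panels.

## The problem

Relative quantification of microRNAs by RT-qPCR stands or falls with the
choice of reference RNAs: every target is reported relative to something, and
if that something drifts with disease state, muscle, or age, the "fold
changes" are artefacts. This is acute in dystrophic skeletal muscle, where
the commonly used reference snRNA U6 is itself dysregulated. `mirnorm`
implements the full reference-identification workflow for panel Cq data —
from raw quantification cycles to validated normalisation factors — for
studies comparing wild-type (WT) and dystrophin-deficient (DE50-MD) dogs
across five muscles and six ages, and for any design with the same shape.

It is aimed at researchers running LNA/SYBR miR panels who want a scripted,
testable alternative to the usual mix of vendor software and spreadsheets.

## What it computes

Let `Cq(i, s)` be the quantification cycle of assay `i` in sample `s` after
interplate calibration and replicate averaging, and
`RQ(i, s) = E^(minCq(i) − Cq(i, s))` the relative quantity at amplification
efficiency `E` (default 2). Three complementary stability scores are
computed per candidate reference:

- **geNorm M**: the mean over partners `k` of `sd(log2(RQ_i / RQ_k))`;
  candidates are discarded iteratively from the highest M until the best
  pair remains. `V(n/n+1)` diagnostics indicate how many references suffice.
- **BestKeeper**: per-sample geometric mean of candidate Cq values (the
  index) and each candidate's Pearson `r` against it; high `r` = stable.
- **NormFinder**: a model-based decomposition `y_is = α_i + β_s + ε_is` on
  log RQ whose candidate variances `σ_i²` are deconvolved from the two-way
  residuals in closed form; the grouped variant adds shrunken intergroup
  differences `d̃_ig` so a candidate that is quiet within groups but biased
  between genotypes is still penalised.

Candidates ranked in the top *k* by all three algorithms form the consensus
shortlist; the per-sample geometric mean RQ of the four best (**NF4**)
normalises the targets, and genotype effects are tested with Welch t-tests
under Holm–Šídák correction.

A synthetic-data module generates Cq datasets with the full study structure
(dog effects, plate offsets, detection dropout, candidate-specific genotype,
age and muscle effects) and known ground truth, so every stage of the
pipeline is testable without any download.

## Worked example

```r
library(mirnorm)

sim <- simulate_study(preset_scenarios("panel9", seed = 3))
cal <- calibrate_ipc(sim$cq, "UniSp3-IPC")$cq
agg <- aggregate_replicates(cal)
cand <- agg[agg$assay_id %in% setdiff(unique(agg$assay_id),
                                      c(sim$truth$targets, "UniSp3-IPC")), ]
rq <- cq_to_rq(cand)

g  <- genorm_rank(rq)$table
b  <- bestkeeper_stats(cand)$table
nf <- normfinder_ungrouped(log_rq(rq))$table
topk_intersection(list(g, b, nf), k = 11)
#> <consensus_shortlist> k = 11; 9 candidate(s) in all top-k sets:
#>   let-7b, miR-191, miR-125a, miR-15a, miR-27b, miR-106b, miR-130a, miR-29b, snRNA-U6

rq_all <- cq_to_rq(agg, missing_policy = "impute_lod")
nf4 <- compute_nf(rq_all, c("let-7b", "miR-191", "miR-125a", "miR-15a"))
compare_groups(normalize_target(rq_all, "miR-1", nf4), sim$meta)
#>   stratum n_wt n_de  log2_fc fc_wt_vs_de fc_de_vs_wt        t       df        p_raw        p_adj
#> 1 overall   47   47 1.551591    2.931401   0.3411338 20.06996 91.77408 2.488307e-35 2.488307e-35
```

The shortlist orders all nine candidates by mean rank across the three
algorithms; with this seed the four designed-stable references head it and
the destabilised snRNA-U6 is last. The final line reads: after NF4
normalisation, the miR-1-like target is ~2.9-fold lower in DE50-MD than WT
muscle (true simulated effect: 3-fold).

The same analysis, staged with narrative output and CSV tables under
`results/`, is in `analysis/01_simulate.R` … `analysis/05_normalise_targets.R`;
`analysis/06_benchmark.R` runs the pipeline on a user-supplied export of the
deposited study dataset. `run_pipeline()` executes all stages in one call
from a YAML or list config.

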