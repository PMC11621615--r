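#!/usr/bin/env Rscript
# Optional stage 6: rank-level reproduction on the deposited dataset.
# The deposited Cq workbook is not redistributed here; export it to
# long-format CSVs (columns assay_id,sample_id,plate_id,replicate,cq and
# sample_id,dog_id,genotype,muscle,age_months) and pass their paths:
#   Rscript analysis/06_benchmark.R <cq_long.csv> <meta.csv>
# Expected rank-level agreement on the full dataset: geNorm final pair
# {miR-125a, let-7b}; BestKeeper top = miR-15a; NormFinder top = miR-191.

suppressMessages(library(mirnorm))

args <- commandArgs(trailingOnly = TRUE)
if (length(args) < 2) {
  cat("usage: Rscript analysis/06_benchmark.R <cq_long.csv> <meta.csv>\n")
  cat("deposited data not supplied; nothing to do.\n")
  quit(status = 0)
}

manifest <- run_benchmark(args[1], args[2], "results/benchmark")
report <- read_stability_report("results/benchmark/stability_report.csv")
for (alg in c("genorm", "bestkeeper", "normfinder")) {
  t <- report[report$algorithm == alg & report$subset_label == "All", ]
  cat(sprintf("%-10s top: %s | last: %s\n", alg,
              paste(t$candidate_id[t$rank <= 2], collapse = ", "),
              t$candidate_id[t$rank == max(t$rank)]))
}
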