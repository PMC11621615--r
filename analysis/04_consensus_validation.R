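#!/usr/bin/env Rscript
# Stage 4: consensus shortlist across the three algorithms on the full
# dataset, NF4 construction from the top four, and within-dataset validation:
# normalise the weak candidates (miR-29b, snRNA-U6) by NF4 and test for
# residual genotype structure.

suppressMessages(library(mirnorm))

dir <- "results/panel9"
agg <- read_cq_table(file.path(dir, "calibrated_cq.csv"))
meta <- read_sample_meta(file.path(dir, "meta.csv"))
truth <- jsonlite::read_json(file.path(dir, "truth.json"), simplifyVector = TRUE)
candidates <- setdiff(unique(agg$assay_id), truth$targets)

report <- read_stability_report(file.path(dir, "stability_report.csv"))
all_tables <- lapply(c("genorm", "bestkeeper", "normfinder"), function(alg) {
  t <- report[report$algorithm == alg & report$subset_label == "All", ]
  class(t) <- c("stability_table", "data.frame")
  t
})
cons <- topk_intersection(all_tables, k = 11)
utils::write.csv(cons$consensus_rank, file.path(dir, "consensus.csv"), row.names = FALSE)
refs <- head(cons$consensus_rank$candidate_id, 4)
cat("consensus top 4 (entering NF4):", paste(refs, collapse = ", "), "\n")
cat("designed stable:", paste(truth$designed_stable, collapse = ", "), "\n")

rq <- suppressMessages(cq_to_rq(agg, missing_policy = "impute_lod"))
nf4 <- compute_nf(rq, refs)
utils::write.csv(data.frame(sample_id = names(nf4$nf), nf = unname(nf4$nf)),
                 file.path(dir, "nf4.csv"), row.names = FALSE)

for (weak in setdiff(candidates, refs)[setdiff(candidates, refs) %in%
                                       c("miR-29b", "snRNA-U6")]) {
  val <- suppressWarnings(validate_reference(weak, rq, nf4, meta))
  cat(sprintf("%s / NF4: overall DE50MD:WT fold change %.2f (Welch p = %.3g)\n",
              weak, val$overall$fc_de_vs_wt, val$overall$p_raw))
  utils::write.csv(val$by_stratum,
                   file.path(dir, sprintf("validation_%s.csv", gsub("[^A-Za-z0-9-]", "_", weak))),
                   row.names = FALSE)
}
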