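#!/usr/bin/env Rscript
# Stage 3: score the 9 reference candidates with geNorm, BestKeeper and
# NormFinder on each of the nine study subsets, plus grouped NormFinder on
# the full dataset (animal / genotype / muscle / age groupings).

suppressMessages(library(mirnorm))

dir <- "results/panel9"
agg <- read_cq_table(file.path(dir, "calibrated_cq.csv"))
meta <- read_sample_meta(file.path(dir, "meta.csv"))
truth <- jsonlite::read_json(file.path(dir, "truth.json"), simplifyVector = TRUE)
candidates <- setdiff(unique(agg$assay_id), truth$targets)

tables <- list()
for (ss in subset_datasets(meta)) {
  cq_sub <- agg[agg$sample_id %in% ss$sample_ids & agg$assay_id %in% candidates, ]
  rq <- cq_to_rq(cq_sub)
  tables[[paste0("g.", ss$label)]] <- genorm_rank(rq, ss$label)$table
  tables[[paste0("b.", ss$label)]] <-
    suppressWarnings(bestkeeper_stats(cq_sub, candidates, subset_label = ss$label)$table)
  tables[[paste0("n.", ss$label)]] <-
    suppressMessages(normfinder_ungrouped(log_rq(rq), ss$label)$table)
}
write_stability_report(tables, file.path(dir, "stability_report.csv"))

cq_all <- agg[agg$assay_id %in% candidates, ]
rq_all <- cq_to_rq(cq_all)
grouped <- lapply(names(grouping_schemes(meta)), function(gname) {
  suppressMessages(normfinder_grouped(log_rq(rq_all), grouping_schemes(meta)[[gname]],
                                      subset_label = paste0("All|", gname))$table)
})
write_stability_report(grouped, file.path(dir, "stability_grouped.csv"))

top1 <- vapply(tables[paste0(c("g", "b", "n"), ".All")],
               function(t) t$candidate_id[t$rank == 1], character(1))
last <- vapply(tables[paste0(c("g", "b", "n"), ".All")],
               function(t) t$candidate_id[t$rank == max(t$rank)], character(1))
cat(sprintf("%d stability tables written (%d subset x algorithm + %d grouped)\n",
            length(tables) + length(grouped), length(tables), length(grouped)))
cat("most stable on All (geNorm, BestKeeper, NormFinder):",
    paste(top1, collapse = ", "), "\n")
cat("least stable on All:", paste(unique(last), collapse = ", "), "\n")
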