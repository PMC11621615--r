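#!/usr/bin/env Rscript
# Stage 5: quantify the muscle-enriched dystromiRs (miR-1, miR-133a, miR-206)
# and the fibrosis-associated miR-214 against NF4, with Welch tests and
# Holm-Sidak correction, overall and per muscle.

suppressMessages(library(mirnorm))

dir <- "results/panel9"
agg <- read_cq_table(file.path(dir, "calibrated_cq.csv"))
meta <- read_sample_meta(file.path(dir, "meta.csv"))
truth <- jsonlite::read_json(file.path(dir, "truth.json"), simplifyVector = TRUE)
refs <- head(utils::read.csv(file.path(dir, "consensus.csv"))$candidate_id, 4)

rq <- suppressMessages(cq_to_rq(agg, missing_policy = "impute_lod"))
nf4 <- compute_nf(rq, refs)

rows <- list()
for (tg in truth$targets) {
  norm <- normalize_target(rq, tg, nf4)
  overall <- compare_groups(norm, meta)
  by_muscle <- suppressWarnings(compare_groups(norm, meta, strata = "muscle"))
  overall$scope <- "overall"; by_muscle$scope <- "by_muscle"
  cmp <- rbind(overall, by_muscle)
  cmp$target <- tg
  rows[[tg]] <- cmp
  dir_word <- if (overall$log2_fc > 0) "lower" else "higher"
  cat(sprintf("%-9s/NF4: %.2f-fold %s in DE50-MD (adj. p = %.3g)\n",
              tg, max(overall$fc_wt_vs_de, overall$fc_de_vs_wt), dir_word,
              overall$p_adj))
}
out <- do.call(rbind, rows)
out$p_adj <- holm_sidak(out$p_raw) # re-adjust jointly across targets and strata
utils::write.csv(out, file.path(dir, "target_comparisons.csv"), row.names = FALSE)
cat("wrote", file.path(dir, "target_comparisons.csv"), "\n")
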