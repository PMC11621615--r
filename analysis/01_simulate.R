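#!/usr/bin/env Rscript
# Stage 1: generate the two synthetic datasets that mirror the study design.
#  - screen87: 87-assay screening panel on 8 six-month VL samples (single wells)
#  - panel9:   9 reference candidates + 4 targets on all 94 samples (duplicates)
# Ground truth (designed-stable set, designed-absent set, injected effects)
# is written alongside each dataset.

suppressMessages(library(mirnorm))

seed <- 20260901
dir.create("results", showWarnings = FALSE)

for (preset in c("screen87", "panel9")) {
  sim <- simulate_study(preset_scenarios(preset, seed = seed))
  out <- file.path("results", preset)
  write_simulation(sim, out)
  cat(sprintf(
    "%s: %d assays x %d samples (%d records, %d undetected wells) -> %s\n",
    preset, length(unique(sim$cq$assay_id)), nrow(sim$meta), nrow(sim$cq),
    sum(is.na(sim$cq$cq)), out))
  cat("  designed stable:", paste(sim$truth$designed_stable, collapse = ", "), "\n")
  if (length(sim$truth$designed_absent) > 0) {
    cat("  designed absent:", length(sim$truth$designed_absent), "assays\n")
  }
}
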