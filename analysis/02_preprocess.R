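#!/usr/bin/env Rscript
# Stage 2: interplate calibration, replicate aggregation and, for the
# screening panel, the low-expression filter (drop assays with every detected
# Cq > 32 and at least one undetected sample). Expects stage 1 outputs.

suppressMessages(library(mirnorm))

for (preset in c("screen87", "panel9")) {
  dir <- file.path("results", preset)
  cq <- read_cq_table(file.path(dir, "cq.csv"))
  cal <- calibrate_ipc(cq, "UniSp3-IPC")
  cat(sprintf("%s: plate offsets span %.2f cycles (%d plates)\n", preset,
              diff(range(cal$calibration$plate_offsets)),
              length(cal$calibration$plate_offsets)))
  agg <- aggregate_replicates(cal$cq)
  agg <- agg[agg$assay_id != "UniSp3-IPC", ]
  write_cq_table(agg, file.path(dir, "calibrated_cq.csv"))

  if (preset == "screen87") {
    truth <- jsonlite::read_json(file.path(dir, "truth.json"), simplifyVector = TRUE)
    report <- filter_low_expression(agg)
    cat(sprintf("  filter: kept %d, dropped %d (designed absent: %d; exact: %s)\n",
                length(report$kept), nrow(report$dropped),
                length(truth$designed_absent),
                setequal(report$dropped$assay_id, truth$designed_absent)))
    utils::write.csv(report$dropped, file.path(dir, "dropped_assays.csv"),
                     row.names = FALSE)
    writeLines(report$kept, file.path(dir, "kept_assays.txt"))
  }
}
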