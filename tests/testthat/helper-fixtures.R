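# Small in-code fixtures shared across test files.

# long-format cq_table from parallel vectors
make_cq <- function(assay, sample, plate = "P1", replicate = 1L, cq = 25) {
  n <- max(length(assay), length(sample), length(plate), length(replicate), length(cq))
  cq_table(data.frame(
    assay_id = rep_len(assay, n), sample_id = rep_len(sample, n),
    plate_id = rep_len(plate, n), replicate = rep_len(replicate, n),
    cq = rep_len(cq, n), stringsAsFactors = FALSE
  ))
}

# rq_matrix from a plain matrix, naming rows/cols if unnamed
make_rq <- function(m, candidates = NULL, samples = NULL) {
  if (is.null(rownames(m))) rownames(m) <- candidates %||% paste0("g", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- samples %||% paste0("s", seq_len(ncol(m)))
  rq_matrix(m)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

# random positive RQ panel (log-normal) with a fixed RNG state
random_rq <- function(k, n, sd = 0.5) {
  m <- matrix(2^rnorm(k * n, sd = sd), k, n,
              dimnames = list(paste0("g", seq_len(k)), paste0("s", seq_len(n))))
  rq_matrix(m)
}

# minimal valid metadata (VL-only longitudinal block)
make_meta <- function(n_dogs = 2, ages = c(3L, 6L), genotypes = c("WT", "DE50MD")) {
  rows <- expand.grid(dog = seq_len(n_dogs), age = ages, genotype = genotypes,
                      stringsAsFactors = FALSE)
  sample_meta(data.frame(
    sample_id = sprintf("%s%02d_VL_%02dm", rows$genotype, rows$dog, rows$age),
    dog_id = sprintf("%s%02d", rows$genotype, rows$dog),
    genotype = rows$genotype, muscle = "VL", age_months = rows$age,
    stringsAsFactors = FALSE
  ))
}

panel9_candidates <- c("miR-191", "let-7b", "miR-125a", "miR-15a", "miR-27b",
                       "miR-106b", "miR-130a", "miR-29b", "snRNA-U6")
panel9_stable <- c("miR-191", "let-7b", "miR-125a", "miR-15a")

# run panel9 preprocessing up to an aggregated, calibrated table
preprocess_panel9 <- function(seed) {
  sim <- simulate_study(preset_scenarios("panel9", seed = seed))
  cal <- calibrate_ipc(sim$cq, "UniSp3-IPC")$cq
  agg <- suppressMessages(aggregate_replicates(cal))
  list(sim = sim, agg = agg,
       candidates = agg[agg$assay_id %in% panel9_candidates, ])
}
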