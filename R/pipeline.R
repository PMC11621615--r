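#' Run the full reference-identification pipeline
#'
#' Orchestrates simulate (or load) -> calibrate -> aggregate -> filter ->
#' stability (three algorithms across the study subsets, plus grouped
#' NormFinder on the full dataset) -> consensus -> normalisation-factor
#' construction -> target normalisation and genotype comparisons. Each
#' stage's outputs are written before the next starts, so a failed run
#' leaves partial outputs behind for inspection.
#'
#' @param config Either a named list or a path to a YAML file with keys:
#'   `preset` (a [preset_scenarios()] name) or `cq_path` + `meta_path`;
#'   `seed`; `calibration` (`method` = `"ipc"`/`"common_assays"`/`"none"`,
#'   `ipc_assay`); `filter` (`cq_max`, `min_undetected`);
#'   `reference_candidates` and `targets` (assay id vectors; defaulted from
#'   simulation ground truth in preset mode); `k_consensus` (top-k for the
#'   shortlist); `n_references` (references entering the normalisation
#'   factor); `lod_cq`; `efficiency`.
#' @param out_dir Output directory.
#' @param resume Skip stages whose output files already exist, reusing them.
#' @return A `run_manifest` (also written to `manifest.json`): config
#'   snapshot, seed, per-stage timings, output paths with MD5 hashes,
#'   consensus shortlist, selected references and headline fold changes.
#' @export
run_pipeline <- function(config, out_dir, resume = FALSE) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) stop_mirnorm("config file not found: ", config,
                                           class = "mirnorm_io_error")
    config <- yaml::read_yaml(config)
  }
  defaults <- list(seed = 1L,
                   calibration = list(method = "ipc", ipc_assay = NULL),
                   filter = list(cq_max = 32, min_undetected = 1L),
                   k_consensus = 11L, n_references = 4L, lod_cq = 35,
                   efficiency = 2.0, missing_policy = "error")
  config <- utils::modifyList(defaults, config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  timings <- list()
  warnings_log <- character(0)
  note <- function(...) warnings_log <<- c(warnings_log, sprintf(...))
  timed <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- withCallingHandlers(expr, warning = function(w) {
      note("[%s] %s", stage, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
    timings[[stage]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    res
  }
  paths <- list(
    cq = file.path(out_dir, "cq.csv"),
    meta = file.path(out_dir, "meta.csv"),
    truth = file.path(out_dir, "truth.json"),
    calibrated = file.path(out_dir, "calibrated_cq.csv"),
    filter = file.path(out_dir, "filter_report.csv"),
    stability = file.path(out_dir, "stability_report.csv"),
    stability_grouped = file.path(out_dir, "stability_grouped.csv"),
    consensus = file.path(out_dir, "consensus.csv"),
    nf = file.path(out_dir, "normalization_factor.csv"),
    normalized = file.path(out_dir, "normalized_targets.csv"),
    comparisons = file.path(out_dir, "genotype_comparisons.csv"),
    manifest = file.path(out_dir, "manifest.json")
  )

  ## stage 1: acquire data -------------------------------------------------
  truth <- NULL
  acquire <- function() {
    if (!is.null(config$preset)) {
      sim <- simulate_study(preset_scenarios(config$preset, seed = config$seed))
      truth <<- sim$truth
      write_simulation(sim, out_dir)
      list(cq = sim$cq, meta = sim$meta)
    } else {
      if (is.null(config$cq_path) || is.null(config$meta_path)) {
        stop_mirnorm("config needs either 'preset' or 'cq_path' + 'meta_path'",
                     class = "mirnorm_config_error")
      }
      cq <- read_cq_table(config$cq_path)
      meta <- read_sample_meta(config$meta_path)
      missing_meta <- setdiff(unique(cq$sample_id), meta$sample_id)
      ipc <- config$calibration$ipc_assay
      missing_meta <- setdiff(missing_meta, ipc)
      if (length(missing_meta) > 0) {
        stop_mirnorm("Cq samples absent from metadata: ",
                     paste(utils::head(missing_meta, 5), collapse = ", "),
                     class = "mirnorm_validation_error")
      }
      write_cq_table(cq, paths$cq)
      write_sample_meta(meta, paths$meta)
      list(cq = cq, meta = meta)
    }
  }
  data <- timed("acquire", {
    if (resume && file.exists(paths$cq) && file.exists(paths$meta)) {
      if (file.exists(paths$truth)) truth <- jsonlite::read_json(paths$truth, simplifyVector = TRUE)
      list(cq = read_cq_table(paths$cq), meta = read_sample_meta(paths$meta))
    } else acquire()
  })
  cq <- data$cq; meta <- data$meta

  ipc_assay <- config$calibration$ipc_assay %||%
    (if (!is.null(truth)) truth$ipc_assay else NULL)
  reference_candidates <- config$reference_candidates %||% (if (!is.null(truth)) {
    setdiff(unique(cq$assay_id), c(unlist(truth$targets), unlist(truth$ipc_assay)))
  } else setdiff(unique(cq$assay_id), c(config$targets, ipc_assay)))
  targets <- config$targets %||% (if (!is.null(truth)) unlist(truth$targets) else character(0))

  ## stage 2: preprocess ---------------------------------------------------
  preprocessed <- timed("preprocess", {
    if (resume && file.exists(paths$calibrated) && file.exists(paths$filter)) {
      list(cq = read_cq_table(paths$calibrated),
           kept = utils::read.csv(paths$filter, stringsAsFactors = FALSE))
    } else {
      calibrated <- switch(config$calibration$method %||% "ipc",
        none = cq,
        ipc = {
          if (is.null(ipc_assay)) stop_mirnorm("ipc calibration needs calibration$ipc_assay",
                                               class = "mirnorm_config_error")
          calibrate_ipc(cq, ipc_assay)$cq
        },
        common_assays = {
          calib <- read_cq_table(config$calibration$calib_path)
          calibrate_common_assays(cq, calib, config$calibration$shared_assays)$cq
        },
        stop_mirnorm("unknown calibration method", class = "mirnorm_config_error")
      )
      agg <- aggregate_replicates(calibrated)
      agg <- agg[agg$assay_id != (ipc_assay %||% ""), ]
      class(agg) <- c("cq_table", "data.frame")
      report <- filter_low_expression(agg[agg$assay_id %in% reference_candidates, ],
                                      cq_max = config$filter$cq_max,
                                      min_undetected = config$filter$min_undetected)
      if (nrow(report$dropped) > 0) {
        note("[filter] dropped %d assay(s): %s", nrow(report$dropped),
             paste(report$dropped$assay_id, collapse = ", "))
      }
      keep <- agg$assay_id %in% c(report$kept, targets)
      out <- agg[keep, ]
      class(out) <- c("cq_table", "data.frame")
      write_cq_table(out, paths$calibrated)
      status <- data.frame(
        assay_id = c(report$kept, report$dropped$assay_id),
        status = c(rep("kept", length(report$kept)), rep("dropped", nrow(report$dropped))),
        reason = c(rep("", length(report$kept)), report$dropped$reason),
        stringsAsFactors = FALSE
      )
      utils::write.csv(status, paths$filter, row.names = FALSE)
      # reload from the written file so reruns and resumed runs see
      # identical (formatted) numbers
      list(cq = read_cq_table(paths$calibrated), kept = status)
    }
  })
  agg_cq <- preprocessed$cq
  kept_candidates <- sort(intersect(reference_candidates, unique(agg_cq$assay_id)))

  ## stage 3: stability across subsets ------------------------------------
  stability <- timed("stability", {
    if (resume && file.exists(paths$stability)) {
      list(report = read_stability_report(paths$stability), tables = NULL)
    } else {
      subsets <- subset_datasets(meta)
      tables <- list()
      for (ss in subsets) {
        cq_sub <- agg_cq[agg_cq$sample_id %in% ss$sample_ids, ]
        class(cq_sub) <- c("cq_table", "data.frame")
        cand_cq <- cq_sub[cq_sub$assay_id %in% kept_candidates, ]
        class(cand_cq) <- c("cq_table", "data.frame")
        rq <- suppressMessages(cq_to_rq(cand_cq, efficiency = config$efficiency, missing_policy = config$missing_policy, lod_cq = config$lod_cq))
        tables[[paste0("genorm.", ss$label)]] <- genorm_rank(rq, ss$label)$table
        tables[[paste0("bestkeeper.", ss$label)]] <-
          bestkeeper_stats(cand_cq, kept_candidates, subset_label = ss$label)$table
        tables[[paste0("normfinder.", ss$label)]] <-
          normfinder_ungrouped(log_rq(rq), ss$label)$table
      }
      write_stability_report(tables, paths$stability)
      # grouped NormFinder on the full dataset, one table per grouping
      cand_all <- agg_cq[agg_cq$assay_id %in% kept_candidates, ]
      class(cand_all) <- c("cq_table", "data.frame")
      rq_all <- suppressMessages(cq_to_rq(cand_all, efficiency = config$efficiency, missing_policy = config$missing_policy, lod_cq = config$lod_cq))
      grouped <- list()
      for (gname in names(grouping_schemes(meta))) {
        groups <- grouping_schemes(meta)[[gname]]
        sizes <- table(groups[rq_all$sample_ids])
        if (length(sizes) < 2 || any(sizes < 2)) {
          note("[stability] grouping '%s' lacks two groups of two samples; skipped", gname)
          next
        }
        grouped[[gname]] <- normfinder_grouped(log_rq(rq_all), groups,
                                               subset_label = paste0("All|", gname))$table
      }
      if (length(grouped) > 0) write_stability_report(grouped, paths$stability_grouped)
      list(report = read_stability_report(paths$stability), tables = tables)
    }
  })

  ## stage 4: consensus selection ------------------------------------------
  selection <- timed("select", {
    report <- stability$report
    all_tables <- lapply(c("genorm", "bestkeeper", "normfinder"), function(alg) {
      t <- report[report$algorithm == alg & report$subset_label == "All", ]
      class(t) <- c("stability_table", "data.frame")
      t
    })
    shortlist <- topk_intersection(all_tables, k = config$k_consensus)
    references <- utils::head(shortlist$consensus_rank$candidate_id, config$n_references)
    utils::write.csv(shortlist$consensus_rank, paths$consensus, row.names = FALSE)
    list(shortlist = shortlist, references = references)
  })

  ## stage 5: normalisation and comparisons --------------------------------
  normalized <- timed("normalize", {
    all_assays <- agg_cq
    rq_full <- cq_to_rq(all_assays, efficiency = config$efficiency,
                        missing_policy = "impute_lod", lod_cq = config$lod_cq)
    nf <- compute_nf(rq_full, selection$references)
    utils::write.csv(
      data.frame(sample_id = names(nf$nf), nf = unname(nf$nf)),
      paths$nf, row.names = FALSE)
    norm_rows <- list(); cmp_rows <- list()
    for (tg in targets) {
      norm <- normalize_target(rq_full, tg, nf)
      norm$target <- tg
      norm_rows[[tg]] <- norm
      overall <- compare_groups(norm, meta, strata = NULL)
      overall$scope <- "overall"
      by_muscle <- compare_groups(norm, meta, strata = "muscle")
      by_muscle$scope <- "by_muscle"
      cmp <- rbind(overall, by_muscle)
      cmp$target <- tg
      cmp_rows[[tg]] <- cmp
    }
    if (length(norm_rows) > 0) {
      utils::write.csv(do.call(rbind, norm_rows), paths$normalized, row.names = FALSE)
      utils::write.csv(do.call(rbind, cmp_rows), paths$comparisons, row.names = FALSE)
    }
    list(nf = nf, comparisons = if (length(cmp_rows) > 0) do.call(rbind, cmp_rows) else NULL)
  })

  ## manifest ---------------------------------------------------------------
  existing <- Filter(file.exists, unlist(paths[names(paths) != "manifest"]))
  manifest <- structure(
    list(
      config = config,
      seed = config$seed,
      stage_timings_s = timings,
      outputs = as.list(existing),
      output_md5 = as.list(tools::md5sum(existing)),
      consensus_shortlist = selection$shortlist$intersection,
      references = selection$references,
      n_stability_tables = if (!is.null(stability$tables)) length(stability$tables)
                           else nrow(unique(stability$report[c("algorithm", "subset_label")])),
      fold_changes = if (!is.null(normalized$comparisons)) {
        oc <- normalized$comparisons[normalized$comparisons$scope == "overall", ]
        stats::setNames(as.list(oc$fc_de_vs_wt), oc$target)
      } else NULL,
      warnings = warnings_log
    ),
    class = "run_manifest"
  )
  jsonlite::write_json(unclass(manifest), paths$manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, force = TRUE)
  manifest
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("<run_manifest>\n")
  cat("  stability tables:", x$n_stability_tables, "\n")
  cat("  consensus shortlist:", paste(x$consensus_shortlist, collapse = ", "), "\n")
  cat("  references:", paste(x$references, collapse = ", "), "\n")
  if (!is.null(x$fold_changes)) {
    cat("  overall DE50MD/WT fold changes:\n")
    for (tg in names(x$fold_changes)) cat(sprintf("    %s: %.3f\n", tg, x$fold_changes[[tg]]))
  }
  invisible(x)
}

#' Reproduce the stability analysis from a deposited Cq export
#'
#' Benchmark entry point for the deposited dataset (not shipped with the
#' package): runs calibration, aggregation, filtering and the three
#' stability algorithms on a user-supplied long-format CSV export of the
#' deposited workbook. Because the workbook layout is not standardised, the
#' caller maps its columns to `assay_id,sample_id,plate_id,replicate,cq`
#' when exporting.
#'
#' @param cq_path Long-format Cq CSV exported from the deposited workbook.
#' @param meta_path Sample metadata CSV.
#' @param out_dir Output directory.
#' @param ... Passed through to [run_pipeline()] config (e.g. `calibration`).
#' @return The [run_pipeline()] manifest.
#' @export
run_benchmark <- function(cq_path, meta_path, out_dir, ...) {
  run_pipeline(utils::modifyList(
    list(cq_path = cq_path, meta_path = meta_path, calibration = list(method = "none")),
    list(...)), out_dir)
}
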