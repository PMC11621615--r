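#' Candidate specification for simulation
#'
#' Describes one assay's ground truth. Effects are on the log2-abundance
#' scale and map to cycles assuming perfect doubling (one log2 unit of
#' abundance = one Cq cycle): an effect of +1 halves the Cq... more
#' precisely lowers it by one cycle. `genotype_log2fc` is the DE50-MD shift
#' relative to WT and may be a single number or a named per-muscle vector
#' (e.g. a fibrosis-associated target elevated more strongly in post-mortem
#' muscles than in vastus lateralis). `age_slope_log2_per_month` acts on age
#' centred at the design's mean age. `absent = TRUE` places the baseline
#' near the detection ceiling so the assay is dropout-prone.
#'
#' @param name Assay id.
#' @param baseline_cq Baseline Cq for a WT sample at the mean age.
#' @param genotype_log2fc Scalar or named per-muscle log2 effect in DE50-MD.
#' @param age_slope_log2_per_month Linear log2 trend per month of age.
#' @param muscle_log2fc Named per-muscle log2 offsets (both genotypes).
#' @param extra_noise_sd_log2 Candidate-specific biological noise SD (log2),
#'   drawn independently per sample; this is what makes a candidate unstable.
#' @param absent Dropout-prone low-abundance assay.
#' @param role `"candidate"` (reference candidate), `"target"`, or `"ipc"`
#'   (interplate calibrator with a fixed template: no biological variation,
#'   only plate offset and well noise).
#' @return A `candidate_spec` list.
#' @export
candidate_spec <- function(name, baseline_cq, genotype_log2fc = 0,
                           age_slope_log2_per_month = 0, muscle_log2fc = NULL,
                           extra_noise_sd_log2 = 0.1, absent = FALSE,
                           role = c("candidate", "target", "ipc")) {
  role <- match.arg(role)
  if (extra_noise_sd_log2 < 0) stop_mirnorm("noise SD must be >= 0", class = "mirnorm_config_error")
  structure(
    list(name = name, baseline_cq = baseline_cq, genotype_log2fc = genotype_log2fc,
         age_slope_log2_per_month = age_slope_log2_per_month,
         muscle_log2fc = muscle_log2fc, extra_noise_sd_log2 = extra_noise_sd_log2,
         absent = absent, role = role),
    class = "candidate_spec"
  )
}

#' Simulation configuration
#'
#' Defines the study design and noise model for [simulate_study()]. The
#' default design mirrors the two-genotype canine study: longitudinal
#' vastus-lateralis biopsies from `n_dogs_per_genotype` dogs at six ages,
#' plus four further muscles sampled post mortem at the final age from
#' `n_pm_dogs_per_genotype` dogs; `mirror_study_missing` withholds one
#' DE50-MD 15-month VL sample and one WT 18-month VL sample, reproducing the
#' deposited dataset's cardinalities (70 VL + 24 post-mortem = 94 samples).
#' One post-mortem dog per design is shared with the longitudinal cohort so
#' the animal count matches the study's 17 dogs.
#'
#' @param candidates List of [candidate_spec()]s.
#' @param n_dogs_per_genotype Longitudinal VL dogs per genotype.
#' @param n_pm_dogs_per_genotype Post-mortem dogs per genotype.
#' @param ages Biopsy ages (months) for the longitudinal VL series.
#' @param muscles Muscles; the first is the longitudinal one, the rest are
#'   post-mortem at the final age.
#' @param n_replicates Wells per (assay, sample).
#' @param samples_per_plate Samples per qPCR plate (sample-major layout: all
#'   of a sample's assays run on its plate).
#' @param replicate_noise_sd Well-level technical noise SD (cycles).
#' @param plate_offset_sd Between-plate systematic offset SD (cycles).
#' @param dog_effect_sd Per-dog global abundance shift SD (cycles), shared
#'   across all of that dog's samples and assays (emulates repeated-measures
#'   correlation and sample-level input variation).
#' @param lod_cq Detection ceiling; wells above it are undetected.
#' @param mirror_study_missing Withhold the study's two unavailable samples.
#' @param seed Integer seed; same seed gives bit-identical output.
#' @return A `sim_config` list.
#' @export
sim_config <- function(candidates,
                       n_dogs_per_genotype = 6,
                       n_pm_dogs_per_genotype = 3,
                       ages = c(3L, 6L, 9L, 12L, 15L, 18L),
                       muscles = c("VL", "CRT", "SEM", "TRI", "DIA"),
                       n_replicates = 2,
                       samples_per_plate = 12,
                       replicate_noise_sd = 0.15,
                       plate_offset_sd = 0.5,
                       dog_effect_sd = 0.8,
                       lod_cq = 35,
                       mirror_study_missing = TRUE,
                       seed = 1L) {
  stopifnot(length(candidates) > 0)
  bad_mu <- setdiff(muscles, c("VL", "CRT", "SEM", "TRI", "DIA"))
  if (length(bad_mu) > 0) {
    stop_mirnorm("unknown muscle(s) in config: ", paste(bad_mu, collapse = ", "),
                 class = "mirnorm_config_error")
  }
  if (replicate_noise_sd < 0 || plate_offset_sd < 0 || dog_effect_sd < 0) {
    stop_mirnorm("noise SDs must be >= 0", class = "mirnorm_config_error")
  }
  if (lod_cq > 45) stop_mirnorm("lod_cq must be <= 45", class = "mirnorm_config_error")
  names(candidates) <- vapply(candidates, `[[`, character(1), "name")
  structure(
    list(candidates = candidates,
         n_dogs_per_genotype = n_dogs_per_genotype,
         n_pm_dogs_per_genotype = n_pm_dogs_per_genotype,
         ages = as.integer(ages), muscles = muscles,
         n_replicates = n_replicates, samples_per_plate = samples_per_plate,
         replicate_noise_sd = replicate_noise_sd, plate_offset_sd = plate_offset_sd,
         dog_effect_sd = dog_effect_sd, lod_cq = lod_cq,
         mirror_study_missing = mirror_study_missing, seed = as.integer(seed)),
    class = "sim_config"
  )
}

# Build the sample-metadata frame implied by a sim_config.
build_design_meta <- function(config) {
  rows <- list()
  vl_dogs <- function(g) sprintf("%s%02d", g, seq_len(config$n_dogs_per_genotype))
  # post-mortem dogs: the last one per genotype, for DE50MD only, is shared
  # with the longitudinal cohort (reproduces the study's 17-animal count)
  pm_dogs <- function(g) {
    n <- config$n_pm_dogs_per_genotype
    if (n == 0) return(character(0))
    fresh <- sprintf("%sP%02d", g, seq_len(n))
    if (g == "DE50MD" && config$n_dogs_per_genotype > 0) {
      c(fresh[-n], vl_dogs(g)[config$n_dogs_per_genotype])
    } else fresh
  }
  longitudinal_muscle <- config$muscles[1]
  pm_muscles <- config$muscles[-1]
  final_age <- max(config$ages)
  for (g in c("WT", "DE50MD")) {
    for (d in vl_dogs(g)) {
      for (a in config$ages) {
        rows[[length(rows) + 1]] <- data.frame(
          dog_id = d, genotype = g, muscle = longitudinal_muscle, age_months = a,
          stringsAsFactors = FALSE)
      }
    }
    for (d in pm_dogs(g)) {
      for (mu in pm_muscles) {
        rows[[length(rows) + 1]] <- data.frame(
          dog_id = d, genotype = g, muscle = mu, age_months = final_age,
          stringsAsFactors = FALSE)
      }
    }
  }
  meta <- do.call(rbind, rows)
  if (config$mirror_study_missing) {
    drop1 <- meta$genotype == "DE50MD" & meta$muscle == longitudinal_muscle &
      meta$age_months == sort(config$ages, decreasing = TRUE)[2] &
      meta$dog_id == vl_dogs("DE50MD")[config$n_dogs_per_genotype]
    drop2 <- meta$genotype == "WT" & meta$muscle == longitudinal_muscle &
      meta$age_months == final_age &
      meta$dog_id == vl_dogs("WT")[config$n_dogs_per_genotype]
    meta <- meta[!(drop1 | drop2), ]
  }
  meta$sample_id <- sprintf("%s_%s_%02dm", meta$dog_id, meta$muscle, meta$age_months)
  # interleave genotypes when walking the table so plates mix genotypes
  meta <- meta[order(meta$age_months, meta$muscle, sub("^(WT|DE50MD)", "", meta$dog_id),
                     meta$genotype), ]
  rownames(meta) <- NULL
  sample_meta(meta)
}

#' Simulate an RT-qPCR study with known ground truth
#'
#' Generates well-level Cq data under the additive model
#' `Cq = baseline - (genotype + age + muscle + candidate noise) - dog effect
#' + plate offset + well noise`, where all biological effects are log2
#' abundances converted to cycles at perfect doubling. Wells whose Cq
#' exceeds the detection ceiling are undetected. The same seed gives
#' bit-identical tables.
#'
#' @param config A [sim_config()].
#' @return List: `cq` (a [cq_table()]), `meta` (a [sample_meta()]) and
#'   `truth` (a `sim_truth` list recording every injected effect, the
#'   per-dog and per-plate draws, and which candidates were designed stable
#'   or absent).
#' @export
simulate_study <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  meta <- build_design_meta(config)
  n <- nrow(meta)
  plate_of <- sprintf("plate%02d", ceiling(seq_len(n) / config$samples_per_plate))
  plates <- unique(plate_of)
  plate_offsets <- stats::setNames(stats::rnorm(length(plates), 0, config$plate_offset_sd), plates)
  dogs <- unique(meta$dog_id)
  dog_effects <- stats::setNames(stats::rnorm(length(dogs), 0, config$dog_effect_sd), dogs)
  mean_age <- mean(config$ages)
  records <- vector("list", length(config$candidates))
  for (ci in seq_along(config$candidates)) {
    spec <- config$candidates[[ci]]
    gfc <- spec$genotype_log2fc
    gt_effect <- if (length(gfc) > 1 || !is.null(names(gfc))) {
      unname(gfc[as.character(meta$muscle)]) * (meta$genotype == "DE50MD")
    } else {
      gfc * (meta$genotype == "DE50MD")
    }
    mu_effect <- if (is.null(spec$muscle_log2fc)) 0 else {
      off <- spec$muscle_log2fc[as.character(meta$muscle)]
      ifelse(is.na(off), 0, unname(off))
    }
    age_effect <- spec$age_slope_log2_per_month * (meta$age_months - mean_age)
    bio <- if (spec$role == "ipc") 0 else {
      gt_effect + mu_effect + age_effect +
        stats::rnorm(n, 0, spec$extra_noise_sd_log2) + dog_effects[meta$dog_id]
    }
    true_cq <- spec$baseline_cq - bio + plate_offsets[plate_of]
    reps <- lapply(seq_len(config$n_replicates), function(r) {
      cqv <- true_cq + stats::rnorm(n, 0, config$replicate_noise_sd)
      cqv[cqv > config$lod_cq] <- NA_real_
      data.frame(assay_id = spec$name, sample_id = meta$sample_id,
                 plate_id = plate_of, replicate = r, cq = cqv,
                 stringsAsFactors = FALSE)
    })
    records[[ci]] <- do.call(rbind, reps)
  }
  cq <- do.call(rbind, records)
  cq <- cq_table(cq)
  specs <- config$candidates
  truth <- structure(
    list(
      seed = config$seed,
      candidates = specs,
      designed_stable = names(specs)[vapply(specs, function(s) {
        s$role == "candidate" && !s$absent && s$extra_noise_sd_log2 <= 0.2 &&
          all(abs(unlist(s$genotype_log2fc)) <= 0.2) && s$age_slope_log2_per_month == 0
      }, logical(1))],
      designed_absent = names(specs)[vapply(specs, `[[`, logical(1), "absent")],
      targets = names(specs)[vapply(specs, function(s) s$role == "target", logical(1))],
      ipc_assay = names(specs)[vapply(specs, function(s) s$role == "ipc", logical(1))],
      dog_effects = dog_effects,
      plate_offsets = plate_offsets,
      noise = list(replicate_noise_sd = config$replicate_noise_sd,
                   plate_offset_sd = config$plate_offset_sd,
                   dog_effect_sd = config$dog_effect_sd,
                   note = paste("between-dog and between-plate variance components are",
                                "plausible placeholders, not estimates from real data")),
      lod_cq = config$lod_cq
    ),
    class = "sim_truth"
  )
  list(cq = cq, meta = meta, truth = truth)
}

#' Preset simulation scenarios
#'
#' Three ready-made configurations:
#' \describe{
#'   \item{screen87}{The screening stage: 87 assays plus an interplate
#'     calibrator on 8 six-month VL samples (4 per genotype, 2 plates,
#'     single wells). 14 assays are designed absent (baseline above the
#'     detection ceiling) and should be recovered exactly by
#'     [filter_low_expression()]; the remaining 73 span a range of
#'     stabilities.}
#'   \item{panel9}{The validation stage: 9 reference candidates and 4
#'     targets over the full 94-sample design with duplicate wells. Four
#'     candidates (miR-191, let-7b, miR-125a, miR-15a) are designed stable;
#'     snRNA-U6 is destabilised (genotype up-shift, age decline, high
#'     noise); miR-29b carries an age trend and elevated noise. Targets
#'     carry genotype effects of -log2(3) (miR-1-like), -1 (miR-133a-like),
#'     0 (miR-206-like) and, for the miR-214-like fibromiR, +1 log2 in VL
#'     and +2 in the post-mortem muscles.}
#'   \item{null_panel}{9 exchangeable candidates with no injected effects,
#'     for type-I-error-style checks.}
#' }
#'
#' @param name Preset name.
#' @param seed Seed stored in the returned config.
#' @return A [sim_config()].
#' @export
preset_scenarios <- function(name = c("screen87", "panel9", "null_panel"), seed = 1L) {
  name <- match.arg(name)
  if (name == "screen87") {
    absent_names <- c("miR-122", "miR-124", "miR-137", "miR-141", "miR-182",
                      "miR-183", "miR-184", "miR-200a", "miR-200b", "miR-203",
                      "miR-205", "miR-34c", "miR-375", "miR-96")
    panel_names <- c("miR-191", "let-7b", "miR-125a", "miR-15a", "miR-27b",
                     "miR-106b", "miR-130a", "miR-29b", "snRNA-U6")
    filler_names <- sprintf("miR-F%02d", seq_len(87 - length(absent_names) - length(panel_names)))
    expressed <- c(panel_names, filler_names)
    baselines <- seq(20, 30, length.out = length(expressed))
    # the filler assays emulate disease-responsive miRs of interest: larger
    # biological spread than reference material, some genotype-shifted
    noises <- rep(c(0.5, 0.6, 0.8, 1.0), length.out = length(expressed))
    gfx <- rep(c(0, -1, 0, 0.75), length.out = length(expressed))
    noises[seq_along(panel_names)] <- c(0.10, 0.12, 0.14, 0.14, 0.35, 0.38, 0.42, 0.40, 1.3)
    gfx[seq_along(panel_names)] <- c(0, 0, log2(1.1), -log2(1.1), 0, 0, 0, 0, log2(1.8))
    cands <- c(
      mapply(function(nm, b, s, g) candidate_spec(nm, b, genotype_log2fc = g,
                                                  extra_noise_sd_log2 = s),
             expressed, baselines, noises, gfx, SIMPLIFY = FALSE),
      lapply(absent_names, function(nm) {
        candidate_spec(nm, baseline_cq = 37, extra_noise_sd_log2 = 0.3, absent = TRUE)
      }),
      list(candidate_spec("UniSp3-IPC", baseline_cq = 20, extra_noise_sd_log2 = 0,
                          role = "ipc"))
    )
    sim_config(cands,
               n_dogs_per_genotype = 4, n_pm_dogs_per_genotype = 0,
               ages = 6L, muscles = "VL", n_replicates = 1,
               samples_per_plate = 4, mirror_study_missing = FALSE, seed = seed)
  } else if (name == "panel9") {
    cands <- list(
      candidate_spec("miR-191", 22, extra_noise_sd_log2 = 0.10),
      candidate_spec("let-7b", 20, extra_noise_sd_log2 = 0.12),
      candidate_spec("miR-125a", 23, genotype_log2fc = log2(1.1),
                     extra_noise_sd_log2 = 0.14),
      candidate_spec("miR-15a", 24, genotype_log2fc = -log2(1.1),
                     extra_noise_sd_log2 = 0.14),
      candidate_spec("miR-27b", 23.5, extra_noise_sd_log2 = 0.35),
      candidate_spec("miR-106b", 25, extra_noise_sd_log2 = 0.38),
      candidate_spec("miR-130a", 24.5, extra_noise_sd_log2 = 0.42),
      candidate_spec("miR-29b", 26, age_slope_log2_per_month = 0.03,
                     extra_noise_sd_log2 = 0.40),
      candidate_spec("snRNA-U6", 19, genotype_log2fc = log2(1.8),
                     age_slope_log2_per_month = -0.06, extra_noise_sd_log2 = 1.3),
      candidate_spec("miR-1", 18, genotype_log2fc = -log2(3),
                     extra_noise_sd_log2 = 0.35, role = "target"),
      candidate_spec("miR-133a", 19, genotype_log2fc = -1,
                     extra_noise_sd_log2 = 0.35, role = "target"),
      candidate_spec("miR-206", 21, genotype_log2fc = 0,
                     extra_noise_sd_log2 = 0.35, role = "target"),
      candidate_spec("miR-214", 25,
                     genotype_log2fc = c(VL = 1, CRT = 2, SEM = 2, TRI = 2, DIA = 2),
                     extra_noise_sd_log2 = 0.35, role = "target"),
      candidate_spec("UniSp3-IPC", 20, extra_noise_sd_log2 = 0, role = "ipc")
    )
    sim_config(cands, seed = seed)
  } else {
    cands <- c(
      lapply(sprintf("miR-N%02d", 1:9), function(nm) {
        candidate_spec(nm, baseline_cq = 24, extra_noise_sd_log2 = 0.2)
      }),
      list(candidate_spec("UniSp3-IPC", 20, extra_noise_sd_log2 = 0, role = "ipc"))
    )
    sim_config(cands, seed = seed)
  }
}

#' Write a simulated study to disk
#'
#' Writes `cq.csv`, `meta.csv` and `truth.json` under `dir`.
#'
#' @param sim A [simulate_study()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_cq_table(sim$cq, file.path(dir, "cq.csv"))
  write_sample_meta(sim$meta, file.path(dir, "meta.csv"))
  truth <- sim$truth
  truth$candidates <- lapply(truth$candidates, unclass)
  jsonlite::write_json(unclass(truth), file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
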