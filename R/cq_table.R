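#' Replicate-level Cq tables
#'
#' A `cq_table` holds quantification-cycle (Cq) measurements at the replicate
#' well level, keyed by assay x sample x plate x replicate. An undetected
#' reaction (no amplification within the run's cycle ceiling) is stored as
#' `NA` in the `cq` column: undetected is a first-class flag, never a sentinel
#' cycle number, because the low-expression filter treats "high Cq" and
#' "undetectable" as distinct evidence.
#'
#' @param df Data frame with columns `assay_id`, `sample_id`, `plate_id`,
#'   `replicate` (integer >= 1) and `cq` (numeric cycles in (0, 45], or `NA`
#'   for undetected).
#' @return A validated data frame of class `cq_table`.
#' @export
cq_table <- function(df) {
  required <- c("assay_id", "sample_id", "plate_id", "replicate", "cq")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop_mirnorm("Cq table is missing column(s): ", paste(missing_cols, collapse = ", "),
                 class = "mirnorm_format_error")
  }
  df <- as.data.frame(df)[required]
  for (col in c("assay_id", "sample_id", "plate_id")) df[[col]] <- trim_id(df[[col]])
  df$replicate <- as.integer(df$replicate)
  df$cq <- as.numeric(df$cq)
  if (anyNA(df$replicate) || any(df$replicate < 1L)) {
    stop_mirnorm("replicate indices must be integers >= 1", class = "mirnorm_validation_error")
  }
  bad <- which(!is.na(df$cq) & (df$cq <= 0 | df$cq > 45))
  if (length(bad) > 0) {
    stop_mirnorm("Cq outside (0, 45] at row(s): ", paste(utils::head(bad, 5), collapse = ", "),
                 class = "mirnorm_validation_error")
  }
  key <- paste(df$assay_id, df$sample_id, df$plate_id, df$replicate, sep = "\r")
  if (anyDuplicated(key)) {
    stop_mirnorm("duplicate (assay, sample, plate, replicate) key at row ",
                 which(duplicated(key))[1], class = "mirnorm_validation_error")
  }
  rownames(df) <- NULL
  class(df) <- c("cq_table", "data.frame")
  df
}

#' @export
print.cq_table <- function(x, ...) {
  cat(sprintf("<cq_table> %d records | %d assays x %d samples x %d plates | %d undetected\n",
              nrow(x), length(unique(x$assay_id)), length(unique(x$sample_id)),
              length(unique(x$plate_id)), sum(is.na(x$cq))))
  print(utils::head(as.data.frame(x), 6))
  invisible(x)
}

# shared Cq-string parser: "Undetermined"/"NA"/"" (any case) -> NA (undetected)
parse_cq_values <- function(x) {
  x <- trimws(as.character(x))
  undet <- is.na(x) | x == "" | tolower(x) %in% c("undetermined", "undetected", "na", "n/a")
  out <- suppressWarnings(as.numeric(x))
  bad <- which(!undet & is.na(out))
  if (length(bad) > 0) {
    stop_mirnorm("unparseable Cq value '", x[bad[1]], "' at data row ", bad[1],
                 class = "mirnorm_format_error")
  }
  out[undet] <- NA_real_
  out
}

#' Read a Cq table from CSV
#'
#' The long dialect (columns `assay_id,sample_id,plate_id,replicate,cq`) is
#' canonical; the wide dialect (first column `assay_id`, one column per
#' sample) is a convenience that implies a single plate and a single
#' replicate, since well-level structure cannot be represented in wide form.
#' Cq cells that are blank, `NA` or `Undetermined` are read as undetected.
#'
#' @param path CSV file path (UTF-8, header row mandatory).
#' @param dialect `"long"` (default) or `"wide"`.
#' @return A [cq_table()].
#' @export
read_cq_table <- function(path, dialect = c("long", "wide")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop_mirnorm("file not found: ", path, class = "mirnorm_io_error")
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                         fileEncoding = "UTF-8")
  if (dialect == "long") {
    required <- c("assay_id", "sample_id", "plate_id", "replicate", "cq")
    missing_cols <- setdiff(required, names(raw))
    if (length(missing_cols) > 0) {
      stop_mirnorm("malformed header: missing column(s) ",
                   paste(missing_cols, collapse = ", "), class = "mirnorm_format_error")
    }
    raw$cq <- parse_cq_values(raw$cq)
    cq_table(raw)
  } else {
    if (names(raw)[1] != "assay_id") {
      stop_mirnorm("malformed header: wide dialect requires first column 'assay_id'",
                   class = "mirnorm_format_error")
    }
    samples <- names(raw)[-1]
    long <- data.frame(
      assay_id = rep(raw$assay_id, times = length(samples)),
      sample_id = rep(samples, each = nrow(raw)),
      plate_id = "P1",
      replicate = 1L,
      cq = parse_cq_values(unlist(raw[-1], use.names = FALSE)),
      stringsAsFactors = FALSE
    )
    cq_table(long)
  }
}

#' Write a Cq table to CSV
#'
#' @param x A [cq_table()].
#' @param path Output CSV path.
#' @param dialect `"long"` or `"wide"`; wide requires a single plate and a
#'   single replicate per (assay, sample).
#' @return `path`, invisibly.
#' @export
write_cq_table <- function(x, path, dialect = c("long", "wide")) {
  dialect <- match.arg(dialect)
  if (dialect == "long") {
    out <- as.data.frame(x)
    out$cq <- ifelse(is.na(out$cq), "Undetermined", format(out$cq, digits = 15, trim = TRUE))
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  } else {
    if (anyDuplicated(paste(x$assay_id, x$sample_id, sep = "\r"))) {
      stop_mirnorm("wide dialect requires one record per (assay, sample); aggregate first",
                   class = "mirnorm_format_error")
    }
    assays <- unique(x$assay_id)
    samples <- unique(x$sample_id)
    m <- matrix(NA_real_, length(assays), length(samples), dimnames = list(assays, samples))
    m[cbind(x$assay_id, x$sample_id)] <- x$cq
    out <- data.frame(assay_id = assays, stringsAsFactors = FALSE, check.names = FALSE)
    for (s in samples) {
      out[[s]] <- ifelse(is.na(m[, s]), "Undetermined", format(m[, s], digits = 15, trim = TRUE))
    }
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Per-sample metadata
#'
#' Annotates each RT-qPCR sample with its dog, genotype (`WT` wild-type vs
#' `DE50MD` dystrophin exon-50 deletion model), muscle (`VL` vastus lateralis,
#' `CRT` cranial tibial, `SEM` semimembranosus, `TRI` lateral triceps, `DIA`
#' diaphragm) and age in months. Under the study design, longitudinal
#' biopsies cover VL at 3-18 months while the other four muscles are sampled
#' post mortem at 18 months only; `strict = FALSE` relaxes the design-grid
#' checks for free-form simulations.
#'
#' @param df Data frame with columns `sample_id`, `dog_id`, `genotype`,
#'   `muscle`, `age_months`.
#' @param strict Enforce the design grid (ages in \{3,6,9,12,15,18\}; non-VL
#'   muscles only at 18 months).
#' @return A validated data frame of class `sample_meta`.
#' @export
sample_meta <- function(df, strict = TRUE) {
  required <- c("sample_id", "dog_id", "genotype", "muscle", "age_months")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop_mirnorm("sample metadata is missing column(s): ",
                 paste(missing_cols, collapse = ", "), class = "mirnorm_format_error")
  }
  df <- as.data.frame(df)[required]
  if (nrow(df) == 0) stop_mirnorm("sample metadata is empty", class = "mirnorm_validation_error")
  for (col in c("sample_id", "dog_id", "genotype", "muscle")) df[[col]] <- trim_id(df[[col]])
  df$age_months <- as.integer(df$age_months)
  if (anyDuplicated(df$sample_id)) {
    stop_mirnorm("duplicate sample_id: ", df$sample_id[duplicated(df$sample_id)][1],
                 class = "mirnorm_validation_error")
  }
  bad_gt <- setdiff(unique(df$genotype), c("WT", "DE50MD"))
  if (length(bad_gt) > 0) {
    stop_mirnorm("unknown genotype label(s): ", paste(bad_gt, collapse = ", "),
                 class = "mirnorm_validation_error")
  }
  bad_mu <- setdiff(unique(df$muscle), c("VL", "CRT", "SEM", "TRI", "DIA"))
  if (length(bad_mu) > 0) {
    stop_mirnorm("unknown muscle label(s): ", paste(bad_mu, collapse = ", "),
                 class = "mirnorm_validation_error")
  }
  key <- paste(df$dog_id, df$muscle, df$age_months, sep = "\r")
  if (anyDuplicated(key)) {
    stop_mirnorm("duplicate (dog, muscle, age) combination",
                 class = "mirnorm_validation_error")
  }
  if (strict) {
    if (!all(df$age_months %in% c(3L, 6L, 9L, 12L, 15L, 18L))) {
      stop_mirnorm("age_months outside the design grid {3,6,9,12,15,18}; ",
                   "use strict = FALSE for free-form designs",
                   class = "mirnorm_validation_error")
    }
    off_design <- df$muscle != "VL" & df$age_months != 18L
    if (any(off_design)) {
      stop_mirnorm("non-VL muscles are sampled post mortem at 18 months only; ",
                   "use strict = FALSE for free-form designs",
                   class = "mirnorm_validation_error")
    }
  }
  df$genotype <- factor(df$genotype, levels = c("WT", "DE50MD"))
  df$muscle <- factor(df$muscle, levels = c("VL", "CRT", "SEM", "TRI", "DIA"))
  rownames(df) <- NULL
  class(df) <- c("sample_meta", "data.frame")
  df
}

#' Read sample metadata from CSV
#'
#' @inheritParams sample_meta
#' @param path CSV with columns `sample_id,dog_id,genotype,muscle,age_months`.
#' @return A [sample_meta()].
#' @export
read_sample_meta <- function(path, strict = TRUE) {
  if (!file.exists(path)) stop_mirnorm("file not found: ", path, class = "mirnorm_io_error")
  raw <- utils::read.csv(path, colClasses = "character", fileEncoding = "UTF-8")
  sample_meta(raw, strict = strict)
}

#' @rdname read_sample_meta
#' @param x A `sample_meta`.
#' @export
write_sample_meta <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Stability tables
#'
#' One algorithm's per-candidate stability scores and ranks on one sample
#' subset. Ranks are 1 = most stable; score polarity differs by algorithm
#' (geNorm M and NormFinder stability: lower is better; BestKeeper r: higher
#' is better) and the rank column already encodes it.
#'
#' @param algorithm `"genorm"`, `"bestkeeper"` or `"normfinder"`.
#' @param subset_label Label of the sample subset scored.
#' @param entries Data frame with `candidate_id`, `score`, `rank` plus any
#'   algorithm-specific extras (e.g. BestKeeper `sd_cq`, `cv_pct`, `p`).
#' @return Data frame of class `stability_table`.
#' @export
stability_table <- function(algorithm, subset_label, entries) {
  algorithm <- match.arg(algorithm, c("genorm", "bestkeeper", "normfinder"))
  entries <- as.data.frame(entries)
  stopifnot(all(c("candidate_id", "score", "rank") %in% names(entries)))
  if (!setequal(entries$rank, seq_len(nrow(entries)))) {
    stop_mirnorm("ranks must form a permutation of 1..k", class = "mirnorm_validation_error")
  }
  out <- cbind(
    data.frame(algorithm = algorithm, subset_label = subset_label,
               stringsAsFactors = FALSE),
    entries
  )
  out <- out[order(out$rank), ]
  rownames(out) <- NULL
  class(out) <- c("stability_table", "data.frame")
  out
}

#' Write stability tables to one tidy CSV
#'
#' @param tables A `stability_table` or non-empty list of them.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_stability_report <- function(tables, path) {
  if (inherits(tables, "stability_table")) tables <- list(tables)
  if (length(tables) == 0) stop_mirnorm("no stability tables to write", class = "mirnorm_validation_error")
  extras <- unique(unlist(lapply(tables, function(t) {
    setdiff(names(t), c("algorithm", "subset_label", "candidate_id", "score", "rank"))
  })))
  cols <- c("algorithm", "subset_label", "candidate_id", "score", "rank", extras)
  rows <- lapply(tables, function(t) {
    t <- as.data.frame(t)
    for (col in setdiff(cols, names(t))) t[[col]] <- NA_real_
    t[cols]
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$algorithm, out$subset_label, out$rank), ]
  tryCatch(
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE),
    error = function(e) stop_mirnorm("failed to write ", path, ": ", conditionMessage(e),
                                     class = "mirnorm_io_error")
  )
  invisible(path)
}

#' @rdname write_stability_report
#' @export
read_stability_report <- function(path) {
  if (!file.exists(path)) stop_mirnorm("file not found: ", path, class = "mirnorm_io_error")
  out <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  out$candidate_id <- trim_id(out$candidate_id)
  out
}
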