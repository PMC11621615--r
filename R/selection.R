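#' Study sample subsets for stability scoring
#'
#' The nine subsets on which stability is scored: all samples, each genotype
#' alone, vastus lateralis only (overall and per genotype), and the
#' 18-month samples (overall and per genotype; at 18 months the design holds
#' both the final longitudinal VL biopsies and all post-mortem muscles).
#' Cardinalities are always derived from the metadata, never hard-coded.
#'
#' @param meta A [sample_meta()].
#' @param scheme `"study_nine"`, or `"custom"` with `predicates`, a named
#'   list of functions `meta -> logical`.
#' @param predicates For `scheme = "custom"`.
#' @return Named list of subset specs: each has `label` and `sample_ids`.
#'   Empty subsets are skipped with a warning.
#' @export
subset_datasets <- function(meta, scheme = c("study_nine", "custom"), predicates = NULL) {
  scheme <- match.arg(scheme)
  preds <- if (scheme == "study_nine") {
    list(
      "All" = function(m) rep(TRUE, nrow(m)),
      "WT" = function(m) m$genotype == "WT",
      "DE50MD" = function(m) m$genotype == "DE50MD",
      "VL" = function(m) m$muscle == "VL",
      "WT-VL" = function(m) m$genotype == "WT" & m$muscle == "VL",
      "DE50MD-VL" = function(m) m$genotype == "DE50MD" & m$muscle == "VL",
      "18m" = function(m) m$age_months == 18,
      "WT-18m" = function(m) m$genotype == "WT" & m$age_months == 18,
      "DE50MD-18m" = function(m) m$genotype == "DE50MD" & m$age_months == 18
    )
  } else {
    if (is.null(predicates) || is.null(names(predicates))) {
      stop_mirnorm("custom scheme needs a named list of predicates", class = "mirnorm_validation_error")
    }
    predicates
  }
  out <- list()
  for (label in names(preds)) {
    ids <- meta$sample_id[preds[[label]](meta)]
    if (length(ids) == 0) {
      warning(sprintf("subset '%s' is empty; skipped", label))
      next
    }
    out[[label]] <- list(label = label, sample_ids = ids)
  }
  out
}

#' Cross-algorithm consensus shortlist
#'
#' Candidates ranked in the top `k` by every supplied algorithm form the
#' shortlist; the consensus rank (mean of per-algorithm ranks, ascending,
#' lexicographic tie-break) orders all candidates for downstream selection.
#'
#' @param tables List of [stability_table()]s over the same candidate set
#'   (typically one per algorithm on one subset).
#' @param k Top-k threshold for the intersection.
#' @return A `consensus_shortlist`: `k_threshold`, `topk` (per-algorithm
#'   top-k sets), `intersection` (sorted by consensus rank), and
#'   `consensus_rank` (data frame over all candidates).
#' @export
topk_intersection <- function(tables, k = 11) {
  if (length(tables) == 0) stop_mirnorm("no stability tables supplied", class = "mirnorm_validation_error")
  universes <- lapply(tables, function(t) sort(t$candidate_id))
  if (!all(vapply(universes, identical, logical(1), y = universes[[1]]))) {
    stop_mirnorm("stability tables cover different candidate universes",
                 class = "mirnorm_validation_error")
  }
  labels <- vapply(tables, function(t) t$algorithm[1], character(1))
  if (anyDuplicated(labels)) labels <- paste0(labels, ".", seq_along(labels))
  topk <- lapply(tables, function(t) t$candidate_id[t$rank <= k])
  names(topk) <- labels
  inter <- Reduce(intersect, topk)
  ranks <- sapply(tables, function(t) t$rank[match(universes[[1]], t$candidate_id)])
  mean_rank <- rowMeans(ranks)
  ord <- order(mean_rank, universes[[1]])
  consensus <- data.frame(
    candidate_id = universes[[1]][ord],
    mean_rank = mean_rank[ord],
    stringsAsFactors = FALSE
  )
  rownames(consensus) <- NULL
  structure(
    list(k_threshold = k, topk = topk,
         intersection = consensus$candidate_id[consensus$candidate_id %in% inter],
         consensus_rank = consensus),
    class = "consensus_shortlist"
  )
}

#' @export
print.consensus_shortlist <- function(x, ...) {
  cat(sprintf("<consensus_shortlist> k = %d; %d candidate(s) in all top-k sets:\n",
              x$k_threshold, length(x$intersection)))
  cat(" ", paste(x$intersection, collapse = ", "), "\n")
  invisible(x)
}

#' Geometric-mean normalisation factor
#'
#' The per-sample geometric mean of the selected reference candidates'
#' relative quantities; with the study's four references this is the NF4.
#' Using several validated references averages out residual instability of
#' any single one.
#'
#' @param rq An `rq_matrix`.
#' @param references Reference candidate ids (non-empty, present in `rq`).
#' @return A `normalization_factor`: `reference_ids` and per-sample `nf`.
#' @export
compute_nf <- function(rq, references) {
  if (length(references) == 0) stop_mirnorm("no reference candidates given", class = "mirnorm_validation_error")
  unknown <- setdiff(references, rq$candidate_ids)
  if (length(unknown) > 0) {
    stop_mirnorm("unknown reference id(s): ", paste(unknown, collapse = ", "),
                 class = "mirnorm_validation_error")
  }
  nf <- apply(rq$rq[references, , drop = FALSE], 2, geomean)
  structure(list(reference_ids = references, nf = nf), class = "normalization_factor")
}

#' @export
print.normalization_factor <- function(x, ...) {
  cat(sprintf("<normalization_factor> NF%d over {%s}; %d samples\n",
              length(x$reference_ids), paste(x$reference_ids, collapse = ", "),
              length(x$nf)))
  invisible(x)
}

#' Normalise a target candidate by a normalisation factor
#'
#' @param rq An `rq_matrix` containing the target.
#' @param target Target candidate id.
#' @param nf A [compute_nf()] result over the same samples.
#' @return Data frame with `sample_id`, `value` (RQ / NF, linear scale) and
#'   `log2_value`.
#' @export
normalize_target <- function(rq, target, nf) {
  if (!target %in% rq$candidate_ids) {
    stop_mirnorm("unknown target id: ", target, class = "mirnorm_validation_error")
  }
  if (!identical(sort(names(nf$nf)), sort(rq$sample_ids))) {
    stop_mirnorm("normalisation factor and RQ matrix cover different samples",
                 class = "mirnorm_alignment_error")
  }
  vals <- rq$rq[target, ] / nf$nf[rq$sample_ids]
  data.frame(sample_id = rq$sample_ids, value = unname(vals),
             log2_value = unname(log2(vals)), stringsAsFactors = FALSE)
}

#' Sidak-sharpened Holm step-down p-value adjustment
#'
#' Orders the raw p-values ascending and sets
#' `p_adj(i) = max_{j <= i} (1 - (1 - p(j))^(m - j + 1))`, clipped to
#' \[0, 1\]; the running maximum enforces monotonicity. Marginally sharper
#' than Holm-Bonferroni under independence.
#'
#' @param p Numeric vector of raw p-values in \[0, 1\] (`NA` passed through).
#' @return Adjusted p-values in the input order.
#' @examples
#' holm_sidak(c(0.01, 0.04)) # 0.0199, 0.04
#' @export
holm_sidak <- function(p) {
  out <- rep(NA_real_, length(p))
  ok <- which(!is.na(p))
  if (length(ok) == 0) return(out)
  pv <- p[ok]
  m <- length(pv)
  ord <- order(pv)
  adj <- -expm1((m - seq_len(m) + 1) * log1p(-pv[ord])) # 1 - (1 - p)^(m - j + 1)
  adj <- pmin(1, pmax(0, cummax(adj)))
  out[ok][ord] <- adj
  out
}

#' Compare genotypes within strata
#'
#' Welch two-sample t-tests on log2 values between WT and DE50-MD, overall
#' or within each stratum (combination of metadata columns), with
#' Holm-Sidak correction across strata. The fold change is the ratio of
#' geometric means, reported in both directions.
#'
#' @param values Data frame from [normalize_target()] (columns `sample_id`,
#'   `value`), or a named positive vector.
#' @param meta A [sample_meta()] covering the samples.
#' @param strata Character vector of metadata columns defining strata (e.g.
#'   `c("muscle", "age_months")`), or `NULL` for a single overall test.
#' @return Data frame: one row per testable stratum with `n_wt`, `n_de`,
#'   `log2_fc` (WT minus DE50-MD mean log2), `fc_wt_vs_de`, `fc_de_vs_wt`,
#'   `t`, `df`, `p_raw`, `p_adj`. Strata with < 2 samples in either genotype
#'   are skipped with a warning.
#' @export
compare_groups <- function(values, meta, strata = NULL) {
  if (is.data.frame(values)) {
    v <- stats::setNames(values$value, values$sample_id)
  } else {
    v <- values
  }
  if (any(v <= 0)) stop_mirnorm("values must be positive (linear scale)", class = "mirnorm_domain_error")
  meta <- meta[match(names(v), meta$sample_id), ]
  if (anyNA(meta$sample_id)) {
    stop_mirnorm("values contain samples absent from metadata", class = "mirnorm_alignment_error")
  }
  lv <- log2(v)
  stratum_id <- if (is.null(strata)) rep("overall", length(v)) else {
    bad <- setdiff(strata, names(meta))
    if (length(bad) > 0) stop_mirnorm("unknown strata column(s): ", paste(bad, collapse = ", "),
                                      class = "mirnorm_validation_error")
    do.call(paste, c(lapply(strata, function(s) as.character(meta[[s]])), sep = ":"))
  }
  rows <- list()
  for (s in unique(stratum_id)) {
    in_s <- stratum_id == s
    wt <- lv[in_s & meta$genotype == "WT"]
    de <- lv[in_s & meta$genotype == "DE50MD"]
    if (length(wt) < 2 || length(de) < 2) {
      warning(sprintf("stratum '%s' has < 2 samples in a genotype; skipped", s))
      next
    }
    if (stats::sd(wt) == 0 && stats::sd(de) == 0) {
      tt <- list(statistic = c(t = 0), parameter = c(df = length(wt) + length(de) - 2),
                 p.value = 1)
    } else {
      tt <- stats::t.test(wt, de, var.equal = FALSE)
    }
    dlog2 <- mean(wt) - mean(de)
    rows[[s]] <- data.frame(
      stratum = s, n_wt = length(wt), n_de = length(de),
      log2_fc = dlog2, fc_wt_vs_de = 2^dlog2, fc_de_vs_wt = 2^(-dlog2),
      t = unname(tt$statistic), df = unname(tt$parameter), p_raw = tt$p.value,
      stringsAsFactors = FALSE
    )
  }
  if (length(rows) == 0) {
    stop_mirnorm("no testable strata (need >= 2 samples per genotype)",
                 class = "mirnorm_validation_error")
  }
  out <- do.call(rbind, rows)
  out$p_adj <- holm_sidak(out$p_raw)
  rownames(out) <- NULL
  out
}

#' Validate a held-out reference candidate against a normalisation factor
#'
#' The within-dataset validation device: normalise a weaker candidate by the
#' normalisation factor built from the strongest ones, then ask whether
#' anything biological is left — a genuinely stable candidate should show a
#' genotype fold change near 1 and no significant strata.
#'
#' @param candidate Candidate id, not among `nf$reference_ids`.
#' @param rq An `rq_matrix`.
#' @param nf A [compute_nf()] result.
#' @param meta A [sample_meta()].
#' @param strata Stratification for per-stratum tests (default muscle x age).
#' @return List: `candidate`, `normalized` (per-sample values), `overall`
#'   (single-row comparison) and `by_stratum` (per-stratum comparisons with
#'   Holm-Sidak adjustment).
#' @export
validate_reference <- function(candidate, rq, nf, meta,
                               strata = c("muscle", "age_months")) {
  if (candidate %in% nf$reference_ids) {
    stop_mirnorm("candidate '", candidate, "' is part of the normalisation factor; ",
                 "validate held-out candidates only", class = "mirnorm_misuse_error")
  }
  norm <- normalize_target(rq, candidate, nf)
  list(
    candidate = candidate,
    normalized = norm,
    overall = compare_groups(norm, meta, strata = NULL),
    by_stratum = compare_groups(norm, meta, strata = strata)
  )
}
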