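# BestKeeper operates on calibrated, replicate-aggregated raw Cq values,
# never on relative quantities.

# candidates x samples Cq matrix from an aggregated cq_table; errors on gaps
cq_matrix <- function(cq, candidates = NULL, samples = NULL) {
  candidates <- candidates %||% sort(unique(cq$assay_id))
  samples <- samples %||% unique(cq$sample_id)
  m <- matrix(NA_real_, length(candidates), length(samples),
              dimnames = list(candidates, samples))
  keep <- cq$assay_id %in% candidates & cq$sample_id %in% samples
  m[cbind(cq$assay_id[keep], cq$sample_id[keep])] <- cq$cq[keep]
  if (anyNA(m)) {
    miss <- which(is.na(m), arr.ind = TRUE)
    coords <- paste0("(", candidates[miss[, 1]], ", ", samples[miss[, 2]], ")")
    stop_mirnorm("missing Cq for: ", paste(utils::head(coords, 5), collapse = ", "),
                 class = "mirnorm_validation_error")
  }
  m
}

#' BestKeeper index
#'
#' The per-sample geometric mean of all candidates' Cq values: a
#' whole-panel normalisation factor on the Cq scale. Candidates are then
#' judged by how well they track this index.
#'
#' @param cq Aggregated, calibrated [cq_table()], complete over
#'   `candidates` x its samples, all Cq > 0.
#' @param candidates Candidate assay ids (default: all assays present).
#' @param samples Sample ids (default: all samples present).
#' @return Named per-sample numeric vector (cycles).
#' @export
bestkeeper_index <- function(cq, candidates = NULL, samples = NULL) {
  m <- cq_matrix(cq, candidates, samples)
  if (any(m <= 0)) stop_mirnorm("Cq values must be positive", class = "mirnorm_domain_error")
  apply(m, 2, geomean)
}

#' BestKeeper descriptive and correlation statistics
#'
#' Per candidate: the SD of its Cq across samples (n-1 denominator), the
#' coefficient of variation (100 * SD / mean Cq), and the Pearson
#' correlation r (with two-sided p) between the candidate's Cq and the
#' BestKeeper index. Following the classic tool, the index includes the
#' candidate itself; `leave_one_out = TRUE` correlates each candidate against
#' the index of the remaining candidates instead, which removes the
#' self-correlation bias. Candidates are ranked by descending r (higher r =
#' more stable), ties broken by ascending SD then lexicographically; a
#' zero-variance candidate has undefined r, reported as `NA` with a warning
#' and ranked after all defined candidates.
#'
#' @inheritParams bestkeeper_index
#' @param subset_label Label recorded in the output table.
#' @param leave_one_out Exclude each candidate from its own comparison index.
#' @return List with `table` (a [stability_table()] with extra columns
#'   `sd_cq`, `cv_pct`, `p`) and `index` (the per-sample index).
#' @export
bestkeeper_stats <- function(cq, candidates = NULL, samples = NULL,
                             subset_label = "all", leave_one_out = FALSE) {
  m <- cq_matrix(cq, candidates, samples)
  if (ncol(m) < 3) stop_mirnorm("BestKeeper correlation needs >= 3 samples",
                                class = "mirnorm_insufficient_data_error")
  index <- apply(m, 2, geomean)
  k <- nrow(m)
  res <- lapply(seq_len(k), function(i) {
    x <- m[i, ]
    idx <- if (leave_one_out) apply(m[-i, , drop = FALSE], 2, geomean) else index
    if (stats::sd(x) < .Machine$double.eps^0.5) {
      warning(sprintf("candidate %s has zero Cq variance; r undefined", rownames(m)[i]))
      r <- NA_real_; p <- NA_real_
    } else {
      ct <- stats::cor.test(x, idx, method = "pearson", alternative = "two.sided")
      r <- unname(ct$estimate); p <- ct$p.value
    }
    data.frame(candidate_id = rownames(m)[i], score = r,
               sd_cq = stats::sd(x), cv_pct = 100 * stats::sd(x) / mean(x), p = p,
               stringsAsFactors = FALSE)
  })
  entries <- do.call(rbind, res)
  ord <- order(is.na(entries$score), -ifelse(is.na(entries$score), -Inf, entries$score),
               entries$sd_cq, entries$candidate_id)
  entries <- entries[ord, ]
  entries$rank <- seq_len(nrow(entries))
  list(table = stability_table("bestkeeper", subset_label, entries), index = index)
}
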