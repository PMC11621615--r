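#' geNorm pairwise variation between two candidates
#'
#' The standard deviation (n-1 denominator) of the log2 ratio of two
#' candidates' relative quantities across samples. Two candidates that are
#' co-regulated (constant ratio) have pairwise variation 0 regardless of how
#' much each varies on its own; this is the building block of the geNorm M
#' value.
#'
#' @param rq_j,rq_k Strictly positive RQ vectors of equal length >= 2.
#' @return Nonnegative pairwise variation (log2 cycles).
#' @export
pairwise_variation <- function(rq_j, rq_k) {
  if (length(rq_j) != length(rq_k) || length(rq_j) < 2) {
    stop_mirnorm("pairwise variation needs two equal-length vectors of >= 2 samples",
                 class = "mirnorm_insufficient_data_error")
  }
  if (any(rq_j <= 0) || any(rq_k <= 0)) {
    stop_mirnorm("relative quantities must be strictly positive", class = "mirnorm_domain_error")
  }
  stats::sd(log2(rq_j / rq_k))
}

#' geNorm M values for a candidate panel
#'
#' `M_j` is the arithmetic mean of `pairwise_variation(j, k)` over all other
#' candidates `k`; low M means the candidate tracks the rest of the panel.
#' With only two candidates M degenerates to the single pairwise variation
#' (returned with a warning).
#'
#' @param rq An `rq_matrix`.
#' @param candidates Candidate ids to score (default: all).
#' @return Named numeric vector of M values.
#' @export
m_values <- function(rq, candidates = NULL) {
  candidates <- candidates %||% rq$candidate_ids
  m <- rq$rq[candidates, , drop = FALSE]
  k <- nrow(m)
  if (k < 2) stop_mirnorm("geNorm M needs >= 2 candidates", class = "mirnorm_insufficient_panel_error")
  if (k == 2) warning("M with 2 candidates equals the single pairwise variation")
  lm2 <- log2(m)
  # V_jk = sd(lm2[j,] - lm2[k,]); mean over k != j
  out <- vapply(seq_len(k), function(j) {
    v <- vapply(seq_len(k)[-j], function(kk) stats::sd(lm2[j, ] - lm2[kk, ]), numeric(1))
    mean(v)
  }, numeric(1))
  names(out) <- candidates
  out
}

#' geNorm iterative stability ranking
#'
#' Repeatedly removes the candidate with the highest M (least stable) and
#' recomputes M on the remaining panel until two candidates are left; those
#' two vary in the most correlated fashion and constitute the best pair.
#' Ties at removal are broken lexicographically by candidate id so the
#' ranking is deterministic. The final pair is a tie by construction
#' (their 2-panel M values are equal) and is serialised as ranks 1 and 2 in
#' lexicographic order.
#'
#' @param rq An `rq_matrix` with >= 3 candidates.
#' @param subset_label Label recorded in the output table.
#' @return List with `table` (a [stability_table()] whose score is each
#'   candidate's M at its removal step; final pair: M in the 2-panel) and
#'   `trace` (a `genorm_trace`: `exclusion_order`, `m_at_removal`,
#'   `final_pair`).
#' @export
genorm_rank <- function(rq, subset_label = "all") {
  k <- length(rq$candidate_ids)
  if (k < 3) stop_mirnorm("geNorm ranking needs >= 3 candidates",
                          class = "mirnorm_insufficient_panel_error")
  remaining <- rq$candidate_ids
  exclusion_order <- character(0)
  m_at_removal <- numeric(0)
  score <- stats::setNames(numeric(k), rq$candidate_ids)
  while (length(remaining) > 2) {
    m <- m_values(rq, remaining)
    worst_value <- max(m)
    worst <- min(names(m)[abs(m - worst_value) < 1e-12])  # lexicographic tie-break
    exclusion_order <- c(exclusion_order, worst)
    m_at_removal <- c(m_at_removal, m[[worst]])
    score[worst] <- m[[worst]]
    remaining <- setdiff(remaining, worst)
  }
  final_pair <- sort(remaining)
  final_m <- suppressWarnings(m_values(rq, final_pair))
  score[final_pair] <- final_m[final_pair]
  ranks <- stats::setNames(integer(k), rq$candidate_ids)
  ranks[final_pair] <- c(1L, 2L)
  ranks[rev(exclusion_order)] <- seq(3L, k)
  entries <- data.frame(
    candidate_id = names(ranks),
    score = unname(score[names(ranks)]),
    rank = unname(ranks),
    stringsAsFactors = FALSE
  )
  trace <- structure(
    list(exclusion_order = exclusion_order, m_at_removal = unname(m_at_removal),
         final_pair = final_pair, pairwise_v = NULL),
    class = "genorm_trace"
  )
  list(table = stability_table("genorm", subset_label, entries), trace = trace)
}

#' geNorm V(n/n+1) pairwise variation between successive normalisation factors
#'
#' For deciding how many reference genes to use: `NF_n` is the per-sample
#' geometric mean RQ of the `n` top-ranked candidates, and `V(n/n+1)` is the
#' SD across samples of `log2(NF_n / NF_{n+1})`. Small V means adding the
#' (n+1)-th candidate hardly changes the normalisation factor.
#'
#' @param rq The `rq_matrix` the ranking was computed on.
#' @param trace A `genorm_trace` from [genorm_rank()].
#' @param n_max Largest n to evaluate (default all, i.e. k - 1).
#' @return Data frame with columns `n` and `v`.
#' @export
pairwise_v <- function(rq, trace, n_max = NULL) {
  ranked <- c(trace$final_pair, rev(trace$exclusion_order))
  k <- length(ranked)
  n_max <- n_max %||% (k - 1)
  if (n_max < 2 || n_max > k - 1) {
    stop_mirnorm("n out of range: need 2 <= n < number of candidates",
                 class = "mirnorm_validation_error")
  }
  lm2 <- log2(rq$rq[ranked, , drop = FALSE])
  nf_log <- function(n) colMeans(lm2[seq_len(n), , drop = FALSE])  # log2 geometric mean
  data.frame(
    n = 2:n_max,
    v = vapply(2:n_max, function(n) stats::sd(nf_log(n) - nf_log(n + 1)), numeric(1))
  )
}
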