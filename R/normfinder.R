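# NormFinder-style model-based stability on log relative quantities.
#
# Ungrouped model: y_ij = alpha_i + beta_j + eps_ij for candidate i, sample j,
# with var(eps_ij) = sigma_i^2. Two-way residuals confound the candidate
# variances (removing the sample mean mixes every candidate's noise into each
# residual), so the naive per-candidate residual variances s_i^2 are
# deconvolved through their expectation
#   E[s_i^2] = ((k-1)/k)^2 sigma_i^2 + (1/k^2) sum_{i' != i} sigma_{i'}^2,
# which inverts in closed form to
#   sigma_i^2 = (k/(k-2)) * (s_i^2 - S / (k (k-1))),  S = sum_i s_i^2.
# Grouped model adds a candidate x group interaction d_ig (the systematic
# intergroup bias of candidate i) which is shrunk toward 0 by an
# empirical-Bayes factor before entering the stability value.

#' NormFinder ungrouped stability
#'
#' @param logq Log relative-quantity matrix (candidates x samples, complete),
#'   k >= 3 candidates and n >= 3 samples.
#' @param subset_label Label recorded in the output table.
#' @return List with `table` (a [stability_table()], score = stability,
#'   ascending rank), `sigma2` (named candidate variance estimates, floored
#'   at 0) and `s2` (raw residual variances).
#' @export
normfinder_ungrouped <- function(logq, subset_label = "all") {
  logq <- as.matrix(logq)
  k <- nrow(logq); n <- ncol(logq)
  if (k < 3) stop_mirnorm("NormFinder needs >= 3 candidates (variance deconvolution is undefined for k < 3)",
                          class = "mirnorm_insufficient_panel_error")
  if (n < 3) stop_mirnorm("NormFinder needs >= 3 samples", class = "mirnorm_insufficient_data_error")
  r <- sweep(sweep(logq, 1, rowMeans(logq)), 2, colMeans(logq)) + mean(logq)
  s2 <- rowSums(r^2) / (n - 1)
  sigma2 <- (k / (k - 2)) * (s2 - sum(s2) / (k * (k - 1)))
  floored <- sigma2 < 0
  if (any(floored)) {
    message(sprintf("normfinder: floored %d negative variance estimate(s) at 0", sum(floored)))
    sigma2[floored] <- 0
  }
  stability <- sqrt(sigma2)
  ord <- order(stability, rownames(logq))
  entries <- data.frame(
    candidate_id = rownames(logq)[ord],
    score = unname(stability[ord]),
    rank = seq_len(k),
    stringsAsFactors = FALSE
  )
  structure(
    list(table = stability_table("normfinder", subset_label, entries),
         stability = stability, sigma2 = sigma2, s2 = s2, grouping = NULL),
    class = "normfinder_result"
  )
}

#' NormFinder grouped stability
#'
#' Decomposes each candidate's variation into intragroup noise and a
#' systematic intergroup difference. For group g: `sigma2_ig` is the
#' ungrouped estimator restricted to the group's samples;
#' `d_ig = (ybar_ig - ybar_i.) - (ybar_.g - ybar_..)` is candidate i's
#' centred group offset (summing to 0 over candidates within each group);
#' the between-candidate spread of true offsets is estimated as
#' `gamma2 = max(0, mean(d_ig^2) - mean(sigma2_ig / n_g))` and each observed
#' offset is shrunk by `gamma2 / (gamma2 + sigma2_ig / n_g)`. The stability
#' value averages `|d~_ig| + sqrt(sigma2_ig / n_g)` over groups; candidates
#' that are both quiet within groups and unbiased between groups score low.
#'
#' @inheritParams normfinder_ungrouped
#' @param groups Named character vector or factor mapping each sample
#'   (column of `logq`) to its group; >= 2 groups of >= 2 samples each.
#' @return A `normfinder_result` as in [normfinder_ungrouped()], plus
#'   `d` and `d_shrunk` (candidate x group matrices), `sigma2_group`,
#'   `gamma2` and the grouping.
#' @export
normfinder_grouped <- function(logq, groups, subset_label = "all") {
  logq <- as.matrix(logq)
  k <- nrow(logq)
  if (k < 3) stop_mirnorm("NormFinder needs >= 3 candidates", class = "mirnorm_insufficient_panel_error")
  groups <- groups[colnames(logq)]
  if (anyNA(groups)) stop_mirnorm("every sample needs a group label", class = "mirnorm_grouping_error")
  groups <- factor(as.character(groups))
  sizes <- table(groups)
  if (length(sizes) < 2) stop_mirnorm("grouped analysis needs >= 2 groups", class = "mirnorm_grouping_error")
  if (any(sizes < 2)) {
    stop_mirnorm("group(s) with < 2 samples: ",
                 paste(names(sizes)[sizes < 2], collapse = ", "), class = "mirnorm_grouping_error")
  }
  glabels <- levels(groups)
  G <- length(glabels)
  # intragroup variances via the ungrouped estimator within each group
  sigma2_g <- sapply(glabels, function(g) {
    sub <- logq[, groups == g, drop = FALSE]
    n_g <- ncol(sub)
    r <- sweep(sweep(sub, 1, rowMeans(sub)), 2, colMeans(sub)) + mean(sub)
    s2 <- rowSums(r^2) / (n_g - 1)
    pmax((k / (k - 2)) * (s2 - sum(s2) / (k * (k - 1))), 0)
  })
  n_g <- as.numeric(sizes[glabels])
  # centred intergroup differences
  ybar_ig <- sapply(glabels, function(g) rowMeans(logq[, groups == g, drop = FALSE]))
  d <- sweep(ybar_ig, 1, rowMeans(logq)) # ybar_ig - ybar_i.
  d <- sweep(d, 2, colMeans(ybar_ig) - mean(logq)) # - (ybar_.g - ybar_..)
  var_of_mean <- sweep(sigma2_g, 2, n_g, `/`)
  gamma2 <- max(0, mean(d^2) - mean(var_of_mean))
  d_shrunk <- d * gamma2 / (gamma2 + var_of_mean)
  d_shrunk[!is.finite(d_shrunk)] <- 0  # gamma2 and noise both zero: nothing to shrink
  stability <- rowMeans(abs(d_shrunk) + sqrt(var_of_mean))
  ord <- order(stability, rownames(logq))
  entries <- data.frame(
    candidate_id = rownames(logq)[ord],
    score = unname(stability[ord]),
    rank = seq_len(k),
    stringsAsFactors = FALSE
  )
  structure(
    list(table = stability_table("normfinder", subset_label, entries),
         stability = stability, sigma2_group = sigma2_g, d = d,
         d_shrunk = d_shrunk, gamma2 = gamma2,
         grouping = stats::setNames(as.character(groups), colnames(logq))),
    class = "normfinder_result"
  )
}

#' @export
print.normfinder_result <- function(x, ...) {
  cat(sprintf("<normfinder_result> %s\n",
              if (is.null(x$grouping)) "ungrouped" else
                sprintf("grouped (%d groups)", length(unique(x$grouping)))))
  print(x$table)
  invisible(x)
}

#' Standard grouping schemes for grouped NormFinder
#'
#' The four groupings used for grouped analysis of the study design:
#' individual animal (dog id), genotype (WT vs DE50-MD), muscle type, and
#' age. Groupings that would leave fewer than two groups among the supplied
#' samples are rejected at analysis time, not here.
#'
#' @param meta A [sample_meta()].
#' @return Named list of named character vectors (sample id -> group label).
#' @export
grouping_schemes <- function(meta) {
  ids <- meta$sample_id
  list(
    animal = stats::setNames(meta$dog_id, ids),
    genotype = stats::setNames(as.character(meta$genotype), ids),
    muscle = stats::setNames(as.character(meta$muscle), ids),
    age = stats::setNames(as.character(meta$age_months), ids)
  )
}
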