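#' Interplate calibration with a dedicated calibrator assay
#'
#' Screening panels carry an interplate calibrator (IPC): a common reaction
#' run on every plate whose Cq should be identical across plates, so any
#' between-plate difference in its mean Cq measures the plate's systematic
#' offset. Each plate's offset is its IPC mean minus the mean of per-plate
#' IPC means (pooled-mean anchor: symmetric and order-independent, rather
#' than privileging one plate), and the offset is subtracted from every
#' numeric Cq on that plate. Undetected entries are unchanged.
#'
#' @param cq A [cq_table()].
#' @param ipc_assay Assay id of the interplate calibrator.
#' @return A list with `cq` (the calibrated [cq_table()]) and `calibration`,
#'   a `calibration_result` with per-plate offsets in cycles.
#' @export
calibrate_ipc <- function(cq, ipc_assay) {
  plates <- unique(cq$plate_id)
  ipc <- cq[cq$assay_id == ipc_assay & !is.na(cq$cq), ]
  missing_plates <- setdiff(plates, unique(ipc$plate_id))
  if (length(missing_plates) > 0) {
    stop_mirnorm("plate(s) lacking numeric IPC wells: ",
                 paste(missing_plates, collapse = ", "), class = "mirnorm_calibration_error")
  }
  plate_means <- stats::setNames(as.vector(tapply(ipc$cq, ipc$plate_id, mean)[plates]), plates)
  offsets <- plate_means - mean(plate_means)
  out <- cq
  numeric_rows <- !is.na(out$cq)
  out$cq[numeric_rows] <- out$cq[numeric_rows] - offsets[out$plate_id[numeric_rows]]
  list(
    cq = cq_table(out),
    calibration = structure(
      list(plate_offsets = offsets, method = "ipc", reference_plate = "pooled_mean"),
      class = "calibration_result"
    )
  )
}

#' Interplate calibration via assays shared with a calibration plate
#'
#' Individual-assay workflows align plates by re-measuring a subset of
#' (assay, sample) reactions on a single dedicated calibration plate: for
#' each original plate, the mean difference between its Cq values and the
#' calibration plate's Cq values over the shared pairs is that plate's
#' offset, which is subtracted from all its numeric Cq. Offsets are anchored
#' to the calibration plate, so a plate that agrees with it perfectly gets
#' offset 0.
#'
#' @param cq Original [cq_table()] to calibrate.
#' @param calib [cq_table()] measured on the calibration plate.
#' @param shared_assays Assay ids re-measured on the calibration plate.
#' @return As [calibrate_ipc()]; `reference_plate` names the calibration plate.
#' @export
calibrate_common_assays <- function(cq, calib, shared_assays) {
  calib_agg <- stats::aggregate(cq ~ assay_id + sample_id,
                                data = calib[calib$assay_id %in% shared_assays, ],
                                FUN = mean, na.action = stats::na.omit)
  calib_key <- paste(calib_agg$assay_id, calib_agg$sample_id, sep = "\r")
  plates <- unique(cq$plate_id)
  offsets <- vapply(plates, function(p) {
    on_plate <- cq[cq$plate_id == p & cq$assay_id %in% shared_assays & !is.na(cq$cq), ]
    if (nrow(on_plate) == 0) return(NA_real_)
    orig_agg <- stats::aggregate(cq ~ assay_id + sample_id, data = on_plate, FUN = mean)
    idx <- match(paste(orig_agg$assay_id, orig_agg$sample_id, sep = "\r"), calib_key)
    keep <- !is.na(idx)
    if (!any(keep)) return(NA_real_)
    mean(orig_agg$cq[keep] - calib_agg$cq[idx[keep]])
  }, numeric(1))
  if (anyNA(offsets)) {
    stop_mirnorm("no overlapping (assay, sample) pairs with the calibration plate for plate(s): ",
                 paste(plates[is.na(offsets)], collapse = ", "),
                 class = "mirnorm_calibration_error")
  }
  names(offsets) <- plates
  out <- cq
  numeric_rows <- !is.na(out$cq)
  out$cq[numeric_rows] <- out$cq[numeric_rows] - offsets[out$plate_id[numeric_rows]]
  list(
    cq = cq_table(out),
    calibration = structure(
      list(plate_offsets = offsets, method = "common_assays",
           reference_plate = paste(unique(calib$plate_id), collapse = "+")),
      class = "calibration_result"
    )
  )
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf("<calibration_result> method=%s, anchor=%s\n", x$method, x$reference_plate))
  print(round(x$plate_offsets, 4))
  invisible(x)
}

#' Collapse replicate wells to one Cq per assay x sample
#'
#' Numeric replicates are averaged; a pair that is entirely undetected stays
#' undetected. Replicate disagreement beyond `max_spread` cycles is a QC
#' flag only (recorded in the `qc_flags` attribute and messaged), not an
#' exclusion: no replicate-agreement cutoff is applied.
#'
#' @param cq A [cq_table()].
#' @param max_spread Replicate range (cycles) above which a pair is flagged.
#' @return A [cq_table()] with one record per (assay, sample),
#'   `replicate = 1`, and attribute `qc_flags` (data frame of flagged pairs).
#' @export
aggregate_replicates <- function(cq, max_spread = 1.0) {
  key <- paste(cq$assay_id, cq$sample_id, sep = "\r")
  groups <- split(seq_len(nrow(cq)), key)
  rows <- lapply(groups, function(idx) {
    vals <- cq$cq[idx]
    numeric_vals <- vals[!is.na(vals)]
    spread <- if (length(numeric_vals) >= 2) diff(range(numeric_vals)) else 0
    data.frame(
      assay_id = cq$assay_id[idx[1]],
      sample_id = cq$sample_id[idx[1]],
      plate_id = cq$plate_id[idx[1]],
      replicate = 1L,
      cq = if (length(numeric_vals) == 0) NA_real_ else mean(numeric_vals),
      spread = spread,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$assay_id, out$sample_id), ]
  flagged <- out[out$spread > max_spread, c("assay_id", "sample_id", "spread")]
  rownames(flagged) <- NULL
  if (nrow(flagged) > 0) {
    message(sprintf("aggregate_replicates: %d (assay, sample) pair(s) exceed replicate spread of %.2f cycles",
                    nrow(flagged), max_spread))
  }
  out$spread <- NULL
  result <- cq_table(out)
  attr(result, "qc_flags") <- flagged
  result
}

#' Drop assays expressed near or below the detection limit
#'
#' An assay is excluded only when both hold over its (aggregated) samples:
#' every numeric Cq exceeds `cq_max`, and at least `min_undetected` samples
#' are undetected. Requiring both distinguishes genuinely absent transcripts
#' from merely low-abundance ones, which remain usable candidates.
#'
#' @param cq Aggregated [cq_table()] (one record per assay x sample).
#' @param cq_max Cq threshold; all numeric Cq must exceed it to drop.
#' @param min_undetected Minimum undetected samples required to drop.
#' @return A `filter_report` list: `kept` (assay ids) and `dropped`
#'   (data frame of assay id + reason).
#' @export
filter_low_expression <- function(cq, cq_max = 32, min_undetected = 1L) {
  assays <- sort(unique(cq$assay_id))
  dropped <- list()
  kept <- character(0)
  for (a in assays) {
    vals <- cq$cq[cq$assay_id == a]
    n_undet <- sum(is.na(vals))
    numeric_vals <- vals[!is.na(vals)]
    if (all(numeric_vals > cq_max) && n_undet >= min_undetected) {
      dropped[[a]] <- data.frame(
        assay_id = a,
        reason = sprintf("all %d detected Cq > %g and %d sample(s) undetected",
                         length(numeric_vals), cq_max, n_undet),
        stringsAsFactors = FALSE
      )
    } else {
      kept <- c(kept, a)
    }
  }
  dropped <- if (length(dropped) > 0) do.call(rbind, dropped) else
    data.frame(assay_id = character(0), reason = character(0), stringsAsFactors = FALSE)
  rownames(dropped) <- NULL
  structure(list(kept = kept, dropped = dropped), class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("<filter_report> kept %d assay(s), dropped %d\n",
              length(x$kept), nrow(x$dropped)))
  if (nrow(x$dropped) > 0) print(x$dropped)
  invisible(x)
}

#' Convert Cq values to relative quantities
#'
#' Relative quantity on the linear scale: `RQ = E^(minCq - Cq)`, anchored so
#' each assay's lowest Cq (most abundant sample) has RQ 1. `E` is the
#' per-cycle amplification efficiency (2 = perfect doubling); with `E = 2`,
#' `log2(RQ)` is exactly `minCq - Cq` (the delta-Cq identity). Undetected
#' entries are handled per `missing_policy`: `"error"` (reference candidates
#' should be complete after filtering), `"impute_lod"` (targets may
#' legitimately drop out; impute at the limit-of-detection Cq), or
#' `"drop_sample"`.
#'
#' @param cq Aggregated, calibrated [cq_table()].
#' @param efficiency Amplification efficiency: scalar, or named vector with
#'   per-assay overrides (values in \[1.6, 2.2\]).
#' @param missing_policy `"error"`, `"impute_lod"` or `"drop_sample"`.
#' @param lod_cq Limit-of-detection Cq used by `"impute_lod"`.
#' @return An `rq_matrix`: list with `rq` (candidate x sample matrix),
#'   `efficiency` (named per-assay vector) and id vectors.
#' @export
cq_to_rq <- function(cq, efficiency = 2.0,
                     missing_policy = c("error", "impute_lod", "drop_sample"),
                     lod_cq = 35) {
  missing_policy <- match.arg(missing_policy)
  assays <- unique(cq$assay_id)
  samples <- unique(cq$sample_id)
  m <- matrix(NA_real_, length(assays), length(samples), dimnames = list(assays, samples))
  m[cbind(cq$assay_id, cq$sample_id)] <- cq$cq
  if (anyNA(m)) {
    miss <- which(is.na(m), arr.ind = TRUE)
    if (missing_policy == "error") {
      coords <- paste0("(", assays[miss[, 1]], ", ", samples[miss[, 2]], ")")
      stop_mirnorm("undetected/missing Cq with missing_policy = 'error': ",
                   paste(utils::head(coords, 5), collapse = ", "),
                   if (nrow(miss) > 5) sprintf(" and %d more", nrow(miss) - 5) else "",
                   class = "mirnorm_conversion_error")
    } else if (missing_policy == "impute_lod") {
      m[is.na(m)] <- lod_cq
      message(sprintf("cq_to_rq: imputed %d undetected entries at LOD Cq = %g", nrow(miss), lod_cq))
    } else {
      bad_samples <- unique(samples[miss[, 2]])
      m <- m[, !(samples %in% bad_samples), drop = FALSE]
      samples <- setdiff(samples, bad_samples)
      message(sprintf("cq_to_rq: dropped %d sample(s) with undetected entries", length(bad_samples)))
      if (length(samples) == 0) {
        stop_mirnorm("all samples dropped by missing_policy = 'drop_sample'",
                     class = "mirnorm_conversion_error")
      }
    }
  }
  eff <- rep(2.0, length(assays))
  names(eff) <- assays
  if (is.null(names(efficiency))) {
    eff[] <- efficiency
  } else {
    if ("default" %in% names(efficiency)) eff[] <- efficiency[["default"]]
    known <- intersect(names(efficiency), assays)
    eff[known] <- efficiency[known]
  }
  if (any(eff < 1.6 | eff > 2.2)) {
    stop_mirnorm("amplification efficiency outside [1.6, 2.2]", class = "mirnorm_validation_error")
  }
  rq <- eff ^ (apply(m, 1, min) - m)  # column-recycled over rows: E_i^(minCq_i - Cq_is)
  rq_matrix(rq, efficiency = eff)
}

#' Construct an rq_matrix
#'
#' @param rq Candidate x sample matrix of positive relative quantities with
#'   dimnames; each row anchored so its maximum is 1.
#' @param efficiency Named per-assay efficiency vector.
#' @return An `rq_matrix`.
#' @export
rq_matrix <- function(rq, efficiency = NULL) {
  stopifnot(is.matrix(rq), !is.null(rownames(rq)), !is.null(colnames(rq)))
  if (anyNA(rq) || any(rq <= 0)) {
    stop_mirnorm("relative quantities must be positive and complete",
                 class = "mirnorm_validation_error")
  }
  if (is.null(efficiency)) {
    efficiency <- stats::setNames(rep(2.0, nrow(rq)), rownames(rq))
  }
  structure(
    list(rq = rq, efficiency = efficiency,
         candidate_ids = rownames(rq), sample_ids = colnames(rq)),
    class = "rq_matrix"
  )
}

#' @export
print.rq_matrix <- function(x, ...) {
  cat(sprintf("<rq_matrix> %d candidates x %d samples\n",
              length(x$candidate_ids), length(x$sample_ids)))
  invisible(x)
}

#' Subset an rq_matrix by candidates and/or samples
#'
#' @param x An `rq_matrix`.
#' @param candidates,samples Ids to keep (default all).
#' @return An `rq_matrix` restricted to the requested rows/columns, with each
#'   remaining row re-anchored to maximum 1.
#' @export
subset_rq <- function(x, candidates = NULL, samples = NULL) {
  candidates <- candidates %||% x$candidate_ids
  samples <- samples %||% x$sample_ids
  unknown <- c(setdiff(candidates, x$candidate_ids), setdiff(samples, x$sample_ids))
  if (length(unknown) > 0) {
    stop_mirnorm("unknown id(s) in subset: ", paste(unknown, collapse = ", "),
                 class = "mirnorm_validation_error")
  }
  m <- x$rq[candidates, samples, drop = FALSE]
  m <- m / apply(m, 1, max)  # re-anchor after dropping samples
  rq_matrix(m, efficiency = x$efficiency[candidates])
}

#' Elementwise logarithm of relative quantities
#'
#' NormFinder operates on log relative quantities; log base 2 matches one
#' PCR cycle at perfect efficiency.
#'
#' @param rq An `rq_matrix` or positive matrix.
#' @param base 2 (default), 10, or `exp(1)`.
#' @return Matrix of logged RQs; each anchored row has maximum 0.
#' @export
log_rq <- function(rq, base = 2) {
  m <- if (inherits(rq, "rq_matrix")) rq$rq else rq
  if (anyNA(m) || any(m <= 0)) {
    stop_mirnorm("log_rq requires strictly positive, complete quantities",
                 class = "mirnorm_domain_error")
  }
  log(m, base = base)
}
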