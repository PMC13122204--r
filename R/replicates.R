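#' Summarize a group of technical qPCR replicates with outlier screening
#'
#' Collapses the raw quantification-cycle (Cq) values of one sample/assay
#' replicate group into a mean and standard error after a single-pass outlier
#' screen: the screening mean is taken over all non-missing raw values, and
#' any replicate whose Cq differs from that mean by strictly more than
#' `outlier_threshold` cycles is discarded. Mean and SEM are then recomputed
#' over the surviving replicates only.
#'
#' Missing Cq values (instrument "Undetermined") are dropped before
#' screening; they are treated as absent replicates, never as the terminal
#' cycle. A deviation of exactly `outlier_threshold` is kept. When a single
#' replicate survives the SEM is reported as 0 but the group is flagged
#' `low_confidence`, and downstream calling treats such samples as needing a
#' repeat run.
#'
#' @param raw_cqs Numeric vector of raw Cq values; `NA` marks an undetermined
#'   well.
#' @param outlier_threshold Maximum allowed absolute deviation (cycles) from
#'   the screening mean; default 1 cycle.
#' @param max_cycles Largest valid Cq; values outside `(0, max_cycles]` are
#'   rejected. Default 45, the usual total cycle count of the protocol.
#' @param sample_id,target_role Optional identifiers carried through to the
#'   result for bookkeeping. `target_role`, when given, must be `"autosome"`
#'   or `"sex"`.
#' @return An object of class `"replicate_group"`: a list with `sample_id`,
#'   `target_role`, `raw_cqs`, `kept_cqs`, `mean_cq`, `sem_cq`,
#'   `n_discarded`, `n_kept`, and `low_confidence`.
#' @examples
#' summarize_replicates(c(20.0, 20.1, 19.9, 22.0))  # 22.0 discarded
#' @export
summarize_replicates <- function(raw_cqs, outlier_threshold = 1.0,
                                 max_cycles = 45,
                                 sample_id = NA_character_,
                                 target_role = NA_character_) {
  if (!is.numeric(raw_cqs)) stop("'raw_cqs' must be numeric")
  if (!is.na(target_role)) target_role <- match.arg(target_role, c("autosome", "sex"))
  vals <- raw_cqs[!is.na(raw_cqs)]
  if (length(vals) == 0L) {
    stop("no usable replicates: all Cq values are missing for sample '",
         sample_id, "' (", target_role, ")")
  }
  bad <- !is.finite(vals) | vals <= 0 | vals > max_cycles
  if (any(bad)) {
    stop("Cq values outside (0, ", max_cycles, "]: ",
         paste(vals[bad], collapse = ", "))
  }
  screen_mean <- mean(vals)
  keep <- abs(vals - screen_mean) <= outlier_threshold
  kept <- vals[keep]
  # a screen that removes everything would leave the group unusable; keep the
  # value closest to the screening mean so a call can still be flagged
  if (length(kept) == 0L) {
    kept <- vals[which.min(abs(vals - screen_mean))]
    keep <- seq_along(vals) == which.min(abs(vals - screen_mean))
  }
  n_kept <- length(kept)
  structure(list(
    sample_id = sample_id,
    target_role = target_role,
    raw_cqs = raw_cqs,
    kept_cqs = kept,
    mean_cq = mean(kept),
    sem_cq = if (n_kept > 1L) stats::sd(kept) / sqrt(n_kept) else 0,
    n_discarded = length(vals) - n_kept,
    n_kept = n_kept,
    low_confidence = n_kept < 2L
  ), class = "replicate_group")
}

#' Within-sample dosage difference between autosome and sex-chromosome assays
#'
#' Computes the sample's delta-Cq, defined as mean Cq of the autosome assay
#' minus mean Cq of the sex-chromosome assay, together with the combined
#' standard error. Because both assays share the same template extract, the
#' subtraction cancels input DNA amount, leaving only the relative copy
#' number of the two loci. The combined SEM is the arithmetic sum of the two
#' per-assay SEMs.
#'
#' @param auto_group,sex_group `"replicate_group"` objects for the autosome
#'   and sex-chromosome assays of the same sample.
#' @return List with `sample_id`, `delta_cq`, `sem_total`, and
#'   `low_confidence` (true when either group has fewer than two surviving
#'   replicates).
#' @export
compute_delta_cq <- function(auto_group, sex_group) {
  stopifnot(inherits(auto_group, "replicate_group"),
            inherits(sex_group, "replicate_group"))
  ida <- auto_group$sample_id
  ids <- sex_group$sample_id
  if (!is.na(ida) && !is.na(ids) && ida != ids) {
    stop("replicate groups belong to different samples: '", ida, "' vs '", ids, "'")
  }
  list(
    sample_id = if (!is.na(ida)) ida else ids,
    delta_cq = auto_group$mean_cq - sex_group$mean_cq,
    sem_total = auto_group$sem_cq + sex_group$sem_cq,
    low_confidence = auto_group$low_confidence || sex_group$low_confidence
  )
}
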