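#' Optimal two-cluster split of one-dimensional dosage values
#'
#' Partitions delta-Cq values into two clusters by exhaustive search over all
#' split points of the sorted values, minimizing the within-cluster sum of
#' squares (the exact 1-D two-means solution, whose optimum is always a
#' contiguous split of the sorted data). The cluster with the greater median
#' is labelled male, reflecting the ZZ/Z0 dosage model in which males carry
#' two copies of the Z-linked target and so show the larger
#' Cq(autosome) - Cq(sex) difference.
#'
#' Ties between splits with equal within-cluster sum of squares are broken
#' toward the larger inter-cluster gap. When the gap between the two clusters
#' falls below `min_gap` the partition is flagged unimodal: the batch may
#' contain only one sex, and normalization should then use a male standard
#' rather than the cluster median.
#'
#' @param delta_cqs Numeric vector of per-sample delta-Cq values (length >= 2).
#' @param ids Sample identifiers; defaults to names of `delta_cqs` or indices.
#' @param min_gap Inter-cluster gap (cycles) below which the split is flagged
#'   unimodal; default 0.3.
#' @return List with `male_ids`, `female_ids` (ids of the higher and lower
#'   cluster), `male_median`, `female_median`, `gap` (distance between the
#'   nearest members of opposite clusters), `median_distance`, `wss`, and
#'   `unimodal`.
#' @export
split_two_clusters <- function(delta_cqs, ids = NULL, min_gap = 0.3) {
  x <- as.numeric(delta_cqs)
  n <- length(x)
  if (n < 2L) {
    stop("need at least 2 samples to split into clusters; ",
         "supply a male standard for single-sample batches")
  }
  if (anyNA(x)) stop("delta_cqs must not contain NA")
  if (is.null(ids)) ids <- if (!is.null(names(delta_cqs))) names(delta_cqs) else as.character(seq_len(n))
  ord <- order(x)
  xs <- x[ord]
  best_k <- 1L
  best_wss <- Inf
  best_gap <- -Inf
  for (k in seq_len(n - 1L)) {
    lo <- xs[seq_len(k)]
    hi <- xs[(k + 1L):n]
    wss <- sum((lo - mean(lo))^2) + sum((hi - mean(hi))^2)
    gap <- xs[k + 1L] - xs[k]
    if (wss < best_wss - 1e-12 ||
        (abs(wss - best_wss) <= 1e-12 && gap > best_gap)) {
      best_wss <- wss
      best_k <- k
      best_gap <- gap
    }
  }
  lo_idx <- ord[seq_len(best_k)]
  hi_idx <- ord[(best_k + 1L):n]
  list(
    male_ids = ids[hi_idx],
    female_ids = ids[lo_idx],
    male_median = stats::median(x[hi_idx]),
    female_median = stats::median(x[lo_idx]),
    gap = best_gap,
    median_distance = stats::median(x[hi_idx]) - stats::median(x[lo_idx]),
    wss = best_wss,
    unimodal = best_gap < min_gap
  )
}

#' Normalize delta-Cq values to a male reference
#'
#' Converts delta-Cq to delta-delta-Cq by subtracting a male reference: either
#' the median of the male (greater delta-Cq) cluster found by
#' [split_two_clusters()], or the measured value of a known-male standard run
#' in the same batch. Under the cluster-median reference the male cluster
#' median maps exactly to 0, so ZZ samples sit near 0 and Z0 samples near -1.
#'
#' @param delta_cqs Named or plain numeric vector of delta-Cq values.
#' @param reference Either the string `"cluster_median"` (default) or a single
#'   numeric male-standard delta-Cq value.
#' @param min_gap Passed to [split_two_clusters()] when clustering is used.
#' @return List with `ddcq` (numeric vector, same order/names as input),
#'   `reference_value`, `reference_used` (`"cluster_median"` or
#'   `"male_standard"`), and `clusters` (the split object, or `NULL` when a
#'   standard was supplied).
#' @export
normalize_ddcq <- function(delta_cqs, reference = "cluster_median", min_gap = 0.3) {
  if (is.numeric(reference)) {
    stopifnot(length(reference) == 1L, is.finite(reference))
    return(list(ddcq = delta_cqs - reference,
                reference_value = reference,
                reference_used = "male_standard",
                clusters = NULL))
  }
  if (!identical(reference, "cluster_median")) {
    stop("'reference' must be \"cluster_median\" or a numeric male-standard value")
  }
  if (length(delta_cqs) < 2L) {
    stop("cluster-median normalization needs >= 2 samples; ",
         "supply a numeric male standard instead")
  }
  cl <- split_two_clusters(delta_cqs, min_gap = min_gap)
  list(ddcq = delta_cqs - cl$male_median,
       reference_value = cl$male_median,
       reference_used = "cluster_median",
       clusters = cl)
}

#' Call sex from a normalized dosage value
#'
#' Classifies a sample from its delta-delta-Cq using the midpoint threshold
#' between the expected male (0) and female (-1) cluster centers. Values
#' above the threshold are called male, values below female. A sample whose
#' value lies within its own combined SEM of the threshold (or exactly at
#' it) is considered insufficiently precise and flagged for a repeat run.
#'
#' @param ddcq Numeric vector of delta-delta-Cq values.
#' @param sem_total Combined SEM per sample (autosome SEM + sex SEM),
#'   recycled if length 1.
#' @param threshold Classification threshold; default -0.5, the midpoint of
#'   the two dosage clusters.
#' @return Character vector of calls: `"male"`, `"female"`, or `"repeat"`.
#' @examples
#' call_sex(c(0, -1, -0.42), c(0.1, 0.1, 0.1))
#' @export
call_sex <- function(ddcq, sem_total, threshold = -0.5) {
  stopifnot(is.numeric(ddcq), is.numeric(sem_total), all(sem_total >= 0, na.rm = TRUE))
  if (length(sem_total) == 1L) sem_total <- rep(sem_total, length(ddcq))
  stopifnot(length(sem_total) == length(ddcq))
  out <- ifelse(ddcq > threshold, "male", "female")
  out[ddcq == threshold | abs(ddcq - threshold) < sem_total] <- "repeat"
  out[!is.finite(ddcq)] <- NA_character_
  out
}
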