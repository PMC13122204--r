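#' Configuration for a genotyping run
#'
#' @param outlier_threshold Replicate outlier screen threshold in cycles.
#' @param threshold Classification threshold on the delta-delta-Cq scale.
#' @param male_standard Optional delta-Cq of a known-male standard; when
#'   supplied it replaces cluster-median normalization.
#' @param min_cluster_gap Gap (cycles) below which the two-cluster split is
#'   flagged unimodal.
#' @param max_cycles Upper bound on valid Cq values.
#' @return A list of class `"cohort_config"`.
#' @export
cohort_config <- function(outlier_threshold = 1.0, threshold = -0.5,
                          male_standard = NULL, min_cluster_gap = 0.3,
                          max_cycles = 45) {
  stopifnot(outlier_threshold > 0, is.finite(threshold),
            is.null(male_standard) || (is.numeric(male_standard) && length(male_standard) == 1L))
  structure(list(outlier_threshold = outlier_threshold,
                 threshold = threshold,
                 male_standard = male_standard,
                 min_cluster_gap = min_cluster_gap,
                 max_cycles = max_cycles),
            class = "cohort_config")
}

#' Genotype a cohort from raw Cq measurements
#'
#' Runs the full dosage-genotyping pipeline on a plate (or several plates) of
#' Cq measurements: per-sample/per-assay replicate summarization with outlier
#' screening, delta-Cq computation, normalization to a male reference
#' (two-cluster median by default, or an explicit male standard), and
#' male/female/repeat calling against the midpoint threshold.
#'
#' Samples missing one of the two target roles are excluded from analysis and
#' reported in `$excluded`; they are never silently dropped. Samples with
#' fewer than two surviving replicates on either assay keep their computed
#' values but are force-flagged `"repeat"`.
#'
#' @param measurements Data frame with columns `sample_id`, `target_role`
#'   (`"autosome"`/`"sex"`), and `cq` (NA for undetermined wells), as
#'   produced by [parse_cq_export()] or [simulate_cohort()].
#' @param config A [cohort_config()] object.
#' @return Object of class `"cohort_result"`: list with `samples` (data frame
#'   of per-sample results), `male_ids`, `female_ids`, `normalization_offset`,
#'   `reference_used`, `threshold`, `diagnostics` (cluster gap, median
#'   distance, unimodal flag), `excluded`, and `config`.
#' @export
genotype_cohort <- function(measurements, config = cohort_config()) {
  stopifnot(is.data.frame(measurements),
            all(c("sample_id", "target_role", "cq") %in% names(measurements)),
            inherits(config, "cohort_config"))
  meas <- measurements
  meas$target_role <- as.character(meas$target_role)
  bad_role <- !meas$target_role %in% c("autosome", "sex")
  if (any(bad_role)) {
    stop("unknown target_role values: ",
         paste(unique(meas$target_role[bad_role]), collapse = ", "))
  }
  ids <- unique(as.character(meas$sample_id))

  excluded <- character(0)
  rows <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    sid <- ids[i]
    sub <- meas[meas$sample_id == sid, ]
    cq_auto <- sub$cq[sub$target_role == "autosome"]
    cq_sex <- sub$cq[sub$target_role == "sex"]
    if (length(cq_auto[!is.na(cq_auto)]) == 0L || length(cq_sex[!is.na(cq_sex)]) == 0L) {
      excluded <- c(excluded, sid)
      next
    }
    ga <- summarize_replicates(cq_auto, config$outlier_threshold,
                               config$max_cycles, sid, "autosome")
    gs <- summarize_replicates(cq_sex, config$outlier_threshold,
                               config$max_cycles, sid, "sex")
    d <- compute_delta_cq(ga, gs)
    rows[[i]] <- data.frame(
      sample_id = sid,
      delta_cq = d$delta_cq,
      sem_total = d$sem_total,
      n_kept_auto = ga$n_kept, n_kept_sex = gs$n_kept,
      n_discarded = ga$n_discarded + gs$n_discarded,
      low_replicate = d$low_confidence,
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(res) || nrow(res) == 0L) {
    stop("no sample has usable replicates for both target roles")
  }

  delta <- stats::setNames(res$delta_cq, res$sample_id)
  reference <- if (!is.null(config$male_standard)) config$male_standard else "cluster_median"
  norm <- normalize_ddcq(delta, reference, min_gap = config$min_cluster_gap)
  res$ddcq <- as.numeric(norm$ddcq)
  res$call <- call_sex(res$ddcq, res$sem_total, config$threshold)
  res$call[res$low_replicate] <- "repeat"

  cl <- norm$clusters
  if (is.null(cl)) {
    male_ids <- res$sample_id[res$call == "male"]
    female_ids <- res$sample_id[res$call == "female"]
    diagnostics <- list(gap = NA_real_, median_distance = NA_real_, unimodal = NA)
  } else {
    male_ids <- cl$male_ids
    female_ids <- cl$female_ids
    diagnostics <- list(gap = cl$gap, median_distance = cl$median_distance,
                        unimodal = cl$unimodal)
    if (isTRUE(cl$unimodal)) {
      warning("delta-Cq values do not separate into two clusters (gap ",
              signif(cl$gap, 3), " < ", config$min_cluster_gap,
              "); the batch may contain a single sex - re-run with a male standard")
    }
    # samples whose threshold call disagrees with their cluster assignment
    disagree <- union(
      intersect(res$sample_id[res$call == "female"], male_ids),
      intersect(res$sample_id[res$call == "male"], female_ids)
    )
    diagnostics$cluster_call_disagreement <- disagree
    if (length(disagree)) {
      warning("threshold call disagrees with cluster assignment for: ",
              paste(disagree, collapse = ", "))
    }
  }

  structure(list(
    samples = res,
    male_ids = male_ids,
    female_ids = female_ids,
    normalization_offset = norm$reference_value,
    reference_used = norm$reference_used,
    threshold = config$threshold,
    diagnostics = diagnostics,
    excluded = excluded,
    config = config
  ), class = "cohort_result")
}

#' @export
print.cohort_result <- function(x, ...) {
  n <- nrow(x$samples)
  calls <- table(factor(x$samples$call, levels = c("male", "female", "repeat")))
  cat("qPCR dosage genotyping of", n, "samples\n")
  cat(sprintf("  calls: %d male, %d female, %d repeat\n",
              calls["male"], calls["female"], calls["repeat"]))
  cat(sprintf("  normalization: %s (offset %.3f cycles)\n",
              x$reference_used, x$normalization_offset))
  if (!is.na(x$diagnostics$gap)) {
    cat(sprintf("  cluster gap %.3f, median distance %.3f%s\n",
                x$diagnostics$gap, x$diagnostics$median_distance,
                if (isTRUE(x$diagnostics$unimodal)) " [UNIMODAL]" else ""))
  }
  if (length(x$excluded)) {
    cat("  excluded (missing a target role):", paste(x$excluded, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Strip plot of normalized dosage values with the classification threshold
#'
#' @param x A `"cohort_result"`.
#' @param ... Passed to [graphics::stripchart()].
#' @export
plot.cohort_result <- function(x, ...) {
  s <- x$samples
  col <- c(male = "#2166ac", female = "#b2182b", `repeat` = "grey50")[s$call]
  graphics::stripchart(s$ddcq, method = "jitter", jitter = 0.1, pch = 19,
                       col = col, vertical = TRUE,
                       ylab = expression(Delta * Delta * "Cq (cycles)"), ...)
  graphics::abline(h = x$threshold, lty = 2)
  graphics::abline(h = c(0, -1), lty = 3, col = "grey70")
  invisible(x)
}

#' Write genotyping results as a TSV table plus a JSON run report
#'
#' @param result A `"cohort_result"`.
#' @param tsv_path,json_path Output paths; either may be `NULL` to skip.
#' @return Invisibly, the paths written.
#' @export
write_cohort_result <- function(result, tsv_path = NULL, json_path = NULL) {
  stopifnot(inherits(result, "cohort_result"))
  if (!is.null(tsv_path)) {
    utils::write.table(result$samples, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(json_path)) {
    report <- list(
      n_samples = nrow(result$samples),
      calls = as.list(table(result$samples$call)),
      reference_used = result$reference_used,
      normalization_offset = result$normalization_offset,
      threshold = result$threshold,
      diagnostics = result$diagnostics,
      excluded = result$excluded
    )
    jsonlite::write_json(report, json_path, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
  }
  invisible(c(tsv = tsv_path, json = json_path))
}
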