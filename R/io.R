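# Reading instrument Cq exports, writing result tables, and plain-text run
# configuration. Cq tables are delimited text with a header; the delimiter
# (tab or comma) is sniffed from the header line.

default_target_aliases <- function() {
  c(autosome = "autosome", auto = "autosome", a = "autosome",
    sex = "sex", z = "sex", zchrom = "sex")
}

sniff_delim <- function(path) {
  header <- readLines(path, n = 1L)
  if (grepl("\t", header, fixed = TRUE)) "\t" else ","
}

#' Read a Cq replicate table exported from a qPCR instrument
#'
#' Parses a comma- or tab-delimited export with (case-insensitive) columns
#' `Sample`, `Target`, `Cq`, and optional `Well` and `Plate`. Target names
#' are mapped to the `autosome`/`sex` roles through an alias table, so
#' instrument-side assay names (e.g. a primer-pair label) can be used
#' directly. `"Undetermined"` or blank Cq entries become missing values;
#' decimal commas are accepted.
#'
#' @param path Path to the export file.
#' @param target_aliases Named character vector mapping lower-cased target
#'   names to `"autosome"`/`"sex"`. Defaults map `autosome`/`auto`/`a` and
#'   `sex`/`z`/`zchrom`.
#' @return Data frame of measurements: `sample_id`, `target_role`,
#'   `well_id`, `cq`. Rows whose target has no alias are dropped with a
#'   warning and returned in the `"unmapped"` attribute.
#' @export
parse_cq_export <- function(path, target_aliases = default_target_aliases()) {
  if (!file.exists(path)) stop("no such file: ", path)
  delim <- sniff_delim(path)
  raw <- utils::read.table(path, sep = delim, header = TRUE,
                           colClasses = "character", check.names = FALSE,
                           strip.white = TRUE, quote = "\"")
  cols <- tolower(names(raw))
  find_col <- function(name) {
    hit <- which(cols == name)
    if (length(hit)) hit[1] else NA_integer_
  }
  required <- c("sample", "target", "cq")
  idx <- vapply(required, find_col, integer(1))
  if (anyNA(idx)) {
    stop("missing required column(s) ",
         paste(sQuote(required[is.na(idx)]), collapse = ", "),
         "; found: ", paste(names(raw), collapse = ", "))
  }
  well_idx <- find_col("well")
  parse_cq <- function(x) {
    x <- trimws(x)
    x[x == "" | toupper(x) == "UNDETERMINED" | toupper(x) == "NA"] <- NA
    v <- suppressWarnings(as.numeric(x))
    # tolerate decimal commas from locale-specific exports
    retry <- !is.na(x) & is.na(v) & grepl(",", x, fixed = TRUE) & !grepl("\\.", x)
    v[retry] <- suppressWarnings(as.numeric(sub(",", ".", x[retry], fixed = TRUE)))
    bad <- !is.na(x) & is.na(v)
    if (any(bad)) stop("unparseable Cq value(s): ", paste(unique(x[bad]), collapse = ", "))
    v
  }
  target_raw <- tolower(trimws(raw[[idx["target"]]]))
  role <- unname(target_aliases[target_raw])
  out <- data.frame(
    sample_id = trimws(raw[[idx["sample"]]]),
    target_role = role,
    well_id = if (!is.na(well_idx)) trimws(raw[[well_idx]]) else NA_character_,
    cq = parse_cq(raw[[idx["cq"]]]),
    stringsAsFactors = FALSE
  )
  unmapped <- unique(raw[[idx["target"]]][is.na(role)])
  if (length(unmapped)) {
    warning("dropping rows with unmapped target name(s): ",
            paste(unmapped, collapse = ", "))
  }
  out <- out[!is.na(out$target_role), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "unmapped") <- unmapped
  out
}

#' Write a measurement table in the Cq-export dialect
#'
#' @param measurements Data frame with `sample_id`, `target_role`,
#'   `well_id`, `cq` (missing Cq written as `"Undetermined"`).
#' @param path Output path; tab-delimited.
#' @export
write_cq_table <- function(measurements, path) {
  out <- data.frame(Sample = measurements$sample_id,
                    Target = measurements$target_role,
                    Well = measurements$well_id,
                    Cq = ifelse(is.na(measurements$cq), "Undetermined",
                                format(measurements$cq, digits = 10, trim = TRUE)),
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

run_config_keys <- c("outlier_threshold", "threshold", "male_standard",
                     "min_cluster_gap", "preset", "seed",
                     "alias.autosome", "alias.sex")

#' Read a plain-text run configuration file
#'
#' `key = value` lines, `#` comments. Recognized keys: `outlier_threshold`,
#' `threshold`, `male_standard`, `min_cluster_gap`, `preset`, `seed`, and
#' comma-separated `alias.autosome`/`alias.sex` target-name lists. Unknown
#' keys are rejected so typos cannot silently change an analysis.
#'
#' @param path Path to the config file.
#' @return Named list of parsed settings.
#' @export
parse_run_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    if (!grepl("=", ln, fixed = TRUE)) stop("config line is not 'key = value': ", ln)
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    if (!key %in% run_config_keys) {
      stop("unknown config key '", key, "'; recognized keys: ",
           paste(run_config_keys, collapse = ", "))
    }
    out[[key]] <- if (key %in% c("outlier_threshold", "threshold",
                                 "male_standard", "min_cluster_gap")) {
      as.numeric(val)
    } else if (key == "seed") {
      as.integer(val)
    } else if (startsWith(key, "alias.")) {
      trimws(strsplit(val, ",", fixed = TRUE)[[1]])
    } else val
  }
  out
}

# merge config-file aliases into the default alias map
aliases_from_config <- function(cfg) {
  al <- default_target_aliases()
  if (!is.null(cfg$alias.autosome)) {
    al <- c(al, stats::setNames(rep("autosome", length(cfg$alias.autosome)),
                                tolower(cfg$alias.autosome)))
  }
  if (!is.null(cfg$alias.sex)) {
    al <- c(al, stats::setNames(rep("sex", length(cfg$alias.sex)),
                                tolower(cfg$alias.sex)))
  }
  al
}
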