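#' Binding-site search policy for in-silico PCR
#'
#' @param max_mismatch Maximum total mismatches allowed per binding site.
#' @param seed_len Number of 3'-terminal bases that must match exactly (the
#'   extension seed).
#' @param max_product_len Longest amplicon considered.
#' @return List of class `"pcr_policy"`.
#' @export
pcr_policy <- function(max_mismatch = 2, seed_len = 5, max_product_len = 5000) {
  stopifnot(max_mismatch >= 0, seed_len >= 1, max_product_len >= 1)
  structure(list(max_mismatch = max_mismatch, seed_len = seed_len,
                 max_product_len = max_product_len), class = "pcr_policy")
}

# all binding sites of one primer on the plus strand of one template string;
# a site is valid when total mismatches <= max_mismatch and the 3'-terminal
# seed matches exactly
primer_sites_plus <- function(primer, template, policy) {
  lp <- nchar(primer)
  lt <- nchar(template)
  if (lp > lt) return(integer(0))
  hits <- Biostrings::matchPattern(primer, Biostrings::DNAString(template),
                                   max.mismatch = policy$max_mismatch)
  starts <- BiocGenerics::start(hits)
  if (!length(starts)) return(integer(0))
  pb <- strsplit(primer, "", fixed = TRUE)[[1]]
  seed_idx <- (lp - min(policy$seed_len, lp) + 1L):lp
  ok <- vapply(starts, function(s) {
    tb <- strsplit(substring(template, s, s + lp - 1L), "", fixed = TRUE)[[1]]
    sum(tb != pb) <= policy$max_mismatch && all(tb[seed_idx] == pb[seed_idx])
  }, logical(1))
  starts[ok]
}

#' Predict amplicons of a primer pair by in-silico PCR
#'
#' Searches every template for binding sites of both primers on both strands
#' (total mismatches up to `policy$max_mismatch`, 3'-terminal seed exact),
#' then pairs each plus-strand site with each downstream minus-strand site
#' within `policy$max_product_len` to enumerate all predicted amplicons. Any
#' primer combination can prime an amplicon (fwd/rev, fwd/fwd, rev/rev), as
#' in a real reaction. The pair is specific when exactly one amplicon is
#' predicted over all templates and, if `constraints` is supplied, its
#' length lies within the constraint product range — the computational
#' surrogate for a single-product melt curve.
#'
#' @param fwd,rev Primer sequences, 5'->3'.
#' @param templates Named character vector or `DNAStringSet` of template
#'   sequences (e.g. a genome or contig set).
#' @param policy A [pcr_policy()].
#' @param constraints Optional [primer_constraints()] whose product range
#'   the single amplicon must satisfy for the specificity verdict.
#' @return List with `amplicons` (data frame: `template`, `plus_primer`,
#'   `minus_primer`, `start`, `end`, `length`, `sequence`) and `specific`.
#' @export
insilico_pcr <- function(fwd, rev, templates, policy = pcr_policy(),
                         constraints = NULL) {
  if (inherits(templates, "DNAStringSet")) {
    templates <- stats::setNames(as.character(templates), names(templates))
  }
  stopifnot(is.character(templates), length(templates) >= 1L)
  if (is.null(names(templates))) names(templates) <- paste0("template_", seq_along(templates))
  fwd <- check_acgt(fwd); rev <- check_acgt(rev)
  primers <- c(fwd = fwd, rev = rev)
  amps <- list()
  for (tn in names(templates)) {
    template <- check_acgt(templates[[tn]])
    # plus-strand sites (primer extends rightward) and minus-strand sites
    # (primer binds the plus strand as its reverse complement, extends left)
    plus <- lapply(primers, primer_sites_plus, template = template, policy = policy)
    minus <- lapply(primers, function(p) {
      s <- primer_sites_plus(p, revcomp_chr(template), policy)
      # convert to plus-strand end coordinate of the site
      nchar(template) - s + 1L
    })
    for (pn in names(primers)) {
      for (qn in names(primers)) {
        for (fs in plus[[pn]]) {
          for (re in minus[[qn]]) {
            len <- re - fs + 1L
            if (len >= nchar(primers[[pn]]) && len >= nchar(primers[[qn]]) &&
                len <= policy$max_product_len) {
              amps[[length(amps) + 1L]] <- data.frame(
                template = tn, plus_primer = pn, minus_primer = qn,
                start = fs, end = re, length = len,
                sequence = substring(template, fs, re),
                stringsAsFactors = FALSE)
            }
          }
        }
      }
    }
  }
  amplicons <- if (length(amps)) do.call(rbind, amps) else
    data.frame(template = character(0), plus_primer = character(0),
               minus_primer = character(0), start = integer(0),
               end = integer(0), length = integer(0),
               sequence = character(0), stringsAsFactors = FALSE)
  specific <- nrow(amplicons) == 1L
  if (specific && !is.null(constraints)) {
    specific <- amplicons$length[1] >= constraints$product_min &&
      amplicons$length[1] <= constraints$product_max
  }
  list(amplicons = amplicons, specific = specific)
}

#' Extract annotated target regions from a genome for primer design
#'
#' Reads a genome FASTA and a GFF3 or BED annotation, optionally filters to
#' one chromosome and one feature type, and returns each feature's sequence
#' (minus-strand features reverse-complemented), named
#' `chrom:start-end(strand)` in 1-based inclusive coordinates. BED input is
#' converted from its 0-based half-open convention on import.
#'
#' @param genome Path to a FASTA file, or a named `DNAStringSet`/character
#'   vector of sequences.
#' @param annotation Path to a GFF3 (`.gff`/`.gff3`) or BED file, or a
#'   `GRanges`.
#' @param chrom Optional chromosome/contig name to restrict to.
#' @param feature_type Optional GFF3 feature type (e.g. `"exon"`); ignored
#'   for BED input, which carries no type column.
#' @param min_length Features shorter than this are dropped with a message;
#'   default 1 (keep all).
#' @return List of target regions: each a list with `name`, `chrom`,
#'   `start`, `end`, `strand`, `feature_type`, `sequence`.
#' @export
extract_targets <- function(genome, annotation, chrom = NULL,
                            feature_type = NULL, min_length = 1) {
  if (is.character(genome) && length(genome) == 1L && file.exists(genome)) {
    genome <- Biostrings::readDNAStringSet(genome)
  }
  if (inherits(genome, "DNAStringSet")) {
    genome <- stats::setNames(as.character(genome), names(genome))
  }
  stopifnot(is.character(genome), !is.null(names(genome)))
  # FASTA headers may carry descriptions after the identifier
  names(genome) <- sub("\\s.*$", "", names(genome))

  if (is.character(annotation)) {
    fmt <- if (grepl("\\.bed$", annotation, ignore.case = TRUE)) "BED" else "GFF3"
    gr <- rtracklayer::import(annotation, format = fmt)
  } else {
    gr <- annotation
  }
  df <- as.data.frame(gr)
  df$seqnames <- as.character(df$seqnames)
  df$strand <- as.character(df$strand)
  if (!is.null(chrom)) df <- df[df$seqnames == chrom, , drop = FALSE]
  if (!is.null(feature_type) && "type" %in% names(df)) {
    df <- df[as.character(df$type) == feature_type, , drop = FALSE]
  }
  if (nrow(df) == 0L) stop("no annotation features match the requested filters")

  out <- vector("list", nrow(df))
  kept <- logical(nrow(df))
  for (i in seq_len(nrow(df))) {
    chr <- df$seqnames[i]
    if (!chr %in% names(genome)) {
      stop("annotation record ", i, " references sequence '", chr,
           "' absent from the genome")
    }
    st <- df$start[i]; en <- df$end[i]
    if (st < 1L || en > nchar(genome[[chr]]) || st > en) {
      stop("feature ", chr, ":", st, "-", en, " out of bounds for sequence '",
           chr, "' (length ", nchar(genome[[chr]]), ")")
    }
    if (en - st + 1L < min_length) next
    strand <- if (df$strand[i] %in% c("+", "-")) df$strand[i] else "+"
    seq <- substring(toupper(genome[[chr]]), st, en)
    if (strand == "-") seq <- revcomp_chr(seq)
    ftype <- if ("type" %in% names(df)) as.character(df$type[i]) else NA_character_
    out[[i]] <- list(name = sprintf("%s:%d-%d(%s)", chr, st, en, strand),
                     chrom = chr, start = st, end = en, strand = strand,
                     feature_type = ftype, sequence = seq)
    kept[i] <- TRUE
  }
  out[kept]
}

#' Write target regions as a FASTA file
#'
#' @param targets Output of [extract_targets()].
#' @param path Output FASTA path.
#' @export
write_targets_fasta <- function(targets, path) {
  seqs <- Biostrings::DNAStringSet(vapply(targets, `[[`, character(1), "sequence"))
  names(seqs) <- vapply(targets, `[[`, character(1), "name")
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Generate synthetic design targets, each seeded with one compliant site
#'
#' Builds random-sequence target regions that are guaranteed to contain at
#' least one primer pair satisfying the given constraints: a
#' constraint-compliant forward site and reverse site (found by rejection
#' sampling under the package's own metrics) are embedded at a spacing in
#' the middle of the product range, inside random flanking sequence at
#' roughly 50% GC. Used to exercise the designer with a known answer.
#'
#' @param n_targets Number of targets.
#' @param constraints A [primer_constraints()] object.
#' @param target_length Total target length, nt; defaults to the product
#'   maximum plus 60 nt of flanks.
#' @param seed Integer seed (the caller's RNG state is preserved).
#' @param prefix Name prefix for the targets.
#' @return Named character vector of target sequences.
#' @export
simulate_design_targets <- function(n_targets,
                                    constraints = constraint_preset("ceph_pipeline"),
                                    target_length = NULL, seed = 1,
                                    prefix = "target") {
  cs <- constraints
  if (is.null(target_length)) target_length <- cs$product_max + 60L
  stopifnot(n_targets >= 1, target_length >= cs$product_min + 20L)
  product_len <- as.integer(round((cs$product_min + cs$product_max) / 2))
  product_len <- min(product_len, target_length - 20L)

  compliant_site <- function() {
    repeat {
      size <- cs$size_opt
      s <- paste(sample(c("A", "C", "G", "T"), size, replace = TRUE), collapse = "")
      bases <- strsplit(s, "", fixed = TRUE)[[1]]
      gc <- 100 * sum(bases %in% c("G", "C")) / size
      if (abs(gc - cs$gc_opt) > 10) next
      if (max_homopolymer(bases) > cs$max_polyx) next
      if (terminal_gc_run(bases) < max(cs$gc_clamp, 1L)) next
      tm <- nn_duplex_tm(s, 50e-9, 0.05)
      if (tm < cs$tm_min || tm > cs$tm_max) next
      if (is.finite(cs$max_dimer_tm) && dimer_tm(s, s) > cs$max_dimer_tm) next
      return(s)
    }
  }
  with_seed(seed, {
    out <- character(n_targets)
    for (i in seq_len(n_targets)) {
      fwd <- compliant_site()
      rev <- compliant_site()
      size <- nchar(fwd)
      insert <- paste0(fwd,
                       paste(sample(c("A", "C", "G", "T"),
                                    product_len - size - nchar(rev),
                                    replace = TRUE), collapse = ""),
                       revcomp_chr(rev))
      flank_total <- target_length - nchar(insert)
      left <- flank_total %/% 2L
      rand_flank <- function(n) {
        if (n <= 0L) return("")
        paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
      }
      out[i] <- paste0(rand_flank(left), insert, rand_flank(flank_total - left))
    }
    stats::setNames(out, sprintf("%s_%02d", prefix, seq_len(n_targets)))
  })
}
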