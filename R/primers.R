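#' Primer design constraint set
#'
#' Hard limits and optima used to filter and rank candidate primer pairs.
#' Two named presets reproduce the constraint sets used to design the
#' published cephalopod sex-genotyping assays: see [constraint_preset()].
#'
#' @param size_min,size_opt,size_max Primer length bounds and optimum, nt.
#' @param tm_opt Optimal melting temperature, degrees C. `tm_min`/`tm_max`
#'   are the hard window applied on the package's own Tm scale (see
#'   [melting_temp()]); defaults span `tm_opt` minus 10 to plus 5.
#' @param tm_min,tm_max Hard Tm window, degrees C.
#' @param gc_opt Optimal GC content, percent; `gc_min`/`gc_max` hard bounds.
#' @param gc_min,gc_max Hard GC window, percent.
#' @param product_min,product_max Amplicon length window, nt.
#' @param gc_clamp Number of consecutive G/C bases required at the 3'
#'   terminus (0 disables the requirement).
#' @param max_polyx Longest allowed single-nucleotide run, nt.
#' @param max_dimer_tm Maximum allowed self/cross primer-dimer Tm, degrees C
#'   (`Inf` disables the check).
#' @param weights Penalty weights per unit deviation from the optimum:
#'   named vector with `tm` (per degree C), `gc` (per percent GC), `size`
#'   (per nt).
#' @return Object of class `"primer_constraints"`.
#' @export
primer_constraints <- function(size_min = 18, size_opt = 20, size_max = 27,
                               tm_opt = 59, tm_min = tm_opt - 10,
                               tm_max = tm_opt + 5,
                               gc_opt = 50, gc_min = 20, gc_max = 80,
                               product_min = 100, product_max = 200,
                               gc_clamp = 1, max_polyx = 3,
                               max_dimer_tm = 30,
                               weights = c(tm = 1, gc = 0.5, size = 1)) {
  stopifnot(size_min <= size_opt, size_opt <= size_max,
            product_min <= product_max, gc_clamp >= 0, max_polyx >= 1,
            all(c("tm", "gc", "size") %in% names(weights)))
  structure(list(size_min = size_min, size_opt = size_opt, size_max = size_max,
                 tm_opt = tm_opt, tm_min = tm_min, tm_max = tm_max,
                 gc_opt = gc_opt, gc_min = gc_min, gc_max = gc_max,
                 product_min = product_min, product_max = product_max,
                 gc_clamp = gc_clamp, max_polyx = max_polyx,
                 max_dimer_tm = max_dimer_tm, weights = weights),
            class = "primer_constraints")
}

#' Named constraint presets used for the published assays
#'
#' `"geneious2025"`: optimal size 20 nt, optimal Tm 59, optimal GC 50%,
#' product 100--200 bp, 3' GC clamp of 1, max homopolymer 3, max dimer Tm
#' 30. `"ceph_pipeline"`: optimal size 20 nt, optimal Tm 60, optimal GC 50%,
#' product 150--300 bp, max homopolymer 5, no clamp or dimer requirement.
#'
#' @param name Preset name.
#' @return A [primer_constraints()] object.
#' @export
constraint_preset <- function(name = c("geneious2025", "ceph_pipeline")) {
  name <- match.arg(name)
  switch(name,
    geneious2025 = primer_constraints(),
    ceph_pipeline = primer_constraints(tm_opt = 60, product_min = 150,
                                       product_max = 300, gc_clamp = 0,
                                       max_polyx = 5, max_dimer_tm = Inf)
  )
}

max_homopolymer <- function(bases) max(rle(bases)$lengths)

terminal_gc_run <- function(bases) {
  r <- rev(bases) %in% c("G", "C")
  if (!r[1L]) 0L else which.min(c(r, FALSE)) - 1L
}

#' Compositional and thermodynamic metrics of a primer
#'
#' Metrics are always recomputed from the sequence, never trusted from
#' input: length, GC percent, nearest-neighbor Tm, longest homopolymer run,
#' length of the 3'-terminal G/C run, and whether that run satisfies the
#' requested GC clamp.
#'
#' @param sequence Primer sequence, 5'->3', ACGT only.
#' @param gc_clamp Number of 3'-terminal G/C bases required for the clamp
#'   flag; default 1.
#' @return List with `sequence`, `length`, `gc`, `tm`, `max_polyx`,
#'   `gc3_run`, `clamp`.
#' @examples
#' primer_metrics("GGCCGTCCTCTACTTGTAATG")
#' @export
primer_metrics <- function(sequence, gc_clamp = 1) {
  s <- check_acgt(sequence)
  bases <- strsplit(s, "", fixed = TRUE)[[1]]
  n <- length(bases)
  if (n < 1L) stop("empty primer sequence")
  gc3 <- terminal_gc_run(bases)
  list(sequence = s,
       length = n,
       gc = 100 * sum(bases %in% c("G", "C")) / n,
       tm = if (n >= 8L) melting_temp(s) else NA_real_,
       max_polyx = max_homopolymer(bases),
       gc3_run = gc3,
       clamp = gc3 >= gc_clamp)
}

#' Tabulate primer metrics and constraint checks for a set of primers
#'
#' @param sequences Named character vector (or `DNAStringSet`) of primer
#'   sequences.
#' @param constraints A [primer_constraints()] object.
#' @return Data frame with one row per primer: metrics plus logical
#'   `pass_size`, `pass_tm`, `pass_gc`, `pass_clamp`, `pass_polyx`,
#'   `pass_self_dimer`, and overall `pass`.
#' @export
check_primers <- function(sequences, constraints = constraint_preset("geneious2025")) {
  if (inherits(sequences, "DNAStringSet")) {
    sequences <- stats::setNames(as.character(sequences), names(sequences))
  }
  stopifnot(is.character(sequences), length(sequences) >= 1L)
  if (is.null(names(sequences))) {
    names(sequences) <- paste0("primer_", seq_along(sequences))
  }
  cs <- constraints
  rows <- lapply(seq_along(sequences), function(i) {
    m <- primer_metrics(sequences[[i]], cs$gc_clamp)
    sd_tm <- if (is.finite(cs$max_dimer_tm)) dimer_tm(m$sequence, m$sequence) else -Inf
    data.frame(
      name = names(sequences)[i], sequence = m$sequence, length = m$length,
      gc = m$gc, tm = m$tm, max_polyx = m$max_polyx, gc3_run = m$gc3_run,
      self_dimer_tm = sd_tm,
      pass_size = m$length >= cs$size_min && m$length <= cs$size_max,
      pass_tm = !is.na(m$tm) && m$tm >= cs$tm_min && m$tm <= cs$tm_max,
      pass_gc = m$gc >= cs$gc_min && m$gc <= cs$gc_max,
      pass_clamp = m$clamp,
      pass_polyx = m$max_polyx <= cs$max_polyx,
      pass_self_dimer = sd_tm <= cs$max_dimer_tm,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out$pass <- out$pass_size & out$pass_tm & out$pass_gc & out$pass_clamp &
    out$pass_polyx & out$pass_self_dimer
  rownames(out) <- NULL
  out
}

primer_penalty <- function(m, cs) {
  cs$weights[["tm"]] * abs(m$tm - cs$tm_opt) +
    cs$weights[["gc"]] * abs(m$gc - cs$gc_opt) +
    cs$weights[["size"]] * abs(m$length - cs$size_opt)
}

#' Evaluate a primer pair against a template and a constraint set
#'
#' Locates both primers on the template (forward on the plus strand, reverse
#' as its reverse complement downstream of the forward site), then checks
#' every constraint: primer sizes, Tm and GC windows, 3' clamp, homopolymer
#' runs, self- and cross-dimer Tm, and product size. The penalty is the sum
#' over both primers of weighted absolute deviations from the size, Tm, and
#' GC optima.
#'
#' @param fwd,rev Primer sequences, 5'->3'.
#' @param template Template sequence containing both binding sites.
#' @param constraints A [primer_constraints()] object.
#' @return List with `checks` (named logicals), `pass`, `penalty`,
#'   `product_length`, `fwd_start`, `rev_end`, and the per-primer metrics.
#' @export
evaluate_pair <- function(fwd, rev, template,
                          constraints = constraint_preset("geneious2025")) {
  cs <- constraints
  template <- check_acgt(template)
  fwd <- check_acgt(fwd); rev <- check_acgt(rev)
  f_at <- regexpr(fwd, template, fixed = TRUE)[1]
  if (f_at < 0) stop("forward primer not found on template")
  r_site <- revcomp_chr(rev)
  r_at <- regexpr(r_site, substring(template, f_at), fixed = TRUE)[1]
  if (r_at < 0) stop("reverse primer (reverse complement) not found downstream of forward site")
  r_start <- f_at + r_at - 1L
  product_length <- r_start + nchar(rev) - f_at
  mf <- primer_metrics(fwd, cs$gc_clamp)
  mr <- primer_metrics(rev, cs$gc_clamp)
  need_dimer <- is.finite(cs$max_dimer_tm)
  checks <- c(
    fwd_size = mf$length >= cs$size_min && mf$length <= cs$size_max,
    rev_size = mr$length >= cs$size_min && mr$length <= cs$size_max,
    fwd_tm = mf$tm >= cs$tm_min && mf$tm <= cs$tm_max,
    rev_tm = mr$tm >= cs$tm_min && mr$tm <= cs$tm_max,
    fwd_gc = mf$gc >= cs$gc_min && mf$gc <= cs$gc_max,
    rev_gc = mr$gc >= cs$gc_min && mr$gc <= cs$gc_max,
    fwd_clamp = mf$clamp, rev_clamp = mr$clamp,
    fwd_polyx = mf$max_polyx <= cs$max_polyx,
    rev_polyx = mr$max_polyx <= cs$max_polyx,
    self_dimer_fwd = !need_dimer || dimer_tm(fwd, fwd) <= cs$max_dimer_tm,
    self_dimer_rev = !need_dimer || dimer_tm(rev, rev) <= cs$max_dimer_tm,
    cross_dimer = !need_dimer || dimer_tm(fwd, rev) <= cs$max_dimer_tm,
    product_size = product_length >= cs$product_min && product_length <= cs$product_max
  )
  list(checks = checks, pass = all(checks),
       penalty = primer_penalty(mf, cs) + primer_penalty(mr, cs),
       product_length = product_length,
       fwd_start = f_at, fwd_end = f_at + mf$length - 1L,
       rev_start = r_start, rev_end = r_start + mr$length - 1L,
       fwd_metrics = mf, rev_metrics = mr)
}

# enumerate all primer windows on one strand of a template and keep those
# passing the hard single-primer constraints; fully vectorized via running
# sums (GC, homopolymer runs, 3' G/C run, nearest-neighbor dH/dS) so whole
# targets are screened without per-window string work
candidate_windows <- function(template, cs) {
  bases <- strsplit(template, "", fixed = TRUE)[[1]]
  n <- length(bases)
  if (n < cs$size_min) return(NULL)
  is_gc <- bases %in% c("G", "C")
  cum_gc <- c(0L, cumsum(is_gc))
  r <- rle(bases)
  runlen <- sequence(r$lengths)                  # run length ending at i
  cum_bad <- c(0L, cumsum(runlen > cs$max_polyx))
  gcr <- rle(is_gc)
  gc_run <- sequence(gcr$lengths)
  gc_run[!is_gc] <- 0L                           # G/C run ending at i
  dinuc <- paste0(bases[-n], bases[-1L])
  cum_dh <- c(0, cumsum(.nn_dh[dinuc]))
  cum_ds <- c(0, cumsum(.nn_ds[dinuc]))
  log_ct <- log(50e-9 / 4)                       # default Tm conditions
  log_na <- log(0.05)
  rows <- list()
  for (size in cs$size_min:min(cs$size_max, n)) {
    s <- seq_len(n - size + 1L)
    e <- s + size - 1L
    gc <- 100 * (cum_gc[e + 1L] - cum_gc[s]) / size
    keep <- gc >= cs$gc_min & gc <= cs$gc_max
    if (size > cs$max_polyx) {
      keep <- keep & (cum_bad[e + 1L] - cum_bad[s + cs$max_polyx]) == 0L
    }
    keep <- keep & gc_run[e] >= cs$gc_clamp
    dh <- cum_dh[e] - cum_dh[s] + .init_dh[bases[s]] + .init_dh[bases[e]]
    ds <- cum_ds[e] - cum_ds[s] + .init_ds[bases[s]] + .init_ds[bases[e]] +
      0.368 * (size - 1L) * log_na
    tm <- dh * 1000 / (ds + .gas_const * log_ct) - 273.15
    keep <- keep & tm >= cs$tm_min & tm <= cs$tm_max
    if (!any(keep)) next
    rows[[length(rows) + 1L]] <- data.frame(
      start = s[keep], end = e[keep], size = size,
      seq = substring(template, s[keep], e[keep]),
      gc = gc[keep], tm = unname(tm[keep]), stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(NULL)
  do.call(rbind, rows)
}

#' Design the best primer pair for each target region
#'
#' For each target, enumerates every forward and reverse primer window within
#' the size bounds, filters on the hard constraints (GC window, homopolymer,
#' 3' clamp, Tm window), pairs windows whose product length falls within the
#' product range, ranks pairs by the weighted penalty, and returns the
#' single lowest-penalty pair per target that also satisfies the self- and
#' cross-dimer limits. Ties are broken deterministically: lower penalty,
#' then leftmost forward site, then shortest product. Targets with no valid
#' pair are reported as failures (NA row), not errors.
#'
#' @param targets Named character vector, `DNAStringSet`, or list of target
#'   regions from [extract_targets()].
#' @param constraints A [primer_constraints()] object.
#' @return Data frame of class `"design_result"` with one row per target:
#'   `target`, `fwd_seq`, `rev_seq`, coordinates, `product_length`,
#'   `penalty`, `fwd_tm`, `rev_tm`, `status`.
#' @export
design_candidates <- function(targets, constraints = constraint_preset("ceph_pipeline")) {
  if (inherits(targets, "DNAStringSet")) {
    targets <- stats::setNames(as.character(targets), names(targets))
  } else if (is.list(targets) && length(targets) && !is.null(targets[[1]]$sequence)) {
    targets <- stats::setNames(vapply(targets, function(t) t$sequence, character(1)),
                               vapply(targets, function(t) t$name, character(1)))
  }
  stopifnot(is.character(targets))
  if (length(targets) == 0L) stop("empty target list")
  if (is.null(names(targets))) names(targets) <- paste0("target_", seq_along(targets))
  cs <- constraints
  rows <- lapply(seq_along(targets), function(ti) {
    template <- check_acgt(targets[[ti]])
    fail_row <- data.frame(target = names(targets)[ti],
                           fwd_seq = NA_character_, rev_seq = NA_character_,
                           fwd_start = NA_integer_, fwd_end = NA_integer_,
                           rev_start = NA_integer_, rev_end = NA_integer_,
                           product_length = NA_integer_, penalty = NA_real_,
                           fwd_tm = NA_real_, rev_tm = NA_real_,
                           status = "no_valid_pair", stringsAsFactors = FALSE)
    fw <- candidate_windows(template, cs)
    rv <- candidate_windows(revcomp_chr(template), cs)
    if (is.null(fw) || is.null(rv)) return(fail_row)
    n <- nchar(template)
    # reverse windows back to plus-strand coordinates
    rv$plus_start <- n - rv$end + 1L
    rv$plus_end <- n - rv$start + 1L
    # per-window penalty, then all product-compatible pairings (vectorized)
    window_penalty <- function(w) {
      cs$weights[["tm"]] * abs(w$tm - cs$tm_opt) +
        cs$weights[["gc"]] * abs(w$gc - cs$gc_opt) +
        cs$weights[["size"]] * abs(w$size - cs$size_opt)
    }
    pen_f <- window_penalty(fw)
    pen_r <- window_penalty(rv)
    fi <- rep(seq_len(nrow(fw)), times = nrow(rv))
    ri <- rep(seq_len(nrow(rv)), each = nrow(fw))
    product_length <- rv$plus_end[ri] - fw$start[fi] + 1L
    ok <- product_length >= cs$product_min & product_length <= cs$product_max &
      rv$plus_start[ri] > fw$end[fi]
    if (!any(ok)) return(fail_row)
    pairs <- data.frame(fi = fi[ok], ri = ri[ok],
                        product_length = product_length[ok],
                        penalty = pen_f[fi[ok]] + pen_r[ri[ok]])
    pairs <- pairs[order(pairs$penalty, fw$start[pairs$fi], pairs$product_length), ,
                   drop = FALSE]
    need_dimer <- is.finite(cs$max_dimer_tm)
    self_ok <- new.env(parent = emptyenv())  # memoize self-dimer checks
    for (pi in seq_len(nrow(pairs))) {
      f <- fw[pairs$fi[pi], ]
      r <- rv[pairs$ri[pi], ]
      if (need_dimer) {
        ok_f <- get0(f$seq, self_ok, ifnotfound = NA)
        if (is.na(ok_f)) {
          ok_f <- dimer_tm(f$seq, f$seq) <= cs$max_dimer_tm
          assign(f$seq, ok_f, envir = self_ok)
        }
        if (!ok_f) next
        ok_r <- get0(r$seq, self_ok, ifnotfound = NA)
        if (is.na(ok_r)) {
          ok_r <- dimer_tm(r$seq, r$seq) <= cs$max_dimer_tm
          assign(r$seq, ok_r, envir = self_ok)
        }
        if (!ok_r) next
        if (dimer_tm(f$seq, r$seq) > cs$max_dimer_tm) next
      }
      return(data.frame(target = names(targets)[ti],
                        fwd_seq = f$seq, rev_seq = r$seq,
                        fwd_start = f$start, fwd_end = f$end,
                        rev_start = r$plus_start, rev_end = r$plus_end,
                        product_length = pairs$product_length[pi],
                        penalty = pairs$penalty[pi],
                        fwd_tm = f$tm, rev_tm = r$tm,
                        status = "ok", stringsAsFactors = FALSE))
    }
    fail_row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("design_result", class(out))
  out
}

#' Refine a primer to a related species' consensus sequence
#'
#' Substitutes each base of a primer designed on a reference sequence with
#' the base observed at the same position in an aligned consensus from the
#' target species (e.g. short-read consensus of a congener), counting the
#' substitutions and re-deriving all metrics from the refined sequence. A
#' substitution inside the 3'-terminal seed raises a warning since it may
#' alter priming efficiency. A gap in the consensus under the primer
#' footprint is an error: the primer must be redesigned.
#'
#' @param primer Primer sequence (ACGT) as designed on the reference.
#' @param start 1-based position of the primer's 5' base in the coordinate
#'   system shared by reference and consensus.
#' @param consensus Consensus sequence aligned to the reference coordinates;
#'   may contain IUPAC ambiguity codes ("-" marks a gap).
#' @param seed_len Length of the 3'-terminal seed checked for
#'   substitutions; default 5.
#' @return List with `sequence` (refined primer), `n_substitutions`,
#'   `seed_substitution` (logical), and `metrics` from [primer_metrics()].
#' @export
refine_to_consensus <- function(primer, start, consensus, seed_len = 5) {
  p <- strsplit(check_acgt(primer), "", fixed = TRUE)[[1]]
  n <- length(p)
  cons <- strsplit(toupper(consensus), "", fixed = TRUE)[[1]]
  if (start < 1L || start + n - 1L > length(cons)) {
    stop("primer footprint [", start, ", ", start + n - 1L,
         "] outside consensus of length ", length(cons))
  }
  window <- cons[start:(start + n - 1L)]
  if (any(window == "-")) {
    stop("consensus gap under primer footprint at position ",
         start + which(window == "-")[1] - 1L, "; redesign the primer")
  }
  iupac <- Biostrings::IUPAC_CODE_MAP
  refined <- p
  subs <- logical(n)
  for (i in seq_len(n)) {
    cb <- window[i]
    if (cb == p[i]) next
    if (cb %in% c("A", "C", "G", "T")) {
      refined[i] <- cb
      subs[i] <- TRUE
    } else if (cb %in% names(iupac)) {
      # ambiguous consensus: keep the reference base when compatible
      if (!grepl(p[i], iupac[[cb]], fixed = TRUE)) {
        stop("consensus ambiguity code '", cb, "' at position ", start + i - 1L,
             " excludes the reference base '", p[i], "'; redesign the primer")
      }
    } else {
      stop("invalid consensus character '", cb, "' at position ", start + i - 1L)
    }
  }
  seed_sub <- any(subs[(n - min(seed_len, n) + 1L):n])
  if (seed_sub) {
    warning("substitution within the 3'-terminal ", seed_len,
            " nt seed; priming efficiency may be affected")
  }
  list(sequence = paste(refined, collapse = ""),
       n_substitutions = sum(subs),
       seed_substitution = seed_sub,
       metrics = primer_metrics(paste(refined, collapse = "")))
}
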