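# Nearest-neighbor duplex thermodynamics (unified DNA parameter set of
# SantaLucia, with the entropy-based monovalent-salt correction). Enthalpies
# kcal/mol, entropies cal/(mol K), keyed by the top-strand dinucleotide.

.nn_dh <- c(AA = -7.9, TT = -7.9, AT = -7.2, TA = -7.2,
            CA = -8.5, TG = -8.5, GT = -8.4, AC = -8.4,
            CT = -7.8, AG = -7.8, GA = -8.2, TC = -8.2,
            CG = -10.6, GC = -9.8, GG = -8.0, CC = -8.0)
.nn_ds <- c(AA = -22.2, TT = -22.2, AT = -20.4, TA = -21.3,
            CA = -22.7, TG = -22.7, GT = -22.4, AC = -22.4,
            CT = -21.0, AG = -21.0, GA = -22.2, TC = -22.2,
            CG = -27.2, GC = -24.4, GG = -19.9, CC = -19.9)
.init_dh <- c(A = 2.3, T = 2.3, G = 0.1, C = 0.1)
.init_ds <- c(A = 4.1, T = 4.1, G = -2.8, C = -2.8)
.gas_const <- 1.987  # cal/(mol K)

.comp <- c(A = "T", T = "A", G = "C", C = "G")

revcomp_chr <- function(x) {
  chartr("ACGT", "TGCA", vapply(x, function(s) {
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE))
}

check_acgt <- function(sequence) {
  s <- toupper(sequence)
  bases <- strsplit(s, "", fixed = TRUE)[[1]]
  bad <- which(!bases %in% c("A", "C", "G", "T"))
  if (length(bad)) {
    stop("non-ACGT character '", bases[bad[1]], "' at position ", bad[1],
         " in '", sequence, "'")
  }
  s
}

# Core duplex Tm of a perfectly matched duplex given by its top strand.
# No minimum-length check: also used for short dimer segments.
nn_duplex_tm <- function(seq, oligo_conc, monovalent) {
  bases <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(bases)
  if (n < 2L) return(-Inf)
  dinucs <- paste0(bases[-n], bases[-1L])
  dh <- sum(.nn_dh[dinucs]) + .init_dh[bases[1L]] + .init_dh[bases[n]]
  ds <- sum(.nn_ds[dinucs]) + .init_ds[bases[1L]] + .init_ds[bases[n]]
  selfcomp <- identical(seq, revcomp_chr(seq))
  if (selfcomp) ds <- ds - 1.4
  ds <- ds + 0.368 * (n - 1L) * log(monovalent)
  ct <- if (selfcomp) oligo_conc else oligo_conc / 4
  unname(dh * 1000 / (ds + .gas_const * log(ct)) - 273.15)
}

#' Nearest-neighbor melting temperature of a primer
#'
#' Duplex melting temperature of the oligo with its perfect complement from
#' unified nearest-neighbor parameters, with the entropy-based monovalent
#' salt correction (0.368 cal/(mol K) per phosphate pair times ln[Na+]).
#' Default conditions are 50 nM total strand and 50 mM monovalent cation.
#' Absolute Tm values depend on the chosen salt model and ion conditions;
#' comparisons between primers at fixed conditions are the robust use.
#'
#' @param sequence Primer sequence, 5'->3', ACGT only, length >= 8.
#'   Ambiguity codes are rejected: refine the primer to a concrete sequence
#'   first.
#' @param oligo_conc Total oligonucleotide concentration, mol/L.
#' @param monovalent Monovalent cation concentration, mol/L.
#' @return Melting temperature in degrees Celsius.
#' @export
melting_temp <- function(sequence, oligo_conc = 50e-9, monovalent = 0.05) {
  s <- check_acgt(sequence)
  if (nchar(s) < 8L) stop("sequence shorter than 8 nt: Tm not meaningful")
  stopifnot(oligo_conc > 0, monovalent > 0)
  nn_duplex_tm(s, oligo_conc, monovalent)
}

#' Highest-Tm primer-dimer duplex between two oligos
#'
#' Scans every ungapped antiparallel alignment register of `seq_a` against
#' `seq_b`, finds all maximal runs of Watson-Crick complementary base pairs,
#' and returns the nearest-neighbor melting temperature of the most stable
#' such duplex segment. Self-dimers are `dimer_tm(seq, seq)`. When no
#' register contains at least two consecutive complementary pairs the
#' sentinel `-Inf` is returned (no predicted duplex).
#'
#' @param seq_a,seq_b Primer sequences, 5'->3'.
#' @param oligo_conc,monovalent Conditions as in [melting_temp()].
#' @param details Return the best segment and its coordinates too.
#' @return Tm in degrees Celsius, or a list when `details = TRUE`.
#' @export
dimer_tm <- function(seq_a, seq_b, oligo_conc = 50e-9, monovalent = 0.05,
                     details = FALSE) {
  a <- strsplit(check_acgt(seq_a), "", fixed = TRUE)[[1]]
  b <- strsplit(check_acgt(seq_b), "", fixed = TRUE)[[1]]
  la <- length(a); lb <- length(b)
  comp_b <- .comp[b]
  best <- -Inf
  best_seg <- NULL
  # antiparallel register: a[i] pairs with b[j], with i + j = off constant
  for (off in 2:(la + lb)) {
    i <- max(1L, off - lb):min(la, off - 1L)
    j <- off - i
    is_pair <- a[i] == comp_b[j]
    if (!any(is_pair)) next
    r <- rle(is_pair)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (seg in which(r$values & r$lengths >= 2L)) {
      seg_seq <- paste(a[i[starts[seg]:ends[seg]]], collapse = "")
      tm <- nn_duplex_tm(seg_seq, oligo_conc, monovalent)
      if (tm > best) {
        best <- tm
        best_seg <- list(segment = seg_seq,
                         a_start = i[starts[seg]], a_end = i[ends[seg]],
                         b_start = j[ends[seg]], b_end = j[starts[seg]])
      }
    }
  }
  if (details) c(list(tm = best), best_seg) else best
}
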