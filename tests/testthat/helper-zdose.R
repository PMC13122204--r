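# Shared fixtures built in code.

# Measurement table with exact per-sample mean Cq values (no noise), four
# identical replicates per target.
plate_from_means <- function(auto_means, sex_means, replicates = 4) {
  stopifnot(length(auto_means) == length(sex_means))
  ids <- names(auto_means)
  if (is.null(ids)) ids <- sprintf("S%02d", seq_along(auto_means))
  do.call(rbind, lapply(seq_along(ids), function(i) {
    data.frame(
      sample_id = ids[i],
      target_role = rep(c("autosome", "sex"), each = replicates),
      well_id = NA_character_,
      cq = c(rep(auto_means[i], replicates), rep(sex_means[i], replicates)),
      stringsAsFactors = FALSE)
  }))
}

# Published cephalopod sex-genotyping primer panel bundled with the package.
load_primer_panel <- function() {
  fa <- system.file("extdata", "cephalopod_sex_primers.fasta", package = "zdose")
  seqs <- Biostrings::readDNAStringSet(fa)
  stats::setNames(as.character(seqs), names(seqs))
}

# Independent brute-force 1-D two-cluster optimum: enumerate every possible
# 2-subset assignment and minimize within-cluster sum of squares.
brute_force_two_cluster <- function(x) {
  n <- length(x)
  best <- Inf
  best_assign <- NULL
  for (mask in 1:(2^n - 2)) {
    a <- as.logical(bitwAnd(mask, 2^(seq_len(n) - 1)))
    wss <- sum((x[a] - mean(x[a]))^2) + sum((x[!a] - mean(x[!a]))^2)
    if (wss < best) {
      best <- wss
      best_assign <- a
    }
  }
  list(wss = best, assign = best_assign)
}

# Independent pooled-variance Student's t computed from the textbook formula.
pooled_t_by_hand <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  df <- na + nb - 2
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}
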