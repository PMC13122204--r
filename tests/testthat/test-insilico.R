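revcomp <- function(x) as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))

# template with one embedded site pair giving a product of exactly 150 nt
make_template <- function(fwd, rev, product = 150, flank = 30, seed = 1) {
  set.seed(seed)
  rand <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                            collapse = "")
  paste0(rand(flank), fwd,
         rand(product - nchar(fwd) - nchar(rev)), revcomp(rev),
         rand(flank))
}

fwd <- "GGCCGTCCTCTACTTGTAATG"
rev <- "AGTAGCTGTGTGGTTGAGAAG"

test_that("in-silico PCR predicts the constructed amplicon", {
  tpl <- c(chr1 = make_template(fwd, rev, product = 150))
  r <- insilico_pcr(fwd, rev, tpl)
  expect_equal(nrow(r$amplicons), 1)
  expect_equal(r$amplicons$length, 150)
  expect_equal(r$amplicons$start, 31)
  expect_true(r$specific)
  expect_true(startsWith(r$amplicons$sequence, fwd))
  expect_true(endsWith(r$amplicons$sequence, revcomp(rev)))
})

test_that("a 3'-terminal mismatch kills priming under the seed-exact policy", {
  tpl <- c(chr1 = make_template(fwd, rev, product = 150))
  fwd_mut <- paste0(substr(fwd, 1, nchar(fwd) - 1), "C")  # 3' G -> C
  r <- insilico_pcr(fwd_mut, rev, tpl)
  expect_equal(nrow(r$amplicons), 0)
  expect_false(r$specific)
  # an internal mismatch is tolerated within the mismatch budget
  fwd_int <- fwd
  substr(fwd_int, 5, 5) <- "A"  # G -> A, outside the seed
  r <- insilico_pcr(fwd_int, rev, tpl)
  expect_equal(nrow(r$amplicons), 1)
})

test_that("a duplicated template yields two amplicons and a non-specific verdict", {
  tpl1 <- make_template(fwd, rev, product = 150)
  r <- insilico_pcr(fwd, rev, c(a = tpl1, b = tpl1))
  expect_equal(nrow(r$amplicons), 2)
  expect_false(r$specific)
})

toy_genome_files <- function(dir) {
  fa <- file.path(dir, "toy.fa")
  writeLines(c(">chrZ", "ACGTACGTAC", ">chrA", "GGGTTTAAACCC"), fa)
  gff <- file.path(dir, "toy.gff3")
  writeLines(c("##gff-version 3",
               "chrZ\ttoy\texon\t3\t6\t.\t+\t.\tID=e1",
               "chrZ\ttoy\texon\t3\t6\t.\t-\t.\tID=e2",
               "chrA\ttoy\tgene\t1\t12\t.\t+\t.\tID=g1"), gff)
  bed <- file.path(dir, "toy.bed")
  writeLines("chrZ\t2\t6\te1\t0\t+", bed)
  list(fa = fa, gff = gff, bed = bed)
}

test_that("target extraction honors GFF3/BED conventions and strand", {
  d <- withr::local_tempdir()
  f <- toy_genome_files(d)

  t_gff <- extract_targets(f$fa, f$gff, chrom = "chrZ", feature_type = "exon")
  expect_equal(length(t_gff), 2)
  expect_equal(t_gff[[1]]$sequence, "GTAC")       # 1-based inclusive 3..6
  expect_equal(t_gff[[2]]$sequence, revcomp("GTAC"))  # minus strand
  expect_equal(t_gff[[1]]$name, "chrZ:3-6(+)")

  t_bed <- extract_targets(f$fa, f$bed)           # BED 2..6 is the same interval
  expect_equal(t_bed[[1]]$sequence, t_gff[[1]]$sequence)
  expect_equal(t_bed[[1]]$start, 3)

  # strand involution: extracting the minus-strand feature twice recovers it
  expect_equal(revcomp(t_gff[[2]]$sequence), t_gff[[1]]$sequence)

  bad_gff <- file.path(d, "bad.gff3")
  writeLines(c("##gff-version 3", "chrZ\ttoy\texon\t5\t99\t.\t+\t.\tID=x"), bad_gff)
  expect_error(extract_targets(f$fa, bad_gff), "out of bounds")

  expect_error(extract_targets(f$fa, f$gff, chrom = "chrX"), "match")
})
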