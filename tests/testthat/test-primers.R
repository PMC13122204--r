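test_that("primer metrics are recomputed from the sequence", {
  m <- primer_metrics("ATAT")
  expect_equal(m$gc, 0)
  expect_equal(m$max_polyx, 1)
  expect_false(m$clamp)

  m <- primer_metrics("GGCCGTCCTCTACTTGTAATG")
  expect_equal(m$length, 21)
  expect_equal(m$gc, 100 * 11 / 21, tolerance = 1e-9)  # 52.4%
  expect_true(m$clamp)                                 # 3' G
  expect_lte(m$max_polyx, 2)

  m <- primer_metrics("AAAACTCCCGACGTCTTGAA")
  expect_equal(m$max_polyx, 4)                         # leading AAAA
  expect_false(m$clamp)                                # 3' A

  expect_error(primer_metrics("ACGTNACGT"), "position 5")
})

test_that("the published primer panel satisfies its design constraint sets", {
  panel <- load_primer_panel()
  illex <- grepl("^Illex", names(panel))

  strict <- check_primers(panel[!illex], constraint_preset("geneious2025"))
  expect_equal(nrow(strict), 20)
  expect_true(all(strict$pass_clamp))          # 3' G/C clamp of 1
  expect_true(all(strict$max_polyx <= 3))      # max homopolymer 3

  pipeline <- check_primers(panel[illex], constraint_preset("ceph_pipeline"))
  expect_equal(nrow(pipeline), 4)
  expect_true(all(pipeline$max_polyx <= 5))
  expect_equal(pipeline$max_polyx[pipeline$name == "Illex_qPCR_auto_F"], 4)
})

test_that("pair evaluation checks product size and locates both primers", {
  cs <- constraint_preset("geneious2025")
  targets <- simulate_design_targets(1, cs, target_length = 420, seed = 5)
  des <- design_candidates(targets, cs)
  expect_equal(des$status, "ok")

  rep150 <- evaluate_pair(des$fwd_seq, des$rev_seq, targets[[1]], cs)
  expect_true(rep150$pass)
  expect_equal(rep150$product_length, des$product_length)
  expect_equal(rep150$penalty, des$penalty, tolerance = 1e-9)

  # same primers against a template where the sites are 350 apart
  spacer <- paste(rep("ACGT", 80), collapse = "")
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(des$rev_seq)))
  far <- paste0(des$fwd_seq, substr(spacer, 1, 350 - nchar(des$fwd_seq) - nchar(rc)), rc)
  repfar <- evaluate_pair(des$fwd_seq, des$rev_seq, far, cs)
  expect_false(repfar$checks[["product_size"]])
  expect_equal(repfar$product_length, 350)

  expect_error(evaluate_pair("ACGTACGTACGTACGTACGT", des$rev_seq, targets[[1]], cs),
               "not found")
})

test_that("the designer returns one specific, optimal pair per seeded target", {
  cs <- constraint_preset("ceph_pipeline")
  targets <- simulate_design_targets(3, cs, seed = 11)
  des <- design_candidates(targets, cs)
  expect_equal(sum(des$status == "ok"), 3)
  expect_true(all(des$product_length >= cs$product_min &
                    des$product_length <= cs$product_max))
  # every returned pair amplifies its own target specifically
  for (i in seq_len(nrow(des))) {
    r <- insilico_pcr(des$fwd_seq[i], des$rev_seq[i], targets[i], constraints = cs)
    expect_true(r$specific)
  }

  # a target of one base offers no compliant primer
  des_a <- design_candidates(c(t1 = strrep("A", 400)), cs)
  expect_equal(des_a$status, "no_valid_pair")
  expect_error(design_candidates(character(0), cs), "empty")
})

test_that("returned pairs are penalty-optimal among valid pairs (recomputation oracle)", {
  cs <- constraint_preset("geneious2025")
  targets <- simulate_design_targets(2, cs, target_length = 300, seed = 23)
  des <- design_candidates(targets, cs)
  pen <- function(m) cs$weights[["tm"]] * abs(m$tm - cs$tm_opt) +
    cs$weights[["gc"]] * abs(m$gc - cs$gc_opt) +
    cs$weights[["size"]] * abs(m$length - cs$size_opt)
  window_ok <- function(m) m$clamp && m$max_polyx <= cs$max_polyx &&
    m$gc >= cs$gc_min && m$gc <= cs$gc_max &&
    m$tm >= cs$tm_min && m$tm <= cs$tm_max
  for (i in 1:2) {
    # the returned pair is itself valid and its penalty recomputes exactly
    expect_true(evaluate_pair(des$fwd_seq[i], des$rev_seq[i], targets[[i]], cs)$pass)
    mf <- primer_metrics(des$fwd_seq[i], cs$gc_clamp)
    mr <- primer_metrics(des$rev_seq[i], cs$gc_clamp)
    expect_equal(des$penalty[i], pen(mf) + pen(mr), tolerance = 1e-9)

    # exhaustive oracle: no valid pair (all hard constraints + dimers) beats
    # the returned penalty; every window's metrics computed once, directly
    # from primer_metrics
    tpl <- targets[[i]]
    n <- nchar(tpl)
    thresh <- des$penalty[i] - 1e-9
    enumerate <- function(orientation) {
      rows <- list()
      for (size in cs$size_min:cs$size_max) {
        for (s in seq_len(n - size + 1L)) {
          seq <- substr(tpl, s, s + size - 1L)
          if (orientation == "rev") {
            seq <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
          }
          m <- primer_metrics(seq, cs$gc_clamp)
          if (!window_ok(m)) next
          rows[[length(rows) + 1L]] <- data.frame(
            start = s, end = s + size - 1L, seq = seq, pen = pen(m))
        }
      }
      do.call(rbind, rows)
    }
    fwdw <- enumerate("fwd")
    revw <- enumerate("rev")
    found_better <- FALSE
    for (fi in which(fwdw$pen < thresh)) {
      prod <- revw$end - fwdw$start[fi] + 1L
      cand <- which(fwdw$pen[fi] + revw$pen < thresh &
                      prod >= cs$product_min & prod <= cs$product_max &
                      revw$start > fwdw$end[fi])
      for (ri in cand) {
        if (dimer_tm(fwdw$seq[fi], fwdw$seq[fi]) <= cs$max_dimer_tm &&
            dimer_tm(revw$seq[ri], revw$seq[ri]) <= cs$max_dimer_tm &&
            dimer_tm(fwdw$seq[fi], revw$seq[ri]) <= cs$max_dimer_tm) {
          found_better <- TRUE
        }
      }
    }
    expect_false(found_better)
  }
})

test_that("consensus refinement substitutes variants and guards the 3' seed", {
  primer <- "CACTTCAGCCCGATGGAATAAG"
  ref <- paste0(strrep("T", 10), primer, strrep("T", 10))

  r <- refine_to_consensus(primer, 11, ref)
  expect_equal(r$sequence, primer)
  expect_equal(r$n_substitutions, 0)

  cons <- ref
  substr(cons, 15, 15) <- "A"   # internal SNP under the footprint
  r <- refine_to_consensus(primer, 11, cons)
  expect_equal(r$n_substitutions, 1)
  expect_equal(substr(r$sequence, 5, 5), "A")
  expect_false(r$seed_substitution)
  expect_equal(r$metrics$sequence, r$sequence)

  cons <- ref
  substr(cons, 32, 32) <- "T"   # SNP at the 3'-terminal base
  expect_warning(r <- refine_to_consensus(primer, 11, cons), "seed")
  expect_true(r$seed_substitution)
  expect_equal(substr(r$sequence, 22, 22), "T")

  cons <- ref
  substr(cons, 20, 20) <- "-"
  expect_error(refine_to_consensus(primer, 11, cons), "gap")

  # compatible ambiguity keeps the reference base
  cons <- ref
  substr(cons, 15, 15) <- "Y"   # primer base at that position is T
  r <- refine_to_consensus(primer, 11, cons)
  expect_equal(r$n_substitutions, 0)
})
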