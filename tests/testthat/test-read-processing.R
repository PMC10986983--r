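lco <- folmer_primers()$fwd
hco <- folmer_primers()$rev

test_that("binning matches the full forward primer, IUPAC-aware", {
  set.seed(5)
  amp <- random_dna_str(200)
  good <- paste0(lco, amp)
  nomatch <- paste0(random_dna_str(25), amp)
  # one substitution anywhere in the primer breaks every covering seed window
  mism <- paste0(mutate_at(lco, 13), amp)
  pairs <- pair_tbl(c(good, nomatch, mism),
                    rep(paste0(hco, random_dna_str(200)), 3))
  binned <- bin_by_primer(pairs, folmer_primers())
  expect_equal(binned$locus, c("Folmer", "unbinned", "unbinned"))

  # exhaustive oracle: every 11-mer window covering position 13 mismatches
  windows <- vapply(1:(nchar(lco) - 10), function(i) {
    substr(mutate_at(lco, 13), i, i + 10) == substr(lco, i, i + 10)
  }, logical(1))
  expect_false(all(windows))

  expect_error(bin_by_primer(pairs, dplyr::bind_rows(folmer_primers(),
                                                     folmer_primers())),
               "duplicate")
})

test_that("binning partitions read pairs across loci", {
  set.seed(6)
  other <- tibble::tibble(name = "Other", fwd = random_dna_str(20),
                          rev = random_dna_str(20))
  primers <- dplyr::bind_rows(folmer_primers(), other)
  pairs <- pair_tbl(
    c(paste0(lco, random_dna_str(50)), paste0(other$fwd, random_dna_str(50)),
      random_dna_str(75)),
    rep(random_dna_str(60), 3))
  binned <- bin_by_primer(pairs, primers)
  expect_equal(sort(binned$locus), c("Folmer", "Other", "unbinned"))
  expect_equal(nrow(binned), nrow(pairs))  # every pair lands in one bucket
})

test_that("trimming removes primers and low-quality 3' tails", {
  set.seed(7)
  amp <- random_dna_str(120)
  q30 <- strrep("?", 120 + nchar(lco))   # '?' = Phred 30
  pairs <- pair_tbl(paste0(lco, amp), paste0(hco, random_dna_str(120)),
                    fwd_qual = q30,
                    rev_qual = strrep("?", 120 + nchar(hco)))
  tr <- trim_pairs(pairs, lco, hco, min_phred = 10)
  expect_equal(tr$fwd_seq, amp)          # only the primer removed
  expect_false(tr$empty)

  # ten terminal Phred-2 bases are removed
  lowtail <- paste0(strrep("?", nchar(lco) + 110), strrep("#", 10))
  pairs2 <- pair_tbl(paste0(lco, amp), paste0(hco, random_dna_str(120)),
                     fwd_qual = lowtail,
                     rev_qual = strrep("?", 120 + nchar(hco)))
  tr2 <- trim_pairs(pairs2, lco, hco, min_phred = 10)
  expect_equal(tr2$fwd_seq, substr(amp, 1, 110))

  # a read entirely below threshold trims to zero length and is flagged
  allbad <- paste0(strrep("?", nchar(lco)), strrep("#", 120))
  tr3 <- trim_pairs(pair_tbl(paste0(lco, amp),
                             paste0(hco, random_dna_str(120)),
                             fwd_qual = allbad,
                             rev_qual = strrep("?", 120 + nchar(hco))),
                    lco, hco, min_phred = 10)
  expect_equal(nchar(tr3$fwd_seq), 0L)
  expect_true(tr3$empty)

  # trimming never increases length
  expect_lte(nchar(tr$fwd_seq), nchar(pairs$fwd_seq))
})

test_that("pair merging respects the overlap and mismatch thresholds", {
  set.seed(8)
  amplicon <- random_dna_str(300)
  fwd <- substr(amplicon, 1, 200)
  rev3 <- revcomp(substr(amplicon, 101, 300))   # exact 100 bp overlap

  merged <- merge_pairs(pair_tbl(fwd, rev3), min_overlap = 80,
                        max_diff = 0.075)
  expect_equal(nrow(merged), 1)
  expect_equal(merged$sequence, amplicon)       # 300 bp reconstruction
  expect_equal(merged$kind, "merged")

  # 7 mismatches in a 100 bp overlap = 7.0% -> succeeds;
  # 8 mismatches = 8.0% -> fails (oracle: brute force over all offsets finds
  # the planted overlap, threshold arithmetic decides)
  plant <- function(k) {
    bad <- revcomp(mutate_at(substr(amplicon, 101, 300), seq_len(k)))
    merge_pairs(pair_tbl(fwd, bad), min_overlap = 80, max_diff = 0.075)
  }
  expect_equal(nrow(plant(7)), 1)
  expect_equal(nrow(plant(8)), 0)

  # merged length bounded by fwd + rev - min_overlap
  expect_lte(nchar(merged$sequence), 200 + 200 - 80)
  expect_gte(nchar(merged$sequence), 200)
})

test_that("merge conflicts take the higher-quality base, ties to forward", {
  amplicon <- strrep("A", 100)
  fwd <- amplicon
  # reverse read disagrees at overlap position 1 (a C), with higher quality
  rev_sense <- paste0("C", strrep("A", 99))
  m_hi <- merge_pairs(pair_tbl(fwd, revcomp(rev_sense),
                               fwd_qual = strrep("5", 100),   # Phred 20
                               rev_qual = strrep("I", 100)),  # Phred 40
                      min_overlap = 80, max_diff = 0.075)
  expect_equal(substr(m_hi$sequence, 1, 1), "C")
  m_tie <- merge_pairs(pair_tbl(fwd, revcomp(rev_sense),
                                fwd_qual = strrep("I", 100),
                                rev_qual = strrep("I", 100)),
                       min_overlap = 80, max_diff = 0.075)
  expect_equal(substr(m_tie$sequence, 1, 1), "A")
})

test_that("scaffolding inserts the N linker between the reads", {
  p <- pair_tbl("ACGT", "ACGT")
  sc <- scaffold_pairs(p, linker_n = 15)
  expect_equal(sc$sequence, paste0("ACGT", strrep("N", 15), "ACGT"))
  expect_equal(sc$kind, "scaffolded")
  expect_equal(scaffold_pairs(p, linker_n = 0)$sequence, "ACGTACGT")
  expect_error(scaffold_pairs(pair_tbl("ACGT", ""), 15), "empty")

  # reverse complement is an involution, so scaffolding round-trips
  set.seed(9)
  x <- random_dna_str(80)
  expect_equal(revcomp(revcomp(x)), x)
})

test_that("process_reads reports per-vial accounting", {
  set.seed(10)
  amp <- random_dna_str(400)
  pairs <- pair_tbl(
    rep(paste0(lco, substr(amp, 1, 200)), 5),
    rep(paste0(hco, revcomp(substr(amp, 201, 400))), 5))
  out <- process_reads(pairs, folmer_primers())
  expect_equal(nrow(out$templates), 5)
  expect_equal(out$report$reads_in, 5)
  expect_equal(out$report$binned, 5)
  expect_equal(out$report$templates, 5)
  expect_true(all(grepl(strrep("N", 15), out$templates$sequence)))
})
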