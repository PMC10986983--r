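test_that("greedy clustering respects the identity threshold", {
  set.seed(12)
  base <- random_dna_str(100)
  # identical templates form one cluster of full size
  cl <- cluster_greedy(tmpl(sprintf("t%02d", 1:10), rep(base, 10)),
                       identity = 0.98, linker_n = 0)
  expect_equal(nrow(cl), 1)
  expect_equal(cl$size, 10L)

  # 3 substitutions in 100 bp = 97% identity (edit-distance oracle):
  # separate at 0.98, together at 0.96
  var3 <- mutate_at(base, c(10, 50, 90))
  expect_equal(template_identity(base, var3, 0), 0.97)
  two <- cluster_greedy(tmpl(c("a", "b"), c(base, var3)), 0.98, 0)
  expect_equal(nrow(two), 2)
  one <- cluster_greedy(tmpl(c("a", "b"), c(base, var3)), 0.96, 0)
  expect_equal(nrow(one), 1)
  expect_equal(one$size, 2L)
})

test_that("linker columns are excluded from identity", {
  set.seed(13)
  f <- random_dna_str(50); r <- random_dna_str(50)
  a <- paste0(f, strrep("N", 15), r)
  b <- paste0(mutate_at(f, 1), strrep("N", 15), r)
  expect_equal(template_identity(a, b, 15), 99 / 100)
  expect_equal(template_distance(a, b, 15), 1)
})

test_that("grafting merges rare variants into near neighbours to a fixed point", {
  set.seed(14)
  base <- random_dna_str(100)
  near <- mutate_at(base, 5)          # 1 edit
  far <- mutate_at(base, c(1, 20, 40, 60, 80))  # 5 edits

  mk <- function(seqs, sizes) {
    cl <- cluster_greedy(tmpl(letters[seq_along(seqs)], seqs), 1, 0)
    cl$size <- sizes[match(cl$representative, seqs)]
    cl
  }
  g <- graft_rare(mk(c(base, near), c(100L, 3L)), d = 1, linker_n = 0)
  expect_equal(nrow(g), 1)
  expect_equal(g$size, 103L)
  expect_equal(g$representative, base)

  g2 <- graft_rare(mk(c(base, far), c(100L, 3L)), d = 1, linker_n = 0)
  expect_equal(sort(g2$size), c(3L, 100L))

  # chain 100 -(1 edit)- 3 -(1 edit)- 2 collapses stepwise to 105
  near2 <- mutate_at(near, 6)
  expect_equal(template_distance(base, near2, 0), 2)  # not directly graftable
  g3 <- graft_rare(mk(c(base, near, near2), c(100L, 3L, 2L)),
                   d = 1, linker_n = 0)
  expect_equal(g3$size, 105L)
})

test_that("censoring flags exactly the clusters below the size floor", {
  set.seed(15)
  cl <- cluster_greedy(tmpl(c("a", "b", "c"),
                            c(random_dna_str(60), random_dna_str(60),
                              random_dna_str(60))), 1, 0)
  cl$size <- c(9L, 10L, 30L)
  cen <- censor_small(cl, min_size = 10)
  expect_equal(cen$censored, c(TRUE, FALSE, FALSE))
  expect_equal(nrow(cen), 3)  # flagged, not removed

  # a vial where everything is censored yields no assignable clusters
  allsmall <- censor_small(dplyr::mutate(cl, size = c(2L, 3L, 4L)), 10)
  expect_true(all(allsmall$censored))
  expect_equal(sum(beelca:::active_clusters(allsmall)), 0)
})

test_that("contaminant screening flags by alignment identity", {
  set.seed(16)
  wolb <- random_dna_str(300)
  bee <- random_dna_str(300)
  ninety <- mutate_at(wolb, seq(1, 300, by = 10))  # 30 edits = 90% identity
  cl <- cluster_greedy(tmpl(c("w", "n", "b"), c(wolb, ninety, bee)), 1, 0)
  cl$size <- c(50L, 50L, 50L)
  out <- screen_contaminant(cl, wolb, min_identity = 0.95, linker_n = 0)
  expect_equal(out$contaminant[match(c("w", "n", "b"), out$rep_id)],
               c(TRUE, FALSE, FALSE))
  expect_equal(nrow(screen_contaminant(cl[0, ], wolb)), 0)
})

test_that("off-phylum screening keeps bees and flags bacterial decoys", {
  db <- make_references(seed = 21)
  bee_seq <- db$species$sequence[1]
  junk <- random_dna_str(60)  # below the score floor against everything
  cl <- cluster_greedy(tmpl(c("bee", "wolb", "junk"),
                            c(bee_seq, db$contaminant$sequence, junk)), 1, 0)
  cl$size <- c(100L, 100L, 100L)
  out <- screen_off_phylum(cl, db$refs, db$tax, linker_n = 0)
  flags <- out$non_arthropod[match(c("bee", "wolb", "junk"), out$rep_id)]
  expect_equal(flags, c(FALSE, TRUE, TRUE))
})

test_that("chimera flagging detects constructed splices, passes clean reads", {
  db <- make_references(seed = 22)
  sp <- db$species
  a <- sp$sequence[sp$genus == "Apis"][1]
  b <- sp$sequence[sp$genus == "Halictus"][1]
  splice <- paste0(substr(a, 1, 329), substr(b, 330, nchar(b)))
  cl <- cluster_greedy(tmpl(c("chim", "clean"), c(splice, a)), 1, 0)
  cl$size <- c(20L, 20L)
  out <- flag_chimeras(cl, db$refs, linker_n = 0)
  expect_true(out$chimera[out$rep_id == "chim"])
  expect_false(out$chimera[out$rep_id == "clean"])

  # a splice whose two parents are identical reference entries is not a
  # chimera: the parents are indistinct
  dup_refs <- refseq_table(c("D1", "D2"), c(sp$taxid[1], sp$taxid[2]),
                           rep(a, 2), source = "synthetic")
  cl2 <- cluster_greedy(tmpl("x", a), 1, 0)
  cl2$size <- 20L
  out2 <- flag_chimeras(cl2, dup_refs, linker_n = 0)
  expect_false(out2$chimera)
})

test_that("cluster sizes are conserved through cluster and graft", {
  for (seed in 1:4) {
    set.seed(seed * 31)
    base <- random_dna_str(80)
    n <- sample(20:60, 1)
    seqs <- vapply(seq_len(n), function(i) {
      k <- sample(0:4, 1)
      if (k == 0) base else mutate_at(base, sample(80, k))
    }, character(1))
    templates <- tmpl(sprintf("t%03d", seq_len(n)), seqs,
                      vial = sample(c("V1", "V2"), n, replace = TRUE))
    cl <- cluster_greedy(templates, 0.98, 0)
    expect_equal(sum(cl$size), n)
    g <- graft_rare(cl, d = 1, linker_n = 0)
    expect_equal(sum(g$size), n)
    cen <- censor_small(g, 10)
    expect_equal(nrow(cen), nrow(g))      # flags only
    expect_equal(sum(cen$size), n)
    # centroid property: unflagged representatives are mutually < threshold
    act <- cen[beelca:::active_clusters(cen), ]
    for (v in unique(act$vial)) {
      reps <- act$representative[act$vial == v]
      if (length(reps) > 1) {
        prs <- utils::combn(length(reps), 2)
        ids <- apply(prs, 2, function(p) {
          template_identity(reps[p[1]], reps[p[2]], 0)
        })
        expect_true(all(ids < 0.98))
      }
    }
  }
})

test_that("clustering at identity 1 equals exact-sequence grouping", {
  set.seed(41)
  seqs <- sample(c(random_dna_str(50), random_dna_str(50), random_dna_str(50)),
                 30, replace = TRUE)
  cl <- cluster_greedy(tmpl(sprintf("t%02d", 1:30), seqs), 1.0, 0)
  oracle <- table(seqs)
  expect_equal(nrow(cl), length(oracle))
  expect_equal(sort(cl$size), sort(unname(as.integer(oracle))))
})
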