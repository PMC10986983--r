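test_that("scoring against the database counts matched bases", {
  toy <- toy_refs()
  ref <- toy$refs$sequence[1]
  m <- score_against_db(ref, toy$refs, score_floor = 100, linker_n = 0)
  self <- m[m$accession == "B1", ]
  expect_equal(self$score, 400)          # perfect match to a 400 bp reference
  expect_equal(self$identity, 1.0)

  # 4 mismatches over 400 aligned columns -> identity 0.99
  mut <- mutate_at(ref, c(50, 150, 250, 350))
  m2 <- score_against_db(mut, toy$refs, score_floor = 100, linker_n = 0)
  expect_equal(m2$identity[m2$accession == "B1"], 0.99)
  expect_equal(m2$score[m2$accession == "B1"], 396)

  # a 60 bp fragment cannot reach a floor of 100 matched bases
  frag <- substr(ref, 1, 60)
  expect_equal(nrow(score_against_db(frag, toy$refs, 100, 0)), 0)
})

test_that("scaffolded templates sum segment scores", {
  toy <- toy_refs()
  ref <- toy$refs$sequence[1]
  scaf <- paste0(substr(ref, 1, 180), strrep("N", 15),
                 substr(ref, 221, 400))
  m <- score_against_db(scaf, toy$refs, 100, linker_n = 15)
  self <- m[m$accession == "B1", ]
  expect_equal(self$score, 180 + 180)
  expect_equal(self$fwd_score, 180)
  expect_equal(self$rev_score, 180)
  expect_equal(self$identity, 1.0)       # linker excluded from columns
})

test_that("windowed LCA follows the 3% inclusive rule", {
  tax <- toy_tax()
  # single match -> that species
  a1 <- lca_window(fake_matches(7L, 400), tax)
  expect_equal(a1$taxid, 7L)
  expect_equal(a1$rank, "species")
  expect_equal(a1$status, "assigned")

  # second match 387 of 400 is >3% below the top: excluded
  out <- lca_window(fake_matches(c(7L, 10L), c(400, 387)), tax)
  expect_equal(out$taxid, 7L)
  # 389 of 400 is within 3%: included, LCA coarsens to family
  out2 <- lca_window(fake_matches(c(7L, 10L), c(400, 389)), tax)
  expect_equal(out2$taxid, 5L)
  # boundary tie at exactly (1-w) * max is included
  out3 <- lca_window(fake_matches(c(7L, 8L), c(400, 388)), tax)
  expect_equal(out3$taxid, 6L)

  # equal scores on two congeners -> the genus
  eq <- lca_window(fake_matches(c(7L, 8L), c(400, 400)), tax)
  expect_equal(eq$taxid, 6L)
  expect_equal(eq$rank, "genus")

  # no matches -> unassigned
  expect_equal(lca_window(fake_matches(integer(0), numeric(0)), tax)$status,
               "unassigned")
})

test_that("lca_window agrees with a brute-force reimplementation on fuzz", {
  tax <- random_tax(40, 77)
  leaves <- tax$taxid[tax$rank %in% c("genus", "species", "subspecies")]
  set.seed(78)
  for (i in 1:300) {
    k <- sample(1:6, 1)
    m <- fake_matches(sample(leaves, k, replace = TRUE),
                      sample(100:500, k, replace = TRUE))
    got <- lca_window(m, tax)
    want <- lca_window_bruteforce(m, tax)
    expect_equal(beelca:::collapse_subspecies(tax, got$taxid),
                 beelca:::collapse_subspecies(tax, want))
  }
})

test_that("widening the window never makes the rank more specific", {
  tax <- toy_tax()
  set.seed(79)
  depth <- function(rank) match(rank, c(TAXON_RANKS, "no_rank"))
  for (i in 1:100) {
    k <- sample(1:5, 1)
    m <- fake_matches(sample(c(7L, 8L, 10L), k, replace = TRUE),
                      sample(300:400, k, replace = TRUE))
    narrow <- lca_window(m, tax, window = 0.03)
    wide <- lca_window(m, tax, window = 0.10)
    expect_lte(depth(wide$rank), depth(narrow$rank))
  }
})

test_that("demotion applies the 96%/92% identity floors exactly", {
  tax <- toy_tax()
  mk <- function(id) {
    a <- lca_window(fake_matches(7L, 400, identities = id), tax)
    a$mean_identity <- id
    a
  }
  # above both floors: unchanged
  expect_equal(demote(mk(0.97), tax)$rank, "species")
  # exactly at the species floor: kept (rule is strictly-below)
  expect_equal(demote(mk(0.96), tax)$rank, "species")
  # just below the species floor: genus
  d <- demote(mk(0.95), tax)
  expect_equal(d$rank, "genus")
  expect_equal(d$taxid, 6L)
  expect_equal(d$demoted_from, "species")
  # exactly at the genus floor after a species demotion: stays at genus
  expect_equal(demote(mk(0.92), tax)$rank, "genus")
  # below both: cascades to family
  d2 <- demote(mk(0.91), tax)
  expect_equal(d2$rank, "family")
  expect_equal(d2$taxid, 5L)

  # genus-rank assignments demote only through the 92% rule
  g <- lca_window(fake_matches(c(7L, 8L), c(400, 400)), tax)
  g$mean_identity <- 0.93
  expect_equal(demote(g, tax)$rank, "genus")
  g$mean_identity <- 0.91
  expect_equal(demote(g, tax)$rank, "family")

  # demotion is idempotent and never increases specificity
  once <- demote(mk(0.91), tax)
  expect_equal(demote(once, tax), once)
})

test_that("counts_table aggregates sizes at genus with an above_genus bin", {
  tax <- toy_tax()
  asg <- dplyr::bind_rows(
    dplyr::bind_cols(tibble::tibble(vial = "V1", cluster_id = "c1",
                                    size = 120L),
                     lca_window(fake_matches(6L, 400), tax)),   # genus Bombus
    dplyr::bind_cols(tibble::tibble(vial = "V1", cluster_id = "c2",
                                    size = 30L),
                     lca_window(fake_matches(7L, 400), tax)),   # B. impatiens
    dplyr::bind_cols(tibble::tibble(vial = "V1", cluster_id = "c3",
                                    size = 7L),
                     lca_window(fake_matches(5L, 400), tax)))   # Apidae
  ct <- counts_table(asg, tax)
  expect_equal(ct$Bombus, 150L)
  expect_equal(ct$above_genus, 7L)
  expect_equal(sum(ct$Bombus, ct$above_genus), sum(asg$size))

  empty <- counts_table(asg[0, ], tax)
  expect_equal(nrow(empty), 0)
})

test_that("Sanger assignment runs the identical path on one sequence", {
  toy <- toy_refs()
  # a sequence equal to one reference -> that species
  a <- assign_sanger(toy$refs$sequence[1], toy$refs, toy$tax)
  expect_equal(a$taxid, 7L)
  expect_equal(a$rank, "species")

  # equal-score matches to two congeners -> the genus
  dup <- dplyr::bind_rows(toy$refs,
    dplyr::mutate(toy$refs[1, ], accession = "B1b", taxid = 8L))
  g <- assign_sanger(toy$refs$sequence[1], dup, toy$tax)
  expect_equal(g$taxid, 6L)

  # a random non-matching sequence stays unassigned at the score floor
  set.seed(80)
  r <- assign_sanger(random_dna_str(80), toy$refs, toy$tax,
                     score_floor = 100)
  expect_equal(r$status, "unassigned")
})

test_that("reads from one species recover it (or its genus) at low error", {
  db <- make_references(seed = 30)
  sp <- db$species[db$species$genus == "Halictus", ][1, ]
  set.seed(31)
  n <- 60
  reads <- vapply(seq_len(n), function(i) {
    k <- stats::rbinom(1, nchar(sp$sequence), 0.005)
    if (k > 0) mutate_at(sp$sequence, sample(nchar(sp$sequence), k))
    else sp$sequence
  }, character(1))
  templates <- tmpl(sprintf("t%03d", seq_len(n)), reads)
  cl <- censor_small(graft_rare(cluster_greedy(templates, 0.98, 0), 1, 0), 10)
  asg <- assign_clusters(cl, db$refs, db$tax, linker_n = 0)
  genus_of <- ancestor_at_rank(db$tax, asg$taxid, "genus")
  ok <- asg$taxid == sp$taxid |
    genus_of == ancestor_at_rank(db$tax, sp$taxid, "genus")
  expect_gte(mean(ok), 0.95)
})
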