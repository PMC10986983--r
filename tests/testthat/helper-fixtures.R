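# Shared toy fixtures and independent oracles.

# 10-node toy tree: two Bombus species, one Apis species, shared Apidae
toy_tax <- function() {
  taxonomy(tibble::tribble(
    ~taxid, ~name, ~rank, ~parent,
    1L, "root", "no_rank", 1L,
    2L, "Arthropoda", "phylum", 1L,
    3L, "Insecta", "class", 2L,
    4L, "Hymenoptera", "order", 3L,
    5L, "Apidae", "family", 4L,
    6L, "Bombus", "genus", 5L,
    7L, "Bombus impatiens", "species", 6L,
    8L, "Bombus griseocollis", "species", 6L,
    9L, "Apis", "genus", 5L,
    10L, "Apis mellifera", "species", 9L
  ))
}

# independent LCA oracle: intersect full root-to-node ancestor paths
lca_bruteforce <- function(tax, taxids) {
  paths <- lapply(taxids, function(t) {
    parent_of <- stats::setNames(tax$parent, tax$taxid)
    p <- integer(0); cur <- t
    repeat {
      p <- c(cur, p)
      nxt <- parent_of[[as.character(cur)]]
      if (nxt == cur) break
      cur <- nxt
    }
    p
  })
  common <- Reduce(intersect, paths)
  # the common ancestor appearing deepest in any path
  depths <- vapply(common, function(x) match(x, paths[[1]]), integer(1))
  common[which.max(depths)]
}

# random tree with <= n nodes: node i's parent is uniform among 1..(i-1)
random_tax <- function(n, seed) {
  set.seed(seed)
  ranks <- c("no_rank", TAXON_RANKS)
  parent <- c(1L, vapply(2:n, function(i) sample(i - 1L, 1), integer(1)))
  # assign ranks non-increasing in specificity down the tree
  depth <- integer(n); depth[1] <- 1
  for (i in 2:n) depth[i] <- depth[parent[i]] + 1L
  rank <- ifelse(depth == 1, "no_rank",
                 TAXON_RANKS[pmin(depth - 1, length(TAXON_RANKS))])
  taxonomy(tibble::tibble(taxid = seq_len(n),
                          name = paste0("n", seq_len(n)),
                          rank = rank, parent = parent))
}

random_dna_str <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# plant k substitutions at distinct positions
mutate_at <- function(seq, positions) {
  chars <- strsplit(seq, "")[[1]]
  for (p in positions) {
    chars[p] <- setdiff(c("A", "C", "G", "T"), chars[p])[1]
  }
  paste(chars, collapse = "")
}

# minimal template tibble
tmpl <- function(ids, seqs, vial = "V1") {
  tibble::tibble(template_id = ids, vial = vial, kind = "merged",
                 sequence = seqs, fwd_len = nchar(seqs), rev_len = 0L)
}

# read-pair tibble from explicit fields
pair_tbl <- function(fwd_seq, rev_seq,
                     fwd_qual = strrep("I", nchar(fwd_seq)),
                     rev_qual = strrep("I", nchar(rev_seq)),
                     vial = "V1") {
  n <- length(fwd_seq)
  tibble::tibble(read_id = sprintf("r%03d", seq_len(n)), vial = vial,
                 fwd_seq = fwd_seq, fwd_qual = fwd_qual,
                 rev_seq = rev_seq, rev_qual = rev_qual)
}

# two-genus, two-species reference bundle with deterministic sequences
toy_refs <- function(len = 400, seed = 11) {
  set.seed(seed)
  base <- random_dna_str(len)
  bom1 <- mutate_at(base, sample(len, 8))
  set.seed(seed + 1)
  bom2 <- mutate_at(base, sample(len, 8))
  set.seed(seed + 2)
  api <- mutate_at(base, round(seq(3, len - 3, length.out = 60)))
  tax <- toy_tax()
  refs <- refseq_table(c("B1", "B2", "A1"), c(7L, 8L, 10L),
                       c(bom1, bom2, api), source = "synthetic")
  list(refs = refs, tax = tax)
}

# node-to-root path of taxids (self first)
tax_path_test <- function(tax, taxid) {
  parent_of <- stats::setNames(tax$parent, tax$taxid)
  p <- integer(0); cur <- taxid
  repeat {
    p <- c(p, cur)
    nxt <- parent_of[[as.character(cur)]]
    if (nxt == cur) break
    cur <- nxt
  }
  p
}

# independent re-implementation of the windowed LCA for cross-checking
lca_window_bruteforce <- function(matches, tax, window = 0.03) {
  if (nrow(matches) == 0) return(NA_integer_)
  ord <- matches[order(-matches$score), ]
  cutoff <- (1 - window) * ord$score[1]
  keep <- ord[ord$score >= cutoff, ]
  lca_bruteforce(tax, unique(keep$taxid))
}

fake_matches <- function(taxids, scores, identities = NULL) {
  tibble::tibble(accession = sprintf("M%02d", seq_along(taxids)),
                 taxid = taxids, score = scores,
                 identity = identities %||%
                   (if (length(scores)) pmin(1, scores / max(scores))
                    else numeric(0)),
                 fwd_score = scores, rev_score = 0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

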