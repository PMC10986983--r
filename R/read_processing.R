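# Paired-read processing: primer binning, primer/quality trimming, and
# merging or N-linker scaffolding into assignment-ready templates.

#' Folmer CO1 primer pair
#'
#' The LCO1490/HCO2198 primer pair amplifying the ~658 bp CO1 barcode region.
#' @return Tibble with columns `name`, `fwd`, `rev`.
#' @export
folmer_primers <- function() {
  tibble::tibble(
    name = "Folmer",
    fwd = "GGTCAACAAATCATAAAGATATTGG",
    rev = "TAAACTTCAGGGTGACCAAAAAATCA"
  )
}

# IUPAC bitmask encoding: two codes are compatible iff their base sets
# intersect
iupac_masks <- local({
  masks <- NULL
  function() {
    if (is.null(masks)) {
      m <- integer(256)
      base_bit <- c(A = 1L, C = 2L, G = 4L, T = 8L)
      for (code in names(Biostrings::IUPAC_CODE_MAP)) {
        bases <- strsplit(Biostrings::IUPAC_CODE_MAP[[code]], "")[[1]]
        m[utf8ToInt(code)] <- sum(base_bit[bases])
      }
      masks <<- m
    }
    masks
  }
})

# n x width matrix of IUPAC bitmasks for the first `width` characters of each
# string (0 where the string is shorter)
mask_matrix <- function(x, width) {
  pad <- strrep(" ", width)
  pref <- substr(paste0(x, pad), 1, width)
  codes <- utf8ToInt(paste(pref, collapse = ""))
  matrix(iupac_masks()[codes], ncol = width, byrow = TRUE)
}

# does each read carry `primer` (IUPAC-compatible, zero mismatches) starting
# at offset `shift`?
primer_at <- function(reads, primer, shift = 0) {
  plen <- nchar(primer)
  pm <- iupac_masks()[utf8ToInt(primer)]
  rmask <- mask_matrix(substr(reads, shift + 1, shift + plen), plen)
  pmat <- matrix(pm, nrow = nrow(rmask), ncol = plen, byrow = TRUE)
  ok <- matrix(bitwAnd(as.integer(rmask), as.integer(pmat)) > 0, ncol = plen)
  rowSums(ok) == plen & nchar(reads) >= shift + plen
}

locate_primer <- function(reads, primer, max_shift = 0) {
  pos <- rep(NA_integer_, length(reads))
  for (s in 0:max_shift) {
    hit <- is.na(pos) & primer_at(reads, primer, s)
    pos[hit] <- s
  }
  pos
}

#' Bin read pairs by locus from the forward primer
#'
#' Each pair is assigned to at most one locus by an IUPAC-aware match of the
#' full forward primer at the start of the forward read (zero mismatches; the
#' seed length `kmer` caps the minimum primer length accepted). Pairs matching
#' no primer receive locus `"unbinned"`.
#'
#' @param pairs Tibble of read pairs with columns `read_id`, `vial`,
#'   `fwd_seq`, `fwd_qual`, `rev_seq`, `rev_qual`.
#' @param primer_sets Tibble with columns `name`, `fwd`, `rev`
#'   (e.g. [folmer_primers()]).
#' @param kmer Seed length; primers shorter than this are rejected.
#' @param max_shift Maximum offset of the primer start within the read.
#' @return `pairs` with an added `locus` column.
#' @export
bin_by_primer <- function(pairs, primer_sets, kmer = 11, max_shift = 0) {
  if (anyDuplicated(primer_sets$name)) {
    rlang::abort("duplicate primer-set names")
  }
  if (any(nchar(primer_sets$fwd) < kmer)) {
    rlang::abort("forward primer shorter than the seed length")
  }
  locus <- rep("unbinned", nrow(pairs))
  for (i in seq_len(nrow(primer_sets))) {
    open <- locus == "unbinned"
    if (!any(open)) break
    pos <- locate_primer(pairs$fwd_seq[open], primer_sets$fwd[i], max_shift)
    locus[open][!is.na(pos)] <- primer_sets$name[i]
  }
  dplyr::mutate(pairs, locus = locus)
}

# strip the trailing run of bases whose Phred score is below `min_phred`
qtrim_3p <- function(seq, qual, min_phred) {
  if (min_phred <= 0) return(list(seq = seq, qual = qual))
  hi <- 33 + min_phred - 1
  pat <- sprintf("[\\x21-\\x%02X]+$", hi)
  qual2 <- sub(pat, "", qual, perl = TRUE)
  list(seq = substr(seq, 1, nchar(qual2)), qual = qual2)
}

cut_before <- function(seq, qual, site) {
  # truncate at the first occurrence of `site` (read-through into the
  # opposite primer), if any
  pos <- regexpr(site, seq, fixed = TRUE)
  keep <- ifelse(pos > 0, pos - 1, nchar(seq))
  list(seq = substr(seq, 1, keep), qual = substr(qual, 1, keep))
}

#' Trim primers and low-quality tails from binned read pairs
#'
#' Removes the primer (and anything 5' of it) from each read, truncates at
#' read-through into the reverse complement of the opposite primer, and trims
#' 3' bases until the terminal base has Phred `>= min_phred`. Reads emptied by
#' trimming are flagged.
#'
#' @param pairs Binned read pairs (see [bin_by_primer()]).
#' @param fwd_primer,rev_primer Primer sequences for this locus.
#' @param min_phred Phred floor for 3' quality trimming.
#' @param max_shift Maximum primer offset (as in [bin_by_primer()]).
#' @return `pairs` with trimmed sequences/qualities and a logical `empty`
#'   column.
#' @export
trim_pairs <- function(pairs, fwd_primer, rev_primer,
                       min_phred = 10, max_shift = 0) {
  trim_one_side <- function(seq, qual, primer, other_primer) {
    pos <- locate_primer(seq, primer, max_shift)
    start <- ifelse(is.na(pos), 1L, pos + nchar(primer) + 1L)
    seq <- substr(seq, start, nchar(seq))
    qual <- substr(qual, start, nchar(qual))
    rt <- cut_before(seq, qual, revcomp(other_primer))
    qtrim_3p(rt$seq, rt$qual, min_phred)
  }
  f <- trim_one_side(pairs$fwd_seq, pairs$fwd_qual, fwd_primer, rev_primer)
  r <- trim_one_side(pairs$rev_seq, pairs$rev_qual, rev_primer, fwd_primer)
  dplyr::mutate(pairs,
    fwd_seq = f$seq, fwd_qual = f$qual,
    rev_seq = r$seq, rev_qual = r$qual,
    empty = nchar(f$seq) == 0 | nchar(r$seq) == 0)
}

merge_one <- function(fseq, fqual, rseq, rqual, min_overlap, max_diff) {
  rc <- revcomp(rseq)
  rcq <- paste(rev(strsplit(rqual, "")[[1]]), collapse = "")
  nf <- nchar(fseq); nr <- nchar(rc)
  if (nf == 0 || nr == 0) return(NULL)
  best <- NULL
  for (o in seq_len(min(nf, nr))) {
    a <- substr(fseq, nf - o + 1, nf)
    b <- substr(rc, 1, o)
    mism <- sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
    matches <- o - mism
    if (is.null(best) || matches > best$matches) {
      best <- list(o = o, mism = mism, matches = matches)
    }
  }
  if (best$o < min_overlap || best$mism / best$o > max_diff) return(NULL)
  o <- best$o
  fo <- strsplit(substr(fseq, nf - o + 1, nf), "")[[1]]
  bo <- strsplit(substr(rc, 1, o), "")[[1]]
  fq <- utf8ToInt(substr(fqual, nf - o + 1, nf))
  bq <- utf8ToInt(substr(rcq, 1, o))
  cons <- ifelse(fo == bo, fo, ifelse(bq > fq, bo, fo))  # ties -> forward
  paste0(substr(fseq, 1, nf - o), paste(cons, collapse = ""),
         substr(rc, o + 1, nr))
}

#' Merge trimmed read pairs on their overlap
#'
#' Best ungapped overlap of the forward read with the reverse-complemented
#' reverse read; merging succeeds iff the best overlap is at least
#' `min_overlap` bases with a mismatch fraction at most `max_diff`.
#' Conflicting overlap bases take the higher-quality call (ties go to the
#' forward read).
#'
#' @param pairs Trimmed pairs (see [trim_pairs()]).
#' @param min_overlap Minimum overlap length in bases.
#' @param max_diff Maximum mismatch fraction within the overlap.
#' @return Template tibble (columns `template_id`, `vial`, `kind`,
#'   `sequence`, `fwd_len`, `rev_len`); pairs that fail to merge are omitted.
#' @export
merge_pairs <- function(pairs, min_overlap = 80, max_diff = 0.075) {
  merged <- purrr::pmap_chr(
    list(pairs$fwd_seq, pairs$fwd_qual, pairs$rev_seq, pairs$rev_qual),
    function(fs, fq, rs, rq) {
      m <- merge_one(fs, fq, rs, rq, min_overlap, max_diff)
      if (is.null(m)) NA_character_ else m
    })
  ok <- !is.na(merged)
  tibble::tibble(
    template_id = pairs$read_id[ok],
    vial = pairs$vial[ok],
    kind = "merged",
    sequence = merged[ok],
    fwd_len = nchar(pairs$fwd_seq[ok]),
    rev_len = nchar(pairs$rev_seq[ok])
  )
}

#' Scaffold read pairs with an N linker
#'
#' Joins each trimmed forward read to the reverse complement of its reverse
#' read through a run of `linker_n` Ns, the construction used when the
#' amplicon is longer than the combined read length.
#'
#' @param pairs Trimmed pairs (see [trim_pairs()]).
#' @param linker_n Linker length (0 gives plain concatenation, and the
#'   template is then of kind `"merged"`).
#' @return Template tibble as in [merge_pairs()], kind `"scaffolded"`.
#' @export
scaffold_pairs <- function(pairs, linker_n = 15) {
  if (any(nchar(pairs$fwd_seq) == 0 | nchar(pairs$rev_seq) == 0)) {
    rlang::abort("cannot scaffold an empty read")
  }
  tibble::tibble(
    template_id = pairs$read_id,
    vial = pairs$vial,
    kind = if (linker_n > 0) "scaffolded" else "merged",
    sequence = paste0(pairs$fwd_seq, strrep("N", linker_n),
                      revcomp(pairs$rev_seq)),
    fwd_len = nchar(pairs$fwd_seq),
    rev_len = nchar(pairs$rev_seq)
  )
}

#' Process raw read pairs into templates for one locus
#'
#' Bins by primer, trims, and converts the pairs of the target locus into
#' templates by scaffolding (default), merging, or forward-read-only
#' passthrough.
#'
#' @param pairs Raw read pairs (see [bin_by_primer()]).
#' @param primer_sets Primer table; the first row is the target locus unless
#'   `locus` is given.
#' @param locus Name of the locus to carry forward.
#' @param mode `"scaffold"`, `"merge"`, or `"forward_only"`.
#' @param min_phred,kmer,max_shift,linker_n,min_overlap,max_diff
#'   Stage parameters (see the stage functions).
#' @return List with `templates` (tibble) and `report` (per-vial tibble of
#'   reads in, binned, trimmed-empty, and templates out).
#' @export
process_reads <- function(pairs, primer_sets = folmer_primers(),
                          locus = primer_sets$name[1],
                          mode = c("scaffold", "merge", "forward_only"),
                          min_phred = 10, kmer = 11, max_shift = 0,
                          linker_n = 15, min_overlap = 80, max_diff = 0.075) {
  mode <- match.arg(mode)
  binned <- bin_by_primer(pairs, primer_sets, kmer = kmer,
                          max_shift = max_shift)
  target <- dplyr::filter(binned, .data$locus == !!locus)
  prow <- primer_sets[primer_sets$name == locus, ]
  trimmed <- trim_pairs(target, prow$fwd, prow$rev,
                        min_phred = min_phred, max_shift = max_shift)
  usable <- dplyr::filter(trimmed, !.data$empty)
  templates <- switch(mode,
    scaffold = scaffold_pairs(usable, linker_n = linker_n),
    merge = merge_pairs(usable, min_overlap = min_overlap,
                        max_diff = max_diff),
    forward_only = tibble::tibble(
      template_id = usable$read_id, vial = usable$vial,
      kind = "forward_only", sequence = usable$fwd_seq,
      fwd_len = nchar(usable$fwd_seq), rev_len = 0L)
  )
  report <- dplyr::left_join(
    dplyr::count(pairs, .data$vial, name = "reads_in"),
    dplyr::count(target, .data$vial, name = "binned"),
    by = "vial") |>
    dplyr::left_join(dplyr::count(dplyr::filter(trimmed, .data$empty),
                                  .data$vial, name = "trimmed_empty"),
                     by = "vial") |>
    dplyr::left_join(dplyr::count(templates, .data$vial, name = "templates"),
                     by = "vial") |>
    dplyr::mutate(dplyr::across(dplyr::where(is.numeric),
                                ~ tidyr::replace_na(.x, 0L)))
  list(templates = templates, report = report)
}

#' Write templates as FASTA
#'
#' @param templates Template tibble.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_templates_fasta <- function(templates, path) {
  x <- Biostrings::DNAStringSet(templates$sequence)
  names(x) <- sprintf("%s vial=%s kind=%s", templates$template_id,
                      templates$vial, templates$kind)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
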