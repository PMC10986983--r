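# Sequence utilities shared by read processing, clustering, and assignment.
#
# Two distance notions are used deliberately:
#   * template-vs-template identity uses unit-cost edit distance
#     (matches / alignment columns), the analogue of vsearch iddef=1;
#   * template-vs-reference scoring uses a semi-global alignment (free end
#     gaps on the reference) whose score is the number of matched bases, so
#     reference sequence outside the amplicon never penalizes a match.

LINKER_RE_FOR <- function(n) sprintf("N{%d}", n)

#' Reverse complement of DNA strings
#'
#' IUPAC-aware; vectorized.
#' @param x Character vector of DNA sequences.
#' @return Character vector.
#' @export
revcomp <- function(x) {
  out <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
  unname(out)
}

# split a template into its informative segments, dropping a scaffold linker
# (an internal run of exactly `linker_n` Ns); merged / forward-only templates
# come back as a single segment
template_segments <- function(seq, linker_n = 15) {
  if (linker_n <= 0) return(seq)
  parts <- strsplit(seq, LINKER_RE_FOR(linker_n))[[1]]
  parts[nzchar(parts)]
}

# edit-distance identity between two sequences: matches / alignment columns.
# adist() transforms a into b; M (match+sub columns) = nchar(a) - deletions.
edit_identity_1 <- function(a, b) {
  d <- utils::adist(a, b, counts = TRUE)
  cnt <- attr(d, "counts")
  ins <- unname(cnt[, , "ins"][1])
  del <- unname(cnt[, , "del"][1])
  sub <- unname(cnt[, , "sub"][1])
  m <- nchar(a) - del
  cols <- m + ins + del
  matches <- m - sub
  list(identity = if (cols == 0) 0 else matches / cols,
       distance = ins + del + sub, columns = cols, matches = matches)
}

#' Pairwise identity between two templates
#'
#' Edit-distance identity (matched columns over alignment columns). Scaffold
#' linker positions are excluded: when both sequences carry a linker the
#' forward and reverse segments are aligned separately and pooled; otherwise
#' linkers are stripped before a single global comparison.
#'
#' @param a,b DNA strings (possibly scaffolded with an internal N linker).
#' @param linker_n Length of the scaffold linker run (default 15).
#' @return Identity in `[0, 1]`.
#' @export
template_identity <- function(a, b, linker_n = 15) {
  sa <- template_segments(a, linker_n)
  sb <- template_segments(b, linker_n)
  if (length(sa) == length(sb) && length(sa) > 1) {
    tot_m <- 0; tot_c <- 0
    for (i in seq_along(sa)) {
      r <- edit_identity_1(sa[i], sb[i])
      tot_m <- tot_m + r$matches; tot_c <- tot_c + r$columns
    }
    if (tot_c == 0) 0 else tot_m / tot_c
  } else {
    edit_identity_1(paste(sa, collapse = ""), paste(sb, collapse = ""))$identity
  }
}

#' Edit distance between two templates, linker excluded
#'
#' @inheritParams template_identity
#' @return Nonnegative integer edit distance.
#' @export
template_distance <- function(a, b, linker_n = 15) {
  sa <- template_segments(a, linker_n)
  sb <- template_segments(b, linker_n)
  if (length(sa) == length(sb) && length(sa) > 1) {
    sum(vapply(seq_along(sa),
               function(i) edit_identity_1(sa[i], sb[i])$distance, numeric(1)))
  } else {
    edit_identity_1(paste(sa, collapse = ""), paste(sb, collapse = ""))$distance
  }
}

# substitution matrix: +1 match, -1 mismatch, over the full IUPAC alphabet
align_submat <- local({
  mat <- NULL
  function() {
    if (is.null(mat)) {
      mat <<- Biostrings::nucleotideSubstitutionMatrix(
        match = 1, mismatch = -1, baseOnly = FALSE)
    }
    mat
  }
})

# semi-global alignment of one segment (pattern, fully aligned) against a
# reference (subject, free end gaps); returns matched bases, alignment
# columns, and optionally a per-pattern-position match profile
align_segment <- function(segment, ref, profile = FALSE) {
  aln <- Biostrings::pairwiseAlignment(
    segment, ref, type = "global-local",
    substitutionMatrix = align_submat(),
    gapOpening = 0, gapExtension = 1)
  p <- as.character(Biostrings::pattern(aln))
  s <- as.character(Biostrings::subject(aln))
  pc <- strsplit(p, "")[[1]]
  sc <- strsplit(s, "")[[1]]
  matches <- sum(pc == sc & pc != "-")
  out <- list(score = matches, columns = length(pc))
  if (profile) {
    keep <- pc != "-"
    prof <- (pc == sc)[keep]  # per template-position match indicator
    # pad in case the aligner clipped a terminal base
    n <- nchar(segment)
    out$profile <- c(prof, logical(max(0, n - length(prof))))[seq_len(n)]
  }
  out
}

#' Score a template against one reference sequence
#'
#' Each linker-delimited segment of the template is aligned semi-globally to
#' the reference and matched bases are summed across segments; identity is
#' total matches over total alignment columns (linker excluded).
#'
#' @param template DNA string, possibly scaffolded.
#' @param ref Reference DNA string.
#' @param linker_n Scaffold linker length.
#' @param profile Also return a per-position match indicator vector along the
#'   linker-stripped template (used by chimera detection).
#' @return List with `score` (matched bases), `identity`, `per_segment`
#'   (numeric vector of per-segment matched bases), and optionally `profile`.
#' @export
align_to_reference <- function(template, ref, linker_n = 15,
                               profile = FALSE) {
  segs <- template_segments(template, linker_n)
  res <- lapply(segs, align_segment, ref = ref, profile = profile)
  score <- sum(vapply(res, `[[`, numeric(1), "score"))
  cols <- sum(vapply(res, `[[`, numeric(1), "columns"))
  out <- list(score = score,
              identity = if (cols == 0) 0 else score / cols,
              per_segment = vapply(res, `[[`, numeric(1), "score"))
  if (profile) {
    # match indicators along the linker-stripped template coordinates
    out$profile <- unlist(lapply(res, `[[`, "profile"), use.names = FALSE)
    out$columns <- cols
  }
  out
}
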