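# Curated regional reference database: candidate filtering, within-taxon
# dereplication, and FASTA round-trip with rank-tagged lineage headers.

#' Construct a reference sequence table
#'
#' @param accession Character vector of accessions.
#' @param taxid Integer vector of taxids.
#' @param sequence Character vector of IUPAC DNA sequences (primer-internal).
#' @param source One of `"genbank-like"`, `"bold-like"`, `"synthetic"`
#'   (recycled).
#' @return Tibble with columns `accession`, `taxid`, `sequence`, `source`,
#'   `length`.
#' @export
refseq_table <- function(accession, taxid, sequence,
                         source = "genbank-like") {
  sequence <- toupper(sequence)
  bad <- grepl("[^ACGTRYSWKMBDHVN]", sequence)
  if (any(bad)) {
    rlang::abort(paste("non-IUPAC characters in sequence(s):",
                       paste(accession[bad], collapse = ", ")))
  }
  tibble::tibble(
    accession = as.character(accession),
    taxid = as.integer(taxid),
    sequence = sequence,
    source = rep_len(as.character(source), length(accession)),
    length = nchar(sequence)
  )
}

ambiguous_fraction <- function(seq) {
  n_amb <- nchar(gsub("[ACGT]", "", seq))
  ifelse(nchar(seq) == 0, 1, n_amb / nchar(seq))
}

#' Filter candidate reference sequences
#'
#' Retains sequences that meet the length floor, the ambiguous-character cap,
#' and regional-checklist membership. Membership is tested at species level
#' with a genus fallback: a sequence passes if its taxid is on the checklist,
#' or if its genus ancestor is among the genera spanned by the checklist
#' (references labelled only to genus are common in public databases).
#'
#' @param refs A [refseq_table()].
#' @param tax A [taxonomy()].
#' @param checklist Integer vector of checklist taxids (species and/or genera).
#' @param min_length Minimum sequence length in bases.
#' @param max_ambig Maximum allowed fraction of non-ACGT characters.
#' @return Filtered tibble (possibly empty), subset of `refs`.
#' @export
filter_candidates <- function(refs, tax, checklist,
                              min_length = 250, max_ambig = 0.04) {
  if (length(checklist) == 0) rlang::abort("checklist must be nonempty")
  checklist <- as.integer(checklist)
  tax_check(tax, checklist)
  cl_species <- unique(collapse_subspecies(tax, checklist))
  cl_genera <- unique(stats::na.omit(
    ancestor_at_rank(tax, cl_species, "genus")))
  refs <- dplyr::filter(refs,
    .data$length >= min_length,
    ambiguous_fraction(.data$sequence) <= max_ambig)
  if (nrow(refs) == 0) return(refs)
  sp <- collapse_subspecies(tax, refs$taxid)
  gen <- ancestor_at_rank(tax, refs$taxid, "genus")
  keep <- sp %in% cl_species | (!is.na(gen) & gen %in% cl_genera)
  refs[keep, ]
}

#' Dereplicate identical sequences within each taxon
#'
#' Collapses exact full-length duplicate sequences that share a taxid to a
#' single record (the lexicographically first accession). Identical sequences
#' under different taxids are both kept.
#'
#' @param refs A [refseq_table()].
#' @return Dereplicated tibble with a `dereplicated_from` count column.
#' @export
dereplicate_within_taxon <- function(refs) {
  refs |>
    dplyr::arrange(.data$taxid, .data$sequence, .data$accession) |>
    dplyr::group_by(.data$taxid, .data$sequence) |>
    dplyr::summarise(
      accession = dplyr::first(.data$accession),
      source = dplyr::first(.data$source),
      length = dplyr::first(.data$length),
      dereplicated_from = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::select("accession", "taxid", "sequence", "source", "length",
                  "dereplicated_from") |>
    dplyr::arrange(.data$accession)
}

#' Build a reference database in inclusive or curated mode
#'
#' Inclusive mode applies a 250-base length floor; curated mode applies a
#' 400-base floor and within-taxon dereplication. Both apply the ambiguity
#' cap and checklist filter.
#'
#' @inheritParams filter_candidates
#' @param mode `"inclusive"` or `"curated"`.
#' @return Filtered (and, for curated mode, dereplicated) reference tibble
#'   with a `mode` attribute.
#' @export
build_refdb <- function(refs, tax, checklist,
                        mode = c("curated", "inclusive"),
                        max_ambig = 0.04) {
  mode <- match.arg(mode)
  min_length <- if (mode == "curated") 400 else 250
  out <- filter_candidates(refs, tax, checklist,
                           min_length = min_length, max_ambig = max_ambig)
  if (mode == "curated") out <- dereplicate_within_taxon(out)
  attr(out, "mode") <- mode
  out
}

rank_tags <- c(phylum = "p", class = "c", order = "o",
               family = "f", genus = "g", species = "s")

lineage_header <- function(tax, taxid) {
  lin <- lineage(tax, taxid)
  lin <- lin[lin$rank %in% names(rank_tags), ]
  paste(sprintf("%s:%s", rank_tags[lin$rank],
                gsub(" ", "_", lin$name)), collapse = ",")
}

#' Write a reference database as rank-tagged FASTA
#'
#' Headers carry the accession, source, and a semicolon-delimited
#' `tax=` field of rank-tagged lineage names
#' (`p:`, `c:`, `o:`, `f:`, `g:`, `s:`), the layout used by kmer classifiers.
#'
#' @param refs A [refseq_table()].
#' @param tax A [taxonomy()].
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_refdb <- function(refs, tax, path) {
  tax_check(tax, refs$taxid)
  headers <- vapply(seq_len(nrow(refs)), function(i) {
    sprintf("%s;src=%s;tax=%s", refs$accession[i], refs$source[i],
            lineage_header(tax, refs$taxid[i]))
  }, character(1))
  seqs <- Biostrings::DNAStringSet(refs$sequence)
  names(seqs) <- headers
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Read a rank-tagged reference FASTA
#'
#' Taxids are recovered by resolving the most specific lineage name against
#' the supplied taxonomy. A header lacking the deeper tags yields a coarser
#' (truncated) lineage; an unknown rank tag is an error.
#'
#' @param path FASTA path written by [write_refdb()].
#' @param tax A [taxonomy()].
#' @return A [refseq_table()].
#' @export
read_refdb <- function(path, tax) {
  seqs <- Biostrings::readDNAStringSet(path)
  headers <- names(seqs)
  parts <- strsplit(headers, ";", fixed = TRUE)
  rows <- lapply(seq_along(parts), function(i) {
    p <- parts[[i]]
    acc <- p[1]
    src <- sub("^src=", "", p[grepl("^src=", p)][1])
    taxf <- sub("^tax=", "", p[grepl("^tax=", p)][1])
    if (is.na(taxf)) rlang::abort(paste("malformed header:", headers[i]))
    tags <- strsplit(taxf, ",", fixed = TRUE)[[1]]
    tag_rank <- sub(":.*$", "", tags)
    bad <- setdiff(tag_rank, unname(rank_tags))
    if (length(bad)) {
      rlang::abort(paste("unknown rank tag:", paste(bad, collapse = ", ")))
    }
    nm <- gsub("_", " ", sub("^.:", "", tags))
    # most specific tag present, in canonical order
    ord <- match(tag_rank, unname(rank_tags))
    deepest <- nm[which.max(ord)]
    tibble::tibble(accession = acc,
                   taxid = resolve_names(tax, deepest),
                   sequence = as.character(seqs[[i]]),
                   source = ifelse(is.na(src), "genbank-like", src))
  })
  out <- dplyr::bind_rows(rows)
  out$length <- nchar(out$sequence)
  out
}

#' Read a regional checklist TSV
#'
#' Two columns, `name` and `taxid`, mirroring a regional species list.
#'
#' @param path TSV path.
#' @return Tibble with `name` and integer `taxid`.
#' @export
read_checklist <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE) |>
    dplyr::mutate(taxid = as.integer(.data$taxid))
}
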