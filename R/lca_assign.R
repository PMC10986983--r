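# Windowed lowest-common-ancestor taxonomic assignment with identity-based
# rank demotion, and genus-level aggregation of cluster counts.

#' Score a template against every reference in a database
#'
#' Semi-global alignment of each linker-delimited segment against each
#' reference; the score is the total number of matched bases (segment scores
#' summed) and identity is matches over alignment columns, linker excluded.
#' Only references whose score reaches `score_floor` are returned.
#'
#' @param template DNA string (scaffolded, merged, or single sequence).
#' @param refs Reference database ([refseq_table()]).
#' @param score_floor Minimum matched-bases score (default 100).
#' @param linker_n Scaffold linker length.
#' @return Tibble of matches: `accession`, `taxid`, `score`, `identity`,
#'   `fwd_score`, `rev_score` (zero when the template has one segment).
#' @export
score_against_db <- function(template, refs, score_floor = 100,
                             linker_n = 15) {
  if (nrow(refs) == 0) rlang::abort("reference database is empty")
  rows <- lapply(seq_len(nrow(refs)), function(i) {
    a <- align_to_reference(template, refs$sequence[i], linker_n)
    tibble::tibble(
      accession = refs$accession[i],
      taxid = refs$taxid[i],
      score = a$score,
      identity = a$identity,
      fwd_score = a$per_segment[1],
      rev_score = if (length(a$per_segment) > 1) a$per_segment[2] else 0
    )
  })
  out <- dplyr::bind_rows(rows)
  dplyr::filter(out, .data$score >= score_floor)
}

empty_assignment <- function() {
  tibble::tibble(taxid = NA_integer_, name = NA_character_,
                 rank = NA_character_, mean_identity = NA_real_,
                 n_window = 0L, status = "unassigned",
                 demoted_from = NA_character_,
                 window = list(tibble::tibble()))
}

#' Assign a taxon by lowest common ancestor over a score window
#'
#' The window holds every match scoring within `window` of the best score
#' (boundary ties included); the assignment is the LCA of the window taxids
#' (subspecies collapsed to species), and the mean identity is averaged over
#' window members only.
#'
#' @param matches Match tibble from [score_against_db()].
#' @param tax A [taxonomy()].
#' @param window Window fraction below the top score (default 0.03).
#' @return One-row assignment tibble: `taxid`, `name`, `rank`,
#'   `mean_identity`, `n_window`, `status`, `demoted_from`, and a `window`
#'   list-column holding the window matches.
#' @export
lca_window <- function(matches, tax, window = 0.03) {
  if (is.null(matches) || nrow(matches) == 0) return(empty_assignment())
  win <- matches[matches$score >= (1 - window) * max(matches$score), ]
  taxids <- collapse_subspecies(tax, win$taxid)
  assigned <- lca(tax, taxids)
  info <- taxon_info(tax, assigned)
  tibble::tibble(
    taxid = assigned, name = info$name, rank = info$rank,
    mean_identity = mean(win$identity),
    n_window = nrow(win), status = "assigned",
    demoted_from = NA_character_, window = list(win)
  )
}

# demote one taxid to the requested rank, or to the nearest more inclusive
# canonical rank present in its lineage
demote_to <- function(tax, taxid, target_rank) {
  want <- rank_depth(target_rank)
  lin <- lineage(tax, taxid)
  lin <- lin[rank_depth(lin$rank) <= want, ]
  if (nrow(lin) == 0) taxid else lin$taxid[nrow(lin)]
}

#' Demote low-identity assignments to a more inclusive rank
#'
#' Species-level assignments whose mean identity among window members is
#' below `species_min_id` are demoted to genus; genus-level assignments (
#' including those just demoted) below `genus_min_id` are demoted to family.
#' Ranks above family are never demoted. Idempotent.
#'
#' @param assignments Assignment tibble from [lca_window()].
#' @param tax A [taxonomy()].
#' @param species_min_id Identity floor for species-rank calls (default 0.96).
#' @param genus_min_id Identity floor for genus-rank calls (default 0.92).
#' @return Assignment tibble with `taxid`/`name`/`rank`/`demoted_from`
#'   updated.
#' @export
demote <- function(assignments, tax, species_min_id = 0.96,
                   genus_min_id = 0.92) {
  for (i in seq_len(nrow(assignments))) {
    if (assignments$status[i] != "assigned") next
    rank <- assignments$rank[i]
    id <- assignments$mean_identity[i]
    from <- NA_character_
    taxid <- assignments$taxid[i]
    if (rank %in% c("species", "subspecies") && id < species_min_id) {
      from <- "species"
      taxid <- demote_to(tax, taxid, "genus")
      rank <- rank_of(tax, taxid)
    }
    if (rank == "genus" && id < genus_min_id) {
      if (is.na(from)) from <- "genus"
      taxid <- demote_to(tax, taxid, "family")
      rank <- rank_of(tax, taxid)
    }
    if (!is.na(from) && taxid != assignments$taxid[i]) {
      info <- taxon_info(tax, taxid)
      assignments$taxid[i] <- taxid
      assignments$name[i] <- info$name
      assignments$rank[i] <- info$rank
      assignments$demoted_from[i] <- from
    }
  }
  assignments
}

#' Assign all active clusters in a cluster table
#'
#' Runs [score_against_db()], [lca_window()], and [demote()] for every
#' unflagged cluster and returns a per-cluster assignment table carrying the
#' cluster sizes, ready for [counts_table()].
#'
#' @param clusters Cluster tibble (flags set by the screening stages).
#' @param refs Reference database.
#' @param tax A [taxonomy()].
#' @param window,score_floor,species_min_id,genus_min_id,linker_n
#'   Assignment parameters (see the stage functions).
#' @return Assignment tibble with `vial`, `cluster_id`, `size` plus the
#'   [lca_window()] columns.
#' @export
assign_clusters <- function(clusters, refs, tax, window = 0.03,
                            score_floor = 100, species_min_id = 0.96,
                            genus_min_id = 0.92, linker_n = 15) {
  active <- clusters[active_clusters(clusters), ]
  if (nrow(active) == 0) {
    return(dplyr::bind_cols(
      tibble::tibble(vial = character(0), cluster_id = character(0),
                     size = integer(0)),
      empty_assignment()[0, ]))
  }
  rows <- lapply(seq_len(nrow(active)), function(i) {
    m <- score_against_db(active$representative[i], refs,
                          score_floor = score_floor, linker_n = linker_n)
    a <- lca_window(m, tax, window = window)
    a <- demote(a, tax, species_min_id = species_min_id,
                genus_min_id = genus_min_id)
    dplyr::bind_cols(tibble::tibble(vial = active$vial[i],
                                    cluster_id = active$cluster_id[i],
                                    size = active$size[i]), a)
  })
  dplyr::bind_rows(rows)
}

#' Genus-level counts table
#'
#' Sums the sizes of assigned clusters within each vial by the genus ancestor
#' of their assigned taxon; assignments above genus rank are tallied in an
#' `above_genus` column. Row sums equal the assignable reads per vial.
#'
#' @param assignments Assignment tibble from [assign_clusters()].
#' @param tax A [taxonomy()].
#' @return Wide tibble, one row per vial, one column per genus plus
#'   `above_genus`.
#' @export
counts_table <- function(assignments, tax) {
  assigned <- dplyr::filter(assignments, .data$status == "assigned")
  if (nrow(assigned) == 0) {
    return(tibble::tibble(vial = character(0), above_genus = integer(0)))
  }
  genus_id <- ancestor_at_rank(tax, assigned$taxid, "genus")
  genus <- ifelse(is.na(genus_id), "above_genus",
                  taxon_info(tax, ifelse(is.na(genus_id), tax_root(tax),
                                         genus_id))$name)
  assigned |>
    dplyr::mutate(genus = genus) |>
    dplyr::group_by(.data$vial, .data$genus) |>
    dplyr::summarise(reads = sum(.data$size), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "genus", values_from = "reads",
                       values_fill = 0L)
}

#' Genus detections from a counts table
#'
#' @param counts Wide counts table from [counts_table()].
#' @param min_reads Minimum summed reads to call a genus detected.
#' @return Long tibble of detections: `vial`, `genus`, `reads`.
#' @export
detected_genera <- function(counts, min_reads = 1) {
  if (nrow(counts) == 0) {
    return(tibble::tibble(vial = character(0), genus = character(0),
                          reads = integer(0)))
  }
  counts |>
    tidyr::pivot_longer(-"vial", names_to = "genus", values_to = "reads") |>
    dplyr::filter(.data$reads >= min_reads, .data$genus != "above_genus")
}

#' Assign a single finished (Sanger) sequence
#'
#' The identical scoring / windowed-LCA / demotion path used for metabarcode
#' clusters, applied to one unscaffolded sequence.
#'
#' @param seq DNA string.
#' @param refs Reference database.
#' @param tax A [taxonomy()].
#' @inheritParams assign_clusters
#' @return One-row assignment tibble (see [lca_window()]).
#' @export
assign_sanger <- function(seq, refs, tax, window = 0.03, score_floor = 100,
                          species_min_id = 0.96, genus_min_id = 0.92) {
  m <- score_against_db(seq, refs, score_floor = score_floor, linker_n = 0)
  a <- lca_window(m, tax, window = window)
  demote(a, tax, species_min_id = species_min_id,
         genus_min_id = genus_min_id)
}
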