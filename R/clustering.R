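# Per-vial greedy centroid clustering with size propagation, abundance
# grafting, crosstalk censoring, and contaminant / off-phylum / chimera
# screens. Screens only ever set flags; clusters are never deleted, so counts
# reconcile at every stage.

new_cluster_tbl <- function(...) {
  tibble::tibble(...,
                 censored = FALSE, chimera = FALSE,
                 contaminant = FALSE, non_arthropod = FALSE)
}

cluster_one_vial <- function(templates, identity, linker_n, vial) {
  # exact dereplication first: identical templates always co-cluster
  variants <- templates |>
    dplyr::group_by(.data$sequence) |>
    dplyr::summarise(size = dplyr::n(),
                     rep_id = min(.data$template_id), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$size), .data$rep_id)
  cent_seq <- character(0)
  cent_id <- character(0)
  cent_size <- integer(0)
  for (i in seq_len(nrow(variants))) {
    joined <- FALSE
    for (j in seq_along(cent_seq)) {
      if (template_identity(variants$sequence[i], cent_seq[j],
                            linker_n) >= identity) {
        cent_size[j] <- cent_size[j] + variants$size[i]
        joined <- TRUE
        break
      }
    }
    if (!joined) {
      cent_seq <- c(cent_seq, variants$sequence[i])
      cent_id <- c(cent_id, variants$rep_id[i])
      cent_size <- c(cent_size, variants$size[i])
    }
  }
  new_cluster_tbl(vial = vial,
                  cluster_id = paste0(vial, "_c", seq_along(cent_seq)),
                  rep_id = cent_id, representative = cent_seq,
                  size = cent_size)
}

#' Greedy centroid clustering of templates within vials
#'
#' Templates are processed by decreasing abundance (then lexicographic id);
#' each joins the first existing centroid with edit-distance identity at or
#' above the threshold, otherwise founds a new cluster. Identity is matched
#' columns over alignment columns, with scaffold linker positions excluded.
#' Clustering is within-vial; cluster sizes sum to the template count.
#'
#' @param templates Template tibble (see [scaffold_pairs()]).
#' @param identity Identity threshold (default 0.98).
#' @param linker_n Scaffold linker length.
#' @return Cluster tibble with columns `vial`, `cluster_id`, `rep_id`,
#'   `representative`, `size`, and logical flag columns `censored`,
#'   `chimera`, `contaminant`, `non_arthropod`.
#' @export
cluster_greedy <- function(templates, identity = 0.98, linker_n = 15) {
  if (nrow(templates) == 0) rlang::abort("no templates to cluster")
  templates |>
    dplyr::group_by(.data$vial) |>
    dplyr::group_map(~ cluster_one_vial(.x, identity, linker_n, .y$vial)) |>
    dplyr::bind_rows()
}

graft_one_vial <- function(cl, d, linker_n) {
  repeat {
    cl <- dplyr::arrange(cl, dplyr::desc(.data$size), .data$rep_id)
    merged <- FALSE
    for (i in rev(seq_len(nrow(cl)))) {   # smallest first
      if (nrow(cl) < 2) break
      dists <- vapply(seq_len(nrow(cl)), function(j) {
        if (j == i) return(Inf)
        template_distance(cl$representative[i], cl$representative[j],
                          linker_n)
      }, numeric(1))
      cand <- which(dists <= d & cl$size > cl$size[i])
      if (length(cand)) {
        # largest target first, ties lexicographic by rep_id
        tgt <- cand[order(-cl$size[cand], cl$rep_id[cand])][1]
        cl$size[tgt] <- cl$size[tgt] + cl$size[i]
        cl <- cl[-i, ]
        merged <- TRUE
        break
      }
    }
    if (!merged) return(cl)
  }
}

#' Graft rare clusters onto nearby abundant clusters
#'
#' Any cluster whose representative is within edit distance `d` of the
#' representative of a strictly larger cluster in the same vial is merged
#' into it (sizes added), iterating to a fixed point. Total size is
#' conserved.
#'
#' @param clusters Cluster tibble (see [cluster_greedy()]).
#' @param d Maximum edit distance for grafting (default 1).
#' @param linker_n Scaffold linker length.
#' @return Cluster tibble after grafting.
#' @export
graft_rare <- function(clusters, d = 1, linker_n = 15) {
  clusters |>
    dplyr::group_by(.data$vial) |>
    dplyr::group_map(~ graft_one_vial(dplyr::mutate(.x, vial = .y$vial),
                                      d, linker_n)) |>
    dplyr::bind_rows() |>
    dplyr::select(dplyr::all_of(names(clusters)))
}

#' Censor small clusters as putative crosstalk
#'
#' Flags (never removes) clusters with fewer than `min_size` member reads;
#' index-hopping crosstalk typically shows up as such low-count clusters.
#'
#' @param clusters Cluster tibble.
#' @param min_size Minimum size to escape censoring (default 10; a size-10
#'   cluster is kept).
#' @return Cluster tibble with the `censored` flag set.
#' @export
censor_small <- function(clusters, min_size = 10) {
  dplyr::mutate(clusters, censored = .data$size < min_size)
}

active_clusters <- function(clusters) {
  !(clusters$censored | clusters$chimera | clusters$contaminant |
      clusters$non_arthropod)
}

#' Screen clusters against a known contaminant reference
#'
#' Flags clusters whose representative aligns to the screen reference (for
#' the Folmer locus, typically a Wolbachia CO1 accession) at or above
#' `min_identity`.
#'
#' @param clusters Cluster tibble.
#' @param screen_ref Contaminant reference DNA string.
#' @param min_identity Identity threshold (default 0.95).
#' @param linker_n Scaffold linker length.
#' @return Cluster tibble with the `contaminant` flag set.
#' @export
screen_contaminant <- function(clusters, screen_ref, min_identity = 0.95,
                               linker_n = 15) {
  if (nrow(clusters) == 0) return(clusters)
  idx <- which(!clusters$censored)
  hit <- vapply(idx, function(i) {
    align_to_reference(clusters$representative[i], screen_ref,
                       linker_n)$identity >= min_identity
  }, logical(1))
  clusters$contaminant[idx] <- hit
  clusters
}

#' Screen clusters whose best-supported phylum is not Arthropoda
#'
#' Scores each cluster against the reference database (which must include at
#' least one non-arthropod decoy lineage), takes the matches within the LCA
#' score window, and flags the cluster unless the fraction of window members
#' assigned within phylum Arthropoda reaches `min_conf`. Clusters with no
#' match above the score floor are flagged (conservative default).
#'
#' @param clusters Cluster tibble.
#' @param refs Reference database including decoys.
#' @param tax A [taxonomy()].
#' @param min_conf Minimum arthropod support in the window (default 0.8).
#' @param window Score window fraction (default 0.03).
#' @param score_floor Minimum matched-bases score (default 100).
#' @param phylum Name of the required phylum.
#' @param linker_n Scaffold linker length.
#' @return Cluster tibble with the `non_arthropod` flag set.
#' @export
screen_off_phylum <- function(clusters, refs, tax, min_conf = 0.8,
                              window = 0.03, score_floor = 100,
                              phylum = "Arthropoda", linker_n = 15) {
  if (nrow(clusters) == 0) return(clusters)
  ref_phyla <- db_phyla(refs, tax)
  idx <- which(!clusters$censored)
  flag <- vapply(idx, function(i) {
    m <- score_against_db(clusters$representative[i], refs,
                          score_floor = score_floor, linker_n = linker_n)
    phylum_flag(m, refs, ref_phyla, min_conf, window, phylum)
  }, logical(1))
  clusters$non_arthropod[idx] <- flag
  clusters
}

db_phyla <- function(refs, tax) {
  vapply(refs$taxid, function(t) {
    lin <- lineage(tax, t)
    ph <- lin$name[lin$rank == "phylum"]
    if (length(ph)) ph else NA_character_
  }, character(1))
}

# TRUE when the window's support for the required phylum is insufficient
phylum_flag <- function(matches, refs, ref_phyla, min_conf, window,
                        phylum = "Arthropoda") {
  if (nrow(matches) == 0) return(TRUE)
  win <- matches$score >= (1 - window) * max(matches$score)
  support <- mean(ref_phyla[match(matches$accession[win], refs$accession)] ==
                    phylum, na.rm = FALSE)
  is.na(support) || support < min_conf
}

#' Flag chimeric clusters against a reference database
#'
#' A simplified two-parent crossover test: a cluster is flagged when some
#' split point of its (linker-stripped) representative has a left segment at
#' least `min_parent_id` identical to one reference and a right segment at
#' least `min_parent_id` identical to a *different* reference, while the
#' full-length identity to every single reference is at most `max_full_id`.
#' Flags only; clusters are never removed.
#'
#' @param clusters Cluster tibble.
#' @param refs Reference database (the inclusive database in the workflow).
#' @param min_parent_id Per-parent segment identity (default 0.99).
#' @param max_full_id Maximum full-length identity to a single reference for
#'   a chimera call (default 0.95).
#' @param min_segment Minimum segment length considered on each side.
#' @param linker_n Scaffold linker length.
#' @return Cluster tibble with the `chimera` flag set.
#' @export
flag_chimeras <- function(clusters, refs, min_parent_id = 0.99,
                          max_full_id = 0.95, min_segment = 40,
                          linker_n = 15) {
  if (nrow(clusters) == 0 || nrow(refs) == 0) return(clusters)
  idx <- which(!clusters$censored & !clusters$contaminant)
  for (i in idx) {
    al <- lapply(refs$sequence, function(r) {
      align_to_reference(clusters$representative[i], r, linker_n,
                         profile = TRUE)
    })
    clusters$chimera[i] <- chimera_decision(al, refs$sequence,
                                            min_parent_id, max_full_id,
                                            min_segment)
  }
  clusters
}

# two-parent crossover decision from per-reference alignment profiles
chimera_decision <- function(al, ref_seqs, min_parent_id = 0.99,
                             max_full_id = 0.95, min_segment = 40) {
  len <- length(al[[1]]$profile)
  if (len < 2 * min_segment) return(FALSE)
  full_id <- vapply(al, function(p) p$score / p$columns, numeric(1))
  if (any(full_id > max_full_id)) return(FALSE)
  cums <- vapply(al, function(p) cumsum(p$profile), numeric(len))
  tots <- cums[len, ]
  for (s in seq(min_segment, len - min_segment)) {
    left_id <- cums[s, ] / s
    right_id <- (tots - cums[s, ]) / (len - s)
    left_ok <- which(left_id >= min_parent_id)
    right_ok <- which(right_id >= min_parent_id)
    if (length(left_ok) && length(right_ok)) {
      pairs <- expand.grid(a = left_ok, b = right_ok)
      distinct <- pairs$a != pairs$b &
        ref_seqs[pairs$a] != ref_seqs[pairs$b]
      if (any(distinct)) return(TRUE)
    }
  }
  FALSE
}
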