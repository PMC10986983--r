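# End-to-end wiring: one configuration object carrying every stage threshold,
# and a single runner from raw read pairs to the genus counts table.

#' Pipeline configuration with the workflow's default thresholds
#'
#' One flat list of every tunable: primer seed length 11, Phred floor 10,
#' merge overlap 80 at max 7.5% difference, 15-N scaffold linker, 98%
#' clustering identity, graft distance 1, minimum cluster size 10, 95%
#' contaminant identity, 0.8 off-phylum support, matched-bases score floor
#' 100, 3% LCA window, demotion identities 96% (species) and 92% (genus),
#' reference length floors 400 (curated) / 250 (inclusive), 4% ambiguity cap,
#' and the 3 mm intertegular-distance size threshold.
#'
#' @param ... Overrides for any default.
#' @return Named list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    kmer = 11, max_shift = 0, min_phred = 10,
    template_mode = "scaffold", linker_n = 15,
    min_overlap = 80, max_diff = 0.075,
    cluster_identity = 0.98, graft_d = 1, min_cluster_size = 10,
    contaminant_identity = 0.95, phylum_conf = 0.8,
    score_floor = 100, lca_window = 0.03,
    species_min_id = 0.96, genus_min_id = 0.92,
    db_min_length_curated = 400, db_min_length_inclusive = 250,
    max_ambiguity = 0.04, itd_threshold_mm = 3,
    run_chimera_check = TRUE, run_phylum_screen = TRUE
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) {
    rlang::abort(paste("unknown config field:",
                       paste(unknown, collapse = ", ")))
  }
  cfg[names(dots)] <- dots
  structure(cfg, class = "pipeline_config")
}

#' Run the full metabarcoding pipeline on a table of read pairs
#'
#' Primer binning, trimming, scaffolding, per-vial greedy clustering,
#' abundance grafting, crosstalk censoring, contaminant / off-phylum /
#' chimera screening, windowed-LCA assignment with demotion, and genus-level
#' aggregation.
#'
#' @param reads Read-pair tibble (see [bin_by_primer()] for columns).
#' @param refs Reference database ([refseq_table()] / [build_refdb()]).
#' @param tax A [taxonomy()].
#' @param primers Primer table (default [folmer_primers()]).
#' @param screen_ref Optional contaminant reference sequence (DNA string).
#' @param config A [pipeline_config()].
#' @return List of class `beelca_run`: `templates`, `report`, `clusters`,
#'   `assignments`, `counts`, `detections`, `excluded_vials` (vials with no
#'   assignable cluster), and the resolved `config`.
#' @export
run_pipeline <- function(reads, refs, tax, primers = folmer_primers(),
                         screen_ref = NULL, config = pipeline_config()) {
  proc <- process_reads(reads, primers,
                        mode = config$template_mode,
                        min_phred = config$min_phred, kmer = config$kmer,
                        max_shift = config$max_shift,
                        linker_n = config$linker_n,
                        min_overlap = config$min_overlap,
                        max_diff = config$max_diff)
  linker <- if (config$template_mode == "scaffold") config$linker_n else 0
  clusters <- proc$templates |>
    cluster_greedy(identity = config$cluster_identity, linker_n = linker) |>
    graft_rare(d = config$graft_d, linker_n = linker) |>
    censor_small(min_size = config$min_cluster_size)
  if (!is.null(screen_ref)) {
    clusters <- screen_contaminant(clusters, screen_ref,
                                   min_identity = config$contaminant_identity,
                                   linker_n = linker)
  }
  sa <- screen_and_assign(clusters, refs, tax, config, linker)
  clusters <- sa$clusters
  assignments <- sa$assignments
  counts <- counts_table(assignments, tax)
  detections <- detected_genera(counts)
  all_vials <- unique(reads$vial)
  assigned_vials <- unique(assignments$vial[assignments$status == "assigned"])
  structure(list(
    templates = proc$templates, report = proc$report,
    clusters = clusters, assignments = assignments,
    counts = counts, detections = detections,
    excluded_vials = setdiff(all_vials, assigned_vials),
    config = config
  ), class = "beelca_run")
}

# Batched screening and assignment: all cluster segments are aligned to each
# reference in one vectorized call, and the resulting score matrix feeds the
# off-phylum screen, the chimera candidate test, and the LCA assignment.
# Decisions match running screen_off_phylum(), flag_chimeras(), and
# assign_clusters() in sequence.
screen_and_assign <- function(clusters, refs, tax, config, linker) {
  empty <- dplyr::bind_cols(tibble::tibble(vial = character(0),
                                           cluster_id = character(0),
                                           size = integer(0)),
                            empty_assignment()[0, ])
  act <- which(active_clusters(clusters))
  if (length(act) == 0) {
    return(list(clusters = clusters, assignments = empty))
  }
  ref_phyla <- if (isTRUE(config$run_phylum_screen)) db_phyla(refs, tax)
  seg_list <- lapply(clusters$representative[act], template_segments,
                     linker_n = linker)
  nseg <- lengths(seg_list)
  n <- length(act); m <- nrow(refs)
  score <- matrix(0, n, m)
  cols <- matrix(0, n, m)
  seg_scores <- array(0, c(n, m, max(nseg)))
  for (s in seq_len(max(nseg))) {
    has <- which(nseg >= s)
    segs <- vapply(seg_list[has], `[[`, character(1), s)
    for (j in seq_len(m)) {
      aln <- Biostrings::pairwiseAlignment(
        Biostrings::DNAStringSet(segs), refs$sequence[j],
        type = "global-local", substitutionMatrix = align_submat(),
        gapOpening = 0, gapExtension = 1)
      nm <- Biostrings::nmatch(aln)
      ind <- Biostrings::nindel(aln)
      width <- nm + Biostrings::nmismatch(aln) +
        Biostrings::insertion(ind)[, "WidthSum"] +
        Biostrings::deletion(ind)[, "WidthSum"]
      score[has, j] <- score[has, j] + nm
      cols[has, j] <- cols[has, j] + width
      seg_scores[has, j, s] <- nm
    }
  }
  identity <- score / cols
  rows <- list()
  for (k in seq_len(n)) {
    i <- act[k]
    keep <- which(score[k, ] >= config$score_floor)
    matches <- tibble::tibble(
      accession = refs$accession[keep],
      taxid = refs$taxid[keep],
      score = score[k, keep],
      identity = identity[k, keep],
      fwd_score = seg_scores[k, keep, 1],
      rev_score = if (dim(seg_scores)[3] > 1) seg_scores[k, keep, 2] else 0)
    if (isTRUE(config$run_phylum_screen) &&
        phylum_flag(matches, refs, ref_phyla, config$phylum_conf,
                    config$lca_window)) {
      clusters$non_arthropod[i] <- TRUE
      next
    }
    if (isTRUE(config$run_chimera_check) && max(identity[k, ]) <= 0.95) {
      # chimera candidate: no single reference explains the full length
      al <- lapply(refs$sequence, function(r) {
        align_to_reference(clusters$representative[i], r, linker,
                           profile = TRUE)
      })
      if (chimera_decision(al, refs$sequence)) {
        clusters$chimera[i] <- TRUE
        next
      }
    }
    a <- lca_window(matches, tax, window = config$lca_window)
    a <- demote(a, tax, species_min_id = config$species_min_id,
                genus_min_id = config$genus_min_id)
    rows[[length(rows) + 1]] <- dplyr::bind_cols(
      tibble::tibble(vial = clusters$vial[i],
                     cluster_id = clusters$cluster_id[i],
                     size = clusters$size[i]), a)
  }
  assignments <- if (length(rows)) dplyr::bind_rows(rows) else empty
  list(clusters = clusters, assignments = assignments)
}

#' @export
print.beelca_run <- function(x, ...) {
  cat(sprintf(
    "beelca run: %d templates, %d clusters (%d active), %d vials (%d excluded)\n",
    nrow(x$templates), nrow(x$clusters), sum(active_clusters(x$clusters)),
    length(unique(x$templates$vial)), length(x$excluded_vials)))
  cat(sprintf("genera detected: %s\n",
              paste(sort(unique(x$detections$genus)), collapse = ", ")))
  invisible(x)
}

#' @method tidy beelca_run
#' @export
tidy.beelca_run <- function(x, ...) {
  dplyr::select(x$assignments, -"window")
}

#' @method glance beelca_run
#' @export
glance.beelca_run <- function(x, ...) {
  cl <- x$clusters
  tibble::tibble(
    n_templates = nrow(x$templates),
    n_clusters = nrow(cl),
    n_censored = sum(cl$censored),
    n_contaminant = sum(cl$contaminant),
    n_chimera = sum(cl$chimera),
    n_non_arthropod = sum(cl$non_arthropod),
    n_assigned = sum(x$assignments$status == "assigned"),
    n_vials = length(unique(x$templates$vial)),
    n_excluded_vials = length(x$excluded_vials),
    n_genera_detected = length(unique(x$detections$genus))
  )
}

#' Write the per-cluster table of a run as TSV
#'
#' @param run A `beelca_run`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cluster_table <- function(run, path) {
  run$clusters |>
    dplyr::select("vial", "cluster_id", "size", "censored", "chimera",
                  "contaminant", "non_arthropod", "rep_id") |>
    readr::write_tsv(path)
  invisible(path)
}
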