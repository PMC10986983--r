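# Morphology vs molecular concordance: per-bee classification against Sanger
# positive controls, per-vial genus-set agreement, and the two comparison
# statistics (paired t-test on detection frequencies, Wilcoxon rank-sum on
# leg proportions).

#' Classify per-bee Sanger vs morphology concordance
#'
#' Categories: `amplification_failed` (no Sanger sequence), `family_level`
#' (Sanger resolved only to family or above), `species_agreement` (both at
#' species rank and identical), `genus_agreement` (genera match and at most
#' one method reached species rank), and `disagreement` (different genera, or
#' two different species within one genus). `sanger_refined` marks genus
#' agreements where the Sanger call holds the species while morphology
#' stopped at genus. Subspecies collapse to species before comparison.
#'
#' @param bees Tibble with columns `sanger_taxid` (`NA` when amplification
#'   failed) and `morph_taxid`; other columns pass through.
#' @param tax A [taxonomy()].
#' @return `bees` with added `category` and `sanger_refined` columns.
#' @export
classify_bees <- function(bees, tax) {
  classify_one <- function(sanger, morph) {
    if (is.na(sanger)) {
      return(list(category = "amplification_failed", refined = FALSE))
    }
    sanger <- collapse_subspecies(tax, sanger)
    morph <- collapse_subspecies(tax, morph)
    s_rank <- rank_of(tax, sanger)
    m_rank <- rank_of(tax, morph)
    if (!s_rank %in% c("genus", "species")) {
      return(list(category = "family_level", refined = FALSE))
    }
    s_genus <- ancestor_at_rank(tax, sanger, "genus")
    m_genus <- ancestor_at_rank(tax, morph, "genus")
    if (s_rank == "species" && m_rank == "species") {
      cat <- if (sanger == morph) "species_agreement" else "disagreement"
      return(list(category = cat, refined = FALSE))
    }
    if (is.na(m_genus) || is.na(s_genus) || s_genus != m_genus) {
      return(list(category = "disagreement", refined = FALSE))
    }
    list(category = "genus_agreement",
         refined = s_rank == "species" && m_rank == "genus")
  }
  res <- purrr::map2(bees$sanger_taxid, bees$morph_taxid, classify_one)
  dplyr::mutate(bees,
    category = purrr::map_chr(res, "category"),
    sanger_refined = purrr::map_lgl(res, "refined"))
}

#' Summarize a classified bee-comparison table
#'
#' @param classified Output of [classify_bees()].
#' @return One-row tibble: per-category counts, `sanger_refined`, and
#'   `assigned_genus_or_species` (Sanger resolved to genus rank or below).
#' @export
summarize_table1 <- function(classified) {
  cats <- c("species_agreement", "genus_agreement", "disagreement",
            "family_level", "amplification_failed")
  counts <- vapply(cats, function(cc) sum(classified$category == cc),
                   integer(1))
  tibble::tibble(
    n = nrow(classified),
    species_agreement = counts[["species_agreement"]],
    genus_agreement = counts[["genus_agreement"]],
    disagreement = counts[["disagreement"]],
    family_level = counts[["family_level"]],
    amplification_failed = counts[["amplification_failed"]],
    sanger_refined = sum(classified$sanger_refined),
    assigned_genus_or_species = counts[["species_agreement"]] +
      counts[["genus_agreement"]] + counts[["disagreement"]]
  )
}

#' Read the packaged (or an external) bee validation table
#'
#' Loads a TSV of per-bee records — `bee_id`, `sanger_taxid` (`ND` for failed
#' amplification), `sanger_taxon`, `morph_taxon`, `metabarcode_detected` —
#' and resolves the morphological names against the taxonomy. The packaged
#' default is a 66-bee Sanger CO1 validation set from an eastern Iowa
#' grassland bee survey, paired with the packaged regional taxonomy
#' ([regional_taxonomy()]).
#'
#' @param path TSV path; defaults to the packaged table.
#' @param tax A [taxonomy()]; defaults to the packaged regional taxonomy.
#' @return Tibble ready for [classify_bees()] (adds integer `sanger_taxid`
#'   and `morph_taxid`).
#' @export
read_bee_validation <- function(path = NULL, tax = regional_taxonomy()) {
  if (is.null(path)) {
    path <- system.file("extdata", "bee_validation.tsv", package = "beelca")
  }
  raw <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = "c"))
  dplyr::mutate(raw,
    sanger_taxid = ifelse(.data$sanger_taxid == "ND", NA,
                          .data$sanger_taxid),
    sanger_taxid = as.integer(.data$sanger_taxid),
    morph_taxid = resolve_names(tax, .data$morph_taxon))
}

#' The packaged regional taxonomy fixture
#'
#' Node table covering the genera and species of the packaged bee validation
#' set (taxids printed in public records where available, fixture-local ids
#' otherwise).
#'
#' @return A [taxonomy()].
#' @export
regional_taxonomy <- function() {
  read_taxonomy(system.file("extdata", "regional_taxonomy.tsv",
                            package = "beelca"))
}

#' Per-vial agreement between morphological and metabarcoding genus sets
#'
#' For each vial: the genus richness difference (morphology minus
#' metabarcoding), the count of concordant genera (detected by both), and the
#' count of misalignments (genus present in exactly one method). Aggregate:
#' the fraction of vials whose genus sets agree exactly and the mean richness
#' difference.
#'
#' @param morph Long tibble of morphological composition: `vial`, `genus`
#'   (optionally `legs`).
#' @param detected Long tibble of metabarcode detections: `vial`, `genus`
#'   (e.g. from [detected_genera()]).
#' @param exclude_vials Vials to drop (e.g. failed amplification).
#' @return Object of class `vial_concordance`; see [tidy()][generics::tidy]
#'   and [glance()][generics::glance] methods.
#' @export
vial_agreement <- function(morph, detected, exclude_vials = character(0)) {
  morph <- dplyr::filter(morph, !.data$vial %in% exclude_vials)
  detected <- dplyr::filter(detected, !.data$vial %in% exclude_vials)
  per_vial <- purrr::map_dfr(unique(morph$vial), function(v) {
    m <- unique(morph$genus[morph$vial == v])
    d <- unique(detected$genus[detected$vial == v])
    tibble::tibble(
      vial = v,
      n_morph = length(m),
      n_detected = length(d),
      richness_diff = length(m) - length(d),
      n_concordant = length(intersect(m, d)),
      n_misaligned = length(union(m, d)) - length(intersect(m, d)),
      exact_agreement = setequal(m, d)
    )
  })
  structure(list(per_vial = per_vial), class = "vial_concordance")
}

#' @method tidy vial_concordance
#' @export
tidy.vial_concordance <- function(x, ...) x$per_vial

#' @method glance vial_concordance
#' @export
glance.vial_concordance <- function(x, ...) {
  pv <- x$per_vial
  tibble::tibble(
    n_vials = nrow(pv),
    frac_exact_agreement = mean(pv$exact_agreement),
    mean_richness_diff = mean(pv$richness_diff),
    total_concordant = sum(pv$n_concordant),
    total_misaligned = sum(pv$n_misaligned)
  )
}

#' @export
print.vial_concordance <- function(x, ...) {
  g <- glance.vial_concordance(x)
  cat(sprintf(
    "Vial-level concordance: %d vials, %.0f%% exact genus-set agreement,\n",
    g$n_vials, 100 * g$frac_exact_agreement))
  cat(sprintf("mean richness difference (morphology - metabarcoding): %.2f\n",
              g$mean_richness_diff))
  invisible(x)
}

#' Paired t-test on per-genus detection frequencies
#'
#' Two-sided paired t-test comparing, genus by genus, how many vials each
#' method detected the genus in. The statistic is computed on
#' metabarcoding minus morphology, so methods that under-detect relative to
#' morphology give a negative t.
#'
#' @param genus_counts Tibble with columns `genus`, `morph`, `metabarcode`
#'   (detection counts per genus).
#' @return One-row tibble: `statistic`, `df`, `p.value`, `mean_difference`,
#'   `n_genera`.
#' @export
detection_frequency_test <- function(genus_counts) {
  if (nrow(genus_counts) < 2) {
    rlang::abort("need at least 2 genera for the paired t-test")
  }
  d <- genus_counts$metabarcode - genus_counts$morph
  if (stats::sd(d) == 0) {
    # degenerate: constant differences; t is 0 (no difference) or +/-Inf
    stat <- if (mean(d) == 0) 0 else sign(mean(d)) * Inf
    return(tibble::tibble(statistic = stat, df = length(d) - 1,
                          p.value = as.numeric(mean(d) == 0),
                          mean_difference = mean(d),
                          n_genera = nrow(genus_counts)))
  }
  ht <- stats::t.test(genus_counts$metabarcode, genus_counts$morph,
                      paired = TRUE)
  tibble::tibble(
    statistic = unname(ht$statistic),
    df = unname(ht$parameter),
    p.value = ht$p.value,
    mean_difference = unname(ht$estimate),
    n_genera = nrow(genus_counts)
  )
}

#' Wilcoxon rank-sum test on leg proportions by detection outcome
#'
#' Tests whether the proportion of a vial's legs belonging to a genus differs
#' between genera that were and were not detected by metabarcoding. Group
#' means are reported (the detected-group mean is a data-dependent summary,
#' not a test parameter).
#'
#' @param props Tibble with columns `proportion` (in `[0, 1]`) and `detected`
#'   (logical).
#' @return One-row tibble: `statistic` (W), `p.value`, `mean_detected`,
#'   `mean_undetected`, `n_detected`, `n_undetected`.
#' @export
proportion_detection_test <- function(props) {
  det <- props$proportion[props$detected]
  und <- props$proportion[!props$detected]
  if (length(det) == 0 || length(und) == 0) {
    rlang::abort("both detected and undetected groups must be nonempty")
  }
  ht <- stats::wilcox.test(det, und, exact = length(det) + length(und) <= 50)
  tibble::tibble(
    statistic = unname(ht$statistic),
    p.value = ht$p.value,
    mean_detected = mean(det),
    mean_undetected = mean(und),
    n_detected = length(det),
    n_undetected = length(und)
  )
}
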