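# Ground-truthed composite-vial simulator: reference taxa with controlled
# divergence, paired reads with amplification bias / errors / chimeras /
# crosstalk / an off-target contaminant, and matching morphological records.

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

mutate_seq <- function(seq, rate) {
  n <- nchar(seq)
  k <- stats::rbinom(1, n, rate)
  apply_substitutions(seq, k)
}

apply_substitutions <- function(seq, k) {
  if (k == 0) return(seq)
  chars <- strsplit(seq, "")[[1]]
  pos <- sample(length(chars), min(k, length(chars)))
  for (p in pos) {
    chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1)
  }
  paste(chars, collapse = "")
}

apply_indel <- function(seq) {
  n <- nchar(seq)
  p <- sample(n, 1)
  if (stats::runif(1) < 0.5) {
    paste0(substr(seq, 1, p - 1), substr(seq, p + 1, n))          # deletion
  } else {
    paste0(substr(seq, 1, p), sample(c("A", "C", "G", "T"), 1),
           substr(seq, p + 1, n))                                  # insertion
  }
}

pairwise_divergence <- function(a, b) {
  1 - edit_identity_1(a, b)$identity
}

#' Default species pool for the vial simulator
#'
#' Eleven bee genera (18 species) spanning the common large-bodied
#' (Apis-, Bombus-, Melissodes-like) and small-bodied (Lasioglossum-,
#' Halictus-like) fauna of a midwestern grassland survey, including one
#' kleptoparasitic genus (Triepeolus).
#'
#' @return Tibble with columns `genus`, `species`, `family`, `size_class`.
#' @export
default_species_pool <- function() {
  tibble::tribble(
    ~genus, ~n_species, ~family, ~size_class,
    "Apis",          1L, "Apidae",        "large",
    "Bombus",        3L, "Apidae",        "large",
    "Melissodes",    2L, "Apidae",        "large",
    "Svastra",       1L, "Apidae",        "large",
    "Megachile",     1L, "Megachilidae",  "large",
    "Lasioglossum",  3L, "Halictidae",    "small",
    "Halictus",      2L, "Halictidae",    "small",
    "Agapostemon",   1L, "Halictidae",    "small",
    "Ceratina",      1L, "Apidae",        "small",
    "Andrena",       2L, "Andrenidae",    "small",
    "Triepeolus",    1L, "Apidae",        "small"
  ) |>
    dplyr::rowwise() |>
    dplyr::reframe(genus = .data$genus, family = .data$family,
                   size_class = .data$size_class,
                   species = paste(.data$genus,
                                   paste0("sp", seq_len(.data$n_species))))
}

#' Generate a synthetic reference database and taxonomy
#'
#' Builds Folmer-length reference amplicons with controlled divergence
#' structure: genus centroids at least `between_genus_divergence` apart, and
#' species within a genus separated by pairwise divergences spanning
#' `within_genus_divergence`. Genera named in `barcode_gap_off` instead get
#' species separated by less than the LCA score window, so their reads
#' resolve only to genus — the behavior seen for bumblebees at this locus.
#' A Wolbachia-like off-target contaminant and its non-arthropod decoy
#' lineage are included for the screening stages.
#'
#' @param pool Species pool (see [default_species_pool()]).
#' @param length Amplicon length in bases (primer-internal region; default
#'   658).
#' @param between_genus_divergence Minimum pairwise divergence between genus
#'   centroids.
#' @param within_genus_divergence Length-2 range of pairwise congeneric
#'   species divergence.
#' @param barcode_gap_off Character vector of genera whose species are made
#'   nearly indistinguishable (pairwise divergence ~`gap_off_divergence`).
#' @param gap_off_divergence Pairwise species divergence inside a
#'   gap-off genus.
#' @param include_decoy Include the contaminant reference (and its bacterial
#'   lineage) in the database, enabling the off-phylum screen.
#' @param seed Optional RNG seed (makes the database reproducible).
#' @return List: `refs` ([refseq_table()]), `tax` ([taxonomy()]), `species`
#'   (per-species metadata with true sequences), `contaminant`
#'   (accession + sequence), `primers` ([folmer_primers()]).
#' @export
make_references <- function(pool = default_species_pool(), length = 658,
                            between_genus_divergence = 0.10,
                            within_genus_divergence = c(0.035, 0.08),
                            barcode_gap_off = character(0),
                            gap_off_divergence = 0.004,
                            include_decoy = TRUE, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (nrow(pool) == 0) rlang::abort("species pool is empty")
  stray <- setdiff(barcode_gap_off, pool$genus)
  if (length(stray)) {
    rlang::abort(paste("barcode_gap_off genus not in pool:",
                       paste(stray, collapse = ", ")))
  }
  genera <- unique(pool$genus)

  # genus centroids: mutate a common ancestor until all pairs diverge enough
  for (try in 1:50) {
    root_seq <- random_dna(length)
    centroids <- vapply(genera, function(g) mutate_seq(root_seq, 0.15),
                        character(1))
    if (length(genera) == 1) break
    pairs <- utils::combn(seq_along(genera), 2)
    divs <- apply(pairs, 2, function(p) {
      pairwise_divergence(centroids[p[1]], centroids[p[2]])
    })
    if (all(divs >= between_genus_divergence)) break
    if (try == 50) rlang::abort("could not satisfy between-genus divergence")
  }

  # species: offsets from the genus centroid so pairwise divergence between
  # congeners falls inside the requested range (half the range per species)
  species <- pool |>
    dplyr::group_by(.data$genus) |>
    dplyr::mutate(
      gap_off = .data$genus %in% barcode_gap_off,
      d = ifelse(.data$gap_off, gap_off_divergence / 2,
                 stats::runif(dplyr::n(), within_genus_divergence[1] / 2,
                              within_genus_divergence[2] / 2))
    ) |>
    dplyr::ungroup()
  species$sequence <- vapply(seq_len(nrow(species)), function(i) {
    mutate_seq(centroids[[species$genus[i]]], species$d[i])
  }, character(1))

  # taxonomy: root -> Arthropoda -> Insecta -> Hymenoptera -> families ->
  # genera -> species; decoy lineage sits under Proteobacteria
  families <- unique(pool$family)
  fam_id <- stats::setNames(10L + seq_along(families), families)
  gen_id <- stats::setNames(100L + seq_along(genera), genera)
  sp_id <- 1000L + seq_len(nrow(species))
  nodes <- dplyr::bind_rows(
    tibble::tibble(taxid = 1L, name = "root", rank = "no_rank", parent = 1L),
    tibble::tibble(taxid = 2L, name = "Arthropoda", rank = "phylum",
                   parent = 1L),
    tibble::tibble(taxid = 3L, name = "Insecta", rank = "class", parent = 2L),
    tibble::tibble(taxid = 4L, name = "Hymenoptera", rank = "order",
                   parent = 3L),
    tibble::tibble(taxid = unname(fam_id), name = families, rank = "family",
                   parent = 4L),
    tibble::tibble(taxid = unname(gen_id), name = genera, rank = "genus",
                   parent = unname(fam_id[pool$family[match(genera,
                                                            pool$genus)]])),
    tibble::tibble(taxid = sp_id, name = species$species, rank = "species",
                   parent = unname(gen_id[species$genus]))
  )
  decoy_sp_id <- 25L
  if (include_decoy) {
    nodes <- dplyr::bind_rows(nodes, tibble::tribble(
      ~taxid, ~name, ~rank, ~parent,
      20L, "Proteobacteria", "phylum", 1L,
      21L, "Alphaproteobacteria", "class", 20L,
      22L, "Rickettsiales", "order", 21L,
      23L, "Anaplasmataceae", "family", 22L,
      24L, "Wolbachia", "genus", 23L,
      decoy_sp_id, "Wolbachia endosymbiont", "species", 24L
    ))
  }
  tax <- taxonomy(nodes)

  species <- dplyr::mutate(species, taxid = sp_id,
                           accession = sprintf("SYN%04d", sp_id))
  contaminant_seq <- random_dna(length)
  refs <- refseq_table(species$accession, species$taxid, species$sequence,
                       source = "synthetic")
  contaminant <- list(accession = "SYNWOLB1", sequence = contaminant_seq)
  if (include_decoy) {
    refs <- dplyr::bind_rows(refs,
      refseq_table(contaminant$accession, decoy_sp_id, contaminant_seq,
                   source = "synthetic"))
  }
  list(refs = refs, tax = tax,
       species = dplyr::select(species, "taxid", "genus", "species",
                               "family", "size_class", "gap_off",
                               "accession", "sequence"),
       contaminant = contaminant, primers = folmer_primers())
}

#' Simulation configuration for composite vials
#'
#' Defaults emulate the field study design: 1-73 legs per vial averaging ~14,
#' large and small vials, lognormal per-taxon amplification bias with a
#' strongly favored Apis-like taxon, and low rates of sequencing error,
#' chimera formation, index-hopping crosstalk, and Wolbachia-like
#' contamination.
#'
#' @param n_vials Number of composite vials.
#' @param legs_mean,legs_max Legs per vial: 1 + NegBin draw with this mean,
#'   capped at `legs_max`.
#' @param reads_per_leg Expected sequencing depth contributed per leg; the
#'   vial total is NegBin with mean `reads_per_leg * n_legs` and is allocated
#'   to bees multinomially by amplification bias.
#' @param depth_dispersion NegBin size parameter of the vial read total.
#' @param bias_sdlog Lognormal sd (log scale) of per-species amplification
#'   bias; 0 means uniform amplification.
#' @param apis_boost Multiplicative bias for the genus Apis.
#' @param error_rate Per-base substitution rate.
#' @param indel_rate Per-read probability of a single indel.
#' @param chimera_rate Per-read probability of a two-parent splice.
#' @param crosstalk_rate Per-read probability of reassignment to a random
#'   other vial.
#' @param contaminant_rate Expected contaminant reads as a fraction of vial
#'   depth.
#' @param species_resolution Probability morphology resolves a bee to
#'   species.
#' @param focal_genus,focal_resolution A genus identified to species more
#'   reliably, and its resolution probability.
#' @param read_len Read length of each mate in bases.
#' @param seed RNG seed; fixed seed gives byte-identical output.
#' @return Named list of class `sim_config`.
#' @export
sim_config <- function(n_vials = 20, legs_mean = 14, legs_max = 73,
                       reads_per_leg = 50, depth_dispersion = 10,
                       bias_sdlog = 0.8, apis_boost = 4,
                       error_rate = 0.002, indel_rate = 1e-4,
                       chimera_rate = 0.01, crosstalk_rate = 0.002,
                       contaminant_rate = 0.02,
                       species_resolution = 0.65,
                       focal_genus = "Bombus", focal_resolution = 0.85,
                       read_len = 300, seed = NULL) {
  cfg <- as.list(environment())
  rates <- c(cfg$error_rate, cfg$indel_rate, cfg$chimera_rate,
             cfg$crosstalk_rate, cfg$contaminant_rate,
             cfg$species_resolution, cfg$focal_resolution)
  if (any(rates < 0 | rates > 1)) rlang::abort("rates must be in [0, 1]")
  structure(cfg, class = "sim_config")
}

# vectorized over amplicons
build_read_pairs <- function(amplicons, primers, read_len) {
  fp <- primers$fwd[1]; rp <- primers$rev[1]
  n <- nchar(amplicons)
  fwd_t <- pmin(read_len - nchar(fp), n)
  rev_t <- pmin(read_len - nchar(rp), n)
  list(fwd = paste0(fp, substr(amplicons, 1, fwd_t)),
       rev = paste0(rp, revcomp(substr(amplicons, n - rev_t + 1, n))))
}

#' Simulate composite vials: reads, ground truth, morphology records
#'
#' Per vial, draws bees from the size-class-appropriate species pool, a
#' NegBin read total allocated multinomially by legs x amplification bias,
#' and injects substitution/indel errors, two-parent chimeras, cross-vial
#' index-hopping, and contaminant reads, all recorded in the ground truth.
#' Morphological records degrade species to genus with the configured
#' probability.
#'
#' @param config A [sim_config()].
#' @param db A reference bundle from [make_references()].
#' @return List of tibbles: `reads` (paired reads, ready for
#'   [process_reads()]), `truth` (per-read provenance), `bees` (per-bee
#'   ground truth + morphological call), `morph` (per-vial genus leg counts
#'   as morphology reports them), `vials` (vial metadata), and `bias` (the
#'   per-species amplification factors used).
#' @export
simulate_vials <- function(config = sim_config(), db = make_references()) {
  if (!is.null(config$seed)) set.seed(config$seed)
  sp <- db$species
  primers <- db$primers

  bias <- stats::setNames(
    exp(stats::rnorm(nrow(sp), 0, config$bias_sdlog)), sp$taxid)
  bias[sp$genus == "Apis"] <- bias[sp$genus == "Apis"] * config$apis_boost

  months <- rep(c("J", "A"), length.out = config$n_vials)
  sizes <- rep(c("L", "S"), length.out = config$n_vials)
  sites <- 100 + seq_len(config$n_vials)
  vials <- tibble::tibble(
    month = months,
    site = sites,
    size_letter = sizes,
    size_class = ifelse(sizes == "L", "large", "small"),
    vial = sprintf("%s-%03d-%s", months, sites, sizes),
    n_legs = pmin(config$legs_max,
                  1L + stats::rnbinom(config$n_vials,
                                      mu = config$legs_mean - 1, size = 1.5))
  )

  all_bees <- list(); all_reads <- list(); all_truth <- list()
  for (v in seq_len(nrow(vials))) {
    pool_v <- sp[sp$size_class == vials$size_class[v], ]
    picks <- sample(nrow(pool_v), vials$n_legs[v], replace = TRUE)
    bees <- tibble::tibble(
      vial = vials$vial[v],
      bee_id = sprintf("%s-b%03d", vials$vial[v], seq_along(picks)),
      taxid = pool_v$taxid[picks],
      genus = pool_v$genus[picks],
      species = pool_v$species[picks],
      legs = 1L
    )
    depth <- stats::rnbinom(1, mu = config$reads_per_leg * nrow(bees),
                            size = config$depth_dispersion)
    reads_per_bee <- if (depth > 0) {
      as.integer(stats::rmultinom(1, depth, prob = bias[as.character(bees$taxid)]))
    } else {
      integer(nrow(bees))
    }
    amps <- sp$sequence[match(bees$taxid, sp$taxid)]

    vial_reads <- list(); vial_truth <- list()
    for (b in seq_len(nrow(bees))) {
      n <- reads_per_bee[b]
      if (n == 0) next
      amp <- amps[b]
      chim <- stats::runif(n) < config$chimera_rate & nrow(bees) > 1
      nerr <- if (config$error_rate > 0) {
        stats::rbinom(n, nchar(amp), config$error_rate)
      } else integer(n)
      indel <- stats::runif(n) < config$indel_rate
      partner <- rep(NA_character_, n)
      seqs <- rep(amp, n)
      for (r in which(chim)) {
        other <- sample(setdiff(seq_len(nrow(bees)), b), 1)
        cut <- sample(seq(100, nchar(amp) - 100), 1)
        seqs[r] <- paste0(substr(amp, 1, cut),
                          substr(amps[other], cut + 1, nchar(amps[other])))
        partner[r] <- bees$bee_id[other]
      }
      for (r in which(nerr > 0)) {
        seqs[r] <- apply_substitutions(seqs[r], nerr[r])
      }
      for (r in which(indel)) seqs[r] <- apply_indel(seqs[r])
      prs <- build_read_pairs(seqs, primers, config$read_len)
      ids <- sprintf("%s-r%04d", bees$bee_id[b], seq_len(n))
      vial_reads[[b]] <- tibble::tibble(
        read_id = ids, vial = bees$vial[b],
        fwd_seq = unname(prs$fwd),
        fwd_qual = strrep("F", nchar(prs$fwd)),
        rev_seq = unname(prs$rev),
        rev_qual = strrep("F", nchar(prs$rev)))
      vial_truth[[b]] <- tibble::tibble(
        read_id = ids, vial = bees$vial[b], bee_id = bees$bee_id[b],
        taxid = bees$taxid[b], genus = bees$genus[b],
        n_errors = nerr, chimera = chim, chimera_partner = partner,
        contaminant = FALSE, crosstalk_from = NA_character_)
    }
    # contaminant (Wolbachia-like) reads
    n_cont <- stats::rbinom(1, max(depth, 0), config$contaminant_rate)
    if (n_cont > 0) {
      camp <- db$contaminant$sequence
      cseqs <- rep(camp, n_cont)
      if (config$error_rate > 0) {
        ne <- stats::rbinom(n_cont, nchar(camp), config$error_rate)
        for (r in which(ne > 0)) cseqs[r] <- apply_substitutions(cseqs[r], ne[r])
      }
      prs <- build_read_pairs(cseqs, primers, config$read_len)
      ids <- sprintf("%s-cont-r%04d", vials$vial[v], seq_len(n_cont))
      vial_reads[["cont"]] <- tibble::tibble(
        read_id = ids, vial = vials$vial[v],
        fwd_seq = unname(prs$fwd),
        fwd_qual = strrep("F", nchar(prs$fwd)),
        rev_seq = unname(prs$rev),
        rev_qual = strrep("F", nchar(prs$rev)))
      vial_truth[["cont"]] <- tibble::tibble(
        read_id = ids, vial = vials$vial[v], bee_id = NA_character_,
        taxid = NA_integer_, genus = NA_character_,
        n_errors = 0L, chimera = FALSE, chimera_partner = NA_character_,
        contaminant = TRUE, crosstalk_from = NA_character_)
    }
    all_bees[[v]] <- bees
    all_reads[[v]] <- dplyr::bind_rows(vial_reads)
    all_truth[[v]] <- dplyr::bind_rows(vial_truth)
  }
  bees <- dplyr::bind_rows(all_bees)
  reads <- dplyr::bind_rows(all_reads)
  truth <- dplyr::bind_rows(all_truth)

  # index-hopping crosstalk: reassign a fraction of reads to another vial
  if (config$crosstalk_rate > 0 && nrow(vials) > 1 && nrow(reads) > 0) {
    hop <- which(stats::runif(nrow(reads)) < config$crosstalk_rate)
    for (r in hop) {
      dest <- sample(setdiff(vials$vial, reads$vial[r]), 1)
      truth$crosstalk_from[r] <- reads$vial[r]
      reads$vial[r] <- dest
      truth$vial[r] <- dest
    }
  }

  # morphology: species-level call degrades to genus with stated probability
  res_p <- ifelse(bees$genus == config$focal_genus,
                  config$focal_resolution, config$species_resolution)
  to_species <- stats::runif(nrow(bees)) < res_p
  gen_ids <- ancestor_at_rank(db$tax, bees$taxid, "genus")
  bees <- dplyr::mutate(bees,
    morph_taxid = ifelse(to_species, .data$taxid, gen_ids),
    morph_rank = ifelse(to_species, "species", "genus"))
  morph <- bees |>
    dplyr::group_by(.data$vial, .data$genus) |>
    dplyr::summarise(legs = sum(.data$legs), .groups = "drop")

  list(reads = reads, truth = truth, bees = bees, morph = morph,
       vials = dplyr::select(vials, "vial", "month", "site", "size_class",
                             "n_legs"),
       bias = bias)
}

#' Write simulated read pairs as a pair of FASTQ files
#'
#' Phred+33 qualities; read ids carry the vial in a `vial=` comment so the
#' pairing round-trips.
#'
#' @param reads Read tibble from [simulate_vials()].
#' @param fwd_path,rev_path Output FASTQ paths.
#' @return Invisibly, the two paths.
#' @export
write_fastq_pairs <- function(reads, fwd_path, rev_path) {
  ids <- sprintf("%s vial=%s", reads$read_id, reads$vial)
  write_one <- function(seqs, quals, path) {
    x <- Biostrings::DNAStringSet(seqs)
    names(x) <- ids
    Biostrings::writeXStringSet(x, path, format = "fastq",
                                qualities = Biostrings::BStringSet(quals))
  }
  write_one(reads$fwd_seq, reads$fwd_qual, fwd_path)
  write_one(reads$rev_seq, reads$rev_qual, rev_path)
  invisible(c(fwd_path, rev_path))
}

#' Read paired FASTQ files into the read-pair table
#'
#' @param fwd_path,rev_path FASTQ paths written by [write_fastq_pairs()].
#' @return Read-pair tibble (see [bin_by_primer()]).
#' @export
read_fastq_pairs <- function(fwd_path, rev_path) {
  f <- Biostrings::readDNAStringSet(fwd_path, format = "fastq",
                                    with.qualities = TRUE)
  r <- Biostrings::readDNAStringSet(rev_path, format = "fastq",
                                    with.qualities = TRUE)
  ids <- sub(" .*$", "", names(f))
  vial <- sub("^.* vial=", "", names(f))
  tibble::tibble(
    read_id = unname(ids), vial = unname(vial),
    fwd_seq = unname(as.character(f)),
    fwd_qual = unname(as.character(S4Vectors::mcols(f)$qualities)),
    rev_seq = unname(as.character(r)),
    rev_qual = unname(as.character(S4Vectors::mcols(r)$qualities)))
}
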