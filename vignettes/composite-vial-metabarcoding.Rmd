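---
title: "Methods: composite-vial bee metabarcoding and concordance analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: composite-vial bee metabarcoding and concordance analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(beelca)
```

## The problem

Surveys of wild bees increasingly pool tissue — a single leg from every bee
captured at a site visit — into composite vials that are sequenced at the CO1
Folmer barcode locus. The question this package addresses is twofold: how to
turn the resulting paired amplicon reads into defensible genus-level
detections, and how those detections compare with image-based morphological
identification of the same bees. A subset of individually Sanger-sequenced
legs serves as a positive control connecting the two.

## The identification procedure

The workflow, stage by stage:

1. **Primer binning.** Read pairs are assigned to a locus by an IUPAC-aware
   match of the full forward primer at the start of the forward read
   (`bin_by_primer()`). The seed length (default 11) caps the shortest
   primer accepted; the default tolerance is zero mismatches, because a
   substitution anywhere in the primer invalidates every seed window that
   covers it and synthetic reads carry exact primers.
2. **Trimming.** The primer and anything outside it are removed, the read is
   truncated at any read-through into the opposite primer's reverse
   complement, and 3' bases are trimmed until the terminal base has Phred
   quality at least 10 (`trim_pairs()`).
3. **Templates.** The Folmer amplicon (~658 bp) is longer than two 300 b
   reads can span, so by default each pair is *scaffolded*: forward read,
   then a linker of exactly 15 Ns, then the reverse complement of the
   reverse read (`scaffold_pairs()`). Merging on a minimum 80 b overlap with
   at most 7.5% overlap mismatches (`merge_pairs()`) and forward-read-only
   processing are available for shorter loci.
4. **Clustering.** Templates are clustered per vial by greedy centroid
   clustering at 98% identity (`cluster_greedy()`). Identity is
   edit-distance identity — matched columns over alignment columns — with
   linker positions excluded. Processing order is decreasing abundance, then
   lexicographic id, so the output is deterministic; exact duplicates are
   collapsed first, which the greedy rule makes exactly equivalent and much
   faster. Cluster sizes are propagated through every later step.
5. **Grafting and censoring.** Rare clusters within edit distance 1 of a
   strictly larger cluster merge into it to a fixed point
   (`graft_rare()`), emulating amplicon-variant refinement; clusters still
   below 10 reads are flagged as putative index-hopping crosstalk
   (`censor_small()`). Flags are never deletions: every table row survives
   to the final report, so read totals reconcile at each stage. The graft
   step runs before censoring (the rare-variant mass belongs with its
   parent before any size rule is applied); both the distance and the order
   are configurable.
6. **Screens.** Clusters at or above 95% alignment identity to a known
   contaminant reference (a Wolbachia CO1 sequence for this primer set) are
   flagged (`screen_contaminant()`). Clusters whose score-window support for
   phylum Arthropoda falls below 0.8 — including clusters with no reference
   match at all — are flagged (`screen_off_phylum()`); the reference
   database therefore carries at least one non-arthropod decoy lineage.
   Chimeras are flagged by a two-parent crossover test: some split point
   leaves each side at least 99% identical to two *different* references
   while no single reference explains the full length at more than 95%
   (`flag_chimeras()`). This is deliberately a simplified, fully
   deterministic test — it detects constructed splices and passes clean
   reads, which is the property the tests assert — not a reimplementation
   of UCHIME's scoring.
7. **Assignment.** Each surviving cluster is scored against every reference
   by semi-global alignment (free end gaps on the reference); the score is
   the number of matched bases, summed over the forward and reverse
   segments of a scaffolded template, and a floor of 100 matched bases
   filters noise (`score_against_db()`). The assigned taxon is the lowest
   common ancestor of all references scoring within 3% of the best score,
   boundary ties included (`lca_window()`). Mean identity is averaged over
   the window members only — they are the accessions that determined the
   assignment.
8. **Demotion.** Species-level assignments with mean window identity below
   96% are demoted to genus; genus-level assignments below 92% are demoted
   to family, and the two rules cascade (`demote()`). Demotion is
   idempotent, never increases specificity, and never proceeds above
   family. Subspecies collapse to species throughout.
9. **Counts.** Assigned cluster sizes are summed per vial by the genus
   ancestor of the assigned taxon; assignments above genus rank land in an
   `above_genus` column (`counts_table()`). Row sums equal the assignable
   reads of each vial, and vials with no assignable cluster are reported as
   excluded rather than silently dropped.

Sanger sequences from individual legs run through the identical
scoring/LCA/demotion path as single unscaffolded sequences
(`assign_sanger()`).

### Alignment choices

Two distance notions coexist on purpose. Template-vs-template comparisons
(clustering, grafting) use unit-cost edit distance, the analogue of
vsearch's `iddef 1`. Template-vs-reference comparisons use
`Biostrings::pairwiseAlignment` in global-local mode (match +1, mismatch
-1, gap open 0, gap extension 1): the template is aligned end to end while
reference sequence outside the amplicon is free, and only matched bases
count toward the score. A single score metric — matched bases — is used
everywhere a bit score would otherwise appear, with the floor of 100
interpreted in matched bases; both are length-scaled similarity scores and
a self-contained metric keeps every stage reproducible without an external
search tool. Ambiguity codes in references are aligned compatibly but only
exact base agreements count as matches, which at the 4% ambiguity cap
understates identity by well under the demotion margins.

## The reference database

`build_refdb()` filters candidate sequences by length (250 bases in
inclusive mode, 400 in curated mode), by a 4% cap on ambiguous characters,
and by membership in a regional checklist — tested at species rank with a
genus fallback, since public barcode records are often labelled only to
genus. Curated mode additionally collapses exact duplicate sequences within
each taxid (`dereplicate_within_taxon()`); near-duplicates are kept, because
they carry real information about within-taxon variation. Databases
round-trip through FASTA with rank-tagged lineage headers
(`p:`, `c:`, `o:`, `f:`, `g:`, `s:`), the layout kmer classifiers consume.

## The concordance analysis

`classify_bees()` compares each bee's Sanger assignment with its
morphological identification: `species_agreement` needs both at species
rank and identical; `genus_agreement` covers matching genera where at most
one method reached species (with `sanger_refined` marking the cases where
the sequence resolved a genus-only morphological call); two different
species of one genus count as `disagreement`, not genus agreement — the
two methods made incompatible claims at the rank both resolved. Sanger
failures (`ND`) and family-rank assignments form their own categories. The
packaged 66-bee validation table reproduces the expected totals exactly
(29 species agreements, 15 genus agreements, 11 Sanger refinements, 46
genus-or-species assignments, 4 family-level, 16 failures).

At the vial level, `vial_agreement()` reports per-vial genus-set overlap
(concordant genera, misalignments = the symmetric set difference, richness
difference) and the aggregate exact-agreement fraction.
`detection_frequency_test()` is a two-sided paired t-test on per-genus
detection counts, computed as metabarcoding minus morphology so that
under-detection by metabarcoding yields a negative t (identical vectors
return t = 0, p = 1 rather than an error); `proportion_detection_test()` is
a two-sample Wilcoxon rank-sum test on the proportion of a vial's legs
belonging to each genus, grouped by detection outcome, with group means
reported as data summaries.

## What the simulator emulates — and what it does not

`make_references()` + `simulate_vials()` generate fully ground-truthed
cohorts. Design choices and their rationale:

* **Vial structure.** Vials alternate large/small size classes (the 3 mm
  intertegular-distance split), legs per vial are 1 + a negative binomial
  draw with mean ~14 capped at 73, and each bee contributes one leg —
  matching the field design being emulated.
* **Divergence structure.** Genus centroids are mutated copies of a common
  ancestor kept at least 10% divergent pairwise; species within a genus are
  offset so pairwise congeneric divergence spans 3.5–8%. The lower edge sits
  deliberately above the 3% LCA window: congeneric CO1 divergence in bees
  is typically above 4%, and a genus whose species fall inside the score
  window is precisely the *barcode-gap-failure* case, which the generator
  produces explicitly via `barcode_gap_off` (congeners ~0.4% apart, the
  qualitative Bombus situation) rather than by accident at the band edge.
* **Read depth.** The vial total is negative binomial with mean
  `reads_per_leg x n_legs` (dispersion configurable), allocated to bees
  multinomially with weights legs x amplification bias. Reads per bee are
  therefore proportional to legs x bias with overdispersion, while the
  fixed per-library total makes detection depend on a genus's tissue
  *proportion* — the mechanism behind the proportion-vs-detection analysis.
* **Amplification bias.** Lognormal per species (sd 0.8 on the log scale by
  default) with a 4x boost for the Apis-like genus, reflecting the
  honey-bee sensitivity of this primer set.
* **Artefacts.** Substitution errors (default 0.002/base) applied to the
  primer-internal region, occasional single indels, two-parent chimeric
  splices, index-hopping crosstalk that relabels a read's vial, and a
  Wolbachia-like contaminant with its own bacterial lineage for the
  screens. Every artefact is recorded per read in the ground truth.
* **Morphology.** Species-level resolution with probability 0.65 overall
  and 0.85 for the focal (Bombus-like) genus, degrading to genus otherwise
  — the resolution profile of image-based identification.

Not emulated: quality-by-cycle MiSeq error profiles (qualities are constant
high Phred; the quality-trimming path is exercised by unit tests instead),
PhiX spike-ins, primer-site mutations (primers are emitted error-free, so
binning losses are not simulated), and PCR-inhibition failures except as
the degenerate all-censored vial. Passing synthetic tests therefore shows
the pipeline's logic is correct under controlled violations, not that real
MiSeq artefacts are fully captured.

## Problem sizes and numerical choices

The test suite runs desk-scale problems: toy taxonomies up to 50 nodes for
the LCA property checks, 100–400 b sequences for clustering and scoring
oracles, a few hundred fuzz cases per invariant, and end-to-end cohorts of
2–4 vials. The acceptance analyses use a 200-vial bias-sweep cohort
(~55k read pairs, error-free so that detection failures isolate the
abundance/bias mechanism) and a 30-vial barcode-gap cohort; both complete
in minutes on one CPU. Ties are broken deterministically everywhere
(abundance then lexicographic id in clustering; largest target then
lexicographic in grafting; forward-read base on equal-quality merge
conflicts), so fixed seeds give byte-identical output.

## Known limitations

* The chimera test requires near-perfect (99%) parental halves, so chimeras
  of very similar parents — which are also taxonomically harmless — are not
  flagged; full-length identity above 95% to any single reference vetoes
  the call.
* Checklist synonymy is not modelled: names absent from the taxonomy simply
  fail to resolve, mirroring the curation decision to omit unmatchable
  names.
* The windowed LCA inherits the reference database's blind spots: a genus
  with no reference cannot be detected, and uneven reference lengths can
  depress scores for the taxa with shorter records (the reason family-level
  Sanger assignments appear in the validation set).
* Cross-vial clustering is intentionally absent — censoring is a
  within-vial rule, and the emulated workflow applies it per sample.
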