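#' Canonical taxonomic ranks, most inclusive first
#'
#' The hierarchy used throughout the package. `no_rank` nodes are permitted
#' anywhere in a lineage and are skipped by rank queries.
#' @export
TAXON_RANKS <- c("phylum", "class", "order", "family", "genus", "species",
                 "subspecies")

rank_depth <- function(rank) match(rank, TAXON_RANKS)

#' Build a taxonomy from a node table
#'
#' Constructs a validated taxonomy from a data frame of nodes. The root node
#' is its own parent; every other node must reference a parent present in the
#' table. Cycles, duplicate taxids, dangling parents, and multiple roots are
#' rejected.
#'
#' @param nodes A data frame with columns `taxid` (positive integer), `name`
#'   (scientific name), `rank` (one of [TAXON_RANKS] or `"no_rank"`), and
#'   `parent` (taxid of the parent node).
#' @return A tibble of class `taxonomy` with the validated node table.
#' @examples
#' tax <- taxonomy(data.frame(
#'   taxid = c(1, 2, 3), name = c("root", "Apidae", "Apis"),
#'   rank = c("no_rank", "family", "genus"), parent = c(1, 1, 2)
#' ))
#' lca(tax, c(2, 3))
#' @export
taxonomy <- function(nodes) {
  nodes <- tibble::as_tibble(nodes)
  req <- c("taxid", "name", "rank", "parent")
  if (!all(req %in% names(nodes))) {
    rlang::abort(paste("taxonomy nodes need columns:", paste(req, collapse = ", ")))
  }
  nodes <- dplyr::mutate(nodes,
    taxid = as.integer(.data$taxid),
    parent = as.integer(.data$parent),
    name = as.character(.data$name),
    rank = as.character(.data$rank)
  )
  if (anyNA(nodes$taxid) || any(nodes$taxid <= 0)) {
    rlang::abort("taxids must be positive integers")
  }
  if (anyDuplicated(nodes$taxid)) {
    dup <- nodes$taxid[duplicated(nodes$taxid)]
    rlang::abort(paste("duplicate taxid:", paste(unique(dup), collapse = ", ")))
  }
  bad_rank <- setdiff(unique(nodes$rank), c(TAXON_RANKS, "no_rank"))
  if (length(bad_rank)) {
    rlang::abort(paste("unknown rank:", paste(bad_rank, collapse = ", ")))
  }
  missing_parent <- setdiff(nodes$parent, nodes$taxid)
  if (length(missing_parent)) {
    rlang::abort(paste("dangling parent taxid:",
                       paste(missing_parent, collapse = ", ")))
  }
  roots <- nodes$taxid[nodes$taxid == nodes$parent]
  if (length(roots) != 1) {
    rlang::abort("taxonomy must contain exactly one self-parented root")
  }
  # cycle check: every node must reach the root in <= n steps
  parent_of <- stats::setNames(nodes$parent, nodes$taxid)
  n <- nrow(nodes)
  for (t in nodes$taxid) {
    cur <- t
    for (step in seq_len(n + 1)) {
      if (cur == roots) break
      cur <- parent_of[[as.character(cur)]]
      if (step > n) rlang::abort(paste("cycle detected at taxid", t))
    }
    if (cur != roots) rlang::abort(paste("cycle detected at taxid", t))
  }
  structure(nodes, class = c("taxonomy", class(nodes)),
            root = roots)
}

#' Read a taxonomy from a TSV file
#'
#' @param path Path to a tab-separated file with columns
#'   `taxid`, `name`, `rank`, `parent`.
#' @return A [taxonomy()] object.
#' @export
read_taxonomy <- function(path) {
  taxonomy(readr::read_tsv(path, show_col_types = FALSE,
                           col_types = readr::cols()))
}

tax_root <- function(tax) attr(tax, "root")

tax_check <- function(tax, taxids) {
  unknown <- setdiff(taxids, tax$taxid)
  if (length(unknown)) {
    rlang::abort(paste("unknown taxid:", paste(unknown, collapse = ", ")))
  }
}

# root-to-node path of taxids (root first)
tax_path <- function(tax, taxid) {
  parent_of <- stats::setNames(tax$parent, tax$taxid)
  path <- integer(0)
  cur <- taxid
  repeat {
    path <- c(cur, path)
    nxt <- parent_of[[as.character(cur)]]
    if (nxt == cur) break
    cur <- nxt
  }
  path
}

#' Look up taxonomy node rows
#'
#' @param tax A [taxonomy()].
#' @param taxids Integer vector of taxids.
#' @return A tibble with one row per taxid, in input order.
#' @export
taxon_info <- function(tax, taxids) {
  tax_check(tax, taxids)
  tibble::as_tibble(tax)[match(taxids, tax$taxid), ]
}

#' Rank of a node
#'
#' @inheritParams taxon_info
#' @return Character vector of ranks.
#' @export
rank_of <- function(tax, taxids) taxon_info(tax, taxids)$rank

#' Lineage of a node
#'
#' Returns the ordered lineage of a node from phylum down to the node's own
#' rank, skipping `no_rank` nodes.
#'
#' @param tax A [taxonomy()].
#' @param taxid A single taxid.
#' @return Tibble with columns `rank`, `taxid`, `name`, ordered from the most
#'   inclusive rank to the node's own.
#' @export
lineage <- function(tax, taxid) {
  tax_check(tax, taxid)
  path <- tax_path(tax, taxid)
  rows <- taxon_info(tax, path)
  rows <- rows[rows$rank %in% TAXON_RANKS, c("rank", "taxid", "name")]
  rows[order(rank_depth(rows$rank)), ]
}

#' Lowest common ancestor of a set of taxa
#'
#' The deepest node ancestral to (or equal to) every input taxid.
#' `lca(tax, x)` with a single taxid returns that taxid.
#'
#' @param tax A [taxonomy()].
#' @param taxids Nonempty vector of taxids present in `tax`.
#' @return A single taxid.
#' @export
lca <- function(tax, taxids) {
  taxids <- unique(as.integer(taxids))
  if (length(taxids) == 0) rlang::abort("lca() needs at least one taxid")
  tax_check(tax, taxids)
  paths <- lapply(taxids, function(t) tax_path(tax, t))
  minlen <- min(lengths(paths))
  common <- tax_root(tax)
  for (i in seq_len(minlen)) {
    level <- vapply(paths, `[[`, integer(1), i)
    if (all(level == level[1])) common <- level[1] else break
  }
  common
}

#' Ancestor of a node at a requested rank
#'
#' Walks up the lineage (skipping `no_rank` nodes) and returns the unique
#' ancestor-or-self having the requested rank, or `NA` if the lineage lacks
#' that rank or the rank is more specific than the node's own.
#'
#' @param tax A [taxonomy()].
#' @param taxids Vector of taxids.
#' @param rank One of [TAXON_RANKS].
#' @return Integer vector of taxids (`NA` where absent).
#' @export
ancestor_at_rank <- function(tax, taxids, rank) {
  rank <- match.arg(rank, TAXON_RANKS)
  tax_check(tax, taxids)
  vapply(as.integer(taxids), function(t) {
    lin <- lineage(tax, t)
    hit <- lin$taxid[lin$rank == rank]
    if (length(hit)) hit[1] else NA_integer_
  }, integer(1))
}

# subspecies are collapsed to their species for all scoring and comparison
collapse_subspecies <- function(tax, taxids) {
  out <- as.integer(taxids)
  ok <- !is.na(out)
  if (!any(ok)) return(out)
  ranks <- rank_of(tax, out[ok])
  sub <- which(ok)[ranks == "subspecies"]
  for (i in sub) {
    sp <- ancestor_at_rank(tax, out[i], "species")
    if (!is.na(sp)) out[i] <- sp
  }
  out
}

#' Resolve scientific names to taxids
#'
#' Exact name matching against the taxonomy node table.
#'
#' @param tax A [taxonomy()].
#' @param names Character vector of scientific names.
#' @return Integer vector of taxids; errors if any name is absent.
#' @export
resolve_names <- function(tax, names) {
  idx <- match(names, tax$name)
  if (anyNA(idx)) {
    rlang::abort(paste("name not in taxonomy:",
                       paste(unique(names[is.na(idx)]), collapse = ", ")))
  }
  tax$taxid[idx]
}
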