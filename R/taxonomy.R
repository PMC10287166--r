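#' Read (or validate) a taxonomy table
#'
#' A taxonomy is a tibble with columns `taxid`, `parent`, `rank`, `name`.
#' The root's `parent` is `NA` (or equal to its own `taxid`). Every node must
#' reach the root; cycles are rejected.
#'
#' @param x Path to a TSV file, or a data frame.
#' @return Validated taxonomy tibble (class `taxonomy_tbl` prepended).
#' @export
read_taxonomy <- function(x) {
  tax <- if (is.character(x))
    readr::read_tsv(x, col_types = readr::cols(taxid = "c", parent = "c",
                                               rank = "c", name = "c"))
  else tibble::as_tibble(x)
  tax$taxid <- as.character(tax$taxid)
  tax$parent <- as.character(tax$parent)
  stopifnot(all(c("taxid", "parent", "rank", "name") %in% names(tax)))
  if (anyDuplicated(tax$taxid)) stop("duplicate taxid in taxonomy")
  tax$parent[tax$parent == tax$taxid] <- NA_character_
  roots <- tax$taxid[is.na(tax$parent)]
  if (length(roots) != 1L) stop("taxonomy must have exactly one root")
  unknown <- setdiff(tax$parent[!is.na(tax$parent)], tax$taxid)
  if (length(unknown))
    stop("parent ids missing from taxonomy: ",
         paste(unknown, collapse = ", "))
  # cycle check: every node must reach the root
  parent_of <- setNames(tax$parent, tax$taxid)
  for (id in tax$taxid) {
    seen <- character(); cur <- id
    while (!is.na(cur)) {
      if (cur %in% seen) stop("cycle in taxonomy at ", cur)
      seen <- c(seen, cur)
      cur <- parent_of[[cur]]
    }
  }
  class(tax) <- c("taxonomy_tbl", class(tax))
  tax
}

# root-to-node path of taxids
taxonomy_path <- function(taxonomy, id) {
  parent_of <- setNames(taxonomy$parent, taxonomy$taxid)
  if (!id %in% taxonomy$taxid) stop("unknown taxid: ", id)
  path <- character()
  cur <- id
  while (!is.na(cur)) {
    path <- c(cur, path)
    cur <- parent_of[[cur]]
  }
  path
}

#' Lowest common ancestor of a set of taxonomy nodes
#'
#' @param node_ids Character (or coercible) vector of taxids, non-empty.
#' @param taxonomy Taxonomy tibble from [read_taxonomy()].
#' @return The taxid of the deepest node ancestral to (or equal to) every
#'   input.
#' @export
lca <- function(node_ids, taxonomy) {
  node_ids <- unique(as.character(node_ids))
  if (length(node_ids) == 0L) stop("empty node set")
  paths <- lapply(node_ids, function(id) taxonomy_path(taxonomy, id))
  depth <- min(lengths(paths))
  anc <- NULL
  for (d in seq_len(depth)) {
    level <- vapply(paths, `[[`, character(1), d)
    if (all(level == level[1])) anc <- level[1] else break
  }
  anc
}

#' Ancestor of a node at a given rank
#'
#' Walks from the node toward the root and returns the first node (self
#' included) whose rank matches; `NA` when the lineage lacks that rank.
#'
#' @param node Taxid.
#' @param rank Rank name (e.g. `"order"`).
#' @param taxonomy Taxonomy tibble.
#' @return Taxid or `NA`.
#' @export
ancestor_at_rank <- function(node, rank, taxonomy) {
  rank_of <- setNames(taxonomy$rank, taxonomy$taxid)
  path <- rev(taxonomy_path(taxonomy, as.character(node)))  # node -> root
  hit <- path[rank_of[path] == rank]
  if (length(hit)) hit[[1]] else NA_character_
}

#' Per-rank read totals used as normalization denominators
#'
#' Sums reads-per-liter over all contigs whose taxon assignment resolves (at
#' or below) the given rank, per sample. Contigs whose assignment sits above
#' the rank contribute to no total and are reported via the
#' `"dropped_contigs"` attribute.
#'
#' @param rpl Long tibble of abundances: `contig_id`, `sample_id`, `rpl`.
#' @param assignments Tibble `contig_id`, `taxid` (the contig's LCA taxon).
#' @param taxonomy Taxonomy tibble.
#' @param rank Aggregation rank (default `"order"`).
#' @return Tibble `taxid` (the rank-level ancestor), `sample_id`, `total`.
#' @export
order_totals <- function(rpl, assignments, taxonomy, rank = "order") {
  missing_assign <- setdiff(unique(rpl$contig_id), assignments$contig_id)
  if (length(missing_assign))
    message("order_totals: ", length(missing_assign),
            " contig(s) without taxon assignment excluded")
  amap <- assignments[!duplicated(assignments$contig_id), ]
  amap$rank_taxid <- vapply(amap$taxid, ancestor_at_rank, character(1),
                            rank = rank, taxonomy = taxonomy)
  dropped <- amap$contig_id[is.na(amap$rank_taxid)]
  out <- rpl |>
    dplyr::inner_join(amap[, c("contig_id", "rank_taxid")], by = "contig_id") |>
    dplyr::filter(!is.na(.data$rank_taxid)) |>
    dplyr::group_by(taxid = .data$rank_taxid, .data$sample_id) |>
    dplyr::summarise(total = sum(.data$rpl), .groups = "drop")
  attr(out, "dropped_contigs") <- dropped
  out
}
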