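#' Place aligned queries on a reference tree (evolutionary placement)
#'
#' Each query, given as a sequence on the reference-alignment coordinate
#' system (`-` where a reference column is not covered), is attached in turn
#' to the midpoint of every edge of the reference tree by a pendant branch
#' whose length is optimized on \[1e-8, 2\] (golden-section/Brent search,
#' tolerance 1e-6). Per-edge likelihood weight ratios are computed from the
#' optimized log-likelihoods in a numerically stable way and sum to 1 over
#' all edges. The best edge is the likelihood argmax; ties break to the
#' smallest edge id.
#'
#' @param queries Named character vector of aligned query sequences (same
#'   column count as the reference alignment), or a single such string.
#' @param tree,model,ref_alignment Reference tree, [aa_model()], and aligned
#'   reference sequences; ignored when `index` is supplied.
#' @param index Optional precomputed [epa_index()] (reuse across queries).
#' @param min_overlap Minimum number of reference columns a query must cover
#'   (default 10); queries below it are returned unplaced with reason
#'   `"insufficient overlap"`.
#' @param pendant_max Upper bound of the pendant branch length search
#'   (default 2 substitutions/site).
#' @return Tibble with one row per query: `query_id`, `best_edge`,
#'   `best_lwr`, `log_likelihood`, `pendant_length`, `n_columns`, `placed`,
#'   `reason`, and a list-column `edges` holding the per-edge tibble
#'   (`edge_id`, `log_likelihood`, `pendant_length`, `like_weight_ratio`).
#' @export
epa_place <- function(queries, tree = NULL, model = NULL,
                      ref_alignment = NULL, index = NULL,
                      min_overlap = 10, pendant_max = 2) {
  if (is.null(index)) index <- epa_index(tree, model, ref_alignment)
  if (is.null(names(queries)))
    names(queries) <- paste0("query", seq_along(queries))
  purrr::map2_dfr(queries, names(queries), function(q, id)
    place_one(index, q, id, min_overlap, pendant_max))
}

place_one <- function(index, query, query_id, min_overlap, pendant_max) {
  S <- index$n_sites
  if (nchar(query) != S)
    stop("query '", query_id, "' has ", nchar(query),
         " columns; reference alignment has ", S)
  code <- encode_residues(strsplit(query, "")[[1]])
  n_cols <- sum(!is.na(code))
  empty_edges <- tibble::tibble(edge_id = integer(),
                                log_likelihood = numeric(),
                                pendant_length = numeric(),
                                like_weight_ratio = numeric())
  if (n_cols < min_overlap)
    return(tibble::tibble(query_id = query_id, best_edge = NA_integer_,
                          best_lwr = NA_real_, log_likelihood = NA_real_,
                          pendant_length = NA_real_, n_columns = n_cols,
                          placed = FALSE, reason = "insufficient overlap",
                          edges = list(empty_edges)))
  Wq <- index$model$Vinv %*% leaf_partial(query)
  n_edge <- nrow(index$edge_table)
  ll <- numeric(n_edge); pend <- numeric(n_edge)
  for (e in seq_len(n_edge)) {
    opt <- optimize(function(t) edge_loglik(index, e, t, Wq),
                    lower = 1e-8, upper = pendant_max,
                    maximum = TRUE, tol = 1e-6)
    ll[e] <- opt$objective; pend[e] <- opt$maximum
  }
  lwr <- exp(ll - logsumexp(ll))
  lwr <- lwr / sum(lwr)
  best <- which.max(ll)            # first index on ties = smallest edge id
  tibble::tibble(
    query_id = query_id, best_edge = as.integer(best),
    best_lwr = lwr[best], log_likelihood = ll[best],
    pendant_length = pend[best], n_columns = n_cols,
    placed = TRUE, reason = "placed",
    edges = list(tibble::tibble(edge_id = seq_len(n_edge),
                                log_likelihood = ll,
                                pendant_length = pend,
                                like_weight_ratio = lwr)))
}

# leaf labels below an edge (the edge's distal leaf set)
edge_distal_leaves <- function(tree, edge_id) {
  child <- tree$edge[edge_id, 2]
  n_tip <- length(tree$tip.label)
  if (child <= n_tip) return(tree$tip.label[child])
  tips <- phangorn::Descendants(tree, child, type = "tips")[[1]]
  tree$tip.label[tips]
}

#' Filter placements and assign clade and genus
#'
#' A placement is kept when (a) its best-edge likelihood weight ratio exceeds
#' `lwr_min`, (b) the leaves below the best edge all belong to a single genus
#' (i.e. the placement is resolved at genus level or deeper), and (c) that
#' genus's clade label is one of `keep_clades`. Unkept placements carry a
#' reason code (`"lwr"`, `"rank"`, `"clade"`, or the placement failure
#' reason).
#'
#' @param placements Tibble from [epa_place()].
#' @param tree The reference tree used for placement (cladewise order, as
#'   stored in the [epa_index()]).
#' @param annotation Tibble with columns `leaf_label`, `clade`, `genus`
#'   (optionally `species`, `order_taxid`) covering every reference leaf.
#' @param lwr_min Minimum likelihood weight ratio (default 0.8; kept
#'   placements have `best_lwr > lwr_min`).
#' @param keep_clades Clade labels retained (default `c("cladeI", "cladeII")`).
#' @return The placement tibble with columns `clade`, `genus`, `kept`,
#'   `reason` filled in; unresolved genus is reported as `"ambiguous"`.
#' @export
filter_and_assign <- function(placements, tree, annotation, lwr_min = 0.8,
                              keep_clades = c("cladeI", "cladeII")) {
  tree <- ape::reorder.phylo(tree, "cladewise")
  miss <- setdiff(tree$tip.label, annotation$leaf_label)
  if (length(miss))
    stop("unannotated reference leaves: ", paste(miss, collapse = ", "))
  ann <- annotation[match(tree$tip.label, annotation$leaf_label), ]
  rows <- purrr::pmap_dfr(
    list(placements$best_edge, placements$best_lwr, placements$placed,
         placements$reason),
    function(best_edge, best_lwr, placed, reason) {
      if (!isTRUE(placed))
        return(tibble::tibble(clade = NA_character_,
                              genus = NA_character_,
                              kept = FALSE, reason = reason))
      leaves <- edge_distal_leaves(tree, best_edge)
      la <- ann[match(leaves, ann$leaf_label), ]
      genera <- unique(la$genus)
      clades <- unique(la$clade)
      if (best_lwr <= lwr_min)
        tibble::tibble(clade = NA_character_, genus = NA_character_,
                       kept = FALSE, reason = "lwr")
      else if (length(genera) != 1L)
        tibble::tibble(clade = if (length(clades) == 1L) clades else
                         NA_character_,
                       genus = "ambiguous", kept = FALSE, reason = "rank")
      else if (length(clades) != 1L || !(clades %in% keep_clades))
        tibble::tibble(clade = if (length(clades) == 1L) clades else
                         NA_character_,
                       genus = genera, kept = FALSE, reason = "clade")
      else
        tibble::tibble(clade = clades, genus = genera,
                       kept = TRUE, reason = "kept")
    })
  dplyr::bind_cols(
    placements[setdiff(names(placements), c("clade", "genus", "kept",
                                            "reason", "edges"))],
    rows,
    placements["edges"])
}

#' Tidy per-edge placement records
#'
#' Unnests the per-edge tibbles of an [epa_place()] result into one long
#' tibble (one row per query x edge).
#'
#' @param x Placement tibble from [epa_place()].
#' @param ... Unused.
#' @return Tibble with `query_id`, `edge_id`, `log_likelihood`,
#'   `pendant_length`, `like_weight_ratio`.
#' @export
tidy_placements <- function(x, ...) {
  tidyr::unnest(x[, c("query_id", "edges")], "edges")
}
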