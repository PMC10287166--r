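# Newick string with jplace edge numbers: "label:length{edge_num}".
# Edge ids are the rows of tree$edge in cladewise order; the root has no edge.
jplace_tree_string <- function(tree) {
  tree <- ape::reorder.phylo(tree, "cladewise")
  n_tip <- length(tree$tip.label)
  edge_of_child <- match(seq_len(n_tip + tree$Nnode), tree$edge[, 2])
  children_of <- split(tree$edge[, 2], tree$edge[, 1])
  rec <- function(node) {
    e <- edge_of_child[node]
    suffix <- if (is.na(e)) "" else
      sprintf(":%.12g{%d}", tree$edge.length[e], e)
    if (node <= n_tip) return(paste0(tree$tip.label[node], suffix))
    kids <- children_of[[as.character(node)]]
    paste0("(", paste(vapply(kids, rec, character(1)), collapse = ","),
           ")", suffix)
  }
  paste0(rec(n_tip + 1L), ";")
}

#' Write placements to a jplace (version 3) document
#'
#' @param placements Placement tibble from [epa_place()] (optionally filtered
#'   by [filter_and_assign()]); unplaced queries are omitted.
#' @param tree The reference tree the placements refer to.
#' @param path Optional output path; when `NULL` the JSON text is returned.
#' @return The JSON text (invisibly when written to `path`).
#' @export
write_jplace <- function(placements, tree, path = NULL) {
  tree <- ape::reorder.phylo(tree, "cladewise")
  n_edge <- nrow(tree$edge)
  placed <- placements[placements$placed, , drop = FALSE]
  plist <- purrr::map2(placed$edges, placed$query_id, function(ed, id) {
    if (any(ed$edge_id < 1 | ed$edge_id > n_edge))
      stop("placement for '", id, "' references an unknown edge")
    list(p = purrr::pmap(ed, function(edge_id, log_likelihood,
                                      pendant_length, like_weight_ratio)
           list(edge_id, log_likelihood, like_weight_ratio, pendant_length)),
         n = list(id))
  })
  doc <- list(
    version = 3L,
    tree = jplace_tree_string(tree),
    placements = plist,
    fields = list("edge_num", "likelihood", "like_weight_ratio",
                  "pendant_length"),
    metadata = list(software = "dielplace")
  )
  txt <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' Read a jplace (version 3) document
#'
#' @param path Path to a jplace file, or a JSON string.
#' @return List with `tree` (an `ape::phylo`; edge numbers in
#'   `$edge_numbers`, one per `tree$edge` row), and `placements`, a long
#'   tibble (`query_id`, `edge_num`, `log_likelihood`, `like_weight_ratio`,
#'   `pendant_length`).
#' @export
read_jplace <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(doc$version) || doc$version < 3)
    stop("unsupported jplace version")
  fields <- unlist(doc$fields)
  tree_txt <- doc$tree
  # pull the {edge_num} tags out, then parse the remaining plain Newick
  plain <- gsub("\\{[0-9]+\\}", "", tree_txt)
  tree <- ape::read.tree(text = plain)
  tree <- ape::reorder.phylo(tree, "cladewise")
  num_re <- regmatches(tree_txt, gregexpr("\\{([0-9]+)\\}", tree_txt))[[1]]
  edge_numbers <- as.integer(gsub("[{}]", "", num_re))
  rows <- purrr::map_dfr(doc$placements, function(pl) {
    name <- if (!is.null(pl$n)) pl$n[[1]] else pl$nm[[1]][[1]]
    purrr::map_dfr(pl$p, function(p) {
      v <- setNames(p, fields)
      tibble::tibble(query_id = name,
                     edge_num = as.integer(v[["edge_num"]]),
                     log_likelihood = as.numeric(v[["likelihood"]]),
                     like_weight_ratio = as.numeric(v[["like_weight_ratio"]]),
                     pendant_length = as.numeric(v[["pendant_length"]]))
    })
  })
  if (nrow(rows) == 0L)
    rows <- tibble::tibble(query_id = character(), edge_num = integer(),
                           log_likelihood = numeric(),
                           like_weight_ratio = numeric(),
                           pendant_length = numeric())
  list(tree = tree, edge_numbers = edge_numbers, placements = rows)
}
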