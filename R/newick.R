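#' Read a Newick tree with validation
#'
#' Thin wrapper over [ape::read.tree()] that additionally rejects malformed
#' strings and duplicate leaf labels, and checks branch lengths.
#'
#' @param text Newick string, or `NULL` when `path` is given.
#' @param path Path to a Newick file.
#' @return An `ape::phylo` tree in cladewise order.
#' @export
read_newick <- function(text = NULL, path = NULL) {
  if (is.null(text)) text <- paste(readLines(path), collapse = "")
  n_open <- lengths(regmatches(text, gregexpr("\\(", text)))
  n_close <- lengths(regmatches(text, gregexpr("\\)", text)))
  if (n_open != n_close)
    stop("unbalanced parentheses in Newick (", n_open, " '(' vs ",
         n_close, " ')')")
  tree <- tryCatch(ape::read.tree(text = text),
                   error = function(e) stop("Newick parse error: ",
                                            conditionMessage(e)))
  if (is.null(tree)) stop("Newick parse error: no tree found")
  dup <- tree$tip.label[duplicated(tree$tip.label)]
  if (length(dup))
    stop("duplicate leaf labels: ", paste(unique(dup), collapse = ", "))
  if (!is.null(tree$edge.length) && any(!is.finite(tree$edge.length)))
    stop("non-finite branch lengths")
  ape::reorder.phylo(tree, "cladewise")
}

#' Write a tree as Newick
#'
#' @param tree An `ape::phylo`.
#' @param path Optional output file; when `NULL` the string is returned.
#' @param digits Significant digits for branch lengths (default 12, ample for
#'   1e-9 round-trips).
#' @return Newick string (invisibly when written to file).
#' @export
write_newick <- function(tree, path = NULL, digits = 12) {
  txt <- ape::write.tree(tree, digits = digits)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}
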