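# Leaf conditional-likelihood matrix (20 x n_sites); gaps/unknowns are
# missing data (all-ones partial).
leaf_partial <- function(seq_string) {
  code <- encode_residues(strsplit(seq_string, "")[[1]])
  S <- length(code)
  m <- matrix(0, 20, S)
  obs <- which(!is.na(code))
  m[cbind(code[obs], obs)] <- 1
  if (length(obs) < S) m[, setdiff(seq_len(S), obs)] <- 1
  m
}

# Postorder (tip-to-root) conditional likelihoods for every node.
# Returns list over nodes; each element list over rate categories of a
# 20 x n_sites matrix.
postorder_partials <- function(tree, model, alignment) {
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  k <- model$n_cat
  miss <- setdiff(tree$tip.label, names(alignment))
  if (length(miss))
    stop("leaf absent from alignment: ", paste(miss, collapse = ", "))
  S <- nchar(alignment[[tree$tip.label[1]]])
  part <- vector("list", n_node)
  for (i in seq_len(n_tip)) {
    lp <- leaf_partial(alignment[[tree$tip.label[i]]])
    part[[i]] <- rep(list(lp), k)
  }
  po <- ape::reorder.phylo(tree, "postorder")
  for (e in seq_len(nrow(po$edge))) {
    parent <- po$edge[e, 1]; child <- po$edge[e, 2]
    b <- po$edge.length[e]
    if (is.null(part[[parent]]))
      part[[parent]] <- rep(list(matrix(1, 20, S)), k)
    for (r in seq_len(k)) {
      msg <- prob_matrix(model, b, model$rates[r]) %*% part[[child]][[r]]
      part[[parent]][[r]] <- part[[parent]][[r]] * msg
    }
  }
  part
}

#' Phylogenetic log-likelihood by Felsenstein pruning
#'
#' Computes the log-likelihood of aligned leaf sequences on a tree under an
#' amino-acid substitution model with discrete-gamma rate heterogeneity,
#' averaging site likelihoods over the rate categories. Gap characters are
#' treated as missing data, so an all-gap column contributes exactly 0.
#'
#' @param tree An `ape::phylo` tree with branch lengths (rooted or with a
#'   basal multifurcation; the model is time-reversible so the root placement
#'   does not change the value).
#' @param model An [aa_model()].
#' @param alignment Named character vector of aligned sequences, one per leaf
#'   label, equal lengths, `-` for gaps.
#' @return Log-likelihood (scalar).
#' @export
felsenstein_loglik <- function(tree, model, alignment) {
  if (any(tree$edge.length < 0)) stop("negative branch length")
  part <- postorder_partials(tree, model, alignment)
  root <- length(tree$tip.label) + 1L
  site_lik <- 0
  for (r in seq_len(model$n_cat))
    site_lik <- site_lik + colSums(model$pi * part[[root]][[r]])
  sum(log(site_lik / model$n_cat))
}

# ---------------------------------------------------------------------------
# EPA support: per-edge "below" and "above" partials, pre-transformed so a
# pendant-length likelihood evaluation is O(20 * n_sites) per rate category.

#' Precompute the per-edge attachment index for phylogenetic placement
#'
#' For every edge of the reference tree this combines the conditional
#' likelihood of the data below the edge and above the edge, both propagated
#' to the edge midpoint, so queries can be attached and their pendant branch
#' length optimized cheaply. Edges are numbered by their row in `tree$edge`
#' (cladewise order).
#'
#' @param tree Reference `phylo` (rooted, branch lengths in subst./site).
#' @param model An [aa_model()].
#' @param ref_alignment Named character vector: aligned reference sequences
#'   (one per leaf label).
#' @return Object of class `epa_index`.
#' @export
epa_index <- function(tree, model, ref_alignment) {
  tree <- ape::reorder.phylo(tree, "cladewise")
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L
  k <- model$n_cat
  S <- nchar(ref_alignment[[tree$tip.label[1]]])
  B <- postorder_partials(tree, model, ref_alignment)
  edges <- tree$edge
  n_edge <- nrow(edges)

  # messages P(b_e) %*% B[child_e] reused by both recursions
  msg <- vector("list", n_edge)
  for (e in seq_len(n_edge)) {
    msg[[e]] <- lapply(seq_len(k), function(r)
      prob_matrix(model, tree$edge.length[e], model$rates[r]) %*%
        B[[edges[e, 2]]][[r]])
  }

  children_of <- split(seq_len(n_edge), edges[, 1])
  parent_edge <- match(edges[, 1], edges[, 2])  # NA for edges off the root

  # A[[e]]: likelihood of all data outside subtree(child_e), as a function of
  # the state at parent_e (per rate). Cladewise order guarantees the parent
  # edge is processed first.
  A <- vector("list", n_edge)
  for (e in seq_len(n_edge)) {
    p <- edges[e, 1]
    sibs <- setdiff(children_of[[as.character(p)]], e)
    acc <- rep(list(matrix(1, 20, S)), k)
    for (s in sibs)
      for (r in seq_len(k)) acc[[r]] <- acc[[r]] * msg[[s]][[r]]
    pe <- parent_edge[e]
    if (!is.na(pe)) {
      bp <- tree$edge.length[pe]
      for (r in seq_len(k)) {
        up <- prob_matrix(model, bp, model$rates[r]) %*% A[[pe]][[r]]
        acc[[r]] <- acc[[r]] * up
      }
    }
    A[[e]] <- acc
  }

  # U[[e]][[r]] = [P(b/2) B_child] * [P(b/2) A_e] at the midpoint, weighted by
  # pi and pre-rotated by t(V) so the query message needs no matrix product.
  VM <- vector("list", n_edge)
  for (e in seq_len(n_edge)) {
    half <- tree$edge.length[e] / 2
    VM[[e]] <- vector("list", k)
    for (r in seq_len(k)) {
      Ph <- prob_matrix(model, half, model$rates[r])
      U <- (Ph %*% B[[edges[e, 2]]][[r]]) * (Ph %*% A[[e]][[r]])
      VM[[e]][[r]] <- crossprod(model$V, model$pi * U)   # 20 x S
    }
  }

  structure(list(tree = tree, model = model, n_sites = S,
                 edge_table = tibble::tibble(
                   edge_id = seq_len(n_edge),
                   parent = edges[, 1], child = edges[, 2],
                   length = tree$edge.length),
                 VM = VM),
            class = "epa_index")
}

#' @export
print.epa_index <- function(x, ...) {
  cat("<epa_index> ", nrow(x$edge_table), " edges, ", x$n_sites,
      " alignment columns\n", sep = "")
  invisible(x)
}

# log-likelihood of the tree with the query attached to edge e at its
# midpoint with pendant length t. Wq = Vinv %*% query_partial.
edge_loglik <- function(index, e, t, Wq) {
  model <- index$model
  site_lik <- 0
  for (r in seq_len(model$n_cat)) {
    d <- exp(model$lambda * t * model$rates[r])
    site_lik <- site_lik + colSums(index$VM[[e]][[r]] * (d * Wq))
  }
  site_lik[site_lik < 1e-300] <- 1e-300
  sum(log(site_lik / model$n_cat))
}
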