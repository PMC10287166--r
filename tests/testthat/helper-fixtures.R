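# Shared fixtures, cached per test run.

.fix <- new.env()

fix_model <- function(alpha = 1) {
  key <- paste0("model_", alpha)
  if (is.null(.fix[[key]])) .fix[[key]] <- aa_model(alpha = alpha)
  .fix[[key]]
}

# small annotated reference: tree + alignment + epa index
fix_reference <- function(seed = 3, n_per_genus = 2, length = 120) {
  key <- sprintf("ref_%d_%d_%d", seed, n_per_genus, length)
  if (is.null(.fix[[key]])) {
    m <- fix_model()
    ref <- sim_tree(n_per_genus = n_per_genus, seed = seed)
    aln <- evolve_sequences(ref$tree, m, length, seed = seed + 1)
    .fix[[key]] <- list(tree = ref$tree, annotation = ref$annotation,
                        alignment = aln, model = m,
                        index = epa_index(ref$tree, m, aln))
  }
  .fix[[key]]
}

# random taxonomy: node "n1" is the root; parents drawn among earlier nodes
rand_taxonomy <- function(n = 500, seed = 1) {
  set.seed(seed)
  ranks <- c("root", "domain", "phylum", "class", "order", "family",
             "genus", "species")
  taxid <- paste0("n", seq_len(n))
  parent <- c(NA_character_,
              vapply(2:n, function(i) taxid[sample.int(i - 1L, 1L)],
                     character(1)))
  # rank = depth capped at species
  depth <- integer(n); depth[1] <- 1L
  for (i in 2:n) depth[i] <- depth[match(parent[i], taxid)] + 1L
  read_taxonomy(tibble::tibble(
    taxid = taxid, parent = parent,
    rank = ranks[pmin(depth, length(ranks))], name = taxid))
}
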