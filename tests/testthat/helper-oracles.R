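# Independent oracles used to cross-check the package's implementations.
# Each is deliberately written by a different route (brute force, exhaustive
# enumeration, closed form) than the code it checks.

# LCA by explicit ancestor-set intersection with maximal depth
oracle_lca <- function(ids, taxonomy) {
  parent_of <- stats::setNames(taxonomy$parent, taxonomy$taxid)
  ancestors <- function(id) {
    out <- character()
    while (!is.na(id)) { out <- c(out, id); id <- parent_of[[id]] }
    out
  }
  common <- Reduce(intersect, lapply(unique(as.character(ids)), ancestors))
  depths <- vapply(common, function(a) length(ancestors(a)), integer(1))
  common[which.max(depths)]
}

# umbrella statistic by direct enumeration of every cross-group pair
oracle_umbrella <- function(values, tod, peak, period = 24) {
  phases <- sort(unique(tod %% period))
  k <- length(phases)
  cyc <- function(a, b) { d <- (a - b) %% period; min(d, period - d) }
  s <- 0
  for (j in seq_len(k)) {
    p1 <- phases[j]; p2 <- phases[j %% k + 1]
    g1 <- values[tod %% period == p1]; g2 <- values[tod %% period == p2]
    d1 <- cyc(p1, peak); d2 <- cyc(p2, peak)
    for (a in g1) for (b in g2) {
      if (d2 < d1) s <- s + (b > a) + 0.5 * (b == a)
      else if (d2 > d1) s <- s + (a > b) + 0.5 * (b == a)
      else s <- s + 0.5
    }
  }
  s
}

# best placement edge by regrafting the query onto each edge midpoint over a
# pendant-length grid and recomputing the full-tree likelihood from scratch
oracle_best_edge <- function(tree, model, aln, qseq,
                             grid = c(1e-6, 0.01, 0.05, 0.1, 0.2, 0.4,
                                      0.8, 1.5)) {
  tree <- ape::reorder.phylo(tree, "cladewise")
  best <- -Inf; best_e <- NA_integer_
  for (e in seq_len(nrow(tree$edge))) {
    child <- tree$edge[e, 2]; blen <- tree$edge.length[e]
    for (pend in grid) {
      tip <- structure(list(edge = matrix(c(2L, 1L), 1, 2),
                            tip.label = "QUERY__", edge.length = pend,
                            Nnode = 1L), class = "phylo")
      tr2 <- ape::bind.tree(tree, tip, where = child, position = blen / 2)
      ll <- felsenstein_loglik(tr2, model,
                               c(aln, stats::setNames(qseq, "QUERY__")))
      if (ll > best) { best <- ll; best_e <- e }
    }
  }
  best_e
}

# global alignment identity by a simple Needleman-Wunsch maximizing matches
# (match 1, mismatch 0, gap -0.5); identity = matches / alignment columns
oracle_identity <- function(a, b) {
  x <- strsplit(a, "")[[1]]; y <- strsplit(b, "")[[1]]
  n <- length(x); m <- length(y)
  S <- matrix(0, n + 1, m + 1)
  S[, 1] <- -0.5 * (0:n); S[1, ] <- -0.5 * (0:m)
  for (i in 1:n) for (j in 1:m)
    S[i + 1, j + 1] <- max(S[i, j] + (x[i] == y[j]),
                           S[i, j + 1] - 0.5, S[i + 1, j] - 0.5)
  # traceback counting matches and columns
  i <- n; j <- m; matches <- 0; cols <- 0
  while (i > 0 || j > 0) {
    if (i > 0 && j > 0 &&
        abs(S[i + 1, j + 1] - (S[i, j] + (x[i] == y[j]))) < 1e-12) {
      matches <- matches + (x[i] == y[j]); i <- i - 1; j <- j - 1
    } else if (i > 0 &&
               abs(S[i + 1, j + 1] - (S[i, j + 1] - 0.5)) < 1e-12) {
      i <- i - 1
    } else {
      j <- j - 1
    }
    cols <- cols + 1
  }
  matches / cols
}
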