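# Genus pools used by the synthetic reference tree, with plausible
# order-level taxonomy for each genus. Purely synthetic stand-ins for a
# curated reference set.
GENUS_ORDERS <- c(
  Fragilariopsis = "Bacillariales", Pseudonitzschia = "Bacillariales",
  Cylindrotheca = "Bacillariales",
  Thalassiosira = "Thalassiosirales", Skeletonema = "Thalassiosirales",
  Minutocellus = "Thalassiosirales",
  Chaetoceros = "Chaetocerotales",
  Amphora = "Thalassiophysales",
  Synechococcus = "Synechococcales", Prochlorococcus = "Synechococcales",
  Ostreococcus = "Mamiellales", Emiliania = "Isochrysidales")

DEFAULT_GENERA <- list(
  cladeI = c("Fragilariopsis", "Pseudonitzschia", "Thalassiosira"),
  cladeII = c("Chaetoceros", "Amphora", "Cylindrotheca"),
  outgroup = c("Synechococcus", "Ostreococcus"))

# Random coalescent-style (Yule-shaped) joining of newick fragments with
# exponential branch lengths. Fragments carry no trailing branch length;
# lengths are attached when fragments are joined.
join_random <- function(parts, mean_branch) {
  while (length(parts) > 1L) {
    i <- sample.int(length(parts), 2L)
    bl <- rexp(2, rate = 1 / mean_branch)
    joined <- sprintf("(%s:%.8f,%s:%.8f)", parts[i[1]], bl[1],
                      parts[i[2]], bl[2])
    parts <- c(parts[-i], joined)
  }
  parts
}

#' Simulate an annotated reference phylogeny
#'
#' Builds a rooted reference tree in which each genus is a monophyletic
#' subtree of species leaves, genera nest monophyletically within their
#' clade (cladeI, cladeII, outgroup), and branch lengths are exponential
#' with the given mean. Topologies are random-joining (Yule-shaped) at every
#' level, so clade and genus monophyly hold by construction.
#'
#' @param n_per_genus Species leaves per genus (default 3).
#' @param genera Named list with character vectors `cladeI`, `cladeII`,
#'   `outgroup` of genus names (defaults drawn from a built-in pool with
#'   order-level taxonomy).
#' @param mean_branch Mean branch length in substitutions/site (default 0.1).
#' @param seed Integer seed.
#' @return List with `tree` (`phylo`, cladewise) and `annotation` tibble
#'   (`leaf_label`, `clade`, `genus`, `species`, `order_taxid`).
#' @export
sim_tree <- function(n_per_genus = 3, genera = DEFAULT_GENERA,
                     mean_branch = 0.1, seed = 1) {
  stopifnot(n_per_genus >= 1, mean_branch > 0)
  unknown <- setdiff(unlist(genera), names(GENUS_ORDERS))
  if (length(unknown))
    stop("no order mapping for genus: ", paste(unknown, collapse = ", "))
  set.seed(seed)
  ann <- list()
  clade_parts <- character()
  for (clade in c("cladeI", "cladeII", "outgroup")) {
    gs <- genera[[clade]]
    if (is.null(gs) || length(gs) == 0L)
      stop("clade '", clade, "' has no genera")
    genus_parts <- vapply(gs, function(g) {
      labs <- sprintf("%s_sp%d", g, seq_len(n_per_genus))
      ann[[length(ann) + 1L]] <<- tibble::tibble(
        leaf_label = labs, clade = clade, genus = g,
        species = sprintf("%s sp%d", g, seq_len(n_per_genus)),
        order_taxid = unname(GENUS_ORDERS[g]))
      join_random(labs, mean_branch)
    }, character(1))
    clade_parts <- c(clade_parts, join_random(genus_parts, mean_branch))
  }
  bl <- rexp(4, 1 / mean_branch)
  nwk <- sprintf("((%s:%.8f,%s:%.8f):%.8f,%s:%.8f);",
                 clade_parts[1], bl[1], clade_parts[2], bl[2], bl[3],
                 clade_parts[3], bl[4])
  tree <- read_newick(text = nwk)
  list(tree = tree, annotation = dplyr::bind_rows(ann))
}

# evolve one sequence along a branch; cats = per-site rate category
evolve_branch <- function(seq_int, model, branch, cats) {
  if (branch == 0) return(seq_int)
  out <- integer(length(seq_int))
  for (r in sort(unique(cats))) {
    P <- prob_matrix(model, branch, model$rates[r])
    P[P < 0] <- 0          # clip spectral round-off before sampling
    idx <- which(cats == r)
    for (a in unique(seq_int[idx])) {
      pos <- idx[seq_int[idx] == a]
      out[pos] <- sample.int(20L, length(pos), replace = TRUE, prob = P[a, ])
    }
  }
  out
}

#' Evolve amino-acid sequences along a tree
#'
#' Draws the root sequence from the model's equilibrium frequencies, assigns
#' each site a discrete-gamma rate category (shared across the whole tree),
#' and applies `P(b * r)` along each branch.
#'
#' @param tree `phylo` with branch lengths.
#' @param model An [aa_model()].
#' @param length Number of sites (>= 1).
#' @param seed Integer seed.
#' @return Named character vector of aligned leaf sequences, with attributes
#'   `"site_categories"` (integer per site) and `"root_sequence"`.
#' @export
evolve_sequences <- function(tree, model, length, seed = 1) {
  stopifnot(length >= 1)
  set.seed(seed)
  tree <- ape::reorder.phylo(tree, "cladewise")
  n_tip <- base::length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  cats <- sample.int(model$n_cat, length, replace = TRUE)
  seqs <- vector("list", n_node)
  root <- n_tip + 1L
  seqs[[root]] <- sample.int(20L, length, replace = TRUE, prob = model$pi)
  for (e in seq_len(nrow(tree$edge))) {
    parent <- tree$edge[e, 1]; child <- tree$edge[e, 2]
    seqs[[child]] <- evolve_branch(seqs[[parent]], model,
                                   tree$edge.length[e], cats)
  }
  out <- vapply(seq_len(n_tip), function(i)
    paste(AA_LEVELS[seqs[[i]]], collapse = ""), character(1))
  names(out) <- tree$tip.label
  attr(out, "site_categories") <- cats
  attr(out, "root_sequence") <- seqs[[root]]
  out
}

#' Simulate environmental query sequences of known origin
#'
#' Each query is a reference leaf's sequence evolved further by a pendant
#' divergence, optionally truncated to a random contiguous span of the
#' alignment columns (everything outside the span becomes a gap).
#'
#' @param alignment Leaf alignment from [evolve_sequences()] (its
#'   `"site_categories"` attribute is reused so rate heterogeneity is
#'   consistent).
#' @param model An [aa_model()].
#' @param annotation Annotation tibble from [sim_tree()].
#' @param source_leaves Leaf labels to evolve queries from (recycled to
#'   `n_queries`).
#' @param n_queries Number of queries.
#' @param pendant Pendant divergence in substitutions/site (default 0.1).
#' @param truncate Truncate queries to a random contiguous span?
#' @param min_frac Minimum spanned fraction of columns when truncating
#'   (default 0.6).
#' @param seed Integer seed.
#' @return List with `queries` (named character vector, aligned to the
#'   reference columns) and `truth` tibble (`query_id`, `source_leaf`,
#'   `clade`, `genus`, `pendant`).
#' @export
sim_queries <- function(alignment, model, annotation, source_leaves,
                        n_queries = length(source_leaves), pendant = 0.1,
                        truncate = FALSE, min_frac = 0.6, seed = 1) {
  stopifnot(all(source_leaves %in% names(alignment)))
  set.seed(seed)
  cats <- attr(alignment, "site_categories")
  S <- nchar(alignment[[1]])
  if (is.null(cats)) cats <- rep(1L, S)
  src <- rep_len(source_leaves, n_queries)
  queries <- character(n_queries)
  for (i in seq_len(n_queries)) {
    base_int <- encode_residues(strsplit(alignment[[src[i]]], "")[[1]])
    q <- evolve_branch(base_int, model, pendant, cats)
    chars <- AA_LEVELS[q]
    if (truncate) {
      w <- max(ceiling(min_frac * S), 10L)
      len <- sample(w:S, 1L)
      start <- sample.int(S - len + 1L, 1L)
      keep <- seq(start, start + len - 1L)
      chars[-keep] <- "-"
    }
    queries[i] <- paste(chars, collapse = "")
  }
  names(queries) <- sprintf("q%03d", seq_len(n_queries))
  ann <- annotation[match(src, annotation$leaf_label), ]
  list(queries = queries,
       truth = tibble::tibble(query_id = names(queries), source_leaf = src,
                              clade = ann$clade, genus = ann$genus,
                              pendant = pendant))
}

#' Synthetic taxonomy covering the reference genera
#'
#' Builds a small rooted taxonomy (root, domain, phylum, class, order,
#' genus, species) containing every genus in the annotation plus its order
#' lineage, using names as taxids.
#'
#' @param annotation Annotation tibble from [sim_tree()].
#' @return Taxonomy tibble (see [read_taxonomy()]).
#' @export
sim_taxonomy <- function(annotation) {
  orders <- unique(annotation$order_taxid)
  rows <- list(
    tibble::tibble(taxid = "root", parent = NA_character_, rank = "root",
                   name = "root"),
    tibble::tibble(taxid = "Eukaryota", parent = "root", rank = "domain",
                   name = "Eukaryota"),
    tibble::tibble(taxid = "Plankton", parent = "Eukaryota", rank = "phylum",
                   name = "Plankton"),
    tibble::tibble(taxid = "Algae", parent = "Plankton", rank = "class",
                   name = "Algae"),
    tibble::tibble(taxid = orders, parent = "Algae", rank = "order",
                   name = orders))
  gen <- unique(annotation[, c("genus", "order_taxid")])
  rows <- c(rows, list(
    tibble::tibble(taxid = gen$genus, parent = gen$order_taxid,
                   rank = "genus", name = gen$genus)))
  sp <- unique(annotation[, c("species", "genus")])
  sp_id <- gsub(" ", "_", sp$species)
  rows <- c(rows, list(
    tibble::tibble(taxid = sp_id, parent = sp$genus, rank = "species",
                   name = sp$species)))
  read_taxonomy(dplyr::bind_rows(rows))
}

#' Simulate a diel metatranscriptome count table with spike-ins
#'
#' Emulates the cruise sampling design: duplicate samples every `interval`
#' hours for `n_days` days, two filter size fractions, `n_standards`
#' internal mRNA standards per sample, and per-contig multiplicative
#' (exponential-cosinor) diel signal with negative-binomial counts:
#'
#'   E\[abundance\](contig, t) = baseline * exp(A * cos(2 pi (t - phase)/24))
#'
#' Per-sample sequencing depth is governed by a lognormal copies-per-read
#' factor; spike-in recovered reads are Poisson around added copies /
#' factor. Background contigs per taxonomic order supply the denominator
#' mass for order-level normalization.
#'
#' @param contigs Tibble describing the focal contigs: `contig_id`, `taxid`
#'   (taxonomy node for the LCA assignment), `baseline` (expected
#'   transcripts per liter at amplitude 0; spike-in-normalized abundances
#'   are of order 1e6-1e9/L), `amplitude` (log-amplitude A, 0 = arrhythmic),
#'   `phase` (peak hour in \[0, 24)).
#' @param taxonomy Taxonomy tibble (e.g. [sim_taxonomy()]).
#' @param n_days,interval Days sampled and sampling interval in hours
#'   (defaults 4 d, every 4 h).
#' @param start_hour Local time of the first sample (default 6, i.e. dawn;
#'   the sampled times of day are then 6, 10, 14, 18, 22, 2 h).
#' @param n_replicates Replicates per timepoint (default 2).
#' @param size_fractions Size-fraction labels (default 0.2 and 3 micron).
#' @param liters Liters filtered per sample (default 2).
#' @param n_standards Spike-in standards per sample (default 14).
#' @param added_copies Copies of each standard added (default 5e9).
#' @param copies_per_read Median copies-per-read factor (default 5e4).
#' @param factor_cv Lognormal sdlog of the per-sample factor (default 0.3).
#' @param dispersion Negative-binomial dispersion (variance = mu + disp *
#'   mu^2); 0 gives Poisson counts (default 0.3).
#' @param n_background Background contigs per order (default 5).
#' @param background_mean Expected transcripts/L of each background contig
#'   (default 1e8).
#' @param seed Integer seed.
#' @return List: `counts`, `meta` (`sample_id`, `station`, `hours`,
#'   `replicate`, `size_fraction`, `liters`), `spikeins`, `assignments`
#'   (focal + background contigs), `sample_truth` (true per-sample factor),
#'   `contig_params`.
#' @export
sim_metatranscriptome <- function(contigs, taxonomy,
                                  n_days = 4, interval = 4,
                                  start_hour = 6,
                                  n_replicates = 2,
                                  size_fractions = c("0.2um", "3um"),
                                  liters = 2,
                                  n_standards = 14, added_copies = 5e9,
                                  copies_per_read = 5e4, factor_cv = 0.3,
                                  dispersion = 0.3,
                                  n_background = 5, background_mean = 1e8,
                                  seed = 1) {
  stopifnot(n_days >= 1, interval >= 1, n_replicates >= 1, liters > 0,
            n_standards >= 1, dispersion >= 0)
  set.seed(seed)
  hours <- start_hour + seq(0, n_days * 24 - interval, by = interval)
  meta <- tidyr::expand_grid(hours = hours,
                             replicate = seq_len(n_replicates),
                             size_fraction = size_fractions)
  meta$station <- sprintf("T%03d", meta$hours)
  meta$sample_id <- sprintf("%s_R%d_F%s", meta$station, meta$replicate,
                            meta$size_fraction)
  meta$liters <- liters
  meta <- tibble::as_tibble(meta[, c("sample_id", "station", "hours",
                                     "replicate", "size_fraction", "liters")])

  # background contigs: flat expected abundance, one set per order present
  orders <- unique(vapply(contigs$taxid, ancestor_at_rank, character(1),
                          rank = "order", taxonomy = taxonomy))
  orders <- orders[!is.na(orders)]
  bg <- tidyr::expand_grid(order_taxid = orders, i = seq_len(n_background))
  bg$contig_id <- sprintf("bg_%s_%d", bg$order_taxid, bg$i)
  background <- tibble::tibble(contig_id = bg$contig_id,
                               taxid = bg$order_taxid,
                               baseline = background_mean,
                               amplitude = 0, phase = 0)
  all_contigs <- dplyr::bind_rows(
    contigs[, c("contig_id", "taxid", "baseline", "amplitude", "phase")],
    background)

  factor_true <- rlnorm(nrow(meta), meanlog = log(copies_per_read),
                        sdlog = factor_cv)
  names(factor_true) <- meta$sample_id

  n_frac <- length(size_fractions)
  draw_counts <- function(mu) {
    if (dispersion <= 0) rpois(length(mu), mu)
    else rnbinom(length(mu), size = 1 / dispersion, mu = mu)
  }
  counts <- tidyr::expand_grid(contig_id = all_contigs$contig_id,
                               sample_id = meta$sample_id)
  counts <- dplyr::inner_join(counts, all_contigs, by = "contig_id")
  counts <- dplyr::inner_join(counts, meta, by = "sample_id")
  mu_rpl <- counts$baseline / n_frac *
    exp(counts$amplitude * cos(2 * pi * (counts$hours - counts$phase) / 24))
  mu_reads <- mu_rpl * counts$liters / factor_true[counts$sample_id]
  counts$count <- draw_counts(mu_reads)
  counts <- counts[, c("contig_id", "sample_id", "count")]

  spikeins <- tidyr::expand_grid(sample_id = meta$sample_id,
                                 standard_id = sprintf("std%02d",
                                                       seq_len(n_standards)))
  spikeins$added_copies <- added_copies
  spikeins$recovered_reads <- rpois(
    nrow(spikeins), added_copies / factor_true[spikeins$sample_id])

  list(counts = tibble::as_tibble(counts),
       meta = meta,
       spikeins = tibble::as_tibble(spikeins),
       assignments = all_contigs[, c("contig_id", "taxid")],
       sample_truth = tibble::tibble(sample_id = meta$sample_id,
                                     factor = unname(factor_true)),
       contig_params = all_contigs)
}

#' Build a long diel series table from reads-per-liter values
#'
#' Sums the size fractions within each (contig, timepoint, replicate) so the
#' result feeds [detect_rhythms()] directly.
#'
#' @param rpl Long tibble `contig_id`, `sample_id`, `rpl`.
#' @param meta Sample table with `sample_id`, `hours`, `replicate`.
#' @return Tibble `contig_id`, `hours`, `replicate`, `value`.
#' @export
build_diel_series <- function(rpl, meta) {
  rpl |>
    dplyr::inner_join(meta[, c("sample_id", "hours", "replicate")],
                      by = "sample_id") |>
    dplyr::group_by(.data$contig_id, .data$hours, .data$replicate) |>
    dplyr::summarise(value = sum(.data$rpl), .groups = "drop")
}
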