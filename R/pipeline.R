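#' Default pipeline configuration
#'
#' Returns the configuration list [run_pipeline()] expects, pre-filled with
#' the workflow's fixed thresholds (recruitment E-value 0.001, dereplication
#' identity 0.99, placement LWR 0.8, FDR 0.05). Input paths must be filled
#' in by the caller (or by [write_pipeline_inputs()] for synthetic data).
#'
#' @param ... Named overrides of any default entry.
#' @return Named list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    ref_tree = NULL, ref_alignment = NULL, annotation = NULL,
    queries = NULL, taxonomy = NULL, counts = NULL, meta = NULL,
    spikeins = NULL, assignments = NULL,
    e_max = 0.001, identity = 0.99, lwr_min = 0.8, q_max = 0.05,
    min_overlap = 10, alpha = 1, n_cat = 4,
    n_sims = 2000, sim_length = 150, n_perm = 999,
    seed = 1, spike_in = TRUE, run_rhythm = TRUE,
    out_dir = NULL)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop("unknown config entries: ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  cfg
}

validate_config <- function(cfg) {
  req <- c("ref_tree", "ref_alignment", "annotation", "queries", "taxonomy",
           "counts", "meta")
  for (f in req)
    if (is.null(cfg[[f]]) || !file.exists(cfg[[f]]))
      stop("config error: missing input '", f, "'")
  with(cfg, {
    stopifnot(e_max > 0, identity > 0, identity <= 1,
              lwr_min >= 0, lwr_min <= 1, q_max > 0, q_max <= 1)
  })
  if (isTRUE(cfg$spike_in)) {
    if (is.null(cfg$spikeins) || !file.exists(cfg$spikeins))
      stop("config error: spike-in mode is on but no spike-in table given")
    sp <- readr::read_tsv(cfg$spikeins, show_col_types = FALSE)
    need <- c("sample_id", "standard_id", "added_copies", "recovered_reads")
    if (!all(need %in% names(sp)))
      stop("config error: spike-in table lacks column(s): ",
           paste(setdiff(need, names(sp)), collapse = ", "))
  }
  invisible(cfg)
}

#' Write synthetic pipeline inputs to a directory
#'
#' Generates a complete synthetic dataset (reference tree + alignment +
#' annotation, queries of known origin, taxonomy, diel count table with
#' spike-ins) and writes every file the pipeline consumes, plus the ground
#' truth.
#'
#' @param dir Output directory (created if needed).
#' @param seed Integer seed driving all generators.
#' @param n_per_genus,seq_length,n_queries,pendant,amplitude,peak_phase
#'   Generator knobs: species per genus (3), alignment columns (150),
#'   number of environmental queries (12), query pendant divergence (0.1),
#'   diel log-amplitude of rhythmic contigs (1.5) and their peak hour (6).
#' @param frac_rhythmic Fraction of query contigs given a diel signal
#'   (default ~13/19, mirroring the cruise series design).
#' @return Named list of file paths (invisibly also written to
#'   `dir/config.yaml`).
#' @export
write_pipeline_inputs <- function(dir, seed = 1, n_per_genus = 3,
                                  seq_length = 150, n_queries = 12,
                                  pendant = 0.1, amplitude = 1.5,
                                  peak_phase = 6,
                                  frac_rhythmic = 13 / 19) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  model <- aa_model()
  ref <- sim_tree(n_per_genus = n_per_genus, seed = seed)
  aln <- evolve_sequences(ref$tree, model, seq_length, seed = seed + 1)
  sources <- ref$annotation$leaf_label[ref$annotation$clade == "cladeII"]
  qs <- sim_queries(aln, model, ref$annotation, sources,
                    n_queries = n_queries, pendant = pendant,
                    seed = seed + 2)
  tax <- sim_taxonomy(ref$annotation)
  set.seed(seed + 3)
  n_r <- max(1L, round(frac_rhythmic * n_queries))
  rhythmic <- seq_len(n_queries) <= n_r
  contigs <- tibble::tibble(
    contig_id = qs$truth$query_id,
    taxid = gsub(" ", "_",
                 ref$annotation$species[match(qs$truth$source_leaf,
                                              ref$annotation$leaf_label)]),
    baseline = 1e7,
    amplitude = ifelse(rhythmic, amplitude, 0),
    phase = peak_phase)
  mt <- sim_metatranscriptome(contigs, tax, seed = seed + 4)

  paths <- list(
    ref_tree = file.path(dir, "ref.nwk"),
    ref_alignment = file.path(dir, "ref.fasta"),
    annotation = file.path(dir, "annot.tsv"),
    queries = file.path(dir, "queries.fasta"),
    taxonomy = file.path(dir, "tax.tsv"),
    counts = file.path(dir, "counts.tsv"),
    meta = file.path(dir, "meta.tsv"),
    spikeins = file.path(dir, "spikeins.tsv"),
    assignments = file.path(dir, "assign.tsv"),
    truth = file.path(dir, "truth.tsv"),
    contig_params = file.path(dir, "contig_params.tsv"))
  write_newick(ref$tree, paths$ref_tree)
  write_fasta(aln, paths$ref_alignment)
  readr::write_tsv(ref$annotation, paths$annotation)
  # pipeline queries are unaligned peptides: strip the gap columns
  write_fasta(setNames(gsub("-", "", qs$queries), names(qs$queries)),
              paths$queries)
  readr::write_tsv(tibble::as_tibble(tax), paths$taxonomy)
  readr::write_tsv(mt$counts, paths$counts)
  readr::write_tsv(mt$meta, paths$meta)
  readr::write_tsv(mt$spikeins, paths$spikeins)
  readr::write_tsv(mt$assignments, paths$assignments)
  readr::write_tsv(qs$truth, paths$truth)
  readr::write_tsv(mt$contig_params, paths$contig_params)
  readr::write_tsv(mt$sample_truth, file.path(dir, "sample_truth.tsv"))
  yaml::write_yaml(lapply(paths, normalizePath),
                   file.path(dir, "config.yaml"))
  paths
}

#' Run the full detection-and-quantification workflow
#'
#' Executes recruit -> place -> quantify -> rhythm on the files named in the
#' config, writes every stage table plus a reproducibility manifest to
#' `out_dir`, and returns the stage results.
#'
#' Stages: (1) build a scoring profile from the reference alignment,
#' calibrate its E-value null, recruit query peptides at `e_max` and
#' dereplicate them at `identity`; (2) map recruited centroids onto the
#' reference columns, place them on the reference tree, keep placements
#' with LWR > `lwr_min` resolved at genus level in clade I/II; (3) convert
#' counts to reads per liter via spike-ins, sum to clade x genus, divide by
#' order-level totals, average replicates and sum size fractions; (4) test
#' each kept contig for diel periodicity and correct with BH FDR.
#'
#' @param config List from [pipeline_config()] (input paths + thresholds).
#' @return List with elements `recruited`, `clusters`, `placements`,
#'   `rpl`, `order_totals`, `clade_genus`, `order_fraction`, `combined`,
#'   `rhythms`, `phase_summary`, `manifest`.
#' @export
run_pipeline <- function(config) {
  cfg <- validate_config(config)
  out_dir <- cfg$out_dir
  if (!is.null(out_dir))
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_msg <- function(...) message("[dielplace] ", ...)

  # --- inputs ---------------------------------------------------------------
  tree <- read_newick(path = cfg$ref_tree)
  ref_aln <- read_fasta(cfg$ref_alignment)
  annotation <- readr::read_tsv(cfg$annotation, show_col_types = FALSE)
  queries <- read_fasta(cfg$queries)
  taxonomy <- read_taxonomy(cfg$taxonomy)
  counts <- readr::read_tsv(cfg$counts, show_col_types = FALSE)
  meta <- readr::read_tsv(cfg$meta, show_col_types = FALSE)
  assignments <- if (!is.null(cfg$assignments))
    readr::read_tsv(cfg$assignments, show_col_types = FALSE) else NULL
  model <- aa_model(alpha = cfg$alpha, n_cat = cfg$n_cat)

  # --- stage 1: recruit -----------------------------------------------------
  log_msg("recruit: building and calibrating profile")
  profile <- build_profile(ref_aln)
  profile <- calibrate_profile(profile, n_sims = cfg$n_sims,
                               length = cfg$sim_length, seed = cfg$seed)
  hits <- search_profile(profile, queries, e_max = cfg$e_max)
  recruited <- queries[hits$query_id]
  clusters <- dereplicate(recruited, identity = cfg$identity)
  centroids <- recruited[unique(clusters$centroid_id)]
  log_msg("recruit: ", length(recruited), " hits, ",
          length(centroids), " centroids")

  # --- stage 2: place -------------------------------------------------------
  index <- epa_index(tree, model, ref_aln)
  aligned <- vapply(centroids, function(q) {
    colmap <- profile_map_query(profile, q)
    chars <- rep("-", index$n_sites)
    ok <- !is.na(colmap)
    chars[profile$match_columns[ok]] <-
      strsplit(q, "")[[1]][colmap[ok]]
    paste(chars, collapse = "")
  }, character(1))
  placements <- epa_place(aligned, index = index,
                          min_overlap = cfg$min_overlap)
  placements <- filter_and_assign(placements, index$tree, annotation,
                                  lwr_min = cfg$lwr_min)
  # kept status propagates to every cluster member
  member_map <- clusters[, c("member_id", "centroid_id")]
  kept_members <- placements[placements$kept, c("query_id", "clade",
                                                "genus")] |>
    dplyr::inner_join(member_map, by = c(query_id = "centroid_id")) |>
    dplyr::transmute(query_id = .data$member_id, clade = .data$clade,
                     genus = .data$genus, kept = TRUE)
  log_msg("place: ", sum(placements$placed), " placed, ",
          sum(placements$kept), " kept")

  # --- stage 3: quantify ----------------------------------------------------
  if (isTRUE(cfg$spike_in)) {
    spikeins <- readr::read_tsv(cfg$spikeins, show_col_types = FALSE)
    rpl <- reads_per_liter(counts, meta, spikeins)
  } else {
    rpl <- counts |>
      dplyr::inner_join(meta[, c("sample_id", "liters")], by = "sample_id") |>
      dplyr::transmute(contig_id = .data$contig_id,
                       sample_id = .data$sample_id,
                       rpl = .data$count / .data$liters)
  }
  totals <- if (!is.null(assignments))
    order_totals(rpl, assignments, taxonomy) else NULL
  cg <- aggregate_clade_genus(kept_members, rpl)
  genus_orders <- dplyr::distinct(annotation[, c("genus", "order_taxid")])
  ofrac <- if (!is.null(totals))
    order_normalize(cg, totals, genus_orders) else NULL
  combined <- if (!is.null(ofrac)) combine_samples(ofrac, meta) else NULL

  # --- stage 4: rhythm ------------------------------------------------------
  rhythms <- phase_summary <- NULL
  if (isTRUE(cfg$run_rhythm) && "hours" %in% names(meta)) {
    series <- build_diel_series(
      rpl[rpl$contig_id %in% kept_members$query_id, ], meta)
    if (nrow(series)) {
      rhythms <- detect_rhythms(series, n_perm = cfg$n_perm,
                                seed = cfg$seed, q_max = cfg$q_max)
      phase_summary <- summarize_phases(rhythms, q_max = cfg$q_max)
    }
  }

  manifest <- list(
    package = "dielplace",
    version = as.character(utils::packageVersion("dielplace")),
    seed = cfg$seed,
    thresholds = cfg[c("e_max", "identity", "lwr_min", "q_max",
                       "min_overlap")],
    inputs = lapply(cfg[c("ref_tree", "ref_alignment", "annotation",
                          "queries", "taxonomy", "counts", "meta")],
                    function(p) unname(tools::md5sum(p))),
    counts = list(queries = length(queries),
                  recruited = length(recruited),
                  centroids = length(centroids),
                  placed = sum(placements$placed),
                  kept = sum(placements$kept),
                  significant = if (is.null(rhythms)) NA_integer_
                                else sum(rhythms$significant)))

  if (!is.null(out_dir)) {
    readr::write_tsv(hits, file.path(out_dir, "hits.tsv"))
    readr::write_tsv(clusters, file.path(out_dir, "clusters.tsv"))
    readr::write_tsv(placements[, setdiff(names(placements), "edges")],
                     file.path(out_dir, "placements.tsv"))
    write_jplace(placements, index$tree,
                 file.path(out_dir, "placements.jplace"))
    readr::write_tsv(rpl, file.path(out_dir, "reads_per_liter.tsv"))
    if (!is.null(totals))
      readr::write_tsv(totals, file.path(out_dir, "order_totals.tsv"))
    readr::write_tsv(cg, file.path(out_dir, "clade_genus_rpl.tsv"))
    if (!is.null(ofrac))
      readr::write_tsv(ofrac, file.path(out_dir, "order_fraction.tsv"))
    if (!is.null(combined))
      readr::write_tsv(combined, file.path(out_dir, "combined.tsv"))
    if (!is.null(rhythms))
      readr::write_tsv(rhythms, file.path(out_dir, "rhythms.tsv"))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }

  list(profile = profile, hits = hits, recruited = recruited,
       clusters = clusters, placements = placements, rpl = rpl,
       order_totals = totals, clade_genus = cg, order_fraction = ofrac,
       combined = combined, rhythms = rhythms,
       phase_summary = phase_summary, manifest = manifest)
}
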