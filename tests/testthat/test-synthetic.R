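test_that("simulated reference trees have monophyletic clades and genera", {
  ref <- sim_tree(n_per_genus = 3, seed = 13)
  expect_setequal(ref$tree$tip.label, ref$annotation$leaf_label)
  ann <- ref$annotation
  for (cl in c("cladeI", "cladeII"))
    expect_true(ape::is.monophyletic(
      ref$tree, ann$leaf_label[ann$clade == cl]))
  for (g in unique(ann$genus))
    expect_true(ape::is.monophyletic(
      ref$tree, ann$leaf_label[ann$genus == g]))
  # determinism: same seed -> identical newick; other seed differs
  expect_identical(write_newick(sim_tree(seed = 13)$tree),
                   write_newick(sim_tree(seed = 13)$tree))
  expect_false(identical(write_newick(sim_tree(seed = 13)$tree),
                         write_newick(sim_tree(seed = 14)$tree)))
})

test_that("sequence evolution is faithful to the transition matrix", {
  m <- fix_model()
  # zero branch copies the parent
  tr0 <- read_newick(text = "(A:0,B:0.4);")
  aln0 <- evolve_sequences(tr0, m, 200, seed = 2)
  root_chars <- paste(AA_LEVELS[attr(aln0, "root_sequence")], collapse = "")
  expect_identical(aln0[["A"]], root_chars)

  # single-branch empirical transition frequencies match P(t) within 3 SE
  m1 <- aa_model(n_cat = 1)
  t <- 0.3
  tr <- read_newick(text = sprintf("(A:0,B:%f);", t))
  aln <- evolve_sequences(tr, m1, 50000, seed = 3)
  P <- prob_matrix(m1, t)
  from <- encode_residues(strsplit(aln[["A"]], "")[[1]])
  to <- encode_residues(strsplit(aln[["B"]], "")[[1]])
  for (a in 1:5) {  # spot-check the commonest source states
    idx <- which(from == a)
    if (length(idx) < 500) next
    for (b in c(a, 1, 7)) {
      phat <- mean(to[idx] == b)
      se <- sqrt(P[a, b] * (1 - P[a, b]) / length(idx))
      expect_lt(abs(phat - P[a, b]), 3 * se + 1e-9)
    }
  }

  # a very long branch drives composition to the equilibrium frequencies
  trl <- read_newick(text = "(A:0,B:60);")
  alnl <- evolve_sequences(trl, m1, 50000, seed = 4)
  tol <- encode_residues(strsplit(alnl[["B"]], "")[[1]])
  freq <- tabulate(tol, 20) / length(tol)
  expect_lt(max(abs(freq - m1$pi)), 0.01)
})

test_that("simulated queries carry their ground truth", {
  ref <- fix_reference()
  src <- ref$annotation$leaf_label[ref$annotation$clade == "cladeII"][1:3]
  q0 <- sim_queries(ref$alignment, ref$model, ref$annotation, src,
                    pendant = 0, seed = 5)
  expect_identical(unname(q0$queries),
                   unname(ref$alignment[src]))    # pendant 0 -> identical
  expect_equal(nrow(q0$truth), length(q0$queries))
  expect_true(all(q0$truth$clade == "cladeII"))

  qt <- sim_queries(ref$alignment, ref$model, ref$annotation, src,
                    n_queries = 10, pendant = 0.1, truncate = TRUE,
                    min_frac = 0.6, seed = 6)
  covered <- nchar(gsub("-", "", qt$queries))
  expect_true(all(covered >= 0.6 * nchar(ref$alignment[[1]]) - 1))
})

test_that("counts approach Poisson as dispersion vanishes and factors are recoverable", {
  tax <- sim_taxonomy(sim_tree(seed = 2)$annotation)
  contigs <- tibble::tibble(contig_id = "c1", taxid = "Chaetoceros_sp1",
                            baseline = 1e7, amplitude = 0, phase = 0)
  # factor_cv = 0 makes all samples share one expected count, so the
  # variance/mean ratio isolates the count distribution itself
  mt0 <- sim_metatranscriptome(contigs, tax, dispersion = 0, factor_cv = 0,
                               n_days = 8, seed = 31)
  cnt <- mt0$counts$count[mt0$counts$contig_id == "c1"]
  expect_lt(abs(var(cnt) / mean(cnt) - 1), 0.35)   # Poisson limit

  # negative-binomial mode is clearly overdispersed
  mt1 <- sim_metatranscriptome(contigs, tax, dispersion = 0.5, factor_cv = 0,
                               n_days = 8, seed = 31)
  cnt1 <- mt1$counts$count[mt1$counts$contig_id == "c1"]
  expect_gt(var(cnt1) / mean(cnt1), 3)

  # spike-in factor recovery within 5% with 14 standards
  mt <- sim_metatranscriptome(contigs, tax, seed = 32)
  rpl <- reads_per_liter(mt$counts, mt$meta, mt$spikeins)
  f <- attr(rpl, "factors")
  truth <- mt$sample_truth$factor[match(f$sample_id,
                                        mt$sample_truth$sample_id)]
  expect_lt(max(abs(f$factor - truth) / truth), 0.05)
})

test_that("generated inputs round-trip through the package's own readers", {
  td <- withr::local_tempdir()
  paths <- write_pipeline_inputs(td, seed = 19, n_queries = 4,
                                 seq_length = 80, n_per_genus = 2)
  tree <- read_newick(path = paths$ref_tree)
  aln <- read_fasta(paths$ref_alignment)
  expect_setequal(tree$tip.label, names(aln))
  queries <- read_fasta(paths$queries)
  expect_equal(length(queries), 4L)
  tax <- read_taxonomy(paths$taxonomy)
  ann <- readr::read_tsv(paths$annotation, show_col_types = FALSE)
  expect_true(all(ann$order_taxid %in% tax$taxid))
  counts <- readr::read_tsv(paths$counts, show_col_types = FALSE)
  meta <- readr::read_tsv(paths$meta, show_col_types = FALSE)
  expect_setequal(unique(counts$sample_id), meta$sample_id)

  # regenerating with the same seed is byte-identical
  td2 <- withr::local_tempdir()
  write_pipeline_inputs(td2, seed = 19, n_queries = 4,
                        seq_length = 80, n_per_genus = 2)
  for (f in c("ref.nwk", "ref.fasta", "counts.tsv", "queries.fasta"))
    expect_identical(readLines(file.path(td, f)),
                     readLines(file.path(td2, f)))
})
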