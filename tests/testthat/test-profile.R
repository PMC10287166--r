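test_that("log-odds scores follow the pseudocount formula and the match-column rule", {
  # two sequences, uniform background, pseudocount 1: hand evaluation
  seed <- c(s1 = "AC-", s2 = "AD-")
  bg <- rep(0.05, 20)
  p <- build_profile(seed, background = bg, pseudocount = 1)
  # column 3 is all gaps -> excluded; columns 1-2 are match columns
  expect_identical(p$match_columns, c(1L, 2L))
  expect_equal(unname(p$scores["A", 1]), log2(((2 + 0.05) / 3) / 0.05))
  expect_equal(unname(p$scores["C", 2]), log2(((1 + 0.05) / 3) / 0.05))
  expect_equal(unname(p$scores["W", 1]), log2(((0 + 0.05) / 3) / 0.05))

  # gap-majority column is dropped at the 50% rule boundary
  seed4 <- c(a = "A-", b = "A-", c = "AC", d = "A-")
  p4 <- build_profile(seed4, background = bg)
  expect_identical(p4$match_columns, 1L)

  # single-sequence profile: observed residue has the max score per column
  p1 <- build_profile(c(x = "ACD"), background = bg)
  expect_identical(AA_LEVELS[apply(p1$scores, 2, which.max)],
                   c("A", "C", "D"))

  expect_error(build_profile(c(a = "--", b = "--")), "no match columns")
})

test_that("profile building is invariant to sequence order in the seed", {
  ref <- fix_reference()
  aln <- ref$alignment
  p1 <- build_profile(aln)
  p2 <- build_profile(rev(aln))
  expect_equal(p1$scores, p2$scores)
  expect_identical(p1$match_columns, p2$match_columns)
})

test_that("Gumbel calibration is deterministic and fits its own null (KS < 0.05)", {
  ref <- fix_reference()
  prof <- build_profile(ref$alignment)
  c1 <- calibrate_profile(prof, n_sims = 10000, length = 80, seed = 42)
  c2 <- calibrate_profile(prof, n_sims = 10000, length = 80, seed = 42)
  expect_identical(c(c1$gumbel_lambda, c1$gumbel_mu),
                   c(c2$gumbel_lambda, c2$gumbel_mu))
  expect_gt(c1$gumbel_lambda, 0)

  # E-value strictly non-increasing in bit score
  s <- seq(0, 80, by = 0.5)
  ev <- profile_evalue(c1, s, db_size = 1000)
  expect_true(all(diff(ev) <= 0))

  # KS distance between fitted Gumbel and the empirical score distribution
  sc <- attr(c1, "calibration_scores")
  gumbel_cdf <- function(x) exp(-exp(-c1$gumbel_lambda * (x - c1$gumbel_mu)))
  emp <- ecdf(sc)
  ks <- max(abs(emp(sort(sc)) - gumbel_cdf(sort(sc))))
  expect_lt(ks, 0.05)

  expect_error(fit_gumbel(rep(1, 100)), "degenerate")
})

test_that("search recruits true homologs, skips empties, and rejects shuffles", {
  ref <- fix_reference()
  prof <- calibrate_profile(build_profile(ref$alignment),
                            n_sims = 5000, length = 100, seed = 7)

  # at e_max = Inf every non-empty sequence is a hit; empties warn
  m <- fix_model()
  qs <- sim_queries(ref$alignment, m, ref$annotation,
                    ref$annotation$leaf_label[1:4], pendant = 0.05, seed = 2)
  seqs <- c(gsub("-", "", qs$queries), none = "")
  expect_warning(hits_all <- search_profile(prof, seqs, e_max = Inf),
                 "empty")
  expect_setequal(hits_all$query_id, names(qs$queries))

  # the consensus achieves the maximal possible score and is recruited
  cons <- profile_consensus(prof)
  hc <- search_profile(prof, c(cons = cons), e_max = 0.001, db_size = 100)
  expect_equal(nrow(hc), 1L)
  expect_equal(hc$bit_score, sum(apply(prof$scores, 2, max)))

  # true homologs pass e < 0.001; residue-shuffles of one are almost never
  # recruited under the calibrated null
  hits <- search_profile(prof, gsub("-", "", qs$queries), e_max = 0.001)
  expect_setequal(hits$query_id, names(qs$queries))
  expect_true(all(diff(hits$e_value) >= 0))
  one <- gsub("-", "", qs$queries[[1]])
  set.seed(99)
  shuffles <- vapply(1:100, function(i)
    paste(sample(strsplit(one, "")[[1]]), collapse = ""), character(1))
  names(shuffles) <- paste0("shuf", 1:100)
  sh <- search_profile(prof, shuffles, e_max = 0.001, db_size = 100)
  expect_lt(nrow(sh), 5L)

  expect_identical(nrow(search_profile(prof, character())), 0L)
})

test_that("recruitment type-I rate on background sequences is at most 1%", {
  ref <- fix_reference()
  prof <- calibrate_profile(build_profile(ref$alignment),
                            n_sims = 5000, length = 100, seed = 11)
  set.seed(12)
  n <- 10000
  bgseqs <- lapply(seq_len(n), function(i)
    sample.int(20L, 100, replace = TRUE, prob = prof$background))
  sc <- pssm_score_batch(bgseqs, prof$scores, prof$gap_open, prof$gap_extend)
  ev <- profile_evalue(prof, sc, db_size = n)
  expect_lte(mean(ev < 0.001), 0.01)
})

test_that("dereplication clusters at the identity threshold and partitions the input", {
  base <- paste(rep("ACDEFGHIKL", 10), collapse = "")   # 100 residues
  mut2 <- base
  substr(mut2, 1, 1) <- "W"; substr(mut2, 50, 50) <- "W"

  # identical sequences collapse to one cluster
  cl <- dereplicate(c(a = base, b = base))
  expect_equal(length(unique(cl$centroid_id)), 1L)
  expect_setequal(cl$member_id, c("a", "b"))

  # 98% identity stays below the 0.99 threshold -> 2 clusters
  cl2 <- dereplicate(c(a = base, b = mut2), identity = 0.99)
  expect_equal(length(unique(cl2$centroid_id)), 2L)

  # random sets: clusters partition the input and every member has
  # identity >= threshold to its centroid by an independent NW oracle
  set.seed(5)
  ref <- fix_reference()
  orig <- gsub("-", "", ref$alignment)
  mut <- vapply(orig, function(s) {
    ch <- strsplit(s, "")[[1]]
    i <- sample(length(ch), 1)      # one mutation in 120: stays within 99%
    ch[i] <- sample(AA_LEVELS, 1)
    paste(ch, collapse = "")
  }, character(1))
  pool <- c(orig, mut)
  names(pool) <- paste0("m", seq_along(pool))
  cl3 <- dereplicate(pool, identity = 0.99)
  expect_setequal(cl3$member_id, names(pool))
  expect_equal(anyDuplicated(cl3$member_id), 0L)
  nontrivial <- cl3[cl3$member_id != cl3$centroid_id, ]
  for (i in seq_len(nrow(nontrivial)))
    expect_gte(oracle_identity(pool[[nontrivial$member_id[i]]],
                               pool[[nontrivial$centroid_id[i]]]), 0.99)
})
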