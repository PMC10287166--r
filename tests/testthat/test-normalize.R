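mini_meta <- function() {
  tibble::tibble(sample_id = c("A", "B"), station = c("st1", "st1"),
                 replicate = c(1, 2), size_fraction = "0.2um",
                 liters = c(7, 7))
}

test_that("reads per liter implements the spike-in conversion", {
  meta <- mini_meta()
  counts <- tibble::tibble(contig_id = c("c1", "c2"), sample_id = "A",
                           count = c(100, 0))
  spike <- tibble::tibble(sample_id = "A", standard_id = "std1",
                          added_copies = 1e6, recovered_reads = 1000)
  rpl <- reads_per_liter(counts, meta, spike)
  expect_equal(rpl$rpl[rpl$contig_id == "c1"], 100 * (1e6 / 1000) / 7)
  expect_equal(rpl$rpl[rpl$contig_id == "c2"], 0)

  # doubling liters halves every value
  meta2 <- meta; meta2$liters <- 14
  rpl2 <- reads_per_liter(counts, meta2, spike)
  expect_equal(rpl2$rpl, rpl$rpl / 2)

  # zero-recovery standards are excluded from the mean; all-zero errors
  spike2 <- dplyr::bind_rows(spike,
    tibble::tibble(sample_id = "A", standard_id = "std2",
                   added_copies = 1e6, recovered_reads = 0))
  expect_message(rpl3 <- reads_per_liter(counts, meta, spike2), "excluded")
  expect_equal(rpl3$rpl, rpl$rpl)
  spike_dead <- spike; spike_dead$recovered_reads <- 0
  expect_error(reads_per_liter(counts, meta, spike_dead), "spike-in failure")
  expect_error(reads_per_liter(
    tibble::tibble(contig_id = "c1", sample_id = "Z", count = 1),
    meta, spike), "no spike-in data")
})

test_that("clade/genus aggregation keeps only filtered placements and conserves mass", {
  placements <- tibble::tibble(
    query_id = c("c1", "c2", "c3"),
    clade = c("cladeII", "cladeII", "cladeI"),
    genus = c("Chaetoceros", "Chaetoceros", "Fragilariopsis"),
    kept = c(TRUE, TRUE, FALSE))
  rpl <- tibble::tibble(contig_id = c("c1", "c2", "c3"),
                        sample_id = "A", rpl = c(3, 4, 100))
  cg <- aggregate_clade_genus(placements, rpl)
  expect_equal(nrow(cg), 1L)
  expect_equal(cg$rpl, 7)                      # 3 + 4, c3 not kept
  expect_equal(sum(cg$rpl),
               sum(rpl$rpl[rpl$contig_id %in% c("c1", "c2")]))
})

test_that("order normalization divides by the order total and maps zero to NA", {
  cg <- tibble::tibble(clade = "cladeII", genus = "Chaetoceros",
                       sample_id = c("A", "B"), rpl = c(10, 5))
  totals <- tibble::tibble(taxid = "Chaetocerotales",
                           sample_id = "A", total = 1000)
  gmap <- tibble::tibble(genus = "Chaetoceros",
                         order_taxid = "Chaetocerotales")
  of <- order_normalize(cg, totals, gmap)
  expect_equal(of$fraction[of$sample_id == "A"], 0.01)
  expect_true(is.na(of$fraction[of$sample_id == "B"]))  # no total -> NA
  expect_error(order_normalize(cg, totals,
                               tibble::tibble(genus = "x", order_taxid = "y")),
               "Chaetoceros")
})

test_that("replicates average then size fractions sum, NA-tolerantly", {
  meta <- tibble::tibble(
    sample_id = c("A1", "A2", "B1", "B2"),
    station = "st1", replicate = c(1, 2, 1, 2),
    size_fraction = c("0.2um", "0.2um", "3um", "3um"), liters = 1)
  of <- tibble::tibble(clade = "cladeII", genus = "g",
                       sample_id = c("A1", "A2", "B1", "B2"),
                       fraction = c(0.02, 0.04, 0.03, 0.01))
  comb <- combine_samples(of, meta)
  expect_equal(comb$value, mean(c(0.02, 0.04)) + mean(c(0.03, 0.01)))

  # permuting replicate order changes nothing
  comb2 <- combine_samples(of[c(2, 1, 4, 3), ], meta)
  expect_equal(comb2$value, comb$value)

  # NA replicate is ignored; an all-NA fraction drops out of the sum
  of$fraction[2] <- NA
  expect_equal(combine_samples(of, meta)$value, 0.02 + 0.02)
  of$fraction[1:2] <- NA
  expect_equal(combine_samples(of, meta)$value, 0.02)
  of$fraction[1:4] <- NA
  expect_true(is.na(combine_samples(of, meta)$value))

  # single size fraction passes the replicate mean through
  meta1 <- meta[1:2, ]
  of1 <- tibble::tibble(clade = "c", genus = "g",
                        sample_id = c("A1", "A2"), fraction = c(0.2, 0.4))
  expect_equal(combine_samples(of1, meta1)$value, 0.3)
})

test_that("row normalization yields fractions that sum to one", {
  wide <- tibble::tibble(genus = c("g1", "g2", "g3"),
                         T0 = c(2, 5, 0), ctrl = c(2, 0, 0),
                         fe = c(4, 0, 0), np = c(8, 0, 0))
  rn <- row_normalize(wide)
  expect_equal(unlist(rn[rn$genus == "g1", -1]),
               c(T0 = 0.125, ctrl = 0.125, fe = 0.25, np = 0.5))
  expect_equal(unlist(rn[rn$genus == "g2", -1]),
               c(T0 = 1, ctrl = 0, fe = 0, np = 0))      # single nonzero -> 1
  expect_true(all(is.na(unlist(rn[rn$genus == "g3", -1]))))  # zero row
  sums <- rowSums(rn[rn$genus != "g3", -1])
  expect_equal(sums, rep(1, 2), tolerance = 1e-9, ignore_attr = TRUE)
  wide$T0[1] <- -1
  expect_error(row_normalize(wide), "negative")
})

test_that("tpm length-normalizes and each sample sums to a million", {
  lengths <- tibble::tibble(gene_id = c("g1", "g2"), length = c(1000, 2000))
  counts <- tibble::tibble(gene_id = c("g1", "g2"), sample_id = "s1",
                           count = c(10, 20))
  tt <- tpm(counts, lengths)
  expect_equal(tt$tpm, c(5e5, 5e5))       # equal rates split evenly

  set.seed(3)
  big <- tidyr::expand_grid(gene_id = paste0("g", 1:50),
                            sample_id = c("s1", "s2"))
  big$count <- rpois(100, 40)
  lens <- tibble::tibble(gene_id = paste0("g", 1:50),
                         length = sample(200:3000, 50))
  tb <- tpm(big, lens)
  sums <- tapply(tb$tpm, tb$sample_id, sum)
  expect_equal(as.numeric(sums), c(1e6, 1e6), tolerance = 1e-6)

  zero <- tibble::tibble(gene_id = c("g1", "g2"), sample_id = "s0",
                         count = 0)
  expect_true(all(is.na(tpm(zero, lengths)$tpm)))
  expect_error(tpm(counts, tibble::tibble(gene_id = c("g1", "g2"),
                                          length = c(0, 100))),
               "non-positive")
})

test_that("scaling a sample's counts scales rpl but not order fractions", {
  tax <- read_taxonomy(tibble::tibble(
    taxid = c("r", "o", "g", "s"), parent = c(NA, "r", "o", "g"),
    rank = c("root", "order", "genus", "species"),
    name = c("r", "o", "g", "s")))
  meta <- tibble::tibble(sample_id = "A", station = "st", replicate = 1,
                         size_fraction = "single", liters = 2)
  spike <- tibble::tibble(sample_id = "A",
                          standard_id = paste0("std", 1:3),
                          added_copies = 1e6,
                          recovered_reads = c(500, 1000, 2000))
  counts <- tibble::tibble(contig_id = c("c1", "bg1"), sample_id = "A",
                           count = c(50, 500))
  assigns <- tibble::tibble(contig_id = c("c1", "bg1"), taxid = c("s", "o"))
  placements <- tibble::tibble(query_id = "c1", clade = "cladeII",
                               genus = "g", kept = TRUE)
  gmap <- tibble::tibble(genus = "g", order_taxid = "o")

  run <- function(cts) {
    rpl <- reads_per_liter(cts, meta, spike)
    of <- order_normalize(aggregate_clade_genus(placements, rpl),
                          order_totals(rpl, assigns, tax), gmap)
    list(rpl = rpl, frac = of$fraction)
  }
  base <- run(counts)
  scaled <- run(dplyr::mutate(counts, count = count * 3))
  expect_equal(scaled$rpl$rpl, base$rpl$rpl * 3)
  expect_equal(scaled$frac, base$frac, tolerance = 1e-12)
  expect_true(all(base$frac >= 0 & base$frac <= 1, na.rm = TRUE))
})
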