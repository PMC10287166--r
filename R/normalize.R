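#' Convert raw read counts to reads per liter via spike-in standards
#'
#' Each sample's conversion factor is the mean, over its internal mRNA
#' standards, of added copies / recovered reads; standards with zero
#' recovered reads are excluded from the mean (and reported). Then
#' `rpl = count * factor / liters`.
#'
#' @param counts Long tibble: `contig_id`, `sample_id`, `count` (>= 0).
#' @param meta Sample table with at least `sample_id`, `liters` (> 0).
#' @param spikeins Tibble `sample_id`, `standard_id`, `added_copies`,
#'   `recovered_reads` (14 standards per sample in the cruise design).
#' @param stat Averaging rule for the per-standard ratios: `"mean"`
#'   (default) or `"median"`.
#' @return Long tibble `contig_id`, `sample_id`, `rpl` with attribute
#'   `"factors"` (per-sample conversion factors) and `"stage"` =
#'   `"reads_per_liter"`.
#' @export
reads_per_liter <- function(counts, meta, spikeins, stat = c("mean", "median")) {
  stat <- match.arg(stat)
  stopifnot(all(counts$count >= 0), all(meta$liters > 0))
  miss <- setdiff(unique(counts$sample_id), unique(spikeins$sample_id))
  if (length(miss))
    stop("no spike-in data for sample(s): ", paste(miss, collapse = ", "))
  avg <- if (stat == "mean") mean else stats::median
  factors <- spikeins |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(
      n_used = sum(.data$recovered_reads > 0),
      factor = {
        ok <- .data$recovered_reads > 0
        if (!any(ok)) NA_real_
        else avg(.data$added_copies[ok] / .data$recovered_reads[ok])
      },
      .groups = "drop")
  if (any(is.na(factors$factor)))
    stop("spike-in failure: all standards have zero recovered reads in ",
         paste(factors$sample_id[is.na(factors$factor)], collapse = ", "))
  n_dropped <- sum(spikeins$recovered_reads == 0)
  if (n_dropped > 0)
    message("reads_per_liter: ", n_dropped,
            " standard(s) with zero recovered reads excluded")
  out <- counts |>
    dplyr::inner_join(factors[, c("sample_id", "factor")], by = "sample_id") |>
    dplyr::inner_join(meta[, c("sample_id", "liters")], by = "sample_id") |>
    dplyr::mutate(rpl = .data$count * .data$factor / .data$liters) |>
    dplyr::select("contig_id", "sample_id", "rpl")
  attr(out, "factors") <- factors
  attr(out, "stage") <- "reads_per_liter"
  out
}

#' Sum reads per liter to the clade and genus level
#'
#' Only placements kept by [filter_and_assign()] contribute. Contigs with a
#' kept placement but no counts are reported and skipped.
#'
#' @param placements Filtered placement tibble (columns `query_id`, `clade`,
#'   `genus`, `kept`).
#' @param rpl Long tibble `contig_id`, `sample_id`, `rpl`.
#' @return Tibble `clade`, `genus`, `sample_id`, `rpl` (stage
#'   `"clade_genus_rpl"`).
#' @export
aggregate_clade_genus <- function(placements, rpl) {
  kept <- placements[placements$kept, c("query_id", "clade", "genus")]
  orphan <- setdiff(kept$query_id, unique(rpl$contig_id))
  if (length(orphan))
    message("aggregate_clade_genus: no counts for ",
            paste(orphan, collapse = ", "))
  out <- kept |>
    dplyr::inner_join(rpl, by = c(query_id = "contig_id")) |>
    dplyr::group_by(.data$clade, .data$genus, .data$sample_id) |>
    dplyr::summarise(rpl = sum(.data$rpl), .groups = "drop")
  attr(out, "stage") <- "clade_genus_rpl"
  out
}

#' Normalize clade x genus abundances by taxonomic-order read totals
#'
#' Divides each (clade, genus, sample) reads-per-liter value by the total
#' reads per liter of the genus's taxonomic order in the same sample (from
#' [order_totals()]). A zero or absent order total yields `NA`, never 0 or
#' infinity.
#'
#' @param clade_genus_rpl Output of [aggregate_clade_genus()].
#' @param totals Output of [order_totals()] (`taxid`, `sample_id`, `total`).
#' @param genus_orders Tibble `genus`, `order_taxid` mapping each genus to
#'   its taxonomic order.
#' @return Tibble `clade`, `genus`, `sample_id`, `rpl`, `order_total`,
#'   `fraction` (stage `"order_fraction"`).
#' @export
order_normalize <- function(clade_genus_rpl, totals, genus_orders) {
  miss <- setdiff(unique(clade_genus_rpl$genus), genus_orders$genus)
  if (length(miss))
    stop("genus without order mapping: ", paste(miss, collapse = ", "))
  out <- clade_genus_rpl |>
    dplyr::left_join(genus_orders[!duplicated(genus_orders$genus), ],
                     by = "genus") |>
    dplyr::left_join(totals, by = c(order_taxid = "taxid", "sample_id")) |>
    dplyr::mutate(
      order_total = ifelse(is.na(.data$total), 0, .data$total),
      fraction = ifelse(.data$order_total > 0,
                        .data$rpl / .data$order_total, NA_real_)) |>
    dplyr::select("clade", "genus", "sample_id", "rpl", "order_total",
                  "fraction")
  attr(out, "stage") <- "order_fraction"
  out
}

#' Average replicates, then sum the two size fractions
#'
#' Within each (station/timepoint, size fraction) the replicate values are
#' averaged ignoring `NA`; the per-fraction means are then summed per
#' station, with `NA + x = x` and all-`NA` groups staying `NA`.
#'
#' @param order_fraction Tibble with a `fraction` value column (or another
#'   column named by `value`), plus `sample_id`.
#' @param meta Sample table: `sample_id`, `station`, `replicate`,
#'   `size_fraction`.
#' @param value Name of the value column (default `"fraction"`).
#' @return Tibble `clade`, `genus`, `station`, `value` (stage `"combined"`).
#' @export
combine_samples <- function(order_fraction, meta, value = "fraction") {
  mean_na <- function(x) if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)
  sum_na <- function(x) if (all(is.na(x))) NA_real_ else sum(x, na.rm = TRUE)
  out <- order_fraction |>
    dplyr::inner_join(
      meta[, c("sample_id", "station", "replicate", "size_fraction")],
      by = "sample_id") |>
    dplyr::group_by(.data$clade, .data$genus, .data$station,
                    .data$size_fraction) |>
    dplyr::summarise(value = mean_na(.data[[value]]), .groups = "drop") |>
    dplyr::group_by(.data$clade, .data$genus, .data$station) |>
    dplyr::summarise(value = sum_na(.data$value), .groups = "drop")
  attr(out, "stage") <- "combined"
  out
}

#' Row-normalize a genus x treatment table
#'
#' Divides every row by its row sum (incubation treatments are expressed as
#' fractions of the row total); an all-zero row becomes all-`NA`.
#'
#' @param values Long tibble `genus`, `treatment`, `value` (values >= 0), or
#'   a wide data frame with a `genus` column and one column per treatment.
#' @return Tibble in the input shape with values replaced by row fractions.
#' @export
row_normalize <- function(values) {
  wide_in <- !("value" %in% names(values) && "treatment" %in% names(values))
  long <- if (wide_in)
    tidyr::pivot_longer(values, -"genus", names_to = "treatment",
                        values_to = "value")
  else tibble::as_tibble(values)
  if (any(long$value < 0, na.rm = TRUE)) stop("negative value")
  long <- long |>
    dplyr::group_by(.data$genus) |>
    dplyr::mutate(value = {
      s <- sum(.data$value, na.rm = TRUE)
      if (s == 0) rep(NA_real_, length(.data$value)) else .data$value / s
    }) |>
    dplyr::ungroup()
  if (wide_in)
    tidyr::pivot_wider(long, names_from = "treatment", values_from = "value")
  else long
}

#' Transcripts per million
#'
#' `rate = count / length`; `tpm = rate / sum(rate) * 1e6` per sample. A
#' sample with zero total rate gets all-`NA` TPM (never division by zero).
#'
#' @param counts Long tibble `gene_id`, `sample_id`, `count`.
#' @param lengths Tibble `gene_id`, `length` (effective lengths, > 0).
#' @return Tibble `gene_id`, `sample_id`, `tpm`.
#' @export
tpm <- function(counts, lengths) {
  if (any(lengths$length <= 0)) stop("non-positive gene length")
  miss <- setdiff(unique(counts$gene_id), lengths$gene_id)
  if (length(miss))
    stop("gene without length: ", paste(miss, collapse = ", "))
  counts |>
    dplyr::inner_join(lengths[, c("gene_id", "length")], by = "gene_id") |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::mutate(tpm = {
      rate <- .data$count / .data$length
      s <- sum(rate)
      if (s == 0) rep(NA_real_, length(rate)) else rate / s * 1e6
    }) |>
    dplyr::ungroup() |>
    dplyr::select("gene_id", "sample_id", "tpm")
}
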