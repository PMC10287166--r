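# Orientation matrix for the umbrella statistic: for each candidate peak
# phase (row) and each cyclically adjacent phase pair j = (phase_j,
# phase_{j+1 mod k}) (column), +1 when the later phase of the pair is closer
# to the peak (rising limb), -1 when farther (falling limb), 0 when
# equidistant.
umbrella_directions <- function(phases, period = 24) {
  k <- length(phases)
  cyc_dist <- function(a, b) {
    d <- (a - b) %% period
    pmin(d, period - d)
  }
  dirs <- matrix(0L, k, k)
  for (p in seq_len(k)) {
    for (j in seq_len(k)) {
      a <- phases[j]; b <- phases[j %% k + 1L]
      da <- cyc_dist(a, phases[p]); db <- cyc_dist(b, phases[p])
      dirs[p, j] <- if (db < da) 1L else if (db > da) -1L else 0L
    }
  }
  dirs
}

#' Umbrella rank statistic for a candidate peak phase
#'
#' Observations are grouped by time-of-day; the groups are ordered cyclically
#' so values rise toward `peak_phase` and fall after it. The statistic sums,
#' over cyclically adjacent group pairs, the Mann-Whitney count of
#' cross-group pairs concordant with that rise/fall orientation (ties count
#' 1/2). Its maximum is the total number of adjacent cross-group pairs; a
#' constant series scores exactly half the maximum.
#'
#' @param values Numeric observations.
#' @param time_of_day Time of day of each observation (hours in
#'   `[0, period)`).
#' @param peak_phase Candidate peak (must be one of the sampled phases).
#' @param period Period in hours (default 24).
#' @return Statistic value (scalar, with attribute `"max"` = the maximal
#'   achievable value).
#' @export
umbrella_statistic <- function(values, time_of_day, peak_phase, period = 24) {
  phases <- sort(unique(time_of_day %% period))
  if (length(phases) < 3L) stop("need at least 3 distinct time-of-day groups")
  if (!(peak_phase %% period) %in% phases)
    stop("peak_phase must be one of the sampled phases")
  group <- match(time_of_day %% period, phases) - 1L
  dirs <- umbrella_directions(phases, period)
  p_idx <- match(peak_phase %% period, phases)
  s <- umbrella_stats_cpp(values, group, length(phases),
                          dirs[p_idx, , drop = FALSE])
  ng <- tabulate(group + 1L, nbins = length(phases))
  structure(s[1], max = sum(ng * ng[c(2:length(ng), 1)]))
}

#' Permutation test for diel periodicity (RAIN-style umbrella test)
#'
#' Computes the umbrella statistic at every sampled phase, takes the maximum
#' over candidate peaks, and calibrates it by permuting which timepoint block
#' (a timepoint with all its replicates) occupies which time slot,
#' recomputing the max-over-phases each time. The p-value uses the add-one
#' estimator `p = (1 + #[null >= observed]) / (n_perm + 1)`. Ties in the
#' best phase break to the earliest phase.
#'
#' @param series Tibble with columns `hours` (time since start), `value`
#'   (>= 0) and optionally `replicate`.
#' @param period Period in hours (default 24); the series must span at least
#'   two full periods.
#' @param n_perm Number of permutations (>= 999).
#' @param seed Integer seed.
#' @return Object of class `rain_test`: list with `statistic`, `best_phase`
#'   (hours), `p_value`, `per_phase` tibble, `n_perm`, `phases`.
#' @export
rain_like_test <- function(series, period = 24, n_perm = 999, seed = 1) {
  stopifnot(n_perm >= 999)
  hours <- series$hours
  if (diff(range(hours)) + min(diff(sort(unique(hours)))) < 2 * period)
    stop("need at least 2 full periods of data")
  tod <- hours %% period
  phases <- sort(unique(tod))
  if (length(phases) < 3L) stop("need at least 3 distinct time-of-day groups")
  blocks <- sort(unique(hours))
  block <- match(hours, blocks) - 1L
  tod_of_block <- match(blocks %% period, phases) - 1L
  dirs <- umbrella_directions(phases, period)
  set.seed(seed)
  res <- umbrella_perm_test(series$value, block, tod_of_block,
                            length(phases), dirs, as.integer(n_perm))
  structure(list(
    statistic = res$statistic,
    max_statistic = res$max_statistic,
    best_phase = phases[res$best_phase_index],
    p_value = res$p_value,
    per_phase = tibble::tibble(phase = phases,
                               statistic = as.numeric(res$per_phase)),
    n_perm = as.integer(n_perm),
    period = period,
    phases = phases), class = "rain_test")
}

#' @export
print.rain_test <- function(x, ...) {
  cat("<rain_test> period ", x$period, " h; statistic ", x$statistic,
      "/", x$max_statistic, "; best phase ", x$best_phase,
      " h; p = ", format(x$p_value), " (", x$n_perm, " permutations)\n",
      sep = "")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Per-phase umbrella statistics of a rhythmicity test
#' @param x A `rain_test`.
#' @param ... Unused.
#' @return Tibble `phase`, `statistic`.
#' @method tidy rain_test
#' @export
tidy.rain_test <- function(x, ...) x$per_phase

#' One-row summary of a rhythmicity test
#' @param x A `rain_test`.
#' @param ... Unused.
#' @return One-row tibble `statistic`, `max_statistic`, `best_phase`,
#'   `p_value`, `n_perm`.
#' @method glance rain_test
#' @export
glance.rain_test <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, max_statistic = x$max_statistic,
                 best_phase = x$best_phase, p_value = x$p_value,
                 n_perm = x$n_perm)
}

#' Benjamini-Hochberg step-up q-values
#'
#' `q_(i) = min_(j >= i) p_(j) * m / j`, capped at 1, mapped back to the
#' input order.
#'
#' @param pvalues Numeric vector of p-values in \[0, 1\].
#' @return Vector of q-values in input order.
#' @export
bh_fdr <- function(pvalues) {
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE) || any(is.na(pvalues)))
    stop("p-values must lie in [0, 1]")
  m <- length(pvalues)
  if (m == 0L) return(numeric())
  o <- order(pvalues)
  q <- pvalues[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  q[order(o)]
}

#' Test many contig series for diel rhythmicity
#'
#' Runs [rain_like_test()] per contig on a long table and corrects the
#' p-values across contigs with [bh_fdr()].
#'
#' @param series Long tibble: `contig_id`, `hours`, `value`, optionally
#'   `replicate`.
#' @param period Period in hours (default 24).
#' @param n_perm Permutations per contig (default 999).
#' @param seed Base seed; contig `i` uses `seed + i`.
#' @param q_max Significance threshold on the q-value (default 0.05).
#' @return Tibble `contig_id`, `statistic`, `max_statistic`, `best_phase`,
#'   `p_value`, `q_value`, `significant`.
#' @export
detect_rhythms <- function(series, period = 24, n_perm = 999, seed = 1,
                           q_max = 0.05) {
  ids <- unique(series$contig_id)
  rows <- purrr::imap_dfr(setNames(ids, ids), function(id, dummy) {
    one <- series[series$contig_id == id, ]
    r <- rain_like_test(one, period = period, n_perm = n_perm,
                        seed = seed + match(id, ids))
    dplyr::bind_cols(tibble::tibble(contig_id = id), glance(r))
  })
  rows$q_value <- bh_fdr(rows$p_value)
  rows$significant <- rows$q_value < q_max
  rows <- dplyr::select(rows, "contig_id", "statistic", "max_statistic",
                        "best_phase", "p_value", "q_value", "significant")
  class(rows) <- c("rhythm_tbl", class(rows))
  rows
}

#' Count significant contigs by peak phase
#'
#' @param results Tibble from [detect_rhythms()].
#' @param q_max Significance threshold (default 0.05).
#' @return Tibble `phase`, `n_significant` (all observed best phases appear,
#'   zeros included) with attributes `"n_tested"` and `"n_significant"`.
#' @export
summarize_phases <- function(results, q_max = 0.05) {
  sig <- results[results$q_value < q_max, ]
  phases <- sort(unique(results$best_phase))
  out <- tibble::tibble(
    phase = phases,
    n_significant = vapply(phases, function(p)
      sum(sig$best_phase == p), integer(1)))
  attr(out, "n_tested") <- nrow(results)
  attr(out, "n_significant") <- nrow(sig)
  out
}
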