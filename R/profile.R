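#' Build a position-specific scoring profile from a seed alignment
#'
#' Alignment columns with at least `match_frac` non-gap residues become match
#' columns. Per match column, the log-odds score (bits) of amino acid `a` is
#'
#'   score(col, a) = log2( (count_a + pseudocount * bg_a) /
#'                         (n_col + pseudocount) / bg_a )
#'
#' where `n_col` is the number of residues observed in the column and `bg` the
#' background frequency vector. The profile is used as a recruitment filter:
#' sequences are scored by best local alignment with affine gap penalties and
#' kept below an E-value threshold once the profile is calibrated
#' ([calibrate_profile()]).
#'
#' @param seed Named character vector: aligned amino-acid sequences (equal
#'   lengths, `-` or `.` for gaps). At least 2 sequences.
#' @param background Amino-acid background frequencies in [AA_LEVELS] order
#'   (default: WAG equilibrium frequencies). Must sum to 1.
#' @param pseudocount Positive pseudocount mass (default 1).
#' @param match_frac Minimum fraction of non-gap residues for a match column
#'   (default 0.5).
#' @param gap_open,gap_extend Affine gap penalties in bits (defaults 10 and 1).
#' @return An object of class `pssm_profile`: list with `match_columns`,
#'   `scores` (20 x n_match bits), `background`, `gap_open`, `gap_extend`,
#'   Gumbel calibration slots (`gumbel_lambda`, `gumbel_mu`, both `NA` until
#'   calibrated) and `db_size`.
#' @seealso [calibrate_profile()], [search_profile()], [dereplicate()]
#' @export
build_profile <- function(seed, background = NULL, pseudocount = 1,
                          match_frac = 0.5, gap_open = 10, gap_extend = 1) {
  if (length(seed) < 1L) stop("seed alignment is empty")
  stopifnot(pseudocount > 0)
  if (is.null(background)) background <- aa_model()$pi
  stopifnot(length(background) == 20L, abs(sum(background) - 1) < 1e-9)
  background <- setNames(as.numeric(background), AA_LEVELS)

  m <- aln_to_matrix(seed)
  code <- apply(m, 2, encode_residues)          # seqs x cols, NA = gap/unknown
  if (length(seed) == 1L) code <- matrix(code, nrow = 1L)
  n_res <- colSums(!is.na(code))
  match_columns <- which(n_res / nrow(code) >= match_frac & n_res > 0L)
  if (length(match_columns) == 0L) stop("no match columns")

  scores <- vapply(match_columns, function(j) {
    counts <- tabulate(code[, j], nbins = 20L)
    n_col <- sum(counts)
    p <- (counts + pseudocount * background) / (n_col + pseudocount)
    log2(p / background)
  }, numeric(20L))
  scores <- matrix(scores, nrow = 20L,
                   dimnames = list(AA_LEVELS, NULL))

  structure(list(match_columns = as.integer(match_columns),
                 scores = scores,
                 background = background,
                 gap_open = gap_open, gap_extend = gap_extend,
                 gumbel_lambda = NA_real_, gumbel_mu = NA_real_,
                 db_size = NA_integer_),
            class = "pssm_profile")
}

#' @export
print.pssm_profile <- function(x, ...) {
  cat("<pssm_profile> ", length(x$match_columns), " match columns; ",
      if (is.na(x$gumbel_lambda)) "uncalibrated"
      else sprintf("Gumbel(lambda = %.4f, mu = %.3f)",
                   x$gumbel_lambda, x$gumbel_mu),
      "\n", sep = "")
  invisible(x)
}

#' Consensus sequence of a profile (per-column argmax residues)
#' @param profile A `pssm_profile`.
#' @return Character scalar peptide.
#' @export
profile_consensus <- function(profile) {
  paste(AA_LEVELS[apply(profile$scores, 2, which.max)], collapse = "")
}

# ML fit of a Gumbel distribution (location mu, scale beta) to scores.
fit_gumbel <- function(x) {
  if (sd(x) < 1e-12) stop("degenerate score distribution")
  f <- function(beta) {
    w <- exp(-x / beta)
    beta - mean(x) + sum(x * w) / sum(w)
  }
  lo <- sd(x) / 10; hi <- sd(x) * 10
  beta <- uniroot(f, c(lo, hi), extendInt = "yes", tol = 1e-10)$root
  mu <- -beta * log(mean(exp(-x / beta)))
  c(lambda = 1 / beta, mu = mu)
}

#' Calibrate a profile's E-value null by simulation
#'
#' Scores `n_sims` i.i.d. background sequences of the given length against the
#' profile and fits a Gumbel distribution to the resulting local-alignment
#' score distribution by maximum likelihood. E-values are then
#' `E(s) = db_size * P(S > s)` under the fitted Gumbel.
#'
#' @param profile A `pssm_profile`.
#' @param n_sims Number of simulated sequences (>= 1000).
#' @param length Length of each simulated sequence.
#' @param seed Integer seed for the simulation.
#' @param db_size Database size used for E-value scaling; by default set at
#'   search time to the number of query sequences.
#' @return The profile with `gumbel_lambda`, `gumbel_mu` (and optionally
#'   `db_size`) filled in, plus attribute `"calibration_scores"` holding the
#'   simulated score vector.
#' @export
calibrate_profile <- function(profile, n_sims = 5000, length = 150,
                              seed = 1, db_size = NULL) {
  stopifnot(inherits(profile, "pssm_profile"), n_sims >= 1000, length >= 1)
  set.seed(seed)
  seqs <- lapply(seq_len(n_sims), function(i)
    sample.int(20L, length, replace = TRUE, prob = profile$background))
  sc <- pssm_score_batch(seqs, profile$scores,
                         profile$gap_open, profile$gap_extend)
  g <- fit_gumbel(sc)
  profile$gumbel_lambda <- unname(g["lambda"])
  profile$gumbel_mu <- unname(g["mu"])
  if (!is.null(db_size)) profile$db_size <- as.integer(db_size)
  attr(profile, "calibration_scores") <- sc
  profile
}

#' E-value of a bit score under a calibrated profile
#' @param profile Calibrated `pssm_profile`.
#' @param score Bit score(s).
#' @param db_size Database size (defaults to the profile's stored value).
#' @return E-value(s).
#' @export
profile_evalue <- function(profile, score, db_size = profile$db_size) {
  if (is.na(profile$gumbel_lambda)) stop("profile is not calibrated")
  if (is.null(db_size) || is.na(db_size)) stop("db_size is not set")
  # Gumbel survival: P(S > s) = 1 - exp(-exp(-lambda (s - mu)))
  z <- exp(-profile$gumbel_lambda * (score - profile$gumbel_mu))
  db_size * (-expm1(-z))
}

#' Search peptide sequences with a calibrated profile
#'
#' Each sequence is scored by its best local alignment to the profile (affine
#' gaps); hits with E-value below `e_max` are returned sorted by E-value.
#'
#' @param profile Calibrated `pssm_profile`.
#' @param sequences Named character vector of peptides.
#' @param e_max E-value threshold (default 0.001).
#' @param db_size Database size for E-value scaling; defaults to
#'   `length(sequences)`.
#' @return Tibble with columns `query_id`, `bit_score`, `e_value`, `start`,
#'   `end` (1-based aligned span on the query), sorted by ascending `e_value`.
#' @export
search_profile <- function(profile, sequences, e_max = 0.001,
                           db_size = length(sequences)) {
  stopifnot(inherits(profile, "pssm_profile"))
  if (length(sequences) == 0L)
    return(tibble::tibble(query_id = character(), bit_score = numeric(),
                          e_value = numeric(), start = integer(),
                          end = integer()))
  if (is.na(profile$gumbel_lambda)) stop("profile is not calibrated")
  empty <- !nzchar(sequences)
  if (any(empty)) {
    warning("skipping ", sum(empty), " empty sequence(s): ",
            paste(names(sequences)[empty], collapse = ", "))
    sequences <- sequences[!empty]
  }
  rows <- purrr::map2_dfr(sequences, names(sequences), function(s, id) {
    r <- pssm_align_one(encode_peptide(s), profile$scores,
                        profile$gap_open, profile$gap_extend, TRUE)
    tibble::tibble(query_id = id, bit_score = r$score,
                   start = r$qstart, end = r$qend)
  })
  rows$e_value <- profile_evalue(profile, rows$bit_score, db_size)
  rows <- rows[rows$e_value < e_max, c("query_id", "bit_score", "e_value",
                                       "start", "end")]
  dplyr::arrange(rows, .data$e_value, .data$query_id)
}

# Map a query onto the profile's match columns via the local alignment
# traceback. Returns an integer vector over match columns: query position per
# column (NA where the column is unaligned).
profile_map_query <- function(profile, sequence) {
  r <- pssm_align_one(encode_peptide(sequence), profile$scores,
                      profile$gap_open, profile$gap_extend, TRUE)
  r$colmap
}

# Global Needleman-Wunsch identity: matches / alignment columns.
pairwise_identity <- function(a, b) {
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "global",
    substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 0.5)
  al1 <- as.character(Biostrings::alignedPattern(pa))
  al2 <- as.character(Biostrings::alignedSubject(pa))
  c1 <- strsplit(al1, "")[[1]]; c2 <- strsplit(al2, "")[[1]]
  sum(c1 == c2 & c1 != "-") / length(c1)
}

#' Greedy centroid clustering at an identity threshold
#'
#' Reproduces the usearch-style dereplication step: sequences are sorted by
#' decreasing length (ties by id), each is joined to the first existing
#' centroid with global-alignment identity >= `identity`, otherwise it founds
#' a new cluster. Identity = matching columns / total alignment columns of a
#' global alignment.
#'
#' @param sequences Named character vector of peptides.
#' @param identity Identity threshold in (0, 1] (default 0.99).
#' @return Tibble with one row per sequence: `member_id`, `centroid_id`,
#'   `identity` (to the centroid; 1 for centroids themselves).
#' @export
dereplicate <- function(sequences, identity = 0.99) {
  stopifnot(identity > 0, identity <= 1)
  if (length(sequences) == 0L)
    return(tibble::tibble(member_id = character(), centroid_id = character(),
                          identity = numeric()))
  ord <- order(-nchar(sequences), names(sequences))
  sequences <- sequences[ord]
  centroids <- character()
  rows <- vector("list", length(sequences))
  for (i in seq_along(sequences)) {
    id <- names(sequences)[i]
    hit <- NA_character_; hit_pid <- NA_real_
    for (cid in centroids) {
      pid <- pairwise_identity(sequences[[i]], sequences[[cid]])
      if (pid >= identity) { hit <- cid; hit_pid <- pid; break }
    }
    if (is.na(hit)) {
      centroids <- c(centroids, id)
      rows[[i]] <- tibble::tibble(member_id = id, centroid_id = id,
                                  identity = 1)
    } else {
      rows[[i]] <- tibble::tibble(member_id = id, centroid_id = hit,
                                  identity = hit_pid)
    }
  }
  dplyr::bind_rows(rows)
}
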