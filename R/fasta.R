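#' Read a peptide FASTA file
#'
#' Sequences are returned as a named character vector (names = record ids,
#' first whitespace-delimited token of the header). Gap characters are kept,
#' so aligned FASTA round-trips unchanged.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  out <- as.character(ss)
  names(out) <- sub("\\s.*$", "", names(ss))
  toupper(out)
}

#' Write sequences to FASTA
#'
#' @param sequences Named character vector of sequences.
#' @param path Output path.
#' @param width Line-wrap width (default 60 columns).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path, width = 60) {
  stopifnot(!is.null(names(sequences)), all(nzchar(names(sequences))))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(sequences)) {
    writeLines(paste0(">", names(sequences)[i]), con)
    s <- sequences[[i]]
    starts <- seq(1, max(nchar(s), 1), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
  }
  invisible(path)
}

# Split an alignment (named character vector of equal-length strings) into a
# character matrix (rows = sequences).
aln_to_matrix <- function(aln) {
  lens <- nchar(aln)
  if (length(unique(lens)) != 1L)
    stop("alignment sequences have unequal lengths")
  m <- do.call(rbind, strsplit(aln, ""))
  rownames(m) <- names(aln)
  m
}

# Integer-code residues 1..20 in AA_LEVELS order; gaps/unknowns -> NA.
encode_residues <- function(chars) {
  match(chars, AA_LEVELS)
}

# Integer-code an unaligned peptide string; unknown letters -> 0 (scored 0).
encode_peptide <- function(seq) {
  v <- match(strsplit(seq, "")[[1]], AA_LEVELS)
  v[is.na(v)] <- 0L
  v
}
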