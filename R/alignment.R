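# Residue alphabet: the 20 standard amino acids plus 'X' (unknown) and '-'
# (gap).  'X' never counts as identity or conservation evidence.
.aa_alphabet <- function() c(.aa_states, "X", "-")

.missing_states <- c("X", "-")

#' Protein sequence records
#'
#' A set of named, possibly gapped, uppercase amino-acid sequences.  The
#' constructor validates ids (non-empty, unique) and the residue alphabet
#' (20 standard amino acids, `X` for unknown, `-` for gaps).
#'
#' @param sequences Named character vector of residue strings.
#' @param descriptions Optional character vector of free-text descriptions,
#'   recycled to the number of records.
#' @return An object of class `seq_records`: a named character vector with a
#'   `descriptions` attribute.
#' @export
seq_records <- function(sequences, descriptions = NULL) {
  ids <- names(sequences)
  if (is.null(ids) || any(!nzchar(ids))) {
    stop_ctx("every sequence record needs a non-empty id")
  }
  if (anyDuplicated(ids)) {
    stop_ctx("duplicate sequence ids: %s",
             paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  sequences <- toupper(as.character(sequences))
  names(sequences) <- ids
  bad <- vapply(sequences, function(s) {
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    w <- which(!ch %in% .aa_alphabet())
    if (length(w)) w[1] else 0L
  }, integer(1))
  if (any(bad > 0L)) {
    i <- which(bad > 0L)[1]
    stop_ctx("illegal residue character '%s' in record '%s' at position %d",
             substr(sequences[i], bad[i], bad[i]), ids[i], bad[i])
  }
  if (is.null(descriptions)) descriptions <- rep("", length(sequences))
  attr(sequences, "descriptions") <- rep_len(as.character(descriptions),
                                             length(sequences))
  class(sequences) <- "seq_records"
  sequences
}

#' Multiple sequence alignment container
#'
#' Validates that all records have identical length and wraps them as an
#' alignment of `n_columns` columns.
#'
#' @param records A `seq_records` object or named character vector of
#'   equal-length gapped sequences.
#' @return An `aa_alignment` object (a `seq_records` with an `n_columns`
#'   attribute).
#' @export
aa_alignment <- function(records) {
  if (!inherits(records, "seq_records")) records <- seq_records(records)
  lens <- nchar(records)
  if (length(unique(lens)) != 1L) {
    stop_ctx("alignment rows differ in length (%s)",
             paste(unique(lens), collapse = ", "))
  }
  if (lens[1] < 1L) stop_ctx("alignment must have at least one column")
  attr(records, "n_columns") <- unname(lens[1])
  class(records) <- c("aa_alignment", "seq_records")
  records
}

#' @export
print.aa_alignment <- function(x, ...) {
  cat(sprintf("aa_alignment: %d sequences x %d columns\n",
              length(x), attr(x, "n_columns")))
  show <- utils::head(seq_along(x), 6L)
  for (i in show) {
    s <- unclass(x)[[i]]
    cat(sprintf("  %-20s %s%s\n", names(x)[i], substr(s, 1, 50),
                if (nchar(s) > 50) "..." else ""))
  }
  if (length(x) > 6L) cat(sprintf("  ... and %d more\n", length(x) - 6L))
  invisible(x)
}

#' @export
print.seq_records <- function(x, ...) {
  cat(sprintf("seq_records: %d sequences\n", length(x)))
  invisible(x)
}

#' @export
as.matrix.aa_alignment <- function(x, ...) {
  m <- do.call(rbind, strsplit(unclass(x), "", fixed = TRUE))
  rownames(m) <- names(x)
  m
}

# Character matrix -> aa_alignment
alignment_from_matrix <- function(m, descriptions = NULL) {
  seqs <- apply(m, 1L, paste, collapse = "")
  names(seqs) <- rownames(m)
  aa_alignment(seq_records(seqs, descriptions))
}

n_columns <- function(alignment) attr(alignment, "n_columns")

# Coerce loose input (named character vector) to aa_alignment.
as_alignment <- function(x) {
  if (inherits(x, "aa_alignment")) x else aa_alignment(x)
}

# Drop gaps from one sequence string.
degap <- function(s) gsub("-", "", s, fixed = TRUE)
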