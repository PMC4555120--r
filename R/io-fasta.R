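#' Read protein sequences from a FASTA file
#'
#' Reads aligned or unaligned protein FASTA.  The first whitespace-delimited
#' token of each header is the record id; the remainder is kept as the
#' description.  Residues are validated against the amino-acid alphabet
#' (20 standard residues, `X`, `-`).
#'
#' @param path Path to a FASTA file.
#' @param aligned If `TRUE`, require equal-length records and return an
#'   [aa_alignment()]; otherwise return [seq_records()].
#' @return `seq_records` or `aa_alignment`.
#' @export
read_fasta <- function(path, aligned = FALSE) {
  if (!file.exists(path)) stop_ctx("FASTA file not found: %s", path)
  first <- readLines(path, n = 1L)
  if (length(first) == 0L || !startsWith(trimws(first), ">")) {
    stop_ctx("malformed FASTA (line 1): expected '>' header in %s", path)
  }
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop_ctx("no records in %s", path)
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  seqs <- stats::setNames(toupper(as.character(set)), ids)
  rec <- seq_records(seqs, desc)
  if (aligned) aa_alignment(rec) else rec
}

#' Write protein sequences to a FASTA file
#'
#' @param records `seq_records` or `aa_alignment` (or named character vector).
#' @param path Output path.
#' @param width Line-wrapping width in residues.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 60L) {
  if (!inherits(records, "seq_records")) records <- seq_records(records)
  desc <- attr(records, "descriptions")
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(records)) {
    hdr <- if (nzchar(desc[i])) paste(names(records)[i], desc[i]) else names(records)[i]
    writeLines(paste0(">", hdr), con)
    s <- unclass(records)[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}
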