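#' Map ungapped reference positions to alignment columns
#'
#' All coordinates are 1-based inclusive, matching the conventional residue
#' numbering of a reference sequence (e.g. human VKORC1 Asp36).
#'
#' @param alignment An [aa_alignment()].
#' @param ref_id Id of the reference row.
#' @return Integer vector `column` indexed by residue number (position `i`
#'   of the ungapped reference maps to `mapping[i]`); the inverse map
#'   (column -> residue number, `NA` for gap columns) is in
#'   `attr(,"inverse")`.
#' @export
map_reference_positions <- function(alignment, ref_id) {
  alignment <- as_alignment(alignment)
  if (!ref_id %in% names(alignment)) {
    stop_ctx("reference id '%s' not in alignment", ref_id)
  }
  row <- strsplit(unclass(alignment)[[ref_id]], "")[[1]]
  non_gap <- which(row != "-")
  mapping <- non_gap
  names(mapping) <- as.character(seq_along(non_gap))
  inverse <- rep(NA_integer_, length(row))
  inverse[non_gap] <- seq_along(non_gap)
  attr(mapping, "inverse") <- inverse
  mapping
}

#' Truncate an alignment to a reference-coordinate span
#'
#' Returns all alignment columns between the columns holding reference
#' residues `start` and `end` (inclusive), for all rows.  The number of
#' reference (non-gap) positions in the result is `end - start + 1`.
#'
#' @param alignment An [aa_alignment()].
#' @param ref_id Id of the reference row.
#' @param start,end 1-based inclusive residue numbers in the ungapped
#'   reference sequence.
#' @return The truncated [aa_alignment()], with attribute `ref_span`.
#' @export
truncate_to_region <- function(alignment, ref_id, start, end) {
  alignment <- as_alignment(alignment)
  if (start < 1L || start > end) stop_ctx("invalid span %d:%d", start, end)
  mapping <- map_reference_positions(alignment, ref_id)
  if (end > length(mapping)) {
    stop_ctx("span %d:%d exceeds reference length %d", start, end, length(mapping))
  }
  cols <- mapping[[as.character(start)]]:mapping[[as.character(end)]]
  m <- as.matrix(alignment)[, cols, drop = FALSE]
  out <- alignment_from_matrix(m, attr(alignment, "descriptions"))
  attr(out, "ref_span") <- c(start = start, end = end)
  out
}

#' Cull redundant, partial and motif-less sequences
#'
#' Applies, in order: removal of exact-duplicate residue strings (keeping
#' the first record in input order); removal of records with a gap or `X`
#' anywhere inside the reference span (not fully encompassing the core
#' region); removal of records lacking any required motif, given as
#' regular expressions over the amino-acid alphabet (e.g. `"C..C"`),
#' matched against the ungapped sequence.
#'
#' @param records `seq_records` or [aa_alignment()].
#' @param required_motifs Character vector of regular-expression motifs.
#' @param ref_id,start,end Optional reference span for the coverage rule;
#'   with an alignment, the span is mapped through the reference row,
#'   otherwise `start:end` index each ungapped sequence directly.
#' @return The surviving records (same class as the input), with a removal
#'   report data frame (`id`, `reason`) in `attr(,"removals")`.
#' @export
cull_redundant <- function(records, required_motifs = NULL, ref_id = NULL,
                           start = NULL, end = NULL) {
  if (length(records) == 0L) stop_ctx("empty input")
  is_aln <- inherits(records, "aa_alignment")
  if (!inherits(records, "seq_records")) records <- seq_records(records)
  seqs <- unclass(records)
  removals <- data.frame(id = character(0), reason = character(0),
                         stringsAsFactors = FALSE)
  drop <- function(ids, reason) {
    removals <<- rbind(removals, data.frame(id = ids, reason = reason,
                                            stringsAsFactors = FALSE))
  }
  keep <- !duplicated(unname(seqs))
  if (any(!keep)) drop(names(seqs)[!keep], "duplicate")
  seqs <- seqs[keep]

  if (!is.null(start) && !is.null(end)) {
    cols <- NULL
    if (is_aln && !is.null(ref_id)) {
      mapping <- map_reference_positions(records, ref_id)
      cols <- mapping[[as.character(start)]]:mapping[[as.character(end)]]
    }
    covered <- vapply(names(seqs), function(id) {
      if (!is.null(cols)) {
        span <- strsplit(seqs[[id]], "")[[1]][cols]
      } else {
        s <- strsplit(degap(seqs[[id]]), "")[[1]]
        if (length(s) < end) return(FALSE)
        span <- s[start:end]
      }
      !any(span %in% .missing_states)
    }, logical(1))
    if (any(!covered)) drop(names(seqs)[!covered], "partial")
    seqs <- seqs[covered]
  }

  if (!is.null(required_motifs)) {
    has_all <- vapply(seqs, function(s) {
      all(vapply(required_motifs, function(m) grepl(m, degap(s)), logical(1)))
    }, logical(1))
    if (any(!has_all)) drop(names(seqs)[!has_all], "missing_motif")
    seqs <- seqs[has_all]
  }

  if (length(seqs) == 0L) stop_ctx("culling removed every record")
  out <- seq_records(seqs)
  if (is_aln) out <- aa_alignment(out)
  attr(out, "removals") <- removals
  out
}

#' Census of major indels in an alignment
#'
#' An indel block is a maximal run of gap columns with an identical column
#' span shared by at least `min_members` rows, of length at least `min_len`
#' residues.  Gap runs contiguous with a row's first or last alignment
#' column are terminal (possible incomplete reads) and excluded when
#' `exclude_terminal` is `TRUE`.
#'
#' @param alignment An [aa_alignment()] with >= 2 rows.
#' @param min_len Minimum block length in columns (single-residue indels
#'   are not counted by default).
#' @param min_members Minimum number of rows sharing the exact span.
#' @param exclude_terminal Drop terminal gap runs.
#' @return Data frame with `col_start`, `col_end`, `length`, `n_members`
#'   and a `member_ids` list column, sorted by `col_start`.
#' @export
census_indels <- function(alignment, min_len = 2L, min_members = 2L,
                          exclude_terminal = TRUE) {
  alignment <- as_alignment(alignment)
  if (length(alignment) < 2L) stop_ctx("indel census needs >= 2 rows")
  m <- as.matrix(alignment)
  nc <- ncol(m)
  runs <- list()
  for (i in seq_len(nrow(m))) {
    gap <- m[i, ] == "-"
    r <- rle(gap)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    idx <- which(r$values)
    for (j in idx) {
      if (exclude_terminal && (starts[j] == 1L || ends[j] == nc)) next
      if (r$lengths[j] < min_len) next
      key <- paste(starts[j], ends[j], sep = ":")
      runs[[key]] <- c(runs[[key]], rownames(m)[i])
    }
  }
  runs <- runs[vapply(runs, length, integer(1)) >= min_members]
  if (length(runs) == 0L) {
    return(data.frame(col_start = integer(0), col_end = integer(0),
                      length = integer(0), n_members = integer(0)))
  }
  spans <- do.call(rbind, lapply(strsplit(names(runs), ":"), as.integer))
  out <- data.frame(col_start = spans[, 1], col_end = spans[, 2],
                    length = spans[, 2] - spans[, 1] + 1L,
                    n_members = vapply(runs, length, integer(1)))
  out$member_ids <- unname(runs)
  out <- out[order(out$col_start, out$col_end), , drop = FALSE]
  rownames(out) <- NULL
  out
}
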