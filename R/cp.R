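#' Exchange the two halves of a sequence
#'
#' Returns `suffix(boundary+1..n) + prefix(1..boundary)` -- the circular
#' rotation used to relate the ABCD and CDAB helix threadings.
#'
#' @param sequence Ungapped residue string.
#' @param boundary Cut point, `1 < boundary < nchar(sequence)`.
#' @return The rearranged sequence (same length).
#' @export
half_swap <- function(sequence, boundary) {
  n <- nchar(sequence)
  if (boundary <= 1L || boundary >= n) {
    stop_ctx("boundary must satisfy 1 < boundary < %d", n)
  }
  paste0(substr(sequence, boundary + 1L, n), substr(sequence, 1L, boundary))
}

# Normalize helix annotations to a named list label -> c(start, end).
as_helix_list <- function(helices) {
  if (is.data.frame(helices)) {
    out <- lapply(seq_len(nrow(helices)),
                  function(i) c(helices$res_start[i], helices$res_end[i]))
    names(out) <- helices$label
    out
  } else {
    helices
  }
}

#' Extract a helix-pair module from a sequence
#'
#' The AB module runs from the start of helix A to the end of helix B
#' (including the intervening loop); the CD module from helix C to helix D.
#' Modules follow the helix labels, not sequence order, so for a CDAB-threaded
#' family the AB module is the C-terminal half of the core domain and both
#' families' redox-active CXXC motifs fall inside their AB modules.
#'
#' @param sequence Ungapped residue string in reference numbering (residue
#'   `i` of the string is reference position `i`).
#' @param helices Helix annotation: data frame (`label`, `res_start`,
#'   `res_end`) or named list `label -> c(start, end)` for labels A--D.
#' @param module_id `"AB"` or `"CD"`.
#' @param ref_id Identifier recorded in the module origin.
#' @param anchor_motif Regular expression located within the module (default
#'   the redox CXXC motif); first match becomes the anchor.
#' @return Object of class `module_seq` with `residues`, `origin`
#'   (`ref_id`, `start`, `end`), `anchor` (module-relative position or `NA`).
#' @export
build_module <- function(sequence, helices, module_id = c("AB", "CD"),
                         ref_id = "seq", anchor_motif = "C..C") {
  module_id <- match.arg(module_id)
  hx <- as_helix_list(helices)
  first <- substr(module_id, 1, 1)
  second <- substr(module_id, 2, 2)
  for (lab in c(first, second)) {
    if (is.null(hx[[lab]])) stop_ctx("missing helix annotation '%s'", lab)
  }
  h1 <- hx[[first]]
  h2 <- hx[[second]]
  if (h1[2] >= h2[1]) {
    stop_ctx("helix %s must precede helix %s in the sequence", first, second)
  }
  n <- nchar(sequence)
  if (h1[1] < 1 || h2[2] > n) {
    stop_ctx("module span %d-%d outside sequence length %d", h1[1], h2[2], n)
  }
  residues <- substr(sequence, h1[1], h2[2])
  anchor <- regexpr(anchor_motif, residues)[1]
  structure(list(module = module_id, residues = residues,
                 origin = list(ref_id = ref_id, start = as.integer(h1[1]),
                               end = as.integer(h2[2])),
                 anchor = if (anchor > 0) as.integer(anchor) else NA_integer_),
            class = "module_seq")
}

#' @export
print.module_seq <- function(x, ...) {
  cat(sprintf("module_seq %s of %s [%d-%d], %d aa, anchor at %s\n",
              x$module, x$origin$ref_id, x$origin$start, x$origin$end,
              nchar(x$residues),
              if (is.na(x$anchor)) "none" else x$anchor))
  invisible(x)
}

# Assemble a module_alignment at a fixed translation offset:
# module-2 position j is aligned with module-1 position j + offset.
module_alignment_at <- function(module1, module2, offset) {
  r1 <- strsplit(module1$residues, "")[[1]]
  r2 <- strsplit(module2$residues, "")[[1]]
  minc <- min(1L, 1L + offset)
  maxc <- max(length(r1), length(r2) + offset)
  pos <- seq_len(maxc - minc + 1L)
  p1 <- pos + minc - 1L
  p2 <- p1 - offset
  res1 <- ifelse(p1 >= 1L & p1 <= length(r1), r1[pmax(pmin(p1, length(r1)), 1L)], NA)
  res2 <- ifelse(p2 >= 1L & p2 <= length(r2), r2[pmax(pmin(p2, length(r2)), 1L)], NA)
  identity <- !is.na(res1) & !is.na(res2) & res1 == res2 & res1 != "X"
  cols <- data.frame(position = pos,
                     pos1 = ifelse(p1 >= 1L & p1 <= length(r1), p1, NA_integer_),
                     res1 = res1,
                     pos2 = ifelse(p2 >= 1L & p2 <= length(r2), p2, NA_integer_),
                     res2 = res2, identity = identity,
                     stringsAsFactors = FALSE)
  structure(list(offset = as.integer(offset), columns = cols,
                 module1 = module1, module2 = module2),
            class = "module_alignment")
}

#' @export
print.module_alignment <- function(x, ...) {
  cat(sprintf("module_alignment: offset %+d, %d columns, %d identity sites\n",
              x$offset, nrow(x$columns), sum(x$columns$identity)))
  invisible(x)
}

#' Translation alignment of two modules anchored on their motifs
#'
#' Translates module 2 relative to module 1 until the anchor motifs (by
#' default the invariant CXXC) coincide; no internal gaps are introduced.
#'
#' @param module1,module2 [build_module()] results carrying anchors.
#' @return A `module_alignment`.
#' @export
anchor_align <- function(module1, module2) {
  if (is.na(module1$anchor) || is.na(module2$anchor)) {
    stop_ctx("both modules need an anchor motif for anchored alignment")
  }
  module_alignment_at(module1, module2, module1$anchor - module2$anchor)
}

#' Identity-maximizing translation alignment of two modules
#'
#' Scans all translations with at least `min_overlap` aligned columns and
#' returns the offset maximizing the identity-site count.  Ties are broken
#' by the smallest absolute offset, then negative before positive.
#'
#' @param module1,module2 [build_module()] results.
#' @param min_overlap Minimum number of aligned residue pairs.
#' @return A `module_alignment` with the per-offset identity profile in
#'   `attr(,"profile")`.
#' @export
best_identity_offset <- function(module1, module2, min_overlap = 10L) {
  n1 <- nchar(module1$residues)
  n2 <- nchar(module2$residues)
  if (min(n1, n2) < min_overlap) {
    stop_ctx("no translation gives an overlap of >= %d columns", min_overlap)
  }
  offsets <- seq(min_overlap - n2, n1 - min_overlap)
  counts <- vapply(offsets, function(o) {
    sum(module_alignment_at(module1, module2, o)$columns$identity)
  }, numeric(1))
  ord <- order(-counts, abs(offsets), offsets)
  best <- offsets[ord[1]]
  out <- module_alignment_at(module1, module2, best)
  attr(out, "profile") <- data.frame(offset = offsets, identities = counts)
  out
}

#' Count identity sites in module alignments
#'
#' For a single alignment, counts columns where both residues are present,
#' equal and informative (`X` never counts).  For a list of alignments that
#' share the same second (partner-family) module, `mode = "union"` counts
#' partner positions whose residue matches at least one of the first-family
#' index sequences, the natural reading of "identity among the index
#' sequences"; `mode = "pairwise"` reports each pair separately.
#'
#' @param alignment A `module_alignment` or list of them (same `module2`).
#' @param mode `"union"` or `"pairwise"`.
#' @return List with `count` (union count, or named pairwise counts) and
#'   `columns`/`positions` describing the matched sites; pairwise counts are
#'   always included as `pairwise`.
#' @export
count_identity_sites <- function(alignment, mode = c("union", "pairwise")) {
  mode <- match.arg(mode)
  alns <- if (inherits(alignment, "module_alignment")) list(alignment) else alignment
  stopifnot(length(alns) >= 1L)
  pairwise <- vapply(alns, function(a) sum(a$columns$identity), numeric(1))
  names(pairwise) <- vapply(alns, function(a) a$module1$origin$ref_id, character(1))
  # union over the shared partner-module coordinates
  pos2 <- sort(unique(unlist(lapply(alns, function(a) {
    a$columns$pos2[a$columns$identity]
  }))))
  union_count <- length(pos2)
  if (mode == "union") {
    list(count = union_count, positions = pos2, pairwise = pairwise)
  } else {
    list(count = pairwise, positions = pos2, pairwise = pairwise,
         union = union_count)
  }
}

# Extract a grade-by-reference-position lookup from a conservation profile
# (data frame with ref_position + grade) or an already-named vector.
grade_lookup <- function(profile) {
  if (is.data.frame(profile)) {
    ok <- !is.na(profile$ref_position)
    stats::setNames(profile$grade[ok], profile$ref_position[ok])
  } else {
    profile
  }
}

#' Match conserved features across an aligned module pair
#'
#' Module positions where both families carry a feature (e.g. helix-helix
#' contact membership or quinone-contact residues, given in each family's
#' reference numbering) and both conservation grades reach `min_grade`.
#'
#' @param alignment A `module_alignment`.
#' @param profile1,profile2 Conservation grades by reference position
#'   (named vector or [conservation_profile()] data frame) for families 1
#'   and 2.
#' @param features1,features2 Integer reference positions carrying the
#'   feature in each family.
#' @param min_grade Minimum conservation grade in both families.
#' @return Data frame with `position` (alignment column), `ref1`, `ref2`,
#'   `grade1`, `grade2` for the matched positions.
#' @export
match_conserved_features <- function(alignment, profile1, profile2,
                                     features1, features2, min_grade = 6L) {
  cols <- alignment$columns
  g1 <- grade_lookup(profile1)
  g2 <- grade_lookup(profile2)
  map_feature <- function(refpos, module, pos_col) {
    mpos <- refpos - module$origin$start + 1L
    hit <- match(mpos, cols[[pos_col]])
    if (any(is.na(hit))) {
      warning(sprintf("%d feature position(s) outside module %s ignored",
                      sum(is.na(hit)), module$origin$ref_id))
    }
    stats::setNames(hit, refpos)
  }
  c1 <- map_feature(features1, alignment$module1, "pos1")
  c2 <- map_feature(features2, alignment$module2, "pos2")
  shared <- intersect(c1[!is.na(c1)], c2[!is.na(c2)])
  res <- lapply(shared, function(p) {
    ref1 <- cols$pos1[p] + alignment$module1$origin$start - 1L
    ref2 <- cols$pos2[p] + alignment$module2$origin$start - 1L
    gr1 <- g1[as.character(ref1)]
    gr2 <- g2[as.character(ref2)]
    if (!is.na(gr1) && !is.na(gr2) && gr1 >= min_grade && gr2 >= min_grade) {
      data.frame(position = cols$position[p], ref1 = ref1, ref2 = ref2,
                 grade1 = as.integer(gr1), grade2 = as.integer(gr2))
    }
  })
  out <- do.call(rbind, res)
  if (is.null(out)) {
    out <- data.frame(position = integer(0), ref1 = integer(0),
                      ref2 = integer(0), grade1 = integer(0),
                      grade2 = integer(0))
  }
  rownames(out) <- NULL
  out[order(out$position), , drop = FALSE]
}

#' Detect a circular-permutation offset between two sequences
#'
#' Aligns `seq_b` locally against the doubled sequence `seq_a + seq_a`
#' (BLOSUM62, affine gaps); the permutation point is the start of the best
#' alignment modulo `nchar(seq_a)`.  Offset `k` means
#' `seq_b ~ rotate(seq_a, k)` where `rotate` is [half_swap()] at boundary
#' `k`; offset 0 means no permutation.
#'
#' @param seq_a,seq_b Ungapped residue strings, length >= 20.
#' @param gap_open,gap_extend Affine gap penalties.
#' @return List with `offset`, `score`, and `profile` -- a data frame of
#'   ungapped rotation scores for every candidate offset (diagnostics).
#' @export
find_cp_offset <- function(seq_a, seq_b, gap_open = 11, gap_extend = 1) {
  n <- nchar(seq_a)
  if (n < 20L || nchar(seq_b) < 20L) stop_ctx("sequences must be >= 20 residues")
  if (length(unique(strsplit(seq_a, "")[[1]])) <= 1L ||
      length(unique(strsplit(seq_b, "")[[1]])) <= 1L) {
    warning("low-complexity input (single-residue alphabet): offset unreliable")
  }
  data("BLOSUM62", package = "Biostrings", envir = environment())
  blosum <- get("BLOSUM62", envir = environment())
  aln <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::AAString(seq_b),
    subject = Biostrings::AAString(paste0(seq_a, seq_a)),
    type = "local", substitutionMatrix = blosum,
    gapOpening = gap_open, gapExtension = gap_extend)
  s_start <- Biostrings::start(Biostrings::subject(aln))
  p_start <- Biostrings::start(Biostrings::pattern(aln))
  offset <- (s_start - p_start) %% n
  a <- strsplit(seq_a, "")[[1]]
  b <- strsplit(seq_b, "")[[1]]
  m <- min(n, length(b))
  prof <- vapply(0:(n - 1L), function(k) {
    rot <- c(a[-seq_len(k)], a[seq_len(k)])[seq_len(m)]
    sum(blosum[cbind(rot, b[seq_len(m)])])
  }, numeric(1))
  list(offset = as.integer(offset), score = Biostrings::score(aln),
       profile = data.frame(offset = 0:(n - 1L), score = prof))
}
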