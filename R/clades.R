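#' Partition tree leaves into labeled clades from seed taxa
#'
#' Each label's clade is the smallest rooted subtree (most recent common
#' ancestor) containing its seed taxa.  The clades must be pairwise disjoint
#' (monophyly check); overlapping clades are an error naming the offenders.
#'
#' @param rooted_tree A rooted `phylo` tree.
#' @param seed_taxa Named list: label -> one or more leaf names.
#' @return Object of class `clade_assignment`: a named character vector
#'   (leaf -> label; unassigned leaves absent) with the label order in
#'   `attr(,"labels")`.
#' @export
clade_partition <- function(rooted_tree, seed_taxa) {
  stopifnot(inherits(rooted_tree, "phylo"))
  if (length(seed_taxa) == 0L || is.null(names(seed_taxa))) {
    stop_ctx("seed_taxa must be a non-empty named list")
  }
  leaves <- rooted_tree$tip.label
  labels <- names(seed_taxa)
  all_seeds <- unlist(seed_taxa, use.names = FALSE)
  missing <- setdiff(all_seeds, leaves)
  if (length(missing)) {
    stop_ctx("seed taxa not in tree: %s", paste(missing, collapse = ", "))
  }
  ntip <- length(leaves)
  parent_of <- integer(ntip + rooted_tree$Nnode)
  parent_of[rooted_tree$edge[, 2]] <- rooted_tree$edge[, 1]
  root <- setdiff(rooted_tree$edge[, 1], rooted_tree$edge[, 2])[1]
  members <- lapply(labels, function(lab) {
    seeds <- seed_taxa[[lab]]
    foreign <- unlist(seed_taxa[setdiff(labels, lab)], use.names = FALSE)
    node <- if (length(seeds) == 1L) match(seeds, leaves) else {
      ape::getMRCA(rooted_tree, seeds)
    }
    tips <- leaves[tips_under(rooted_tree, node)]
    ov <- intersect(tips, foreign)
    if (length(ov)) {
      lab2 <- labels[vapply(seed_taxa, function(s) ov[1] %in% s, logical(1))][1]
      stop_ctx("clades '%s' and '%s' overlap (seed %s falls inside the subtree spanned by clade '%s'): seed groups are not mutually monophyletic",
               lab, lab2, ov[1], lab)
    }
    # extend to the largest subtree containing this label's seeds and no
    # other label's seeds (the clade the seeds represent)
    repeat {
      if (node == root) break
      up <- parent_of[node]
      up_tips <- leaves[tips_under(rooted_tree, up)]
      if (length(intersect(up_tips, foreign))) break
      node <- up
      tips <- up_tips
    }
    tips
  })
  names(members) <- labels
  for (i in seq_along(members)) {
    for (j in seq_len(i - 1L)) {
      ov <- intersect(members[[i]], members[[j]])
      if (length(ov)) {
        stop_ctx("clades '%s' and '%s' overlap (e.g. %s)",
                 labels[j], labels[i], ov[1])
      }
    }
  }
  assignment <- unlist(lapply(labels, function(l) {
    stats::setNames(rep(l, length(members[[l]])), members[[l]])
  }))
  structure(assignment, labels = labels, class = "clade_assignment")
}

#' @export
print.clade_assignment <- function(x, ...) {
  tab <- table(factor(unclass(x), levels = attr(x, "labels")))
  cat("clade_assignment:",
      paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

clade_members <- function(assignment, label) {
  names(assignment)[unclass(assignment) == label]
}

#' Fully conserved alignment columns
#'
#' Columns where all non-missing residues are a single state and non-gap
#' occupancy is at least `min_occupancy` (the family "signature" residues).
#'
#' @param alignment An [aa_alignment()] with >= 2 rows.
#' @param min_occupancy Minimum fraction of rows with a real residue.
#' @param ref_id Optional reference row; adds reference positions.
#' @return Data frame with `column`, `state`, `occupancy`, `ref_position`.
#' @export
fully_conserved_sites <- function(alignment, min_occupancy = 0.9,
                                  ref_id = NULL) {
  alignment <- as_alignment(alignment)
  if (length(alignment) < 2L) stop_ctx("needs >= 2 rows")
  m <- as.matrix(alignment)
  inv <- if (!is.null(ref_id)) attr(map_reference_positions(alignment, ref_id), "inverse")
  res <- lapply(seq_len(ncol(m)), function(j) {
    col <- m[, j]
    obs <- col[!col %in% .missing_states]
    occ <- length(obs) / length(col)
    if (length(obs) && length(unique(obs)) == 1L && occ >= min_occupancy) {
      data.frame(column = j, state = obs[1], occupancy = occ,
                 ref_position = if (is.null(inv)) NA_integer_ else inv[j],
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, res)
  if (is.null(out)) {
    out <- data.frame(column = integer(0), state = character(0),
                      occupancy = numeric(0), ref_position = integer(0))
  }
  rownames(out) <- NULL
  out
}

#' Clade-differential absent segments
#'
#' Maximal column spans gapped throughout clade `clade_a` but occupied (a
#' real residue) in at least half of clade `clade_b`, of length at least
#' `min_len` -- the "systematically absent" segments of one clade relative
#' to another.
#'
#' @param alignment An [aa_alignment()].
#' @param assignment A [clade_partition()] result (or named label vector).
#' @param clade_a,clade_b Clade labels (absent-in vs present-in).
#' @param min_len Minimum span length in columns.
#' @param min_b_occupancy Minimum fraction of `clade_b` rows occupied.
#' @param ref_id Optional reference row; adds reference coordinates of the
#'   span boundaries.
#' @return Data frame with `col_start`, `col_end`, `length`,
#'   `ref_start`, `ref_end`, sorted by `col_start`.
#' @export
clade_absent_segments <- function(alignment, assignment, clade_a, clade_b,
                                  min_len = 2L, min_b_occupancy = 0.5,
                                  ref_id = NULL) {
  alignment <- as_alignment(alignment)
  for (lab in c(clade_a, clade_b)) {
    if (!lab %in% unclass(assignment)) stop_ctx("unknown clade label '%s'", lab)
  }
  a_ids <- clade_members(assignment, clade_a)
  b_ids <- clade_members(assignment, clade_b)
  m <- as.matrix(alignment)
  a_gapped <- colSums(m[a_ids, , drop = FALSE] == "-") == length(a_ids)
  b_occ <- colMeans(!(m[b_ids, , drop = FALSE] == "-" |
                        m[b_ids, , drop = FALSE] == "X"))
  flag <- a_gapped & b_occ >= min_b_occupancy
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  idx <- which(r$values & r$lengths >= min_len)
  inv <- if (!is.null(ref_id)) attr(map_reference_positions(alignment, ref_id), "inverse")
  ref_at <- function(col) if (is.null(inv)) NA_integer_ else inv[col]
  out <- data.frame(col_start = starts[idx], col_end = ends[idx],
                    length = r$lengths[idx],
                    ref_start = vapply(starts[idx], ref_at, integer(1)),
                    ref_end = vapply(ends[idx], ref_at, integer(1)))
  out <- out[order(out$col_start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Scan for group-specific single-site markers
#'
#' Columns where some residue state has frequency at least `min_in_freq`
#' among the group's non-missing rows and at most `max_out_freq` among the
#' complement's non-missing rows.  With the defaults (1, 0) this is a
#' perfect presence/absence determinant, like a diagnostic covariant site.
#' Missing states (`-`, `X`) are excluded from both numerator and
#' denominator.
#'
#' @param alignment An [aa_alignment()].
#' @param group_members Sequence ids of the focal group (non-empty, proper
#'   subset of the alignment).
#' @param max_out_freq Maximum frequency of the marker state outside the
#'   group.
#' @param min_in_freq Minimum frequency inside the group.
#' @param ref_id Optional reference row for reference numbering.
#' @return Data frame with `column`, `ref_position`, `state`, `in_freq`,
#'   `out_freq`, sorted by column.
#' @export
single_site_markers <- function(alignment, group_members, max_out_freq = 0,
                                min_in_freq = 1, ref_id = NULL) {
  alignment <- as_alignment(alignment)
  ids <- names(alignment)
  missing <- setdiff(group_members, ids)
  if (length(missing)) {
    stop_ctx("group members not in alignment: %s", paste(missing, collapse = ", "))
  }
  if (length(group_members) == 0L) stop_ctx("empty group")
  comp <- setdiff(ids, group_members)
  if (length(comp) == 0L) stop_ctx("empty complement: marker undefined")
  m <- as.matrix(alignment)
  inv <- if (!is.null(ref_id)) attr(map_reference_positions(alignment, ref_id), "inverse")
  res <- lapply(seq_len(ncol(m)), function(j) {
    gin <- m[group_members, j]
    gin <- gin[!gin %in% .missing_states]
    gout <- m[comp, j]
    gout <- gout[!gout %in% .missing_states]
    # both sides need at least one observed residue: presence/absence is
    # undefined otherwise
    if (length(gin) == 0L || length(gout) == 0L) return(NULL)
    states <- unique(gin)
    hits <- lapply(states, function(s) {
      in_f <- mean(gin == s)
      out_f <- mean(gout == s)
      if (in_f >= min_in_freq && out_f <= max_out_freq) {
        data.frame(column = j,
                   ref_position = if (is.null(inv)) NA_integer_ else inv[j],
                   state = s, in_freq = in_f, out_freq = out_f,
                   stringsAsFactors = FALSE)
      }
    })
    do.call(rbind, hits)
  })
  out <- do.call(rbind, res)
  if (is.null(out)) {
    out <- data.frame(column = integer(0), ref_position = integer(0),
                      state = character(0), in_freq = numeric(0),
                      out_freq = numeric(0))
  }
  rownames(out) <- NULL
  out
}

#' Per-clade residue spectrum at a reference position
#'
#' Reports, for one alignment column (addressed by reference position),
#' which residue states each clade carries and at what frequencies --
#' the kind of per-clade breakdown used to interpret catalytic positions.
#'
#' @param alignment An [aa_alignment()].
#' @param assignment A [clade_partition()] result.
#' @param ref_id Reference row id.
#' @param ref_position 1-based residue number in the ungapped reference.
#' @return Data frame with `clade`, `state`, `count`, `freq` (missing states
#'   excluded).
#' @export
clade_state_spectrum <- function(alignment, assignment, ref_id, ref_position) {
  alignment <- as_alignment(alignment)
  mapping <- map_reference_positions(alignment, ref_id)
  if (ref_position < 1L || ref_position > length(mapping)) {
    stop_ctx("reference position %d outside reference length %d",
             ref_position, length(mapping))
  }
  col <- as.matrix(alignment)[, mapping[[as.character(ref_position)]]]
  labels <- attr(assignment, "labels") %||% unique(unclass(assignment))
  res <- lapply(labels, function(lab) {
    obs <- col[intersect(clade_members(assignment, lab), names(col))]
    obs <- obs[!obs %in% .missing_states]
    if (length(obs) == 0L) return(NULL)
    tab <- sort(table(obs), decreasing = TRUE)
    data.frame(clade = lab, state = names(tab), count = as.integer(tab),
               freq = as.numeric(tab) / length(obs), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
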