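#' Empirical-Bayes posterior mean site rates
#'
#' For each alignment column the posterior mean evolutionary rate under a
#' discrete-gamma prior:
#' \deqn{\hat r_i = \sum_k r_k L_i(r_k) w_k / \sum_k L_i(r_k) w_k}
#' where \eqn{L_i(r_k)} is the pruning likelihood of column `i` with all
#' branch lengths scaled by the category rate \eqn{r_k} and \eqn{w_k} are the
#' equal category prior weights.  The estimate is a convex combination of the
#' category rates, hence bounded by the extreme categories.
#'
#' @param alignment An [aa_alignment()].
#' @param tree A `phylo` tree with branch lengths covering the alignment ids.
#' @param model A [substitution_model()] with `alpha` set (the rate prior).
#' @param n_cat Number of gamma categories for rate inference (finer than
#'   the tree-likelihood default, for resolution).
#' @return Numeric vector of posterior mean rates (`NA` for all-gap
#'   columns); columns with under 10\% non-gap occupancy are flagged in
#'   `attr(,"low_confidence")`.
#' @export
site_rate_posteriors <- function(alignment, tree, model, n_cat = 16L) {
  alignment <- as_alignment(alignment)
  if (is.na(model$alpha)) {
    stop_ctx("model must carry a gamma shape (alpha) as the rate prior")
  }
  rates <- discretize_gamma(model$alpha, n_cat)
  ll <- category_site_logliks(alignment, tree, model, rates)
  m <- as.matrix(alignment)
  occupancy <- colMeans(matrix(!(m %in% .missing_states), nrow(m)))
  all_gap <- occupancy == 0
  post <- vapply(seq_len(nrow(ll)), function(i) {
    w <- ll[i, ]
    mx <- max(w)
    if (!is.finite(mx)) return(NA_real_)
    p <- exp(w - mx)
    sum(rates * p) / sum(p)
  }, numeric(1))
  post[all_gap] <- NA_real_
  attr(post, "low_confidence") <- occupancy < 0.1 & !all_gap
  attr(post, "occupancy") <- occupancy
  post
}

#' Nine-grade conservation binning
#'
#' Standardizes posterior rates to zero mean and unit variance across the
#' scored columns and partitions the observed score range into nine
#' equal-width bins: the lowest-score bin (most conserved, slowest) is grade
#' 9, the highest grade 1.  When all scores are identical every column gets
#' the mid grade 5.  Columns without a rate (`NA`, e.g. all-gap in the
#' scored subset) get grade 0.
#'
#' @param rates Posterior mean rates from [site_rate_posteriors()].
#' @return Integer grades (0--9) with the standardized scores in
#'   `attr(,"scores")`.
#' @export
grades_from_scores <- function(rates) {
  if (length(rates) == 0L) stop_ctx("no scored columns")
  ok <- is.finite(rates)
  if (!any(ok)) stop_ctx("no scored columns (all NA)")
  x <- rates[ok]
  s <- if (stats::sd(x) > 0) (x - mean(x)) / stats::sd(x) else rep(0, length(x))
  grades <- rep(0L, length(rates))
  if (diff(range(s)) == 0) {
    grades[ok] <- 5L
  } else {
    bin <- floor(9 * (s - min(s)) / (max(s) - min(s)))
    bin[bin == 9] <- 8                      # the maximum falls in the top bin
    grades[ok] <- as.integer(9 - bin)
  }
  scores <- rep(NA_real_, length(rates))
  scores[ok] <- s
  attr(grades, "scores") <- scores
  grades
}

#' Conservation profile of an alignment on a tree
#'
#' Runs [site_rate_posteriors()] and [grades_from_scores()] and assembles the
#' per-column profile table.
#'
#' @inheritParams site_rate_posteriors
#' @param ref_id Optional reference row for reference-coordinate annotation.
#' @return Data frame of class `conservation_profile` with `column`,
#'   `ref_position`, `ref_residue`, `rate`, `score`, `grade`,
#'   `low_confidence`.
#' @export
conservation_profile <- function(alignment, tree, model, n_cat = 16L,
                                 ref_id = NULL) {
  alignment <- as_alignment(alignment)
  post <- site_rate_posteriors(alignment, tree, model, n_cat)
  grades <- grades_from_scores(post)
  nc <- n_columns(alignment)
  ref_pos <- rep(NA_integer_, nc)
  ref_res <- rep(NA_character_, nc)
  if (!is.null(ref_id)) {
    mapping <- map_reference_positions(alignment, ref_id)
    inv <- attr(mapping, "inverse")
    ref_pos <- inv
    row <- strsplit(unclass(alignment)[[ref_id]], "")[[1]]
    ref_res <- ifelse(row == "-", NA_character_, row)
  }
  out <- data.frame(column = seq_len(nc), ref_position = ref_pos,
                    ref_residue = ref_res, rate = as.numeric(post),
                    score = attr(grades, "scores"), grade = as.integer(grades),
                    low_confidence = attr(post, "low_confidence"),
                    stringsAsFactors = FALSE)
  class(out) <- c("conservation_profile", "data.frame")
  out
}

#' Clade-restricted conservation profile
#'
#' Restricts the alignment rows and prunes the tree to the clade members,
#' then recomputes the rate posteriors and grades within the clade.  Columns
#' that are all-gap within the clade get grade 0 (the "absent" code).
#'
#' @inheritParams conservation_profile
#' @param clade_members Character vector of >= 3 sequence ids.
#' @return A `conservation_profile` data frame over the full column range of
#'   the input alignment.
#' @export
clade_profile <- function(alignment, tree, clade_members, model, n_cat = 16L,
                          ref_id = NULL) {
  alignment <- as_alignment(alignment)
  missing <- setdiff(clade_members, names(alignment))
  if (length(missing)) {
    stop_ctx("clade members not in alignment: %s", paste(missing, collapse = ", "))
  }
  if (length(clade_members) < 3L) {
    stop_ctx("clade profile needs >= 3 members (rate inference unreliable)")
  }
  sub <- aa_alignment(seq_records(unclass(alignment)[clade_members]))
  subtree <- prune_to_taxa(tree, clade_members)
  if (!is.null(ref_id) && !ref_id %in% clade_members) ref_id <- NULL
  conservation_profile(sub, subtree, model, n_cat, ref_id)
}
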