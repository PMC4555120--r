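#' Neighbor-joining tree from a distance matrix
#'
#' Standard neighbor joining (via `ape::nj`) with negative branch-length
#' estimates clamped to zero.
#'
#' @param distance_matrix Symmetric matrix with zero diagonal and at least
#'   3 taxa (row/column names are taxon labels).
#' @return An unrooted `phylo` tree with branch lengths.
#' @export
nj_tree <- function(distance_matrix) {
  D <- as.matrix(distance_matrix)
  if (nrow(D) != ncol(D) || max(abs(D - t(D))) > 1e-8) {
    stop_ctx("distance matrix must be symmetric")
  }
  if (any(abs(diag(D)) > 1e-12)) stop_ctx("distance matrix must have zero diagonal")
  if (nrow(D) < 3L) stop_ctx("neighbor joining needs at least 3 taxa")
  tr <- ape::nj(D)
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

#' Optimize branch lengths by maximum likelihood on a fixed topology
#'
#' Coordinate-wise scalar optimization of each branch length in
#' `[0, max_branch]`, repeated in passes over the tree until the total
#' log-likelihood improves by less than `tol` or `max_passes` passes are
#' done.  The log-likelihood never decreases across passes.
#'
#' @inheritParams site_log_likelihoods
#' @param max_branch Upper bound for any single branch length.
#' @param tol Convergence tolerance on the total log-likelihood.
#' @param max_passes Maximum number of passes over all branches.
#' @return The tree with optimized `edge.length` and attributes
#'   `log_likelihood` and `passes`.
#' @export
optimize_branch_lengths <- function(tree, alignment, model, max_branch = 10,
                                    tol = 1e-6, max_passes = 20L) {
  alignment <- as_alignment(alignment)
  ev <- likelihood_evaluator(alignment, tree, model)
  tree <- ev$tree
  elen <- tree$edge.length
  ll <- ev$eval(elen, model)
  passes <- 0L
  repeat {
    passes <- passes + 1L
    pass_start_ll <- ll
    for (e in seq_len(nrow(tree$edge))) {
      f <- function(t) {
        el <- elen
        el[e] <- t
        -ev$eval(el, model)
      }
      opt <- optimize(f, c(0, max_branch), tol = 1e-5)
      if (-opt$objective > ll) {
        elen[e] <- opt$minimum
        ll <- -opt$objective
      }
    }
    if (passes >= max_passes || (ll - pass_start_ll) < tol) break
  }
  tree$edge.length <- elen
  attr(tree, "log_likelihood") <- ll
  attr(tree, "passes") <- passes
  tree
}

#' Estimate rate-heterogeneity parameters (+G shape, +I proportion)
#'
#' Joint maximization of the tree likelihood over the gamma shape
#' `alpha` in `[0.05, 20]` and the invariant proportion `p_inv` in
#' `[0, 0.95]` by nested scalar optimization (outer over `p_inv`, inner over
#' `alpha`), on a fixed topology with fixed branch lengths.
#'
#' @inheritParams site_log_likelihoods
#' @param estimate_alpha,estimate_p_inv Which parameters to free; a fixed
#'   parameter keeps the model's current value.
#' @return List with `alpha`, `p_inv`, `log_likelihood`, `model` (the updated
#'   model) and a `degenerate` flag set when the alignment carries no
#'   rate signal (e.g. all columns identical).
#' @export
estimate_rate_params <- function(alignment, tree, model,
                                 estimate_alpha = TRUE, estimate_p_inv = TRUE) {
  alignment <- as_alignment(alignment)
  m <- as.matrix(alignment)
  degenerate <- all(apply(m, 2L, function(col) {
    obs <- col[!col %in% .missing_states]
    length(unique(obs)) <= 1L
  }))
  if (degenerate) warning("degenerate alignment: all columns constant; rate parameters are at their boundary")

  ev <- likelihood_evaluator(alignment, tree, model)
  elen <- ev$tree$edge.length
  ll_at <- function(alpha, p_inv) {
    ev$eval(elen, set_rate_params(model, alpha = alpha, p_inv = p_inv))
  }
  best_alpha <- function(p_inv) {
    if (!estimate_alpha) return(list(alpha = model$alpha, ll = ll_at(model$alpha, p_inv)))
    opt <- optimize(function(la) -ll_at(exp(la), p_inv),
                    log(c(0.05, 20)), tol = 1e-4)
    list(alpha = exp(opt$minimum), ll = -opt$objective)
  }
  if (estimate_p_inv) {
    opt <- optimize(function(p) -best_alpha(p)$ll, c(0, 0.95), tol = 1e-4)
    p_inv <- opt$minimum
    inner <- best_alpha(p_inv)
    # the boundary p_inv = 0 is checked explicitly
    inner0 <- best_alpha(0)
    if (inner0$ll >= inner$ll) {
      p_inv <- 0
      inner <- inner0
    }
  } else {
    p_inv <- if (is.na(model$p_inv)) 0 else model$p_inv
    inner <- best_alpha(p_inv)
  }
  mod <- set_rate_params(model,
                         alpha = if (estimate_alpha) inner$alpha else model$alpha,
                         p_inv = if (estimate_p_inv) p_inv else model$p_inv)
  list(alpha = inner$alpha, p_inv = p_inv, log_likelihood = inner$ll,
       model = mod, degenerate = degenerate)
}

#' Fit and rank substitution-model candidates by information criteria
#'
#' Each candidate configuration (base matrix, optional `+I`, optional `+G`)
#' is fitted on the given topology -- branch lengths by coordinate-wise
#' maximum likelihood, then rate parameters -- and scored by AIC, corrected
#' AIC and BIC.  Following common practice for comparing nested rate models
#' on a fixed topology, the free-parameter count `k` covers the rate
#' parameters only (branch lengths are shared by all candidates).
#'
#' @param alignment An [aa_alignment()].
#' @param tree Starting tree with branch lengths (e.g. from [nj_tree()]).
#' @param candidates List of lists with elements `name` ("WAG"/"JTT"),
#'   `inv` and `gamma` (logicals).
#' @param criterion Criterion used for the final ordering.
#' @param bl_passes Branch-length optimization passes per candidate.
#' @return A data frame (one row per candidate, sorted by the chosen
#'   criterion, ascending) with `model`, `log_likelihood`, `k`, `n`, `aic`,
#'   `aicc`, `bic`; fitted models in `attr(,"fits")`.
#' @export
select_model <- function(alignment, tree, candidates,
                         criterion = c("bic", "aic", "aicc"),
                         bl_passes = 2L) {
  criterion <- match.arg(criterion)
  alignment <- as_alignment(alignment)
  n <- n_columns(alignment)
  rows <- list()
  fits <- list()
  for (cand in candidates) {
    mod <- substitution_model(cand$name,
                              alpha = if (isTRUE(cand$gamma)) 1 else NA,
                              p_inv = if (isTRUE(cand$inv)) 0.1 else NA)
    tr <- optimize_branch_lengths(tree, alignment, mod, max_passes = bl_passes)
    if (isTRUE(cand$gamma) || isTRUE(cand$inv)) {
      est <- estimate_rate_params(alignment, tr, mod,
                                  estimate_alpha = isTRUE(cand$gamma),
                                  estimate_p_inv = isTRUE(cand$inv))
      mod <- est$model
      tr <- optimize_branch_lengths(tr, alignment, mod, max_passes = bl_passes)
    }
    ll <- attr(tr, "log_likelihood")
    k <- sum(isTRUE(cand$gamma), isTRUE(cand$inv))
    label <- paste0(cand$name,
                    if (isTRUE(cand$inv)) "+I" else "",
                    if (isTRUE(cand$gamma)) "+G" else "")
    ic <- information_criteria(ll, k, n)
    rows[[label]] <- data.frame(model = label, log_likelihood = ll, k = k,
                                n = n, aic = ic$aic, aicc = ic$aicc,
                                bic = ic$bic, stringsAsFactors = FALSE)
    fits[[label]] <- list(model = mod, tree = tr)
  }
  out <- do.call(rbind, rows)
  out <- out[order(out[[criterion]]), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "fits") <- fits
  out
}

#' Information criteria from a log-likelihood
#'
#' `aic = -2 lnL + 2k`, `aicc = aic + 2k(k+1)/(n-k-1)` (undefined, `NA`, when
#' `n <= k + 1`), `bic = -2 lnL + k ln(n)`.
#'
#' @param log_likelihood Maximized log-likelihood.
#' @param k Number of free parameters.
#' @param n Number of sites.
#' @return List with `aic`, `aicc`, `bic`.
#' @export
information_criteria <- function(log_likelihood, k, n) {
  aic <- -2 * log_likelihood + 2 * k
  aicc <- if (n > k + 1) aic + 2 * k * (k + 1) / (n - k - 1) else NA_real_
  bic <- -2 * log_likelihood + k * log(n)
  list(aic = aic, aicc = aicc, bic = bic)
}

#' Nonparametric bootstrap supports for an alignment-derived tree
#'
#' Resamples alignment columns with replacement, rebuilds a tree per
#' replicate with `tree_builder`, and annotates each internal bipartition of
#' the point-estimate tree with the percentage of replicate trees containing
#' it (stored as internal node labels).
#'
#' @param alignment An [aa_alignment()].
#' @param n_reps Number of bootstrap replicates (>= 1).
#' @param seed Integer seed; the same seed reproduces the same supports.
#' @param tree_builder Function `alignment -> phylo`; defaults to
#'   maximum-likelihood distances under `model` followed by [nj_tree()].
#' @param model Model for the default builder.
#' @return The point-estimate tree with supports in `[0, 100]` as
#'   `node.label` (empty for the root) and a `supports` attribute keyed by
#'   canonical split.
#' @export
bootstrap_supports <- function(alignment, n_reps, seed, tree_builder = NULL,
                               model = substitution_model("WAG")) {
  alignment <- as_alignment(alignment)
  if (n_reps < 1L) stop_ctx("n_reps must be >= 1")
  if (is.null(tree_builder)) {
    tree_builder <- function(aln) nj_tree(ml_distance_matrix(aln, model))
  }
  point <- tree_builder(alignment)
  m <- as.matrix(alignment)
  splits <- tree_splits(point)
  counts <- stats::setNames(numeric(length(splits)), splits)
  with_seed(seed, {
    for (r in seq_len(n_reps)) {
      cols <- sample.int(ncol(m), ncol(m), replace = TRUE)
      rep_aln <- alignment_from_matrix(m[, cols, drop = FALSE])
      rep_tree <- tree_builder(rep_aln)
      rep_splits <- tree_splits(rep_tree)
      hit <- splits %in% rep_splits
      counts[hit] <- counts[hit] + 1
    }
  })
  pct <- 100 * counts / n_reps
  point <- annotate_supports(point, pct)
  attr(point, "supports") <- pct
  point
}

# Write per-split support percentages onto internal node labels.
annotate_supports <- function(tree, split_pct) {
  ntip <- length(tree$tip.label)
  anchor <- sort(tree$tip.label)[1]
  labels <- rep("", tree$Nnode)
  for (node in (ntip + 1L):(ntip + tree$Nnode)) {
    tips <- tree$tip.label[tips_under(tree, node)]
    if (length(tips) <= 1L || length(tips) >= ntip - 1L) next
    side <- if (anchor %in% tips) setdiff(tree$tip.label, tips) else tips
    key <- paste(sort(side), collapse = "|")
    if (key %in% names(split_pct)) {
      labels[node - ntip] <- format(round(split_pct[[key]]), trim = TRUE)
    }
  }
  tree$node.label <- labels
  tree
}

#' Root a tree on an outgroup taxon
#'
#' Places the root on the outgroup's pendant branch, splitting its length in
#' half; the ingroup topology is unchanged.
#'
#' @param tree An (un)rooted `phylo` tree.
#' @param outgroup_taxon A leaf label.
#' @return A rooted `phylo` tree.
#' @export
root_with_outgroup <- function(tree, outgroup_taxon) {
  if (!outgroup_taxon %in% tree$tip.label) {
    stop_ctx("outgroup taxon '%s' not in tree", outgroup_taxon)
  }
  tree <- ape::unroot(tree)
  tip <- which(tree$tip.label == outgroup_taxon)
  pend <- which(tree$edge[, 2] == tip)
  len <- tree$edge.length[pend]
  rooted <- ape::root(tree, outgroup = outgroup_taxon, resolve.root = TRUE)
  ntip <- length(rooted$tip.label)
  root_node <- ntip + 1L
  root_edges <- which(rooted$edge[, 1] == root_node)
  # distribute the original pendant length half-and-half around the root
  rooted$edge.length[root_edges] <- len / 2
  rooted
}

#' Prune a tree to a subset of taxa
#'
#' Removes leaves outside `keep_set`, suppressing resulting degree-2 nodes
#' with branch lengths summed, so path lengths between kept leaves are
#' preserved.
#'
#' @param tree A `phylo` tree.
#' @param keep_set Character vector of leaf labels to keep (>= 2, all
#'   present in the tree).
#' @return The pruned `phylo` tree.
#' @export
prune_to_taxa <- function(tree, keep_set) {
  missing <- setdiff(keep_set, tree$tip.label)
  if (length(missing)) {
    stop_ctx("taxa not in tree: %s", paste(missing, collapse = ", "))
  }
  if (length(keep_set) < 2L) stop_ctx("keep_set must contain at least 2 taxa")
  if (setequal(keep_set, tree$tip.label)) return(tree)
  ape::drop.tip(tree, setdiff(tree$tip.label, keep_set))
}
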