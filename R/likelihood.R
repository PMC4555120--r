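# Integer state codes for an alignment (rows ordered as `ids`):
# 1..20 for amino acids, 0 for missing ('X' or '-').
encode_states <- function(alignment, ids) {
  m <- as.matrix(as_alignment(alignment))
  missing_ids <- setdiff(ids, rownames(m))
  if (length(missing_ids)) {
    stop_ctx("tree leaves without sequences: %s",
             paste(missing_ids, collapse = ", "))
  }
  m <- m[ids, , drop = FALSE]
  codes <- match(m, .aa_states)
  codes[is.na(codes)] <- 0L
  matrix(as.integer(codes), nrow = nrow(m), dimnames = dimnames(m))
}

# Per-category site log-likelihoods (nsites x ncat) by pruning.
category_site_logliks <- function(alignment, tree, model, rates) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) stop_ctx("tree has no branch lengths")
  if (any(tree$edge.length < 0)) stop_ctx("negative branch length in tree")
  tree <- ape::reorder.phylo(tree, "postorder")
  codes <- encode_states(alignment, tree$tip.label)
  .prune_loglik_cpp(codes, tree$edge, tree$edge.length, tree$Nnode,
                    model$V, model$Vinv, model$lambda, model$pi, rates)
}

# +I mixture weight per column: pi of the shared state for columns whose
# non-missing residues are all equal (1 for all-missing columns), else 0.
invariant_site_factor <- function(alignment, model) {
  m <- as.matrix(as_alignment(alignment))
  apply(m, 2L, function(col) {
    obs <- col[!col %in% .missing_states]
    if (length(obs) == 0L) return(1)
    if (length(unique(obs)) == 1L) return(unname(model$pi[match(obs[1], .aa_states)]))
    0
  })
}

#' Per-column log-likelihoods of an alignment on a tree
#'
#' Computes site log-likelihoods by Felsenstein pruning under an empirical
#' amino-acid model, mixing over a proportion of invariant sites (`+I`) and
#' discrete-gamma rate categories (`+G`) when the model carries them.  Gaps
#' and `X` are treated as missing data (partial-likelihood vector of ones).
#'
#' @param alignment An [aa_alignment()] whose ids cover the tree leaves.
#' @param tree A `phylo` tree with branch lengths.
#' @param model A [substitution_model()].
#' @return Numeric vector of per-column log-likelihoods (`-Inf` for
#'   zero-probability configurations).
#' @export
site_log_likelihoods <- function(alignment, tree, model) {
  rates <- model_rates(model)
  ll <- category_site_logliks(alignment, tree, model, rates)
  mix_site_logliks(ll, alignment, model)
}

# Combine per-category logliks with the +I term, stably.
mix_site_logliks <- function(cat_ll, alignment, model) {
  p_inv <- if (is.na(model$p_inv)) 0 else model$p_inv
  # log of the category mixture mean
  mx <- apply(cat_ll, 1L, max)
  gm <- ifelse(is.finite(mx),
               mx + log(rowMeans(exp(cat_ll - mx))),
               -Inf)
  if (p_inv == 0) return(unname(gm))
  inv <- invariant_site_factor(alignment, model)
  a <- ifelse(inv > 0, log(p_inv) + log(inv), -Inf)
  b <- log1p(-p_inv) + gm
  m <- pmax(a, b)
  unname(ifelse(is.finite(m), m + log(exp(a - m) + exp(b - m)), -Inf))
}

#' Total log-likelihood of an alignment on a tree
#'
#' @inheritParams site_log_likelihoods
#' @return The summed site log-likelihood.
#' @export
tree_log_likelihood <- function(alignment, tree, model) {
  sum(site_log_likelihoods(alignment, tree, model))
}

# Cached likelihood evaluator: encodes the alignment and fixes the postorder
# once, so optimizers can re-evaluate with new branch lengths or rate
# parameters cheaply.  `eval(elen, model)` returns the total log-likelihood
# for the postorder tree with branch lengths `elen`.
likelihood_evaluator <- function(alignment, tree, model) {
  alignment <- as_alignment(alignment)
  ptree <- ape::reorder.phylo(tree, "postorder")
  codes <- encode_states(alignment, ptree$tip.label)
  inv_cache <- new.env(parent = emptyenv())
  inv_factor <- function(model) {
    key <- model$name
    if (is.null(inv_cache[[key]])) {
      inv_cache[[key]] <- invariant_site_factor(alignment, model)
    }
    inv_cache[[key]]
  }
  eval_ll <- function(elen, model) {
    rates <- model_rates(model)
    ll <- .prune_loglik_cpp(codes, ptree$edge, elen, ptree$Nnode,
                            model$V, model$Vinv, model$lambda, model$pi, rates)
    p_inv <- if (is.na(model$p_inv)) 0 else model$p_inv
    mx <- apply(ll, 1L, max)
    gm <- ifelse(is.finite(mx), mx + log(rowMeans(exp(ll - mx))), -Inf)
    if (p_inv == 0) return(sum(gm))
    inv <- inv_factor(model)
    a <- ifelse(inv > 0, log(p_inv) + log(inv), -Inf)
    b <- log1p(-p_inv) + gm
    m <- pmax(a, b)
    sum(ifelse(is.finite(m), m + log(exp(a - m) + exp(b - m)), -Inf))
  }
  list(tree = ptree, eval = eval_ll)
}

#' Maximum-likelihood pairwise distance
#'
#' Maximizes the two-sequence likelihood over the evolutionary distance
#' `t` in `[0, t_max]` (expected substitutions per site).  Columns where
#' either sequence is missing (`-` or `X`) are ignored.
#'
#' @param seq_i,seq_j Equal-length (possibly gapped) residue strings.
#' @param model A [substitution_model()]; its `+I`/`+G` parameters, when set,
#'   enter the pairwise likelihood.
#' @param t_max Upper search bound.
#' @return The distance estimate (0 for identical sequences).
#' @export
ml_distance <- function(seq_i, seq_j, model, t_max = 10) {
  ci <- strsplit(toupper(seq_i), "")[[1]]
  cj <- strsplit(toupper(seq_j), "")[[1]]
  if (length(ci) != length(cj)) stop_ctx("sequences differ in length")
  ai <- match(ci, .aa_states)
  aj <- match(cj, .aa_states)
  ok <- !is.na(ai) & !is.na(aj)
  if (!any(ok)) stop_ctx("no shared non-missing columns; distance undefined")
  counts <- table(factor(ai[ok], levels = 1:20), factor(aj[ok], levels = 1:20))
  counts <- unclass(counts)
  if (sum(counts) == sum(diag(counts))) return(0)
  nll <- function(t) -pair_loglik(counts, model, t)
  opt <- optimize(nll, c(0, t_max), tol = 1e-8)
  # the interior optimum can beat the boundary only if it is better
  if (nll(0) <= opt$objective) 0 else opt$minimum
}

# Two-sequence log-likelihood from a 20x20 count table at distance t.
pair_loglik <- function(counts, model, t) {
  rates <- model_rates(model)
  p_inv <- if (is.na(model$p_inv)) 0 else model$p_inv
  P <- matrix(0, 20, 20)
  for (r in rates) P <- P + transition_prob(model, t * r) / length(rates)
  site_p <- model$pi * P              # pi_a * P_ab averaged over categories
  if (p_inv > 0) {
    site_p <- (1 - p_inv) * site_p + p_inv * diag(model$pi)
  }
  lp <- suppressWarnings(log(site_p))
  lp[counts == 0] <- 0
  if (any(is.infinite(lp) & counts > 0)) return(-Inf)
  sum(counts * lp)
}

#' Matrix of pairwise maximum-likelihood distances
#'
#' @param alignment An [aa_alignment()].
#' @inheritParams ml_distance
#' @return A symmetric distance matrix with zero diagonal.
#' @export
ml_distance_matrix <- function(alignment, model, t_max = 10) {
  alignment <- as_alignment(alignment)
  n <- length(alignment)
  ids <- names(alignment)
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      d <- ml_distance(unclass(alignment)[[i]], unclass(alignment)[[j]],
                       model, t_max)
      D[i, j] <- D[j, i] <- d
    }
  }
  D
}
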