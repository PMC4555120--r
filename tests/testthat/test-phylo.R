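test_that("neighbor joining solves the 3-taxon case in closed form", {
  D <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- nj_tree(D)
  # three-point formulas: x = (dab + dac - dbc)/2 etc.
  pend <- stats::setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(unname(pend[c("a", "b", "c")]), c(1, 2, 3))
  expect_error(nj_tree(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric|3 taxa")
  Dasym <- D
  Dasym[1, 2] <- 9
  expect_error(nj_tree(Dasym), "symmetric")
})

test_that("neighbor joining recovers topology from additive distances", {
  set.seed(30)
  for (i in 1:25) {
    n <- sample(5:12, 1)
    tr <- ape::rtree(n)
    tr$edge.length <- runif(nrow(tr$edge), 0.05, 0.6)
    D <- ape::cophenetic.phylo(tr)
    got <- nj_tree(D)
    expect_equal(vkorcp:::rf_distance(tr, got), 0)
  }
})

test_that("nj is deterministic on tied matrices", {
  D <- matrix(2, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(D) <- 0
  t1 <- nj_tree(D)
  t2 <- nj_tree(D)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
})

test_that("branch-length optimization recovers simulated lengths", {
  tr <- simulate_tree(8, seed = 11)
  mod <- substitution_model("WAG")
  aln <- evolve_alignment(tr, mod, 3000, rate_plan = 1, seed = 12)
  start <- tr
  start$edge.length <- rep(0.1, nrow(tr$edge))
  opt <- optimize_branch_lengths(start, aln, mod)
  # compare on the unrooted trees (the two root-adjacent branch lengths are
  # not separately identifiable)
  true_u <- ape::unroot(tr)
  opt_u <- ape::unroot(opt)
  key <- function(t) {
    s <- sapply(seq_len(nrow(t$edge)), function(e) {
      paste(sort(t$tip.label[vkorcp:::tips_under(t, t$edge[e, 2])]),
            collapse = "|")
    })
    stats::setNames(t$edge.length, s)
  }
  tk <- key(true_u)
  ok <- key(opt_u)
  shared <- intersect(names(tk), names(ok))
  ntip <- length(tr$tip.label)
  internal <- names(tk)[vapply(strsplit(names(tk), "\\|"), length, integer(1)) > 1]
  check <- intersect(shared, internal)
  check <- check[tk[check] >= 0.05]
  expect_true(all(abs(ok[check] - tk[check]) / tk[check] < 0.15))
})

test_that("branch optimization is a monotone ascent with a fixed point", {
  tr <- simulate_tree(6, seed = 13)
  mod <- substitution_model("WAG")
  aln <- evolve_alignment(tr, mod, 400, rate_plan = 1, seed = 14)
  o1 <- optimize_branch_lengths(tr, aln, mod, max_passes = 1L)
  o2 <- optimize_branch_lengths(o1, aln, mod, max_passes = 1L)
  o3 <- optimize_branch_lengths(o2, aln, mod, max_passes = 1L)
  lls <- c(attr(o1, "log_likelihood"), attr(o2, "log_likelihood"),
           attr(o3, "log_likelihood"))
  expect_true(all(diff(lls) >= 0))
  # fixed point: re-optimizing an optimum changes the likelihood < 1e-6
  o4 <- optimize_branch_lengths(o3, aln, mod, max_passes = 1L)
  expect_lt(attr(o4, "log_likelihood") - attr(o3, "log_likelihood"), 1e-4)
})

test_that("rate-parameter estimation recovers alpha and p_inv", {
  tr <- simulate_tree(24, seed = 15)
  gen <- substitution_model("WAG", alpha = 0.7)
  aln <- evolve_alignment(tr, gen, 400,
                          rate_plan = list(alpha = 0.7, n_invariant = 80),
                          seed = 16)
  est <- estimate_rate_params(aln, tr, substitution_model("WAG", alpha = 1,
                                                          p_inv = 0.1))
  expect_gt(est$alpha, 0.45)
  expect_lt(est$alpha, 1.05)
  expect_gt(est$p_inv, 0.1)
  expect_lt(est$p_inv, 0.3)
})

test_that("homogeneous data pushes alpha high and p_inv low", {
  tr <- simulate_tree(16, seed = 17)
  aln <- evolve_alignment(tr, substitution_model("WAG"), 500, rate_plan = 1,
                          seed = 18)
  est <- estimate_rate_params(aln, tr, substitution_model("WAG", alpha = 1,
                                                          p_inv = 0.1))
  expect_gte(est$alpha, 5)
  # strip constant columns: no invariant signal left
  m <- as.matrix(aln)
  varying <- m[, apply(m, 2, function(c) length(unique(c)) > 1), drop = FALSE]
  est2 <- estimate_rate_params(vkorcp:::alignment_from_matrix(varying), tr,
                               substitution_model("WAG", alpha = 1, p_inv = 0.1),
                               estimate_alpha = FALSE)
  expect_lte(est2$p_inv, 0.05)
  const <- vkorcp:::alignment_from_matrix(
    matrix("A", 6, 4, dimnames = list(tr$tip.label[1:6], NULL)))
  expect_warning(
    estimate_rate_params(const, prune_to_taxa(tr, tr$tip.label[1:6]),
                         substitution_model("WAG", alpha = 1, p_inv = 0.1)),
    "degenerate")
})

test_that("information criteria obey their closed forms", {
  ic <- information_criteria(-100, 3, 1000)
  expect_equal(ic$aic, 206)
  expect_equal(ic$aicc, 206 + 2 * 3 * 4 / (1000 - 4))
  expect_equal(ic$bic, 200 + 3 * log(1000))
  ic0 <- information_criteria(0, 0, 100)
  expect_equal(ic0$aic, 0)
  expect_equal(ic0$bic, 0)
  expect_true(is.na(information_criteria(-5, 10, 11)$aicc))
})

test_that("model selection ranks a gamma model above the homogeneous one", {
  tr <- simulate_tree(12, seed = 19)
  gen <- substitution_model("WAG", alpha = 0.5)
  aln <- evolve_alignment(tr, gen, 400, rate_plan = list(alpha = 0.5), seed = 20)
  start <- nj_tree(ml_distance_matrix(aln, substitution_model("WAG")))
  tab <- select_model(aln, start,
                      list(list(name = "WAG"), list(name = "WAG", gamma = TRUE)))
  expect_identical(tab$model[1], "WAG+G")
  expect_equal(tab$aic, -2 * tab$log_likelihood + 2 * tab$k)
  expect_equal(tab$bic, -2 * tab$log_likelihood + tab$k * log(tab$n))
})

test_that("bootstrap supports are reproducible and sane", {
  tr <- simulate_tree(8, seed = 31, clade_spec = list(sizes = c(a = 4, b = 4),
                                                      stem_length = 0.8))
  aln <- evolve_alignment(tr, substitution_model("WAG"), 150, rate_plan = 1,
                          seed = 32)
  one <- bootstrap_supports(aln, 1, seed = 5)
  expect_true(all(attr(one, "supports") %in% c(0, 100)))
  b1 <- bootstrap_supports(aln, 25, seed = 6)
  b2 <- bootstrap_supports(aln, 25, seed = 6)
  expect_identical(attr(b1, "supports"), attr(b2, "supports"))
  expect_error(bootstrap_supports(aln, 0, seed = 1), "n_reps")
})

test_that("outgroup rooting bisects the pendant branch and is reversible", {
  tr <- ape::read.tree(text = "(A:1,B:2,C:3);")
  rooted <- root_with_outgroup(tr, "A")
  expect_true(ape::is.rooted(rooted))
  lens <- rooted$edge.length[rooted$edge[, 1] == length(rooted$tip.label) + 1L]
  expect_equal(sort(lens)[1], 0.5)   # half of A's pendant branch
  set.seed(33)
  big <- ape::rtree(10)
  rr <- root_with_outgroup(big, big$tip.label[4])
  expect_equal(vkorcp:::rf_distance(ape::unroot(rr), ape::unroot(big)), 0)
  expect_error(root_with_outgroup(big, "nope"), "not in tree")
})

test_that("pruning preserves path lengths among kept taxa", {
  set.seed(34)
  tr <- ape::rtree(8)
  keep <- tr$tip.label[c(1, 3, 5, 8)]
  pruned <- prune_to_taxa(tr, keep)
  d_full <- ape::cophenetic.phylo(tr)[keep, keep]
  d_sub <- ape::cophenetic.phylo(pruned)[keep, keep]
  expect_equal(d_sub, d_full, tolerance = 1e-10)
  expect_identical(prune_to_taxa(tr, tr$tip.label), tr)
  expect_error(prune_to_taxa(tr, tr$tip.label[1]), "at least 2")
  expect_error(prune_to_taxa(tr, c("zz", tr$tip.label[1:2])), "not in tree")
})
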