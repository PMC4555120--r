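test_that("tree simulation is reproducible and respects clade specs", {
  t1 <- simulate_tree(5, seed = 80)
  t2 <- simulate_tree(5, seed = 80)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
  expect_error(simulate_tree(2, seed = 1), ">= 3")
  spec <- list(sizes = c(a = 4, b = 3, c = 5), stem_length = 0.5)
  tr <- simulate_tree(12, seed = 81, clade_spec = spec)
  labs <- attr(tr, "clade_labels")
  expect_equal(unname(table(labs)[c("a", "b", "c")]), c(4L, 3L, 5L),
               ignore_attr = TRUE)
  asg <- clade_partition(tr, list(a = "ca_t1", b = "cb_t1", c = "cc_t1"))
  expect_identical(unclass(asg)[names(labs)], labs)
  expect_error(simulate_tree(10, seed = 1, clade_spec = spec), "sum")
})

test_that("average total branch length grows with taxon count", {
  mean_total <- function(n) {
    mean(vapply(1:15, function(s) {
      sum(simulate_tree(n, seed = 900 + s)$edge.length)
    }, numeric(1)))
  }
  expect_lt(mean_total(5), mean_total(20))
  expect_lt(mean_total(20), mean_total(60))
})

test_that("two-taxon evolution matches the closed-form difference probability", {
  mod <- substitution_model("WAG")
  t <- 1.0
  tr <- ape::read.tree(text = sprintf("(A:%f,B:%f);", t / 2, t / 2))
  n <- 20000
  aln <- evolve_alignment(tr, mod, n, rate_plan = 1, seed = 82)
  m <- as.matrix(aln)
  p_obs <- mean(m[1, ] != m[2, ])
  # oracle: matrix exponential of the generator
  P <- as.matrix(Matrix::expm(mod$Q * t))
  p_true <- 1 - sum(mod$pi * diag(P))
  se <- sqrt(p_true * (1 - p_true) / n)
  expect_lt(abs(p_obs - p_true), 3 * se)
})

test_that("zero branch lengths copy the root everywhere", {
  tr <- ape::read.tree(text = "((A:0,B:0):0,(C:0,D:0):0);")
  aln <- evolve_alignment(tr, substitution_model("WAG"), 30, rate_plan = 1,
                          seed = 83)
  m <- as.matrix(aln)
  expect_true(all(apply(m, 2, function(c) length(unique(c)) == 1)))
})

test_that("planted invariant columns are constant in every row", {
  tr <- simulate_tree(25, seed = 84)
  aln <- evolve_alignment(tr, substitution_model("WAG"), 100,
                          rate_plan = list(alpha = 0.8, n_invariant = 10),
                          seed = 85)
  truth <- attr(aln, "truth")
  expect_length(truth$invariant_columns, 10)
  m <- as.matrix(aln)
  for (col in truth$invariant_columns) {
    expect_equal(length(unique(m[, col])), 1L)
  }
})

test_that("feature planting round-trips through the scanners", {
  tr <- simulate_tree(12, seed = 86, clade_spec = list(
    sizes = c("1" = 4, "2" = 4, "3" = 4), stem_length = 0.5))
  aln <- evolve_alignment(tr, substitution_model("WAG"), 60, rate_plan = 1,
                          seed = 87)
  truth <- attr(aln, "truth")
  truth$clade_labels <- attr(tr, "clade_labels")
  grp <- c("c1_t1", "c1_t2", "c2_t1")
  planted <- plant_features(aln, truth,
                            marker_spec = list(column = 40, state = "C",
                                               group = grp),
                            insertion_spec = list(clades = "3", length = 13,
                                                  after_column = 20),
                            seed = 88)
  mk <- single_site_markers(planted, grp)
  expect_equal(nrow(mk), 1)
  expect_equal(mk$column, 53)            # shifted by the 13-column insertion
  expect_identical(mk$state, "C")
  asg <- clade_partition(tr, list("1" = "c1_t1", "2" = "c2_t1", "3" = "c3_t1"))
  seg <- clade_absent_segments(planted, asg, "1", "3")
  expect_equal(seg$col_start, 21)
  expect_equal(seg$col_end, 33)
  # empty specs change nothing
  same <- plant_features(aln, truth)
  expect_identical(c(unclass(same)), c(unclass(aln)))
})

test_that("cp partner construction is exact at zero divergence", {
  set.seed(89)
  rec <- seq_records(stats::setNames(
    vapply(1:5, function(i) paste(sample(aa20, 80, TRUE), collapse = ""),
           character(1)), sprintf("s%d", 1:5)))
  cp0 <- make_cp_family(rec, truth = list(), boundary = 30, divergence = 0,
                        seed = 90)
  for (i in 1:5) {
    expect_identical(unclass(cp0)[[i]], half_swap(unclass(rec)[[i]], 30))
    expect_equal(find_cp_offset(unclass(rec)[[i]], unclass(cp0)[[i]])$offset, 30)
  }
  # involution: rotating back at the complementary boundary restores input
  back <- make_cp_family(cp0, truth = list(), boundary = 80 - 30,
                         divergence = 0, seed = 91)
  expect_identical(unname(c(unclass(back))), unname(c(unclass(rec))))
  expect_error(make_cp_family(rec, list(), boundary = 100, divergence = 0),
               "boundary")
})

test_that("toy bundles are deterministic with exact stored truth", {
  b1 <- make_toy_bundle(seed = 92)
  b2 <- make_toy_bundle(seed = 92)
  expect_identical(b1$atoms, b2$atoms)
  expect_identical(b1$truth$contacts, b2$truth$contacts)
  far <- make_toy_bundle(spacing = 40, seed = 93)
  expect_equal(nrow(far$truth$contacts), 0)
  expect_error(make_toy_bundle(spacing = 0), "positive")
})

test_that("study bundles audit cleanly, reproduce, and reject bad configs", {
  b1 <- generate_study_bundle(seed = 94)
  b2 <- generate_study_bundle(seed = 94)
  expect_identical(c(unclass(b1$alignment)), c(unclass(b2$alignment)))
  expect_identical(ape::write.tree(b1$tree), ape::write.tree(b2$tree))
  expect_identical(c(unclass(b1$partner)), c(unclass(b2$partner)))
  expect_error(generate_study_bundle(list(clade_sizes = integer(0)), seed = 1),
               "at least one clade")
  # written bundle round-trips through the readers
  d <- withr::local_tempdir()
  generate_study_bundle(seed = 94, dir = d)
  expect_identical(c(unclass(read_fasta(file.path(d, "msa.fasta"), aligned = TRUE))),
                   c(unclass(b1$alignment)))
  tr <- read_newick(file.path(d, "tree.nwk"))
  expect_equal(vkorcp:::rf_distance(tr, b1$tree), 0)
  atoms <- read_pdb_atoms(file.path(d, "bundle.pdb"))
  expect_equal(nrow(atoms), nrow(b1$bundle$atoms))
  truth <- jsonlite::read_json(file.path(d, "truth.json"))
  expect_equal(truth$marker$column, b1$truth$marker$column)
})
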