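test_that("clade partition recovers the planted partition from single seeds", {
  b <- generate_study_bundle(seed = 10)
  seeds <- lapply(split(names(b$clades), unname(b$clades)), `[`, 1L)
  asg <- clade_partition(b$tree, seeds)
  expect_setequal(names(asg), names(b$clades))
  expect_true(all(unclass(asg)[names(b$clades)] == b$clades))
  # multi-seed version agrees
  seeds2 <- lapply(split(names(b$clades), unname(b$clades)),
                   function(x) x[c(1, length(x))])
  asg2 <- clade_partition(b$tree, seeds2)
  expect_identical(unclass(asg2)[names(asg)], unclass(asg)[names(asg)])
})

test_that("partition rejects non-monophyletic seed groups", {
  b <- generate_study_bundle(seed = 10)
  expect_error(clade_partition(b$tree, list(a = c("c1_t1", "c2_t1"),
                                            b = "c2_t2")), "overlap")
  expect_error(clade_partition(b$tree, list(a = "zzz")), "not in tree")
  all_in_one <- clade_partition(b$tree, list(everything = b$tree$tip.label))
  expect_equal(length(all_in_one), length(b$tree$tip.label))
})

test_that("partition commutes with pruning to a clade", {
  b <- generate_study_bundle(seed = 12)
  keep <- names(b$clades)[b$clades %in% c("1", "2", "3")]
  pruned <- prune_to_taxa(b$tree, keep)
  seeds <- lapply(split(keep, b$clades[keep]), `[`, 1L)
  asg_pruned <- clade_partition(pruned, seeds)
  asg_full <- clade_partition(b$tree, lapply(
    split(names(b$clades), unname(b$clades)), `[`, 1L))
  restricted <- unclass(asg_full)[keep]
  expect_identical(unclass(asg_pruned)[keep], restricted)
})

test_that("fully conserved sites include exactly the planted invariants among high-occupancy constants", {
  b <- generate_study_bundle(seed = 13)
  fc <- fully_conserved_sites(b$alignment)
  expect_true(all(b$truth$invariant_columns %in% fc$column))
  # every reported column really is constant over non-missing states
  m <- as.matrix(b$alignment)
  for (j in fc$column) {
    obs <- m[, j]
    obs <- obs[!obs %in% c("X", "-")]
    expect_equal(length(unique(obs)), 1L)
  }
  # negative case
  varying <- aa_alignment(c(a = "AC", b = "CA", c = "GW"))
  expect_equal(nrow(fully_conserved_sites(varying)), 0)
  expect_error(fully_conserved_sites(aa_alignment(c(a = "AC"))), ">= 2 rows")
})

test_that("clade-absent segments recover the planted insertion exactly", {
  b <- generate_study_bundle(seed = 14)
  blk <- b$truth$insertion_blocks[[1]]
  seeds <- lapply(split(names(b$clades), unname(b$clades)), `[`, 1L)
  asg <- clade_partition(b$tree, seeds)
  seg <- clade_absent_segments(b$alignment, asg, "1", "4")
  expect_equal(nrow(seg), 1)
  expect_equal(seg$col_start, blk$col_start)
  expect_equal(seg$col_end, blk$col_end)
  expect_equal(seg$length, 13)
  # clades with the same gap structure have no differential absence
  seg2 <- clade_absent_segments(b$alignment, asg, "1", "5")
  expect_equal(nrow(seg2), 0)
  expect_error(clade_absent_segments(b$alignment, asg, "1", "99"), "unknown")
})

test_that("length-1 differential absences are excluded at min_len 2", {
  asg <- structure(c(a1 = "A", a2 = "A", b1 = "B", b2 = "B"),
                   labels = c("A", "B"), class = "clade_assignment")
  aln <- aa_alignment(c(a1 = "AC-E", a2 = "AC-E", b1 = "ACDE", b2 = "ACDE"))
  expect_equal(nrow(clade_absent_segments(aln, asg, "A", "B")), 0)
  expect_equal(nrow(clade_absent_segments(aln, asg, "A", "B", min_len = 1)), 1)
})

test_that("single-site marker scan finds hand-planted determinants", {
  aln <- aa_alignment(c(g1 = "AAACAAA", g2 = "AAACAAA",
                        o1 = "AAAIAAA", o2 = "AAALAAA"))
  mk <- single_site_markers(aln, c("g1", "g2"))
  expect_equal(mk$column, 4)
  expect_identical(mk$state, "C")
  expect_equal(mk$in_freq, 1)
  expect_equal(mk$out_freq, 0)
  # no signal when group and complement share states everywhere
  none <- single_site_markers(aa_alignment(c(a = "AC", b = "AC", c = "AC")), "a")
  expect_equal(nrow(none), 0)
  expect_error(single_site_markers(aln, character(0)), "empty group")
  expect_error(single_site_markers(aln, names(aln)), "complement")
})

test_that("marker columns with monomorphic sides are symmetric under group swap", {
  set.seed(50)
  grp <- sprintf("s%d", 1:3)
  comp <- sprintf("s%d", 4:6)
  mono <- function(m, rows, j) {
    obs <- m[rows, j]
    obs <- obs[!obs %in% c("X", "-")]
    length(obs) > 0 && length(unique(obs)) == 1
  }
  for (i in 1:10) {
    m <- matrix(sample(c(aa20, "-"), 6 * 30, TRUE, prob = c(rep(1, 20), 3)),
                6, 30, dimnames = list(sprintf("s%d", 1:6), NULL))
    aln <- vkorcp:::alignment_from_matrix(m)
    cols_a <- single_site_markers(aln, grp)$column
    cols_b <- single_site_markers(aln, comp)$column
    # a perfect determinant whose complement is also single-state must be
    # found from either side (and vice versa)
    both_mono <- Filter(function(j) mono(m, grp, j) && mono(m, comp, j), 1:30)
    expect_setequal(intersect(cols_a, both_mono), intersect(cols_b, both_mono))
  }
  # planted two-sided determinant is seen from both directions
  aln2 <- aa_alignment(c(s1 = "AC", s2 = "AC", s3 = "AW", s4 = "AW"))
  expect_equal(single_site_markers(aln2, c("s1", "s2"))$column, 2)
  expect_equal(single_site_markers(aln2, c("s3", "s4"))$column, 2)
})

test_that("planted markers are recovered with zero false positives", {
  for (s in 1:5) {
    b <- generate_study_bundle(seed = 100 + s)
    mk <- single_site_markers(b$alignment, b$truth$marker$group)
    expect_equal(nrow(mk), 1L)
    expect_equal(mk$column, b$truth$marker$column)
    expect_identical(mk$state, b$truth$marker$state)
  }
})

test_that("per-clade state spectrum reports the marker split", {
  b <- generate_study_bundle(seed = 15)
  seeds <- lapply(split(names(b$clades), unname(b$clades)), `[`, 1L)
  asg <- clade_partition(b$tree, seeds)
  mp <- map_reference_positions(b$alignment, names(b$alignment)[1])
  refpos <- attr(mp, "inverse")[b$truth$marker$column]
  spec <- clade_state_spectrum(b$alignment, asg, names(b$alignment)[1], refpos)
  expect_true(all(c("clade", "state", "count", "freq") %in% names(spec)))
  expect_true(b$truth$marker$state %in% spec$state)
})
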