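test_that("half swap exchanges halves and inverts with the complement", {
  expect_identical(half_swap("ABCDEF", 3), "DEFABC")
  set.seed(70)
  for (i in 1:10) {
    s <- paste(sample(aa20, sample(20:60, 1), TRUE), collapse = "")
    k <- sample(2:(nchar(s) - 2), 1)
    expect_identical(half_swap(half_swap(s, k), nchar(s) - k), s)
  }
  expect_error(half_swap("ABC", 0), "boundary")
  expect_error(half_swap("ABC", 3), "boundary")
})

test_that("modules follow helix labels and carry CXXC anchors", {
  ix <- index_fixture()
  vk_ab <- build_module(ix$vkorc1, ix$helices$VKORC1_HUMAN, "AB",
                        ref_id = "VKORC1")
  # CDAB threading: the AB module is the C-terminal half and contains CXXC
  expect_equal(vk_ab$origin$start, 107)
  expect_true(grepl("C..C", vk_ab$residues))
  expect_equal(vk_ab$anchor, 132 - 107 + 1)
  db_ab <- build_module(ix$dsbb, ix$helices$DSBB_ECOLI, "AB", ref_id = "DsbB")
  # ABCD threading: the AB module is the N-terminal half, CXXC at Cys41
  expect_equal(db_ab$origin$start, 15)
  expect_equal(db_ab$anchor, 41 - 15 + 1)
  vk_cd <- build_module(ix$vkorc1, ix$helices$VKORC1_HUMAN, "CD",
                        ref_id = "VKORC1")
  db_cd <- build_module(ix$dsbb, ix$helices$DSBB_ECOLI, "CD", ref_id = "DsbB")
  # the two modules never overlap and jointly cover all four helices
  for (pair in list(list(vk_ab, vk_cd), list(db_ab, db_cd))) {
    spans <- lapply(pair, function(m) m$origin$start:m$origin$end)
    expect_length(intersect(spans[[1]], spans[[2]]), 0)
    hl <- if (pair[[1]]$origin$start == 107) ix$helices$VKORC1_HUMAN else ix$helices$DSBB_ECOLI
    for (h in hl) expect_true(all(h[1]:h[2] %in% unlist(spans)))
  }
  # helix order violation
  bad <- list(A = c(50, 60), B = c(10, 20), C = c(1, 5), D = c(30, 40))
  expect_error(build_module("X", bad, "AB"), "precede")
})

test_that("anchored alignment brings the motifs into the same column", {
  m1 <- structure(list(module = "AB", residues = "AAAAAAAAACWWCAAAA",
                       origin = list(ref_id = "x", start = 1, end = 17),
                       anchor = 10L), class = "module_seq")
  m2 <- structure(list(module = "AB", residues = "GGGGGGGGGGGGGCWWCGG",
                       origin = list(ref_id = "y", start = 1, end = 19),
                       anchor = 14L), class = "module_seq")
  al <- anchor_align(m1, m2)
  expect_equal(al$offset, -4)
  hit <- al$columns[which(al$columns$pos1 == 10), ]
  expect_equal(hit$pos2, 14)
  expect_identical(hit$res1, "C")
  expect_identical(hit$res2, "C")
  # identical modules align at offset 0 with full identity
  self <- anchor_align(m1, m1)
  expect_equal(self$offset, 0)
  expect_true(all(self$columns$identity))
  m3 <- m1
  m3$anchor <- NA_integer_
  expect_error(anchor_align(m1, m3), "anchor")
})

test_that("best identity offset matches an exhaustive scan and tie rules", {
  set.seed(71)
  core <- paste(sample(aa20, 40, TRUE), collapse = "")
  mod1 <- structure(list(module = "CD", residues = core,
                         origin = list(ref_id = "a", start = 1, end = 40),
                         anchor = NA_integer_), class = "module_seq")
  padded <- paste0(paste(sample(aa20, 5, TRUE), collapse = ""), core,
                   paste(sample(aa20, 7, TRUE), collapse = ""))
  mod2 <- structure(list(module = "CD", residues = padded,
                         origin = list(ref_id = "b", start = 1, end = nchar(padded)),
                         anchor = NA_integer_), class = "module_seq")
  best <- best_identity_offset(mod1, mod2)
  expect_equal(best$offset, -5)
  expect_equal(sum(best$columns$identity), 40)
  # unrelated modules: reported max equals a brute-force recount scan
  for (i in 1:10) {
    r1 <- paste(sample(aa20, sample(25:40, 1), TRUE), collapse = "")
    r2 <- paste(sample(aa20, sample(25:40, 1), TRUE), collapse = "")
    u1 <- structure(list(module = "AB", residues = r1,
                         origin = list(ref_id = "u", start = 1, end = nchar(r1)),
                         anchor = NA_integer_), class = "module_seq")
    u2 <- structure(list(module = "AB", residues = r2,
                         origin = list(ref_id = "v", start = 1, end = nchar(r2)),
                         anchor = NA_integer_), class = "module_seq")
    got <- best_identity_offset(u1, u2)
    offsets <- (10 - nchar(r2)):(nchar(r1) - 10)
    brute <- max(vapply(offsets, function(o) recount_identities(u1, u2, o),
                        numeric(1)))
    expect_equal(sum(got$columns$identity), brute)
    expect_equal(recount_identities(u1, u2, got$offset),
                 sum(got$columns$identity))
  }
  # deterministic tie-break: smallest |offset|, negative before positive
  t1 <- structure(list(module = "AB", residues = "AAAAAAAAAAAA",
                       origin = list(ref_id = "t1", start = 1, end = 12),
                       anchor = NA_integer_), class = "module_seq")
  t2 <- t1
  t2$origin$ref_id <- "t2"
  tie <- best_identity_offset(t1, t2)
  expect_equal(tie$offset, 0)
  expect_error(best_identity_offset(t1, t2, min_overlap = 50), "overlap")
})

test_that("identity counting supports union and pairwise modes", {
  mk <- function(res, id) structure(
    list(module = "AB", residues = res,
         origin = list(ref_id = id, start = 1, end = nchar(res)),
         anchor = NA_integer_), class = "module_seq")
  target <- mk("ACDEFGHIKL", "fam2")
  idx1 <- mk("ACWWFGWWWW", "fam1a")   # matches at 1,2,5,6
  idx2 <- mk("WWDEWGWWKW", "fam1b")   # matches at 3,4,6,9
  a1 <- vkorcp:::module_alignment_at(idx1, target, 0)
  a2 <- vkorcp:::module_alignment_at(idx2, target, 0)
  expect_equal(sum(a1$columns$identity), 4)
  res <- count_identity_sites(list(a1, a2))
  expect_equal(res$count, 7)                     # union of {1,2,5,6} and {3,4,6,9}
  expect_equal(unname(res$pairwise), c(4, 4))
  pw <- count_identity_sites(list(a1, a2), mode = "pairwise")
  expect_equal(unname(pw$count), c(4, 4))
  expect_equal(pw$union, 7)
  # invariance under a common translation of both modules
  a1s <- vkorcp:::module_alignment_at(idx1, target, 0)
  expect_equal(sum(a1s$columns$identity),
               recount_identities(idx1, target, 0))
  # X never counts as identity
  xa <- vkorcp:::module_alignment_at(mk("XCDE", "x1"), mk("XCDE", "x2"), 0)
  expect_equal(sum(xa$columns$identity), 3)
})

test_that("conserved-feature matching returns planted coincidences only", {
  mk <- function(res, id, start) structure(
    list(module = "AB", residues = res,
         origin = list(ref_id = id, start = start, end = start + nchar(res) - 1),
         anchor = NA_integer_), class = "module_seq")
  m1 <- mk(paste(rep("A", 30), collapse = ""), "f1", 101)
  m2 <- mk(paste(rep("G", 30), collapse = ""), "f2", 11)
  al <- vkorcp:::module_alignment_at(m1, m2, 0)
  g1 <- stats::setNames(rep(9L, 30), 101:130)
  g2 <- stats::setNames(c(rep(9L, 20), rep(3L, 10)), 11:40)
  # features: coincide at module positions 5, 12; f1-only at 20; f2-only at 25
  f1 <- c(105, 112, 120)
  f2 <- c(15, 22, 35)
  got <- match_conserved_features(al, g1, g2, f1, f2)
  expect_equal(got$position, c(5, 12))
  expect_equal(got$ref1, c(105, 112))
  expect_equal(got$ref2, c(15, 22))
  # a low grade in either family suppresses the match
  g2b <- g2
  g2b["15"] <- 2L
  got2 <- match_conserved_features(al, g1, g2b, f1, f2)
  expect_equal(got2$position, 12)
  # empty feature sets give no matches
  expect_equal(nrow(match_conserved_features(al, g1, g2, integer(0), integer(0))), 0)
  # out-of-module features warn and are ignored
  expect_warning(match_conserved_features(al, g1, g2, c(105, 999), f2),
                 "outside module")
})

test_that("cp offset detection recovers exact rotations", {
  set.seed(72)
  s <- paste(sample(aa20, 150, TRUE), collapse = "")
  expect_equal(find_cp_offset(s, s)$offset, 0)
  for (k in c(2, 37, 75, 148)) {
    expect_equal(find_cp_offset(s, half_swap(s, k))$offset, k)
  }
  for (i in 1:40) {
    a <- paste(sample(aa20, sample(50:120, 1), TRUE), collapse = "")
    k <- sample(2:(nchar(a) - 2), 1)
    expect_equal(find_cp_offset(a, half_swap(a, k))$offset, k)
  }
  expect_error(find_cp_offset("ACDE", "ACDE"), ">= 20")
  expect_warning(find_cp_offset(strrep("A", 30), strrep("A", 30)),
                 "low-complexity")
})

test_that("cp offset detection tolerates moderate divergence", {
  ok <- 0L
  for (s in 1:20) {
    set.seed(400 + s)
    a <- paste(sample(aa20, 150, TRUE), collapse = "")
    rec <- make_cp_family(seq_records(c(x = a)), truth = list(), boundary = 37,
                          divergence = 0.15, seed = 500 + s)
    if (find_cp_offset(a, unclass(rec)[[1]])$offset == 37) ok <- ok + 1L
  }
  expect_gte(ok / 20, 0.9)
})
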