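test_that("fitch_length on textbook cases", {
  t4 <- parse_newick("((A,B),(C,D));")
  expect_equal(fitch_length(t4, char_matrix(c(A="0",B="0",C="1",D="1")), 1L), 1L)
  # 0,1,0,1: checked against exhaustive internal-assignment minimisation
  cm <- char_matrix(c(A="0",B="1",C="0",D="1"))
  expect_equal(brute_force_length(t4, cm, 1L), 2L)
  expect_equal(fitch_length(t4, cm, 1L), 2L)
  # all leaves missing: no forced change
  expect_equal(fitch_length(t4, char_matrix(c(A="?",B="?",C="?",D="-")), 1L), 0L)
  expect_error(fitch_length(t4, char_matrix(c(A="0",B="1",C="0")), 1L),
               "absent from character matrix")
})

test_that("fitch equals the brute-force oracle incl. polytomies/ambiguity", {
  for (s in 1:25) {
    n <- sample(4:6, 1L)
    pt <- random_tree(n, poly_prob = 0.3, seed = 2000L + s)
    cm <- random_matrix(leaf_labels(pt), 4L, n_states = sample(2:4, 1L),
                        p_missing = 0.2, p_poly = 0.2, seed = 3000L + s)
    for (j in seq_len(n_characters(cm))) {
      expect_equal(fitch_length(pt, cm, j), brute_force_length(pt, cm, j),
                   info = sprintf("seed %d char %d", s, j))
    }
  }
})

test_that("fitch agrees with phangorn on clean binary data", {
  skip_if_not_installed("phangorn")
  for (s in 1:5) {
    pt <- random_tree(8L, seed = 4000L + s)
    cm <- random_matrix(leaf_labels(pt), 25L, p_missing = 0, p_poly = 0,
                        seed = 5000L + s)
    chr <- matrix(as.character(log2(cm$bits)), nrow(cm$bits),
                  dimnames = list(cm$taxa, NULL))
    pd <- phangorn::phyDat(chr, type = "USER", levels = c("0", "1"))
    expect_equal(
      sum(fossilplace:::fitch_lengths(pt, cm)),
      phangorn::parsimony(as.phylo.phylotree(pt), pd, method = "fitch"))
  }
})

test_that("score_tree combines steps, minima and implied weights", {
  t4 <- parse_newick("((A,B),(C,D));")
  const <- char_matrix(c(A = "000", B = "000", C = "000", D = "000"))
  ts <- score_tree(t4, const)
  expect_equal(ts$total_steps, 0L)
  expect_equal(ts$iw_score, 0)
  # single character with one extra step at k = 12 fits 1/13
  cm <- char_matrix(c(A = "0", B = "1", C = "0", D = "1"))
  ts2 <- score_tree(t4, cm, weighting_scheme("implied", 12))
  expect_equal(ts2$per_character$es, 1L)
  expect_equal(ts2$iw_score, 1 / 13, tolerance = 1e-12)
  expect_true(all(ts2$per_character$s >= ts2$per_character$m))
  expect_lt(ts2$iw_score, n_characters(cm))
})

test_that("minimum steps are computed over tree taxa only", {
  # fossil carries a state unique in the matrix; when absent from the tree
  # it must not create phantom extra steps
  cm <- char_matrix(c(A = "0", B = "0", C = "1", D = "1", Fossil = "2"))
  t4 <- parse_newick("((A,B),(C,D));")
  ts <- score_tree(t4, cm)
  expect_equal(ts$per_character$m, 1L)
  expect_equal(ts$total_extra_steps, 0L)
})

test_that("scoring is invariant to rerooting", {
  for (s in 1:5) {
    pt <- random_tree(8L, poly_prob = 0.2, seed = 6000L + s)
    cm <- random_matrix(leaf_labels(pt), 12L, n_states = 3L,
                        p_missing = 0.2, p_poly = 0.1, seed = 7000L + s)
    ref <- score_tree(pt, cm)
    for (lab in sample(leaf_labels(pt), 3L)) {
      ts <- score_tree(reroot_tree(pt, lab), cm)
      expect_equal(ts$total_steps, ref$total_steps)
      expect_equal(ts$iw_score, ref$iw_score, tolerance = 1e-12)
    }
  }
})

test_that("implied-weight fit is concave-monotone in k", {
  t4 <- parse_newick("((A,B),(C,D));")
  cm <- char_matrix(c(A = "01", B = "10", C = "01", D = "10"))
  fits <- vapply(c(3, 12, 100, 1e6), function(k)
    score_tree(t4, cm, weighting_scheme("implied", k))$iw_score, numeric(1L))
  expect_true(all(diff(fits) < 0))
  expect_error(weighting_scheme("implied", 0), "positive")
})

test_that("step counts are additive over character partitions", {
  pt <- random_tree(7L, seed = 8000L)
  cm <- random_matrix(leaf_labels(pt), 20L, n_states = 3L, seed = 8001L)
  cm$partitions <- rep(c("a", "b"), each = 10L)
  full <- score_tree(pt, cm)
  pa <- score_tree(pt, cm, character_filter = "a")
  pb <- score_tree(pt, cm, character_filter = "b")
  expect_equal(pa$total_steps + pb$total_steps, full$total_steps)
})

test_that("characters without extra steps never change rankings", {
  pt <- parse_newick("((A,B),(C,D));")
  cm1 <- char_matrix(c(A = "0", B = "1", C = "0", D = "1", F = "0"))
  # add a constant character: es = 0 on every candidate tree
  cm2 <- char_matrix(c(A = "00", B = "10", C = "00", D = "10", F = "00"))
  p1 <- exhaustive_placement(pt, cm1, "F")
  p2 <- exhaustive_placement(pt, cm2, "F")
  expect_equal(order(p1$rows$ew_steps), order(p2$rows$ew_steps))
  expect_equal(p1$optima, p2$optima)
})

test_that("per-character score table writes a self-describing TSV", {
  pt <- parse_newick("((A,B),(C,D));")
  ts <- score_tree(pt, char_matrix(c(A = "01", B = "10", C = "01", D = "10")),
                   weighting_scheme("implied", 12))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_score_table(ts, f)
  lines <- readLines(f)
  expect_match(lines[1L], "k=12")
  got <- utils::read.delim(f, comment.char = "#")
  expect_equal(nrow(got), 2L)
  expect_named(got, c("char", "partition", "s", "m", "es", "fit"))
})
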