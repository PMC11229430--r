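test_that("exhaustive placement covers every branch with both objectives", {
  t3 <- parse_newick("(A,B,C);")
  cm <- char_matrix(c(A = "00", B = "01", C = "11", F = "01"))
  ps <- exhaustive_placement(t3, cm, "F")
  expect_equal(nrow(ps$rows), 3L)
  expect_equal(ps$rows$branch, enumerate_branches(t3))
  # backbone score is a lower bound for every insertion
  bb <- score_tree(t3, cm, character_filter = NULL)
  expect_true(all(ps$rows$ew_steps >= bb$total_steps))
  expect_error(exhaustive_placement(t3, cm, "A"), "already on the backbone")
  expect_error(exhaustive_placement(t3, cm, "Zz"), "unknown taxon")
})

test_that("a fossil coded identically to a leaf lands on that leaf's branch", {
  # the bundled toy fixture: Fossilis is a verbatim copy of Charlie
  cm <- read_char_matrix(extdata("toy_matrix.nex"))
  bb <- read_newick(extdata("toy_backbone.nwk"))
  ps <- exhaustive_placement(bb, cm, "Fossilis", weighting_scheme("implied", 12))
  expect_equal(nrow(ps$rows), 13L)  # 2*8 - 3
  expect_equal(ps$optima$equal, "Charlie")
  expect_equal(ps$optima$implied, "Charlie")
})

test_that("an uncoded fossil ties on every branch", {
  t4 <- parse_newick("((A,B),(C,D));")
  cm <- char_matrix(c(A = "010", B = "001", C = "110", D = "101", F = "???"))
  ps <- exhaustive_placement(t4, cm, "F")
  expect_equal(length(unique(ps$rows$ew_steps)), 1L)
  expect_setequal(ps$optima$equal, ps$rows$branch)
  expect_setequal(ps$optima$implied, ps$rows$branch)
})

test_that("ew_steps spread is bounded by the fossil's coded characters", {
  for (s in 1:5) {
    pt <- random_tree(7L, seed = 9000L + s)
    cm <- random_matrix(c(leaf_labels(pt), "F"), 15L, n_states = 2L,
                        p_missing = 0.3, p_poly = 0, seed = 9100L + s)
    ps <- exhaustive_placement(pt, cm, "F")
    expect_lte(max(ps$rows$ew_steps) - min(ps$rows$ew_steps),
               count_coded(cm, "F"))
  }
})

test_that("map_scores stars optima and round trips through Newick", {
  t4 <- parse_newick("((A,B),(C,D));")
  cm <- char_matrix(c(A = "010", B = "001", C = "110", D = "101", F = "???"))
  ps <- exhaustive_placement(t4, cm, "F")
  mt <- map_scores(ps, "equal")
  notes <- mt$note[!is.na(mt$note)]
  expect_length(notes, 5L)
  expect_true(all(grepl("\\*$", notes)))            # all branches tie
  expect_equal(length(unique(sub("\\*$", "", notes))), 1L)
  txt <- write_newick(mt)
  expect_identical(write_newick(read_annotated_newick(txt)), txt)
  # implied map carries 6-decimal fixed scores
  cmv <- char_matrix(c(A = "01", B = "10", C = "01", D = "10", F = "11"))
  mi <- map_scores(exhaustive_placement(t4, cmv, "F"), "implied")
  expect_true(all(grepl("^[0-9]+\\.[0-9]{6}\\*?$", mi$note[!is.na(mi$note)])))
})

test_that("at huge k the implied-weight stars equal the equal-weight stars", {
  for (s in 1:5) {
    pt <- random_tree(6L, seed = 9500L + s)
    cm <- random_matrix(c(leaf_labels(pt), "F"), 20L, n_states = 2L,
                        p_missing = 0.2, seed = 9600L + s)
    ps <- exhaustive_placement(pt, cm, "F", weighting_scheme("implied", 1e6))
    expect_setequal(ps$optima$implied, ps$optima$equal)
    expect_true(ranking_equivalent(ps$rows$ew_steps, ps$rows$iw_score))
  }
})

test_that("constrained_search with no floating taxa returns the backbone", {
  pt <- parse_newick("((A,B),(C,D));")
  cm <- char_matrix(c(A = "01", B = "10", C = "01", D = "10"))
  res <- constrained_search(pt, cm, character(0))
  expect_length(res$best_trees, 1L)
  expect_true(same_topology(res$best_trees[[1L]], pt))
  expect_equal(res$best_score$total_steps, score_tree(pt, cm)$total_steps)
})

test_that("single-fossil search equals exhaustive enumeration", {
  for (s in 1:6) {
    pt <- random_tree(7L, seed = 10000L + s)
    cfg <- sim_config(insert_leaf(pt, sample(enumerate_branches(pt), 1L), "F"),
                      40L, 2L, missing_fraction = 0.3,
                      designated_taxon = "F", seed = 10100L + s)
    ds <- simulate_dataset(cfg)
    for (mode in c("equal", "implied")) {
      ps <- exhaustive_placement(ds$backbone, ds$matrix, "F",
                                 weighting_scheme(mode, 12))
      res <- constrained_search(ds$backbone, ds$matrix, "F",
                                weighting_scheme(mode, 12),
                                n_restarts = 2L, seed = s)
      obj <- if (mode == "equal") res$best_score$total_steps else
        res$best_score$iw_score
      best <- if (mode == "equal") min(ps$rows$ew_steps) else
        min(ps$rows$iw_score)
      expect_equal(obj, best, tolerance = 1e-9)
      att <- vapply(res$best_trees, function(tr) prune_leaf(tr, "F")$branch,
                    character(1L))
      expect_setequal(att, ps$optima[[mode]])
    }
  }
})

test_that("search respects the backbone constraint and is deterministic", {
  pt <- random_tree(6L, seed = 11000L)
  cm <- random_matrix(c(leaf_labels(pt), "F1", "F2"), 30L, n_states = 2L,
                      p_missing = 0.2, seed = 11001L)
  expect_error(constrained_search(pt, cm, c("t1", "F1")), "overlap")
  r1 <- constrained_search(pt, cm, c("F1", "F2"), n_restarts = 3L, seed = 7L)
  r2 <- constrained_search(pt, cm, c("F1", "F2"), n_restarts = 3L, seed = 7L)
  expect_identical(r1$log, r2$log)
  for (tr in r1$best_trees) {
    expect_true(same_topology(tr, pt, restrict_to = leaf_labels(pt)))
  }
  # more restarts never worsen the best score
  r5 <- constrained_search(pt, cm, c("F1", "F2"), n_restarts = 6L, seed = 7L)
  expect_lte(r5$best_score$iw_score, r1$best_score$iw_score + 1e-9)
})

test_that("placement TSV is complete, flagged and byte-stable", {
  cm <- read_char_matrix(extdata("toy_matrix.nex"))
  bb <- read_newick(extdata("toy_backbone.nwk"))
  ps <- exhaustive_placement(bb, cm, "Fossilis")
  f1 <- withr::local_tempfile(fileext = ".tsv")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_placement_tsv(ps, f1)
  write_placement_tsv(ps, f2)
  expect_identical(readLines(f1), readLines(f2))
  got <- utils::read.delim(f1, comment.char = "#")
  expect_equal(nrow(got), 13L)
  expect_equal(sum(got$is_optimum_ew), 1L)
  expect_match(readLines(f1)[1L], "k=12")
})
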