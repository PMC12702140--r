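test_that("every 8-state letter maps to exactly one 3-state class", {
  expect_identical(ss3_class(c("H", "G", "I")), rep("helix", 3))
  expect_identical(ss3_class(c("E", "B")), rep("strand", 2))
  expect_identical(ss3_class(c("T", "S", "-")), rep("loop", 3))
  expect_error(ss3_class("Q"), "unknown")
})

test_that("propensities are hit fractions, invariant to hit order", {
  p <- propensities(c("H", "H", "E", "T"))
  expect_equal(p, c(h = 0.5, e = 0.25, l = 0.25))
  expect_equal(sum(p), 1)
  expect_equal(propensities(c("E", "E")), c(h = 0, e = 1, l = 0))
  set.seed(5)
  for (i in 1:20) {
    ss <- sample(c("H", "G", "I", "E", "B", "T", "S", "-"), 12, TRUE)
    expect_equal(propensities(sample(ss)), propensities(ss))
  }
  expect_error(propensities(character(0)), "default")
})

test_that("diversity index and entropy hit their closed-form limits", {
  expect_equal(diversity_index(c(1, 0, 0)), 1)
  expect_equal(diversity_index(rep(1 / 3, 3)), 3)
  expect_equal(diversity_index(c(0.5, 0.5, 0)), 2)
  expect_equal(shannon_entropy(c(1, 0, 0)), 0)
  expect_equal(shannon_entropy(rep(1 / 3, 3)), log(3))
  expect_equal(shannon_entropy(c(0.5, 0.5, 0)), log(2))
})

test_that("substitution score averages the matrix over unordered pairs", {
  M <- substitution_matrix()
  expect_equal(unname(diag(M)), c(0, 0, 0))
  expect_equal(M["helix", "strand"], 0.7)
  expect_equal(M["helix", "loop"], 0.3)
  expect_equal(M["strand", "loop"], 1)
  expect_identical(M, t(M))
  expect_equal(substitution_score(c("H", "E")), 0.7)
  expect_equal(substitution_score(c("H", "E", "T")), (0.7 + 0.3 + 1) / 3)
  expect_equal(substitution_score(c("H", "H", "H", "G", "I")), 0)
  expect_equal(substitution_score("H"), 0)  # single hit
})

test_that("uncertainty decays exponentially in the unique-cluster count", {
  expect_equal(uncertainty_score(0), 1)
  expect_equal(uncertainty_score(2), exp(-1))
  u <- uncertainty_score(0:20)
  expect_true(all(diff(u) < 0))
  expect_true(all(u > 0 & u <= 1))
  expect_error(uncertainty_score(-1))
})

test_that("no-hit windows carry exactly the default scores", {
  d <- default_scores()
  expect_identical(d, c(diversity = 1, entropy = 0, substitution = 0,
                        uncertainty = 1.0))
  # a query against an empty database is all defaults
  idx <- build_index(list())
  tr <- score_protein(idx, strrep("A", 20))
  expect_true(all(tr$diversity == 1))
  expect_true(all(tr$entropy == 0))
  expect_true(all(tr$substitution == 0))
  expect_true(all(tr$uncertainty == 1))
  expect_true(all(is.na(tr$h)))
  expect_equal(feature_vector(tr),
               c(max_rolled_diversity = 1, max_rolled_entropy = 0,
                 max_rolled_substitution = 0, mean_uncertainty = 1))
})

test_that("rolling average equals the naive per-window mean", {
  expect_equal(rolling_average(c(0, 0, 1, 1), 2), c(0, 0.5, 1))
  expect_equal(rolling_average(rep(4.2, 10), 3), rep(4.2, 8))
  naive <- function(x, w) {
    vapply(seq_len(length(x) - w + 1L), function(i) mean(x[i:(i + w - 1L)]), 0)
  }
  set.seed(9)
  for (i in 1:100) {
    x <- stats::rnorm(sample(5:40, 1))
    w <- sample.int(length(x), 1)
    expect_equal(rolling_average(x, w), naive(x, w))
  }
  # shorter than the window: one window over the whole track
  expect_equal(rolling_average(c(1, 2, 3), 8), 2)
})

test_that("rolling window width switches at the length threshold", {
  expect_identical(window_width(100), 8L)
  expect_identical(window_width(251), 8L)
  expect_identical(window_width(252), 18L)
  expect_identical(window_width(300), 18L)
  expect_identical(window_width(300, threshold = 500), 8L)
})

test_that("feature vector takes rolled maxima and the plain uncertainty mean", {
  tr <- make_track(60, plateau_start = 20, plateau_end = 40,
                   plateau_entropy = log(2))
  fv <- feature_vector(tr, ww = 8)
  # a plateau longer than the window realises its full value
  expect_equal(unname(fv["max_rolled_entropy"]), log(2))
  expect_equal(unname(fv["max_rolled_diversity"]), 2)
  expect_equal(unname(fv["mean_uncertainty"]), mean(tr$uncertainty))
  # palindromic track: reversal leaves the features unchanged
  rev_tr <- tr
  rev_tr$entropy <- rev(tr$entropy)
  rev_tr$diversity <- rev(tr$diversity)
  rev_tr$substitution <- rev(tr$substitution)
  rev_tr$uncertainty <- rev(tr$uncertainty)
  expect_equal(feature_vector(rev_tr, ww = 8), fv)
})

test_that("scores stay inside their ranges on random windows", {
  set.seed(31)
  for (i in 1:200) {
    ss <- sample(c("H", "G", "I", "E", "B", "T", "S", "-"),
                 sample(1:15, 1), TRUE)
    p <- propensities(ss)
    di <- diversity_index(p)
    en <- shannon_entropy(p)
    su <- substitution_score(ss)
    expect_true(di >= 1 - 1e-12 && di <= 3 + 1e-12)
    expect_true(en >= 0 && en <= log(3) + 1e-12)
    expect_true(su >= 0 && su <= 1)
  }
})

test_that("diversity index and entropy are rank-correlated over random triples", {
  set.seed(17)
  raw <- matrix(stats::rexp(3000), ncol = 3)
  triples <- raw / rowSums(raw)
  di <- apply(triples, 1, diversity_index)
  en <- apply(triples, 1, shannon_entropy)
  expect_gt(stats::cor(di, en, method = "spearman"), 0.9)
})

test_that("identical query and database give bit-identical tracks", {
  plan <- data.frame(segment = "WWHEAACDFKL", n_helix = 3, n_strand = 3,
                     n_loop = 1)
  db <- make_database(plan, n_decoys = 2, seed = 13)
  idx <- build_index(db$records)
  q <- make_query(db, "WWHEAACDFKL", seed = 14)
  t1 <- score_protein(idx, q$sequence, id = "Q")
  t2 <- score_protein(build_index(db$records), q$sequence, id = "Q")
  expect_identical(t1, t2)
})

test_that("score tracks survive the TSV round trip", {
  tr <- make_track(40, plateau_start = 15, plateau_end = 30)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_score_track(tr, path)
  back <- read_score_track(path, id = "T1", seq_length = 40)
  expect_equal(as.data.frame(back), as.data.frame(tr), tolerance = 1e-12)
})
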