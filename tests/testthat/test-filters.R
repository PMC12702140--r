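test_that("region calling recovers entropy plateaus", {
  # one rectangular plateau, longer than the rolling window
  tr <- make_track(80, plateau_start = 30, plateau_end = 55)
  reg <- call_region(tr, ww = 8)
  expect_lte(abs(reg$start - 30), 1)
  expect_lte(abs(reg$end - 55), 1)
  expect_equal(reg$peak_entropy, log(2))
  # two plateaus: the region contains the higher one
  tr2 <- make_track(120, plateau_start = 20, plateau_end = 40,
                    plateau_entropy = 0.4)
  hi <- tr2$position >= 80 & tr2$position <= 100
  tr2$entropy[hi] <- 1.0
  reg2 <- call_region(tr2, ww = 8)
  expect_true(reg2$start >= 70 && reg2$end <= 110)
  expect_true(reg2$start <= 81 && reg2$end >= 99)
  # constant positive track: everything ties the max, whole scored range
  tr3 <- make_track(40)
  tr3$entropy <- 0.5
  reg3 <- call_region(tr3, ww = 8)
  expect_identical(reg3$start, 3L)
  expect_identical(reg3$end, 36L)
  # all-default track has no signal to call
  expect_error(call_region(make_track(40), ww = 8), "no entropy signal")
})

test_that("disorder consensus overlap drops regions above 50%", {
  region <- list(start = 11, end = 20)
  # consensus 11..16 covers 6/10 residues -> dropped
  res <- disorder_overlap_filter(region,
                                 data.frame(start = 5, end = 16),
                                 data.frame(start = 11, end = 30))
  expect_equal(res$fraction, 0.6)
  expect_false(res$keep)
  # no disorder annotation at all -> kept
  res0 <- disorder_overlap_filter(region, NULL, NULL)
  expect_equal(res0$fraction, 0)
  expect_true(res0$keep)
  # fully disordered in both -> dropped
  res1 <- disorder_overlap_filter(region,
                                  data.frame(start = 1, end = 50),
                                  data.frame(start = 1, end = 50))
  expect_equal(res1$fraction, 1)
  expect_false(res1$keep)
  # exactly 50% is kept ("more than 50%" drops)
  res5 <- disorder_overlap_filter(region,
                                  data.frame(start = 11, end = 15),
                                  data.frame(start = 11, end = 15))
  expect_equal(res5$fraction, 0.5)
  expect_true(res5$keep)
  # consensus requires both predictors in intersection mode
  one_sided <- disorder_overlap_filter(region,
                                       data.frame(start = 11, end = 20),
                                       NULL)
  expect_equal(one_sided$fraction, 0)
  # union mode counts either predictor
  un <- disorder_overlap_filter(region, data.frame(start = 11, end = 20),
                                NULL, mode = "union")
  expect_equal(un$fraction, 1)
})

test_that("interval order never changes filter verdicts", {
  region <- list(start = 40, end = 80)
  a <- data.frame(start = c(10, 45, 70), end = c(20, 60, 90))
  b <- data.frame(start = c(50, 5), end = c(85, 15))
  base <- disorder_overlap_filter(region, a, b)
  set.seed(3)
  for (i in 1:10) {
    perm <- disorder_overlap_filter(region, a[sample(nrow(a)), ],
                                    b[sample(nrow(b)), ])
    expect_equal(perm, base)
  }
})

test_that("domain annotation splits positives into the three categories", {
  region <- list(start = 51, end = 100)
  expect_identical(domain_overlap_filter(region,
                                         data.frame(start = 40, end = 120)),
                   "domain_overlap")
  expect_identical(domain_overlap_filter(region,
                                         data.frame(start = 150, end = 200)),
                   "no_overlap")
  expect_identical(domain_overlap_filter(region, NULL),
                   "no_domain_annotation")
  # a single shared residue counts as overlap
  expect_identical(domain_overlap_filter(region,
                                         data.frame(start = 100, end = 130)),
                   "domain_overlap")
})

test_that("shortlisting requires sustained simultaneous helix and strand propensity", {
  co <- make_track(60, plateau_start = 20, plateau_end = 45,
                   h = 0.5, e = 0.4, id = "CO")
  alt <- make_track(60, plateau_start = 20, plateau_end = 45,
                    h = 0.5, e = 0.4, id = "ALT")
  # alternating pure helix / pure strand, never simultaneous
  on <- which(!is.na(alt$h))
  alt$h[on] <- rep(c(1, 0), length.out = length(on))
  alt$e[on] <- 1 - alt$h[on]
  preds <- data.frame(protein_id = c("CO", "ALT", "NOPE"),
                      label = c("fold_switching", "fold_switching",
                                "monomorphic"),
                      domain_status = c("domain_overlap", "domain_overlap",
                                        "domain_overlap"),
                      stringsAsFactors = FALSE)
  tracks <- list(CO = co, ALT = alt, NOPE = co)
  expect_identical(shortlist_candidates(tracks, preds), "CO")
  # the co-propensity run must overlap a domain
  preds$domain_status[1] <- "no_domain_annotation"
  expect_identical(shortlist_candidates(tracks, preds), character(0))
  expect_identical(shortlist_candidates(tracks, preds[0, ]), character(0))
})
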