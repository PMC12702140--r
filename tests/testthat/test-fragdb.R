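test_that("consistent records round-trip through the on-disk layout", {
  dir <- withr::local_tempdir()
  set.seed(11)
  recs <- random_records(3)
  # two identical sequences in one cluster
  recs[[2]] <- protein_record("R002", recs[[1]]$sequence, recs[[1]]$ss8,
                              recs[[1]]$confidence, cluster_id = "R001")
  db <- list(records = recs,
             cluster_table = data.frame(
               representative = c("R001", "R001", "R003"),
               member = c("R001", "R002", "R003")))
  paths <- write_database(db, dir)
  loaded <- load_records(paths[["fasta"]], paths[["ss"]],
                         paths[["confidence"]], paths[["clusters"]])
  expect_length(loaded, 3L)
  expect_equal(vapply(loaded, function(r) r$sequence, ""),
               vapply(recs, function(r) r$sequence, ""))
  expect_equal(vapply(loaded, function(r) r$ss8, ""),
               vapply(recs, function(r) r$ss8, ""))
  expect_equal(loaded[[1]]$confidence, recs[[1]]$confidence)
  # identical-sequence members share the representative's cluster id
  expect_identical(loaded[[1]]$cluster_id, "R001")
  expect_identical(loaded[[2]]$cluster_id, "R001")
})

test_that("invalid records are rejected record-wise, others still load", {
  dir <- withr::local_tempdir()
  writeLines(c(">good", "ACDEFGHIK", ">short_ss", "ACDEFGHIK",
               ">bad_letter", "ACDEFGHIK", ">no_conf", "ACDEFGHIK"),
             file.path(dir, "seqs.fasta"))
  writeLines(c("good\tHHHEEETTS", "short_ss\tHHH", "bad_letter\tHHHEEETTQ",
               "no_conf\tHHHEEETTS"),
             file.path(dir, "ss.tsv"))
  conf <- paste(rep(100, 9), collapse = ",")
  writeLines(c(paste0("good\t", conf), paste0("short_ss\t", conf),
               paste0("bad_letter\t", conf)),
             file.path(dir, "conf.tsv"))
  warns <- capture_warnings(
    loaded <- load_records(file.path(dir, "seqs.fasta"),
                           file.path(dir, "ss.tsv"),
                           file.path(dir, "conf.tsv"))
  )
  expect_length(loaded, 1L)
  expect_identical(loaded[[1]]$id, "good")
  expect_true(any(grepl("short_ss", warns)))
  expect_true(any(grepl("bad_letter", warns)))
  expect_true(any(grepl("no_conf", warns)))
})

test_that("occurrence count matches the closed form sum(max(0, L - k + 1))", {
  r10 <- protein_record("A", strrep("AC", 5), strrep("H", 10), rep(100, 10))
  expect_identical(n_occurrences(build_index(list(r10), k = 7)), 4L)
  r6 <- protein_record("B", "ACDEFG", "HHHHHH", rep(100, 6))
  expect_identical(n_occurrences(build_index(list(r6), k = 7)), 0L)
  set.seed(21)
  recs <- random_records(8, len_min = 4L, len_max = 30L)
  idx <- build_index(recs, k = 7)
  expect_identical(
    n_occurrences(idx),
    as.integer(sum(pmax(0L, vapply(recs, function(r)
      nchar(r$sequence), 0L) - 7L + 1L))))
  # empty record list gives a valid, empty index
  empty <- build_index(list())
  expect_identical(n_occurrences(empty), 0L)
  expect_identical(nrow(query_index(empty, "ACDEACD")), 0L)
})

test_that("index queries equal the naive substring scan on random databases", {
  set.seed(42)
  for (rep in 1:30) {
    recs <- random_records(5)
    idx <- build_index(recs, k = 7)
    # probe with fragments drawn from the records plus random ones
    probes <- character(0)
    for (r in recs[1:2]) {
      s <- sample.int(nchar(r$sequence) - 6L, 1L)
      probes <- c(probes, substring(r$sequence, s, s + 6L))
    }
    probes <- c(probes, paste(sample(c("A", "C", "D", "E"), 7, TRUE),
                              collapse = ""))
    for (frag in probes) {
      expect_identical(query_index(idx, frag), naive_scan(recs, frag))
    }
  }
})

test_that("hits report the annotations of the requested scoring residue", {
  rec <- protein_record("P1", "ACDEFGH", "HGIEBTS",
                        c(10, 20, 30, 40, 50, 60, 70))
  idx <- build_index(list(rec), k = 7)
  for (off in 1:7) {
    h <- query_index(idx, "ACDEFGH", scoring_offset = off)
    expect_identical(h$ss_state, substring("HGIEBTS", off, off))
    expect_identical(h$confidence, off * 10)
  }
  expect_error(query_index(idx, "ACDEFGH", scoring_offset = 8))
  expect_error(query_index(idx, "ACDEF"))
})

test_that("non-canonical query fragments return no hits with a warning", {
  rec <- protein_record("P1", "ACDXFGHIK", "HHHEEETTS", rep(100, 9))
  idx <- build_index(list(rec), k = 7)
  expect_warning(h <- query_index(idx, "ACDXFGH"), "non-canonical")
  expect_identical(nrow(h), 0L)
  # absent but canonical fragment: silently empty
  expect_silent(h2 <- query_index(idx, "AAAAAAA"))
  expect_identical(nrow(h2), 0L)
})

test_that("serialization round-trip preserves all query results", {
  set.seed(7)
  recs <- random_records(5)
  idx <- build_index(recs, k = 7)
  path <- withr::local_tempfile(fileext = ".rds")
  save_index(idx, path)
  idx2 <- load_index(path)
  kmers <- unique(unlist(lapply(recs, function(r) {
    s <- seq_len(nchar(r$sequence) - 6L)
    substring(r$sequence, s, s + 6L)
  })))
  for (km in kmers) {
    expect_identical(query_index(idx2, km), query_index(idx, km))
  }
})
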