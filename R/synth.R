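# Synthetic data with planted ground truth: fragment databases whose
# per-fragment secondary-structure mixtures are known by construction,
# matched query sequences, and labelled feature sets for the classifier.

seq_kmers <- function(sequence, k) {
  L <- nchar(sequence)
  if (L < k) return(character(0))
  starts <- seq_len(L - k + 1L)
  substring(sequence, starts, starts + k - 1L)
}

random_aa <- function(n) {
  paste(sample(AA_CANONICAL, n, replace = TRUE), collapse = "")
}

# filler that introduces no forbidden k-mer anywhere in left+core+right
filler_around <- function(core, left_len, right_len, forbidden, k,
                          max_tries = 100L) {
  core_kmers <- seq_kmers(core, k)
  for (try in seq_len(max_tries)) {
    left <- if (left_len > 0L) random_aa(left_len) else ""
    right <- if (right_len > 0L) random_aa(right_len) else ""
    full <- paste0(left, core, right)
    km <- seq_kmers(full, k)
    # windows fully inside the core are the planted ones; everything else
    # must avoid the forbidden set
    n_core <- length(core_kmers)
    inside <- if (n_core > 0L) left_len + seq_len(n_core) else integer(0)
    outside <- setdiff(seq_along(km), inside)
    if (!any(km[outside] %in% forbidden)) {
      return(list(left = left, right = right, sequence = full))
    }
  }
  stop("could not generate collision-free filler after ", max_tries,
       " attempts")
}

#' Generate a synthetic fragment database with planted SS mixtures
#'
#' Each plan row names a segment (7 or more residues) and how many
#' distinct-cluster records carry it with an all-helix, all-strand or
#' all-loop secondary structure. Every record embeds one copy of its
#' segment between random filler that provably contains no copy of any
#' planted k-mer, so after cluster deduplication the propensities of every
#' window inside a planted segment equal the planned class mixture exactly.
#' All records get their own 100%-identity cluster unless `redundancy`
#' adds identical-sequence copies (which share the original's cluster).
#'
#' @param plan data.frame with columns `segment`, `n_helix`, `n_strand`,
#'   `n_loop` (record counts per class).
#' @param n_decoys number of additional random records containing no
#'   planted k-mer.
#' @param flank filler length added on each side of a planted segment.
#' @param decoy_length length of decoy records.
#' @param redundancy extra identical copies per planted record (same
#'   cluster, distinct ids) to exercise deduplication.
#' @param confidence per-residue confidence assigned to all records
#'   (default 100).
#' @param source source tag for all records (default `"predicted"`).
#' @param seed RNG seed; the same seed reproduces the database exactly.
#' @param k fragment length used for collision checks (default 7).
#' @return list with `records` (list of [protein_record()]) and
#'   `cluster_table` (data.frame `representative`, `member`).
#' @export
make_database <- function(plan, n_decoys = 0L, flank = 15L,
                          decoy_length = 40L, redundancy = 0L,
                          confidence = 100, source = "predicted",
                          seed = 1L, k = 7L) {
  stopifnot(is.data.frame(plan),
            all(c("segment", "n_helix", "n_strand", "n_loop") %in% names(plan)))
  plan$segment <- toupper(plan$segment)
  if (any(nchar(plan$segment) < k)) {
    stop("planted segments must be at least k = ", k, " residues long")
  }
  per_seg_kmers <- lapply(plan$segment, seq_kmers, k = k)
  all_planted <- unlist(per_seg_kmers)
  if (anyDuplicated(all_planted)) {
    stop("infeasible plan: planted segments share k-mer(s): ",
         paste(unique(all_planted[duplicated(all_planted)]), collapse = ", "))
  }
  set.seed(seed)
  class_letters <- c(helix = "H", strand = "E", loop = "T")
  records <- list()
  cluster_rows <- list()
  for (i in seq_len(nrow(plan))) {
    seg <- plan$segment[i]
    classes <- rep(names(class_letters),
                   times = c(plan$n_helix[i], plan$n_strand[i], plan$n_loop[i]))
    for (j in seq_along(classes)) {
      id <- sprintf("SYN_%02d_%02d", i, j)
      f <- filler_around(seg, flank, flank, all_planted, k)
      ss <- paste0(strrep("-", nchar(f$left)),
                   strrep(class_letters[[classes[j]]], nchar(seg)),
                   strrep("-", nchar(f$right)))
      rec <- protein_record(id, f$sequence, ss,
                            rep(confidence, nchar(f$sequence)),
                            source = source, cluster_id = id)
      records[[length(records) + 1L]] <- rec
      cluster_rows[[length(cluster_rows) + 1L]] <- c(id, id)
      if (redundancy > 0L) {
        for (r in seq_len(redundancy)) {
          cid <- sprintf("%s_copy%d", id, r)
          records[[length(records) + 1L]] <-
            protein_record(cid, f$sequence, ss,
                           rep(confidence, nchar(f$sequence)),
                           source = source, cluster_id = id)
          cluster_rows[[length(cluster_rows) + 1L]] <- c(id, cid)
        }
      }
    }
  }
  for (d in seq_len(n_decoys)) {
    id <- sprintf("DECOY_%03d", d)
    f <- filler_around("", 0L, decoy_length, all_planted, k)
    ss_letters <- sample(SS8_ALPHABET, decoy_length, replace = TRUE)
    records[[length(records) + 1L]] <-
      protein_record(id, f$sequence, paste(ss_letters, collapse = ""),
                     rep(confidence, decoy_length),
                     source = source, cluster_id = id)
    cluster_rows[[length(cluster_rows) + 1L]] <- c(id, id)
  }
  cluster_table <- as.data.frame(do.call(rbind, cluster_rows),
                                 stringsAsFactors = FALSE)
  names(cluster_table) <- c("representative", "member")
  list(records = records, cluster_table = cluster_table)
}

#' Write a synthetic database in the on-disk layout [load_records()] reads
#'
#' Emits `sequences.fasta`, `ss.tsv`, `confidence.tsv` and `clusters.tsv`
#' under `dir`.
#'
#' @param db list with `records` and `cluster_table` (from
#'   [make_database()]).
#' @param dir output directory (created if needed).
#' @return named character vector of the four file paths, invisibly.
#' @export
write_database <- function(db, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  seqs <- Biostrings::AAStringSet(
    vapply(db$records, function(r) r$sequence, ""))
  names(seqs) <- vapply(db$records, function(r) r$id, "")
  paths <- c(fasta = file.path(dir, "sequences.fasta"),
             ss = file.path(dir, "ss.tsv"),
             confidence = file.path(dir, "confidence.tsv"),
             clusters = file.path(dir, "clusters.tsv"))
  Biostrings::writeXStringSet(seqs, paths[["fasta"]])
  ss_tab <- data.frame(id = names(seqs),
                       ss8 = vapply(db$records, function(r) r$ss8, ""))
  utils::write.table(ss_tab, paths[["ss"]], sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  conf_tab <- data.frame(
    id = names(seqs),
    values = vapply(db$records, function(r)
      paste(r$confidence, collapse = ","), ""))
  utils::write.table(conf_tab, paths[["confidence"]], sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  utils::write.table(db$cluster_table, paths[["clusters"]], sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(paths)
}

#' Build a query sequence containing a planted segment
#'
#' The segment is embedded between random filler chosen so that no query
#' window outside the segment matches any k-mer present in the database:
#' scored positions outside the segment receive exactly the default scores,
#' and the entropy plateau of the planted mixture is the only signal.
#'
#' @param db database from [make_database()] (used for the avoidance set).
#' @param segment planted segment present in `db`.
#' @param flank_left,flank_right filler lengths.
#' @param seed RNG seed.
#' @param k fragment length (default 7).
#' @return list with `sequence`, `segment_start`, `segment_end` (1-based
#'   residue coordinates of the segment within the query).
#' @export
make_query <- function(db, segment, flank_left = 20L, flank_right = 20L,
                       seed = 1L, k = 7L) {
  segment <- toupper(segment)
  db_kmers <- unique(unlist(lapply(db$records, function(r)
    seq_kmers(r$sequence, k))))
  set.seed(seed)
  f <- filler_around(segment, flank_left, flank_right, db_kmers, k)
  list(sequence = f$sequence,
       segment_start = flank_left + 1L,
       segment_end = flank_left + nchar(segment))
}

#' Generate a labelled synthetic feature set for the classifier
#'
#' Draws the four features from class-conditional uniform boxes. The
#' monomorphic box sits at low diversity/entropy/substitution and high
#' uncertainty; the fold-switching box is displaced by `separation` times a
#' fixed effect vector (higher diversity, entropy and substitution, lower
#' uncertainty). At `separation = 1` the boxes are disjoint in every
#' feature with a clear margin (the linearly separable limit); at
#' `separation = 0` the two classes are identically distributed (the
#' permutation null). Values are clipped to each score's valid range.
#'
#' @param n_fold_switching,n_monomorphic class sizes (defaults 189 and 198,
#'   the training-set split).
#' @param separation class-displacement multiplier (default 1).
#' @param seed RNG seed.
#' @return data.frame with `protein_id`, the four feature columns and
#'   `label`.
#' @export
make_classifier_set <- function(n_fold_switching = 189L,
                                n_monomorphic = 198L,
                                separation = 1, seed = 1L) {
  set.seed(seed)
  center_mono <- c(1.25, 0.25, 0.12, 0.75)
  halfwidth <- c(0.15, 0.15, 0.10, 0.20)
  delta <- c(0.90, 0.60, 0.45, -0.60)
  lo_bound <- c(1, 0, 0, 1e-6)
  hi_bound <- c(3, log(3), 1, 1)
  draw <- function(n, center) {
    m <- vapply(1:4, function(j)
      stats::runif(n, center[j] - halfwidth[j], center[j] + halfwidth[j]),
      numeric(n))
    m <- matrix(m, nrow = n)
    for (j in 1:4) m[, j] <- pmin(pmax(m[, j], lo_bound[j]), hi_bound[j])
    m
  }
  fs <- draw(n_fold_switching, center_mono + separation * delta)
  mono <- draw(n_monomorphic, center_mono)
  m <- rbind(fs, mono)
  colnames(m) <- FEATURE_NAMES
  data.frame(
    protein_id = sprintf("SYNFEAT_%03d", seq_len(nrow(m))),
    m,
    label = rep(c("fold_switching", "monomorphic"),
                c(n_fold_switching, n_monomorphic)),
    stringsAsFactors = FALSE
  )
}
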