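# Fragment database: structure-annotated protein records and the exact-match
# 7-mer index that answers fragment queries with residue-level annotations.

#' Canonical amino-acid alphabet (20 letters)
#' @keywords internal
AA_CANONICAL <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' DSSP 8-state secondary-structure alphabet
#' @keywords internal
SS8_ALPHABET <- c("H", "G", "I", "E", "B", "T", "S", "-")

#' Construct a structure-annotated protein record
#'
#' A record couples an amino-acid sequence with its per-residue 8-state
#' secondary structure (DSSP alphabet), per-residue confidence (pLDDT on
#' 0--100 for predicted structures; observed/unobserved encoded 100/0 for
#' experimental ones), a source tag and a 100%-identity cluster assignment.
#'
#' @param id unique record identifier.
#' @param sequence amino-acid string (20 canonical letters plus `X`;
#'   non-canonical letters are stored literally).
#' @param ss8 secondary-structure string over `H,G,I,E,B,T,S,-`, same length
#'   as `sequence`.
#' @param confidence numeric vector of per-residue confidence values in
#'   `[0, 100]`, one per residue.
#' @param source `"experimental"` or `"predicted"`.
#' @param cluster_id non-empty string naming the 100%-sequence-identity
#'   cluster the record belongs to.
#' @return an object of class `ProteinRecord`.
#' @export
protein_record <- function(id, sequence, ss8, confidence,
                           source = c("predicted", "experimental"),
                           cluster_id = id) {
  source <- match.arg(source)
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  sequence <- toupper(as.character(sequence))
  ss8 <- as.character(ss8)
  if (nchar(ss8) != nchar(sequence)) {
    stop("record '", id, "': ss8 length (", nchar(ss8),
         ") != sequence length (", nchar(sequence), ")")
  }
  ss_chars <- strsplit(ss8, "", fixed = TRUE)[[1L]]
  bad <- setdiff(unique(ss_chars), SS8_ALPHABET)
  if (length(bad) > 0L) {
    stop("record '", id, "': unknown secondary-structure letter(s): ",
         paste(bad, collapse = ", "))
  }
  confidence <- as.numeric(confidence)
  if (length(confidence) != nchar(sequence)) {
    stop("record '", id, "': confidence length (", length(confidence),
         ") != sequence length (", nchar(sequence), ")")
  }
  if (anyNA(confidence) || any(confidence < 0 | confidence > 100)) {
    stop("record '", id, "': confidence values must lie in [0, 100]")
  }
  if (!nzchar(cluster_id)) stop("record '", id, "': empty cluster_id")
  structure(
    list(id = id, sequence = sequence, ss8 = ss8,
         ss_chars = ss_chars, confidence = confidence,
         source = source, cluster_id = as.character(cluster_id)),
    class = "ProteinRecord"
  )
}

#' @export
print.ProteinRecord <- function(x, ...) {
  cat("<ProteinRecord> ", x$id, " (", nchar(x$sequence), " aa, ",
      x$source, ", cluster ", x$cluster_id, ")\n", sep = "")
  invisible(x)
}

#' Load protein records from the on-disk database layout
#'
#' The database is stored as four plain-text files: a FASTA of sequences, a
#' two-column TSV of 8-state secondary-structure strings (`id`, `ss8`), a
#' two-column TSV of comma-separated per-residue confidence values
#' (`id`, `values`), and an MMseqs2-style cluster TSV
#' (`representative_id`, `member_id`). Records lacking a secondary-structure
#' or confidence entry, or violating the length/alphabet invariants, are
#' skipped with a warning naming the record; the remaining records load.
#'
#' @param sequence_file FASTA file of amino-acid sequences.
#' @param ss_file TSV mapping id to 8-state SS string.
#' @param confidence_file TSV mapping id to comma-separated confidence values.
#' @param cluster_file MMseqs2-style cluster TSV (representative, member).
#'   Ids absent from the table become singleton clusters.
#' @param source source tag applied to all records, or a named character
#'   vector (id -> source) for mixed databases.
#' @return list of [protein_record()] objects.
#' @export
load_records <- function(sequence_file, ss_file, confidence_file,
                         cluster_file = NULL, source = "predicted") {
  for (f in c(sequence_file, ss_file, confidence_file)) {
    if (!file.exists(f)) stop("file not found: ", f)
  }
  seqs <- Biostrings::readAAStringSet(sequence_file)
  ids <- vapply(strsplit(names(seqs), "\\s+"), `[`, "", 1L)
  ss_tab <- utils::read.delim(ss_file, header = FALSE,
                              col.names = c("id", "ss8"),
                              colClasses = "character")
  conf_tab <- utils::read.delim(confidence_file, header = FALSE,
                                col.names = c("id", "values"),
                                colClasses = "character")
  ss_map <- stats::setNames(ss_tab$ss8, ss_tab$id)
  conf_map <- stats::setNames(conf_tab$values, conf_tab$id)
  clu_map <- character(0)
  if (!is.null(cluster_file) && file.exists(cluster_file) &&
      file.size(cluster_file) > 0) {
    clu_tab <- utils::read.delim(cluster_file, header = FALSE,
                                 col.names = c("representative", "member"),
                                 colClasses = "character")
    clu_map <- stats::setNames(clu_tab$representative, clu_tab$member)
  }
  records <- vector("list", length(ids))
  kept <- logical(length(ids))
  for (i in seq_along(ids)) {
    id <- ids[i]
    if (is.na(ss_map[id]) || is.na(conf_map[id])) {
      warning("record '", id, "' skipped: missing ",
              if (is.na(ss_map[id])) "secondary-structure" else "confidence",
              " annotation", call. = FALSE)
      next
    }
    src <- if (length(source) > 1L) unname(source[id]) else source
    rec <- tryCatch(
      protein_record(
        id = id,
        sequence = as.character(seqs[[i]]),
        ss8 = unname(ss_map[id]),
        confidence = as.numeric(strsplit(unname(conf_map[id]), ",")[[1L]]),
        source = src,
        cluster_id = if (!is.na(clu_map[id])) unname(clu_map[id]) else id
      ),
      error = function(e) {
        warning("record '", id, "' rejected: ", conditionMessage(e),
                call. = FALSE)
        NULL
      }
    )
    if (!is.null(rec)) {
      records[[i]] <- rec
      kept[i] <- TRUE
    }
  }
  records[kept]
}

#' Build an exact-match k-mer index over a set of protein records
#'
#' Every k-mer occurring in any record is stored with its (record, 0-based
#' offset) occurrences in a hashed lookup table, so fragment queries are O(1)
#' exact lookups. Non-canonical letters in database sequences are indexed
#' literally.
#'
#' @param records list of [protein_record()] objects.
#' @param k fragment length (default 7).
#' @return an object of class `FragmentIndex`.
#' @export
build_index <- function(records, k = 7L) {
  k <- as.integer(k)
  stopifnot(k >= 1L)
  entries <- new.env(hash = TRUE, parent = emptyenv())
  n_occ <- 0L
  if (length(records) > 0L) {
    kmer_list <- vector("list", length(records))
    rec_list <- vector("list", length(records))
    start_list <- vector("list", length(records))
    for (i in seq_along(records)) {
      len <- nchar(records[[i]]$sequence)
      n <- len - k + 1L
      if (n < 1L) next
      starts <- seq_len(n)
      kmer_list[[i]] <- substring(records[[i]]$sequence, starts,
                                  starts + k - 1L)
      rec_list[[i]] <- rep.int(i, n)
      start_list[[i]] <- starts - 1L   # 0-based
    }
    kmers <- unlist(kmer_list, use.names = FALSE)
    recs <- unlist(rec_list, use.names = FALSE)
    starts0 <- unlist(start_list, use.names = FALSE)
    n_occ <- length(kmers)
    if (n_occ > 0L) {
      grp <- split(seq_len(n_occ), kmers)
      for (km in names(grp)) {
        v <- grp[[km]]
        assign(km, cbind(rec = recs[v], start = starts0[v]), envir = entries)
      }
    }
  }
  structure(
    list(k = k, entries = entries, records = records,
         n_occurrences = n_occ),
    class = "FragmentIndex"
  )
}

#' @export
print.FragmentIndex <- function(x, ...) {
  cat("<FragmentIndex> k =", x$k, "|", length(x$records), "records |",
      x$n_occurrences, "occurrences |",
      length(ls(x$entries)), "distinct k-mers\n")
  invisible(x)
}

#' Number of stored k-mer occurrences
#'
#' Equals the closed form sum over records of `max(0, length - k + 1)`.
#' @param index a `FragmentIndex`.
#' @return integer occurrence count.
#' @export
n_occurrences <- function(index) index$n_occurrences

empty_hits <- function() {
  data.frame(protein_id = character(0), start = integer(0),
             ss_state = character(0), confidence = numeric(0),
             cluster_id = character(0), source = character(0),
             stringsAsFactors = FALSE)
}

#' Query the fragment index for all exact occurrences of a fragment
#'
#' Each hit reports the secondary-structure state and confidence of the
#' residue at `scoring_offset` (1-based position within the fragment) in the
#' matched window, along with the source record's cluster assignment. Hits
#' are returned sorted by (protein_id, start) so results are deterministic.
#' Fragments containing letters outside the 20-letter canonical amino-acid
#' alphabet return an empty result with a warning (exact-match semantics:
#' no substitution of ambiguity codes).
#'
#' @param index a `FragmentIndex`.
#' @param fragment string of length `index$k`.
#' @param scoring_offset 1-based residue within the fragment whose SS state
#'   and confidence are reported (default 3, the classification residue).
#' @return data.frame with columns `protein_id`, `start` (0-based),
#'   `ss_state`, `confidence`, `cluster_id`, `source`.
#' @export
query_index <- function(index, fragment, scoring_offset = 3L) {
  stopifnot(inherits(index, "FragmentIndex"))
  fragment <- toupper(as.character(fragment))
  if (nchar(fragment) != index$k) {
    stop("fragment length (", nchar(fragment), ") != index k (", index$k, ")")
  }
  scoring_offset <- as.integer(scoring_offset)
  if (scoring_offset < 1L || scoring_offset > index$k) {
    stop("scoring_offset must lie in 1..k")
  }
  letters_in <- strsplit(fragment, "", fixed = TRUE)[[1L]]
  if (!all(letters_in %in% AA_CANONICAL)) {
    warning("fragment '", fragment,
            "' contains non-canonical letters; returning no hits",
            call. = FALSE)
    return(empty_hits())
  }
  occ <- get0(fragment, envir = index$entries, inherits = FALSE)
  if (is.null(occ)) return(empty_hits())
  ri <- occ[, "rec"]
  st <- occ[, "start"]
  pos <- st + scoring_offset          # 1-based residue index in the record
  hits <- data.frame(
    protein_id = vapply(ri, function(i) index$records[[i]]$id, ""),
    start = as.integer(st),
    ss_state = vapply(seq_along(ri), function(j)
      index$records[[ri[j]]]$ss_chars[pos[j]], ""),
    confidence = vapply(seq_along(ri), function(j)
      index$records[[ri[j]]]$confidence[pos[j]], 0),
    cluster_id = vapply(ri, function(i) index$records[[i]]$cluster_id, ""),
    source = vapply(ri, function(i) index$records[[i]]$source, ""),
    stringsAsFactors = FALSE
  )
  hits <- hits[order(hits$protein_id, hits$start), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Save / load a fragment index
#'
#' Serializes the index (records plus lookup table) so a database built once
#' can be reused across runs. Reloading yields identical query results.
#'
#' @param index a `FragmentIndex`.
#' @param path file path for the serialized index.
#' @return `save_index` returns `path` invisibly; `load_index` returns the
#'   restored `FragmentIndex`.
#' @export
save_index <- function(index, path) {
  stopifnot(inherits(index, "FragmentIndex"))
  saveRDS(index, path)
  invisible(path)
}

#' @rdname save_index
#' @export
load_index <- function(path) {
  index <- readRDS(path)
  stopifnot(inherits(index, "FragmentIndex"))
  index
}
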