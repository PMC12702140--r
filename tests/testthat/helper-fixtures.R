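# Shared fixtures and independent oracles used across the test files.

# Brute-force substring scan: the independent oracle for index queries.
naive_scan <- function(records, fragment, scoring_offset = 3L) {
  k <- nchar(fragment)
  rows <- list()
  for (r in records) {
    L <- nchar(r$sequence)
    if (L < k) next
    for (s in seq_len(L - k + 1L)) {
      if (substring(r$sequence, s, s + k - 1L) == fragment) {
        pos <- s + scoring_offset - 1L
        rows[[length(rows) + 1L]] <- data.frame(
          protein_id = r$id, start = s - 1L,
          ss_state = substring(r$ss8, pos, pos),
          confidence = r$confidence[pos],
          cluster_id = r$cluster_id, source = r$source,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(protein_id = character(0), start = integer(0),
                      ss_state = character(0), confidence = numeric(0),
                      cluster_id = character(0), source = character(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$protein_id, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Random records over a reduced alphabet so short fragments recur often.
random_records <- function(n, len_min = 20L, len_max = 40L,
                           alphabet = c("A", "C", "D", "E"),
                           ss_alphabet = c("H", "G", "I", "E", "B",
                                           "T", "S", "-")) {
  lapply(seq_len(n), function(i) {
    L <- sample(len_min:len_max, 1L)
    protein_record(
      id = sprintf("R%03d", i),
      sequence = paste(sample(alphabet, L, TRUE), collapse = ""),
      ss8 = paste(sample(ss_alphabet, L, TRUE), collapse = ""),
      confidence = round(stats::runif(L, 0, 100), 1),
      source = sample(c("predicted", "experimental"), 1L),
      cluster_id = sprintf("C%03d", sample.int(max(1L, n %/% 2L), 1L))
    )
  })
}

# Hand-built hit table for the picking filters.
make_hits <- function(protein_id, start = seq_along(protein_id) - 1L,
                      ss_state = "H", confidence = 100,
                      cluster_id = protein_id, source = "predicted") {
  data.frame(protein_id = protein_id, start = as.integer(start),
             ss_state = ss_state, confidence = confidence,
             cluster_id = cluster_id, source = source,
             stringsAsFactors = FALSE)
}

# Synthetic residue score track: entropy plateau over positions
# [plateau_start, plateau_end], defaults elsewhere.
make_track <- function(seq_length, plateau_start = NULL, plateau_end = NULL,
                       plateau_entropy = log(2), h = 0.5, e = 0.5,
                       id = "T1") {
  positions <- 3:(seq_length - 4L)
  tr <- data.frame(
    position = positions,
    aa = "A",
    h = NA_real_, e = NA_real_, l = NA_real_,
    n_unique = 0L,
    diversity = 1, entropy = 0, substitution = 0, uncertainty = 1,
    stringsAsFactors = FALSE
  )
  if (!is.null(plateau_start)) {
    on <- tr$position >= plateau_start & tr$position <= plateau_end
    tr$entropy[on] <- plateau_entropy
    tr$h[on] <- h; tr$e[on] <- e; tr$l[on] <- 1 - h - e
    tr$diversity[on] <- 1 / (h^2 + e^2 + (1 - h - e)^2)
    tr$n_unique[on] <- 10L
    tr$uncertainty[on] <- exp(-5)
  }
  attr(tr, "id") <- id
  attr(tr, "seq_length") <- seq_length
  class(tr) <- c("ResidueScoreTrack", "data.frame")
  tr
}

# Textbook metric formulas, implemented independently of compute_metrics.
textbook_metrics <- function(tp, fn, tn, fp) {
  n <- tp + fn + tn + fp
  c(sensitivity = tp / (tp + fn),
    specificity = tn / (tn + fp),
    precision = tp / (tp + fp),
    accuracy = 100 * (tp + tn) / n,
    f1 = (2 * tp) / (2 * tp + fp + fn),
    mcc = (tp * tn - fp * fn) /
      sqrt((tp + fp)) / sqrt((tp + fn)) / sqrt((tn + fp)) / sqrt((tn + fn)))
}
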