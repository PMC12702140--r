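# Fragment picking: decompose a query into overlapping 7-mers, query the
# index and apply the hit filters (confidence/observation, cluster dedup).

#' Decompose a query sequence into overlapping k-mer windows
#'
#' The window starting at 1-based residue `s` is assigned to query position
#' `s + scoring_offset - 1`, the residue whose secondary structure the window
#' scores. With the defaults (k = 7, third residue) a length-L sequence
#' yields L - 6 windows at positions 3 .. L - 4.
#'
#' @param sequence amino-acid string.
#' @param k fragment length (default 7).
#' @param scoring_offset 1-based scoring residue within the fragment
#'   (default 3).
#' @return data.frame with columns `position` (1-based query residue the
#'   window scores) and `fragment`.
#' @export
window_fragments <- function(sequence, k = 7L, scoring_offset = 3L) {
  sequence <- toupper(as.character(sequence))
  L <- nchar(sequence)
  if (L < k) {
    stop("sequence of length ", L, " is shorter than the fragment size k = ",
         k, if (!is.null(names(sequence))) paste0(" (", names(sequence), ")"))
  }
  starts <- seq_len(L - k + 1L)
  data.frame(
    position = starts + as.integer(scoring_offset) - 1L,
    fragment = substring(sequence, starts, starts + k - 1L),
    stringsAsFactors = FALSE
  )
}

#' Filter fragment hits by confidence at the scoring residue
#'
#' Predicted-structure hits whose scoring-residue pLDDT is below `plddt_min`
#' are removed (the threshold itself passes: the rule is strictly below).
#' Experimental-structure hits whose scoring residue is unobserved
#' (confidence encoded 0) are removed. Hit order is preserved.
#'
#' @param hits data.frame of hits as returned by [query_index()].
#' @param plddt_min minimum pLDDT for predicted hits (default 70).
#' @return the retained hits, in the original order.
#' @export
filter_hits <- function(hits, plddt_min = 70) {
  if (nrow(hits) == 0L) return(hits)
  keep <- ifelse(hits$source == "predicted",
                 hits$confidence >= plddt_min,
                 hits$confidence > 0)
  out <- hits[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Collapse hits to one representative per 100%-identity cluster
#'
#' Redundant structure depositions of the same sequence would otherwise
#' dominate the propensity estimate, so hits are reduced to one per cluster.
#' The representative is the hit with the lexicographically smallest
#' (protein_id, start); output is sorted by (protein_id, start).
#'
#' @param hits data.frame of hits carrying a `cluster_id` column.
#' @return deduplicated hits, one row per cluster.
#' @export
dedup_by_cluster <- function(hits) {
  if (nrow(hits) == 0L) return(hits)
  ord <- order(hits$protein_id, hits$start)
  h <- hits[ord, , drop = FALSE]
  h <- h[!duplicated(h$cluster_id), , drop = FALSE]
  rownames(h) <- NULL
  h
}

#' Gather, filter and deduplicate the hits for one query window
#'
#' Applies the fixed filter order: confidence/observation filter first, then
#' cluster deduplication (the order matters because it decides which cluster
#' representative survives).
#'
#' @param index a `FragmentIndex`.
#' @param fragment the window's k-mer.
#' @param position 1-based query position the window scores.
#' @param scoring_offset scoring residue within the fragment.
#' @param plddt_min confidence threshold, see [filter_hits()].
#' @param exclude_self optional protein id whose own database hits are
#'   dropped before filtering (leakage-free validation of database members).
#' @return an object of class `WindowHits` with elements `position`,
#'   `fragment`, `hits_raw`, `hits_filtered`, `hits_unique`,
#'   `n_unique_clusters`.
#' @export
window_hits <- function(index, fragment, position, scoring_offset = 3L,
                        plddt_min = 70, exclude_self = NULL) {
  raw <- query_index(index, fragment, scoring_offset = scoring_offset)
  if (!is.null(exclude_self) && nrow(raw) > 0L) {
    raw <- raw[raw$protein_id != exclude_self, , drop = FALSE]
    rownames(raw) <- NULL
  }
  filtered <- filter_hits(raw, plddt_min = plddt_min)
  uniq <- dedup_by_cluster(filtered)
  structure(
    list(position = as.integer(position), fragment = fragment,
         hits_raw = raw, hits_filtered = filtered, hits_unique = uniq,
         n_unique_clusters = nrow(uniq)),
    class = "WindowHits"
  )
}
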