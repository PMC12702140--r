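# Post-prediction filters: fold-switch region calling, disorder-consensus
# overlap rejection, and domain-annotation classification.

as_iranges <- function(intervals) {
  if (is.null(intervals) || NROW(intervals) == 0L) {
    return(IRanges::IRanges())
  }
  if (is.data.frame(intervals)) {
    start <- intervals$start; end <- intervals$end
  } else {
    start <- intervals[["start"]]; end <- intervals[["end"]]
  }
  if (any(start < 1 | end < start)) {
    stop("intervals must satisfy 1 <= start <= end (1-based inclusive)")
  }
  IRanges::reduce(IRanges::IRanges(start = as.integer(start),
                                   end = as.integer(end)))
}

#' Call the fold-switch region of a scored protein
#'
#' The rolled entropy track is thresholded at a fraction of its maximum and
#' the maximal contiguous run of above-threshold windows containing the
#' arg-max window is reported, converted back to 1-based residue
#' coordinates (first residue of the first qualifying window to last
#' residue of the last). A track with no entropy signal (all positions at
#' the no-hit default) has no region and raises an error.
#'
#' @param track a `ResidueScoreTrack`.
#' @param ww rolling window width (defaults to [window_width()] of the
#'   track's sequence length).
#' @param threshold_frac fraction of the maximum rolled entropy defining the
#'   region (default 0.8).
#' @return a `FoldSwitchRegion`: list with `protein_id`, `start`, `end`
#'   (1-based inclusive residue indices) and `peak_entropy` (the maximum
#'   rolled entropy).
#' @export
call_region <- function(track, ww = NULL, threshold_frac = 0.8) {
  stopifnot(nrow(track) > 0L)
  if (is.null(ww)) {
    L <- attr(track, "seq_length")
    if (is.null(L)) L <- max(track$position) + 4L
    ww <- window_width(L)
  }
  rolled <- rolling_average(track$entropy, ww)
  eff_ww <- min(as.integer(ww), nrow(track))  # short-track fallback width
  if (max(rolled) <= 0) {
    stop("track has no entropy signal (all defaults); no region to call")
  }
  thr <- threshold_frac * max(rolled)
  above <- rolled >= thr
  peak <- which.max(rolled)
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  run_idx <- which(runs$values & starts <= peak & ends >= peak)
  first_win <- starts[run_idx]
  last_win <- ends[run_idx]
  structure(
    list(protein_id = attr(track, "id"),
         start = track$position[first_win],
         end = track$position[min(last_win + eff_ww - 1L, nrow(track))],
         peak_entropy = max(rolled)),
    class = "FoldSwitchRegion"
  )
}

#' @export
print.FoldSwitchRegion <- function(x, ...) {
  cat("<FoldSwitchRegion>", if (!is.null(x$protein_id)) x$protein_id else "",
      sprintf("%d-%d (peak rolled entropy %.3f)\n",
              x$start, x$end, x$peak_entropy))
  invisible(x)
}

#' Disorder-consensus overlap filter
#'
#' The consensus disordered set is the residue-wise agreement of two
#' disorder predictors (intersection by default; union available). The
#' called fold-switch region is rejected when more than 50% of its residues
#' fall in the consensus — exactly 50% is kept.
#'
#' @param region a `FoldSwitchRegion` (or list with `start`, `end`).
#' @param disordered_a,disordered_b data.frames of 1-based inclusive
#'   intervals (`start`, `end`) from the two predictors; `NULL` or empty
#'   means no disorder annotation.
#' @param mode `"intersection"` (consensus = disordered in both) or
#'   `"union"`.
#' @param max_fraction rejection threshold (default 0.5; the rule is
#'   strictly greater-than).
#' @return list with `keep` (logical) and `fraction` (overlap fraction of
#'   the region, in `[0, 1]`).
#' @export
disorder_overlap_filter <- function(region, disordered_a, disordered_b,
                                    mode = c("intersection", "union"),
                                    max_fraction = 0.5) {
  mode <- match.arg(mode)
  reg <- IRanges::IRanges(start = region$start, end = region$end)
  a <- as_iranges(disordered_a)
  b <- as_iranges(disordered_b)
  consensus <- if (mode == "intersection") IRanges::intersect(a, b)
               else IRanges::reduce(c(a, b))
  ov <- IRanges::intersect(reg, consensus)
  fraction <- sum(IRanges::width(ov)) / sum(IRanges::width(reg))
  list(keep = fraction <= max_fraction, fraction = fraction)
}

#' Domain-annotation overlap classification
#'
#' Positive predictions whose fold-switch region intersects an annotated
#' domain are retained (`domain_overlap`); proteins with domain annotation
#' that never touches the region are excluded from the final set
#' (`no_overlap`); proteins with no domain annotation at all are retained
#' in their own category (`no_domain_annotation`). Any nonempty
#' intersection counts as overlap.
#'
#' @param region a `FoldSwitchRegion` (or list with `start`, `end`).
#' @param domains data.frame of 1-based inclusive domain intervals, or
#'   `NULL`/empty.
#' @return one of `"domain_overlap"`, `"no_domain_annotation"`,
#'   `"no_overlap"`.
#' @export
domain_overlap_filter <- function(region, domains) {
  dom <- as_iranges(domains)
  if (length(dom) == 0L) return("no_domain_annotation")
  reg <- IRanges::IRanges(start = region$start, end = region$end)
  ov <- IRanges::intersect(reg, dom)
  if (sum(IRanges::width(ov)) > 0L) "domain_overlap" else "no_overlap"
}

#' Shortlist candidate fold-switching proteins by helix/strand co-propensity
#'
#' Among positive, domain-overlapping predictions, proteins possessing a
#' contiguous run of scored positions where the helix and strand
#' propensities are simultaneously at least `min_coprop` — i.e. the
#' fragment evidence supports both conformations along a stretch — are
#' shortlisted as the strongest experimental candidates.
#'
#' @param tracks named list of `ResidueScoreTrack`s (names are protein ids).
#' @param predictions data.frame with columns `protein_id`, `label` and
#'   `domain_status` (as produced by [run_predict()]).
#' @param min_coprop minimum simultaneous helix and strand propensity
#'   (default 0.05).
#' @param min_run minimum run length in positions; defaults to each
#'   protein's [window_width()].
#' @return character vector of shortlisted protein ids.
#' @export
shortlist_candidates <- function(tracks, predictions, min_coprop = 0.05,
                                 min_run = NULL) {
  if (NROW(predictions) == 0L) return(character(0))
  pos <- predictions[predictions$label == "fold_switching" &
                     predictions$domain_status == "domain_overlap", ,
                     drop = FALSE]
  out <- character(0)
  for (id in pos$protein_id) {
    tr <- tracks[[id]]
    if (is.null(tr)) next
    need <- min_run
    if (is.null(need)) {
      L <- attr(tr, "seq_length")
      if (is.null(L)) L <- max(tr$position) + 4L
      need <- window_width(L)
    }
    co <- !is.na(tr$h) & !is.na(tr$e) &
      tr$h >= min_coprop & tr$e >= min_coprop
    runs <- rle(co)
    if (any(runs$values & runs$lengths >= need)) out <- c(out, id)
  }
  out
}
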