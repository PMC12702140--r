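# Scoring: 3-state propensities per window, the four per-position scores
# (diversity index, Shannon entropy, substitution, uncertainty), the rolling
# average, and the reduction of a protein to the 4-D classifier features.

#' Map DSSP 8-state letters to the 3-state classes
#'
#' H, G, I (helices) map to `helix`; E, B (extended/bridge) to `strand`;
#' T, S and `-` (turn, bend, coil) to `loop`.
#'
#' @param ss8 character vector of 8-state letters.
#' @return character vector over `helix`, `strand`, `loop`.
#' @export
ss3_class <- function(ss8) {
  map <- c(H = "helix", G = "helix", I = "helix",
           E = "strand", B = "strand",
           T = "loop", S = "loop", "-" = "loop")
  out <- map[as.character(ss8)]
  if (anyNA(out)) {
    stop("unknown secondary-structure letter(s): ",
         paste(unique(ss8[is.na(out)]), collapse = ", "))
  }
  unname(out)
}

#' The 3x3 secondary-structure substitution matrix
#'
#' Dissimilarity of 3-state classes: diagonal 0, helix--strand 0.7,
#' helix--loop 0.3, strand--loop 1. Symmetric with entries in `[0, 1]`.
#'
#' @return named 3x3 numeric matrix over `helix`, `strand`, `loop`.
#' @export
substitution_matrix <- function() {
  m <- matrix(c(0,   0.7, 0.3,
                0.7, 0,   1,
                0.3, 1,   0),
              nrow = 3, byrow = TRUE,
              dimnames = list(c("helix", "strand", "loop"),
                              c("helix", "strand", "loop")))
  m
}

#' 3-state propensities of a window's unique hits
#'
#' Fractions of unique-cluster hits whose scoring-residue secondary
#' structure falls in the helix, strand and loop classes; they sum to 1.
#'
#' @param ss_states character vector of 8-state letters (one per unique hit).
#' @return named numeric vector `c(h=, e=, l=)`.
#' @export
propensities <- function(ss_states) {
  n <- length(ss_states)
  if (n == 0L) stop("propensities are undefined for zero hits; use default_scores()")
  cls <- ss3_class(ss_states)
  c(h = sum(cls == "helix") / n,
    e = sum(cls == "strand") / n,
    l = sum(cls == "loop") / n)
}

#' Diversity index of a propensity triple
#'
#' `DI = 1 / (h^2 + e^2 + l^2)`, the inverse Simpson concentration: 1 for a
#' pure state, 3 at the uniform triple.
#'
#' @param p propensity triple (h, e, l) summing to 1.
#' @return numeric in `[1, 3]`.
#' @export
diversity_index <- function(p) {
  1 / sum(p^2)
}

#' Shannon entropy of a propensity triple
#'
#' Natural-log entropy `-h log h - e log e - l log l` with the
#' `0 * log 0 = 0` convention; ranges from 0 (pure) to `log(3)` (uniform).
#'
#' @param p propensity triple (h, e, l) summing to 1.
#' @return numeric in `[0, log(3)]`.
#' @export
shannon_entropy <- function(p) {
  nz <- p[p > 0]
  -sum(nz * log(nz))
}

#' Mean pairwise substitution score of a window's unique hits
#'
#' All unordered pairs of unique hits are scored with the 3-state
#' [substitution_matrix()] and averaged. Windows with a single hit score 0.
#'
#' @param ss_states character vector of 8-state letters (one per unique hit).
#' @param M substitution matrix (default [substitution_matrix()]).
#' @return numeric in `[0, 1]`.
#' @export
substitution_score <- function(ss_states, M = substitution_matrix()) {
  n <- length(ss_states)
  if (n < 2L) return(0)
  cls <- ss3_class(ss_states)
  mm <- M[cls, cls, drop = FALSE]
  sum(mm[upper.tri(mm)]) / (n * (n - 1) / 2)
}

#' Uncertainty score from the unique-cluster hit count
#'
#' `exp(-0.5 * n)`, a Hoeffding-motivated confidence penalty: 1 with no
#' data, decaying as unique-cluster evidence accumulates.
#'
#' @param n_unique_clusters non-negative hit count.
#' @return numeric in `(0, 1]`.
#' @export
uncertainty_score <- function(n_unique_clusters) {
  if (any(n_unique_clusters < 0)) stop("hit count must be non-negative")
  exp(-0.5 * n_unique_clusters)
}

#' Default scores for windows with no database hits
#'
#' Diversity 1, entropy 0, substitution 0, uncertainty 1.0 — the minimum of
#' each diversity metric and maximal uncertainty, so fragments with no data
#' cannot create false positives.
#'
#' @return named numeric vector of the four defaults.
#' @export
default_scores <- function() {
  c(diversity = 1, entropy = 0, substitution = 0, uncertainty = 1.0)
}

#' Rolling (moving) average of a score track
#'
#' `output[i] = mean(track[i .. i + width - 1])`; the output has
#' `length(track) - width + 1` values. Tracks shorter than `width` fall back
#' to a single window spanning the whole track (short designed proteins are
#' scored without error).
#'
#' @param track numeric vector.
#' @param width window width (>= 1).
#' @return numeric vector of windowed means.
#' @export
rolling_average <- function(track, width) {
  width <- as.integer(width)
  stopifnot(width >= 1L, length(track) >= 1L)
  if (length(track) < width) return(mean(track))
  if (width == 1L) return(as.numeric(track))
  as.numeric(zoo::rollmean(track, width, align = "left"))
}

#' Rolling-window width as a step function of protein length
#'
#' Width 8 for sequences up to `threshold` residues, 18 above it. The
#' default threshold is 251.
#'
#' @param sequence_length protein length (>= 7).
#' @param short_width,long_width widths below/above the threshold.
#' @param threshold length cut-over (default 251).
#' @return integer window width.
#' @export
window_width <- function(sequence_length, short_width = 8L, long_width = 18L,
                         threshold = 251L) {
  stopifnot(sequence_length >= 7L)
  if (sequence_length <= threshold) as.integer(short_width)
  else as.integer(long_width)
}

#' Score every residue of a query protein against the fragment database
#'
#' Slides a k-mer window over the query, collects filtered unique-cluster
#' hits per window ([window_hits()]) and computes the per-position scores.
#' Positions with no surviving hits carry exactly the [default_scores()]
#' and `NA` propensities. Scored positions run from `scoring_offset` to
#' `L - k + scoring_offset` (L - 6 positions with the defaults).
#'
#' @param index a `FragmentIndex`.
#' @param sequence query amino-acid string.
#' @param id optional query identifier (stored as an attribute).
#' @param scoring_offset scoring residue within each fragment (default 3).
#' @param plddt_min confidence threshold for hits (default 70).
#' @param exclude_self if `TRUE` and `id` is given, the query's own database
#'   entry is excluded from its hits.
#' @return a `ResidueScoreTrack` data.frame with one row per scored position
#'   and columns `position`, `aa`, `h`, `e`, `l`, `n_unique`, `diversity`,
#'   `entropy`, `substitution`, `uncertainty`; attributes `id` and
#'   `seq_length`.
#' @export
score_protein <- function(index, sequence, id = NULL, scoring_offset = 3L,
                          plddt_min = 70, exclude_self = FALSE) {
  sequence <- toupper(as.character(sequence))
  k <- index$k
  wins <- window_fragments(sequence, k = k, scoring_offset = scoring_offset)
  n <- nrow(wins)
  excl <- if (isTRUE(exclude_self) && !is.null(id)) id else NULL
  defaults <- default_scores()
  out <- data.frame(
    position = wins$position,
    aa = substring(sequence, wins$position, wins$position),
    h = NA_real_, e = NA_real_, l = NA_real_,
    n_unique = 0L,
    diversity = defaults[["diversity"]],
    entropy = defaults[["entropy"]],
    substitution = defaults[["substitution"]],
    uncertainty = defaults[["uncertainty"]],
    stringsAsFactors = FALSE
  )
  for (i in seq_len(n)) {
    wh <- suppressWarnings(
      window_hits(index, wins$fragment[i], wins$position[i],
                  scoring_offset = scoring_offset, plddt_min = plddt_min,
                  exclude_self = excl)
    )
    m <- wh$n_unique_clusters
    out$n_unique[i] <- m
    out$uncertainty[i] <- uncertainty_score(m)
    if (m > 0L) {
      ss <- wh$hits_unique$ss_state
      p <- propensities(ss)
      out$h[i] <- p[["h"]]; out$e[i] <- p[["e"]]; out$l[i] <- p[["l"]]
      out$diversity[i] <- diversity_index(p)
      out$entropy[i] <- shannon_entropy(p)
      out$substitution[i] <- substitution_score(ss)
    }
  }
  attr(out, "id") <- id
  attr(out, "seq_length") <- nchar(sequence)
  attr(out, "k") <- k
  attr(out, "scoring_offset") <- as.integer(scoring_offset)
  class(out) <- c("ResidueScoreTrack", "data.frame")
  out
}

#' Reduce a residue score track to the 4-D classifier feature vector
#'
#' The first three features are the maxima of the rolling averages (width
#' `ww`) of the diversity, entropy and substitution tracks; the fourth is
#' the plain mean of the per-position uncertainty (no rolling).
#'
#' @param track a `ResidueScoreTrack` (or data.frame with the score columns).
#' @param ww rolling window width; defaults to [window_width()] of the
#'   track's sequence length.
#' @return named numeric vector `max_rolled_diversity`,
#'   `max_rolled_entropy`, `max_rolled_substitution`, `mean_uncertainty`.
#' @export
feature_vector <- function(track, ww = NULL) {
  stopifnot(nrow(track) > 0L)
  if (is.null(ww)) {
    L <- attr(track, "seq_length")
    if (is.null(L)) L <- max(track$position) + 4L
    ww <- window_width(L)
  }
  c(max_rolled_diversity = max(rolling_average(track$diversity, ww)),
    max_rolled_entropy = max(rolling_average(track$entropy, ww)),
    max_rolled_substitution = max(rolling_average(track$substitution, ww)),
    mean_uncertainty = mean(track$uncertainty))
}

#' Write a residue score track as TSV
#'
#' @param track a `ResidueScoreTrack`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_score_track <- function(track, path) {
  utils::write.table(as.data.frame(track), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a residue score track written by [write_score_track()]
#'
#' @param path TSV file.
#' @param id optional id to attach.
#' @param seq_length optional sequence length to attach (reconstructed from
#'   the position range and the default fragment geometry if omitted).
#' @return a `ResidueScoreTrack`.
#' @export
read_score_track <- function(path, id = NULL, seq_length = NULL) {
  tr <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(aa = "character"))
  if (is.null(seq_length)) seq_length <- max(tr$position) + 4L
  attr(tr, "id") <- id
  attr(tr, "seq_length") <- seq_length
  class(tr) <- c("ResidueScoreTrack", "data.frame")
  tr
}
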