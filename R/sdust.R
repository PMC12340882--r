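#' Symmetric DUST score of a window
#'
#' With `n = length - 2` overlapping triplets and `c_t` the count of triplet
#' type `t`, the score is `sum_t c_t (c_t - 1) / 2` divided by `n - 1`
#' (defined as 0 for a 3 bp window).  A window whose triplets are all
#' distinct scores 0; a homopolymer of length `L` scores `(L - 2) / 2`.
#' Triplets containing `N` have no identity: windows containing `N` score 0
#' here and split scanning into independent runs in [perfect_intervals()].
#'
#' @param window nucleotide string of length `>= 3`.
#' @return numeric score.
#' @export
dust_score <- function(window) {
  stopifnot(is.character(window), length(window) == 1)
  L <- nchar(window)
  if (L < 3) stop("dust_score requires a window of length >= 3")
  if (grepl("[^ACGT]", window)) return(0)
  tri <- substring(window, 1:(L - 2), 3:L)
  cc <- table(tri)
  n <- L - 2
  if (n == 1) return(0)
  sum(cc * (cc - 1) / 2) / (n - 1)
}

#' Perfect low-complexity intervals (symmetric DUST)
#'
#' All intervals of length `<= window` with [dust_score()] strictly greater
#' than `threshold`, such that no proper subinterval scores strictly higher
#' and the interval is not properly contained in another reported interval.
#' Runs separated by `N` are scanned independently.
#'
#' @param seq nucleotide string.
#' @param window maximum interval length in bp (default 64).
#' @param threshold score threshold, strict (default 2.0, the classical
#'   DUST cutoff of 20 expressed per unit triplet).
#' @return data.frame with columns `start`, `end` (0-based half-open),
#'   `score`, ordered by start.
#' @export
perfect_intervals <- function(seq, window = 64, threshold = 2.0) {
  stopifnot(is.character(seq), length(seq) == 1, window >= 3, threshold >= 0)
  out <- list()
  # split on non-ACGT characters; scan each run independently
  runs <- gregexpr("[ACGT]+", seq)[[1]]
  if (runs[1] != -1) {
    lens <- attr(runs, "match.length")
    for (i in seq_along(runs)) {
      off <- runs[i] - 1 # 0-based offset of run
      sub <- substr(seq, runs[i], runs[i] + lens[i] - 1)
      h <- cpp_sdust_perfect(sub, as.integer(window), threshold)
      if (length(h$start) > 0) {
        out[[length(out) + 1L]] <- data.frame(start = h$start + off,
                                              end = h$end + off,
                                              score = h$score)
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(start = numeric(), end = numeric(), score = numeric()))
  }
  df <- do.call(rbind, out)
  df <- df[order(df$start, -df$end), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Low-complexity regions of a sequence set
#'
#' Merged union of all perfect DUST intervals per sequence; overlapping or
#' abutting perfect intervals chain into one region, so chained regions may
#' exceed the window length.
#'
#' @param seqs named character vector of sequences.
#' @inheritParams perfect_intervals
#' @return a `RegionSet`; use [perfect_intervals()] when per-interval scores
#'   are needed.
#' @export
lcr_regions <- function(seqs, window = 64, threshold = 2.0) {
  iv <- list()
  for (sn in names(seqs)) {
    pi <- perfect_intervals(seqs[[sn]], window, threshold)
    if (nrow(pi) > 0) {
      iv[[length(iv) + 1L]] <- data.frame(seq = sn, start = pi$start, end = pi$end)
    }
  }
  lens <- vapply(seqs, nchar, numeric(1))
  if (length(iv) == 0) return(region_set(NULL, seqlengths = lens))
  region_set(do.call(rbind, iv), seqlengths = lens)
}
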