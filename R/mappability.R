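#' Exhaustive Hamming-distance window count on a reference
#'
#' Number of length-`k` windows of the reference within Hamming distance
#' `<= max_mm` of the query, scanning every offset (no sampling, no
#' heuristics).  Gapless by definition; forward strand by default, matching
#' the behavior of exact k-mer mappability tools.
#'
#' @param query k-mer over `{A,C,G,T}`.
#' @param reference named character vector of reference sequences.
#' @param max_mm maximum number of mismatches, `< k`.
#' @param strand_mode `"forward"` (default) or `"both"`.
#' @return integer hit count; `>= 1` for a query extracted from the
#'   reference.
#' @export
hamming_hit_count <- function(query, reference, max_mm,
                              strand_mode = c("forward", "both")) {
  strand_mode <- match.arg(strand_mode)
  stopifnot(is.character(query), length(query) == 1)
  if (grepl("[^ACGT]", query)) stop("query contains ambiguous bases")
  if (max_mm < 0 || max_mm >= nchar(query)) stop("max_mm must satisfy 0 <= max_mm < k")
  qs <- query
  if (strand_mode == "both") qs <- c(qs, revcomp(query))
  total <- 0L
  for (sq in reference) {
    for (q in qs) {
      total <- total + cpp_hamming_count_batch(q, sq, as.integer(max_mm),
                                               .Machine$integer.max)
    }
  }
  total
}

#' Multi-mapping k-mer footprint mask
#'
#' The mappability rescue stage: among the sampled reference k-mers, any
#' whose exhaustive Hamming-window count is `>= 2` has a gapless near-copy
#' elsewhere in the reference and its footprint `[i, i+k)` is masked.
#' K-mers containing `N` are skipped here (they are masked upstream as
#' ambiguous).
#'
#' @param reference named character vector of reference sequences.
#' @param positions list mapping sequence name to sampled 0-based offsets
#'   (as from [sample_positions()]), or `NULL` to sample with `params`.
#' @param params a [mask_params()] object (uses `k`, `w`, `hamming_d`).
#' @param strand_mode `"forward"` (default) or `"both"`.
#' @return a `RegionSet` of masked footprints (merged form).
#' @export
multi_mapping_mask <- function(reference, positions = NULL, params = mask_params(),
                               strand_mode = c("forward", "both")) {
  strand_mode <- match.arg(strand_mode)
  k <- params$k
  if (is.null(positions)) {
    positions <- lapply(reference, function(s) sample_positions(nchar(s), k, params$w))
    names(positions) <- names(reference)
  }
  iv <- list()
  for (sn in names(positions)) {
    pos <- positions[[sn]]
    if (length(pos) == 0) next
    kmers <- substring(reference[[sn]], pos + 1, pos + k)
    ok <- !grepl("[^ACGT]", kmers)
    if (!any(ok)) next
    counts <- rep(0L, length(kmers))
    for (sq in reference) {
      counts[ok] <- counts[ok] +
        cpp_hamming_count_batch(kmers[ok], sq, as.integer(params$hamming_d), 2L)
      if (strand_mode == "both") {
        counts[ok] <- counts[ok] +
          cpp_hamming_count_batch(revcomp(kmers[ok]), sq,
                                  as.integer(params$hamming_d), 2L)
      }
    }
    multi <- ok & counts >= 2
    if (any(multi)) {
      iv[[length(iv) + 1L]] <- data.frame(seq = sn, start = pos[multi],
                                          end = pos[multi] + k)
    }
  }
  lens <- vapply(reference, nchar, numeric(1))
  if (length(iv) == 0) return(region_set(NULL, seqlengths = lens))
  region_set(do.call(rbind, iv), seqlengths = lens)
}
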