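#' @importFrom IRanges IRanges reduce start end width
NULL

# Coordinates are 0-based half-open (BED convention) at the package surface;
# conversion to IRanges' 1-based closed form happens only inside this file.

.iv_df <- function(seq = character(), start = integer(), end = integer()) {
  data.frame(seq = as.character(seq), start = as.numeric(start),
             end = as.numeric(end), stringsAsFactors = FALSE)
}

.validate_intervals <- function(df) {
  stopifnot(is.data.frame(df), all(c("seq", "start", "end") %in% names(df)))
  bad <- which(!(df$start >= 0 & df$start < df$end))
  if (length(bad) > 0) {
    stop(sprintf("invalid interval (start >= end or start < 0): %s:%s-%s",
                 df$seq[bad[1]], df$start[bad[1]], df$end[bad[1]]))
  }
  invisible(df)
}

.to_ir <- function(df) IRanges::IRanges(start = df$start + 1, end = df$end)

.from_ir <- function(ir, seq) {
  if (length(ir) == 0) return(.iv_df())
  .iv_df(seq = rep(seq, length(ir)), start = IRanges::start(ir) - 1,
         end = IRanges::end(ir))
}

#' Construct a region set
#'
#' A `RegionSet` holds, per sequence, a sorted list of non-overlapping,
#' non-abutting 0-based half-open intervals, plus (optionally) the sequence
#' lengths needed for complement operations.  Inputs are merged to canonical
#' form: overlapping and abutting intervals are unioned.
#'
#' @param intervals data.frame with columns `seq`, `start`, `end`
#'   (0-based half-open), or `NULL` for an empty set.
#' @param seqlengths named numeric vector of sequence lengths in bp, or
#'   `NULL` if unknown.
#' @return an object of class `RegionSet`.
#' @export
region_set <- function(intervals = NULL, seqlengths = NULL) {
  if (is.null(intervals)) intervals <- .iv_df()
  intervals <- .iv_df(intervals$seq, intervals$start, intervals$end)
  .validate_intervals(intervals)
  if (!is.null(seqlengths)) {
    stopifnot(!is.null(names(seqlengths)), !any(duplicated(names(seqlengths))))
    seqlengths <- vapply(seqlengths, as.numeric, numeric(1))
    known <- intervals$seq %in% names(seqlengths)
    over <- which(known & intervals$end > seqlengths[intervals$seq])
    if (length(over) > 0) {
      stop(sprintf("interval exceeds declared sequence length: %s:%s-%s",
                   intervals$seq[over[1]], intervals$start[over[1]],
                   intervals$end[over[1]]))
    }
  }
  out <- list()
  for (s in sort(unique(intervals$seq))) {
    ir <- IRanges::reduce(.to_ir(intervals[intervals$seq == s, , drop = FALSE]))
    out[[length(out) + 1L]] <- .from_ir(ir, s)
  }
  df <- if (length(out) > 0) do.call(rbind, out) else .iv_df()
  rownames(df) <- NULL
  structure(list(intervals = df, seqlengths = seqlengths), class = "RegionSet")
}

#' @export
print.RegionSet <- function(x, ...) {
  cat(sprintf("RegionSet: %d intervals on %d sequence(s), %s bp total\n",
              nrow(x$intervals), length(unique(x$intervals$seq)),
              format(region_width(x), big.mark = ",")))
  invisible(x)
}

.is_region_set <- function(x) inherits(x, "RegionSet")

#' Total width of a region set in bp
#' @param r a `RegionSet`.
#' @return numeric scalar, the number of bases covered.
#' @export
region_width <- function(r) {
  stopifnot(.is_region_set(r))
  if (nrow(r$intervals) == 0) return(0)
  sum(r$intervals$end - r$intervals$start)
}

#' Merge intervals into a canonical region set
#'
#' Computes the minimal sorted, non-overlapping interval list covering
#' exactly the union of the inputs.  Abutting intervals are merged (region
#' sets are per-base masks, so abutment carries no information).
#'
#' @inheritParams region_set
#' @return a `RegionSet`.
#' @export
regions_merge <- function(intervals, seqlengths = NULL) {
  region_set(intervals, seqlengths)
}

# apply a per-sequence IRanges binary op over the union of sequence names in
# a; sequences present only in b are ignored.
.per_seq_op <- function(a, b, op) {
  stopifnot(.is_region_set(a), .is_region_set(b))
  out <- list()
  for (s in sort(unique(a$intervals$seq))) {
    ia <- .to_ir(a$intervals[a$intervals$seq == s, , drop = FALSE])
    ib <- .to_ir(b$intervals[b$intervals$seq == s, , drop = FALSE])
    out[[length(out) + 1L]] <- .from_ir(op(ia, ib), s)
  }
  df <- if (length(out) > 0) do.call(rbind, out) else .iv_df()
  rownames(df) <- NULL
  structure(list(intervals = df, seqlengths = a$seqlengths), class = "RegionSet")
}

#' Complement of a region set within its sequences
#'
#' Per-base complement within `[0, length)` of every sequence named in
#' `seqlengths`; `regions_complement(regions_complement(r)) == r`.
#'
#' @param r a `RegionSet` with `seqlengths` set for every sequence it touches.
#' @return a `RegionSet` over the same `seqlengths`.
#' @export
regions_complement <- function(r) {
  stopifnot(.is_region_set(r))
  if (is.null(r$seqlengths)) stop("complement requires sequence lengths")
  missing <- setdiff(unique(r$intervals$seq), names(r$seqlengths))
  if (length(missing) > 0) {
    stop("no declared length for sequence(s): ", paste(missing, collapse = ", "))
  }
  out <- list()
  for (s in sort(names(r$seqlengths))) {
    len <- r$seqlengths[[s]]
    ir <- .to_ir(r$intervals[r$intervals$seq == s, , drop = FALSE])
    gp <- IRanges::gaps(ir, start = 1, end = len)
    out[[length(out) + 1L]] <- .from_ir(gp, s)
  }
  df <- if (length(out) > 0) do.call(rbind, out) else .iv_df()
  rownames(df) <- NULL
  structure(list(intervals = df, seqlengths = r$seqlengths), class = "RegionSet")
}

#' Set difference of two region sets
#'
#' Bases in `a` and not in `b`.  Sequences present only in `b` are ignored,
#' so genome-wide sets can be trimmed by chromosome subsets.
#'
#' @param a,b `RegionSet` objects.
#' @return a `RegionSet` carrying `a`'s sequence lengths.
#' @export
regions_subtract <- function(a, b) {
  .per_seq_op(a, b, function(ia, ib) IRanges::setdiff(ia, ib))
}

#' Intersection of two region sets
#'
#' Bases in both `a` and `b`; commutative up to `a`'s sequence universe.
#'
#' @inheritParams regions_subtract
#' @return a `RegionSet` carrying `a`'s sequence lengths.
#' @export
regions_intersect <- function(a, b) {
  .per_seq_op(a, b, function(ia, ib) IRanges::intersect(ia, ib))
}

#' Drop intervals shorter than a minimum length
#'
#' Retains intervals of length `>= min_len` ("shorter than" is strict: an
#' interval of exactly `min_len` bp is kept).
#'
#' @param r a `RegionSet`.
#' @param min_len minimum interval length in bp (`>= 1`).
#' @return a `RegionSet`.
#' @export
regions_filter_min_length <- function(r, min_len) {
  stopifnot(.is_region_set(r), min_len >= 1)
  keep <- (r$intervals$end - r$intervals$start) >= min_len
  df <- r$intervals[keep, , drop = FALSE]
  rownames(df) <- NULL
  structure(list(intervals = df, seqlengths = r$seqlengths), class = "RegionSet")
}
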