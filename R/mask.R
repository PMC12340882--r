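#' Masking parameters
#'
#' Houses every tunable of the easy-region derivation.  The defaults are the
#' published operating point for human-scale pangenomes of 151 bp read
#' k-mers: `k = 151`, sampling stride `w = 10`, copy-number tolerance
#' `c = 1.01`, reference-uniqueness edit radius `d1 = 3`, pangenome edit
#' radius `d2 = 7`, Hamming mappability radius 3, minimum easy-region length
#' 50 bp, low-complexity exclusion above 18 bp with DUST window 64 and score
#' threshold 2.0.
#'
#' @param k k-mer length in bp.
#' @param w sampling stride in bp (one k-mer per `w` bases).
#' @param c copy-number tolerance, `> 1`; a k-mer fails when its pangenome
#'   hit count reaches `c * N` (real-valued comparison, no rounding).
#' @param d1 edit radius of the reference-uniqueness condition.
#' @param d2 edit radius of the pangenome condition; must exceed `d1`.
#' @param hamming_d Hamming radius of the mappability rescue.
#' @param min_region_len minimum retained easy-region length in bp.
#' @param lcr_max_len low-complexity regions strictly longer than this are
#'   excluded from the strict set.
#' @param sdust_window,sdust_threshold DUST scan window (bp) and strict
#'   score threshold.
#' @return an object of class `MaskParams`.
#' @export
mask_params <- function(k = 151, w = 10, c = 1.01, d1 = 3, d2 = 7,
                        hamming_d = 3, min_region_len = 50, lcr_max_len = 18,
                        sdust_window = 64, sdust_threshold = 2.0) {
  stopifnot(k >= 1, w >= 1, min_region_len >= 1, lcr_max_len >= 1,
            sdust_window >= 3, sdust_threshold >= 0, hamming_d >= 0)
  if (!(d2 > d1 && d1 >= 0)) stop("parameter violation: require d2 > d1 >= 0")
  if (!(c > 1)) stop("parameter violation: require c > 1")
  if (!(k > d2)) stop("parameter violation: require k > d2")
  structure(list(k = as.integer(k), w = as.integer(w), c = c,
                 d1 = as.integer(d1), d2 = as.integer(d2),
                 hamming_d = as.integer(hamming_d),
                 min_region_len = as.integer(min_region_len),
                 lcr_max_len = as.integer(lcr_max_len),
                 sdust_window = as.integer(sdust_window),
                 sdust_threshold = sdust_threshold),
            class = "MaskParams")
}

#' @export
print.MaskParams <- function(x, ...) {
  cat(sprintf(paste0("MaskParams: k=%d w=%d c=%g d1=%d d2=%d hamming=%d ",
                     "min_len=%d lcr_len=%d dust(%d, %g)\n"),
              x$k, x$w, x$c, x$d1, x$d2, x$hamming_d, x$min_region_len,
              x$lcr_max_len, x$sdust_window, x$sdust_threshold))
  invisible(x)
}

#' Sampled k-mer start offsets along a sequence
#'
#' Offsets `0, w, 2w, ...` up to `seq_len - k`, with the tail offset
#' `seq_len - k` appended when it is not already on the grid, so the last
#' `w - 1` bases of a sequence are still spanned by a tested k-mer.  A
#' sequence shorter than `k` yields no offsets (it is untestable and falls
#' wholly outside the easy regions).
#'
#' @param seq_len sequence length in bp.
#' @param k k-mer length.
#' @param w sampling stride.
#' @return strictly increasing integer vector of 0-based offsets.
#' @export
sample_positions <- function(seq_len, k, w) {
  if (seq_len < k) return(integer())
  last <- seq_len - k
  pos <- seq.int(0L, last, by = w)
  if (pos[length(pos)] != last) pos <- c(pos, last)
  as.integer(pos)
}

# Batched classification of all sampled k-mers of one reference sequence.
# Returns a data.frame of verdicts.  Engine note: counting runs in C++ with
# collapse radius equal to the search radius and early exit at the relevant
# threshold; counts are therefore reported capped at that threshold.
.classify_positions <- function(coll, seq_name, positions, params,
                                strand_mode = "both", engine = "seeded") {
  exact <- identical(engine, "exact")
  k <- params$k
  N <- n_genomes(coll)
  ref <- coll$assemblies[[1]]
  kmers <- substring(ref[[seq_name]], positions + 1, positions + k)
  n <- length(positions)
  has_n <- grepl("[^ACGT]", kmers)
  both <- strand_mode == "both"

  # condition 1: collapsed reference hits at radius d1 must equal 1
  ref_cap <- 2L
  ref_counts <- rep(NA_integer_, n)
  caps <- ifelse(has_n, 0L, ref_cap)
  acc <- rep(0L, n)
  for (sq in ref) {
    remaining <- pmax(ref_cap - acc, 0L)
    remaining[has_n] <- 0L
    got <- cpp_count_collapsed_batch(kmers, sq, params$d1, both, remaining,
                                     exact)
    got[is.na(got)] <- 0L
    acc <- acc + got
  }
  ref_counts[!has_n] <- acc[!has_n]
  fail_ref <- !has_n & ref_counts != 1

  # condition 2: collapsed hits over all N genomes at radius d2 < c*N
  thr <- params$c * N
  cap2 <- as.integer(ceiling(thr))
  if (cap2 <= thr) cap2 <- cap2 + 1L  # need to distinguish count >= thr
  pan_counts <- rep(NA_integer_, n)
  active <- !has_n & !fail_ref
  acc <- rep(0L, n)
  for (asm in coll$assemblies) {
    for (sq in asm) {
      remaining <- pmax(cap2 - acc, 0L)
      remaining[!active] <- 0L
      if (all(remaining == 0L)) break
      got <- cpp_count_collapsed_batch(kmers, sq, params$d2, both, remaining,
                                       exact)
      got[is.na(got)] <- 0L
      acc <- acc + got
    }
  }
  pan_counts[active] <- acc[active]
  fail_pan <- active & acc >= thr

  # mappability rescue: exhaustive Hamming multi-mapping on the reference
  mm <- rep(NA, n)
  ok <- !has_n
  cnt <- rep(0L, n)
  for (sq in ref) {
    cnt[ok] <- cnt[ok] + cpp_hamming_count_batch(kmers[ok], sq,
                                                 params$hamming_d, 2L)
  }
  mm[ok] <- cnt[ok] >= 2L

  status <- rep("unique", n)
  status[ok & !fail_ref & !fail_pan & mm] <- "fail_mappability"
  status[fail_pan] <- "fail_pan_excess"
  status[fail_ref] <- "fail_ref_multi"
  status[has_n] <- "fail_ambiguous_base"

  data.frame(seq = seq_name, position = positions,
             ref_hits_d1 = ref_counts, pan_hits_d2 = pan_counts,
             mappability_multi = mm, status = status)
}

#' Mask insufficiently unique k-mer footprints on the reference
#'
#' Every sampled reference k-mer is tested for sufficient uniqueness:
#' (i) a k-mer containing `N` fails as ambiguous; (ii) it must have exactly
#' one collapsed hit at edit radius `d1` in the reference; (iii) its
#' collapsed hit count at radius `d2` summed over all `N` assemblies
#' (including the reference) must stay strictly below `c * N`; (iv) an
#' exhaustive Hamming scan of the reference at radius `hamming_d` must not
#' find a second gapless near-copy.  The footprint `[i, i + k)` of every
#' failing k-mer is masked.
#'
#' @param coll a `GenomeCollection` (assembly 1 is the reference).
#' @param params a [mask_params()] object.
#' @param strand_mode strand handling for the edit-distance searches;
#'   `"both"` (default) also counts reverse-complement placements.
#' @param engine `"seeded"` (default) or `"exact"`; both are complete, the
#'   exact full-DP engine is kept for verification runs.
#' @return list with elements `masked` (a `RegionSet`) and `verdicts`
#'   (a data.frame audit trail: seq, position, capped hit counts,
#'   mappability flag, status).
#' @export
mask_reference <- function(coll, params = mask_params(),
                           strand_mode = c("both", "forward"),
                           engine = c("seeded", "exact")) {
  strand_mode <- match.arg(strand_mode)
  engine <- match.arg(engine)
  stopifnot(inherits(coll, "GenomeCollection"), inherits(params, "MaskParams"))
  ref <- coll$assemblies[[1]]
  lens <- vapply(ref, nchar, numeric(1))
  verdicts <- list()
  iv <- list()
  for (sn in names(ref)) {
    pos <- sample_positions(lens[[sn]], params$k, params$w)
    if (length(pos) == 0) next
    v <- .classify_positions(coll, sn, pos, params, strand_mode, engine)
    verdicts[[length(verdicts) + 1L]] <- v
    bad <- v$status != "unique"
    if (any(bad)) {
      iv[[length(iv) + 1L]] <- data.frame(seq = sn, start = v$position[bad],
                                          end = v$position[bad] + params$k)
    }
  }
  vdf <- if (length(verdicts) > 0) do.call(rbind, verdicts) else
    data.frame(seq = character(), position = numeric(), ref_hits_d1 = integer(),
               pan_hits_d2 = integer(), mappability_multi = logical(),
               status = character())
  rownames(vdf) <- NULL
  masked <- if (length(iv) > 0) region_set(do.call(rbind, iv), seqlengths = lens)
            else region_set(NULL, seqlengths = lens)
  list(masked = masked, verdicts = vdf)
}

#' Classify a single sampled k-mer
#'
#' Convenience wrapper returning the verdict for one reference offset; see
#' [mask_reference()] for the classification rules.
#'
#' @inheritParams mask_reference
#' @param seq_name reference sequence name.
#' @param position 0-based offset of the sampled k-mer.
#' @return one-row data.frame verdict.
#' @export
classify_kmer <- function(coll, seq_name, position, params = mask_params(),
                          strand_mode = c("both", "forward"),
                          engine = c("seeded", "exact")) {
  strand_mode <- match.arg(strand_mode)
  engine <- match.arg(engine)
  .classify_positions(coll, seq_name, as.integer(position), params,
                      strand_mode, engine)
}

# union of sampled k-mer footprints: [0, L) for every sequence of length
# >= k (the tail k-mer is always sampled), nothing for shorter sequences.
.covered_footprint <- function(ref, params) {
  lens <- vapply(ref, nchar, numeric(1))
  testable <- names(lens)[lens >= params$k]
  if (length(testable) == 0) return(region_set(NULL, seqlengths = lens))
  region_set(data.frame(seq = testable, start = 0, end = lens[testable]),
             seqlengths = lens)
}

#' Derive the lenient easy-region set
#'
#' Easy regions are the sampled-k-mer footprint of the reference minus the
#' masked footprints of insufficiently unique k-mers, with regions shorter
#' than `min_region_len` dropped to reduce fragmentation.  Bases never
#' spanned by a sampled k-mer (sequences or tails shorter than `k`) are
#' never easy: untested sequence is not assumed easy.
#'
#' @inheritParams mask_reference
#' @param mask optional precomputed result of [mask_reference()]; computed
#'   when `NULL`.
#' @return a `RegionSet`; deterministic for fixed inputs.
#' @export
derive_lenient <- function(coll, params = mask_params(), mask = NULL,
                           strand_mode = c("both", "forward"),
                           engine = c("seeded", "exact")) {
  strand_mode <- match.arg(strand_mode)
  engine <- match.arg(engine)
  if (is.null(mask)) mask <- mask_reference(coll, params, strand_mode, engine)
  covered <- .covered_footprint(coll$assemblies[[1]], params)
  easy <- regions_subtract(covered, mask$masked)
  regions_filter_min_length(easy, params$min_region_len)
}

#' Derive the strict easy-region set from the lenient set
#'
#' Removes low-complexity regions strictly longer than `lcr_max_len`
#' (detected by the symmetric DUST scan of the reference) from the lenient
#' set, re-applying the minimum region length filter.  The strict set is a
#' per-base subset of the lenient set.
#'
#' @param lenient the `RegionSet` produced by [derive_lenient()] on the
#'   same reference.
#' @param reference named character vector of reference sequences.
#' @param params a [mask_params()] object.
#' @return a `RegionSet`.
#' @export
derive_strict <- function(lenient, reference, params = mask_params()) {
  lcr <- lcr_regions(reference, params$sdust_window, params$sdust_threshold)
  long <- regions_filter_min_length(lcr, params$lcr_max_len + 1L)
  strict <- regions_subtract(lenient, long)
  regions_filter_min_length(strict, params$min_region_len)
}

#' Run the full easy-region pipeline
#'
#' Masks insufficiently unique sampled k-mers, derives the lenient set, and
#' carves the strict set out of it.
#'
#' @inheritParams mask_reference
#' @return list with `lenient` and `strict` `RegionSet`s, the `masked`
#'   `RegionSet`, and the `verdicts` audit data.frame.
#' @export
easy_regions <- function(coll, params = mask_params(),
                         strand_mode = c("both", "forward"),
                         engine = c("seeded", "exact")) {
  strand_mode <- match.arg(strand_mode)
  engine <- match.arg(engine)
  mask <- mask_reference(coll, params, strand_mode, engine)
  lenient <- derive_lenient(coll, params, mask = mask, strand_mode = strand_mode)
  strict <- derive_strict(lenient, coll$assemblies[[1]], params)
  list(lenient = lenient, strict = strict, masked = mask$masked,
       verdicts = mask$verdicts)
}

#' Write verdicts as a TSV audit file
#'
#' @param verdicts data.frame from [mask_reference()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_verdicts <- function(verdicts, path) {
  utils::write.table(verdicts, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
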