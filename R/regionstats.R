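#' Fraction of a target covered by a region set
#'
#' `|intersect(r, target)| / |target|`.  When `target` is `NULL` the whole
#' genome (every sequence declared in `r$seqlengths`) is the target.
#'
#' @param r a `RegionSet`.
#' @param target a `RegionSet`, or `NULL` for whole-genome coverage.
#' @return fraction in `[0, 1]`.
#' @export
coverage_fraction <- function(r, target = NULL) {
  stopifnot(.is_region_set(r))
  if (is.null(target)) {
    if (is.null(r$seqlengths)) stop("whole-genome coverage requires seqlengths")
    target <- region_set(data.frame(seq = names(r$seqlengths), start = 0,
                                    end = unname(r$seqlengths)),
                         seqlengths = r$seqlengths)
  }
  denom <- region_width(target)
  if (denom == 0) stop("coverage target has zero length")
  region_width(regions_intersect(target, r)) / denom
}

#' Fraction of one region set included in another
#'
#' `|intersect(a, b)| / |a|`; asymmetric by design (the fraction of `a`'s
#' bases that `b` also covers).
#'
#' @param a,b `RegionSet` objects; `a` must be non-empty.
#' @return fraction in `[0, 1]`.
#' @export
subset_fraction <- function(a, b) {
  wa <- region_width(a)
  if (wa == 0) stop("subset_fraction is undefined for an empty first set")
  region_width(regions_intersect(a, b)) / wa
}

# which sites fall inside r: a site is inside iff its 0-based start position
# is covered (single unambiguous rule also for multi-base alleles).
.sites_in_regions <- function(sites, r) {
  if (nrow(sites) == 0) return(logical(0))
  inside <- logical(nrow(sites))
  for (sn in unique(sites$seq)) {
    iv <- r$intervals[r$intervals$seq == sn, , drop = FALSE]
    idx <- which(sites$seq == sn)
    if (nrow(iv) == 0) { inside[idx] <- FALSE; next }
    # intervals are sorted and disjoint; position p is inside iff the last
    # start <= p belongs to an interval whose end > p
    j <- findInterval(sites$pos[idx], iv$start)
    inside[idx] <- j >= 1 & sites$pos[idx] < iv$end[pmax(j, 1)]
  }
  inside
}

#' Variant density within a region set
#'
#' Count of sites whose position lies in `r`, divided by the total region
#' length; optionally also the density relative to a confident-region set
#' (density in `r` over density in `confident`).
#'
#' @param sites data.frame of variant sites (`seq`, `pos`, `ref`, `alt`).
#' @param r a non-empty `RegionSet`.
#' @param confident optional `RegionSet` of confident regions with nonzero
#'   variant density.
#' @return list with `density` (per bp) and `relative` (or `NULL`).
#' @export
variant_density <- function(sites, r, confident = NULL) {
  wr <- region_width(r)
  if (wr == 0) stop("variant density is undefined for an empty region set")
  dens <- sum(.sites_in_regions(sites, r)) / wr
  rel <- NULL
  if (!is.null(confident)) {
    wc <- region_width(confident)
    if (wc == 0) stop("confident region set is empty")
    dc <- sum(.sites_in_regions(sites, confident)) / wc
    if (dc == 0) stop("confident region set has zero variant density")
    rel <- dens / dc
  }
  list(density = dens, relative = rel)
}

#' Site-level concordance within regions
#'
#' Restricts both site lists to positions inside `r`, then matches calls to
#' truth on exact normalized representation `(seq, pos, ref, alt)`.
#' `FDR` is the fraction of in-region calls not matching truth; `FNR` the
#' fraction of in-region truth sites not matched by any call.  Both are 0
#' when their denominator is 0.  Genotypes are ignored; matching is not
#' haplotype-aware, so equivalent complex-region representations count as
#' errors (a deliberate simplification relative to haplotype-aware
#' comparison engines).
#'
#' @param truth,calls data.frames of normalized variant sites.
#' @param r a `RegionSet`.
#' @return list with `fdr`, `fnr`, and the in-region counts
#'   `n_calls`, `n_truth`, `n_matched`.
#' @export
site_concordance <- function(truth, calls, r) {
  tkey <- with(truth[.sites_in_regions(truth, r), , drop = FALSE],
               paste(seq, pos, ref, alt, sep = "\r"))
  ckey <- with(calls[.sites_in_regions(calls, r), , drop = FALSE],
               paste(seq, pos, ref, alt, sep = "\r"))
  tkey <- unique(tkey); ckey <- unique(ckey)
  matched <- sum(ckey %in% tkey)
  fdr <- if (length(ckey) == 0) 0 else (length(ckey) - matched) / length(ckey)
  fnr <- if (length(tkey) == 0) 0 else (length(tkey) - matched) / length(tkey)
  list(fdr = fdr, fnr = fnr, n_calls = length(ckey), n_truth = length(tkey),
       n_matched = matched)
}
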