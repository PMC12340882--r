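#' Genome collection
#'
#' An ordered list of assemblies; each assembly is a named character vector
#' of sequences.  The first assembly is the reference; `N` (the genome count
#' used by the uniqueness threshold) is the number of assemblies including
#' the reference.
#'
#' @param assemblies list of named character vectors; index 1 is the
#'   reference.
#' @return an object of class `GenomeCollection`.
#' @export
genome_collection <- function(assemblies) {
  stopifnot(is.list(assemblies), length(assemblies) >= 1)
  for (i in seq_along(assemblies)) {
    a <- assemblies[[i]]
    stopifnot(is.character(a), length(a) >= 1, !is.null(names(a)))
    if (any(duplicated(names(a)))) {
      stop("duplicate sequence names within assembly ", i)
    }
  }
  structure(list(assemblies = assemblies), class = "GenomeCollection")
}

#' @export
print.GenomeCollection <- function(x, ...) {
  cat(sprintf("GenomeCollection: %d assemblies (reference + %d samples)\n",
              length(x$assemblies), length(x$assemblies) - 1))
  invisible(x)
}

#' Number of genomes in a collection
#' @param coll a `GenomeCollection`.
#' @return integer, the number of assemblies including the reference.
#' @export
n_genomes <- function(coll) length(coll$assemblies)

#' Reverse complement
#' @param x character vector of DNA strings.
#' @return character vector of reverse complements (non-ACGT characters
#'   become `N`).
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    chartr("ACGTacgt", "TGCAtgca",
           paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}

.check_query <- function(query, max_d) {
  stopifnot(is.character(query), length(query) == 1)
  if (grepl("[^ACGT]", query)) {
    stop("query contains ambiguous bases; pre-filter k-mers containing N")
  }
  if (max_d < 0 || max_d >= nchar(query)) {
    stop("max_d must satisfy 0 <= max_d < k")
  }
}

.hits_df <- function() {
  data.frame(assembly = integer(), seq = character(), strand = character(),
             start = numeric(), end = numeric(), dist = integer())
}

.find_hits_engine <- function(query, coll, max_d, strand_mode, engine_fun) {
  .check_query(query, max_d)
  stopifnot(inherits(coll, "GenomeCollection"))
  strand_mode <- match.arg(strand_mode, c("both", "forward"))
  out <- list()
  queries <- list(`+` = query)
  if (strand_mode == "both") queries[["-"]] <- revcomp(query)
  for (ai in seq_along(coll$assemblies)) {
    asm <- coll$assemblies[[ai]]
    for (sn in names(asm)) {
      for (std in names(queries)) {
        h <- engine_fun(queries[[std]], asm[[sn]], as.integer(max_d))
        if (length(h$start) > 0) {
          out[[length(out) + 1L]] <- data.frame(
            assembly = ai - 1L, seq = sn, strand = std,
            start = h$start, end = h$end, dist = h$dist)
        }
      }
    }
  }
  if (length(out) == 0) return(.hits_df())
  df <- do.call(rbind, out)
  df <- df[order(df$assembly, df$seq, df$strand, df$start), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Find all bounded-edit-distance placements of a k-mer (exact engine)
#'
#' Reports every end-to-end placement of `query` in every assembly of the
#' collection with unit-cost edit distance `<= max_d`, by full dynamic
#' programming over all windows; complete by construction.  Per candidate
#' start only the minimum achievable distance (and the smallest end position
#' attaining it) is reported.  Reverse-strand hits are placements of the
#' reverse complement of the query, reported in forward coordinates.
#'
#' @param query k-mer over `{A,C,G,T}`.
#' @param coll a `GenomeCollection`.
#' @param max_d maximum edit distance, `0 <= max_d < k`.
#' @param strand_mode `"both"` (default) or `"forward"`.
#' @return data.frame of raw (uncollapsed) hits with columns `assembly`
#'   (0-based index), `seq`, `strand`, `start`, `end` (0-based half-open on
#'   the assembly sequence), `dist`.
#' @seealso [find_hits_seeded()], [collapse_hits()]
#' @export
find_hits_exact <- function(query, coll, max_d, strand_mode = c("both", "forward")) {
  .find_hits_engine(query, coll, max_d, strand_mode, cpp_hits_exact)
}

#' Find all bounded-edit-distance placements of a k-mer (seeded engine)
#'
#' Same contract and output as [find_hits_exact()], computed by pigeonhole
#' seeding: the query is split into `max_d + 1` non-overlapping seeds, exact
#' seed matches are located, and candidate starts are verified with banded
#' dynamic programming.  Any placement with `<= max_d` edits must contain at
#' least one exact seed, so the hit set is complete.
#'
#' @inheritParams find_hits_exact
#' @return data.frame of raw hits; identical to the exact engine's output on
#'   every input.
#' @export
find_hits_seeded <- function(query, coll, max_d, strand_mode = c("both", "forward")) {
  .find_hits_engine(query, coll, max_d, strand_mode, cpp_hits_seeded)
}

#' Collapse alignment jitter among hits of one query
#'
#' An alignment with `<= d` edits can shift its reported start by at most
#' `d`, so raw hits at nearby starts describe the same locus.  Hits on the
#' same (assembly, sequence, strand) are grouped by single linkage: a new
#' group starts whenever the gap between successive start positions exceeds
#' `max_d`.  Each group is represented by its minimum-distance hit (ties
#' broken by leftmost start).  Tandem copies with period `> max_d` stay
#' distinct.
#'
#' @param hits data.frame of raw hits from a single query.
#' @param max_d the edit radius the hits were searched at.
#' @return data.frame of collapsed hits sorted by (assembly, seq, strand,
#'   start).
#' @export
collapse_hits <- function(hits, max_d) {
  if (nrow(hits) == 0) return(hits)
  hits <- hits[order(hits$assembly, hits$seq, hits$strand, hits$start), , drop = FALSE]
  key <- paste(hits$assembly, hits$seq, hits$strand, sep = "\r")
  newgrp <- c(TRUE, key[-1] != key[-nrow(hits)] |
                diff(hits$start) > max_d)
  grp <- cumsum(newgrp)
  keep <- integer(max(grp))
  for (g in seq_len(max(grp))) {
    idx <- which(grp == g)
    best <- idx[order(hits$dist[idx], hits$start[idx])][1]
    keep[g] <- best
  }
  out <- hits[keep, , drop = FALSE]
  out <- out[order(out$assembly, out$seq, out$strand, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}
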