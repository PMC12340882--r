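#' @importFrom Biostrings readDNAStringSet writeXStringSet DNAStringSet
NULL

#' Read a FASTA file into sequence records
#'
#' Sequence names are the first whitespace-delimited token of each header.
#' Lowercase is folded to uppercase; characters outside `{A,C,G,T,N}`
#' (IUPAC ambiguity codes, gaps) are mapped to `N`.
#'
#' @param path path to a (possibly multi-record, wrapped) FASTA file.
#' @return named character vector of uppercase sequences.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  if (length(ss) == 0) stop("empty FASTA file: ", path)
  nm <- vapply(strsplit(names(ss), "[ \t]+"), `[`, character(1), 1)
  dup <- nm[duplicated(nm)]
  if (length(dup) > 0) stop("duplicate sequence name in FASTA: ", dup[1])
  seqs <- toupper(as.character(ss))
  seqs <- gsub("[^ACGTN]", "N", seqs)
  empty <- which(nchar(seqs) == 0)
  if (length(empty) > 0) stop("empty sequence in FASTA: ", nm[empty[1]])
  names(seqs) <- nm
  seqs
}

#' Write sequences to a FASTA file
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @param width line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 80) {
  ss <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}

#' Read a BED3 file into a region set
#'
#' Tab- or space-delimited, 0-based half-open, at least three columns; extra
#' columns are ignored.  Malformed lines (non-integer coordinates,
#' `start >= end`) are rejected with the offending line number.
#'
#' @param path path to a BED file.
#' @param seqlengths optional named numeric vector of sequence lengths.
#' @return a `RegionSet`.
#' @export
read_bed <- function(path, seqlengths = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) return(region_set(NULL, seqlengths))
  parts <- strsplit(lines, "[ \t]+")
  seqs <- character(length(parts))
  starts <- ends <- numeric(length(parts))
  for (i in seq_along(parts)) {
    p <- parts[[i]]
    if (length(p) < 3) stop(sprintf("BED line %d: fewer than 3 columns", i))
    st <- suppressWarnings(as.numeric(p[2]))
    en <- suppressWarnings(as.numeric(p[3]))
    if (is.na(st) || is.na(en) || st != floor(st) || en != floor(en)) {
      stop(sprintf("BED line %d: non-integer coordinates", i))
    }
    if (st >= en) stop(sprintf("BED line %d: start >= end", i))
    seqs[i] <- p[1]; starts[i] <- st; ends[i] <- en
  }
  region_set(data.frame(seq = seqs, start = starts, end = ends),
             seqlengths = seqlengths)
}

#' Write a region set as BED3
#'
#' Tab-delimited, no header, sorted by (sequence, start).  Reading the file
#' back recovers the same region set.
#'
#' @param r a `RegionSet`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(r, path) {
  stopifnot(.is_region_set(r))
  df <- r$intervals[order(r$intervals$seq, r$intervals$start), , drop = FALSE]
  lines <- sprintf("%s\t%d\t%d", df$seq, as.integer(df$start), as.integer(df$end))
  writeLines(lines, path)
  invisible(path)
}

#' Read variant sites from a VCF file
#'
#' Minimal sites-only reading of VCF 4.x text: one site per ALT allele,
#' `POS` converted to 0-based, records with symbolic alleles (`<...>`),
#' breakends, or a FILTER other than `PASS`/`.` skipped.  When a reference
#' genome is supplied, indel sites are normalized (shared trailing then
#' leading bases trimmed, indels left-aligned).
#'
#' @param path path to an uncompressed VCF file.
#' @param reference optional named character vector of reference sequences
#'   used for normalization.
#' @return data.frame with columns `seq`, `pos` (0-based), `ref`, `alt`.
#' @export
read_vcf_sites <- function(path, reference = NULL) {
  lines <- readLines(path)
  hdr <- grep("^#CHROM\t", lines)
  if (length(hdr) == 0) stop("missing #CHROM header line in VCF: ", path)
  body <- lines[seq_along(lines) > hdr[1]]
  body <- body[nzchar(body) & !startsWith(body, "#")]
  out <- list()
  for (ln in body) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 5) next
    filt <- if (length(f) >= 7) f[7] else "."
    if (!(filt %in% c("PASS", "."))) next
    ref <- toupper(f[4])
    if (grepl("[^ACGT]", ref)) next
    for (alt in strsplit(toupper(f[5]), ",", fixed = TRUE)[[1]]) {
      if (grepl("[^ACGT]", alt)) next  # symbolic, breakend, N, *
      if (alt == ref) next
      site <- list(seq = f[1], pos = as.numeric(f[2]) - 1, ref = ref, alt = alt)
      if (!is.null(reference)) site <- .normalize_site(site, reference)
      out[[length(out) + 1L]] <- site
    }
  }
  if (length(out) == 0) {
    return(data.frame(seq = character(), pos = numeric(),
                      ref = character(), alt = character()))
  }
  df <- data.frame(seq = vapply(out, `[[`, "", "seq"),
                   pos = vapply(out, `[[`, 0, "pos"),
                   ref = vapply(out, `[[`, "", "ref"),
                   alt = vapply(out, `[[`, "", "alt"))
  df[order(df$seq, df$pos, df$ref, df$alt), , drop = FALSE]
}

# Left-align and trim a single-ALT site against the reference: repeatedly
# drop a shared trailing base (extending left from the reference when an
# allele would become empty), then trim shared leading bases.
.normalize_site <- function(site, reference) {
  ref <- site$ref; alt <- site$alt; pos <- site$pos
  seq <- reference[[site$seq]]
  last1 <- function(x) substr(x, nchar(x), nchar(x))
  repeat {
    if (nchar(ref) > 0 && nchar(alt) > 0 && last1(ref) == last1(alt)) {
      ref <- substr(ref, 1, nchar(ref) - 1)
      alt <- substr(alt, 1, nchar(alt) - 1)
      if ((nchar(ref) == 0 || nchar(alt) == 0) && pos > 0) {
        prev <- substr(seq, pos, pos) # base preceding 0-based pos
        ref <- paste0(prev, ref); alt <- paste0(prev, alt)
        pos <- pos - 1
      }
      next
    }
    break
  }
  if (nchar(ref) == 0 || nchar(alt) == 0) {
    # at sequence start with nothing to extend into; re-anchor on next base
    nxt <- substr(seq, pos + nchar(ref) + 1, pos + nchar(ref) + 1)
    ref <- paste0(ref, nxt); alt <- paste0(alt, nxt)
  }
  while (nchar(ref) > 1 && nchar(alt) > 1 &&
         substr(ref, 1, 1) == substr(alt, 1, 1)) {
    ref <- substr(ref, 2, nchar(ref)); alt <- substr(alt, 2, nchar(alt))
    pos <- pos + 1
  }
  list(seq = site$seq, pos = pos, ref = ref, alt = alt)
}

#' Write variant sites as a minimal VCF
#'
#' @param sites data.frame as returned by [read_vcf_sites()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_vcf_sites <- function(sites, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  if (nrow(sites) > 0) {
    writeLines(sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.", sites$seq,
                       as.integer(sites$pos) + 1L, sites$ref, sites$alt), con)
  }
  invisible(path)
}
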