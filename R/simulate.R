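#' @importFrom stats rbinom
NULL

# ---------------------------------------------------------------------------
# Synthetic pangenome generator with planted features and exact truth labels.
#
# The generator builds the reference left-to-right from blocks: random
# backbone segments alternating with feature blocks.  Constructions use two
# alphabet tricks so that the edit distance between a planted copy and any
# reference window is *piecewise exact* and truth labels can be computed
# from the construction alone (never by running the pipeline):
#
#  * inserted duplicate copies are wrapped in poly-T "guard" runs of length
#    d2 + 2, while the chars flanking the source locus are rewritten over
#    {A,C,G} to the same depth.  A k-mer protruding p bases beyond a locus
#    therefore pays >= min(p, d2 + 2) unavoidable edits against the other
#    copy, so a window is a radius-d hit iff p + (divergence edits in span)
#    <= d -- sharply, for every d <= d2.
#  * low-complexity runs and tandem arrays are wrapped in short "break" pads
#    drawn from letters outside the motif, so periodic self-alignments pay
#    at least 2*min(|shift|, pad) edits; shifts <= the search radius
#    collapse with the self hit, larger shifts cost more than the radius.
#    Run features are therefore never uniqueness-masked; tandem arrays
#    (period > d1) always are.
#
# Remaining truth costs are evaluated as Hamming distances between the
# constructed strings at the designed alignment offsets ("pairings").
# ---------------------------------------------------------------------------

.rand_seq <- function(n, letters = c("A", "C", "G", "T")) {
  if (n <= 0) return("")
  paste(sample(letters, n, replace = TRUE), collapse = "")
}

.subchar <- function(s, i, ch) { # i 1-based
  substr(s, i, i) <- ch
  s
}

#' Default planted-feature list for a simulated pangenome
#'
#' A feature mix exercising every masking pathway: reference duplications
#' (exact and diverged), sample-only duplications (carried and not carried),
#' a sample deletion, homopolymer and dinucleotide low-complexity runs
#' around the strict-set length cutoff, and (for short k) a 5 bp-period
#' tandem array.
#'
#' @param k k-mer length the simulation is sized for.
#' @param d1 reference-uniqueness radius the divergence values target.
#' @param n_samples number of sample assemblies; carrier counts are clamped
#'   to it.
#' @return list of feature descriptors.
#' @export
sim_default_features <- function(k = 31, d1 = 1, n_samples = 5) {
  feats <- list(
    list(kind = "ref_duplication", len = 4 * k, divergence = 0),
    list(kind = "ref_duplication", len = 4 * k, divergence = d1),
    list(kind = "sample_duplication", len = 4 * k, divergence = 0,
         n_carriers = min(1, n_samples)),
    list(kind = "sample_duplication", len = 4 * k, divergence = 0, n_carriers = 0),
    list(kind = "sample_deletion", len = 4 * k, n_carriers = min(5, n_samples)),
    list(kind = "lcr_run", motif = "A", len = 30),
    list(kind = "lcr_run", motif = "AC", len = 19),
    list(kind = "lcr_run", motif = "AG", len = 18)
  )
  if (k <= 64) {
    feats[[length(feats) + 1L]] <-
      list(kind = "tandem_repeat", motif = "ACGCA", reps = 9)
  }
  feats
}

#' Simulation configuration
#'
#' @param seed RNG seed; all randomness flows from it.
#' @param ref_len target reference length in bp (`>= 10 * k`).
#' @param n_samples number of non-reference assemblies (`N - 1`).
#' @param snp_rate per-base substitution probability per sample, applied
#'   only to backbone positions at least `k` away from any feature block,
#'   so truth labels stay exact (`0 <= snp_rate < 0.02`).
#' @param k k-mer length the masking run will use.
#' @param d1,d2 edit radii the masking run will use; guard and pad sizes
#'   are derived from `d2`, and truth labels are valid for any masking
#'   parameters with radii up to these values.
#' @param features list of planted features (see [sim_default_features()]).
#' @return an object of class `SimConfig`.
#' @export
sim_config <- function(seed = 1, ref_len = 50000, n_samples = 19,
                       snp_rate = 0, k = 31, d1 = 1, d2 = 2,
                       features = sim_default_features(k, d1, n_samples)) {
  stopifnot(ref_len >= 10 * k, n_samples >= 0, snp_rate >= 0, snp_rate < 0.02,
            d2 > d1, d1 >= 0, k > d2)
  for (f in features) {
    if (f$kind == "lcr_run" && f$len >= k) {
      stop("lcr_run features must be shorter than k")
    }
    if (!is.null(f$n_carriers) && f$n_carriers > n_samples) {
      stop("feature carrier count exceeds n_samples")
    }
  }
  structure(list(seed = as.integer(seed), ref_len = as.integer(ref_len),
                 n_samples = as.integer(n_samples), snp_rate = snp_rate,
                 k = as.integer(k), d1 = as.integer(d1), d2 = as.integer(d2),
                 features = features),
            class = "SimConfig")
}

#' Masking parameters matching a simulation configuration
#'
#' @param scfg a [sim_config()] object.
#' @param ... overrides passed to [mask_params()] (e.g. `c`, `w`).
#' @return a `MaskParams` with `k`, `d1`, `d2` (and `hamming_d = d1`) taken
#'   from the configuration.
#' @export
sim_params <- function(scfg, ...) {
  args <- list(k = scfg$k, d1 = scfg$d1, d2 = scfg$d2, hamming_d = scfg$d1)
  over <- list(...)
  args[names(over)] <- over
  do.call(mask_params, args)
}

# build one feature's block strings and metadata.  Returns a list of
# "slots"; each slot is a list(blocks = list of (type, str), feature = id).
# ref_duplication yields two slots (source and copy site).
.build_feature <- function(f, id, k, d1, d2) {
  g <- d2 + 2L   # guard length (poly-T around inserted copies)
  fl <- d2 + 2L  # T-free flank depth around source loci
  br <- d2 + 1L  # break-pad depth around periodic runs
  nonT <- c("A", "C", "G")
  rand_locus <- function(len) {
    s <- .rand_seq(len)
    s <- .subchar(s, 1, sample(nonT, 1))
    .subchar(s, len, sample(nonT, 1))
  }
  diverge <- function(s, div) {
    if (div == 0) return(list(str = s, offs = integer()))
    len <- nchar(s)
    lo <- fl + 2L; hi <- len - fl - 1L
    offs <- unique(round(seq(lo, hi, length.out = div)))
    for (o in offs) {
      orig <- substr(s, o, o)
      s <- .subchar(s, o, sample(setdiff(c("A", "C", "G"), orig), 1))
    }
    list(str = s, offs = offs) # 1-based offsets within locus
  }
  guard <- strrep("T", g)
  if (f$kind == "ref_duplication") {
    locus <- rand_locus(f$len)
    dv <- diverge(locus, f$divergence)
    list(
      list(feature = id, blocks = list(
        list(type = "flank", str = .rand_seq(fl, nonT)),
        list(type = "locus", str = locus),
        list(type = "flank", str = .rand_seq(fl, nonT)))),
      list(feature = id, blocks = list(
        list(type = "guard", str = guard),
        list(type = "locus_copy", str = dv$str),
        list(type = "guard", str = guard)),
        div_offs = dv$offs)
    )
  } else if (f$kind == "sample_duplication") {
    locus <- rand_locus(f$len)
    dv <- diverge(locus, f$divergence)
    list(list(feature = id, blocks = list(
      list(type = "flank", str = .rand_seq(fl, nonT)),
      list(type = "locus", str = locus),
      list(type = "flank", str = .rand_seq(fl, nonT))),
      copy_str = paste0(guard, dv$str, guard), div_offs = dv$offs))
  } else if (f$kind == "sample_deletion") {
    list(list(feature = id, blocks = list(
      list(type = "locus", str = rand_locus(f$len)))))
  } else if (f$kind == "lcr_run") {
    motif <- f$motif
    letters_in <- unique(strsplit(motif, "")[[1]])
    brk <- setdiff(c("A", "C", "G", "T"), letters_in)
    run <- substr(strrep(motif, ceiling(f$len / nchar(motif))), 1, f$len)
    list(list(feature = id, blocks = list(
      list(type = "break", str = .rand_seq(br, brk)),
      list(type = "run", str = run),
      list(type = "break", str = .rand_seq(br, brk)))))
  } else if (f$kind == "tandem_repeat") {
    arr <- strrep(f$motif, f$reps)
    list(list(feature = id, blocks = list(
      list(type = "pad", str = strrep("T", br)),
      list(type = "array", str = arr),
      list(type = "pad", str = strrep("T", br)))))
  } else {
    stop("unknown feature kind: ", f$kind)
  }
}

# Hamming distance between two equal-length strings (utf8 codepoints).
.hamming <- function(a, b) sum(utf8ToInt(a) != utf8ToInt(b))

#' Simulate a pangenome with planted features
#'
#' Builds a reference and `n_samples` haploid single-contig sample
#' assemblies, installing the configured features, and records the designed
#' alignment geometry ("pairings") from which [expected_regions()] computes
#' exact expected easy-region sets without running the pipeline.
#'
#' @param cfg a [sim_config()] object.
#' @return list with `collection` (a `GenomeCollection`; assembly 1 is the
#'   reference) and `truth` (construction record: feature table, pairings,
#'   designed low-complexity excisions).
#' @export
simulate_pangenome <- function(cfg) {
  stopifnot(inherits(cfg, "SimConfig"))
  set.seed(cfg$seed)
  k <- cfg$k; d1 <- cfg$d1; d2 <- cfg$d2
  g <- d2 + 2L

  slots <- list()
  for (i in seq_along(cfg$features)) {
    built <- .build_feature(cfg$features[[i]], i, k, d1, d2)
    slots <- c(slots, built)
  }
  feat_bp <- sum(vapply(slots, function(sl)
    sum(vapply(sl$blocks, function(b) nchar(b$str), numeric(1))), numeric(1)))
  nseg <- length(slots) + 1L
  seg_len <- floor((cfg$ref_len - feat_bp) / nseg)
  if (seg_len < max(2 * k + 20, 170)) {
    stop("ref_len too small for the requested features (backbone spacing < 2k)")
  }

  # interleave backbone segments and feature slots into one block list
  blocks <- list() # each: type, str, feature (NA for backbone), seg_id
  seg_id <- 0L
  for (i in seq_len(nseg)) {
    seg_id <- seg_id + 1L
    blocks[[length(blocks) + 1L]] <- list(type = "backbone",
                                          str = .rand_seq(seg_len),
                                          feature = NA_integer_, seg = seg_id)
    if (i <= length(slots)) {
      for (b in slots[[i]]$blocks) {
        blocks[[length(blocks) + 1L]] <- list(type = b$type, str = b$str,
                                              feature = slots[[i]]$feature,
                                              seg = NA_integer_)
      }
    }
  }

  # force backbone chars adjacent to poly-T guards/pads to be non-T so that
  # guard runs have exactly the designed length
  nonT <- c("A", "C", "G")
  for (i in seq_along(blocks)) {
    if (blocks[[i]]$type %in% c("guard", "pad")) {
      if (i > 1 && blocks[[i - 1]]$type == "backbone") {
        s <- blocks[[i - 1]]$str
        if (substr(s, nchar(s), nchar(s)) == "T") {
          blocks[[i - 1]]$str <- .subchar(s, nchar(s), sample(nonT, 1))
        }
      }
      if (i < length(blocks) && blocks[[i + 1]]$type == "backbone") {
        s <- blocks[[i + 1]]$str
        if (substr(s, 1, 1) == "T") {
          blocks[[i + 1]]$str <- .subchar(s, 1, sample(nonT, 1))
        }
      }
    }
  }

  # Sterile-boundary repair for planted low-complexity features: backbone
  # chance near-repeats adjacent to a run or array can chain with it into a
  # longer region than designed.  Resample the immediate surroundings until
  # no detected low-complexity interval crosses the planted boundary, so the
  # designed excision spans are exact.
  CTX <- 64L
  feat_kind <- vapply(cfg$features, `[[`, character(1), "kind")
  for (i in which(feat_kind %in% c("lcr_run", "tandem_repeat"))) {
    rows <- which(vapply(blocks, function(b) identical(b$feature, i),
                         logical(1)))
    prevb <- rows[1] - 1L; nextb <- rows[length(rows)] + 1L
    stopifnot(blocks[[prevb]]$type == "backbone",
              blocks[[nextb]]$type == "backbone")
    blens <- vapply(rows, function(r) nchar(blocks[[r]]$str), numeric(1))
    main <- which(vapply(rows, function(r)
      blocks[[r]]$type %in% c("run", "array"), logical(1)))
    if (feat_kind[i] == "tandem_repeat" && d2 + 1L >= 7L) {
      span_off <- 0L; span_len <- sum(blens) # pads chain with the array
    } else {
      span_off <- sum(blens[seq_len(main - 1)]); span_len <- blens[main]
    }
    motif <- cfg$features[[i]]$motif
    brk_letters <- setdiff(c("A", "C", "G", "T"),
                           unique(strsplit(motif, "")[[1]]))
    for (try in 1:100) {
      pstr <- blocks[[prevb]]$str; nstr <- blocks[[nextb]]$str
      test <- paste0(substr(pstr, nchar(pstr) - CTX + 1, nchar(pstr)),
                     paste(vapply(rows, function(r) blocks[[r]]$str,
                                  character(1)), collapse = ""),
                     substr(nstr, 1, CTX))
      lo <- CTX + span_off; hi <- lo + span_len
      h <- cpp_sdust_perfect(test, 64L, 2.0)
      bad <- !((h$end < lo) | (h$start > hi) |
                 (h$start >= lo & h$end <= hi))
      if (!any(bad)) break
      # resample the flanking context (and break pads for runs)
      blocks[[prevb]]$str <- paste0(substr(pstr, 1, nchar(pstr) - CTX),
                                    .rand_seq(CTX))
      blocks[[nextb]]$str <- paste0(.rand_seq(CTX),
                                    substr(nstr, CTX + 1, nchar(nstr)))
      if (feat_kind[i] == "lcr_run") {
        btypes <- vapply(rows, function(x) blocks[[x]]$type, character(1))
        for (r in rows[btypes == "break"]) {
          blocks[[r]]$str <- .rand_seq(nchar(blocks[[r]]$str), brk_letters)
        }
      } else {
        # keep T-pads; re-force non-T backbone chars next to them
        s <- blocks[[prevb]]$str
        if (substr(s, nchar(s), nchar(s)) == "T") {
          blocks[[prevb]]$str <- .subchar(s, nchar(s), sample(nonT, 1))
        }
        s <- blocks[[nextb]]$str
        if (substr(s, 1, 1) == "T") {
          blocks[[nextb]]$str <- .subchar(s, 1, sample(nonT, 1))
        }
      }
    }
  }

  # choose insertion points for sample duplications: middle of a distinct
  # backbone segment, adjacent chars forced non-T
  samp_dups <- which(vapply(cfg$features, function(f)
    f$kind == "sample_duplication", logical(1)))
  backbone_idx <- which(vapply(blocks, function(b) b$type == "backbone",
                               logical(1)))
  # use late backbone segments, far from the corresponding source loci
  ins_blocks <- rev(backbone_idx)[seq_along(samp_dups)]
  insertions <- list()
  for (j in seq_along(samp_dups)) {
    fid <- samp_dups[j]
    bi <- ins_blocks[j]
    off <- floor(nchar(blocks[[bi]]$str) / 2)
    for (p in c(off, off + 1L)) {
      if (substr(blocks[[bi]]$str, p, p) == "T") {
        blocks[[bi]]$str <- .subchar(blocks[[bi]]$str, p, sample(nonT, 1))
      }
    }
    f <- cfg$features[[fid]]
    m <- f$n_carriers
    carriers <- if (m > 0) sort(sample(cfg$n_samples, m)) else integer()
    sl <- slots[[which(vapply(slots, function(s) s$feature == fid &&
                                !is.null(s$copy_str), logical(1)))[1]]]
    insertions[[length(insertions) + 1L]] <-
      list(feature = fid, block = bi, uid = bi, off = off,
           copy_str = sl$copy_str, div_offs = sl$div_offs,
           carriers = carriers)
  }

  # stable block ids (sample-side edits remove/modify blocks by identity)
  for (i in seq_along(blocks)) blocks[[i]]$uid <- i

  # reference string and block coordinates
  strs <- vapply(blocks, `[[`, character(1), "str")
  lens <- nchar(strs)
  starts <- cumsum(c(0, lens[-length(lens)])) # 0-based
  refstr <- paste(strs, collapse = "")
  L <- nchar(refstr)
  blk_coord <- data.frame(
    type = vapply(blocks, `[[`, character(1), "type"),
    feature = vapply(blocks, function(b) as.integer(b$feature), integer(1)),
    start = starts, end = starts + lens)

  # feature table (reference coordinates of the planted loci)
  feats <- list()
  for (i in seq_along(cfg$features)) {
    f <- cfg$features[[i]]
    rows <- blk_coord[which(blk_coord$feature == i), , drop = FALSE]
    main <- rows[rows$type %in% c("locus", "run", "array"), , drop = FALSE][1, ]
    feats[[i]] <- data.frame(
      feature = i, kind = f$kind, start = main$start, end = main$end,
      divergence = if (!is.null(f$divergence)) f$divergence else 0L,
      n_carriers = if (!is.null(f$n_carriers)) f$n_carriers else 0L)
  }
  features_df <- do.call(rbind, feats)

  # pairings: designed alignment offsets for truth costs
  pairings <- list()
  add_pair <- function(lo, hi, mode, delta = NA, ctx = NULL, ctx_shift = NA,
                       scope, m = 0L, cond1, cond2, hamming) {
    pairings[[length(pairings) + 1L]] <<- list(
      lo = max(0L, as.integer(lo)), hi = as.integer(hi), mode = mode,
      delta = delta, ctx = ctx, ctx_shift = ctx_shift, scope = scope,
      m = as.integer(m), cond1 = cond1, cond2 = cond2, hamming = hamming)
  }
  for (i in seq_along(cfg$features)) {
    f <- cfg$features[[i]]
    rows <- which(blk_coord$feature == i)
    if (f$kind == "ref_duplication") {
      li <- rows[blk_coord$type[rows] == "locus"]
      ci <- rows[blk_coord$type[rows] == "locus_copy"]
      sa <- blk_coord$start[li]; sb <- blk_coord$start[ci]
      ea <- blk_coord$end[li]
      delta <- sb - sa
      add_pair(sa - k, ea, "shift", delta = delta, scope = "inherited",
               cond1 = TRUE, cond2 = TRUE, hamming = TRUE)
      add_pair(sb - k, blk_coord$end[ci], "shift", delta = -delta,
               scope = "inherited", cond1 = TRUE, cond2 = TRUE, hamming = TRUE)
    } else if (f$kind == "sample_duplication") {
      ins <- insertions[[which(vapply(insertions, function(x)
        x$feature == i, logical(1)))]]
      li <- rows[blk_coord$type[rows] == "locus"]
      sa <- blk_coord$start[li]; ea <- blk_coord$end[li]
      q <- blk_coord$start[ins$block] + ins$off # ref coord of split point
      ctx <- paste0(substr(refstr, q - k + 1, q), ins$copy_str,
                    substr(refstr, q + 1, q + k))
      # ref window [i, i+k) maps to ctx offset (i - sa) + k + g (0-based)
      add_pair(sa - k, ea, "ctx", ctx = ctx, ctx_shift = -sa + k + g,
               scope = "sample", m = length(ins$carriers),
               cond1 = FALSE, cond2 = TRUE, hamming = FALSE)
    } else if (f$kind == "tandem_repeat") {
      ai <- rows[blk_coord$type[rows] == "array"]
      as_ <- blk_coord$start[ai]; ae <- blk_coord$end[ai]
      P <- nchar(f$motif)
      deltas <- c(1:(2 * P), -(1:(2 * P)))
      if (3 * P <= ae - as_ - 1) {
        mult <- seq(3 * P, ae - as_ - 1, by = P)
        deltas <- unique(c(deltas, mult, -mult))
      }
      for (dd in deltas) {
        add_pair(as_ - k - d2 - 1, ae + d2 + 1, "shift", delta = dd,
                 scope = "inherited", cond1 = TRUE, cond2 = TRUE,
                 hamming = TRUE)
      }
    } else if (f$kind == "lcr_run") {
      # short periodic self-shifts: shifts within the search radius collapse
      # with the self hit, but the gapless mappability scan counts them, and
      # boundary windows can sit within the Hamming radius of a 1-2 bp shift
      ri <- rows[blk_coord$type[rows] == "run"]
      rs <- blk_coord$start[ri]; re <- blk_coord$end[ri]
      P <- nchar(f$motif)
      for (dd in c(1:(2 * P + 2), -(1:(2 * P + 2)))) {
        add_pair(rs - k - d2 - 1, re + d2 + 1, "shift", delta = dd,
                 scope = "inherited", cond1 = TRUE, cond2 = TRUE,
                 hamming = TRUE)
      }
    }
    # sample_deletion plants no extra designed hits
  }

  # designed low-complexity excision regions (for the strict set)
  excise <- list()
  for (i in seq_along(cfg$features)) {
    f <- cfg$features[[i]]
    rows <- which(blk_coord$feature == i)
    if (f$kind == "lcr_run") {
      ri <- rows[blk_coord$type[rows] == "run"]
      excise[[length(excise) + 1L]] <-
        data.frame(start = blk_coord$start[ri], end = blk_coord$end[ri])
    } else if (f$kind == "tandem_repeat") {
      # T-pads of length >= 7 score above the DUST threshold themselves and
      # chain with the array into one region; shorter pads do not
      ai <- rows[blk_coord$type[rows] == "array"]
      if (d2 + 1L >= 7L) {
        excise[[length(excise) + 1L]] <-
          data.frame(start = min(blk_coord$start[rows]),
                     end = max(blk_coord$end[rows]))
      } else {
        excise[[length(excise) + 1L]] <-
          data.frame(start = blk_coord$start[ai], end = blk_coord$end[ai])
      }
    }
  }
  excise_df <- if (length(excise) > 0) do.call(rbind, excise) else
    data.frame(start = numeric(), end = numeric())

  # sample assemblies: block-wise edits, then SNPs on backbone interiors
  del_feats <- which(vapply(cfg$features, function(f)
    f$kind == "sample_deletion", logical(1)))
  del_carriers <- lapply(del_feats, function(fid) {
    m <- cfg$features[[fid]]$n_carriers
    if (m > 0) sort(sample(cfg$n_samples, m)) else integer()
  })
  names(del_carriers) <- as.character(del_feats)

  samples <- vector("list", cfg$n_samples)
  for (s in seq_len(cfg$n_samples)) {
    sblocks <- blocks
    # insertions first (while ref block indices are still valid): splice the
    # guarded copy into the chosen backbone segment
    for (ins in insertions) {
      if (s %in% ins$carriers) {
        bstr <- sblocks[[ins$block]]$str
        sblocks[[ins$block]]$str <- paste0(substr(bstr, 1, ins$off),
                                           ins$copy_str,
                                           substr(bstr, ins$off + 1, nchar(bstr)))
      }
    }
    # deletions: drop the locus block for carriers
    for (j in seq_along(del_feats)) {
      if (s %in% del_carriers[[j]]) {
        fid <- del_feats[j]
        drop <- which(vapply(sblocks, function(b)
          identical(b$feature, fid) && b$type == "locus", logical(1)))
        sblocks[drop] <- NULL
      }
    }
    # SNP noise on backbone interiors only, >= k from block edges and from
    # insertion splice points
    if (cfg$snp_rate > 0) {
      for (bi in seq_along(sblocks)) {
        if (sblocks[[bi]]$type != "backbone") next
        bstr <- sblocks[[bi]]$str
        blen <- nchar(bstr)
        if (blen <= 2 * k) next
        allowed <- seq.int(k + 1L, blen - k) # 1-based within block
        uid <- sblocks[[bi]]$uid
        ins_here <- Filter(function(x) x$uid == uid, insertions)
        for (ins in ins_here) {
          splice <- ins$off + if (s %in% ins$carriers) nchar(ins$copy_str) else 0L
          bad <- allowed >= ins$off - k & allowed <= splice + k + 1L
          allowed <- allowed[!bad]
        }
        nmut <- rbinom(1, length(allowed), cfg$snp_rate)
        if (nmut > 0) {
          at <- sample(allowed, nmut)
          for (p in at) {
            orig <- substr(bstr, p, p)
            bstr <- .subchar(bstr, p, sample(setdiff(c("A", "C", "G", "T"),
                                                     orig), 1))
          }
          sblocks[[bi]]$str <- bstr
        }
      }
    }
    samples[[s]] <- paste(vapply(sblocks, `[[`, character(1), "str"),
                          collapse = "")
  }

  assemblies <- c(list(c(chr1 = refstr)),
                  lapply(samples, function(x) c(chr1 = x)))
  truth <- structure(list(
    cfg = cfg, seq_name = "chr1", ref = refstr, ref_len = L,
    features = features_df, pairings = pairings, excise = excise_df,
    guard_len = g), class = "SimTruth")
  list(collection = genome_collection(assemblies), truth = truth)
}

# evaluate one pairing's Hamming cost at window starts `pos` (0-based).
.pairing_costs <- function(truth, pr, pos, k) {
  n <- length(pos)
  costs <- rep(Inf, n)
  use <- pos >= pr$lo & pos <= pr$hi
  if (!any(use)) return(costs)
  p <- pos[use]
  a <- substring(truth$ref, p + 1, p + k)
  if (pr$mode == "shift") {
    q <- p + pr$delta
    ok <- q >= 0 & q + k <= truth$ref_len
    b <- substring(truth$ref, q + 1, q + k)
  } else {
    q <- p + pr$ctx_shift
    ok <- q >= 0 & q + k <= nchar(pr$ctx)
    b <- substring(pr$ctx, q + 1, q + k)
  }
  cc <- rep(Inf, length(p))
  idx <- which(ok)
  if (length(idx) > 0) {
    cc[idx] <- mapply(.hamming, a[idx], b[idx], USE.NAMES = FALSE)
  }
  costs[use] <- cc
  costs
}

#' Expected easy regions implied by a simulation's construction
#'
#' Computes, from the planted-feature geometry alone (designed alignment
#' offsets and Hamming costs on the constructed strings -- never the search
#' engines), which sampled k-mers must fail each sufficiency condition, and
#' assembles the implied lenient and strict region sets, including the
#' `k - 1` bp flanking erosion of every masked footprint.
#'
#' @param truth the `SimTruth` record from [simulate_pangenome()].
#' @param params a [mask_params()] object; its radii must not exceed the
#'   values the simulation was sized for.
#' @return list with `lenient`, `strict`, `masked` expected `RegionSet`s and
#'   the per-position expected verdict data.frame `verdicts`.
#' @export
expected_regions <- function(truth, params) {
  stopifnot(inherits(truth, "SimTruth"), inherits(params, "MaskParams"))
  cfg <- truth$cfg
  if (params$k != cfg$k) stop("params$k must match the simulated k")
  if (params$d2 > cfg$d2 || params$d1 > cfg$d1 || params$hamming_d > cfg$d2) {
    stop("masking radii exceed the values the simulation was sized for")
  }
  k <- params$k
  N <- cfg$n_samples + 1L
  pos <- sample_positions(truth$ref_len, k, params$w)
  n <- length(pos)
  cond1 <- logical(n); inh2 <- logical(n); ham <- logical(n)
  samp_sum <- numeric(n)
  for (pr in truth$pairings) {
    costs <- .pairing_costs(truth, pr, pos, k)
    sep <- if (pr$mode == "shift") abs(pr$delta) else Inf
    if (pr$cond1 && sep > params$d1) {
      cond1 <- cond1 | (costs <= params$d1)
    }
    if (pr$cond2 && sep > params$d2) {
      if (pr$scope == "inherited") {
        inh2 <- inh2 | (costs <= params$d2)
      } else {
        samp_sum <- samp_sum + pr$m * (costs <= params$d2)
      }
    }
    if (pr$hamming && sep >= 1) {
      ham <- ham | (costs <= params$hamming_d)
    }
  }
  cond2 <- !cond1 & (inh2 | (samp_sum >= (params$c - 1) * N))
  mappa <- !cond1 & !cond2 & ham
  status <- rep("unique", n)
  status[mappa] <- "fail_mappability"
  status[cond2] <- "fail_pan_excess"
  status[cond1] <- "fail_ref_multi"
  masked_any <- cond1 | cond2 | mappa

  lens <- c(chr1 = truth$ref_len)
  names(lens) <- truth$seq_name
  masked <- if (any(masked_any)) {
    region_set(data.frame(seq = truth$seq_name, start = pos[masked_any],
                          end = pos[masked_any] + k), seqlengths = lens)
  } else region_set(NULL, seqlengths = lens)
  covered <- region_set(data.frame(seq = truth$seq_name, start = 0,
                                   end = truth$ref_len), seqlengths = lens)
  lenient <- regions_filter_min_length(regions_subtract(covered, masked),
                                       params$min_region_len)
  exc <- truth$excise
  exc <- exc[(exc$end - exc$start) > params$lcr_max_len, , drop = FALSE]
  strict <- if (nrow(exc) > 0) {
    excr <- region_set(data.frame(seq = truth$seq_name, start = exc$start,
                                  end = exc$end), seqlengths = lens)
    regions_filter_min_length(regions_subtract(lenient, excr),
                              params$min_region_len)
  } else lenient
  verdicts <- data.frame(seq = truth$seq_name, position = pos, status = status)
  list(lenient = lenient, strict = strict, masked = masked,
       verdicts = verdicts)
}

#' Expected verdict class per planted feature
#'
#' @param truth `SimTruth` from [simulate_pangenome()].
#' @param params a [mask_params()] object.
#' @return data.frame of features with an `expected_class` column
#'   (`masked_by_cond1`, `masked_by_cond2`, `masked_by_lcr`, `easy`).
#' @export
truth_classes <- function(truth, params) {
  cfg <- truth$cfg
  N <- cfg$n_samples + 1L
  cls <- character(nrow(truth$features))
  for (i in seq_len(nrow(truth$features))) {
    f <- truth$features[i, ]
    cls[i] <- switch(f$kind,
      ref_duplication = if (f$divergence <= params$d1) "masked_by_cond1"
                        else if (f$divergence <= params$d2) "masked_by_cond2"
                        else "easy",
      sample_duplication = if (f$n_carriers >= (params$c - 1) * N)
                             "masked_by_cond2" else "easy",
      tandem_repeat = "masked_by_cond1",
      lcr_run = if ((f$end - f$start) > params$lcr_max_len) "masked_by_lcr"
                else "easy",
      sample_deletion = "easy")
  }
  cbind(truth$features, expected_class = cls)
}

#' Write a simulated pangenome to disk
#'
#' Writes `ref.fa`, `samples/sample_NN.fa`, a `truth.tsv` feature table and
#' `expected.lenient.bed` / `expected.strict.bed` for the given parameters.
#'
#' @param sim result of [simulate_pangenome()].
#' @param dir output directory (created if needed).
#' @param params a [mask_params()] object used for the expected BED files;
#'   defaults to [sim_params()] of the simulation's configuration.
#' @return `dir`, invisibly.
#' @export
write_pangenome <- function(sim, dir, params = sim_params(sim$truth$cfg)) {
  dir.create(file.path(dir, "samples"), recursive = TRUE, showWarnings = FALSE)
  write_fasta(sim$collection$assemblies[[1]], file.path(dir, "ref.fa"))
  for (s in seq_along(sim$collection$assemblies)[-1]) {
    write_fasta(sim$collection$assemblies[[s]],
                file.path(dir, "samples", sprintf("sample_%02d.fa", s - 1)))
  }
  utils::write.table(truth_classes(sim$truth, params),
                     file.path(dir, "truth.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  exp <- expected_regions(sim$truth, params)
  write_bed(exp$lenient, file.path(dir, "expected.lenient.bed"))
  write_bed(exp$strict, file.path(dir, "expected.strict.bed"))
  invisible(dir)
}
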