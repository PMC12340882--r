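# Independent oracles and small generators used across the suite.

DNA <- c("A", "C", "G", "T")

rand_dna <- function(n, letters = DNA) {
  paste(sample(letters, n, replace = TRUE), collapse = "")
}

# --- per-base bitmap oracle for interval algebra -----------------------------

# a region set as a list of logical per-base vectors, one per sequence
bitmap_from_df <- function(df, lens) {
  bm <- lapply(lens, function(L) rep(FALSE, L))
  names(bm) <- names(lens)
  for (i in seq_len(nrow(df))) {
    s <- df$seq[i]
    bm[[s]][(df$start[i] + 1):df$end[i]] <- TRUE
  }
  bm
}

bitmap_from_regions <- function(r, lens) bitmap_from_df(r$intervals, lens)

df_from_bitmap <- function(bm) {
  out <- list()
  for (s in names(bm)) {
    v <- bm[[s]]
    if (!any(v)) next
    r <- rle(v)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- r$values
    out[[length(out) + 1L]] <- data.frame(seq = s,
                                          start = as.numeric(starts[keep]),
                                          end = as.numeric(ends[keep]))
  }
  if (length(out) == 0) {
    return(data.frame(seq = character(), start = numeric(), end = numeric()))
  }
  df <- do.call(rbind, out)
  df <- df[order(df$seq, df$start), , drop = FALSE]
  rownames(df) <- NULL
  df
}

rand_interval_df <- function(n, lens) {
  seqs <- sample(names(lens), n, replace = TRUE)
  starts <- vapply(seqs, function(s) sample.int(lens[[s]] - 1, 1) - 1,
                   numeric(1))
  widths <- vapply(seq_len(n), function(i)
    sample.int(min(200, lens[[seqs[i]]] - starts[i]), 1), numeric(1))
  data.frame(seq = seqs, start = starts, end = starts + widths)
}

expect_regions_equal_bitmap <- function(r, bm) {
  expect_identical(r$intervals[, c("seq", "start", "end")], df_from_bitmap(bm))
}

# --- naive per-start edit-distance oracle (tiny inputs only) -----------------

# min over end >= start of Levenshtein(query, text[start:end]); full DP.
naive_start_dist <- function(query, text, start) { # start 0-based
  q <- strsplit(query, "")[[1]]
  t <- strsplit(substr(text, start + 1, nchar(text)), "")[[1]]
  m <- length(q); n <- length(t)
  D <- matrix(0L, m + 1, n + 1)
  D[, 1] <- 0:m
  D[1, ] <- 0:n
  for (i in seq_len(m)) {
    for (j in seq_len(n)) {
      D[i + 1, j + 1] <- min(D[i, j] + (q[i] != t[j]),
                             D[i, j + 1] + 1L, D[i + 1, j] + 1L)
    }
  }
  min(D[m + 1, ])
}

naive_hits <- function(query, text, max_d) {
  L <- nchar(text)
  starts <- integer(); dists <- integer()
  for (s in 0:(L - 1)) {
    d <- naive_start_dist(query, text, s)
    if (d <= max_d) { starts <- c(starts, s); dists <- c(dists, d) }
  }
  data.frame(start = starts, dist = dists)
}

# --- brute-force symmetric DUST oracle ---------------------------------------

# literal evaluation: score every interval of length 3..window, apply the
# perfect-interval definition, then drop intervals properly contained in a
# reported one (containers processed first).
brute_sdust <- function(seq, window = 64, threshold = 2.0) {
  L <- nchar(seq)
  empty <- data.frame(start = numeric(), end = numeric(), score = numeric())
  if (L < 3) return(empty)
  stopifnot(!grepl("[^ACGT]", seq))
  tri <- substring(seq, 1:(L - 2), 3:L)
  # score[i, len] via incremental triplet counts
  score <- matrix(NA_real_, L, window)
  for (i in 1:(L - 2)) {
    cnt <- integer(0)
    maxlen <- min(window, L - i + 1)
    for (len in 3:maxlen) {
      tr <- tri[i + len - 3]
      cnt[tr] <- if (is.na(cnt[tr])) 1L else cnt[tr] + 1L
      n <- len - 2
      r <- sum(cnt * (cnt - 1) / 2, na.rm = TRUE)
      score[i, len] <- if (n == 1) 0 else r / (n - 1)
    }
  }
  # max score over subintervals (including self)
  maxall <- score
  if (window >= 4) {
    for (len in 4:window) {
      for (i in 1:L) {
        if (i + len - 1 > L) next
        maxall[i, len] <- max(score[i, len], maxall[i, len - 1],
                              maxall[i + 1, len - 1], na.rm = TRUE)
      }
    }
  }
  cands <- list()
  for (i in 1:(L - 2)) {
    for (len in 3:min(window, L - i + 1)) {
      sc <- score[i, len]
      if (is.na(sc) || sc <= threshold) next
      sub <- if (len == 3) -Inf else suppressWarnings(
        max(maxall[i, len - 1], maxall[i + 1, len - 1], na.rm = TRUE))
      if (sub > sc) next
      cands[[length(cands) + 1L]] <- c(i - 1, i - 1 + len, sc) # 0-based
    }
  }
  if (length(cands) == 0) return(empty)
  cd <- do.call(rbind, cands)
  cd <- cd[order(-(cd[, 2] - cd[, 1]), cd[, 1]), , drop = FALSE]
  rep_iv <- matrix(numeric(0), ncol = 3)
  for (i in seq_len(nrow(cd))) {
    x <- cd[i, ]
    contained <- any(rep_iv[, 1] <= x[1] & rep_iv[, 2] >= x[2] &
                       !(rep_iv[, 1] == x[1] & rep_iv[, 2] == x[2]))
    if (!contained) rep_iv <- rbind(rep_iv, x)
  }
  df <- data.frame(start = rep_iv[, 1], end = rep_iv[, 2], score = rep_iv[, 3])
  df <- df[order(df$start, -df$end), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# N-splitting wrapper matching perfect_intervals' contract
brute_sdust_n <- function(seq, window = 64, threshold = 2.0) {
  runs <- gregexpr("[ACGT]+", seq)[[1]]
  out <- list()
  if (runs[1] != -1) {
    lens <- attr(runs, "match.length")
    for (i in seq_along(runs)) {
      sub <- substr(seq, runs[i], runs[i] + lens[i] - 1)
      h <- brute_sdust(sub, window, threshold)
      if (nrow(h) > 0) {
        h$start <- h$start + runs[i] - 1
        h$end <- h$end + runs[i] - 1
        out[[length(out) + 1L]] <- h
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

# small helper: a single-assembly collection from one sequence
coll1 <- function(seq, name = "s") {
  x <- c(seq); names(x) <- name
  genome_collection(list(x))
}
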