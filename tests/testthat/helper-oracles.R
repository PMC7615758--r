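# Independent oracles used to validate the alignment and RSS scanning code.
# They share no code path with the package internals: the alignment oracle is
# a top-down exhaustive recursion over the affine-gap alignment space (with
# memoisation; a memo-free pure enumeration cross-checks it on tiny strings),
# and the RSS oracle evaluates every window position directly.

# ---- alignment score oracle -------------------------------------------------

# states: 1 = last column was a substitution, 2 = gap in `a`, 3 = gap in `b`
oracle_align_score <- function(a, b, type = c("local", "global"),
                               match, mismatch, gap_open, gap_ext) {
  type <- match.arg(type)
  av <- strsplit(a, "")[[1L]]
  bv <- strsplit(b, "")[[1L]]
  n <- length(av); m <- length(bv)
  NEG <- -1e9
  memo <- array(NA_real_, dim = c(n + 1L, m + 1L, 3L))
  rec <- function(i, j, st) {
    if (!is.na(memo[i + 1L, j + 1L, st])) return(memo[i + 1L, j + 1L, st])
    val <- if (i == 0L && j == 0L) {
      if (st == 1L) 0 else NEG
    } else if (st == 1L) {
      if (i == 0L || j == 0L) NEG else {
        s <- if (av[i] == bv[j]) match else mismatch
        s + max(rec(i - 1L, j - 1L, 1L), rec(i - 1L, j - 1L, 2L), rec(i - 1L, j - 1L, 3L))
      }
    } else if (st == 2L) {            # consume b[j], gap in a
      if (j == 0L) NEG else {
        max(rec(i, j - 1L, 1L) - gap_open - gap_ext,
            rec(i, j - 1L, 2L) - gap_ext,
            rec(i, j - 1L, 3L) - gap_open - gap_ext)
      }
    } else {                          # consume a[i], gap in b
      if (i == 0L) NEG else {
        max(rec(i - 1L, j, 1L) - gap_open - gap_ext,
            rec(i - 1L, j, 3L) - gap_ext,
            rec(i - 1L, j, 2L) - gap_open - gap_ext)
      }
    }
    memo[i + 1L, j + 1L, st] <<- val
    val
  }
  if (type == "global") {
    return(max(rec(n, m, 1L), rec(n, m, 2L), rec(n, m, 3L)))
  }
  # local: free start (max with 0 before a substitution column), best over
  # all end cells ending in a substitution column
  memo2 <- array(NA_real_, dim = c(n + 1L, m + 1L, 3L))
  rec2 <- function(i, j, st) {
    if (!is.na(memo2[i + 1L, j + 1L, st])) return(memo2[i + 1L, j + 1L, st])
    val <- if (st == 1L) {
      if (i == 0L || j == 0L) NEG else {
        s <- if (av[i] == bv[j]) match else mismatch
        s + max(0, rec2(i - 1L, j - 1L, 1L), rec2(i - 1L, j - 1L, 2L), rec2(i - 1L, j - 1L, 3L))
      }
    } else if (st == 2L) {
      if (j == 0L) NEG else {
        max(rec2(i, j - 1L, 1L) - gap_open - gap_ext,
            rec2(i, j - 1L, 2L) - gap_ext)
      }
    } else {
      if (i == 0L) NEG else {
        max(rec2(i - 1L, j, 1L) - gap_open - gap_ext,
            rec2(i - 1L, j, 3L) - gap_ext)
      }
    }
    memo2[i + 1L, j + 1L, st] <<- val
    val
  }
  best <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      v <- rec2(i, j, 1L)
      if (v > best) best <- v
    }
  }
  best
}

# memo-free pure enumeration of all global alignments (tiny strings only)
enum_global_score <- function(a, b, match, mismatch, gap_open, gap_ext) {
  av <- strsplit(a, "")[[1L]]
  bv <- strsplit(b, "")[[1L]]
  go <- function(i, j, prev) {
    if (i == 0L && j == 0L) return(0)
    best <- -Inf
    if (i > 0L && j > 0L) {
      s <- if (av[i] == bv[j]) match else mismatch
      best <- max(best, s + go(i - 1L, j - 1L, 1L))
    }
    if (j > 0L) {
      pen <- if (prev == 2L) gap_ext else gap_open + gap_ext
      best <- max(best, go(i, j - 1L, 2L) - pen)
    }
    if (i > 0L) {
      pen <- if (prev == 3L) gap_ext else gap_open + gap_ext
      best <- max(best, go(i - 1L, j, 3L) - pen)
    }
    best
  }
  go(length(av), length(bv), 0L)
}

# memo-free local score by enumerating all substring pairs
enum_local_score <- function(a, b, match, mismatch, gap_open, gap_ext) {
  best <- 0
  na <- nchar(a); nb <- nchar(b)
  for (i1 in seq_len(na)) for (i2 in i1:na) {
    for (j1 in seq_len(nb)) for (j2 in j1:nb) {
      v <- enum_global_score(substr(a, i1, i2), substr(b, j1, j2),
                             match, mismatch, gap_open, gap_ext)
      if (v > best) best <- v
    }
  }
  best
}

oracle_local <- function(a, b) oracle_align_score(a, b, "local", 2, -3, 5, 2)
oracle_global <- function(a, b) oracle_align_score(a, b, "global", 1, -1, 4, 1)

# ---- RSS sliding-window oracle ----------------------------------------------

# evaluates every position of one strand directly; no anchor prefilter
oracle_rss_strand <- function(s, spacer_class, min_score, tol = 1L) {
  ch <- strsplit(s, "")[[1L]]
  L <- length(ch)
  hept <- strsplit("CACAGTG", "")[[1L]]
  nona <- strsplit("ACAAAAACC", "")[[1L]]
  w_h <- c(0, 0, 0, 3, 2, 1, 1)   # CAC handled as a hard requirement
  w_n <- c(1, 2, 2, 3, 3, 3, 2, 1, 1)
  out <- list()
  for (sl in (spacer_class - tol):(spacer_class + tol)) {
    wlen <- 16L + sl
    for (p in seq_len(max(0L, L - wlen + 1L))) {
      if (ch[p] != "C" || ch[p + 1L] != "A" || ch[p + 2L] != "C") next
      hseg <- ch[p:(p + 6L)]
      nseg <- ch[(p + 7L + sl):(p + wlen - 1L)]
      mw <- sum(w_h[hseg == hept]) + sum(w_n[nseg == nona])
      sc <- mw / 25
      if (sc >= min_score) {
        out[[length(out) + 1L]] <- data.frame(
          start = p, end = p + wlen - 1L, spacer_len = sl, score = sc,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(start = integer(), end = integer(),
                      spacer_len = integer(), score = numeric()))
  }
  do.call(rbind, out)
}

# both strands on plus coordinates, with the same best-score overlap
# resolution contract the scanner documents
oracle_rss_scan <- function(s, spacer_class, min_score, tol = 1L) {
  L <- nchar(s)
  fwd <- oracle_rss_strand(s, spacer_class, min_score, tol)
  fwd$strand <- rep("+", nrow(fwd))
  rc <- paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1L]]), collapse = "")
  rev <- oracle_rss_strand(rc, spacer_class, min_score, tol)
  rev$strand <- rep("-", nrow(rev))
  if (nrow(rev) > 0) {
    ns <- L - rev$end + 1L
    rev$end <- L - rev$start + 1L
    rev$start <- ns
  }
  hits <- rbind(fwd, rev)
  if (nrow(hits) == 0L) return(hits)
  ord <- order(-hits$score, abs(hits$spacer_len - spacer_class), hits$start)
  hits <- hits[ord, , drop = FALSE]
  keep <- rep(TRUE, nrow(hits))
  for (str in c("+", "-")) {
    idx <- which(hits$strand == str)
    ts <- integer(0); te <- integer(0)
    for (i in idx) {
      if (any(hits$start[i] <= te & hits$end[i] >= ts)) keep[i] <- FALSE
      else { ts <- c(ts, hits$start[i]); te <- c(te, hits$end[i]) }
    }
  }
  hits <- hits[keep, , drop = FALSE]
  hits[order(hits$start, hits$strand), , drop = FALSE]
}

# ---- misc helpers ------------------------------------------------------------

rnd_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

consensus_rss <- function(spacer_class, spacer = NULL) {
  if (is.null(spacer)) spacer <- rnd_dna(spacer_class)
  paste0("CACAGTG", spacer, "ACAAAAACC")
}
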