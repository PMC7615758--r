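#' @name rss
#' @title Recombination signal sequence (RSS) detection
#'
#' @description
#' V(D)J-recombining gene segments are flanked by recombination signal
#' sequences: a conserved heptamer (consensus `CACAGTG`) and nonamer
#' (consensus `ACAAAAACC`) separated by a spacer of roughly 12 or 23 bp (the
#' 12/23 rule governs which segments can join). Detection here uses
#' consensus-weighted scoring: the first three heptamer bases (`CAC`) are
#' functionally obligatory and must match exactly for any hit; the remaining
#' heptamer positions (`AGTG`) carry weights 3,2,1,1 and the nonamer positions
#' weights 1,2,2,3,3,3,2,1,1 (emphasising the poly-A tract). The score of a
#' window is the matched weight divided by the total weight (25), so 1.0 means
#' exact consensus. `N` never matches. Spacers are allowed to deviate from the
#' canonical length by one base.
NULL

rss_heptamer <- "CACAGTG"
rss_nonamer <- "ACAAAAACC"
rss_hept_w <- c(3, 2, 1, 1)          # weights for AGTG (positions 4-7)
rss_nona_w <- c(1, 2, 2, 3, 3, 3, 2, 1, 1)
rss_total_w <- sum(rss_hept_w) + sum(rss_nona_w)

#' Score one candidate RSS window
#'
#' @param seq Nucleotide string (plus strand of the scanned sequence).
#' @param offset 1-based position of the first heptamer base.
#' @param spacer_class 12 or 23.
#' @param spacer_len Actual spacer length to evaluate.
#' @return A one-row data.frame describing the hit, or `NULL` if the window
#'   does not fit, the `CAC` anchor is broken, or the score is below
#'   `min_score`.
#' @param min_score Minimum weighted score in (0, 1].
#' @export
score_rss_window <- function(seq, offset, spacer_class, spacer_len,
                             min_score = 0.70) {
  wlen <- 7L + spacer_len + 9L
  if (offset < 1L || offset + wlen - 1L > nchar(seq)) return(NULL)
  hept <- substr(seq, offset, offset + 6L)
  if (substr(hept, 1L, 3L) != "CAC") return(NULL)
  nona <- substr(seq, offset + 7L + spacer_len, offset + wlen - 1L)
  hm <- strsplit(substr(hept, 4L, 7L), "")[[1L]] == strsplit("AGTG", "")[[1L]]
  nm <- strsplit(nona, "")[[1L]] == strsplit(rss_nonamer, "")[[1L]]
  score <- (sum(rss_hept_w[hm]) + sum(rss_nona_w[nm])) / rss_total_w
  if (score < min_score) return(NULL)
  data.frame(
    seq_id = NA_character_, start = offset, end = offset + wlen - 1L,
    strand = "+", spacer_class = spacer_class, spacer_len = spacer_len,
    heptamer_mismatches = sum(!hm), nonamer_mismatches = sum(!nm),
    score = score, stringsAsFactors = FALSE
  )
}

# Vectorized plus-strand scan of one string; returns hit table.
scan_rss_strand <- function(s, spacer_class, min_score, spacer_tolerance) {
  L <- nchar(s)
  hits <- list()
  anchors <- gregexpr("(?=CAC)", s, perl = TRUE)[[1L]]  # overlapping occurrences
  if (anchors[1L] == -1L) return(empty_rss())
  anchors <- as.integer(anchors)
  hept_tail_cons <- c("A", "G", "T", "G")
  nona_cons <- strsplit(rss_nonamer, "")[[1L]]
  for (sl in (spacer_class - spacer_tolerance):(spacer_class + spacer_tolerance)) {
    wlen <- 16L + sl
    p <- anchors[anchors + wlen - 1L <= L]
    if (length(p) == 0L) next
    mw <- numeric(length(p))
    hmis <- integer(length(p))
    nmis <- integer(length(p))
    for (k in 1:4) {
      ok <- substring(s, p + 2L + k, p + 2L + k) == hept_tail_cons[k]
      mw <- mw + rss_hept_w[k] * ok
      hmis <- hmis + !ok
    }
    for (k in 1:9) {
      ok <- substring(s, p + 6L + sl + k, p + 6L + sl + k) == nona_cons[k]
      mw <- mw + rss_nona_w[k] * ok
      nmis <- nmis + !ok
    }
    sc <- mw / rss_total_w
    keep <- sc >= min_score
    if (any(keep)) {
      hits[[length(hits) + 1L]] <- data.frame(
        start = p[keep], end = p[keep] + wlen - 1L, strand = "+",
        spacer_class = spacer_class, spacer_len = sl,
        heptamer_mismatches = hmis[keep], nonamer_mismatches = nmis[keep],
        score = sc[keep], stringsAsFactors = FALSE
      )
    }
  }
  if (length(hits) == 0L) return(empty_rss())
  cbind(seq_id = NA_character_, do.call(rbind, hits), stringsAsFactors = FALSE)
}

empty_rss <- function() {
  data.frame(
    seq_id = character(), start = integer(), end = integer(),
    strand = character(), spacer_class = integer(), spacer_len = integer(),
    heptamer_mismatches = integer(), nonamer_mismatches = integer(),
    score = numeric(), stringsAsFactors = FALSE
  )
}

#' Scan a sequence for RSS motifs on both strands
#'
#' Finds all heptamer-spacer-nonamer windows of the requested spacer class
#' (spacer length within `spacer_tolerance` of the canonical 12 or 23) whose
#' weighted consensus score reaches `min_score`. Minus-strand hits are
#' reported on plus-strand coordinates with `strand = "-"`. Overlapping
#' same-strand hits are resolved to the best-scoring one (ties: spacer length
#' closer to canonical, then leftmost).
#'
#' @param genome `DNAStringSet`, named character vector, or single string.
#' @param spacer_class 12 or 23.
#' @param min_score Minimum weighted score in (0, 1]; default 0.70.
#' @param spacer_tolerance Allowed deviation from the canonical spacer
#'   length, default 1.
#' @param seq_id Which record of `genome` to scan (default: first).
#' @return Hit table: one row per RSS with interval, spacer class/length,
#'   motif mismatch counts and score.
#' @export
scan_rss <- function(genome, spacer_class, min_score = 0.70,
                     spacer_tolerance = 1L, seq_id = NULL) {
  stopifnot(spacer_class %in% c(12L, 23L), min_score > 0, min_score <= 1)
  s <- genome_string(genome, seq_id)
  if (is.null(seq_id)) {
    seq_id <- if (methods::is(genome, "XStringSet")) names(genome)[1L] else "seq1"
    if (is.null(seq_id) || is.na(seq_id)) seq_id <- "seq1"
  }
  L <- nchar(s)
  if (L < 16L + spacer_class - spacer_tolerance) return(empty_rss())
  fwd <- scan_rss_strand(s, spacer_class, min_score, spacer_tolerance)
  rev <- scan_rss_strand(reverse_complement(s), spacer_class, min_score, spacer_tolerance)
  if (nrow(rev) > 0) {
    new_start <- L - rev$end + 1L
    rev$end <- L - rev$start + 1L
    rev$start <- new_start
    rev$strand <- "-"
  }
  hits <- rbind(fwd, rev)
  if (nrow(hits) == 0L) return(hits)
  hits$seq_id <- seq_id
  # resolve overlapping same-strand hits: best score, canonical spacer, leftmost
  ord <- order(-hits$score, abs(hits$spacer_len - hits$spacer_class), hits$start)
  hits <- hits[ord, , drop = FALSE]
  keep <- rep(TRUE, nrow(hits))
  for (str in c("+", "-")) {
    idx <- which(hits$strand == str)
    taken_s <- integer(0); taken_e <- integer(0)
    for (i in idx) {
      if (any(hits$start[i] <= taken_e & hits$end[i] >= taken_s)) {
        keep[i] <- FALSE
      } else {
        taken_s <- c(taken_s, hits$start[i])
        taken_e <- c(taken_e, hits$end[i])
      }
    }
  }
  hits <- hits[keep, , drop = FALSE]
  hits <- hits[order(hits$start, hits$strand), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Pair RSS hits flanking putative D segments
#'
#' A D gene segment carries an RSS on both sides, heptamers abutting the
#' coding core. On plus-strand coordinates that geometry is a minus-strand
#' hit (heptamer at its right edge) followed by a plus-strand hit (heptamer
#' at its left edge), with the core in between. The default layout expects a
#' 12-bp-spacer RSS on both sides (IgH-like); `"12/23"` accepts one 12 and
#' one 23 spacer in either order (TRD-like).
#'
#' @param hits RSS hit table from [scan_rss()] (concatenate the 12 and 23
#'   scans when using the 12/23 layout).
#' @param max_d_core Maximum core length in bp (default 40); minimum is 3.
#' @param layout `"12/12"` or `"12/23"`.
#' @return Data frame of candidate flank pairs with the enclosed core
#'   interval (`core_start`, `core_end`) and both flank descriptions.
#' @export
pair_rss_for_d <- function(hits, max_d_core = 40L, layout = c("12/12", "12/23")) {
  layout <- match.arg(layout)
  if (nrow(hits) == 0L) return(empty_d_pairs())
  up <- hits[hits$strand == "-", , drop = FALSE]    # heptamer right edge, core to the right
  dn <- hits[hits$strand == "+", , drop = FALSE]    # heptamer left edge, core to the left
  out <- list()
  for (i in seq_len(nrow(up))) {
    core_start <- up$end[i] + 1L
    cand <- which(dn$start >= core_start + 3L & dn$start <= core_start + max_d_core)
    for (j in cand) {
      cls <- c(up$spacer_class[i], dn$spacer_class[j])
      ok <- if (layout == "12/12") all(cls == 12L) else setequal(cls, c(12L, 23L))
      if (!ok) next
      out[[length(out) + 1L]] <- data.frame(
        seq_id = up$seq_id[i],
        core_start = core_start, core_end = dn$start[j] - 1L,
        up_start = up$start[i], up_end = up$end[i], up_class = up$spacer_class[i],
        up_score = up$score[i],
        down_start = dn$start[j], down_end = dn$end[j], down_class = dn$spacer_class[j],
        down_score = dn$score[j],
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(out) == 0L) return(empty_d_pairs())
  res <- do.call(rbind, out)
  res <- res[order(res$core_start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

empty_d_pairs <- function() {
  data.frame(
    seq_id = character(), core_start = integer(), core_end = integer(),
    up_start = integer(), up_end = integer(), up_class = integer(), up_score = numeric(),
    down_start = integer(), down_end = integer(), down_class = integer(),
    down_score = numeric(), stringsAsFactors = FALSE
  )
}
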