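#' @name segment_annotation
#' @title V, J and C gene-segment annotation
#'
#' @description
#' Germline segments are located by three evidence routes: homology to known
#' sequences ([find_homologous_segments()]), conserved amino-acid landmarks
#' (the Ig/TCR framework cysteines and the J-segment `[FW]GxG` motif), and
#' flanking RSS motifs ([scan_rss()]). V candidates are split into ordinary V
#' genes (downstream 23-spacer RSS, awaiting recombination) and germline-joined
#' Vj genes (J motif already in frame, no RSS); platypus-style V genes are
#' subtyped Vmu1/Vmu2 by the presence or absence of downstream D segments.
NULL

#' Locate framework cysteine landmarks in a V-like sequence
#'
#' Scans all three frames for the canonical V-domain landmarks: a first
#' cysteine (FR1) followed 55-80 codons later by the second cysteine (FR3),
#' preferring frames in which a tryptophan sits 10-20 codons after the first
#' cysteine.
#'
#' @param seq Oriented nucleotide string of the candidate V.
#' @return List with `frame` (0-2), codon indices `cys1`, `cys2`, `trp`
#'   (NA when absent), and nt coordinates `fr_start`, `fr_end` (1-based,
#'   inclusive, within `seq`) of the FR1-FR3 span; or `NULL` when no landmark
#'   pair exists.
#' @export
v_landmarks <- function(seq) {
  best <- NULL
  for (f in 0:2) {
    aa <- strsplit(translate_nt(seq, f), "")[[1L]]
    if (length(aa) < 60L) next
    cys <- which(aa == "C")
    c1s <- cys[cys >= 5L & cys <= 45L]
    for (c1 in c1s) {
      c2s <- cys[cys - c1 >= 55L & cys - c1 <= 80L]
      if (length(c2s) == 0L) next
      c2 <- c2s[[1L]]
      trp <- which(aa == "W")
      trp <- trp[trp - c1 >= 10L & trp - c1 <= 20L]
      hit <- list(
        frame = f, cys1 = c1, cys2 = c2,
        trp = if (length(trp)) trp[[1L]] else NA_integer_,
        fr_start = f + (c1 - 1L) * 3L + 1L,
        fr_end = f + c2 * 3L
      )
      if (!is.na(hit$trp)) return(hit)       # landmark triple: take it
      if (is.null(best)) best <- hit
    }
  }
  best
}

# Does the candidate carry a J motif ([FW]GxG) in its 3' tail (last ~35
# codons, any frame)? Germline-joined Vj signature; ordinary V genes with a
# chance tail motif are still rescued by their downstream RSS.
has_joined_j_motif <- function(seq, lm = NULL) {
  n <- nchar(seq)
  tail_nt <- substr(seq, max(1L, n - 105L), n)
  for (f in 0:2) {
    if (grepl("[FW]G.G", translate_nt(tail_nt, f))) return(TRUE)
  }
  FALSE
}

#' Annotate J gene segments from RSS hits and the [FW]GxG motif
#'
#' A J candidate is the interval immediately on the heptamer side of an RSS
#' (the side the RSS points into), whose translation in some frame contains
#' the canonical J motif `[FW]GxG` within the first 40 bp, stop-free from the
#' RSS boundary through the motif, and which ends at a `GT` splice donor
#' within 30 bp of the motif (J segments are short, with the motif near
#' their 3' end). Evidence is `motif,rss`.
#'
#' @param genome Genome sequence.
#' @param rss_hits Hit table from [scan_rss()] (any spacer class).
#' @param search_intervals Optional data.frame with `start`,`end` columns;
#'   candidates must start within one of them.
#' @param seq_id Genome record id.
#' @param min_rss_score J calling demands a convincing RSS (default 0.80;
#'   random sequence produces about one >= 0.80 hit per 50 kb and strand).
#' @return Segment table of J candidates (column `rss_score` records the
#'   supporting RSS score). Overlapping candidates are resolved to the one
#'   with the best RSS.
#' @export
annotate_j <- function(genome, rss_hits, search_intervals = NULL, seq_id = NULL,
                       min_rss_score = 0.80) {
  s <- genome_string(genome, seq_id)
  if (is.null(seq_id)) {
    seq_id <- if (methods::is(genome, "XStringSet")) names(genome)[1L] else "seq1"
    if (is.null(seq_id) || is.na(seq_id)) seq_id <- "seq1"
  }
  L <- nchar(s)
  out <- list()
  for (i in seq_len(nrow(rss_hits))) {
    h <- rss_hits[i, ]
    if (h$score < min_rss_score) next
    if (h$strand == "-") {
      # segment to the right, plus orientation
      ws <- h$end + 1L
      we <- min(L, h$end + 150L)
      if (ws > we) next
      w <- substr(s, ws, we)
      strand <- "+"
    } else {
      we <- h$start - 1L
      ws <- max(1L, h$start - 150L)
      if (ws > we) next
      w <- reverse_complement(substr(s, ws, we))
      strand <- "-"
    }
    cand <- find_j_in_window(w)
    if (is.null(cand)) next
    if (strand == "+") {
      gs <- ws
      ge <- ws + cand$end - 1L
    } else {
      ge <- we
      gs <- we - cand$end + 1L
    }
    if (!is.null(search_intervals) && nrow(search_intervals) > 0) {
      if (!any(gs >= search_intervals$start & gs <= search_intervals$end)) next
    }
    row <- new_segments(
      segment_id = NA_character_, seq_id = seq_id, start = gs, end = ge,
      strand = strand, kind = "J", subtype = "none", evidence = "motif,rss",
      best_identity = NA_real_, best_query = NA_character_, pseudogene = FALSE,
      cluster_index = NA_integer_, ordinal = NA_integer_
    )
    row$rss_score <- h$score
    out[[length(out) + 1L]] <- row
  }
  if (length(out) == 0L) {
    res <- empty_segments()
    res$rss_score <- numeric(0)
    return(res)
  }
  res <- do.call(rbind, out)
  # overlapping candidates (e.g. near-duplicate RSS windows): keep best RSS
  res <- res[order(-res$rss_score, res$start), , drop = FALSE]
  keep <- rep(TRUE, nrow(res))
  for (i in seq_len(nrow(res))[-1L]) {
    prev <- which(keep[seq_len(i - 1L)])
    if (any(res$start[i] <= res$end[prev] & res$end[i] >= res$start[prev])) keep[i] <- FALSE
  }
  res <- res[keep, , drop = FALSE]
  res <- res[order(res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# J detector on an oriented window starting right after the RSS heptamer.
# The J coding span must be translatable: the frame carrying the [FW]GxG
# motif may not contain a stop codon upstream of it.
# Returns list(end = last coding base before the GT donor) or NULL.
find_j_in_window <- function(w, motif_within = 40L, donor_within = 30L) {
  for (f in 0:2) {
    aa <- translate_nt(w, f)
    m <- regexpr("[FW]G.G", aa)
    if (m[[1L]] == -1L) next
    motif_nt_start <- f + (as.integer(m) - 1L) * 3L + 1L
    if (motif_nt_start > motif_within) next
    if (grepl("*", substr(aa, 1L, as.integer(m) + 3L), fixed = TRUE)) next
    motif_nt_end <- motif_nt_start + 11L
    tail_start <- motif_nt_end + 1L
    tail <- substr(w, tail_start, min(nchar(w), motif_nt_end + donor_within))
    gt <- regexpr("GT", tail, fixed = TRUE)
    if (gt[[1L]] == -1L) next
    return(list(end = tail_start + as.integer(gt) - 2L))
  }
  NULL
}

#' Flag a segment as a presumptive pseudogene
#'
#' TRUE when every reading frame of the segment's span contains a stop codon,
#' or when the alignment to its best homology query contains a frameshifting
#' indel (gap length not divisible by 3).
#'
#' @param segment One-row segment table (kind V, Vj or C).
#' @param genome Genome sequence.
#' @param query Optional nucleotide string of the segment's best homology
#'   query, enabling the frameshift rule.
#' @return Logical.
#' @export
flag_pseudogene <- function(segment, genome, query = NULL) {
  cs <- seq_extract(genome, segment$seq_id, segment$start, segment$end, segment$strand)
  stop_free <- vapply(0:2, function(f) {
    !grepl("*", translate_nt(cs, f), fixed = TRUE)
  }, logical(1))
  if (!any(stop_free)) return(TRUE)
  if (!is.null(query)) {
    al <- local_align(query, cs)
    gaps <- c(
      attr(gregexpr("-+", al$aligned_query)[[1L]], "match.length"),
      attr(gregexpr("-+", al$aligned_target)[[1L]], "match.length")
    )
    gaps <- gaps[gaps > 0L]
    if (any(gaps %% 3L != 0L)) return(TRUE)
  }
  FALSE
}

#' Subtype a V gene as Vmu1-like or Vmu2-like
#'
#' Vmu1 genes recombine with D segments; Vmu2 genes join J directly. The call
#' is `Vmu1` when at least one D candidate lies 3' of the V before the next
#' V/J/C segment. A V in cluster context with no such D is `Vmu2`. For an
#' isolated V (no neighbouring segment within `max_gap`, so absence of D is
#' uninformative) the call falls back to the highest reference identity;
#' ties go to `Vmu2` with a low-confidence flag.
#'
#' @param v One-row segment table (kind V).
#' @param d_candidates Segment table of D calls.
#' @param identity_to_refs Named numeric, identities to `Vmu1`/`Vmu2`
#'   reference families (optional).
#' @param segments Full segment table, used to find the next V/J/C boundary.
#' @param max_gap Cluster-context distance, default 15000.
#' @return List with `subtype` (`"Vmu1"`/`"Vmu2"`) and `low_confidence`.
#' @export
classify_v_subtype <- function(v, d_candidates, identity_to_refs = NULL,
                               segments = NULL, max_gap = 15000L) {
  stopifnot(v$kind == "V")
  # 3' window from the V to the next V/J/C segment (strand-aware)
  lim <- NA_integer_
  others <- if (!is.null(segments)) {
    segments[segments$kind %in% c("V", "Vj", "J", "C") &
               !(segments$start == v$start & segments$end == v$end), , drop = FALSE]
  } else empty_segments()
  if (v$strand == "+") {
    nxt <- others$start[others$start > v$end]
    lim <- if (length(nxt)) min(nxt) else v$end + max_gap
    ds <- d_candidates[d_candidates$start > v$end & d_candidates$end < lim, , drop = FALSE]
    clustered <- length(nxt) > 0 && min(nxt) - v$end <= max_gap
  } else {
    nxt <- others$end[others$end < v$start]
    lim <- if (length(nxt)) max(nxt) else v$start - max_gap
    ds <- d_candidates[d_candidates$end < v$start & d_candidates$start > lim, , drop = FALSE]
    clustered <- length(nxt) > 0 && v$start - max(nxt) <= max_gap
  }
  if (nrow(ds) > 0) return(list(subtype = "Vmu1", low_confidence = FALSE))
  if (clustered) return(list(subtype = "Vmu2", low_confidence = FALSE))
  if (!is.null(identity_to_refs) && length(identity_to_refs) > 0) {
    best <- names(identity_to_refs)[which.max(identity_to_refs)]
    tie <- sum(identity_to_refs == max(identity_to_refs)) > 1L
    if (!tie && best %in% c("Vmu1", "Vmu2")) {
      return(list(subtype = best, low_confidence = FALSE))
    }
  }
  list(subtype = "Vmu2", low_confidence = TRUE)
}

# Split V-homologous candidates into V vs Vj using downstream RSS and the
# germline-joined J motif; attaches rss evidence and landmark info.
refine_v_kinds <- function(cands, genome, rss23, slack = 25L) {
  if (nrow(cands) == 0L) return(cands)
  kinds <- character(nrow(cands))
  evid <- cands$evidence
  for (i in seq_len(nrow(cands))) {
    seg <- cands[i, ]
    if (seg$strand == "+") {
      has_rss <- any(rss23$strand == "+" &
                       rss23$start >= seg$end - 5L & rss23$start <= seg$end + slack)
    } else {
      has_rss <- any(rss23$strand == "-" &
                       rss23$end <= seg$start + 5L & rss23$end >= seg$start - slack)
    }
    cs <- seq_extract(genome, seg$seq_id, seg$start, seg$end, seg$strand)
    lm <- v_landmarks(cs)
    joined <- has_joined_j_motif(cs, lm)
    if (joined && !has_rss) {
      kinds[i] <- "Vj"
    } else {
      kinds[i] <- "V"
    }
    tags <- strsplit(evid[i], ",")[[1L]]
    if (has_rss) tags <- union(tags, "rss")
    if (!is.null(lm)) tags <- union(tags, "motif")
    evid[i] <- paste(tags, collapse = ",")
  }
  cands$kind <- kinds
  cands$evidence <- evid
  cands
}
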