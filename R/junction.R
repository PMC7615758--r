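#' @name junction_inference
#' @title D segment inference from V-D-J junction transcripts
#'
#' @description
#' D gene segments are too short for reliable homology search; they are
#' recovered from recombined transcripts. Each transcript is anchored to its
#' best germline V (5' part) and J (3' part); the residue between the anchors
#' is the junction. Exact junction substrings of at least `min_d_match` bases
#' that match the germline sequence between the V and J are templated blocks
#' (candidate D exposure); untemplated N additions never match by chance at
#' that length. A D call requires either two independently supporting
#' junctions or one junction plus a compatible RSS flank pair.
NULL

#' Map a recombined transcript onto the germline locus
#'
#' @param genome Genome sequence.
#' @param transcript Named character of length 1, or `DNAStringSet` of 1.
#' @param v_segments,j_segments Segment tables of annotated V and J genes.
#' @param min_anchor_identity Both anchors must reach this identity
#'   (default 0.85) or the transcript is rejected (returns `NULL`).
#' @return A `junction_map` list: transcript/anchor ids, genomic anchor
#'   blocks, `junction_seq`, the V reading frame on the transcript, and
#'   `productive`; or `NULL` when anchoring fails.
#' @export
map_transcript <- function(genome, transcript, v_segments, j_segments,
                           min_anchor_identity = 0.85) {
  stopifnot(nrow(v_segments) > 0, nrow(j_segments) > 0)
  if (methods::is(transcript, "XStringSet")) {
    tx_id <- names(transcript)[1L]
    tx <- as.character(transcript[[1L]])
  } else {
    tx_id <- if (!is.null(names(transcript))) names(transcript)[1L] else "tx"
    tx <- unname(transcript[[1L]])
  }
  best_anchor <- function(segs) {
    best <- NULL
    has_seq <- "seq" %in% names(segs)   # precomputed oriented sequences
    for (i in seq_len(nrow(segs))) {
      seg <- segs[i, ]
      sseq <- if (has_seq) seg$seq else
        seq_extract(genome, seg$seq_id, seg$start, seg$end, seg$strand)
      al <- local_align(sseq, tx)
      if (is.null(best) || al$score > best$al$score) best <- list(seg = seg, al = al)
    }
    best
  }
  v <- best_anchor(v_segments)
  j <- best_anchor(j_segments)
  if (is.null(v) || is.null(j)) return(NULL)
  if (v$al$identity < min_anchor_identity || j$al$identity < min_anchor_identity) return(NULL)
  v_tx_end <- v$al$target_end
  j_tx_start <- j$al$target_start
  if (j_tx_start <= v_tx_end) return(NULL)
  junction <- substr(tx, v_tx_end + 1L, j_tx_start - 1L)
  # genomic footprint of the anchors (plus-strand coordinates)
  blk <- function(seg, al) {
    if (seg$strand == "+") {
      c(seg$start + al$query_start - 1L, seg$start + al$query_end - 1L)
    } else {
      c(seg$end - al$query_end + 1L, seg$end - al$query_start + 1L)
    }
  }
  vb <- blk(v$seg, v$al)
  jb <- blk(j$seg, j$al)
  # reading frame of the V coding span on the transcript
  v_tx_start <- v$al$target_start
  frame <- (v_tx_start - 1L - (v$al$query_start - 1L)) %% 3L
  out <- list(
    transcript_id = tx_id, transcript = tx,
    v_id = v$seg$segment_id, j_id = j$seg$segment_id,
    v_identity = v$al$identity, j_identity = j$al$identity,
    v_block = vb, j_block = jb, strand = v$seg$strand,
    v_tx_range = c(v_tx_start, v_tx_end), j_tx_range = c(j_tx_start, j$al$target_end),
    junction_seq = junction, v_anchor_frame = frame
  )
  out$productive <- is_productive(tx, frame)
  class(out) <- "junction_map"
  out
}

#' Productivity of a recombined transcript
#'
#' TRUE when the translation from the V reading frame runs stop-free through
#' the J motif and the `[FW]GxG` motif is in that frame.
#'
#' @param transcript Nucleotide string (or named character/`DNAStringSet`).
#' @param v_anchor_frame Reading frame (0-2) of the V coding span on the
#'   transcript.
#' @return Logical.
#' @export
is_productive <- function(transcript, v_anchor_frame) {
  stopifnot(v_anchor_frame %in% 0:2)
  tx <- if (methods::is(transcript, "XStringSet")) as.character(transcript[[1L]]) else unname(transcript[[1L]])
  aa <- translate_nt(tx, v_anchor_frame)
  m <- regexpr("[FW]G.G", aa)
  if (m[[1L]] == -1L) return(FALSE)
  prefix <- substr(aa, 1L, as.integer(m) + 3L)
  !grepl("*", prefix, fixed = TRUE)
}

#' Infer D gene segments from junction maps and RSS flank pairs
#'
#' Templated blocks are exact junction substrings of length >=
#' `min_d_match` matching the germline between the V and J used by that
#' junction. A D is reported when a position is supported by at least
#' `min_support` independent junctions, or by one junction plus an
#' overlapping RSS flank pair; flank pairs with no junction support are
#' reported with evidence `rss` only and flagged unconfirmed.
#'
#' @param junctions List of `junction_map` objects (NULLs are dropped).
#' @param genome Genome sequence.
#' @param d_flank_pairs Data frame from [pair_rss_for_d()].
#' @param min_d_match Minimum templated block length, default 6.
#' @param min_support Junction-only support count, default 2.
#' @param exclude Optional segment table; D calls overlapping these intervals
#'   are discarded.
#' @param seq_id Genome record id.
#' @param min_flank_score Flank pairs with *no* junction support are reported
#'   only when both RSS scores reach this value (default 0.80); pairs backing
#'   a junction-supported call are accepted at any score.
#' @return Segment table of D calls (column `confirmed` marks calls with
#'   junction support).
#' @export
infer_d_segments <- function(junctions, genome, d_flank_pairs,
                             min_d_match = 6L, min_support = 2L,
                             exclude = NULL, seq_id = NULL,
                             min_flank_score = 0.80) {
  stopifnot(min_d_match >= 5L)
  junctions <- Filter(Negate(is.null), junctions)
  s <- genome_string(genome, seq_id)
  if (is.null(seq_id)) {
    seq_id <- if (methods::is(genome, "XStringSet")) names(genome)[1L] else "seq1"
    if (is.null(seq_id) || is.na(seq_id)) seq_id <- "seq1"
  }
  # collect templated blocks: (junction index, genome interval)
  blocks <- list()
  for (ji in seq_along(junctions)) {
    jm <- junctions[[ji]]
    jseq <- jm$junction_seq
    if (nchar(jseq) < min_d_match) next
    if (jm$strand == "+") {
      rs <- jm$v_block[2L] + 1L; re <- jm$j_block[1L] - 1L
      if (re - rs + 1L < min_d_match) next
      region <- substr(s, rs, re)
    } else {
      rs <- jm$j_block[2L] + 1L; re <- jm$v_block[1L] - 1L
      if (re - rs + 1L < min_d_match) next
      region <- reverse_complement(substr(s, rs, re))
    }
    for (b in maximal_exact_blocks(jseq, region, min_d_match)) {
      # b: c(junction offset, region start, length); map region coords to genome
      if (jm$strand == "+") {
        gs <- rs + b[2L] - 1L
        ge <- gs + b[3L] - 1L
      } else {
        ge <- re - b[2L] + 1L
        gs <- ge - b[3L] + 1L
      }
      blocks[[length(blocks) + 1L]] <- c(ji, gs, ge)
    }
  }
  calls <- list()
  used_pairs <- rep(FALSE, nrow(d_flank_pairs))
  if (length(blocks) > 0L) {
    bm <- do.call(rbind, blocks)
    # group blocks by genomic overlap
    ord <- order(bm[, 2L])
    bm <- bm[ord, , drop = FALSE]
    grp <- cumsum(c(1L, bm[-1L, 2L] > cummax(bm[-nrow(bm), 3L])))
    for (g in unique(grp)) {
      sub <- bm[grp == g, , drop = FALSE]
      n_junc <- length(unique(sub[, 1L]))
      gs <- min(sub[, 2L]); ge <- max(sub[, 3L])
      ov <- which(d_flank_pairs$core_start <= ge & d_flank_pairs$core_end >= gs)
      has_rss <- length(ov) > 0L
      if (n_junc >= min_support || (n_junc >= 1L && has_rss)) {
        if (has_rss) {
          used_pairs[ov] <- TRUE
          # the RSS flanks delimit the germline D core exactly
          gs <- min(d_flank_pairs$core_start[ov])
          ge <- max(d_flank_pairs$core_end[ov])
          ev <- "junction,rss"
        } else {
          ev <- "junction"
        }
        calls[[length(calls) + 1L]] <- data.frame(
          start = gs, end = ge, evidence = ev, confirmed = TRUE,
          support = n_junc, stringsAsFactors = FALSE
        )
      }
    }
  }
  for (p in which(!used_pairs)) {
    if (d_flank_pairs$up_score[p] < min_flank_score ||
        d_flank_pairs$down_score[p] < min_flank_score) next
    calls[[length(calls) + 1L]] <- data.frame(
      start = d_flank_pairs$core_start[p], end = d_flank_pairs$core_end[p],
      evidence = "rss", confirmed = FALSE, support = 0L, stringsAsFactors = FALSE
    )
  }
  if (length(calls) == 0L) return(empty_segments())
  df <- do.call(rbind, calls)
  # merge duplicate/overlapping calls
  df <- df[order(df$start, df$end), , drop = FALSE]
  keep <- rep(TRUE, nrow(df))
  last <- 1L
  for (i in seq_len(nrow(df))[-1L]) {
    if (df$start[i] <= df$end[last]) {
      df$end[last] <- max(df$end[last], df$end[i])
      df$evidence[last] <- paste(sort(unique(unlist(strsplit(c(df$evidence[last], df$evidence[i]), ",")))), collapse = ",")
      df$confirmed[last] <- df$confirmed[last] || df$confirmed[i]
      df$support[last] <- df$support[last] + df$support[i]
      keep[i] <- FALSE
    } else {
      last <- i
    }
  }
  df <- df[keep, , drop = FALSE]
  if (!is.null(exclude) && nrow(exclude) > 0) {
    inside <- vapply(seq_len(nrow(df)), function(i) {
      any(df$start[i] <= exclude$end & df$end[i] >= exclude$start)
    }, logical(1))
    df <- df[!inside, , drop = FALSE]
  }
  if (nrow(df) == 0L) return(empty_segments())
  out <- new_segments(
    segment_id = NA_character_, seq_id = seq_id, start = df$start, end = df$end,
    strand = "+", kind = "D", subtype = "none", evidence = df$evidence,
    best_identity = NA_real_, best_query = NA_character_, pseudogene = FALSE,
    cluster_index = NA_integer_, ordinal = NA_integer_
  )
  out$confirmed <- df$confirmed
  out$support <- df$support
  rownames(out) <- NULL
  out
}

# All maximal exact matches of substrings of `jseq` (length >= minlen) in
# `region`. Returns list of c(junction offset, region position, length).
maximal_exact_blocks <- function(jseq, region, minlen) {
  jl <- nchar(jseq)
  out <- list()
  i <- 1L
  while (i + minlen - 1L <= jl) {
    # longest match starting at junction offset i
    pos <- find_sub(substr(jseq, i, i + minlen - 1L), region)
    if (length(pos) == 0L) { i <- i + 1L; next }
    best_len <- minlen
    best_pos <- pos
    len <- minlen + 1L
    while (i + len - 1L <= jl) {
      p2 <- find_sub(substr(jseq, i, i + len - 1L), region)
      if (length(p2) == 0L) break
      best_len <- len; best_pos <- p2
      len <- len + 1L
    }
    for (p in best_pos) out[[length(out) + 1L]] <- c(i, p, best_len)
    i <- i + best_len  # jump past this maximal block
  }
  out
}

find_sub <- function(pat, s) {
  m <- gregexpr(pat, s, fixed = TRUE)[[1L]]
  if (m[1L] == -1L) integer(0) else as.integer(m)
}
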