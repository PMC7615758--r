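#' @name alignment
#' @title Pairwise alignment primitives and homology search
#'
#' @description
#' Segment discovery by homology mirrors a BLASTn-style workflow without an
#' external binary: exact k-mer seeding followed by local alignment of the
#' seeded window. Local alignments use match +2, mismatch -3, gap opening 5
#' and gap extension 2 (a gap of length L costs 5 + 2L); identity-matrix
#' computations use global alignment with match +1, mismatch -1, gap opening
#' 4, extension 1, end gaps penalized. Identity is always matches divided by
#' alignment columns, gap columns included in the denominator.
NULL

# Substitution matrix over {A,C,G,T,N}; N mismatches everything (incl. N).
trm_submat <- function(match, mismatch) {
  b <- c("A", "C", "G", "T", "N")
  m <- matrix(mismatch, 5, 5, dimnames = list(b, b))
  diag(m) <- match
  m["N", "N"] <- mismatch
  m
}

aln_stats <- function(aln) {
  p <- as.character(Biostrings::pattern(aln))
  s <- as.character(Biostrings::subject(aln))
  pc <- strsplit(p, "")[[1L]]
  sc <- strsplit(s, "")[[1L]]
  columns <- length(pc)
  matches <- sum(pc == sc & pc != "-")
  gaps <- sum(pc == "-" | sc == "-")
  list(
    matches = matches, columns = columns, gap_columns = gaps,
    identity = if (columns > 0) matches / columns else 0,
    aligned_query = p, aligned_target = s
  )
}

#' Optimal local alignment of two nucleotide strings
#'
#' Smith-Waterman alignment under match +2, mismatch -3, gap opening 5, gap
#' extension 2 (affine: a gap of length L costs 5 + 2L). The caller is
#' responsible for trying both strands; no reverse-complement search is done.
#'
#' @param query,target Nucleotide strings.
#' @return List with `score`, `identity` (matches / aligned columns, gaps in
#'   the denominator), `query_start/end`, `target_start/end`, `matches`,
#'   `columns`, `gap_columns`, and the gapped `aligned_query`/`aligned_target`
#'   strings.
#' @export
local_align <- function(query, target) {
  stopifnot(nchar(query) > 0, nchar(target) > 0)
  aln <- Biostrings::pairwiseAlignment(
    query, target, type = "local",
    substitutionMatrix = trm_submat(2, -3), gapOpening = 5, gapExtension = 2
  )
  st <- aln_stats(aln)
  c(list(
    score = Biostrings::score(aln),
    query_start = Biostrings::start(Biostrings::pattern(aln)),
    query_end = Biostrings::end(Biostrings::pattern(aln)),
    target_start = Biostrings::start(Biostrings::subject(aln)),
    target_end = Biostrings::end(Biostrings::subject(aln))
  ), st)
}

#' Global nucleotide identity of two sequences
#'
#' Needleman-Wunsch with end-gap penalties (match +1, mismatch -1, gap
#' opening 4, extension 1); identity is matches over all alignment columns,
#' terminal and internal gap columns included in the denominator.
#'
#' @param a,b Nucleotide strings.
#' @return Identity in `[0, 1]`.
#' @export
global_identity <- function(a, b) {
  stopifnot(nchar(a) > 0, nchar(b) > 0)
  aln <- Biostrings::pairwiseAlignment(
    a, b, type = "global",
    substitutionMatrix = trm_submat(1, -1), gapOpening = 4, gapExtension = 1
  )
  aln_stats(aln)$identity
}

# Global alignment score under the identity scoring scheme (for oracle tests).
global_align_score <- function(a, b) {
  aln <- Biostrings::pairwiseAlignment(
    a, b, type = "global",
    substitutionMatrix = trm_submat(1, -1), gapOpening = 4, gapExtension = 1
  )
  Biostrings::score(aln)
}

# Hash index of k-mer positions in a strand string; `restrict` (a character
# vector of k-mers worth indexing, e.g. all query k-mers) keeps it small.
kmer_index <- function(s, k, restrict = NULL) {
  L <- nchar(s)
  if (L < k) return(list())
  starts <- seq_len(L - k + 1L)
  kms <- substring(s, starts, starts + k - 1L)
  if (!is.null(restrict)) {
    sel <- kms %in% restrict
    starts <- starts[sel]
    kms <- kms[sel]
  }
  split(starts, kms)
}

# all k-mers occurring in a set of query strings (both given strands handled
# by the caller)
query_kmers <- function(qs, k) {
  unique(unlist(lapply(qs, function(q) {
    if (nchar(q) < k) return(character(0))
    st <- seq_len(nchar(q) - k + 1L)
    substring(q, st, st + k - 1L)
  }), use.names = FALSE))
}

# Seed k-mer matches of one query against one strand string (via its index).
# Returns one row per seeded region: the seed span, the padded alignment
# window and the seed count.
seed_windows <- function(query, s, k, band = 32L, index = NULL) {
  qlen <- nchar(query)
  if (qlen < k) return(NULL)
  if (is.null(index)) index <- kmer_index(s, k)
  starts <- seq_len(qlen - k + 1L)
  kmers <- substring(query, starts, starts + k - 1L)
  keep <- !grepl("N", kmers, fixed = TRUE)
  if (!any(keep)) return(NULL)
  kmers <- kmers[keep]; qpos <- starts[keep]
  ml <- index[kmers]
  nhit <- lengths(ml)
  tpos <- unlist(ml, use.names = FALSE)
  qrep <- rep(qpos, nhit)
  if (length(tpos) == 0L) return(NULL)
  diag <- tpos - qrep
  ord <- order(diag, tpos)
  diag <- diag[ord]; tpos <- tpos[ord]
  # group seeds on nearby diagonals into candidate regions
  grp <- cumsum(c(1L, diff(diag) > band))
  out <- list()
  for (g in unique(grp)) {
    tp <- tpos[grp == g]
    # split distant seed runs on the same diagonal band
    o <- order(tp); tp <- tp[o]
    sub <- cumsum(c(1L, diff(tp) > qlen))
    for (h in unique(sub)) {
      t2 <- tp[sub == h]
      out[[length(out) + 1L]] <- c(
        span_start = min(t2), span_end = max(t2) + k - 1L,
        win_start = max(1L, min(t2) - qlen),
        win_end = min(nchar(s), max(t2) + k - 1L + qlen),
        n_seeds = length(t2)
      )
    }
  }
  do.call(rbind, out)
}

#' Find gene-segment candidates by homology to known sequences
#'
#' Seed-and-extend search: exact k-mer seeds on both strands, local alignment
#' of each seeded window, and per-family merging of overlapping hits keeping
#' the best identity. A candidate is reported when its alignment identity
#' reaches `min_identity` over at least `min_coverage` of the query length.
#'
#' @param genome Genome (`DNAStringSet`, named character, or string).
#' @param queries `DNAStringSet` (or named character vector) of known
#'   nucleotide sequences; headers may carry `kind=`/`class=` tags.
#' @param min_identity Minimum alignment identity, default 0.70.
#' @param min_coverage Minimum fraction of the query length aligned,
#'   default 0.60.
#' @param k Seed k-mer length, default 11.
#' @param families Optional named vector mapping query id to a family label;
#'   overlapping same-strand hits within a family are merged (best identity
#'   wins). Default: all queries form one family.
#' @param seq_id Genome record to search.
#' @param min_seeds Seeded regions need at least this many exact k-mer seeds
#'   before alignment is attempted (default 2; single random k-mer matches
#'   are abundant and never extend to a reportable hit).
#' @param index Optional precomputed k-mer index (`list("+" = , "-" = )` from
#'   the plus strand and its reverse complement), reused across searches.
#' @return Segment candidate table (kind left `NA`; evidence `"homology"`),
#'   with `best_identity` and `best_query` filled in.
#' @export
find_homologous_segments <- function(genome, queries, min_identity = 0.70,
                                     min_coverage = 0.60, k = 11L,
                                     families = NULL, seq_id = NULL,
                                     min_seeds = 2L, index = NULL) {
  if (length(queries) == 0L) stop("no queries supplied")
  stopifnot(min_identity > 0, min_identity <= 1, min_coverage > 0, min_coverage <= 1)
  s <- genome_string(genome, seq_id)
  if (is.null(seq_id)) {
    seq_id <- if (methods::is(genome, "XStringSet")) names(genome)[1L] else "seq1"
    if (is.null(seq_id) || is.na(seq_id)) seq_id <- "seq1"
  }
  qs <- if (is.character(queries)) queries else stats::setNames(as.character(queries), names(queries))
  if (is.null(names(qs))) names(qs) <- paste0("q", seq_along(qs))
  if (is.null(families)) families <- stats::setNames(rep("family1", length(qs)), names(qs))
  L <- nchar(s)
  rc <- reverse_complement(s)
  idx <- if (!is.null(index)) index else {
    qk <- query_kmers(qs, k)
    list("+" = kmer_index(s, k, qk), "-" = kmer_index(rc, k, qk))
  }
  hits <- list()
  for (strand in c("+", "-")) {
    str_seq <- if (strand == "+") s else rc
    # seeded regions of every query on this strand
    cand <- list()
    for (qi in names(qs)) {
      w <- seed_windows(qs[[qi]], str_seq, k, index = idx[[strand]])
      if (is.null(w)) next
      cand[[length(cand) + 1L]] <- data.frame(
        query = qi, family = unname(families[qi]),
        span_start = w[, "span_start"], span_end = w[, "span_end"],
        win_start = w[, "win_start"], win_end = w[, "win_end"],
        n_seeds = w[, "n_seeds"], stringsAsFactors = FALSE
      )
    }
    if (length(cand) == 0L) next
    cd <- do.call(rbind, cand)
    cd <- cd[cd$n_seeds >= min_seeds, , drop = FALSE]
    if (nrow(cd) == 0L) next
    # group same-family regions whose *seed spans* overlap; align the
    # best-seeded queries first and keep the first acceptable alignment
    # (the best-seeded query is in practice the closest homolog)
    for (fam in unique(cd$family)) {
      sub <- cd[cd$family == fam, , drop = FALSE]
      sub <- sub[order(sub$span_start), , drop = FALSE]
      grp <- cumsum(c(1L, sub$span_start[-1L] > cummax(sub$span_end[-nrow(sub)])))
      for (g in unique(grp)) {
        gg <- sub[grp == g, , drop = FALSE]
        gg <- gg[order(-gg$n_seeds), , drop = FALSE]
        for (r in seq_len(nrow(gg))) {
          win <- substr(str_seq, gg$win_start[r], gg$win_end[r])
          qi <- gg$query[r]
          al <- local_align(qs[[qi]], win)
          cov <- (al$query_end - al$query_start + 1L) / nchar(qs[[qi]])
          if (al$identity < min_identity || cov < min_coverage) next
          ts <- gg$win_start[r] + al$target_start - 1L
          te <- gg$win_start[r] + al$target_end - 1L
          if (strand == "-") {
            tmp <- ts
            ts <- L - te + 1L
            te <- L - tmp + 1L
          }
          hits[[length(hits) + 1L]] <- data.frame(
            seq_id = seq_id, start = ts, end = te, strand = strand,
            best_identity = al$identity, best_query = qi,
            family = fam, coverage = cov, score = al$score,
            stringsAsFactors = FALSE
          )
          break
        }
      }
    }
  }
  if (length(hits) == 0L) return(cbind(empty_segments()[0, ], family = character()))
  df <- do.call(rbind, hits)
  # merge overlapping same-strand hits within a family: keep best score
  df <- df[order(df$family, df$strand, -df$score, df$start), , drop = FALSE]
  keep <- rep(TRUE, nrow(df))
  for (grp_id in unique(paste(df$family, df$strand))) {
    rows <- which(paste(df$family, df$strand) == grp_id)
    kept_s <- integer(0); kept_e <- integer(0)
    for (i in rows) {
      if (any(df$start[i] <= kept_e & df$end[i] >= kept_s)) {
        keep[i] <- FALSE
      } else {
        kept_s <- c(kept_s, df$start[i]); kept_e <- c(kept_e, df$end[i])
      }
    }
  }
  df <- df[keep, , drop = FALSE]
  out <- new_segments(
    segment_id = NA_character_, seq_id = df$seq_id, start = df$start, end = df$end,
    strand = df$strand, kind = NA_character_, subtype = "none",
    evidence = "homology", best_identity = df$best_identity,
    best_query = df$best_query, pseudogene = FALSE,
    cluster_index = NA_integer_, ordinal = NA_integer_
  )
  out$family <- df$family
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}
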