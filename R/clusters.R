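#' @name cluster_assembly
#' @title Cluster assembly, completeness and duplication patterns
#'
#' @description
#' TRM-style loci are organized as repeated self-contained clusters
#' (`[V-D-J-Vj-C]` in marsupials, `[V1-D..-J1-V2-J2-C]` in the platypus),
#' each ending in a single C gene in transcription order. Assembly is a
#' greedy 5'-to-3' grouping of same-orientation segments separated by at most
#' `max_intra_gap`; the C segment terminates a cluster. Completeness compares
#' observed segment kinds against the expected layout; shared upstream repeat
#' elements and class alternation distinguish tandem-pair from singlet
#' duplications.
NULL

cluster_layouts <- list(
  marsupial = c("V", "D", "J", "Vj", "C"),
  platypus = c("V", "D", "J", "V", "J", "C")
)

#' Group annotated segments into clusters
#'
#' Greedy left-to-right grouping: a cluster is a maximal run of
#' same-orientation segments with consecutive gaps of at most `max_intra_gap`
#' containing exactly one C, which terminates the run in transcription order
#' (a plus-strand run closes after its C; a minus-strand run opens at its C).
#' Runs without a C are emitted as orphans (missing C). Cluster indices are
#' assigned 5' to 3' along the locus; segment `ordinal` numbers each kind 5'
#' to 3'.
#'
#' @param segments Segment table (any order; re-sorted internally).
#' @param max_intra_gap Maximum intra-cluster gap in bp, default 15000.
#' @return List with `clusters` (one row per cluster: interval, orientation,
#'   kinds, completeness placeholders) and `segments` (input with
#'   `cluster_index` and `ordinal` filled in).
#' @export
assemble_clusters <- function(segments, max_intra_gap = 15000L) {
  segs <- segments[order(segments$start, segments$end), , drop = FALSE]
  rownames(segs) <- NULL
  n <- nrow(segs)
  # D cores are strand-symmetric (convergent RSS flanks look identical on
  # both strands): adopt the strand of the nearest non-D segment so a D never
  # breaks its cluster's orientation run
  d_idx <- which(segs$kind == "D")
  nd_idx <- which(segs$kind != "D")
  if (length(d_idx) && length(nd_idx)) {
    for (i in d_idx) {
      dist <- pmax(segs$start[nd_idx] - segs$end[i], segs$start[i] - segs$end[nd_idx], 0)
      j <- nd_idx[which.min(dist)]
      if (dist[which.min(dist)] <= max_intra_gap) segs$strand[i] <- segs$strand[j]
    }
  }
  segs$cluster_index <- NA_integer_
  run_id <- integer(n)
  cur <- 0L
  open <- FALSE
  for (i in seq_len(n)) {
    new_run <- !open ||
      segs$strand[i] != segs$strand[i - 1L] ||
      segs$start[i] - segs$end[i - 1L] > max_intra_gap ||
      (segs$strand[i] == "-" && segs$kind[i] == "C")
    if (new_run) {
      cur <- cur + 1L
      open <- TRUE
    }
    run_id[i] <- cur
    # a C closes a plus-strand run; on the minus strand the C opened it,
    # so the run stays open for the upstream (rightward) segments
    if (segs$kind[i] == "C" && segs$strand[i] == "+") open <- FALSE
  }
  segs$cluster_index <- run_id
  if (n == 0L) {
    return(list(clusters = empty_clusters(), segments = segs))
  }
  # per-kind 5'->3' ordinals
  segs$ordinal <- stats::ave(seq_len(n), segs$kind, FUN = seq_along)
  cl <- lapply(sort(unique(run_id)), function(ci) {
    sub <- segs[segs$cluster_index == ci, , drop = FALSE]
    kinds_tx <- if (sub$strand[1L] == "+") sub$kind else rev(sub$kind)
    data.frame(
      index = ci,
      cluster_id = paste0("cluster", ci),
      seq_id = sub$seq_id[1L],
      start = min(sub$start), end = max(sub$end),
      strand = sub$strand[1L],
      n_segments = nrow(sub),
      kinds = paste(kinds_tx, collapse = "-"),
      has_c = any(sub$kind == "C"),
      complete = NA, missing = NA_character_,
      class_label = "unassigned",
      upstream_repeat_start = NA_integer_, upstream_repeat_end = NA_integer_,
      stringsAsFactors = FALSE
    )
  })
  clusters <- do.call(rbind, cl)
  if (any(!clusters$has_c)) {
    warning(sum(!clusters$has_c), " segment run(s) without a C gene emitted as orphan clusters")
  }
  list(clusters = clusters, segments = segs)
}

empty_clusters <- function() {
  data.frame(
    index = integer(), cluster_id = character(), seq_id = character(),
    start = integer(), end = integer(), strand = character(),
    n_segments = integer(), kinds = character(), has_c = logical(),
    complete = logical(), missing = character(), class_label = character(),
    upstream_repeat_start = integer(), upstream_repeat_end = integer(),
    stringsAsFactors = FALSE
  )
}

#' Call cluster completeness against an expected layout
#'
#' @param cluster One cluster row (or its `kinds` string) from
#'   [assemble_clusters()].
#' @param expected_layout Character vector of expected segment kinds with
#'   multiplicity, e.g. `c("V","D","J","Vj","C")` (marsupial) or
#'   `c("V","D","J","V","J","C")` (platypus).
#' @return List with `complete` (logical) and `missing` (character vector of
#'   kinds present fewer times than expected).
#' @export
call_completeness <- function(cluster, expected_layout) {
  stopifnot(length(expected_layout) > 0)
  kinds <- if (is.character(cluster)) cluster else cluster$kinds
  have <- table(strsplit(kinds, "-", fixed = TRUE)[[1L]])
  want <- table(expected_layout)
  missing <- names(want)[vapply(names(want), function(k) {
    got <- if (k %in% names(have)) have[[k]] else 0L
    got < want[[k]]
  }, logical(1))]
  list(complete = length(missing) == 0L, missing = sort(missing))
}

#' Detect shared repeat elements upstream of clusters
#'
#' Compares the `flank` bp upstream (5' in cluster orientation) of every
#' cluster against every other; flank pairs sharing at least `min_identity`
#' over `min_length` aligned bases indicate copies of a common repeat
#' element, the pattern expected from repeat-mediated duplication. Matching
#' clusters get their `upstream_repeat` interval attached.
#'
#' @param genome Genome sequence.
#' @param clusters Cluster table from [assemble_clusters()].
#' @param flank Upstream window size in bp (>= 1000), default 2000.
#' @param min_identity Minimum alignment identity, default 0.80.
#' @param min_length Minimum aligned length in bp, default 500.
#' @return List with `repeats` (repeat-element table; `copy_partners` as a
#'   comma-separated interval list) and `clusters` (input with
#'   `upstream_repeat_*` filled).
#' @export
find_upstream_repeats <- function(genome, clusters, flank = 2000L,
                                  min_identity = 0.80, min_length = 500L) {
  stopifnot(flank >= 1000L)
  s <- genome_string(genome)
  L <- nchar(s)
  n <- nrow(clusters)
  empty <- data.frame(
    repeat_id = character(), family = integer(), seq_id = character(),
    start = integer(), end = integer(), cluster_index = integer(),
    family_hint = character(), copy_partners = character(),
    stringsAsFactors = FALSE
  )
  if (n < 2L) return(list(repeats = empty, clusters = clusters))
  fl <- lapply(seq_len(n), function(i) {
    if (clusters$strand[i] == "+") {
      ws <- max(1L, clusters$start[i] - flank); we <- clusters$start[i] - 1L
      if (we < ws) return(NULL)
      list(start = ws, end = we, seq = substr(s, ws, we), strand = "+")
    } else {
      ws <- clusters$end[i] + 1L; we <- min(L, clusters$end[i] + flank)
      if (we < ws) return(NULL)
      list(start = ws, end = we, seq = reverse_complement(substr(s, ws, we)), strand = "-")
    }
  })
  # pairwise comparison; a shared-13-mer prefilter skips unrelated flank
  # pairs, and the alignment is restricted to the seeded subregions
  kf <- 13L
  fidx <- lapply(fl, function(f) if (is.null(f)) NULL else kmer_index(f$seq, kf))
  adj <- matrix(FALSE, n, n)
  span <- vector("list", n)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (is.null(fl[[i]]) || is.null(fl[[j]])) next
      shared <- intersect(names(fidx[[i]]), names(fidx[[j]]))
      if (length(shared) < 10L) next
      pi_ <- unlist(fidx[[i]][shared], use.names = FALSE)
      pj <- unlist(fidx[[j]][shared], use.names = FALSE)
      ri <- c(max(1L, min(pi_) - 50L), min(nchar(fl[[i]]$seq), max(pi_) + kf - 1L + 50L))
      rj <- c(max(1L, min(pj) - 50L), min(nchar(fl[[j]]$seq), max(pj) + kf - 1L + 50L))
      al <- local_align(substr(fl[[i]]$seq, ri[1L], ri[2L]),
                        substr(fl[[j]]$seq, rj[1L], rj[2L]))
      alen <- al$columns
      if (al$identity >= min_identity && alen >= min_length) {
        adj[i, j] <- adj[j, i] <- TRUE
        upd <- function(cur, a, b) {
          if (is.null(cur)) c(a, b) else c(min(cur[1L], a), max(cur[2L], b))
        }
        span[[i]] <- upd(span[[i]], ri[1L] + al$query_start - 1L, ri[1L] + al$query_end - 1L)
        span[[j]] <- upd(span[[j]], rj[1L] + al$target_start - 1L, rj[1L] + al$target_end - 1L)
      }
    }
  }
  # connected components with >= 2 members are repeat families
  comp <- rep(NA_integer_, n)
  cid <- 0L
  for (i in seq_len(n)) {
    if (!is.na(comp[i]) || !any(adj[i, ])) next
    cid <- cid + 1L
    stack <- i
    while (length(stack)) {
      v <- stack[[1L]]; stack <- stack[-1L]
      if (!is.na(comp[v])) next
      comp[v] <- cid
      stack <- c(stack, which(adj[v, ] & is.na(comp)))
    }
  }
  reps <- list()
  for (i in which(!is.na(comp))) {
    # map flank-local span back to plus-strand genome coordinates
    sp <- span[[i]]
    if (fl[[i]]$strand == "+") {
      rs <- fl[[i]]$start + sp[1L] - 1L
      re <- fl[[i]]$start + sp[2L] - 1L
    } else {
      re <- fl[[i]]$end - sp[1L] + 1L
      rs <- fl[[i]]$end - sp[2L] + 1L
    }
    reps[[length(reps) + 1L]] <- data.frame(
      family = comp[i], seq_id = clusters$seq_id[i], start = rs, end = re,
      cluster_index = clusters$index[i], family_hint = "unknown",
      stringsAsFactors = FALSE
    )
    clusters$upstream_repeat_start[i] <- rs
    clusters$upstream_repeat_end[i] <- re
  }
  if (length(reps) == 0L) return(list(repeats = empty, clusters = clusters))
  rdf <- do.call(rbind, reps)
  rdf$repeat_id <- paste0("repeat_f", rdf$family, "_c", rdf$cluster_index)
  rdf$copy_partners <- vapply(seq_len(nrow(rdf)), function(i) {
    part <- rdf[rdf$family == rdf$family[i], , drop = FALSE]
    part <- part[part$cluster_index != rdf$cluster_index[i], , drop = FALSE]
    paste(sprintf("%d-%d", part$start, part$end), collapse = ",")
  }, character(1))
  rdf <- rdf[, c("repeat_id", "family", "seq_id", "start", "end",
                 "cluster_index", "family_hint", "copy_partners")]
  list(repeats = rdf, clusters = clusters)
}

#' Infer the duplication pattern of a cluster series
#'
#' Adjacent clusters with different class labels sharing an upstream repeat
#' before the first of the pair only are called a tandem pair (two-cluster
#' duplication unit); a cluster with its own upstream repeat and no such
#' pairing is a singlet duplication; anything else is left unlabeled.
#'
#' @param clusters Cluster table carrying `class_label` and
#'   `upstream_repeat_*` (run [label_clusters()] and
#'   [find_upstream_repeats()] first).
#' @param repeats Optional repeat-element table (kept for interface
#'   symmetry; the per-cluster `upstream_repeat_*` columns carry the signal).
#' @return Data frame with columns `pattern` (`tandem_pair`, `singlet`,
#'   `unlabeled`), `i`, `j` (second member for tandem pairs, else NA).
#' @export
infer_duplication_pattern <- function(clusters, repeats = NULL) {
  n <- nrow(clusters)
  has_rep <- !is.na(clusters$upstream_repeat_start)
  out <- list()
  i <- 1L
  while (i <= n) {
    paired <- FALSE
    if (i < n && has_rep[i] && !has_rep[i + 1L] &&
        clusters$class_label[i] != "unassigned" &&
        clusters$class_label[i + 1L] != "unassigned" &&
        clusters$class_label[i] != clusters$class_label[i + 1L]) {
      out[[length(out) + 1L]] <- data.frame(
        pattern = "tandem_pair", i = clusters$index[i], j = clusters$index[i + 1L],
        stringsAsFactors = FALSE
      )
      i <- i + 2L
      paired <- TRUE
    }
    if (!paired) {
      out[[length(out) + 1L]] <- data.frame(
        pattern = if (has_rep[i]) "singlet" else "unlabeled",
        i = clusters$index[i], j = NA_integer_, stringsAsFactors = FALSE
      )
      i <- i + 1L
    }
  }
  do.call(rbind, out)
}
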