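#' @name identity_classification
#' @title Pairwise identity matrices and class assignment
#'
#' @description
#' Cluster classes are defined by nucleotide identity: V genes are compared
#' over the framework-1 through framework-3 span (first to second canonical
#' cysteine), C genes over their full coding span. Queries inherit the class
#' of their best reference when identity strictly exceeds the threshold
#' (default 0.75, reading "greater than 75%" literally); unassignable
#' sequences are single-linkage clustered among themselves at the same
#' threshold into new classes.
NULL

#' Extract the FR1-FR3 nucleotide span of a V segment
#'
#' Returns the coding span from the FR1 first-cysteine codon through the FR3
#' second-cysteine codon inclusive. When the landmarks cannot be found
#' (typically a pseudogene) the full segment span is returned with attribute
#' `landmarks_found = FALSE`.
#'
#' @param v One-row segment table (kind V or Vj).
#' @param genome Genome sequence.
#' @return Nucleotide string with attribute `landmarks_found`.
#' @export
extract_fr_region <- function(v, genome) {
  stopifnot(v$kind %in% c("V", "Vj"))
  cs <- seq_extract(genome, v$seq_id, v$start, v$end, v$strand)
  if (nchar(cs) == 0L) stop("segment has no coding span")
  lm <- v_landmarks(cs)
  if (is.null(lm)) {
    attr(cs, "landmarks_found") <- FALSE
    return(cs)
  }
  out <- substr(cs, lm$fr_start, lm$fr_end)
  attr(out, "landmarks_found") <- TRUE
  out
}

#' Build a symmetric pairwise nucleotide-identity matrix
#'
#' All pairs are scored with [global_identity()]; ordering follows the input.
#'
#' @param seqs Named character vector or `DNAStringSet` (>= 2 sequences,
#'   unique ids).
#' @param region Label stored as attribute (e.g. `"V_FR1_FR3"`, `"C_full"`).
#' @return Numeric matrix with unit diagonal and `dimnames` = ids.
#' @export
build_identity_matrix <- function(seqs, region = "V_FR1_FR3") {
  x <- if (is.character(seqs)) seqs else stats::setNames(as.character(seqs), names(seqs))
  stopifnot(length(x) >= 2L)
  if (is.null(names(x))) names(x) <- paste0("s", seq_along(x))
  if (anyDuplicated(names(x))) stop("duplicate ids: ", names(x)[duplicated(names(x))][1L])
  n <- length(x)
  m <- diag(1, n)
  dimnames(m) <- list(names(x), names(x))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      m[i, j] <- m[j, i] <- global_identity(x[[i]], x[[j]])
    }
  }
  attr(m, "region") <- region
  m
}

#' Assign sequences to classes by best-reference identity
#'
#' Each unlabeled sequence receives the label of its highest-identity
#' reference when that identity strictly exceeds `threshold`. Remaining
#' unlabeled sequences are single-linkage clustered among themselves at the
#' same threshold; groups of two or more become `new-class-k`, singletons
#' stay `unassigned`.
#'
#' @param matrix Identity matrix from [build_identity_matrix()].
#' @param reference_labels Named character vector mapping reference ids (a
#'   subset of the matrix ids) to class labels.
#' @param threshold Strict identity threshold, default 0.75.
#' @return Data frame: `id`, `label`, `best_reference`, `best_identity`.
#' @export
assign_classes <- function(matrix, reference_labels, threshold = 0.75) {
  ids <- rownames(matrix)
  refs <- intersect(names(reference_labels), ids)
  if (length(refs) == 0L) stop("no labeled reference present in the matrix")
  queries <- setdiff(ids, refs)
  out <- data.frame(
    id = queries, label = rep("unassigned", length(queries)),
    best_reference = rep(NA_character_, length(queries)),
    best_identity = rep(NA_real_, length(queries)),
    stringsAsFactors = FALSE
  )
  if (length(queries) == 0L) return(out)
  for (k in seq_along(queries)) {
    idv <- matrix[queries[k], refs]
    b <- which.max(idv)
    out$best_reference[k] <- refs[b]
    out$best_identity[k] <- idv[b]
    if (idv[b] > threshold) out$label[k] <- unname(reference_labels[refs[b]])
  }
  un <- which(out$label == "unassigned")
  if (length(un) >= 2L) {
    sub <- matrix[queries[un], queries[un], drop = FALSE]
    d <- stats::as.dist(1 - sub)
    hc <- stats::hclust(d, method = "single")
    grp <- stats::cutree(hc, h = (1 - threshold) - 1e-9)
    tab <- table(grp)
    newk <- 0L
    for (g in sort(unique(grp))) {
      if (tab[[as.character(g)]] < 2L) next
      newk <- newk + 1L
      members <- un[grp == g]
      out$label[members] <- paste0("new-class-", newk)
      # best in-group partner becomes the reported reference
      member_ids <- out$id[members]
      for (mi in members) {
        others <- setdiff(member_ids, out$id[mi])
        idv <- matrix[out$id[mi], others]
        b <- which.max(idv)
        out$best_reference[mi] <- others[b]
        out$best_identity[mi] <- idv[b]
      }
    }
  }
  out
}

#' Label clusters from their segment class assignments
#'
#' Cluster label = majority label over its V/Vj and C assignments; on a
#' V-versus-C conflict the V label wins and the cluster is flagged; ties or
#' all-unassigned leave the cluster `unassigned`.
#'
#' @param clusters Cluster table.
#' @param segments Segment table with `cluster_index` (ids matching the
#'   assignment tables).
#' @param v_assignments,c_assignments Data frames from [assign_classes()]
#'   (either may be NULL).
#' @return `clusters` with `class_label` and logical `class_conflict` filled.
#' @export
label_clusters <- function(clusters, segments, v_assignments = NULL,
                           c_assignments = NULL) {
  lab_of <- function(df, ids) {
    if (is.null(df)) return(character(0))
    l <- df$label[match(ids, df$id)]
    l[!is.na(l) & l != "unassigned"]
  }
  clusters$class_conflict <- FALSE
  for (i in seq_len(nrow(clusters))) {
    sub <- segments[!is.na(segments$cluster_index) &
                      segments$cluster_index == clusters$index[i], , drop = FALSE]
    vl <- lab_of(v_assignments, sub$segment_id[sub$kind %in% c("V", "Vj")])
    cl <- lab_of(c_assignments, sub$segment_id[sub$kind == "C"])
    modal <- function(x) {
      if (length(x) == 0L) return(NA_character_)
      t <- sort(table(x), decreasing = TRUE)
      if (length(t) > 1L && t[[1L]] == t[[2L]]) return(NA_character_)  # tie
      names(t)[1L]
    }
    mv <- modal(vl); mc <- modal(cl)
    if (!is.na(mv) && !is.na(mc) && mv != mc) {
      clusters$class_label[i] <- mv
      clusters$class_conflict[i] <- TRUE
    } else if (!is.na(mv)) {
      clusters$class_label[i] <- mv
    } else if (!is.na(mc)) {
      clusters$class_label[i] <- mc
    } else {
      all_lab <- modal(c(vl, cl))
      clusters$class_label[i] <- if (is.na(all_lab)) "unassigned" else all_lab
    }
  }
  clusters
}
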