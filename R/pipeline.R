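#' @name cli_report
#' @title End-to-end pipeline, locus reports and comparisons
#'
#' @description
#' `run_pipeline()` composes the full annotation workflow from a single
#' configuration: RSS scan, homology search for V/Vj/C, motif-based J
#' annotation, D inference (junction transcripts and/or RSS flank pairs),
#' cluster assembly and completeness, upstream-repeat detection, identity
#' matrices with class assignment, V subtyping, and duplication-pattern
#' calls. The pipeline is deterministic: the same configuration and inputs
#' always produce identical output.
NULL

#' Default pipeline configuration
#'
#' Every threshold used anywhere in the pipeline appears here, so a written
#' config file documents a run completely. Values are defaults, not fitted
#' constants; see the package vignette for rationale.
#'
#' @param layout `"marsupial"` or `"platypus"` (expected cluster layout).
#' @return Nested configuration list.
#' @export
default_config <- function(layout = c("marsupial", "platypus")) {
  layout <- match.arg(layout)
  list(
    layout = layout,
    genome = NULL, queries = NULL, transcripts = NULL, references = NULL,
    flanking_genes = character(0),
    locus_id = "locus",
    rss = list(min_score = 0.70, spacer_tolerance = 1L, d_flank_layout = "12/12"),
    annotate = list(k = 11L, min_identity = 0.70, min_coverage = 0.60,
                    j_min_rss_score = 0.80),
    junction = list(min_d_match = 6L, min_support = 2L, min_flank_score = 0.80),
    cluster = list(max_intra_gap = 15000L, flank = 2000L),
    classify = list(threshold = 0.75),
    outdir = NULL
  )
}

#' Write / read a pipeline configuration
#'
#' Configurations are stored as JSON; in-memory sequence objects cannot be
#' serialized and must be file paths when writing.
#'
#' @param config Configuration list.
#' @param path File path.
#' @return `read_config` returns the configuration list.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(config, path, auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  jsonlite::fromJSON(path, simplifyVector = TRUE)
}

as_seqset <- function(x, what) {
  if (is.null(x)) return(NULL)
  if (methods::is(x, "XStringSet")) return(x)
  if (is.character(x) && length(x) == 1L && file.exists(x)) return(read_fasta(x))
  if (is.character(x) && !is.null(names(x))) return(Biostrings::DNAStringSet(x))
  stop("cannot interpret ", what, " input")
}

#' Run the full locus-annotation pipeline
#'
#' @param config Configuration list (see [default_config()]) or path to a
#'   JSON config file. `genome` and `queries` are required; `transcripts`
#'   enables junction-based D confirmation. Partial configs are merged over
#'   the defaults.
#' @return A `trm_report` object (see [locus_report()] fields).
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) config <- read_config(config)
  cfg <- utils::modifyList(default_config(config$layout %||% "marsupial"), config)
  if (is.null(cfg$genome)) stop("config$genome is required")
  if (is.null(cfg$queries)) stop("config$queries is required")
  genome <- as_seqset(cfg$genome, "genome")
  queries <- as_seqset(cfg$queries, "queries")
  transcripts <- as_seqset(cfg$transcripts, "transcripts")
  seq_id <- names(genome)[1L]

  rss12 <- scan_rss(genome, 12L, cfg$rss$min_score, cfg$rss$spacer_tolerance)
  rss23 <- scan_rss(genome, 23L, cfg$rss$min_score, cfg$rss$spacer_tolerance)

  kinds <- header_tags(queries, "kind")
  kinds[is.na(kinds)] <- "V"
  vq <- queries[kinds %in% c("V", "Vj")]
  cq <- queries[kinds == "C"]
  if (length(vq) == 0L) stop("no V-kind queries supplied")
  gstr <- genome_string(genome)
  qk <- query_kmers(as.character(queries), cfg$annotate$k)
  gidx <- list("+" = kmer_index(gstr, cfg$annotate$k, qk),
               "-" = kmer_index(reverse_complement(gstr), cfg$annotate$k, qk))
  v_cands <- find_homologous_segments(
    genome, vq, cfg$annotate$min_identity, cfg$annotate$min_coverage,
    k = cfg$annotate$k,
    families = stats::setNames(rep("Vlike", length(vq)), names(vq)),
    index = gidx
  )
  v_cands <- refine_v_kinds(v_cands, genome, rss23)
  c_cands <- if (length(cq) > 0L) {
    cc <- find_homologous_segments(
      genome, cq, cfg$annotate$min_identity, cfg$annotate$min_coverage,
      k = cfg$annotate$k,
      families = stats::setNames(rep("C", length(cq)), names(cq)),
      index = gidx
    )
    if (nrow(cc)) cc$kind <- "C"
    cc
  } else empty_segments()

  all_hits <- rbind(rss12, rss23)
  pair_hits <- if (cfg$rss$d_flank_layout == "12/12") rss12 else all_hits
  d_pairs <- pair_rss_for_d(pair_hits, max_d_core = 40L, layout = cfg$rss$d_flank_layout)
  j_cands <- annotate_j(genome, all_hits,
                        min_rss_score = cfg$annotate$j_min_rss_score)
  if (nrow(j_cands) > 0) {
    # J candidates inside homology candidates are V/Vj/C internal motifs;
    # J candidates colliding with a 12-spacer RSS or sitting inside a
    # convergent flank-pair core are D-core artefacts
    blockers <- rbind(v_cands[names(empty_segments())], c_cands[names(empty_segments())])
    ov <- vapply(seq_len(nrow(j_cands)), function(i) {
      any(j_cands$start[i] <= blockers$end & j_cands$end[i] >= blockers$start) ||
        any(j_cands$start[i] <= rss12$end & j_cands$end[i] >= rss12$start) ||
        (nrow(d_pairs) > 0 &&
           any(j_cands$start[i] <= d_pairs$core_end & j_cands$end[i] >= d_pairs$core_start))
    }, logical(1))
    j_cands <- j_cands[!ov, , drop = FALSE]
  }
  junction_maps <- list()
  if (!is.null(transcripts) && nrow(v_cands[v_cands$kind == "V", ]) > 0 && nrow(j_cands) > 0) {
    vset <- v_cands[v_cands$kind == "V", ]
    vset$segment_id <- paste0("V", seq_len(nrow(vset)))
    jset <- j_cands
    jset$segment_id <- paste0("J", seq_len(nrow(jset)))
    oriented <- function(df) vapply(seq_len(nrow(df)), function(i) {
      seq_extract(genome, df$seq_id[i], df$start[i], df$end[i], df$strand[i])
    }, character(1))
    vset$seq <- oriented(vset)
    jset$seq <- oriented(jset)
    junction_maps <- lapply(seq_along(transcripts), function(i) {
      map_transcript(genome, transcripts[i], vset, jset)
    })
  }
  d_cands <- infer_d_segments(
    junction_maps, genome, d_pairs,
    min_d_match = cfg$junction$min_d_match, min_support = cfg$junction$min_support,
    min_flank_score = cfg$junction$min_flank_score,
    exclude = rbind(v_cands[names(empty_segments())],
                    j_cands[names(empty_segments())],
                    c_cands[names(empty_segments())])
  )

  core <- names(empty_segments())
  segments <- rbind(v_cands[core], j_cands[core], d_cands[core], c_cands[core])
  if (nrow(segments) > 0) segments$seq_id <- seq_id

  asm <- suppressWarnings(assemble_clusters(segments, cfg$cluster$max_intra_gap))
  segments <- asm$segments
  clusters <- asm$clusters
  if (nrow(segments) > 0) {
    segments$segment_id <- paste0(segments$kind, segments$ordinal)
  }

  # pseudogene flags (V/Vj/C) against the best homology query
  qseq <- stats::setNames(as.character(queries), names(queries))
  for (i in which(segments$kind %in% c("V", "Vj", "C"))) {
    q <- if (!is.na(segments$best_query[i])) qseq[[segments$best_query[i]]] else NULL
    segments$pseudogene[i] <- flag_pseudogene(segments[i, ], genome, q)
  }

  # completeness against the layout
  layout_kinds <- cluster_layouts[[cfg$layout]]
  clusters$complete <- NA
  for (i in seq_len(nrow(clusters))) {
    cc <- call_completeness(clusters[i, ], layout_kinds)
    clusters$complete[i] <- cc$complete
    clusters$missing[i] <- paste(cc$missing, collapse = ",")
  }

  multi <- clusters$n_segments >= 2L
  reps <- find_upstream_repeats(genome, clusters[multi, , drop = FALSE],
                                flank = cfg$cluster$flank)
  clusters[multi, ] <- reps$clusters
  repeats <- reps$repeats

  # classification: V/Vj over FR1-FR3, C over the full span
  cls_refs <- class_references(queries, cfg$references)
  v_assign <- c_assign <- NULL
  vmat <- cmat <- NULL
  vs <- segments[segments$kind %in% c("V", "Vj"), , drop = FALSE]
  if (nrow(vs) > 0 && length(cls_refs$v_seqs) > 0) {
    frs <- vapply(seq_len(nrow(vs)), function(i) {
      as.character(extract_fr_region(vs[i, ], genome))
    }, character(1))
    names(frs) <- vs$segment_id
    vmat <- build_identity_matrix(c(cls_refs$v_seqs, frs), region = "V_FR1_FR3")
    v_assign <- assign_classes(vmat, cls_refs$v_labels, cfg$classify$threshold)
  }
  cs <- segments[segments$kind == "C", , drop = FALSE]
  if (nrow(cs) > 0 && length(cls_refs$c_seqs) > 0) {
    cseqs <- vapply(seq_len(nrow(cs)), function(i) {
      seq_extract(genome, cs$seq_id[i], cs$start[i], cs$end[i], cs$strand[i])
    }, character(1))
    names(cseqs) <- cs$segment_id
    cmat <- build_identity_matrix(c(cls_refs$c_seqs, cseqs), region = "C_full")
    c_assign <- assign_classes(cmat, cls_refs$c_labels, cfg$classify$threshold)
  }
  clusters <- label_clusters(clusters, segments, v_assign, c_assign)

  # V subtyping (Vmu1/Vmu2)
  subrefs <- header_tags(queries, "subtype")
  subref_ids <- names(subrefs)[!is.na(subrefs)]
  dsegs <- segments[segments$kind == "D", , drop = FALSE]
  for (i in which(segments$kind == "V")) {
    id_refs <- NULL
    if (length(subref_ids) > 0) {
      vals <- vapply(subref_ids, function(r) {
        global_identity(
          seq_extract(genome, segments$seq_id[i], segments$start[i],
                      segments$end[i], segments$strand[i]),
          qseq[[r]]
        )
      }, numeric(1))
      id_refs <- tapply(vals, subrefs[subref_ids], max)
    }
    st <- classify_v_subtype(segments[i, ], dsegs, id_refs, segments,
                             cfg$cluster$max_intra_gap)
    segments$subtype[i] <- st$subtype
  }

  duplication <- if (sum(multi) > 0) {
    infer_duplication_pattern(clusters[multi, , drop = FALSE], repeats)
  } else data.frame(pattern = character(), i = integer(), j = integer())

  report <- locus_report(
    locus_id = cfg$locus_id, seq_id = seq_id,
    genome_length = nchar(genome_string(genome)),
    segments = segments, clusters = clusters, repeats = repeats,
    duplication = duplication, v_assignments = v_assign, c_assignments = c_assign,
    v_matrix = vmat, c_matrix = cmat,
    junction_maps = junction_maps, flanking_genes = cfg$flanking_genes,
    config = cfg
  )
  if (!is.null(cfg$outdir)) write_report_files(report, genome, cfg$outdir)
  report
}

# classification references: explicit `references` (named character + labels
# in names like "id|label") or derived from class= tagged queries (FR span
# for V-kind queries, full span for C)
class_references <- function(queries, references = NULL) {
  if (!is.null(references)) {
    refs <- as_seqset(references, "references")
    labs <- header_tags(refs, "class")
    kind <- header_tags(refs, "kind")
    kind[is.na(kind)] <- "V"
    keep <- !is.na(labs)
    v <- kind %in% c("V", "Vj") & keep
    c_ <- kind == "C" & keep
    return(list(
      v_seqs = stats::setNames(as.character(refs[v]), names(refs)[v]),
      v_labels = stats::setNames(labs[v], names(refs)[v]),
      c_seqs = stats::setNames(as.character(refs[c_]), names(refs)[c_]),
      c_labels = stats::setNames(labs[c_], names(refs)[c_])
    ))
  }
  labs <- header_tags(queries, "class")
  kinds <- header_tags(queries, "kind")
  kinds[is.na(kinds)] <- "V"
  v_ids <- names(queries)[kinds %in% c("V", "Vj") & !is.na(labs)]
  c_ids <- names(queries)[kinds == "C" & !is.na(labs)]
  v_seqs <- character(0)
  for (id in v_ids) {
    s <- as.character(queries[[id]])
    lm <- v_landmarks(s)
    v_seqs[[id]] <- if (!is.null(lm)) substr(s, lm$fr_start, lm$fr_end) else s
  }
  list(
    v_seqs = v_seqs,
    v_labels = stats::setNames(labs[v_ids], v_ids),
    c_seqs = stats::setNames(as.character(queries)[match(c_ids, names(queries))], c_ids),
    c_labels = stats::setNames(labs[c_ids], c_ids)
  )
}

#' Assemble a locus report
#'
#' Aggregates the pipeline results: cluster table (multi-segment groups),
#' singleton segments, per-kind segment counts, V subtype counts, class
#' tally, partial-cluster count, duplication calls and flanking genes.
#' Normally produced by [run_pipeline()].
#'
#' @param locus_id,seq_id Identifiers.
#' @param genome_length Genome record length in bp.
#' @param segments,clusters,repeats,duplication Pipeline tables.
#' @param v_assignments,c_assignments,v_matrix,c_matrix Classification results.
#' @param junction_maps List of junction maps (possibly empty).
#' @param flanking_genes User-supplied ordered flanking gene ids.
#' @param config The configuration used.
#' @return `trm_report` object.
#' @export
locus_report <- function(locus_id, seq_id, genome_length, segments, clusters,
                         repeats, duplication, v_assignments = NULL,
                         c_assignments = NULL, v_matrix = NULL, c_matrix = NULL,
                         junction_maps = list(), flanking_genes = character(0),
                         config = list()) {
  multi <- clusters[clusters$n_segments >= 2L, , drop = FALSE]
  single <- clusters[clusters$n_segments < 2L, , drop = FALSE]
  multi$index_5p3p <- seq_len(nrow(multi))
  seg_counts <- table(factor(segments$kind, levels = c("V", "D", "J", "Vj", "C")))
  v_sub <- table(factor(segments$subtype[segments$kind == "V"], levels = c("Vmu1", "Vmu2", "none")))
  n_c_in_clusters <- sum(segments$kind == "C" &
                           segments$cluster_index %in% multi$index)
  out <- list(
    locus_id = locus_id, seq_id = seq_id,
    locus_span = if (nrow(segments)) max(segments$end) - min(segments$start) + 1L else 0L,
    genome_length = genome_length,
    clusters = multi, singletons = single, segments = segments,
    repeats = repeats, duplication = duplication,
    segment_counts = seg_counts,
    v_subtype_counts = v_sub,
    n_c_in_clusters = n_c_in_clusters,
    class_tally = table(multi$class_label),
    n_clusters = nrow(multi),
    n_partial = sum(!multi$complete),
    v_assignments = v_assignments, c_assignments = c_assignments,
    v_matrix = v_matrix, c_matrix = c_matrix,
    junction_maps = junction_maps,
    flanking_genes = flanking_genes,
    config = config
  )
  class(out) <- "trm_report"
  out
}

#' @export
print.trm_report <- function(x, ...) {
  cat("Locus report:", x$locus_id, "\n")
  cat(sprintf("  span %s bp, %d clusters (%d partial), %d singleton segments\n",
              format(x$locus_span, big.mark = ","), x$n_clusters, x$n_partial,
              nrow(x$singletons)))
  cat("  segments:", paste(sprintf("%s=%d", names(x$segment_counts), x$segment_counts),
                           collapse = " "), "\n")
  if (sum(x$v_subtype_counts[c("Vmu1", "Vmu2")]) > 0) {
    cat("  V subtypes:", sprintf("Vmu1=%d Vmu2=%d",
                                 x$v_subtype_counts[["Vmu1"]], x$v_subtype_counts[["Vmu2"]]), "\n")
  }
  if (length(x$class_tally)) {
    cat("  classes:", paste(sprintf("%s=%d", names(x$class_tally), x$class_tally),
                            collapse = " "), "\n")
  }
  cat("\n")
  cat(render_locus_map(x), sep = "\n")
  invisible(x)
}

#' Render a text map of the locus
#'
#' One line per cluster: index, interval, orientation arrow, segment string
#' in transcription order (pseudogenes marked with a Psi), class label and a
#' repeat flag.
#'
#' @param report A `trm_report`.
#' @return Character vector of lines.
#' @export
render_locus_map <- function(report) {
  cl <- report$clusters
  if (nrow(cl) == 0L) return("  (no clusters)")
  lines <- character(nrow(cl))
  for (i in seq_len(nrow(cl))) {
    sub <- report$segments[!is.na(report$segments$cluster_index) &
                             report$segments$cluster_index == cl$index[i], , drop = FALSE]
    sub <- sub[order(sub$start), , drop = FALSE]
    if (cl$strand[i] == "-") sub <- sub[rev(seq_len(nrow(sub))), , drop = FALSE]
    toks <- paste0(sub$kind, ifelse(sub$pseudogene, "Ψ", ""))
    lines[i] <- sprintf(
      "%-3d [%s..%s]  %s  %-18s (%s)%s",
      i, format(cl$start[i], big.mark = ",", scientific = FALSE),
      format(cl$end[i], big.mark = ",", scientific = FALSE),
      if (cl$strand[i] == "+") ">" else "<",
      paste(toks, collapse = "-"),
      cl$class_label[i],
      if (!is.na(cl$upstream_repeat_start[i])) "  [repeat]" else ""
    )
  }
  lines
}

#' Compare two locus reports
#'
#' Tabulates cluster counts, partial counts and class tallies side by side,
#' and calls synteny conservation from an exact ordered comparison of the
#' user-supplied flanking gene lists.
#'
#' @param a,b `trm_report` objects.
#' @return Character vector of summary lines.
#' @export
compare_loci <- function(a, b) {
  tal <- function(r) {
    if (length(r$class_tally) == 0L) return("-")
    paste(sprintf("%s=%d", names(r$class_tally), r$class_tally), collapse = " ")
  }
  shared <- intersect(names(a$class_tally), names(b$class_tally))
  synteny <- length(a$flanking_genes) > 0 && identical(a$flanking_genes, b$flanking_genes)
  c(
    sprintf("%-22s %-16s %-16s", "", a$locus_id, b$locus_id),
    sprintf("%-22s %-16d %-16d", "clusters", a$n_clusters, b$n_clusters),
    sprintf("%-22s %-16d %-16d", "partial clusters", a$n_partial, b$n_partial),
    sprintf("%-22s %-16s %-16s", "class tally", tal(a), tal(b)),
    sprintf("shared classes: %s", if (length(shared)) paste(shared, collapse = ",") else "none"),
    sprintf("synteny conserved: %s", if (synteny) "yes" else "no")
  )
}

write_report_files <- function(report, genome, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write_gff3(report$segments, file.path(outdir, "annotations.gff3"),
             clusters = rbind(report$clusters[names(empty_clusters())],
                              report$singletons[names(empty_clusters())]),
             repeats = report$repeats, genome = genome)
  writeLines(c(utils::capture.output(print(report))), file.path(outdir, "report.txt"))
  if (!is.null(report$v_matrix)) {
    utils::write.table(report$v_matrix, file.path(outdir, "identity_V.tsv"),
                       sep = "\t", quote = FALSE)
  }
  if (!is.null(report$c_matrix)) {
    utils::write.table(report$c_matrix, file.path(outdir, "identity_C.tsv"),
                       sep = "\t", quote = FALSE)
  }
  jm <- Filter(Negate(is.null), report$junction_maps)
  if (length(jm)) {
    df <- do.call(rbind, lapply(jm, function(m) {
      data.frame(transcript_id = m$transcript_id, v_id = m$v_id, j_id = m$j_id,
                 junction_seq = m$junction_seq, productive = m$productive,
                 stringsAsFactors = FALSE)
    }))
    utils::write.table(df, file.path(outdir, "junctions.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(outdir)
}
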