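#' Evaluate a pipeline result against planted truth
#'
#' Matches predicted segments to planted ones (same kind, same strand except
#' for the strand-symmetric D cores, reciprocal overlap of at least
#' `min_overlap`) and predicted clusters to planted clusters (interval
#' overlap), and summarizes recovery: segment recall/precision, cluster count
#' agreement, per-cluster missing-set agreement, and class-label accuracy.
#'
#' @param report A `trm_report` from [run_pipeline()].
#' @param truth A `synthetic_truth` from [generate_locus()].
#' @param min_overlap Minimum reciprocal overlap fraction, default 0.5.
#' @return List of summary statistics.
#' @export
evaluate_against_truth <- function(report, truth, min_overlap = 0.5) {
  pred <- report$segments
  tr <- truth$segments
  ov_frac <- function(s1, e1, s2, e2) {
    ov <- min(e1, e2) - max(s1, s2) + 1L
    if (ov <= 0L) return(0)
    min(ov / (e1 - s1 + 1L), ov / (e2 - s2 + 1L))
  }
  matched_t <- logical(nrow(tr))
  matched_p <- logical(nrow(pred))
  for (ti in seq_len(nrow(tr))) {
    cand <- which(pred$kind == tr$kind[ti] & !matched_p &
                    (pred$strand == tr$strand[ti] | tr$kind[ti] == "D"))
    for (pi in cand) {
      if (ov_frac(pred$start[pi], pred$end[pi], tr$start[ti], tr$end[ti]) >= min_overlap) {
        matched_t[ti] <- TRUE
        matched_p[pi] <- TRUE
        break
      }
    }
  }
  recall <- if (nrow(tr)) mean(matched_t) else NA_real_
  precision <- if (nrow(pred)) mean(matched_p) else NA_real_

  # cluster matching by interval overlap
  tcl <- truth$clusters
  pcl <- report$clusters
  n_match <- 0L
  missing_ok <- logical(nrow(tcl))
  class_ok <- logical(nrow(tcl))
  cluster_map <- rep(NA_integer_, nrow(tcl))
  for (i in seq_len(nrow(tcl))) {
    ovs <- vapply(seq_len(nrow(pcl)), function(j) {
      max(0L, min(tcl$end[i], pcl$end[j]) - max(tcl$start[i], pcl$start[j]) + 1L)
    }, numeric(1))
    if (length(ovs) == 0L || max(ovs) <= 0) next
    j <- which.max(ovs)
    cluster_map[i] <- j
    n_match <- n_match + 1L
    t_missing <- sort(strsplit(tcl$missing[i], ",")[[1L]])
    p_missing <- sort(strsplit(pcl$missing[j], ",")[[1L]])
    missing_ok[i] <- identical(t_missing, p_missing)
    class_ok[i] <- identical(tcl$class_label[i], pcl$class_label[j])
  }
  list(
    segment_recall = recall,
    segment_precision = precision,
    n_truth_segments = nrow(tr),
    n_pred_segments = nrow(pred),
    n_clusters_truth = nrow(tcl),
    n_clusters_pred = nrow(pcl),
    cluster_count_match = nrow(tcl) == nrow(pcl),
    clusters_matched = n_match,
    missing_sets_match = all(missing_ok[!is.na(cluster_map)]) && n_match == nrow(tcl),
    class_accuracy = if (n_match) mean(class_ok[!is.na(cluster_map)]) else NA_real_
  )
}

#' Run the pipeline on a synthetic truth object
#'
#' Convenience wrapper: builds the pipeline configuration from a
#' `synthetic_truth` (genome + archetype queries, layout from the blueprint),
#' optionally generates junction transcripts, runs [run_pipeline()] and
#' returns both the report and its evaluation.
#'
#' @param truth `synthetic_truth` object.
#' @param transcripts `NULL`, `TRUE` (generate 2 per eligible cluster, seeded
#'   from the blueprint), a number, or a `DNAStringSet`.
#' @param config_overrides Named list merged into the default config.
#' @return List with `report`, `evaluation`, `transcripts`.
#' @export
run_on_truth <- function(truth, transcripts = NULL, config_overrides = list()) {
  tx <- NULL
  if (isTRUE(transcripts) || is.numeric(transcripts)) {
    n_eligible <- sum(truth$clusters$complete)
    n <- if (is.numeric(transcripts)) as.integer(transcripts) else min(12L, 2L * max(1L, n_eligible))
    tx <- tryCatch(
      generate_junction_transcripts(truth, n, rng_seed = truth$blueprint$seed + 17L),
      error = function(e) NULL
    )
  } else if (!is.null(transcripts) && !isFALSE(transcripts)) {
    tx <- transcripts
  }
  cfg <- utils::modifyList(
    list(
      layout = truth$blueprint$layout,
      genome = truth$genome,
      queries = truth$queries,
      transcripts = tx,
      locus_id = paste0("synthetic_", truth$blueprint$layout)
    ),
    config_overrides
  )
  report <- run_pipeline(cfg)
  list(report = report, evaluation = evaluate_against_truth(report, truth),
       transcripts = tx)
}
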