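test_that("mutate_seq hits the requested divergence and is deterministic", {
  set.seed(81)
  s <- rnd_dna(10000)
  expect_identical(mutate_seq(s, 0, rng_seed = 1), s)
  m <- mutate_seq(s, 0.10, rng_seed = 2)
  frac <- mean(strsplit(s, "")[[1]] != strsplit(m, "")[[1]])
  expect_lt(abs(frac - 0.10), 0.01)
  expect_identical(mutate_seq(s, 0.10, rng_seed = 2), m)
  # indels change length but stay deterministic
  mi <- mutate_seq(s, 0.10, rng_seed = 3, indels = TRUE)
  expect_false(nchar(mi) == nchar(s) && identical(mi, m))
  expect_identical(mutate_seq(s, 0.10, rng_seed = 3, indels = TRUE), mi)
})

test_that("blueprint validation catches inconsistent requests", {
  expect_error(locus_blueprint(partial_plan = list("2" = "Q")), "unknown kinds")
  expect_error(locus_blueprint(n_clusters = 3, class_plan = rep("I", 3),
                               duplication_mode = "tandem"),
               "tandem")
  expect_error(locus_blueprint(within_class_divergence = 0.9))
})

test_that("a pristine single cluster is a fixed point of the pipeline", {
  tr <- generate_locus(locus_blueprint(n_clusters = 1L, layout = "marsupial",
                                       within_class_divergence = 0,
                                       between_class_divergence = 0, seed = 82))
  expect_equal(nrow(tr$segments), 5L)
  expect_setequal(tr$segments$kind, c("V", "D", "J", "Vj", "C"))
  res <- run_on_truth(tr, transcripts = TRUE)
  expect_equal(res$evaluation$segment_recall, 1)
  expect_equal(res$evaluation$segment_precision, 1)
  expect_equal(res$report$n_clusters, 1L)
})

test_that("planted RSS motifs score 1.0 and truth GFF3 validates", {
  tr <- generate_locus(locus_blueprint(n_clusters = 3L, layout = "marsupial", seed = 83))
  g <- trmloci:::genome_string(tr$genome)
  for (i in seq_len(nrow(tr$rss))) {
    win <- substr(g, tr$rss$start[i], tr$rss$end[i])
    if (substr(win, 1, 3) != "CAC") win <- reverse_complement(win)
    sl <- nchar(win) - 16L
    hit <- score_rss_window(win, 1L, if (sl > 17L) 23L else 12L, sl)
    expect_equal(hit$score, 1.0)
  }
  f <- withr::local_tempfile(fileext = ".gff3")
  asm <- assemble_clusters(tr$segments)
  write_gff3(asm$segments, f, clusters = asm$clusters, genome = tr$genome)
  back <- rtracklayer::import(f)
  expect_equal(sum(back$type != "vdj_cluster"), nrow(tr$segments))
})

test_that("planted intact segments never flag as pseudogenes", {
  tr <- generate_locus(locus_blueprint(n_clusters = 4L, layout = "marsupial",
                                       within_class_divergence = 0.15, seed = 84))
  for (i in which(tr$segments$kind %in% c("V", "Vj", "C"))) {
    expect_false(flag_pseudogene(tr$segments[i, ], tr$genome))
  }
})

test_that("the same blueprint seed reproduces the genome byte for byte", {
  bp <- locus_blueprint(n_clusters = 3L, layout = "platypus", seed = 85)
  t1 <- generate_locus(bp)
  t2 <- generate_locus(bp)
  expect_identical(as.character(t1$genome), as.character(t2$genome))
  expect_identical(t1$segments, t2$segments)
  expect_identical(t1$clusters, t2$clusters)
})

test_that("generated transcripts map back to their recorded segments", {
  tr <- generate_locus(locus_blueprint(n_clusters = 2L, layout = "marsupial", seed = 86))
  tx <- generate_junction_transcripts(tr, 10L, rng_seed = 9)
  prov <- S4Vectors::metadata(tx)$provenance
  v <- tr$segments[tr$segments$kind == "V", ]
  j <- tr$segments[tr$segments$kind == "J", ]
  ok <- 0L
  for (i in 1:10) {
    jm <- map_transcript(tr$genome, tx[i], v, j)
    expect_false(is.null(jm))
    if (jm$v_id == prov$v_id[i] && jm$j_id == prov$j_id[i]) ok <- ok + 1L
    expect_identical(jm$productive, prov$productive[i])
  }
  expect_equal(ok, 10L)
})

test_that("without trimming or N additions the junction equals the planted D", {
  tr <- generate_locus(locus_blueprint(n_clusters = 1L, layout = "marsupial",
                                       within_class_divergence = 0,
                                       between_class_divergence = 0, seed = 87))
  tx <- generate_junction_transcripts(tr, 3L, n_addition_max = 0L, rng_seed = 10,
                                      trim = FALSE)
  d <- tr$segments[tr$segments$kind == "D", ]
  dseq <- seq_extract(tr$genome, d$seq_id, d$start, d$end, d$strand)
  v <- tr$segments[tr$segments$kind == "V", ]
  j <- tr$segments[tr$segments$kind == "J", ]
  for (i in 1:3) {
    jm <- map_transcript(tr$genome, tx[i], v, j)
    expect_equal(jm$junction_seq, dseq)
  }
})

test_that("the productive fraction concentrates near its target", {
  tr <- generate_locus(locus_blueprint(n_clusters = 2L, layout = "marsupial", seed = 88))
  tx <- generate_junction_transcripts(tr, 1000L, rng_seed = 11)
  prov <- S4Vectors::metadata(tx)$provenance
  expect_lt(abs(mean(prov$productive) - 0.70), 0.04)
})

test_that("partial plans delete segments and the truth records the gap", {
  tr <- generate_locus(locus_blueprint(
    n_clusters = 3L, layout = "marsupial",
    partial_plan = list("2" = c("V", "D")), seed = 89
  ))
  c2 <- tr$segments[!is.na(tr$segments$cluster_index) & tr$segments$cluster_index == 2L, ]
  expect_setequal(c2$kind, c("J", "Vj", "C"))
  expect_false(tr$clusters$complete[2])
  expect_equal(tr$clusters$missing[2], "D,V")
  expect_true(all(tr$clusters$complete[c(1, 3)]))
})
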