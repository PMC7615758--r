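# fixture: one pristine marsupial cluster with known V/D/J coordinates
junction_fixture <- function(seed = 51) {
  bp <- locus_blueprint(n_clusters = 1L, layout = "marsupial",
                        within_class_divergence = 0, between_class_divergence = 0,
                        seed = seed)
  generate_locus(bp)
}

test_that("map_transcript anchors V and J and extracts the junction", {
  tr <- junction_fixture()
  segs <- tr$segments
  v <- segs[segs$kind == "V", ]
  d <- segs[segs$kind == "D", ]
  j <- segs[segs$kind == "J", ]
  g <- tr$genome
  vs <- seq_extract(g, v$seq_id, v$start, v$end, v$strand)
  ds <- seq_extract(g, d$seq_id, d$start, d$end, d$strand)
  js <- seq_extract(g, j$seq_id, j$start, j$end, j$strand)
  # pick junction ends that cannot extend either anchor by chance
  first <- setdiff(c("A", "C", "G", "T"), substr(vs, nchar(vs) - 2, nchar(vs) - 2))[1]
  last <- setdiff(c("A", "C", "G", "T"), substr(js, 2, 2))[1]
  insert <- paste0(first, "GGACTA", last)
  tx <- c(tx1 = paste0(substr(vs, 1, nchar(vs) - 3), insert, substr(js, 3, nchar(js))))
  jm <- map_transcript(g, tx, v, j)
  expect_false(is.null(jm))
  expect_equal(jm$junction_seq, insert)
  expect_equal(jm$v_id, v$segment_id)
  expect_equal(jm$j_id, j$segment_id)
  expect_equal(jm$v_block[2], v$end - 3L)
  expect_equal(jm$j_block[1], j$start + 2L)

  # pure V sequence: no J anchor, soft failure
  expect_null(map_transcript(g, c(tx2 = vs), v, j))

  # one internal mismatch in the V anchor: still mapped, identity below 1
  mid <- 150L
  old <- substr(vs, mid, mid)
  vs_mut <- paste0(substr(vs, 1, mid - 1L),
                   setdiff(c("A", "C", "G", "T"), old)[1],
                   substr(vs, mid + 1L, nchar(vs)))
  tx3 <- c(tx3 = paste0(vs_mut, insert, js))
  jm3 <- map_transcript(g, tx3, v, j)
  expect_false(is.null(jm3))
  expect_lt(jm3$v_identity, 1)
  expect_gt(jm3$v_identity, 0.9)
})

test_that("infer_d_segments recovers a planted D from junctions plus RSS", {
  tr <- junction_fixture()
  segs <- tr$segments
  v <- segs[segs$kind == "V", ]
  d <- segs[segs$kind == "D", ]
  j <- segs[segs$kind == "J", ]
  g <- tr$genome
  tx <- generate_junction_transcripts(tr, 3L, n_addition_max = 2L, rng_seed = 5)
  maps <- lapply(seq_along(tx), function(i) map_transcript(g, tx[i], v, j))
  hits12 <- scan_rss(g, 12L, min_score = 0.9)
  pairs <- pair_rss_for_d(hits12)
  calls <- infer_d_segments(maps, g, pairs, min_d_match = 6L)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$start, d$start)
  expect_equal(calls$end, d$end)
  expect_setequal(strsplit(calls$evidence, ",")[[1]], c("junction", "rss"))
  expect_true(calls$confirmed)
})

test_that("short templated matches do not support a D on their own", {
  set.seed(52)
  g <- rnd_dna(2000)
  jm <- list(
    transcript_id = "t", transcript = "x", v_id = "V1", j_id = "J1",
    v_identity = 1, j_identity = 1,
    v_block = c(100L, 400L), j_block = c(900L, 940L), strand = "+",
    v_tx_range = c(1L, 301L), j_tx_range = c(310L, 350L),
    junction_seq = paste0(substr(g, 500, 503), "TTTT"),  # only 4 bp templated
    v_anchor_frame = 0L, productive = TRUE
  )
  class(jm) <- "junction_map"
  calls <- infer_d_segments(list(jm, jm), g, trmloci:::empty_d_pairs(), min_d_match = 6L)
  expect_equal(nrow(calls), 0L)
})

test_that("an unsupported RSS flank pair is reported as unconfirmed D", {
  set.seed(53)
  core <- rnd_dna(12)
  g <- paste0(rnd_dna(300), reverse_complement(consensus_rss(12)), core,
              consensus_rss(12), rnd_dna(300))
  pairs <- pair_rss_for_d(scan_rss(g, 12L, min_score = 0.9))
  calls <- infer_d_segments(list(), g, pairs)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$evidence, "rss")
  expect_false(calls$confirmed)
  # weak flanks are not enough without junction support
  calls2 <- infer_d_segments(list(), g, pairs, min_flank_score = 1.01)
  expect_equal(nrow(calls2), 0L)
})

test_that("D calls never fall inside annotated segments", {
  set.seed(54)
  core <- rnd_dna(12)
  g <- paste0(rnd_dna(300), reverse_complement(consensus_rss(12)), core,
              consensus_rss(12), rnd_dna(300))
  pairs <- pair_rss_for_d(scan_rss(g, 12L, min_score = 0.9))
  v <- trmloci:::new_segments(
    segment_id = "V1", seq_id = "seq1", start = 200L, end = 400L, strand = "+",
    kind = "V", subtype = "none", evidence = "homology", best_identity = 1,
    best_query = "q", pseudogene = FALSE, cluster_index = NA_integer_, ordinal = 1L
  )
  expect_equal(nrow(infer_d_segments(list(), g, pairs, exclude = v)), 0L)
})

test_that("is_productive demands an in-frame stop-free path to the J motif", {
  v <- trmloci:::rand_orf(40L)             # 120 nt, stop-free in frame 0
  jmotif <- "TTCGGCAAAGGC"
  expect_true(is_productive(paste0(v, "GCA", jmotif), 0L))
  # 1 bp insertion shifts the motif out of frame
  expect_false(is_productive(paste0(v, "G", "GCA", jmotif), 0L))
  # in-frame stop before the motif
  expect_false(is_productive(paste0(v, "TAA", jmotif), 0L))
})

test_that("productivity is invariant to 5' padding by whole codons", {
  set.seed(55)
  v <- trmloci:::rand_orf(30L)
  jmotif <- "TTCGGCAAAGGC"
  tx <- paste0(v, jmotif)
  base <- is_productive(tx, 0L)
  for (k in 1:4) {
    expect_identical(is_productive(paste0(strrep("GCA", k), tx), 0L), base)
  }
})
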