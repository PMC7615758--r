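# shared fixture: a clean J body (F-G-K-G motif in codons 3-6, GT donor after)
make_j_fixture <- function() {
  j_coding <- paste0("GCTAGA", "TTCGGCAAAGGC", "GCAACCATAGCAACCATAGCA")  # 39 bp
  list(coding = j_coding, donor = "GTAAGT")
}

test_that("annotate_j calls a J next to an RSS with motif and GT donor", {
  set.seed(41)
  j <- make_j_fixture()
  s <- paste0(rnd_dna(200), reverse_complement(consensus_rss(23)),
              j$coding, j$donor, rnd_dna(200))
  hits <- scan_rss(s, 23L, min_score = 0.9)
  out <- annotate_j(s, hits)
  expect_equal(nrow(out), 1L)
  expect_equal(out$start, 240L)             # immediately 3' of the RSS
  expect_equal(out$end, 239L + nchar(j$coding))
  expect_equal(out$strand, "+")
  expect_setequal(strsplit(out$evidence, ",")[[1]], c("motif", "rss"))

  # same J body with no upstream RSS: no candidate
  s2 <- paste0(rnd_dna(239), j$coding, j$donor, rnd_dna(200))
  hits2 <- scan_rss(s2, 23L, min_score = 0.9)
  expect_equal(nrow(annotate_j(s2, hits2)), 0L)
})

test_that("annotate_j works on the minus strand", {
  set.seed(42)
  j <- make_j_fixture()
  plus <- paste0(rnd_dna(200), reverse_complement(consensus_rss(23)),
                 j$coding, j$donor, rnd_dna(200))
  s <- reverse_complement(plus)
  hits <- rbind(scan_rss(s, 23L, min_score = 0.9))
  out <- annotate_j(s, hits)
  expect_equal(nrow(out), 1L)
  expect_equal(out$strand, "-")
  L <- nchar(s)
  expect_equal(out$end, L - 240L + 1L)
})

test_that("the W variant of the J motif is accepted, matching a regex oracle", {
  j_w <- paste0("GCTAGA", "TGGGGCCAAGGC", "GCAACCATAGCAACCATAGCA")  # W-G-Q-G
  got <- trmloci:::find_j_in_window(paste0(j_w, "GTAAGT"))
  expect_false(is.null(got))
  set.seed(43)
  for (i in 1:100) {
    aa <- trmloci::translate_nt(rnd_dna(60), 0)
    expect_identical(
      grepl("[FW]G.G", aa),
      regexpr("[FW]G.G", aa) > 0
    )
  }
})

test_that("flag_pseudogene follows the stop-codon and frameshift rules", {
  set.seed(44)
  intact <- trmloci:::rand_orf(100L)
  seg <- trmloci:::new_segments(
    segment_id = "V1", seq_id = "g", start = 101L, end = 400L, strand = "+",
    kind = "V", subtype = "none", evidence = "homology", best_identity = 1,
    best_query = "q", pseudogene = FALSE, cluster_index = NA_integer_, ordinal = 1L
  )
  g <- paste0(rnd_dna(100), intact, rnd_dna(100))
  expect_false(flag_pseudogene(seg, g))

  # single-base deletion: frameshift detected via alignment to the query
  shifted <- paste0(substr(intact, 1, 150), substr(intact, 152, 300))
  g2 <- paste0(rnd_dna(100), shifted, rnd_dna(100))
  seg2 <- seg; seg2$end <- 399L
  expect_true(flag_pseudogene(seg2, g2, query = intact))

  # stops in all three frames (TAAA repeats phase through TAA in every frame)
  allstop <- strrep("TAAA", 30)
  g3 <- paste0(rnd_dna(100), allstop, rnd_dna(100))
  seg3 <- seg; seg3$end <- 100L + nchar(allstop)
  expect_true(flag_pseudogene(seg3, g3))
})

test_that("classify_v_subtype applies the downstream-D rule and fallbacks", {
  v <- trmloci:::new_segments(
    segment_id = "V1", seq_id = "g", start = 1000L, end = 1300L, strand = "+",
    kind = "V", subtype = "none", evidence = "homology", best_identity = 1,
    best_query = "q", pseudogene = FALSE, cluster_index = NA_integer_, ordinal = 1L
  )
  d <- trmloci:::new_segments(
    segment_id = "D1", seq_id = "g", start = 1600L, end = 1611L, strand = "+",
    kind = "D", subtype = "none", evidence = "rss", best_identity = NA_real_,
    best_query = NA_character_, pseudogene = FALSE, cluster_index = NA_integer_,
    ordinal = 1L
  )
  j <- trmloci:::new_segments(
    segment_id = "J1", seq_id = "g", start = 2000L, end = 2040L, strand = "+",
    kind = "J", subtype = "none", evidence = "motif,rss", best_identity = NA_real_,
    best_query = NA_character_, pseudogene = FALSE, cluster_index = NA_integer_,
    ordinal = 1L
  )
  segs <- rbind(v, j)
  # D 300 bp downstream before the next J: Vmu1
  expect_equal(classify_v_subtype(v, d, segments = segs)$subtype, "Vmu1")
  # clustered (J nearby) but no D: Vmu2
  none <- d[0, ]
  expect_equal(classify_v_subtype(v, none, segments = segs)$subtype, "Vmu2")
  # isolated V: identity fallback
  alone <- v
  st <- classify_v_subtype(alone, none, identity_to_refs = c(Vmu1 = 0.92, Vmu2 = 0.61),
                           segments = v)
  expect_equal(st$subtype, "Vmu1")
  expect_false(st$low_confidence)
  # tie: Vmu2 with a low-confidence flag
  st2 <- classify_v_subtype(alone, none, identity_to_refs = c(Vmu1 = 0.8, Vmu2 = 0.8),
                            segments = v)
  expect_equal(st2$subtype, "Vmu2")
  expect_true(st2$low_confidence)
})

test_that("v_landmarks finds the planted framework cysteines", {
  set.seed(45)
  v <- trmloci:::make_v_body()
  lm <- v_landmarks(v$seq)
  expect_equal(lm$frame, 0L)
  expect_equal(lm$cys1, 22L)
  expect_equal(lm$cys2, 96L)
  expect_equal(lm$trp, 36L)
  expect_equal(lm$fr_start, 64L)
  expect_equal(lm$fr_end, 288L)
})
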