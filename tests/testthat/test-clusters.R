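seg_row <- function(id, kind, start, end, strand = "+", cluster = NA_integer_) {
  trmloci:::new_segments(
    segment_id = id, seq_id = "g", start = as.integer(start), end = as.integer(end),
    strand = strand, kind = kind, subtype = "none", evidence = "homology",
    best_identity = NA_real_, best_query = NA_character_, pseudogene = FALSE,
    cluster_index = cluster, ordinal = NA_integer_
  )
}

test_that("assemble_clusters groups planted clusters and respects orientation", {
  tr <- generate_locus(locus_blueprint(n_clusters = 6L, layout = "marsupial",
                                       duplication_mode = "singlet", seed = 71))
  asm <- assemble_clusters(tr$segments)
  expect_equal(nrow(asm$clusters), 6L)
  for (i in 1:6) {
    expect_gte(asm$clusters$start[i], tr$clusters$start[i] - 1L)
    expect_lte(asm$clusters$end[i], tr$clusters$end[i] + 1L)
    expect_equal(asm$clusters$strand[i], tr$clusters$strand[i])
  }
  # every segment belongs to exactly one cluster; intervals never overlap
  expect_true(all(!is.na(asm$segments$cluster_index)))
  cl <- asm$clusters[order(asm$clusters$start), ]
  expect_true(all(cl$start[-1] > cl$end[-nrow(cl)]))
})

test_that("opposite-strand neighbours are never merged", {
  a <- rbind(
    seg_row("V1", "V", 1000, 1300), seg_row("C1", "C", 2000, 2400),
    seg_row("C2", "C", 3400, 3800, "-"), seg_row("V2", "V", 4500, 4800, "-")
  )
  asm <- assemble_clusters(a, max_intra_gap = 50000L)
  expect_equal(nrow(asm$clusters), 2L)
  expect_setequal(asm$clusters$strand, c("-", "+"))
})

test_that("a lone V becomes an orphan cluster with a warning", {
  expect_warning(asm <- assemble_clusters(seg_row("V1", "V", 1000, 1300)),
                 "orphan")
  expect_equal(nrow(asm$clusters), 1L)
  cc <- call_completeness(asm$clusters[1, ], c("V", "D", "J", "Vj", "C"))
  expect_false(cc$complete)
  expect_setequal(cc$missing, c("D", "J", "Vj", "C"))
})

test_that("assembly is invariant to input segment order", {
  tr <- generate_locus(locus_blueprint(n_clusters = 4L, layout = "marsupial", seed = 72))
  a1 <- assemble_clusters(tr$segments)
  set.seed(1)
  a2 <- assemble_clusters(tr$segments[sample(nrow(tr$segments)), ])
  expect_equal(a1$clusters, a2$clusters)
  expect_equal(a1$segments, a2$segments)
})

test_that("call_completeness reports missing kinds with multiplicity", {
  expect_equal(call_completeness("J-Vj-C", c("V", "D", "J", "Vj", "C"))$missing,
               c("D", "V"))
  expect_equal(call_completeness("D-J-Vj-C", c("V", "D", "J", "Vj", "C"))$missing, "V")
  full <- call_completeness("V-D-J-Vj-C", c("V", "D", "J", "Vj", "C"))
  expect_true(full$complete)
  expect_length(full$missing, 0L)
  # platypus layout needs two V and two J
  expect_equal(call_completeness("V-D-J-J-C", c("V", "D", "J", "V", "J", "C"))$missing, "V")
})

test_that("shared upstream repeats are found and attached to clusters", {
  tr <- generate_locus(locus_blueprint(
    n_clusters = 5L, layout = "marsupial", duplication_mode = "singlet",
    repeat_before = c(1L, 3L, 5L), cluster_strands = rep("+", 5L), seed = 73
  ))
  asm <- assemble_clusters(tr$segments)
  fr <- find_upstream_repeats(tr$genome, asm$clusters, flank = 2000L)
  expect_equal(sort(unique(fr$repeats$cluster_index)), c(1L, 3L, 5L))
  expect_equal(length(unique(fr$repeats$family)), 1L)
  got_rep <- !is.na(fr$clusters$upstream_repeat_start)
  expect_equal(which(got_rep), c(1L, 3L, 5L))
  # each copy records its partners
  expect_true(all(nchar(fr$repeats$copy_partners) > 0))
})

test_that("unique flanks yield no repeat elements", {
  tr <- generate_locus(locus_blueprint(n_clusters = 4L, layout = "marsupial",
                                       repeat_before = integer(0), seed = 74))
  asm <- assemble_clusters(tr$segments)
  fr <- find_upstream_repeats(tr$genome, asm$clusters, flank = 2000L)
  expect_equal(nrow(fr$repeats), 0L)
})

test_that("heavily diverged repeat copies fall below the identity bar", {
  set.seed(75)
  el <- rnd_dna(1500)
  el2 <- mutate_seq(el, 0.25, rng_seed = 750)  # ~25% divergence: < 80% identity
  g <- paste0(rnd_dna(500), el, rnd_dna(300), "CCC",
              rnd_dna(4000), el2, rnd_dna(300), "CCC", rnd_dna(500))
  cl <- data.frame(
    index = 1:2, cluster_id = c("c1", "c2"), seq_id = "g",
    start = c(2304L, 8107L), end = c(2350L, 8150L), strand = "+",
    n_segments = 2L, kinds = "V-C", has_c = TRUE, complete = TRUE,
    missing = "", class_label = "I",
    upstream_repeat_start = NA_integer_, upstream_repeat_end = NA_integer_,
    stringsAsFactors = FALSE
  )
  fr <- find_upstream_repeats(g, cl, flank = 2000L)
  expect_equal(nrow(fr$repeats), 0L)
})

test_that("duplication patterns: tandem pairs, singlets, unlabeled", {
  mk <- function(labels, reps) {
    data.frame(
      index = seq_along(labels), class_label = labels,
      upstream_repeat_start = ifelse(reps, 1L, NA_integer_),
      upstream_repeat_end = ifelse(reps, 2L, NA_integer_),
      stringsAsFactors = FALSE
    )
  }
  # alternating classes, repeat before each odd cluster: tandem pairs
  tandem <- infer_duplication_pattern(mk(rep(c("II", "III"), 3),
                                         rep(c(TRUE, FALSE), 3)))
  expect_equal(tandem$pattern, rep("tandem_pair", 3))
  expect_equal(tandem$i, c(1L, 3L, 5L))
  expect_equal(tandem$j, c(2L, 4L, 6L))
  # same class everywhere, repeat before every cluster: singlets
  singl <- infer_duplication_pattern(mk(rep("III", 4), rep(TRUE, 4)))
  expect_equal(singl$pattern, rep("singlet", 4))
  # no repeats at all: unlabeled
  none <- infer_duplication_pattern(mk(c("II", "III"), c(FALSE, FALSE)))
  expect_equal(none$pattern, rep("unlabeled", 2))
})
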