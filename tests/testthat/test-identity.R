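test_that("global_identity matches hand-countable cases", {
  set.seed(61)
  a <- rnd_dna(300)
  expect_equal(global_identity(a, a), 1.0)
  # substitute exactly 30 of 300 positions: identity 0.90, no gaps involved
  ch <- strsplit(a, "")[[1]]
  idx <- sample(300, 30)
  for (i in idx) ch[i] <- setdiff(c("A", "C", "G", "T"), ch[i])[1]
  b <- paste(ch, collapse = "")
  expect_equal(global_identity(a, b), 0.90)
})

test_that("global identity is symmetric", {
  set.seed(62)
  for (i in 1:50) {
    a <- rnd_dna(sample(20:80, 1))
    b <- rnd_dna(sample(20:80, 1))
    expect_equal(global_identity(a, b), global_identity(b, a))
  }
})

test_that("identity matrices are symmetric with unit diagonal", {
  set.seed(63)
  seqs <- vapply(1:8, function(i) rnd_dna(60), "")
  names(seqs) <- paste0("s", 1:8)
  m <- build_identity_matrix(seqs)
  expect_equal(diag(m), setNames(rep(1, 8), names(seqs)))
  expect_equal(m, t(m))
  expect_true(all(m >= 0 & m <= 1))
  expect_error(build_identity_matrix(setNames(seqs, rep("x", 8))), "duplicate")
  m3 <- build_identity_matrix(c(a = "ACGTACGT", b = "ACGTACGT", c = "ACGTACGT"))
  expect_true(all(m3 == 1))
})

test_that("planted class structure separates within from between identities", {
  set.seed(64)
  anc <- rnd_dna(240)
  arch <- lapply(1:3, function(k) mutate_seq(anc, 0.20, rng_seed = 640 + k))
  seqs <- character(0)
  lab <- character(0)
  for (k in 1:3) for (r in 1:3) {
    seqs <- c(seqs, mutate_seq(arch[[k]], 0.05, rng_seed = 6400 + 10 * k + r))
    lab <- c(lab, k)
  }
  names(seqs) <- paste0("s", seq_along(seqs))
  m <- build_identity_matrix(seqs)
  within <- m[outer(lab, lab, "==") & upper.tri(m)]
  between <- m[outer(lab, lab, "!=") & upper.tri(m)]
  expect_gt(min(within), 0.85)
  expect_lt(max(between), 0.75)
})

test_that("class assignment is strict at the threshold", {
  m <- matrix(c(
    1.00, 0.80, 0.75, 0.60,
    0.80, 1.00, 0.70, 0.58,
    0.75, 0.70, 1.00, 0.55,
    0.60, 0.58, 0.55, 1.00
  ), 4, 4, dimnames = list(c("refII", "q80", "q75", "qlow"),
                           c("refII", "q80", "q75", "qlow")))
  out <- assign_classes(m, c(refII = "II"), threshold = 0.75)
  expect_equal(out$label[out$id == "q80"], "II")
  expect_equal(out$label[out$id == "q75"], "unassigned")   # strictly greater only
  expect_equal(out$label[out$id == "qlow"], "unassigned")
  expect_equal(out$best_identity[out$id == "q75"], 0.75)
})

test_that("distant families form their own new class", {
  # platypus-like: below 64% to every reference, above 75% among themselves
  m <- matrix(0.55, 5, 5)
  ids <- c("refI", "refII", "p1", "p2", "p3")
  dimnames(m) <- list(ids, ids)
  diag(m) <- 1
  m["refI", "refII"] <- m["refII", "refI"] <- 0.70
  for (i in c("p1", "p2", "p3")) for (j in c("p1", "p2", "p3")) {
    if (i != j) m[i, j] <- 0.88
  }
  for (i in c("p1", "p2", "p3")) {
    m[i, c("refI", "refII")] <- 0.60
    m[c("refI", "refII"), i] <- 0.60
  }
  out <- assign_classes(m, c(refI = "I", refII = "II"), threshold = 0.75)
  expect_true(all(out$label[out$id %in% c("p1", "p2", "p3")] == "new-class-1"))
})

test_that("assign_classes is idempotent and monotone in the threshold", {
  set.seed(65)
  anc <- rnd_dna(200)
  seqs <- c(
    ref1 = mutate_seq(anc, 0.05, 1), q1 = mutate_seq(anc, 0.08, 2),
    q2 = mutate_seq(anc, 0.12, 3),
    far1 = rnd_dna(200), far2 = NA
  )
  seqs[["far2"]] <- mutate_seq(seqs[["far1"]], 0.10, 4)
  m <- build_identity_matrix(seqs)
  out <- assign_classes(m, c(ref1 = "A"), threshold = 0.75)
  # idempotence: feed the produced labels back as references
  labs <- setNames(out$label, out$id)
  labs <- labs[labs != "unassigned"]
  again <- assign_classes(m, c(c(ref1 = "A"), labs), threshold = 0.75)
  # queries not yet labeled stay exactly as before
  for (id in again$id) {
    expect_equal(again$label[again$id == id], out$label[out$id == id])
  }
  # monotonicity: lowering the threshold never unassigns
  lo <- assign_classes(m, c(ref1 = "A"), threshold = 0.60)
  for (id in out$id[out$label != "unassigned"]) {
    expect_true(lo$label[lo$id == id] != "unassigned")
  }
})

test_that("extract_fr_region spans the planted framework cysteines", {
  tr <- generate_locus(locus_blueprint(n_clusters = 1L, layout = "marsupial",
                                       within_class_divergence = 0,
                                       between_class_divergence = 0, seed = 66))
  v <- tr$segments[tr$segments$kind == "V", ]
  fr <- extract_fr_region(v, tr$genome)
  expect_true(attr(fr, "landmarks_found"))
  expect_equal(nchar(fr), 225L)  # codons 22..96 inclusive
  vs <- seq_extract(tr$genome, v$seq_id, v$start, v$end, v$strand)
  expect_equal(as.character(fr), substr(vs, 64, 288))
  # a Vj is V-homologous: same rule applies
  vj <- tr$segments[tr$segments$kind == "Vj", ]
  frj <- extract_fr_region(vj, tr$genome)
  expect_true(attr(frj, "landmarks_found"))
  expect_equal(nchar(frj), 225L)
})

test_that("label_clusters uses majority with V priority on conflict", {
  cl <- data.frame(index = 1:3, class_label = "unassigned", stringsAsFactors = FALSE)
  segs <- trmloci:::new_segments(
    segment_id = c("V1", "C1", "C2", "V2", "C3"),
    seq_id = "g", start = c(1, 100, 200, 300, 400), end = c(50, 150, 250, 350, 450),
    strand = "+", kind = c("V", "C", "C", "V", "C"), subtype = "none",
    evidence = "homology", best_identity = 1, best_query = "q",
    pseudogene = FALSE, cluster_index = c(1L, 1L, 2L, 3L, 3L), ordinal = 1:5
  )
  va <- data.frame(id = c("V1", "V2"), label = c("II", "unassigned"),
                   best_reference = NA, best_identity = NA, stringsAsFactors = FALSE)
  ca <- data.frame(id = c("C1", "C2", "C3"), label = c("III", "II", "III"),
                   best_reference = NA, best_identity = NA, stringsAsFactors = FALSE)
  out <- label_clusters(cl, segs, va, ca)
  expect_equal(out$class_label[1], "II")      # V wins the conflict
  expect_true(out$class_conflict[1])
  expect_equal(out$class_label[2], "II")      # C-only cluster takes the C label
  expect_equal(out$class_label[3], "III")     # V unassigned, C decides
})
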