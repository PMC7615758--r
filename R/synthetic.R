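#' @name synthetic_locus
#' @title Synthetic TRM-like loci with planted ground truth
#'
#' @description
#' Generates genomes containing cluster-organized antigen-receptor loci with
#' known (planted) annotation: RSS-flanked V/D/J segments, germline-joined Vj
#' genes, C genes, class-structured divergence between cluster copies,
#' tandem/singlet duplication with shared upstream repeat elements, partial
#' clusters, and recombined V-D-J junction transcripts. Every pipeline stage
#' can be validated against the emitted truth tables without any download.
#'
#' Divergence is modelled as i.i.d. substitutions. Class archetypes are
#' mutated from a common ancestral cluster at half the nominal between-class
#' divergence and cluster copies at half the within-class divergence, so that
#' *pairwise* distances match the nominal rates. Planted RSS motifs, framework
#' cysteine/tryptophan landmarks, the J motif and splice donors are protected
#' from mutation, and coding spans are mutated codon-aware so no stop codons
#' are introduced (planted intact segments never look like pseudogenes).
NULL

# run code with a private, restored RNG stream
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

rand_dna <- function(n) {
  if (n <= 0L) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

stop_codons <- c("TAA", "TAG", "TGA")
sense_codons <- local({
  b <- c("A", "C", "G", "T")
  all <- as.vector(outer(outer(b, b, paste0), b, paste0))
  setdiff(all, stop_codons)
})

rand_orf <- function(n_codons) {
  paste(sample(sense_codons, n_codons, replace = TRUE), collapse = "")
}

# substitution-only mutation using the ambient RNG stream
mutate_sub <- function(seq, divergence, protect = integer(0)) {
  n <- nchar(seq)
  if (n == 0L || divergence <= 0) return(seq)
  hit <- which(stats::runif(n) < divergence)
  hit <- setdiff(hit, protect)
  if (length(hit) == 0L) return(seq)
  ch <- strsplit(seq, "")[[1L]]
  alt <- list(A = c("C", "G", "T"), C = c("A", "G", "T"),
              G = c("A", "C", "T"), T = c("A", "C", "G"),
              N = c("A", "C", "G", "T"))
  for (i in hit) ch[i] <- sample(alt[[ch[i]]], 1L)
  paste(ch, collapse = "")
}

# codon-aware mutation of a frame-0 coding span: protected positions fixed,
# codons that would become stops revert to the original codon
mutate_coding <- function(seq, divergence, protect = integer(0)) {
  out <- mutate_sub(seq, divergence, protect)
  n <- nchar(out) %/% 3L
  if (n == 0L) return(out)
  starts <- seq.int(1L, by = 3L, length.out = n)
  cods <- substring(out, starts, starts + 2L)
  bad <- which(cods %in% stop_codons)
  if (length(bad)) {
    orig <- substring(seq, starts, starts + 2L)
    for (b in bad) cods[b] <- orig[b]
    out <- paste(cods, collapse = "")
    if (nchar(seq) %% 3L != 0L) {
      out <- paste0(out, substr(seq, 3L * n + 1L, nchar(seq)))
    }
  }
  out
}

#' Mutate a sequence at a fixed expected divergence
#'
#' I.i.d. substitutions at expected rate `divergence` (each hit site gets one
#' of the three other bases); optionally indels at rate `divergence / 10`
#' with geometric(0.5) lengths. Deterministic given `rng_seed`.
#'
#' @param seq Nucleotide string.
#' @param divergence Expected substitutions per site, in `[0, 0.75)`.
#' @param rng_seed Integer seed.
#' @param indels Add indels at rate `divergence/10` (default FALSE).
#' @return Mutated string.
#' @export
mutate_seq <- function(seq, divergence, rng_seed, indels = FALSE) {
  stopifnot(divergence >= 0, divergence < 0.75)
  with_seed(rng_seed, {
    out <- mutate_sub(seq, divergence)
    if (indels && divergence > 0) {
      n <- nchar(out)
      sites <- which(stats::runif(n) < divergence / 10)
      if (length(sites)) {
        ch <- strsplit(out, "")[[1L]]
        pieces <- character(0)
        prev <- 1L
        for (p in sites) {
          len <- stats::rgeom(1L, 0.5) + 1L
          if (stats::runif(1L) < 0.5) {
            # deletion of `len` bases starting at p
            pieces <- c(pieces, substr(out, prev, p - 1L))
            prev <- min(n + 1L, p + len)
          } else {
            pieces <- c(pieces, substr(out, prev, p), rand_dna(len))
            prev <- p + 1L
          }
        }
        pieces <- c(pieces, substr(out, prev, n))
        out <- paste(pieces, collapse = "")
      }
    }
    out
  })
}

# ---- part construction -----------------------------------------------------

part <- function(unit, role, kind = NA_character_, subtype = "none",
                 seq = "", protect = integer(0), mut = "plain") {
  list(unit = unit, role = role, kind = kind, subtype = subtype,
       seq = seq, protect = protect, mut = mut)
}

rss_fwd <- function(class) {
  paste0(rss_heptamer, rand_dna(class), rss_nonamer)
}
rss_rev <- function(class) reverse_complement(rss_fwd(class))

make_v_body <- function() {
  # the body avoids chance Cys/Trp codons so the planted landmarks are the
  # only framework anchors a scanner can find
  pool <- setdiff(sense_codons, c("TGT", "TGC", "TGG"))
  cods <- sample(pool, 100L, replace = TRUE)
  cods[22L] <- "TGC"   # FR1 first cysteine
  cods[36L] <- "TGG"   # conserved tryptophan, 14 codons later
  cods[96L] <- "TGT"   # FR3 second cysteine
  list(seq = paste(cods, collapse = ""),
       protect = c(64:66, 106:108, 286:288))
}

make_j_body <- function() {
  pool <- setdiff(sense_codons, c("TTT", "TTC", "TGG"))  # no F/W before the motif
  for (try in 1:200) {
    cods <- sample(pool, 13L, replace = TRUE)
    cods[3:6] <- c("TTC", "GGC", "AAA", "GGC")   # F G K G
    seq <- paste(cods, collapse = "")
    # no premature splice-donor dinucleotide after the motif
    if (grepl("GT", substr(seq, 19L, 39L), fixed = TRUE)) next
    probe <- paste0(seq, "GTAAGT", rand_orf(10L))
    got <- find_j_in_window(probe)
    if (!is.null(got) && got$end == nchar(seq)) {
      return(list(seq = seq, protect = 7:39))
    }
  }
  stop("could not construct a clean J body")
}

gap_part <- function(unit, len) part(unit, "spacer", seq = rand_dna(len))

# ancestral cluster as an ordered part list
ancestral_parts <- function(layout) {
  v <- make_v_body()
  j <- make_j_body()
  cbody <- rand_orf(150L)
  g <- function(u) gap_part(u, sample(200:450, 1L))
  d_unit <- function(unit) list(
    part(unit, "rss", seq = rss_rev(12L)),
    part(unit, "segment", kind = "D", seq = rand_dna(12L), mut = "plain"),
    part(unit, "rss", seq = rss_fwd(12L))
  )
  j_unit <- function(unit, class) list(
    part(unit, "rss", seq = rss_rev(class)),
    part(unit, "segment", kind = "J", seq = j$seq, protect = j$protect, mut = "coding"),
    part(unit, "donor", seq = "GTAAGT")
  )
  if (layout == "marsupial") {
    vj_body <- paste0(v$seq, j$seq)   # germline-joined: V body + J block in frame
    c(
      list(part("V", "segment", kind = "V", seq = v$seq, protect = v$protect, mut = "coding"),
           part("V", "rss", seq = rss_fwd(23L)),
           g("gap1")),
      d_unit("D"),
      list(g("gap2")),
      j_unit("J", 23L),
      list(g("gap3"),
           part("Vj", "segment", kind = "Vj", seq = vj_body,
                protect = c(v$protect, 300L + j$protect), mut = "coding"),
           g("gap4"),
           part("C", "segment", kind = "C", seq = cbody, mut = "coding"))
    )
  } else {
    v2 <- make_v_body()
    c(
      list(part("V", "segment", kind = "V", subtype = "Vmu1", seq = v$seq,
                protect = v$protect, mut = "coding"),
           part("V", "rss", seq = rss_fwd(23L)),
           g("gap1")),
      d_unit("D"),
      list(g("gap2")),
      d_unit("D2"),
      list(g("gap3")),
      j_unit("J", 23L),
      list(g("gap4"),
           part("V2", "segment", kind = "V", subtype = "Vmu2", seq = v2$seq,
                protect = v2$protect, mut = "coding"),
           part("V2", "rss", seq = rss_fwd(23L)),
           g("gap5")),
      j_unit("J2", 12L),
      list(g("gap6"),
           part("C", "segment", kind = "C", seq = cbody, mut = "coding"))
    )
  }
}

mutate_parts <- function(parts, divergence) {
  lapply(parts, function(p) {
    if (divergence <= 0 || p$role %in% c("rss", "donor")) return(p)
    p$seq <- switch(p$mut,
      coding = mutate_coding(p$seq, divergence, p$protect),
      plain = mutate_sub(p$seq, divergence, p$protect)
    )
    p
  })
}

# drop the first unit carrying each missing kind (with its RSS/donor parts)
delete_kinds <- function(parts, kinds) {
  for (k in kinds) {
    seg_units <- vapply(parts, function(p) {
      if (p$role == "segment" && p$kind == k) p$unit else NA_character_
    }, character(1))
    u <- seg_units[!is.na(seg_units)][1L]
    if (is.na(u)) next
    parts <- Filter(function(p) p$unit != u, parts)
  }
  parts
}

# concatenate parts into a block; return seq + local feature tables
assemble_block <- function(parts, strand) {
  lens <- vapply(parts, function(p) nchar(p$seq), integer(1))
  ends <- cumsum(lens)
  starts <- ends - lens + 1L
  B <- ends[length(ends)]
  seq <- paste(vapply(parts, `[[`, "", "seq"), collapse = "")
  segs <- list(); rss <- list()
  for (i in seq_along(parts)) {
    p <- parts[[i]]
    if (p$role == "segment") {
      segs[[length(segs) + 1L]] <- data.frame(
        unit = p$unit, kind = p$kind, subtype = p$subtype,
        start = starts[i], end = ends[i], stringsAsFactors = FALSE
      )
    } else if (p$role == "rss") {
      rss[[length(rss) + 1L]] <- data.frame(
        start = starts[i], end = ends[i], stringsAsFactors = FALSE
      )
    }
  }
  segs <- if (length(segs)) do.call(rbind, segs) else NULL
  rss <- if (length(rss)) do.call(rbind, rss) else NULL
  if (strand == "-") {
    seq <- reverse_complement(seq)
    flip <- function(df) {
      if (is.null(df)) return(df)
      s <- B - df$end + 1L
      df$end <- B - df$start + 1L
      df$start <- s
      df[order(df$start), , drop = FALSE]
    }
    segs <- flip(segs); rss <- flip(rss)
  }
  list(seq = seq, len = B, segments = segs, rss = rss)
}

#' Construct a synthetic-locus blueprint
#'
#' The blueprint fixes everything about a planted locus: cluster count and
#' layout, per-cluster class labels, nominal within/between-class divergence,
#' partial-cluster deletions, duplication mode (which decides where upstream
#' repeat elements are planted), extra singleton segments (platypus-style
#' interspersed genes), spacer sizes and the seed.
#'
#' @param n_clusters Number of clusters (>= 1).
#' @param layout `"marsupial"` (`V-D-J-Vj-C`) or `"platypus"`
#'   (`V1-D-D-J1-V2-J2-C`).
#' @param class_plan Character vector of class labels per cluster; default:
#'   `I`, then alternating `II`/`III`.
#' @param within_class_divergence,between_class_divergence Expected pairwise
#'   substitutions/site within and between classes, in `[0, 0.75)`.
#' @param partial_plan Named list: cluster index (as character) -> kinds to
#'   delete, e.g. `list("4" = c("V","D"))`.
#' @param duplication_mode `"tandem"`, `"singlet"` or `"mixed"`; decides the
#'   default repeat placement (before the first cluster of each tandem pair,
#'   or before every cluster).
#' @param repeat_before Optional integer vector of cluster indices that get an
#'   upstream repeat copy (overrides the mode-derived default).
#' @param repeat_length Repeat element length in bp (default 1500).
#' @param spacer_length_range Inter-cluster spacer range in bp before scaling.
#' @param scale Multiplier applied to inter-cluster spacers (default 0.1 for
#'   desk-speed loci).
#' @param cluster_strands Optional `+`/`-` vector per cluster (default: first
#'   `+`, the rest drawn at 70% `+`).
#' @param n_extra_v1,n_extra_v2,n_extra_c Interspersed singleton segments
#'   planted outside clusters (platypus-style).
#' @param seed Integer RNG seed.
#' @return A `locus_blueprint` list.
#' @export
locus_blueprint <- function(n_clusters = 6L, layout = c("marsupial", "platypus"),
                            class_plan = NULL,
                            within_class_divergence = 0.10,
                            between_class_divergence = 0.40,
                            partial_plan = list(),
                            duplication_mode = c("tandem", "singlet", "mixed"),
                            repeat_before = NULL, repeat_length = 1500L,
                            spacer_length_range = c(20000L, 120000L),
                            scale = 0.1, cluster_strands = NULL,
                            n_extra_v1 = 0L, n_extra_v2 = 0L, n_extra_c = 0L,
                            seed = 1L) {
  layout <- match.arg(layout)
  duplication_mode <- match.arg(duplication_mode)
  stopifnot(n_clusters >= 1L,
            within_class_divergence >= 0, within_class_divergence < 0.75,
            between_class_divergence >= 0, between_class_divergence < 0.75)
  if (is.null(class_plan)) {
    class_plan <- c("I", rep(c("II", "III"), length.out = max(0L, n_clusters - 1L)))
    class_plan <- class_plan[seq_len(n_clusters)]
  }
  stopifnot(length(class_plan) == n_clusters)
  bad <- setdiff(unlist(partial_plan), c("V", "D", "J", "Vj", "C"))
  if (length(bad)) stop("unknown kinds in partial_plan: ", paste(bad, collapse = ","))
  if (duplication_mode == "tandem" && n_clusters >= 2L &&
      !any(class_plan[-n_clusters] != class_plan[-1L])) {
    stop("tandem duplication mode needs at least one adjacent pair of distinct classes")
  }
  if (is.null(repeat_before)) {
    repeat_before <- derive_repeat_plan(class_plan, duplication_mode)
  }
  bp <- list(
    n_clusters = as.integer(n_clusters), layout = layout, class_plan = class_plan,
    within_class_divergence = within_class_divergence,
    between_class_divergence = between_class_divergence,
    partial_plan = partial_plan, duplication_mode = duplication_mode,
    repeat_before = as.integer(repeat_before), repeat_length = as.integer(repeat_length),
    spacer_length_range = as.integer(spacer_length_range), scale = scale,
    cluster_strands = cluster_strands,
    n_extra_v1 = as.integer(n_extra_v1), n_extra_v2 = as.integer(n_extra_v2),
    n_extra_c = as.integer(n_extra_c), seed = as.integer(seed)
  )
  class(bp) <- "locus_blueprint"
  bp
}

# greedy pairing: adjacent clusters with distinct labels duplicate as a
# tandem pair (repeat before the first); everything else is a singlet
derive_repeat_plan <- function(class_plan, mode) {
  n <- length(class_plan)
  if (mode == "singlet") return(seq_len(n))
  out <- integer(0)
  i <- 1L
  while (i <= n) {
    out <- c(out, i)
    if (i < n && class_plan[i] != class_plan[i + 1L] &&
        (mode %in% c("tandem", "mixed"))) {
      i <- i + 2L
    } else {
      i <- i + 1L
    }
  }
  out
}

#' Ready-made blueprints mirroring published locus architectures
#'
#' `"opossum"`: 8 marsupial clusters (unique class I head, alternating
#' II/III), clusters 4 and 8 lacking V and D, tandem duplication.
#' `"devil"`: 9 marsupial clusters (I,II,I,II,III...III), cluster 4 lacking
#' V and D, clusters 8 and 9 lacking V, mixed duplication.
#' `"platypus"`: 5 platypus clusters plus 6 extra Vmu1-like and 2 extra
#' Vmu2-like singleton V genes and 10 singleton C genes, singlet duplication.
#'
#' @param species `"opossum"`, `"devil"` or `"platypus"`.
#' @param seed Integer seed.
#' @param ... Overrides passed to [locus_blueprint()].
#' @return A `locus_blueprint`.
#' @export
blueprint_mirror <- function(species = c("opossum", "devil", "platypus"),
                             seed = 1L, ...) {
  species <- match.arg(species)
  args <- switch(species,
    opossum = list(
      n_clusters = 8L, layout = "marsupial",
      class_plan = c("I", "II", "III", "II", "III", "II", "III", "II"),
      partial_plan = list("4" = c("V", "D"), "8" = c("V", "D")),
      duplication_mode = "tandem"
    ),
    devil = list(
      n_clusters = 9L, layout = "marsupial",
      class_plan = c("I", "II", "I", "II", "III", "III", "III", "III", "III"),
      partial_plan = list("4" = c("V", "D"), "8" = "V", "9" = "V"),
      duplication_mode = "mixed"
    ),
    platypus = list(
      n_clusters = 5L, layout = "platypus",
      class_plan = rep("P", 5L),
      duplication_mode = "singlet",
      n_extra_v1 = 6L, n_extra_v2 = 2L, n_extra_c = 10L
    )
  )
  over <- list(...)
  args[names(over)] <- over
  args$seed <- seed
  do.call(locus_blueprint, args)
}

#' Generate a synthetic locus with planted truth
#'
#' Builds one ancestral cluster, derives one archetype per class (at half the
#' between-class divergence), copies archetypes into clusters (at half the
#' within-class divergence), deletes segments per the partial plan, plants
#' repeat copies and inter-cluster spacers, pads with i.i.d. background, and
#' records every planted feature.
#'
#' @param blueprint A [locus_blueprint()].
#' @return A `synthetic_truth` list: `genome` (`DNAStringSet`), `segments`,
#'   `clusters`, `repeats`, `rss` truth tables, `queries` (per-class archetype
#'   sequences with `kind=`/`class=`/`subtype=` header tags, the homology and
#'   classification references), and the `blueprint`.
#' @export
generate_locus <- function(blueprint) {
  bp <- blueprint
  with_seed(bp$seed, {
    anc <- ancestral_parts(bp$layout)
    labels <- unique(bp$class_plan)
    archetypes <- lapply(labels, function(l) {
      mutate_parts(anc, bp$between_class_divergence / 2)
    })
    names(archetypes) <- labels
    strands <- bp$cluster_strands
    if (is.null(strands)) {
      strands <- c("+", ifelse(stats::runif(max(0L, bp$n_clusters - 1L)) < 0.7, "+", "-"))
    }
    stopifnot(length(strands) == bp$n_clusters)
    rep_master <- rand_dna(bp$repeat_length)
    # spacers never drop below 2.5 kb so a cluster's upstream-flank window
    # cannot reach its neighbour's repeat copy
    scaled <- function(x) max(2500L, as.integer(round(x * bp$scale)))
    draw_spacer <- function() {
      scaled(sample(bp$spacer_length_range[1L]:bp$spacer_length_range[2L], 1L))
    }

    chunks <- character(0)
    offset <- 0L
    push <- function(s) {
      chunks[[length(chunks) + 1L]] <<- s
      offset <<- offset + nchar(s)
    }
    push(rand_dna(2500L))

    seg_rows <- list(); cl_rows <- list(); rep_rows <- list(); rss_rows <- list()
    for (ci in seq_len(bp$n_clusters)) {
      lab <- bp$class_plan[ci]
      parts <- mutate_parts(archetypes[[lab]], bp$within_class_divergence / 2)
      miss <- bp$partial_plan[[as.character(ci)]]
      if (!is.null(miss)) parts <- delete_kinds(parts, miss)
      strand <- strands[ci]
      blk <- assemble_block(parts, strand)
      has_rep <- ci %in% bp$repeat_before
      push(rand_dna(draw_spacer()))
      rep_seq <- NULL
      if (has_rep) {
        rep_seq <- mutate_sub(rep_master, 0.02)
        if (strand == "+") {
          rs <- offset + 1L
          push(rep_seq)
          rep_rows[[length(rep_rows) + 1L]] <- data.frame(
            start = rs, end = offset, cluster_index = ci, stringsAsFactors = FALSE
          )
          push(rand_dna(250L))
        }
      }
      blk_start <- offset
      push(blk$seq)
      if (!is.null(blk$segments)) {
        sr <- blk$segments
        sr$start <- sr$start + blk_start
        sr$end <- sr$end + blk_start
        sr$strand <- strand
        sr$cluster_index <- ci
        sr$class <- lab
        seg_rows[[length(seg_rows) + 1L]] <- sr
      }
      if (!is.null(blk$rss)) {
        rr <- blk$rss
        rr$start <- rr$start + blk_start
        rr$end <- rr$end + blk_start
        rss_rows[[length(rss_rows) + 1L]] <- rr
      }
      kinds_left <- vapply(Filter(function(p) p$role == "segment", parts), `[[`, "", "kind")
      cc <- call_completeness(paste(kinds_left, collapse = "-"), cluster_layouts[[bp$layout]])
      cl_rows[[length(cl_rows) + 1L]] <- data.frame(
        index = ci, start = blk_start + 1L, end = offset, strand = strand,
        class_label = lab,
        complete = cc$complete, missing = paste(cc$missing, collapse = ","),
        has_repeat = has_rep, stringsAsFactors = FALSE
      )
      if (has_rep && strand == "-") {
        push(rand_dna(250L))
        rs <- offset + 1L
        push(reverse_complement(rep_seq))
        rep_rows[[length(rep_rows) + 1L]] <- data.frame(
          start = rs, end = offset, cluster_index = ci, stringsAsFactors = FALSE
        )
      }
    }

    # interspersed singleton segments (platypus-style), spaced beyond any
    # plausible intra-cluster gap so they never join a cluster
    extras <- c(rep("V1", bp$n_extra_v1), rep("V2", bp$n_extra_v2), rep("C", bp$n_extra_c))
    if (length(extras)) extras <- sample(extras)
    arch1 <- archetypes[[bp$class_plan[1L]]]
    pick_part <- function(parts, unit) Filter(function(p) p$unit == unit, parts)
    for (ei in seq_along(extras)) {
      push(rand_dna(16000L + sample(0:4000, 1L)))
      kind <- extras[[ei]]
      unit <- switch(kind, V1 = "V", V2 = if (bp$layout == "platypus") "V2" else "V", C = "C")
      ps <- mutate_parts(pick_part(arch1, unit), bp$within_class_divergence / 2)
      strand <- if (stats::runif(1L) < 0.7) "+" else "-"
      blk <- assemble_block(ps, strand)
      blk_start <- offset
      push(blk$seq)
      sr <- blk$segments
      sr$start <- sr$start + blk_start
      sr$end <- sr$end + blk_start
      sr$strand <- strand
      sr$cluster_index <- NA_integer_
      sr$class <- bp$class_plan[1L]
      seg_rows[[length(seg_rows) + 1L]] <- sr
      if (!is.null(blk$rss)) {
        rr <- blk$rss
        rr$start <- rr$start + blk_start
        rr$end <- rr$end + blk_start
        rss_rows[[length(rss_rows) + 1L]] <- rr
      }
    }
    push(rand_dna(2500L))

    genome <- Biostrings::DNAStringSet(paste(chunks, collapse = ""))
    names(genome) <- "synthetic_locus"

    segments <- do.call(rbind, seg_rows)
    segments <- segments[order(segments$start), , drop = FALSE]
    segments$ordinal <- stats::ave(seq_len(nrow(segments)), segments$kind, FUN = seq_along)
    segments$segment_id <- paste0(segments$kind, segments$ordinal)
    segments$seq_id <- "synthetic_locus"
    rownames(segments) <- NULL
    clusters <- do.call(rbind, cl_rows)
    repeats <- if (length(rep_rows)) do.call(rbind, rep_rows) else
      data.frame(start = integer(), end = integer(), cluster_index = integer())
    rss <- if (length(rss_rows)) do.call(rbind, rss_rows) else
      data.frame(start = integer(), end = integer())

    queries <- build_queries(archetypes, bp$layout)

    out <- list(
      genome = genome, segments = segments, clusters = clusters,
      repeats = repeats, rss = rss, queries = queries, blueprint = bp
    )
    class(out) <- "synthetic_truth"
    out
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# per-class archetype query set with kind=/class=/subtype= header tags
build_queries <- function(archetypes, layout) {
  ids <- character(0); seqs <- character(0); desc <- character(0)
  for (lab in names(archetypes)) {
    parts <- archetypes[[lab]]
    grab <- function(unit) {
      p <- Filter(function(q) q$unit == unit && q$role == "segment", parts)
      if (length(p)) p[[1L]]$seq else NULL
    }
    add <- function(id, seq, tags) {
      ids <<- c(ids, id); seqs <<- c(seqs, seq)
      desc <<- c(desc, paste(id, tags))
    }
    if (layout == "marsupial") {
      add(paste0("Vref_", lab), grab("V"), paste0("kind=V class=", lab))
      add(paste0("Vjref_", lab), grab("Vj"), paste0("kind=Vj class=", lab))
      add(paste0("Cref_", lab), grab("C"), paste0("kind=C class=", lab))
    } else {
      add(paste0("V1ref_", lab), grab("V"), paste0("kind=V class=", lab, " subtype=Vmu1"))
      add(paste0("V2ref_", lab), grab("V2"), paste0("kind=V class=", lab, " subtype=Vmu2"))
      add(paste0("Cref_", lab), grab("C"), paste0("kind=C class=", lab))
    }
  }
  q <- Biostrings::DNAStringSet(seqs)
  names(q) <- ids
  S4Vectors::metadata(q)$description <- stats::setNames(desc, ids)
  q
}

#' Generate recombined V-D-J junction transcripts from a planted locus
#'
#' Each transcript is V (3' trimmed 0-3 bp) + N additions + D core (trimmed
#' 0-2 bp per side) + N additions + J (5' trimmed 0-2 bp) + the start of the
#' cluster's C gene. About `productive_fraction` of transcripts are
#' constructed in frame (stop-free through the J motif).
#'
#' @param truth A `synthetic_truth` from [generate_locus()].
#' @param n Number of transcripts.
#' @param n_addition_max Maximum untemplated N bases per joint (default 4).
#' @param rng_seed Integer seed.
#' @param productive_fraction Target fraction of productive transcripts.
#' @param trim Exonuclease-style trimming of segment ends (default TRUE;
#'   FALSE keeps every segment end intact).
#' @return `DNAStringSet` with a `provenance` data.frame in its metadata
#'   (`transcript_id`, `v_id`, `d_id`, `j_id`, `n_additions`, `productive`).
#' @export
generate_junction_transcripts <- function(truth, n, n_addition_max = 4L,
                                          rng_seed = 1L, productive_fraction = 0.7,
                                          trim = TRUE) {
  segs <- truth$segments
  cl_ok <- vapply(unique(segs$cluster_index[!is.na(segs$cluster_index)]), function(ci) {
    sub <- segs[!is.na(segs$cluster_index) & segs$cluster_index == ci, ]
    any(sub$kind == "V" & sub$subtype %in% c("none", "Vmu1")) &&
      any(sub$kind == "D") && any(sub$kind == "J") && any(sub$kind == "C")
  }, logical(1))
  cl_ids <- unique(segs$cluster_index[!is.na(segs$cluster_index)])[cl_ok]
  if (length(cl_ids) == 0L) stop("no cluster with V, D and J available")
  g <- truth$genome
  oriented <- function(row) seq_extract(g, row$seq_id, row$start, row$end, row$strand)
  with_seed(rng_seed, {
    seqs <- character(n); prov <- vector("list", n)
    for (i in seq_len(n)) {
      ci <- if (length(cl_ids) == 1L) cl_ids else sample(cl_ids, 1L)
      sub <- segs[!is.na(segs$cluster_index) & segs$cluster_index == ci, ]
      vrow <- sub[sub$kind == "V" & sub$subtype %in% c("none", "Vmu1"), ][1L, ]
      drows <- sub[sub$kind == "D", ]
      drow <- drows[sample(nrow(drows), 1L), ]
      jrow <- sub[sub$kind == "J", ][1L, ]
      crow <- sub[sub$kind == "C", ][1L, ]
      vs <- oriented(vrow); ds <- oriented(drow); js <- oriented(jrow)
      cs <- substr(oriented(crow), 1L, 60L)
      want_prod <- stats::runif(1L) < productive_fraction
      tx <- NULL
      for (att in 1:80) {
        t3 <- if (trim) sample(0:3, 1L) else 0L
        d5 <- if (trim) sample(0:2, 1L) else 0L
        d3 <- if (trim) sample(0:2, 1L) else 0L
        j5 <- if (trim) sample(0:2, 1L) else 0L
        n1 <- rand_dna(sample(0:n_addition_max, 1L))
        n2 <- rand_dna(sample(0:n_addition_max, 1L))
        cand <- paste0(
          substr(vs, 1L, nchar(vs) - t3), n1,
          substr(ds, 1L + d5, nchar(ds) - d3), n2,
          substr(js, 1L + j5, nchar(js)), cs
        )
        if (is_productive(cand, 0L) == want_prod) {
          tx <- cand
          n_add <- nchar(n1) + nchar(n2)
          break
        }
      }
      if (is.null(tx)) {  # rare: accept the last candidate
        tx <- cand
        n_add <- nchar(n1) + nchar(n2)
        want_prod <- is_productive(tx, 0L)
      }
      seqs[i] <- tx
      prov[[i]] <- data.frame(
        transcript_id = sprintf("tx%04d", i), v_id = vrow$segment_id,
        d_id = drow$segment_id, j_id = jrow$segment_id,
        n_additions = n_add, productive = want_prod, stringsAsFactors = FALSE
      )
    }
    out <- Biostrings::DNAStringSet(seqs)
    names(out) <- sprintf("tx%04d", seq_len(n))
    S4Vectors::metadata(out)$provenance <- do.call(rbind, prov)
    out
  })
}
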