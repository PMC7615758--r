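#' Read a FASTA file of nucleotide sequences
#'
#' Reads DNA sequences, uppercases them, maps RNA `U` to `T`, and checks the
#' basic hygiene the rest of the pipeline relies on: non-empty records and
#' unique identifiers. The identifier is the first whitespace-delimited token
#' of the header; the remainder of the header is kept and can carry
#' `key=value` tags (e.g. `kind=V class=II`) parsed by [header_tags()].
#'
#' @param path Path to a FASTA file.
#' @return A [Biostrings::DNAStringSet] named by record id, with the full
#'   header line stored in `S4Vectors::metadata()$description`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  x <- Biostrings::readBStringSet(path)
  if (length(x) == 0L) stop("empty FASTA file: ", path)
  headers <- names(x)
  ids <- sub("\\s.*$", "", headers)
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L) stop("duplicate id ", dup[[1L]], " in ", path)
  seqs <- chartr("u", "t", as.character(x))
  seqs <- toupper(seqs)
  if (any(nchar(seqs) == 0L)) stop("empty sequence record in ", path)
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- ids
  S4Vectors::metadata(out)$description <- stats::setNames(headers, ids)
  out
}

#' Write sequences to FASTA
#'
#' @param x Named character vector or `DNAStringSet`.
#' @param path Output path.
#' @export
write_fasta <- function(x, path) {
  if (is.character(x)) x <- Biostrings::DNAStringSet(x)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Parse key=value tags from FASTA headers
#'
#' @param seqs A `DNAStringSet` as returned by [read_fasta()], or a character
#'   vector of header lines.
#' @param key Tag name, e.g. `"class"` or `"kind"`.
#' @return Character vector of tag values (NA where absent), named by id.
#' @export
header_tags <- function(seqs, key) {
  if (is.character(seqs)) {
    headers <- seqs
    ids <- sub("\\s.*$", "", headers)
  } else {
    headers <- S4Vectors::metadata(seqs)$description
    if (is.null(headers)) headers <- names(seqs)
    ids <- names(seqs)
  }
  pat <- paste0(".*\\b", key, "=([^ \t]+).*")
  val <- ifelse(grepl(paste0("\\b", key, "="), headers), sub(pat, "\\1", headers), NA_character_)
  stats::setNames(val, ids)
}

#' Reverse complement of a nucleotide string
#'
#' Length-preserving involution over the alphabet `{A,C,G,T,N}`.
#'
#' @param seq Nucleotide string.
#' @return The reverse complement, as a plain character string.
#' @export
reverse_complement <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  if (grepl("[^ACGTN]", seq)) stop("reverse_complement: alphabet is {A,C,G,T,N}")
  cpl <- chartr("ACGTN", "TGCAN", seq)
  paste(rev(strsplit(cpl, "", fixed = TRUE)[[1L]]), collapse = "")
}

#' Translate a nucleotide string in a fixed frame
#'
#' Standard genetic code; stop codons render `*`; codons containing `N` (or
#' any ambiguity) render `X`; a trailing partial codon is dropped.
#'
#' @param seq Nucleotide string.
#' @param frame 0, 1 or 2: number of 5' bases skipped before the first codon.
#' @return Amino-acid string.
#' @export
translate_nt <- function(seq, frame = 0L) {
  stopifnot(frame %in% 0:2)
  s <- substr(seq, frame + 1L, nchar(seq))
  n <- nchar(s) %/% 3L
  if (n == 0L) return("")
  starts <- seq.int(1L, by = 3L, length.out = n)
  codons <- substring(s, starts, starts + 2L)
  code <- Biostrings::GENETIC_CODE
  aa <- unname(code[codons])
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

#' Extract the oriented sequence of an interval
#'
#' Coordinates are 1-based inclusive on the plus strand; minus-strand
#' intervals are reverse-complemented on extraction, so the result always
#' reads 5' to 3' in the feature's own orientation.
#'
#' @param genome A `DNAStringSet` (the record named by `seq_id` is used) or a
#'   single character string.
#' @param seq_id Sequence record id (ignored when `genome` is a string).
#' @param start,end 1-based inclusive plus-strand coordinates.
#' @param strand `"+"` or `"-"`.
#' @return Character string.
#' @export
seq_extract <- function(genome, seq_id, start, end, strand = "+") {
  s <- genome_string(genome, seq_id)
  if (start < 1L || end > nchar(s) || start > end) {
    stop("interval [", start, ",", end, "] out of bounds for ", seq_id)
  }
  x <- substr(s, start, end)
  if (strand == "-") x <- reverse_complement(x)
  x
}

# Resolve a genome argument to one plain character string.
genome_string <- function(genome, seq_id = NULL) {
  if (is.character(genome) && length(genome) == 1L && !file.exists(genome)) return(genome)
  if (is.character(genome) && length(genome) == 1L) genome <- read_fasta(genome)
  if (methods::is(genome, "XStringSet")) {
    if (!is.null(seq_id) && seq_id %in% names(genome)) {
      return(as.character(genome[[seq_id]]))
    }
    return(as.character(genome[[1L]]))
  }
  if (is.character(genome)) {
    if (!is.null(seq_id) && !is.null(names(genome)) && seq_id %in% names(genome)) {
      return(unname(genome[[seq_id]]))
    }
    return(unname(genome[[1L]]))
  }
  stop("cannot interpret genome argument")
}

# Empty annotation table with the canonical segment columns.
empty_segments <- function() {
  data.frame(
    segment_id = character(), seq_id = character(),
    start = integer(), end = integer(), strand = character(),
    kind = character(), subtype = character(), evidence = character(),
    best_identity = numeric(), best_query = character(),
    pseudogene = logical(), cluster_index = integer(), ordinal = integer(),
    stringsAsFactors = FALSE
  )
}

new_segments <- function(...) {
  df <- data.frame(..., stringsAsFactors = FALSE)
  base <- empty_segments()
  for (col in names(base)) {
    if (!col %in% names(df)) df[[col]] <- base[[col]][NA_integer_][seq_len(nrow(df))]
  }
  df[names(base)]
}

gff3_type_map <- c(
  V = "V_gene_segment", D = "D_gene_segment", J = "J_gene_segment",
  Vj = "V_gene_segment", C = "C_gene_segment"
)

#' Write annotations to GFF3
#'
#' Emits gene segments, clusters and repeat elements as GFF3 (1-based
#' inclusive coordinates). Segments assigned to a cluster carry a `Parent`
#' attribute pointing at the cluster feature; the file round-trips through
#' standard GFF3 parsers.
#'
#' @param segments Segment table (as produced by the annotation functions),
#'   or NULL.
#' @param path Output path.
#' @param clusters Optional cluster table from [assemble_clusters()].
#' @param repeats Optional repeat-element table from [find_upstream_repeats()].
#' @param genome Optional genome used to bounds-check intervals.
#' @return The path, invisibly.
#' @export
write_gff3 <- function(segments, path, clusters = NULL, repeats = NULL, genome = NULL) {
  feats <- list()
  if (!is.null(genome)) {
    glen <- nchar(genome_string(genome))
    check <- function(df) {
      if (!is.null(df) && nrow(df) > 0 && (any(df$start < 1) || any(df$end > glen))) {
        stop("interval out of bounds for genome")
      }
    }
    check(segments); check(clusters); check(repeats)
  }
  if (!is.null(clusters) && nrow(clusters) > 0) {
    feats[[length(feats) + 1L]] <- GenomicRanges::GRanges(
      seqnames = clusters$seq_id,
      ranges = IRanges::IRanges(clusters$start, clusters$end),
      strand = clusters$strand,
      type = "vdj_cluster",
      ID = clusters$cluster_id,
      class_label = as.character(clusters$class_label)
    )
  }
  if (!is.null(segments) && nrow(segments) > 0) {
    parent <- rep(NA_character_, nrow(segments))
    if (!is.null(clusters) && nrow(clusters) > 0 && "cluster_index" %in% names(segments)) {
      m <- match(segments$cluster_index, clusters$index)
      parent <- ifelse(is.na(m), NA_character_, clusters$cluster_id[m])
    }
    gr <- GenomicRanges::GRanges(
      seqnames = segments$seq_id,
      ranges = IRanges::IRanges(segments$start, segments$end),
      strand = segments$strand,
      type = unname(gff3_type_map[segments$kind]),
      ID = segments$segment_id
    )
    S4Vectors::mcols(gr)$Parent <- parent
    feats[[length(feats) + 1L]] <- gr
  }
  if (!is.null(repeats) && nrow(repeats) > 0) {
    feats[[length(feats) + 1L]] <- GenomicRanges::GRanges(
      seqnames = repeats$seq_id,
      ranges = IRanges::IRanges(repeats$start, repeats$end),
      strand = "+",
      type = "repeat_region",
      ID = repeats$repeat_id
    )
  }
  if (length(feats) == 0L) {
    writeLines("##gff-version 3", path)
    return(invisible(path))
  }
  all <- suppressWarnings(do.call(c, lapply(feats, function(g) {
    # harmonize mcols across feature kinds
    want <- c("type", "ID", "Parent", "class_label")
    mc <- S4Vectors::mcols(g)
    for (col in setdiff(want, names(mc))) mc[[col]] <- NA_character_
    S4Vectors::mcols(g) <- mc[want]
    g
  })))
  rtracklayer::export.gff3(all, path)
  invisible(path)
}
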