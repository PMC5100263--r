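#' @importFrom stats pbinom p.adjust runif setNames
#' @importFrom utils read.table write.table
NULL

VALID_BASES <- c("A", "C", "G", "T", "N")

#' Read a multi-record FASTA file
#'
#' Sequences are uppercase-normalized on read (repeat-masked lowercase is
#' accepted); only the residues A, C, G, T and N are permitted. The token
#' before the first whitespace in each header becomes the sequence name.
#'
#' @param path Path to a FASTA file.
#' @return A named character vector of uppercase sequences, one element per
#'   record, in file order.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">chr1", "acgT"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path) {
  stopifnot(file.exists(path))
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop("cannot parse FASTA '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  if (length(set) == 0L)
    stop("empty FASTA file: ", path, call. = FALSE)
  seqs <- toupper(as.character(set))
  names(seqs) <- sub("\\s.*$", "", names(set))
  if (any(!nzchar(names(seqs))))
    stop("FASTA record with empty name in ", path, call. = FALSE)
  if (any(nchar(seqs) == 0L))
    stop("FASTA record with no residues in ", path, call. = FALSE)
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    # locate offending character and line for the error message
    lines <- readLines(path)
    for (i in seq_along(lines)) {
      ln <- lines[i]
      if (startsWith(ln, ">")) next
      m <- regexpr("[^ACGTNacgtn \t]", ln)
      if (m > 0L)
        stop("non-IUPAC character '", substr(ln, m, m), "' on line ", i,
             " of ", path, call. = FALSE)
    }
    stop("invalid residues in ", path, call. = FALSE)
  }
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line-wrap width.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  set <- Biostrings::BStringSet(seqs)
  names(set) <- names(seqs)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Reverse complement of a nucleotide string
#'
#' Standard Watson-Crick complement, reversed; N maps to N. Applying the
#' function twice returns the input.
#'
#' @param sequence A string over A, C, G, T, N (case-insensitive).
#' @return The reverse complement, uppercase.
#' @examples
#' reverse_complement("ACACA")  # "TGTGT"
#' @export
reverse_complement <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  s <- toupper(sequence)
  if (nchar(s) == 0L) return(s)
  if (grepl("[^ACGTN]", s))
    stop("reverse_complement: sequence contains characters outside A,C,G,T,N",
         call. = FALSE)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

#' Convert 1-based closed (genome-browser) coordinates to 0-based half-open
#'
#' @param coord Numeric vector of length 2: browser start and end (1-based,
#'   fully closed).
#' @return Integer vector of length 2: internal start (0-based) and end
#'   (exclusive).
#' @examples
#' browser_to_internal(c(18854300, 18855055))
#' @export
browser_to_internal <- function(coord) {
  stopifnot(length(coord) == 2L)
  start <- coord[[1]]; end <- coord[[2]]
  if (start < 1 || start > end)
    stop("invalid browser coordinates (", start, ", ", end,
         "): need 1 <= start <= end", call. = FALSE)
  c(as.integer(start) - 1L, as.integer(end))
}

#' @rdname browser_to_internal
#' @export
internal_to_browser <- function(coord) {
  stopifnot(length(coord) == 2L)
  start <- coord[[1]]; end <- coord[[2]]
  if (start < 0 || start >= end)
    stop("invalid internal coordinates (", start, ", ", end, ")",
         call. = FALSE)
  c(as.integer(start) + 1L, as.integer(end))
}

empty_bed <- function(scored = FALSE) {
  df <- data.frame(chrom = character(), start = integer(), end = integer(),
                   name = character(), strand = character(),
                   stringsAsFactors = FALSE)
  if (scored) df$score <- numeric()
  df
}

#' Read a BED file
#'
#' Plain BED3/4/6 or, with \code{scored = TRUE}, BED5/6 where column 5 is a
#' real-valued score (e.g. an F-Seq peak score). Coordinates are 0-based
#' half-open, as in the file.
#'
#' @param path Path to a tab-separated BED file.
#' @param scored Parse column 5 as a numeric score.
#' @return A data.frame with columns chrom, start, end, name, strand and,
#'   when \code{scored}, score; rows in file order.
#' @export
read_bed <- function(path, scored = FALSE) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(lines) == 0L) return(empty_bed(scored))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ncol <- vapply(parts, length, 1L)
  if (any(ncol < 3L))
    stop("BED line with fewer than 3 columns at line ",
         which(ncol < 3L)[1], call. = FALSE)
  get <- function(i, default = NA_character_)
    vapply(parts, function(p) if (length(p) >= i) p[[i]] else default, "")
  df <- data.frame(
    chrom = get(1L),
    start = as.integer(get(2L)),
    end = as.integer(get(3L)),
    name = get(4L, "."),
    strand = get(6L, "."),
    stringsAsFactors = FALSE
  )
  df$name[is.na(df$name)] <- "."
  df$strand[is.na(df$strand) | !(df$strand %in% c("+", "-"))] <- "."
  bad <- which(is.na(df$start) | is.na(df$end) | df$start >= df$end |
                 df$start < 0L)
  if (length(bad))
    stop("invalid BED interval at line ", bad[1], " of ", path,
         " (need 0 <= start < end)", call. = FALSE)
  if (scored) {
    sc <- suppressWarnings(as.numeric(get(5L)))
    if (anyNA(sc) || any(!is.finite(sc)) || any(sc < 0))
      stop("scored BED requires a finite non-negative score in column 5 (",
           path, ")", call. = FALSE)
    df$score <- sc
  }
  df
}

#' Write intervals as BED
#'
#' Emits BED6 (name, score, strand) in deterministic (chrom, start, end, name)
#' order unless \code{keep_order} is set. Score column is the \code{score}
#' column when present, otherwise 0.
#'
#' @param intervals Interval data.frame (chrom, start, end, optional name,
#'   score, strand).
#' @param path Output path.
#' @param keep_order Keep input row order instead of sorting.
#' @export
write_bed <- function(intervals, path, keep_order = FALSE) {
  df <- intervals
  if (is.null(df$name)) df$name <- "."
  if (is.null(df$strand)) df$strand <- "."
  if (is.null(df$score)) df$score <- 0
  if (!keep_order && nrow(df) > 0L)
    df <- df[order(df$chrom, df$start, df$end, df$name), , drop = FALSE]
  out <- df[, c("chrom", "start", "end", "name", "score", "strand")]
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read gene models from genePred or BED12
#'
#' Returns one row per transcript with exon structure as list columns and the
#' CDS span (NA for non-coding transcripts; BED12 rows with
#' thickStart == thickEnd are treated as non-coding by convention).
#'
#' @param path Path to the gene-model file.
#' @param dialect "genePred" (name, chrom, strand, txStart, txEnd, cdsStart,
#'   cdsEnd, exonCount, exonStarts, exonEnds[, score, name2]) or "BED12".
#' @return data.frame with columns gene, tx_id, chrom, strand, tx_start,
#'   tx_end, cds_start, cds_end and list columns exon_starts, exon_ends
#'   (0-based half-open).
#' @export
read_gene_models <- function(path, dialect = c("genePred", "BED12")) {
  dialect <- match.arg(dialect)
  stopifnot(file.exists(path))
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(lines) == 0L) {
    gm <- data.frame(gene = character(), tx_id = character(),
                     chrom = character(), strand = character(),
                     tx_start = integer(), tx_end = integer(),
                     cds_start = integer(), cds_end = integer(),
                     stringsAsFactors = FALSE)
    gm$exon_starts <- list(); gm$exon_ends <- list()
    return(gm)
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  split_ints <- function(x) as.integer(strsplit(sub(",+$", "", x), ",")[[1]])
  rows <- lapply(seq_along(parts), function(i) {
    p <- parts[[i]]
    if (dialect == "genePred") {
      if (length(p) < 10L)
        stop("genePred line ", i, " has fewer than 10 fields", call. = FALSE)
      n_exon <- as.integer(p[[8]])
      ex_s <- split_ints(p[[9]]); ex_e <- split_ints(p[[10]])
      gene <- if (length(p) >= 12L) p[[12]] else p[[1]]
      cds_s <- as.integer(p[[6]]); cds_e <- as.integer(p[[7]])
      tx_s <- as.integer(p[[4]]); tx_e <- as.integer(p[[5]])
      tx_id <- p[[1]]; chrom <- p[[2]]; strand <- p[[3]]
    } else {
      if (length(p) < 12L)
        stop("BED12 line ", i, " has fewer than 12 fields", call. = FALSE)
      tx_s <- as.integer(p[[2]]); tx_e <- as.integer(p[[3]])
      tx_id <- p[[4]]; gene <- p[[4]]; chrom <- p[[1]]; strand <- p[[6]]
      cds_s <- as.integer(p[[7]]); cds_e <- as.integer(p[[8]])
      n_exon <- as.integer(p[[10]])
      sizes <- split_ints(p[[11]]); offsets <- split_ints(p[[12]])
      if (length(sizes) != n_exon || length(offsets) != n_exon)
        stop("BED12 line ", i, ": blockCount=", n_exon,
             " disagrees with block lists", call. = FALSE)
      ex_s <- tx_s + offsets; ex_e <- ex_s + sizes
    }
    if (length(ex_s) != n_exon || length(ex_e) != n_exon)
      stop("gene-model line ", i, ": exonCount=", n_exon,
           " disagrees with exon lists (", length(ex_s), " starts, ",
           length(ex_e), " ends)", call. = FALSE)
    o <- order(ex_s); ex_s <- ex_s[o]; ex_e <- ex_e[o]
    if (any(ex_e <= ex_s) || any(ex_s < tx_s) || any(ex_e > tx_e))
      stop("gene-model line ", i, ": exons malformed or outside transcript",
           call. = FALSE)
    if (n_exon > 1L && any(ex_s[-1] < ex_e[-n_exon]))
      stop("gene-model line ", i, ": overlapping exons", call. = FALSE)
    coding <- !is.na(cds_s) && !is.na(cds_e) && cds_e > cds_s
    list(gene = gene, tx_id = tx_id, chrom = chrom, strand = strand,
         tx_start = tx_s, tx_end = tx_e,
         cds_start = if (coding) cds_s else NA_integer_,
         cds_end = if (coding) cds_e else NA_integer_,
         exon_starts = ex_s, exon_ends = ex_e)
  })
  gm <- data.frame(
    gene = vapply(rows, `[[`, "", "gene"),
    tx_id = vapply(rows, `[[`, "", "tx_id"),
    chrom = vapply(rows, `[[`, "", "chrom"),
    strand = vapply(rows, `[[`, "", "strand"),
    tx_start = vapply(rows, `[[`, 1L, "tx_start"),
    tx_end = vapply(rows, `[[`, 1L, "tx_end"),
    cds_start = vapply(rows, `[[`, 1L, "cds_start"),
    cds_end = vapply(rows, `[[`, 1L, "cds_end"),
    stringsAsFactors = FALSE
  )
  gm$exon_starts <- lapply(rows, `[[`, "exon_starts")
  gm$exon_ends <- lapply(rows, `[[`, "exon_ends")
  gm
}

#' Write gene models as genePred
#'
#' @param gm Gene-model data.frame as returned by [read_gene_models()].
#' @param path Output path.
#' @export
write_gene_models <- function(gm, path) {
  fmt <- function(v) paste0(paste(v, collapse = ","), ",")
  lines <- vapply(seq_len(nrow(gm)), function(i) {
    cds_s <- gm$cds_start[i]; cds_e <- gm$cds_end[i]
    if (is.na(cds_s)) { cds_s <- gm$tx_end[i]; cds_e <- gm$tx_end[i] }
    paste(gm$tx_id[i], gm$chrom[i], gm$strand[i], gm$tx_start[i],
          gm$tx_end[i], cds_s, cds_e, length(gm$exon_starts[[i]]),
          fmt(gm$exon_starts[[i]]), fmt(gm$exon_ends[[i]]),
          0L, gm$gene[i], sep = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a MAF multiple-alignment file
#'
#' Parses 'a' blocks of 's' rows. The reference row of each block is its
#' first 's' row unless \code{reference} names a species, in which case that
#' species' row is the reference where present. A reference row given on the
#' '-' source strand is converted to '+' source coordinates; non-reference
#' rows are used only for column identity so their coordinates are kept as
#' read.
#'
#' @param path Path to a MAF file.
#' @param reference Optional species id (prefix of the src field before the
#'   first '.') designating the reference row.
#' @return A list of alignment blocks. Each block is a data.frame with
#'   columns src, species, chrom, start, size, strand, src_size, text and an
#'   attribute \code{reference} holding the reference row index (NA if the
#'   requested species is absent from the block).
#' @export
read_maf <- function(path, reference = NULL) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  blocks <- list()
  current <- NULL
  flush <- function(current) {
    if (is.null(current) || length(current) == 0L) return(NULL)
    df <- do.call(rbind, current)
    df <- as.data.frame(df, stringsAsFactors = FALSE)
    df$start <- as.integer(df$start)
    df$size <- as.integer(df$size)
    df$src_size <- as.integer(df$src_size)
    widths <- nchar(df$text)
    if (length(unique(widths)) != 1L)
      stop("MAF block with unequal aligned-text lengths", call. = FALSE)
    nongap <- nchar(gsub("-", "", df$text, fixed = TRUE))
    bad <- which(nongap != df$size)
    if (length(bad))
      stop("MAF row for '", df$src[bad[1]], "' declares size ",
           df$size[bad[1]], " but has ", nongap[bad[1]], " non-gap bases",
           call. = FALSE)
    ref <- 1L
    if (!is.null(reference)) {
      hit <- which(df$species == reference)
      ref <- if (length(hit)) hit[1] else NA_integer_
    }
    if (!is.na(ref) && df$strand[ref] == "-") {
      # reference coordinates must be on '+': flip the whole block
      df$text <- vapply(df$text, revcomp_aln, "", USE.NAMES = FALSE)
      df$start <- df$src_size - df$start - df$size
      df$strand <- ifelse(df$strand == "-", "+", "-")
    }
    attr(df, "reference") <- ref
    df
  }
  for (ln in lines) {
    if (startsWith(ln, "a")) {
      b <- flush(current)
      if (!is.null(b)) blocks[[length(blocks) + 1L]] <- b
      current <- list()
    } else if (startsWith(ln, "s ")) {
      f <- strsplit(trimws(ln), "\\s+")[[1]]
      if (length(f) < 7L)
        stop("malformed MAF 's' line: ", ln, call. = FALSE)
      src <- f[2]
      dot <- regexpr(".", src, fixed = TRUE)
      species <- if (dot > 0L) substr(src, 1L, dot - 1L) else src
      chrom <- if (dot > 0L) substr(src, dot + 1L, nchar(src)) else src
      current[[length(current) + 1L]] <- data.frame(
        src = src, species = species, chrom = chrom,
        start = as.integer(f[3]), size = as.integer(f[4]), strand = f[5],
        src_size = as.integer(f[6]), text = toupper(f[7]),
        stringsAsFactors = FALSE)
    }
  }
  b <- flush(current)
  if (!is.null(b)) blocks[[length(blocks) + 1L]] <- b
  blocks
}

# reverse-complement aligned text, keeping gap characters
revcomp_aln <- function(text) {
  chars <- rev(strsplit(text, "")[[1]])
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N", `-` = "-")
  paste(comp[chars], collapse = "")
}

#' Write alignment blocks as MAF
#'
#' @param blocks List of alignment blocks (see [read_maf()]).
#' @param path Output path.
#' @param header Optional comment lines written after the "##maf" line.
#' @export
write_maf <- function(blocks, path, header = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##maf version=1", con)
  if (length(header)) writeLines(paste("#", header), con)
  for (b in blocks) {
    writeLines("", con)
    writeLines("a", con)
    for (i in seq_len(nrow(b))) {
      writeLines(sprintf("s %s %d %d %s %d %s", b$src[i], b$start[i],
                         b$size[i], b$strand[i], b$src_size[i], b$text[i]),
                 con)
    }
  }
  invisible(path)
}

# interval data.frame -> GRanges (internal)
as_granges <- function(df) {
  strand <- if (!is.null(df$strand)) {
    s <- df$strand
    s[!(s %in% c("+", "-"))] <- "*"
    s
  } else "*"
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand = strand)
}
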