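IUPAC_CLASSES <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"))

IUPAC_COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R",
                      S = "S", W = "W", K = "M", M = "K", B = "V", V = "B",
                      D = "H", H = "D")

iupac_revcomp <- function(pattern) {
  chars <- rev(strsplit(pattern, "")[[1]])
  paste(IUPAC_COMPLEMENT[chars], collapse = "")
}

# IUPAC pattern -> plain regex using character classes; N is deliberately
# absent from every class so assembly padding can never match
pattern_regex <- function(pattern) {
  chars <- strsplit(pattern, "")[[1]]
  paste(vapply(chars, function(ch) {
    cls <- IUPAC_CLASSES[[ch]]
    if (is.null(cls)) stop("unsupported pattern character: ", ch,
                           call. = FALSE)
    if (length(cls) == 1L) cls else paste0("[", paste(cls, collapse = ""), "]")
  }, ""), collapse = "")
}

# all literal words matching an IUPAC pattern
pattern_literals <- function(pattern) {
  chars <- strsplit(pattern, "")[[1]]
  grids <- lapply(chars, function(ch) IUPAC_CLASSES[[ch]])
  apply(expand.grid(grids, stringsAsFactors = FALSE), 1L, paste, collapse = "")
}

#' Construct a dimeric motif grammar
#'
#' The grammar describes a family of fixed-length monomer consensus patterns
#' (IUPAC single-position degeneracy allowed) and the admissible spacer range
#' of a head-to-head dimer: a forward monomer, then \code{spacer_min} to
#' \code{spacer_max} unconstrained bases, then the reverse complement of a
#' monomer. Reverse patterns are always derived from the forward set, never
#' supplied. The default is the SOX10 grammar: ACACA or ACAAD (D = G/T/A)
#' with a 5-10 bp spacer, giving reverse patterns TGTGT and HTTGT
#' (H = A/C/T).
#'
#' @param forward_patterns Character vector of equal-length IUPAC patterns.
#' @param spacer_min,spacer_max Inclusive spacer-length bounds in bp.
#' @return An object of class \code{motif_grammar}.
#' @examples
#' g <- motif_grammar()
#' g$reverse_patterns  # "TGTGT" "HTTGT"
#' @export
motif_grammar <- function(forward_patterns = c("ACACA", "ACAAD"),
                          spacer_min = 5L, spacer_max = 10L) {
  stopifnot(length(forward_patterns) >= 1L, is.character(forward_patterns))
  forward_patterns <- toupper(forward_patterns)
  lens <- nchar(forward_patterns)
  if (length(unique(lens)) != 1L)
    stop("all forward patterns must have equal length", call. = FALSE)
  spacer_min <- as.integer(spacer_min); spacer_max <- as.integer(spacer_max)
  if (!(spacer_min > 0L && spacer_min <= spacer_max))
    stop("need 0 < spacer_min <= spacer_max", call. = FALSE)
  g <- list(
    forward_patterns = forward_patterns,
    reverse_patterns = vapply(forward_patterns, iupac_revcomp, "",
                              USE.NAMES = FALSE),
    monomer_length = lens[1],
    spacer_min = spacer_min,
    spacer_max = spacer_max)
  class(g) <- "motif_grammar"
  g
}

#' @export
print.motif_grammar <- function(x, ...) {
  cat("Motif grammar:", length(x$forward_patterns), "monomer pattern(s) of",
      x$monomer_length, "bp\n")
  cat("  forward:", paste(x$forward_patterns, collapse = ", "), "\n")
  cat("  reverse:", paste(x$reverse_patterns, collapse = ", "), "\n")
  cat("  dimer spacer:", x$spacer_min, "-", x$spacer_max, "bp\n")
  invisible(x)
}

# all (0-based) start positions where any of `patterns` matches `text`,
# overlapping occurrences included, with the pattern that matched
pattern_starts <- function(text, patterns) {
  out_start <- integer(); out_pat <- character()
  for (p in patterns) {
    rx <- paste0("(?=", pattern_regex(p), ")")
    m <- gregexpr(rx, text, perl = TRUE)[[1]]
    if (m[1] != -1L) {
      out_start <- c(out_start, as.integer(m) - 1L)
      out_pat <- c(out_pat, rep(p, length(m)))
    }
  }
  o <- order(out_start)
  list(start = out_start[o], pattern = out_pat[o])
}

#' Scan sequences for monomeric consensus matches
#'
#' Every position is tested; overlapping matches are all reported. In
#' \code{"both"} mode a minus-strand match is a position where the plus-strand
#' text matches a reverse pattern (the reverse complement of a forward
#' pattern).
#'
#' @param seqs Named character vector of uppercase sequences (names are
#'   chromosome ids), as returned by [read_fasta()].
#' @param grammar A [motif_grammar()].
#' @param strand_mode "both" (default) or "plus".
#' @return data.frame with columns chrom, start, end (0-based half-open),
#'   name (the pattern, as written, that matched), score (0), strand,
#'   matched_text (the plus-strand substring); sorted by chrom, start,
#'   strand.
#' @examples
#' scan_monomers(c(chr1 = "ACACACA"), strand_mode = "plus")
#' @export
scan_monomers <- function(seqs, grammar = motif_grammar(),
                          strand_mode = c("both", "plus")) {
  strand_mode <- match.arg(strand_mode)
  stopifnot(inherits(grammar, "motif_grammar"), is.character(seqs))
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  L <- grammar$monomer_length
  per_chrom <- lapply(names(seqs), function(chrom) {
    text <- seqs[[chrom]]
    fwd <- pattern_starts(text, grammar$forward_patterns)
    res <- data.frame(chrom = character(), start = integer(),
                      name = character(), strand = character(),
                      stringsAsFactors = FALSE)
    if (length(fwd$start))
      res <- data.frame(chrom = chrom, start = fwd$start, name = fwd$pattern,
                        strand = "+", stringsAsFactors = FALSE)
    if (strand_mode == "both") {
      rev <- pattern_starts(text, grammar$reverse_patterns)
      if (length(rev$start))
        res <- rbind(res, data.frame(chrom = chrom, start = rev$start,
                                     name = rev$pattern, strand = "-",
                                     stringsAsFactors = FALSE))
    }
    if (nrow(res))
      res$matched_text <- substring(text, res$start + 1L, res$start + L)
    res
  })
  out <- do.call(rbind, per_chrom)
  if (is.null(out) || nrow(out) == 0L) {
    out <- data.frame(chrom = character(), start = integer(),
                      end = integer(), name = character(), score = numeric(),
                      strand = character(), matched_text = character(),
                      stringsAsFactors = FALSE)
    return(out)
  }
  out$end <- out$start + L
  out$score <- 0
  out <- out[order(out$chrom, out$start, out$strand), ,
             drop = FALSE]
  rownames(out) <- NULL
  out[, c("chrom", "start", "end", "name", "score", "strand",
          "matched_text")]
}

#' Scan sequences for head-to-head dimeric consensus matches
#'
#' A single plus-strand pass: every forward-pattern occurrence is paired with
#' every reverse-pattern occurrence that starts \code{spacer_min} to
#' \code{spacer_max} bases after it ends. All pairings are reported (one
#' forward monomer may take part in several dimers at different spacers);
#' exact duplicates are removed. The dimer pattern family is closed under
#' reverse complement, so a plus-strand pass already covers both strands.
#' Spacer content is unconstrained (N allowed).
#'
#' @inheritParams scan_monomers
#' @return data.frame with columns chrom, start, end (spanning both
#'   monomers), name ("F=<seq>;S=<spacer>;R=<seq>"), score (spacer length),
#'   strand ("+"), forward_start, forward_text, spacer, spacer_length,
#'   reverse_start, reverse_text; sorted by chrom, start, end.
#' @examples
#' scan_dimers(c(chr1 = "ACAATCAAGCATTGT"))
#' @export
scan_dimers <- function(seqs, grammar = motif_grammar()) {
  stopifnot(inherits(grammar, "motif_grammar"), is.character(seqs))
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  L <- grammar$monomer_length
  per_chrom <- lapply(names(seqs), function(chrom) {
    text <- seqs[[chrom]]
    n <- nchar(text)
    fwd <- pattern_starts(text, grammar$forward_patterns)
    rev <- pattern_starts(text, grammar$reverse_patterns)
    if (!length(fwd$start) || !length(rev$start)) return(NULL)
    is_rev <- logical(n)
    is_rev[rev$start + 1L] <- TRUE
    pieces <- lapply(grammar$spacer_min:grammar$spacer_max, function(s) {
      rstart <- fwd$start + L + s
      ok <- rstart + L <= n & is_rev[rstart + 1L]
      if (!any(ok)) return(NULL)
      data.frame(chrom = chrom, forward_start = fwd$start[ok],
                 spacer_length = s, reverse_start = rstart[ok],
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, pieces)
  })
  out <- do.call(rbind, per_chrom)
  if (is.null(out) || nrow(out) == 0L) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), name = character(), score = integer(),
                      strand = character(), forward_start = integer(),
                      forward_text = character(), spacer = character(),
                      spacer_length = integer(), reverse_start = integer(),
                      reverse_text = character(), stringsAsFactors = FALSE))
  }
  out$start <- out$forward_start
  out$end <- out$reverse_start + L
  key <- paste(out$chrom, out$start, out$end, out$forward_start,
               out$reverse_start)
  out <- out[!duplicated(key), , drop = FALSE]
  txt <- function(starts, len, chrom)
    substring(seqs[[chrom]], starts + 1L, starts + len)
  out$forward_text <- NA_character_
  out$spacer <- NA_character_
  out$reverse_text <- NA_character_
  for (chrom in unique(out$chrom)) {
    i <- out$chrom == chrom
    out$forward_text[i] <- txt(out$forward_start[i], L, chrom)
    out$reverse_text[i] <- txt(out$reverse_start[i], L, chrom)
    out$spacer[i] <- substring(seqs[[chrom]], out$forward_start[i] + L + 1L,
                               out$reverse_start[i])
  }
  out$name <- paste0("F=", out$forward_text, ";S=", out$spacer,
                     ";R=", out$reverse_text)
  out$score <- out$spacer_length
  out$strand <- "+"
  out <- out[order(out$chrom, out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out[, c("chrom", "start", "end", "name", "score", "strand",
          "forward_start", "forward_text", "spacer", "spacer_length",
          "reverse_start", "reverse_text")]
}

#' Summarize a match table
#'
#' Exact totals by strand and by pattern and, for dimers, a spacer-length
#' histogram over the grammar's admissible range.
#'
#' @param matches A match data.frame from [scan_monomers()] or
#'   [scan_dimers()].
#' @param grammar The [motif_grammar()] the matches were produced under
#'   (fixes the histogram support).
#' @return A list with elements n_total, by_strand, by_pattern and, for
#'   dimers, spacer_histogram.
#' @export
count_matches <- function(matches, grammar = motif_grammar()) {
  is_dimer <- "spacer_length" %in% names(matches)
  strands <- factor(matches$strand, levels = c("+", "-"))
  out <- list(
    n_total = nrow(matches),
    by_strand = table(strands),
    by_pattern = if (is_dimer)
      table(paste(matches$forward_text, matches$reverse_text))
    else table(matches$name))
  if (is_dimer) {
    lv <- grammar$spacer_min:grammar$spacer_max
    out$spacer_histogram <- table(factor(matches$spacer_length, levels = lv))
  }
  out
}
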