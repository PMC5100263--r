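#' Keep matches fully contained in a conserved segment
#'
#' A match survives only when its whole interval (for dimers: both monomers
#' and the intervening spacer) is a subset of a single segment; partial
#' overlap does not qualify. The containing segment is recorded.
#'
#' @param matches Match data.frame (chrom, start, end, ...).
#' @param segments Segment data.frame (chrom, start, end, ...).
#' @return The surviving rows of \code{matches} with added columns
#'   segment_start, segment_end.
#' @export
require_containment <- function(matches, segments) {
  if (nrow(matches) == 0L || nrow(segments) == 0L) {
    out <- matches[integer(), , drop = FALSE]
    out$segment_start <- integer(); out$segment_end <- integer()
    return(out)
  }
  hits <- GenomicRanges::findOverlaps(as_granges(matches),
                                      as_granges(segments),
                                      type = "within", ignore.strand = TRUE)
  q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
  first <- !duplicated(q)          # link each match to one containing segment
  out <- matches[q[first], , drop = FALSE]
  out$segment_start <- segments$start[s[first]]
  out$segment_end <- segments$end[s[first]]
  rownames(out) <- NULL
  out
}

# CDS-exon intervals of a gene-model table: per coding transcript, the
# intersection of each exon with the CDS span
cds_exons <- function(gene_models) {
  pieces <- lapply(seq_len(nrow(gene_models)), function(i) {
    cs <- gene_models$cds_start[i]; ce <- gene_models$cds_end[i]
    if (is.na(cs)) return(NULL)
    s <- pmax(gene_models$exon_starts[[i]], cs)
    e <- pmin(gene_models$exon_ends[[i]], ce)
    keep <- s < e
    if (!any(keep)) return(NULL)
    data.frame(chrom = gene_models$chrom[i], start = s[keep], end = e[keep],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  if (is.null(out))
    out <- data.frame(chrom = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE)
  out
}

#' Drop matches that overlap protein-coding sequence
#'
#' A match is excluded when it overlaps at least 1 bp of any CDS exon (the
#' CDS span intersected with the exon structure). UTR exons and introns do
#' not exclude.
#'
#' @param matches Match data.frame.
#' @param gene_models Gene-model data.frame from [read_gene_models()].
#' @return The non-coding subset of \code{matches}.
#' @export
exclude_coding <- function(matches, gene_models) {
  if (nrow(matches) == 0L) return(matches)
  cds <- cds_exons(gene_models)
  if (nrow(cds) == 0L) return(matches)
  hits <- GenomicRanges::findOverlaps(as_granges(matches), as_granges(cds),
                                      ignore.strand = TRUE)
  drop <- unique(S4Vectors::queryHits(hits))
  out <- if (length(drop)) matches[-drop, , drop = FALSE] else matches
  rownames(out) <- NULL
  out
}

#' Assign matches to nearby transcripts
#'
#' A match is assigned to every transcript whose span extended by
#' \code{flank} bp on both sides overlaps it; matches with no assignment are
#' removed. Relations are labeled per assignment: \code{exonic-noncoding}
#' (overlaps an exon), \code{intronic} (inside the span but only over
#' introns), or the strand-aware \code{upstream-flank} / \code{downstream-flank}.
#'
#' @param matches Match data.frame.
#' @param gene_models Gene-model data.frame.
#' @param flank Flank size in bp (default 2500).
#' @return The assigned subset of \code{matches} with columns genes (comma-
#'   joined unique symbols) and relations (comma-joined "symbol:relation"
#'   labels).
#' @export
assign_genes <- function(matches, gene_models, flank = 2500L) {
  stopifnot(flank >= 0L)
  if (nrow(matches) == 0L) {
    matches$genes <- character(); matches$relations <- character()
    return(matches)
  }
  if (nrow(gene_models) == 0L)
    return(assign_genes(matches[integer(), , drop = FALSE],
                        gene_models, flank))
  spans <- data.frame(chrom = gene_models$chrom,
                      start = pmax(0L, gene_models$tx_start - flank),
                      end = gene_models$tx_end + flank,
                      stringsAsFactors = FALSE)
  hits <- GenomicRanges::findOverlaps(as_granges(matches), as_granges(spans),
                                      ignore.strand = TRUE)
  q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
  if (length(q) == 0L)
    return(assign_genes(matches[integer(), , drop = FALSE],
                        gene_models, flank))
  relation <- vapply(seq_along(q), function(k) {
    mi <- q[k]; gi <- s[k]
    ms <- matches$start[mi]; me <- matches$end[mi]
    ts <- gene_models$tx_start[gi]; te <- gene_models$tx_end[gi]
    plus <- gene_models$strand[gi] != "-"
    if (me > ts && ms < te) {
      ex_s <- gene_models$exon_starts[[gi]]; ex_e <- gene_models$exon_ends[[gi]]
      if (any(me > ex_s & ms < ex_e)) "exonic-noncoding" else "intronic"
    } else if (me <= ts) {
      if (plus) "upstream-flank" else "downstream-flank"
    } else {
      if (plus) "downstream-flank" else "upstream-flank"
    }
  }, "")
  genes <- gene_models$gene[s]
  keep <- sort(unique(q))
  out <- matches[keep, , drop = FALSE]
  out$genes <- vapply(keep, function(mi)
    paste(unique(genes[q == mi]), collapse = ","), "")
  out$relations <- vapply(keep, function(mi)
    paste(paste0(genes[q == mi], ":", relation[q == mi]), collapse = ","), "")
  rownames(out) <- NULL
  out
}

#' Require scored-peak support from every peak set
#'
#' A peak supports a match when they overlap by at least 1 bp and the peak's
#' score meets that set's threshold. A match is kept only when every named
#' peak set supports it; the best supporting score per set is recorded.
#'
#' @param matches Match data.frame.
#' @param peak_sets Named list of scored-interval data.frames (from
#'   \code{read_bed(scored = TRUE)}).
#' @param min_scores Named numeric vector of per-set score thresholds;
#'   unnamed sets default to 0. Unknown names are an error.
#' @return The supported subset with one "<set>_score" column per peak set.
#' @export
intersect_peaks <- function(matches, peak_sets, min_scores = numeric()) {
  stopifnot(is.list(peak_sets), !is.null(names(peak_sets)))
  unknown <- setdiff(names(min_scores), names(peak_sets))
  if (length(unknown))
    stop("threshold given for unknown peak set(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  if (nrow(matches) == 0L) {
    for (nm in names(peak_sets)) matches[[paste0(nm, "_score")]] <- numeric()
    return(matches)
  }
  keep <- rep(TRUE, nrow(matches))
  best <- list()
  gr_m <- as_granges(matches)
  for (nm in names(peak_sets)) {
    pk <- peak_sets[[nm]]
    thr <- if (nm %in% names(min_scores)) min_scores[[nm]] else 0
    sc <- rep(NA_real_, nrow(matches))
    if (nrow(pk) > 0L) {
      pk_ok <- pk[pk$score >= thr, , drop = FALSE]
      if (nrow(pk_ok) > 0L) {
        hits <- GenomicRanges::findOverlaps(gr_m, as_granges(pk_ok),
                                            ignore.strand = TRUE)
        q <- S4Vectors::queryHits(hits)
        s <- pk_ok$score[S4Vectors::subjectHits(hits)]
        if (length(q))
          for (mi in unique(q)) sc[mi] <- max(s[q == mi])
      }
    }
    keep <- keep & !is.na(sc)
    best[[paste0(nm, "_score")]] <- sc
  }
  out <- matches[keep, , drop = FALSE]
  for (nm in names(best)) out[[nm]] <- best[[nm]][keep]
  rownames(out) <- NULL
  out
}

#' Nearest gene to each match
#'
#' Distance is 0 when the match overlaps a transcript span, otherwise the
#' minimal gap between the match interval and the span. The sign is negative
#' when the match lies 5' of the transcript in transcript orientation. Ties
#' break by smaller distance, then alphabetical gene symbol.
#'
#' @param matches Match data.frame.
#' @param gene_models Gene-model data.frame.
#' @return \code{matches} with columns nearest_gene and nearest_distance
#'   (signed).
#' @export
nearest_gene <- function(matches, gene_models) {
  if (nrow(matches) == 0L) {
    matches$nearest_gene <- character()
    matches$nearest_distance <- integer()
    return(matches)
  }
  empty <- setdiff(unique(matches$chrom), unique(gene_models$chrom))
  if (length(empty))
    stop("no gene models on chromosome(s): ", paste(empty, collapse = ", "),
         call. = FALSE)
  res <- lapply(seq_len(nrow(matches)), function(mi) {
    g <- gene_models[gene_models$chrom == matches$chrom[mi], , drop = FALSE]
    ms <- matches$start[mi]; me <- matches$end[mi]
    gap <- ifelse(me <= g$tx_start, g$tx_start - me,
                  ifelse(ms >= g$tx_end, ms - g$tx_end, 0L))
    o <- order(gap, g$gene)
    best <- o[1]
    d <- gap[best]
    if (d > 0L) {
      plus <- g$strand[best] != "-"
      before <- me <= g$tx_start[best]      # match left of the span
      five_prime <- (plus && before) || (!plus && !before)
      if (five_prime) d <- -d
    }
    list(gene = g$gene[best], dist = as.integer(d))
  })
  matches$nearest_gene <- vapply(res, `[[`, "", "gene")
  matches$nearest_distance <- vapply(res, `[[`, 1L, "dist")
  matches
}

#' Count surviving segments and their unique genes
#'
#' @param matches Annotated match data.frame carrying either a
#'   \code{nearest_gene} or a \code{genes} column.
#' @return Named integer vector c(n_segments, n_unique_genes).
#' @export
count_loci <- function(matches) {
  genes <- character()
  if (nrow(matches)) {
    if (!is.null(matches$nearest_gene)) genes <- matches$nearest_gene
    else if (!is.null(matches$genes))
      genes <- unlist(strsplit(matches$genes, ",", fixed = TRUE))
    else stop("matches carry neither nearest_gene nor genes", call. = FALSE)
  }
  c(n_segments = nrow(matches), n_unique_genes = length(unique(genes)))
}
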