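#' Define the species set for conservation analysis
#'
#' @param species Ordered character vector of species ids (>= 2).
#' @param reference The reference species (must be in \code{species});
#'   extracted segments are reported in its coordinates.
#' @return An object of class \code{species_set}.
#' @export
species_set <- function(species = c("hg18", "mm9", "galGal3"),
                        reference = species[1]) {
  stopifnot(length(species) >= 2L, reference %in% species)
  structure(list(species = species, reference = reference),
            class = "species_set")
}

#' Extract maximal exact-identity conserved segments
#'
#' A column of an alignment block qualifies when every species in the set is
#' present in the block and carries the same nucleotide there
#' (case-insensitive; a gap or an N in any set species disqualifies the
#' column, so qualifying runs are ungapped in the reference). Maximal runs of
#' consecutive qualifying columns of reference length at least
#' \code{min_length} are reported in reference coordinates. Blocks missing
#' any set species contribute nothing.
#'
#' @param blocks List of alignment blocks from [read_maf()].
#' @param species A [species_set()].
#' @param min_length Minimum segment length in reference bp (default 5, the
#'   monomer length of the SOX10 consensus).
#' @return data.frame with columns chrom, start, end, name
#'   ("exact:<species-joined>"), length; sorted, non-overlapping within a
#'   block.
#' @export
extract_identical_segments <- function(blocks, species = species_set(),
                                       min_length = 5L) {
  stopifnot(inherits(species, "species_set"), min_length >= 1L)
  min_length <- as.integer(min_length)
  label <- paste0("exact:", paste(species$species, collapse = ","))
  segs <- lapply(seq_along(blocks), function(bi) {
    b <- blocks[[bi]]
    idx <- match(species$species, b$species)
    ref_i <- match(species$reference, b$species)
    if (is.na(ref_i))
      stop("alignment block ", bi, " lacks the reference species '",
           species$reference, "'", call. = FALSE)
    if (anyNA(idx)) return(NULL)      # missing species: nothing qualifies
    mat <- do.call(rbind, strsplit(b$text[idx], ""))
    qual <- colSums(mat == rep(mat[1, ], each = nrow(mat))) == nrow(mat) &
      mat[1, ] != "-" & mat[1, ] != "N"
    # gaps elsewhere in the column already break identity with row 1 unless
    # row 1 is a gap itself, which the mat[1,]!="-" term covers
    ref_chars <- strsplit(b$text[ref_i], "")[[1]]
    ref_pos <- cumsum(ref_chars != "-") - 1L + b$start[ref_i]  # 0-based
    r <- rle(qual)
    ends_col <- cumsum(r$lengths)
    starts_col <- ends_col - r$lengths + 1L
    keep <- r$values & r$lengths >= min_length
    if (!any(keep)) return(NULL)
    data.frame(
      chrom = b$chrom[ref_i],
      start = ref_pos[starts_col[keep]],
      end = ref_pos[ends_col[keep]] + 1L,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, segs)
  if (is.null(out) || nrow(out) == 0L)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), name = character(), length = integer(),
                      stringsAsFactors = FALSE))
  out$name <- label
  out$length <- out$end - out$start
  out <- out[order(out$chrom, out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Merge book-ended or overlapping conserved segments
#'
#' Adjacent multiz blocks can abut on the reference; segments that touch or
#' overlap in reference coordinates are unioned.
#'
#' @param segments Segment data.frame from [extract_identical_segments()].
#' @return Merged segment data.frame, same columns.
#' @export
merge_segments <- function(segments) {
  if (nrow(segments) == 0L) return(segments)
  segments <- segments[order(segments$chrom, segments$start, segments$end), ,
                       drop = FALSE]
  gr <- as_granges(segments)
  # min.gapwidth = 1 merges book-ended ranges (gap 0) but not a 1-bp gap
  merged <- GenomicRanges::reduce(gr, min.gapwidth = 1L)
  out <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(merged)),
    start = GenomicRanges::start(merged) - 1L,
    end = GenomicRanges::end(merged),
    stringsAsFactors = FALSE)
  out$name <- if (nrow(segments)) segments$name[1] else character()
  out$length <- out$end - out$start
  out <- out[order(out$chrom, out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}
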