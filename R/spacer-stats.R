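#' GC content of a nucleotide sequence
#'
#' (G + C) / (A + C + G + T); N is excluded from numerator and denominator.
#'
#' @param sequence Non-empty nucleotide string.
#' @return Fraction in [0, 1].
#' @examples
#' gc_content("GAACATT")  # 2/7
#' @export
gc_content <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  s <- toupper(sequence)
  if (nchar(s) == 0L) stop("empty sequence", call. = FALSE)
  chars <- strsplit(s, "")[[1]]
  denom <- sum(chars %in% c("A", "C", "G", "T"))
  if (denom == 0L) stop("sequence has no unambiguous bases", call. = FALSE)
  sum(chars %in% c("G", "C")) / denom
}

#' Summarize a group of spacer sequences
#'
#' Pooled GC is computed over the concatenated bases (the canonical group
#' statistic here); the arithmetic mean of per-spacer GC fractions is also
#' reported.
#'
#' @param spacers Character vector of spacer sequences (length >= 1).
#' @param label Group label.
#' @return Object of class \code{spacer_group}: label, spacers, n, lengths,
#'   length min/max/mean, pooled_gc, per_site_gc, per_site_mean_gc.
#' @export
summarize_group <- function(spacers, label = "group") {
  stopifnot(length(spacers) >= 1L, all(nchar(spacers) >= 1L))
  spacers <- toupper(spacers)
  lens <- nchar(spacers)
  per_site <- vapply(spacers, gc_content, 1.0, USE.NAMES = FALSE)
  structure(list(
    label = label,
    spacers = spacers,
    n = length(spacers),
    lengths = lens,
    length_min = min(lens),
    length_max = max(lens),
    length_mean = mean(lens),
    pooled_gc = gc_content(paste(spacers, collapse = "")),
    per_site_gc = per_site,
    per_site_mean_gc = mean(per_site)),
    class = "spacer_group")
}

#' @export
print.spacer_group <- function(x, ...) {
  cat(sprintf("Spacer group '%s': n = %d\n", x$label, x$n))
  cat(sprintf("  lengths: min %d, max %d, mean %.2f\n",
              x$length_min, x$length_max, x$length_mean))
  cat(sprintf("  pooled GC: %.1f%%  (per-site mean %.1f%%)\n",
              100 * x$pooled_gc, 100 * x$per_site_mean_gc))
  invisible(x)
}

#' Compare two spacer groups
#'
#' Descriptive comparison only: differences in pooled GC and mean length,
#' with both group summaries echoed. An optional Wilcoxon rank-sum test on
#' per-site GC is offered as an extension beyond the descriptive record.
#'
#' @param group_all,group_active [summarize_group()] objects (e.g. the total
#'   dimer population vs the validated active sites).
#' @param rank_sum Also run a two-sided Wilcoxon rank-sum test on per-site
#'   GC fractions.
#' @return List with delta_pooled_gc, delta_mean_length, the two summaries
#'   and (optionally) rank_sum_p.
#' @export
compare_groups <- function(group_all, group_active, rank_sum = FALSE) {
  stopifnot(inherits(group_all, "spacer_group"),
            inherits(group_active, "spacer_group"))
  out <- list(
    delta_pooled_gc = group_active$pooled_gc - group_all$pooled_gc,
    delta_mean_length = group_active$length_mean - group_all$length_mean,
    n_all = group_all$n, n_active = group_active$n,
    all = group_all, active = group_active)
  if (rank_sum)
    out$rank_sum_p <- stats::wilcox.test(group_all$per_site_gc,
                                         group_active$per_site_gc,
                                         exact = FALSE)$p.value
  out
}

#' Functionally validated SOX10 dimeric sites
#'
#' The luciferase-validated SOX10 response elements at Schwann-cell
#' myelination loci shipped with the package: element id, locus, assembly
#' coordinates, the consensus-site string, the intervening (spacer) sequence,
#' and whether the site was both active and consensus-dependent
#' ("active_required"). Sites whose second monomer degenerates from the
#' strict reverse consensus are included as data; their spacer strings are
#' annotation, not scanner output.
#'
#' @param active_only Return only the active, consensus-required dimeric
#'   sites whose spacer lies in the canonical 5-8 bp window (the n = 7 set;
#'   this drops the one required site with a 20-bp spacer, whose two
#'   monomers act independently rather than as a spaced dimer).
#' @return data.frame of validated sites.
#' @export
validated_sites <- function(active_only = FALSE) {
  path <- system.file("extdata", "validated_sox10_sites.tsv",
                      package = "regscreen", mustWork = TRUE)
  df <- read.table(path, sep = "\t", header = TRUE, colClasses = "character",
                   comment.char = "#")
  df$active_required <- df$active_required == "yes"
  if (active_only) df <- df[df$active_required & nchar(df$spacer) >= 5L &
                              nchar(df$spacer) <= 8L, , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Extract spacer sequences from a dimer match table
#'
#' Accepts either the data.frame from [scan_dimers()] (spacer column) or a
#' BED read back from disk whose name field encodes "F=<seq>;S=<spacer>;R=<seq>".
#'
#' @param dimers data.frame of dimer matches or BED intervals.
#' @return Character vector of spacer sequences.
#' @export
dimer_spacers <- function(dimers) {
  if (!is.null(dimers$spacer)) return(dimers$spacer)
  if (!is.null(dimers$name) && all(grepl("S=", dimers$name, fixed = TRUE)))
    return(sub("^.*S=([A-ZN]*);.*$", "\\1", dimers$name))
  stop("cannot locate spacer sequences in input", call. = FALSE)
}
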