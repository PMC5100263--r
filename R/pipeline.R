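#' Build a pipeline configuration
#'
#' Paths plus parameters for one end-to-end screen. Input files are checked
#' at run time; parameter ranges are validated here.
#'
#' @param genome_fa FASTA path.
#' @param maf MAF path.
#' @param genes genePred path.
#' @param peaks Named character vector of scored BED paths (e.g.
#'   c(dnase = "...", chip = "...")).
#' @param peak_thresholds Named numeric vector of per-set score thresholds.
#' @param annotation_tsv Optional two-column gene/category file for
#'   enrichment.
#' @param universe Optional path to a one-gene-per-line universe file.
#' @param gene_list Optional path to a designated gene list for enrichment;
#'   when absent, the screen's nearest genes are tested.
#' @param outdir Output directory.
#' @param species Species ids, reference first.
#' @param min_segment_length Minimum conserved-segment length (bp).
#' @param flank Gene-proximity flank (bp).
#' @param spacer_min,spacer_max Dimer spacer bounds (bp).
#' @param strand_mode Monomer scan mode ("both" or "plus").
#' @param verbose Log stage-by-stage row counts.
#' @return Object of class \code{pipeline_config}.
#' @export
pipeline_config <- function(genome_fa, maf, genes,
                            peaks = character(),
                            peak_thresholds = c(dnase = 0.08, chip = 0),
                            annotation_tsv = NULL, universe = NULL,
                            gene_list = NULL,
                            outdir = NULL,
                            species = c("hg18", "mm9", "galGal3"),
                            min_segment_length = 5L,
                            flank = 2500L,
                            spacer_min = 5L, spacer_max = 10L,
                            strand_mode = "both",
                            verbose = TRUE) {
  stopifnot(min_segment_length >= 1L, flank >= 0L,
            spacer_min > 0L, spacer_min <= spacer_max,
            strand_mode %in% c("both", "plus"))
  if (length(peaks)) stopifnot(!is.null(names(peaks)))
  cfg <- list(genome_fa = genome_fa, maf = maf, genes = genes,
              peaks = peaks, peak_thresholds = peak_thresholds,
              annotation_tsv = annotation_tsv, universe = universe,
              gene_list = gene_list, outdir = outdir, species = species,
              min_segment_length = as.integer(min_segment_length),
              flank = as.integer(flank),
              spacer_min = as.integer(spacer_min),
              spacer_max = as.integer(spacer_max),
              strand_mode = strand_mode, verbose = verbose)
  class(cfg) <- "pipeline_config"
  cfg
}

stage_log <- function(verbose, stage, ...) {
  if (verbose)
    message(format(Sys.time(), "[%H:%M:%S] "), stage, ": ", ...)
}

#' Prioritize dimer matches through the filter chain
#'
#' Containment in a conserved segment (spacer included), coding-sequence
#' exclusion, gene-proximity assignment, scored-peak support, nearest-gene
#' annotation.
#'
#' @param dimers Dimer match data.frame from [scan_dimers()].
#' @param segments Conserved-segment data.frame.
#' @param gene_models Gene-model data.frame.
#' @param peak_sets Named list of scored-interval data.frames (may be
#'   empty).
#' @param min_scores Named per-set score thresholds.
#' @param flank Gene-proximity flank in bp.
#' @return List: \code{candidates} (the surviving annotated matches) and
#'   \code{counts} (the row-count funnel through every stage).
#' @export
screen_candidates <- function(dimers, segments, gene_models,
                              peak_sets = list(), min_scores = numeric(),
                              flank = 2500L) {
  counts <- c(dimers = nrow(dimers))
  out <- require_containment(dimers, segments)
  counts["conserved"] <- nrow(out)
  out <- exclude_coding(out, gene_models)
  counts["noncoding"] <- nrow(out)
  out <- assign_genes(out, gene_models, flank = flank)
  counts["gene_proximal"] <- nrow(out)
  if (length(peak_sets)) {
    out <- intersect_peaks(out, peak_sets, min_scores)
    counts["peak_supported"] <- nrow(out)
  }
  if (nrow(out)) out <- nearest_gene(out, gene_models)
  else { out$nearest_gene <- character(); out$nearest_distance <- integer() }
  loci <- count_loci(out)
  counts["unique_genes"] <- loci[["n_unique_genes"]]
  list(candidates = out, counts = counts)
}

#' Run the full screen
#'
#' Stage chain: monomer and dimer scans, exact-identity conserved-segment
#' extraction (book-ended segments merged), the prioritization filters, and
#' optionally spacer statistics and category overrepresentation. When
#' \code{config$outdir} is set, the stage outputs (monomers.bed, dimers.bed,
#' conserved.bed, candidates.bed, report.tsv, spacer_stats.tsv,
#' enrichment.tsv) and a manifest.json with parameters, input digests and
#' the full row-count funnel are written.
#'
#' @param config A [pipeline_config()].
#' @return List: candidates, counts, dimers, segments, spacer_summary,
#'   enrichment (NULL without annotation), manifest.
#' @export
run_screen <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  v <- config$verbose
  inputs <- c(genome_fa = config$genome_fa, maf = config$maf,
              genes = config$genes, config$peaks)
  missing <- inputs[!file.exists(inputs)]
  if (length(missing))
    stop("missing input file(s): ",
         paste(names(missing), "=", missing, collapse = ", "), call. = FALSE)
  grammar <- motif_grammar(spacer_min = config$spacer_min,
                           spacer_max = config$spacer_max)
  genome <- read_fasta(config$genome_fa)
  stage_log(v, "scan", length(genome), " sequence(s), ",
            sum(nchar(genome)), " bp")
  monomers <- scan_monomers(genome, grammar, strand_mode = config$strand_mode)
  stage_log(v, "scan-monomers", nrow(monomers), " monomer matches")
  dimers <- scan_dimers(genome, grammar)
  stage_log(v, "scan-dimers", nrow(dimers), " dimer matches")
  blocks <- read_maf(config$maf, reference = config$species[1])
  segments <- merge_segments(extract_identical_segments(
    blocks, species_set(config$species), config$min_segment_length))
  stage_log(v, "conserved-segments", nrow(segments), " segments")
  gene_models <- read_gene_models(config$genes)
  peak_sets <- lapply(config$peaks, read_bed, scored = TRUE)
  screened <- screen_candidates(dimers, segments, gene_models, peak_sets,
                                config$peak_thresholds, config$flank)
  for (nm in names(screened$counts))
    stage_log(v, "prioritize", nm, " = ", screened$counts[[nm]])
  cand <- screened$candidates
  spacer_summary <- if (nrow(cand))
    summarize_group(dimer_spacers(cand), "candidates") else NULL
  enrichment <- NULL
  if (!is.null(config$annotation_tsv)) {
    ann <- read_annotation(config$annotation_tsv, config$universe)
    genes <- if (!is.null(config$gene_list)) readLines(config$gene_list)
             else unique(cand$nearest_gene)
    enrichment <- overrepresentation(genes, ann)
    stage_log(v, "enrich", nrow(enrichment), " categories tested on ",
              length(genes), " genes")
  }
  counts <- c(monomers = nrow(monomers), screened$counts,
              conserved_segments = nrow(segments))
  manifest <- list(
    parameters = config[c("species", "min_segment_length", "flank",
                          "spacer_min", "spacer_max", "strand_mode",
                          "peak_thresholds")],
    inputs = as.list(tools::md5sum(inputs)),
    counts = as.list(counts))
  result <- list(candidates = cand, counts = counts, dimers = dimers,
                 monomers = monomers, segments = segments,
                 spacer_summary = spacer_summary, enrichment = enrichment,
                 manifest = manifest)
  if (!is.null(config$outdir)) {
    dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
    p <- function(f) file.path(config$outdir, f)
    write_bed(monomers, p("monomers.bed"))
    write_bed(dimers, p("dimers.bed"))
    write_bed(segments, p("conserved.bed"))
    write_bed(cand, p("candidates.bed"))
    report_cols <- intersect(
      c("chrom", "start", "end", "spacer", "spacer_length", "segment_start",
        "segment_end", "genes", "relations",
        paste0(names(peak_sets), "_score"), "nearest_gene",
        "nearest_distance"), names(cand))
    write.table(cand[, report_cols, drop = FALSE], p("report.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(enrichment))
      write.table(enrichment, p("enrichment.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
    if (!is.null(spacer_summary))
      write.table(
        data.frame(label = spacer_summary$label, n = spacer_summary$n,
                   length_min = spacer_summary$length_min,
                   length_max = spacer_summary$length_max,
                   length_mean = spacer_summary$length_mean,
                   pooled_gc = spacer_summary$pooled_gc,
                   per_site_mean_gc = spacer_summary$per_site_mean_gc),
        p("spacer_stats.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
    manifest$outputs <- as.list(tools::md5sum(
      vapply(c("monomers.bed", "dimers.bed", "conserved.bed",
               "candidates.bed", "report.tsv"), p, "")))
    jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                         pretty = TRUE)
    result$manifest <- manifest
  }
  result
}
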