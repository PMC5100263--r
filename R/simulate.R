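default_site_specs <- function() {
  data.frame(
    id = c("dim_pos1", "dim_pos2", "dim_pos3", "dim_pos4", "dim_pos5",
           "dim_cds", "dim_nopeak", "dim_noncons", "dim_intergenic",
           "mono_cons1", "mono_cons2"),
    kind = c(rep("dimer", 9L), "monomer", "monomer"),
    compartment = c("intronic", "intronic", "intronic", "upstream-flank",
                    "downstream-flank", "cds", "intronic", "intronic",
                    "intergenic", "intronic", "upstream-flank"),
    gene_index = c(1L, 2L, 3L, 4L, 5L, 6L, 1L, 2L, NA, 3L, 5L),
    conserved = c(TRUE, TRUE, TRUE, TRUE, TRUE,
                  TRUE, TRUE, FALSE, TRUE, TRUE, TRUE),
    dnase = c(TRUE, TRUE, TRUE, TRUE, TRUE,
              TRUE, FALSE, TRUE, TRUE, FALSE, FALSE),
    chip = c(TRUE, TRUE, TRUE, TRUE, TRUE,
             TRUE, FALSE, TRUE, TRUE, FALSE, FALSE),
    spacer_length = c(5L, 6L, 7L, 8L, 10L, 6L, 6L, 7L, 8L, NA, NA),
    stringsAsFactors = FALSE)
}

#' Build a simulation configuration
#'
#' One integer seed drives every pseudo-random draw. The defaults define the
#' study conditions the rest of the package is tested under: a 100-kb
#' i.i.d. background at human-like AT-rich composition, six protein-coding
#' gene models with a three-exon geometry, planted dimeric/monomeric
#' consensus sites across genomic compartments (five fully supported
#' positives plus coding, peak-less, non-conserved and intergenic decoys),
#' a three-species alignment whose exact-identity runs cover exactly the
#' declared conserved sites, scored peak sets, and an annotation universe
#' with one enriched category.
#'
#' @param seed Integer seed.
#' @param genome_length Genome length in bp.
#' @param base_probs Named numeric(4), probabilities of A, C, G, T.
#' @param sites data.frame of planted-site specs (see
#'   \code{default_site_specs} in the package sources for the shape).
#' @param n_genes Number of gene models.
#' @param flank Flank size in bp used for "gene-proximal".
#' @param spacer_gc Per-base G+C probability of planted dimer spacers.
#' @param species Species ids; first is the reference.
#' @param divergence Named per-species substitution probabilities outside
#'   conserved blocks (reference excluded).
#' @param min_segment_length Exact-identity run length the generator
#'   guarantees never to create by chance outside declared blocks.
#' @param conserved_pad Pad in bp added around each conserved planted site
#'   when declaring its identity block.
#' @param dnase_threshold F-Seq-style score threshold supported peaks must
#'   meet.
#' @param n_decoy_peaks Peaks placed away from every truth site.
#' @param universe_size,n_categories,category_size,list_size,planted_overlap
#'   Annotation-universe geometry: N, number of categories, K, designated
#'   gene-list size n, and how many list genes the planted category gets.
#' @return Object of class \code{simulation_config}.
#' @export
simulation_config <- function(seed = 1L,
                              genome_length = 100000L,
                              base_probs = c(A = 0.295, C = 0.205,
                                             G = 0.205, T = 0.295),
                              sites = default_site_specs(),
                              n_genes = 6L,
                              flank = 2500L,
                              spacer_gc = 0.35,
                              species = c("hg18", "mm9", "galGal3"),
                              divergence = c(mm9 = 0.25, galGal3 = 0.40),
                              min_segment_length = 5L,
                              conserved_pad = 4L,
                              dnase_threshold = 0.08,
                              n_decoy_peaks = 5L,
                              universe_size = 20000L,
                              n_categories = 100L,
                              category_size = 50L,
                              list_size = 191L,
                              planted_overlap = 10L) {
  stopifnot(abs(sum(base_probs) - 1) < 1e-9, genome_length > 0,
            all(divergence > 0 & divergence < 1),
            length(species) >= 2L,
            setequal(names(divergence), species[-1]),
            planted_overlap <= list_size,
                planted_overlap <= category_size)
  cfg <- list(seed = as.integer(seed), genome_length = as.integer(genome_length),
              base_probs = base_probs, sites = sites,
              n_genes = as.integer(n_genes), flank = as.integer(flank),
              spacer_gc = spacer_gc, species = species,
              divergence = divergence,
              min_segment_length = as.integer(min_segment_length),
              conserved_pad = as.integer(conserved_pad),
              dnase_threshold = dnase_threshold,
              n_decoy_peaks = as.integer(n_decoy_peaks),
              universe_size = as.integer(universe_size),
              n_categories = as.integer(n_categories),
              category_size = as.integer(category_size),
              list_size = as.integer(list_size),
              planted_overlap = as.integer(planted_overlap))
  class(cfg) <- "simulation_config"
  cfg
}

#' Simulate gene models
#'
#' A deterministic three-exon geometry: gene i occupies a 6-kb transcript on
#' alternating strands at a fixed pitch chosen so that flanks never touch and
#' a genuinely intergenic corridor remains between neighbours. The CDS starts
#' 200 bp into exon 1 and ends 200 bp into exon 3, leaving non-coding UTR
#' exon sequence on both sides.
#'
#' @param config A [simulation_config()].
#' @return Gene-model data.frame (see [read_gene_models()]).
#' @export
simulate_gene_models <- function(config) {
  n <- config$n_genes
  pitch <- 12000L; margin <- 4000L; tx_len <- 6000L
  need <- margin + (n - 1L) * pitch + tx_len + config$flank + 1000L
  if (config$genome_length < need)
    stop("genome too short for ", n, " gene models (need >= ", need, " bp)",
         call. = FALSE)
  ts <- margin + (seq_len(n) - 1L) * pitch
  ex_off_s <- c(0L, 2400L, 5600L); ex_off_e <- c(400L, 2800L, 6000L)
  gm <- data.frame(
    gene = sprintf("GENE%02d", seq_len(n)),
    tx_id = sprintf("TX%02d", seq_len(n)),
    chrom = "chrS1",
    strand = rep(c("+", "-"), length.out = n),
    tx_start = ts, tx_end = ts + tx_len,
    cds_start = ts + 200L, cds_end = ts + 5800L,
    stringsAsFactors = FALSE)
  gm$exon_starts <- lapply(ts, function(s) s + ex_off_s)
  gm$exon_ends <- lapply(ts, function(s) s + ex_off_e)
  gm
}

site_window <- function(spec, gm, config) {
  # candidate placement window (0-based half-open) for one site spec
  flank <- config$flank
  if (spec$compartment == "intergenic") {
    last <- max(gm$tx_end)
    lo <- last + flank + 500L
    hi <- config$genome_length - 200L
  } else {
    g <- gm[spec$gene_index, ]
    win <- switch(spec$compartment,
      "intronic" = c(g$exon_ends[[1]][1] + 50L, g$exon_starts[[1]][2] - 50L),
      "cds" = c(g$cds_start + 50L, g$exon_ends[[1]][1] - 10L),
      "upstream-flank" = if (g$strand == "+")
        c(g$tx_start - flank + 100L, g$tx_start - 100L)
      else c(g$tx_end + 100L, g$tx_end + flank - 100L),
      "downstream-flank" = if (g$strand == "+")
        c(g$tx_end + 100L, g$tx_end + flank - 100L)
      else c(g$tx_start - flank + 100L, g$tx_start - 100L),
      stop("unknown compartment: ", spec$compartment, call. = FALSE))
    lo <- win[1]; hi <- win[2]
  }
  c(lo, hi)
}

FORWARD_LITERALS <- c("ACACA", "ACAAG", "ACAAT", "ACAAA")
REVERSE_LITERALS <- c("TGTGT", "CTTGT", "ATTGT", "TTTGT")

draw_spacer <- function(len, gc) {
  paste(sample(c("G", "C", "A", "T"), len, replace = TRUE,
               prob = c(gc / 2, gc / 2, (1 - gc) / 2, (1 - gc) / 2)),
        collapse = "")
}

draw_site_sequence <- function(spec, config) {
  if (spec$kind == "monomer") {
    sample(FORWARD_LITERALS, 1L)
  } else {
    paste0(sample(FORWARD_LITERALS, 1L),
           draw_spacer(spec$spacer_length, config$spacer_gc),
           sample(REVERSE_LITERALS, 1L))
  }
}

#' Simulate a genome with planted consensus sites
#'
#' Draws an i.i.d. background from the configured base composition, places
#' every configured site in its declared genomic compartment (relative to
#' [simulate_gene_models()] of the same config), and overwrites the
#' background with the site sequences. Windows around planted dimers are
#' redrawn until they contain exactly the planted dimer call and no
#' accidental extra one, so truth records stay exact. Identical seeds give
#' identical output.
#'
#' @param config A [simulation_config()].
#' @return List with elements \code{genome} (named character vector),
#'   \code{gene_models}, and \code{truth} (data.frame: id, kind, chrom,
#'   start, end, sequence, spacer, compartment, conserved, noncoding,
#'   gene_proximal, dnase, chip, gene).
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  gm <- simulate_gene_models(config)
  L <- config$genome_length
  bases <- sample(names(config$base_probs), L, replace = TRUE,
                  prob = config$base_probs)
  sites <- config$sites
  grammar <- motif_grammar()
  pad <- config$conserved_pad
  truth <- vector("list", nrow(sites))
  used <- cbind(start = integer(), end = integer())
  for (i in seq_len(nrow(sites))) {
    spec <- sites[i, ]
    win <- site_window(spec, gm, config)
    site_seq <- NULL; start <- NA_integer_
    for (try in 1:200) {
      cand_seq <- draw_site_sequence(spec, config)
      w <- nchar(cand_seq)
      if (win[2] - win[1] < w + 2L * pad)
        stop("placement window too small for site ", spec$id, call. = FALSE)
      cand_start <- win[1] + pad +
        sample.int(win[2] - win[1] - w - 2L * pad + 1L, 1L) - 1L
      clash <- any(cand_start - pad < used[, "end"] + pad &
                     cand_start + w + pad > used[, "start"] - pad)
      if (clash) next
      # write candidate and verify the window scans to exactly one dimer
      probe <- bases
      probe[(cand_start + 1L):(cand_start + w)] <- strsplit(cand_seq, "")[[1]]
      wlo <- max(0L, cand_start - pad); whi <- min(L, cand_start + w + pad)
      wtext <- paste(probe[(wlo + 1L):whi], collapse = "")
      dm <- scan_dimers(setNames(wtext, "w"), grammar)
      ok <- if (spec$kind == "dimer")
        nrow(dm) == 1L && dm$start[1] == cand_start - wlo &&
          dm$end[1] == cand_start - wlo + w
      else nrow(dm) == 0L
      if (ok) { site_seq <- cand_seq; start <- cand_start; bases <- probe; break }
    }
    if (is.null(site_seq))
      stop("could not place site ", spec$id, " without scan artifacts",
           call. = FALSE)
    used <- rbind(used, c(start = start, end = start + nchar(site_seq)))
    g_idx <- spec$gene_index
    truth[[i]] <- data.frame(
      id = spec$id, kind = spec$kind, chrom = "chrS1",
      start = start, end = start + nchar(site_seq),
      sequence = site_seq,
      spacer = if (spec$kind == "dimer")
        substr(site_seq, grammar$monomer_length + 1L,
               nchar(site_seq) - grammar$monomer_length) else "",
      compartment = spec$compartment,
      conserved = spec$conserved,
      noncoding = spec$compartment != "cds",
      gene_proximal = spec$compartment != "intergenic",
      dnase = spec$dnase, chip = spec$chip,
      gene = if (!is.na(g_idx)) gm$gene[g_idx] else NA_character_,
      stringsAsFactors = FALSE)
  }
  truth <- do.call(rbind, truth)
  list(genome = setNames(paste(bases, collapse = ""), "chrS1"),
       gene_models = gm, truth = truth)
}

#' Simulate a three-species alignment over a reference genome
#'
#' Non-reference species copy the reference inside the declared conserved
#' blocks (each conserved truth site padded by \code{conserved_pad} bp) and
#' mutate every other base independently at their divergence probability.
#' Identity runs of \code{min_segment_length} or more can never arise by
#' chance: the generator forces a mismatch into any such accidental run and
#' at the flanking column of every declared block, so the extracted segments
#' equal the declared truth exactly.
#'
#' @param genome Named character vector (the reference), from
#'   [simulate_genome()].
#' @param config The same [simulation_config()].
#' @param truth The truth table from [simulate_genome()].
#' @param block_cols Alignment-block width in columns.
#' @return List with \code{blocks} (see [read_maf()]) and
#'   \code{truth_segments} (BED-like data.frame of declared identity blocks).
#' @export
simulate_alignment <- function(genome, config, truth, block_cols = 2000L) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed + 1L)
  ref_name <- config$species[1]
  chrom <- names(genome)[1]
  ref <- strsplit(genome[[1]], "")[[1]]
  L <- length(ref)
  pad <- config$conserved_pad
  cons <- truth[truth$conserved, , drop = FALSE]
  win_s <- pmax(0L, cons$start - pad)
  win_e <- pmin(L, cons$end + pad)
  cons_mask <- logical(L)
  for (j in seq_along(win_s)) cons_mask[(win_s[j] + 1L):win_e[j]] <- TRUE
  others <- list()
  # uniformly draw a different base, vectorized via a 4x3 lookup
  alt_tab <- rbind(A = c("C", "G", "T"), C = c("A", "G", "T"),
                   G = c("A", "C", "T"), T = c("A", "C", "G"))
  mutate <- function(base) {
    base[!(base %in% rownames(alt_tab))] <- "A"   # N-safe fallback
    alt_tab[cbind(match(base, rownames(alt_tab)),
                  sample.int(3L, length(base), replace = TRUE))]
  }
  for (sp in config$species[-1]) {
    d <- config$divergence[[sp]]
    row <- ref
    hit <- runif(L) < d & !cons_mask
    if (any(hit)) row[hit] <- mutate(ref[hit])
    others[[sp]] <- row
  }
  # force a break at the flanking column of every declared block
  breaker <- config$species[2]
  edges <- unique(c(win_s - 1L, win_e))           # 0-based positions
  edges <- edges[edges >= 0L & edges < L]
  edges <- edges[!cons_mask[edges + 1L]]
  if (length(edges))
    others[[breaker]][edges + 1L] <- mutate(ref[edges + 1L])
  # break any accidental identity run outside the declared blocks
  ident <- ref != "N"
  for (sp in names(others)) ident <- ident & (others[[sp]] == ref)
  ident <- ident & !cons_mask
  r <- rle(ident)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  k <- config$min_segment_length
  for (j in which(r$values & r$lengths >= k)) {
    at <- seq(starts[j] + k - 1L, ends[j], by = k)
    others[[breaker]][at] <- mutate(ref[at])
  }
  # chunk into gapless blocks
  chunk_starts <- seq(0L, L - 1L, by = block_cols)
  blocks <- lapply(chunk_starts, function(s) {
    e <- min(L, s + block_cols)
    texts <- c(paste(ref[(s + 1L):e], collapse = ""),
               vapply(others, function(x)
                 paste(x[(s + 1L):e], collapse = ""), ""))
    b <- data.frame(
      src = paste0(config$species, ".", chrom),
      species = config$species,
      chrom = chrom,
      start = s, size = e - s, strand = "+", src_size = L,
      text = texts, stringsAsFactors = FALSE)
    attr(b, "reference") <- 1L
    b
  })
  segs <- data.frame(chrom = rep(chrom, length(win_s)), start = win_s,
                     end = win_e, name = cons$id, stringsAsFactors = FALSE)
  segs <- segs[order(segs$start), , drop = FALSE]
  rownames(segs) <- NULL
  list(blocks = blocks, truth_segments = segs)
}

#' Simulate scored peak sets
#'
#' Every truth site flagged for a peak set gets one covering peak whose
#' score clears the configured threshold; dnase-negative truth sites get a
#' sub-threshold dnase peak (so score filtering is exercised), and decoy
#' peaks are placed away from every truth site.
#'
#' @param config A [simulation_config()].
#' @param truth Truth table from [simulate_genome()].
#' @return Named list of scored-interval data.frames (dnase, chip).
#' @export
simulate_peaks <- function(config, truth) {
  set.seed(config$seed + 2L)
  chrom <- truth$chrom[1]
  mk <- function(flag_col, threshold, tag) {
    on <- truth[truth[[flag_col]], , drop = FALSE]
    off <- truth[!truth[[flag_col]] & truth$kind == "dimer", , drop = FALSE]
    peaks <- data.frame(chrom = character(), start = integer(),
                        end = integer(), name = character(),
                        score = numeric(), strand = character(),
                        stringsAsFactors = FALSE)
    if (nrow(on))
      peaks <- rbind(peaks, data.frame(
        chrom = chrom, start = pmax(0L, on$start - 20L), end = on$end + 20L,
        name = paste0(tag, "_", on$id),
        score = round(runif(nrow(on), threshold, 1), 4), strand = ".",
        stringsAsFactors = FALSE))
    if (tag == "dnase" && nrow(off) && threshold > 0)
      peaks <- rbind(peaks, data.frame(
        chrom = chrom, start = pmax(0L, off$start - 20L), end = off$end + 20L,
        name = paste0(tag, "_weak_", off$id),
        score = round(runif(nrow(off), 0, threshold * 0.9), 4), strand = ".",
        stringsAsFactors = FALSE))
    # decoys away from all truth sites
    placed <- 0L; guard <- 0L
    while (placed < config$n_decoy_peaks && guard < 1000L) {
      guard <- guard + 1L
      s <- sample.int(config$genome_length - 60L, 1L) - 1L
      if (any(s < truth$end + 40L & s + 60L > truth$start - 40L)) next
      placed <- placed + 1L
      peaks <- rbind(peaks, data.frame(
        chrom = chrom, start = s, end = s + 60L,
        name = paste0(tag, "_decoy", placed),
        score = round(runif(1, 0, 1), 4), strand = ".",
        stringsAsFactors = FALSE))
    }
    peaks[order(peaks$chrom, peaks$start, peaks$end), , drop = FALSE]
  }
  list(dnase = mk("dnase", config$dnase_threshold, "dnase"),
       chip = mk("chip", 0, "chip"))
}

#' Simulate an annotation universe with one enriched category
#'
#' @param config A [simulation_config()].
#' @return List: \code{annotation} (an [annotation_set()]),
#'   \code{list_genes} (the designated gene list), and
#'   \code{planted_category} (its id).
#' @export
simulate_annotation <- function(config) {
  set.seed(config$seed + 3L)
  N <- config$universe_size
  universe <- sprintf("G%05d", seq_len(N))
  cats <- lapply(seq_len(config$n_categories), function(i)
    sample(universe, config$category_size))
  names(cats) <- sprintf("CAT%03d", seq_len(config$n_categories))
  planted <- "CAT001"
  in_cat <- sample(cats[[planted]], config$planted_overlap)
  rest <- sample(setdiff(universe, cats[[planted]]),
                 config$list_size - config$planted_overlap)
  list(annotation = annotation_set(universe, cats),
       list_genes = sample(c(in_cat, rest)),
       planted_category = planted)
}

#' Simulate the full input bundle for one screen
#'
#' Runs every generator under one seed and optionally writes the files a
#' command-line screen would consume (genome.fa, alignment.maf,
#' genes.genePred, cds.bed, dnase.bed, chip.bed, annotation.tsv,
#' universe.txt, list_genes.txt, truth_sites.bed, truth_sites.tsv,
#' truth_segments.bed, manifest.json).
#'
#' @param config A [simulation_config()].
#' @param outdir Output directory (created if needed); NULL returns objects
#'   only.
#' @return List: genome, gene_models, truth, blocks, truth_segments, peaks,
#'   annotation, list_genes, planted_category, and (when written) files.
#' @export
simulate_bundle <- function(config = simulation_config(), outdir = NULL) {
  gen <- simulate_genome(config)
  aln <- simulate_alignment(gen$genome, config, gen$truth)
  peaks <- simulate_peaks(config, gen$truth)
  ann <- simulate_annotation(config)
  bundle <- c(gen, aln, list(peaks = peaks, annotation = ann$annotation,
                             list_genes = ann$list_genes,
                             planted_category = ann$planted_category,
                             config = config))
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    p <- function(f) file.path(outdir, f)
    stamp <- paste0("seed=", config$seed)
    write_fasta(gen$genome, p("genome.fa"))
    write_maf(bundle$blocks, p("alignment.maf"), header = stamp)
    write_gene_models(gen$gene_models, p("genes.genePred"))
    write_bed(cds_exons(gen$gene_models), p("cds.bed"))
    write_bed(peaks$dnase, p("dnase.bed"))
    write_bed(peaks$chip, p("chip.bed"))
    tb <- gen$truth
    tb$name <- tb$id
    write_bed(tb, p("truth_sites.bed"), keep_order = TRUE)
    write.table(gen$truth, p("truth_sites.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    write_bed(bundle$truth_segments, p("truth_segments.bed"))
    annot_df <- do.call(rbind, lapply(names(bundle$annotation$categories),
      function(cat) data.frame(gene = bundle$annotation$categories[[cat]],
                               category = cat, stringsAsFactors = FALSE)))
    write.table(annot_df, p("annotation.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    writeLines(bundle$annotation$universe, p("universe.txt"))
    writeLines(bundle$list_genes, p("list_genes.txt"))
    manifest <- list(seed = config$seed,
                     genome_length = config$genome_length,
                     n_truth_sites = nrow(gen$truth),
                     n_conserved_blocks = nrow(bundle$truth_segments),
                     config_digest = config_digest(config))
    jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                         pretty = TRUE)
    bundle$files <- vapply(c("genome.fa", "alignment.maf", "genes.genePred",
                             "cds.bed", "dnase.bed", "chip.bed",
                             "annotation.tsv", "universe.txt",
                             "list_genes.txt", "truth_sites.bed",
                             "truth_sites.tsv", "truth_segments.bed",
                             "manifest.json"), p, "")
  }
  bundle
}

config_digest <- function(config) {
  flat <- config[setdiff(names(config), "sites")]
  txt <- paste(c(vapply(flat, function(x) paste(x, collapse = ","), ""),
                 paste(unlist(config$sites), collapse = ",")),
               collapse = ";")
  as.character(sum(utf8ToInt(txt) * seq_along(utf8ToInt(txt))) %% 1e9)
}
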