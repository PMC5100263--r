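# Brute-force oracles and tiny fixture builders, independent of the
# implementation paths they check.

FWD_LITERALS <- c("ACACA", "ACAAG", "ACAAT", "ACAAA")
REV_LITERALS <- c("TGTGT", "ATTGT", "CTTGT", "TTTGT")

random_seq <- function(n, probs = c(A = 0.295, C = 0.205, G = 0.205,
                                    T = 0.295)) {
  paste(sample(names(probs), n, replace = TRUE, prob = probs), collapse = "")
}

# test every length-5 window against the literal pattern sets
brute_monomers <- function(text, strand_mode = "both") {
  L <- 5L
  n <- nchar(text)
  if (n < L) return(data.frame(start = integer(), strand = character()))
  starts <- 0:(n - L)
  win <- substring(text, starts + 1L, starts + L)
  fwd <- starts[win %in% FWD_LITERALS]
  out <- data.frame(start = fwd, strand = rep("+", length(fwd)),
                    stringsAsFactors = FALSE)
  if (strand_mode == "both") {
    rev <- starts[win %in% REV_LITERALS]
    out <- rbind(out, data.frame(start = rev, strand = rep("-", length(rev)),
                                 stringsAsFactors = FALSE))
  }
  out[order(out$start, out$strand), , drop = FALSE]
}

# test every (forward position, spacer, reverse position) triple
brute_dimers <- function(text, spacer_min = 5L, spacer_max = 10L) {
  L <- 5L
  n <- nchar(text)
  res <- list()
  for (i in 0:(max(0L, n - (2L * L + spacer_min)))) {
    if (!(substring(text, i + 1L, i + L) %in% FWD_LITERALS)) next
    for (s in spacer_min:spacer_max) {
      j <- i + L + s
      if (j + L > n) break
      if (substring(text, j + 1L, j + L) %in% REV_LITERALS)
        res[[length(res) + 1L]] <- data.frame(start = i, end = j + L,
                                              spacer_length = s)
    }
  }
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(start = integer(), end = integer(),
                      spacer_length = integer())
  out[order(out$start, out$end), , drop = FALSE]
}

# column-wise conservation oracle over parsed blocks
brute_conserved <- function(blocks, species, reference, min_length) {
  segs <- list()
  for (b in blocks) {
    idx <- match(species, b$species)
    if (anyNA(idx)) next
    ref_i <- match(reference, b$species)
    cols <- lapply(strsplit(b$text[idx], ""), identity)
    width <- nchar(b$text[1])
    ref_chars <- strsplit(b$text[ref_i], "")[[1]]
    ref_coord <- cumsum(ref_chars != "-") - 1L + b$start[ref_i]
    run <- integer()
    flush <- function(run) {
      if (length(run) >= min_length)
        segs[[length(segs) + 1L]] <<- data.frame(
          chrom = b$chrom[ref_i], start = ref_coord[run[1]],
          end = ref_coord[run[length(run)]] + 1L)
    }
    for (ci in seq_len(width)) {
      ch <- toupper(vapply(cols, `[[`, "", ci))
      ok <- all(ch == ch[1]) && ch[1] != "-" && ch[1] != "N"
      if (ok) run <- c(run, ci)
      else { flush(run); run <- integer() }
    }
    flush(run)
  }
  out <- do.call(rbind, segs)
  if (is.null(out))
    out <- data.frame(chrom = character(), start = integer(),
                      end = integer())
  out[order(out$chrom, out$start), , drop = FALSE]
}

# exact binomial upper tail by direct summation
brute_binom_upper <- function(k, n, q) {
  if (k <= 0) return(1)
  sum(choose(n, k:n) * q^(k:n) * (1 - q)^(n - (k:n)))
}

# random toy alignment block over 2-4 species with gaps and Ns
random_block <- function(ncol = 50L, species = c("hg18", "mm9", "galGal3"),
                         chrom = "chr1", start = 0L) {
  texts <- vapply(species, function(s)
    paste(sample(c("A", "C", "G", "T", "-", "N"), ncol, replace = TRUE,
                 prob = c(0.3, 0.2, 0.2, 0.24, 0.04, 0.02)), collapse = ""),
    "")
  # reference must be gapless at least somewhere; leave as drawn (gaps allowed)
  sizes <- nchar(gsub("-", "", texts, fixed = TRUE))
  b <- data.frame(src = paste0(species, ".", chrom), species = species,
                  chrom = chrom, start = start, size = sizes, strand = "+",
                  src_size = 100000L, text = texts, stringsAsFactors = FALSE)
  attr(b, "reference") <- 1L
  b
}

# high-identity toy block: start from one sequence and perturb
correlated_block <- function(ncol = 80L, start = 0L, divergence = 0.12) {
  ref <- sample(c("A", "C", "G", "T"), ncol, replace = TRUE)
  perturb <- function() {
    x <- ref
    hit <- runif(ncol) < divergence
    x[hit] <- sample(c("A", "C", "G", "T", "-", "N"), sum(hit),
                     replace = TRUE)
    x
  }
  texts <- c(paste(ref, collapse = ""),
             paste(perturb(), collapse = ""),
             paste(perturb(), collapse = ""))
  species <- c("hg18", "mm9", "galGal3")
  b <- data.frame(src = paste0(species, ".chr1"), species = species,
                  chrom = "chr1", start = start,
                  size = nchar(gsub("-", "", texts, fixed = TRUE)),
                  strand = "+", src_size = 100000L, text = texts,
                  stringsAsFactors = FALSE)
  attr(b, "reference") <- 1L
  b
}

# minimal two-gene model table on one chromosome for filter tests
toy_gene_models <- function() {
  gm <- data.frame(
    gene = c("ALPHA", "BETA"),
    tx_id = c("TX_A", "TX_B"),
    chrom = "chr1",
    strand = c("+", "-"),
    tx_start = c(10000L, 40000L),
    tx_end = c(16000L, 46000L),
    cds_start = c(10200L, 40200L),
    cds_end = c(15800L, 45800L),
    stringsAsFactors = FALSE)
  gm$exon_starts <- list(c(10000L, 12400L, 15600L),
                         c(40000L, 42400L, 45600L))
  gm$exon_ends <- list(c(10400L, 12800L, 16000L),
                       c(40400L, 42800L, 46000L))
  gm
}

toy_match <- function(start, end, chrom = "chr1") {
  data.frame(chrom = chrom, start = as.integer(start), end = as.integer(end),
             name = sprintf("m_%d_%d", start, end), score = 0L, strand = "+",
             stringsAsFactors = FALSE)
}
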