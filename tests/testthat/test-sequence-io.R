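test_that("FASTA reading normalizes case, keeps order, and validates", {
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">chr1 extra tokens", "acgT", ">b", "NNNN"), fa)
  seqs <- read_fasta(fa)
  expect_identical(seqs, c(chr1 = "ACGT", b = "NNNN"))
  expect_identical(read_fasta(fa), seqs)  # normalization is idempotent

  writeLines(c(">only_header"), fa)
  expect_error(read_fasta(fa), "no residues")

  writeLines(c(">x", "ACGU"), fa)
  expect_error(read_fasta(fa), "'U' on line 2")

  writeLines(character(), fa)
  expect_error(read_fasta(fa))
})

test_that("FASTA round-trips through write_fasta", {
  fa <- withr::local_tempfile(fileext = ".fa")
  seqs <- c(chr1 = "ACGTACGTNN", chr2 = strrep("ACGT", 40))
  write_fasta(seqs, fa)
  expect_identical(read_fasta(fa), seqs)
})

test_that("reverse_complement follows complement rules and is an involution", {
  expect_identical(reverse_complement("ACACA"), "TGTGT")
  expect_identical(reverse_complement("ACAAG"), "CTTGT")
  expect_identical(reverse_complement(""), "")
  expect_identical(reverse_complement("NNA"), "TNN")
  expect_error(reverse_complement("ACGX"), "outside")
  set.seed(42)
  for (i in 1:20) {
    s <- random_seq(sample(1:50, 1))
    expect_identical(reverse_complement(reverse_complement(s)), s)
  }
})

test_that("browser/internal coordinate conversion is a length-preserving bijection", {
  expect_identical(browser_to_internal(c(18854300, 18855055)),
                   c(18854299L, 18855055L))
  v <- browser_to_internal(c(18854300, 18855055))
  expect_identical(v[2] - v[1], 18855055L - 18854300L + 1L)  # closed length
  expect_identical(browser_to_internal(c(1, 1)), c(0L, 1L))
  expect_error(browser_to_internal(c(0, 5)))
  set.seed(7)
  for (i in 1:25) {
    a <- sample(1:10000, 1); b <- a + sample(0:500, 1)
    expect_identical(internal_to_browser(browser_to_internal(c(a, b))),
                     c(a, b))
  }
})

test_that("BED reading/writing validates and round-trips", {
  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t0\t5\tm1", bed)
  df <- read_bed(bed)
  expect_identical(df$start, 0L)
  expect_identical(df$end, 5L)
  expect_identical(df$name, "m1")

  writeLines("chr1\t10\t60\tpk\t0.08", bed)
  sc <- read_bed(bed, scored = TRUE)
  expect_identical(sc$score, 0.08)

  writeLines("chr1\t5\t5", bed)
  expect_error(read_bed(bed), "line 1")

  set.seed(11)
  df <- data.frame(chrom = sample(c("chr1", "chr2"), 20, TRUE),
                   start = sample(0:1000, 20),
                   stringsAsFactors = FALSE)
  df$end <- df$start + sample(1:50, 20, TRUE)
  df$name <- sprintf("iv%02d", 1:20)
  df$score <- round(runif(20), 4)
  df$strand <- sample(c("+", "-", "."), 20, TRUE)
  df <- df[order(df$chrom, df$start, df$end, df$name), ]
  rownames(df) <- NULL
  write_bed(df, bed)
  back <- read_bed(bed, scored = TRUE)
  expect_identical(back[, c("chrom", "start", "end", "name", "strand",
                            "score")],
                   df[, c("chrom", "start", "end", "name", "strand",
                          "score")])
})

test_that("gene models parse from genePred and BED12 with CDS conventions", {
  gp <- withr::local_tempfile(fileext = ".genePred")
  # 2 exons, CDS inside exon 1
  writeLines("tx1\tchr1\t+\t100\t900\t150\t350\t2\t100,500,\t400,900,", gp)
  gm <- read_gene_models(gp)
  expect_identical(length(gm$exon_starts[[1]]), 2L)
  expect_identical(gm$cds_start, 150L)

  # exonCount mismatch
  writeLines("tx1\tchr1\t+\t100\t900\t150\t350\t2\t100,500,700,\t400,900,950,",
             gp)
  expect_error(read_gene_models(gp), "exonCount")

  bed12 <- withr::local_tempfile(fileext = ".bed")
  # thickStart == thickEnd -> non-coding
  writeLines("chr1\t100\t900\tnc1\t0\t-\t100\t100\t0\t2\t300,200\t0,600",
             bed12)
  gm <- read_gene_models(bed12, dialect = "BED12")
  expect_true(is.na(gm$cds_start))
  expect_identical(gm$exon_starts[[1]], c(100L, 700L))
  expect_identical(gm$exon_ends[[1]], c(400L, 900L))
})

test_that("gene models round-trip through genePred", {
  gm <- toy_gene_models()
  gp <- withr::local_tempfile(fileext = ".genePred")
  write_gene_models(gm, gp)
  back <- read_gene_models(gp)
  expect_identical(back$gene, gm$gene)
  expect_identical(back$tx_start, gm$tx_start)
  expect_identical(back$cds_end, gm$cds_end)
  expect_identical(back$exon_starts, gm$exon_starts)
})

test_that("MAF parsing checks sizes, designates the reference, round-trips", {
  maf <- withr::local_tempfile(fileext = ".maf")
  writeLines(c("##maf version=1", "",
               "a",
               "s hg18.chr1 0 4 + 10 AC-GT",
               "s mm9.chr1  5 5 + 20 ACAGT",
               "s galGal3.chr2 2 5 + 30 ACAGT"), maf)
  blocks <- read_maf(maf)
  expect_length(blocks, 1L)
  b <- blocks[[1]]
  expect_identical(attr(b, "reference"), 1L)
  expect_identical(b$species, c("hg18", "mm9", "galGal3"))
  expect_identical(b$chrom[3], "chr2")

  out <- withr::local_tempfile(fileext = ".maf")
  write_maf(blocks, out)
  again <- read_maf(out)
  expect_identical(again[[1]]$text, b$text)
  expect_identical(again[[1]]$start, b$start)

  writeLines(c("a", "s hg18.chr1 0 4 + 10 ACGGT"), maf)  # 5 non-gaps, says 4
  expect_error(read_maf(maf), "declares size 4")
})

test_that("a minus-strand reference row is flipped to plus coordinates", {
  maf <- withr::local_tempfile(fileext = ".maf")
  writeLines(c("a",
               "s hg18.chr1 2 4 - 10 AC-GT",
               "s mm9.chr1  0 5 + 20 ACAGT"), maf)
  b <- read_maf(maf, reference = "hg18")[[1]]
  # source start 2 size 4 on '-' of a 10 bp chrom -> plus start 10-2-4 = 4
  expect_identical(b$start[1], 4L)
  expect_identical(b$strand[1], "+")
  expect_identical(b$text[1], "AC-GT")  # reverse complement of AC-GT
})
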