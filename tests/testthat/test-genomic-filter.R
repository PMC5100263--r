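seg_df <- function(s, e) data.frame(chrom = "chr1", start = s, end = e,
                                    name = "exact:x", length = e - s,
                                    stringsAsFactors = FALSE)

test_that("containment requires the full match inside one segment", {
  m <- toy_match(10, 25)
  expect_identical(nrow(require_containment(m, seg_df(0L, 30L))), 1L)
  expect_identical(nrow(require_containment(m, seg_df(12L, 40L))), 0L)
  expect_identical(nrow(require_containment(m, seg_df(0L, 30L)[0, ])), 0L)
  kept <- require_containment(m, seg_df(0L, 30L))
  expect_identical(kept$segment_start, 0L)
  expect_identical(kept$segment_end, 30L)
})

test_that("coding exclusion drops CDS-exon overlap only", {
  gm <- toy_gene_models()
  # ALPHA: exons [10000,10400) [12400,12800) [15600,16000), CDS [10200,15800)
  intronic <- toy_match(11000, 11015)
  expect_identical(nrow(exclude_coding(intronic, gm)), 1L)
  cds_hit <- toy_match(12790, 12805)     # 10 bp inside a CDS exon
  expect_identical(nrow(exclude_coding(cds_hit, gm)), 0L)
  one_bp <- toy_match(12799, 12814)      # 1 bp overlap is enough to drop
  expect_identical(nrow(exclude_coding(one_bp, gm)), 0L)
  utr5 <- toy_match(10050, 10065)        # exon 1 before cds_start
  expect_identical(nrow(exclude_coding(utr5, gm)), 1L)
})

test_that("gene assignment is flank-bounded and strand-aware", {
  gm <- toy_gene_models()
  # 1 kb 5' of the '+' gene ALPHA (tx_start 10000)
  up <- assign_genes(toy_match(8985, 9000), gm)
  expect_identical(nrow(up), 1L)
  expect_match(up$relations, "ALPHA:upstream-flank")
  # 3 kb away from anything
  expect_identical(nrow(assign_genes(toy_match(20000, 20015), gm)), 0L)
  # 1 kb left of the '-' gene BETA (tx_start 40000): genomically upstream of
  # the span but 3' in transcript orientation
  down <- assign_genes(toy_match(38985, 39000), gm)
  expect_match(down$relations, "BETA:downstream-flank")
  # intronic and exonic-noncoding relations
  expect_match(assign_genes(toy_match(11000, 11015), gm)$relations,
               "ALPHA:intronic")
  expect_match(assign_genes(toy_match(10050, 10065), gm)$relations,
               "ALPHA:exonic-noncoding")
  # right at the flank edge: 2500 bp away overlaps by 0 -> dropped;
  # 2499 bp away overlaps by 1 -> kept
  expect_identical(nrow(assign_genes(toy_match(7485, 7500), gm)), 0L)
  expect_identical(nrow(assign_genes(toy_match(7486, 7501), gm)), 1L)
})

test_that("peak intersection enforces per-set thresholds and any-overlap", {
  m <- toy_match(100, 115)
  dnase <- data.frame(chrom = "chr1", start = 90L, end = 130L, name = "pk",
                      score = 0.10, strand = ".", stringsAsFactors = FALSE)
  chip <- data.frame(chrom = "chr1", start = 114L, end = 160L, name = "ck",
                     score = 5, strand = ".", stringsAsFactors = FALSE)
  res <- intersect_peaks(m, list(dnase = dnase, chip = chip),
                         c(dnase = 0.08))
  expect_identical(nrow(res), 1L)
  expect_identical(res$dnase_score, 0.10)
  expect_identical(res$chip_score, 5)

  weak <- dnase; weak$score <- 0.05
  expect_identical(nrow(intersect_peaks(m, list(dnase = weak),
                                        c(dnase = 0.08))), 0L)
  # 1 bp overlap qualifies
  expect_identical(nrow(intersect_peaks(m, list(chip = chip))), 1L)
  expect_error(intersect_peaks(m, list(dnase = dnase), c(atac = 1)),
               "unknown peak set")
})

test_that("nearest gene uses span distance, signed 5' negative, ties alphabetical", {
  gm <- toy_gene_models()
  inside <- nearest_gene(toy_match(11000, 11015), gm)
  expect_identical(inside$nearest_gene, "ALPHA")
  expect_identical(inside$nearest_distance, 0L)

  # 100 bp left of ALPHA ('+'): 5' side -> negative
  left <- nearest_gene(toy_match(9885, 9900), gm)
  expect_identical(left$nearest_gene, "ALPHA")
  expect_identical(left$nearest_distance, -100L)

  # 100 bp right of BETA ('-' strand): genomically right = 5' in transcript
  # orientation -> negative
  right <- nearest_gene(toy_match(46100, 46115), gm)
  expect_identical(right$nearest_gene, "BETA")
  expect_identical(right$nearest_distance, -100L)

  # equidistant genes break alphabetically
  gm2 <- toy_gene_models()
  gm2$gene <- c("ZETA", "ALPHA")
  mid <- toy_match(27995, 28005)   # 12000-ish from both spans? compute:
  # ZETA span ends 16000, ALPHA(') span starts 40000; midpoint 28000 with
  # match [27995,28005): gaps 11995 and 11995
  eq <- nearest_gene(mid, gm2)
  expect_identical(eq$nearest_gene, "ALPHA")

  expect_error(nearest_gene(toy_match(5, 10, chrom = "chrX"), gm), "chrX")
})

test_that("filters are subsetting, idempotent, and commute where claimed", {
  set.seed(404)
  gm <- toy_gene_models()
  segs <- rbind(seg_df(10500L, 11500L), seg_df(12700L, 13000L),
                seg_df(41000L, 42000L))
  matches <- do.call(rbind, lapply(1:60, function(i) {
    s <- sample(9000:47000, 1); toy_match(s, s + 15)
  }))
  a <- require_containment(matches, segs)
  b <- exclude_coding(matches, gm)
  expect_true(nrow(a) <= nrow(matches))
  expect_true(nrow(b) <= nrow(matches))
  # idempotence
  expect_identical(exclude_coding(b, gm), b)
  a2 <- require_containment(a[names(matches)], segs)
  expect_identical(a2[names(matches)], a[names(matches)])
  # commutation of containment and coding exclusion
  ab <- exclude_coding(require_containment(matches, segs), gm)
  ba <- require_containment(exclude_coding(matches, gm), segs)
  expect_identical(ab[order(ab$start), names(matches)],
                   ba[order(ba$start), names(matches)])
})

test_that("interval intersection agrees with an all-pairs overlap oracle", {
  set.seed(505)
  matches <- do.call(rbind, lapply(1:200, function(i) {
    s <- sample(0:5000, 1); toy_match(s, s + sample(5:30, 1))
  }))
  peaks <- data.frame(chrom = "chr1",
                      start = sample(0:5000, 80),
                      stringsAsFactors = FALSE)
  peaks$end <- peaks$start + sample(10:80, 80, replace = TRUE)
  peaks$name <- sprintf("p%d", 1:80)
  peaks$score <- runif(80)
  peaks$strand <- "."
  thr <- 0.3
  got <- intersect_peaks(matches, list(pk = peaks), c(pk = thr))
  keep_oracle <- vapply(seq_len(nrow(matches)), function(i)
    any(peaks$score >= thr & peaks$start < matches$end[i] &
          peaks$end > matches$start[i]), TRUE)
  expect_identical(sort(got$start), sort(matches$start[keep_oracle]))
})

test_that("count_loci counts segments and unique genes", {
  m <- rbind(toy_match(1, 10), toy_match(20, 30), toy_match(40, 50))
  m$nearest_gene <- c("A", "A", "B")
  expect_identical(count_loci(m),
                   c(n_segments = 3L, n_unique_genes = 2L))
  expect_identical(count_loci(m[0, ]),
                   c(n_segments = 0L, n_unique_genes = 0L))
})
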