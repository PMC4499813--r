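.ann <- function() {
  nc <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(c(1001, 5001), c(1100, 5080)), strand = c("+", "-"))
  nc$label <- c("miRNA", "snoRNA")
  reg <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(c(1, 2001, 3001), c(2000, 3000, 3500)), strand = "*")
  reg$label <- c("intron", "exon", "intron")
  list(ncrna = nc, region = reg)
}

test_that("one-nucleotide ncRNA overlap annotates, strand-aware", {
  ann <- .ann()
  # overlap of exactly 1 nt with the miRNA at [1000, 1100) (0-based)
  r <- annotateInterval("chr1", 1099, 1120, "+", ann)
  expect_equal(r$ncrna, "miRNA")
  # same interval on minus strand misses the plus-strand miRNA
  r <- annotateInterval("chr1", 1099, 1120, "-", ann)
  expect_true(is.na(r$ncrna))
  # no overlap at all
  r <- annotateInterval("chr1", 1100, 1120, "+", ann)
  expect_true(is.na(r$ncrna))
})

test_that("region labels follow the >50% and maximum-overlap rules", {
  ann <- .ann()
  # 60% in intron [0,2000), 40% in exon
  r <- annotateInterval("chr1", 1970, 2020, "+", ann)
  expect_equal(r$region, "intron")
  # exactly 50% in exon and 50% in intron: no class >50% -> intergenic
  r <- annotateInterval("chr1", 2950, 3050, "+", ann)
  expect_equal(r$region, "intergenic")
  # no overlap at all
  r <- annotateInterval("chr1", 3600, 3700, "+", ann)
  expect_equal(r$region, "intergenic")
  # fully inside the exon
  r <- annotateInterval("chr1", 2100, 2150, "+", ann)
  expect_equal(r$region, "exon")
})

test_that("annotation assignment is input-order independent", {
  ann <- .ann()
  ann2 <- list(ncrna = rev(ann$ncrna), region = rev(ann$region))
  q <- list(c(1050, 1090), c(1970, 2020), c(2100, 2150))
  for (iv in q) {
    expect_identical(annotateInterval("chr1", iv[1], iv[2], "+", ann),
                     annotateInterval("chr1", iv[1], iv[2], "+", ann2))
  }
})

test_that("binomial enrichment follows the dart model", {
  feat <- data.frame(chrom = "chr1", start = 0, end = 1000)       # 1% of genome
  hits <- data.frame(chrom = "chr1", start = seq(0, 900, 100), end = seq(20, 920, 100))
  miss <- data.frame(chrom = "chr1", start = seq(2000, 91000, 1000),
                     end = seq(2020, 91020, 1000))
  res <- binomialEnrichment(rbind(hits, miss), feat, genomeSize = 1e5)
  expect_equal(res$observed, 10L)
  expect_equal(res$expectedFraction, 0.01)
  expect_lt(res$pValue, 1e-6)
  expect_equal(res$pValue, pbinom(9, 100, 0.01, lower.tail = FALSE))

  # zero observed -> p = 1
  res0 <- binomialEnrichment(miss[1:10, ], feat, genomeSize = 1e5)
  expect_equal(res0$pValue, 1)

  # feature covering the whole genome -> all hit, p = 1
  all <- data.frame(chrom = "chr1", start = 0, end = 1e5)
  resA <- binomialEnrichment(hits, all, genomeSize = 1e5)
  expect_equal(resA$observed, nrow(hits))
  expect_equal(resA$pValue, 1)

  expect_warning(resE <- binomialEnrichment(hits, feat[0, ], 1e5), "zero")
  expect_equal(resE$pValue, 1)
})

test_that("overlapping feature intervals are merged before the null", {
  feat <- data.frame(chrom = "chr1", start = c(0, 500), end = c(1000, 1500))
  q <- data.frame(chrom = "chr1", start = 5000, end = 5020)
  res <- binomialEnrichment(q, feat, genomeSize = 1e5)
  expect_equal(res$expectedFraction, 1500 / 1e5)  # not 2000
})

test_that("the dart null matches a Monte Carlo point-dart simulation", {
  set.seed(77)
  G <- 1e5
  feat <- data.frame(chrom = "chr1",
                     start = sort(sample(seq(0, G - 200, 50), 40)))
  feat$end <- feat$start + sample(20:150, 40, replace = TRUE)
  res <- binomialEnrichment(
    data.frame(chrom = "chr1", start = 1, end = 2), feat, G)
  p <- res$expectedFraction
  darts <- sample.int(G, 1e5, replace = TRUE) - 1L
  fm <- GenomicRanges::reduce(GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(feat$start + 1, feat$end)))
  hit <- IRanges::overlapsAny(
    GenomicRanges::GRanges("chr1", IRanges::IRanges(darts + 1, darts + 1)), fm)
  phat <- mean(hit)
  se <- sqrt(p * (1 - p) / 1e5)
  expect_lt(abs(phat - p), 3 * se)
  # tail probabilities computed under p and under phat agree closely
  expect_equal(pbinom(14, 200, phat, lower.tail = FALSE),
               pbinom(14, 200, p, lower.tail = FALSE), tolerance = 0.05)
})

test_that("TSS metaprofile bins, orients and restricts to the window", {
  # plus-strand TSS at 10000; sense interval covering +40..+60
  tss <- data.frame(chrom = "chr1", pos = 10000, strand = "+")
  iv <- data.frame(chrom = "chr1", start = 10040, end = 10060, strand = "+")
  pr <- tssProfile(iv, tss)
  on <- pr$sense > 0
  expect_equal(pr$bin_start[on], c(40))
  expect_equal(pr$sense[on], 100)
  expect_true(all(pr$antisense == 0))

  # interval 2000 nt away contributes nothing
  far <- data.frame(chrom = "chr1", start = 12500, end = 12520, strand = "+")
  pr2 <- tssProfile(far, tss)
  expect_true(all(pr2$sense == 0) && all(pr2$antisense == 0))

  # minus-strand TSS: an interval 40-60 nt 3' of it lands downstream
  tssm <- data.frame(chrom = "chr1", pos = 10000, strand = "-")
  ivm <- data.frame(chrom = "chr1", start = 9940, end = 9960, strand = "-")
  prm <- tssProfile(ivm, tssm)
  expect_equal(prm$bin_start[prm$sense > 0], c(40))

  # antisense track: opposite strand to the TSS
  iva <- data.frame(chrom = "chr1", start = 10040, end = 10060, strand = "-")
  pra <- tssProfile(iva, tss)
  expect_true(all(pra$sense == 0))
  expect_equal(pra$bin_start[pra$antisense > 0], c(40))
})

test_that("TSS profile percentages stay in [0, 100] and shift-invariantly", {
  set.seed(88)
  tss <- data.frame(chrom = "chr1", pos = c(5000, 20000), strand = c("+", "-"))
  iv <- data.frame(chrom = "chr1",
                   start = c(4500, 5300, 19500, 20200, 4990),
                   end = c(4560, 5370, 19560, 20290, 5060),
                   strand = sample(c("+", "-"), 5, replace = TRUE))
  pr <- tssProfile(iv, tss)
  expect_true(all(pr$sense >= 0 & pr$sense <= 100))
  expect_true(all(pr$antisense >= 0 & pr$antisense <= 100))
  shift <- 12345L
  pr2 <- tssProfile(transform(iv, start = start + shift, end = end + shift),
                    transform(tss, pos = pos + shift))
  expect_equal(pr2$sense, pr$sense)
  expect_equal(pr2$antisense, pr$antisense)
})
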