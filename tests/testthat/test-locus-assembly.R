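# two samples sharing a two-block locus, used throughout
.twoSampleReads <- function(shiftB = 0L, minorFrac2 = 0.2) {
  mk <- function(sample, minor) {
    n2 <- round(100 * minor); n1 <- 100 - n2
    rbind(
      makeReads(rep(100, n1), rep(122, n1), sample = sample),
      makeReads(rep(160, n2), rep(182, n2), sample = sample)
    )
  }
  list(s1 = mk("s1", 0.2), s2 = mk("s2", minorFrac2))
}

test_that("loci require a block group in every sample", {
  reads <- .twoSampleReads()
  gbs <- lapply(names(reads), function(s) buildBlockGroups(reads[[s]], s))
  names(gbs) <- names(reads)
  loci <- selectCommonLoci(gbs, mode = "independent")
  expect_length(loci, 1)
  expect_setequal(locusSamples(loci[[1]]), c("s1", "s2"))

  # drop the locus from s2: no common locus remains
  gbs$s2 <- list()
  expect_length(selectCommonLoci(gbs, mode = "independent"), 0)
})

test_that("combined mode requires both replicates of every cell line", {
  reads <- list(
    A_R1 = makeReads(rep(100, 20), rep(122, 20), sample = "A_R1"),
    A_R2 = makeReads(rep(100, 20), rep(122, 20), sample = "A_R2"),
    B_R1 = makeReads(rep(100, 20), rep(122, 20), sample = "B_R1"),
    B_R2 = makeReads(rep(500, 20), rep(522, 20), sample = "B_R2")  # elsewhere
  )
  gbs <- lapply(names(reads), function(s) buildBlockGroups(reads[[s]], s))
  names(gbs) <- names(reads)
  rm <- c(A_R1 = "A", A_R2 = "A", B_R1 = "B", B_R2 = "B")
  loci <- selectCommonLoci(gbs, mode = "combined", replicateMap = rm)
  expect_length(loci, 0)  # B_R2 misses the locus at 100
})

test_that("one-nucleotide overlap joins groups into one locus", {
  reads <- list(
    s1 = makeReads(rep(100, 20), rep(140, 20), sample = "s1"),
    s2 = makeReads(rep(139, 20), rep(180, 20), sample = "s2")
  )
  gbs <- lapply(names(reads), function(s) buildBlockGroups(reads[[s]], s))
  names(gbs) <- names(reads)
  expect_length(selectCommonLoci(gbs, mode = "independent"), 1)
  # zero overlap: abutting groups do not share a locus
  reads$s2 <- makeReads(rep(140, 20), rep(180, 20), sample = "s2")
  gbs$s2 <- buildBlockGroups(reads$s2, "s2")
  expect_length(selectCommonLoci(gbs, mode = "independent"), 0)
})

test_that("consensus coordinates merge at >= 90% reciprocal overlap", {
  mkLocus <- function(s2start, s2end) {
    g1 <- makeBlockGroup(list(data.frame(start = 100, end = 120, count = 20)),
                         sample = "s1")
    g2 <- makeBlockGroup(list(data.frame(start = s2start, end = s2end,
                                         count = 20)), sample = "s2")
    new("ProfileLocus", chrom = "chr1", start = 100L, end = 140L,
        strand = "+", groups = list(s1 = g1, s2 = g2))
  }
  # 19/20 = 95% reciprocal -> one coordinate
  l <- consensusBlockCoordinates(mkLocus(101, 121))
  expect_equal(nrow(consensusBlocks(l)), 1)
  # 8/20 = 40% -> two coordinates
  l <- consensusBlockCoordinates(mkLocus(112, 132))
  expect_equal(nrow(consensusBlocks(l)), 2)
  # identical -> one per distinct block
  l <- consensusBlockCoordinates(mkLocus(100, 120))
  expect_equal(nrow(consensusBlocks(l)), 1)
})

test_that("harmonization equalizes block structure and plants dummy reads", {
  reads <- .twoSampleReads()
  # sample s2 lacks the minor block entirely
  reads$s2 <- reads$s2[reads$s2$start == 100, ]
  gbs <- lapply(names(reads), function(s) buildBlockGroups(reads[[s]], s))
  names(gbs) <- names(reads)
  loci <- selectCommonLoci(gbs, mode = "independent")
  l <- harmonizeLocus(consensusBlockCoordinates(loci[[1]]), reads)
  expect_true(isHarmonized(l))
  nb <- vapply(groupList(l), nBlocks, 1L)
  expect_equal(unname(nb), c(2L, 2L))
  # identical block coordinates across samples
  b1 <- blocks(groupList(l)$s1); b2 <- blocks(groupList(l)$s2)
  expect_equal(b1$start, b2$start)
  expect_equal(b1$end, b2$end)
  # s2's minor block holds only the dummy pseudo-read
  expect_equal(b2$height[2], 1)
  r2 <- profileReads(groupList(l)$s2)
  expect_true(all(r2$is_dummy[r2$block == 2]))
  # s1's blocks carry raw expression + the pseudo-read
  expect_equal(b1$height, c(81, 21))
})

test_that("single-block loci get a shared 10% dummy block", {
  reads <- list(
    s1 = makeReads(rep(100, 50), rep(122, 50), sample = "s1"),
    s2 = makeReads(rep(100, 30), rep(122, 30), sample = "s2")
  )
  gbs <- lapply(names(reads), function(s) buildBlockGroups(reads[[s]], s))
  names(gbs) <- names(reads)
  loci <- selectCommonLoci(gbs, mode = "independent")
  l <- harmonizeLocus(consensusBlockCoordinates(loci[[1]]), reads)
  for (s in c("s1", "s2")) {
    b <- blocks(groupList(l)[[s]])
    expect_equal(nrow(b), 2)
    expect_true(b$is_dummy[2])
  }
  # 10% of the parent group total (50 reads + 1 pseudo-read), rounded up
  expect_equal(blocks(groupList(l)$s1)$height[2], ceiling(0.10 * 51))
  expect_equal(blocks(groupList(l)$s2)$height[2], ceiling(0.10 * 31))
  # identical dummy coordinates across samples
  expect_equal(blocks(groupList(l)$s1)$start[2],
               blocks(groupList(l)$s2)$start[2])
})

test_that("multi-block loci get no appended dummy block", {
  reads <- .twoSampleReads()
  gbs <- lapply(names(reads), function(s) buildBlockGroups(reads[[s]], s))
  names(gbs) <- names(reads)
  l <- harmonizeLocus(consensusBlockCoordinates(
    selectCommonLoci(gbs, mode = "independent")[[1]]), reads)
  expect_false(any(blocks(groupList(l)$s1)$is_dummy))
})

test_that("harmonizing twice is a no-op", {
  reads <- .twoSampleReads()
  gbs <- lapply(names(reads), function(s) buildBlockGroups(reads[[s]], s))
  names(gbs) <- names(reads)
  l <- harmonizeLocus(consensusBlockCoordinates(
    selectCommonLoci(gbs, mode = "independent")[[1]]), reads)
  expect_identical(harmonizeLocus(l, reads), l)
})

test_that("missing raw reads for a sample is a hard error", {
  reads <- .twoSampleReads()
  gbs <- lapply(names(reads), function(s) buildBlockGroups(reads[[s]], s))
  names(gbs) <- names(reads)
  loci <- selectCommonLoci(gbs, mode = "independent")
  expect_error(harmonizeLocus(consensusBlockCoordinates(loci[[1]]),
                              reads["s1"]), "missing")
})
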