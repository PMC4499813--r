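test_that("size factors match hand-computed median-of-ratios", {
  s <- computeSizeFactors(matrix(c(10, 30, 20, 60), 2, 2))
  expect_equal(unname(s), c(1 / sqrt(2), sqrt(2)), tolerance = 1e-12)

  k <- matrix(c(5, 7, 9, 5, 7, 9), 3, 2)
  expect_equal(unname(computeSizeFactors(k)), c(1, 1))
})

test_that("rows with zeros are skipped and all-zero usable sets error", {
  k <- rbind(c(10, 20), c(0, 50), c(30, 60))
  expect_equal(unname(computeSizeFactors(k)), c(1 / sqrt(2), sqrt(2)))
  expect_error(computeSizeFactors(rbind(c(0, 5), c(3, 0))), "positive")
})

test_that("size factors are scale-equivariant", {
  set.seed(10)
  for (i in 1:5) {
    k <- matrix(rpois(20, 50) + 1, 10, 2)
    s <- computeSizeFactors(k)
    for (c0 in c(2, 5, 10)) {
      k2 <- k; k2[, 2] <- k2[, 2] * c0
      s2 <- computeSizeFactors(k2)
      expect_equal(s2[2] / s2[1], c0 * s[2] / s[1], tolerance = 1e-12)
    }
  }
})

test_that("size factors agree with the DESeq2 reference implementation", {
  skip_if_not_installed("DESeq2")
  set.seed(20)
  # odd row count: the sample median is a single ratio, on which the
  # ratio-scale and log-scale median-of-ratios definitions coincide
  for (i in 1:10) {
    k <- matrix(rpois(66, 80) + 1, 11, 6)
    expect_equal(unname(computeSizeFactors(k)),
                 unname(DESeq2::estimateSizeFactorsForMatrix(k)),
                 tolerance = 1e-9)
  }
})

test_that("2x2 Fisher matches exact enumeration on canonical tables", {
  expect_equal(fisherM2(c(3, 1), c(1, 3)), 34 / 70, tolerance = 1e-9)
  expect_equal(fisherM2(c(10, 0), c(0, 10)), 2 / choose(20, 10),
               tolerance = 1e-9)
  expect_equal(fisherM2(c(6, 4), c(6, 4)), 1)
})

test_that("Fisher p-values match enumeration on random small tables", {
  set.seed(30)
  # all 2x2 shapes with moderate totals
  for (i in 1:200) {
    a <- sample(0:12, 4, replace = TRUE)
    tab <- matrix(a, 2, 2)
    if (any(colSums(tab) == 0) || any(rowSums(tab) == 0)) next
    expect_equal(fisherM2(tab[, 1], tab[, 2]), fisherEnumM2(tab),
                 tolerance = 1e-7)
  }
  # 3x2 tables
  for (i in 1:40) {
    tab <- matrix(sample(1:8, 6, replace = TRUE), 3, 2)
    expect_equal(fisherM2(tab[, 1], tab[, 2]), fisherEnumM2(tab),
                 tolerance = 1e-7)
  }
})

test_that("degenerate Fisher inputs are handled", {
  expect_warning(p <- fisherM2(c(0, 0), c(3, 4)), "all-zero")
  expect_equal(p, 1)
  expect_equal(suppressWarnings(fisherM2(c(5, 5), c(5, 5))), 1)
})

test_that("normalization removes depth differences between samples", {
  # scaling one sample's counts by c rescales the geometric-mean reference
  # by c^(1/m); normalized expression changes only by that common factor,
  # so every between-sample comparison (and hence every verdict) is
  # unaffected
  set.seed(40)
  k <- matrix(rpois(40, 100) + 1, 20, 2)
  s <- computeSizeFactors(k)
  k2 <- k; k2[, 2] <- k2[, 2] * 4
  s2 <- computeSizeFactors(k2)
  bhat1 <- sweep(k, 2, s, "/")
  bhat2 <- sweep(k2, 2, s2, "/")
  expect_equal(bhat2, bhat1 * 4^(1 / 2), tolerance = 1e-9)
  expect_equal(bhat2[, 1] / bhat2[, 2], bhat1[, 1] / bhat1[, 2],
               tolerance = 1e-9)
})

test_that("the majority rule is strict", {
  # synthetic two-block locus: 4 inside samples, 4 outside
  mkReads <- function(frac, n = 100) {
    n1 <- round(n * frac)
    rbind(makeReads(rep(100, n1), rep(122, n1)),
          makeReads(rep(160, n - n1), rep(182, n - n1)))
  }
  reads <- c(
    lapply(1:4, function(i) { r <- mkReads(0.2); r$sample <- paste0("in", i); r }),
    lapply(1:4, function(i) { r <- mkReads(0.8); r$sample <- paste0("out", i); r })
  )
  names(reads) <- vapply(reads, function(r) r$sample[1], "")
  gbs <- lapply(names(reads), function(s) buildBlockGroups(reads[[s]], s))
  names(gbs) <- names(reads)
  l <- harmonizeLocus(consensusBlockCoordinates(
    selectCommonLoci(gbs, mode = "independent")[[1]]), reads)
  S <- computeScoreMatrix(l)
  cl <- bootstrapCluster(S, nBoot = 500, seed = 3)
  cl <- computeClusterScore(S, cl)
  sf <- setNames(rep(1, 8), locusSamples(l))
  v <- validateDPL(l, cl, sf)
  expect_true(v$verdict)  # 100% of inside samples beat all outside samples
  expect_true(isSymmetric(unname(ifelse(is.na(v$pMatrix), 0, v$pMatrix))))
})

test_that("exactly half qualifying inside samples is not a majority", {
  # 4-sample "inside" cluster imposed by hand: two inside samples differ
  # strongly from all outside samples, two are indistinguishable from them,
  # so exactly 50% qualify and the strict rule must refuse the locus
  mkReads <- function(frac, n = 300) {
    n1 <- round(n * frac)
    rbind(makeReads(rep(100, n1), rep(122, n1)),
          makeReads(rep(160, n - n1), rep(182, n - n1)))
  }
  fracs <- c(in1 = 0.1, in2 = 0.1, in3 = 0.6, in4 = 0.6,
             out1 = 0.6, out2 = 0.6, out3 = 0.6, out4 = 0.6)
  reads <- lapply(names(fracs), function(s) {
    r <- mkReads(fracs[[s]]); r$sample <- s; r
  })
  names(reads) <- names(fracs)
  gbs <- lapply(names(reads), function(s) buildBlockGroups(reads[[s]], s))
  names(gbs) <- names(reads)
  l <- harmonizeLocus(consensusBlockCoordinates(
    selectCommonLoci(gbs, mode = "independent")[[1]]), reads)
  forced <- new("ProfileClustering",
    hclust = NULL, clusters = list(1:4), pvalues = 0.01,
    significant = 1L, labels = locusSamples(l)
  )
  sf <- setNames(rep(1, 8), locusSamples(l))
  v <- validateDPL(l, forced, sf)
  beats <- apply(v$clusterMatrices[[1]] < 0.05, 1, all)
  expect_equal(unname(beats), c(TRUE, TRUE, FALSE, FALSE))
  expect_false(v$verdict)  # 50% is not > 50%
  # shrink the cluster to the two truly different samples: 100% > 50%
  forced@clusters <- list(1:2)
  v2 <- validateDPL(l, forced, sf)
  expect_true(v2$verdict)
})

test_that("depth-only differences are not validated as differential", {
  sim <- simulateLocus(depthControlScenario(), seed = 55)
  res <- suppressMessages(runPipeline(sim$reads, sim$replicateMap,
                                      mode = "combined", nBoot = 300,
                                      seed = 56))
  expect_false(any(res$summary$dpl))
})
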