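# Depth-independent validation of candidate differentially processed loci:
# median-of-ratios size factors, normalized block expression, all-vs-all
# Fisher's exact tests and the cluster-matrix majority rule.

#' Median-of-ratios size factors
#'
#' For a block x sample count matrix \code{k}, the size factor of sample j is
#' the median over usable rows i of \eqn{k_{ij} / (\prod_m k_{im})^{1/m}},
#' i.e. the median ratio to a pseudo-reference sample built from the
#' geometric mean across samples.  Rows containing a zero are skipped (their
#' geometric-mean ratio is undefined).  Size factors render counts from
#' samples sequenced at different depths comparable.
#'
#' @param k Numeric matrix of raw block counts, blocks in rows, samples in
#'   columns; dummy contributions must already be excluded.
#' @return Named numeric vector of positive size factors, one per column.
#' @export
computeSizeFactors <- function(k) {
  k <- as.matrix(k)
  stopifnot(ncol(k) >= 2)
  usable <- rowSums(k <= 0) == 0
  if (!any(usable)) {
    stop("no block has positive counts in every sample; ",
         "pool loci or use a pooled fallback before normalizing")
  }
  ku <- k[usable, , drop = FALSE]
  geo <- exp(rowMeans(log(ku)))
  s <- apply(ku / geo, 2, median)
  names(s) <- colnames(k)
  s
}

#' Fisher's exact test on an m x 2 expression table
#'
#' Two-sided exact conditional test of independence between two block
#' expression vectors (one per sample), each of length m >= 2.  Entries are
#' rounded to the nearest non-negative integer (exact tests need counts).
#' 2 x 2 tables use exact hypergeometric enumeration; larger tables use the
#' exact network algorithm while the table total stays small and a seeded
#' Monte Carlo estimate (>= 10^4 tables) beyond that.
#'
#' @param colA,colB Numeric vectors of normalized block expression, equal
#'   length m >= 2.
#' @param seed Integer seed for the Monte Carlo branch.
#' @param mcTables Monte Carlo replicates (default 10^4).
#' @param exactLimit Largest table total handled by the exact network
#'   algorithm for m > 2 (default 300).
#' @return p-value in (0, 1].
#' @export
fisherM2 <- function(colA, colB, seed = 1L, mcTables = 10000L,
                     exactLimit = 300) {
  stopifnot(length(colA) == length(colB), length(colA) >= 2)
  tab <- cbind(pmax(0, round(colA)), pmax(0, round(colB)))
  if (any(colSums(tab) == 0)) {
    warning("all-zero column in contingency table; p = 1")
    return(1)
  }
  tab <- tab[rowSums(tab) > 0, , drop = FALSE]
  if (nrow(tab) < 2) return(1)  # a single informative row cannot deviate
  if (nrow(tab) == 2 || sum(tab) <= exactLimit) {
    ft <- fisher.test(tab, workspace = 2e7)
  } else {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
    ft <- fisher.test(tab, simulate.p.value = TRUE, B = mcTables)
  }
  min(1, ft$p.value)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Raw block count matrix of a harmonized locus
#'
#' Blocks x samples matrix of block expression at a locus.  The appended
#' dummy block (if any) is dropped and the per-coordinate dummy pseudo-read
#' is subtracted, leaving raw counts; use \code{keepPseudo = TRUE} to retain
#' the single pseudo-read as a continuity correction for zero cells (the
#' form used in the Fisher validation tables).
#'
#' @param locus Harmonized \code{\linkS4class{ProfileLocus}}.
#' @param keepPseudo Keep the +1 dummy pseudo-read in each block's count.
#' @param keepDummyBlock Keep the appended dummy block row.
#' @return Numeric matrix, blocks in rows, samples in columns.
#' @export
locusBlockCounts <- function(locus, keepPseudo = FALSE,
                             keepDummyBlock = FALSE) {
  stopifnot(is(locus, "ProfileLocus"), isHarmonized(locus))
  gs <- groupList(locus)
  cols <- lapply(gs, function(g) {
    b <- g@blocks
    if (!keepDummyBlock) b <- b[!b$is_dummy, , drop = FALSE]
    h <- b$height
    if (!keepPseudo) h <- pmax(0, h - ifelse(b$is_dummy, 0, 1))
    h
  })
  do.call(cbind, cols)
}

#' Validate a candidate differentially processed locus
#'
#' Depth-independent validation: block expression is normalized by
#' genome-wide size factors, an n x n "p-value matrix" of all-vs-all
#' m x 2 Fisher tests is built, and for every supported cluster a "cluster
#' matrix" (rows = in-cluster samples, columns = out-of-cluster samples) is
#' examined.  The locus is a validated DPL iff in at least one cluster
#' matrix strictly more than 50\% of the in-cluster samples have p <
#' \code{alpha} against every out-of-cluster sample.  In combined mode the
#' majority is counted over cell lines, a cell line qualifying only when
#' both its replicates do.
#'
#' @param locus Harmonized candidate \code{\linkS4class{ProfileLocus}}.
#' @param clustering \code{\linkS4class{ProfileClustering}} with supported
#'   clusters.
#' @param sizeFactors Named size factor vector covering the locus' samples.
#' @param alpha Significance level (default 0.05).
#' @param mode \code{"independent"} or \code{"combined"}.
#' @param replicateMap Sample -> cell line map (combined mode).
#' @param seed Seed for Monte Carlo Fisher branches.
#' @return List: \code{verdict} (logical), \code{pMatrix}, and
#'   \code{clusterMatrices} (one p-value submatrix per supported cluster).
#' @export
validateDPL <- function(locus, clustering, sizeFactors, alpha = 0.05,
                        mode = c("independent", "combined"),
                        replicateMap = NULL, seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(is(locus, "ProfileLocus"), isHarmonized(locus))
  samples <- locusSamples(locus)
  stopifnot(all(samples %in% names(sizeFactors)))
  if (mode == "combined") stopifnot(all(samples %in% names(replicateMap)))
  b <- locusBlockCounts(locus, keepPseudo = TRUE, keepDummyBlock = TRUE)
  colnames(b) <- samples
  bhat <- sweep(b, 2, sizeFactors[samples], "/")
  n <- length(samples)
  P <- matrix(NA_real_, n, n, dimnames = list(samples, samples))
  if (nrow(bhat) >= 2) {
    for (i in seq_len(n - 1)) {
      for (j in seq.int(i + 1, n)) {
        p <- suppressWarnings(fisherM2(bhat[, i], bhat[, j], seed = seed))
        P[i, j] <- P[j, i] <- p
      }
    }
  } else {
    P[] <- 1
  }
  verdict <- FALSE
  cms <- list()
  for (ci in clustering@significant) {
    inside <- clustering@clusters[[ci]]
    outside <- setdiff(seq_len(n), inside)
    if (!length(outside) || !length(inside)) next
    cm <- P[inside, outside, drop = FALSE]
    cms[[length(cms) + 1L]] <- cm
    beats_all <- apply(cm < alpha, 1, all)
    if (mode == "combined") {
      lines_in <- replicateMap[samples[inside]]
      ok_lines <- tapply(beats_all, lines_in, all)
      frac <- mean(ok_lines)
    } else {
      frac <- mean(beats_all)
    }
    if (frac > 0.5) verdict <- TRUE
  }
  list(verdict = verdict, pMatrix = P, clusterMatrices = cms)
}
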