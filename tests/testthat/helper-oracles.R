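# Fixture builders and independent oracles used across the suite.

makeReads <- function(starts, ends, counts = 1, chrom = "chr1",
                      strand = "+", sample = "s1") {
  n <- max(length(starts), length(ends))
  data.frame(
    chrom = chrom, start = as.integer(starts), end = as.integer(ends),
    strand = strand, count = rep_len(counts, n), sample = sample
  )
}

# Direct BlockGroup construction for alignment-level tests: `blockReads` is
# a list of read data.frames (start, end, count), one per block.
makeBlockGroup <- function(blockReads, sample = "s1", chrom = "chr1",
                           strand = "+", total = NULL) {
  bl <- lapply(seq_along(blockReads), function(i) {
    r <- blockReads[[i]]
    data.frame(start = min(r$start), end = max(r$end),
               height = sum(r$count), is_dummy = FALSE)
  })
  bdf <- do.call(rbind, bl)
  if (is.null(total)) total <- sum(bdf$height)
  bdf$rel_height <- bdf$height / total
  rdf <- do.call(rbind, lapply(seq_along(blockReads), function(i) {
    r <- blockReads[[i]]
    data.frame(start = as.integer(r$start), end = as.integer(r$end),
               count = r$count, is_dummy = FALSE, block = i)
  }))
  new("BlockGroup",
    chrom = chrom, start = as.integer(min(bdf$start)),
    end = as.integer(max(bdf$end)), strand = strand, sample = sample,
    totalReads = as.numeric(total),
    blocks = bdf[, c("start", "end", "height", "rel_height", "is_dummy")],
    reads = rdf
  )
}

# random block group on a fixed two-block consensus skeleton, so that two
# draws are structurally alignable (harmonized-like)
randomHarmonizedGroup <- function(sample = "s1", shift = 0L) {
  starts <- c(100L, 160L) + shift
  blockReads <- lapply(starts, function(s) {
    k <- sample(1:4, 1)
    data.frame(
      start = s + sample(0:3, k, replace = TRUE),
      end = s + 20 + sample(0:3, k, replace = TRUE),
      count = sample(1:40, k, replace = TRUE)
    )
  })
  makeBlockGroup(blockReads, sample = sample)
}

# Brute-force block detection: independent naive re-derivation (explicit
# Gaussian formula, explicit scans) of the iterative peak procedure.
bruteForceBlocks <- function(reads, scale = 0.5, minBlockHeight = 10,
                             heightMode = "rel", captureFactor = 2) {
  total <- sum(reads$count)
  thr <- if (heightMode == "rel") minBlockHeight / 100 * total else minBlockHeight
  left <- reads
  out <- list()
  while (nrow(left) > 0) {
    pos <- seq(min(left$start), max(left$end))
    best <- -Inf; bestpos <- NA
    for (p in pos) {
      d <- 0
      for (i in seq_len(nrow(left))) {
        mid <- (left$start[i] + left$end[i]) / 2
        s <- scale * (left$end[i] - left$start[i])
        d <- d + left$count[i] * exp(-(p - mid)^2 / (2 * s^2)) / (s * sqrt(2 * pi))
      }
      if (d > best) { best <- d; bestpos <- p }  # strict >: leftmost tie wins
    }
    cap <- logical(nrow(left))
    for (i in seq_len(nrow(left))) {
      mid <- (left$start[i] + left$end[i]) / 2
      win <- captureFactor * scale * (left$end[i] - left$start[i])
      cap[i] <- abs(mid - bestpos) <= win
    }
    if (!any(cap)) break
    h <- sum(left$count[cap])
    if (h < thr) break
    out[[length(out) + 1]] <- c(start = min(left$start[cap]),
                                end = max(left$end[cap]), height = h)
    left <- left[!cap, , drop = FALSE]
  }
  if (!length(out)) {
    return(data.frame(start = integer(), end = integer(), height = numeric()))
  }
  df <- as.data.frame(do.call(rbind, out))
  df[order(df$start, df$end), , drop = FALSE]
}

# Exhaustive enumeration oracle for the two-sided Fisher test on an m x 2
# table: all tables with the observed margins, summing the probabilities of
# tables no more likely than the observed one.
fisherEnumM2 <- function(tab) {
  tab <- as.matrix(tab)
  r <- rowSums(tab); c1 <- sum(tab[, 1]); N <- sum(tab)
  logP <- function(a) sum(lchoose(r, a)) - lchoose(N, c1)
  # enumerate all column-1 assignments a_i in [0, r_i] with sum a = c1
  grids <- lapply(r, function(ri) 0:ri)
  combos <- expand.grid(grids)
  combos <- combos[rowSums(combos) == c1, , drop = FALSE]
  lp <- apply(combos, 1, logP)
  lobs <- logP(tab[, 1])
  sum(exp(lp[lp <= lobs + 1e-7]))
}

# standard 18-sample layout (9 cell lines x 2 replicates)
standardReplicateMap <- function() {
  samples <- as.vector(vapply(1:9, function(l) {
    sprintf("L%02d_R%d", l, 1:2)
  }, character(2)))
  setNames(rep(sprintf("L%02d", 1:9), each = 2), samples)
}
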