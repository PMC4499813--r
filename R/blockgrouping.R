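#' Cluster mapped reads into loci
#'
#' Assigns two reads to the same locus when they are separated by less than
#' \code{maxGap} nucleotides, the classical small RNA locus definition: with
#' reads averaging ~40 nt, stretches of >= 50 empty nucleotides separate
#' distinct transcriptional units.
#'
#' @param reads \code{data.frame} with 0-based half-open \code{start},
#'   \code{end} and \code{count} columns for a single chromosome and strand,
#'   sorted by \code{start}.
#' @param maxGap Reads closer than this many nucleotides share a locus
#'   (default 50).
#' @return List of read \code{data.frame}s, one per locus, ordered by
#'   coordinate; together they partition the input.
#' @export
clusterReadsIntoLoci <- function(reads, maxGap = 50L) {
  stopifnot(is.data.frame(reads))
  if (nrow(reads) == 0) return(list())
  if (is.unsorted(reads$start)) stop("reads must be sorted by start")
  run_end <- cummax(reads$end)
  # a new locus opens when the gap to everything before is >= maxGap
  gap <- reads$start[-1] - run_end[-nrow(reads)]
  cl <- cumsum(c(1L, as.integer(gap >= maxGap)))
  unname(split(reads, cl))
}

# Summed Gaussian read density on integer genomic positions.  Each read
# contributes a Gaussian centred at its midpoint with sd = scale * length,
# weighted by its count.
.readDensity <- function(reads, pos, scale) {
  mid <- (reads$start + reads$end) / 2
  sdv <- pmax(scale * (reads$end - reads$start), 1e-6)
  dens <- numeric(length(pos))
  for (i in seq_len(nrow(reads))) {
    dens <- dens + reads$count[i] * dnorm(pos, mean = mid[i], sd = sdv[i])
  }
  dens
}

#' Detect read blocks within one read cluster
#'
#' Iterative Gaussian-peak block detection: every read contributes a Gaussian
#' density (sd = \code{scale} x read length) at its midpoint, weighted by
#' count.  The highest summed-density peak (leftmost on ties) seeds a block;
#' reads whose midpoint lies within the peak's capture window (+/-
#' \code{captureFactor} x \code{scale} x read length of the peak centre) join
#' it and are removed, and the procedure repeats until no peak collects the
#' minimum block height.
#'
#' @param reads Read \code{data.frame} of one cluster (columns \code{start},
#'   \code{end}, \code{count}).
#' @param scale Gaussian width as a fraction of read length (default 0.5).
#' @param minBlockHeight Minimum block height; an absolute read count when
#'   \code{heightMode = "abs"}, a percentage of the cluster total when
#'   \code{heightMode = "rel"} (so the default 10 means 10\%).
#' @param heightMode \code{"rel"} (default, matching relative scoring used
#'   for depth-variable samples) or \code{"abs"}.
#' @param captureFactor Capture window half-width in units of scale x read
#'   length (default 2, i.e. ~2 sd).
#' @return \code{data.frame} of blocks ordered by start with columns
#'   \code{start}, \code{end}, \code{height} and an attribute
#'   \code{"assignment"}: integer block index per input read (NA when a read
#'   remained unassigned).
#' @export
detectBlocks <- function(reads, scale = 0.5, minBlockHeight = 10,
                         heightMode = c("rel", "abs"), captureFactor = 2) {
  heightMode <- match.arg(heightMode)
  stopifnot(nrow(reads) > 0)
  total <- sum(reads$count)
  thr <- if (heightMode == "rel") minBlockHeight / 100 * total else minBlockHeight
  remaining <- seq_len(nrow(reads))
  assignment <- rep(NA_integer_, nrow(reads))
  out <- list()
  while (length(remaining)) {
    sub <- reads[remaining, , drop = FALSE]
    pos <- seq.int(min(sub$start), max(sub$end))
    dens <- .readDensity(sub, pos, scale)
    peak <- pos[which.max(dens)]  # leftmost maximum wins
    mid <- (sub$start + sub$end) / 2
    win <- captureFactor * scale * (sub$end - sub$start)
    captured <- abs(mid - peak) <= win
    if (!any(captured)) break  # no read reaches the peak; degenerate guard
    height <- sum(sub$count[captured])
    if (height < thr) break
    idx <- length(out) + 1L
    out[[idx]] <- data.frame(
      start = min(sub$start[captured]), end = max(sub$end[captured]),
      height = height
    )
    assignment[remaining[captured]] <- idx
    remaining <- remaining[!captured]
  }
  if (!length(out)) {
    blocks <- data.frame(start = integer(), end = integer(), height = numeric())
  } else {
    blocks <- do.call(rbind, out)
    ord <- order(blocks$start, blocks$end)
    blocks <- blocks[ord, , drop = FALSE]
    assignment <- match(assignment, ord)
    rownames(blocks) <- NULL
  }
  attr(blocks, "assignment") <- assignment
  blocks
}

#' Build block groups (read profiles) for one sample
#'
#' Full profiling of one sample's mapped reads: reads are clustered into loci
#' (gap < \code{maxGap}), blocks are detected within each locus, clusters with
#' fewer than \code{minClusterHeight} reads are dropped, and blocks holding
#' less than \code{relCutoff} of the cluster's total reads are removed so that
#' profiles from samples sequenced at different depths stay comparable.  The
#' group span is recomputed from the surviving blocks; \code{totalReads}
#' retains the pre-filter cluster total, which is the reference for relative
#' block heights.
#'
#' @param reads \code{data.frame} of one sample's mapped reads: columns
#'   \code{chrom}, \code{start}, \code{end}, \code{strand}, \code{count}
#'   (0-based half-open coordinates).
#' @param sample Sample identifier stored in each group.
#' @param maxGap Locus gap threshold (default 50).
#' @param minClusterHeight Minimum reads per retained group (default 10).
#' @param relCutoff Minimum block expression relative to the group total
#'   (default 0.10).
#' @param scale Gaussian width fraction for block detection (default 0.5).
#' @param captureFactor Passed to \code{\link{detectBlocks}}.
#' @return List of \code{\linkS4class{BlockGroup}} objects ordered by
#'   chromosome, strand and start.
#' @export
buildBlockGroups <- function(reads, sample, maxGap = 50L,
                             minClusterHeight = 10, relCutoff = 0.10,
                             scale = 0.5, captureFactor = 2) {
  stopifnot(all(c("chrom", "start", "end", "strand", "count") %in% names(reads)))
  groups <- list()
  if (nrow(reads) == 0) return(groups)
  key <- paste(reads$chrom, reads$strand)
  for (k in sort(unique(key))) {
    sub <- reads[key == k, , drop = FALSE]
    sub <- sub[order(sub$start, sub$end), , drop = FALSE]
    for (cl in clusterReadsIntoLoci(sub, maxGap = maxGap)) {
      total <- sum(cl$count)
      if (total < minClusterHeight) next
      blk <- detectBlocks(cl, scale = scale,
                          minBlockHeight = relCutoff * 100,
                          heightMode = "rel", captureFactor = captureFactor)
      if (nrow(blk) == 0) next
      keep <- blk$height / total >= relCutoff
      if (!any(keep)) next
      assignment <- attr(blk, "assignment")
      keep_idx <- which(keep)
      blk <- blk[keep, , drop = FALSE]
      new_index <- match(assignment, keep_idx)
      rdf <- data.frame(
        start = cl$start, end = cl$end, count = cl$count,
        is_dummy = FALSE, block = new_index
      )
      rdf <- rdf[!is.na(rdf$block), , drop = FALSE]
      rownames(rdf) <- rownames(blk) <- NULL
      bg <- .newBlockGroup(
        chrom = cl$chrom[1], start = min(blk$start), end = max(blk$end),
        strand = cl$strand[1], sample = sample, totalReads = total,
        blocks = data.frame(
          start = as.integer(blk$start), end = as.integer(blk$end),
          height = blk$height, rel_height = blk$height / total,
          is_dummy = FALSE
        ),
        reads = rdf
      )
      groups[[length(groups) + 1L]] <- bg
    }
  }
  groups
}
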