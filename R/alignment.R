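# Profile alignment: a two-tier similarity between block groups.
# Tier 1 scores pairs of blocks on normalized height and read arrangement;
# tier 2 chains block scores with an order-preserving global alignment.

# Distribution of a block's reads over (start offset from modal start,
# read length), weighted by count.  Anchoring at the modal start makes the
# distribution invariant under translation of the whole group.
.blockReadDistribution <- function(reads) {
  stopifnot(nrow(reads) > 0)
  byStart <- tapply(reads$count, reads$start, sum)
  modal <- as.integer(names(byStart))[which.max(byStart)]  # leftmost mode
  key <- paste(reads$start - modal, reads$end - reads$start, sep = ":")
  p <- tapply(reads$count, key, sum)
  p / sum(p)
}

#' Similarity between two read blocks
#'
#' Tier-1 block score: \eqn{\sigma = (1 - |h_x - h_y|) \sum_u \min(p_x(u),
#' p_y(u))} where \eqn{h} are block heights normalized by their group totals
#' and \eqn{p} are the blocks' read distributions over (start offset from the
#' modal start, read length).  \eqn{\sigma \in [0, 1]} with
#' \eqn{\sigma(x, x) = 1}.
#'
#' @param xReads,yReads Read \code{data.frame}s of the two blocks
#'   (\code{start}, \code{end}, \code{count}).
#' @param hx,hy Normalized block heights (height / group total).
#' @return Similarity in \code{[0, 1]}.
#' @export
blockSimilarity <- function(xReads, yReads, hx, hy) {
  px <- .blockReadDistribution(xReads)
  py <- .blockReadDistribution(yReads)
  shared <- intersect(names(px), names(py))
  overlap <- if (length(shared)) {
    sum(pmin(px[shared], py[shared]))
  } else 0
  max(0, (1 - abs(hx - hy))) * overlap
}

#' Align two block groups
#'
#' Computes the \code{[0, 1]} profile alignment score between two block
#' groups.  Per-block similarities (\code{\link{blockSimilarity}}) are chained
#' by an order-preserving global alignment (match or skip; skipped blocks
#' contribute 0, no crossing matches) maximizing the total similarity; the
#' final score is \eqn{2 \Sigma\sigma / (m + n)} for block counts \eqn{m},
#' \eqn{n}.  The score is 1 exactly for groups with identical block structure
#' and identical normalized read arrangements, symmetric, and invariant under
#' joint translation and under scaling of either group's read counts.
#'
#' @param a,b \code{\linkS4class{BlockGroup}} objects (>= 1 block each).
#' @return List with \code{value} (the score) and \code{block_pairs}
#'   (two-column matrix of matched block indices in \code{a} and \code{b}).
#' @export
alignBlockGroups <- function(a, b) {
  stopifnot(is(a, "BlockGroup"), is(b, "BlockGroup"))
  m <- nBlocks(a); n <- nBlocks(b)
  if (m == 0 || n == 0) stop("cannot align an empty block group")
  ta <- a@totalReads; tb <- b@totalReads
  sig <- matrix(0, m, n)
  areads <- split(a@reads, a@reads$block)
  breads <- split(b@reads, b@reads$block)
  for (i in seq_len(m)) {
    ri <- areads[[as.character(i)]]
    if (is.null(ri)) next
    for (j in seq_len(n)) {
      rj <- breads[[as.character(j)]]
      if (is.null(rj)) next
      sig[i, j] <- blockSimilarity(
        ri, rj,
        hx = a@blocks$height[i] / ta, hy = b@blocks$height[j] / tb
      )
    }
  }
  # order-preserving chaining, zero-cost skips
  M <- matrix(0, m + 1, n + 1)
  for (i in seq_len(m)) {
    for (j in seq_len(n)) {
      M[i + 1, j + 1] <- max(M[i, j + 1], M[i + 1, j], M[i, j] + sig[i, j])
    }
  }
  pairs <- matrix(integer(), ncol = 2,
                  dimnames = list(NULL, c("a", "b")))
  i <- m; j <- n
  while (i > 0 && j > 0) {
    if (M[i + 1, j + 1] == M[i, j] + sig[i, j] && sig[i, j] > 0) {
      pairs <- rbind(c(i, j), pairs)
      i <- i - 1; j <- j - 1
    } else if (M[i + 1, j + 1] == M[i, j + 1]) {
      i <- i - 1
    } else {
      j <- j - 1
    }
  }
  list(value = 2 * M[m + 1, n + 1] / (m + n), block_pairs = pairs)
}

#' Entropy of the read arrangement within a block group
#'
#' Shannon entropy (base 2) of the distribution of read start positions,
#' weighted by read count; dummy reads inserted by harmonization are excluded.
#' Low entropy means precisely arranged read starts (precise processing);
#' reads uniform over \eqn{k} starts give \eqn{\log_2 k} bits.
#'
#' @param bg A \code{\linkS4class{BlockGroup}}.
#' @return Entropy in bits.
#' @export
blockGroupEntropy <- function(bg) {
  stopifnot(is(bg, "BlockGroup"))
  r <- bg@reads[!bg@reads$is_dummy, , drop = FALSE]
  if (nrow(r) == 0) stop("entropy undefined: block group holds only dummy reads")
  f <- tapply(r$count, r$start, sum)
  f <- f / sum(f)
  -sum(f * log2(f))
}
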