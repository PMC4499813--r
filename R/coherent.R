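# Coherent processing: loci whose read profiles are similar across all
# samples, and the short-and-precise profile classification.

#' Call a coherently processed locus
#'
#' The mean pairwise alignment score of a locus is the mean of the
#' off-diagonal upper-triangle entries of its alignment score matrix; the
#' locus is coherently processed when the mean reaches \code{threshold}
#' (inclusive).
#'
#' @param S Alignment score matrix of a harmonized locus.
#' @param threshold Mean-score threshold (default 0.8).
#' @return List: \code{meanScore}, \code{isCPL}.
#' @export
callCPL <- function(S, threshold = 0.8) {
  stopifnot(is.matrix(S), nrow(S) == ncol(S), nrow(S) >= 2)
  m <- mean(S[upper.tri(S)])
  list(meanScore = m, isCPL = m >= threshold)
}

#' Classify a block group as short and precise
#'
#' A profile is short and precise when it consists of a single (non-dummy)
#' read block, its read-start entropy is at most \code{maxEntropy} bits and
#' its non-dummy span is at most \code{maxLength} nt - the signature of
#' precisely processed short RNAs.
#'
#' @param bg A \code{\linkS4class{BlockGroup}} with non-dummy reads.
#' @param maxEntropy Entropy ceiling in bits (default 2).
#' @param maxLength Span ceiling in nt (default 40).
#' @return Logical.
#' @export
classifyShortPrecise <- function(bg, maxEntropy = 2, maxLength = 40L) {
  stopifnot(is(bg, "BlockGroup"))
  b <- bg@blocks[!bg@blocks$is_dummy, , drop = FALSE]
  if (nrow(b) != 1L) return(FALSE)
  span <- max(b$end) - min(b$start)
  span <= maxLength && blockGroupEntropy(bg) <= maxEntropy
}
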