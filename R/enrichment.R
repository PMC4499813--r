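# Annotation assignment and enrichment statistics: ncRNA / genomic-region
# labels, the binomial dart-throwing null and strand-aware TSS metaprofiles.

.toGRanges <- function(df, stranded = TRUE) {
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand = if (stranded && "strand" %in% names(df)) {
      df$strand
    } else rep("*", nrow(df))
  )
}

#' Annotate an interval against ncRNA and genomic-region annotations
#'
#' ncRNA assignment: an interval is "annotated" if it overlaps any ncRNA
#' annotation by at least one nucleotide on the same strand; the class of
#' the overlapping ncRNA is assigned, ties going to the larger overlap.
#' Genomic-region assignment: the region class covering more than 50\% of
#' the interval wins (maximum overlap when several qualify); otherwise the
#' interval is "intergenic".  Chromatin-state style queries are strandless.
#'
#' @param chrom,start,end,strand Interval (0-based half-open).
#' @param annotations An \code{"AnnotationSet"} from
#'   \code{\link{readAnnotations}}, or a list with \code{ncrna} and/or
#'   \code{region} \code{GRanges} carrying a \code{label} column.
#' @return List: \code{ncrna} (class label or \code{NA} if unannotated),
#'   \code{region} (region label or \code{"intergenic"}).
#' @export
annotateInterval <- function(chrom, start, end, strand, annotations) {
  q <- GenomicRanges::GRanges(chrom,
                              IRanges::IRanges(start + 1L, end),
                              strand = strand)
  nclab <- NA_character_
  if (!is.null(annotations$ncrna) && length(annotations$ncrna)) {
    hit <- GenomicRanges::findOverlaps(q, annotations$ncrna,
                                       ignore.strand = FALSE)
    if (length(hit)) {
      sub <- annotations$ncrna[S4Vectors::subjectHits(hit)]
      ov <- IRanges::width(IRanges::pintersect(
        IRanges::ranges(rep(q, length(sub))), IRanges::ranges(sub)))
      nclab <- sub$label[which.max(ov)]
    }
  }
  reglab <- "intergenic"
  if (!is.null(annotations$region) && length(annotations$region)) {
    hit <- GenomicRanges::findOverlaps(q, annotations$region,
                                       ignore.strand = TRUE)
    if (length(hit)) {
      sub <- annotations$region[S4Vectors::subjectHits(hit)]
      ov <- IRanges::width(IRanges::pintersect(
        IRanges::ranges(rep(q, length(sub))), IRanges::ranges(sub)))
      per_class <- tapply(ov, sub$label, sum)
      best <- which.max(per_class)
      if (per_class[best] / (end - start) > 0.5) reglab <- names(per_class)[best]
    }
  }
  list(ncrna = nclab, region = reglab)
}

#' Binomial dart-throwing enrichment
#'
#' Null model of throwing each query interval like a dart onto the genome:
#' the success probability is the fraction of the genome covered by the
#' (merged) feature set, and the p-value is the upper-tail binomial
#' probability of observing at least the seen number of feature overlaps
#' among the n query intervals.  Overlap counting is strandless and an
#' overlap of >= 1 nt counts.
#'
#' @param intervals \code{data.frame} of query intervals (\code{chrom},
#'   \code{start}, \code{end}; 0-based half-open).
#' @param feature \code{data.frame} or \code{GRanges} of feature intervals.
#' @param genomeSize Genome length in nt.
#' @return List of class \code{"EnrichmentResult"}: \code{n},
#'   \code{observed}, \code{expectedFraction}, \code{pValue}.
#' @export
binomialEnrichment <- function(intervals, feature, genomeSize) {
  q <- if (is(intervals, "GRanges")) intervals else .toGRanges(intervals, FALSE)
  f <- if (is(feature, "GRanges")) feature else .toGRanges(feature, FALSE)
  n <- length(q)
  fm <- GenomicRanges::reduce(f, ignore.strand = TRUE)
  covered <- sum(IRanges::width(fm))
  if (covered == 0) {
    warning("feature set has zero covered length; p-value = 1")
    res <- list(n = n, observed = 0L, expectedFraction = 0, pValue = 1)
    class(res) <- "EnrichmentResult"
    return(res)
  }
  stopifnot(genomeSize > covered || covered == genomeSize)
  p <- covered / genomeSize
  obs <- sum(IRanges::overlapsAny(q, fm, ignore.strand = TRUE))
  pval <- if (obs == 0) 1 else pbinom(obs - 1, n, p, lower.tail = FALSE)
  res <- list(n = n, observed = as.integer(obs), expectedFraction = p,
              pValue = min(1, pval))
  class(res) <- "EnrichmentResult"
  res
}

#' @export
print.EnrichmentResult <- function(x, ...) {
  cat(sprintf(
    "EnrichmentResult: %d/%d intervals hit the feature (null fraction %.4f), p = %.3g\n",
    x$observed, x$n, x$expectedFraction, x$pValue
  ))
  invisible(x)
}

#' Strand-aware TSS metaprofile
#'
#' Bins the window around transcription start sites and reports the mean
#' percent coverage of each bin by the query intervals, separately for
#' intervals on the TSS strand (sense) and the opposite strand (antisense).
#' Coordinates are flipped for minus-strand TSS so that positive bin
#' positions are always downstream of transcription.  An interval near two
#' TSS contributes to both profiles.
#'
#' @param intervals \code{data.frame} of stranded query intervals.
#' @param tss \code{data.frame} of TSS points (\code{chrom}, \code{pos}
#'   0-based, \code{strand}).
#' @param window Half-window in nt (default 1000, i.e. a 2000-nt window).
#' @param bin Bin width in nt (default 20).
#' @return \code{data.frame}: \code{bin_start}, \code{bin_end} (TSS-relative),
#'   \code{sense}, \code{antisense} (mean percent coverage per bin), with
#'   attributes \code{nSense}/\code{nAntisense} (contributing interval-TSS
#'   pairs).
#' @export
tssProfile <- function(intervals, tss, window = 1000L, bin = 20L) {
  edges <- seq.int(-window, window, by = bin)
  nb <- length(edges) - 1L
  sense_sum <- anti_sum <- numeric(nb)
  n_sense <- n_anti <- 0L
  for (t in seq_len(nrow(tss))) {
    tchrom <- tss$chrom[t]; tpos <- tss$pos[t]; tstr <- tss$strand[t]
    cand <- intervals[intervals$chrom == tchrom, , drop = FALSE]
    if (!nrow(cand)) next
    for (i in seq_len(nrow(cand))) {
      s <- cand$start[i]; e <- cand$end[i]
      if (tstr == "+") { rs <- s - tpos; re <- e - tpos }
      else { rs <- tpos - e; re <- tpos - s }  # flip for minus-strand TSS
      if (re <= -window || rs >= window) next  # outside the window
      cov <- pmax(0, pmin(re, edges[-1]) - pmax(rs, edges[-length(edges)]))
      pct <- 100 * cov / bin
      if (cand$strand[i] == tstr) {
        sense_sum <- sense_sum + pct; n_sense <- n_sense + 1L
      } else {
        anti_sum <- anti_sum + pct; n_anti <- n_anti + 1L
      }
    }
  }
  out <- data.frame(
    bin_start = edges[-length(edges)], bin_end = edges[-1],
    sense = if (n_sense) sense_sum / n_sense else numeric(nb),
    antisense = if (n_anti) anti_sum / n_anti else numeric(nb)
  )
  attr(out, "nSense") <- n_sense
  attr(out, "nAntisense") <- n_anti
  out
}
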