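#' @import methods
#' @importFrom stats median cor hclust as.dist dnorm pnorm qnorm pbinom
#'   fisher.test lm coef p.adjust setNames
#' @importFrom utils head read.table write.table
NULL

# Internal coordinate convention: 0-based half-open [start, end) everywhere.
# GRanges (1-based closed) only appears at the annotation / IO boundary.

#' BlockGroup: a locus-level small RNA read profile in one sample
#'
#' A block group (read profile) is the ordered set of read blocks observed at
#' one genomic locus in one sample.  Reads are kept alongside the block table
#' so that profile alignment can compare the positional arrangement of reads,
#' not just block heights.
#'
#' @slot chrom Chromosome name.
#' @slot start,end 0-based half-open span of the group.
#' @slot strand \code{"+"} or \code{"-"}.
#' @slot sample Sample identifier.
#' @slot totalReads Total read count of the underlying read cluster
#'   (before any relative block-height filtering), so that retained block
#'   heights sum to at most \code{totalReads}.
#' @slot blocks \code{data.frame} with columns \code{start}, \code{end},
#'   \code{height}, \code{rel_height}, \code{is_dummy}, ordered by start.
#' @slot reads \code{data.frame} with columns \code{start}, \code{end},
#'   \code{count}, \code{is_dummy}, \code{block} (index into \code{blocks}).
#'
#' @exportClass BlockGroup
setClass("BlockGroup",
  representation(
    chrom = "character", start = "integer", end = "integer",
    strand = "character", sample = "character", totalReads = "numeric",
    blocks = "data.frame", reads = "data.frame"
  )
)

setValidity("BlockGroup", function(object) {
  msg <- character()
  b <- object@blocks
  r <- object@reads
  if (object@start >= object@end) msg <- c(msg, "start must be < end")
  if (!object@strand %in% c("+", "-")) msg <- c(msg, "strand must be + or -")
  need_b <- c("start", "end", "height", "rel_height", "is_dummy")
  if (!all(need_b %in% names(b))) {
    msg <- c(msg, "blocks must have start/end/height/rel_height/is_dummy")
  } else {
    if (nrow(b) > 1 && is.unsorted(b$start)) msg <- c(msg, "blocks must be ordered by start")
    if (any(b$height <= 0)) msg <- c(msg, "block heights must be positive")
    if (any(b$rel_height <= 0 | b$rel_height > 1 + 1e-9)) {
      msg <- c(msg, "rel_height must lie in (0, 1]")
    }
  }
  need_r <- c("start", "end", "count", "is_dummy", "block")
  if (!all(need_r %in% names(r))) {
    msg <- c(msg, "reads must have start/end/count/is_dummy/block")
  } else if (nrow(r) > 0) {
    if (any(r$start >= r$end)) msg <- c(msg, "read start must be < end")
    if (any(r$count < 1)) msg <- c(msg, "read counts must be >= 1")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn BlockGroup number of blocks (dummies included)
#' @param x,object A \code{BlockGroup}.
#' @export
nBlocks <- function(x) nrow(x@blocks)

#' @describeIn BlockGroup block table accessor
#' @export
blocks <- function(x) x@blocks

#' @describeIn BlockGroup read table accessor
#' @export
profileReads <- function(x) x@reads

#' @describeIn BlockGroup total read count of the underlying cluster
#' @export
totalReads <- function(x) x@totalReads

#' @describeIn BlockGroup sample identifier
#' @export
sampleId <- function(x) x@sample

setMethod("show", "BlockGroup", function(object) {
  cat(sprintf(
    "BlockGroup %s:%d-%d(%s) sample=%s | %d block(s), %g reads\n",
    object@chrom, object@start, object@end, object@strand,
    object@sample, nBlocks(object), object@totalReads
  ))
  if (nrow(object@blocks)) {
    print(object@blocks, row.names = FALSE)
  }
})

#' ProfileLocus: one genomic locus with block groups across all samples
#'
#' Holds the member block groups of every sample at a common locus, plus the
#' consensus block coordinates once computed and the harmonized per-sample
#' groups (same block structure in every sample).
#'
#' @slot chrom,start,end,strand Locus span (0-based half-open).
#' @slot groups Named list (by sample id) of member \code{BlockGroup}s.
#' @slot consensus \code{data.frame} of consensus block coordinates
#'   (\code{start}, \code{end}), empty until computed.
#' @slot harmonized \code{logical}; \code{TRUE} once every sample carries the
#'   same block structure.
#'
#' @exportClass ProfileLocus
setClass("ProfileLocus",
  representation(
    chrom = "character", start = "integer", end = "integer",
    strand = "character", groups = "list", consensus = "data.frame",
    harmonized = "logical"
  ),
  prototype(consensus = data.frame(start = integer(), end = integer()),
            harmonized = FALSE)
)

setValidity("ProfileLocus", function(object) {
  msg <- character()
  if (!length(object@groups)) msg <- c(msg, "locus must hold >= 1 block group")
  if (is.null(names(object@groups)) || anyDuplicated(names(object@groups))) {
    msg <- c(msg, "groups must be uniquely named by sample")
  }
  if (!all(vapply(object@groups, is, TRUE, class2 = "BlockGroup"))) {
    msg <- c(msg, "groups must all be BlockGroup objects")
  }
  if (isTRUE(object@harmonized)) {
    nb <- vapply(object@groups, nBlocks, 1L)
    if (length(unique(nb)) != 1L) {
      msg <- c(msg, "harmonized locus must have equal block counts across samples")
    }
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn ProfileLocus consensus block coordinate accessor
#' @param x A \code{ProfileLocus}.
#' @export
consensusBlocks <- function(x) x@consensus

#' @describeIn ProfileLocus per-sample block group accessor
#' @export
groupList <- function(x) x@groups

#' @describeIn ProfileLocus sample identifiers at the locus
#' @export
locusSamples <- function(x) names(x@groups)

#' @describeIn ProfileLocus whether every sample shares the block structure
#' @export
isHarmonized <- function(x) isTRUE(x@harmonized)

setMethod("show", "ProfileLocus", function(object) {
  cat(sprintf(
    "ProfileLocus %s:%d-%d(%s) | %d sample(s)%s\n",
    object@chrom, object@start, object@end, object@strand,
    length(object@groups),
    if (isHarmonized(object)) {
      sprintf(", harmonized (%d consensus blocks)", nrow(object@consensus))
    } else ""
  ))
})

#' ProfileClustering: bootstrap-supported clustering of one score matrix
#'
#' Result of multiscale-bootstrap hierarchical clustering of a per-locus
#' alignment score matrix, later augmented with the cluster score.
#'
#' @slot hclust The average-linkage tree (\code{stats::hclust} object).
#' @slot clusters List of integer vectors: members of each internal node
#'   (root excluded).
#' @slot pvalues Per-cluster p-value (1 - AU support).
#' @slot bp Per-cluster bootstrap probability at scale 1.
#' @slot significant Indices into \code{clusters} with p < alpha.
#' @slot Xk Per significant cluster score (clamped at 0).
#' @slot X Cluster score of the locus: mean of \code{Xk}, 0 when none.
#' @slot candidate Whether the locus is a candidate differentially
#'   processed locus.
#' @slot labels Object (sample) labels.
#'
#' @exportClass ProfileClustering
setClass("ProfileClustering",
  representation(
    hclust = "ANY", clusters = "list", pvalues = "numeric", bp = "numeric",
    significant = "integer", Xk = "numeric", X = "numeric",
    candidate = "logical", labels = "character"
  ),
  prototype(significant = integer(), Xk = numeric(), X = 0,
            candidate = FALSE)
)

setValidity("ProfileClustering", function(object) {
  msg <- character()
  if (length(object@pvalues) != length(object@clusters)) {
    msg <- c(msg, "one p-value per cluster required")
  }
  if (length(object@X) == 1 && (object@X < -1e-9 || object@X > 1 + 1e-9)) {
    msg <- c(msg, "X must lie in [0, 1]")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn ProfileClustering the locus cluster score X
#' @param x A \code{ProfileClustering}.
#' @export
clusterScore <- function(x) x@X

#' @describeIn ProfileClustering indices of supported clusters (p < alpha)
#' @export
significantClusters <- function(x) x@significant

#' @describeIn ProfileClustering membership list of all internal clusters
#' @export
clusterMembers <- function(x) x@clusters

#' @describeIn ProfileClustering candidate flag accessor
#' @export
isCandidate <- function(x) isTRUE(x@candidate)

setMethod("show", "ProfileClustering", function(object) {
  cat(sprintf(
    "ProfileClustering | %d object(s), %d internal cluster(s), %d supported; X = %.3f%s\n",
    length(object@labels), length(object@clusters),
    length(object@significant), object@X,
    if (isTRUE(object@candidate)) " (candidate DPL)" else ""
  ))
})

# internal constructor used throughout
.newBlockGroup <- function(chrom, start, end, strand, sample, totalReads,
                           blocks, reads) {
  new("BlockGroup",
    chrom = as.character(chrom), start = as.integer(start),
    end = as.integer(end), strand = as.character(strand),
    sample = as.character(sample), totalReads = as.numeric(totalReads),
    blocks = blocks, reads = reads
  )
}

.emptyReads <- function() {
  data.frame(start = integer(), end = integer(), count = numeric(),
             is_dummy = logical(), block = integer())
}
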