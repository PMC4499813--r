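# Locus assembly: pick loci observed in every sample and harmonize block
# structure across samples so profiles become directly alignable.

#' Select loci common to all samples
#'
#' A genomic region becomes an analyzable locus iff overlapping block groups
#' (same strand, >= 1 nt overlap) exist in every required sample: in
#' \code{"independent"} mode every sample of the given set, in
#' \code{"combined"} mode both replicates of every cell line (the
#' conservative requirement that the profile is observed in all replicate
#' tracks).
#'
#' @param groupsBySample Named list (sample id -> list of
#'   \code{\linkS4class{BlockGroup}}).
#' @param mode \code{"combined"} or \code{"independent"}.
#' @param replicateMap Named character vector mapping sample id to cell-line
#'   id; required in combined mode.
#' @return List of \code{\linkS4class{ProfileLocus}} objects (not yet
#'   harmonized), ordered by coordinate.
#' @export
selectCommonLoci <- function(groupsBySample,
                             mode = c("combined", "independent"),
                             replicateMap = NULL) {
  mode <- match.arg(mode)
  samples <- names(groupsBySample)
  stopifnot(length(samples) >= 2)
  if (mode == "combined") {
    stopifnot(!is.null(replicateMap), all(samples %in% names(replicateMap)))
  }
  flat <- list()
  for (s in samples) for (g in groupsBySample[[s]]) flat[[length(flat) + 1L]] <- g
  if (!length(flat)) return(list())
  df <- data.frame(
    chrom = vapply(flat, function(g) g@chrom, ""),
    start = vapply(flat, function(g) g@start, 1L),
    end = vapply(flat, function(g) g@end, 1L),
    strand = vapply(flat, function(g) g@strand, ""),
    sample = vapply(flat, function(g) g@sample, ""),
    idx = seq_along(flat)
  )
  loci <- list()
  key <- paste(df$chrom, df$strand)
  for (k in sort(unique(key))) {
    sub <- df[key == k, , drop = FALSE]
    sub <- sub[order(sub$start, sub$end), , drop = FALSE]
    run_end <- cummax(sub$end)
    newreg <- c(TRUE, sub$start[-1] >= run_end[-nrow(sub)])  # >=1nt overlap merges
    reg <- cumsum(newreg)
    for (r in unique(reg)) {
      rs <- sub[reg == r, , drop = FALSE]
      have <- unique(rs$sample)
      if (!all(samples %in% have)) next
      members <- list()
      for (s in samples) {
        cand <- rs[rs$sample == s, , drop = FALSE]
        # several same-sample groups can touch one region; keep the largest
        pick <- cand$idx[which.max(cand$end - cand$start)]
        members[[s]] <- flat[[pick]]
      }
      loci[[length(loci) + 1L]] <- new("ProfileLocus",
        chrom = rs$chrom[1], start = as.integer(min(rs$start)),
        end = as.integer(max(rs$end)), strand = rs$strand[1],
        groups = members
      )
    }
  }
  loci
}

#' Consensus block coordinates at a locus
#'
#' Greedy merge of all member blocks across samples: blocks are visited by
#' descending height (determinism) and two blocks share a consensus
#' coordinate iff their reciprocal overlap is >= \code{minReciprocal};
#' otherwise they seed distinct coordinates.  Residual coordinate pairs
#' overlap less than the threshold.
#'
#' @param locus A \code{\linkS4class{ProfileLocus}}.
#' @param minReciprocal Reciprocal overlap fraction defining "the same"
#'   block coordinate (default 0.9).
#' @return The locus with its \code{consensus} slot filled
#'   (\code{data.frame} of \code{start}, \code{end}, sorted).
#' @export
consensusBlockCoordinates <- function(locus, minReciprocal = 0.9) {
  stopifnot(is(locus, "ProfileLocus"))
  bl <- do.call(rbind, lapply(groupList(locus), function(g) {
    b <- g@blocks[!g@blocks$is_dummy, , drop = FALSE]
    b[, c("start", "end", "height")]
  }))
  bl <- bl[order(-bl$height, bl$start), , drop = FALSE]
  coords <- data.frame(start = integer(), end = integer())
  for (i in seq_len(nrow(bl))) {
    s <- bl$start[i]; e <- bl$end[i]
    assigned <- FALSE
    if (nrow(coords)) {
      ov <- pmax(0, pmin(e, coords$end) - pmax(s, coords$start))
      rec <- pmin(ov / (e - s), ov / (coords$end - coords$start))
      if (any(rec >= minReciprocal)) assigned <- TRUE
    }
    if (!assigned) coords <- rbind(coords, data.frame(start = s, end = e))
  }
  coords <- coords[order(coords$start, coords$end), , drop = FALSE]
  rownames(coords) <- NULL
  locus@consensus <- coords
  locus
}

#' Harmonize block groups across samples at a locus
#'
#' Gives every sample the same block structure: for each consensus
#' coordinate and sample, a block is built from a single dummy pseudo-read
#' (count 1, flagged) plus all of the sample's raw reads whose midpoint lies
#' within the coordinate, so block expression is the raw value unaffected by
#' the relative 10\% cut-off used during profiling.  When the locus has a
#' single consensus block, a shared dummy block (identical coordinates in
#' every sample, expression 10\% of the parent group total, rounded up) is
#' appended immediately downstream so profile alignment has the two blocks it
#' needs; being identical across samples it can never drive differences.
#'
#' Harmonizing an already-harmonized locus is a no-op.
#'
#' @param locus A \code{\linkS4class{ProfileLocus}} with consensus
#'   coordinates (computed on the fly if absent).
#' @param readsBySample Named list (sample id -> raw mapped read
#'   \code{data.frame} with \code{chrom}, \code{start}, \code{end},
#'   \code{strand}, \code{count}).
#' @param dummyGap,dummyWidth Placement of the appended dummy block: gap
#'   downstream of the parent block and width, in nt (defaults 10 and 20).
#' @return The harmonized \code{\linkS4class{ProfileLocus}}.
#' @export
harmonizeLocus <- function(locus, readsBySample, dummyGap = 10L,
                           dummyWidth = 20L) {
  stopifnot(is(locus, "ProfileLocus"))
  if (isHarmonized(locus)) return(locus)
  if (!nrow(locus@consensus)) locus <- consensusBlockCoordinates(locus)
  coords <- locus@consensus
  samples <- locusSamples(locus)
  missing <- setdiff(samples, names(readsBySample))
  if (length(missing)) {
    stop("raw reads missing for sample(s): ", paste(missing, collapse = ", "))
  }
  single <- nrow(coords) == 1L
  dummy_start <- if (single) coords$end[1] + dummyGap else NA_integer_
  newGroups <- list()
  for (s in samples) {
    raw <- readsBySample[[s]]
    raw <- raw[raw$chrom == locus@chrom & raw$strand == locus@strand, ,
               drop = FALSE]
    mid <- (raw$start + raw$end) / 2
    blocks <- list(); reads <- list()
    for (ci in seq_len(nrow(coords))) {
      cs <- coords$start[ci]; ce <- coords$end[ci]
      inb <- which(mid >= cs & mid < ce)
      rd <- data.frame(
        start = c(cs, raw$start[inb]), end = c(ce, raw$end[inb]),
        count = c(1, raw$count[inb]),
        is_dummy = c(TRUE, rep(FALSE, length(inb))),
        block = ci
      )
      blocks[[ci]] <- data.frame(
        start = cs, end = ce, height = sum(rd$count), is_dummy = FALSE
      )
      reads[[ci]] <- rd
    }
    bdf <- do.call(rbind, blocks)
    rdf <- do.call(rbind, reads)
    if (single) {
      h <- ceiling(0.10 * sum(bdf$height))
      bdf <- rbind(bdf, data.frame(
        start = dummy_start, end = dummy_start + dummyWidth,
        height = h, is_dummy = TRUE
      ))
      rdf <- rbind(rdf, data.frame(
        start = dummy_start, end = dummy_start + dummyWidth,
        count = h, is_dummy = TRUE, block = nrow(bdf)
      ))
    }
    total <- sum(bdf$height)
    bdf$rel_height <- bdf$height / total
    bdf <- bdf[, c("start", "end", "height", "rel_height", "is_dummy")]
    rownames(bdf) <- rownames(rdf) <- NULL
    newGroups[[s]] <- .newBlockGroup(
      chrom = locus@chrom, start = min(bdf$start), end = max(bdf$end),
      strand = locus@strand, sample = s, totalReads = total,
      blocks = bdf, reads = rdf
    )
  }
  locus@groups <- newGroups
  locus@harmonized <- TRUE
  validObject(locus)
  locus
}
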