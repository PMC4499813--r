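# Synthetic read simulator: multi-sample, replicated mapped-read datasets
# with known processing truth, emulating arm switching, arm loss, coherent
# single/two-block profiles and unstructured noise loci at variable depth.

#' Describe one synthetic locus scenario
#'
#' @param scenario One of \code{"arm_switch"}, \code{"arm_loss"},
#'   \code{"coherent_one_block"}, \code{"coherent_two_block"},
#'   \code{"noise"}.
#' @param nCellLines Number of cell lines (default 9).
#' @param replicates Replicates per line (default 2).
#' @param switchedLines Indices of the cell lines carrying the switched /
#'   lost arm (default \code{1:3}; ignored for coherent and noise loci).
#' @param dominantFraction Expression fraction of the dominant block
#'   (default 0.8); switched lines mirror the fractions.
#' @param lossFraction Minor-arm fraction in the arm-loss subset (default
#'   0.05, i.e. below the 10\% detectability cut-off).
#' @param depth Expected reads per sample before depth multipliers
#'   (default 200).
#' @param depthMultipliers Per-sample depth multipliers (length
#'   \code{nCellLines * replicates}); default cycles through
#'   \code{c(1, 0.5, 2, 5)} to emulate variable sequencing depth.
#' @param readLenMode Modal read length in nt (default 22; 17 and 24
#'   reproduce the two read-length regimes of TSS-associated and annotated
#'   short RNAs).
#' @param jitter Half-width of the discrete triangular start-position
#'   kernel; 0 gives perfectly precise (zero-entropy) profiles and larger
#'   values monotonically raise profile entropy (default 1; noise loci
#'   default to 6).
#' @param armGap Gap in nt between the two arm blocks (default 22).
#' @return List of class \code{"LocusScenario"}.
#' @export
locusScenario <- function(scenario = c("arm_switch", "arm_loss",
                                       "coherent_one_block",
                                       "coherent_two_block", "noise"),
                          nCellLines = 9L, replicates = 2L,
                          switchedLines = 1:3, dominantFraction = 0.8,
                          lossFraction = 0.05, depth = 200,
                          depthMultipliers = NULL, readLenMode = 22L,
                          jitter = NULL, armGap = 22L) {
  scenario <- match.arg(scenario)
  nSamples <- nCellLines * replicates
  if (is.null(depthMultipliers)) {
    depthMultipliers <- rep_len(c(1, 0.5, 2, 5), nSamples)
  }
  stopifnot(length(depthMultipliers) == nSamples, all(depthMultipliers > 0))
  if (is.null(jitter)) jitter <- if (scenario == "noise") 6L else 1L
  if (scenario %in% c("arm_switch", "arm_loss")) {
    stopifnot(length(switchedLines) >= 1,
              all(switchedLines %in% seq_len(nCellLines)))
  }
  f <- dominantFraction
  stopifnot(f > 0, f < 1, lossFraction > 0, lossFraction < 0.10)
  sc <- list(
    scenario = scenario, nCellLines = nCellLines, replicates = replicates,
    switchedLines = switchedLines, dominantFraction = f,
    lossFraction = lossFraction, depth = depth,
    depthMultipliers = depthMultipliers, readLenMode = as.integer(readLenMode),
    jitter = as.integer(jitter), armGap = as.integer(armGap)
  )
  class(sc) <- "LocusScenario"
  sc
}

# fractions per block for one cell line under a scenario
.scenarioFractions <- function(sc, line) {
  f <- sc$dominantFraction
  switch(sc$scenario,
    arm_switch = if (line %in% sc$switchedLines) c(1 - f, f) else c(f, 1 - f),
    arm_loss = if (line %in% sc$switchedLines) {
      c(1 - sc$lossFraction, sc$lossFraction)
    } else c(f, 1 - f),
    coherent_one_block = 1,
    coherent_two_block = c(f, 1 - f),
    noise = c(0.5, 0.5)
  )
}

# multinomial draw of reads for one block: joint kernel over start offset
# (triangular, half-width jitter) x read length (peaked at the mode)
.sampleBlockReads <- function(n, blockStart, lenMode, jitter) {
  if (n <= 0) return(NULL)
  offs <- seq.int(-jitter, jitter)
  w_off <- jitter + 1 - abs(offs)
  lens <- lenMode + (-2:2)
  w_len <- c(1, 2, 4, 2, 1)
  keep <- lens >= 15
  lens <- lens[keep]; w_len <- w_len[keep]
  grid <- expand.grid(off = offs, len = lens)
  w <- as.vector(outer(w_off, w_len))
  cnt <- as.vector(stats::rmultinom(1, n, w / sum(w)))
  sel <- cnt > 0
  data.frame(
    start = blockStart + grid$off[sel],
    end = blockStart + grid$off[sel] + grid$len[sel],
    count = cnt[sel]
  )
}

#' Simulate reads for one locus
#'
#' Draws per-sample reads according to a \code{\link{locusScenario}}.
#' Arm-switch loci have two blocks separated by \code{armGap} nt whose
#' expression fractions are mirrored in the switched cell lines; arm-loss
#' loci drop the minor arm below detectability in the switched subset;
#' coherent loci use the same fractions everywhere.  Replicates are
#' independent draws from the same parameters (sampling noise only); for
#' noise loci the start positions are additionally scattered widely so no
#' sample-group structure exists.  Read counts per block are multinomial in
#' the scenario fractions and everything is deterministic given
#' \code{seed}.
#'
#' @param sc A \code{\link{locusScenario}}.
#' @param chrom Chromosome name (default \code{"chrS"}).
#' @param origin Genomic start of the first block (0-based).
#' @param strand Strand (default \code{"+"}).
#' @param seed Integer seed.
#' @return List: \code{reads} (named list per sample of read
#'   \code{data.frame}s), \code{truth} (one-row \code{data.frame} with the
#'   expected DPL/CPL labels and the locus envelope), \code{replicateMap}.
#' @export
simulateLocus <- function(sc, chrom = "chrS", origin = 1000L, strand = "+",
                          seed = 1L) {
  stopifnot(inherits(sc, "LocusScenario"))
  set.seed(seed)
  blockStarts <- c(origin, origin + sc$readLenMode + sc$armGap)
  samples <- character(0)
  lines <- character(0)
  reads <- list()
  for (line in seq_len(sc$nCellLines)) {
    fr <- .scenarioFractions(sc, line)
    for (rep in seq_len(sc$replicates)) {
      sid <- sprintf("L%02d_R%d", line, rep)
      si <- (line - 1) * sc$replicates + rep
      total <- max(1L, round(sc$depth * sc$depthMultipliers[si]))
      per_block <- as.vector(stats::rmultinom(1, total, fr))
      rd <- list()
      for (b in seq_along(per_block)) {
        rb <- .sampleBlockReads(per_block[b], blockStarts[b],
                                sc$readLenMode, sc$jitter)
        if (!is.null(rb)) rd[[length(rd) + 1L]] <- rb
      }
      rdf <- do.call(rbind, rd)
      rdf <- rdf[order(rdf$start, rdf$end), , drop = FALSE]
      rdf$chrom <- chrom
      rdf$strand <- strand
      rdf$sample <- sid
      rownames(rdf) <- NULL
      reads[[sid]] <- rdf[, c("chrom", "start", "end", "strand", "count",
                              "sample")]
      samples <- c(samples, sid)
      lines <- c(lines, sprintf("L%02d", line))
    }
  }
  envelope <- range(unlist(lapply(reads, function(r) c(r$start, r$end))))
  truth <- data.frame(
    chrom = chrom, start = envelope[1], end = envelope[2], strand = strand,
    scenario = sc$scenario,
    expected_dpl = sc$scenario %in% c("arm_switch", "arm_loss"),
    # precision-coherent profiles: single-block, or multi-block with zero
    # start jitter; jittered multi-block same-condition loci belong to the
    # neither-differential-nor-coherent middle class
    expected_cpl = sc$scenario == "coherent_one_block" ||
      (sc$scenario == "coherent_two_block" && sc$jitter == 0),
    switched = paste(
      if (sc$scenario %in% c("arm_switch", "arm_loss")) {
        sprintf("L%02d", sc$switchedLines)
      } else character(0),
      collapse = ","
    )
  )
  list(reads = reads, truth = truth,
       replicateMap = setNames(lines, samples))
}

#' The bundled synthetic study configuration
#'
#' Fifty loci mirroring the benchmark conditions used throughout the
#' package: 20 arm-switch loci (dominant fraction 0.8, 3 of 9 cell lines
#' switched), 20 coherent single-block loci (the precisely processed
#' profile class that dominates coherently processed loci in real data) and
#' 10 unstructured noise loci, 9 cell lines x 2 replicates at depth 200
#' with depth multipliers up to 5x.
#'
#' @param nArmSwitch,nCoherent,nNoise Locus counts per class.
#' @return List of \code{\link{locusScenario}} objects.
#' @export
studyScenarios <- function(nArmSwitch = 20L, nCoherent = 20L, nNoise = 10L) {
  out <- list()
  for (i in seq_len(nArmSwitch)) out[[length(out) + 1L]] <- locusScenario("arm_switch")
  for (i in seq_len(nCoherent)) out[[length(out) + 1L]] <- locusScenario("coherent_one_block")
  for (i in seq_len(nNoise)) out[[length(out) + 1L]] <- locusScenario("noise")
  out
}

#' Same-condition null scenarios for cluster-score calibration
#'
#' Loci where every sample is drawn from one and the same profile
#' distribution, at the reproducibility level real replicated profiles
#' show: a mix of single-block loci (start jitter 0 and 1) and precisely
#' processed two-block loci (jitter 0).  Used to calibrate the fraction of
#' false candidate calls at the cluster-score threshold.
#'
#' @param n Number of loci (default 50).
#' @return List of \code{\link{locusScenario}} objects.
#' @export
nullScenarios <- function(n = 50L) {
  lapply(seq_len(n), function(i) {
    switch((i %% 3) + 1,
      locusScenario("coherent_one_block", jitter = 1L),
      locusScenario("coherent_one_block", jitter = 0L),
      locusScenario("coherent_two_block", jitter = 0L)
    )
  })
}

#' Depth-only negative-control scenario
#'
#' Identical profile shape in every cell line, but one subset of cell lines
#' sequenced at a \code{fold}-times higher depth (replicate-consistent).
#' Any differential-processing call on such a locus would be a sequencing
#' depth artifact; the size-factor normalization of the validation stage
#' must reject it.
#'
#' @param deepLines Cell lines sequenced deeper (default \code{1:3}).
#' @param fold Depth imbalance (default 5).
#' @param ... Passed to \code{\link{locusScenario}}.
#' @return A \code{\link{locusScenario}}.
#' @export
depthControlScenario <- function(deepLines = 1:3, fold = 5, ...) {
  sc <- locusScenario("coherent_two_block", depthMultipliers = rep(1, 18), ...)
  idx <- as.vector(vapply(deepLines, function(l) {
    (l - 1L) * sc$replicates + seq_len(sc$replicates)
  }, integer(sc$replicates)))
  sc$depthMultipliers[idx] <- fold
  sc
}

#' Simulate a multi-locus dataset
#'
#' Places the scenarios' loci on one synthetic chromosome (non-overlapping,
#' \code{spacing} nt apart), draws all reads, and optionally writes one BED6
#' file per sample, a truth table TSV and a toy ncRNA annotation BED (an
#' annotation over every arm-switch/arm-loss locus) for end-to-end tests.
#'
#' @param scenarios List of \code{\link{locusScenario}}s (they must agree
#'   on sample layout).
#' @param seed Integer master seed; per-locus seeds are derived from it.
#' @param chrom Chromosome name.
#' @param spacing Distance between consecutive locus origins (default
#'   1000 nt).
#' @param outDir Optional output directory for BED/TSV files.
#' @return List: \code{readsBySample} (combined read \code{data.frame} per
#'   sample), \code{truth} (\code{data.frame}, one row per locus),
#'   \code{replicateMap}, \code{samples}, and \code{files} when
#'   \code{outDir} was given.
#' @export
simulateDataset <- function(scenarios, seed = 1L, chrom = "chrS",
                            spacing = 1000L, outDir = NULL) {
  stopifnot(length(scenarios) >= 1)
  set.seed(seed)
  locusSeeds <- sample.int(.Machine$integer.max - 1L, length(scenarios))
  truths <- list()
  perSample <- NULL
  repMap <- NULL
  for (i in seq_along(scenarios)) {
    origin <- 1000L + (i - 1L) * spacing
    sim <- simulateLocus(scenarios[[i]], chrom = chrom, origin = origin,
                         seed = locusSeeds[i])
    if (sim$truth$start < origin - spacing / 2 ||
        sim$truth$end > origin + spacing / 2) {
      stop("locus ", i, " overlaps its neighbour; increase spacing")
    }
    tr <- sim$truth; tr$locus <- i
    truths[[i]] <- tr
    if (is.null(perSample)) {
      perSample <- sim$reads
      repMap <- sim$replicateMap
    } else {
      stopifnot(identical(names(perSample), names(sim$reads)))
      for (s in names(perSample)) {
        perSample[[s]] <- rbind(perSample[[s]], sim$reads[[s]])
      }
    }
  }
  truth <- do.call(rbind, truths)
  truth <- truth[, c("locus", setdiff(names(truth), "locus"))]
  out <- list(readsBySample = perSample, truth = truth,
              replicateMap = repMap, samples = names(perSample))
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    files <- character(0)
    for (s in names(perSample)) {
      r <- perSample[[s]]
      path <- file.path(outDir, paste0(s, ".bed"))
      write.table(
        data.frame(r$chrom, r$start, r$end,
                   paste0("read", seq_len(nrow(r))), r$count, r$strand),
        path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
      )
      files <- c(files, path)
    }
    tpath <- file.path(outDir, "truth.tsv")
    write.table(truth, tpath, sep = "\t", quote = FALSE, row.names = FALSE)
    files <- c(files, tpath)
    dp <- truth[truth$expected_dpl, , drop = FALSE]
    if (nrow(dp)) {
      apath <- file.path(outDir, "ncrna_synthetic.bed")
      write.table(
        data.frame(dp$chrom, dp$start, dp$end, "miRNA", 0, dp$strand),
        apath, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
      )
      files <- c(files, apath)
    }
    out$files <- files
  }
  out
}
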