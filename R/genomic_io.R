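# Format boundary: mapped reads (BED/BAM), annotations (BED/GFF) and the
# block-group text format.  Internal coordinates are 0-based half-open;
# GRanges appears only here and in the enrichment module.

#' Read mapped short RNA reads
#'
#' Reads mapped reads from BED6 (natively 0-based half-open; the score
#' column is the read multiplicity) or coordinate-sorted BAM.  For BAM, the
#' mapping identity is computed as (aligned length - edit distance) /
#' aligned length from the standard NM tag and reads below
#' \code{minAccuracy} are dropped; secondary and supplementary alignments
#' are always dropped so only uniquely mapped reads are profiled.  BED
#' carries no edit-distance information, so there the accuracy filter is a
#' no-op and a warning is emitted (unless \code{minAccuracy = 0}).
#'
#' @param path File path.
#' @param format \code{"bed"} or \code{"bam"} (guessed from the extension
#'   by default).
#' @param minAccuracy Minimum mapping identity in [0, 1] (default 0.85).
#' @return \code{data.frame} with columns \code{chrom}, \code{start},
#'   \code{end} (0-based half-open), \code{strand}, \code{count},
#'   \code{sample} (file stem), \code{is_dummy}.
#' @export
readMappedReads <- function(path, format = c("auto", "bed", "bam"),
                            minAccuracy = 0.85) {
  format <- match.arg(format)
  stopifnot(file.exists(path), minAccuracy >= 0, minAccuracy <= 1)
  if (format == "auto") {
    format <- if (grepl("\\.bam$", path, ignore.case = TRUE)) "bam" else "bed"
  }
  stem <- sub("\\.(bed|bam)$", "", basename(path), ignore.case = TRUE)
  if (format == "bed") {
    if (file.size(path) == 0) return(.emptyMapped())
    df <- tryCatch(
      read.table(path, sep = "\t", header = FALSE, comment.char = "#",
                 stringsAsFactors = FALSE),
      error = function(e) stop("unparseable BED file '", path, "': ",
                               conditionMessage(e))
    )
    if (ncol(df) < 6) stop("BED input needs 6 columns (chrom start end name count strand)")
    names(df)[1:6] <- c("chrom", "start", "end", "name", "count", "strand")
    bad <- which(!df$strand %in% c("+", "-"))
    if (length(bad)) stop("unknown strand symbol at record ", bad[1])
    bad <- which(df$start >= df$end)
    if (length(bad)) stop("start >= end at record ", bad[1])
    if (minAccuracy > 0) {
      warning("BED input carries no edit-distance information; ",
              "mapping-accuracy filter is a no-op")
    }
    out <- data.frame(
      chrom = as.character(df$chrom), start = as.integer(df$start),
      end = as.integer(df$end), strand = as.character(df$strand),
      count = as.numeric(df$count), sample = stem, is_dummy = FALSE
    )
    if (any(out$count < 1)) stop("read multiplicity must be >= 1")
    return(out)
  }
  # BAM branch
  flags <- Rsamtools::scanBamFlag(isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE,
                                  isUnmappedQuery = FALSE)
  par <- Rsamtools::ScanBamParam(flag = flags, tag = "NM",
                                 what = c("rname", "pos", "qwidth", "strand",
                                          "cigar"))
  res <- Rsamtools::scanBam(path, param = par)[[1]]
  if (!length(res$pos)) return(.emptyMapped())
  w <- .cigarRefWidth(res$cigar, res$qwidth)
  nm <- res$tag$NM
  keep <- rep(TRUE, length(res$pos))
  if (is.null(nm) || all(is.na(nm))) {
    message("NM tag absent; ", length(res$pos),
            " read(s) kept without accuracy information")
  } else {
    ident <- (w - ifelse(is.na(nm), 0, nm)) / w
    keep <- ident >= minAccuracy
    noinfo <- sum(is.na(nm))
    if (noinfo) message(noinfo, " read(s) lacked the NM tag and were kept")
  }
  data.frame(
    chrom = as.character(res$rname)[keep],
    start = as.integer(res$pos[keep] - 1L),        # 1-based -> 0-based
    end = as.integer(res$pos[keep] - 1L + w[keep]),
    strand = as.character(res$strand)[keep],
    count = 1, sample = stem, is_dummy = FALSE
  )
}

# reference-aligned width from CIGAR (M/D/N/=/X consume reference)
.cigarRefWidth <- function(cigar, qwidth) {
  ops <- gregexpr("[0-9]+[MIDNSHP=X]", cigar)
  vapply(seq_along(cigar), function(i) {
    if (is.na(cigar[i]) || cigar[i] == "*") return(qwidth[i])
    toks <- regmatches(cigar[i], ops[i])[[1]]
    n <- as.integer(sub("[A-Z=]", "", toks))
    op <- sub("[0-9]+", "", toks)
    sum(n[op %in% c("M", "D", "N", "=", "X")])
  }, 1L)
}

.emptyMapped <- function() {
  data.frame(chrom = character(), start = integer(), end = integer(),
             strand = character(), count = numeric(), sample = character(),
             is_dummy = logical())
}

#' Read annotation files into an annotation set
#'
#' Loads ncRNA, genomic-region, chromatin-segmentation and TSS annotations
#' from BED (native coordinates) or GFF3 (converted on read from 1-based
#' inclusive to 0-based half-open).  Identical intervals are deduplicated so
#' overlap queries return each source interval once.
#'
#' @param paths Named character vector of file paths; names are roles drawn
#'   from \code{ncrna}, \code{region}, \code{segmentation}, \code{tss}.
#' @param labels Optional named character vector giving a fixed class label
#'   per role; by default the BED name / GFF type column is used.
#' @return A list of class \code{"AnnotationSet"} with one
#'   \code{\link[GenomicRanges]{GRanges}} per role (label in the
#'   \code{label} metadata column).  TSS entries may be zero-width points;
#'   all other zero-length intervals are rejected.
#' @export
readAnnotations <- function(paths, labels = NULL) {
  roles <- names(paths)
  ok <- c("ncrna", "region", "segmentation", "tss")
  if (is.null(roles) || !all(roles %in% ok)) {
    stop("annotation roles must be named among: ", paste(ok, collapse = ", "))
  }
  out <- list()
  for (role in roles) {
    path <- paths[[role]]
    gff <- grepl("\\.gff3?$", path, ignore.case = TRUE)
    df <- read.table(path, sep = "\t", header = FALSE, comment.char = "#",
                     stringsAsFactors = FALSE)
    if (gff) {
      ann <- data.frame(
        chrom = df[[1]], start = df[[4]] - 1L, end = df[[5]],
        label = df[[3]],
        strand = ifelse(df[[7]] %in% c("+", "-"), df[[7]], "*")
      )
    } else {
      ann <- data.frame(
        chrom = df[[1]], start = df[[2]], end = df[[3]],
        label = if (ncol(df) >= 4) as.character(df[[4]]) else role,
        strand = if (ncol(df) >= 6) {
          ifelse(df[[6]] %in% c("+", "-"), df[[6]], "*")
        } else "*"
      )
    }
    if (!is.null(labels) && role %in% names(labels)) ann$label <- labels[[role]]
    if (any(ann$end < ann$start)) stop("annotation interval with end < start in ", path)
    if (role != "tss" && any(ann$end == ann$start)) {
      stop("zero-length interval outside the tss role in ", path)
    }
    ann <- unique(ann)
    gr <- GenomicRanges::GRanges(
      seqnames = ann$chrom,
      ranges = IRanges::IRanges(start = ann$start + 1L,
                                end = pmax(ann$end, ann$start + 1L)),
      strand = ann$strand
    )
    gr$label <- ann$label
    gr$point <- ann$end == ann$start
    out[[role]] <- gr
  }
  class(out) <- "AnnotationSet"
  out
}

#' Write block groups in the block-group text format
#'
#' Tab-separated text: one group header line (\code{>chrom start end id
#' total_reads strand n_blocks}) followed by one line per block
#' (\code{blockNb start end reads is_dummy}) with bit-exact integers.
#' \code{\link{readBlockGroups}} inverts it exactly, dummy flags included.
#'
#' @param groups List of \code{\linkS4class{BlockGroup}}s.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
writeBlockGroups <- function(groups, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# blockProc block groups v1", con)
  for (i in seq_along(groups)) {
    g <- groups[[i]]
    writeLines(sprintf(">%s\t%d\t%d\t%s|%d\t%s\t%s\t%d",
                       g@chrom, g@start, g@end, g@sample, i,
                       format(g@totalReads), g@strand, nBlocks(g)), con)
    b <- g@blocks
    for (k in seq_len(nrow(b))) {
      writeLines(sprintf("%d\t%d\t%d\t%s\t%d", k, b$start[k], b$end[k],
                         format(b$height[k]), as.integer(b$is_dummy[k])), con)
    }
  }
  invisible(path)
}

#' Read block groups from the block-group text format
#'
#' @param path File written by \code{\link{writeBlockGroups}}.
#' @return List of \code{\linkS4class{BlockGroup}}s (read tables empty:
#'   the text format stores the block summary, not individual reads).
#' @export
readBlockGroups <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  groups <- list()
  i <- 1
  while (i <= length(lines)) {
    if (!startsWith(lines[i], ">")) stop("malformed header at line ", i)
    h <- strsplit(sub("^>", "", lines[i]), "\t")[[1]]
    if (length(h) != 7) stop("malformed header at line ", i)
    nb <- as.integer(h[7])
    if (i + nb > length(lines)) stop("truncated block list after line ", i)
    bl <- lapply(seq_len(nb), function(k) {
      f <- strsplit(lines[i + k], "\t")[[1]]
      if (length(f) != 5 || anyNA(suppressWarnings(as.numeric(f)))) {
        stop("malformed block line at line ", i + k)
      }
      data.frame(start = as.integer(f[2]), end = as.integer(f[3]),
                 height = as.numeric(f[4]), is_dummy = as.integer(f[5]) == 1L)
    })
    bdf <- do.call(rbind, bl)
    total <- as.numeric(h[5])
    bdf$rel_height <- bdf$height / total
    groups[[length(groups) + 1L]] <- .newBlockGroup(
      chrom = h[1], start = as.integer(h[2]), end = as.integer(h[3]),
      strand = h[6], sample = sub("\\|[0-9]+$", "", h[4]),
      totalReads = total, blocks = bdf, reads = .emptyReads()
    )
    i <- i + nb + 1L
  }
  groups
}
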