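# Differential processing: per-locus alignment score matrix, multiscale
# bootstrap clustering with approximately-unbiased (AU) support, and the
# cluster score X used to flag candidate differentially processed loci.

#' Alignment score matrix of a harmonized locus
#'
#' All-vs-all profile alignment of the locus' block groups; each pair is
#' computed once, so the matrix is symmetric by construction with a unit
#' diagonal.
#'
#' @param locus A harmonized \code{\linkS4class{ProfileLocus}}.
#' @return Symmetric n x n numeric matrix with sample labels.
#' @export
computeScoreMatrix <- function(locus) {
  stopifnot(is(locus, "ProfileLocus"), isHarmonized(locus))
  gs <- groupList(locus)
  n <- length(gs)
  S <- diag(1, n)
  dimnames(S) <- list(names(gs), names(gs))
  if (n >= 2) {
    for (i in seq_len(n - 1)) {
      for (j in seq.int(i + 1, n)) {
        v <- alignBlockGroups(gs[[i]], gs[[j]])$value
        S[i, j] <- S[j, i] <- v
      }
    }
  }
  S
}

# leaf members of every internal node of an hclust tree, root included
.hclustClusters <- function(hc) {
  n <- nrow(hc$merge) + 1L
  members <- vector("list", nrow(hc$merge))
  for (k in seq_len(nrow(hc$merge))) {
    left <- hc$merge[k, 1]; right <- hc$merge[k, 2]
    lm <- if (left < 0) -left else members[[left]]
    rm <- if (right < 0) -right else members[[right]]
    members[[k]] <- sort(c(lm, rm))
  }
  members
}

# bitmask (sum of 2^(leaf-1)) per internal node; fast cluster identity for
# n <= 50 objects without sorting or string keys
.hclustMasks <- function(merge) {
  m <- nrow(merge)
  out <- numeric(m)
  for (k in seq_len(m)) {
    l <- merge[k, 1]; r <- merge[k, 2]
    out[k] <- (if (l < 0) 2^(-l - 1) else out[l]) +
      (if (r < 0) 2^(-r - 1) else out[r])
  }
  out
}

# correlation distance between columns, tolerating zero-variance columns:
# identical degenerate columns are at distance 0, otherwise maximally far.
.corDist <- function(X) {
  n <- ncol(X)
  cc <- suppressWarnings(cor(X))
  if (anyNA(cc)) {
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (is.na(cc[i, j])) {
        cc[i, j] <- if (all(X[, i] == X[, j])) 1 else 0
      }
    }
  }
  1 - cc
}

#' Multiscale-bootstrap hierarchical clustering of a score matrix
#'
#' Objects are the matrix columns, feature vectors the matrix rows;
#' dissimilarity is 1 - Pearson correlation and linkage is average.  For each
#' resampling ratio r the rows are resampled with replacement at size
#' round(r x nrow) and the bootstrap probability BP_r of every internal
#' cluster of the original tree is the fraction of bootstrap trees containing
#' it.  Approximately-unbiased support is fitted by the signed-distance
#' regression \eqn{qnorm(1 - BP_r) \approx v\sqrt{r} + c/\sqrt{r}} giving
#' \eqn{AU = 1 - \Phi(v - c)}; the reported per-cluster p-value is 1 - AU.
#' Deterministic given \code{seed}.
#'
#' A constant score matrix carries no cluster structure (the objects are
#' exchangeable); all p-values are then 1.
#'
#' @param S Symmetric alignment score matrix.
#' @param nBoot Bootstrap replicates per scale (>= 100; default 1000).
#' @param scales Resampling ratios (default \code{seq(0.5, 1.4, 0.1)}).
#' @param seed Integer seed.
#' @param auFit \code{TRUE} (default) for AU support; \code{FALSE} reports
#'   1 - BP at scale 1 only (fast mode).
#' @return A \code{\linkS4class{ProfileClustering}} (cluster score slots
#'   unfilled; see \code{\link{computeClusterScore}}).  The root cluster is
#'   excluded from the cluster list.
#' @export
bootstrapCluster <- function(S, nBoot = 1000L, scales = seq(0.5, 1.4, 0.1),
                             seed = 1L, auFit = TRUE) {
  stopifnot(is.matrix(S), nrow(S) == ncol(S))
  n <- ncol(S)
  labels <- colnames(S)
  if (is.null(labels)) labels <- as.character(seq_len(n))
  if (n < 3) {
    return(new("ProfileClustering",
      hclust = NULL, clusters = list(), pvalues = numeric(),
      bp = numeric(), labels = labels
    ))
  }
  hc <- hclust(as.dist(.corDist(S)), method = "average")
  all_members <- .hclustClusters(hc)
  keep <- vapply(all_members, length, 1L) < n  # drop root
  members <- all_members[keep]
  if (!length(members) || max(S) - min(S) < 1e-12) {
    return(new("ProfileClustering",
      hclust = hc, clusters = members,
      pvalues = rep(1, length(members)), bp = rep(0, length(members)),
      labels = labels
    ))
  }
  keys <- vapply(members, function(m) sum(2^(m - 1)), 1)
  if (!auFit) scales <- 1
  set.seed(seed)
  BP <- matrix(0, nrow = length(members), ncol = length(scales))
  for (si in seq_along(scales)) {
    nr <- max(2L, round(scales[si] * n))
    hits <- integer(length(members))
    for (b in seq_len(nBoot)) {
      idx <- sample.int(n, nr, replace = TRUE)
      db <- .corDist(S[idx, , drop = FALSE])
      hb <- hclust(as.dist(db), method = "average")
      hits <- hits + (keys %in% .hclustMasks(hb$merge))
    }
    BP[, si] <- hits / nBoot
  }
  bp1 <- BP[, which.min(abs(scales - 1))]
  if (auFit && length(scales) > 1) {
    pv <- vapply(seq_along(members), function(ci) {
      bps <- BP[ci, ]
      if (all(bps >= 1)) return(0)
      if (all(bps <= 0)) return(1)
      eps <- 0.5 / nBoot
      bps <- pmin(pmax(bps, eps), 1 - eps)
      z <- qnorm(1 - bps)
      sq <- sqrt(scales)
      fit <- lm(z ~ 0 + sq + I(1 / sq))
      v <- coef(fit)[[1]]; cc <- coef(fit)[[2]]
      pnorm(v - cc)  # = 1 - AU
    }, 1)
  } else {
    pv <- 1 - bp1
  }
  new("ProfileClustering",
    hclust = hc, clusters = members, pvalues = pv, bp = unname(bp1),
    labels = labels
  )
}

# pairwise mean of S over index sets; within = mean over unordered pairs
.meanWithin <- function(S, idx) {
  if (length(idx) < 2) return(NA_real_)
  sub <- S[idx, idx, drop = FALSE]
  mean(sub[upper.tri(sub)])
}
.meanBetween <- function(S, inside, outside) {
  if (!length(inside) || !length(outside)) return(NA_real_)
  mean(S[inside, outside, drop = FALSE])
}

#' Cluster score X of a locus
#'
#' For every supported cluster k (p < \code{alpha}) the per-cluster score is
#' \eqn{X_k = \max(0, \bar{S}_{in}(k) - \bar{S}_{out}(k))}: the average
#' alignment score within the cluster minus the average score between
#' in-cluster and out-of-cluster block groups.  The locus cluster score X is
#' the mean of \eqn{X_k} over the supported clusters (0 when there are none)
#' and lies in [0, 1]; loci with \eqn{X \ge} \code{xThreshold} become
#' candidate differentially processed loci.
#'
#' In \code{"combined"} (replicated) mode, samples whose two replicates do
#' not sit on the same side of a cluster's boundary are excluded from that
#' cluster's averages, and candidacy additionally requires some supported
#' cluster to retain >= 4 member block groups (two per cell line).
#'
#' @param S Alignment score matrix of the locus.
#' @param clustering \code{\linkS4class{ProfileClustering}} from
#'   \code{\link{bootstrapCluster}}.
#' @param replicateMap Named character vector sample -> cell line (combined
#'   mode only).
#' @param mode \code{"combined"} or \code{"independent"}.
#' @param alpha Cluster support threshold (default 0.05).
#' @param xThreshold Candidate threshold on X (default 0.15).
#' @return The clustering object with \code{significant}, \code{Xk},
#'   \code{X} and \code{candidate} filled.
#' @export
computeClusterScore <- function(S, clustering, replicateMap = NULL,
                                mode = c("independent", "combined"),
                                alpha = 0.05, xThreshold = 0.15) {
  mode <- match.arg(mode)
  stopifnot(is(clustering, "ProfileClustering"))
  if (mode == "combined") {
    stopifnot(!is.null(replicateMap),
              all(clustering@labels %in% names(replicateMap)))
  }
  n <- ncol(S)
  sig <- which(clustering@pvalues < alpha)
  Xk <- numeric(0)
  bigCluster <- FALSE
  for (ci in sig) {
    inside <- clustering@clusters[[ci]]
    outside <- setdiff(seq_len(n), inside)
    if (mode == "combined") {
      lines <- replicateMap[clustering@labels]
      keep <- rep(TRUE, n)
      for (ln in unique(lines)) {
        reps <- which(lines == ln)
        n_in <- sum(reps %in% inside)
        if (n_in != 0 && n_in != length(reps)) keep[reps] <- FALSE
      }
      inside <- inside[keep[inside]]
      outside <- outside[keep[outside]]
      if (length(inside) >= 4) bigCluster <- TRUE
    }
    s_in <- .meanWithin(S, inside)
    s_out <- .meanBetween(S, inside, outside)
    if (is.na(s_in) || is.na(s_out)) next
    xk <- max(0, s_in - s_out)
    if (s_in - s_out < 0) {
      message("cluster score clamped at 0 for a poorly separated cluster")
    }
    Xk <- c(Xk, setNames(xk, paste(clustering@clusters[[ci]], collapse = ",")))
  }
  X <- if (length(Xk)) mean(Xk) else 0
  candidate <- X >= xThreshold
  if (mode == "combined") candidate <- candidate && bigCluster
  clustering@significant <- as.integer(sig)
  clustering@Xk <- Xk
  clustering@X <- X
  clustering@candidate <- candidate
  clustering
}
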