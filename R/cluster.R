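## Core density clustering: the full laminar hierarchy of maximal-scoring
## segments over all density parameters d.
##
## For a fixed d > 0, a segment spanning sites i..j scores
##   S = T(i..j) - d * (pos_j - pos_i)
## and the cluster set at d is the maximal-scoring-subsequence decomposition
## (Ruzzo & Tompa) of the alternating sequence (+count, -d*gap, +count, ...),
## trimmed to begin and end on sites. A segment enters the decomposition when
## its enclosing segment splits (at the enclosing segment's break density)
## and leaves it at its own break density: the smallest d at which one of its
## proper prefixes or suffixes (including the flanking gap) reaches score 0,
##   prefix  i..b:  T(i..b)   / (pos_{b+1} - pos_i)
##   suffix b+1..j: T(b+1..j) / (pos_j    - pos_b)
## minimised over internal boundaries b. The recursion below splits each
## segment at its leftmost minimising boundary and annotates every emitted
## segment with minD (the density at which it first appears) and maxD (its
## own break density); segments whose break density does not exceed their
## entry density never appear at any d and are skipped (their children link
## to the nearest emitted ancestor).

paracluBlock <- function(pos, val) {
  n <- length(pos)
  cs <- cumsum(as.numeric(val))
  segSum <- function(i, j) cs[j] - if (i > 1L) cs[i - 1L] else 0
  maxRows <- 2L * n
  out <- list(start = integer(maxRows), end = integer(maxRows),
              nSites = integer(maxRows), tagSum = numeric(maxRows),
              minD = numeric(maxRows), maxD = numeric(maxRows),
              parent = integer(maxRows))
  nres <- 0L
  ## explicit work stack: (i, j, minD, parentRow)
  si <- sj <- sp <- integer(2L * n + 2L)
  sm <- numeric(2L * n + 2L)
  top <- 1L
  si[1L] <- 1L; sj[1L] <- n; sm[1L] <- 0; sp[1L] <- NA_integer_
  while (top > 0L) {
    i <- si[top]; j <- sj[top]; minD <- sm[top]; par <- sp[top]
    top <- top - 1L
    if (i == j) {
      breakD <- Inf
      b <- NA_integer_
    } else {
      idx <- i:(j - 1L)
      prefT <- cs[idx] - if (i > 1L) cs[i - 1L] else 0
      prefDen <- prefT / (pos[idx + 1L] - pos[i])
      sufT <- segSum(i, j) - prefT
      sufDen <- sufT / (pos[j] - pos[idx])
      dmin <- pmin(prefDen, sufDen)
      breakD <- min(dmin)
      b <- idx[which(dmin == breakD)[1L]]   # leftmost minimising boundary
    }
    if (breakD > minD) {
      nres <- nres + 1L
      out$start[nres] <- pos[i]; out$end[nres] <- pos[j]
      out$nSites[nres] <- j - i + 1L
      out$tagSum[nres] <- segSum(i, j)
      out$minD[nres] <- minD; out$maxD[nres] <- breakD
      out$parent[nres] <- par
      par <- nres
    }
    if (i < j) {
      childMin <- max(minD, breakD)
      top <- top + 1L
      si[top] <- b + 1L; sj[top] <- j; sm[top] <- childMin; sp[top] <- par
      top <- top + 1L
      si[top] <- i; sj[top] <- b; sm[top] <- childMin; sp[top] <- par
    }
  }
  lapply(out, function(x) x[seq_len(nres)])
}

#' Cluster CTSS sites into the full density hierarchy
#'
#' Decomposes the CTSS signal of every chromosome and strand independently
#' into the complete laminar family of maximal-scoring segments over all
#' density parameters d (see the package vignette for the model). Each
#' emitted cluster is annotated with the density interval `[minD, maxD)` over
#' which it is part of the decomposition, its stability `maxD / minD`
#' (capped at `stabilityCap` so that root and single-site clusters, whose
#' raw ratio is infinite, remain rank-usable), its tag sum, site count and
#' TPM per base.
#'
#' @param table a [CTSStable].
#' @param stabilityCap finite ceiling applied to `maxD / minD` before any
#'   hierarchical summation (default 1000).
#' @return a [ClusterSet] whose clusters are in pre-order (every parent
#'   precedes its children).
#' @examples
#' tb <- CTSStable("chr1", c(1, 101), "+", c(10L, 10L))
#' as.data.frame(clusterSites(tb))
#' @export
clusterSites <- function(table, stabilityCap = 1000) {
  stopifnot(is(table, "CTSStable"))
  if (stabilityCap <= 1) stop("stabilityCap must exceed 1")
  sites <- table@sites
  key <- paste(seqnames(sites), strand(sites))
  blocks <- split(seq_along(sites), factor(key, levels = unique(key)))
  res <- vector("list", length(blocks))
  offset <- 0L
  for (k in seq_along(blocks)) {
    idx <- blocks[[k]]
    if (is.unsorted(start(sites)[idx], strictly = TRUE))
      stop("CTSS sites must be strictly sorted within one chrom+strand")
    r <- paracluBlock(start(sites)[idx], sites$count[idx])
    r$chrom <- rep(as.character(seqnames(sites))[idx[1L]], length(r$start))
    r$strand <- rep(as.character(strand(sites))[idx[1L]], length(r$start))
    r$parent <- r$parent + offset
    offset <- offset + length(r$start)
    res[[k]] <- r
  }
  cat1 <- function(f) do.call(c, lapply(res, `[[`, f))
  if (!length(res) || !offset) {
    gr <- GRanges()
    mcols(gr) <- S4Vectors::DataFrame(nSites = integer(), tagSum = numeric(),
      minD = numeric(), maxD = numeric(), stability = numeric(),
      hierStability = numeric(), tpmPerBase = numeric(), parent = integer())
    return(new("ClusterSet", ranges = gr, librarySize = table@librarySize))
  }
  gr <- GRanges(cat1("chrom"), IRanges(cat1("start"), cat1("end")),
                strand = cat1("strand"))
  gr$nSites <- cat1("nSites")
  gr$tagSum <- cat1("tagSum")
  gr$minD <- cat1("minD")
  gr$maxD <- cat1("maxD")
  st <- ifelse(gr$minD == 0, Inf, gr$maxD / gr$minD)
  gr$stability <- pmin(st, stabilityCap)
  gr$hierStability <- rep(NA_real_, length(gr))
  gr$tpmPerBase <- (gr$tagSum * 1e6 / table@librarySize) / width(gr)
  gr$parent <- cat1("parent")
  new("ClusterSet", ranges = gr, librarySize = table@librarySize)
}

## Rewire parent links through removed clusters to the nearest kept ancestor
## and return re-indexed parent vector for the kept subset.
rewireParents <- function(parent, keep) {
  newIdx <- cumsum(keep)
  vapply(which(keep), function(k) {
    p <- parent[k]
    while (!is.na(p) && !keep[p]) p <- parent[p]
    if (is.na(p)) NA_integer_ else as.integer(newIdx[p])
  }, integer(1))
}

#' Discard weak clusters by TPM-per-base density
#'
#' Removes clusters whose normalized tag density, `tagSum * 1e6 /
#' librarySize / width`, is strictly below `minTPMPerBase` (default 0.1;
#' clusters at exactly the threshold are kept). Survivors keep their
#' hierarchy, with parent links rewired to the nearest surviving ancestor.
#'
#' @param clusters a [ClusterSet].
#' @param minTPMPerBase non-negative density threshold.
#' @return the filtered [ClusterSet].
#' @export
densityFilter <- function(clusters, minTPMPerBase = 0.1) {
  stopifnot(is(clusters, "ClusterSet"))
  if (minTPMPerBase < 0) stop("threshold must be non-negative")
  gr <- clusters@ranges
  keep <- gr$tpmPerBase >= minTPMPerBase
  out <- gr[keep]
  out$parent <- rewireParents(gr$parent, keep)
  new("ClusterSet", ranges = out, librarySize = clusters@librarySize)
}

#' Sum stabilities down the cluster hierarchy
#'
#' Sets `hierStability(c) = stability(c) + stability of every ancestor of c`,
#' i.e. each cluster inherits its parent's hierarchical stability and adds
#' its own. Orphans get their own stability. This is the replicate-comparable
#' score consumed by the IDR step.
#'
#' @param clusters a [ClusterSet] in pre-order (parents before children), as
#'   produced by [clusterSites()] and preserved by [densityFilter()].
#' @return the [ClusterSet] with `hierStability` populated.
#' @export
addHierStability <- function(clusters) {
  stopifnot(is(clusters, "ClusterSet"))
  gr <- clusters@ranges
  n <- length(gr)
  hs <- numeric(n)
  par <- gr$parent
  for (k in seq_len(n)) {
    p <- par[k]
    if (!is.na(p) && p >= k)
      stop("parent links must form a forest (parents precede children)")
    hs[k] <- gr$stability[k] + if (is.na(p)) 0 else hs[p]
  }
  gr$hierStability <- hs
  new("ClusterSet", ranges = gr, librarySize = clusters@librarySize)
}

#' Legacy single-scale cluster selection
#'
#' The classic Paraclu post-processing used for side-by-side comparison with
#' the multiscale pipeline: clusters with fewer than `minTags` tags, raw
#' stability (`maxD / minD`, uncapped) below `minStability`, or longer than
#' `maxLen` bases are discarded, and the hierarchy is then collapsed by
#' keeping only the largest surviving cluster at each site (clusters
#' contained in another survivor are dropped).
#'
#' @param clusters a [ClusterSet] from [clusterSites()].
#' @param minTags minimum tag count (default 30).
#' @param minStability minimum raw stability (default 2).
#' @param maxLen maximum cluster width in bases (default 200).
#' @return a flat [ClusterSet] (all parents `NA`).
#' @export
legacyFilter <- function(clusters, minTags = 30, minStability = 2,
                         maxLen = 200) {
  stopifnot(is(clusters, "ClusterSet"))
  gr <- clusters@ranges
  rawStab <- ifelse(gr$minD == 0, Inf, gr$maxD / gr$minD)
  keep <- gr$tagSum >= minTags & rawStab >= minStability & width(gr) <= maxLen
  out <- gr[keep]
  if (length(out)) {
    hits <- findOverlaps(out, out, type = "within")
    hits <- hits[queryHits(hits) != subjectHits(hits) &
                 as.character(strand(out))[queryHits(hits)] ==
                 as.character(strand(out))[subjectHits(hits)]]
    inner <- unique(queryHits(hits))
    if (length(inner)) out <- out[-inner]
  }
  out$parent <- rep(NA_integer_, length(out))
  new("ClusterSet", ranges = out, librarySize = clusters@librarySize)
}
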