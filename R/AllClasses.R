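#' @import methods
#' @import BiocGenerics
#' @import S4Vectors
#' @import IRanges
#' @import GenomicRanges
NULL

#' CTSStable: single-nucleotide CAGE TSS counts
#'
#' A strand-aware table of CAGE transcription start sites (CTSS): each record
#' is one genomic position carrying the number of CAGE tags whose 5' end maps
#' there, plus its tags-per-million (TPM) value. Positions are stored as a
#' width-1 [GenomicRanges::GRanges] (1-based, as is conventional for GRanges;
#' exported BED files use the 0-based half-open convention).
#'
#' Invariants enforced by the validity method: every count is a positive
#' integer (zero-count positions are never materialised), (chrom, pos, strand)
#' is unique, records are sorted by (chrom, strand, pos), the library size
#' equals the sum of counts, and when TPM values are present they sum to 1e6.
#'
#' @slot sites width-1 `GRanges` with metadata columns `count` (integer) and
#'   `tpm` (numeric, `NA` until [tpmNormalize()] is called).
#' @slot librarySize total tag count over all records.
#' @aliases CTSStable
#' @seealso [countCTSS()], [readCTSS()], [tpmNormalize()]
#' @export
setClass("CTSStable",
  slots = c(sites = "GRanges", librarySize = "numeric"))

setValidity("CTSStable", function(object) {
  gr <- object@sites
  msg <- character()
  if (length(gr)) {
    if (!all(width(gr) == 1L))
      msg <- c(msg, "all CTSS records must have width 1")
    if (is.null(gr$count) || anyNA(gr$count) || any(gr$count < 1) ||
        any(gr$count != round(gr$count)))
      msg <- c(msg, "'count' must be positive integers")
    if (anyDuplicated(paste(seqnames(gr), start(gr), strand(gr))))
      msg <- c(msg, "(chrom, pos, strand) must be unique")
    o <- base::order(as.character(seqnames(gr)),
                     match(as.character(strand(gr)), c("+", "-", "*")),
                     start(gr), method = "radix")
    if (!identical(o, seq_along(gr)))
      msg <- c(msg, "records must be sorted by (chrom, strand, pos)")
    if (!isTRUE(all.equal(object@librarySize, sum(as.numeric(gr$count)))))
      msg <- c(msg, "librarySize must equal sum of counts")
    if (!is.null(gr$tpm) && !anyNA(gr$tpm) &&
        abs(sum(gr$tpm) - 1e6) > 1e-6 * 1e6)
      msg <- c(msg, "TPM values must sum to 1e6")
  } else if (object@librarySize != 0) {
    msg <- c(msg, "empty table must have librarySize 0")
  }
  if (length(msg)) msg else TRUE
})

#' ClusterSet: a laminar hierarchy of TSS clusters
#'
#' Clusters are maximal-scoring segments of CTSS counts for some density
#' parameter d (see [clusterSites()]). Coordinates are the 1-based inclusive
#' positions of the first and last CTSS inside the cluster, so `width()` is
#' the number of covered bases and `end - start` is the extent penalised in
#' the segment score.
#'
#' Metadata columns of `ranges`:
#' \describe{
#'   \item{nSites}{number of CTSS positions inside}
#'   \item{tagSum}{total tag count}
#'   \item{minD, maxD}{infimum / supremum of the density interval over which
#'     the segment is maximal-scoring (`minD = 0` for roots, `maxD = Inf`
#'     for single-site clusters)}
#'   \item{stability}{`maxD / minD`, capped at a finite ceiling}
#'   \item{hierStability}{stability summed over the cluster and all its
#'     ancestors (`NA` until [addHierStability()] is called)}
#'   \item{tpmPerBase}{cluster TPM divided by width}
#'   \item{parent}{integer index of the immediately containing cluster in the
#'     same set, `NA` for roots}
#' }
#'
#' @slot ranges `GRanges` of clusters with the columns above.
#' @slot librarySize tag total of the source CTSS table (used for TPM).
#' @aliases ClusterSet
#' @seealso [clusterSites()], [densityFilter()], [legacyFilter()]
#' @export
setClass("ClusterSet",
  slots = c(ranges = "GRanges", librarySize = "numeric"))

setValidity("ClusterSet", function(object) {
  gr <- object@ranges
  msg <- character()
  need <- c("nSites", "tagSum", "minD", "maxD", "stability", "parent")
  miss <- setdiff(need, colnames(mcols(gr)))
  if (length(miss))
    msg <- c(msg, paste("missing metadata column(s):",
                        paste(miss, collapse = ", ")))
  if (!length(msg) && length(gr)) {
    if (any(gr$minD < 0) || any(gr$minD >= gr$maxD))
      msg <- c(msg, "need 0 <= minD < maxD for every cluster")
    p <- gr$parent
    ok <- !is.na(p)
    if (any(ok & (p < 1 | p > length(gr))))
      msg <- c(msg, "parent indices out of range")
    if (any(ok & p == seq_along(gr)))
      msg <- c(msg, "a cluster cannot be its own parent")
  }
  if (length(msg)) msg else TRUE
})

#' MergedClusters: replicate-merged clusters with IDR annotations
#'
#' Intersection intervals of reciprocally overlapping cluster pairs from two
#' replicates, carrying both hierarchical stabilities and (after [fitIDR()])
#' the local and global irreproducible discovery rates.
#'
#' Metadata columns of `ranges`: `scoreA`, `scoreB` (hierarchical stabilities
#' from replicates A and B), `localIDR` (posterior probability of the
#' irreproducible mixture component) and `globalIDR` (expected
#' irreproducibility rate of the set selected down to this cluster's rank).
#'
#' @slot ranges `GRanges` of intersection intervals.
#' @aliases MergedClusters
#' @seealso [mergeReplicates()], [idrFilter()], [lengthFilter()]
#' @export
setClass("MergedClusters", slots = c(ranges = "GRanges"))

setValidity("MergedClusters", function(object) {
  gr <- object@ranges
  msg <- character()
  if (length(gr)) {
    if (is.null(gr$scoreA) || is.null(gr$scoreB))
      msg <- c(msg, "scoreA/scoreB metadata columns are required")
    for (col in c("localIDR", "globalIDR")) {
      v <- mcols(gr)[[col]]
      if (!is.null(v) && !anyNA(v) && (any(v < 0) || any(v > 1)))
        msg <- c(msg, paste(col, "must lie in [0, 1]"))
    }
  }
  if (length(msg)) msg else TRUE
})

#' IDRFit: fitted copula mixture for replicate reproducibility
#'
#' Parameters of the two-component Gaussian copula mixture underlying the
#' irreproducible discovery rate: with probability `pi1` a signal pair comes
#' from the reproducible component, a bivariate normal with mean
#' `(mu, mu)`, common standard deviation `sigma` and correlation `rho`;
#' otherwise from an independent standard bivariate normal. Observed scores
#' enter only through their ranks.
#'
#' @slot pi1 mixture proportion of the reproducible component, in `[0, 1]`.
#' @slot mu,sigma,rho reproducible-component latent mean, sd (> 0) and
#'   correlation (in `(-1, 1)`).
#' @slot loglikTrace pseudo-log-likelihood after each EM iteration.
#' @slot localIDR per-pair posterior probability of irreproducibility.
#' @slot globalIDR per-pair expected irreproducibility rate at its rank.
#' @slot converged whether the EM reached the tolerance within `maxIter`.
#' @aliases IDRFit
#' @seealso [fitIDR()]
#' @export
setClass("IDRFit",
  slots = c(pi1 = "numeric", mu = "numeric", sigma = "numeric",
            rho = "numeric", loglikTrace = "numeric",
            localIDR = "numeric", globalIDR = "numeric",
            converged = "logical"))

setValidity("IDRFit", function(object) {
  msg <- character()
  if (object@pi1 < 0 || object@pi1 > 1) msg <- c(msg, "pi1 must be in [0,1]")
  if (object@sigma <= 0) msg <- c(msg, "sigma must be > 0")
  if (abs(object@rho) >= 1) msg <- c(msg, "rho must be in (-1,1)")
  if (length(object@localIDR) &&
      (any(object@localIDR < 0) || any(object@localIDR > 1)))
    msg <- c(msg, "localIDR must lie in [0,1]")
  if (length(msg)) msg else TRUE
})
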