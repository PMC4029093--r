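#' Accessors for CAGEstack objects
#'
#' `ctssSites()` returns the width-1 site `GRanges` of a [CTSStable];
#' `librarySize()` the total tag count; `clusterRanges()` the cluster (or
#' merged-cluster) `GRanges` of a [ClusterSet] / [MergedClusters].
#'
#' @param x a CAGEstack object.
#' @return a `GRanges` or a number, as described above.
#' @name accessors
#' @aliases ctssSites librarySize clusterRanges
NULL

#' @rdname accessors
#' @export
setGeneric("ctssSites", function(x) standardGeneric("ctssSites"))

#' @rdname accessors
#' @export
setGeneric("librarySize", function(x) standardGeneric("librarySize"))

#' @rdname accessors
#' @export
setGeneric("clusterRanges", function(x) standardGeneric("clusterRanges"))

#' @rdname accessors
setMethod("ctssSites", "CTSStable", function(x) x@sites)

#' @rdname accessors
setMethod("librarySize", "CTSStable", function(x) x@librarySize)

#' @rdname accessors
setMethod("librarySize", "ClusterSet", function(x) x@librarySize)

#' @rdname accessors
setMethod("clusterRanges", "ClusterSet", function(x) x@ranges)

#' @rdname accessors
setMethod("clusterRanges", "MergedClusters", function(x) x@ranges)

#' @describeIn accessors number of CTSS records.
setMethod("length", "CTSStable", function(x) length(x@sites))

#' @describeIn accessors number of clusters.
setMethod("length", "ClusterSet", function(x) length(x@ranges))

#' @describeIn accessors number of merged clusters.
setMethod("length", "MergedClusters", function(x) length(x@ranges))

setMethod("show", "CTSStable", function(object) {
  cat("CTSStable with", length(object), "CTSS on",
      length(unique(as.character(seqnames(object@sites)))),
      "sequence(s); library size", format(object@librarySize), "\n")
  if (length(object)) {
    tpm <- object@sites$tpm
    cat("  TPM:", if (is.null(tpm) || anyNA(tpm)) "not computed"
        else "computed", "\n")
  }
})

setMethod("show", "ClusterSet", function(object) {
  gr <- object@ranges
  cat("ClusterSet with", length(gr), "clusters")
  if (length(gr)) {
    cat("; widths", min(width(gr)), "-", max(width(gr)), "bp;",
        sum(is.na(gr$parent)), "root(s)")
    hs <- gr$hierStability
    if (!is.null(hs) && !anyNA(hs))
      cat("; hierarchical stability up to", format(max(hs), digits = 4))
  }
  cat("\n")
})

setMethod("show", "MergedClusters", function(object) {
  gr <- object@ranges
  cat("MergedClusters with", length(gr), "replicate-merged clusters")
  if (length(gr) && !is.null(gr$globalIDR) && !anyNA(gr$globalIDR))
    cat(";", sum(gr$globalIDR < 0.1), "with global IDR < 0.1")
  cat("\n")
})

setMethod("show", "IDRFit", function(object) {
  cat(sprintf(
    "IDRFit: pi1 = %.3f, mu = %.3f, sigma = %.3f, rho = %.3f (%s, %d iter)\n",
    object@pi1, object@mu, object@sigma, object@rho,
    if (object@converged) "converged" else "not converged",
    length(object@loglikTrace)))
})

#' @describeIn accessors merged clusters as a data.frame (one row per
#'   cluster, BED-like 0-based half-open coordinates).
#' @export
setMethod("as.data.frame", "MergedClusters", function(x, ...) {
  gr <- x@ranges
  data.frame(chrom = as.character(seqnames(gr)), start = start(gr) - 1L,
             end = end(gr), strand = as.character(strand(gr)),
             as.data.frame(mcols(gr)), row.names = NULL)
})

#' @describeIn accessors clusters as a data.frame (1-based inclusive site
#'   coordinates, as stored).
#' @export
setMethod("as.data.frame", "ClusterSet", function(x, ...) {
  gr <- x@ranges
  data.frame(chrom = as.character(seqnames(gr)), strand =
             as.character(strand(gr)), start = start(gr), end = end(gr),
             as.data.frame(mcols(gr)), row.names = NULL)
})
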