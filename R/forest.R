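#' Build the containment forest over clusters
#'
#' Computes, for every cluster, its immediate container: the smallest
#' cluster in the set that strictly contains it on the same chromosome and
#' strand (ties between equally small containers are broken leftmost).
#' Clusters that only partially overlap share no edge. Input intervals must
#' be unique on (chrom, strand, start, end); de-duplicate first (e.g. with
#' [dedupeClusters()]).
#'
#' @param gr a `GRanges` of clusters (e.g. `clusterRanges()` of a
#'   [MergedClusters]).
#' @return a list with `nodes` (the input `GRanges`), `parent` (integer
#'   index of the immediate container, `NA` for roots) and `nContained`
#'   (number of clusters strictly contained in each node, i.e. all
#'   descendants by containment).
#' @export
buildForest <- function(gr) {
  stopifnot(is(gr, "GRanges"))
  if (anyDuplicated(paste(seqnames(gr), strand(gr), start(gr), end(gr))))
    stop("duplicate intervals; de-duplicate before building the forest")
  hits <- findOverlaps(gr, gr, type = "within")   # strand-aware
  qh <- queryHits(hits); sh <- subjectHits(hits)
  strict <- qh != sh   # equality impossible after dedupe
  qh <- qh[strict]; sh <- sh[strict]
  parent <- rep(NA_integer_, length(gr))
  if (length(qh)) {
    o <- order(qh, width(gr)[sh], start(gr)[sh])
    qh <- qh[o]; sh <- sh[o]
    first <- !duplicated(qh)
    parent[qh[first]] <- sh[first]
  }
  nContained <- integer(length(gr))
  tb <- table(sh)
  nContained[as.integer(names(tb))] <- as.integer(tb)
  list(nodes = gr, parent = parent, nContained = nContained)
}

#' Extract bottom (broadest) peaks
#'
#' Bottom peaks are the clusters not themselves included in any other peak:
#' the roots of the containment forest. An isolated cluster is both bottom
#' and top.
#'
#' @param forest result of [buildForest()].
#' @return the root-node `GRanges`.
#' @export
extractBottom <- function(forest) {
  forest$nodes[is.na(forest$parent)]
}

#' Extract top (narrowest) peaks
#'
#' Top peaks are the clusters that do not contain any other peak: the
#' leaves of the containment forest.
#'
#' @param forest result of [buildForest()].
#' @return the leaf-node `GRanges`.
#' @export
extractTop <- function(forest) {
  isParent <- seq_along(forest$nodes) %in% forest$parent
  forest$nodes[!isParent]
}

#' Tabulate cluster size against contained-cluster count
#'
#' Cross-tabulates cluster width (binned at `binWidth`) against the number
#' of clusters each one contains (all strictly contained clusters, not only
#' direct children), the summary behind "clusters within clusters" size
#' histograms.
#'
#' @param forest result of [buildForest()].
#' @param binWidth width of the length bins in bases.
#' @param contentBinWidth width of the containment-count bins.
#' @return a data.frame with `lengthBin`, `containedBin` and `count`;
#'   counts sum to the number of clusters.
#' @export
sizeContentTable <- function(forest, binWidth = 10, contentBinWidth = 40) {
  w <- width(forest$nodes)
  lengthBin <- (ceiling(w / binWidth)) * binWidth
  containedBin <- floor(forest$nContained / contentBinWidth) *
    contentBinWidth
  d <- as.data.frame(table(lengthBin = lengthBin,
                           containedBin = containedBin),
                     stringsAsFactors = FALSE)
  d <- d[d$Freq > 0, ]
  data.frame(lengthBin = as.numeric(d$lengthBin),
             containedBin = as.numeric(d$containedBin), count = d$Freq,
             row.names = NULL)
}

#' De-duplicate identical cluster intervals
#'
#' Merged cluster sets pooled across conditions can contain identical
#' intervals; this keeps, per (chrom, strand, start, end), the record with
#' the highest combined replicate score (`scoreA + scoreB` where present).
#'
#' @param gr a `GRanges` of clusters.
#' @return the de-duplicated `GRanges`.
#' @export
dedupeClusters <- function(gr) {
  if (!length(gr)) return(gr)
  key <- paste(seqnames(gr), strand(gr), start(gr), end(gr))
  score <- if (!is.null(gr$scoreA) && !is.null(gr$scoreB))
    gr$scoreA + gr$scoreB else rep(0, length(gr))
  o <- order(key, -score)
  gr <- gr[o]
  gr[!duplicated(key[o])]
}
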