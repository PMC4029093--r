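#' Read gene TSS models
#'
#' Reads gene models from refFlat text or BED (BED6/BED12 via rtracklayer)
#' and reduces each transcript to its transcription start site: `txStart`
#' on the forward strand, `txEnd - 1` (0-based) on the reverse strand.
#' Duplicate (gene, tss, strand) triples are collapsed.
#'
#' @param path file path.
#' @param format `"refFlat"` or `"bed"`.
#' @return a width-1 `GRanges` with a `gene` metadata column.
#' @export
readGeneTSS <- function(path, format = c("refFlat", "bed")) {
  format <- match.arg(format)
  if (format == "bed") {
    gr <- rtracklayer::import(path, format = "bed")
    gene <- if (!is.null(gr$name)) gr$name else as.character(seq_along(gr))
    tss <- ifelse(as.character(strand(gr)) == "-", end(gr), start(gr))
    out <- GRanges(seqnames(gr), IRanges(tss, width = 1L),
                   strand = strand(gr))
  } else {
    d <- utils::read.table(path, sep = "\t", comment.char = "#",
                           stringsAsFactors = FALSE)
    ## refFlat: geneName name chrom strand txStart txEnd ...
    gene <- d[[1L]]
    tss0 <- ifelse(d[[4L]] == "-", d[[6L]] - 1L, d[[5L]])
    out <- GRanges(d[[3L]], IRanges(tss0 + 1L, width = 1L), strand = d[[4L]])
  }
  out$gene <- gene
  out[!duplicated(paste(out$gene, seqnames(out), start(out), strand(out)))]
}

#' Assign clusters to genes through promoter windows
#'
#' A cluster is assigned to every gene whose TSS +/- `window` bp interval
#' overlaps the cluster by at least one base on the same strand (set
#' `ignoreStrand = TRUE` for strand-agnostic assignment). Clusters with no
#' assignment are classified as novel.
#'
#' @param clusters `GRanges` of clusters; names (or a `cluster` metadata
#'   column) identify them in the output.
#' @param geneTSS width-1 `GRanges` with a `gene` column, from
#'   [readGeneTSS()].
#' @param window half-width of the promoter window in bases (default 500).
#' @param ignoreStrand assign across strands.
#' @return a list with `assignments` (data.frame `cluster`, `gene`,
#'   `distance`: signed cluster-edge-to-TSS distance, 0 when the TSS falls
#'   inside the cluster) and `novel` (integer indices of unassigned
#'   clusters).
#' @export
assignClusters <- function(clusters, geneTSS, window = 500,
                           ignoreStrand = FALSE) {
  if (window < 0) stop("window must be non-negative")
  prom <- GRanges(seqnames(geneTSS),
                  IRanges(pmax(1L, start(geneTSS) - window),
                          start(geneTSS) + window),
                  strand = strand(geneTSS))
  hits <- findOverlaps(clusters, prom, ignore.strand = ignoreStrand)
  qh <- queryHits(hits); sh <- subjectHits(hits)
  tss <- start(geneTSS)[sh]
  dist <- ifelse(tss < start(clusters)[qh], start(clusters)[qh] - tss,
                 ifelse(tss > end(clusters)[qh], end(clusters)[qh] - tss,
                        0L))
  ids <- if (!is.null(clusters$cluster)) clusters$cluster
         else if (!is.null(names(clusters))) names(clusters)
         else as.character(seq_along(clusters))
  list(assignments = data.frame(cluster = ids[qh],
                                gene = geneTSS$gene[sh],
                                distance = as.integer(dist),
                                row.names = NULL),
       novel = setdiff(seq_along(clusters), unique(qh)))
}

#' Summarise clusters per expression bin
#'
#' Counts clusters per TPM bin, split by reproducibility and by known/novel
#' gene association (the summary behind expression-stratified
#' reproducibility plots). Bins are right-closed: a cluster exactly on an
#' edge falls in the bin ending at that edge.
#'
#' @param tpm numeric cluster TPM values.
#' @param reproducible logical flag per cluster.
#' @param known logical flag per cluster (assigned to a gene or not).
#' @param breaks bin edges passed to [cut()]; values outside are pooled
#'   into the flanking bins.
#' @return data.frame with `bin`, `reproducible`, `known`, `count`; counts
#'   sum to `length(tpm)`.
#' @export
tpmBinSummary <- function(tpm, reproducible, known,
                          breaks = c(0, 1, 10, 100, 1000, Inf)) {
  stopifnot(length(reproducible) == length(tpm),
            length(known) == length(tpm))
  b <- cut(pmin(pmax(tpm, min(breaks)), max(breaks)), breaks = breaks,
           right = TRUE, include.lowest = TRUE)
  d <- as.data.frame(table(bin = b, reproducible = reproducible,
                           known = known))
  names(d)[4L] <- "count"
  d$reproducible <- as.logical(d$reproducible)
  d$known <- as.logical(d$known)
  d
}
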