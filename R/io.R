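#' @importFrom stats approx dnbinom dnorm dpois optim optimize p.adjust pnorm qnorm rbinom
#'   rgamma rnorm rpois
#' @importFrom utils read.table write.table
NULL

#' Write a ClusterSet as tab-separated text
#'
#' Columns: chrom, strand, start, end (1-based inclusive site coordinates),
#' nSites, tagSum, minD, maxD, stability, hierStability; one header line
#' starting with `#`.
#'
#' @param clusters a [ClusterSet].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeClusters <- function(clusters, path) {
  stopifnot(is(clusters, "ClusterSet"))
  gr <- clusters@ranges
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#", paste(c("chrom", "strand", "start", "end",
                                 "nSites", "tagSum", "minD", "maxD",
                                 "stability", "hierStability"),
                               collapse = "\t")), con)
  if (length(gr))
    writeLines(paste(seqnames(gr), strand(gr), start(gr), end(gr),
                     gr$nSites, gr$tagSum,
                     format(gr$minD, digits = 12, trim = TRUE),
                     format(gr$maxD, digits = 12, trim = TRUE),
                     format(gr$stability, digits = 12, trim = TRUE),
                     format(gr$hierStability, digits = 12, trim = TRUE),
                     sep = "\t"), con)
  invisible(path)
}

#' Export clusters as BED6
#'
#' Half-open 0-based coordinates; the score column carries the hierarchical
#' stability rounded and capped at 1000 (BED scores are bounded).
#'
#' @param clusters a [ClusterSet].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
exportClustersBED <- function(clusters, path) {
  stopifnot(is(clusters, "ClusterSet"))
  gr <- clusters@ranges
  score <- gr$hierStability
  if (is.null(score) || anyNA(score)) score <- gr$stability
  writeLines(paste(seqnames(gr), start(gr) - 1L, end(gr),
                   clusterIds(gr), pmin(round(score), 1000L), strand(gr),
                   sep = "\t"), path)
  invisible(path)
}
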