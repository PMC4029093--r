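# Shared fixture builders (everything is generated in code at test time).

writeSAM <- function(aln, path = tempfile(fileext = ".sam")) {
  writeLines(c("@HD\tVN:1.6\tSO:coordinate",
               "@SQ\tSN:chr1\tLN:100000",
               "@SQ\tSN:chr2\tLN:100000", aln), path)
  path
}

samLine <- function(qname, flag, chrom, pos1, cigar) {
  paste(qname, flag, chrom, pos1, 60, cigar, "*", 0, 0, "*", "*",
        sep = "\t")
}

# Minimal ClusterSet with arbitrary annotations, for filter-boundary tests.
makeClusterSet <- function(start, end, tagSum, minD, maxD,
                           strand = "+", chrom = "chr1", parent = NA,
                           librarySize = 1e6, stabilityCap = 1000) {
  n <- length(start)
  gr <- GenomicRanges::GRanges(rep(chrom, n),
                               IRanges::IRanges(start, end),
                               strand = rep(strand, length.out = n))
  gr$nSites <- rep(2L, n)
  gr$tagSum <- tagSum
  gr$minD <- minD
  gr$maxD <- maxD
  st <- ifelse(minD == 0, Inf, maxD / minD)
  gr$stability <- pmin(st, stabilityCap)
  gr$hierStability <- rep(NA_real_, n)
  gr$tpmPerBase <- (tagSum * 1e6 / librarySize) / (end - start + 1)
  gr$parent <- as.integer(rep(parent, length.out = n))
  new("ClusterSet", ranges = gr, librarySize = librarySize)
}

makeMerged <- function(start, end, scoreA = 1, scoreB = 1,
                       globalIDR = NA_real_, strand = "+") {
  n <- length(start)
  gr <- GenomicRanges::GRanges(rep("chr1", n),
                               IRanges::IRanges(start, end),
                               strand = rep(strand, length.out = n))
  gr$scoreA <- rep(scoreA, length.out = n)
  gr$scoreB <- rep(scoreB, length.out = n)
  gr$localIDR <- rep(NA_real_, n)
  gr$globalIDR <- rep(globalIDR, length.out = n)
  new("MergedClusters", ranges = gr)
}
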