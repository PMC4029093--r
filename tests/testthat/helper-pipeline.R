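# End-to-end run on one simulated dataset: returns the fraction of planted
# sub-peak-shift promoters showing the TSS-shift signature (a significant
# narrow/top peak inside the shifted sub-peak together with a
# non-significant broad/bottom peak), plus the mode-unique gene counts.
runShiftRecovery <- function(seed, cfg = simConfig(seed = seed)) {
  sim <- simulateCTSS(cfg)
  gtss <- truthGeneTSS(sim$truth)
  res <- suppressMessages(suppressWarnings(
    runPipeline(sim$tables, sim$conditions, gtss)))
  leg <- suppressMessages(suppressWarnings(
    runPipeline(sim$tables, sim$conditions, gtss, mode = "legacy")))
  cl <- res$clusters
  tr <- sim$truth
  shiftProm <- unique(tr$promoter[tr$deClass == "shift" & tr$reproducible])
  ok <- 0L
  for (p in shiftProm) {
    b <- tr[tr$promoter == p & tr$type == "broad", ]
    sub <- tr[tr$promoter == p & tr$shifted, ]
    pr <- GenomicRanges::GRanges("chrS", IRanges::IRanges(b$start, b$end),
                                 strand = b$strand)
    sh <- GenomicRanges::GRanges("chrS",
                                 IRanges::IRanges(sub$start, sub$end),
                                 strand = sub$strand)
    tops <- cl[cl$class == "top" & IRanges::overlapsAny(cl, sh)]
    bots <- cl[cl$class == "bottom" & IRanges::overlapsAny(cl, pr)]
    if (any(tops$significant) && length(bots) && !any(bots$significant))
      ok <- ok + 1L
  }
  cmp <- compareModes(res$geneCalls, leg$geneCalls)
  list(rate = ok / length(shiftProm), nShift = length(shiftProm),
       onlyMultiscale = unname(cmp$counts["onlyA"]),
       onlyLegacy = unname(cmp$counts["onlyB"]),
       both = unname(cmp$counts["both"]),
       multiscale = res, legacy = leg, sim = sim)
}
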