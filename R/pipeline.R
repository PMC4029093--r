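#' Pipeline configuration
#'
#' Collects every tunable threshold of the peak-calling pipeline. Defaults
#' are the published operating point: density filter 0.1 TPM per base,
#' 90% reciprocal replicate overlap, global IDR < 0.1, maximum reproducible
#' cluster length 200 bp, differential calls at |log2 FC| > 2 and
#' BH-adjusted p < 0.05, and legacy-mode selection at >= 30 tags,
#' >= 2 stability, <= 200 bp.
#'
#' @param minTPMPerBase density filter threshold (TPM per base).
#' @param overlapFrac reciprocal overlap fraction for replicate merging.
#' @param idrThreshold global IDR cutoff (strict).
#' @param maxClusterLen maximum reproducible cluster width (bp).
#' @param minAbsLogFC,alpha differential-expression call thresholds.
#' @param legacyMinTags,legacyMinStability,legacyMaxLen legacy-mode filter.
#' @param stabilityCap finite ceiling for infinite raw stabilities.
#' @param promoterWindow TSS +/- window for gene assignment (bp).
#' @param idrInit,idrTol,idrMaxIter EM settings for [fitIDR()].
#' @return a config list of class `"pipelineConfig"`.
#' @export
pipelineConfig <- function(minTPMPerBase = 0.1, overlapFrac = 0.9,
                           idrThreshold = 0.1, maxClusterLen = 200,
                           minAbsLogFC = 2, alpha = 0.05,
                           legacyMinTags = 30, legacyMinStability = 2,
                           legacyMaxLen = 200, stabilityCap = 1000,
                           promoterWindow = 500,
                           idrInit = list(pi1 = 0.7, mu = 2.6,
                                          sigma = 1.3, rho = 0.8),
                           idrTol = 1e-4, idrMaxIter = 200) {
  cfg <- as.list(environment())
  stopifnot(minTPMPerBase >= 0, overlapFrac > 0, overlapFrac <= 1,
            idrThreshold > 0, idrThreshold <= 1, maxClusterLen >= 1,
            minAbsLogFC >= 0, alpha > 0, alpha <= 1, stabilityCap > 1)
  class(cfg) <- "pipelineConfig"
  cfg
}

clusterIds <- function(gr) {
  paste0(seqnames(gr), ":", start(gr) - 1L, "-", end(gr), ":", strand(gr))
}

## One condition, multiscale path: cluster each replicate, density filter,
## hierarchical stability, merge first two replicates, IDR + length filter.
reproducibleClustersOneCondition <- function(tables, cfg) {
  sets <- lapply(tables, function(tb)
    addHierStability(densityFilter(clusterSites(tb, cfg$stabilityCap),
                                   cfg$minTPMPerBase)))
  merged <- mergeReplicates(sets[[1L]], sets[[2L]], cfg$overlapFrac)
  scored <- scoreIDR(merged, init = cfg$idrInit, tol = cfg$idrTol,
                     maxIter = cfg$idrMaxIter)
  kept <- lengthFilter(idrFilter(scored$merged, cfg$idrThreshold),
                       cfg$maxClusterLen)
  list(sets = sets, merged = merged, scored = scored$merged,
       fit = scored$fit, kept = kept)
}

## One condition, legacy path: classic filtering per replicate, then the
## same reciprocal-overlap merge (no IDR; the legacy filter already imposes
## its own stability and length rules).
legacyClustersOneCondition <- function(tables, cfg) {
  sets <- lapply(tables, function(tb) {
    cs <- legacyFilter(clusterSites(tb, cfg$stabilityCap),
                       cfg$legacyMinTags, cfg$legacyMinStability,
                       cfg$legacyMaxLen)
    gr <- cs@ranges
    gr$hierStability <- gr$stability   # flat set: no ancestors
    new("ClusterSet", ranges = gr, librarySize = cs@librarySize)
  })
  mergeReplicates(sets[[1L]], sets[[2L]], cfg$overlapFrac)
}

#' Run the multi-scale reproducible peak pipeline end to end
#'
#' Executes, per condition: density clustering of each replicate, the
#' TPM-per-base density filter, hierarchical stability, reciprocal-overlap
#' merging of the two replicates, IDR fitting and filtering, and the 200 bp
#' length filter. The reproducible clusters of both conditions are then
#' pooled, the containment forest is built, top (narrowest) and bottom
#' (broadest) peaks are extracted and each class is tested separately for
#' differential expression with the NB exact test; cluster calls are lifted
#' to genes through promoter windows. In `mode = "legacy"` the per-replicate
#' clustering is instead filtered the classic single-scale way (tag count,
#' stability, length, largest cluster per site) and the single flat class is
#' tested.
#'
#' @param tables named list of [CTSStable]s (two conditions, >= 2 replicates
#'   each; the first two replicates per condition are merged).
#' @param conditions factor of length `length(tables)` with two levels.
#' @param geneTSS width-1 `GRanges` with a `gene` column (e.g.
#'   [readGeneTSS()] or [truthGeneTSS()]); `NULL` skips gene-level calls.
#' @param cfg a [pipelineConfig()].
#' @param mode `"multiscale"` or `"legacy"`.
#' @return a list with per-condition intermediates (`perCondition`), the
#'   pooled tested clusters (`clusters`: `GRanges` with class, test results
#'   and calls), `geneCalls`, `idrFits`, and `stageCounts` (records in and
#'   out of every stage).
#' @export
runPipeline <- function(tables, conditions, geneTSS = NULL,
                        cfg = pipelineConfig(),
                        mode = c("multiscale", "legacy")) {
  mode <- match.arg(mode)
  stopifnot(inherits(cfg, "pipelineConfig"))
  conditions <- as.factor(conditions)
  if (nlevels(conditions) != 2L)
    stop("exactly two conditions are required")
  if (length(tables) != length(conditions))
    stop("one condition label per table is required")
  for (lv in levels(conditions))
    if (sum(conditions == lv) < 2L)
      stop("condition '", lv, "' has fewer than 2 replicates")
  stages <- list()
  note <- function(stage, nIn, nOut) {
    stages[[length(stages) + 1L]] <<- data.frame(stage = stage, n_in = nIn,
                                                 n_out = nOut)
    message(sprintf("[%s] %s: %d -> %d", mode, stage, nIn, nOut))
  }
  perCondition <- list()
  idrFits <- list()
  pooledList <- list()
  for (lv in levels(conditions)) {
    tb <- tables[conditions == lv]
    if (mode == "multiscale") {
      res <- reproducibleClustersOneCondition(tb, cfg)
      nAll <- sum(vapply(res$sets, length, 0L))
      note(paste0(lv, ": cluster+density"), sum(vapply(tb, length, 0L)),
           nAll)
      note(paste0(lv, ": overlap merge"), nAll, length(res$merged))
      note(paste0(lv, ": IDR filter"), length(res$merged),
           sum(res$scored@ranges$globalIDR < cfg$idrThreshold))
      note(paste0(lv, ": length filter"),
           sum(res$scored@ranges$globalIDR < cfg$idrThreshold),
           length(res$kept))
      perCondition[[lv]] <- res
      idrFits[[lv]] <- res$fit
      pooledList[[lv]] <- clusterRanges(res$kept)
    } else {
      merged <- legacyClustersOneCondition(tb, cfg)
      note(paste0(lv, ": legacy cluster+filter+merge"),
           sum(vapply(tb, length, 0L)), length(merged))
      perCondition[[lv]] <- list(kept = merged)
      pooledList[[lv]] <- clusterRanges(merged)
    }
  }
  pooled <- dedupeClusters(do.call(c, unname(pooledList)))
  note("pool conditions (dedupe)", NA_integer_, length(pooled))
  if (mode == "multiscale") {
    forest <- buildForest(pooled)
    tops <- extractTop(forest)
    bottoms <- extractBottom(forest)
    classes <- list(top = tops, bottom = bottoms)
    note("extract top/bottom", length(pooled),
         length(tops) + length(bottoms))
  } else {
    forest <- NULL
    classes <- list(legacy = pooled)
  }
  resList <- list()
  for (cl in names(classes)) {
    gr <- classes[[cl]]
    if (!length(gr)) next
    cm <- buildCountMatrix(gr, tables)
    de <- callDEClusters(
      exactTestMatrix(cm$counts, cm$libSizes, conditions),
      cfg$minAbsLogFC, cfg$alpha)
    mcols(gr) <- cbind(mcols(gr),
                       S4Vectors::DataFrame(cluster = clusterIds(gr),
                                            class = cl, de))
    resList[[cl]] <- gr
    note(paste0("exact test (", cl, ")"), length(gr),
         sum(de$significant))
  }
  clusters <- if (length(resList)) unname(do.call(c, unname(resList)))
              else GRanges()
  geneCalls <- NULL
  if (!is.null(geneTSS) && length(clusters)) {
    asg <- assignClusters(clusters, geneTSS, cfg$promoterWindow)
    calls <- data.frame(cluster = clusters$cluster,
                        class = clusters$class,
                        significant = clusters$significant)
    geneCalls <- callDEGenes(calls, asg$assignments)
    note("gene calls", nrow(geneCalls), sum(geneCalls$called))
  }
  list(mode = mode, perCondition = perCondition, forest = forest,
       clusters = clusters, geneCalls = geneCalls, idrFits = idrFits,
       stageCounts = do.call(rbind, stages), config = cfg)
}

#' Partition differentially expressed genes between two modes
#'
#' Splits the union of called genes into those detected by both runs and
#' those unique to either (the usual method-comparison summary).
#'
#' @param callsA,callsB `geneCalls` data.frames from [runPipeline()] (only
#'   rows with `called == TRUE` count as detected).
#' @return list with character vectors `both`, `onlyA`, `onlyB` and a
#'   `counts` summary.
#' @export
compareModes <- function(callsA, callsB) {
  a <- if (is.null(callsA)) character() else callsA$gene[callsA$called]
  b <- if (is.null(callsB)) character() else callsB$gene[callsB$called]
  out <- list(both = sort(intersect(a, b)), onlyA = sort(setdiff(a, b)),
              onlyB = sort(setdiff(b, a)))
  out$counts <- c(both = length(out$both), onlyA = length(out$onlyA),
                  onlyB = length(out$onlyB))
  out
}

#' Write pipeline results as browser-loadable text
#'
#' Writes, per peak class, a BED6 track (score = hierarchical-stability
#' rank surrogate: the combined replicate score, capped at 1000) and a full
#' tab-separated results table, plus the stage-count log. All output is
#' plain text and deterministic, so identical runs produce byte-identical
#' files.
#'
#' @param result a [runPipeline()] result.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
writeResults <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  gr <- result$clusters
  if (length(gr)) {
    for (cl in unique(gr$class)) {
      g <- gr[gr$class == cl]
      bed <- file.path(dir, paste0("peaks_", cl, ".bed"))
      score <- pmin(round(g$scoreA + g$scoreB), 1000L)
      writeLines(paste(seqnames(g), start(g) - 1L, end(g), g$cluster,
                       score, strand(g), sep = "\t"), bed)
      tsv <- file.path(dir, paste0("results_", cl, ".tsv"))
      df <- as.data.frame(mcols(g))
      df <- cbind(chrom = as.character(seqnames(g)), start = start(g) - 1L,
                  end = end(g), strand = as.character(strand(g)), df)
      con <- file(tsv, "w")
      writeLines(paste0("#", paste(colnames(df), collapse = "\t")), con)
      utils::write.table(format(df, digits = 10, trim = TRUE), con,
                         sep = "\t", quote = FALSE, row.names = FALSE,
                         col.names = FALSE)
      close(con)
      paths <- c(paths, bed, tsv)
    }
  }
  if (!is.null(result$geneCalls)) {
    gp <- file.path(dir, "gene_calls.tsv")
    utils::write.table(result$geneCalls, gp, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths <- c(paths, gp)
  }
  sp <- file.path(dir, "stage_counts.tsv")
  utils::write.table(result$stageCounts, sp, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(paths, sp))
}
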