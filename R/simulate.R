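#' Configuration for the CTSS simulator
#'
#' Describes the synthetic study the simulator emulates: a set of promoters
#' on one chromosome, each a broad peak (50-200 bp) containing 1-5 narrow
#' sub-peaks (1-10 bp) over a sparse per-base background - the laminar
#' architecture that multi-scale clustering is designed to recover - with
#' negative-binomial tag counts, tunable replicate concordance, and planted
#' differential expression including sub-peak-only TSS shifts that leave the
#' whole-promoter output unchanged.
#'
#' Counts are Gamma-Poisson: a promoter-level Gamma factor (dispersion
#' `phiPromoter`) is shared by all samples and creates the correlated
#' replicate scores the IDR model assumes, while an independent per-sample
#' Gamma factor (dispersion `phiRep`) creates between-replicate
#' overdispersion for the differential test.
#'
#' @param genomeLength simulated chromosome length in bp.
#' @param nPromoters number of promoters.
#' @param broadWidthRange,broadSiteFrac broad-peak width range (bp) and the
#'   fraction of broad bases carrying a background CTSS site.
#' @param nSubRange,subWidthRange number and width range of sub-peaks
#'   (kept strictly inside the broad peak).
#' @param meanTags expected tags per promoter per sample.
#' @param bgShare share of a promoter's signal in its broad background.
#' @param phiRep per-sample NB dispersion of site counts.
#' @param phiPromoter dispersion of the shared promoter-level factor.
#' @param irreproducibleFrac fraction of promoters emitted in a single
#'   replicate only (spurious, replicate-specific signal).
#' @param noiseRate background noise sites per bp per sample.
#' @param deWholeFrac,deShiftFrac,fold fractions of reproducible promoters
#'   with whole-promoter differential expression and with a sub-peak-only
#'   shift, and the planted fold change.
#' @param nReps replicates per condition (two conditions are simulated).
#' @param seed integer seed; the same config is byte-reproducible.
#' @return a validated config list of class `"simConfig"`.
#' @export
simConfig <- function(genomeLength = 1e6, nPromoters = 40,
                      broadWidthRange = c(50, 200), broadSiteFrac = 1 / 3,
                      nSubRange = c(1, 5), subWidthRange = c(1, 10),
                      meanTags = 400, bgShare = 0.3, phiRep = 0.05,
                      phiPromoter = 0.15, irreproducibleFrac = 0.1,
                      noiseRate = 2e-5, deWholeFrac = 0.2,
                      deShiftFrac = 0.2, fold = 8, nReps = 2, seed = 1) {
  cfg <- list(genomeLength = genomeLength, nPromoters = nPromoters,
              broadWidthRange = broadWidthRange,
              broadSiteFrac = broadSiteFrac, nSubRange = nSubRange,
              subWidthRange = subWidthRange, meanTags = meanTags,
              bgShare = bgShare, phiRep = phiRep,
              phiPromoter = phiPromoter,
              irreproducibleFrac = irreproducibleFrac,
              noiseRate = noiseRate, deWholeFrac = deWholeFrac,
              deShiftFrac = deShiftFrac, fold = fold, nReps = nReps,
              seed = seed)
  fr <- c(broadSiteFrac, bgShare, irreproducibleFrac, deWholeFrac,
          deShiftFrac)
  if (any(fr < 0) || any(fr > 1))
    stop("all fractions must lie in [0, 1]")
  if (deWholeFrac + deShiftFrac > 1)
    stop("DE fractions must sum to at most 1")
  if (any(c(phiRep, phiPromoter, noiseRate, meanTags) < 0) || fold < 1)
    stop("rates must be non-negative and fold >= 1")
  if (broadSiteFrac <= 0)
    stop("broadSiteFrac must be positive")
  spacing <- floor((genomeLength - 4000) / nPromoters)
  if (spacing < broadWidthRange[2L] + 2500)
    stop("genome too short for this many promoters")
  class(cfg) <- "simConfig"
  cfg
}

## Uniform draw from an explicit candidate vector (immune to R's
## sample()-on-scalar surprise).
pick1 <- function(v) v[sample.int(length(v), 1L)]

## Architecture: promoter intervals, per-site means per condition, truth.
simArchitecture <- function(cfg) {
  n <- cfg$nPromoters
  spacing <- floor((cfg$genomeLength - 4000) / n)
  nRepro <- round(n * (1 - cfg$irreproducibleFrac))
  repro <- seq_len(n) <= nRepro
  deClass <- rep("none", n)
  nW <- round(nRepro * cfg$deWholeFrac)
  nS <- round(nRepro * cfg$deShiftFrac)
  deClass[seq_len(nW)] <- "whole"
  deClass[nW + seq_len(nS)] <- "shift"
  ## which single sample carries an irreproducible promoter
  privCond <- sample(1:2, n, replace = TRUE)
  privRep <- sample(seq_len(cfg$nReps), n, replace = TRUE)
  ## alternate whole-promoter DE direction so that expected library sizes
  ## stay balanced between conditions (total-count normalisation is the
  ## pipeline's library model)
  wholeUp <- cumsum(deClass == "whole") %% 2L == 1L
  sites <- list()
  truth <- list()
  for (p in seq_len(n)) {
    broadW <- pick1(cfg$broadWidthRange[1L]:cfg$broadWidthRange[2L])
    nSub <- pick1(cfg$nSubRange[1L]:cfg$nSubRange[2L])
    if (deClass[p] == "shift") nSub <- max(nSub, 2L)
    bStart <- 2000L + (p - 1L) * spacing + pick1(0:500)
    bEnd <- bStart + broadW - 1L
    strand <- pick1(c("+", "-"))
    slotW <- (broadW - 2L) %/% nSub
    if (slotW < 2L)
      stop("infeasible architecture: sub-peaks do not fit the broad peak")
    subs <- lapply(seq_len(nSub), function(k) {
      w <- min(pick1(cfg$subWidthRange[1L]:cfg$subWidthRange[2L]),
               slotW - 1L)
      s0 <- bStart + 1L + (k - 1L) * slotW + pick1(0:(slotW - w - 1L))
      c(s0, s0 + w - 1L)
    })
    if (any(vapply(subs, `[`, numeric(1), 1L) <= bStart) ||
        any(vapply(subs, `[`, numeric(1), 2L) >= bEnd))
      stop("infeasible architecture: sub-peak outside the broad peak")
    subPos <- unlist(lapply(subs, function(s) s[1L]:s[2L]))
    bgPos <- setdiff(seq(bStart, bEnd,
                         by = max(1L, round(1 / cfg$broadSiteFrac))),
                     subPos)
    ## intensity shares
    shareA <- if (deClass[p] == "shift") min(0.1, 0.8 / cfg$fold) else NA
    subShare <- rep((1 - cfg$bgShare) / nSub, nSub)
    if (deClass[p] == "shift") {
      subShare <- rep((1 - cfg$bgShare - shareA) / (nSub - 1L), nSub)
      subShare[1L] <- shareA
    }
    mean1 <- numeric(0)
    pos <- integer(0)
    part <- integer(0)   # 0 = background, k = sub-peak k
    for (k in seq_len(nSub)) {
      kp <- subs[[k]][1L]:subs[[k]][2L]
      pos <- c(pos, kp)
      part <- c(part, rep(k, length(kp)))
      mean1 <- c(mean1, rep(cfg$meanTags * subShare[k] / length(kp),
                            length(kp)))
    }
    if (length(bgPos)) {
      pos <- c(pos, bgPos)
      part <- c(part, rep(0L, length(bgPos)))
      mean1 <- c(mean1, rep(cfg$meanTags * cfg$bgShare / length(bgPos),
                            length(bgPos)))
    }
    fold1 <- rep(1, length(pos))
    fold2 <- rep(1, length(pos))
    lfc <- rep(0, nSub + 1L)   # per part: background + subs
    if (deClass[p] == "whole") {
      ## mirror the direction (elevate condition 1 instead of dividing
      ## condition 2) so up- and down-regulated promoters contribute the
      ## same expected library mass to each condition
      if (wholeUp[p]) fold2[] <- cfg$fold else fold1[] <- cfg$fold
      lfc[] <- if (wholeUp[p]) log2(cfg$fold) else -log2(cfg$fold)
    } else if (deClass[p] == "shift") {
      comp <- (1 - cfg$fold * shareA) / (1 - shareA)
      fold2[part == 1L] <- cfg$fold
      fold2[part != 1L] <- comp
      lfc <- c(log2(comp), log2(cfg$fold), rep(log2(comp), nSub - 1L))
    }
    sites[[p]] <- data.frame(promoter = p, pos = pos, strand = strand,
                             mean1 = mean1 * fold1, mean2 = mean1 * fold2)
    truth[[p]] <- data.frame(
      promoter = p, type = c("broad", rep("sub", nSub)),
      subIndex = c(NA_integer_, seq_len(nSub)),
      start = c(bStart, vapply(subs, `[`, numeric(1), 1L)),
      end = c(bEnd, vapply(subs, `[`, numeric(1), 2L)),
      strand = strand, reproducible = repro[p], deClass = deClass[p],
      trueLog2FC = if (deClass[p] == "shift") c(0, lfc[-1L])
                   else lfc[c(1L, seq_len(nSub) + 1L)],
      shifted = c(FALSE, seq_len(nSub) == 1L & deClass[p] == "shift"),
      privCond = privCond[p], privRep = privRep[p])
  }
  list(sites = do.call(rbind, sites), truth = do.call(rbind, truth),
       repro = repro)
}

#' Simulate replicate CTSS tables with known truth
#'
#' Generates two conditions with `nReps` replicates each from a
#' [simConfig()], together with a machine-readable truth table of the
#' planted intervals, reproducibility flags and true fold changes. The
#' output is deterministic given the config (including its seed).
#'
#' @param cfg a [simConfig()].
#' @param sampleSeeds optional integer matrix (2 x nReps) of per-sample
#'   seeds; defaults are derived from `cfg$seed`. Passing equal seeds with
#'   `phiRep = 0`, `noiseRate = 0` and `irreproducibleFrac = 0` yields
#'   byte-identical replicates.
#' @return list with `tables` (named list of [CTSStable]s,
#'   `cond<c>_rep<r>`), `conditions` (factor per table), `truth`
#'   (data.frame of planted intervals, 1-based inclusive coordinates) and
#'   `config`.
#' @examples
#' sim <- simulateCTSS(simConfig(nPromoters = 5, seed = 42))
#' names(sim$tables)
#' head(sim$truth)
#' @export
simulateCTSS <- function(cfg, sampleSeeds = NULL) {
  stopifnot(inherits(cfg, "simConfig"))
  set.seed(cfg$seed)
  arch <- simArchitecture(cfg)
  nProm <- cfg$nPromoters
  gShared <- if (cfg$phiPromoter > 0)
    rgamma(nProm, shape = 1 / cfg$phiPromoter, scale = cfg$phiPromoter)
  else rep(1, nProm)
  if (is.null(sampleSeeds))
    sampleSeeds <- matrix((cfg$seed %% 10000000L) * 100L +
                            rep(1:2, each = cfg$nReps) * 10L +
                            rep(seq_len(cfg$nReps), 2L),
                          nrow = 2L, byrow = TRUE)
  tables <- list()
  conds <- character(0)
  tr <- arch$truth[arch$truth$type == "broad", ]
  for (cond in 1:2) {
    for (r in seq_len(cfg$nReps)) {
      set.seed(sampleSeeds[cond, r])
      s <- arch$sites
      ## replicate-specific promoters appear in exactly one sample
      keepProm <- tr$reproducible |
        (tr$privCond == cond & tr$privRep == r)
      s <- s[keepProm[s$promoter], ]
      mu <- (if (cond == 1L) s$mean1 else s$mean2) *
        gShared[s$promoter]
      if (cfg$phiRep > 0) {
        h <- rgamma(nProm, shape = 1 / cfg$phiRep, scale = cfg$phiRep)
        mu <- mu * h[s$promoter]
      }
      cnt <- rpois(length(mu), mu)
      pos <- s$pos; str <- s$strand
      if (cfg$noiseRate > 0) {
        nNoise <- rpois(1L, cfg$noiseRate * cfg$genomeLength)
        if (nNoise > 0) {
          pos <- c(pos, sample.int(cfg$genomeLength, nNoise))
          str <- c(str, sample(c("+", "-"), nNoise, replace = TRUE))
          cnt <- c(cnt, 1L + rpois(nNoise, 0.5))
        }
      }
      ok <- cnt > 0
      if (!any(ok)) {
        tb <- CTSStable()
      } else {
        key <- paste(str[ok], pos[ok])
        agg <- rowsum(cnt[ok], key)
        parts <- strsplit(rownames(agg), " ", fixed = TRUE)
        tb <- CTSStable(chrom = "chrS",
                        pos = as.integer(vapply(parts, `[`, "", 2L)),
                        strand = vapply(parts, `[`, "", 1L),
                        count = as.integer(agg[, 1L]))
      }
      nm <- sprintf("cond%d_rep%d", cond, r)
      tables[[nm]] <- tb
      conds <- c(conds, sprintf("cond%d", cond))
    }
  }
  list(tables = tables, conditions = factor(conds), truth = arch$truth,
       siteMeans = arch$sites, config = cfg)
}

#' Gene TSS annotation for a simulated truth table
#'
#' Creates one gene per planted promoter, with its TSS at the 5' end of the
#' broad peak (strand-aware), for use with [assignClusters()] and gene-level
#' differential calls.
#'
#' @param truth truth table from [simulateCTSS()].
#' @param chrom chromosome name used by the simulator.
#' @return width-1 `GRanges` with a `gene` column.
#' @export
truthGeneTSS <- function(truth, chrom = "chrS") {
  b <- truth[truth$type == "broad", ]
  tss <- ifelse(b$strand == "-", b$end, b$start)
  gr <- GRanges(chrom, IRanges(tss, width = 1L), strand = b$strand)
  gr$gene <- sprintf("gene%03d", b$promoter)
  gr
}
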