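#' Build a cluster-by-sample count matrix
#'
#' Counts, for every cluster interval and every sample, the CTSS tags
#' falling inside the interval on the same strand.
#'
#' @param clusters `GRanges` of clusters (rows).
#' @param tables named list of [CTSStable]s (columns).
#' @return a list with integer matrix `counts` and numeric `libSizes`
#'   (per-sample total CTSS counts).
#' @export
buildCountMatrix <- function(clusters, tables) {
  counts <- vapply(tables, function(tb) countInIntervals(clusters, tb),
                   integer(length(clusters)))
  if (length(clusters) == 1L)
    counts <- matrix(counts, nrow = 1L, dimnames = list(NULL, names(tables)))
  libSizes <- vapply(tables, librarySize, numeric(1))
  if (any(libSizes <= 0)) stop("all library sizes must be positive")
  list(counts = counts, libSizes = libSizes)
}

## Counts rescaled to the geometric-mean library size (rounded to integers).
equalizeCounts <- function(counts, libSizes) {
  ref <- exp(mean(log(libSizes)))
  round(sweep(counts, 2L, ref / libSizes, `*`))
}

## Conditional log-likelihood of within-group counts given their sum for n
## iid NB observations with dispersion phi (phi = 0 is the multinomial /
## Poisson limit); only rows of y from one group.
condLogLik <- function(y, phi) {
  n <- ncol(y)
  s <- rowSums(y)
  if (phi == 0)
    return(sum(lgamma(s + 1)) - sum(lgamma(y + 1)) - sum(s) * log(n))
  r <- 1 / phi
  sum(lgamma(y + r)) - length(y) * lgamma(r) - sum(lgamma(y + 1)) -
    sum(lgamma(s + n * r)) + nrow(y) * lgamma(n * r) + sum(lgamma(s + 1))
}

#' Estimate a common negative-binomial dispersion
#'
#' Maximizes the conditional likelihood of the within-group counts given the
#' group sums, on counts equalized to a common (geometric-mean) library
#' size, over a single dispersion `phi` shared by all clusters
#' (`variance = mu + phi * mu^2`; `phi = 0` is the Poisson limit and is an
#' admissible boundary estimate). With only one replicate per group the
#' conditional likelihood carries no information and a configured default is
#' returned with a warning.
#'
#' @param counts integer matrix, clusters x samples.
#' @param libSizes per-sample library sizes.
#' @param groups factor (two levels) of sample conditions.
#' @param fallback dispersion used when no group has two replicates.
#' @return a list with `phi` and `method`.
#' @export
estimateCommonDispersion <- function(counts, libSizes, groups,
                                     fallback = 0.1) {
  groups <- as.factor(groups)
  y <- equalizeCounts(counts, libSizes)
  ok <- table(groups) >= 2
  if (!any(ok)) {
    warning("no condition has >= 2 replicates; using fallback dispersion ",
            fallback)
    return(list(phi = fallback, method = "fallback"))
  }
  grps <- names(ok)[ok]
  f <- function(phi)
    sum(vapply(grps, function(g) condLogLik(y[, groups == g, drop = FALSE],
                                            phi), numeric(1)))
  opt <- optimize(f, interval = c(1e-6, 10), maximum = TRUE)
  phi <- if (f(0) >= opt$objective) 0 else opt$maximum
  list(phi = phi, method = "conditional maximum likelihood")
}

#' Negative-binomial exact test for one cluster
#'
#' Conditional two-sided exact test comparing the two group sums of counts
#' given their total, under independent negative-binomial group sums with
#' means proportional to group sizes and a shared dispersion `phi`. Counts
#' are first equalized to the geometric-mean library size. The p-value sums
#' the conditional probabilities of all outcomes at most as probable as the
#' observed one ("small-p" rejection region); at `phi = 0` the conditional
#' law is binomial.
#'
#' @param y1,y2 count vectors for group 1 and group 2 (one value per
#'   sample).
#' @param lib1,lib2 library sizes for the two groups.
#' @param phi common NB dispersion (>= 0).
#' @param priorCount prior count added per group for the log fold change.
#' @return list with `pvalue`, `logFC` (log2, group 2 vs group 1) and
#'   `logConc` (log2 mean normalized abundance).
#' @examples
#' nbExactTest(0, 10, 1e6, 1e6, phi = 0)$pvalue   # 2/1024
#' @export
nbExactTest <- function(y1, y2, lib1, lib2, phi, priorCount = 0.5) {
  if (phi < 0) stop("dispersion must be non-negative")
  n1 <- length(y1); n2 <- length(y2)
  stopifnot(length(lib1) == n1, length(lib2) == n2)
  ref <- exp(mean(log(c(lib1, lib2))))
  Y1 <- round(sum(y1 * ref / lib1))
  Y2 <- round(sum(y2 * ref / lib2))
  s <- Y1 + Y2
  logConc <- log2((Y1 + Y2 + 2 * priorCount) / (n1 + n2)) - log2(ref)
  logFC <- log2((Y2 + priorCount) / n2) - log2((Y1 + priorCount) / n1)
  if (s == 0)
    return(list(pvalue = 1, logFC = 0, logConc = logConc))
  mu <- s / (n1 + n2)
  yy <- 0:s
  lp <- if (phi == 0) {
    dpois(yy, n1 * mu, log = TRUE) + dpois(s - yy, n2 * mu, log = TRUE)
  } else {
    dnbinom(yy, size = n1 / phi, mu = n1 * mu, log = TRUE) +
      dnbinom(s - yy, size = n2 / phi, mu = n2 * mu, log = TRUE)
  }
  w <- exp(lp - max(lp))
  pobs <- w[Y1 + 1]
  p <- sum(w[w <= pobs * (1 + 1e-10)]) / sum(w)
  list(pvalue = min(p, 1), logFC = logFC, logConc = logConc)
}

#' Benjamini-Hochberg adjustment with input validation
#'
#' Step-up false discovery rate adjustment (via [stats::p.adjust()]) after
#' checking that all p-values lie in `[0, 1]`.
#'
#' @param pvalues numeric vector of raw p-values.
#' @return adjusted p-values, same length and order.
#' @export
bhAdjust <- function(pvalues) {
  if (anyNA(pvalues) || any(pvalues < 0) || any(pvalues > 1))
    stop("p-values must lie in [0, 1]")
  p.adjust(pvalues, method = "BH")
}

#' Run the exact test over a count matrix
#'
#' Applies [estimateCommonDispersion()] and [nbExactTest()] row-wise and
#' adjusts p-values with [bhAdjust()].
#'
#' @param counts integer matrix, clusters x samples.
#' @param libSizes per-sample library sizes.
#' @param groups two-level factor of sample conditions; the fold change is
#'   level 2 versus level 1.
#' @param phi optional fixed dispersion; estimated when `NULL`.
#' @return a data.frame with `logFC`, `logConc`, `pvalue`, `padj` (one row
#'   per cluster, input order).
#' @export
exactTestMatrix <- function(counts, libSizes, groups, phi = NULL) {
  groups <- as.factor(groups)
  stopifnot(nlevels(groups) == 2L, ncol(counts) == length(groups))
  if (is.null(phi))
    phi <- estimateCommonDispersion(counts, libSizes, groups)$phi
  g1 <- groups == levels(groups)[1L]
  g2 <- groups == levels(groups)[2L]
  res <- lapply(seq_len(nrow(counts)), function(k)
    nbExactTest(counts[k, g1], counts[k, g2], libSizes[g1], libSizes[g2],
                phi = phi))
  data.frame(logFC = vapply(res, `[[`, 0, "logFC"),
             logConc = vapply(res, `[[`, 0, "logConc"),
             pvalue = vapply(res, `[[`, 0, "pvalue"),
             padj = bhAdjust(vapply(res, `[[`, 0, "pvalue")))
}

#' Flag significantly differentially expressed clusters
#'
#' A cluster is significant when `|logFC| > minAbsLogFC` (strict) and
#' `padj < alpha` (strict); the defaults reproduce the usual
#' "absolute log fold change > 2 and adjusted p < 0.05" call.
#'
#' @param results data.frame from [exactTestMatrix()].
#' @param minAbsLogFC minimum absolute log2 fold change (exclusive).
#' @param alpha adjusted-p cutoff (exclusive).
#' @return `results` with a logical `significant` column appended.
#' @export
callDEClusters <- function(results, minAbsLogFC = 2, alpha = 0.05) {
  results$significant <- abs(results$logFC) > minAbsLogFC &
    results$padj < alpha
  results
}

#' Gene-level differential-expression calls
#'
#' A gene is called differentially expressed when its promoter contains at
#' least one significantly differentially expressed top or bottom cluster;
#' the trigger classes record which peak class produced the call (a gene can
#' show a significant narrow (top) peak while its broad (bottom) peak is
#' unchanged - the TSS-shift signature).
#'
#' @param clusterCalls data.frame with columns `cluster`, `class` (e.g.
#'   "top" / "bottom") and `significant`.
#' @param clusterToGene data.frame with columns `cluster` and `gene`
#'   (clusters may map to several genes; each mapped gene is evaluated).
#' @return data.frame with `gene`, `called` and `trigger` (comma-separated
#'   classes with a significant cluster, `""` if none).
#' @export
callDEGenes <- function(clusterCalls, clusterToGene) {
  m <- merge(clusterToGene, clusterCalls, by = "cluster")
  genes <- sort(unique(clusterToGene$gene))
  trig <- vapply(genes, function(g) {
    cls <- sort(unique(m$class[m$gene == g & m$significant]))
    paste(cls, collapse = ",")
  }, character(1))
  data.frame(gene = genes, called = nzchar(trig), trigger = trig,
             row.names = NULL)
}
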