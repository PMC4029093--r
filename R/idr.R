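#' Merge two replicate cluster sets by reciprocal overlap
#'
#' A cluster pair (a, b) on the same strand matches when the overlap covers
#' at least `minFrac` of the width of *both* clusters (reciprocal overlap;
#' default 0.9, inclusive). Matching is resolved greedily: candidate pairs
#' are ranked by the smaller of their two overlap fractions (ties broken by
#' larger overlap length, then leftmost), and each input cluster joins at
#' most one output pair. Each merged cluster takes the intersection
#' coordinates and carries the two hierarchical stabilities as `scoreA` /
#' `scoreB`.
#'
#' @param a,b [ClusterSet]s from two replicates of the same sample, with
#'   `hierStability` populated (see [addHierStability()]).
#' @param minFrac reciprocal overlap fraction, in (0, 1].
#' @return a [MergedClusters] object (IDR columns `NA` until [fitIDR()]).
#' @export
mergeReplicates <- function(a, b, minFrac = 0.9) {
  stopifnot(is(a, "ClusterSet"), is(b, "ClusterSet"))
  if (minFrac <= 0 || minFrac > 1)
    stop("minFrac must lie in (0, 1]")
  gra <- a@ranges
  grb <- b@ranges
  hits <- findOverlaps(gra, grb)   # strand-aware
  qh <- queryHits(hits); sh <- subjectHits(hits)
  ov <- width(pintersect(ranges(gra)[qh], ranges(grb)[sh]))
  fa <- ov / width(gra)[qh]
  fb <- ov / width(grb)[sh]
  ok <- fa >= minFrac & fb >= minFrac
  qh <- qh[ok]; sh <- sh[ok]; ov <- ov[ok]
  frac <- pmin(fa[ok], fb[ok])
  istart <- pmax(start(gra)[qh], start(grb)[sh])
  o <- order(-frac, -ov, istart)
  usedA <- logical(length(gra)); usedB <- logical(length(grb))
  pick <- logical(length(qh))
  for (k in o) {
    if (!usedA[qh[k]] && !usedB[sh[k]]) {
      pick[k] <- TRUE
      usedA[qh[k]] <- TRUE
      usedB[sh[k]] <- TRUE
    }
  }
  qh <- qh[pick]; sh <- sh[pick]
  gr <- GRanges(seqnames(gra)[qh],
                IRanges(pmax(start(gra)[qh], start(grb)[sh]),
                        pmin(end(gra)[qh], end(grb)[sh])),
                strand = strand(gra)[qh])
  gr$scoreA <- gra$hierStability[qh]
  gr$scoreB <- grb$hierStability[sh]
  gr$localIDR <- rep(NA_real_, length(gr))
  gr$globalIDR <- rep(NA_real_, length(gr))
  gr <- sort(gr, ignore.strand = FALSE)
  new("MergedClusters", ranges = gr)
}

## Bivariate normal log-density with common sd and correlation.
logBVN <- function(z1, z2, mu, sigma, rho) {
  a <- (z1 - mu) / sigma
  b <- (z2 - mu) / sigma
  -log(2 * pi * sigma^2 * sqrt(1 - rho^2)) -
    (a^2 - 2 * rho * a * b + b^2) / (2 * (1 - rho^2))
}

## Proper log-likelihood of the copula mixture for rank data u1, u2:
## z-space mixture density at the pseudo-scores divided by the marginal
## Jacobian (invariant to the latent location/scale).
copulaLL <- function(u1, u2, pi1, mu, sigma, rho) {
  z <- mixInvCDF(c(u1, u2), pi1, mu, sigma)
  z1 <- z[seq_along(u1)]
  z2 <- z[length(u1) + seq_along(u2)]
  l1 <- logBVN(z1, z2, mu, sigma, rho)
  l0 <- logBVN(z1, z2, 0, 1, 0)
  m <- pmax(l1, l0)
  mix <- m + log(pi1 * exp(l1 - m) + (1 - pi1) * exp(l0 - m))
  jac <- log(pi1 * dnorm(z1, mu, sigma) + (1 - pi1) * dnorm(z1)) +
    log(pi1 * dnorm(z2, mu, sigma) + (1 - pi1) * dnorm(z2))
  sum(mix - jac)
}

## Invert the mixture marginal CDF
##   G(z) = pi1 * pnorm(z, mu, sigma) + (1 - pi1) * pnorm(z)
## by vectorised bisection.
mixInvCDF <- function(u, pi1, mu, sigma) {
  lo <- min(qnorm(min(u)), qnorm(min(u), mu, sigma)) - 0.5
  hi <- max(qnorm(max(u)), qnorm(max(u), mu, sigma)) + 0.5
  zg <- seq(lo, hi, length.out = 4096L)
  Gg <- pi1 * pnorm(zg, mu, sigma) + (1 - pi1) * pnorm(zg)
  keep <- !duplicated(Gg)
  stats::approx(Gg[keep], zg[keep], xout = u, rule = 2)$y
}

#' Fit the IDR copula mixture to paired replicate scores
#'
#' Fits the two-component Gaussian copula mixture of the irreproducible
#' discovery rate to paired scores (here, hierarchical stabilities) from two
#' replicates. Scores enter only through their ranks: each replicate is
#' rank-transformed (average ranks for ties, scaled by `1 / (n + 1)`),
#' mapped to pseudo-scores through the inverse of the current mixture
#' marginal CDF, and the mixture parameters `(pi1, mu, sigma, rho)` are
#' updated by EM until the pseudo-log-likelihood changes by less than
#' `tol`; the fit is then polished by direct maximisation of the proper
#' copula likelihood from several starts. The convergence trace is the
#' copula (Jacobian-corrected) log-likelihood, which unlike the raw
#' z-space quantity cannot be inflated by rescaling the latent axes; see
#' the package vignette for why this matters on concordance-free data.
#'
#' The local IDR of a pair is the posterior probability that it belongs to
#' the irreproducible (independent standard normal) component; the global
#' IDR at rank r is the mean of the r smallest local IDRs, i.e. the expected
#' irreproducibility rate of the set obtained by keeping the r most
#' reproducible pairs.
#'
#' @param scoreA,scoreB numeric score vectors, one value per merged cluster
#'   (at least 20 pairs; scores need only be rank-meaningful).
#' @param init named list of starting values `pi1`, `mu`, `sigma`, `rho`.
#' @param tol convergence tolerance on the pseudo-log-likelihood.
#' @param maxIter maximum EM iterations (warning on non-convergence; the
#'   best-so-far fit is returned).
#' @param rhoMin lower bound kept on the reproducible component's
#'   correlation. Positive association is what defines reproducibility in
#'   this model; without the bound the mixture is unidentifiable on
#'   concordance-free data (any labelling fits equally well) and the EM can
#'   drift to calling everything reproducible. Data whose true correlation
#'   is below `rhoMin` are reported irreproducible.
#' @return an [IDRFit].
#' @examples
#' set.seed(1)
#' sim <- simulateIDRPairs(500, pi1 = 0.7, mu = 2.6, sigma = 1.3, rho = 0.8)
#' fitIDR(sim$scoreA, sim$scoreB)
#' @export
fitIDR <- function(scoreA, scoreB,
                   init = list(pi1 = 0.7, mu = 2.6, sigma = 1.3, rho = 0.8),
                   tol = 1e-4, maxIter = 200, rhoMin = 0.1) {
  n <- length(scoreA)
  if (length(scoreB) != n)
    stop("scoreA and scoreB must have equal length")
  if (n < 20)
    stop("need at least 20 pairs to fit the mixture")
  if (length(unique(scoreA)) == 1L || length(unique(scoreB)) == 1L)
    stop("degenerate ranks: constant scores in a replicate")
  u1 <- rank(scoreA, ties.method = "average") / (n + 1)
  u2 <- rank(scoreB, ties.method = "average") / (n + 1)
  pi1 <- init$pi1; mu <- init$mu; sigma <- init$sigma; rho <- init$rho
  trace <- numeric(0)
  post <- rep(pi1, n)
  bestPost <- post
  best <- c(pi1, mu, sigma, rho)
  prevLL <- -Inf
  converged <- FALSE
  for (iter in seq_len(maxIter)) {
    z <- mixInvCDF(c(u1, u2), pi1, mu, sigma)
    z1 <- z[seq_len(n)]
    z2 <- z[n + seq_len(n)]
    ## E step
    l1 <- logBVN(z1, z2, mu, sigma, rho)
    l0 <- logBVN(z1, z2, 0, 1, 0)
    m <- pmax(l1, l0)
    d1 <- pi1 * exp(l1 - m)
    d0 <- (1 - pi1) * exp(l0 - m)
    post <- d1 / (d1 + d0)
    ## pseudo-log-likelihood on the copula (rank) scale: the z-space
    ## mixture density divided by the marginal Jacobian, so that the trace
    ## is invariant to the location/scale of the latent parametrisation
    ## and cannot be inflated by degenerate single-component fits
    jac <- log(pi1 * dnorm(z1, mu, sigma) + (1 - pi1) * dnorm(z1)) +
      log(pi1 * dnorm(z2, mu, sigma) + (1 - pi1) * dnorm(z2))
    ll <- sum(m + log(d1 + d0) - jac)
    if (ll < prevLL) {
      ## a decrease means the parameter path has left the likelihood
      ## ridge; keep the best-so-far fit
      pi1 <- best[1L]; mu <- best[2L]; sigma <- best[3L]; rho <- best[4L]
      post <- bestPost
      converged <- TRUE
      break
    }
    trace <- c(trace, ll)
    bestPost <- post
    best <- c(pi1, mu, sigma, rho)
    if (iter > 1 && ll - prevLL < tol) {
      converged <- TRUE
      break
    }
    prevLL <- ll
    ## M step
    sk <- sum(post)
    pi1 <- min(max(sk / n, 1e-4), 1 - 1e-4)
    mu <- max(sum(post * (z1 + z2)) / (2 * sk), 0)
    sigma <- sqrt(sum(post * ((z1 - mu)^2 + (z2 - mu)^2)) / (2 * sk))
    sigma <- min(max(sigma, 0.5), 10)
    rho <- sum(post * (z1 - mu) * (z2 - mu)) / (sk * sigma^2)
    rho <- min(max(rho, rhoMin), 0.999)
  }
  if (!converged)
    warning("IDR EM did not converge in ", maxIter,
            " iterations; returning best-so-far fit")
  ## Likelihood polish: the moment-based EM updates do not account for the
  ## dependence of the rank inversion on the parameters, so they can climb
  ## a spurious ridge when the two components are poorly separated (e.g.
  ## concordance-free data). Re-maximise the proper copula likelihood
  ## directly from several starts and keep the best solution.
  obj <- function(p) -copulaLL(u1, u2, p[1L], p[2L], p[3L], p[4L])
  starts <- list(c(pi1, mu, sigma, rho),
                 c(init$pi1, init$mu, init$sigma, max(init$rho, rhoMin)),
                 c(0.05, init$mu, init$sigma, rhoMin))
  bestPar <- c(pi1, mu, sigma, rho)
  bestVal <- obj(bestPar)
  for (st in starts) {
    o <- tryCatch(
      optim(st, obj, method = "L-BFGS-B",
            lower = c(1e-3, 0, 0.5, rhoMin),
            upper = c(1 - 1e-3, 10, 10, 0.999),
            control = list(maxit = 60, factr = 1e9)),
      error = function(e) NULL)
    if (!is.null(o) && o$value < bestVal) {
      bestVal <- o$value
      bestPar <- o$par
    }
  }
  pi1 <- bestPar[1L]; mu <- bestPar[2L]; sigma <- bestPar[3L]
  rho <- bestPar[4L]
  z <- mixInvCDF(c(u1, u2), pi1, mu, sigma)
  z1 <- z[seq_len(n)]
  z2 <- z[n + seq_len(n)]
  l1 <- logBVN(z1, z2, mu, sigma, rho)
  l0 <- logBVN(z1, z2, 0, 1, 0)
  m <- pmax(l1, l0)
  d1 <- pi1 * exp(l1 - m)
  d0 <- (1 - pi1) * exp(l0 - m)
  post <- d1 / (d1 + d0)
  if (!length(trace) || -bestVal >= trace[length(trace)])
    trace <- c(trace, -bestVal)
  localIDR <- 1 - post
  o <- order(localIDR)
  globalIDR <- numeric(n)
  globalIDR[o] <- cumsum(localIDR[o]) / seq_len(n)
  new("IDRFit", pi1 = pi1, mu = mu, sigma = sigma, rho = rho,
      loglikTrace = trace, localIDR = localIDR, globalIDR = globalIDR,
      converged = converged)
}

#' Attach an IDR fit to merged clusters
#'
#' Fits the IDR mixture to the `scoreA` / `scoreB` columns of a
#' [MergedClusters] object and stores the per-cluster local and global IDR.
#'
#' @param merged a [MergedClusters] object.
#' @inheritParams fitIDR
#' @return a list with elements `merged` (annotated [MergedClusters]) and
#'   `fit` (the [IDRFit]).
#' @export
scoreIDR <- function(merged,
                     init = list(pi1 = 0.7, mu = 2.6, sigma = 1.3,
                                 rho = 0.8),
                     tol = 1e-4, maxIter = 200) {
  stopifnot(is(merged, "MergedClusters"))
  gr <- merged@ranges
  fit <- fitIDR(gr$scoreA, gr$scoreB, init = init, tol = tol,
                maxIter = maxIter)
  gr$localIDR <- fit@localIDR
  gr$globalIDR <- fit@globalIDR
  list(merged = new("MergedClusters", ranges = gr), fit = fit)
}

#' Keep reproducible clusters by global IDR
#'
#' Survivors have `globalIDR < threshold` (strict; clusters at exactly the
#' threshold are discarded as irreproducible). Default threshold 0.1.
#'
#' @param merged a [MergedClusters] with IDR columns populated.
#' @param threshold global IDR cutoff.
#' @export
idrFilter <- function(merged, threshold = 0.1) {
  stopifnot(is(merged, "MergedClusters"))
  gr <- merged@ranges
  if (!length(gr))
    return(merged)
  if (anyNA(gr$globalIDR))
    stop("globalIDR not populated; run scoreIDR() first")
  new("MergedClusters", ranges = gr[gr$globalIDR < threshold])
}

#' Drop over-long clusters
#'
#' Removes merged clusters wider than `maxLen` bases (strictly longer;
#' default 200, so a 200 bp cluster is kept).
#'
#' @param merged a [MergedClusters].
#' @param maxLen maximum width in bases.
#' @export
lengthFilter <- function(merged, maxLen = 200) {
  stopifnot(is(merged, "MergedClusters"))
  gr <- merged@ranges
  new("MergedClusters", ranges = gr[width(gr) <= maxLen])
}

#' Simulate paired scores from the IDR copula mixture
#'
#' Draws `n` latent pairs from the two-component model (used for parameter
#' recovery checks and worked examples): with probability `pi1` a pair is
#' bivariate normal with mean `(mu, mu)`, sd `sigma` and correlation `rho`,
#' otherwise independent standard normal.
#'
#' @param n number of pairs.
#' @param pi1,mu,sigma,rho mixture parameters.
#' @return list with `scoreA`, `scoreB` and the latent `reproducible` flag.
#' @export
simulateIDRPairs <- function(n, pi1 = 0.7, mu = 2.6, sigma = 1.3,
                             rho = 0.8) {
  k <- rbinom(n, 1L, pi1)
  z1 <- rnorm(n)
  e <- rnorm(n)
  z2 <- ifelse(k == 1L, rho * z1 + sqrt(1 - rho^2) * e, e)
  list(scoreA = ifelse(k == 1L, mu + sigma * z1, z1),
       scoreB = ifelse(k == 1L, mu + sigma * z2, z2),
       reproducible = k == 1L)
}
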