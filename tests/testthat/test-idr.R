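mkSet <- function(start, end, hs, strand = "+") {
  cs <- makeClusterSet(start, end, tagSum = 50, minD = 1, maxD = 5,
                       strand = strand)
  cs@ranges$hierStability <- rep(hs, length.out = length(start))
  cs
}

test_that("reciprocal overlap matching honours the 90% boundary", {
  # 0-based [0,100) vs [10,110): overlap 90 = 0.9 of both -> matched,
  # intersection [10,100) (1-based 11..100)
  a <- mkSet(1, 100, 7)
  b <- mkSet(11, 110, 9)
  m <- clusterRanges(mergeReplicates(a, b))
  expect_equal(length(m), 1L)
  expect_equal(c(start(m), end(m)), c(11, 100))
  expect_equal(c(m$scoreA, m$scoreB), c(7, 9))
  # identical intervals stay put
  m2 <- clusterRanges(mergeReplicates(mkSet(5, 50, 1), mkSet(5, 50, 2)))
  expect_equal(c(start(m2), end(m2)), c(5, 50))
  # 50% reciprocal overlap is no match
  expect_equal(length(mergeReplicates(mkSet(1, 100, 1), mkSet(51, 150, 1))),
               0L)
  # opposite strands never match
  expect_equal(length(mergeReplicates(mkSet(1, 100, 1),
                                      mkSet(1, 100, 1, strand = "-"))), 0L)
  expect_error(mergeReplicates(a, b, minFrac = 0), "minFrac")
  expect_error(mergeReplicates(a, b, minFrac = 1.2), "minFrac")
})

test_that("merging is symmetric and one-to-one", {
  set.seed(5)
  st <- sort(sample.int(10000, 30)) * 50
  a <- mkSet(st, st + 99, runif(30, 1, 10))
  b <- mkSet(st + 5, st + 104, runif(30, 1, 10))
  ab <- clusterRanges(mergeReplicates(a, b))
  ba <- clusterRanges(mergeReplicates(b, a))
  expect_equal(as.data.frame(ranges(ab)), as.data.frame(ranges(ba)))
  expect_equal(ab$scoreA, ba$scoreB)
  expect_equal(ab$scoreB, ba$scoreA)
  # raising minFrac never yields more matches
  n95 <- length(mergeReplicates(a, b, 0.95))
  n90 <- length(mergeReplicates(a, b, 0.90))
  n80 <- length(mergeReplicates(a, b, 0.80))
  expect_true(n95 <= n90 && n90 <= n80)
})

test_that("the copula mixture is recovered from simulated pairs", {
  set.seed(202)
  sim <- simulateIDRPairs(2000, pi1 = 0.7, mu = 2.6, sigma = 1.3,
                          rho = 0.8)
  f <- fitIDR(sim$scoreA, sim$scoreB)
  expect_lt(abs(f@pi1 - 0.7), 0.1)
  expect_lt(abs(f@mu - 2.6), 0.3)
  expect_lt(abs(f@sigma - 1.3), 0.3)
  expect_lt(abs(f@rho - 0.8), 0.1)
  # posteriors and the cumulative-mean global IDR behave as probabilities
  expect_true(all(f@localIDR >= 0 & f@localIDR <= 1))
  o <- order(f@localIDR)
  expect_true(all(diff(f@globalIDR[o]) >= -1e-12))
  expect_true(all(f@globalIDR <= f@localIDR + 1e-12))
  # the trace never decreases (up to tolerance)
  expect_true(all(diff(f@loglikTrace) >= -1e-8))
})

test_that("degenerate inputs are rejected", {
  expect_error(fitIDR(1:10, 1:10), "at least 20")
  expect_error(fitIDR(rep(1, 50), rnorm(50)), "degenerate ranks")
  expect_error(fitIDR(rnorm(50), rnorm(49)), "equal length")
})

test_that("IDR filter discards at the threshold, keeps strictly below", {
  m <- makeMerged(c(1, 200, 400), c(100, 300, 500),
                  globalIDR = c(0.1, 0.0999, 0.5))
  out <- clusterRanges(idrFilter(m, 0.1))
  expect_equal(start(out), 200)
  expect_equal(length(idrFilter(makeMerged(integer(0), integer(0)))), 0L)
  expect_error(idrFilter(makeMerged(1, 50)), "globalIDR")
})

test_that("length filter drops strictly-longer-than-200 clusters", {
  m <- makeMerged(c(1, 300, 600), c(201, 499, 600))  # widths 201, 200, 1
  out <- clusterRanges(lengthFilter(m))
  expect_equal(start(out), c(300, 600))
})

test_that("scoreIDR annotates merged clusters with both IDR flavours", {
  set.seed(9)
  sim <- simulateIDRPairs(200, pi1 = 0.8, mu = 3, sigma = 1, rho = 0.9)
  st <- seq(1, by = 1000, length.out = 200)
  m <- makeMerged(st, st + 50, scoreA = sim$scoreA, scoreB = sim$scoreB)
  sc <- scoreIDR(m)
  gr <- clusterRanges(sc$merged)
  expect_true(all(gr$localIDR >= 0 & gr$localIDR <= 1))
  expect_true(all(gr$globalIDR >= 0 & gr$globalIDR <= 1))
  expect_s4_class(sc$fit, "IDRFit")
})
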