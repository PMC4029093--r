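grp22 <- factor(c("a", "a", "b", "b"))

test_that("common dispersion hits the Poisson and NB regimes", {
  set.seed(1)
  mu <- runif(800, 5, 500)
  m <- matrix(rpois(800 * 4, rep(mu, 4)), ncol = 4)
  expect_lt(estimateCommonDispersion(m, rep(1e6, 4), grp22)$phi, 0.02)
  set.seed(2)
  m2 <- matrix(rnbinom(800 * 4, mu = rep(mu, 4), size = 5), ncol = 4)
  phi2 <- estimateCommonDispersion(m2, rep(1e6, 4), grp22)$phi
  expect_gt(phi2, 0.15)
  expect_lt(phi2, 0.25)
  # identical columns: zero between-replicate variance, boundary estimate
  ident <- matrix(rep(rpois(200, 50), 4), ncol = 4)
  expect_identical(estimateCommonDispersion(ident, rep(1e6, 4), grp22)$phi,
                   0)
  # single replicate per group falls back with a warning
  expect_warning(
    f <- estimateCommonDispersion(ident[, 1:2], rep(1e6, 2),
                                  factor(c("a", "b"))),
    "fallback")
  expect_equal(f$phi, 0.1)
})

test_that("dispersion agrees with edgeR's conditional-likelihood estimate", {
  set.seed(4)
  cnt <- matrix(rnbinom(1000 * 4, mu = 80, size = 1 / 0.15), ncol = 4)
  mine <- estimateCommonDispersion(cnt, rep(1e6, 4), grp22)$phi
  d <- edgeR::DGEList(counts = cnt, group = grp22)
  d$samples$lib.size <- rep(1e6, 4)
  ref <- edgeR::estimateCommonDisp(d)$common.dispersion
  expect_lt(abs(mine - ref) / ref, 0.15)
})

test_that("the exact test reduces to the conditional binomial at phi 0", {
  # 0 vs 10 with equal libraries: p = P(y in {0, 10} | Binomial(10, 1/2))
  r <- nbExactTest(0, 10, 1e6, 1e6, phi = 0)
  expect_equal(r$pvalue, 2 / 1024, tolerance = 1e-12)
  for (s in c(3, 17, 50)) for (y in c(0, s %/% 3, s)) {
    p <- nbExactTest(y, s - y, 1, 1, 0)$pvalue
    pr <- dbinom(0:s, s, 0.5)
    expect_equal(p, sum(pr[pr <= pr[y + 1] * (1 + 1e-10)]),
                 tolerance = 1e-12)
  }
})

test_that("exact test symmetry, scaling, and edge cases", {
  r <- nbExactTest(c(5, 5), c(5, 5), rep(1e6, 2), rep(1e6, 2), 0.1)
  expect_equal(r$pvalue, 1)
  expect_equal(r$logFC, 0)
  # the conditional law depends only on library proportions: scaling both
  # libraries leaves the test unchanged
  a <- nbExactTest(3, 9, 1e6, 1e6, 0)
  b <- nbExactTest(3, 9, 2e6, 2e6, 0)
  expect_equal(a$pvalue, b$pvalue, tolerance = 1e-12)
  expect_equal(a$logFC, b$logFC, tolerance = 1e-12)
  z <- nbExactTest(0, 0, 1e6, 1e6, 0.1)
  expect_equal(z$pvalue, 1)
  expect_equal(z$logFC, 0)
  expect_error(nbExactTest(1, 2, 1, 1, -0.5), "non-negative")
})

test_that("exact test matches edgeR's small-p exact test", {
  set.seed(7)
  cnt <- matrix(rnbinom(200 * 4, mu = 50, size = 10), ncol = 4)
  d <- edgeR::DGEList(counts = cnt, group = grp22)
  d$samples$lib.size <- rep(1e6, 4)
  et <- edgeR::exactTest(d, dispersion = 0.1, rejection.region = "smallp")
  mine <- vapply(seq_len(nrow(cnt)), function(k)
    nbExactTest(cnt[k, 1:2], cnt[k, 3:4], rep(1e6, 2), rep(1e6, 2),
                0.1)$pvalue, numeric(1))
  expect_equal(mine, et$table$PValue, tolerance = 1e-10)
})

test_that("BH adjustment is validated and correct", {
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(bhAdjust(0.2), 0.2)
  set.seed(8)
  p <- runif(50)
  q <- bhAdjust(p)
  expect_true(all(q >= p & q <= 1))
  expect_equal(order(q[order(p)]), seq_len(50))  # rank order preserved
  expect_error(bhAdjust(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(bhAdjust(c(-0.1)), "\\[0, 1\\]")
})

test_that("significance calls use strict thresholds on both axes", {
  res <- data.frame(logFC = c(2, 2.5, 2.5, -2.5),
                    logConc = 0,
                    pvalue = c(0.001, 0.01, 0.02, 0.001),
                    padj = c(0.01, 0.05, 0.01, 0.001))
  out <- callDEClusters(res)
  expect_equal(out$significant, c(FALSE, FALSE, TRUE, TRUE))
})

test_that("gene calls aggregate over assigned clusters with trigger class", {
  calls <- data.frame(cluster = c("c1", "c2", "c3"),
                      class = c("top", "bottom", "top"),
                      significant = c(TRUE, FALSE, FALSE))
  map <- data.frame(cluster = c("c1", "c2", "c3", "c1"),
                    gene = c("g1", "g1", "g2", "g3"))
  out <- callDEGenes(calls, map)
  expect_equal(out$called[out$gene == "g1"], TRUE)
  expect_equal(out$trigger[out$gene == "g1"], "top")
  expect_equal(out$called[out$gene == "g2"], FALSE)
  # a significant cluster assigned to two genes calls both
  expect_equal(out$called[out$gene == "g3"], TRUE)
})

test_that("null counts give calibrated raw p-values", {
  set.seed(30)
  mu <- runif(1000, 20, 200)
  cnt <- matrix(rnbinom(1000 * 4, mu = rep(mu, 4), size = 10), ncol = 4)
  res <- exactTestMatrix(cnt, rep(1e6, 4), grp22)
  expect_gt(mean(res$pvalue < 0.05), 0.02)
  expect_lt(mean(res$pvalue < 0.05), 0.08)
  expect_true(all(res$padj >= res$pvalue))
})

test_that("detection improves with fold change", {
  set.seed(31)
  pow <- vapply(c(2, 4, 8), function(f) {
    cnt <- cbind(matrix(rnbinom(300 * 2, mu = 50, size = 10), ncol = 2),
                 matrix(rnbinom(300 * 2, mu = 50 * f, size = 10), ncol = 2))
    res <- exactTestMatrix(cnt, rep(1e6, 4), grp22)
    mean(res$pvalue < 0.01)
  }, numeric(1))
  expect_true(all(diff(pow) >= 0))
})
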