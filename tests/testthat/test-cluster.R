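test_that("a single site is one cluster over all densities", {
  d <- clusterBlockDF(100, 5)
  expect_equal(d, data.frame(start = 100, end = 100, tagSum = 5,
                             minD = 0, maxD = Inf))
})

test_that("two distant equal sites split at the flank density", {
  d <- clusterBlockDF(c(1, 101), c(10, 10))
  expect_equal(d, data.frame(start = c(1, 1, 101), end = c(1, 101, 101),
                             tagSum = c(10, 20, 10),
                             minD = c(0.1, 0, 0.1), maxD = c(Inf, 0.1, Inf)))
})

test_that("three-site example matches the exhaustive decomposition", {
  pos <- c(1, 11, 21); val <- c(10, 1, 10)
  d <- clusterBlockDF(pos, val)
  o <- oracleClusters(pos, val)
  rownames(o) <- NULL
  expect_equal(d, o)
  # whole span and outer singletons are members
  expect_true(any(d$start == 1 & d$end == 21 & d$tagSum == 21))
  expect_true(any(d$start == 1 & d$end == 1))
  expect_true(any(d$start == 21 & d$end == 21))
})

test_that("recursive clustering equals the brute-force oracle", {
  set.seed(42)
  for (k in 1:25) {
    b <- randomBlock()
    o <- oracleClusters(b$pos, b$val)
    rownames(o) <- NULL
    expect_equal(clusterBlockDF(b$pos, b$val), o)
  }
})

test_that("cluster families are laminar with consistent parent links", {
  set.seed(7)
  for (k in 1:10) {
    b <- randomBlock(30)
    tb <- CTSStable(rep("c", length(b$pos)), b$pos, rep("+", length(b$pos)),
                    as.integer(b$val))
    gr <- clusterRanges(clusterSites(tb))
    # laminarity: any two overlapping clusters are nested
    lam <- TRUE
    for (i in seq_along(gr)) {
      ov <- which(start(gr) <= end(gr)[i] & end(gr) >= start(gr)[i])
      nested <- (start(gr)[i] <= start(gr)[ov] & end(gr)[i] >= end(gr)[ov]) |
                (start(gr)[ov] <= start(gr)[i] & end(gr)[ov] >= end(gr)[i])
      lam <- lam && all(nested)
    }
    expect_true(lam)
    # parent's density interval abuts the child's
    p <- gr$parent
    has <- !is.na(p)
    expect_equal(gr$minD[has], gr$maxD[p[has]])
    # depth bounded by the number of sites
    depth <- vapply(seq_along(gr), function(i) {
      d <- 0L
      while (!is.na(p[i])) { i <- p[i]; d <- d + 1L }
      d
    }, integer(1))
    expect_true(all(depth < length(b$pos)))
  }
})

test_that("count scaling scales densities; translation shifts coordinates", {
  set.seed(11)
  b <- randomBlock(10)
  base <- clusterBlockDF(b$pos, b$val)
  scaled <- clusterBlockDF(b$pos, b$val * 3)
  expect_equal(scaled$minD, base$minD * 3)
  expect_equal(scaled$maxD, base$maxD * 3)
  expect_equal(scaled$tagSum, base$tagSum * 3)
  shifted <- clusterBlockDF(b$pos + 1000, b$val)
  expect_equal(shifted$start, base$start + 1000)
  expect_equal(shifted$minD, base$minD)
  expect_equal(shifted$maxD, base$maxD)
})

test_that("strands and chromosomes are clustered independently", {
  tb <- CTSStable(c("chr1", "chr1", "chr2"), c(1, 2, 1),
                  c("+", "-", "+"), c(5L, 5L, 5L))
  gr <- clusterRanges(clusterSites(tb))
  expect_equal(length(gr), 3L)  # three singletons, no cross-strand merging
  expect_true(all(is.na(gr$parent)))
})

test_that("density filter keeps exactly-at-threshold clusters", {
  # tpmPerBase: 0.0099 (discarded), 5 (kept), exactly 0.1 (kept)
  cs <- makeClusterSet(start = c(1, 50, 200), end = c(101, 50, 209),
                       tagSum = c(1, 5, 0.001 * 1e6 / 1e6 * 1),
                       minD = c(0, 0, 0), maxD = c(1, 1, 1))
  cs@ranges$tpmPerBase <- c(1 / 101, 5, 0.1)
  out <- densityFilter(cs, 0.1)
  expect_equal(start(clusterRanges(out)), c(50, 200))
  expect_error(densityFilter(cs, -1), "non-negative")
})

test_that("density filter rewires parents to surviving ancestors", {
  # chain 1 -> 2 -> 3; middle cluster filtered out
  cs <- makeClusterSet(start = c(1, 10, 20), end = c(100, 60, 30),
                       tagSum = c(100, 1, 50), minD = c(0, 1, 2),
                       maxD = c(1, 2, 3), parent = c(NA, 1L, 2L))
  cs@ranges$tpmPerBase <- c(10, 0.01, 10)
  out <- densityFilter(cs, 0.1)
  expect_equal(length(out), 2L)
  expect_equal(clusterRanges(out)$parent, c(NA_integer_, 1L))
})

test_that("hierarchical stability sums down the ancestor chain", {
  cs <- makeClusterSet(start = c(1, 10, 12), end = c(100, 20, 18),
                       tagSum = c(10, 5, 3), minD = c(1, 2, 6),
                       maxD = c(2, 6, 24), parent = c(NA, 1L, 2L))
  out <- clusterRanges(addHierStability(cs))
  expect_equal(out$stability, c(2, 3, 4))
  expect_equal(out$hierStability, c(2, 5, 9))
  # root + child example
  cs2 <- makeClusterSet(start = c(1, 10), end = c(100, 20),
                        tagSum = c(9, 9), minD = c(1, 3), maxD = c(3, 6),
                        parent = c(NA, 1L))
  expect_equal(clusterRanges(addHierStability(cs2))$hierStability, c(3, 5))
  # orphan keeps its own stability
  cs3 <- makeClusterSet(1, 10, 5, 2, 8)
  expect_equal(clusterRanges(addHierStability(cs3))$hierStability, 4)
  # forward parent link (cycle surrogate) is rejected
  bad <- makeClusterSet(start = c(1, 10), end = c(100, 20),
                        tagSum = c(9, 9), minD = c(1, 3), maxD = c(3, 6),
                        parent = c(2L, NA))
  expect_error(addHierStability(bad), "forest")
})

test_that("legacy filter enforces the classic tag/stability/length rules", {
  mk <- function(tagSum, minD, maxD, len)
    makeClusterSet(1, len, tagSum, minD, maxD)
  expect_equal(length(legacyFilter(mk(29, 1, 5, 50))), 0L)   # < 30 tags
  expect_equal(length(legacyFilter(mk(100, 1, 1.9, 50))), 0L) # < 2 stability
  expect_equal(length(legacyFilter(mk(100, 1, 5, 201))), 0L)  # > 200 bp
  expect_equal(length(legacyFilter(mk(100, 1, 5, 200))), 1L)  # boundary kept
  expect_equal(length(legacyFilter(mk(30, 1, 2, 50))), 1L)    # both at boundary
})

test_that("legacy filter keeps only the largest surviving cluster per site", {
  cs <- makeClusterSet(start = c(1, 10, 300), end = c(100, 50, 340),
                       tagSum = c(100, 90, 80), minD = c(1, 2, 1),
                       maxD = c(5, 10, 5), parent = c(NA, 1L, NA))
  out <- clusterRanges(legacyFilter(cs))
  expect_equal(start(out), c(1, 300))  # nested [10,50] collapsed away
})
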