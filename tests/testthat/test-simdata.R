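test_that("the simulator is deterministic given its config", {
  cfg <- simConfig(nPromoters = 8, seed = 77)
  s1 <- simulateCTSS(cfg)
  s2 <- simulateCTSS(cfg)
  expect_identical(s1$truth, s2$truth)
  for (nm in names(s1$tables))
    expect_identical(as.data.frame(ctssSites(s1$tables[[nm]])),
                     as.data.frame(ctssSites(s2$tables[[nm]])))
})

test_that("planted architectures are laminar with sub-peaks strictly inside", {
  tr <- simulateCTSS(simConfig(nPromoters = 30, seed = 5))$truth
  for (p in unique(tr$promoter)) {
    b <- tr[tr$promoter == p & tr$type == "broad", ]
    subs <- tr[tr$promoter == p & tr$type == "sub", ]
    expect_true(all(subs$start > b$start & subs$end < b$end))
    if (nrow(subs) > 1) {
      o <- order(subs$start)
      expect_true(all(subs$start[o][-1] > subs$end[o][-nrow(subs)]))
    }
    expect_true(b$end - b$start + 1 >= 50 && b$end - b$start + 1 <= 200)
  }
})

test_that("sub-peak-shift promoters keep whole-promoter means balanced", {
  sim <- simulateCTSS(simConfig(nPromoters = 20, seed = 3))
  tr <- sim$truth
  sm <- sim$siteMeans
  shift <- unique(tr$promoter[tr$deClass == "shift"])
  expect_gt(length(shift), 0)
  for (p in shift) {
    s <- sm[sm$promoter == p, ]
    expect_equal(sum(s$mean1), sum(s$mean2), tolerance = 1e-10)
    sub <- tr[tr$promoter == p & tr$shifted, ]
    inA <- s$pos >= sub$start & s$pos <= sub$end
    expect_equal(sum(s$mean2[inA]) / sum(s$mean1[inA]), 8)
  }
  # whole-promoter DE moves everything by the planted fold
  whole <- unique(tr$promoter[tr$deClass == "whole"])
  for (p in whole) {
    s <- sm[sm$promoter == p, ]
    expect_equal(abs(log2(sum(s$mean2) / sum(s$mean1))), 3,
                 tolerance = 1e-10)
  }
})

test_that("counts at a strong site follow the negative binomial", {
  cfg <- simConfig(nPromoters = 4, nReps = 120, phiPromoter = 0,
                   phiRep = 0.2, noiseRate = 0, irreproducibleFrac = 0,
                   deWholeFrac = 0, deShiftFrac = 0, seed = 13)
  sim <- simulateCTSS(cfg)
  sm <- sim$siteMeans
  site <- sm[which.max(sm$mean1), ]
  draws <- vapply(sim$tables, function(tb) {
    gr <- ctssSites(tb)
    i <- which(start(gr) == site$pos &
               as.character(strand(gr)) == site$strand)
    if (length(i)) gr$count[i] else 0L
  }, integer(1))
  m <- mean(draws); v <- var(draws)
  expect_equal(m, site$mean1, tolerance = 0.15)
  phiHat <- (v - m) / m^2
  expect_gt(phiHat, 0.08)
  expect_lt(phiHat, 0.4)
})

test_that("degenerate config with shared seeds gives identical replicates", {
  cfg <- simConfig(nPromoters = 6, phiRep = 0, noiseRate = 0,
                   irreproducibleFrac = 0, seed = 5)
  sim <- simulateCTSS(cfg, sampleSeeds = matrix(c(11, 11, 22, 22), 2,
                                                byrow = TRUE))
  expect_identical(as.data.frame(ctssSites(sim$tables$cond1_rep1)),
                   as.data.frame(ctssSites(sim$tables$cond1_rep2)))
  expect_identical(as.data.frame(ctssSites(sim$tables$cond2_rep1)),
                   as.data.frame(ctssSites(sim$tables$cond2_rep2)))
})

test_that("replicate-specific promoters appear in exactly one sample", {
  cfg <- simConfig(nPromoters = 20, irreproducibleFrac = 0.5,
                   noiseRate = 0, seed = 9)
  sim <- simulateCTSS(cfg)
  tr <- sim$truth[sim$truth$type == "broad", ]
  irr <- tr[!tr$reproducible, ]
  expect_gt(nrow(irr), 0)
  for (k in seq_len(nrow(irr))) {
    present <- vapply(sim$tables, function(tb) {
      gr <- ctssSites(tb)
      any(start(gr) >= irr$start[k] & start(gr) <= irr$end[k] &
          as.character(strand(gr)) == irr$strand[k])
    }, logical(1))
    expect_equal(sum(present), 1L)
    expect_equal(names(sim$tables)[present],
                 sprintf("cond%d_rep%d", irr$privCond[k], irr$privRep[k]))
  }
})

test_that("invalid configs are rejected", {
  expect_error(simConfig(irreproducibleFrac = 1.5), "fractions")
  expect_error(simConfig(deWholeFrac = 0.7, deShiftFrac = 0.7), "sum")
  expect_error(simConfig(nPromoters = 1e5), "genome too short")
  expect_error(simConfig(fold = 0.5), "fold")
})

test_that("gene models derived from the truth point at broad 5' ends", {
  sim <- simulateCTSS(simConfig(nPromoters = 10, seed = 2))
  tss <- truthGeneTSS(sim$truth)
  tr <- sim$truth[sim$truth$type == "broad", ]
  expect_equal(length(tss), nrow(tr))
  plus <- as.character(GenomicRanges::strand(tss)) == "+"
  expect_equal(start(tss)[plus], tr$start[plus])
  expect_equal(start(tss)[!plus], tr$end[!plus])
})
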