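# Brute-force oracle for the density-clustering semantics: for a fixed
# density d, the cluster set is the Ruzzo-Tompa maximal-scoring-subsequence
# decomposition of the alternating sequence (+count, -d*gap, ...). The
# oracle enumerates every critical density (all segment tag-sum / extent
# ratios), evaluates the decomposition at each critical value and at
# midpoints between consecutive ones, and reads off each segment's density
# interval. Densities are carried as exact rationals (d = num/den) and the
# decomposition is run on integer-scaled values, so ties at critical
# densities are resolved exactly: a segment tied with its split parts does
# NOT merge, matching the strict-inequality convention of the recursion.

# Ruzzo-Tompa maximal scoring subsequences of a real/integer vector;
# returns element index ranges of the maximal segments.
rtMaximalSegments <- function(x) {
  segs <- list()   # each: c(startElem, endElem, L, R)
  cum <- 0
  for (k in seq_along(x)) {
    v <- x[k]
    cumBefore <- cum
    cum <- cum + v
    if (v <= 0) next
    s <- c(k, k, cumBefore, cum)
    repeat {
      j <- length(segs)
      while (j >= 1 && segs[[j]][3] >= s[3]) j <- j - 1
      if (j == 0) { segs[[length(segs) + 1]] <- s; break }
      if (segs[[j]][4] >= s[4]) { segs[[length(segs) + 1]] <- s; break }
      s <- c(segs[[j]][1], s[2], segs[[j]][3], s[4])
      segs <- segs[seq_len(j - 1)]
    }
  }
  segs
}

# Decomposition at rational density num/den for sites (pos, val):
# site i is element 2i-1 with value val_i * den, the gap after it is an
# element with value -num * (pos_{i+1} - pos_i). All integer arithmetic.
rtDecomposeAt <- function(pos, val, num, den) {
  n <- length(pos)
  elems <- numeric(2 * n - 1)
  elems[seq(1, 2 * n - 1, by = 2)] <- val * den
  if (n > 1)
    elems[seq(2, 2 * n - 2, by = 2)] <- -num * diff(pos)
  segs <- rtMaximalSegments(elems)
  vapply(segs, function(s) {
    c((s[1] + 1) %/% 2, (s[2] + 1) %/% 2)   # element -> site index
  }, numeric(2))
}

# All segments appearing in the decomposition for some d > 0, with their
# exact [minD, maxD] density interval. Returns a data.frame sorted by
# (start, end) with columns start, end (site positions), tagSum, minD, maxD.
oracleClusters <- function(pos, val) {
  n <- length(pos)
  if (n == 1)
    return(data.frame(start = pos, end = pos, tagSum = val,
                      minD = 0, maxD = Inf))
  # Critical densities as exact fractions num/den: all ratios
  # T(i..j) / (pos_B - pos_A) with A in {i-1, i}, B in {j, j+1} - the zero
  # scores of every contiguous element range (sites plus optional flanking
  # gaps), a superset of every density at which the decomposition can
  # change.
  critL <- vector("list", n * n)
  for (i in 1:n) for (j in i:n) {
    Tij <- sum(val[i:j])
    As <- unique(pmax(c(i - 1, i), 1))
    Bs <- unique(pmin(c(j, j + 1), n))
    ext <- outer(pos[Bs], pos[As], `-`)
    ext <- ext[ext > 0]
    if (length(ext))
      critL[[(i - 1) * n + j]] <- cbind(Tij, ext)
  }
  crit <- do.call(rbind, critL)
  critVal <- crit[, 1] / crit[, 2]
  o <- order(critVal)
  crit <- crit[o, , drop = FALSE]
  critVal <- critVal[o]
  uniq <- !duplicated(critVal)
  crit <- crit[uniq, , drop = FALSE]
  critVal <- critVal[uniq]
  m <- length(critVal)
  # sample points: below all criticals, each critical, midpoints, above all
  samples <- list(list(num = crit[1, 1], den = 2 * crit[1, 2],
                       v = critVal[1] / 2))
  for (k in seq_len(m)) {
    samples[[length(samples) + 1]] <-
      list(num = crit[k, 1], den = crit[k, 2], v = critVal[k])
    if (k < m) {
      # midpoint (a/b + c/d)/2 = (ad + cb) / (2bd)
      samples[[length(samples) + 1]] <-
        list(num = crit[k, 1] * crit[k + 1, 2] +
                   crit[k + 1, 1] * crit[k, 2],
             den = 2 * crit[k, 2] * crit[k + 1, 2],
             v = (critVal[k] + critVal[k + 1]) / 2)
    }
  }
  samples[[length(samples) + 1]] <-
    list(num = 2 * crit[m, 1], den = crit[m, 2], v = 2 * critVal[m])
  appear <- new.env()
  for (sm in samples) {
    segs <- rtDecomposeAt(pos, val, sm$num, sm$den)
    if (length(segs))
      for (c0 in seq_len(ncol(segs))) {
        key <- paste(segs[1, c0], segs[2, c0])
        appear[[key]] <- c(appear[[key]], sm$v)
      }
  }
  svals <- vapply(samples, `[[`, 0, "v")
  out <- lapply(ls(appear), function(key) {
    ij <- as.numeric(strsplit(key, " ")[[1]])
    a <- appear[[key]]
    lo <- min(a); hi <- max(a)
    minD <- if (lo == min(svals)) 0 else max(critVal[critVal <= lo])
    maxD <- if (hi == max(svals)) Inf else min(critVal[critVal >= hi])
    data.frame(start = pos[ij[1]], end = pos[ij[2]],
               tagSum = sum(val[ij[1]:ij[2]]), minD = minD, maxD = maxD)
  })
  out <- do.call(rbind, out)
  out[order(out$start, out$end), , drop = FALSE]
}

# Random CTSS block on one chrom+strand: <= maxSites sites, positions
# uniform on [0, 500], counts uniform on 1..20.
randomBlock <- function(maxSites = 12) {
  n <- sample.int(maxSites, 1)
  pos <- sort(sample.int(501, n)) # 1..501, distinct
  val <- sample.int(20, n, replace = TRUE)
  list(pos = pos, val = val)
}

clusterBlockDF <- function(pos, val) {
  tb <- CTSStable(rep("c", length(pos)), pos, rep("+", length(pos)),
                  as.integer(val))
  d <- as.data.frame(clusterSites(tb))
  d <- d[order(d$start, d$end), c("start", "end", "tagSum", "minD", "maxD")]
  rownames(d) <- NULL
  d
}
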