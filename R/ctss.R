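#' Build a CTSStable from positions and counts
#'
#' Low-level constructor. Records are canonically re-sorted by
#' (chrom, strand, pos) and validated; zero-count records are rejected.
#'
#' @param chrom character vector of chromosome names.
#' @param pos 1-based genomic positions of the tag 5' ends.
#' @param strand `"+"` or `"-"`.
#' @param count positive integer tag counts.
#' @return a [CTSStable].
#' @export
CTSStable <- function(chrom = character(), pos = integer(),
                      strand = character(), count = integer()) {
  n <- length(pos)
  chrom <- rep_len(as.character(chrom), n)
  strand <- rep_len(as.character(strand), n)
  o <- base::order(chrom, match(strand, c("+", "-", "*")), pos,
                   method = "radix")
  gr <- GRanges(chrom[o], IRanges(start = pos[o], width = 1L),
                strand = strand[o])
  gr$count <- rep_len(as.integer(count), n)[o]
  gr$tpm <- rep(NA_real_, length(gr))
  new("CTSStable", sites = gr, librarySize = sum(as.numeric(gr$count)))
}

## Reference-space width of an alignment from its CIGAR string: sum of the
## operations that consume the reference (M, D, N, =, X).
cigarRefWidth <- function(cigar) {
  ops <- gregexpr("\\d+[MIDNSHP=X]", cigar)
  vapply(regmatches(cigar, ops), function(tok) {
    if (!length(tok) || is.na(tok[1L])) return(NA_integer_)
    n <- as.integer(sub("[MIDNSHP=X]$", "", tok))
    op <- substring(tok, nchar(tok), nchar(tok))
    sum(n[op %in% c("M", "D", "N", "=", "X")])
  }, integer(1))
}

#' Count CAGE tag 5' ends per single-nucleotide position
#'
#' Reads mapped CAGE alignments (SAM or BAM) and counts, for every
#' (chromosome, position, strand), the number of reads whose mapping starts
#' there: the leftmost aligned base for forward-strand reads and the
#' rightmost aligned base for reverse-strand reads (the biological 5' end of
#' the tag in both cases). Unmapped reads are skipped; secondary and
#' supplementary alignments are excluded by default so that one tag
#' contributes one transcript 5' end.
#'
#' @param file path to a SAM or BAM file (SAM is converted on the fly).
#' @param includeSecondary count secondary/supplementary alignments too.
#' @return a [CTSStable]; empty input yields an empty table.
#' @examples
#' sam <- tempfile(fileext = ".sam")
#' writeLines(c("@HD\tVN:1.6\tSO:coordinate", "@SQ\tSN:chr1\tLN:1000",
#'   "r1\t0\tchr1\t101\t60\t20M\t*\t0\t0\t*\t*",
#'   "r2\t16\tchr1\t101\t60\t20M\t*\t0\t0\t*\t*"), sam)
#' countCTSS(sam)
#' @export
countCTSS <- function(file, includeSecondary = FALSE) {
  bam <- file
  if (grepl("\\.sam$", file, ignore.case = TRUE))
    bam <- Rsamtools::asBam(file, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  p <- Rsamtools::ScanBamParam(
    what = c("rname", "pos", "strand", "cigar", "flag"))
  a <- Rsamtools::scanBam(bam, param = p)[[1L]]
  keep <- !is.na(a$pos)
  if (!includeSecondary)
    keep <- keep & bitwAnd(a$flag, 0x900L) == 0L    # secondary/supplementary
  if (!any(keep))
    return(CTSStable())
  chrom <- as.character(a$rname)[keep]
  pos <- a$pos[keep]
  str <- as.character(a$strand)[keep]
  cig <- a$cigar[keep]
  bad <- which(is.na(chrom) | is.na(str) | str == "*" | is.na(cig))
  if (length(bad))
    stop("malformed alignment record at index ", bad[1L])
  w <- cigarRefWidth(cig)
  if (anyNA(w))
    stop("malformed CIGAR at record ", which(is.na(w))[1L])
  p5 <- ifelse(str == "-", pos + w - 1L, pos)
  key <- paste(chrom, str, p5, sep = "\r")
  tab <- table(key)
  parts <- strsplit(names(tab), "\r", fixed = TRUE)
  CTSStable(chrom = vapply(parts, `[`, "", 1L),
            pos = as.integer(vapply(parts, `[`, "", 3L)),
            strand = vapply(parts, `[`, "", 2L),
            count = as.integer(tab))
}

#' Normalize CTSS counts to tags per million
#'
#' Sets `tpm = count * 1e6 / librarySize` for every record; counts are left
#' unchanged. The library size is the per-sample total CTSS count.
#'
#' @param table a [CTSStable].
#' @return the table with the `tpm` column populated (sums to 1e6).
#' @export
tpmNormalize <- function(table) {
  stopifnot(is(table, "CTSStable"))
  if (table@librarySize <= 0)
    stop("empty library")
  table@sites$tpm <- table@sites$count * 1e6 / table@librarySize
  validObject(table)
  table
}

#' Read / write CTSS tables as BED6 text
#'
#' The on-disk format is BED6-like tab-separated text: chrom, 0-based start,
#' end = start + 1, name, count (in the score column), strand, preceded by a
#' single header line starting with `#`. `writeCTSS()` followed by
#' `readCTSS()` is the identity on canonically sorted tables.
#'
#' @param path file path.
#' @return `readCTSS()` returns a [CTSStable] (re-sorted canonically);
#'   `writeCTSS()` returns `path` invisibly.
#' @export
readCTSS <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (!length(lines))
    return(CTSStable())
  d <- utils::read.table(text = lines, sep = "\t",
                         colClasses = c("character", "integer", "integer",
                                        "character", "character",
                                        "character"))
  if (ncol(d) != 6L)
    stop("CTSS BED must have exactly 6 columns")
  if (any(d[[3L]] != d[[2L]] + 1L))
    stop("CTSS records must be single-nucleotide (end == start + 1)")
  cnt <- suppressWarnings(as.numeric(d[[5L]]))
  if (anyNA(cnt) || any(cnt != round(cnt)))
    stop("non-integer count in score column")
  CTSStable(chrom = d[[1L]], pos = d[[2L]] + 1L, strand = d[[6L]],
            count = as.integer(cnt))
}

#' @rdname readCTSS
#' @param table a [CTSStable] to write.
#' @export
writeCTSS <- function(table, path) {
  stopifnot(is(table, "CTSStable"))
  gr <- table@sites
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#chrom\tstart\tend\tname\tcount\tstrand", con)
  if (length(gr)) {
    nm <- paste0(seqnames(gr), ":", start(gr) - 1L, ":", strand(gr))
    writeLines(paste(seqnames(gr), start(gr) - 1L, start(gr), nm, gr$count,
                     strand(gr), sep = "\t"), con)
  }
  invisible(path)
}

## Sum of CTSS counts falling inside each query interval (same strand).
countInIntervals <- function(gr, table) {
  sites <- table@sites
  hits <- findOverlaps(gr, sites)
  hits <- hits[as.character(strand(gr))[queryHits(hits)] ==
               as.character(strand(sites))[subjectHits(hits)]]
  out <- integer(length(gr))
  if (length(hits)) {
    s <- tapply(sites$count[subjectHits(hits)], queryHits(hits), sum)
    out[as.integer(names(s))] <- as.integer(s)
  }
  out
}
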