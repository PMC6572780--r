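# Internal coordinate helpers.
#
# Every interval in this package is 0-based half-open [start, end) on a named
# chromosome. GRanges is 1-based closed, so conversion shifts start by +1; a
# >=1 bp overlap in our convention is exactly a GRanges overlap after the shift.

.gr <- function(chrom, start, end) {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start = start + 1L, end = end))
}

# midpoint of [start, end), integer floor
.mid <- function(start, end) (as.numeric(start) + as.numeric(end)) %/% 2

.gr_points <- function(chrom, pos) {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start = pos + 1L, width = 1L))
}

.check_intervals <- function(chrom, start, end, what = "interval") {
  if (any(is.na(chrom) | !nzchar(chrom))) {
    stop(sprintf("%s: chromosome names must be non-empty", what), call. = FALSE)
  }
  bad <- which(!(start >= 0 & start < end))
  if (length(bad)) {
    stop(sprintf("%s: need 0 <= start < end (first offending record %d: [%s, %s))",
                 what, bad[1], start[bad[1]], end[bad[1]]), call. = FALSE)
  }
  invisible(TRUE)
}

.is_count <- function(x) length(x) == 1L && is.numeric(x) && !is.na(x) && x == floor(x)

# numerically stable log(sum(exp(x)))
.logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

.empty_pets <- function() {
  data.frame(chrom1 = character(0), start1 = integer(0), end1 = integer(0),
             chrom2 = character(0), start2 = integer(0), end2 = integer(0),
             count = integer(0), stringsAsFactors = FALSE)
}

.empty_peaks <- function() {
  data.frame(chrom = character(0), start = integer(0), end = integer(0),
             id = character(0), signal = numeric(0), mark = character(0),
             stringsAsFactors = FALSE)
}

.empty_interactions <- function() {
  data.frame(chrom1 = character(0), start1 = integer(0), end1 = integer(0),
             chrom2 = character(0), start2 = integer(0), end2 = integer(0),
             anchorA = character(0), anchorB = character(0),
             petCount = integer(0), pValue = numeric(0), fdr = numeric(0),
             class = character(0), markProvenance = character(0),
             anchor1Type = character(0), anchor2Type = character(0),
             tissue = character(0), stringsAsFactors = FALSE)
}

# canonical ordering of PET ends: (chrom, start, end) of end1 <= end2
.canonicalize_pets <- function(pets) {
  if (!nrow(pets)) return(pets)
  swap <- (pets$chrom2 < pets$chrom1) |
    (pets$chrom2 == pets$chrom1 & (pets$start2 < pets$start1 |
      (pets$start2 == pets$start1 & pets$end2 < pets$end1)))
  if (any(swap)) {
    tmp <- pets[swap, c("chrom1", "start1", "end1")]
    pets[swap, c("chrom1", "start1", "end1")] <- pets[swap, c("chrom2", "start2", "end2")]
    pets[swap, c("chrom2", "start2", "end2")] <- tmp
  }
  pets
}

.validate_interactions <- function(x, what = "interactions") {
  req <- c("chrom1", "start1", "end1", "chrom2", "start2", "end2",
           "anchorA", "anchorB", "petCount", "pValue", "fdr", "class",
           "markProvenance", "anchor1Type", "anchor2Type", "tissue")
  miss <- setdiff(req, names(x))
  if (length(miss)) {
    stop(sprintf("%s: missing columns: %s", what, paste(miss, collapse = ", ")),
         call. = FALSE)
  }
  if (nrow(x)) {
    .check_intervals(x$chrom1, x$start1, x$end1, paste(what, "anchor A"))
    .check_intervals(x$chrom2, x$start2, x$end2, paste(what, "anchor B"))
    ok <- is.na(x$class) | x$class %in% c("PP", "PD", "DD")
    if (!all(ok)) {
      stop(sprintf("%s: class must be PP, PD, DD or NA (record %d has '%s')",
                   what, which(!ok)[1], x$class[which(!ok)[1]]), call. = FALSE)
    }
    if (any(!is.na(x$pValue) & (x$pValue < 0 | x$pValue > 1)) ||
        any(!is.na(x$fdr) & (x$fdr < 0 | x$fdr > 1))) {
      stop(sprintf("%s: p-values and FDR must lie in [0, 1]", what), call. = FALSE)
    }
  }
  invisible(TRUE)
}
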