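#' Merge overlapping same-mark peaks
#'
#' Peaks of the same mark that overlap by >= 1 bp are merged into their union
#' interval, keeping the maximum signal; merged peaks get a fresh
#' \code{mark_chrom_start} id. Interaction calling requires non-overlapping
#' anchors per mark, so this runs automatically inside
#' \code{\link{call_interactions}}.
#'
#' @param peaks Peak data.frame.
#' @return Peak data.frame with non-overlapping intervals per mark.
#' @export
merge_peaks <- function(peaks) {
  if (!nrow(peaks)) return(peaks)
  out <- lapply(split(peaks, peaks$mark), function(p) {
    gr <- .gr(p$chrom, p$start, p$end)
    red <- GenomicRanges::reduce(gr)
    hit <- GenomicRanges::findOverlaps(gr, red)
    sig <- tapply(p$signal[S4Vectors::queryHits(hit)],
                  S4Vectors::subjectHits(hit), max)
    merged <- data.frame(chrom = as.character(GenomicRanges::seqnames(red)),
                         start = GenomicRanges::start(red) - 1L,
                         end = GenomicRanges::end(red),
                         stringsAsFactors = FALSE)
    merged$signal <- as.numeric(sig[as.character(seq_along(red))])
    merged$mark <- p$mark[1]
    # untouched peaks keep their id; true merges get a positional id
    n_src <- tabulate(S4Vectors::subjectHits(hit), length(red))
    orig <- p$id[S4Vectors::queryHits(hit)][match(seq_along(red),
                                                  S4Vectors::subjectHits(hit))]
    merged$id <- ifelse(n_src == 1L, orig,
                        paste(p$mark[1], merged$chrom, merged$start, sep = "_"))
    merged[, c("chrom", "start", "end", "id", "signal", "mark")]
  })
  out <- do.call(rbind, out)
  out <- out[order(out$chrom, out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assign PET ends to peaks
#'
#' Each PET end is assigned to the peak whose interval contains the end's
#' midpoint (half-open, so a midpoint equal to the peak end coordinate is
#' outside). Peaks must be non-overlapping (see \code{\link{merge_peaks}}).
#'
#' @param pets PET data.frame.
#' @param peaks Non-overlapping peak data.frame.
#' @return A data.frame with one row per PET: \code{peak1}, \code{peak2}
#'   (peak ids or NA).
#' @export
assign_pets_to_peaks <- function(pets, peaks) {
  pk <- .gr(peaks$chrom, peaks$start, peaks$end)
  assign_one <- function(chrom, start, end) {
    hit <- GenomicRanges::findOverlaps(.gr_points(chrom, .mid(start, end)), pk,
                                       select = "first")
    peaks$id[hit]
  }
  data.frame(peak1 = assign_one(pets$chrom1, pets$start1, pets$end1),
             peak2 = assign_one(pets$chrom2, pets$start2, pets$end2),
             stringsAsFactors = FALSE)
}

#' Hypergeometric upper-tail probability
#'
#' P[X >= x] where X ~ Hypergeometric(population \code{n_tot}, successes
#' \code{n_a}, draws \code{n_b}): the chance of seeing at least the observed
#' number of linking PETs between two anchors if the \code{n_b} draws were
#' taken at random from the pooled PET population. Computed by summation of
#' log-space PMF terms (numerically stable for large populations); returns 1
#' when \code{x == 0}.
#'
#' @param x Observed overlap count(s), 0 <= x <= min(n_a, n_b).
#' @param n_a,n_b Per-anchor PET counts.
#' @param n_tot Total PET population size.
#' @return Vector of tail probabilities in [0, 1].
#' @export
hypergeom_tail <- function(x, n_a, n_b, n_tot) {
  n <- max(length(x), length(n_a), length(n_b), length(n_tot))
  x <- rep_len(x, n); n_a <- rep_len(n_a, n)
  n_b <- rep_len(n_b, n); n_tot <- rep_len(n_tot, n)
  if (any(x < 0 | n_a < 0 | n_b < 0 | x > pmin(n_a, n_b) |
          n_a > n_tot | n_b > n_tot)) {
    stop("hypergeom_tail: need 0 <= x <= min(n_a, n_b) and n_a, n_b <= n_tot",
         call. = FALSE)
  }
  vapply(seq_len(n), function(i) {
    if (x[i] == 0) return(1)
    k <- x[i]:min(n_a[i], n_b[i])
    lp <- stats::dhyper(k, n_a[i], n_tot[i] - n_a[i], n_b[i], log = TRUE)
    min(exp(.logsumexp(lp)), 1)
  }, numeric(1))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Textbook step-up FDR adjustment: sort p ascending, q_i = min_{j >= i}
#' (p_j * m / j), clip at 1, return in input order.
#'
#' @param pvalues Vector of p-values in [0, 1].
#' @return Adjusted values in [0, 1], same order as the input.
#' @export
bh_adjust <- function(pvalues) {
  if (!length(pvalues)) return(numeric(0))
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  m <- length(pvalues)
  o <- order(pvalues)
  q <- pvalues[o] * m / seq_len(m)
  q <- pmin(rev(cummin(rev(q))), 1)
  out <- numeric(m)
  out[o] <- q
  out
}

#' Call high-confidence chromatin interactions
#'
#' Candidate interactions are all peak pairs linked by at least one PET (a PET
#' links peaks A and B when its two end midpoints fall in A and B, A != B).
#' Each candidate is scored with the hypergeometric upper tail
#' (\code{\link{hypergeom_tail}}): population = PETs with both ends
#' peak-assigned, per-anchor counts = PET ends falling in the anchor within
#' that population, observed = linking PETs. p-values are Benjamini-Hochberg
#' adjusted jointly across all candidates of the run, and interactions with
#' \code{petCount >= min_pets} and \code{fdr < fdr_max} are reported, sorted
#' by genomic position.
#'
#' @param pets Classified PET data.frame (see \code{\link{classify_pets}}).
#' @param peaks Peak data.frame; overlapping same-mark peaks are merged first.
#' @param min_pets Minimum linking PETs (default 3).
#' @param fdr_max FDR cutoff (default 0.01, strict \code{<}).
#' @param pet_class Which PET class to use: "intra" (default) for
#'   intra-chromosomal calls or "inter" for inter-chromosomal candidates,
#'   which are scored identically but reported separately and never enter
#'   distance-based downstream analyses.
#' @param tissue Optional tissue label stored on the output.
#' @return Interaction data.frame with anchors, petCount, pValue, fdr,
#'   markProvenance and (not yet assigned) class columns.
#' @export
call_interactions <- function(pets, peaks, min_pets = 3, fdr_max = 0.01,
                              pet_class = "intra", tissue = NA_character_) {
  if (!"class" %in% names(pets)) {
    stop("PETs are not classified; run classify_pets() first", call. = FALSE)
  }
  if (!.is_count(min_pets) || min_pets < 1) stop("min_pets must be >= 1", call. = FALSE)
  if (is.null(tissue)) tissue <- NA_character_
  pets <- pets[pets$class == pet_class, , drop = FALSE]
  peaks <- merge_peaks(peaks)
  asg <- assign_pets_to_peaks(pets, peaks)
  both <- !is.na(asg$peak1) & !is.na(asg$peak2)
  if (!any(both)) {
    warning("no peak-assigned PETs; returning empty interaction set")
    return(.empty_interactions())
  }
  pop <- asg[both, , drop = FALSE]
  n_tot <- nrow(pop)
  ends_per_peak <- table(c(pop$peak1, pop$peak2))
  linking <- pop[pop$peak1 != pop$peak2, , drop = FALSE]
  if (!nrow(linking)) {
    warning("no linking PETs; returning empty interaction set")
    return(.empty_interactions())
  }
  # order each linked pair by genomic position of the peak
  pk_rank <- seq_len(nrow(peaks))
  names(pk_rank) <- peaks$id
  swap <- pk_rank[linking$peak1] > pk_rank[linking$peak2]
  a <- ifelse(swap, linking$peak2, linking$peak1)
  b <- ifelse(swap, linking$peak1, linking$peak2)
  key <- paste(a, b, sep = "\r")
  tab <- table(key)
  uniq <- !duplicated(key)
  cand <- data.frame(peakA = a[uniq], peakB = b[uniq], stringsAsFactors = FALSE)
  cand$x <- as.integer(tab[key[uniq]])
  cand$nA <- as.integer(ends_per_peak[cand$peakA])
  cand$nB <- as.integer(ends_per_peak[cand$peakB])
  cand$p <- hypergeom_tail(cand$x, cand$nA, cand$nB, n_tot)
  cand$fdr <- bh_adjust(cand$p)
  keep <- cand$x >= min_pets & cand$fdr < fdr_max
  cand <- cand[keep, , drop = FALSE]
  if (!nrow(cand)) return(.empty_interactions())
  ia <- match(cand$peakA, peaks$id)
  ib <- match(cand$peakB, peaks$id)
  out <- data.frame(chrom1 = peaks$chrom[ia], start1 = peaks$start[ia],
                    end1 = peaks$end[ia],
                    chrom2 = peaks$chrom[ib], start2 = peaks$start[ib],
                    end2 = peaks$end[ib],
                    anchorA = cand$peakA, anchorB = cand$peakB,
                    petCount = cand$x, pValue = cand$p, fdr = cand$fdr,
                    class = rep(NA_character_, nrow(cand)),
                    markProvenance = vapply(seq_along(ia), function(i) {
                      paste(sort(unique(c(peaks$mark[ia[i]], peaks$mark[ib[i]]))),
                            collapse = ",")
                    }, character(1)),
                    anchor1Type = NA_character_, anchor2Type = NA_character_,
                    tissue = tissue, stringsAsFactors = FALSE)
  out <- out[order(out$chrom1, out$start1, out$chrom2, out$start2), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# match interactions of a against b: both-anchor reciprocal overlap >= 1 bp.
# returns data.frame(qa, qb) of matching row pairs (anchors are canonically
# ordered on both sides, so A-vs-A / B-vs-B is the right orientation).
.match_interactions <- function(a, b) {
  if (!nrow(a) || !nrow(b)) return(data.frame(qa = integer(0), qb = integer(0)))
  f1 <- GenomicRanges::findOverlaps(.gr(a$chrom1, a$start1, a$end1),
                                    .gr(b$chrom1, b$start1, b$end1))
  f2 <- GenomicRanges::findOverlaps(.gr(a$chrom2, a$start2, a$end2),
                                    .gr(b$chrom2, b$start2, b$end2))
  k1 <- paste(S4Vectors::queryHits(f1), S4Vectors::subjectHits(f1))
  k2 <- paste(S4Vectors::queryHits(f2), S4Vectors::subjectHits(f2))
  shared <- intersect(k1, k2)
  if (!length(shared)) return(data.frame(qa = integer(0), qb = integer(0)))
  parts <- do.call(rbind, strsplit(shared, " ", fixed = TRUE))
  data.frame(qa = as.integer(parts[, 1]), qb = as.integer(parts[, 2]))
}

#' Merge interaction sets from two marks of the same tissue
#'
#' Two interactions are the same event when the A anchors and the B anchors
#' each overlap by >= 1 bp. Matched events are collapsed keeping the record
#' with the smaller FDR (its coordinates and class), the maximum PET count,
#' the minimum p-value/FDR, and the union of mark provenance.
#'
#' @param set_a,set_b Interaction data.frames from the same tissue.
#' @return Merged interaction data.frame.
#' @export
merge_mark_sets <- function(set_a, set_b) {
  ta <- unique(stats::na.omit(set_a$tissue))
  tb <- unique(stats::na.omit(set_b$tissue))
  if (length(ta) && length(tb) && !identical(sort(ta), sort(tb))) {
    stop("cannot merge interaction sets from different tissues (",
         paste(ta, collapse = ","), " vs ", paste(tb, collapse = ","), ")",
         call. = FALSE)
  }
  m <- .match_interactions(set_a, set_b)
  merged <- .empty_interactions()
  if (nrow(m)) {
    rows <- lapply(unique(m$qa), function(i) {
      js <- m$qb[m$qa == i]
      j <- js[which.min(set_b$fdr[js])]
      base <- if (set_a$fdr[i] <= set_b$fdr[j]) set_a[i, ] else set_b[j, ]
      base$petCount <- max(set_a$petCount[i], set_b$petCount[js])
      base$pValue <- min(set_a$pValue[i], set_b$pValue[js])
      base$fdr <- min(set_a$fdr[i], set_b$fdr[js])
      base$markProvenance <- paste(sort(unique(unlist(strsplit(
        c(set_a$markProvenance[i], set_b$markProvenance[js]), ",")))),
        collapse = ",")
      base
    })
    merged <- do.call(rbind, rows)
  }
  out <- rbind(merged,
               set_a[setdiff(seq_len(nrow(set_a)), m$qa), , drop = FALSE],
               set_b[setdiff(seq_len(nrow(set_b)), m$qb), , drop = FALSE])
  out <- out[order(out$chrom1, out$start1, out$chrom2, out$start2), , drop = FALSE]
  rownames(out) <- NULL
  out
}
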