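#' Pool replicates and deduplicate PETs
#'
#' Concatenates one or more PET tables (e.g. biological replicates) and
#' collapses exact duplicates -- records with identical coordinates of both
#' ends after canonical ordering -- recording the multiplicity in
#' \code{count}. The result carries a \code{stats} attribute with
#' \code{total} (input PET occurrences) and \code{unique} (collapsed records).
#'
#' @param replicates A list of PET data.frames (see \code{\link{read_bedpe}}),
#'   or a single PET data.frame.
#' @return A deduplicated PET data.frame of class \code{pet_set}.
#' @export
pool_and_dedup <- function(replicates) {
  if (is.data.frame(replicates)) replicates <- list(replicates)
  if (!length(replicates)) stop("need at least one replicate", call. = FALSE)
  pets <- do.call(rbind, lapply(replicates, function(x) {
    x <- .canonicalize_pets(x[, c("chrom1", "start1", "end1",
                                  "chrom2", "start2", "end2",
                                  if ("count" %in% names(x)) "count")])
    if (!"count" %in% names(x)) x$count <- 1L
    x
  }))
  total <- sum(pets$count)
  key <- paste(pets$chrom1, pets$start1, pets$end1,
               pets$chrom2, pets$start2, pets$end2, sep = "\r")
  agg <- rowsum(pets$count, key, reorder = FALSE)
  first <- !duplicated(key)
  out <- pets[first, , drop = FALSE]
  out$count <- as.integer(agg[match(key[first], rownames(agg)), 1])
  out <- out[order(out$chrom1, out$start1, out$end1,
                   out$chrom2, out$start2, out$end2), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "stats") <- c(total = total, unique = nrow(out))
  class(out) <- c("pet_set", class(out))
  out
}

#' Genomic span of PETs
#'
#' Midpoint-to-midpoint distance between the two ends of each PET (integer
#' floor midpoints). Chosen over inner-edge distance because it is invariant
#' to read length. Inter-chromosomal PETs get \code{NA}.
#'
#' @param pets PET data.frame.
#' @return Numeric vector of spans (NA for inter-chromosomal PETs).
#' @export
pet_span <- function(pets) {
  span <- abs(.mid(pets$start2, pets$end2) - .mid(pets$start1, pets$end1))
  span[pets$chrom1 != pets$chrom2] <- NA_real_
  span
}

#' Classify PETs as self-ligation, intra- or inter-chromosomal
#'
#' Same-chromosome PETs with span strictly below \code{min_span} (default
#' 10 kb) are self-ligation products of fragment circularization and are
#' excluded from loop calling; spans of exactly \code{min_span} are kept as
#' intra-chromosomal. Different-chromosome PETs are inter-chromosomal.
#'
#' @param pets Deduplicated PET data.frame (see \code{\link{pool_and_dedup}}).
#' @param min_span Minimum genomic span (bp) for a long-range PET; must be > 0.
#' @return The input with a \code{class} column in \{selfLigation, intra,
#'   inter\} and a \code{stats} attribute with selfLigation/intra/inter/unique
#'   counts.
#' @export
classify_pets <- function(pets, min_span = 10000) {
  if (!.is_count(min_span) || min_span <= 0) {
    stop("min_span must be a positive integer", call. = FALSE)
  }
  span <- pet_span(pets)
  cls <- ifelse(is.na(span), "inter",
                ifelse(span < min_span, "selfLigation", "intra"))
  pets$class <- cls
  prev <- attr(pets, "stats")
  if (is.null(prev)) {
    prev <- c(total = sum(if ("count" %in% names(pets)) pets$count else
      rep(1L, nrow(pets))), unique = nrow(pets))
  }
  stats <- c(prev[c("total", "unique")],
             selfLigation = sum(cls == "selfLigation"),
             intra = sum(cls == "intra"),
             inter = sum(cls == "inter"))
  attr(pets, "stats") <- stats
  if (!inherits(pets, "pet_set")) class(pets) <- c("pet_set", class(pets))
  pets
}

#' @export
print.pet_set <- function(x, ...) {
  s <- attr(x, "stats")
  cat("PET set:", nrow(x), "unique PETs\n")
  if (!is.null(s)) {
    for (nm in names(s)) cat(sprintf("  %-13s %d\n", nm, s[[nm]]))
  }
  invisible(x)
}

#' Simple window-based PET peak caller for synthetic data
#'
#' Tiles each chromosome into fixed-size windows, counts PET end midpoints
#' per window, and tests each count against a Poisson null with the
#' genome-wide mean window rate. Adjacent significant windows are merged into
#' one peak whose signal is -log10 of the best window p-value. This is a
#' deliberately minimal enrichment model so synthetic end-to-end runs need no
#' external peak caller; for real data supply MACS peaks via
#' \code{\link{read_peaks}}.
#'
#' @param pets PET data.frame (deduplicated).
#' @param window_size Window width in bp, >= 100.
#' @param p_threshold Poisson upper-tail p-value cutoff per window.
#' @param chrom_sizes Named vector of chromosome lengths; inferred from the
#'   data when NULL.
#' @param mark Mark label to attach to the called peaks.
#' @return Peak data.frame (\code{chrom, start, end, id, signal, mark}).
#' @export
call_pet_peaks_simple <- function(pets, window_size = 500, p_threshold = 1e-9,
                                  chrom_sizes = NULL, mark = "combined") {
  if (!.is_count(window_size) || window_size < 100) {
    stop("window_size must be an integer >= 100", call. = FALSE)
  }
  if (!nrow(pets)) {
    warning("no PETs; returning empty peak set")
    return(.empty_peaks())
  }
  ends <- data.frame(chrom = c(pets$chrom1, pets$chrom2),
                     pos = c(.mid(pets$start1, pets$end1),
                             .mid(pets$start2, pets$end2)))
  if (is.null(chrom_sizes)) {
    chrom_sizes <- tapply(ends$pos, ends$chrom, max) + window_size
  }
  n_windows <- sum(ceiling(chrom_sizes / window_size))
  lambda <- nrow(ends) / n_windows
  peaks <- .empty_peaks()
  for (chrom in names(chrom_sizes)) {
    pos <- ends$pos[ends$chrom == chrom]
    if (!length(pos)) next
    win <- pos %/% window_size
    cnt <- table(win)
    p <- stats::ppois(as.integer(cnt) - 1L, lambda, lower.tail = FALSE)
    sig <- as.integer(names(cnt))[p < p_threshold]
    pv <- p[p < p_threshold]
    if (!length(sig)) next
    o <- order(sig)
    sig <- sig[o]; pv <- pv[o]
    grp <- cumsum(c(1L, diff(sig) > 1L))
    for (g in unique(grp)) {
      w <- sig[grp == g]
      peaks <- rbind(peaks, data.frame(
        chrom = chrom, start = min(w) * window_size,
        end = (max(w) + 1L) * window_size,
        id = paste(mark, chrom, min(w) * window_size, sep = "_"),
        signal = -log10(max(min(pv[grp == g]), .Machine$double.xmin)),
        mark = mark, stringsAsFactors = FALSE))
    }
  }
  rownames(peaks) <- NULL
  peaks
}
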