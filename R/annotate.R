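#' Annotate peaks as proximal (P) or distal (D)
#'
#' A peak is proximal when its interval overlaps (>= 1 bp) the window
#' [tss - window, tss + window) of at least one gene; all overlapped genes are
#' listed. Otherwise it is distal. The overlap is between the peak interval
#' and the TSS window, not a midpoint distance, so the rule is symmetric with
#' the distal-regulatory-region definition ("peak away from TSS").
#'
#' @param peaks Peak data.frame.
#' @param genes Gene data.frame (see \code{\link{read_gff3_genes}}).
#' @param window Half-width of the TSS window in bp (default 2000).
#' @return A data.frame with columns \code{id, type ("P"/"D"), genes
#'   (comma-separated gene ids, "" for D), n_genes}.
#' @export
annotate_peaks <- function(peaks, genes, window = 2000) {
  if (!.is_count(window) || window <= 0) stop("window must be > 0", call. = FALSE)
  ann <- data.frame(id = peaks$id, type = "D", genes = "", n_genes = 0L,
                    stringsAsFactors = FALSE)
  if (nrow(peaks) && nrow(genes)) {
    win <- .gr(genes$chrom, pmax(genes$tss - window, 0L), genes$tss + window)
    hit <- GenomicRanges::findOverlaps(.gr(peaks$chrom, peaks$start, peaks$end), win)
    if (length(hit)) {
      gl <- tapply(genes$id[S4Vectors::subjectHits(hit)],
                   S4Vectors::queryHits(hit),
                   function(g) paste(sort(unique(g)), collapse = ","))
      idx <- as.integer(names(gl))
      ann$genes[idx] <- as.character(gl)
      ann$n_genes[idx] <- lengths(strsplit(as.character(gl), ","))
      ann$type[idx] <- "P"
    }
  }
  ann
}

#' Identify distal regulatory regions (DRs)
#'
#' DRs are H3K27ac peaks at least \code{window} bp away from every TSS, i.e.
#' peaks whose interval does not overlap any [tss - window, tss + window)
#' window. These are the putative enhancers of the ChIA-PET landscape.
#'
#' @param k27_peaks H3K27ac peak data.frame.
#' @param genes Gene data.frame.
#' @param window TSS window half-width (default 2000).
#' @return The subset of \code{k27_peaks} that are DRs.
#' @export
identify_drs <- function(k27_peaks, genes, window = 2000) {
  ann <- annotate_peaks(k27_peaks, genes, window)
  out <- k27_peaks[ann$type == "D", , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify DR genomic location
#'
#' Assigns each DR exactly one label by >= 1 bp overlap with precedence
#' geneBody > downstream2kb > TE > intergenic. "downstream2kb" is the
#' strand-aware 2 kb window past the TTS.
#'
#' @param drs DR peak data.frame.
#' @param genes Gene data.frame.
#' @param tes Optional TE annotation data.frame (\code{chrom, start, end});
#'   NULL or empty means no TE category.
#' @return Character vector of labels, one per DR.
#' @export
classify_dr_location <- function(drs, genes, tes = NULL) {
  n <- nrow(drs)
  lab <- rep("intergenic", n)
  if (!n) return(character(0))
  gr <- .gr(drs$chrom, drs$start, drs$end)
  hit_any <- function(subject) {
    if (is.null(subject) || !length(subject)) return(logical(n))
    seq_len(n) %in% S4Vectors::queryHits(GenomicRanges::findOverlaps(gr, subject))
  }
  te_gr <- if (!is.null(tes) && nrow(tes)) .gr(tes$chrom, tes$start, tes$end)
  lab[hit_any(te_gr)] <- "TE"
  if (nrow(genes)) {
    down_start <- ifelse(genes$strand == "+", genes$end, pmax(genes$start - 2000L, 0L))
    down_end <- ifelse(genes$strand == "+", genes$end + 2000L, genes$start)
    ok <- down_start < down_end
    lab[hit_any(.gr(genes$chrom[ok], down_start[ok], down_end[ok]))] <- "downstream2kb"
    lab[hit_any(.gr(genes$chrom, genes$start, genes$end))] <- "geneBody"
  }
  lab
}

#' Classify interactions into P-P, P-D and D-D
#'
#' Looks up both anchors in a peak annotation table and stores the anchor
#' types and the interaction class (PP if both proximal, DD if both distal,
#' PD otherwise -- order-invariant).
#'
#' @param interactions Interaction data.frame.
#' @param annotations Annotation data.frame from \code{\link{annotate_peaks}}.
#' @return The interactions with \code{anchor1Type}, \code{anchor2Type} and
#'   \code{class} filled in.
#' @export
classify_interactions <- function(interactions, annotations) {
  if (!nrow(interactions)) return(interactions)
  ia <- match(interactions$anchorA, annotations$id)
  ib <- match(interactions$anchorB, annotations$id)
  if (anyNA(ia) || anyNA(ib)) {
    missing <- c(interactions$anchorA[is.na(ia)], interactions$anchorB[is.na(ib)])
    stop("no annotation for anchor(s): ",
         paste(utils::head(missing, 3), collapse = ", "), call. = FALSE)
  }
  ta <- annotations$type[ia]
  tb <- annotations$type[ib]
  interactions$anchor1Type <- ta
  interactions$anchor2Type <- tb
  interactions$class <- ifelse(ta == "P" & tb == "P", "PP",
                               ifelse(ta == "D" & tb == "D", "DD", "PD"))
  interactions
}

#' Anchor-midpoint distance of intra-chromosomal interactions
#'
#' @param interactions Interaction data.frame; all records must be
#'   intra-chromosomal.
#' @return Numeric vector of |midpoint(anchorB) - midpoint(anchorA)|.
#' @export
interaction_distance <- function(interactions) {
  if (any(interactions$chrom1 != interactions$chrom2)) {
    stop("interaction_distance is defined for intra-chromosomal interactions only",
         call. = FALSE)
  }
  abs(.mid(interactions$start2, interactions$end2) -
        .mid(interactions$start1, interactions$end1))
}

#' Histogram of interaction distances
#'
#' Counts interactions in half-open distance bins. \code{edges} are interior
#' cut points over the implicit support [0, Inf), so with the defaults the
#' bins are [0,10k), [10k,50k), [50k,100k), [100k,1M), [1M,Inf) and the bin
#' masses always sum to the number of input interactions.
#'
#' @param interactions Intra-chromosomal interaction data.frame.
#' @param edges Strictly increasing interior bin edges (bp).
#' @return Named integer vector of per-bin counts.
#' @export
distance_bins <- function(interactions, edges = c(1e4, 5e4, 1e5, 1e6)) {
  if (is.unsorted(edges, strictly = TRUE)) {
    stop("edges must be strictly increasing", call. = FALSE)
  }
  breaks <- c(0, edges, Inf)
  d <- interaction_distance(interactions)
  cuts <- cut(d, breaks = breaks, right = FALSE, dig.lab = 12)
  out <- table(cuts)
  stats::setNames(as.integer(out), names(out))
}

#' Promoter-enhancer connectivity statistics
#'
#' For P-D interactions only: the number of distinct D partners per P anchor
#' and distinct P partners per D anchor (distinctness by peak id), plus the
#' means. Mirrors the one-promoter-many-enhancer connectivity summaries of
#' ChIA-PET studies.
#'
#' @param interactions Classified interaction data.frame.
#' @return A list with \code{d_per_p} and \code{p_per_d} (named integer
#'   vectors: anchor id -> partner count), and \code{mean_d_per_p},
#'   \code{mean_p_per_d}.
#' @export
connectivity_stats <- function(interactions) {
  pd <- interactions[!is.na(interactions$class) & interactions$class == "PD", ,
                     drop = FALSE]
  if (!nrow(pd)) {
    return(list(d_per_p = integer(0), p_per_d = integer(0),
                mean_d_per_p = NaN, mean_p_per_d = NaN))
  }
  p_anchor <- ifelse(pd$anchor1Type == "P", pd$anchorA, pd$anchorB)
  d_anchor <- ifelse(pd$anchor1Type == "P", pd$anchorB, pd$anchorA)
  pairs <- unique(data.frame(p = p_anchor, d = d_anchor, stringsAsFactors = FALSE))
  d_per_p <- vapply(split(pairs$d, pairs$p), function(x) length(unique(x)), integer(1))
  p_per_d <- vapply(split(pairs$p, pairs$d), function(x) length(unique(x)), integer(1))
  list(d_per_p = d_per_p, p_per_d = p_per_d,
       mean_d_per_p = mean(d_per_p), mean_p_per_d = mean(p_per_d))
}

#' Genes skipped by P-D interactions
#'
#' For each intra-chromosomal P-D interaction, the genes whose TSS lies
#' strictly between the two anchor midpoints and whose TSS window overlaps
#' neither anchor. When an expression matrix is supplied, the "typically
#' expressed" subset (mean FPKM over \code{samples} >= \code{fpkm_min}) is
#' also reported.
#'
#' @param interactions Classified interaction data.frame (P-D rows are used;
#'   passing anything else is an error).
#' @param genes Gene data.frame.
#' @param expr Optional expression matrix.
#' @param samples Sample ids for the expression average (default all).
#' @param window TSS window half-width (default 2000).
#' @param fpkm_min Expression threshold for "typically expressed" (default 1).
#' @return A list with \code{skipped} and (if \code{expr} given)
#'   \code{skipped_expressed}: per-interaction character vectors of gene ids.
#' @export
skipped_genes <- function(interactions, genes, expr = NULL, samples = NULL,
                          window = 2000, fpkm_min = 1) {
  if (!nrow(interactions)) return(list(skipped = list(), skipped_expressed = list()))
  if (any(is.na(interactions$class) | interactions$class != "PD")) {
    stop("skipped_genes expects P-D interactions only", call. = FALSE)
  }
  if (any(interactions$chrom1 != interactions$chrom2)) {
    stop("skipped_genes expects intra-chromosomal interactions", call. = FALSE)
  }
  mid1 <- .mid(interactions$start1, interactions$end1)
  mid2 <- .mid(interactions$start2, interactions$end2)
  lo <- pmin(mid1, mid2); hi <- pmax(mid1, mid2)
  expressed <- NULL
  if (!is.null(expr)) {
    if (is.null(samples)) samples <- colnames(expr)
    expressed <- rownames(expr)[rowMeans(expr[, samples, drop = FALSE]) >= fpkm_min]
  }
  win_lo <- genes$tss - window
  win_hi <- genes$tss + window  # [tss-w, tss+w)
  skipped <- vector("list", nrow(interactions))
  skipped_expr <- vector("list", nrow(interactions))
  for (i in seq_len(nrow(interactions))) {
    g <- genes[genes$chrom == interactions$chrom1[i] &
                 genes$tss > lo[i] & genes$tss < hi[i], , drop = FALSE]
    if (nrow(g)) {
      wl <- win_lo[match(g$id, genes$id)]
      wh <- win_hi[match(g$id, genes$id)]
      clear <- !(wl < interactions$end1[i] & wh > interactions$start1[i]) &
        !(wl < interactions$end2[i] & wh > interactions$start2[i])
      g <- g[clear, , drop = FALSE]
    }
    skipped[[i]] <- g$id
    if (!is.null(expressed)) skipped_expr[[i]] <- intersect(g$id, expressed)
  }
  out <- list(skipped = skipped)
  if (!is.null(expressed)) out$skipped_expressed <- skipped_expr
  out
}
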