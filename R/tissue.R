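#' Tissue-specific expressed genes
#'
#' Stringent two-tissue rule: a gene is specific to tissue B when its mean
#' FPKM over tissue A's samples is exactly 0 and its mean over tissue B's
#' samples is at least \code{min_fpkm} (default 2), and symmetrically for A.
#' All other genes are common/unclassified.
#'
#' @param expr Expression matrix.
#' @param group_a,group_b Disjoint sample-id groups (>= 1 sample each).
#' @param min_fpkm Expression floor in the expressing tissue (default 2).
#' @return List with \code{a_specific}, \code{b_specific} (gene-id vectors)
#'   and \code{fpkm} (data.frame of per-tissue means).
#' @export
tissue_specific_genes <- function(expr, group_a, group_b, min_fpkm = 2) {
  if (!length(group_a) || !length(group_b)) {
    stop("both sample groups must be non-empty", call. = FALSE)
  }
  if (length(intersect(group_a, group_b))) {
    stop("sample groups overlap", call. = FALSE)
  }
  missing <- setdiff(c(group_a, group_b), colnames(expr))
  if (length(missing)) {
    stop("unknown sample(s): ", paste(utils::head(missing, 3), collapse = ", "),
         call. = FALSE)
  }
  ma <- rowMeans(expr[, group_a, drop = FALSE])
  mb <- rowMeans(expr[, group_b, drop = FALSE])
  list(a_specific = rownames(expr)[mb == 0 & ma >= min_fpkm],
       b_specific = rownames(expr)[ma == 0 & mb >= min_fpkm],
       fpkm = data.frame(gene = rownames(expr), fpkm_a = ma, fpkm_b = mb,
                         row.names = NULL, stringsAsFactors = FALSE))
}

#' Tissue-specific and common chromatin interactions
#'
#' Compares the combined-mark interaction sets of two tissues. An interaction
#' of tissue A is common when some interaction of tissue B matches it (both
#' anchors reciprocally overlap by >= 1 bp, the same rule used for mark
#' merging), otherwise it is A-specific; symmetrically for B.
#'
#' @param interactions_a,interactions_b Classified interaction data.frames.
#' @return List with \code{a_specific}, \code{b_specific}, \code{a_common},
#'   \code{b_common} (row subsets of the inputs).
#' @export
tissue_specific_interactions <- function(interactions_a, interactions_b) {
  for (x in list(interactions_a, interactions_b)) {
    if (nrow(x) && any(is.na(x$class))) {
      stop("interactions must be classified (run classify_interactions)",
           call. = FALSE)
    }
  }
  m <- .match_interactions(interactions_a, interactions_b)
  ca <- sort(unique(m$qa))
  cb <- sort(unique(m$qb))
  list(a_specific = interactions_a[setdiff(seq_len(nrow(interactions_a)), ca), ,
                                   drop = FALSE],
       b_specific = interactions_b[setdiff(seq_len(nrow(interactions_b)), cb), ,
                                   drop = FALSE],
       a_common = interactions_a[ca, , drop = FALSE],
       b_common = interactions_b[cb, , drop = FALSE])
}

#' Promoter interaction strength per gene
#'
#' For each gene, the number of intra-chromosomal PETs with at least one end
#' midpoint inside the promoter window [tss - window, tss + window); a PET
#' with both ends in the window counts once.
#'
#' @param pets Classified PET data.frame.
#' @param genes Gene data.frame.
#' @param gene_set Optional gene ids to report (default all).
#' @param window Promoter window half-width (default 2000).
#' @return Named integer vector, gene id -> PET count.
#' @export
interaction_strength_at_genes <- function(pets, genes, gene_set = NULL,
                                          window = 2000) {
  if (is.null(gene_set)) gene_set <- genes$id
  genes <- genes[genes$id %in% gene_set, , drop = FALSE]
  if ("class" %in% names(pets)) pets <- pets[pets$class == "intra", , drop = FALSE]
  counts <- stats::setNames(integer(nrow(genes)), genes$id)
  if (nrow(pets) && nrow(genes)) {
    win <- .gr(genes$chrom, pmax(genes$tss - window, 0L), genes$tss + window)
    h1 <- GenomicRanges::findOverlaps(
      .gr_points(pets$chrom1, .mid(pets$start1, pets$end1)), win)
    h2 <- GenomicRanges::findOverlaps(
      .gr_points(pets$chrom2, .mid(pets$start2, pets$end2)), win)
    pairs <- unique(rbind(
      data.frame(pet = S4Vectors::queryHits(h1), gene = S4Vectors::subjectHits(h1)),
      data.frame(pet = S4Vectors::queryHits(h2), gene = S4Vectors::subjectHits(h2))))
    tab <- table(factor(pairs$gene, levels = seq_len(nrow(genes))))
    counts[] <- as.integer(tab)
  }
  counts[gene_set[gene_set %in% names(counts)]]
}

#' Class enrichment among tissue-specific vs common interactions
#'
#' For each interaction class (PP/PD/DD), compares its frequency among
#' tissue-specific interactions with its frequency among common interactions
#' using a 2x2 contingency table, two-sided Fisher exact test and odds ratio.
#'
#' @param specific Classified tissue-specific interaction data.frame (both
#'   tissues pooled or one tissue, as desired).
#' @param common Classified common interaction data.frame.
#' @return Data.frame with per-class counts, fractions, odds ratio, p-value
#'   and an \code{undefined} flag for empty classes.
#' @export
specificity_enrichment <- function(specific, common) {
  classes <- c("PP", "PD", "DD")
  rows <- lapply(classes, function(cl) {
    a <- sum(specific$class == cl); b <- nrow(specific) - a
    c_ <- sum(common$class == cl); d <- nrow(common) - c_
    undefined <- (a + c_) == 0 || nrow(specific) == 0 || nrow(common) == 0
    if (!undefined) {
      ft <- stats::fisher.test(matrix(c(a, b, c_, d), nrow = 2))
      or <- unname(ft$estimate); pv <- ft$p.value
    } else {
      or <- NA_real_; pv <- NA_real_
    }
    data.frame(class = cl, n_specific = a, n_common = c_,
               frac_specific = if (nrow(specific)) a / nrow(specific) else NaN,
               frac_common = if (nrow(common)) c_ / nrow(common) else NaN,
               odds_ratio = or, p_value = pv, undefined = undefined,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
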