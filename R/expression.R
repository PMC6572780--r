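#' Transcriptional activity call
#'
#' A gene is "active" when its mean FPKM over the given samples is at least
#' \code{threshold} (default 1, the conventional FPKM cutoff).
#'
#' @param expr Expression matrix (genes x samples).
#' @param genes Gene ids to call (default all rows).
#' @param samples Sample ids to average over (default all columns).
#' @param threshold Activity threshold on mean FPKM (default 1).
#' @return Named character vector, "active"/"inactive" per gene.
#' @export
activity_call <- function(expr, genes = NULL, samples = NULL, threshold = 1) {
  if (is.null(genes)) genes <- rownames(expr)
  if (is.null(samples)) samples <- colnames(expr)
  missing <- setdiff(genes, rownames(expr))
  if (length(missing)) {
    stop("unknown gene(s): ", paste(utils::head(missing, 3), collapse = ", "),
         call. = FALSE)
  }
  m <- rowMeans(expr[genes, samples, drop = FALSE])
  stats::setNames(ifelse(m >= threshold, "active", "inactive"), genes)
}

#' Shannon entropy of expression profiles
#'
#' Tissue-specificity entropy per gene: with relative expression
#' p_t = w_t / sum(w) over the N samples, H = sum(-p_t log2 p_t) with
#' 0 log2 0 := 0. H ranges from 0 (expressed in a single sample, maximally
#' tissue-restricted) to log2(N) (uniform, constitutive). Genes with
#' all-zero expression have no defined profile and get NA with a warning;
#' exclude them upstream.
#'
#' @param expr Expression matrix (genes x samples).
#' @param genes Gene ids (default all rows).
#' @return Named numeric vector of entropies in bits.
#' @export
shannon_entropy <- function(expr, genes = NULL) {
  if (is.null(genes)) genes <- rownames(expr)
  w <- expr[genes, , drop = FALSE]
  tot <- rowSums(w)
  zero <- tot == 0
  if (any(zero)) {
    warning(sum(zero), " gene(s) with all-zero expression excluded from entropy")
  }
  p <- w / ifelse(tot > 0, tot, 1)
  h <- -rowSums(ifelse(p > 0, p * log2(p), 0))
  h[zero] <- NA_real_
  stats::setNames(h, genes)
}

#' Co-expression of P-P interacting promoter pairs vs shifted controls
#'
#' Tests whether gene pairs whose promoters are connected by a P-P
#' interaction are more co-expressed than distance-matched random controls.
#' Eligible pairs: P-P interactions where each anchor overlaps exactly one
#' gene promoter window and the two genes differ. Observed values are the
#' per-pair Pearson correlations across the sample panel. Controls: each
#' eligible interaction is shifted along its chromosome by a uniform random
#' offset (anchor distance preserved exactly, anchors kept inside the
#' chromosome) \code{n_shifts} times; a shifted loop is retained when both
#' shifted anchors overlap promoter windows of two different genes and both
#' overlap a peak whose signal reaches the \code{signal_quantile} quantile of
#' the peak signals at real interacting anchors (a reproducible proxy for
#' "similar H3K4me3/H3K27ac level"). Observed and control correlation sets
#' are compared with a two-sided Welch t test.
#'
#' @param interactions Classified interaction data.frame.
#' @param annotations Peak annotations from \code{\link{annotate_peaks}}.
#' @param genes Gene data.frame.
#' @param expr Expression matrix.
#' @param peaks Peak data.frame (for the control signal filter).
#' @param chrom_sizes Named vector of chromosome lengths (bp).
#' @param n_shifts Shifts per interaction (default 100).
#' @param seed RNG seed for the shifts.
#' @param signal_quantile Control peak-signal quantile filter (default 0.25).
#' @param samples Sample panel (default all columns of \code{expr}).
#' @param window Promoter window half-width (default 2000).
#' @return An object of class \code{coexpression_test}: list with
#'   \code{observed}, \code{control} (correlation vectors), \code{statistic},
#'   \code{p_value}, \code{n_obs}, \code{n_ctrl}, \code{signal_threshold},
#'   \code{seed}.
#' @export
coexpression_test <- function(interactions, annotations, genes, expr, peaks,
                              chrom_sizes, n_shifts = 100, seed = 1,
                              signal_quantile = 0.25, samples = NULL,
                              window = 2000) {
  if (!.is_count(n_shifts) || n_shifts < 1) {
    stop("n_shifts must be a positive integer", call. = FALSE)
  }
  if (is.null(samples)) samples <- colnames(expr)
  if (length(samples) < 2) stop("need >= 2 samples for correlations", call. = FALSE)
  pp <- interactions[!is.na(interactions$class) & interactions$class == "PP", ,
                     drop = FALSE]
  ann_genes <- function(ids) {
    idx <- match(ids, annotations$id)
    list(n = annotations$n_genes[idx], g = annotations$genes[idx])
  }
  a1 <- ann_genes(pp$anchorA)
  a2 <- ann_genes(pp$anchorB)
  elig <- !is.na(a1$n) & !is.na(a2$n) & a1$n == 1 & a2$n == 1 &
    a1$g != a2$g & a1$g %in% rownames(expr) & a2$g %in% rownames(expr)
  pp <- pp[elig, , drop = FALSE]
  g1 <- a1$g[elig]; g2 <- a2$g[elig]
  if (!nrow(pp)) {
    warning("no eligible P-P promoter pairs")
    return(structure(list(observed = numeric(0), control = numeric(0),
                          statistic = NA_real_, p_value = NA_real_,
                          n_obs = 0L, n_ctrl = 0L,
                          signal_threshold = NA_real_, seed = seed),
                     class = "coexpression_test"))
  }
  ex <- expr[, samples, drop = FALSE]
  observed <- vapply(seq_len(nrow(pp)),
                     function(i) stats::cor(ex[g1[i], ], ex[g2[i], ]),
                     numeric(1))

  # signal landscape at real interacting anchors
  pk_gr <- .gr(peaks$chrom, peaks$start, peaks$end)
  anchor_gr <- .gr(c(pp$chrom1, pp$chrom2), c(pp$start1, pp$start2),
                   c(pp$end1, pp$end2))
  hit <- GenomicRanges::findOverlaps(anchor_gr, pk_gr)
  anchor_sig <- tapply(peaks$signal[S4Vectors::subjectHits(hit)],
                       S4Vectors::queryHits(hit), max)
  sig_thr <- stats::quantile(as.numeric(anchor_sig), signal_quantile, names = FALSE)
  prom_gr <- .gr(genes$chrom, pmax(genes$tss - window, 0L), genes$tss + window)

  set.seed(seed)
  n <- nrow(pp)
  m <- n * n_shifts
  len <- rep(chrom_sizes[pp$chrom1], n_shifts)
  span <- rep(pp$end2 - pp$start1, n_shifts)
  new_start <- floor(stats::runif(m, 0, pmax(len - span, 1)))
  delta <- new_start - rep(pp$start1, n_shifts)
  sh1 <- .gr(rep(pp$chrom1, n_shifts), rep(pp$start1, n_shifts) + delta,
             rep(pp$end1, n_shifts) + delta)
  sh2 <- .gr(rep(pp$chrom2, n_shifts), rep(pp$start2, n_shifts) + delta,
             rep(pp$end2, n_shifts) + delta)
  one_gene <- function(sh) {
    hits <- GenomicRanges::findOverlaps(sh, prom_gr)
    q <- S4Vectors::queryHits(hits)
    cnt <- tabulate(q, m)
    g <- rep(NA_character_, m)
    g[q[cnt[q] == 1L]] <- genes$id[S4Vectors::subjectHits(hits)[cnt[q] == 1L]]
    g
  }
  cg1 <- one_gene(sh1)
  cg2 <- one_gene(sh2)
  peak_ok <- function(sh) {
    hits <- GenomicRanges::findOverlaps(sh, pk_gr)
    best <- tapply(peaks$signal[S4Vectors::subjectHits(hits)],
                   S4Vectors::queryHits(hits), max)
    ok <- logical(m)
    ok[as.integer(names(best))] <- as.numeric(best) >= sig_thr
    ok
  }
  keep <- !is.na(cg1) & !is.na(cg2) & cg1 != cg2 &
    cg1 %in% rownames(expr) & cg2 %in% rownames(expr) &
    peak_ok(sh1) & peak_ok(sh2)
  ctrl_g1 <- cg1[keep]
  ctrl_g2 <- cg2[keep]
  control <- if (length(ctrl_g1)) {
    vapply(seq_along(ctrl_g1),
           function(i) stats::cor(ex[ctrl_g1[i], ], ex[ctrl_g2[i], ]),
           numeric(1))
  } else numeric(0)
  control <- control[!is.na(control)]
  tt <- if (length(observed) >= 2 && length(control) >= 2) {
    stats::t.test(observed, control, alternative = "two.sided")
  } else NULL
  structure(list(observed = observed, control = control,
                 statistic = if (is.null(tt)) NA_real_ else unname(tt$statistic),
                 p_value = if (is.null(tt)) NA_real_ else tt$p.value,
                 n_obs = length(observed), n_ctrl = length(control),
                 signal_threshold = sig_thr, seed = seed),
            class = "coexpression_test")
}

#' @export
print.coexpression_test <- function(x, ...) {
  cat("P-P promoter co-expression vs shifted controls\n")
  cat(sprintf("  observed pairs: %d (mean r = %.3f)\n", x$n_obs,
              mean(x$observed)))
  cat(sprintf("  control pairs:  %d (mean r = %.3f)\n", x$n_ctrl,
              if (x$n_ctrl) mean(x$control) else NaN))
  cat(sprintf("  Welch t = %.3f, two-sided p = %.3g\n", x$statistic, x$p_value))
  invisible(x)
}

#' Shannon entropy by distal-anchor context
#'
#' Groups genes by how they relate to distal (D) anchors and reports
#' per-gene entropies per group. Following the genic/intergenic dichotomy,
#' a D anchor is "genic" when it overlaps any gene body and "intergenic"
#' otherwise. Groups (not mutually exclusive):
#' \describe{
#'   \item{interactsGenicD}{genes on the P side of a P-D interaction whose D
#'     anchor is genic}
#'   \item{interactsIntergenicD}{likewise with an intergenic D anchor}
#'   \item{dInOwnBody}{genes whose own body overlaps a distal peak,
#'     regardless of interactions}
#'   \item{control}{genes not interacting with intergenic D whose promoter
#'     window overlaps an H3K4me3/H3K27ac peak}
#' }
#' Also returns strata of interactsIntergenicD genes by their number of
#' distinct intergenic D partners (1, 2, >=3).
#'
#' @param interactions Classified interaction data.frame.
#' @param annotations Peak annotations from \code{\link{annotate_peaks}}.
#' @param genes Gene data.frame.
#' @param expr Expression matrix.
#' @param peaks Peak data.frame.
#' @param window Promoter window half-width for the control group.
#' @return List with \code{groups} (data.frame gene/group/entropy),
#'   \code{strata} (data.frame gene/n_intergenic_d/stratum/entropy) and
#'   \code{n_samples}.
#' @export
entropy_by_context <- function(interactions, annotations, genes, expr, peaks,
                               window = 2000) {
  h <- suppressWarnings(shannon_entropy(expr))
  h <- h[!is.na(h)]
  pd <- interactions[!is.na(interactions$class) & interactions$class == "PD", ,
                     drop = FALSE]
  gene_gr <- .gr(genes$chrom, genes$start, genes$end)
  genic_hit <- function(chrom, start, end) {
    ov <- GenomicRanges::findOverlaps(.gr(chrom, start, end), gene_gr)
    seq_along(chrom) %in% S4Vectors::queryHits(ov)
  }
  p_genes <- character(0); d_id <- character(0); d_genic <- logical(0)
  if (nrow(pd)) {
    p_first <- pd$anchor1Type == "P"
    p_anchor <- ifelse(p_first, pd$anchorA, pd$anchorB)
    d_anchor <- ifelse(p_first, pd$anchorB, pd$anchorA)
    d_chrom <- ifelse(p_first, pd$chrom2, pd$chrom1)
    d_start <- ifelse(p_first, pd$start2, pd$start1)
    d_end <- ifelse(p_first, pd$end2, pd$end1)
    genic <- genic_hit(d_chrom, d_start, d_end)
    glist <- strsplit(annotations$genes[match(p_anchor, annotations$id)], ",")
    reps <- lengths(glist)
    p_genes <- unlist(glist)
    d_id <- rep(d_anchor, reps)
    d_genic <- rep(genic, reps)
  }
  grp <- list()
  grp$interactsGenicD <- unique(p_genes[d_genic])
  grp$interactsIntergenicD <- unique(p_genes[!d_genic])
  # genes hosting a distal peak in their own body
  d_peaks <- peaks[peaks$id %in% annotations$id[annotations$type == "D"], ,
                   drop = FALSE]
  host <- character(0)
  if (nrow(d_peaks)) {
    ov <- GenomicRanges::findOverlaps(gene_gr, .gr(d_peaks$chrom, d_peaks$start,
                                                   d_peaks$end))
    host <- unique(genes$id[S4Vectors::queryHits(ov)])
  }
  grp$dInOwnBody <- host
  prom_gr <- .gr(genes$chrom, pmax(genes$tss - window, 0L), genes$tss + window)
  ovp <- GenomicRanges::findOverlaps(prom_gr, .gr(peaks$chrom, peaks$start,
                                                  peaks$end))
  marked <- unique(genes$id[S4Vectors::queryHits(ovp)])
  grp$control <- setdiff(marked, grp$interactsIntergenicD)
  groups <- do.call(rbind, lapply(names(grp), function(nm) {
    g <- intersect(grp[[nm]], names(h))
    if (!length(g)) return(NULL)
    data.frame(gene = g, group = nm, entropy = unname(h[g]),
               stringsAsFactors = FALSE)
  }))
  if (is.null(groups)) {
    groups <- data.frame(gene = character(0), group = character(0),
                         entropy = numeric(0), stringsAsFactors = FALSE)
  }
  # strata by number of distinct intergenic D partners
  strata <- data.frame(gene = character(0), n_intergenic_d = integer(0),
                       stratum = character(0), entropy = numeric(0),
                       stringsAsFactors = FALSE)
  if (length(p_genes)) {
    tab <- tapply(d_id[!d_genic], p_genes[!d_genic],
                  function(x) length(unique(x)))
    g <- intersect(names(tab), names(h))
    if (length(g)) {
      nd <- as.integer(tab[g])
      strata <- data.frame(gene = g, n_intergenic_d = nd,
                           stratum = ifelse(nd >= 3, ">=3", as.character(nd)),
                           entropy = unname(h[g]), stringsAsFactors = FALSE)
    }
  }
  list(groups = groups, strata = strata, n_samples = ncol(expr))
}
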