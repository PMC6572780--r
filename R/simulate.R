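#' Configuration for the synthetic ChIA-PET data generator
#'
#' Bundles and validates every knob of the simulator. The defaults define the
#' package's reference scenario: a desk-scale two-chromosome genome with 300
#' genes and 200 planted loops in the 0.60/0.35/0.05 P-P/P-D/D-D mix typical
#' of promoter-centred ChIA-PET landscapes, 50,000 background PETs with
#' power-law distance decay, 30\% self-ligation contamination, 10\%
#' inter-chromosomal noise (about 90\% of PETs intra-chromosomal), 2 kb
#' anchors, and a 78-sample expression panel shaped as 53 "seed" plus 25
#' "non-seed" samples.
#'
#' @param seed Master RNG seed; every simulator stage derives its stream from
#'   it, so (config, seed) reproduces outputs exactly.
#' @param n_chroms,chrom_length Number and length (bp) of chromosomes.
#' @param n_genes Total genes, spread evenly across chromosomes.
#' @param n_distal_peaks Distal (enhancer-like) peaks, >= 2 kb from all TSS.
#' @param n_loops Planted loops.
#' @param loop_class_mix Named proportions over PP/PD/DD, summing to 1.
#' @param loop_pet_mean Expected PETs per planted loop (Poisson mean).
#' @param background_pets Total non-loop PETs (self-ligation + inter +
#'   distance-decay intra).
#' @param decay_exponent alpha of the background contact density P(d) ~ d^-alpha.
#' @param self_lig_fraction,inter_fraction Fractions of background PETs that
#'   are self-ligation (span uniform in [100, 9999]) or inter-chromosomal.
#' @param n_samples,n_seed_samples Expression panel size and size of its
#'   first ("seed") block; the remaining samples form the second block used
#'   as the other tissue group.
#' @param coexpression_rho Target Pearson correlation of planted co-expressed
#'   gene pairs.
#' @param n_tissue_specific_genes Genes planted with FPKM exactly 0 in one
#'   tissue group and mean >= 2 in the other (split between tissues).
#' @param shared_loop_fraction In two-tissue mode, the fraction of planted
#'   loops present in both tissues.
#' @param peak_width Anchor/peak width (bp).
#' @param read_width Mapped read-end width (bp).
#' @param n_te,te_width Transposable-element annotation intervals.
#' @param distal_mix Named proportions over geneBody/downstream2kb/TE/
#'   intergenic placement targets for distal peaks.
#' @return A validated list of class \code{sim_config}.
#' @export
sim_config <- function(seed = 1, n_chroms = 2, chrom_length = 20e6,
                       n_genes = 300, n_distal_peaks = 300, n_loops = 200,
                       loop_class_mix = c(PP = 0.60, PD = 0.35, DD = 0.05),
                       loop_pet_mean = 10, background_pets = 50000,
                       decay_exponent = 1.0, self_lig_fraction = 0.30,
                       inter_fraction = 0.10, n_samples = 78,
                       n_seed_samples = 53, coexpression_rho = 0.6,
                       n_tissue_specific_genes = 40,
                       shared_loop_fraction = 0.55, peak_width = 2000,
                       read_width = 100, n_te = 150, te_width = 5000,
                       distal_mix = c(geneBody = 0.15, downstream2kb = 0.10,
                                      TE = 0.20, intergenic = 0.55)) {
  cfg <- list(seed = seed, n_chroms = n_chroms, chrom_length = chrom_length,
              n_genes = n_genes, n_distal_peaks = n_distal_peaks,
              n_loops = n_loops, loop_class_mix = loop_class_mix,
              loop_pet_mean = loop_pet_mean, background_pets = background_pets,
              decay_exponent = decay_exponent,
              self_lig_fraction = self_lig_fraction,
              inter_fraction = inter_fraction, n_samples = n_samples,
              n_seed_samples = n_seed_samples,
              coexpression_rho = coexpression_rho,
              n_tissue_specific_genes = n_tissue_specific_genes,
              shared_loop_fraction = shared_loop_fraction,
              peak_width = peak_width, read_width = read_width,
              n_te = n_te, te_width = te_width, distal_mix = distal_mix)
  stopifnot(.is_count(seed), .is_count(n_chroms), n_chroms >= 1,
            chrom_length > 1e5, n_genes >= 0, n_distal_peaks >= 0,
            n_loops >= 0, loop_pet_mean > 0, background_pets >= 0,
            decay_exponent > 0, n_samples >= 2,
            n_seed_samples >= 1, n_seed_samples < n_samples,
            peak_width > read_width, read_width >= 10)
  if (abs(sum(loop_class_mix) - 1) > 1e-8 ||
      !all(c("PP", "PD", "DD") %in% names(loop_class_mix))) {
    stop("loop_class_mix must be named PP/PD/DD proportions summing to 1",
         call. = FALSE)
  }
  fr <- c(self_lig_fraction, inter_fraction, shared_loop_fraction,
          coexpression_rho)
  if (any(fr < 0 | fr > 1) || self_lig_fraction + inter_fraction > 1) {
    stop("fractions must lie in [0, 1] (and self + inter <= 1)", call. = FALSE)
  }
  structure(cfg, class = "sim_config")
}

# deterministic per-stage RNG streams derived from the master seed
.sim_seed <- function(config, stage, offset = 0L) {
  stages <- c(genome = 1L, truth = 2L, pets = 3L, expression = 4L, terms = 5L)
  set.seed((config$seed * 101L + stages[[stage]] + offset) %% .Machine$integer.max)
}

#' Simulate a genome annotation: genes, peaks, TEs
#'
#' Genes are placed with >= 12 kb spacing and random strands; every gene gets
#' one proximal H3K4me3-like peak overlapping its TSS window, and
#' \code{n_distal_peaks} H3K27ac-like distal peaks are placed at least 2 kb
#' from every TSS, in gene bodies, downstream windows, TE intervals and
#' intergenic space per \code{distal_mix}. All peaks are mutually
#' non-overlapping by construction; peak signals are log-normal.
#'
#' @param config A \code{\link{sim_config}}.
#' @return List with \code{genes}, \code{peaks} (with mark column),
#'   \code{tes}, \code{chrom_sizes}.
#' @export
simulate_genome <- function(config) {
  .sim_seed(config, "genome")
  w <- config$peak_width
  chroms <- paste0("chr", seq_len(config$n_chroms))
  chrom_sizes <- stats::setNames(rep(config$chrom_length, config$n_chroms),
                                 chroms)
  per <- diff(round(seq(0, config$n_genes, length.out = config$n_chroms + 1)))
  genes_list <- list()
  gi <- 0L
  for (ci in seq_along(chroms)) {
    n <- per[ci]
    if (!n) next
    len <- pmin(pmax(round(stats::rlnorm(n, log(3000), 0.6)), 800L), 30000L)
    budget <- config$chrom_length - sum(len) - 40000
    mean_gap <- budget / n
    if (mean_gap < 12000) {
      stop("genome too small for the requested gene count", call. = FALSE)
    }
    gaps <- 12000 + round(stats::rexp(n, 1 / (mean_gap - 12000)))
    start <- 20000 + c(0, cumsum(len[-n] + gaps[-n]))
    keep <- start + len < config$chrom_length - 20000
    len <- len[keep]; start <- start[keep]; n <- sum(keep)
    strand <- sample(c("+", "-"), n, replace = TRUE)
    id <- sprintf("g%04d", gi + seq_len(n))
    gi <- gi + n
    end <- start + len
    genes_list[[ci]] <- data.frame(
      id = id, chrom = chroms[ci], start = as.integer(start),
      end = as.integer(end), strand = strand,
      tss = as.integer(ifelse(strand == "+", start, end - 1L)),
      tts = as.integer(ifelse(strand == "+", end - 1L, start)),
      stringsAsFactors = FALSE)
  }
  genes <- do.call(rbind, genes_list)
  if (is.null(genes)) {
    genes <- data.frame(id = character(0), chrom = character(0),
                        start = integer(0), end = integer(0),
                        strand = character(0), tss = integer(0),
                        tts = integer(0), stringsAsFactors = FALSE)
  }
  # proximal peak per gene, centred near the TSS
  n_p <- nrow(genes)
  prox_start <- pmax(genes$tss - w %/% 2 + sample(-300:300, n_p, replace = TRUE),
                     0L)
  prox <- data.frame(chrom = genes$chrom, start = as.integer(prox_start),
                     end = as.integer(prox_start + w),
                     id = if (n_p) paste0("P_", genes$id) else character(0),
                     signal = stats::rlnorm(n_p, log(20), 1),
                     mark = rep("H3K4me3", n_p), stringsAsFactors = FALSE)

  tes <- data.frame(chrom = sample(chroms, config$n_te, replace = TRUE),
                    start = as.integer(floor(stats::runif(
                      config$n_te, 0, config$chrom_length - config$te_width))),
                    stringsAsFactors = FALSE)
  tes$end <- tes$start + as.integer(config$te_width)
  tes <- tes[order(tes$chrom, tes$start), , drop = FALSE]
  rownames(tes) <- NULL

  # distal peaks: >= 2 kb from every TSS window, never overlapping other peaks
  n_d <- config$n_distal_peaks
  cat_n <- round(n_d * config$distal_mix)
  cat_n["intergenic"] <- n_d - sum(cat_n[c("geneBody", "downstream2kb", "TE")])
  occupied <- stats::setNames(lapply(chroms, function(ch) {
    prox[prox$chrom == ch, c("chrom", "start", "end"), drop = FALSE]
  }), chroms)
  tss_win <- data.frame(chrom = genes$chrom,
                        start = pmax(genes$tss - 2000L, 0L),
                        end = genes$tss + 2000L)
  clash <- function(chrom, start, end) {
    occ <- occupied[[chrom]]
    tw <- tss_win[tss_win$chrom == chrom, , drop = FALSE]
    any(occ$start < end & occ$end > start) ||
      any(tw$start < end & tw$end > start)
  }
  add_peak <- function(chrom, start) {
    occupied[[chrom]] <<- rbind(occupied[[chrom]],
                                data.frame(chrom = chrom, start = start,
                                           end = start + w))
    data.frame(chrom = chrom, start = as.integer(start),
               end = as.integer(start + w), stringsAsFactors = FALSE)
  }
  placed <- list()
  place_category <- function(category, n_want) {
    got <- 0L
    tries <- 0L
    while (got < n_want && tries < n_want * 200L) {
      tries <- tries + 1L
      if (category %in% c("geneBody", "downstream2kb") && !nrow(genes)) break
      cand <- switch(category,
        geneBody = {
          g <- genes[sample(nrow(genes), 1L), ]
          lo <- if (g$strand == "+") g$tss + 2000L else g$start
          hi <- if (g$strand == "+") g$end - w else g$tss - 2000L - w
          if (hi <= lo) NULL else c(g$chrom, floor(stats::runif(1, lo, hi)))
        },
        downstream2kb = {
          g <- genes[sample(nrow(genes), 1L), ]
          s <- if (g$strand == "+") g$end + sample(0:1500, 1L)
               else g$start - w - sample(0:1500, 1L)
          if (s < 0) NULL else c(g$chrom, s)
        },
        TE = {
          if (!nrow(tes)) NULL else {
            te <- tes[sample(nrow(tes), 1L), ]
            if (te$end - te$start <= w) NULL
            else c(te$chrom, floor(stats::runif(1, te$start, te$end - w)))
          }
        },
        intergenic = {
          chrom <- sample(names(occupied), 1L)
          c(chrom, floor(stats::runif(1, 0, config$chrom_length - w)))
        })
      if (is.null(cand)) next
      chrom <- cand[1]; s <- as.numeric(cand[2])
      if (clash(chrom, s, s + w)) next
      if (category == "intergenic") {
        gb <- genes[genes$chrom == chrom, , drop = FALSE]
        if (any(gb$start < s + w & gb$end > s)) next
      }
      placed[[length(placed) + 1L]] <<- add_peak(chrom, s)
      got <- got + 1L
    }
    got
  }
  short <- 0L
  for (category in c("geneBody", "downstream2kb", "TE", "intergenic")) {
    short <- short + (cat_n[[category]] - place_category(category, cat_n[[category]]))
  }
  if (short > 0) place_category("intergenic", short)
  distal <- if (length(placed)) do.call(rbind, placed) else
    data.frame(chrom = character(0), start = integer(0), end = integer(0))
  if (nrow(distal)) {
    distal$id <- sprintf("D_%04d", seq_len(nrow(distal)))
    distal$signal <- stats::rlnorm(nrow(distal), log(20), 1)
    distal$mark <- "H3K27ac"
  } else {
    distal <- .empty_peaks()
  }
  peaks <- rbind(prox[, c("chrom", "start", "end", "id", "signal", "mark")],
                 distal[, c("chrom", "start", "end", "id", "signal", "mark")])
  peaks <- peaks[order(peaks$chrom, peaks$start), , drop = FALSE]
  rownames(peaks) <- NULL
  list(genes = genes, peaks = peaks, tes = tes, chrom_sizes = chrom_sizes)
}

#' Plant ground-truth structure on a simulated genome
#'
#' Chooses the planted loop set (peak pairs with midpoint distance >= 10 kb,
#' in the configured P-P/P-D/D-D mix, preferring nearby partners), assigns
#' two-tissue membership per \code{shared_loop_fraction}, and derives the
#' expression ground truth: co-expressed pairs (the P-P loop gene pairs),
#' tissue-specific genes, constitutive genes (genes hosting a distal peak in
#' their body) and a per-gene expression class used by
#' \code{\link{simulate_expression}}. Genes interacting with intergenic D
#' anchors are planted as tissue-restricted, genes interacting with genic D
#' as intermediate -- the generative contrast behind the entropy-by-context
#' analysis.
#'
#' Classes are assigned with precedence tissue-specific > co-expressed >
#' constitutive > restricted > intermediate, so in dense configurations where
#' a gene plays several roles only the highest applies;
#' \code{truth$coexpressed$realized} flags the pairs whose both genes
#' actually carry the co-expression class.
#'
#' @param config A \code{\link{sim_config}}.
#' @param genome Output of \code{\link{simulate_genome}}.
#' @return A truth manifest list: \code{loops}, \code{coexpressed},
#'   \code{tissue_specific}, \code{constitutive}, \code{expr_class},
#'   \code{pair_id}.
#' @export
plant_truth <- function(config, genome) {
  .sim_seed(config, "truth")
  genes <- genome$genes
  peaks <- genome$peaks
  prox_of <- stats::setNames(paste0("P_", genes$id), genes$id)
  distal <- peaks[peaks$mark == "H3K27ac", , drop = FALSE]
  gene_gr <- .gr(genes$chrom, genes$start, genes$end)
  d_genic <- rep(FALSE, nrow(distal))
  host_genes <- character(0)
  if (nrow(distal)) {
    ov <- GenomicRanges::findOverlaps(.gr(distal$chrom, distal$start, distal$end),
                                      gene_gr)
    d_genic[unique(S4Vectors::queryHits(ov))] <- TRUE
    host_genes <- unique(genes$id[S4Vectors::subjectHits(ov)])
  }
  n_cls <- round(config$n_loops * config$loop_class_mix)
  n_cls[["PP"]] <- config$n_loops - n_cls[["PD"]] - n_cls[["DD"]]
  pk_mid <- stats::setNames(.mid(peaks$start, peaks$end), peaks$id)

  used_genes <- character(0)
  # P-D first so their genes get clean entropy classes when genes are scarce
  pd_rows <- list()
  if (n_cls[["PD"]] > 0 && nrow(distal)) {
    d_order <- sample(nrow(distal))
    for (di in d_order) {
      if (length(pd_rows) >= n_cls[["PD"]]) break
      cand <- genes[genes$chrom == distal$chrom[di], , drop = FALSE]
      dmid <- pk_mid[[distal$id[di]]]
      dist <- abs(cand$tss - dmid)
      ok <- dist >= 10000 & dist <= 1e6
      cand <- cand[ok, , drop = FALSE]; dist <- dist[ok]
      if (!nrow(cand)) next
      fresh <- !(cand$id %in% c(used_genes, host_genes))
      if (any(fresh)) { cand <- cand[fresh, , drop = FALSE]; dist <- dist[fresh] }
      g <- cand$id[sample.int(nrow(cand), 1L, prob = 1 / dist)]
      used_genes <- c(used_genes, g)
      pd_rows[[length(pd_rows) + 1L]] <- data.frame(
        peak_a = prox_of[[g]], peak_b = distal$id[di], class = "PD",
        gene_a = g, gene_b = NA_character_,
        genic_d = d_genic[di], stringsAsFactors = FALSE)
    }
  }
  pd_genes <- vapply(pd_rows, function(r) r$gene_a, character(1))
  pd_genic <- vapply(pd_rows, function(r) r$genic_d, logical(1))

  # P-P pairs: adjacent-ish promoter pairs, genes used at most once if possible
  pp_rows <- list()
  if (n_cls[["PP"]] > 0 && nrow(genes) >= 2) {
    cand_pairs <- list()
    for (chrom in unique(genes$chrom)) {
      g <- genes[genes$chrom == chrom, , drop = FALSE]
      g <- g[order(g$tss), , drop = FALSE]
      for (k in 1:6) {
        if (nrow(g) <= k) next
        i <- seq_len(nrow(g) - k)
        d <- abs(g$tss[i + k] - g$tss[i])
        ok <- d >= 10000 & d <= 2e6
        if (any(ok)) {
          cand_pairs[[length(cand_pairs) + 1L]] <-
            data.frame(ga = g$id[i][ok], gb = g$id[i + k][ok],
                       stringsAsFactors = FALSE)
        }
      }
    }
    cand_pairs <- do.call(rbind, cand_pairs)
    cand_pairs <- cand_pairs[sample(nrow(cand_pairs)), , drop = FALSE]
    taken_pair <- character(0)
    for (pass in 1:2) {
      for (i in seq_len(nrow(cand_pairs))) {
        if (length(pp_rows) >= n_cls[["PP"]]) break
        ga <- cand_pairs$ga[i]; gb <- cand_pairs$gb[i]
        key <- paste(ga, gb)
        if (key %in% taken_pair) next
        fresh <- !(ga %in% c(used_genes, host_genes)) &&
          !(gb %in% c(used_genes, host_genes))
        if (pass == 1 && !fresh) next
        taken_pair <- c(taken_pair, key)
        used_genes <- c(used_genes, ga, gb)
        pp_rows[[length(pp_rows) + 1L]] <- data.frame(
          peak_a = prox_of[[ga]], peak_b = prox_of[[gb]], class = "PP",
          gene_a = ga, gene_b = gb, genic_d = NA, stringsAsFactors = FALSE)
      }
      if (length(pp_rows) >= n_cls[["PP"]]) break
    }
  }

  # D-D pairs among distal peaks not used by P-D loops
  dd_rows <- list()
  if (n_cls[["DD"]] > 0 && nrow(distal) >= 2) {
    used_d <- vapply(pd_rows, function(r) r$peak_b, character(1))
    free_d <- distal[!(distal$id %in% used_d), , drop = FALSE]
    free_d <- free_d[sample(nrow(free_d)), , drop = FALSE]
    i <- 1L
    while (length(dd_rows) < n_cls[["DD"]] && i < nrow(free_d)) {
      a <- free_d[i, ]; rest <- free_d[-seq_len(i), , drop = FALSE]
      rest <- rest[rest$chrom == a$chrom, , drop = FALSE]
      d <- abs(.mid(rest$start, rest$end) - .mid(a$start, a$end))
      ok <- d >= 10000 & d <= 2e6
      if (any(ok)) {
        b <- rest$id[ok][which.min(d[ok])]
        dd_rows[[length(dd_rows) + 1L]] <- data.frame(
          peak_a = a$id, peak_b = b, class = "DD",
          gene_a = NA_character_, gene_b = NA_character_, genic_d = NA,
          stringsAsFactors = FALSE)
        free_d <- free_d[free_d$id != b, , drop = FALSE]
      }
      i <- i + 1L
    }
  }
  loops <- do.call(rbind, c(pd_rows, pp_rows, dd_rows))
  if (is.null(loops)) {
    loops <- data.frame(peak_a = character(0), peak_b = character(0),
                        class = character(0), gene_a = character(0),
                        gene_b = character(0), genic_d = logical(0),
                        stringsAsFactors = FALSE)
  }
  # order anchors genomically and attach coordinates
  if (nrow(loops)) {
    ia <- match(loops$peak_a, peaks$id); ib <- match(loops$peak_b, peaks$id)
    swap <- peaks$start[ib] < peaks$start[ia]
    tmp <- loops$peak_a[swap]; loops$peak_a[swap] <- loops$peak_b[swap]
    loops$peak_b[swap] <- tmp
    loops$chrom <- peaks$chrom[match(loops$peak_a, peaks$id)]
    shared <- stats::runif(nrow(loops)) < config$shared_loop_fraction
    loops$tissue <- ifelse(shared, "shared",
                           sample(c("A", "B"), nrow(loops), replace = TRUE))
    rownames(loops) <- NULL
  }

  # expression ground truth
  expr_class <- stats::setNames(rep("other", nrow(genes)), genes$id)
  pair_id <- stats::setNames(rep(NA_integer_, nrow(genes)), genes$id)
  free <- setdiff(genes$id, c(used_genes, host_genes))
  n_ts <- min(config$n_tissue_specific_genes, length(free))
  ts_genes <- if (n_ts) sample(free, n_ts) else character(0)
  ts_tissue <- rep(c("A", "B"), length.out = n_ts)
  expr_class[ts_genes] <- paste0("tissue", ts_tissue)
  pp <- loops[loops$class == "PP", , drop = FALSE]
  coex <- data.frame(gene_a = pp$gene_a, gene_b = pp$gene_b,
                     rho = config$coexpression_rho, realized = FALSE,
                     stringsAsFactors = FALSE)
  gene_pair_count <- table(c(coex$gene_a, coex$gene_b))
  if (nrow(coex)) {
    for (i in seq_len(nrow(coex))) {
      ga <- coex$gene_a[i]; gb <- coex$gene_b[i]
      ok <- gene_pair_count[[ga]] == 1 && gene_pair_count[[gb]] == 1 &&
        expr_class[[ga]] == "other" && expr_class[[gb]] == "other"
      if (ok) {
        coex$realized[i] <- TRUE
        expr_class[c(ga, gb)] <- "coexpressed"
        pair_id[c(ga, gb)] <- i
      }
    }
  }
  const_genes <- setdiff(host_genes, names(expr_class)[expr_class != "other"])
  expr_class[const_genes] <- "constitutive"
  restricted <- setdiff(pd_genes[!pd_genic],
                        names(expr_class)[expr_class != "other"])
  expr_class[restricted] <- "restricted"
  intermediate <- setdiff(pd_genes[pd_genic],
                          names(expr_class)[expr_class != "other"])
  expr_class[intermediate] <- "intermediate"

  list(loops = loops,
       coexpressed = coex,
       tissue_specific = data.frame(gene = ts_genes, tissue = ts_tissue,
                                    stringsAsFactors = FALSE),
       constitutive = const_genes,
       expr_class = expr_class,
       pair_id = pair_id)
}

#' Simulate paired-end tags with planted loops
#'
#' Three strata: (i) loop PETs -- per planted loop a Poisson
#' (\code{loop_pet_mean}) number of PETs with both ends uniform within the
#' loop's anchors; (ii) background intra-chromosomal PETs anchored at a
#' random peak with the partner end at a distance drawn from the truncated
#' power-law d^-alpha on [1 kb, chrom_length/2]; (iii) self-ligation PETs
#' (span uniform in [100, 9999] bp) and inter-chromosomal PETs per the
#' configured fractions. Read ends are \code{read_width} bp; the output is
#' shuffled and canonically ordered.
#'
#' @param config A \code{\link{sim_config}}.
#' @param genome Output of \code{\link{simulate_genome}}.
#' @param truth Output of \code{\link{plant_truth}}.
#' @param tissue NULL (use all planted loops) or "A"/"B" (loops shared or
#'   belonging to that tissue).
#' @return PET data.frame with count 1 per record.
#' @export
simulate_pets <- function(config, genome, truth, tissue = NULL) {
  offset <- if (is.null(tissue)) 0L else 10L * match(tissue, c("A", "B"))
  .sim_seed(config, "pets", offset)
  w <- config$read_width
  peaks <- genome$peaks
  sizes <- genome$chrom_sizes
  loops <- truth$loops
  if (!is.null(tissue) && nrow(loops)) {
    loops <- loops[loops$tissue %in% c("shared", tissue), , drop = FALSE]
  }
  parts <- list()
  if (nrow(loops)) {
    k <- stats::rpois(nrow(loops), config$loop_pet_mean)
    idx <- rep(seq_len(nrow(loops)), k)
    ia <- match(loops$peak_a[idx], peaks$id)
    ib <- match(loops$peak_b[idx], peaks$id)
    s1 <- floor(stats::runif(length(idx), peaks$start[ia], peaks$end[ia] - w))
    s2 <- floor(stats::runif(length(idx), peaks$start[ib], peaks$end[ib] - w))
    parts$loops <- data.frame(chrom1 = peaks$chrom[ia], start1 = s1,
                              end1 = s1 + w, chrom2 = peaks$chrom[ib],
                              start2 = s2, end2 = s2 + w,
                              stringsAsFactors = FALSE)
  }
  n_bg <- config$background_pets
  if (n_bg > 0) {
    cat <- sample(c("self", "inter", "intra"), n_bg, replace = TRUE,
                  prob = c(config$self_lig_fraction, config$inter_fraction,
                           1 - config$self_lig_fraction - config$inter_fraction))
    n_self <- sum(cat == "self"); n_inter <- sum(cat == "inter")
    n_intra <- sum(cat == "intra")
    if (n_self) {
      chrom <- sample(names(sizes), n_self, replace = TRUE)
      span <- round(stats::runif(n_self, 100, 9999))
      s1 <- floor(stats::runif(n_self, 0, sizes[chrom] - span - w))
      parts$self <- data.frame(chrom1 = chrom, start1 = s1, end1 = s1 + w,
                               chrom2 = chrom, start2 = s1 + span,
                               end2 = s1 + span + w, stringsAsFactors = FALSE)
    }
    if (n_inter && length(sizes) >= 2) {
      c1 <- sample(names(sizes), n_inter, replace = TRUE)
      c2 <- sample(names(sizes), n_inter, replace = TRUE)
      while (any(c1 == c2)) {
        eq <- c1 == c2
        c2[eq] <- sample(names(sizes), sum(eq), replace = TRUE)
      }
      s1 <- floor(stats::runif(n_inter, 0, sizes[c1] - w))
      s2 <- floor(stats::runif(n_inter, 0, sizes[c2] - w))
      parts$inter <- data.frame(chrom1 = c1, start1 = s1, end1 = s1 + w,
                                chrom2 = c2, start2 = s2, end2 = s2 + w,
                                stringsAsFactors = FALSE)
    }
    if (n_intra && nrow(peaks)) {
      pk <- sample(nrow(peaks), n_intra, replace = TRUE)
      chrom <- peaks$chrom[pk]
      s1 <- floor(stats::runif(n_intra, peaks$start[pk], peaks$end[pk] - w))
      dmin <- 1000; dmax <- config$chrom_length / 2
      u <- stats::runif(n_intra)
      a <- config$decay_exponent
      d <- if (abs(a - 1) < 1e-12) {
        dmin * (dmax / dmin)^u
      } else {
        (dmin^(1 - a) + u * (dmax^(1 - a) - dmin^(1 - a)))^(1 / (1 - a))
      }
      dir <- sample(c(-1, 1), n_intra, replace = TRUE)
      s2 <- pmin(pmax(s1 + dir * round(d), 0), sizes[chrom] - w)
      parts$intra <- data.frame(chrom1 = chrom, start1 = s1, end1 = s1 + w,
                                chrom2 = chrom, start2 = s2, end2 = s2 + w,
                                stringsAsFactors = FALSE)
    }
  }
  pets <- do.call(rbind, parts)
  if (is.null(pets) || !nrow(pets)) return(.empty_pets())
  for (col in c("start1", "end1", "start2", "end2")) {
    pets[[col]] <- as.integer(pets[[col]])
  }
  pets$count <- 1L
  strata <- vapply(parts, nrow, integer(1))
  pets <- .canonicalize_pets(pets)
  pets <- pets[sample(nrow(pets)), , drop = FALSE]
  rownames(pets) <- NULL
  attr(pets, "strata") <- strata
  pets
}

#' Simulate a gene x sample FPKM matrix from the truth manifest
#'
#' Baseline expression is log-normal per gene with log-normal sample noise.
#' Planted structure by expression class: realized co-expressed pairs share a
#' per-pair latent factor whose loading is calibrated in closed form so the
#' expected pairwise Pearson correlation of the (log-normal) values equals
#' the target rho; tissue-specific genes are exactly 0 in one tissue group
#' and log-normal with mean >= 2 in the other; constitutive genes have
#' near-uniform profiles (entropy near log2 N); restricted genes are
#' expressed in 2-4 samples over a small noise floor; intermediate genes
#' have moderately concentrated profiles.
#'
#' @param config A \code{\link{sim_config}}.
#' @param genome Output of \code{\link{simulate_genome}}.
#' @param truth Output of \code{\link{plant_truth}}.
#' @return FPKM matrix with a \code{groups} attribute (list with
#'   \code{tissue_a}, \code{tissue_b} sample ids).
#' @export
simulate_expression <- function(config, genome, truth) {
  .sim_seed(config, "expression")
  genes <- genome$genes$id
  n_g <- length(genes)
  n_s <- config$n_samples
  samples <- c(sprintf("seed_%02d", seq_len(config$n_seed_samples)),
               sprintf("nonseed_%02d", seq_len(n_s - config$n_seed_samples)))
  group_a <- samples[seq_len(config$n_seed_samples)]
  group_b <- samples[-seq_len(config$n_seed_samples)]
  expr <- matrix(0, n_g, n_s, dimnames = list(genes, samples))
  cls <- truth$expr_class[genes]
  base <- stats::rlnorm(n_g, log(8), 0.8)
  # latent factors for realized co-expressed pairs
  rho <- config$coexpression_rho
  sig_e <- 0.5
  a_load <- if (rho <= 0) 0 else {
    if (rho * exp(sig_e^2) >= 1) stop("coexpression_rho too large", call. = FALSE)
    sqrt(log((1 - rho) / (1 - rho * exp(sig_e^2))))
  }
  pair_ids <- unique(truth$pair_id[!is.na(truth$pair_id)])
  z_pair <- matrix(stats::rnorm(length(pair_ids) * n_s), length(pair_ids), n_s)
  rownames(z_pair) <- as.character(pair_ids)
  for (i in seq_len(n_g)) {
    g <- genes[i]
    expr[i, ] <- switch(cls[[g]],
      tissueA = {
        v <- numeric(n_s)
        v[seq_along(group_a)] <- stats::rlnorm(length(group_a), log(5), 0.5)
        v
      },
      tissueB = {
        v <- numeric(n_s)
        v[length(group_a) + seq_along(group_b)] <-
          stats::rlnorm(length(group_b), log(5), 0.5)
        v
      },
      coexpressed = {
        z <- z_pair[as.character(truth$pair_id[[g]]), ]
        base[i] * exp(a_load * z + stats::rnorm(n_s, 0, sig_e))
      },
      constitutive = base[i] * exp(stats::rnorm(n_s, 0, 0.08)),
      restricted = {
        v <- 0.05 * stats::rlnorm(n_s, 0, 0.2)
        on <- sample(n_s, sample(2:4, 1))
        v[on] <- stats::rlnorm(length(on), log(60), 0.3)
        v
      },
      intermediate = base[i] * exp(stats::rnorm(n_s, 0, 1.2)),
      base[i] * exp(stats::rnorm(n_s, 0, stats::runif(1, 0.3, 2.0))))
  }
  attr(expr, "groups") <- list(tissue_a = group_a, tissue_b = group_b)
  expr
}

#' Simulate a flat gene-to-term annotation map
#'
#' Random background terms for every gene plus one planted term shared by the
#' genes of the first planted P-P loops, giving term enrichment something to
#' find in end-to-end runs.
#'
#' @param config A \code{\link{sim_config}}.
#' @param genome Output of \code{\link{simulate_genome}}.
#' @param truth Output of \code{\link{plant_truth}}.
#' @param n_terms Number of background terms.
#' @return Data.frame with columns \code{gene}, \code{term}.
#' @export
simulate_term_map <- function(config, genome, truth, n_terms = 25) {
  .sim_seed(config, "terms")
  genes <- genome$genes$id
  k <- sample(1:2, length(genes), replace = TRUE)
  bg <- data.frame(gene = rep(genes, k),
                   term = sprintf("TERM_%03d", unlist(lapply(k, sample,
                                                             x = n_terms))),
                   stringsAsFactors = FALSE)
  # plant a shared term on the genes of the largest planted-loop component,
  # so network-level enrichment has a true signal to find
  planted_genes <- character(0)
  if (nrow(truth$loops)) {
    g <- igraph::graph_from_data_frame(truth$loops[, c("peak_a", "peak_b")],
                                       directed = FALSE)
    comp <- igraph::components(g)
    biggest <- names(comp$membership)[comp$membership == which.max(comp$csize)]
    in_comp <- truth$loops$peak_a %in% biggest | truth$loops$peak_b %in% biggest
    planted_genes <- unique(stats::na.omit(
      c(truth$loops$gene_a[in_comp], truth$loops$gene_b[in_comp])))
  }
  if (!length(planted_genes)) return(bg)
  rbind(bg, data.frame(gene = planted_genes, term = "TERM_planted",
                       stringsAsFactors = FALSE))
}

#' One-call synthetic dataset (single tissue)
#'
#' @param config A \code{\link{sim_config}}.
#' @return List with \code{genome}, \code{truth}, \code{pets}, \code{expr},
#'   \code{terms}.
#' @export
simulate_dataset <- function(config) {
  genome <- simulate_genome(config)
  truth <- plant_truth(config, genome)
  list(genome = genome, truth = truth,
       pets = simulate_pets(config, genome, truth),
       expr = simulate_expression(config, genome, truth),
       terms = simulate_term_map(config, genome, truth))
}

#' Two-tissue synthetic dataset
#'
#' One genome and truth manifest; the planted loop set is split into shared
#' and tissue-exclusive subsets per \code{shared_loop_fraction}, PET sets are
#' generated independently per tissue, and the expression matrix carries the
#' two tissue sample groups.
#'
#' @param config A \code{\link{sim_config}}.
#' @return List with \code{genome}, \code{truth}, \code{pets_a},
#'   \code{pets_b}, \code{expr}.
#' @export
simulate_two_tissues <- function(config) {
  genome <- simulate_genome(config)
  truth <- plant_truth(config, genome)
  list(genome = genome, truth = truth,
       pets_a = simulate_pets(config, genome, truth, tissue = "A"),
       pets_b = simulate_pets(config, genome, truth, tissue = "B"),
       expr = simulate_expression(config, genome, truth))
}

#' Planted loops as a classified interaction table
#'
#' Renders the truth manifest's loop set (optionally one tissue's subset) as
#' an interaction data.frame with anchor coordinates and classes taken from
#' the manifest -- the noiseless reference used to validate tissue
#' comparison and recovery.
#'
#' @param truth Output of \code{\link{plant_truth}}.
#' @param genome Output of \code{\link{simulate_genome}}.
#' @param tissue NULL for all loops, or "A"/"B" for shared + tissue-exclusive
#'   loops of one tissue.
#' @return Classified interaction data.frame.
#' @export
planted_interactions <- function(truth, genome, tissue = NULL) {
  loops <- truth$loops
  if (!is.null(tissue) && nrow(loops)) {
    loops <- loops[loops$tissue %in% c("shared", tissue), , drop = FALSE]
  }
  if (!nrow(loops)) return(.empty_interactions())
  peaks <- genome$peaks
  ia <- match(loops$peak_a, peaks$id)
  ib <- match(loops$peak_b, peaks$id)
  out <- data.frame(chrom1 = peaks$chrom[ia], start1 = peaks$start[ia],
                    end1 = peaks$end[ia], chrom2 = peaks$chrom[ib],
                    start2 = peaks$start[ib], end2 = peaks$end[ib],
                    anchorA = loops$peak_a, anchorB = loops$peak_b,
                    petCount = NA_integer_, pValue = NA_real_, fdr = NA_real_,
                    class = loops$class, markProvenance = NA_character_,
                    anchor1Type = NA_character_, anchor2Type = NA_character_,
                    tissue = if (is.null(tissue)) NA_character_ else tissue,
                    stringsAsFactors = FALSE)
  # anchors are genomically ordered; for PD loops either side may be the P
  out$anchor1Type <- ifelse(out$class == "PP", "P",
                            ifelse(out$class == "DD", "D",
                                   ifelse(startsWith(out$anchorA, "P_"), "P", "D")))
  out$anchor2Type <- ifelse(out$class == "PP", "P",
                            ifelse(out$class == "DD", "D",
                                   ifelse(startsWith(out$anchorB, "P_"), "P", "D")))
  rownames(out) <- NULL
  out
}
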