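#' Build chromatin interaction network (ChIN) components
#'
#' Nodes are interaction anchors (peak ids), edges are interactions; anchors
#' that interact directly or indirectly form a connected component. Only
#' components with at least \code{min_interactions} edges are reported
#' (sorted by edge count, descending), mirroring the >= 3-interaction rule
#' for ChINs.
#'
#' @param interactions Classified interaction data.frame.
#' @param min_interactions Minimum edges per reported component (default 3).
#' @param annotations Optional peak annotations; when given, genes of P nodes
#'   are attached to each component.
#' @return A list of class \code{chin_set}; each element is a \code{chin}
#'   list with \code{id}, \code{nodes}, \code{node_types}, \code{edges}
#'   (row indices into \code{interactions}), \code{edge_classes},
#'   \code{n_interactions}, \code{genes}, \code{anchors} (node coordinate
#'   data.frame).
#' @export
build_chins <- function(interactions, min_interactions = 3, annotations = NULL) {
  if (!nrow(interactions)) {
    return(structure(list(), class = "chin_set",
                     all_components = list(), n_filtered = 0L))
  }
  g <- igraph::graph_from_data_frame(
    data.frame(from = interactions$anchorA, to = interactions$anchorB,
               row = seq_len(nrow(interactions)), stringsAsFactors = FALSE),
    directed = FALSE)
  comp <- igraph::components(g)
  membership <- comp$membership
  node_names <- names(membership)
  edge_comp <- membership[interactions$anchorA]
  # per-node coordinates and types from first appearance as an anchor
  node_tab <- unique(rbind(
    data.frame(id = interactions$anchorA, chrom = interactions$chrom1,
               start = interactions$start1, end = interactions$end1,
               type = interactions$anchor1Type, stringsAsFactors = FALSE),
    data.frame(id = interactions$anchorB, chrom = interactions$chrom2,
               start = interactions$start2, end = interactions$end2,
               type = interactions$anchor2Type, stringsAsFactors = FALSE)))
  node_tab <- node_tab[!duplicated(node_tab$id), , drop = FALSE]
  comps <- lapply(seq_len(comp$no), function(ci) {
    edges <- which(edge_comp == ci)
    nodes <- node_names[membership == ci]
    nt <- node_tab[match(nodes, node_tab$id), , drop = FALSE]
    genes <- character(0)
    if (!is.null(annotations)) {
      gl <- annotations$genes[match(nodes, annotations$id)]
      genes <- sort(unique(unlist(strsplit(gl[!is.na(gl) & nzchar(gl)], ","))))
    }
    structure(list(id = NA_character_, nodes = nodes,
                   node_types = stats::setNames(nt$type, nodes),
                   edges = edges,
                   edge_classes = interactions$class[edges],
                   n_interactions = length(edges),
                   genes = genes, anchors = nt), class = "chin")
  })
  o <- order(vapply(comps, function(x) x$n_interactions, integer(1)),
             decreasing = TRUE)
  comps <- comps[o]
  keep <- vapply(comps, function(x) x$n_interactions >= min_interactions,
                 logical(1))
  reported <- comps[keep]
  for (i in seq_along(reported)) reported[[i]]$id <- sprintf("ChIN_%04d", i)
  structure(reported, class = "chin_set",
            all_components = comps, n_filtered = sum(!keep))
}

#' @export
print.chin_set <- function(x, ...) {
  cat("ChIN set:", length(x), "components with >=",
      if (length(x)) min(vapply(x, `[[`, integer(1), "n_interactions")) else 0,
      "interactions\n")
  invisible(x)
}

#' Node degrees of a ChIN component
#'
#' Degree = number of incident edges; the degrees always sum to twice the
#' edge count (handshake identity).
#'
#' @param component A \code{chin} component.
#' @param interactions The interaction data.frame the component was built from.
#' @return Named integer vector node -> degree.
#' @export
degree_stats <- function(component, interactions) {
  ends <- c(interactions$anchorA[component$edges],
            interactions$anchorB[component$edges])
  tab <- table(factor(ends, levels = component$nodes))
  stats::setNames(as.integer(tab), names(tab))
}

#' Cross-tissue conservation of P-P network components
#'
#' For each component of tissue A (built from P-P interactions only), the
#' fraction of its P-P edges matched -- both anchors overlapping >= 1 bp --
#' by P-P interactions anywhere in tissue B. A component is conserved when
#' its overlap fraction exceeds \code{threshold} (default 0.65). The
#' alternative \code{method = "nodes"} reports the fraction of the
#' component's nodes overlapped by any B anchor instead.
#'
#' @param chins_a \code{chin_set} built from tissue A's P-P interactions.
#' @param interactions_a Tissue A's P-P interaction data.frame (the one
#'   \code{chins_a} was built from).
#' @param interactions_b Tissue B's P-P interaction data.frame.
#' @param threshold Conservation threshold on the overlap fraction.
#' @param method "edges" (default) or "nodes".
#' @return Data.frame with component id, n_edges, overlap fraction and a
#'   conserved flag.
#' @export
pp_component_overlap <- function(chins_a, interactions_a, interactions_b,
                                 threshold = 0.65, method = c("edges", "nodes")) {
  method <- match.arg(method)
  if (!length(chins_a)) {
    return(data.frame(id = character(0), n_edges = integer(0),
                      overlap = numeric(0), conserved = logical(0),
                      stringsAsFactors = FALSE))
  }
  matched_edges <- integer(0)
  if (nrow(interactions_b)) {
    m <- .match_interactions(interactions_a, interactions_b)
    matched_edges <- unique(m$qa)
  }
  b_anchor_gr <- .gr(c(interactions_b$chrom1, interactions_b$chrom2),
                     c(interactions_b$start1, interactions_b$start2),
                     c(interactions_b$end1, interactions_b$end2))
  rows <- lapply(chins_a, function(cp) {
    if (method == "edges") {
      frac <- if (length(cp$edges)) mean(cp$edges %in% matched_edges) else 0
      n <- length(cp$edges)
    } else {
      hit <- GenomicRanges::findOverlaps(
        .gr(cp$anchors$chrom, cp$anchors$start, cp$anchors$end), b_anchor_gr)
      frac <- if (nrow(cp$anchors)) {
        length(unique(S4Vectors::queryHits(hit))) / nrow(cp$anchors)
      } else 0
      n <- length(cp$edges)
    }
    data.frame(id = cp$id, n_edges = n, overlap = frac,
               conserved = frac > threshold, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Annotation-term enrichment of a gene set
#'
#' Generic hypergeometric term enrichment (the GO-style analysis): for each
#' term, the upper-tail probability of seeing at least the observed number of
#' term-carrying genes in the component gene set, drawn from the gene
#' universe; Benjamini-Hochberg correction across the terms tested.
#'
#' @param component_genes Gene ids of a ChIN component.
#' @param gene_terms Data.frame mapping \code{gene} to \code{term} (one row
#'   per pair).
#' @param universe Gene-id universe (must contain \code{component_genes}).
#' @param fdr_max Significance cutoff on the BH FDR (default 0.05).
#' @return Data.frame with one row per term: hits in component, component
#'   size, hits in genome, universe size, p, fdr, significant.
#' @export
term_enrichment <- function(component_genes, gene_terms, universe,
                            fdr_max = 0.05) {
  empty <- data.frame(term = character(0), hits_component = integer(0),
                      component_genes = integer(0), hits_genome = integer(0),
                      genome_genes = integer(0), p = numeric(0),
                      fdr = numeric(0), significant = logical(0),
                      stringsAsFactors = FALSE)
  component_genes <- unique(component_genes)
  if (!length(component_genes)) return(empty)
  if (length(setdiff(component_genes, universe))) {
    stop("component genes must be contained in the universe", call. = FALSE)
  }
  universe <- unique(universe)
  gene_terms <- gene_terms[gene_terms$gene %in% universe, , drop = FALSE]
  if (!nrow(gene_terms)) return(empty)
  gene_terms <- unique(gene_terms[, c("gene", "term")])
  terms <- split(gene_terms$gene, gene_terms$term)
  n_tot <- length(universe)
  n_b <- length(component_genes)
  rows <- lapply(names(terms), function(tm) {
    hits_genome <- length(terms[[tm]])
    hits_comp <- length(intersect(terms[[tm]], component_genes))
    data.frame(term = tm, hits_component = hits_comp, component_genes = n_b,
               hits_genome = hits_genome, genome_genes = n_tot,
               p = hypergeom_tail(hits_comp, hits_genome, n_b, n_tot),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- bh_adjust(out$p)
  out$significant <- out$fdr < fdr_max
  out[order(out$p), , drop = FALSE]
}

#' Genomic span of a ChIN component
#'
#' Per chromosome, the hull [min anchor start, max anchor end) over the
#' component's anchors; the total span is the sum of hull lengths.
#'
#' @param component A \code{chin} component.
#' @return Data.frame \code{chrom, start, end, length} with a
#'   \code{total_span} attribute.
#' @export
component_span <- function(component) {
  a <- component$anchors
  rows <- lapply(split(a, a$chrom), function(x) {
    data.frame(chrom = x$chrom[1], start = min(x$start), end = max(x$end),
               length = max(x$end) - min(x$start), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "total_span") <- sum(out$length)
  out
}
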