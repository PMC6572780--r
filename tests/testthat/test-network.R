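# every node gets one fixed genomic interval (by first-appearance index) so
# id-based and interval-based matching agree
mk_ints <- function(from, to, cls = "PP") {
  n <- length(from)
  nodes <- unique(c(from, to))
  pos <- stats::setNames(seq_along(nodes) * 100000L, nodes)
  x <- petloop:::.empty_interactions()
  for (i in seq_len(n)) {
    cl <- rep_len(cls, n)[i]
    x[i, ] <- list("chr1", pos[[from[i]]], pos[[from[i]]] + 2000L, "chr1",
                   pos[[to[i]]], pos[[to[i]]] + 2000L,
                   from[i], to[i], 3L, 1e-8, 1e-6, cl,
                   "H3K4me3", substr(cl, 1, 1), substr(cl, 2, 2),
                   NA_character_)
  }
  x
}

test_that("ChIN components follow connectivity and the >= 3 interaction rule", {
  ints <- mk_ints(c("A", "B", "C", "X"), c("B", "C", "D", "Y"))
  chins <- build_chins(ints)
  expect_length(chins, 1)  # X-Y pair filtered out
  expect_setequal(chins[[1]]$nodes, c("A", "B", "C", "D"))
  expect_equal(chins[[1]]$n_interactions, 3L)
  expect_equal(attr(chins, "n_filtered"), 1L)

  deg <- degree_stats(chins[[1]], ints)
  expect_equal(sum(deg), 2L * chins[[1]]$n_interactions)  # handshake
  star <- mk_ints(rep("HUB", 5), paste0("L", 1:5))
  dstar <- degree_stats(build_chins(star)[[1]], star)
  expect_equal(dstar[["HUB"]], 5L)
  expect_true(all(dstar[paste0("L", 1:5)] == 1L))
  tri <- mk_ints(c("A", "B", "C"), c("B", "C", "A"))
  expect_true(all(degree_stats(build_chins(tri)[[1]], tri) == 2L))
})

test_that("component extraction equals brute-force DFS on random graphs", {
  set.seed(99)
  for (rep in 1:100) {
    n <- sample(4:50, 1)
    n_edges <- sample(2:min(60, n * 2), 1)
    from <- sprintf("n%02d", sample(n, n_edges, replace = TRUE))
    to <- sprintf("n%02d", sample(n, n_edges, replace = TRUE))
    keep <- from != to
    if (sum(keep) < 1) next
    ints <- mk_ints(from[keep], to[keep])
    chins <- build_chins(ints, min_interactions = 1)
    got <- lapply(chins, function(cp) sort(cp$nodes))
    want <- dfs_components(unique(c(from[keep], to[keep])),
                           data.frame(from = from[keep], to = to[keep],
                                      stringsAsFactors = FALSE))
    expect_setequal(vapply(got, paste, character(1), collapse = ","),
                    vapply(want, paste, character(1), collapse = ","))
    # components partition the node set
    expect_equal(sort(unlist(lapply(got, identity))),
                 sort(unique(c(from[keep], to[keep]))))
  }
})

test_that("P-P component overlap fractions and conservation threshold", {
  a <- mk_ints(c("A", "B", "C"), c("B", "C", "D"))
  chins_a <- build_chins(a)
  # identical set in the other tissue: fully conserved
  tab <- pp_component_overlap(chins_a, a, a)
  expect_equal(tab$overlap, 1.0)
  expect_true(tab$conserved)
  # no shared edges
  far <- a
  far[, c("start1", "end1", "start2", "end2")] <-
    far[, c("start1", "end1", "start2", "end2")] + 10000000L
  expect_equal(pp_component_overlap(chins_a, a, far)$overlap, 0)
  # 2 of 3 edges shared: 0.667 > 0.65
  tab2 <- pp_component_overlap(chins_a, a, a[1:2, ])
  expect_equal(tab2$overlap, 2 / 3, tolerance = 1e-12)
  expect_true(tab2$conserved)
  # duplicating every edge in B leaves the fraction unchanged
  expect_equal(pp_component_overlap(chins_a, a, rbind(a[1:2, ], a[1:2, ]))$overlap,
               2 / 3, tolerance = 1e-12)
  # node-based alternative
  tabn <- pp_component_overlap(chins_a, a, a[1, ], method = "nodes")
  expect_equal(tabn$overlap, 0.5)
})

test_that("term enrichment reuses the hypergeometric tail with BH", {
  universe <- sprintf("g%03d", 1:100)
  gene_terms <- rbind(
    data.frame(gene = universe[1:10], term = "rare", stringsAsFactors = FALSE),
    data.frame(gene = universe, term = "everywhere", stringsAsFactors = FALSE),
    data.frame(gene = universe[51:100], term = "half", stringsAsFactors = FALSE))
  comp <- universe[1:10]  # all carry "rare"
  out <- term_enrichment(comp, gene_terms, universe)
  expect_equal(out$p[out$term == "rare"],
               hyper_tail_oracle(10, 10, 10, 100), tolerance = 1e-12)
  expect_true(out$significant[out$term == "rare"])
  expect_equal(out$p[out$term == "everywhere"], 1.0)  # nA == nTot
  expect_equal(out$fdr, bh_adjust(out$p), tolerance = 1e-12)
  # component disjoint from a term: x = 0 gives p = 1
  out2 <- term_enrichment(universe[51:60], gene_terms, universe)
  expect_equal(out2$p[out2$term == "rare"], 1.0)
  expect_equal(nrow(term_enrichment(character(0), gene_terms, universe)), 0)
  expect_error(term_enrichment("zzz", gene_terms, universe), "universe")
})

test_that("component spans take per-chromosome hulls", {
  ints <- mk_ints(c("A", "B", "C"), c("B", "C", "D"))
  ints$start1[1] <- 1000L; ints$end1[1] <- 2000L
  ints$start2[3] <- 900000L; ints$end2[3] <- 905000L
  cp <- build_chins(ints)[[1]]
  sp <- component_span(cp)
  expect_equal(nrow(sp), 1)
  expect_equal(sp$start, 1000)
  expect_equal(sp$end, 905000)
  expect_equal(attr(sp, "total_span"), 904000)
  # two-chromosome component gives two hulls
  ints2 <- ints
  ints2$chrom2[3] <- "chr2"
  cp2 <- build_chins(ints2)[[1]]
  expect_equal(nrow(component_span(cp2)), 2)
})
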