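test_that("the generator is fully deterministic given (config, seed)", {
  cfg <- sim_config(seed = 8, n_genes = 40, n_distal_peaks = 30, n_loops = 20,
                    background_pets = 3000, chrom_length = 5e6)
  s1 <- simulate_dataset(cfg)
  s2 <- simulate_dataset(cfg)
  expect_identical(s1$genome, s2$genome)
  expect_identical(s1$truth, s2$truth)
  expect_identical(s1$pets, s2$pets)
  expect_identical(s1$expr, s2$expr)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_bedpe(s1$pets, f1); write_bedpe(s2$pets, f2)
  expect_identical(readLines(f1), readLines(f2))
  cfg2 <- sim_config(seed = 9, n_genes = 40, n_distal_peaks = 30, n_loops = 20,
                     background_pets = 3000, chrom_length = 5e6)
  expect_false(identical(simulate_dataset(cfg2)$pets, s1$pets))
})

test_that("simulated genome satisfies the anchor-annotation construction", {
  cfg <- sim_config(seed = 12, n_genes = 60, n_distal_peaks = 80,
                    chrom_length = 8e6, n_loops = 30)
  genome <- simulate_genome(cfg)
  ann <- annotate_peaks(genome$peaks, genome$genes)
  prox <- startsWith(genome$peaks$id, "P_")
  expect_true(all(ann$type[match(genome$peaks$id[prox], ann$id)] == "P"))
  expect_true(all(ann$type[match(genome$peaks$id[!prox], ann$id)] == "D"))
  # peaks never overlap each other
  expect_equal(nrow(merge_peaks(transform(genome$peaks, mark = "one"))),
               nrow(genome$peaks))
  # with no genes every peak is distal
  cfg0 <- sim_config(seed = 12, n_genes = 0, n_distal_peaks = 30,
                     chrom_length = 8e6, n_loops = 0,
                     n_tissue_specific_genes = 0)
  g0 <- simulate_genome(cfg0)
  expect_true(all(annotate_peaks(g0$peaks, g0$genes)$type == "D"))
  expect_error(simulate_genome(sim_config(n_genes = 5000, chrom_length = 2e6)),
               "too small")
})

test_that("PET strata respect configured fractions and planted linkage", {
  cfg <- sim_config(seed = 13, n_genes = 40, n_distal_peaks = 30, n_loops = 1,
                    loop_class_mix = c(PP = 1, PD = 0, DD = 0),
                    background_pets = 10000, self_lig_fraction = 0.2,
                    inter_fraction = 0.1, chrom_length = 6e6)
  genome <- simulate_genome(cfg)
  truth <- plant_truth(cfg, genome)
  raw <- simulate_pets(cfg, genome, truth)
  strata <- attr(raw, "strata")
  # generator strata are binomial draws: 99% CI around 2000 / 1000 of 10000
  expect_gt(strata[["self"]], 2000 - 2.58 * sqrt(10000 * 0.2 * 0.8))
  expect_lt(strata[["self"]], 2000 + 2.58 * sqrt(10000 * 0.2 * 0.8))
  expect_gt(strata[["inter"]], 1000 - 2.58 * sqrt(10000 * 0.1 * 0.9))
  expect_lt(strata[["inter"]], 1000 + 2.58 * sqrt(10000 * 0.1 * 0.9))
  pets <- classify_pets(pool_and_dedup(raw))
  s <- attr(pets, "stats")
  # the classifier sees at least the generated self-ligations (short
  # distance-decay draws add more) and exactly the generated inter PETs
  expect_gte(s[["selfLigation"]], strata[["self"]] - 5)
  expect_lte(abs(s[["inter"]] - strata[["inter"]]), 5)

  # with no background, all long-range PETs link the planted pair
  cfg1 <- sim_config(seed = 14, n_genes = 40, n_distal_peaks = 10, n_loops = 1,
                     loop_class_mix = c(PP = 1, PD = 0, DD = 0),
                     background_pets = 0, chrom_length = 6e6)
  g1 <- simulate_genome(cfg1)
  t1 <- plant_truth(cfg1, g1)
  p1 <- classify_pets(pool_and_dedup(simulate_pets(cfg1, g1, t1)))
  asg <- assign_pets_to_peaks(p1[p1$class == "intra", ], g1$peaks)
  expect_true(all(sort(unique(c(asg$peak1, asg$peak2))) ==
                    sort(c(t1$loops$peak_a, t1$loops$peak_b))))
})

test_that("planted expression structure matches its manifest", {
  cfg <- sim_config(seed = 15, n_genes = 200, n_distal_peaks = 100,
                    n_loops = 40, n_tissue_specific_genes = 30,
                    chrom_length = 15e6)
  genome <- simulate_genome(cfg)
  truth <- plant_truth(cfg, genome)
  expr <- simulate_expression(cfg, genome, truth)
  groups <- attr(expr, "groups")
  expect_equal(ncol(expr), 78)
  expect_length(groups$tissue_a, 53)
  # tissue-specific genes satisfy the FPKM 0 vs >= 2 rule exactly, and
  # nothing else does
  ts <- tissue_specific_genes(expr, groups$tissue_a, groups$tissue_b)
  man <- truth$tissue_specific
  expect_setequal(ts$a_specific, man$gene[man$tissue == "A"])
  expect_setequal(ts$b_specific, man$gene[man$tissue == "B"])
  # realized co-expressed pairs approach the target correlation
  rp <- truth$coexpressed[truth$coexpressed$realized, ]
  r <- mapply(function(a, b) cor(expr[a, ], expr[b, ]), rp$gene_a, rp$gene_b)
  expect_gt(mean(r), cfg$coexpression_rho - 0.15)
  expect_lt(mean(r), cfg$coexpression_rho + 0.15)
  # no all-zero genes: entropy defined everywhere
  expect_false(any(rowSums(expr) == 0))
})

test_that("two-tissue loop membership drives shared/specific recovery", {
  for (frac in c(0, 1)) {
    cfg <- sim_config(seed = 16 + frac, n_genes = 80, n_distal_peaks = 60,
                      n_loops = 40, shared_loop_fraction = frac,
                      chrom_length = 10e6, background_pets = 0)
    two <- simulate_two_tissues(cfg)
    ann <- annotate_peaks(two$genome$peaks, two$genome$genes)
    a <- classify_interactions(planted_interactions(two$truth, two$genome, "A"), ann)
    b <- classify_interactions(planted_interactions(two$truth, two$genome, "B"), ann)
    out <- tissue_specific_interactions(a, b)
    if (frac == 1) {
      expect_equal(nrow(out$a_specific), 0)
      expect_equal(nrow(out$b_specific), 0)
    } else {
      expect_equal(nrow(out$a_common), 0)
      expect_equal(nrow(out$b_common), 0)
    }
  }
  # intermediate sharing recovered end to end through real calling
  cfg <- sim_config(seed = 18, n_genes = 150, n_distal_peaks = 150,
                    n_loops = 80, shared_loop_fraction = 0.55,
                    background_pets = 20000, chrom_length = 15e6)
  two <- simulate_two_tissues(cfg)
  ann <- annotate_peaks(two$genome$peaks, two$genome$genes)
  call_one <- function(p) {
    classify_interactions(
      call_interactions(classify_pets(pool_and_dedup(p)), two$genome$peaks,
                        tissue = NULL), ann)
  }
  out <- tissue_specific_interactions(call_one(two$pets_a), call_one(two$pets_b))
  common_frac <- nrow(out$a_common) /
    (nrow(out$a_common) + nrow(out$a_specific))
  # compare to the realized membership draw of this seed's manifest
  tl <- two$truth$loops
  realized <- sum(tl$tissue == "shared") / sum(tl$tissue %in% c("shared", "A"))
  expect_lt(abs(common_frac - realized), 0.05)
})
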