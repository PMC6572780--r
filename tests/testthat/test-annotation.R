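genes_fix <- make_genes("chr1", start = c(10000, 60000), end = c(14000, 66000),
                        strand = c("+", "-"), id = c("gA", "gB"))
# TSS: gA = 10000 (+), gB = 65999 (-)

test_that("proximal/distal peak annotation uses half-open TSS windows", {
  pk <- make_peaks("chr1", c(9000, 12000, 7000), c(9500, 13000, 8001),
                   id = c("in", "out", "edge"))
  ann <- annotate_peaks(pk, genes_fix)
  expect_equal(ann$type[ann$id == "in"], "P")      # overlaps [8000, 12000)
  expect_equal(ann$type[ann$id == "out"], "D")     # 12000 itself is outside
  expect_equal(ann$type[ann$id == "edge"], "P")    # 1 bp overlap at 8000
  expect_equal(ann$genes[ann$id == "in"], "gA")
  # a peak spanning both TSS windows lists both genes
  wide <- make_peaks("chr1", 9000, 67000, id = "wide")
  expect_equal(annotate_peaks(wide, genes_fix)$genes, "gA,gB")
  expect_equal(annotate_peaks(wide, genes_fix)$n_genes, 2L)
  expect_error(annotate_peaks(pk, genes_fix, window = 0), "window")
  # deterministic and independent of gene input order
  expect_equal(annotate_peaks(pk, genes_fix[2:1, ]), ann)
})

test_that("DR identification keeps only peaks clear of all TSS windows", {
  pk <- make_peaks("chr1", c(12500, 11999, 30000), c(13500, 12500, 32000),
                   id = c("body", "touch", "far"), mark = "H3K27ac")
  drs <- identify_drs(pk, genes_fix)
  # inside gA's body but > 2 kb from its TSS: a DR
  expect_true("body" %in% drs$id)
  # touching the TSS window by 1 bp (11999 < 12000): excluded
  expect_false("touch" %in% drs$id)
  expect_true("far" %in% drs$id)
  # no genes: everything is distal
  expect_equal(nrow(identify_drs(pk, genes_fix[0, ])), 3)
})

test_that("DR location labels follow the geneBody > downstream > TE > intergenic precedence", {
  tes <- data.frame(chrom = "chr1", start = 12800L, end = 40000L)
  drs <- make_peaks("chr1", c(12800, 14500, 25000, 900000),
                    c(13400, 15500, 26000, 901000),
                    id = c("bodyAndTe", "down", "te", "nothing"))
  lab <- classify_dr_location(drs, genes_fix, tes)
  expect_equal(lab, c("geneBody", "downstream2kb", "TE", "intergenic"))
  # downstream window is strand-aware: 2 kb before gB's body start
  drsm <- make_peaks("chr1", 58500, 59500, id = "downMinus")
  expect_equal(classify_dr_location(drsm, genes_fix, NULL), "downstream2kb")
  expect_equal(length(classify_dr_location(drs[0, ], genes_fix, tes)), 0)
})

test_that("interaction classes combine anchor types order-invariantly", {
  mk <- function(a, b) {
    x <- petloop:::.empty_interactions()
    x[1, ] <- list("chr1", 0L, 2000L, "chr1", 50000L, 52000L, a, b,
                   5L, 1e-6, 1e-4, NA_character_, "H3K4me3",
                   NA_character_, NA_character_, NA_character_)
    x
  }
  ann <- data.frame(id = c("p1", "p2", "d1", "d2"),
                    type = c("P", "P", "D", "D"),
                    genes = c("gA", "gB", "", ""),
                    n_genes = c(1L, 1L, 0L, 0L), stringsAsFactors = FALSE)
  expect_equal(classify_interactions(mk("p1", "p2"), ann)$class, "PP")
  expect_equal(classify_interactions(mk("p1", "d1"), ann)$class, "PD")
  expect_equal(classify_interactions(mk("d1", "p1"), ann)$class, "PD")
  expect_equal(classify_interactions(mk("d1", "d2"), ann)$class, "DD")
  expect_error(classify_interactions(mk("p1", "zz"), ann), "zz")
})

test_that("distances and distance bins use midpoints and half-open bins", {
  x <- petloop:::.empty_interactions()
  x[1, ] <- list("chr1", 0L, 2000L, "chr1", 48000L, 52000L, "a", "b",
                 3L, 1e-6, 1e-4, "PP", "H3K4me3", "P", "P", NA_character_)
  expect_equal(interaction_distance(x), 49000)
  expect_equal(unname(distance_bins(x)), c(0L, 1L, 0L, 0L, 0L))

  x2 <- x
  x2$start2 <- 99000L; x2$end2 <- 103000L  # distance exactly 100,000
  b <- distance_bins(x2)
  expect_equal(unname(b[["[100000,1000000)"]]), 1L)
  expect_equal(sum(distance_bins(rbind(x, x2))), 2L)
  expect_equal(sum(distance_bins(x[0, ])), 0L)
  expect_error(distance_bins(x, edges = c(5, 2)), "increasing")
  inter <- x
  inter$chrom2 <- "chr2"
  expect_error(interaction_distance(inter), "intra")
})

test_that("connectivity statistics count distinct P-D partners", {
  mk <- function(a, b, ta, tb) {
    x <- petloop:::.empty_interactions()
    x[1, ] <- list("chr1", 0L, 2000L, "chr1", 50000L, 52000L, a, b,
                   3L, 1e-6, 1e-4, paste0(sort(c(ta, tb))[1], sort(c(ta, tb))[2]),
                   "H3K4me3", ta, tb, NA_character_)
    x$class <- if (ta == tb) paste0(ta, tb) else "PD"
    x
  }
  ints <- rbind(mk("P1", "D1", "P", "D"), mk("P1", "D2", "P", "D"))
  cs <- connectivity_stats(ints)
  expect_equal(cs$d_per_p[["P1"]], 2L)
  expect_equal(cs$p_per_d[["D1"]], 1L)
  expect_equal(cs$mean_d_per_p, 2.0)

  star <- do.call(rbind, lapply(1:5, function(i) mk(paste0("P", i), "D1", "P", "D")))
  expect_equal(connectivity_stats(star)$mean_p_per_d, 5.0)
  none <- connectivity_stats(mk("P1", "P2", "P", "P"))
  expect_equal(length(none$d_per_p), 0)
})

test_that("skipped genes lie strictly between anchors, clear of both windows", {
  genes <- make_genes("chr1", start = c(30000, 1500, 90000),
                      end = c(34000, 5500, 94000),
                      id = c("between", "nearA", "outside"))
  expr <- matrix(c(5, 5, 0.2, 0.2, 9, 9), nrow = 3, byrow = TRUE,
                 dimnames = list(c("between", "nearA", "outside"),
                                 c("s1", "s2")))
  pd <- petloop:::.empty_interactions()
  pd[1, ] <- list("chr1", 0L, 2000L, "chr1", 60000L, 62000L, "a", "b",
                  3L, 1e-6, 1e-4, "PD", "H3K27ac", "P", "D", NA_character_)
  sk <- skipped_genes(pd, genes, expr)
  expect_equal(sk$skipped[[1]], "between")
  expect_equal(sk$skipped_expressed[[1]], "between")
  # expression filter: low-FPKM genes are skipped but not "typically expressed"
  expr["between", ] <- c(0.4, 0.4)
  expect_equal(skipped_genes(pd, genes, expr)$skipped_expressed[[1]], character(0))
  expect_error(skipped_genes({
    x <- pd; x$class <- "PP"; x
  }, genes, expr), "P-D")
})

test_that("classified synthetic interactions partition into PP/PD/DD and recover planted classes", {
  cfg <- sim_config(seed = 6, n_genes = 80, n_distal_peaks = 60, n_loops = 40,
                    background_pets = 10000, chrom_length = 8e6)
  sim <- simulate_dataset(cfg)
  pets <- classify_pets(pool_and_dedup(sim$pets))
  calls <- call_interactions(pets, sim$genome$peaks)
  ann <- annotate_peaks(sim$genome$peaks, sim$genome$genes)
  calls <- classify_interactions(calls, ann)
  expect_equal(sum(calls$class == "PP") + sum(calls$class == "PD") +
                 sum(calls$class == "DD"), nrow(calls))
  m <- match(loop_key(calls$anchorA, calls$anchorB),
             loop_key(sim$truth$loops$peak_a, sim$truth$loops$peak_b))
  expect_gt(sum(!is.na(m)), 30)
  expect_equal(calls$class[!is.na(m)], sim$truth$loops$class[m[!is.na(m)]])
})
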