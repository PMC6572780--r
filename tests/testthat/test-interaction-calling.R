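test_that("hypergeometric tail equals exact combinatorial enumeration", {
  # spot-check the combinatorial oracle itself against subset enumeration
  for (case in list(c(2, 3, 3, 10), c(1, 4, 2, 8), c(3, 5, 4, 9))) {
    expect_equal(hyper_tail_oracle(case[1], case[2], case[3], case[4]),
                 hyper_tail_brute(case[1], case[2], case[3], case[4]),
                 tolerance = 1e-12)
  }
  # full sweep: all (nTot <= 30, nA, nB, x) on a grid
  for (nTot in c(1:12, 20, 30)) {
    for (nA in 0:nTot) {
      for (nB in seq(0, nTot, by = max(1, nTot %/% 6))) {
        xs <- 0:min(nA, nB)
        got <- hypergeom_tail(xs, nA, nB, nTot)
        want <- vapply(xs, hyper_tail_oracle, numeric(1), nA = nA, nB = nB,
                       nTot = nTot)
        expect_equal(got, want, tolerance = 1e-12)
      }
    }
  }
})

test_that("hypergeometric tail matches phyper, is monotone, handles edge cases", {
  expect_equal(hypergeom_tail(0, 5, 5, 20), 1.0)
  expect_equal(hypergeom_tail(3, 10, 3, 10), 1.0)  # all draws are successes
  set.seed(1)
  for (i in 1:50) {
    nTot <- sample(50:5000, 1)
    nA <- sample.int(nTot, 1); nB <- sample.int(nTot, 1)
    x <- sample.int(min(nA, nB), 1)
    expect_equal(hypergeom_tail(x, nA, nB, nTot),
                 phyper(x - 1, nA, nTot - nA, nB, lower.tail = FALSE),
                 tolerance = 1e-10)
  }
  p <- hypergeom_tail(0:5, 8, 5, 40)
  expect_true(all(diff(p) <= 0))
  expect_error(hypergeom_tail(4, 3, 5, 10), "min")
  expect_error(hypergeom_tail(1, 11, 5, 10), "n_tot")
})

test_that("BH adjustment is the textbook step-up and matches p.adjust", {
  expect_equal(bh_adjust(0.04), 0.04)
  expect_equal(bh_adjust(c(0.01, 0.01, 0.01)), rep(0.01, 3))
  expect_equal(bh_adjust(c(0.01, 0.02, 0.04, 0.05)),
               p.adjust(c(0.01, 0.02, 0.04, 0.05), method = "BH"))
  set.seed(7)
  for (i in 1:200) {
    m <- sample(1:500, 1)
    p <- runif(m)^sample(1:3, 1)
    q <- bh_adjust(p)
    expect_equal(q, p.adjust(p, method = "BH"))
    expect_true(all(q >= 0 & q <= 1))
    # order invariance
    perm <- sample(m)
    expect_equal(bh_adjust(p[perm]), q[perm])
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_equal(bh_adjust(numeric(0)), numeric(0))
})

test_that("PET ends assign to peaks by midpoint with half-open boundaries", {
  peaks <- make_peaks("chr1", c(1000, 5000), c(3000, 7000), id = c("A", "B"))
  pets <- make_pets("chr1",
                    start1 = c(1400, 2900, 1500, 1000),
                    end1 = c(1600, 3100, 1700, 1200),
                    start2 = c(5400, 5400, 2000, 1400),
                    end2 = c(5600, 5600, 2200, 1600))
  asg <- assign_pets_to_peaks(pets, peaks)
  expect_equal(asg$peak1[1], "A")
  expect_equal(asg$peak2[1], "B")
  # midpoint 3000 is exactly the (exclusive) peak end: unassigned
  expect_true(is.na(asg$peak1[2]))
  # both ends inside the same peak: assigned but links nothing
  expect_equal(asg$peak1[3], "A")
  expect_equal(asg$peak2[3], "A")
})

test_that("interaction calling applies the count and FDR rules", {
  # one strong candidate over a sparse background of singleton links
  peaks <- make_peaks("chr1", seq(0, 19) * 50000, seq(0, 19) * 50000 + 2000)
  strong <- make_pets("chr1",
                      start1 = rep(500, 5), end1 = rep(700, 5),
                      start2 = rep(100500, 5), end2 = rep(100700, 5) + 1:5)
  bg_i <- 4:19
  bg <- make_pets("chr1", start1 = bg_i * 50000 + 500,
                  end1 = bg_i * 50000 + 700,
                  start2 = (bg_i + rep(c(2, 3), 8) - (bg_i %% 2)) * 50000 + 500,
                  end2 = (bg_i + rep(c(2, 3), 8) - (bg_i %% 2)) * 50000 + 700)
  pets <- classify_pets(pool_and_dedup(list(strong, bg)))
  calls <- call_interactions(pets, peaks)
  expect_equal(nrow(calls), 1)
  expect_equal(calls$anchorA, "pk01")
  expect_equal(calls$anchorB, "pk03")
  expect_equal(calls$petCount, 5L)
  expect_lt(calls$fdr, 0.01)
  # high-confidence invariant by construction
  expect_true(all(calls$petCount >= 3 & calls$fdr < 0.01))

  # a 2-PET candidate is rejected by the count rule however small its p
  calls2 <- call_interactions(pets, peaks, min_pets = 6)
  expect_equal(nrow(calls2), 0)
})

test_that("mark merging unions by both-anchor overlap", {
  base <- petloop:::.empty_interactions()
  base[1, ] <- list("chr1", 0L, 2000L, "chr1", 100000L, 102000L,
                    "k4a", "k4b", 5L, 1e-8, 1e-5, NA_character_,
                    "H3K4me3", NA_character_, NA_character_, "leaf")
  other <- base
  other$anchorA <- "k27a"; other$anchorB <- "k27b"
  other$markProvenance <- "H3K27ac"
  other$fdr <- base$fdr / 10
  merged <- merge_mark_sets(base, other)
  expect_equal(nrow(merged), 1)
  expect_equal(merged$markProvenance, "H3K27ac,H3K4me3")
  expect_equal(merged$fdr, other$fdr)

  # disjoint sets just concatenate
  shifted <- base
  shifted[, c("start1", "end1", "start2", "end2")] <-
    shifted[, c("start1", "end1", "start2", "end2")] + 500000
  expect_equal(nrow(merge_mark_sets(base, shifted)), 2)

  # A anchors overlap but B anchors do not: two records
  half <- base
  half$start2 <- base$start2 + 300000
  half$end2 <- base$end2 + 300000
  expect_equal(nrow(merge_mark_sets(base, half)), 2)

  # cross-tissue merges refuse
  wrong <- other
  wrong$tissue <- "root"
  expect_error(merge_mark_sets(base, wrong), "tissue")
})
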