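# shared fixtures and independent oracles

make_pets <- function(chrom1, start1, end1, chrom2 = chrom1,
                      start2, end2, count = 1L) {
  data.frame(chrom1 = chrom1, start1 = as.integer(start1),
             end1 = as.integer(end1), chrom2 = chrom2,
             start2 = as.integer(start2), end2 = as.integer(end2),
             count = as.integer(count), stringsAsFactors = FALSE)
}

make_peaks <- function(chrom, start, end, id = NULL, signal = 1,
                       mark = "combined") {
  n <- length(start)
  data.frame(chrom = rep_len(chrom, n), start = as.integer(start),
             end = as.integer(end),
             id = if (is.null(id)) sprintf("pk%02d", seq_len(n)) else id,
             signal = rep_len(signal, n), mark = rep_len(mark, n),
             stringsAsFactors = FALSE)
}

make_genes <- function(chrom, start, end, strand = "+", id = NULL) {
  n <- length(start)
  strand <- rep_len(strand, n)
  start <- as.integer(start); end <- as.integer(end)
  data.frame(id = if (is.null(id)) sprintf("g%02d", seq_len(n)) else id,
             chrom = rep_len(chrom, n), start = start, end = end,
             strand = strand,
             tss = ifelse(strand == "+", start, end - 1L),
             tts = ifelse(strand == "+", end - 1L, start),
             stringsAsFactors = FALSE)
}

# exact combinatorial oracle for the hypergeometric upper tail:
# integer-valued binomial coefficients are exact in doubles up to C(30,15)
hyper_tail_oracle <- function(x, nA, nB, nTot) {
  if (x == 0) return(1)
  k <- x:min(nA, nB)
  sum(choose(nA, k) * choose(nTot - nA, nB - k)) / choose(nTot, nB)
}

# subset-level brute force: enumerate every draw of size nB from nTot
hyper_tail_brute <- function(x, nA, nB, nTot) {
  if (nB == 0) return(as.numeric(x == 0))
  draws <- utils::combn(nTot, nB)
  mean(colSums(draws <= nA) >= x)
}

# brute-force connected components by depth-first search on an edge list
dfs_components <- function(nodes, edges) {
  adj <- lapply(stats::setNames(vector("list", length(nodes)), nodes),
                function(x) character(0))
  for (i in seq_len(nrow(edges))) {
    a <- edges$from[i]; b <- edges$to[i]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  seen <- character(0)
  comps <- list()
  for (v in nodes) {
    if (v %in% seen) next
    stack <- v
    comp <- character(0)
    while (length(stack)) {
      u <- stack[[length(stack)]]
      stack <- stack[-length(stack)]
      if (u %in% comp) next
      comp <- c(comp, u)
      stack <- c(stack, setdiff(adj[[u]], comp))
    }
    comps[[length(comps) + 1L]] <- sort(comp)
    seen <- c(seen, comp)
  }
  comps
}

loop_key <- function(a, b) paste(a, b, sep = "|")

# recovery metrics against a truth manifest
recovery_metrics <- function(calls, truth) {
  called <- loop_key(calls$anchorA, calls$anchorB)
  planted <- loop_key(truth$loops$peak_a, truth$loops$peak_b)
  list(recall = mean(planted %in% called),
       fdr = if (length(called)) mean(!(called %in% planted)) else 0)
}
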