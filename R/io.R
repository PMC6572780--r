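#' Read paired-end tags from a BEDPE file
#'
#' Parses a BEDPE file (>= 6 tab-separated columns: chrom1, start1, end1,
#' chrom2, start2, end2) into a PET table. Coordinates are taken as 0-based
#' half-open, BEDPE's native convention, and kept that way throughout the
#' package. Ends are put into canonical order (the genomically smaller end
#' first) and every record gets multiplicity \code{count = 1};
#' \code{\link{pool_and_dedup}} collapses duplicates.
#'
#' @param path Path to a BEDPE file (no header).
#' @return A data.frame with columns \code{chrom1, start1, end1, chrom2,
#'   start2, end2, count}.
#' @seealso \code{\link{write_bedpe}}, \code{\link{pool_and_dedup}}
#' @export
read_bedpe <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    warning("empty BEDPE file: ", path)
    return(.empty_pets())
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 6L)) {
    stop(sprintf("malformed BEDPE line %d in %s: expected >= 6 tab-separated fields, got %d",
                 which(nf < 6L)[1], path, nf[which(nf < 6L)[1]]), call. = FALSE)
  }
  m <- vapply(fields, function(f) f[1:6], character(6))
  coord <- suppressWarnings(matrix(as.numeric(m[c(2, 3, 5, 6), ]), nrow = 4))
  if (anyNA(coord)) {
    bad <- which(colSums(is.na(coord)) > 0)[1]
    stop(sprintf("malformed BEDPE line %d in %s: non-numeric coordinate", bad, path),
         call. = FALSE)
  }
  if (any(coord > .Machine$integer.max)) {
    stop("coordinate overflow in ", path, call. = FALSE)
  }
  pets <- data.frame(chrom1 = m[1, ], start1 = as.integer(coord[1, ]),
                     end1 = as.integer(coord[2, ]),
                     chrom2 = m[4, ], start2 = as.integer(coord[3, ]),
                     end2 = as.integer(coord[4, ]),
                     count = 1L, stringsAsFactors = FALSE)
  .check_intervals(pets$chrom1, pets$start1, pets$end1, "BEDPE end 1")
  .check_intervals(pets$chrom2, pets$start2, pets$end2, "BEDPE end 2")
  .canonicalize_pets(pets)
}

#' Write paired-end tags as BEDPE
#'
#' One line per PET occurrence: a record with \code{count = k} is written k
#' times, so reading the file back yields count-1 records and
#' \code{\link{pool_and_dedup}} reconstructs the multiplicities.
#'
#' @param pets PET data.frame as returned by \code{\link{read_bedpe}}.
#' @param path Output path.
#' @export
write_bedpe <- function(pets, path) {
  idx <- rep.int(seq_len(nrow(pets)), if ("count" %in% names(pets)) pets$count else 1L)
  out <- pets[idx, c("chrom1", "start1", "end1", "chrom2", "start2", "end2")]
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read peaks from a BED file
#'
#' Reads a BED3/BED4/BED5 peak file. Column 5, when present, is used as the
#' enrichment signal; otherwise the signal defaults to 1.0 so that
#' signal-threshold filters degrade gracefully. Missing names (column 4) are
#' auto-assigned as \code{mark_chrom_start}. Peaks are returned sorted by
#' (chrom, start); overlapping same-mark peaks are permitted here but flagged
#' with a warning (see \code{\link{merge_peaks}}).
#'
#' @param path Path to a BED file.
#' @param mark Mark label attached to every peak (e.g. "H3K4me3", "H3K27ac",
#'   or "combined").
#' @return A data.frame with columns \code{chrom, start, end, id, signal, mark}.
#' @export
read_peaks <- function(path, mark = "combined") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (!length(readLines(path, n = 1L))) {
    warning("empty BED file: ", path)
    return(.empty_peaks())
  }
  gr <- rtracklayer::import(path, format = "bed")
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr),
                   stringsAsFactors = FALSE)
  nm <- if (!is.null(gr$name)) as.character(gr$name) else rep(NA_character_, nrow(df))
  sig <- if (!is.null(gr$score)) as.numeric(gr$score) else rep(NA_real_, nrow(df))
  df$id <- ifelse(is.na(nm) | !nzchar(nm),
                  paste(mark, df$chrom, df$start, sep = "_"), nm)
  df$signal <- ifelse(is.na(sig), 1.0, sig)
  df$mark <- mark
  if (any(df$signal < 0)) stop("negative peak signal in ", path, call. = FALSE)
  if (anyDuplicated(df$id)) stop("duplicate peak ids in ", path, call. = FALSE)
  df <- df[order(df$chrom, df$start, df$end), , drop = FALSE]
  rownames(df) <- NULL
  ov <- GenomicRanges::findOverlaps(.gr(df$chrom, df$start, df$end), drop.self = TRUE)
  if (length(ov)) warning("overlapping peaks in ", path,
                          "; consider merge_peaks() before interaction calling")
  df
}

#' Write peaks as BED5
#'
#' @param peaks Peak data.frame (\code{chrom, start, end, id, signal}).
#' @param path Output path.
#' @export
write_peaks <- function(peaks, path) {
  out <- data.frame(peaks$chrom, peaks$start, peaks$end, peaks$id,
                    sprintf("%.17g", peaks$signal))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read gene models from a GFF3 file
#'
#' Keeps records with feature type \code{gene}. GFF3's 1-based inclusive
#' coordinates are converted to 0-based half-open (\code{start - 1, end}), so
#' interval lengths are preserved. The TSS is the strand-dependent first base
#' of the gene body (start for +, end - 1 for -) and the TTS the opposite end.
#'
#' @param path Path to a GFF3 file.
#' @return A data.frame with columns \code{id, chrom, start, end, strand, tss,
#'   tts}.
#' @export
read_gff3_genes <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[gr$type == "gene"]
  if (!length(gr)) {
    warning("no 'gene' records in ", path)
    return(data.frame(id = character(0), chrom = character(0), start = integer(0),
                      end = integer(0), strand = character(0), tss = integer(0),
                      tts = integer(0), stringsAsFactors = FALSE))
  }
  strand <- as.character(GenomicRanges::strand(gr))
  if (any(strand == "*")) {
    stop("gene without strand in ", path, " (record ",
         which(strand == "*")[1], ")", call. = FALSE)
  }
  id <- as.character(gr$ID)
  if (anyNA(id)) id[is.na(id)] <- as.character(gr$Name)[is.na(id)]
  if (anyNA(id)) stop("gene without ID attribute in ", path, call. = FALSE)
  if (anyDuplicated(id)) {
    stop("duplicate gene id in ", path, ": ", id[duplicated(id)][1], call. = FALSE)
  }
  start0 <- GenomicRanges::start(gr) - 1L
  end0 <- GenomicRanges::end(gr)
  genes <- data.frame(id = id,
                      chrom = as.character(GenomicRanges::seqnames(gr)),
                      start = start0, end = end0, strand = strand,
                      tss = ifelse(strand == "+", start0, end0 - 1L),
                      tts = ifelse(strand == "+", end0 - 1L, start0),
                      stringsAsFactors = FALSE)
  rownames(genes) <- NULL
  genes
}

#' Write gene models as GFF3
#'
#' Inverse of \code{\link{read_gff3_genes}}: internal 0-based half-open gene
#' bodies are written back as 1-based inclusive GFF3 \code{gene} records.
#'
#' @param genes Gene data.frame from \code{\link{read_gff3_genes}} or
#'   \code{\link{simulate_genome}}.
#' @param path Output path.
#' @export
write_gff3_genes <- function(genes, path) {
  lines <- c("##gff-version 3",
             sprintf("%s\tpetloop\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                     genes$chrom, genes$start + 1L, genes$end, genes$strand,
                     genes$id))
  writeLines(lines, path)
  invisible(path)
}

#' Read a gene x sample FPKM matrix
#'
#' Expects a TSV with a header row of sample ids and gene ids in the first
#' column. All values must be finite and non-negative.
#'
#' @param path Path to the TSV.
#' @return A numeric matrix, genes in rows, samples in columns.
#' @export
read_expression <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("expression table needs gene id + >=1 sample column", call. = FALSE)
  genes <- as.character(df[[1]])
  if (anyDuplicated(genes)) {
    stop("duplicate gene id in ", path, ": ", genes[duplicated(genes)][1], call. = FALSE)
  }
  samples <- colnames(df)[-1]
  if (anyDuplicated(samples)) stop("duplicate sample id in ", path, call. = FALSE)
  vals <- as.matrix(df[, -1, drop = FALSE])
  suppressWarnings(storage.mode(vals) <- "double")
  bad <- which(is.na(vals) | !is.finite(vals) | vals < 0, arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("invalid FPKM at gene '%s', sample '%s' in %s",
                 genes[bad[1, 1]], samples[bad[1, 2]], path), call. = FALSE)
  }
  rownames(vals) <- genes
  colnames(vals) <- samples
  vals
}

#' Write a gene x sample FPKM matrix as TSV
#'
#' @param expr Numeric matrix with gene row names and sample column names.
#' @param path Output path.
#' @export
write_expression <- function(expr, path) {
  df <- data.frame(gene = rownames(expr),
                   matrix(sprintf("%.17g", expr), nrow = nrow(expr)),
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("gene", colnames(expr))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write an interaction table
#'
#' BEDPE-extended TSV with one header line and columns chrom1, start1, end1,
#' chrom2, start2, end2, anchorA, anchorB, petCount, pValue, fdr, class,
#' markProvenance, anchor1Type, anchor2Type, tissue. Numeric columns are
#' written with 17 significant digits so the table round-trips bit-exactly
#' through \code{\link{read_interactions}}.
#'
#' @param interactions Interaction data.frame (see \code{\link{call_interactions}}).
#' @param path Output path.
#' @export
write_interactions <- function(interactions, path) {
  .validate_interactions(interactions)
  out <- interactions[, c("chrom1", "start1", "end1", "chrom2", "start2", "end2",
                          "anchorA", "anchorB", "petCount", "pValue", "fdr",
                          "class", "markProvenance", "anchor1Type", "anchor2Type",
                          "tissue")]
  out$pValue <- sprintf("%.17g", out$pValue)
  out$fdr <- sprintf("%.17g", out$fdr)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an interaction table written by \code{write_interactions}
#'
#' @param path Path to the TSV.
#' @return Interaction data.frame.
#' @export
read_interactions <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(chrom1 = "character", chrom2 = "character",
                                         anchorA = "character", anchorB = "character",
                                         class = "character",
                                         markProvenance = "character",
                                         anchor1Type = "character",
                                         anchor2Type = "character",
                                         tissue = "character"))
  if (!nrow(df)) return(.empty_interactions())
  df$petCount <- as.integer(df$petCount)
  .validate_interactions(df)
  df
}
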