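# Shared fixtures and independent oracles. The oracles deliberately avoid
# the package's code paths: CIGAR strings are parsed by hand here so splice
# and depth results can be checked against an unrelated implementation.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(IRanges)
})

# Write a hand-specified read set (data.frame: qname, flag, pos, cigar) as
# an indexed BAM over a single contig; returns the BAM path.
make_bam <- function(reads, contig = "chrT", contig_length = 100000L,
                     prefix = tempfile("reads")) {
  mlen <- vapply(reads$cigar, function(cg) {
    ops <- cigar_ops(cg)
    sum(ops$len[ops$op %in% c("M", "=", "X", "I", "S")])
  }, numeric(1))
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           paste0("@SQ\tSN:", contig, "\tLN:", contig_length))
  reads <- reads[order(reads$pos), , drop = FALSE]
  body <- sprintf("%s\t%d\t%s\t%d\t60\t%s\t*\t0\t0\t%s\t*",
                  reads$qname, reads$flag, contig, reads$pos, reads$cigar,
                  strrep("A", mlen[order(reads$pos)]))
  sam <- paste0(prefix, ".sam")
  writeLines(c(hdr, body), sam)
  suppressMessages(Rsamtools::asBam(sam, prefix, overwrite = TRUE,
                                    indexDestination = TRUE))
}

cigar_ops <- function(cg) {
  len <- as.integer(regmatches(cg, gregexpr("[0-9]+", cg))[[1L]])
  op <- regmatches(cg, gregexpr("[A-Z=]", cg))[[1L]]
  list(len = len, op = op)
}

# Reference-space gaps (N operations) of one alignment: matrix with one row
# per gap, columns gap_start / gap_end (1-based inclusive skipped bases).
cigar_gaps <- function(pos, cg) {
  ops <- cigar_ops(cg)
  ref <- pos
  out <- NULL
  for (i in seq_along(ops$op)) {
    o <- ops$op[i]; l <- ops$len[i]
    if (o == "N") out <- rbind(out, c(ref, ref + l - 1L))
    if (o %in% c("M", "=", "X", "D", "N")) ref <- ref + l
  }
  out
}

# Brute-force splice-count oracle: enumerates every read's gaps from the SAM
# text and applies the per-endpoint jitter rule directly.
oracle_splices <- function(sam_path, s, e, jitter) {
  lines <- readLines(sam_path)
  lines <- lines[!startsWith(lines, "@")]
  sl <- sr <- ex <- 0L
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    gaps <- cigar_gaps(as.integer(f[4L]), f[6L])
    if (is.null(gaps)) next
    okL <- abs(gaps[, 1L] - s) <= jitter
    okR <- abs(gaps[, 2L] - e) <= jitter
    sl <- sl + any(okL)
    sr <- sr + any(okR)
    ex <- ex + any(okL & okR)
  }
  list(splice_left = sl, splice_right = sr, exact_splice = ex)
}

# Per-base pileup oracle over [from, to] from the SAM text (M/=/X only).
oracle_depth <- function(sam_path, from, to) {
  lines <- readLines(sam_path)
  lines <- lines[!startsWith(lines, "@")]
  depth <- rep(0L, to - from + 1L)
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    ref <- as.integer(f[4L])
    ops <- cigar_ops(f[6L])
    for (i in seq_along(ops$op)) {
      o <- ops$op[i]; l <- ops$len[i]
      if (o %in% c("M", "=", "X")) {
        a <- max(ref, from); b <- min(ref + l - 1L, to)
        if (a <= b) depth[(a - from + 1L):(b - from + 1L)] <-
            depth[(a - from + 1L):(b - from + 1L)] + 1L
      }
      if (o %in% c("M", "=", "X", "D", "N")) ref <- ref + l
    }
  }
  depth
}

# Two-exon toy annotation: exon [1,100] and [201,300], intron [101,200].
toy_gtf <- function(path = tempfile(fileext = ".gtf"), extra = character(0)) {
  lines <- c(
    "chrT\ttoy\tgene\t1\t300\t.\t+\t.\tgene_id \"gA\";",
    "chrT\ttoy\ttranscript\t1\t300\t.\t+\t.\tgene_id \"gA\"; transcript_id \"tA\";",
    "chrT\ttoy\texon\t1\t100\t.\t+\t.\tgene_id \"gA\"; transcript_id \"tA\";",
    "chrT\ttoy\texon\t201\t300\t.\t+\t.\tgene_id \"gA\"; transcript_id \"tA\";",
    extra)
  writeLines(lines, path)
  path
}

toy_catalog <- function(...) build_catalog(parse_annotation(toy_gtf(...)))

# A small record data.frame in the quantify-table layout.
make_records <- function(ratio, warnings = "-", depth = 100,
                         exon = NULL, n = length(ratio)) {
  ratio <- rep_len(ratio, n); warnings <- rep_len(warnings, n)
  a_e <- if (is.null(exon)) round(depth * (1 - ratio)) else rep_len(exon, n)
  a_i <- round(depth * ratio)
  data.frame(Chr = "simC", Start = seq_len(n) * 1000L + 1L,
             End = seq_len(n) * 1000L + 400L,
             Name = paste0("g", seq_len(n), "/t", seq_len(n)),
             Score = 0L, Strand = "+",
             ExactSplice = a_e, SpliceLeft = a_e, SpliceRight = a_e,
             IntronDepth = a_i, ExonAbundance = a_e,
             IRratio = ifelse(a_i + a_e == 0, 0, a_i / (a_i + a_e)),
             Warnings = warnings, stringsAsFactors = FALSE)
}
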