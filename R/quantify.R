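#' Exonic abundance estimators
#'
#' Short-read mode takes the larger of the donor- and acceptor-side splice
#' counts; long-read mode requires the read to be spliced at both
#' boundaries and uses the ExactSplice count.
#'
#' @param counts a `splice_counts` object (or list with `splice_left`,
#'   `splice_right`, `exact_splice`).
#' @return non-negative count.
#' @export
exon_abundance_short <- function(counts) {
  max(counts$splice_left, counts$splice_right)
}

#' @rdname exon_abundance_short
#' @export
exon_abundance_long <- function(counts) {
  counts$exact_splice
}

#' Intron retention ratio
#'
#' `IRratio = A_i / (A_i + A_e)`, the estimated fraction of transcripts
#' retaining the intron. When both abundances are zero the ratio is
#' reported as 0 and the caller attaches the `LowCover` warning.
#'
#' @param a_i intronic abundance (non-negative).
#' @param a_e exonic abundance (non-negative).
#' @return value in `[0, 1]`.
#' @export
irratio <- function(a_i, a_e) {
  if (any(is.na(a_i)) || any(is.na(a_e)) || any(a_i < 0) || any(a_e < 0))
    stop("abundances must be non-negative")
  ifelse(a_i + a_e == 0, 0, a_i / (a_i + a_e))
}

#' Format an IRratio for display
#'
#' Three decimal places, round-half-even (4/73 prints as `"0.055"`).
#'
#' @param x numeric IRratio values.
#' @param digits decimal places (default 3).
#' @return character vector.
#' @export
format_irratio <- function(x, digits = 3L) {
  formatC(round(x, digits), format = "f", digits = digits)
}

#' Assign reliability warnings to a quantified intron
#'
#' `LowCover`: the informative depth `A_i + A_e` is below
#' `lowcover_min_depth`. `MinorIsoform` (long-read mode only): the
#' ExactSplice count is strongly imbalanced relative to
#' `max(SpliceLeft, SpliceRight)` — below `minor_isoform_fraction` of it —
#' indicating alternative boundary usage. `NoEvaluablePositions`: the
#' intron had no unmasked base.
#'
#' @param a_i,a_e intronic and exonic abundance (`a_i` may be `NA` when no
#'   position was evaluable).
#' @param counts `splice_counts` for the intron.
#' @param mode `"short"` or `"long"`.
#' @param lowcover_min_depth minimum informative depth (default 10).
#' @param minor_isoform_fraction imbalance threshold (default 0.5).
#' @return character vector of warning names (possibly empty).
#' @export
assign_warnings <- function(a_i, a_e, counts, mode = c("short", "long"),
                            lowcover_min_depth = 10,
                            minor_isoform_fraction = 0.5) {
  mode <- match.arg(mode)
  w <- character(0)
  no_eval <- is.na(a_i)
  if (no_eval) {
    w <- c(w, "NoEvaluablePositions")
    a_i <- 0
  }
  if (a_i + a_e < lowcover_min_depth) w <- c(w, "LowCover")
  if (mode == "long") {
    mx <- max(counts$splice_left, counts$splice_right)
    if (mx > 0 && counts$exact_splice < minor_isoform_fraction * mx)
      w <- c(w, "MinorIsoform")
  }
  w
}

#' Quantify intron retention for one sample
#'
#' For every intron in the catalog, composes the depth profile and splice
#' counts into an IR record using the estimators of the requested mode:
#' short reads use the median intron depth and `max(SpliceLeft,
#' SpliceRight)`; long reads use the minimum intron depth and ExactSplice,
#' with jitter-tolerant boundary matching (default 3 nt). The BAM is read
#' once and reads are assigned to introns by overlap.
#'
#' @param bam path to a coordinate-sorted, indexed BAM (or `BamFile`).
#' @param catalog masked intron catalog from [build_catalog()].
#' @param mode `"short"` or `"long"`.
#' @param jitter per-endpoint splice matching tolerance; defaults to 0 in
#'   short mode and 3 in long mode.
#' @param mapq minimum mapping quality (default 0).
#' @param stranded library strandedness passed to read filtering:
#'   `"none"`, `"forward"` or `"reverse"`.
#' @param lowcover_min_depth,minor_isoform_fraction warning thresholds, see
#'   [assign_warnings()].
#' @return `data.frame` of IR records with columns `Chr`, `Start`, `End`,
#'   `Name`, `Score`, `Strand`, `ExactSplice`, `SpliceLeft`,
#'   `SpliceRight`, `IntronDepth`, `ExonAbundance`, `IRratio`, `Warnings`
#'   (comma-joined, `"-"` when none). Coordinates are 1-based inclusive.
#' @export
quantify_sample <- function(bam, catalog, mode = c("short", "long"),
                            jitter = NULL, mapq = 0L,
                            stranded = c("none", "forward", "reverse"),
                            lowcover_min_depth = 10,
                            minor_isoform_fraction = 0.5) {
  mode <- match.arg(mode)
  stranded <- match.arg(stranded)
  if (is.null(jitter)) jitter <- if (mode == "long") 3L else 0L
  ga <- load_alignments(bam, region = NULL, mapq = mapq)
  gr <- granges(ga)
  pad <- IRanges::ranges(catalog)
  pad <- IRanges(pmax(1L, start(pad) - jitter - 1L), end(pad) + jitter + 1L)
  pad <- GRanges(seqnames(catalog), pad)
  hits <- findOverlaps(pad, gr, ignore.strand = TRUE)
  n <- length(catalog)
  rec <- vector("list", n)
  for (i in seq_len(n)) {
    sub <- ga[subjectHits(hits)[queryHits(hits) == i]]
    if (stranded != "none") {
      want <- as.character(strand(catalog))[i]
      if (want %in% c("+", "-")) {
        keep <- if (stranded == "forward") as.character(strand(sub)) == want
                else as.character(strand(sub)) != want
        sub <- sub[keep]
      }
    }
    prof <- depth_profile(sub, catalog[i])
    cnt <- count_splices(sub, catalog[i], jitter = jitter)
    a_i <- if (mode == "short") intron_abundance_short(prof)
           else intron_abundance_long(prof)
    a_e <- if (mode == "short") exon_abundance_short(cnt)
           else exon_abundance_long(cnt)
    w <- assign_warnings(a_i, a_e, cnt, mode,
                         lowcover_min_depth, minor_isoform_fraction)
    ai0 <- if (is.na(a_i)) 0 else a_i
    rec[[i]] <- data.frame(
      Chr = as.character(seqnames(catalog))[i],
      Start = start(catalog)[i], End = end(catalog)[i],
      Name = paste0(catalog$gene_id[i], "/", catalog$transcript_id[i]),
      Score = 0L, Strand = as.character(strand(catalog))[i],
      ExactSplice = cnt$exact_splice, SpliceLeft = cnt$splice_left,
      SpliceRight = cnt$splice_right,
      IntronDepth = ai0, ExonAbundance = a_e,
      IRratio = irratio(ai0, a_e),
      Warnings = if (length(w)) paste(w, collapse = ",") else "-",
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rec)
}

#' Classify introns as retained or not
#'
#' An intron is called `IR` when its IRratio reaches the threshold and it
#' carries no warnings; common thresholds for benchmarking are 0.05 and
#' 0.10.
#'
#' @param records IR record `data.frame` from [quantify_sample()].
#' @param threshold IRratio classification threshold (default 0.05).
#' @return character vector, `"IR"` or `"not-IR"`, one per record.
#' @export
classify_ir <- function(records, threshold = 0.05) {
  ifelse(records$IRratio >= threshold & records$Warnings == "-",
         "IR", "not-IR")
}

#' Read and write per-sample IR result tables
#'
#' Tab-delimited with one header line and the fixed column set documented
#' in [quantify_sample()]; coordinates 1-based inclusive; IRratio written
#' at full precision so a write/read cycle is lossless.
#'
#' @param records IR record `data.frame`.
#' @param path file path.
#' @return `read_ir_table` returns the records `data.frame`;
#'   `write_ir_table` returns `path` invisibly.
#' @export
write_ir_table <- function(records, path) {
  out <- records
  out$IRratio <- sprintf("%.10g", out$IRratio)
  out$IntronDepth <- sprintf("%.10g", out$IntronDepth)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ir_table
#' @export
read_ir_table <- function(path) {
  read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
             colClasses = c(Chr = "character", Name = "character",
                            Strand = "character", Warnings = "character"))
}
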