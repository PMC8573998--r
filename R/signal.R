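#' Load alignments overlapping a region
#'
#' Thin wrapper over [GenomicAlignments::readGAlignments()] applying the
#' package's read-level filters: secondary alignments are dropped, an
#' optional minimum mapping quality is enforced, and in stranded mode only
#' reads on the required strand are kept.
#'
#' @param bam path to a coordinate-sorted, indexed BAM file (or a
#'   `BamFile`).
#' @param region `GRanges` of length one to fetch; `NULL` fetches the whole
#'   file.
#' @param mapq minimum mapping quality (default 0: keep everything; records
#'   with unknown MAPQ 255 always pass).
#' @param stranded `"none"` (default), `"forward"` (keep reads whose
#'   alignment strand equals the region's strand) or `"reverse"` (opposite
#'   strand).
#' @return `GAlignments`.
#' @export
load_alignments <- function(bam, region = NULL, mapq = 0L,
                            stranded = c("none", "forward", "reverse")) {
  stranded <- match.arg(stranded)
  bf <- if (is(bam, "BamFile")) bam else Rsamtools::BamFile(bam)
  if (!is.null(region)) {
    known <- names(Rsamtools::scanBamHeader(bf)$targets)
    miss <- setdiff(as.character(seqnames(region)), known)
    if (length(miss))
      stop("contig not present in BAM: ", paste(miss, collapse = ", "))
  }
  flag <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                 isSecondaryAlignment = FALSE)
  param <- if (is.null(region))
    Rsamtools::ScanBamParam(flag = flag, what = "mapq")
  else
    Rsamtools::ScanBamParam(flag = flag, what = "mapq",
                            which = granges(region))
  ga <- GenomicAlignments::readGAlignments(bf, param = param)
  if (mapq > 0L) {
    q <- mcols(ga)$mapq
    ga <- ga[is.na(q) | q == 255L | q >= mapq]
  }
  if (stranded != "none" && !is.null(region)) {
    want <- as.character(strand(region))[1L]
    if (want %in% c("+", "-")) {
      keep <- if (stranded == "forward") as.character(strand(ga)) == want
              else as.character(strand(ga)) != want
      ga <- ga[keep]
    }
  }
  ga
}

.as_galignments <- function(alignments, intron, pad = 0L, ...) {
  if (is(alignments, "GAlignments")) return(alignments)
  region <- granges(intron)
  start(region) <- max(1L, start(region) - pad)
  end(region) <- end(region) + pad
  load_alignments(alignments, region = region, ...)
}

#' Per-base depth profile over an intron
#'
#' Depth at each intron position counts aligned read bases from CIGAR
#' match/mismatch operations (`M`, `=`, `X`); deletions, skips and clips do
#' not contribute. Positions inside the intron's exclusion mask are flagged
#' and excluded from the abundance statistics. Optional flanking windows
#' capture exonic coverage on both sides for the coverage-array transform.
#'
#' @param alignments a `GAlignments`, or a BAM path/`BamFile` from which
#'   reads overlapping the intron are fetched.
#' @param intron one row of an intron catalog (`GRanges` with a `mask`
#'   column; a missing mask column is treated as empty).
#' @param flank number of exonic bases to record on each side (default 0).
#' @param ... passed to [load_alignments()] when `alignments` is a file.
#' @return A `depth_profile` object: list with `intron_id`, `contig`,
#'   `start`, `end`, `strand`, `depth` (integer vector over the intron
#'   body), `masked` (logical vector, same length), `flank_left`,
#'   `flank_right` (numeric vectors of length `flank`).
#' @export
depth_profile <- function(alignments, intron, flank = 0L, ...) {
  stopifnot(length(intron) == 1L)
  ga <- .as_galignments(alignments, intron, pad = flank, ...)
  s <- start(intron); e <- end(intron)
  lo <- max(1L, s - flank); hi <- e + flank
  cov <- rep(0L, hi - lo + 1L)
  if (length(ga)) {
    blocks <- unlist(GenomicAlignments::cigarRangesAlongReferenceSpace(
      GenomicAlignments::cigar(ga), ops = c("M", "=", "X"),
      pos = start(ga)), use.names = FALSE)
    blocks <- restrict(blocks, start = lo, end = hi)
    blocks <- blocks[width(blocks) > 0L]
    if (length(blocks)) {
      rle <- IRanges::coverage(IRanges::shift(blocks, 1L - lo), width = length(cov))
      cov <- as.integer(rle)
    }
  }
  body <- cov[(s - lo + 1L):(s - lo + (e - s + 1L))]
  masked <- rep(FALSE, e - s + 1L)
  mk <- mcols(intron)$mask
  if (!is.null(mk)) {
    mk <- mk[[1L]]
    for (i in seq_along(mk)) {
      a <- max(start(mk)[i], s); b <- min(end(mk)[i], e)
      if (a <= b) masked[(a - s + 1L):(b - s + 1L)] <- TRUE
    }
  }
  fl <- if (flank > 0L) cov[seq_len(s - lo)] else numeric(0)
  fr <- if (flank > 0L) cov[(e - lo + 2L):length(cov)] else numeric(0)
  if (flank > 0L && length(fl) < flank) fl <- c(rep(0, flank - length(fl)), fl)
  structure(list(intron_id = mcols(intron)$intron_id %||%
                   paste0(seqnames(intron), ":", s, "-", e, ":", strand(intron)),
                 contig = as.character(seqnames(intron)),
                 start = s, end = e, strand = as.character(strand(intron)),
                 depth = body, masked = masked,
                 flank_left = as.numeric(fl), flank_right = as.numeric(fr)),
            class = "depth_profile")
}

#' Count spliced reads at an intron's boundaries
#'
#' A read's alignment gap (CIGAR `N`) matches the donor boundary when its
#' first skipped base lies within `jitter` nucleotides of the annotated
#' intron start, and the acceptor boundary when its last skipped base lies
#' within `jitter` of the annotated intron end. `splice_left` and
#' `splice_right` count reads with at least one gap matching the respective
#' boundary, irrespective of the other endpoint; `exact_splice` counts reads
#' with at least one single gap matching both. Each read contributes at most
#' once to each tally.
#'
#' @inheritParams depth_profile
#' @param jitter non-negative per-endpoint tolerance in nucleotides
#'   (default 0; long-read mode uses 3).
#' @return A `splice_counts` object: list with `splice_left`,
#'   `splice_right`, `exact_splice`, `jitter`.
#' @export
count_splices <- function(alignments, intron, jitter = 0L, ...) {
  if (length(jitter) != 1L || is.na(jitter) || jitter < 0)
    stop("jitter must be a single non-negative integer")
  jitter <- as.integer(jitter)
  stopifnot(length(intron) == 1L)
  ga <- .as_galignments(alignments, intron, pad = jitter + 1L, ...)
  s <- start(intron); e <- end(intron)
  sl <- sr <- ex <- 0L
  if (length(ga)) {
    j <- GenomicAlignments::junctions(ga)
    u <- unlist(j, use.names = FALSE)
    if (length(u)) {
      grp <- rep(seq_along(j), lengths(j))
      okL <- abs(start(u) - s) <= jitter
      okR <- abs(end(u) - e) <= jitter
      sl <- sum(vapply(split(okL, grp), any, logical(1)))
      sr <- sum(vapply(split(okR, grp), any, logical(1)))
      ex <- sum(vapply(split(okL & okR, grp), any, logical(1)))
    }
  }
  structure(list(splice_left = sl, splice_right = sr, exact_splice = ex,
                 jitter = jitter),
            class = "splice_counts")
}

#' Intronic abundance estimators
#'
#' Short-read mode summarises the intron body as the median per-base depth
#' over unmasked positions; long-read mode uses the minimum, which is 0 as
#' soon as any unmasked base is uncovered — full-length reads must traverse
#' the entire intron for it to count as retained. With no unmasked
#' positions both return `NA` and the caller raises
#' `NoEvaluablePositions`.
#'
#' @param profile a `depth_profile`.
#' @return non-negative scalar, or `NA_real_` when no position is evaluable.
#' @export
intron_abundance_short <- function(profile) {
  d <- profile$depth[!profile$masked]
  if (length(d) == 0L) return(NA_real_)
  median(d)
}

#' @rdname intron_abundance_short
#' @export
intron_abundance_long <- function(profile) {
  d <- profile$depth[!profile$masked]
  if (length(d) == 0L) return(NA_real_)
  as.numeric(min(d))
}
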