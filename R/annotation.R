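#' Parse a GTF annotation
#'
#' Reads a GTF file (ENSEMBL dialect: tab-delimited, nine columns, attribute
#' strings of `key "value";` pairs; unquoted values are tolerated) and returns
#' the exon structure grouped by transcript. Only `gene_id` and
#' `transcript_id` attributes are required; unknown feature types are kept in
#' the underlying table but ignored by downstream catalog construction.
#'
#' @param gtf path to a GTF file.
#' @return A `genome_annotation` object: a list with
#'   \item{exons}{`GRanges` of exon features with `gene_id` and
#'     `transcript_id` metadata columns, sorted by position;}
#'   \item{features}{`GRanges` of all parsed features;}
#'   \item{contigs}{named integer vector of contig lengths (`NA` when the
#'     GTF carries no sequence lengths; the observed maximum coordinate is
#'     used as a lower bound).}
#' @export
parse_annotation <- function(gtf) {
  lines <- readLines(gtf)
  body <- !startsWith(lines, "#") & nzchar(lines)
  nfield <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  if (any(nfield != 9L)) {
    bad <- which(body)[which(nfield != 9L)[1L]]
    stop("malformed GTF line ", bad, " in '", gtf, "': expected 9 tab-separated fields, found ",
         nfield[which(nfield != 9L)[1L]])
  }
  feats <- rtracklayer::import(gtf, format = "gtf")
  if (!all(c("type", "gene_id") %in% names(mcols(feats))))
    stop("GTF lacks required attributes (gene_id)")
  exons <- feats[feats$type == "exon"]
  if (length(exons) &&
      (is.null(exons$transcript_id) || anyNA(exons$transcript_id)))
    stop("exon feature without transcript_id in '", gtf, "'")
  # within-transcript exons must not overlap each other
  if (length(exons)) {
    by_tx <- S4Vectors::split(ranges(exons), exons$transcript_id)
    n_red <- lengths(IRanges::reduce(by_tx, min.gapwidth = 0L))
    if (any(n_red != lengths(by_tx))) {
      bad_tx <- names(by_tx)[which(n_red != lengths(by_tx))[1L]]
      stop("overlapping exons within transcript '", bad_tx, "'")
    }
  }
  exons <- BiocGenerics::sort(exons, ignore.strand = TRUE)
  contigs <- seqlengths(feats)
  obs <- vapply(split(end(feats), as.character(seqnames(feats))), max, numeric(1))
  contigs[is.na(contigs)] <- obs[names(contigs)[is.na(contigs)]]
  structure(list(exons = exons, features = feats, contigs = contigs),
            class = "genome_annotation")
}

#' Derive the intron catalog from an annotation
#'
#' One intron per gap between consecutive exons of each transcript.
#' Duplicate introns arising from different transcripts (same contig, start,
#' end and strand) are collapsed into a single unit whose `gene_id` and
#' `transcript_id` columns aggregate all parents, comma-separated.
#' Transcripts with fewer than two exons contribute nothing.
#'
#' @param annotation a `genome_annotation` from [parse_annotation()].
#' @return `GRanges` of intron bodies (1-based, inclusive), sorted by
#'   position, with metadata columns `intron_id` (`contig:start-end:strand`),
#'   `gene_id`, `transcript_id`, and `mask` (an `IRangesList` of excluded
#'   sub-intervals, empty until [apply_exclusion_mask()] is used).
#' @export
build_intron_catalog <- function(annotation) {
  stopifnot(inherits(annotation, "genome_annotation"))
  ex <- annotation$exons
  grl <- S4Vectors::split(ex, ex$transcript_id)
  introns <- GenomicRanges::psetdiff(unlist(range(grl)), grl)
  tx <- rep(names(introns), lengths(introns))
  introns <- unlist(introns, use.names = FALSE)
  gene_of_tx <- vapply(split(as.character(ex$gene_id), ex$transcript_id),
                       function(g) g[[1L]], character(1))
  gene <- unname(gene_of_tx[tx])
  if (length(introns) == 0L) {
    out <- GRanges()
    mcols(out) <- DataFrame(intron_id = character(0), gene_id = character(0),
                            transcript_id = character(0),
                            mask = IRanges::IRangesList())
    return(out)
  }
  key <- paste0(seqnames(introns), ":", start(introns), "-", end(introns),
                ":", strand(introns))
  first <- !duplicated(key)
  agg <- function(x) vapply(split(x, key), function(v)
    paste(unique(v), collapse = ","), character(1))
  out <- introns[first]
  k <- key[first]
  mcols(out) <- DataFrame(intron_id = k,
                          gene_id = unname(agg(gene)[k]),
                          transcript_id = unname(agg(tx)[k]),
                          mask = IRanges::IRangesList(
                            rep(list(IRanges()), sum(first))))
  out <- BiocGenerics::sort(out, ignore.strand = TRUE)
  GenomeInfoDb::seqlengths(out) <- annotation$contigs[seqlevels(out)]
  out
}

#' Build the genome-wide exclusion mask
#'
#' Excluded intervals come from two sources: exonic intervals of the
#' annotation (any exon overlapping an intron body necessarily belongs to a
#' different transcript, because a transcript's own exons cannot fall inside
#' its own intron) and optional pre-computed low-mappability regions.
#' Intervals are merged per reason and strand is ignored: an antisense exon
#' inside an intron masks it just as a sense one does.
#'
#' @param annotation a `genome_annotation`.
#' @param mappability optional `GRanges`, or path to a BED3 file, of
#'   low-mappability regions. Intervals on contigs unknown to the annotation
#'   are skipped with a warning.
#' @return `GRanges` with a `reason` metadata column, one of
#'   `"overlapping-feature"` or `"low-mappability"`; merged and
#'   non-overlapping within each reason.
#' @export
build_exclusion_mask <- function(annotation, mappability = NULL) {
  stopifnot(inherits(annotation, "genome_annotation"))
  feat <- reduce(annotation$exons, ignore.strand = TRUE)
  mcols(feat)$reason <- if (length(feat)) "overlapping-feature" else character(0)
  lowmap <- GRanges()
  if (!is.null(mappability)) {
    if (is.character(mappability))
      mappability <- rtracklayer::import(mappability, format = "bed")
    unknown <- !(as.character(seqnames(mappability)) %in% names(annotation$contigs))
    if (any(unknown)) {
      warning("skipping ", sum(unknown), " low-mappability interval(s) on unknown contig(s): ",
              paste(unique(as.character(seqnames(mappability))[unknown]), collapse = ", "))
      mappability <- mappability[!unknown]
    }
    lowmap <- reduce(granges(mappability), ignore.strand = TRUE)
    if (length(lowmap)) mcols(lowmap)$reason <- "low-mappability"
    else mcols(lowmap)$reason <- character(0)
  }
  mask <- suppressWarnings(c(feat, lowmap))
  BiocGenerics::sort(mask, ignore.strand = TRUE)
}

#' Attach per-intron masks to a catalog
#'
#' Intersects each intron body with the exclusion mask and stores the result
#' in the catalog's `mask` column. Masked bases are dropped from intron depth
#' statistics at quantification time; an intron fully covered by its mask is
#' retained in the catalog and raises `NoEvaluablePositions` when quantified.
#'
#' @param catalog intron `GRanges` from [build_intron_catalog()].
#' @param mask exclusion `GRanges` from [build_exclusion_mask()].
#' @return the catalog with the `mask` column populated (absolute
#'   coordinates, clipped to each intron body).
#' @export
apply_exclusion_mask <- function(catalog, mask) {
  if (length(catalog) == 0L) return(catalog)
  red <- reduce(granges(mask), ignore.strand = TRUE)
  hits <- findOverlaps(catalog, red, ignore.strand = TRUE)
  per <- rep(list(IRanges()), length(catalog))
  if (length(hits)) {
    clipped <- IRanges::pintersect(ranges(catalog)[queryHits(hits)],
                                   ranges(red)[subjectHits(hits)])
    sp <- split(clipped, queryHits(hits))
    for (i in seq_along(sp))
      per[[as.integer(names(sp)[i])]] <- IRanges::reduce(sp[[i]])
  }
  prev <- mcols(catalog)$mask
  if (!is.null(prev)) {  # masks only ever grow when more regions are supplied
    per <- lapply(seq_along(per), function(i)
      IRanges::reduce(c(prev[[i]], per[[i]])))
  }
  mcols(catalog)$mask <- IRanges::IRangesList(per)
  catalog
}

#' Build a masked intron catalog in one call
#'
#' @inheritParams build_exclusion_mask
#' @return masked intron catalog `GRanges`.
#' @export
build_catalog <- function(annotation, mappability = NULL) {
  apply_exclusion_mask(build_intron_catalog(annotation),
                       build_exclusion_mask(annotation, mappability))
}

#' Write an intron catalog as BED6
#'
#' Name is `gene_id/transcript_id`, score 0. Coordinates follow BED
#' conventions (0-based, half-open) in the file; the in-memory catalog stays
#' 1-based inclusive.
#'
#' @param catalog intron catalog `GRanges`.
#' @param path output file.
#' @export
write_catalog_bed <- function(catalog, path) {
  out <- granges(catalog)
  mcols(out)$name <- paste0(catalog$gene_id, "/", catalog$transcript_id)
  mcols(out)$score <- 0L
  rtracklayer::export(out, path, format = "bed")
  invisible(path)
}
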