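#' Render an intron locus as a fixed-size coverage array
#'
#' The numeric rendering a genome browser would show, reduced to a
#' `channels x width` grid the classifier can consume. Channel 1 is read
#' depth: `flank` exonic bases at native resolution on each side and the
#' intron body linearly resampled to `body_width` positions. Channel 2
#' carries the splice evidence as piecewise-constant spans (donor-side
#' count over the left flank, ExactSplice over the body, acceptor-side
#' count over the right flank). Channel 3 marks the two exon/intron
#' boundaries. Each channel is divided by its maximum; an all-zero channel
#' stays zero.
#'
#' @param profile `depth_profile` built with `flank > 0`.
#' @param counts `splice_counts` for the same intron.
#' @param flank flank width in bases (default 30); profiles with shorter
#'   recorded flanks are zero-padded.
#' @param body_width resampled intron-body width (default 100).
#' @return A `coverage_array`: numeric matrix of dimension
#'   `3 x (2 * flank + body_width)` with values in `[0, 1]` and attribute
#'   `intron_id`.
#' @export
make_input_array <- function(profile, counts, flank = 30L, body_width = 100L) {
  if (flank <= 0L || body_width <= 0L) stop("flank and body_width must be positive")
  d <- profile$depth
  if (length(d) == 0L) stop("zero-length intron")
  body <- resample_linear(d, body_width)
  fit <- function(x, n) {
    x <- as.numeric(x)
    if (length(x) >= n) x[seq_len(n) + length(x) - n][seq_len(n)] else c(rep(0, n - length(x)), x)
  }
  fl <- fit(profile$flank_left, flank)
  fr <- rev(fit(rev(profile$flank_right), flank))
  w <- 2L * flank + body_width
  ch1 <- c(fl, body, fr)
  ch2 <- c(rep(counts$splice_left, flank),
           rep(counts$exact_splice, body_width),
           rep(counts$splice_right, flank))
  ch3 <- rep(0, w)
  ch3[c(flank, flank + 1L, flank + body_width, flank + body_width + 1L)] <- 1
  norm <- function(x) if (max(x) > 0) x / max(x) else x
  arr <- rbind(norm(ch1), norm(ch2), ch3)
  dimnames(arr) <- list(c("depth", "splice", "boundary"), NULL)
  structure(arr, intron_id = profile$intron_id, class = c("coverage_array", "matrix"))
}

# Linear resampling of a numeric vector to a fixed length.
resample_linear <- function(x, n) {
  if (length(x) == 1L) return(rep(as.numeric(x), n))
  approx(seq_along(x), as.numeric(x), xout = seq(1, length(x), length.out = n))$y
}

#' Select putative IR candidates from a short-read table
#'
#' Candidates for the convolutional filter: IRratio above 0.05 and no
#' warnings in the short-read quantification.
#'
#' @param sr_records short-read IR record `data.frame`.
#' @param min_ratio IRratio cutoff (exclusive, default 0.05).
#' @return the candidate subset of `sr_records`.
#' @export
select_candidates <- function(sr_records, min_ratio = 0.05) {
  sr_records[sr_records$IRratio > min_ratio & sr_records$Warnings == "-", ,
             drop = FALSE]
}

# Label one long-read record: "true-IR", "false-IR" or "unlabeled".
.label_one <- function(depth, ratio, warn, min_depth_tp, min_ratio_tp,
                       min_depth_fp) {
  ifelse(warn == "-" & depth >= min_depth_tp & ratio > min_ratio_tp, "true-IR",
  ifelse(depth >= min_depth_fp & ratio == 0, "false-IR", "unlabeled"))
}

#' Derive IR ground-truth labels from long-read quantification
#'
#' A record is labeled `true-IR` when it has no warning, informative depth
#' (`A_i + A_e`) of at least 25, and IRratio above 0.1; `false-IR` when it
#' has depth of at least 50 and IRratio exactly 0 (the deeper requirement
#' makes absence of retention more trustworthy); anything else is
#' `unlabeled`. A final label is assigned only when the directional and
#' non-directional long-read runs agree; incongruent introns stay
#' `unlabeled`.
#'
#' @param lr_dir,lr_nondir long-read IR record `data.frame`s from the
#'   directional and non-directional runs, matched by `Chr`, `Start`,
#'   `End`, `Strand`.
#' @param min_depth_tp,min_ratio_tp,min_depth_fp labeling thresholds
#'   (defaults 25, 0.1, 50).
#' @return `data.frame` with the intron identity columns and a `label`
#'   column in `{"true-IR", "false-IR", "unlabeled"}`.
#' @export
label_from_longreads <- function(lr_dir, lr_nondir, min_depth_tp = 25,
                                 min_ratio_tp = 0.1, min_depth_fp = 50) {
  key <- function(x) paste(x$Chr, x$Start, x$End, x$Strand, sep = ":")
  lab <- function(x) .label_one(x$IntronDepth + x$ExonAbundance, x$IRratio,
                                x$Warnings, min_depth_tp, min_ratio_tp,
                                min_depth_fp)
  ld <- lab(lr_dir); names(ld) <- key(lr_dir)
  ln <- lab(lr_nondir); names(ln) <- key(lr_nondir)
  common <- intersect(names(ld), names(ln))
  final <- ifelse(ld[common] == ln[common], ld[common], "unlabeled")
  idx <- match(common, key(lr_dir))
  data.frame(Chr = lr_dir$Chr[idx], Start = lr_dir$Start[idx],
             End = lr_dir$End[idx], Strand = lr_dir$Strand[idx],
             label = unname(final), stringsAsFactors = FALSE)
}

#' Assemble a balanced training set
#'
#' Positives are short-read candidates labeled `true-IR` by the long
#' reads. The negative class starts from candidates labeled `false-IR`;
#' because such false positives are scarce, it is augmented with
#' long-read-negative introns whose short-read IRratio exceeds 0.01
#' (true negatives that still show some intronic signal), sampled without
#' replacement. If the classes still differ in size, the majority class is
#' downsampled. Deterministic given `seed`.
#'
#' @param candidates candidate subset from [select_candidates()].
#' @param labels label `data.frame` from [label_from_longreads()].
#' @param sr_records the full short-read record table (augmentation pool).
#' @param seed integer seed.
#' @param min_ratio_neg short-read IRratio floor for augmentation
#'   negatives (default 0.01, exclusive).
#' @return `data.frame` with intron identity columns and `label` in
#'   `{"true-IR", "false-IR"}`, balanced between the two classes.
#' @export
build_training_set <- function(candidates, labels, sr_records, seed = 1L,
                               min_ratio_neg = 0.01) {
  key <- function(x) paste(x$Chr, x$Start, x$End, x$Strand, sep = ":")
  lab_of <- labels$label; names(lab_of) <- key(labels)
  cand_lab <- lab_of[key(candidates)]
  pos <- key(candidates)[!is.na(cand_lab) & cand_lab == "true-IR"]
  neg <- key(candidates)[!is.na(cand_lab) & cand_lab == "false-IR"]
  if (length(neg) < length(pos)) {
    pool_keys <- key(sr_records)[sr_records$IRratio > min_ratio_neg]
    pool <- setdiff(intersect(names(lab_of)[lab_of == "false-IR"], pool_keys),
                    neg)
    take <- min(length(pool), length(pos) - length(neg))
    if (take > 0)
      neg <- c(neg, with_seed(seed, sample(pool, take)))
  }
  n <- min(length(pos), length(neg))
  if (n == 0L) stop("training set would have an empty class")
  trim <- function(k, n) if (length(k) > n) with_seed(seed + 1L, sample(k, n)) else k
  pos <- trim(pos, n); neg <- trim(neg, n)
  all_keys <- c(pos, neg)
  src <- rbind(candidates[, c("Chr", "Start", "End", "Strand")],
               sr_records[, c("Chr", "Start", "End", "Strand")])
  idx <- match(all_keys, key(src))
  out <- src[idx, , drop = FALSE]
  out$label <- rep(c("true-IR", "false-IR"), c(length(pos), length(neg)))
  rownames(out) <- NULL
  out
}
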