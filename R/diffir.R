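#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment across the tested introns; `NA` p-values (e.g.
#' untestable introns) are excluded from the adjustment and stay `NA`.
#'
#' @param pvalues numeric vector of p-values.
#' @return adjusted p-values, same length and order.
#' @export
bh_adjust <- function(pvalues) {
  p.adjust(pvalues, method = "BH")
}

.intron_key <- function(x) paste(x$Chr, x$Start, x$End, x$Strand, sep = ":")

# Stack a list of per-sample record tables into intron x sample matrices
# of one numeric column, after verifying a shared catalog.
.stack_samples <- function(samples, column) {
  keys <- lapply(samples, .intron_key)
  ref <- keys[[1L]]
  for (k in keys) if (!identical(sort(k), sort(ref)))
    stop("samples do not share the same intron catalog")
  out <- vapply(samples, function(s)
    s[[column]][match(ref, .intron_key(s))], numeric(length(ref)))
  if (is.null(dim(out))) out <- matrix(out, nrow = length(ref))
  rownames(out) <- ref
  out
}

#' Filter introns before differential testing
#'
#' Keeps introns whose IRratio reaches `min_ratio` in at least one sample
#' of any group, and (by default) drops any intron carrying `LowCover` in
#' at least one sample.
#'
#' @param sets named list of conditions, each a list of IR record
#'   `data.frame`s (one per replicate) sharing the intron catalog.
#' @param min_ratio minimum IRratio at least one sample must reach
#'   (default 0.05).
#' @param drop_lowcover drop introns with `LowCover` in any sample
#'   (default `TRUE`).
#' @return character vector of intron keys (`Chr:Start:End:Strand`)
#'   surviving the filter.
#' @export
filter_introns <- function(sets, min_ratio = 0.05, drop_lowcover = TRUE) {
  samples <- unlist(sets, recursive = FALSE)
  ratios <- .stack_samples(samples, "IRratio")
  keep <- apply(ratios, 1L, max) >= min_ratio
  if (drop_lowcover) {
    lc <- vapply(samples, function(s)
      grepl("LowCover", s$Warnings)[match(rownames(ratios), .intron_key(s))],
      logical(nrow(ratios)))
    if (is.null(dim(lc))) lc <- matrix(lc, nrow = nrow(ratios))
    keep <- keep & !apply(lc, 1L, any)
  }
  rownames(ratios)[keep]
}

# Per-sample counts used by the GLM: intronic = IntronDepth, exonic =
# max(SpliceLeft, SpliceRight).
.glm_counts <- function(samples, introns) {
  intr <- round(.stack_samples(samples, "IntronDepth")[introns, , drop = FALSE])
  sl <- .stack_samples(samples, "SpliceLeft")[introns, , drop = FALSE]
  sr <- .stack_samples(samples, "SpliceRight")[introns, , drop = FALSE]
  list(intron = intr, exon = round(pmax(sl, sr)))
}

#' Count-based differential IR test (negative binomial GLM)
#'
#' For every intron, the intronic abundance (intron depth) and the exonic
#' abundance (max of the donor- and acceptor-side splice counts) of each
#' sample enter a negative binomial GLM with condition, count-type and
#' condition x count-type terms; the Wald p-value of the interaction tests
#' whether the intron:exon balance — the retention level — changes between
#' conditions. Fitting is delegated to DESeq2 with all size factors fixed
#' at 1, since the two counts of a sample are already on a common depth
#' scale. The effect is the log2 fold change of the intron:exon ratio.
#' Introns with all-zero counts are untestable: their p-values are `NA`
#' and they are excluded from the BH adjustment.
#'
#' @param groupA,groupB lists of IR record `data.frame`s (>= 2 replicates
#'   each) sharing the intron catalog.
#' @param min_ratio,drop_lowcover pre-test filters, see
#'   [filter_introns()].
#' @param alpha,lfc_call calling thresholds: BH-adjusted p below `alpha`
#'   (default 0.05) and absolute fold change above `lfc_call` (default
#'   1.5).
#' @return `data.frame` with one row per tested intron: `intron`,
#'   `method`, `mean_ratio_A`, `mean_ratio_B`, `effect` (log2 fold change
#'   of the intron:exon ratio, B over A), `pvalue`, `padj`, `called`.
#' @export
glm_diff <- function(groupA, groupB, min_ratio = 0.05, drop_lowcover = TRUE,
                     alpha = 0.05, lfc_call = 1.5) {
  stopifnot(length(groupA) >= 2L, length(groupB) >= 2L)
  sets <- list(A = groupA, B = groupB)
  introns <- filter_introns(sets, min_ratio, drop_lowcover)
  if (length(introns) == 0L)
    return(.empty_diff("glm"))
  samples <- c(groupA, groupB)
  cts <- .glm_counts(samples, introns)
  counts <- cbind(cts$intron, cts$exon)
  cond <- factor(rep(rep(c("A", "B"), c(length(groupA), length(groupB))), 2L))
  type <- factor(rep(c("intron", "exon"), each = length(samples)),
                 levels = c("exon", "intron"))
  storage.mode(counts) <- "integer"
  colnames(counts) <- paste0("s", seq_len(ncol(counts)))
  coldata <- DataFrame(condition = cond, type = type)
  dds <- DESeq2::DESeqDataSetFromMatrix(countData = counts,
                                        colData = coldata,
                                        design = ~ condition + type +
                                          condition:type)
  DESeq2::sizeFactors(dds) <- rep(1, ncol(counts))
  # small or low-dispersion intron sets can defeat the dispersion-trend fit;
  # fall back to gene-wise estimates as final dispersions
  dds <- tryCatch(
    suppressMessages(DESeq2::DESeq(dds, test = "Wald", quiet = TRUE)),
    error = function(e) {
      d2 <- suppressMessages(DESeq2::estimateDispersionsGeneEst(dds))
      DESeq2::dispersions(d2) <- pmax(S4Vectors::mcols(d2)$dispGeneEst, 1e-8)
      suppressMessages(DESeq2::nbinomWaldTest(d2))
    })
  term <- grep("condition.*type", DESeq2::resultsNames(dds), value = TRUE)[1L]
  res <- DESeq2::results(dds, name = term, independentFiltering = FALSE,
                         cooksCutoff = FALSE)
  ratios <- .stack_samples(samples, "IRratio")[introns, , drop = FALSE]
  nA <- length(groupA)
  untestable <- rowSums(counts) == 0
  p <- res$pvalue
  p[untestable] <- NA
  out <- data.frame(
    intron = introns, method = "glm",
    mean_ratio_A = rowMeans(ratios[, seq_len(nA), drop = FALSE]),
    mean_ratio_B = rowMeans(ratios[, -seq_len(nA), drop = FALSE]),
    effect = res$log2FoldChange, pvalue = p, padj = bh_adjust(p),
    stringsAsFactors = FALSE)
  out$called <- !is.na(out$padj) & out$padj < alpha &
    abs(out$effect) > log2(lfc_call)
  rownames(out) <- NULL
  out
}

.empty_diff <- function(method) {
  data.frame(intron = character(0), method = character(0),
             mean_ratio_A = numeric(0), mean_ratio_B = numeric(0),
             effect = numeric(0), pvalue = numeric(0), padj = numeric(0),
             called = logical(0))
}

#' Ratio-based differential IR test (empirical delta-ratio)
#'
#' The PSI-style scheme with IRratio in place of percent-spliced-in and
#' the flanking-exon abundance in place of transcript expression. The
#' effect is `delta = mean IRratio(B) - mean IRratio(A)`. Significance
#' comes from an empirical null of between-replicate delta IRratios:
#' within-condition replicate pairs of every intron contribute |delta|
#' values tagged with their exon abundance; the pool is split into
#' abundance bins (deciles, merged until each holds at least
#' `min_null_per_bin` values) and an intron's p-value is the fraction of
#' null deltas in its bin at least as large as its observed |delta|
#' (with a +1 continuity correction).
#'
#' @inheritParams glm_diff
#' @param n_bins number of abundance bins before merging (default 10).
#' @param min_null_per_bin minimum null deltas per bin (default 100).
#' @param delta_call minimum |delta| for a call (default 0.1).
#' @return `data.frame` as in [glm_diff()] with `effect` holding the
#'   delta IRratio.
#' @export
ratio_diff <- function(groupA, groupB, min_ratio = 0.05,
                       drop_lowcover = TRUE, alpha = 0.05,
                       delta_call = 0.1, n_bins = 10L,
                       min_null_per_bin = 100L) {
  stopifnot(length(groupA) >= 2L, length(groupB) >= 2L)
  sets <- list(A = groupA, B = groupB)
  introns <- filter_introns(sets, min_ratio, drop_lowcover)
  if (length(introns) == 0L)
    return(.empty_diff("ratio"))
  samples <- c(groupA, groupB)
  nA <- length(groupA)
  ratios <- .stack_samples(samples, "IRratio")[introns, , drop = FALSE]
  abund <- .stack_samples(samples, "ExonAbundance")[introns, , drop = FALSE]
  grp <- rep(c("A", "B"), c(nA, length(groupB)))
  # null pool: within-condition replicate pair deltas, abundance-tagged
  null_delta <- numeric(0); null_ab <- numeric(0)
  for (g in c("A", "B")) {
    cols <- which(grp == g)
    for (pr in utils::combn(cols, 2L, simplify = FALSE)) {
      null_delta <- c(null_delta, abs(ratios[, pr[1L]] - ratios[, pr[2L]]))
      null_ab <- c(null_ab, rowMeans(abund[, pr, drop = FALSE]))
    }
  }
  la <- log10(null_ab + 1)
  brk <- unique(quantile(la, probs = seq(0, 1, length.out = n_bins + 1L)))
  bin_of <- function(x) findInterval(pmin(pmax(x, brk[1L]), brk[length(brk)]),
                                     brk, rightmost.closed = TRUE,
                                     all.inside = TRUE)
  nb <- bin_of(la)
  # merge sparse bins into their left neighbour
  repeat {
    sizes <- tabulate(nb, nbins = max(nb))
    small <- which(sizes > 0 & sizes < min_null_per_bin)
    if (length(small) == 0L || length(unique(nb)) == 1L) break
    s <- small[1L]
    tgt <- if (s > 1L && any(nb < s)) max(nb[nb < s]) else min(nb[nb > s])
    nb[nb == s] <- tgt
  }
  obs_delta <- rowMeans(ratios[, grp == "B", drop = FALSE]) -
    rowMeans(ratios[, grp == "A", drop = FALSE])
  obs_ab <- rowMeans(abund)
  obs_bin <- bin_of(log10(obs_ab + 1))
  # map observed bins onto surviving (merged) null bins
  surv <- sort(unique(nb))
  obs_bin <- vapply(obs_bin, function(b) {
    if (b %in% surv) b else if (any(surv < b)) max(surv[surv < b]) else min(surv)
  }, numeric(1))
  p <- vapply(seq_along(obs_delta), function(i) {
    pool <- null_delta[nb == obs_bin[i]]
    (1 + sum(pool >= abs(obs_delta[i]))) / (1 + length(pool))
  }, numeric(1))
  out <- data.frame(
    intron = introns, method = "ratio",
    mean_ratio_A = rowMeans(ratios[, grp == "A", drop = FALSE]),
    mean_ratio_B = rowMeans(ratios[, grp == "B", drop = FALSE]),
    effect = obs_delta, pvalue = p, padj = bh_adjust(p),
    stringsAsFactors = FALSE)
  out$called <- !is.na(out$padj) & out$padj < alpha &
    abs(out$effect) >= delta_call
  rownames(out) <- NULL
  out
}

#' All pairwise differential comparisons
#'
#' With more than two conditions, every unordered condition pair is tested
#' and reported separately.
#'
#' @param sets named list of >= 2 conditions, each a list of replicate IR
#'   record `data.frame`s.
#' @param method `"glm"` (default) or `"ratio"`.
#' @param ... passed to [glm_diff()] / [ratio_diff()].
#' @return named list of result `data.frame`s, one per pair, named
#'   `"A_vs_B"`.
#' @export
pairwise_compare <- function(sets, method = c("glm", "ratio"), ...) {
  method <- match.arg(method)
  stopifnot(length(sets) >= 2L, !is.null(names(sets)))
  fun <- if (method == "glm") glm_diff else ratio_diff
  pairs <- utils::combn(names(sets), 2L, simplify = FALSE)
  out <- lapply(pairs, function(pr) fun(sets[[pr[1L]]], sets[[pr[2L]]], ...))
  names(out) <- vapply(pairs, function(pr) paste0(pr[1L], "_vs_", pr[2L]),
                       character(1))
  out
}
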