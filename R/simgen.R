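#' Simulate a toy gene model
#'
#' Multi-exon genes laid out head-to-tail on one synthetic contig, with
#' alternating strand, fixed exon and intron lengths, and an optional
#' number of planted antisense exons (each sitting in the middle third of
#' an intron of another gene) for exclusion-mask tests. The generator is
#' deterministic: equal arguments give byte-identical GTF text.
#'
#' @param n_genes number of genes (one transcript each).
#' @param introns_per_gene introns per transcript (exons =
#'   `introns_per_gene + 1`).
#' @param exon_length,intron_length feature sizes in bases (defaults 100
#'   and 300).
#' @param gene_gap intergenic spacing (default 1000).
#' @param antisense_introns how many introns (taken in order) receive a
#'   planted antisense exon (default 0).
#' @param seed kept for interface symmetry; the layout is deterministic.
#' @return list with
#'   \item{gtf}{character vector of GTF lines;}
#'   \item{truth}{`data.frame` of true introns: `intron_id`, `gene_id`,
#'     `transcript_id`, `contig`, `start`, `end`, `strand`, `mask_start`,
#'     `mask_end` (NA when no antisense exon was planted);}
#'   \item{exons}{`data.frame` of exon coordinates per transcript;}
#'   \item{contig}{contig name;}
#'   \item{contig_length}{contig length in bases.}
#' @export
simulate_model <- function(n_genes = 5L, introns_per_gene = 3L,
                           exon_length = 100L, intron_length = 300L,
                           gene_gap = 1000L, antisense_introns = 0L,
                           seed = 1L) {
  contig <- "simC"
  n_ex <- introns_per_gene + 1L
  span <- n_ex * exon_length + introns_per_gene * intron_length
  gtf <- character(0)
  truth <- list(); exdf <- list()
  attr_str <- function(g, t = NULL)
    if (is.null(t)) sprintf('gene_id "%s";', g)
    else sprintf('gene_id "%s"; transcript_id "%s";', g, t)
  line <- function(type, s, e, strand, attrs)
    paste(contig, "sim", type, s, e, ".", strand, ".", attrs, sep = "\t")
  planted <- 0L
  for (g in seq_len(n_genes)) {
    off <- (g - 1L) * (span + gene_gap) + 1L
    strand <- if (g %% 2L == 1L) "+" else "-"
    gid <- paste0("g", g); tid <- paste0("t", g)
    es <- off + (seq_len(n_ex) - 1L) * (exon_length + intron_length)
    ee <- es + exon_length - 1L
    gtf <- c(gtf, line("gene", off, off + span - 1L, strand, attr_str(gid)),
             line("transcript", off, off + span - 1L, strand,
                  attr_str(gid, tid)))
    for (j in seq_len(n_ex))
      gtf <- c(gtf, line("exon", es[j], ee[j], strand, attr_str(gid, tid)))
    exdf[[g]] <- data.frame(gene_id = gid, transcript_id = tid,
                            exon = seq_len(n_ex), start = es, end = ee,
                            strand = strand, stringsAsFactors = FALSE)
    for (j in seq_len(introns_per_gene)) {
      is <- ee[j] + 1L; ie <- es[j + 1L] - 1L
      ms <- me <- NA_integer_
      if (planted < antisense_introns) {
        planted <- planted + 1L
        third <- (ie - is + 1L) %/% 3L
        ms <- is + third; me <- ms + third - 1L
        as_strand <- if (strand == "+") "-" else "+"
        agid <- paste0("as", g, "_", j); atid <- paste0("ast", g, "_", j)
        gtf <- c(gtf, line("gene", ms, me, as_strand, attr_str(agid)),
                 line("transcript", ms, me, as_strand, attr_str(agid, atid)),
                 line("exon", ms, me, as_strand, attr_str(agid, atid)))
      }
      truth[[length(truth) + 1L]] <- data.frame(
        intron_id = paste0(contig, ":", is, "-", ie, ":", strand),
        gene_id = gid, transcript_id = tid, contig = contig,
        start = is, end = ie, strand = strand,
        mask_start = ms, mask_end = me, stringsAsFactors = FALSE)
    }
  }
  list(gtf = gtf, truth = do.call(rbind, truth), exons = do.call(rbind, exdf),
       contig = contig,
       contig_length = n_genes * (span + gene_gap) + gene_gap)
}

# Shared SAM emission: rows is a data.frame(qname, flag, pos, cigar, seqlen),
# written coordinate-sorted, then converted to an indexed BAM.
.write_sim_sam <- function(rows, model, out_prefix) {
  rows <- rows[order(rows$pos), , drop = FALSE]
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           paste0("@SQ\tSN:", model$contig, "\tLN:", model$contig_length))
  body <- sprintf("%s\t%d\t%s\t%d\t60\t%s\t*\t0\t0\t%s\t*",
                  rows$qname, rows$flag, model$contig, rows$pos, rows$cigar,
                  strrep("A", rows$seqlen))
  sam <- paste0(out_prefix, ".sam")
  writeLines(c(hdr, body), sam)
  bam <- suppressMessages(Rsamtools::asBam(sam, out_prefix, overwrite = TRUE,
                                           indexDestination = TRUE))
  list(sam = sam, bam = bam)
}

.ir_per_intron <- function(model, ir) {
  ids <- model$truth$intron_id
  if (length(ir) == 1L && is.null(names(ir))) {
    out <- rep(as.numeric(ir), length(ids)); names(out) <- ids; return(out)
  }
  out <- rep(0, length(ids)); names(out) <- ids
  out[names(ir)] <- as.numeric(ir)
  out
}

#' Simulate short spliced reads with known retention
#'
#' For each intron, a fraction `ir` of the local transcript pool retains
#' the intron: retained molecules yield unspliced reads whose starts are
#' spread evenly across the intron (body coverage close to
#' `ir * depth`), the remainder yield gapped reads spliced exactly at the
#' annotated boundaries (`(1 - ir) * depth` junction reads). Read
#' placement, not molecule counts, is the only stochastic element, so the
#' planted IRratio is recovered up to placement noise.
#'
#' @param model output of [simulate_model()].
#' @param ir true IRratio: scalar or named vector by `intron_id` (missing
#'   introns default to 0).
#' @param depth target per-intron molecule count (default 100).
#' @param read_length read length in bases (default 50).
#' @param out_prefix path prefix for the `.sam`/`.bam` output.
#' @param seed integer seed.
#' @return list with `sam`, `bam` paths and `truth` (the per-intron true
#'   IRratio used).
#' @export
simulate_short_reads <- function(model, ir, depth = 100L, read_length = 50L,
                                 out_prefix = tempfile("sr"), seed = 1L) {
  rl <- as.integer(read_length)
  irs <- .ir_per_intron(model, ir)
  rows <- with_seed(seed, {
    acc <- list()
    for (i in seq_len(nrow(model$truth))) {
      tr <- model$truth[i, ]
      r <- irs[[tr$intron_id]]
      n_ret <- round(r * depth); n_spl <- depth - n_ret
      flag <- if (tr$strand == "+") 0L else 16L
      L <- tr$end - tr$start + 1L
      if (n_ret > 0L) {
        n_reads <- ceiling(n_ret * (L + rl - 1L) / rl)
        starts <- round(seq(tr$start - rl + 1L, tr$end, length.out = n_reads))
        starts <- pmax(1L, starts + sample(-2L:2L, n_reads, replace = TRUE))
        acc[[length(acc) + 1L]] <- data.frame(
          qname = sprintf("ret_%d_%d", i, seq_len(n_reads)), flag = flag,
          pos = starts, cigar = paste0(rl, "M"), seqlen = rl)
      }
      if (n_spl > 0L) {
        a <- 10L + (seq_len(n_spl) - 1L) %% (rl - 20L)  # left block length
        acc[[length(acc) + 1L]] <- data.frame(
          qname = sprintf("spl_%d_%d", i, seq_len(n_spl)), flag = flag,
          pos = tr$start - a,
          cigar = sprintf("%dM%dN%dM", a, L, rl - a), seqlen = rl)
      }
    }
    do.call(rbind, acc)
  })
  out <- .write_sim_sam(rows, model, out_prefix)
  out$truth <- irs
  out
}

#' Simulate full-length long reads with splice-boundary jitter
#'
#' Each transcript emits `depth` full-length molecules. Every intron is
#' independently retained in an exact `round(ir * depth)`-sized molecule
#' subset; spliced introns get a per-endpoint displacement drawn uniformly
#' from `-endpoint_noise..endpoint_noise`, emulating basecalling-driven
#' alignment jitter at the junction. An optional alternative-3'-end locus
#' replaces part of the pool with molecules that run into the chosen
#' intron and terminate inside it — covered at the 5' side of the intron
#' only, so the minimum-coverage estimator sees zero retention.
#'
#' @inheritParams simulate_short_reads
#' @param depth molecules per transcript (default 50).
#' @param endpoint_noise maximum per-endpoint displacement in nucleotides
#'   (default 0).
#' @param alt3 optional list(`intron_id`, `fraction`, `extent`): a
#'   fraction of molecules terminate inside that intron after covering
#'   `extent` of its length (defaults 0.4 and 0.6).
#' @return list with `sam`, `bam`, `truth`.
#' @export
simulate_long_reads <- function(model, ir, depth = 50L, endpoint_noise = 0L,
                                alt3 = NULL, out_prefix = tempfile("lr"),
                                seed = 1L) {
  irs <- .ir_per_intron(model, ir)
  noise <- as.integer(endpoint_noise)
  rows <- with_seed(seed, {
    acc <- list()
    for (tid in unique(model$truth$transcript_id)) {
      tr_in <- model$truth[model$truth$transcript_id == tid, , drop = FALSE]
      ex <- model$exons[model$exons$transcript_id == tid, , drop = FALSE]
      strand <- ex$strand[1L]
      flag <- if (strand == "+") 0L else 16L
      retained <- lapply(seq_len(nrow(tr_in)), function(j) {
        n_ret <- round(irs[[tr_in$intron_id[j]]] * depth)
        if (n_ret > 0L) sample.int(depth, n_ret) else integer(0)
      })
      alt_idx <- 0L; alt_mols <- integer(0); alt_stop <- NA_integer_
      if (!is.null(alt3) && alt3$intron_id %in% tr_in$intron_id) {
        alt_idx <- match(alt3$intron_id, tr_in$intron_id)
        frac <- alt3$fraction %||% 0.4
        extent <- alt3$extent %||% 0.6
        pool <- setdiff(seq_len(depth), retained[[alt_idx]])
        alt_mols <- sample(pool, min(length(pool), round(frac * depth)))
        alt_stop <- tr_in$start[alt_idx] +
          round(extent * (tr_in$end[alt_idx] - tr_in$start[alt_idx] + 1L)) - 1L
      }
      for (m in seq_len(depth)) {
        segs <- list(); cur <- ex$start[1L]
        truncated <- FALSE
        for (j in seq_len(nrow(ex))) {
          if (j > 1L) {
            k <- j - 1L  # intron k precedes exon j
            if (alt_idx == k && m %in% alt_mols) {
              segs[[length(segs) + 1L]] <- c(cur, alt_stop)
              truncated <- TRUE
              break
            }
            if (!(m %in% retained[[k]])) {
              dl <- if (noise > 0L) sample(-noise:noise, 1L) else 0L
              dr <- if (noise > 0L) sample(-noise:noise, 1L) else 0L
              segs[[length(segs) + 1L]] <- c(cur, tr_in$start[k] - 1L + dl)
              cur <- tr_in$end[k] + 1L + dr
            }  # retained: aligned block continues through the intron
          }
        }
        if (!truncated) segs[[length(segs) + 1L]] <- c(cur, ex$end[nrow(ex)])
        segs <- do.call(rbind, segs)
        mlen <- segs[, 2L] - segs[, 1L] + 1L
        cig <- paste0(mlen[1L], "M")
        if (nrow(segs) > 1L)
          for (sgi in 2L:nrow(segs))
            cig <- paste0(cig, segs[sgi, 1L] - segs[sgi - 1L, 2L] - 1L, "N",
                          mlen[sgi], "M")
        acc[[length(acc) + 1L]] <- data.frame(
          qname = paste0(tid, "_m", m), flag = flag, pos = segs[1L, 1L],
          cigar = cig, seqlen = sum(mlen))
      }
    }
    do.call(rbind, acc)
  })
  out <- .write_sim_sam(rows, model, out_prefix)
  out$truth <- irs
  out
}

#' Simulate replicate-level IR tables for differential testing
#'
#' Generates per-sample IR record tables over a synthetic intron set with
#' condition-specific true IRratios: biological replicate noise is
#' logit-normal on the retention level (sd `sigma` on the logit scale) and
#' counting noise is Poisson on the intronic and exonic abundances at the
#' given depth. Conditions other than the first can carry planted
#' differences through `delta`.
#'
#' @param n_introns number of introns (default 500).
#' @param n_per_group replicates per condition (default 3).
#' @param depth expected informative depth per intron (default 100).
#' @param conditions condition names (default `c("A", "B")`).
#' @param baseline true IRratio per intron in the first condition;
#'   scalar, vector of length `n_introns`, or `NULL` to draw uniformly
#'   from `[0.05, 0.25]`.
#' @param delta named list (by condition) of IRratio shifts relative to
#'   baseline; each entry a scalar or length-`n_introns` vector. Unlisted
#'   conditions shift by 0.
#' @param sigma logit-scale replicate noise sd (default 0.2).
#' @param seed integer seed.
#' @return list with `sets` (named list of conditions, each a list of IR
#'   record `data.frame`s) and `truth` (`data.frame` of per-condition
#'   true IRratios per intron).
#' @export
simulate_groups <- function(n_introns = 500L, n_per_group = 3L, depth = 100L,
                            conditions = c("A", "B"), baseline = NULL,
                            delta = NULL, sigma = 0.2, seed = 1L) {
  with_seed(seed, {
    base <- if (is.null(baseline)) runif(n_introns, 0.05, 0.25)
            else rep_len(baseline, n_introns)
    ids <- seq_len(n_introns)
    coords <- data.frame(
      Chr = "simC", Start = (ids - 1L) * 1000L + 101L,
      End = (ids - 1L) * 1000L + 500L,
      Name = paste0("g", ids, "/t", ids), Score = 0L, Strand = "+",
      stringsAsFactors = FALSE)
    truth <- data.frame(intron = paste(coords$Chr, coords$Start, coords$End,
                                       coords$Strand, sep = ":"))
    sets <- list()
    for (cond in conditions) {
      d <- delta[[cond]] %||% 0
      r_cond <- pmin(pmax(base + rep_len(d, n_introns), 0), 1)
      truth[[paste0("ratio_", cond)]] <- r_cond
      reps <- list()
      for (s in seq_len(n_per_group)) {
        lg <- qlogis(pmin(pmax(r_cond, 1e-6), 1 - 1e-6))
        r_s <- plogis(lg + rnorm(n_introns, 0, sigma))
        r_s[r_cond == 0] <- 0
        a_i <- rpois(n_introns, depth * r_s)
        sl <- rpois(n_introns, depth * (1 - r_s))
        sr <- rpois(n_introns, depth * (1 - r_s))
        rec <- coords
        rec$ExactSplice <- pmin(sl, sr)
        rec$SpliceLeft <- sl
        rec$SpliceRight <- sr
        rec$IntronDepth <- a_i
        rec$ExonAbundance <- pmax(sl, sr)
        rec$IRratio <- irratio(a_i, rec$ExonAbundance)
        rec$Warnings <- ifelse(a_i + rec$ExonAbundance < 10, "LowCover", "-")
        reps[[s]] <- rec
      }
      sets[[cond]] <- reps
    }
    list(sets = sets, truth = truth)
  })
}

#' Simulate labeled coverage arrays for the CNN filter
#'
#' Builds `coverage_array` examples through [make_input_array()] from
#' synthetic depth profiles. Two regimes:
#' `"separable"` — positives have constant intron-body coverage at half
#' the flank level, negatives an empty body; a noiseless sanity dataset.
#' `"realistic"` — positives carry even Poisson body coverage at a drawn
#' retention level (0.1-0.5) with slow amplitude modulation; negatives
#' mimic mapping artifacts: near-empty bodies with one to three narrow
#' high spikes, the pattern the filter exists to reject.
#'
#' @param n total examples (half per class).
#' @param mode `"separable"` or `"realistic"`.
#' @param flank,body_width array geometry (defaults 30 and 100).
#' @param seed integer seed.
#' @return list with `x` (list of `coverage_array` matrices), `y`
#'   (1 = true IR, 0 = artifact) and `meta` (`data.frame` of generating
#'   parameters).
#' @export
simulate_cnn_dataset <- function(n = 200L, mode = c("separable", "realistic"),
                                 flank = 30L, body_width = 100L, seed = 1L) {
  mode <- match.arg(mode)
  n_pos <- n %/% 2L; n_neg <- n - n_pos
  with_seed(seed, {
    mk <- function(body, fl, fr, sl, sr, ex, id) {
      prof <- structure(list(intron_id = id, contig = "simC", start = 1L,
                             end = length(body), strand = "+",
                             depth = body, masked = rep(FALSE, length(body)),
                             flank_left = fl, flank_right = fr),
                        class = "depth_profile")
      cnt <- structure(list(splice_left = sl, splice_right = sr,
                            exact_splice = ex, jitter = 0L),
                       class = "splice_counts")
      make_input_array(prof, cnt, flank = flank, body_width = body_width)
    }
    xs <- vector("list", n); meta <- vector("list", n)
    y <- rep(c(1, 0), c(n_pos, n_neg))
    for (i in seq_len(n)) {
      pos <- y[i] == 1
      if (mode == "separable") {
        d <- 20 + (i %% 50)
        body_depth <- if (pos) d else 0
        body <- rep(body_depth, 400L)
        fl <- rep(2 * d, flank); fr <- rep(2 * d, flank)
        spl <- if (pos) d else 2 * d
        xs[[i]] <- mk(body, fl, fr, spl, spl, spl, paste0("sep", i))
        meta[[i]] <- data.frame(depth = d, ratio = if (pos) 0.5 else 0)
      } else {
        L <- sample(150:1500, 1L)
        D <- sample(30:200, 1L)
        r <- runif(1, 0.1, 0.5)
        if (pos) {
          mod <- approx(seq_len(10L), runif(10L, 0.8, 1.2),
                        xout = seq(1, 10, length.out = L))$y
          body <- rpois(L, D * r * mod)
          spl <- rpois(1, D * (1 - r))
        } else {
          body <- rpois(L, 0.05 * D * runif(1, 0.1, 0.5))
          for (k in seq_len(sample(1:3, 1L))) {
            w <- max(3L, round(L * runif(1, 0.05, 0.15)))
            at <- sample(L - w, 1L)
            body[at:(at + w - 1L)] <- rpois(w, D * runif(1, 0.2, 0.8))
          }
          spl <- rpois(1, D)
        }
        fl <- rpois(flank, D); fr <- rpois(flank, D)
        sl <- spl + rpois(1, 0.1 * D); sr <- spl + rpois(1, 0.1 * D)
        xs[[i]] <- mk(body, fl, fr, sl, sr, spl, paste0("rl", i))
        meta[[i]] <- data.frame(depth = D, ratio = if (pos) r else 0)
      }
    }
    list(x = xs, y = y, meta = do.call(rbind, meta))
  })
}
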