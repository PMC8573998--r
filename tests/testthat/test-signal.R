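test_that("depth profile counts aligned bases; unspliced reads give flat coverage", {
  cat_ <- toy_catalog()
  reads <- data.frame(qname = paste0("r", 1:10), flag = 0L, pos = 95L,
                      cigar = "110M")  # spans the whole intron [101,200]
  bam <- make_bam(reads)
  prof <- depth_profile(bam, cat_[1L])
  expect_equal(length(prof$depth), 100L)
  expect_true(all(prof$depth == 10L))
  expect_false(any(prof$masked))
})

test_that("empty alignments give an all-zero profile; unknown contig errors", {
  cat_ <- toy_catalog()
  bam <- make_bam(data.frame(qname = "r1", flag = 0L, pos = 5000L,
                             cigar = "50M"))
  prof <- depth_profile(bam, cat_[1L])
  expect_true(all(prof$depth == 0L))
  bad <- GRanges("chrMissing", IRanges(1, 100))
  expect_error(load_alignments(bam, bad), "chrMissing")
})

test_that("gaps and deletions do not count toward depth; masks are flagged", {
  path <- toy_gtf(extra =
    "chrT\ttoy\texon\t150\t170\t.\t-\t.\tgene_id \"gX\"; transcript_id \"tX\";")
  ann <- parse_annotation(path)
  cat_ <- apply_exclusion_mask(build_intron_catalog(ann),
                               build_exclusion_mask(ann))
  intr <- cat_[cat_$intron_id == "chrT:101-200:+"]
  reads <- data.frame(
    qname = c("gap", "del", "full"), flag = 0L, pos = c(96L, 96L, 101L),
    cigar = c("5M100N5M", "5M10D5M", "100M"))
  bam <- make_bam(reads)
  prof <- depth_profile(bam, intr)
  # the N gap and D deletion contribute nothing inside the intron body
  expect_equal(prof$depth[1L], 1L)   # only "full": N and D skip this base
  # del: 5M [96,100], 10D [101,110], 5M [111,115] -> depth at 111 is 2
  expect_equal(prof$depth[11L], 2L)
  expect_equal(sum(prof$masked), 21L)
  expect_equal(which(prof$masked), 50:70)
})

test_that("splice counting applies per-endpoint jitter and counts reads once", {
  cat_ <- toy_catalog()
  intr <- cat_[1L]
  exact <- data.frame(qname = "e", flag = 0L, pos = 91L, cigar = "10M100N10M")
  bam <- make_bam(exact)
  c0 <- count_splices(bam, intr, jitter = 0)
  expect_equal(c(c0$splice_left, c0$splice_right, c0$exact_splice), c(1L, 1L, 1L))
  # gap [donor+2, acceptor-3]: invisible at jitter 0, fully matched at 3
  off <- data.frame(qname = "o", flag = 0L, pos = 93L, cigar = "10M95N10M")
  bam2 <- make_bam(off)
  j0 <- count_splices(bam2, intr, jitter = 0)
  expect_equal(c(j0$splice_left, j0$splice_right, j0$exact_splice), c(0L, 0L, 0L))
  j3 <- count_splices(bam2, intr, jitter = 3)
  expect_equal(c(j3$splice_left, j3$splice_right, j3$exact_splice), c(1L, 1L, 1L))
  expect_error(count_splices(bam2, intr, jitter = -1), "jitter")
})

test_that("simulated long-read splice counts match the brute-force oracle", {
  m <- simulate_model(2, 3)
  lr <- simulate_long_reads(m, ir = 0.2, depth = 90, endpoint_noise = 2,
                            out_prefix = tempfile("lr"), seed = 11)
  cat_ <- {
    f <- tempfile(fileext = ".gtf"); writeLines(m$gtf, f)
    build_catalog(parse_annotation(f))
  }
  for (j in c(0L, 1L, 3L)) {
    for (i in seq_along(cat_)) {
      got <- count_splices(lr$bam, cat_[i], jitter = j)
      want <- oracle_splices(lr$sam, start(cat_)[i], end(cat_)[i], j)
      expect_equal(got$splice_left, want$splice_left)
      expect_equal(got$splice_right, want$splice_right)
      expect_equal(got$exact_splice, want$exact_splice)
      expect_lte(got$exact_splice, min(got$splice_left, got$splice_right))
    }
  }
})

test_that("splice counts are non-decreasing in jitter", {
  m <- simulate_model(1, 2)
  lr <- simulate_long_reads(m, ir = 0.3, depth = 60, endpoint_noise = 2,
                            out_prefix = tempfile("lr"), seed = 5)
  f <- tempfile(fileext = ".gtf"); writeLines(m$gtf, f)
  cat_ <- build_catalog(parse_annotation(f))
  prev <- c(0L, 0L, 0L)
  for (j in 0:4) {
    cnt <- count_splices(lr$bam, cat_[1L], jitter = j)
    cur <- c(cnt$splice_left, cnt$splice_right, cnt$exact_splice)
    expect_true(all(cur >= prev))
    prev <- cur
  }
})

test_that("simulated depth matches the pileup oracle and masking excludes positions", {
  m <- simulate_model(2, 2, antisense_introns = 1)
  f <- tempfile(fileext = ".gtf"); writeLines(m$gtf, f)
  cat_ <- build_catalog(parse_annotation(f))
  sr <- simulate_short_reads(m, ir = 0.4, depth = 80,
                             out_prefix = tempfile("sr"), seed = 21)
  masked_intron <- cat_[lengths(cat_$mask) > 0][1L]
  prof <- depth_profile(sr$bam, masked_intron)
  want <- oracle_depth(sr$sam, start(masked_intron), end(masked_intron))
  expect_equal(prof$depth, want)
  expect_true(any(prof$masked))
  # unmasked positions sit near the planted intronic depth
  expect_lt(abs(median(prof$depth[!prof$masked]) - 0.4 * 80), 6)
})

test_that("abundance estimators: median for short, minimum for long, min <= median", {
  prof <- structure(list(depth = c(0, 0, 5, 5), masked = rep(FALSE, 4)),
                    class = "depth_profile")
  expect_equal(intron_abundance_short(prof), 2.5)
  prof$depth <- rep(7, 10)
  expect_equal(intron_abundance_short(prof), 7)
  prof$depth <- c(4, 9, 4, 12)
  expect_equal(intron_abundance_long(prof), 4)
  prof$depth <- c(3, 0, 8, 1)
  expect_equal(intron_abundance_long(prof), 0)
  # sort-based oracle + ordering property on random profiles
  set.seed(42)
  for (k in 1:20) {
    d <- rpois(50, 5)
    p <- structure(list(depth = d, masked = rep(FALSE, 50)),
                   class = "depth_profile")
    srt <- sort(d)
    expect_equal(intron_abundance_short(p), (srt[25] + srt[26]) / 2)
    expect_lte(intron_abundance_long(p), intron_abundance_short(p))
  }
  # fully masked: no evaluable positions
  pm <- structure(list(depth = c(1, 2), masked = c(TRUE, TRUE)),
                  class = "depth_profile")
  expect_true(is.na(intron_abundance_short(pm)))
  expect_true(is.na(intron_abundance_long(pm)))
})

test_that("directional mode restricts counting to the intron's strand", {
  cat_ <- toy_catalog()  # intron on +
  reads <- data.frame(qname = c("fwd", "rev"), flag = c(0L, 16L),
                      pos = 91L, cigar = "10M100N10M")
  bam <- make_bam(reads)
  both <- count_splices(bam, cat_[1L], jitter = 0)
  expect_equal(both$exact_splice, 2L)
  fwd <- count_splices(bam, cat_[1L], jitter = 0, stranded = "forward")
  expect_equal(fwd$exact_splice, 1L)
  rev_ <- count_splices(bam, cat_[1L], jitter = 0, stranded = "reverse")
  expect_equal(rev_$exact_splice, 1L)
})
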