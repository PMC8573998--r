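fake_profile <- function(body, fl = rep(50, 30), fr = rep(50, 30), id = "x") {
  structure(list(intron_id = id, contig = "c", start = 1L,
                 end = length(body), strand = "+", depth = body,
                 masked = rep(FALSE, length(body)),
                 flank_left = fl, flank_right = fr),
            class = "depth_profile")
}
fake_counts <- function(sl = 10, sr = 10, ex = 10)
  structure(list(splice_left = sl, splice_right = sr, exact_splice = ex,
                 jitter = 0L), class = "splice_counts")

test_that("coverage arrays have fixed geometry and max-normalized channels", {
  arr <- make_input_array(fake_profile(rep(25, 500)), fake_counts())
  expect_equal(dim(arr), c(3L, 160L))
  expect_true(all(arr >= 0 & arr <= 1))
  # constant-depth intron at half the flank depth -> constant 0.5 body
  expect_true(all(arr["depth", 31:130] == 0.5))
  expect_true(all(arr["depth", c(1:30, 131:160)] == 1))
  # all-zero coverage stays all-zero
  arr0 <- make_input_array(fake_profile(rep(0, 100), fl = rep(0, 30),
                                        fr = rep(0, 30)),
                           fake_counts(0, 0, 0))
  expect_true(all(arr0[c("depth", "splice"), ] == 0))
  # boundary markers flank the body on channel 3
  expect_equal(which(arr["boundary", ] == 1), c(30L, 31L, 130L, 131L))
  expect_error(make_input_array(fake_profile(numeric(0)), fake_counts()),
               "zero-length")
})

test_that("body resampling equals an independent linear-interpolation oracle", {
  ramp <- 0:999
  arr <- make_input_array(fake_profile(ramp, fl = rep(999, 30),
                                       fr = rep(999, 30)), fake_counts())
  got <- arr["depth", 31:130] * 999
  # oracle: value at output j sits at source position 1 + (j-1)*(n-1)/(w-1)
  pos <- 1 + (seq_len(100) - 1) * 999 / 99
  lo <- floor(pos); frac <- pos - lo
  want <- ramp[lo] * (1 - frac) + ramp[pmin(lo + 1, 1000)] * frac
  expect_equal(got, want, tolerance = 1e-9)
})

test_that("candidate selection keeps unwarned records above the ratio cutoff", {
  rec <- make_records(c(0.06, 0.5, 0.04, 0.2),
                      warnings = c("-", "LowCover", "-", "-"))
  kept <- select_candidates(rec)
  expect_equal(kept$IRratio, c(0.06, 0.2))
  # re-filter oracle on a large random table
  set.seed(9)
  big <- make_records(runif(1000), warnings = sample(c("-", "LowCover", "MinorIsoform"),
                                                     1000, TRUE))
  expect_equal(select_candidates(big),
               big[big$IRratio > 0.05 & big$Warnings == "-", ],
               ignore_attr = TRUE)
})

test_that("long-read labels follow the depth/ratio rules and require congruence", {
  mk <- function(ratio, depth, warn = "-") {
    r <- make_records(0.5, n = 1)
    r$IntronDepth <- round(depth * ratio)
    r$ExonAbundance <- depth - r$IntronDepth
    r$IRratio <- ratio; r$Warnings <- warn
    r
  }
  # depth 30, ratio 0.2, clean, congruent -> true-IR
  expect_equal(label_from_longreads(mk(0.2, 30), mk(0.2, 30))$label, "true-IR")
  # depth 60, ratio 0 in both -> false-IR
  expect_equal(label_from_longreads(mk(0, 60), mk(0, 60))$label, "false-IR")
  # incongruent runs stay unlabeled
  expect_equal(label_from_longreads(mk(0.2, 30), mk(0, 60))$label, "unlabeled")
  # boundary conditions: depth and ratio rules are strict where stated
  expect_equal(label_from_longreads(mk(0.1, 30), mk(0.1, 30))$label, "unlabeled")
  expect_equal(label_from_longreads(mk(0.2, 24), mk(0.2, 24))$label, "unlabeled")
  expect_equal(label_from_longreads(mk(0.2, 30, "LowCover"),
                                    mk(0.2, 30, "LowCover"))$label, "unlabeled")
  expect_equal(label_from_longreads(mk(0, 49), mk(0, 49))$label, "unlabeled")
})

test_that("training sets balance classes by augmentation, then truncation", {
  n <- 320
  # 100 true-IR candidates, 20 false-IR candidates, 200 eligible negatives
  # (long-read negative, short-read IRratio above the 0.01 floor but below
  # the 0.05 candidate cutoff)
  sr <- make_records(rep(c(0.3, 0.2, 0.03), c(100, 20, 200)))
  lr_ratio <- ifelse(seq_len(n) <= 100, 0.3, 0)
  lr <- sr
  lr$IRratio <- lr_ratio
  lr$IntronDepth <- round(60 * lr_ratio)
  lr$ExonAbundance <- 60 - lr$IntronDepth
  lr$Warnings <- "-"
  labels <- label_from_longreads(lr, lr)
  cand <- select_candidates(sr)
  ts <- build_training_set(cand, labels, sr, seed = 3)
  tab <- table(ts$label)
  # 80 sampled negatives complete the false-IR class: 100 vs 100
  expect_equal(unname(tab["true-IR"]), 100L)
  expect_equal(unname(tab["false-IR"]), 100L)
  # determinism
  ts2 <- build_training_set(cand, labels, sr, seed = 3)
  expect_identical(ts, ts2)
  # augmented negatives all show short-read signal above the floor
  key <- function(x) paste(x$Chr, x$Start, x$End, x$Strand, sep = ":")
  neg <- ts[ts$label == "false-IR", ]
  expect_true(all(sr$IRratio[match(key(neg), key(sr))] > 0.01))
})

test_that("training is deterministic and the CV machinery rejects bad input", {
  ds <- simulate_cnn_dataset(60, "separable", seed = 2)
  cfg <- irquant:::cnn_config(epochs = 8L)
  m1 <- train_cnn(ds$x, ds$y, folds = 3, seed = 5, config = cfg)
  m2 <- train_cnn(ds$x, ds$y, folds = 3, seed = 5, config = cfg)
  expect_identical(m1$weights, m2$weights)
  expect_identical(m1$fold_metrics, m2$fold_metrics)
  expect_equal(nrow(m1$fold_metrics), 3L)
  expect_error(train_cnn(ds$x, rep(1, 60), folds = 3), "both classes")
  expect_error(train_cnn(ds$x, ds$y, folds = 1), "folds")
})

test_that("a small separable problem is learned and filtering behaves", {
  ds <- simulate_cnn_dataset(80, "separable", seed = 6)
  cfg <- irquant:::cnn_config(epochs = 15L)
  m <- train_cnn(ds$x, ds$y, folds = 4, seed = 8, config = cfg)
  expect_gte(m$cv[["balanced_accuracy"]], 0.9)
  prob <- predict(m, ds$x)
  expect_true(all(prob >= 0 & prob <= 1))
  rec <- make_records(runif(80, 0.1, 0.6))
  kept <- apply_cnn_filter(rec, prob, cutoff = 0.5)
  expect_lte(nrow(kept), nrow(rec))
  expect_true(all(kept$Name %in% rec$Name))
  # an all-zero body (the negative archetype) is rejected by the model
  ev <- evaluate_predictions(prob, ds$y)
  expect_equal(ev[["balanced_accuracy"]],
               (ev[["sensitivity"]] + ev[["specificity"]]) / 2)
  expect_gte(ev[["specificity"]], 0.9)
  # persistence round trip
  f <- tempfile(fileext = ".rds")
  save_cnn_model(m, f)
  expect_equal(predict(load_cnn_model(f), ds$x[1:4]), prob[1:4])
})

test_that("evaluation metrics are definitional", {
  truth <- c(1, 1, 1, 0, 0)
  pred <- c(0.9, 0.8, 0.2, 0.1, 0.7)
  ev <- evaluate_predictions(pred, truth)
  expect_equal(ev[["sensitivity"]], 2 / 3)
  expect_equal(ev[["specificity"]], 1 / 2)
  expect_equal(ev[["balanced_accuracy"]], (2 / 3 + 1 / 2) / 2)
  evl <- evaluate_predictions(c(1, 0), c("true-IR", "false-IR"))
  expect_equal(evl[["balanced_accuracy"]], 1)
})
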