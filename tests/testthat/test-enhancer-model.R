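test_that("call_enhancers reproduces the 2 kb-on-intersection construction", {
  g <- genome(c(chr1 = paste(rep("A", 20000), collapse = "")))
  h3 <- data.frame(chrom = "chr1", start = 10000L, end = 10900L)
  ac <- data.frame(chrom = "chr1", start = 10500L, end = 11200L)
  e <- call_enhancers(h3, ac, g)
  # intersection [10500,10900), midpoint 10700, window [9700,11700)
  expect_equal(e$start, 9700L)
  expect_equal(e$end, 11700L)
  # disjoint peaks -> empty
  ac2 <- data.frame(chrom = "chr1", start = 12000L, end = 12500L)
  expect_equal(nrow(call_enhancers(h3, ac2, g)), 0L)
  # window running off the chromosome start -> dropped
  gs <- genome(c(chr1 = paste(rep("A", 5000), collapse = "")))
  h3s <- data.frame(chrom = "chr1", start = 400L, end = 800L)
  acs <- data.frame(chrom = "chr1", start = 500L, end = 900L)
  expect_equal(nrow(call_enhancers(h3s, acs, gs)), 0L)
  # near-duplicate centers are deduplicated (first kept)
  h3d <- data.frame(chrom = "chr1", start = c(10000L, 10950L),
                    end = c(10900L, 11100L))
  acd <- data.frame(chrom = "chr1", start = 10500L, end = 11050L)
  ed <- call_enhancers(h3d, acd, gs <- g)
  expect_equal(nrow(ed), 1L)
})

test_that("phase-1 labels follow the 50%-of-central-bin rule and splits are
           disciplined", {
  g <- genome(c(chr1 = paste(rep("A", 8000), collapse = ""),
                chr2 = paste(rep("A", 8000), collapse = "")))
  # window [0,2000) has central bin [900,1100)
  tracks <- list(
    full = data.frame(chrom = "chr1", start = 850L, end = 1150L),  # covers
    part = data.frame(chrom = "chr1", start = 900L, end = 980L))   # 80 bp
  ds <- make_phase1_dataset(g, tracks, holdout_chroms = "chr2",
                            validation_chrom = "chr1")
  i <- which(ds$validation$windows$start == 0)
  expect_equal(unname(ds$validation$y[1, i]), 1)
  expect_equal(unname(ds$validation$y[2, i]), 0)
  # holdout windows appear only in the test split
  expect_true(all(ds$test$windows$chrom == "chr2"))
  expect_false(any(ds$train$windows$chrom %in% "chr2"))
  expect_error(make_phase1_dataset(g, tracks, holdout_chroms = "chrX"),
               "absent")
})

test_that("same-seed retraining gives identical predictions; different seed
           differs", {
  p1 <- tiny_phase1(seed = 7L)
  p2 <- tiny_phase1(seed = 7L)
  x <- p1$ds$test$x
  expect_identical(predict_epigenome(p1$handle, x),
                   predict_epigenome(p2$handle, x))
  p3 <- tiny_phase1(seed = 8L)
  expect_false(identical(predict_epigenome(p1$handle, x),
                         predict_epigenome(p3$handle, x)))
})

test_that("model save -> load -> predict is bit-identical", {
  p1 <- tiny_phase1()
  tf <- tempfile(fileext = ".rds")
  save_model(p1$handle, tf)
  h2 <- load_model(tf)
  x <- p1$ds$test$x[, , 1:5, drop = FALSE]
  expect_identical(predict_epigenome(p1$handle, x),
                   predict_epigenome(h2, x))
})

test_that("predict_epigenome enforces contracts", {
  p1 <- tiny_phase1()
  expect_error(predict_epigenome(p1$handle, "ACGT"), "length")
  s <- paste(rep("A", 2000), collapse = "")
  pr <- predict_epigenome(p1$handle, s)
  expect_equal(length(pr), nrow(p1$ds$train$y))
  expect_true(all(pr >= 0 & pr <= 1))
  expect_identical(pr, predict_epigenome(p1$handle, s))
  # N bases are tolerated (all-zero rows)
  sN <- paste0("N", substr(s, 2, 2000))
  expect_true(all(is.finite(predict_epigenome(p1$handle, sN))))
})

test_that("single-feature phase-1 dataset trains (F = 1 edge case)", {
  tw <- tiny_world()
  ds1 <- make_phase1_dataset(tw$reg$genome, tw$reg$tracks["H3K27ac"],
                             holdout_chroms = "chr2")
  h <- train_phase1(ds1, phase1_config(filters = 8L, epochs = 2L,
                                       patience = 2L, seed_kmers = FALSE),
                    seed = 1L)
  p <- predict_epigenome(h, ds1$test$x)
  expect_equal(nrow(matrix(p, nrow = 1)), 1L)
})

test_that("enhancer_probability equals the phase-1/phase-2 composition and
           respects the probability range", {
  pl <- demo_pipeline()
  s <- extract_window(pl$reg$genome, "chr4",
                      pl$enh$center[pl$enh$chrom == "chr4"][1])
  p_feat <- predict_epigenome(pl$h1, s)
  expect_equal(enhancer_probability(pl$h1, pl$h2, s),
               predict_phase2(pl$h2, p_feat), tolerance = 0)
  # all-N window is still a valid input
  nn <- paste(rep("N", 2000), collapse = "")
  pN <- enhancer_probability(pl$h1, pl$h2, nn)
  expect_true(is.finite(pN) && pN >= 0 && pN <= 1)
})

test_that("phase-1 reaches the synthetic-benchmark holdout accuracy", {
  pl <- demo_pipeline()
  p <- predict_epigenome(pl$h1, pl$ds$test$x)
  aucs <- vapply(seq_len(nrow(p)), function(f)
    auroc(p[f, ], pl$ds$test$y[f, ]), numeric(1))
  expect_gte(mean(aucs), 0.85)
})

test_that("planted enhancer windows outscore random background windows", {
  pl <- demo_pipeline()
  g <- pl$reg$genome
  enh4 <- pl$enh[pl$enh$chrom == "chr4", ][1:20, ]
  s_enh <- vapply(seq_len(nrow(enh4)), function(i)
    substr(g$seqs[["chr4"]], enh4$start[i] + 1L, enh4$end[i]), "")
  set.seed(31)
  starts <- sample(seq_lengths(g)[["chr4"]] - 2000L, 50)
  s_bg <- vapply(starts, function(s0)
    substr(g$seqs[["chr4"]], s0 + 1L, s0 + 2000L), "")
  p_enh <- enhancer_probability(pl$h1, pl$h2, s_enh)
  p_bg <- enhancer_probability(pl$h1, pl$h2, s_bg)
  expect_gt(min(mean(p_enh > median(p_bg)), 1), 0.8)
})
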