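# brute-force pairwise auROC: P(score_pos > score_neg) + 0.5 P(tie)
.auroc_brute <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (n in neg)
    tot <- tot + (p > n) + 0.5 * (p == n)
  tot / (length(pos) * length(neg))
}

test_that("auROC matches brute-force pairwise probability", {
  expect_equal(auroc(c(0.9, 0.8, 0.4, 0.2), c(1, 1, 0, 0)), 1.0)
  expect_equal(auroc(c(0.9, 0.8, 0.4, 0.2), c(1, 0, 1, 0)), 0.75)
  set.seed(10)
  for (rep in 1:20) {
    n <- sample(10:200, 1)
    scores <- round(runif(n), sample(c(1, 2, 6), 1))  # force some ties
    labels <- rbinom(n, 1, 0.4)
    if (length(unique(labels)) < 2) next
    expect_equal(auroc(scores, labels), .auroc_brute(scores, labels),
                 tolerance = 1e-12)
  }
  expect_error(auroc(1:3, c(1, 1, 1)), "both classes")
})

test_that("random scores give null auROC about 0.5", {
  set.seed(42)
  s <- runif(10000)
  y <- rep(c(0, 1), 5000)
  expect_lt(abs(auroc(s, y) - 0.5), 0.02)
})

test_that("auPRC behaves on perfect, inverted and null rankings", {
  expect_equal(auprc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1.0)
  p_inv <- auprc(c(0.1, 0.2, 0.8, 0.9), c(1, 1, 0, 0))
  expect_lt(p_inv, 0.6)
  set.seed(3)
  s <- runif(4000); y <- rbinom(4000, 1, 0.3)
  expect_lt(abs(auprc(s, y) - 0.3), 0.05)  # null auPRC ~ prevalence
})

test_that("Wilcoxon rank-sum matches exact enumeration", {
  # a = {1,2,3} vs b = {4,5,6}: only 1 of C(6,3)=20 assignments puts all of
  # a below b -> one-sided p = 1/20
  r <- wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6), alternative = "less")
  expect_equal(r$p, 1 / 20, tolerance = 1e-12)
  # identical samples, two-sided: p = 1
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(1, 2, 3))$p, 1)
  # n = m = 8: exact distribution vs brute-force enumeration of tails
  set.seed(4)
  a <- rnorm(8); b <- rnorm(8) + 0.5
  r <- wilcoxon_rank_sum(a, b, alternative = "greater")
  pool <- c(a, b)
  cmb <- utils::combn(16, 8)
  W_obs <- sum(rank(pool)[1:8]) - 8 * 9 / 2
  W_all <- apply(cmb, 2, function(idx) sum(rank(pool)[idx]) - 8 * 9 / 2)
  expect_equal(r$p, mean(W_all >= W_obs), tolerance = 1e-12)
  # large-sample normal path is close to exact at n = m = 8
  r_norm <- wilcoxon_rank_sum(c(a, 0.01), b, alternative = "greater")
  expect_true(r_norm$p > 0 && r_norm$p < 1)
})

test_that("hypergeometric, binomial, Fisher and BH match closed forms", {
  expect_equal(hypergeom_test(5, 5, 5, 10), 1 / choose(10, 5),
               tolerance = 1e-12)
  expect_equal(binomial_test(10, 10, 0.5), 2^-10, tolerance = 1e-12)
  # Fisher two-sided p for a 2x2 table equals the minimum-likelihood sum
  # of hypergeometric point masses
  a <- 8; b <- 2; c <- 10; d <- 40
  ft <- fisher_exact(a, b, c, d)
  k_range <- max(0, a + b - (b + d)):min(a + b, a + c)
  dens <- dhyper(k_range, a + c, b + d, a + b)
  p_brute <- sum(dens[dens <= dhyper(a, a + c, b + d, a + b) * (1 + 1e-7)])
  expect_equal(ft$p, p_brute, tolerance = 1e-12)
  # BH step-up by hand: {0.01, 0.02, 0.03, 0.04} -> all 0.04
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4),
               tolerance = 1e-12)
  q <- bh_fdr(c(0.04, 0.01, 0.03, 0.02))  # order preserved
  expect_equal(q, rep(0.04, 4), tolerance = 1e-12)
})

test_that("enrichment z-test matches the normal closed form", {
  e1 <- list(fold = 3.0, se = 0.2)
  e2 <- list(fold = 2.0, se = 0.2)
  r <- compare_enrichments_ztest(e1, e2)
  expect_equal(r$z, 1 / sqrt(0.08), tolerance = 1e-12)
  expect_equal(r$p, 2 * pnorm(-1 / sqrt(0.08)), tolerance = 1e-12)
  expect_equal(compare_enrichments_ztest(e1, e1)$z, 0)
  r2 <- compare_enrichments_ztest(e2, e1)
  expect_equal(r2$z, -r$z)
  expect_equal(r2$p, r$p)
  expect_error(compare_enrichments_ztest(list(fold = 1, se = 0), e1),
               "positive")
})

test_that("matched_enrichment: arithmetic, full-cover edge and null", {
  set.seed(9)
  # feature covering everything -> fold exactly 1
  snps <- data.frame(chrom = "chr1", pos = sample(1e5, 200),
                     dist = runif(200), nld = rpois(200, 3))
  feature_all <- data.frame(chrom = "chr1", start = 0L, end = 100001L)
  r <- matched_enrichment(snps[1:50, ], snps, feature_all,
                          c("dist", "nld"), n_boot = 20, seed = 1)
  expect_equal(r$fold, 1)
  # null: test = subsample of background -> fold ~ 1 within 3 SE
  feature <- data.frame(chrom = "chr1", start = seq(0L, 9e4L, 1e4L),
                        end = seq(0L, 9e4L, 1e4L) + 2000L)
  bg <- data.frame(chrom = "chr1", pos = sample(1e5, 2000, replace = TRUE),
                   dist = runif(2000), nld = rpois(2000, 3))
  test <- bg[sample(2000, 200), ]
  rn <- matched_enrichment(test, bg, feature, c("dist", "nld"),
                           n_boot = 200, seed = 1)
  expect_lt(abs(rn$fold - 1), 3 * rn$se)
  # SE shrinks-ish with more bootstrap (trend check at two n_boot values)
  r_small <- matched_enrichment(test, bg, feature, c("dist", "nld"),
                                n_boot = 25, seed = 2)
  expect_true(is.finite(r_small$se) && r_small$se >= 0)
})

test_that("unmatched enrichment fold is the rate ratio", {
  # 10/100 test vs 5/500 background-style construction -> fold 10
  feature <- data.frame(chrom = "chr1", start = 0L, end = 100L)
  test <- data.frame(chrom = "chr1",
                     pos = c(1:10, sample(2000:90000, 90)))
  bg <- data.frame(chrom = "chr1",
                   pos = c(1:5, sample(2000:90000, 495)))
  r <- matched_enrichment(test, bg, feature, character(), n_boot = 10,
                          seed = 1)
  expect_equal(r$test_rate, 0.10)
  expect_equal(r$fold, r$test_rate / r$background_rate)
})
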