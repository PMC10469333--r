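mk_scores <- function(ids, ieps) {
  data.frame(id = ids, iep = ieps, stringsAsFactors = FALSE)
}

mk_set <- function(sig, ids, trait = "T2D") {
  data.frame(signal_id = sig, trait = trait, snp_id = ids,
             chrom = "chr1", pos = seq_along(ids), ref = "A", alt = "C",
             ppa = rep(1 / length(ids), length(ids)),
             stringsAsFactors = FALSE)
}

test_that("iep_ratio arithmetic, sentinels and tie rule", {
  sc <- mk_scores(c("a", "b", "c"), c(0.50, 0.02, 0.01))
  r <- iep_ratio(mk_set("s1", c("a", "b", "c")), sc)
  expect_equal(r$ratio, 25)
  expect_equal(r$top_snp, "a")
  r1 <- iep_ratio(mk_set("s2", "a"), sc)
  expect_equal(r1$flag, "single_snp")
  expect_true(is.infinite(r1$ratio))
  sc2 <- mk_scores(c("a", "b", "c"), c(0.4, 0.4, 0.1))
  r2 <- iep_ratio(mk_set("s3", c("a", "b", "c")), sc2)
  expect_equal(r2$ratio, 1)
  sc3 <- mk_scores(c("a", "b"), c(0.4, 0))
  r3 <- iep_ratio(mk_set("s4", c("a", "b")), sc3)
  expect_equal(r3$flag, "top2_zero")
  expect_error(iep_ratio(mk_set("s5", c("a", "zz")), sc), "unscored")
})

test_that("prioritize counts resolved signals and deduplicates top SNPs", {
  sc <- mk_scores(c("a", "b", "c", "d", "e"),
                  c(0.50, 0.01, 0.30, 0.025, 0.9))
  cs <- rbind(mk_set("s1", c("a", "b"), "T2D"),       # ratio 50 -> resolved
              mk_set("s2", c("c", "d"), "glucose"),   # ratio 12 -> not
              mk_set("s3", "e", "HbA1c"),             # single-SNP
              mk_set("s4", c("a", "d"), "glucose"))   # ratio 20 -> not
  pr <- prioritize(cs, sc, ratio_threshold = 24)
  expect_equal(pr$summary$n_signals, 4L)
  expect_equal(pr$summary$n_single_snp, 1L)
  expect_equal(pr$summary$n_newly_resolved, 1L)
  expect_equal(pr$summary$n_unique_snps, 1L)
  # same SNP topping two resolved traits counts once
  pr2 <- prioritize(cs, sc, ratio_threshold = 15)
  expect_equal(pr2$summary$n_newly_resolved, 2L)
  expect_equal(pr2$summary$n_unique_snps, 1L)   # "a" tops s1 and s4
  # order of SNPs within sets does not matter
  cs_shuf <- cs[rev(seq_len(nrow(cs))), ]
  pr3 <- prioritize(cs_shuf, sc, ratio_threshold = 24)
  expect_equal(pr3$summary, pr$summary)
  # resolved count non-increasing in the threshold
  cnt <- vapply(c(2, 10, 30, 60),
                function(t) prioritize(cs, sc, t)$summary$n_newly_resolved,
                integer(1))
  expect_true(all(diff(cnt) <= 0))
})

test_that("calibrate_ratio_threshold reproduces brute-force hypergeometric
           tails on a toy configuration", {
  # 4 signals x 10 SNPs; top-IEP SNP always the truth; ratios huge
  ids <- paste0("v", 1:40)
  sc <- mk_scores(ids, rep(0.001, 40))
  sets <- NULL
  truth <- NULL
  for (s in 1:4) {
    members <- ids[((s - 1) * 10 + 1):(s * 10)]
    sc$iep[sc$id == members[1]] <- 0.9
    sets <- rbind(sets, mk_set(paste0("sig", s), members))
    truth <- rbind(truth, data.frame(signal_id = paste0("sig", s),
                                     snp_id = members[1]))
  }
  cal <- calibrate_ratio_threshold(sets, truth, sc, grid = c(2, 8, 32))
  expect_equal(cal$threshold, 2)
  # brute-force tail: N = 40 SNPs, K = 4 truths, n = 4 draws, k = 4
  p_brute <- sum(vapply(4:4, function(k)
    choose(4, k) * choose(36, 4 - k) / choose(40, 4), numeric(1)))
  expect_equal(cal$scan$p[1], p_brute, tolerance = 1e-12)
  expect_equal(cal$scan$n_correct[1], 4L)
  # truth never matched -> no threshold passes
  truth_bad <- truth; truth_bad$snp_id <- ids[c(2, 12, 22, 32)]
  cal2 <- calibrate_ratio_threshold(sets, truth_bad, sc,
                                    grid = c(2, 8, 32))
  expect_true(is.na(cal2$threshold))
  expect_error(calibrate_ratio_threshold(sets, truth[0, ], sc), "empty")
})

test_that("ed_overlap_enrichment matches closed-form binomial tails", {
  regions <- data.frame(chrom = "chr1", start = 0L, end = 5000L,
                        kind = "EDR", mean_ed = 1, peak_ed = 1,
                        length = 5000L)
  set.seed(30)
  all_snps <- data.frame(id = paste0("r", 1:2000), chrom = "chr1",
                         pos = sample(10000L, 2000))
  cand <- all_snps[all_snps$pos <= 5000, ][1:40, ]  # all overlap
  r <- ed_overlap_enrichment(cand, all_snps, regions, n_draws = 5000,
                             seed = 2)
  expect_equal(r$candidate_rate, 1)
  expect_equal(r$fold, 1 / r$background_rate)
  expect_equal(r$p, pbinom(39, 40, r$background_rate, lower.tail = FALSE),
               tolerance = 1e-12)
  # candidate rate equal to background -> fold ~ 1, p large
  set.seed(4)
  cand2 <- all_snps[sample(2000, 60), ]
  r2 <- ed_overlap_enrichment(cand2, all_snps, regions, n_draws = 5000,
                              seed = 2)
  expect_lt(abs(r2$fold - 1), 0.35)
  expect_gt(r2$p, 0.05)
})

test_that("credible_vs_ld_enrichment separates dominated groups and is
           null for identical ones", {
  sc <- mk_scores(c(paste0("c", 1:50), paste0("l", 1:50)),
                  c(runif(50, 0.5, 1), runif(50, 0, 0.4)))
  r <- credible_vs_ld_enrichment(paste0("c", 1:50), paste0("l", 1:50), sc,
                                 mode = "rank", seed = 1)
  expect_lt(r$p, 1e-6)
  expect_equal(r$prob_greater, 1)
  thr <- credible_vs_ld_enrichment(paste0("c", 1:50), paste0("l", 1:50),
                                   sc, mode = "threshold", seed = 1)
  expect_true(all(thr$enrichment >= 1, na.rm = TRUE))
  # identical distributions -> enrichment about 1
  sc2 <- mk_scores(c(paste0("c", 1:50), paste0("l", 1:50)),
                   rep(seq(0.1, 1, length.out = 50), 2))
  thr2 <- credible_vs_ld_enrichment(paste0("c", 1:50), paste0("l", 1:50),
                                    sc2, mode = "threshold", seed = 1)
  expect_true(all(abs(thr2$enrichment - 1) < 0.3, na.rm = TRUE))
  expect_error(credible_vs_ld_enrichment(c("c1", "l1"), c("l1"), sc),
               "overlap")
})
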