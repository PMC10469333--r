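#' Read a credible-set table
#'
#' Tab-separated with header: `signal_id`, `trait`, `snp_id`, `chrom`,
#' `pos`, `ref`, `alt`, `ppa`.
#'
#' @param path TSV file.
#' @return Long data.frame, one row per (signal, SNP).
#' @export
read_credible_sets <- function(path) {
  dt <- data.table::fread(path, sep = "\t", data.table = FALSE)
  need <- c("signal_id", "trait", "snp_id", "chrom", "pos", "ref", "alt",
            "ppa")
  if (!all(need %in% names(dt)))
    stop("credible-set table must have columns: ",
         paste(need, collapse = ", "))
  stopifnot(all(dt$ppa >= 0 & dt$ppa <= 1))
  if (any(duplicated(dt[, c("signal_id", "snp_id")])))
    stop("duplicate SNP within a signal")
  dt
}

#' IEP ratio of the top two SNPs of one credible set
#'
#' `ratio = top1 / top2` over the set's IEP scores. Single-SNP sets return
#' an infinite ratio flagged `"single_snp"`; a vanishing second score
#' (`top2 < 1e-8`) returns an infinite ratio flagged `"top2_zero"`; exact
#' ties give ratio 1 (never resolved by any threshold > 1).
#'
#' @param credible_set Rows of one signal (long credible-set format).
#' @param score_table Output of [score_snp_catalog()].
#' @return list `signal_id`, `trait`, `top_snp`, `top_iep`, `second_iep`,
#'   `ratio`, `flag` ("ok", "single_snp" or "top2_zero").
#' @export
iep_ratio <- function(credible_set, score_table) {
  sid <- credible_set$signal_id[1]
  sc <- score_table$iep[match(credible_set$snp_id, score_table$id)]
  if (anyNA(sc))
    stop("unscored SNP(s) in ", sid, ": ",
         paste(credible_set$snp_id[is.na(sc)], collapse = ", "))
  o <- order(-sc, credible_set$snp_id)  # deterministic tie order
  top <- sc[o[1]]
  res <- list(signal_id = sid, trait = credible_set$trait[1],
              top_snp = credible_set$snp_id[o[1]], top_iep = top)
  if (length(sc) == 1L) {
    c(res, list(second_iep = NA_real_, ratio = Inf, flag = "single_snp"))
  } else {
    second <- sc[o[2]]
    if (second < 1e-8) {
      c(res, list(second_iep = second, ratio = Inf, flag = "top2_zero"))
    } else {
      c(res, list(second_iep = second, ratio = top / second, flag = "ok"))
    }
  }
}

#' Prioritize credible sets by the IEP top-two ratio
#'
#' A multi-SNP signal is "newly resolved" when its ratio exceeds
#' `ratio_threshold`; single-SNP signals are counted as already resolved.
#' Unique SNP counts deduplicate top SNPs shared across traits.
#'
#' @param credible_sets Long credible-set data.frame.
#' @param score_table Output of [score_snp_catalog()].
#' @param ratio_threshold Decision threshold (> 1; default 24).
#' @return list `results` (one row per signal) and `summary` (counts).
#' @export
prioritize <- function(credible_sets, score_table, ratio_threshold = 24) {
  stopifnot(ratio_threshold > 1)
  sets <- split(credible_sets, credible_sets$signal_id)
  rows <- lapply(sets, function(cs) {
    r <- iep_ratio(cs, score_table)
    data.frame(signal_id = r$signal_id, trait = r$trait,
               top_snp = r$top_snp, top_iep = r$top_iep,
               second_iep = r$second_iep, ratio = r$ratio, flag = r$flag,
               n_snps = nrow(cs),
               passes_threshold = r$flag != "single_snp" &
                 r$ratio > ratio_threshold,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  newly <- res[res$passes_threshold, , drop = FALSE]
  summary <- list(
    n_signals = nrow(res),
    n_single_snp = sum(res$flag == "single_snp"),
    n_newly_resolved = nrow(newly),
    n_unique_snps = length(unique(newly$top_snp)),
    ratio_threshold = ratio_threshold
  )
  list(results = res, summary = summary)
}

#' Calibrate the IEP ratio threshold against single-SNP reference truth
#'
#' Emulates deriving the decision cutoff from a higher-powered reference:
#' for each candidate threshold `t`, signals with ratio > t are "resolved"
#' and the number whose top SNP matches the reference truth is tested with
#' an upper-tail hypergeometric test (population = all SNPs of the
#' evaluated multi-SNP sets, successes = the truth SNPs present there,
#' draws = number of resolved signals). Returns the smallest threshold
#' with p < `alpha` plus the full scan.
#'
#' @param credible_sets Long credible-set data.frame (multi-SNP sets; any
#'   single-SNP sets are dropped).
#' @param truth Named vector or data.frame (`signal_id`, `snp_id`) mapping
#'   signals to their known causal SNP.
#' @param score_table Output of [score_snp_catalog()].
#' @param grid Candidate thresholds (default `c(2, 4, 8, 16, 24, 32, 48)`).
#' @param alpha Significance level (default 0.05).
#' @return list `threshold` (NA if none passes), `scan` (data.frame
#'   `threshold`, `n_resolved`, `n_correct`, `p`), `n_signals`.
#' @export
calibrate_ratio_threshold <- function(credible_sets, truth, score_table,
                                      grid = c(2, 4, 8, 16, 24, 32, 48),
                                      alpha = 0.05) {
  if (is.data.frame(truth))
    truth <- stats::setNames(truth$snp_id, truth$signal_id)
  if (!length(truth)) stop("empty truth set")
  sets <- split(credible_sets, credible_sets$signal_id)
  sets <- Filter(function(cs) nrow(cs) > 1, sets)
  sets <- sets[names(sets) %in% names(truth)]
  if (!length(sets)) stop("no evaluable multi-SNP signals with truth")
  rat <- lapply(sets, iep_ratio, score_table = score_table)
  ratios <- vapply(rat, `[[`, 0, "ratio")
  tops <- vapply(rat, `[[`, "", "top_snp")
  correct <- tops == truth[names(sets)]
  N <- sum(vapply(sets, nrow, 1L))                # population: all SNPs
  K <- length(sets)                               # one truth SNP per set
  scan <- do.call(rbind, lapply(grid, function(t) {
    sel <- ratios > t
    n <- sum(sel)
    k <- sum(correct & sel)
    p <- if (n == 0) 1 else hypergeom_test(k, K, n, N)
    data.frame(threshold = t, n_resolved = n, n_correct = k, p = p)
  }))
  pass <- scan$threshold[scan$p < alpha]
  list(threshold = if (length(pass)) min(pass) else NA_real_,
       scan = scan, n_signals = length(sets))
}

#' EDR/ESR overlap enrichment of candidate SNPs vs random SNPs
#'
#' The background rate is the fraction of `n_draws` randomly drawn SNPs
#' (from `all_snps`, with replacement, seeded) overlapping any EDR/ESR;
#' the fold is the candidate overlap rate over that background, with an
#' upper-tail binomial test of the candidate overlap count at the
#' background rate.
#'
#' @param candidate_snps,all_snps SNP data.frames (`chrom`, `pos`).
#' @param ed_regions data.frame of called regions.
#' @param n_draws Background draws (default 10000).
#' @param seed RNG seed.
#' @return list `fold`, `p`, `candidate_rate`, `background_rate`,
#'   `n_candidates`.
#' @export
ed_overlap_enrichment <- function(candidate_snps, all_snps, ed_regions,
                                  n_draws = 10000L, seed = 1L) {
  stopifnot(nrow(all_snps) >= 10 * nrow(candidate_snps))
  hit_c <- .point_in_intervals(candidate_snps$chrom,
                               candidate_snps$pos - 1L, ed_regions)
  idx <- with_seed(seed, sample.int(nrow(all_snps), n_draws,
                                    replace = TRUE))
  hit_b <- .point_in_intervals(all_snps$chrom[idx],
                               all_snps$pos[idx] - 1L, ed_regions)
  bg_rate <- mean(hit_b)
  if (bg_rate == 0) stop("zero background overlap rate; fold undefined")
  cand_rate <- mean(hit_c)
  list(fold = cand_rate / bg_rate,
       p = binomial_test(sum(hit_c), length(hit_c), bg_rate, "greater"),
       candidate_rate = cand_rate, background_rate = bg_rate,
       n_candidates = nrow(candidate_snps))
}

#' Enrichment of credible-set SNPs over LD SNPs by IEP score
#'
#' Threshold mode computes, at increasing IEP cutoffs (percentiles of the
#' pooled scores), the ratio of the credible-set exceedance rate to the LD
#' exceedance rate, with bootstrap SE per cutoff. Rank mode reports the
#' Wilcoxon rank-sum test between the two groups and the rank-based
#' enrichment statistic P(credible > LD) (the common-language effect
#' size), with bootstrap SE.
#'
#' @param credible_snps,ld_snps Disjoint vectors of SNP ids.
#' @param score_table Output of [score_snp_catalog()].
#' @param mode "threshold" or "rank".
#' @param n_boot Bootstrap replicates (default 200).
#' @param seed RNG seed.
#' @return Threshold mode: data.frame `cutoff`, `enrichment`, `se`.
#'   Rank mode: list `statistic`, `p`, `prob_greater`, `se`.
#' @export
credible_vs_ld_enrichment <- function(credible_snps, ld_snps, score_table,
                                      mode = c("threshold", "rank"),
                                      n_boot = 200L, seed = 1L) {
  mode <- match.arg(mode)
  if (length(intersect(credible_snps, ld_snps)))
    stop("credible and LD SNP groups overlap")
  sc <- stats::setNames(score_table$iep, score_table$id)
  a <- sc[credible_snps]; b <- sc[ld_snps]
  if (anyNA(a) || anyNA(b)) stop("unscored SNPs in a group")
  if (mode == "rank") {
    wt <- wilcoxon_rank_sum(a, b, alternative = "greater")
    pg <- wt$statistic / (length(a) * length(b))  # P(a > b), midranks
    se <- with_seed(seed, stats::sd(replicate(n_boot, {
      aa <- sample(a, replace = TRUE); bb <- sample(b, replace = TRUE)
      wilcoxon_rank_sum(aa, bb)$statistic / (length(a) * length(b))
    })))
    return(list(statistic = wt$statistic, p = wt$p, prob_greater = pg,
                se = se))
  }
  cuts <- stats::quantile(c(a, b), probs = seq(0.1, 0.9, 0.1))
  rows <- with_seed(seed, lapply(seq_along(cuts), function(i) {
    cu <- cuts[i]
    enr <- function(x, y) {
      ry <- mean(y > cu)
      if (ry == 0) return(NA_real_)
      mean(x > cu) / ry
    }
    boots <- replicate(n_boot, enr(sample(a, replace = TRUE),
                                   sample(b, replace = TRUE)))
    data.frame(cutoff = unname(cu), enrichment = enr(a, b),
               se = stats::sd(boots, na.rm = TRUE))
  }))
  do.call(rbind, rows)
}
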