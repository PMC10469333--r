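#' Area under the ROC curve (rank-based)
#'
#' Mann-Whitney formulation with midranks for ties.
#'
#' @param scores Numeric predictions.
#' @param labels Binary labels (0/1 or logical).
#' @return auROC in \[0, 1\].
#' @export
auroc <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stop("both classes required for auROC")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve
#'
#' Step interpolation over the ranked list (average precision); ties in the
#' scores are broken conservatively by grouping tied scores.
#'
#' @inheritParams auroc
#' @return auPRC in \[0, 1\].
#' @export
auprc <- function(scores, labels) {
  labels <- as.integer(labels)
  if (!any(labels == 1L) || !any(labels == 0L))
    stop("both classes required for auPRC")
  o <- order(-scores)
  s <- scores[o]; y <- labels[o]
  # group tied scores so the curve does not depend on within-tie order
  grp <- cumsum(!duplicated(s))
  tp_g <- tapply(y, grp, sum)
  n_g <- tapply(y, grp, length)
  tp <- cumsum(tp_g)
  n <- cumsum(n_g)
  prec <- tp / n
  rec <- tp / sum(labels)
  drec <- diff(c(0, rec))
  sum(prec * drec)
}

#' Wilcoxon rank-sum test
#'
#' Exact null distribution when `min(length(a), length(b)) <= 12` and no
#' ties are present; otherwise normal approximation with tie correction and
#' continuity correction.
#'
#' @param a,b Numeric samples.
#' @param alternative "two.sided", "greater" (a tends larger) or "less".
#' @return list `statistic` (rank-sum based W of sample `a`), `p`,
#'   `method`.
#' @export
wilcoxon_rank_sum <- function(a, b,
                              alternative = c("two.sided", "greater",
                                              "less")) {
  alternative <- match.arg(alternative)
  if (!length(a) || !length(b)) stop("both samples must be nonempty")
  n <- length(a); m <- length(b)
  r <- rank(c(a, b), ties.method = "average")
  W <- sum(r[seq_len(n)]) - n * (n + 1) / 2  # Mann-Whitney U of a
  ties <- anyDuplicated(c(a, b)) > 0
  if (min(n, m) <= 12 && !ties) {
    p_le <- stats::pwilcox(W, n, m)
    p_ge <- 1 - stats::pwilcox(W - 1, n, m)
    p <- switch(alternative,
                greater = p_ge,
                less = p_le,
                two.sided = min(1, 2 * min(p_le, p_ge)))
    return(list(statistic = W, p = p, method = "exact"))
  }
  N <- n + m
  mu <- n * m / 2
  tie_tab <- table(r)
  tie_term <- sum(tie_tab^3 - tie_tab)
  sigma2 <- n * m / 12 * ((N + 1) - tie_term / (N * (N - 1)))
  sigma <- sqrt(sigma2)
  z <- switch(alternative,
              greater = (W - mu - 0.5) / sigma,
              less = (W - mu + 0.5) / sigma,
              two.sided = (W - mu - sign(W - mu) * 0.5) / sigma)
  p <- switch(alternative,
              greater = stats::pnorm(z, lower.tail = FALSE),
              less = stats::pnorm(z),
              two.sided = 2 * stats::pnorm(-abs(z)))
  list(statistic = W, p = min(1, p), method = "normal")
}

#' Hypergeometric upper-tail test
#'
#' P(X >= k) drawing `n` from a population of `N` containing `K` successes.
#'
#' @param k Observed successes in the draw.
#' @param K Successes in the population.
#' @param n Draw size.
#' @param N Population size.
#' @return p-value.
#' @export
hypergeom_test <- function(k, K, n, N) {
  stopifnot(K <= N, n <= N, k >= 0, k <= min(n, K))
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Binomial tail test
#'
#' @param k Observed successes.
#' @param n Trials.
#' @param p Null success probability.
#' @param alternative "greater" (default), "less" or "two.sided"
#'   (two-sided uses the small-probability-sum rule of `binom.test`).
#' @return p-value.
#' @export
binomial_test <- function(k, n, p,
                          alternative = c("greater", "less", "two.sided")) {
  alternative <- match.arg(alternative)
  switch(alternative,
         greater = stats::pbinom(k - 1, n, p, lower.tail = FALSE),
         less = stats::pbinom(k, n, p),
         two.sided = stats::binom.test(k, n, p)$p.value)
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided by the minimum-likelihood rule; returns the conditional
#' maximum-likelihood odds ratio as computed by `stats::fisher.test`.
#'
#' @param a,b,c,d Table cells: rows = group (candidate/background),
#'   columns = outcome (hit/other).
#' @return list `p`, `odds_ratio`.
#' @export
fisher_exact <- function(a, b, c, d) {
  if (any(c(a, b, c, d) < 0)) stop("negative cell count")
  ft <- stats::fisher.test(matrix(c(a, b, c, d), nrow = 2, byrow = TRUE))
  list(p = ft$p.value, odds_ratio = unname(ft$estimate))
}

#' Benjamini-Hochberg q-values
#'
#' @param p Vector of p-values.
#' @return q-values in the input order.
#' @export
bh_fdr <- function(p) {
  stats::p.adjust(p, method = "BH")
}

#' Compare two enrichment estimates with a z-test
#'
#' @param e1,e2 Lists with `fold` and `se` (e.g. from
#'   [matched_enrichment()]).
#' @return list `z`, `p` (two-sided).
#' @export
compare_enrichments_ztest <- function(e1, e2) {
  if (e1$se <= 0 || e2$se <= 0) stop("standard errors must be positive")
  z <- (e1$fold - e2$fold) / sqrt(e1$se^2 + e2$se^2)
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Covariate-matched enrichment of SNPs in a feature set
#'
#' Test and background SNPs are stratified by deciles of each matching
#' covariate (cross-binned); the background is resampled to match the test
#' set's stratum profile, and the fold enrichment is the test overlap rate
#' divided by the matched-background overlap rate. The SE comes from
#' bootstrap resampling of the test set (and of the matched background
#' within strata).
#'
#' @param test_snps,background_snps data.frames with `chrom`, `pos`
#'   (1-based) and the covariate columns.
#' @param feature_intervals data.frame `chrom`, `start`, `end` (0-based
#'   half-open).
#' @param matching_covariates Character vector of covariate column names
#'   (may be empty for unmatched enrichment).
#' @param n_boot Bootstrap replicates.
#' @param seed RNG seed.
#' @return list of class `enrichment_result`: `fold`, `se`, `n_test`,
#'   `n_background`, `test_rate`, `background_rate`.
#' @export
matched_enrichment <- function(test_snps, background_snps, feature_intervals,
                               matching_covariates = character(),
                               n_boot = 200, seed = 1) {
  stopifnot(nrow(test_snps) > 0, nrow(background_snps) > 0)
  stratum_of <- function(df, breaks_list) {
    if (!length(matching_covariates)) return(rep("all", nrow(df)))
    key <- lapply(matching_covariates, function(cv)
      as.integer(cut(df[[cv]], breaks = breaks_list[[cv]],
                     include.lowest = TRUE)))
    do.call(paste, c(key, sep = "_"))
  }
  breaks_list <- lapply(stats::setNames(matching_covariates,
                                        matching_covariates), function(cv) {
    q <- unique(stats::quantile(c(test_snps[[cv]], background_snps[[cv]]),
                                probs = seq(0, 1, 0.1), na.rm = TRUE))
    if (length(q) < 2) q <- c(-Inf, Inf)
    q
  })
  ts <- stratum_of(test_snps, breaks_list)
  bs <- stratum_of(background_snps, breaks_list)
  need <- table(ts)
  missing <- setdiff(names(need), unique(bs))
  if (length(missing))
    stop("background lacks covariate stratum(s): ",
         paste(missing, collapse = ", "))
  hit_t <- .point_in_intervals(test_snps$chrom, test_snps$pos - 1L,
                               feature_intervals)
  hit_b <- .point_in_intervals(background_snps$chrom, background_snps$pos - 1L,
                               feature_intervals)
  bg_by_stratum <- split(seq_len(nrow(background_snps)), bs)
  draw_bg_rate <- function() {
    tot <- 0L; hits <- 0L
    for (s in names(need)) {
      pool <- bg_by_stratum[[s]]
      take <- sample(pool, size = need[[s]], replace = TRUE)
      tot <- tot + length(take)
      hits <- hits + sum(hit_b[take])
    }
    c(hits, tot)
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  hb <- draw_bg_rate()
  test_rate <- mean(hit_t)
  bg_rate <- hb[1] / hb[2]
  fold <- if (bg_rate > 0) test_rate / bg_rate else Inf
  boots <- replicate(n_boot, {
    ti <- sample(seq_len(nrow(test_snps)), replace = TRUE)
    tr <- mean(hit_t[ti])
    hb2 <- draw_bg_rate()
    br <- hb2[1] / hb2[2]
    if (br > 0) tr / br else NA_real_
  })
  structure(list(fold = fold, se = stats::sd(boots, na.rm = TRUE),
                 n_test = nrow(test_snps),
                 n_background = nrow(background_snps),
                 test_rate = test_rate, background_rate = bg_rate),
            class = "enrichment_result")
}

# save/restore the global RNG state so seeded helpers do not perturb the
# caller's stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

# run expr with a local seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  expr
}
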