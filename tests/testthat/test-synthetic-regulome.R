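test_that("generation is deterministic for a fixed seed", {
  cfg <- regulome_config(n_chromosomes = 2L, chromosome_length = 60000L,
                         n_enhancers = 6L, n_signals = 3L, seed = 11L)
  r1 <- generate_regulome(cfg)
  r2 <- generate_regulome(cfg)
  expect_identical(r1$genome$seqs, r2$genome$seqs)
  expect_identical(r1$truth, r2$truth)
  expect_identical(r1$tracks, r2$tracks)
  s1 <- generate_snps_and_credible_sets(r1)
  s2 <- generate_snps_and_credible_sets(r2)
  expect_identical(s1, s2)
})

test_that("every planted enhancer is covered by both peak types and decoys
           of different types never intersect", {
  tw <- tiny_world()
  reg <- tw$reg
  expect_equal(nrow(reg$truth$enhancers), 12L)
  for (i in seq_len(nrow(reg$truth$enhancers))) {
    e <- reg$truth$enhancers[i, ]
    covered <- function(track) any(
      track$chrom == e$chrom & track$start <= e$center &
        track$end > e$center)
    expect_true(covered(reg$tracks$H3K27ac))
    expect_true(covered(reg$tracks$accessibility))
  }
  dec <- reg$truth$decoys
  expect_equal(nrow(edscan:::.intersect_intervals(dec$H3K27ac,
                                                  dec$accessibility)), 0L)
})

test_that("planted motifs lie inside exactly one enhancer and spell PWM-
           plausible sequence", {
  tw <- tiny_world()
  reg <- tw$reg
  m <- reg$truth$motifs
  enh <- reg$truth$enhancers
  n_inside <- vapply(seq_len(nrow(m)), function(i)
    sum(enh$chrom == m$chrom[i] & enh$start <= m$start[i] &
          enh$end >= m$end[i]), integer(1))
  expect_true(all(n_inside == 1L))
  # instance sequences score well under their own PWM
  lib <- stats::setNames(reg$config$motif_library,
                         vapply(reg$config$motif_library, `[[`, "", "id"))
  sc <- vapply(seq_len(nrow(m)), function(i) {
    p <- lib[[m$pwm[i]]]
    s <- substr(reg$genome$seqs[[m$chrom[i]]], m$start[i] + 1L, m$end[i])
    if (m$strand[i] == "-") s <- reverse_complement(s)
    idx <- match(strsplit(s, "")[[1]], c("A", "C", "G", "T"))
    sum(log2((p$matrix[cbind(seq_len(nrow(p$matrix)), idx)] + 1e-6) / 0.25))
  }, numeric(1))
  # planted instances should score far above random sequence (~0 expected
  # log-odds for background)
  expect_gt(median(sc), 5)
})

test_that("credible sets respect their construction invariants", {
  tw <- tiny_world()
  cs <- tw$snps$credible_sets
  k <- table(cs$signal_id)
  expect_true(all(k >= 2 & k <= 4))
  ppa_sum <- tapply(cs$ppa, cs$signal_id, sum)
  expect_true(all(ppa_sum > 0.95 & ppa_sum <= 1))
  expect_false(any(duplicated(cs[, c("signal_id", "snp_id")])))
  # every SNP ref matches the genome
  g <- tw$reg$genome
  ok <- mapply(function(ch, p, r) get_base(g, ch, p) == r,
               cs$chrom, cs$pos, cs$ref)
  expect_true(all(ok))
  # exactly one causal SNP per signal, member of its set
  caus <- tw$snps$causal
  expect_equal(sort(unique(cs$signal_id)), sort(caus$signal_id))
  expect_true(all(mapply(function(sig, id)
    id %in% cs$snp_id[cs$signal_id == sig], caus$signal_id, caus$snp_id)))
})

test_that("causal_in_motif_fraction = 1 places every causal SNP in a motif", {
  cfg <- regulome_config(n_chromosomes = 2L, chromosome_length = 60000L,
                         n_enhancers = 8L, n_signals = 5L,
                         causal_in_motif_fraction = 1, seed = 5L)
  reg <- generate_regulome(cfg)
  snps <- generate_snps_and_credible_sets(reg)
  caus <- merge(snps$causal, snps$snps, by.x = "snp_id", by.y = "id")
  m <- reg$truth$motifs
  inmot <- vapply(seq_len(nrow(caus)), function(i)
    any(m$chrom == caus$chrom[i] & m$start <= caus$pos[i] - 1L &
          caus$pos[i] - 1L < m$end), logical(1))
  expect_true(all(inmot))
})

test_that("emitted files reproduce the ground truth (lossless round trip)", {
  tw <- tiny_world()
  dir <- tempfile("regulome")
  paths <- write_regulome_files(tw$reg, dir, tw$snps)
  g2 <- read_fasta(paths[["genome"]])
  expect_identical(g2$seqs, tw$reg$genome$seqs)
  h3 <- read_bed(paths[["track_H3K27ac"]])
  expect_equal(h3$start, tw$reg$tracks$H3K27ac$start)
  enh2 <- read_bed(paths[["enhancers"]])
  expect_equal(enh2$start, tw$reg$truth$enhancers$start)
  s2 <- read_snp_table(paths[["snps"]], g2)
  expect_equal(nrow(s2), nrow(tw$snps$snps))
  cs2 <- read_credible_sets(paths[["credible_sets"]])
  expect_equal(cs2$ppa, tw$snps$credible_sets$ppa)
})

test_that("default PWM library is a constant and leaves the caller's RNG
           stream alone", {
  set.seed(123)
  before <- runif(1)
  set.seed(123)
  lib <- default_pwm_library(5)
  expect_equal(runif(1), before)
  lib2 <- default_pwm_library(5)
  expect_identical(lapply(lib, `[[`, "matrix"),
                   lapply(lib2, `[[`, "matrix"))
  ic <- vapply(lib, function(p) sum(information_content(p)), numeric(1))
  expect_true(all(ic > 10))  # informative, JASPAR-scale motifs
})
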