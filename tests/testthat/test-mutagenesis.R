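test_that("ED profile matches brute-force enumeration for analytic oracles", {
  set.seed(21)
  motif <- "ACGTACGT"
  bg <- sample(c("A", "C", "G", "T"), 2000, TRUE)
  seq <- paste(bg, collapse = "")
  # plant a single copy away from other spurious copies
  while (grepl(motif, seq, fixed = TRUE)) {
    bg <- sample(c("A", "C", "G", "T"), 2000, TRUE)
    seq <- paste(bg, collapse = "")
  }
  substr(seq, 1001, 1008) <- motif
  g <- genome(c(chr1 = seq))
  oracle <- motif_presence_oracle(motif)
  win <- data.frame(chrom = "chr1", start = 0L, end = 2000L)
  prof <- saturated_mutagenesis(oracle, g, win)
  brute <- brute_mutagenesis(oracle, seq)
  expect_lt(max(abs(prof$ed - brute$ed)), 1e-12)
  expect_equal(prof$p_ref, 0.9)
  # positions where every substitution destroys the only match: ed = 0.8
  expect_true(any(abs(prof$ed - 0.8) < 1e-12))
  # far outside the motif: ed exactly 0
  expect_true(all(abs(prof$ed[1:900]) < 1e-12))
})

test_that("constant oracle yields an all-zero profile; bad oracles error", {
  g <- genome(c(chr1 = paste(rep("ACGT", 500), collapse = "")))
  win <- data.frame(chrom = "chr1", start = 0L, end = 2000L)
  prof <- saturated_mutagenesis(function(s) 0.42, g, win)
  expect_true(all(prof$ed == 0))
  expect_error(saturated_mutagenesis(function(s) 1.5, g, win), "range")
  expect_error(saturated_mutagenesis(function(s) NaN, g, win), "range")
})

test_that("N reference positions are masked with zero ED", {
  s <- paste(rep("ACGT", 500), collapse = "")
  substr(s, 100, 103) <- "NNNN"
  g <- genome(c(chr1 = s))
  prof <- saturated_mutagenesis(function(x) 0.5, g,
                                data.frame(chrom = "chr1", start = 0L,
                                           end = 2000L))
  expect_true(all(prof$mask[100:103]))
  expect_true(all(prof$ed[100:103] == 0))
})

test_that("fast incremental path equals the generic oracle path exactly", {
  pl <- demo_pipeline()
  win <- pl$enh[pl$enh$chrom == "chr4", ][1, c("chrom", "start", "end")]
  prof_fast <- saturated_mutagenesis(pl$oracle, pl$reg$genome, win)
  # strip the class so the generic 3L-calls path is used
  plain <- function(s) pl$oracle(s)
  prof_slow <- saturated_mutagenesis(plain, pl$reg$genome, win)
  expect_lt(max(abs(prof_fast$ed - prof_slow$ed)), 1e-12)
  expect_equal(prof_fast$p_ref, prof_slow$p_ref, tolerance = 1e-12)
})

test_that("call_ed_regions: run definition, minimum length and symmetry", {
  ed <- rep(0, 2000)
  ed[3:5] <- 2
  # explicit tau via a profile whose SD gives tau < 2 but > noise
  prof <- fake_profile(ed)
  r <- call_ed_regions(prof)
  expect_equal(nrow(r), 1L)
  expect_equal(r$kind, "EDR")
  expect_equal(r$start, 2L)   # 0-based
  expect_equal(r$end, 5L)
  expect_equal(r$length, 3L)
  # run of length 2 -> nothing
  ed2 <- rep(0, 2000); ed2[10:11] <- 3
  expect_equal(nrow(call_ed_regions(fake_profile(ed2))), 0L)
  # negation swaps kinds exactly
  edr <- rep(0, 200)
  edr[10:14] <- 2; edr[50:53] <- -3; edr[90:95] <- 1.5
  a <- call_ed_regions(fake_profile(edr))
  b <- call_ed_regions(fake_profile(-edr))
  expect_gt(nrow(a), 1)
  expect_equal(nrow(a), nrow(b))
  expect_equal(a$start, b$start)
  expect_equal(a$mean_ed, -b$mean_ed)
  expect_equal(ifelse(a$kind == "EDR", "ESR", "EDR"), b$kind)
  # zero-variance profile -> empty
  expect_equal(nrow(call_ed_regions(fake_profile(rep(0, 100)))), 0L)
})

test_that("region invariants hold on random profiles (property test)", {
  set.seed(14)
  for (rep in 1:15) {
    ed <- rnorm(500) * sample(c(0.1, 1), 500, TRUE, prob = c(0.8, 0.2))
    r <- call_ed_regions(fake_profile(ed))
    if (!nrow(r)) next
    expect_true(all(r$length >= 3))
    expect_true(all(r$end - r$start == r$length))
    expect_true(all((r$kind == "EDR") == (r$mean_ed > 0)))
    # disjoint within profile
    if (nrow(r) > 1) {
      o <- order(r$start)
      expect_true(all(r$start[o][-1] >= r$end[o][-nrow(r)]))
    }
  }
})

test_that("gap merging fuses internal sub-threshold gaps only when asked", {
  ed <- rep(0, 2000)
  ed[11:14] <- 2; ed[16:19] <- 2  # gap of 1 at position 15
  r0 <- call_ed_regions(fake_profile(ed), gap = 0L)
  expect_equal(nrow(r0), 2L)
  r1 <- call_ed_regions(fake_profile(ed), gap = 1L)
  expect_equal(nrow(r1), 1L)
  expect_equal(r1$length, 9L)
})

test_that("rank_regions_by_mean_ed bins, breaks ties and takes percentiles", {
  reg <- data.frame(chrom = "chr1", start = seq(0, 90, 10),
                    end = seq(5, 95, 10),
                    kind = "EDR", mean_ed = c(5:1, 5:1) / 10,
                    peak_ed = 1, length = 5L)
  b <- rank_regions_by_mean_ed(reg, n_bins = 5)
  expect_equal(as.vector(table(b$bin)), rep(2L, 5))
  # ties broken by genomic coordinate: of the two mean_ed = 0.5 rows the
  # earlier one ranks lower
  t5 <- b[b$mean_ed == 0.5, ]
  expect_equal(t5$bin[order(t5$start)], sort(t5$bin))
  p <- rank_regions_by_mean_ed(reg, mode = "percentile", top_pct = 20)
  expect_equal(sum(p$top), 2L)
  expect_error(rank_regions_by_mean_ed(reg[1:3, ], n_bins = 5), "fewer")
})

test_that("ED-annotation correlation returns +-1 on constructed cases and
           favours information content on the trained model", {
  pl <- demo_pipeline()
  mot <- pl$reg$truth$motifs
  # constructed: annotation == |ed| -> rho 1; reversed -> rho -1
  prof <- pl$profs[[1]]
  iv <- prof$interval
  m1 <- data.frame(chrom = iv$chrom, start = iv$start + 500L,
                   end = iv$start + 512L)
  v <- abs(prof$ed[501:512])
  if (sd(v) > 0) {
    r1 <- correlate_ed_with_annotation(pl$profs[1], m1, list(v))
    expect_equal(r1$rho, 1)
    r2 <- correlate_ed_with_annotation(pl$profs[1], m1, list(-v))
    expect_equal(r2$rho, -1)
  }
  # trained model: IC annotation beats a random annotation
  ann_ic <- motif_ic_annotation(mot, pl$reg$config$motif_library)
  rho_ic <- correlate_ed_with_annotation(pl$profs, mot, ann_ic)$rho
  set.seed(17)
  ann_rand <- lapply(ann_ic, sample)
  rho_rand <- correlate_ed_with_annotation(pl$profs, mot, ann_rand)$rho
  expect_gt(median(rho_ic, na.rm = TRUE), median(rho_rand, na.rm = TRUE))
})

test_that("ED profiles serialize to bedGraph + JSON sidecar", {
  pl <- demo_pipeline()
  pre <- tempfile("edprof")
  write_ed_profile(pl$profs[[1]], pre)
  bg <- read.table(paste0(pre, ".bedGraph"), sep = "\t")
  expect_equal(nrow(bg), 2000L)
  expect_equal(bg$V4, pl$profs[[1]]$ed, tolerance = 1e-9)
  side <- jsonlite::read_json(paste0(pre, ".json"), simplifyVector = TRUE)
  expect_equal(side$p_ref, pl$profs[[1]]$p_ref, tolerance = 1e-12)
})
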