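# Shared fixtures. The full synthetic-benchmark pipeline (the spec'd
# desk-scale world: 4 x 500 kb, 200 enhancers, 5 PWMs, 60 signals, seed 1)
# takes a few minutes to train, so it is built lazily once per test run and
# reused by the module and acceptance tests.

.fixture_cache <- new.env(parent = emptyenv())

demo_pipeline <- function() {
  if (!is.null(.fixture_cache$pipeline)) return(.fixture_cache$pipeline)
  reg <- generate_regulome(regulome_config(seed = 1L))
  snps <- generate_snps_and_credible_sets(reg)
  ds <- make_phase1_dataset(reg$genome, reg$tracks, stride = 500L,
                            holdout_chroms = "chr4")
  h1 <- train_phase1(ds, seed = 1L)
  enh <- call_enhancers(reg$tracks$H3K27ac, reg$tracks$accessibility,
                        reg$genome)
  h2 <- train_phase2(h1, enh, reg$genome, seed = 1L)
  oracle <- two_phase_oracle(h1, h2)
  profs <- mutagenesis_profiles(oracle, reg$genome, enh)
  regions <- call_ed_regions_all(profs)
  tab <- score_snp_catalog(h1, h2, reg$genome, snps$snps)
  .fixture_cache$pipeline <- list(reg = reg, snps = snps, ds = ds, h1 = h1,
                                  h2 = h2, enh = enh, oracle = oracle,
                                  profs = profs, regions = regions,
                                  tab = tab)
  .fixture_cache$pipeline
}

# small world for cheap structural tests (no model training)
tiny_world <- function() {
  if (!is.null(.fixture_cache$tiny)) return(.fixture_cache$tiny)
  cfg <- regulome_config(n_chromosomes = 2L, chromosome_length = 80000L,
                         n_enhancers = 12L, n_signals = 6L,
                         snps_per_signal = c(2L, 4L), seed = 42L)
  reg <- generate_regulome(cfg)
  snps <- generate_snps_and_credible_sets(reg)
  .fixture_cache$tiny <- list(reg = reg, snps = snps)
  .fixture_cache$tiny
}

# fast phase-1 training setup for determinism/serialization tests
tiny_phase1 <- function(seed = 1L, epochs = 3L) {
  tw <- tiny_world()
  ds <- make_phase1_dataset(tw$reg$genome, tw$reg$tracks,
                            holdout_chroms = "chr2")
  cfg <- phase1_config(filters = 8L, epochs = epochs, patience = epochs,
                       seed_kmers = FALSE)
  list(ds = ds, handle = train_phase1(ds, cfg, seed = seed), config = cfg)
}

# synthetic ED profile from a raw vector
fake_profile <- function(ed, chrom = "chr1", start = 0L) {
  structure(list(interval = data.frame(chrom = chrom, start = start,
                                       end = start + length(ed),
                                       stringsAsFactors = FALSE),
                 p_ref = 0.5, alt_probs = NULL, ed = as.numeric(ed),
                 mask = rep(FALSE, length(ed))),
            class = "ed_profile")
}

# analytic motif-presence oracle: P = p_hi iff the window contains `motif`
motif_presence_oracle <- function(motif = "ACGTACGT", p_hi = 0.9,
                                  p_lo = 0.1) {
  function(s) if (grepl(motif, s, fixed = TRUE)) p_hi else p_lo
}

# brute-force saturated mutagenesis with an arbitrary oracle (the
# independent enumeration the fast path is checked against)
brute_mutagenesis <- function(oracle, seq) {
  L <- nchar(seq)
  bases <- c("A", "C", "G", "T")
  p_ref <- oracle(seq)
  alt <- matrix(NA_real_, L, 3)
  for (i in seq_len(L)) {
    ref <- substr(seq, i, i)
    col <- 0L
    for (b in bases) {
      if (b == ref) next
      col <- col + 1L
      mut <- seq
      substr(mut, i, i) <- b
      alt[i, col] <- oracle(mut)
    }
  }
  list(p_ref = p_ref, alt = alt, ed = p_ref - rowMeans(alt))
}
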