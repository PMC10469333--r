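# edscan

Two-phase enhancer modelling, in silico saturated mutagenesis, and
credible-set variant prioritization — with a fully synthetic regulome so
the whole pipeline is testable end to end without external data.

## The problem

Most disease-associated variants from GWAS fall in non-coding DNA, and
statistical fine-mapping usually leaves several candidate SNPs per
signal. If a model can score how *enhancer-like* a 2 kb stretch of DNA
is, then (i) mutating every base in silico reveals the short footprints
— transcription-factor binding sites — that the enhancer depends on, and
(ii) scoring both alleles of a SNP measures its predicted regulatory
impact, which can single out the causal variant in a credible set.

edscan implements that programme for R users:

1. **Two-phase model.** Phase one: a small CNN maps a one-hot 2,000 bp
   window to per-track epigenomic peak probabilities (DHS/ATAC, histone
   marks, TF ChIP). Phase two: a dense network maps that probability
   vector to an enhancer probability, where enhancers are 2 kb windows
   centered on H3K27ac x accessibility peak intersections. Holdout
   chromosomes are excluded from all training.
2. **ED profiles.** For every base `i` of an enhancer,
   `ED(i) = P_ref − mean(P_alt over the 3 substitutions)`; positive ED =
   damaging. Maximal runs of ≥ 3 positions beyond ±1 SD are called EDRs
   (damaging) and ESRs (strengthening) — proxies for TF binding sites. A
   second classifier predicts TFBS overlap from the ED shape alone, with
   a sequence-only baseline for comparison.
3. **IEP scores.** Per SNP, `iep = max(P_ref, P_alt) · |P_alt − P_ref|`
   over the SNP-centered window. Per credible set, the ratio of the two
   largest IEP scores (`ratio_1:2 > 24` by default) flags signals where a
   single candidate causal SNP stands out; the threshold can be
   re-calibrated against higher-powered reference truth with a
   hypergeometric test.
4. **Synthetic regulome.** A generator plants PWM motif instances inside
   enhancers on an i.i.d. genome, emits peak tracks (including
   single-mark decoys with their own sequence drivers), SNP catalogs and
   credible sets with known causal variants — the ground truth every
   claim is tested against.

There is no deep-learning runtime dependency: the CNN core (conv → ReLU →
max-pool → dense, AdamW, dropout, early stopping, motif-seeded filters)
is implemented in Rcpp/Armadillo and is bit-deterministic per seed.

## Worked example

```r
library(edscan)

reg  <- generate_regulome(regulome_config(seed = 1))
snps <- generate_snps_and_credible_sets(reg)
ds   <- make_phase1_dataset(reg$genome, reg$tracks, stride = 500,
                            holdout_chroms = "chr4")
h1   <- train_phase1(ds, seed = 1)
enh  <- call_enhancers(reg$tracks$H3K27ac, reg$tracks$accessibility,
                       reg$genome)
h2   <- train_phase2(h1, enh, reg$genome, seed = 1)

p <- predict_epigenome(h1, ds$test$x)
mean(sapply(1:nrow(p), function(f) auroc(p[f, ], ds$test$y[f, ])))
#> [1] 0.9334
auroc(predict_phase2(h2, h2$test$x), h2$test$labels)
#> [1] 0.9734

profs   <- mutagenesis_profiles(two_phase_oracle(h1, h2), reg$genome, enh)
regions <- call_ed_regions_all(profs)
rec <- label_regions(reg$truth$motifs[, c("chrom","start","end")], regions)
mean(rec$label)        # planted motif instances recovered by EDRs/ESRs
#> [1] 0.765

tab <- score_snp_catalog(h1, h2, reg$genome, snps$snps)
pri <- prioritize(snps$credible_sets, tab, ratio_threshold = 24)
res <- merge(pri$results, snps$causal, by = "signal_id")
mm  <- res[res$n_snps > 1 & res$in_motif, ]
mean(mm$top_snp == mm$snp_id)   # top-IEP SNP == planted causal SNP
#> [1] 0.836
```

Phase-1 holdout auROC 0.93 averaged over 7 tracks, phase-2 enhancer
auROC 0.97 on the held-out chromosome, 76% of planted binding sites
recovered as ED footprints, and the top-IEP SNP is the planted causal
variant in 84% of multi-SNP credible sets whose causal SNP disrupts a
motif (values printed by the code above at seed 1).

## Command line

An `edscan` executable (installed under `exec/`) wraps the pipeline:

```sh
edscan simulate       --out-dir demo --seed 1
edscan train-phase1   --genome demo/genome.fa \
                      --tracks demo/H3K27ac.bed,demo/accessibility.bed \
                      --holdout-chroms chr4 --out-dir demo/models
edscan train-phase2   --genome demo/genome.fa --model-dir demo/models \
                      --h3k27ac demo/H3K27ac.bed \
                      --accessibility demo/accessibility.bed
edscan mutagenesis    --genome demo/genome.fa --model-dir demo/models \
                      --enhancers demo/true_enhancers.bed \
                      --out-prefix demo/mut/prof
edscan score-snps     --genome demo/genome.fa --model-dir demo/models \
                      --snps demo/snps.tsv --out demo/scores.tsv
edscan prioritize     --scores demo/scores.tsv \
                      --credible-sets demo/credible_sets.tsv \
                      --ratio-threshold 24 --out-dir demo/pri
```

Subcommands accept `--config FILE` (JSON; explicit flags override) and
exit 0/1/2 for success/runtime error/usage error.

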