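Package: edscan
Title: Two-Phase Enhancer Modelling, In Silico Saturated Mutagenesis and
    Credible-Set SNP Prioritization
Version: 0.1.0
Authors@R:
    person("edscan", "developers", email = "edscan@example.org", role = c("aut", "cre"))
Description: Predicts enhancers from DNA sequence with a two-phase
    convolutional model (sequence to epigenomic feature probabilities,
    then feature probabilities to enhancer probability), probes enhancer
    architecture by in silico saturated mutagenesis to produce per-base
    enhancer-damage (ED) profiles, calls enhancer damaging/strengthening
    regions (EDRs/ESRs), predicts transcription-factor binding sites from
    ED profiles, scores SNPs for allelic enhancer perturbation (IEP), and
    refines fine-mapping credible sets with the IEP ratio of the top two
    SNPs. Ships a fully synthetic regulome generator (genome, peak tracks,
    planted motifs, SNPs and credible sets) so the entire pipeline is
    testable end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Rcpp,
    jsonlite,
    data.table,
    Biostrings,
    IRanges,
    S4Vectors
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
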