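#' Built-in synthetic PWM library
#'
#' A fixed library of informative motifs (widths 11-15) mimicking typical
#' TF PWMs: about 60% of columns are strongly constrained (consensus
#' probability 0.88-0.99) and the rest weakly constrained (0.65-0.88),
#' giving total information contents of roughly 12-20 bits so that planted
#' instances are recognizable against background yet show position-wise
#' variability. The library is a package constant: it is generated from a
#' hard-coded internal seed and does not depend on the caller's RNG.
#'
#' @param n Number of motifs (<= 8).
#' @return List of `pwm` objects named `PWM1`, `PWM2`, ...
#' @export
default_pwm_library <- function(n = 5) {
  stopifnot(n >= 1, n <= 8)
  with_seed(772001L, {
    lapply(seq_len(n), function(i) {
      w <- sample(11:15, 1)
      cons <- sample(1:4, w, replace = TRUE)
      m <- matrix(0, w, 4)
      for (j in seq_len(w)) {
        pc <- if (stats::runif(1) < 0.6) stats::runif(1, 0.88, 0.99)
              else stats::runif(1, 0.65, 0.88)
        rest <- stats::runif(3)
        rest <- rest / sum(rest) * (1 - pc)
        m[j, cons[j]] <- pc
        m[j, -cons[j]] <- rest
      }
      pwm(paste0("PWM", i), m)
    })
  })
}

#' Configuration for the synthetic regulome
#'
#' Defaults are the desk-scale stated world used throughout the test suite:
#' 4 chromosomes of 500 kb, GC 0.41, 200 enhancers carrying 3-6 planted
#' motif instances each from a 5-PWM library, 5 TF tracks, 60 credible-set
#' signals of 2-8 SNPs with 90% of causal SNPs placed at high-information
#' motif positions.
#'
#' @param n_chromosomes,chromosome_length Genome shape.
#' @param gc_content Background GC fraction.
#' @param motif_library List of `pwm` objects.
#' @param n_enhancers Number of planted enhancers.
#' @param motifs_per_enhancer Integer range `c(lo, hi)`.
#' @param n_tf_tracks Number of TF peak tracks (<= length of library).
#' @param n_signals Number of credible sets.
#' @param snps_per_signal Integer range `c(lo, hi)`.
#' @param causal_in_motif_fraction Probability a signal's causal SNP is
#'   placed at a high-information position of a planted motif.
#' @param decoy_pwms Two `pwm` objects driving the single-mark decoy peaks
#'   (first: H3K27ac-only, second: accessibility-only). Every peak track
#'   has a sequence determinant — as in real chromatin — so single marks
#'   are predictable from sequence while only mark co-occurrence defines
#'   an enhancer.
#' @param seed RNG seed.
#' @return list of class `regulome_config`.
#' @export
regulome_config <- function(n_chromosomes = 4L,
                            chromosome_length = 500000L,
                            gc_content = 0.41,
                            motif_library = default_pwm_library(5),
                            n_enhancers = 200L,
                            motifs_per_enhancer = c(3L, 6L),
                            n_tf_tracks = 5L,
                            n_signals = 60L,
                            snps_per_signal = c(2L, 8L),
                            causal_in_motif_fraction = 0.9,
                            decoy_pwms = default_pwm_library(7)[6:7],
                            seed = 1L) {
  stopifnot(n_chromosomes >= 1, chromosome_length >= 20000,
            gc_content > 0, gc_content < 1,
            n_enhancers >= 1, n_signals >= 1,
            length(motifs_per_enhancer) == 2,
            motifs_per_enhancer[1] >= 1,
            diff(motifs_per_enhancer) >= 0,
            length(snps_per_signal) == 2, snps_per_signal[1] >= 1,
            n_tf_tracks <= length(motif_library),
            causal_in_motif_fraction >= 0, causal_in_motif_fraction <= 1,
            n_signals <= n_enhancers)
  structure(as.list(environment()), class = "regulome_config")
}

# sample one motif instance string from a PWM, per-column
.sample_motif_instance <- function(p) {
  bases <- c("A", "C", "G", "T")
  paste(vapply(seq_len(nrow(p$matrix)), function(j)
    sample(bases, 1, prob = p$matrix[j, ]), character(1)), collapse = "")
}

#' Generate a synthetic regulome
#'
#' Builds an i.i.d. background genome at the configured GC content, places
#' non-overlapping enhancers, plants per-column-sampled motif instances
#' inside each enhancer, and emits peak tracks: "H3K27ac" and
#' "accessibility" peaks that jointly (and only jointly) mark enhancers,
#' single-type decoy peaks, and one TF track per motif covering its planted
#' instances with ChIP-scale (~500 bp) peaks.
#'
#' @param config A [regulome_config()].
#' @return list of class `regulome` with elements `genome`, `truth`
#'   (enhancers, motifs, causal placeholders), `tracks` (named list of
#'   interval data.frames) and `config`.
#' @export
generate_regulome <- function(config) {
  stopifnot(inherits(config, "regulome_config"))
  with_seed(config$seed, .generate_regulome_impl(config))
}

.generate_regulome_impl <- function(cfg) {
  bases <- c("A", "C", "G", "T")
  pb <- c((1 - cfg$gc_content) / 2, cfg$gc_content / 2,
          cfg$gc_content / 2, (1 - cfg$gc_content) / 2)
  chroms <- paste0("chr", seq_len(cfg$n_chromosomes))
  seqs <- stats::setNames(vapply(chroms, function(ch)
    paste(sample(bases, cfg$chromosome_length, replace = TRUE, prob = pb),
          collapse = ""), character(1)), chroms)

  # enhancer anchor positions: even split across chromosomes, spacing so
  # that 2 kb windows plus peaks never collide; >= 3 kb margin from ends
  per_chrom <- table(factor(sample(chroms, cfg$n_enhancers, replace = TRUE),
                            levels = chroms))
  min_space <- 5000L
  margin <- 3000L
  anchors <- NULL
  for (ch in chroms) {
    k <- per_chrom[[ch]]
    if (k == 0) next
    placed <- integer(0)
    tries <- 0L
    lo <- margin; hi <- cfg$chromosome_length - margin
    while (length(placed) < k) {
      tries <- tries + 1L
      if (tries > 200L * k)
        stop("enhancer placement failed; lower enhancer density")
      cand <- sample(lo:hi, 1)
      if (!length(placed) || min(abs(placed - cand)) >= min_space)
        placed <- c(placed, cand)
    }
    anchors <- rbind(anchors, data.frame(chrom = ch, anchor = sort(placed)))
  }

  # peak pairs around each anchor; enhancer window = 2 kb centered on the
  # midpoint of the H3K27ac/accessibility intersection
  n <- nrow(anchors)
  h3_lo <- anchors$anchor - round(stats::runif(n, 500, 900))
  h3_hi <- anchors$anchor + round(stats::runif(n, 500, 900))
  ac_lo <- anchors$anchor - round(stats::runif(n, 400, 800))
  ac_hi <- anchors$anchor + round(stats::runif(n, 400, 800))
  int_lo <- pmax(h3_lo, ac_lo)
  int_hi <- pmin(h3_hi, ac_hi)
  center <- (int_lo + int_hi) %/% 2L
  enhancers <- data.frame(chrom = anchors$chrom,
                          start = center - 1000L, end = center + 1000L,
                          center = center,
                          enhancer_id = paste0("enh", seq_len(n)),
                          stringsAsFactors = FALSE)
  h3 <- data.frame(chrom = anchors$chrom, start = h3_lo, end = h3_hi,
                   stringsAsFactors = FALSE)
  ac <- data.frame(chrom = anchors$chrom, start = ac_lo, end = ac_hi,
                   stringsAsFactors = FALSE)

  # decoy peaks of each single type, mutually disjoint and clear of
  # enhancers, so co-occurrence alone defines an enhancer
  # decoy count scales with enhancer count but is capped by genome size so
  # placement cannot exhaust small test genomes (default world: 100/type)
  n_decoy <- min(max(50L, cfg$n_enhancers %/% 2L),
                 (cfg$n_chromosomes * cfg$chromosome_length) %/% 12000L)
  n_decoy <- max(n_decoy, 4L)
  # forbid decoys near enhancers with a margin covering real peak tails, so
  # a decoy of one type can never intersect a real peak of the other type
  occupied <- data.frame(chrom = enhancers$chrom,
                         start = enhancers$start - 500L,
                         end = enhancers$end + 500L)
  place_decoys <- function(m) {
    out <- NULL
    tries <- 0L
    while (is.null(out) || nrow(out) < m) {
      tries <- tries + 1L
      if (tries > 200L * m) stop("decoy placement failed")
      ch <- sample(chroms, 1)
      width <- round(stats::runif(1, 800, 1600))
      s <- sample(seq(margin, cfg$chromosome_length - margin - width), 1)
      cand <- data.frame(chrom = ch, start = s, end = s + width,
                         stringsAsFactors = FALSE)
      clash <- nrow(.intersect_intervals(
        rbind(occupied, if (!is.null(out)) out), cand)) > 0
      if (!clash) out <- rbind(out, cand)
    }
    out
  }
  dec_h3 <- place_decoys(n_decoy)
  occupied <- rbind(occupied, dec_h3)
  dec_ac <- place_decoys(n_decoy)
  occupied <- rbind(occupied, dec_ac)

  # decoy peaks carry instances of their own driver PWM so each single
  # mark is sequence-predictable (real peaks are never sequence-random)
  decoy_motifs <- NULL
  plant_decoy_motifs <- function(peaks, p) {
    w <- nrow(p$matrix)
    out <- NULL
    for (i in seq_len(nrow(peaks))) {
      k <- sample(2:4, 1)
      lo <- peaks$start[i] + 10L
      hi <- peaks$end[i] - 10L - w
      pos <- integer(0)
      tries <- 0L
      while (length(pos) < k && tries < 100L) {
        tries <- tries + 1L
        s <- sample(lo:hi, 1)
        if (!length(pos) || min(abs(pos - s)) >= w) pos <- c(pos, s)
      }
      out <- rbind(out, data.frame(chrom = peaks$chrom[i], start = pos,
                                   end = pos + w, pwm = p$id,
                                   strand = sample(c("+", "-"),
                                                   length(pos), TRUE),
                                   stringsAsFactors = FALSE))
    }
    out
  }
  decoy_motifs <- rbind(plant_decoy_motifs(dec_h3, cfg$decoy_pwms[[1]]),
                        plant_decoy_motifs(dec_ac, cfg$decoy_pwms[[2]]))
  decoy_lib <- stats::setNames(cfg$decoy_pwms,
                               vapply(cfg$decoy_pwms, `[[`, "", "id"))
  for (i in seq_len(nrow(decoy_motifs))) {
    inst <- .sample_motif_instance(decoy_lib[[decoy_motifs$pwm[i]]])
    if (decoy_motifs$strand[i] == "-") inst <- reverse_complement(inst)
    ch <- decoy_motifs$chrom[i]
    substr(seqs[[ch]], decoy_motifs$start[i] + 1L, decoy_motifs$end[i]) <-
      inst
  }

  # plant motifs inside enhancer windows (within +/- 700 of center)
  n_m <- sample(cfg$motifs_per_enhancer[1]:cfg$motifs_per_enhancer[2],
                n, replace = TRUE)
  motifs <- vector("list", n)
  lib <- cfg$motif_library
  for (i in seq_len(n)) {
    got <- NULL
    tries <- 0L
    while (is.null(got) || nrow(got) < n_m[i]) {
      tries <- tries + 1L
      if (tries > 500L) stop("motif placement failed")
      k <- sample(length(lib), 1)
      w <- nrow(lib[[k]]$matrix)
      s <- enhancers$center[i] + sample(seq(-700L, 700L - w), 1)
      if (!is.null(got) && any(s < got$end & s + w > got$start)) next
      strand <- sample(c("+", "-"), 1)
      got <- rbind(got, data.frame(chrom = enhancers$chrom[i], start = s,
                                   end = s + w, pwm = lib[[k]]$id,
                                   strand = strand,
                                   enhancer_id = enhancers$enhancer_id[i],
                                   stringsAsFactors = FALSE))
    }
    motifs[[i]] <- got
  }
  motifs <- do.call(rbind, motifs)
  motifs <- motifs[order(motifs$chrom, motifs$start), , drop = FALSE]
  rownames(motifs) <- NULL
  motifs$motif_id <- paste0("mot", seq_len(nrow(motifs)))

  # write instances into the genome
  lib_by_id <- stats::setNames(lib, vapply(lib, `[[`, "", "id"))
  for (i in seq_len(nrow(motifs))) {
    inst <- .sample_motif_instance(lib_by_id[[motifs$pwm[i]]])
    if (motifs$strand[i] == "-") inst <- reverse_complement(inst)
    ch <- motifs$chrom[i]
    substr(seqs[[ch]], motifs$start[i] + 1L, motifs$end[i]) <- inst
  }

  # TF tracks: ~500 bp ChIP-style peaks centered on instances of each PWM
  tf_tracks <- list()
  for (k in seq_len(cfg$n_tf_tracks)) {
    id <- lib[[k]]$id
    mk <- motifs[motifs$pwm == id, , drop = FALSE]
    if (nrow(mk)) {
      mid <- (mk$start + mk$end) %/% 2L
      half <- round(stats::runif(nrow(mk), 200, 300))
      tr <- data.frame(chrom = mk$chrom, start = pmax(0L, mid - half),
                       end = pmin(cfg$chromosome_length, mid + half),
                       stringsAsFactors = FALSE)
      tr <- .reduce_intervals(tr)
    } else {
      tr <- data.frame(chrom = character(), start = integer(),
                       end = integer())
    }
    tf_tracks[[paste0("TF_", id)]] <- tr
  }

  tracks <- c(list(
    H3K27ac = .reduce_intervals(rbind(h3, dec_h3)),
    accessibility = .reduce_intervals(rbind(ac, dec_ac))
  ), tf_tracks)

  g <- genome(seqs)
  truth <- list(enhancers = enhancers, motifs = motifs,
                decoys = list(H3K27ac = dec_h3, accessibility = dec_ac),
                decoy_motifs = decoy_motifs)
  structure(list(genome = g, truth = truth, tracks = tracks,
                 config = cfg), class = "regulome")
}

#' Generate SNPs and credible sets on a synthetic regulome
#'
#' Each signal is anchored to a distinct enhancer and receives one causal
#' SNP: with probability `causal_in_motif_fraction` it sits at the
#' highest-information column of a planted motif and flips the reference
#' base to the most disfavoured base at that column; otherwise it is a
#' random non-motif position near the enhancer. LD-companion SNPs are
#' positional neighbours within +/- 50 kb placed outside motif instances.
#' PPAs are Dirichlet-distributed, scaled to sum in (0.95, 1], and assigned
#' so the causal SNP is not systematically the PPA maximum.
#'
#' @param regulome A `regulome` from [generate_regulome()].
#' @return list `snps` (SNP data.frame), `credible_sets` (long data.frame:
#'   `signal_id`, `trait`, `snp_id`, `chrom`, `pos`, `ref`, `alt`, `ppa`),
#'   `causal` (data.frame `signal_id`, `snp_id`, `in_motif`).
#' @export
generate_snps_and_credible_sets <- function(regulome) {
  stopifnot(inherits(regulome, "regulome"))
  with_seed(regulome$config$seed + 1000L, .generate_snps_impl(regulome))
}

.generate_snps_impl <- function(reg) {
  cfg <- reg$config
  g <- reg$genome
  bases <- c("A", "C", "G", "T")
  lens <- seq_lengths(g)
  motifs <- reg$truth$motifs
  enh <- reg$truth$enhancers
  lib <- stats::setNames(cfg$motif_library,
                         vapply(cfg$motif_library, `[[`, "", "id"))
  traits <- c("T2D", "glucose", "fasting_glucose", "HbA1c")

  signal_enh <- sample(nrow(enh), cfg$n_signals)
  rows <- list()
  causal <- list()
  snp_n <- 0L
  taken <- new.env()  # chrom:pos -> TRUE, avoid duplicate positions
  new_pos_ok <- function(ch, pos1) {
    key <- paste0(ch, ":", pos1)
    if (!is.null(taken[[key]])) return(FALSE)
    assign(key, TRUE, envir = taken)
    TRUE
  }
  for (s in seq_len(cfg$n_signals)) {
    e <- enh[signal_enh[s], ]
    ch <- e$chrom
    in_motif <- stats::runif(1) < cfg$causal_in_motif_fraction
    emot <- motifs[motifs$enhancer_id == e$enhancer_id, , drop = FALSE]
    if (in_motif && nrow(emot)) {
      m <- emot[sample(nrow(emot), 1), ]
      p <- lib[[m$pwm]]
      ic <- information_content(p)
      j <- which.max(ic)  # motif column (1-based, + strand orientation)
      pos0 <- if (m$strand == "+") m$start + (j - 1L)
              else m$end - j       # reverse strand: column j counts from end
      pos1 <- pos0 + 1L
      ref <- get_base(g, ch, pos1)
      # most disfavoured base at that column in genomic orientation
      col <- p$matrix[j, ]
      if (m$strand == "-") col <- rev(col)  # A<->T, C<->G complement flip
      ord <- bases[order(col)]
      alt <- setdiff(ord, ref)[1]
    } else {
      in_motif <- FALSE
      repeat {
        pos1 <- e$center + sample(-900:900, 1) + 1L
        pos0 <- pos1 - 1L
        if (!.point_in_intervals(ch, pos0, motifs)) break
      }
      ref <- get_base(g, ch, pos1)
      alt <- sample(setdiff(bases, ref), 1)
    }
    if (!new_pos_ok(ch, pos1)) next  # extremely rare; drop signal silently
    snp_n <- snp_n + 1L
    causal_id <- sprintf("rs%06d", snp_n)
    sig_rows <- data.frame(id = causal_id, chrom = ch, pos = pos1,
                           ref = ref, alt = alt, stringsAsFactors = FALSE)
    k <- sample(cfg$snps_per_signal[1]:cfg$snps_per_signal[2], 1)
    tries <- 0L
    while (nrow(sig_rows) < k) {
      tries <- tries + 1L
      if (tries > 2000L) break
      off <- sample(c(-50000:-200, 200:50000), 1)
      pos1c <- e$center + off + 1L
      if (pos1c < 1001L || pos1c > lens[[ch]] - 1000L) next
      if (.point_in_intervals(ch, pos1c - 1L, motifs)) next
      if (!new_pos_ok(ch, pos1c)) next
      snp_n <- snp_n + 1L
      refc <- get_base(g, ch, pos1c)
      sig_rows <- rbind(sig_rows, data.frame(
        id = sprintf("rs%06d", snp_n), chrom = ch, pos = pos1c, ref = refc,
        alt = sample(setdiff(bases, refc), 1), stringsAsFactors = FALSE))
    }
    ppa <- stats::rgamma(nrow(sig_rows), 1)
    ppa <- ppa / sum(ppa) * stats::runif(1, 0.955, 0.999)
    sig_id <- sprintf("signal%03d", s)
    rows[[s]] <- data.frame(signal_id = sig_id,
                            trait = sample(traits, 1),
                            snp_id = sig_rows$id, chrom = sig_rows$chrom,
                            pos = sig_rows$pos, ref = sig_rows$ref,
                            alt = sig_rows$alt,
                            ppa = sample(ppa),  # decouple PPA from causality
                            stringsAsFactors = FALSE)
    causal[[s]] <- data.frame(signal_id = sig_id, snp_id = causal_id,
                              in_motif = in_motif, stringsAsFactors = FALSE)
  }
  cs <- do.call(rbind, rows)
  snps <- unique(cs[, c("snp_id", "chrom", "pos", "ref", "alt")])
  names(snps)[1] <- "id"
  rownames(snps) <- NULL
  list(snps = snps, credible_sets = cs, causal = do.call(rbind, causal))
}

#' Write a regulome and its SNPs/credible sets to files
#'
#' Emits FASTA, one BED per track, a ground-truth motif/enhancer BED pair,
#' a SNP table, a credible-set TSV and a ground-truth JSON.
#'
#' @param regulome A `regulome`.
#' @param dir Output directory (created if needed).
#' @param snps Optional result of [generate_snps_and_credible_sets()].
#' @return Invisibly, the named vector of written paths.
#' @export
write_regulome_files <- function(regulome, dir, snps = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(genome = file.path(dir, "genome.fa"))
  write_fasta(regulome$genome, paths[["genome"]])
  for (tn in names(regulome$tracks)) {
    p <- file.path(dir, paste0(tn, ".bed"))
    write_bed(regulome$tracks[[tn]], p)
    paths[[paste0("track_", tn)]] <- p
  }
  paths[["enhancers"]] <- file.path(dir, "true_enhancers.bed")
  write_bed(regulome$truth$enhancers[, c("chrom", "start", "end",
                                         "enhancer_id")],
            paths[["enhancers"]])
  paths[["motifs"]] <- file.path(dir, "true_motifs.bed")
  m <- regulome$truth$motifs
  write_bed(data.frame(chrom = m$chrom, start = m$start, end = m$end,
                       name = m$pwm, score = 0, strand = m$strand),
            paths[["motifs"]])
  paths[["truth_json"]] <- file.path(dir, "ground_truth.json")
  jsonlite::write_json(list(enhancers = regulome$truth$enhancers,
                            motifs = regulome$truth$motifs),
                       paths[["truth_json"]], digits = NA)
  if (!is.null(snps)) {
    paths[["snps"]] <- file.path(dir, "snps.tsv")
    write_snp_table(snps$snps, paths[["snps"]])
    paths[["credible_sets"]] <- file.path(dir, "credible_sets.tsv")
    data.table::fwrite(snps$credible_sets, paths[["credible_sets"]],
                       sep = "\t", quote = FALSE)
    paths[["causal"]] <- file.path(dir, "causal_truth.tsv")
    data.table::fwrite(snps$causal, paths[["causal"]], sep = "\t",
                       quote = FALSE)
  }
  invisible(paths)
}
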