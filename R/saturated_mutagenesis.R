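#' In silico saturated mutagenesis of one enhancer window
#'
#' Every position of the window is substituted with each of the three
#' non-reference bases and re-scored with the enhancer-probability oracle;
#' the ED score at position i is
#' `P_ref - mean(P_alt over the three substitutions)`, so positive ED means
#' mutating the base tends to destroy the enhancer (the base is
#' "damaging-sensitive"). Positions whose reference base is N get ED 0 and
#' a mask flag. When the oracle is a [two_phase_oracle()], an exact
#' incremental path recomputes only the convolution columns a single-base
#' edit can touch; otherwise the oracle is called once per substitution
#' (3L calls plus the reference call).
#'
#' @param oracle Function mapping a window sequence to a probability in
#'   \[0, 1\], or a [two_phase_oracle()].
#' @param genome A `genome`.
#' @param enhancer_window One-row data.frame with `chrom`, `start`, `end`
#'   (0-based half-open; the oracle's window length).
#' @return Object of class `ed_profile`: `interval`, `p_ref`, `alt_probs`
#'   (L x 3; non-reference bases in A<C<G<T order), `ed` (length L),
#'   `mask` (logical; TRUE where reference is N).
#' @export
saturated_mutagenesis <- function(oracle, genome, enhancer_window) {
  ch <- enhancer_window$chrom[1]
  s <- enhancer_window$start[1]
  e <- enhancer_window$end[1]
  seq <- substr(genome$seqs[[ch]], s + 1L, e)
  L <- nchar(seq)
  bases <- c("A", "C", "G", "T")
  refc <- strsplit(seq, "", fixed = TRUE)[[1]]
  refidx <- match(refc, bases)  # NA for N
  if (inherits(oracle, "two_phase_oracle")) {
    h1 <- attr(oracle, "phase1")
    h2 <- attr(oracle, "phase2")
    if (L != h1$arch$input_length)
      stop("window length must be ", h1$arch$input_length)
    x <- t(one_hot_encode(seq))  # 4 x L
    res <- mutagenesis_two_phase_cpp(x, h1$arch, h1$weights, h2$arch,
                                     h2$weights,
                                     ifelse(is.na(refidx), -1L,
                                            refidx - 1L))
    p_ref <- .apply_temperature(res$p_ref, h2$temperature)
    alt <- res$alt
    alt[] <- .apply_temperature(as.numeric(alt), h2$temperature)
  } else {
    p_ref <- oracle(seq)
    .check_prob(p_ref)
    alt <- matrix(NA_real_, L, 3)
    for (i in seq_len(L)) {
      if (is.na(refidx[i])) { alt[i, ] <- p_ref; next }
      col <- 0L
      for (b in bases) {
        if (b == refc[i]) next
        col <- col + 1L
        mut <- seq
        substr(mut, i, i) <- b
        p <- oracle(mut)
        .check_prob(p)
        alt[i, col] <- p
      }
    }
  }
  ed <- p_ref - rowMeans(alt)
  mask <- is.na(refidx)
  ed[mask] <- 0
  structure(list(interval = data.frame(chrom = ch, start = s, end = e,
                                       stringsAsFactors = FALSE),
                 p_ref = p_ref, alt_probs = alt, ed = as.numeric(ed),
                 mask = mask),
            class = "ed_profile")
}

.check_prob <- function(p) {
  if (!is.finite(p) || p < 0 || p > 1)
    stop("oracle returned a non-finite or out-of-range value: ", p)
  invisible(p)
}

#' Saturated mutagenesis over a set of enhancers
#'
#' @inheritParams saturated_mutagenesis
#' @param enhancers Interval data.frame; one profile per row.
#' @return List of `ed_profile` (named `profile1`, ...).
#' @export
mutagenesis_profiles <- function(oracle, genome, enhancers) {
  out <- lapply(seq_len(nrow(enhancers)), function(i)
    saturated_mutagenesis(oracle, genome, enhancers[i, , drop = FALSE]))
  names(out) <- paste0("profile", seq_along(out))
  out
}

#' Call enhancer damaging / strengthening regions from an ED profile
#'
#' The threshold is profile-local: `tau = tau_sd * sigma`, where `sigma`
#' is a noise-scale estimate of the profile: by default the plain SD of
#' the ED values; `scale = "trimmed"` instead uses the SD after excluding
#' the top 1% of |ED|, a noise-floor estimate useful for very sparse
#' profiles where the signal itself dominates the SD (it recovers weaker
#' sites at the cost of more spurious calls). EDRs are maximal runs of at least `min_len`
#' consecutive positions with `ed >= tau`; ESRs are runs with
#' `ed <= -tau`. No gap merging is applied unless `gap > 0` (same-kind
#' runs separated by at most `gap` sub-threshold positions are fused).
#'
#' @param profile An `ed_profile`.
#' @param tau_sd Threshold in noise-scale units (default 1).
#' @param min_len Minimum run length (default 3).
#' @param gap Gap tolerance in bp (default 0).
#' @param scale Noise-scale estimator, "sd" (default) or "trimmed".
#' @return data.frame `chrom`, `start`, `end` (genomic, half-open), `kind`
#'   ("EDR"/"ESR"), `mean_ed`, `peak_ed`, `length`.
#' @export
call_ed_regions <- function(profile, tau_sd = 1.0, min_len = 3L, gap = 0L,
                            scale = c("sd", "trimmed")) {
  stopifnot(inherits(profile, "ed_profile"))
  scale <- match.arg(scale)
  ed <- profile$ed
  sdv <- stats::sd(ed)
  empty <- data.frame(chrom = character(), start = integer(),
                      end = integer(), kind = character(),
                      mean_ed = numeric(), peak_ed = numeric(),
                      length = integer())
  if (!is.finite(sdv) || sdv == 0) return(empty)
  sigma <- if (scale == "sd") sdv else {
    s <- stats::sd(ed[abs(ed) <= stats::quantile(abs(ed), 0.99)])
    if (!is.finite(s) || s < 1e-9) 1e-9 else s
  }
  tau <- tau_sd * sigma
  runs_of <- function(flag, kind) {
    if (gap > 0L) {
      r <- rle(flag)
      fill <- !r$values & r$lengths <= gap
      # only internal gaps (not leading/trailing) are fused
      if (length(r$values) > 2)
        for (j in 2:(length(r$values) - 1))
          if (fill[j] && r$values[j - 1] && r$values[j + 1])
            r$values[j] <- TRUE
      flag <- inverse.rle(r)
    }
    r <- rle(flag)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    sel <- which(r$values & r$lengths >= min_len)
    if (!length(sel)) return(NULL)
    do.call(rbind, lapply(sel, function(j) {
      i0 <- starts[j]; i1 <- ends[j]
      seg <- ed[i0:i1]
      data.frame(chrom = profile$interval$chrom,
                 start = profile$interval$start + i0 - 1L,
                 end = profile$interval$start + i1,
                 kind = kind,
                 mean_ed = mean(seg),
                 peak_ed = seg[which.max(abs(seg))],
                 length = i1 - i0 + 1L,
                 stringsAsFactors = FALSE)
    }))
  }
  out <- rbind(runs_of(ed >= tau, "EDR"), runs_of(ed <= -tau, "ESR"))
  if (is.null(out)) return(empty)
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Call ED regions over a list of profiles
#'
#' @param profiles List of `ed_profile` (e.g. [mutagenesis_profiles()]).
#' @inheritParams call_ed_regions
#' @return Single data.frame with an extra `profile_id` column.
#' @export
call_ed_regions_all <- function(profiles, tau_sd = 1.0, min_len = 3L,
                                gap = 0L, scale = c("sd", "trimmed")) {
  scale <- match.arg(scale)
  out <- lapply(names(profiles), function(nm) {
    r <- call_ed_regions(profiles[[nm]], tau_sd, min_len, gap, scale)
    if (nrow(r)) r$profile_id <- nm
    r
  })
  out <- do.call(rbind, out[vapply(out, nrow, 1L) > 0])
  if (is.null(out))
    out <- data.frame(chrom = character(), start = integer(),
                      end = integer(), kind = character(),
                      mean_ed = numeric(), peak_ed = numeric(),
                      length = integer(), profile_id = character())
  rownames(out) <- NULL
  out
}

#' Rank ED regions by |mean ED| into bins
#'
#' Quantile mode assigns `n_bins` equal-count bins by the rank of
#' `|mean_ed|` (bin `n_bins` = strongest); ties are broken by genomic
#' coordinate (chrom, start). Percentile mode instead flags the top
#' `top_pct` percent of regions.
#'
#' @param regions data.frame from [call_ed_regions_all()].
#' @param n_bins Number of quantile bins (default 5).
#' @param mode "quantile" or "percentile".
#' @param top_pct Percent of regions flagged in percentile mode (default 2).
#' @return `regions` with an added `bin` (quantile mode) or `top`
#'   (percentile mode) column.
#' @export
rank_regions_by_mean_ed <- function(regions, n_bins = 5L,
                                    mode = c("quantile", "percentile"),
                                    top_pct = 2) {
  mode <- match.arg(mode)
  n <- nrow(regions)
  if (n < n_bins) stop("fewer regions (", n, ") than bins (", n_bins, ")")
  o <- order(abs(regions$mean_ed), regions$chrom, regions$start)
  r <- integer(n)
  r[o] <- seq_len(n)  # 1 = weakest
  if (mode == "quantile") {
    regions$bin <- as.integer(ceiling(r / n * n_bins))
  } else {
    k <- max(1L, floor(n * top_pct / 100))
    regions$top <- r > n - k
  }
  regions
}

#' Correlate |ED| with a per-base annotation over motif instances
#'
#' For each motif instance, computes the Spearman correlation between the
#' |ED| values at its positions and an aligned per-base annotation (e.g.
#' PWM information content or conservation). Instances shorter than 3 bp
#' or falling outside every profile are skipped.
#'
#' @param profiles List of `ed_profile`.
#' @param motif_instances data.frame `chrom`, `start`, `end` (plus
#'   arbitrary columns, carried through).
#' @param annotation_values List of numeric vectors, one per motif-instance
#'   row, aligned 5'->3' on the + strand of the genome.
#' @return data.frame of the instances with an added `rho` column (NA when
#'   skipped).
#' @export
correlate_ed_with_annotation <- function(profiles, motif_instances,
                                         annotation_values) {
  stopifnot(nrow(motif_instances) == length(annotation_values))
  ivs <- do.call(rbind, lapply(profiles, function(p) p$interval))
  rho <- rep(NA_real_, nrow(motif_instances))
  for (i in seq_len(nrow(motif_instances))) {
    m <- motif_instances[i, ]
    len <- m$end - m$start
    if (len < 3) next
    hit <- which(ivs$chrom == m$chrom & ivs$start <= m$start &
                 ivs$end >= m$end)
    if (!length(hit)) next
    p <- profiles[[hit[1]]]
    idx <- (m$start - p$interval$start + 1L):(m$end - p$interval$start)
    v <- abs(p$ed[idx])
    a <- annotation_values[[i]]
    if (length(a) != len || stats::sd(v) == 0 || stats::sd(a) == 0) next
    rho[i] <- stats::cor(v, a, method = "spearman")
  }
  out <- motif_instances
  out$rho <- rho
  out
}

#' Per-base information-content annotation for planted motif instances
#'
#' Builds the `annotation_values` list for
#' [correlate_ed_with_annotation()]: the PWM information-content profile of
#' each instance, reversed for minus-strand instances so it aligns with
#' genomic coordinates.
#'
#' @param motif_instances data.frame with `pwm` and `strand` columns.
#' @param pwms List of `pwm` objects.
#' @return List of numeric vectors.
#' @export
motif_ic_annotation <- function(motif_instances, pwms) {
  by_id <- stats::setNames(pwms, vapply(pwms, `[[`, "", "id"))
  lapply(seq_len(nrow(motif_instances)), function(i) {
    ic <- information_content(by_id[[motif_instances$pwm[i]]])
    if (motif_instances$strand[i] == "-") rev(ic) else ic
  })
}

#' Write an ED profile as bedGraph plus JSON sidecar
#' @param profile An `ed_profile`.
#' @param prefix Output path prefix (writes `<prefix>.bedGraph` and
#'   `<prefix>.json`).
#' @export
write_ed_profile <- function(profile, prefix) {
  bg <- data.frame(chrom = profile$interval$chrom,
                   start = profile$interval$start +
                     seq_along(profile$ed) - 1L,
                   end = profile$interval$start + seq_along(profile$ed),
                   ed = profile$ed)
  data.table::fwrite(bg, paste0(prefix, ".bedGraph"), sep = "\t",
                     col.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(interval = profile$interval,
                            p_ref = profile$p_ref,
                            mask = which(profile$mask)),
                       paste0(prefix, ".json"), digits = NA,
                       auto_unbox = TRUE)
  invisible(prefix)
}
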