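#' Construct a position weight matrix
#'
#' @param id Motif identifier.
#' @param matrix w x 4 matrix of per-position base probabilities (columns
#'   A,C,G,T; each row sums to 1 within 1e-9). Width must be >= 4.
#' @param background Background base frequencies (default uniform).
#' @return Object of class `pwm`.
#' @export
pwm <- function(id, matrix, background = rep(0.25, 4)) {
  matrix <- as.matrix(matrix)
  if (ncol(matrix) != 4L) stop("PWM must have 4 columns (A,C,G,T)")
  if (nrow(matrix) < 4L) stop("PWM width must be >= 4")
  if (any(abs(rowSums(matrix) - 1) > 1e-9)) stop("PWM rows must sum to 1")
  if (any(matrix < 0)) stop("PWM probabilities must be non-negative")
  colnames(matrix) <- c("A", "C", "G", "T")
  structure(list(id = id, matrix = matrix,
                 background = background / sum(background)),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat("pwm", x$id, "width", nrow(x$matrix), "consensus",
      consensus_sequence(x), "\n")
  invisible(x)
}

#' Consensus sequence of a PWM
#' @param p A `pwm`.
#' @return Character scalar.
#' @export
consensus_sequence <- function(p) {
  paste(c("A", "C", "G", "T")[apply(p$matrix, 1, which.max)], collapse = "")
}

#' Per-position information content of a PWM (bits)
#'
#' IC_j = 2 + sum_b p_jb log2 p_jb against a uniform background, with a
#' pseudocount of 1e-6 before the log, clamped below at 0.
#'
#' @param p A `pwm`.
#' @return Numeric vector of length `nrow(p$matrix)`.
#' @export
information_content <- function(p) {
  m <- p$matrix + 1e-6
  ic <- 2 + rowSums(m * log2(m))
  pmax(ic, 0)
}

#' Scan a sequence with a PWM on both strands
#'
#' Log-odds score of each placement versus the PWM background; hits with
#' score >= `threshold_bits` are returned sorted by offset.
#'
#' @param p A `pwm`.
#' @param sequence Character scalar (length >= motif width).
#' @param threshold_bits Minimum log-odds score in bits.
#' @return data.frame `offset` (0-based), `strand`, `score`.
#' @export
scan_pwm <- function(p, sequence, threshold_bits) {
  w <- nrow(p$matrix)
  L <- nchar(sequence)
  if (L < w) stop("sequence shorter than motif")
  lo <- log2((p$matrix + 1e-6) /
             matrix(p$background, nrow = w, ncol = 4, byrow = TRUE))
  score_strand <- function(seq) {
    idx <- match(strsplit(seq, "", fixed = TRUE)[[1]], c("A", "C", "G", "T"))
    n <- L - w + 1L
    s <- numeric(n)
    for (j in seq_len(w)) {
      b <- idx[j:(j + n - 1L)]
      contrib <- ifelse(is.na(b), min(lo[j, ]), lo[j, ifelse(is.na(b), 1L, b)])
      s <- s + contrib
    }
    s
  }
  fwd <- score_strand(toupper(sequence))
  rev <- score_strand(reverse_complement(sequence))
  fi <- which(fwd >= threshold_bits)
  ri <- which(rev >= threshold_bits)
  hits <- rbind(
    data.frame(offset = fi - 1L, strand = rep("+", length(fi)),
               score = fwd[fi]),
    # offset i on the reverse-complement corresponds to forward offset
    # L - w - i
    data.frame(offset = L - w - (ri - 1L), strand = rep("-", length(ri)),
               score = rev[ri])
  )
  hits <- hits[order(hits$offset, hits$strand), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Allelic motif disruption score for a SNP
#'
#' Over all motif placements (both strands) covering the SNP, the placement
#' maximizing `max(ref score, alt score)` is selected (rule
#' `"max_allele"`; `"max_ref"` maximizes the reference score instead); the
#' function returns the two scores there and `delta = alt - ref`. A negative
#' delta means the alternate allele weakens the motif.
#'
#' @param p A `pwm`.
#' @param genome A `genome`.
#' @param snp One-row data.frame (or list) with `chrom`, `pos` (1-based),
#'   `ref`, `alt`.
#' @param rule Placement-selection rule.
#' @return list `ref_score`, `alt_score`, `delta`, `offset`, `strand`.
#' @export
allelic_motif_delta <- function(p, genome, snp, rule = c("max_allele",
                                                         "max_ref")) {
  rule <- match.arg(rule)
  w <- nrow(p$matrix)
  pos0 <- snp$pos - 1L  # 0-based
  clen <- nchar(genome$seqs[[snp$chrom]])
  if (pos0 < w - 1L || pos0 > clen - w)
    stop("SNP within motif width of chromosome end")
  ctx_start <- pos0 - (w - 1L)         # 0-based window of all placements
  ctx <- substr(genome$seqs[[snp$chrom]], ctx_start + 1L,
                pos0 + w)              # length 2w-1, SNP at index w
  if (substr(ctx, w, w) != snp$ref) stop("ref allele mismatch at SNP ", snp$id)
  alt_ctx <- ctx
  substr(alt_ctx, w, w) <- snp$alt
  lo <- log2((p$matrix + 1e-6) /
             matrix(p$background, nrow = w, ncol = 4, byrow = TRUE))
  score_at <- function(seq, off, strand) {
    sub <- substr(seq, off + 1L, off + w)
    if (strand == "-") sub <- reverse_complement(sub)
    idx <- match(strsplit(sub, "", fixed = TRUE)[[1]], c("A", "C", "G", "T"))
    sum(lo[cbind(seq_len(w), idx)])
  }
  best <- NULL
  for (off in 0:(w - 1L)) for (st in c("+", "-")) {
    rs <- score_at(ctx, off, st)
    as <- score_at(alt_ctx, off, st)
    key <- if (rule == "max_allele") max(rs, as) else rs
    if (is.null(best) || key > best$key)
      best <- list(key = key, ref_score = rs, alt_score = as,
                   offset = ctx_start + off, strand = st)
  }
  list(ref_score = best$ref_score, alt_score = best$alt_score,
       delta = best$alt_score - best$ref_score,
       offset = best$offset, strand = best$strand)
}

#' Motif-family enrichment of candidate SNPs by Fisher's exact test
#'
#' For each PWM, SNPs are classified as motif-disrupting
#' (`delta <= -delta_threshold` under [allelic_motif_delta()]) or not, and a
#' 2x2 Fisher exact test compares candidate vs background SNPs, with
#' Benjamini-Hochberg correction across PWMs.
#'
#' @param candidate_snps,background_snps SNP data.frames.
#' @param genome A `genome`.
#' @param pwms List of `pwm` objects.
#' @param delta_threshold Minimum log-odds loss (bits) to call disruption.
#' @return data.frame `pwm`, counts, `odds_ratio`, `p`, `q`.
#' @export
motif_family_enrichment <- function(candidate_snps, background_snps, genome,
                                    pwms, delta_threshold = 3) {
  if (nrow(candidate_snps) == 0 || nrow(background_snps) == 0)
    stop("empty SNP set")
  disrupts <- function(snps, p) {
    vapply(seq_len(nrow(snps)), function(i) {
      d <- tryCatch(allelic_motif_delta(p, genome, snps[i, ]),
                    error = function(e) NULL)
      !is.null(d) && d$delta <= -delta_threshold
    }, logical(1))
  }
  rows <- lapply(pwms, function(p) {
    a <- sum(disrupts(candidate_snps, p))
    b <- nrow(candidate_snps) - a
    c <- sum(disrupts(background_snps, p))
    d <- nrow(background_snps) - c
    ft <- fisher_exact(a, b, c, d)
    data.frame(pwm = p$id, cand_disrupt = a, cand_other = b,
               bg_disrupt = c, bg_other = d,
               odds_ratio = ft$odds_ratio, p = ft$p)
  })
  out <- do.call(rbind, rows)
  out$q <- bh_fdr(out$p)
  rownames(out) <- NULL
  out
}

#' Read PWMs from a MEME minimal motif file
#' @param path MEME-format file.
#' @return List of `pwm` objects.
#' @export
read_meme <- function(path) {
  lines <- readLines(path)
  starts <- grep("^MOTIF", lines)
  bg <- rep(0.25, 4)
  bgl <- grep("^Background letter frequencies", lines)
  if (length(bgl)) {
    tok <- strsplit(trimws(lines[bgl[1] + 1L]), "\\s+")[[1]]
    bg <- as.numeric(tok[c(2, 4, 6, 8)])
  }
  lapply(starts, function(s) {
    id <- strsplit(lines[s], "\\s+")[[1]][2]
    h <- grep("^letter-probability matrix", lines[s:length(lines)])[1] + s - 1L
    wtok <- regmatches(lines[h], regexec("w=\\s*(\\d+)", lines[h]))[[1]][2]
    w <- as.integer(wtok)
    m <- do.call(rbind, lapply(lines[(h + 1L):(h + w)], function(l)
      as.numeric(strsplit(trimws(l), "\\s+")[[1]])))
    m <- m / rowSums(m)
    pwm(id, m, bg)
  })
}

#' Write PWMs to a MEME minimal motif file
#' @param pwms List of `pwm` objects.
#' @param path Output file.
#' @export
write_meme <- function(pwms, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "Background letter frequencies", "A 0.25 C 0.25 G 0.25 T 0.25",
               ""), con)
  for (p in pwms) {
    writeLines(sprintf("MOTIF %s", p$id), con)
    writeLines(sprintf("letter-probability matrix: alength= 4 w= %d",
                       nrow(p$matrix)), con)
    apply(p$matrix, 1, function(r)
      writeLines(paste(sprintf("%.6f", r), collapse = " "), con))
    writeLines("", con)
  }
  invisible(path)
}
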