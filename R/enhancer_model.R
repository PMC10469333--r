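#' Call enhancers as 2 kb windows on peak intersections
#'
#' For each maximal nonempty intersection interval between the (merged)
#' H3K27ac and accessibility peak sets, a `width`-bp window centered on the
#' intersection midpoint is emitted. Windows running off a chromosome are
#' dropped; windows whose centers fall within `width/2` of an
#' already-emitted center (in chrom/start order) are deduplicated.
#'
#' @param h3k27ac_peaks,accessibility_peaks Interval data.frames (`chrom`,
#'   `start`, `end`; 0-based half-open).
#' @param genome A `genome`.
#' @param width Window width (default 2000).
#' @return data.frame `chrom`, `start`, `end`, `center`.
#' @export
call_enhancers <- function(h3k27ac_peaks, accessibility_peaks, genome,
                           width = 2000L) {
  ints <- .intersect_intervals(h3k27ac_peaks, accessibility_peaks)
  if (nrow(ints) == 0)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), center = integer()))
  lens <- seq_lengths(genome)
  mid <- (ints$start + ints$end) %/% 2L
  start <- mid - width %/% 2L
  end <- start + width
  keep <- start >= 0L & end <= lens[ints$chrom]
  out <- data.frame(chrom = ints$chrom, start = start, end = end,
                    center = mid, stringsAsFactors = FALSE)[keep, ,
                                                            drop = FALSE]
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  # dedupe centers closer than width/2 to an emitted center (first kept)
  sel <- logical(nrow(out))
  last_center <- -Inf; last_chrom <- ""
  for (i in seq_len(nrow(out))) {
    if (out$chrom[i] != last_chrom ||
        out$center[i] - last_center >= width %/% 2L) {
      sel[i] <- TRUE
      last_chrom <- out$chrom[i]
      last_center <- out$center[i]
    }
  }
  out <- out[sel, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# one-hot cube (4 x L x N) from a character vector of windows
.onehot_cube <- function(seqs) {
  if (!length(seqs)) return(array(0, dim = c(4L, 0L, 0L)))
  L <- nchar(seqs[1])
  arr <- array(0, dim = c(4L, L, length(seqs)))
  for (i in seq_along(seqs)) arr[, , i] <- t(one_hot_encode(seqs[i]))
  arr
}

#' Build the phase-one tiling dataset
#'
#' The genome is tiled with `window`-bp windows at `stride`; feature `f` is
#' labelled 1 iff its peak track covers at least 50% of the window's
#' central 200 bp bin. Windows with more than 10% N are dropped. Test =
#' holdout chromosomes; validation = one designated non-holdout chromosome
#' (default the last non-holdout one); train = the remainder.
#'
#' @param genome A `genome`.
#' @param tracks Named list of peak interval data.frames.
#' @param window,stride Tiling geometry.
#' @param holdout_chroms Character vector of test chromosomes.
#' @param validation_chrom Validation chromosome (default: last non-holdout).
#' @return list of class `phase1_dataset` with `train`/`validation`/`test`
#'   (each `x` = 4 x L x N one-hot array, `y` = F x N label matrix,
#'   `windows` = interval data.frame) and `feature_names`.
#' @export
make_phase1_dataset <- function(genome, tracks, window = 2000L,
                                stride = 2000L, holdout_chroms,
                                validation_chrom = NULL) {
  stopifnot(length(tracks) >= 1)
  chroms <- names(genome$seqs)
  if (!all(holdout_chroms %in% chroms))
    stop("holdout chromosome(s) absent from genome")
  non_hold <- setdiff(chroms, holdout_chroms)
  if (!length(non_hold)) stop("no non-holdout chromosomes left")
  # with a single non-holdout chromosome a whole-chromosome validation
  # split would leave no training data; fall back to holding out every
  # fifth window of that chromosome instead
  window_level_val <- length(non_hold) == 1L && is.null(validation_chrom)
  if (is.null(validation_chrom) && !window_level_val)
    validation_chrom <- non_hold[length(non_hold)]
  if (!window_level_val && !(validation_chrom %in% non_hold))
    stop("validation chromosome must be a non-holdout chromosome")
  lens <- seq_lengths(genome)
  wins <- do.call(rbind, lapply(chroms, function(ch) {
    starts <- seq(0L, lens[[ch]] - window, by = stride)
    data.frame(chrom = ch, start = starts, end = starts + window,
               stringsAsFactors = FALSE)
  }))
  seqs <- vapply(seq_len(nrow(wins)), function(i)
    substr(genome$seqs[[wins$chrom[i]]], wins$start[i] + 1L, wins$end[i]),
    character(1))
  names(seqs) <- NULL
  n_frac <- vapply(seqs, function(s)
    lengths(regmatches(s, gregexpr("N", s))) / nchar(s), numeric(1))
  keep <- n_frac <= 0.1
  wins <- wins[keep, , drop = FALSE]
  seqs <- seqs[keep]
  # central 200 bp bin coverage labels
  c0 <- wins$start + window %/% 2L - 100L
  c1 <- c0 + 200L
  y <- vapply(tracks, function(tr) {
    cov <- numeric(nrow(wins))
    for (ch in unique(wins$chrom)) {
      sel <- wins$chrom == ch
      trc <- tr[tr$chrom == ch, , drop = FALSE]
      if (nrow(trc) == 0) next
      q <- IRanges::IRanges(start = c0[sel] + 1L, end = c1[sel])
      s <- .as_iranges(trc)
      ov <- IRanges::findOverlaps(q, s)
      if (length(ov) == 0) next
      w <- IRanges::width(IRanges::pintersect(
        q[S4Vectors::queryHits(ov)], s[S4Vectors::subjectHits(ov)]))
      covch <- tapply(w, S4Vectors::queryHits(ov), sum)
      tmp <- numeric(sum(sel))
      tmp[as.integer(names(covch))] <- covch
      cov[sel] <- tmp
    }
    as.numeric(cov >= 100)
  }, numeric(nrow(wins)))
  if (window_level_val) {
    validation_chrom <- NA_character_
    split_of <- ifelse(wins$chrom %in% holdout_chroms, "test",
                       ifelse(seq_len(nrow(wins)) %% 5L == 0L,
                              "validation", "train"))
  } else {
    split_of <- ifelse(wins$chrom %in% holdout_chroms, "test",
                       ifelse(wins$chrom == validation_chrom, "validation",
                              "train"))
  }
  mk <- function(sel) list(x = .onehot_cube(seqs[sel]),
                           y = t(y[sel, , drop = FALSE]),
                           windows = wins[sel, , drop = FALSE],
                           seqs = seqs[sel])
  structure(list(train = mk(split_of == "train"),
                 validation = mk(split_of == "validation"),
                 test = mk(split_of == "test"),
                 feature_names = names(tracks),
                 window = window, stride = stride,
                 holdout_chroms = holdout_chroms,
                 validation_chrom = validation_chrom),
            class = "phase1_dataset")
}

#' Default phase-one model configuration
#'
#' A small sequence CNN: one convolution (44 filters of width 14), ReLU,
#' non-overlapping max-pooling over 400-bp bins (optionally concatenated
#' with mean-pooling), one 32-unit dense hidden layer, sigmoid outputs per
#' feature; AdamW with dropout, an L1 penalty on the first dense layer,
#' and early stopping on validation loss. At desk-scale sample sizes a
#' randomly initialized convolution essentially never discovers motifs
#' before it memorizes the training windows, so by default the filter
#' bank is seeded: discriminative k-mers are mined from the training
#' split, extended to kernel-wide position frequency matrices from their
#' aligned occurrences, and written into the filters as log-odds (each
#' motif and its reverse complement). Each seeded filter's bias is then
#' "hinged" at a high quantile of its pooled activations over background
#' windows, so background sequence almost never activates it — this is
#' what makes downstream saturated-mutagenesis profiles near zero away
#' from binding sites. Seeding uses only training data, never ground
#' truth.
#'
#' @param filters,kernel,pool,hidden,mean_channel Architecture knobs.
#' @param lr,weight_decay,dropout,l1_readout,batch,epochs,patience
#'   Optimiser knobs.
#' @param seed_kmers Seed filters with mined k-mers (default TRUE).
#' @param kmers_per_feature Mined k-mers per output feature.
#' @param kmer_length Length of mined k-mers.
#' @param hinge_quantile,hinge_margin Background-activation quantile and
#'   additive margin for the seeded-filter bias hinge.
#' @return list.
#' @export
phase1_config <- function(filters = 44L, kernel = 14L, pool = 400L,
                          hidden = 32L, lr = 0.001, weight_decay = 0.5,
                          dropout = 0.2, l1_readout = 0.05, batch = 32L,
                          epochs = 80L, patience = 15L,
                          seed_kmers = TRUE, kmers_per_feature = 3L,
                          kmer_length = 8L, mean_channel = FALSE,
                          hinge_quantile = 0.995, hinge_margin = 0.25) {
  as.list(environment())
}

# discriminative k-mer mining from the training split: per feature, count
# k-mers in the central 600 bp of positive windows against a background of
# negative windows plus the positives' own flanks; rank by the upper-tail
# binomial p-value of the center count at the background rate (count-aware,
# unlike a smoothed ratio which over-ranks low-count noise); deduplicate
# against shifts and reverse complements; round-robin across features.
.mine_kmers <- function(seqs, y, k = 8L, per_feature = 3L, max_total = 22L) {
  kmers_of <- function(s) substring(s, 1:(nchar(s) - k + 1L), k:nchar(s))
  L <- nchar(seqs[1])
  c0 <- L %/% 2L - 300L
  per_task <- lapply(seq_len(nrow(y)), function(f) {
    pos <- which(y[f, ] == 1)
    neg <- which(y[f, ] == 0)
    if (length(pos) < 5 || !length(neg)) return(character(0))
    cen <- unlist(lapply(seqs[pos], function(s)
      kmers_of(substr(s, c0 + 1L, c0 + 600L))))
    bg <- c(unlist(lapply(seqs[neg], kmers_of)),
            unlist(lapply(seqs[pos], function(s)
              c(kmers_of(substr(s, 1L, c0 - 100L)),
                kmers_of(substr(s, L - c0 + 100L, L))))))
    tc <- table(cen)
    tc <- tc[tc >= 6]
    if (!length(tc)) return(character(0))
    tb <- table(bg)
    fb <- as.numeric(tb[names(tc)])
    fb[is.na(fb)] <- 0
    fb <- (fb + 0.5) / length(bg)
    p <- stats::pbinom(as.numeric(tc) - 1, length(cen), fb,
                       lower.tail = FALSE)
    names(p) <- names(tc)
    names(sort(p))
  })
  picked <- character(0)
  is_dup <- function(km) {
    rc <- reverse_complement(km)
    any(vapply(picked, function(p2)
      km == p2 || rc == p2 ||
        grepl(substr(km, 2, k - 1), p2, fixed = TRUE) ||
        grepl(substr(rc, 2, k - 1), p2, fixed = TRUE), logical(1)))
  }
  for (r in seq_len(per_feature)) {
    for (f in seq_along(per_task)) {
      if (length(picked) >= max_total) break
      for (km in per_task[[f]]) {
        if (!is_dup(km)) { picked <- c(picked, km); break }
      }
      per_task[[f]] <- setdiff(per_task[[f]], picked)
    }
  }
  picked
}

# seed-and-extend: estimate a kernel-wide position frequency matrix from
# the aligned occurrences (both strands) of a mined k-mer in the central
# kb of positive windows
.extend_kmer_pfm <- function(kmer, center_seqs, kernel = 12L) {
  k <- nchar(kmer)
  rc <- reverse_complement(kmer)
  off <- (kernel - k) %/% 2L
  ctx <- character(0)
  for (s in center_seqs) {
    for (pat in c(kmer, rc)) {
      hits <- gregexpr(pat, s, fixed = TRUE)[[1]]
      for (p0 in hits[hits > 0]) {
        a <- p0 - off
        if (a < 1L || a + kernel - 1L > nchar(s)) next
        c2 <- substr(s, a, a + kernel - 1L)
        if (pat == rc) c2 <- reverse_complement(c2)
        ctx <- c(ctx, c2)
      }
    }
  }
  if (length(ctx) < 5L) return(NULL)
  mat <- do.call(rbind, strsplit(ctx, "", fixed = TRUE))
  t(apply(mat, 2, function(col)
    (c(sum(col == "A"), sum(col == "C"), sum(col == "G"),
       sum(col == "T")) + 1) / (length(col) + 4)))
}

# write log-odds of extended PFMs (each plus its reverse complement) into
# the first conv filter rows; remaining rows keep their random init
.seed_conv_filters <- function(w0, pfms, scale = 0.35) {
  f <- 1L
  for (pf in pfms) {
    if (is.null(pf) || f + 1L > nrow(w0$Wc)) next
    lo <- log2(pf / 0.25) * scale
    w0$Wc[f, ] <- as.vector(t(lo))          # layout: base + 4 * position
    w0$Wc[f + 1L, ] <- as.vector(t(lo[nrow(lo):1, 4:1]))  # reverse strand
    f <- f + 2L
  }
  w0
}

#' Default phase-two model configuration (dense network on the phase-one
#' feature-probability vector)
#'
#' Weight decay is deliberately substantial: it bounds the logits so that
#' the class probabilities stay calibrated rather than saturating at
#' 0/1, which is what keeps single-base allelic deltas (ED and IEP
#' scores) on a usable probability scale.
#'
#' @param hidden Hidden units.
#' @param lr,weight_decay,batch,epochs,patience Optimiser knobs.
#' @return list.
#' @export
phase2_config <- function(hidden = 8L, lr = 0.01, weight_decay = 1.0,
                          batch = 32L, epochs = 300L, patience = 25L) {
  as.list(environment())
}

.new_handle <- function(phase, arch, weights, config, seed, feature_names,
                        holdout_chroms, history) {
  structure(list(phase = phase, arch = arch, weights = weights,
                 config = config, seed = seed,
                 feature_names = feature_names,
                 holdout_chroms = holdout_chroms, history = history),
            class = "model_handle")
}

#' @export
print.model_handle <- function(x, ...) {
  cat("model_handle phase =", x$phase, "| outputs =", x$arch$outputs,
      "| seed =", x$seed, "| best epoch =", x$history$best_epoch, "\n")
  invisible(x)
}

#' Train the phase-one epigenomic feature model
#'
#' Multitask binary classifier: one sigmoid output per peak track,
#' minimizing mean per-feature cross-entropy, early-stopped on validation
#' loss. Deterministic for a fixed seed.
#'
#' @param dataset A [make_phase1_dataset()] result.
#' @param config A [phase1_config()].
#' @param seed Training seed.
#' @return A `model_handle` with `phase = 1`.
#' @export
train_phase1 <- function(dataset, config = phase1_config(), seed = 1L) {
  stopifnot(inherits(dataset, "phase1_dataset"))
  if (!dim(dataset$train$x)[3] || !dim(dataset$validation$x)[3])
    stop("train/validation splits must be nonempty")
  arch <- list(type = "conv", in_channels = 4L,
               input_length = dim(dataset$train$x)[2],
               filters = config$filters, kernel = config$kernel,
               pool = config$pool, hidden = config$hidden,
               outputs = nrow(dataset$train$y),
               mean_channel = isTRUE(config$mean_channel))
  w0 <- nn_init_cpp(arch, seed)
  if (isTRUE(config$seed_kmers) && !is.null(dataset$train$seqs)) {
    mined <- .mine_kmers(dataset$train$seqs, dataset$train$y,
                         k = config$kmer_length,
                         per_feature = config$kmers_per_feature,
                         max_total = config$filters %/% 2L - 2L)
    L <- dim(dataset$train$x)[2]
    pos_any <- which(colSums(dataset$train$y) > 0)
    cen <- vapply(dataset$train$seqs[pos_any], function(s)
      substr(s, L %/% 2L - 499L, L %/% 2L + 500L), "")
    pfms <- lapply(mined, .extend_kmer_pfm, center_seqs = cen,
                   kernel = config$kernel)
    w0 <- .seed_conv_filters(w0, pfms)
    # hinge: bias each seeded filter so that background sequence almost
    # never activates it (quantile of its pooled maxima over negative
    # training windows, plus a margin). Activations, and therefore
    # saturated-mutagenesis ED scores, are then exactly zero at almost
    # all non-motif positions.
    neg <- which(colSums(dataset$train$y) == 0)
    if (length(neg) > 20) {
      neg <- neg[seq_len(min(300L, length(neg)))]
      Fx <- nn_features_cpp(dataset$train$x[, , neg, drop = FALSE], arch,
                            w0)
      npool <- ceiling((L - config$kernel + 1) / config$pool)
      n_seeded <- 2L * sum(!vapply(pfms, is.null, logical(1)))
      for (f in seq_len(min(n_seeded, config$filters))) {
        vals <- as.vector(Fx[f + (seq_len(npool) - 1L) * config$filters, ])
        w0$bc[f] <- -(stats::quantile(vals, config$hinge_quantile) +
                        config$hinge_margin)
      }
    }
  }
  hyper <- list(lr = config$lr, weight_decay = config$weight_decay,
                dropout = config$dropout, l1_readout = config$l1_readout,
                pos_weight = FALSE,
                batch = config$batch, epochs = config$epochs,
                patience = config$patience, seed = seed)
  fit <- nn_train_cpp(dataset$train$x, dataset$train$y,
                      dataset$validation$x, dataset$validation$y,
                      arch, w0, hyper)
  .new_handle(1L, arch, fit$weights, config, seed, dataset$feature_names,
              dataset$holdout_chroms,
              list(train_loss = fit$train_loss, val_loss = fit$val_loss,
                   best_epoch = fit$best_epoch))
}

#' Phase-one feature probabilities for 2 kb windows
#'
#' @param handle Phase-1 `model_handle`.
#' @param window_sequence Character vector of window sequences (each of the
#'   trained input length), or a precomputed 4 x L x N one-hot array.
#' @return F x N matrix of probabilities (rows named by feature) — or a
#'   named vector when a single window is given.
#' @export
predict_epigenome <- function(handle, window_sequence) {
  stopifnot(inherits(handle, "model_handle"), handle$phase == 1L)
  single <- is.character(window_sequence) && length(window_sequence) == 1L
  x <- if (is.character(window_sequence)) {
    if (any(nchar(window_sequence) != handle$arch$input_length))
      stop("window length must be ", handle$arch$input_length)
    .onehot_cube(window_sequence)
  } else window_sequence
  if (dim(x)[2] != handle$arch$input_length)
    stop("window length must be ", handle$arch$input_length)
  p <- nn_predict_cpp(x, handle$arch, handle$weights)
  rownames(p) <- handle$feature_names
  if (single) p[, 1] else p
}

#' Train the phase-two enhancer classifier
#'
#' Positives are phase-one probability vectors of enhancer windows;
#' negatives are vectors of random same-width windows not overlapping any
#' enhancer, at `negative_ratio`:1. Enhancers and negatives on the phase-1
#' holdout chromosomes are set aside as the test split; a fraction of the
#' training windows is used for validation/early stopping.
#'
#' @param phase1_handle Trained phase-1 handle.
#' @param enhancers data.frame from [call_enhancers()].
#' @param genome A `genome`.
#' @param negative_ratio Negatives per positive (default 10).
#' @param seed RNG seed (negative sampling + training).
#' @param config A [phase2_config()].
#' @return A `model_handle` with `phase = 2`; its `$test` element holds the
#'   holdout feature matrix, labels and windows.
#' @export
train_phase2 <- function(phase1_handle, enhancers, genome,
                         negative_ratio = 10L, seed = 1L,
                         config = phase2_config()) {
  stopifnot(inherits(phase1_handle, "model_handle"),
            phase1_handle$phase == 1L, nrow(enhancers) > 0)
  width <- phase1_handle$arch$input_length
  holdout <- phase1_handle$holdout_chroms
  lens <- seq_lengths(genome)
  n_neg <- negative_ratio * nrow(enhancers)
  negs <- with_seed(seed, {
    out <- NULL
    tries <- 0L
    chroms <- names(genome$seqs)
    while (is.null(out) || nrow(out) < n_neg) {
      tries <- tries + 1L
      if (tries > 50L * n_neg) stop("insufficient negative windows")
      ch <- sample(chroms, 1)
      s <- sample.int(lens[[ch]] - width, 1) - 1L
      cand <- data.frame(chrom = ch, start = s, end = s + width,
                         stringsAsFactors = FALSE)
      if (nrow(.intersect_intervals(enhancers, cand)) > 0) next
      out <- rbind(out, cand)
    }
    out
  })
  wins <- rbind(enhancers[, c("chrom", "start", "end")],
                negs[, c("chrom", "start", "end")])
  labels <- c(rep(1, nrow(enhancers)), rep(0, nrow(negs)))
  seqs <- vapply(seq_len(nrow(wins)), function(i)
    substr(genome$seqs[[wins$chrom[i]]], wins$start[i] + 1L, wins$end[i]),
    character(1))
  feats <- predict_epigenome(phase1_handle, .onehot_cube(seqs))  # F x N
  is_test <- wins$chrom %in% holdout
  tr_idx <- which(!is_test)
  val_idx <- with_seed(seed + 1L,
                       sample(tr_idx, max(1L, round(0.15 * length(tr_idx)))))
  tr_idx <- setdiff(tr_idx, val_idx)
  if (!length(tr_idx) || sum(labels[tr_idx]) == 0)
    stop("no training positives after holdout split")
  arch <- list(type = "dense", input_dim = nrow(feats),
               hidden = config$hidden, outputs = 1L)
  w0 <- nn_init_cpp(arch, seed)
  hyper <- list(lr = config$lr, weight_decay = config$weight_decay,
                dropout = 0,
                pos_weight = FALSE, batch = config$batch,
                epochs = config$epochs, patience = config$patience,
                seed = seed)
  fit <- nn_train_cpp(feats[, tr_idx, drop = FALSE],
                      matrix(labels[tr_idx], nrow = 1),
                      feats[, val_idx, drop = FALSE],
                      matrix(labels[val_idx], nrow = 1),
                      arch, w0, hyper)
  h <- .new_handle(2L, arch, fit$weights, config, seed,
                   phase1_handle$feature_names, holdout,
                   list(train_loss = fit$train_loss,
                        val_loss = fit$val_loss,
                        best_epoch = fit$best_epoch))
  # temperature calibration on the validation split: the raw classifier is
  # overconfident (validation logits far into saturation), which collapses
  # probability-scale allelic deltas at strong enhancers; dividing the
  # logit by the NLL-minimizing temperature restores a usable probability
  # scale without changing the ranking (auROC invariant)
  pv <- as.numeric(nn_predict_cpp(feats[, val_idx, drop = FALSE], arch,
                                  fit$weights))
  h$temperature <- .fit_temperature(pv, labels[val_idx])
  h$test <- list(x = feats[, is_test, drop = FALSE],
                 labels = labels[is_test],
                 windows = wins[is_test, , drop = FALSE])
  h$train_data <- list(x = feats[, tr_idx, drop = FALSE],
                       labels = labels[tr_idx])
  h
}

#' Phase-two prediction from phase-one feature vectors
#' @param handle Phase-2 `model_handle`.
#' @param features F-vector or F x N matrix of phase-one probabilities.
#' @return Numeric vector of enhancer probabilities.
#' @export
predict_phase2 <- function(handle, features) {
  stopifnot(inherits(handle, "model_handle"), handle$phase == 2L)
  if (is.null(dim(features))) features <- matrix(features, ncol = 1)
  p <- as.numeric(nn_predict_cpp(features, handle$arch, handle$weights))
  .apply_temperature(p, handle$temperature)
}

# NLL-minimizing temperature for probability calibration (T >= 1)
.fit_temperature <- function(p, y) {
  z <- .logit(p)
  nll <- function(Tval) {
    q <- stats::plogis(z / Tval)
    q <- pmin(pmax(q, 1e-12), 1 - 1e-12)
    -mean(y * log(q) + (1 - y) * log(1 - q))
  }
  stats::optimize(nll, c(1, 50))$minimum
}

.logit <- function(p) stats::qlogis(pmin(pmax(p, 1e-14), 1 - 1e-14))

.apply_temperature <- function(p, temperature) {
  if (is.null(temperature) || temperature <= 1) return(p)
  stats::plogis(.logit(p) / temperature)
}

#' Enhancer probability of a 2 kb window
#'
#' By construction equals `predict_phase2(predict_epigenome(x))`.
#'
#' @param phase1_handle,phase2_handle Trained handles.
#' @param window_sequence Character vector of window sequences.
#' @return Numeric vector of probabilities in \[0, 1\].
#' @export
enhancer_probability <- function(phase1_handle, phase2_handle,
                                 window_sequence) {
  f <- predict_epigenome(phase1_handle, window_sequence)
  if (is.null(dim(f))) f <- matrix(f, ncol = 1)
  predict_phase2(phase2_handle, f)
}

#' Bundle the two phases into a sequence-to-probability oracle
#'
#' The returned function maps a window sequence to its enhancer
#' probability; it carries the two handles so that saturated mutagenesis
#' can use the fast incremental path.
#'
#' @inheritParams enhancer_probability
#' @return Function of class `two_phase_oracle`.
#' @export
two_phase_oracle <- function(phase1_handle, phase2_handle) {
  f <- function(window_sequence)
    enhancer_probability(phase1_handle, phase2_handle, window_sequence)
  attr(f, "phase1") <- phase1_handle
  attr(f, "phase2") <- phase2_handle
  class(f) <- c("two_phase_oracle", "function")
  f
}

#' Save a model handle to a checkpoint file
#' @param handle A `model_handle`.
#' @param path Output file (RDS).
#' @export
save_model <- function(handle, path) {
  stopifnot(inherits(handle, "model_handle"))
  saveRDS(handle, path)
  invisible(path)
}

#' Load a model handle from a checkpoint file
#' @param path Checkpoint written by [save_model()].
#' @return A `model_handle`.
#' @export
load_model <- function(path) {
  h <- readRDS(path)
  stopifnot(inherits(h, "model_handle"))
  h
}
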