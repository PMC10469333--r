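#' Label ED regions by TFBS overlap
#'
#' A region is labelled 1 iff it intersects (>= `min_overlap` bp,
#' half-open) any TFBS interval.
#'
#' @param regions data.frame from [call_ed_regions_all()].
#' @param tfbs_intervals Interval data.frame of binding sites (in the
#'   synthetic setting, the planted motif instances).
#' @param min_overlap Minimum overlap in bp (default 1).
#' @return `regions` with an added `label` column (0/1).
#' @export
label_regions <- function(regions, tfbs_intervals, min_overlap = 1L) {
  lab <- integer(nrow(regions))
  if (nrow(regions) && nrow(tfbs_intervals)) {
    for (ch in unique(regions$chrom)) {
      sel <- regions$chrom == ch
      tf <- tfbs_intervals[tfbs_intervals$chrom == ch, , drop = FALSE]
      if (!nrow(tf)) next
      q <- .as_iranges(regions[sel, , drop = FALSE])
      s <- .as_iranges(tf)
      ov <- IRanges::findOverlaps(q, s, minoverlap = min_overlap)
      lab[which(sel)[unique(S4Vectors::queryHits(ov))]] <- 1L
    }
  }
  regions$label <- lab
  regions
}

#' Fixed-width ED feature vectors for regions
#'
#' Extracts a `W`-bp slice of each region's ED profile centered on the
#' region midpoint, zero-padded where the slice runs past the enhancer
#' window.
#'
#' @param regions Labelled regions with a `profile_id` column.
#' @param profiles The list of `ed_profile` the regions were called from.
#' @param W Feature window width (default 40).
#' @return list `x` (n x W matrix), `regions` (the input rows).
#' @export
ed_region_features <- function(regions, profiles, W = 40L) {
  n <- nrow(regions)
  x <- matrix(0, n, W)
  for (i in seq_len(n)) {
    p <- profiles[[regions$profile_id[i]]]
    mid <- (regions$start[i] + regions$end[i]) %/% 2L - p$interval$start
    lo <- mid - W %/% 2L  # 0-based within profile
    for (j in seq_len(W)) {
      k <- lo + j  # 1-based profile index
      if (k >= 1L && k <= length(p$ed)) x[i, j] <- p$ed[k]
    }
  }
  list(x = x, regions = regions)
}

#' One-hot sequence features for regions (baseline input)
#'
#' @param regions Labelled regions.
#' @param genome A `genome`.
#' @param W Window width (default 40).
#' @return list `x` (4 x W x n one-hot array), `regions`.
#' @export
seq_region_features <- function(regions, genome, W = 40L) {
  n <- nrow(regions)
  lens <- seq_lengths(genome)
  arr <- array(0, dim = c(4L, W, n))
  for (i in seq_len(n)) {
    mid <- (regions$start[i] + regions$end[i]) %/% 2L
    lo <- mid - W %/% 2L
    s <- max(0L, lo)
    e <- min(lens[[regions$chrom[i]]], lo + W)
    if (e > s) {
      seq <- substr(genome$seqs[[regions$chrom[i]]], s + 1L, e)
      arr[, (s - lo + 1L):(e - lo), i] <- t(one_hot_encode(seq))
    }
  }
  list(x = arr, regions = regions)
}

.tfbs_config <- function() {
  list(filters = 8L, kernel = 7L, pool = 5L, hidden = 16L,
       lr = 0.005, batch = 16L, epochs = 200L, patience = 20L)
}

# shared trainer for both TFBS models; x is either n x W (ED) or
# 4 x W x n (sequence)
.train_region_classifier <- function(x, regions, kind, seed, holdout_chroms,
                                     phase_tag) {
  lab <- regions$label
  is_test <- regions$chrom %in% holdout_chroms
  tr <- which(!is_test)
  if (length(unique(lab[tr])) < 2)
    stop("training data contain a single class")
  val <- with_seed(seed + 1L, sample(tr, max(1L, round(0.2 * length(tr)))))
  tr <- setdiff(tr, val)
  if (length(unique(lab[tr])) < 2) stop("single-class training split")
  cfg <- .tfbs_config()
  conv_input <- length(dim(x)) == 3L
  if (conv_input) {
    arch <- list(type = "conv", in_channels = dim(x)[1],
                 input_length = dim(x)[2], filters = cfg$filters,
                 kernel = cfg$kernel, pool = cfg$pool, hidden = cfg$hidden,
                 outputs = 1L)
    take <- function(idx) x[, , idx, drop = FALSE]
  } else {
    # ED vector treated as a 1-channel signal for the 1-D conv classifier
    arch <- list(type = "conv", in_channels = 1L, input_length = ncol(x),
                 filters = cfg$filters, kernel = cfg$kernel,
                 pool = cfg$pool, hidden = cfg$hidden, outputs = 1L)
    take <- function(idx) {
      a <- array(0, dim = c(1L, ncol(x), length(idx)))
      a[1, , ] <- t(x[idx, , drop = FALSE])
      a
    }
  }
  w0 <- nn_init_cpp(arch, seed)
  hyper <- list(lr = cfg$lr, weight_decay = 0.2, dropout = 0.1,
                pos_weight = FALSE, batch = cfg$batch, epochs = cfg$epochs,
                patience = cfg$patience, seed = seed)
  fit <- nn_train_cpp(take(tr), matrix(lab[tr], nrow = 1),
                      take(val), matrix(lab[val], nrow = 1),
                      arch, w0, hyper)
  h <- .new_handle(phase_tag, arch, fit$weights, cfg, seed, kind,
                   holdout_chroms,
                   list(train_loss = fit$train_loss,
                        val_loss = fit$val_loss,
                        best_epoch = fit$best_epoch))
  h$split <- list(train = tr, validation = val, test = which(is_test))
  h
}

#' Train a TFBS-from-ED classifier
#'
#' A small 1-D convolutional classifier over the fixed-width ED vector of
#' each region; one model per region kind (EDR or ESR). Regions on the
#' holdout chromosomes form the test split.
#'
#' @param features Result of [ed_region_features()] on labelled regions of
#'   one kind.
#' @param kind "edr" or "esr" (recorded on the handle).
#' @param seed Training seed.
#' @param holdout_chroms Test chromosomes.
#' @return `model_handle` with `phase = "tfbs"`; `$split` records the
#'   train/validation/test row indices.
#' @export
train_tfbs_model <- function(features, kind = c("edr", "esr"), seed = 1L,
                             holdout_chroms) {
  kind <- match.arg(kind)
  .train_region_classifier(features$x, features$regions, kind, seed,
                           holdout_chroms, "tfbs")
}

#' Train the sequence-only TFBS baseline
#'
#' Identical protocol to [train_tfbs_model()] but the input is the one-hot
#' sequence of the same window.
#'
#' @param features Result of [seq_region_features()] on the same labelled
#'   regions.
#' @inheritParams train_tfbs_model
#' @return `model_handle` with `phase = "tfbs_seq"`.
#' @export
train_sequence_baseline <- function(features, kind = c("edr", "esr"),
                                    seed = 1L, holdout_chroms) {
  kind <- match.arg(kind)
  .train_region_classifier(features$x, features$regions, kind, seed,
                           holdout_chroms, "tfbs_seq")
}

#' Predict TFBS probability for region features
#' @param handle Handle from [train_tfbs_model()] or
#'   [train_sequence_baseline()].
#' @param features Matching feature object.
#' @param idx Optional row indices (default all).
#' @return Numeric probabilities.
#' @export
predict_tfbs <- function(handle, features, idx = NULL) {
  stopifnot(inherits(handle, "model_handle"),
            handle$phase %in% c("tfbs", "tfbs_seq"))
  x <- features$x
  n <- if (length(dim(x)) == 3L) dim(x)[3] else nrow(x)
  if (is.null(idx)) idx <- seq_len(n)
  if (length(dim(x)) == 3L) {
    xi <- x[, , idx, drop = FALSE]
  } else {
    xi <- array(0, dim = c(1L, ncol(x), length(idx)))
    xi[1, , ] <- t(x[idx, , drop = FALSE])
  }
  as.numeric(nn_predict_cpp(xi, handle$arch, handle$weights))
}
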