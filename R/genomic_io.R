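#' Construct a genome object
#'
#' A genome is a named set of chromosome sequences over the alphabet
#' A, C, G, T, N. All coordinates in this package are 0-based, half-open;
#' SNP positions are converted from 1-based at the I/O boundary.
#'
#' @param sequences Named character vector (or list) of chromosome sequences.
#' @return An object of class `genome`.
#' @export
genome <- function(sequences) {
  sequences <- vapply(sequences, as.character, character(1))
  if (is.null(names(sequences)) || anyDuplicated(names(sequences)))
    stop("chromosome names must be present and unique")
  sequences <- toupper(sequences)
  if (any(nchar(sequences) == 0L)) stop("empty chromosome sequence")
  bad <- grepl("[^ACGTN]", sequences)
  if (any(bad))
    stop("invalid characters in chromosome(s): ",
         paste(names(sequences)[bad], collapse = ", "))
  structure(list(seqs = sequences), class = "genome")
}

#' @export
print.genome <- function(x, ...) {
  cat("genome:", length(x$seqs), "chromosome(s),",
      format(sum(nchar(x$seqs)), big.mark = ","), "bp total\n")
  invisible(x)
}

#' Chromosome lengths of a genome
#' @param g A `genome`.
#' @return Named integer vector of lengths.
#' @export
seq_lengths <- function(g) {
  stopifnot(inherits(g, "genome"))
  vapply(g$seqs, nchar, integer(1))
}

#' Read a FASTA file into a genome
#'
#' Sequences are case-normalized to uppercase.
#'
#' @param path FASTA file.
#' @return A `genome`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ss <- Biostrings::readDNAStringSet(path)
  seqs <- as.character(ss)
  # keep only the first whitespace-delimited token of each header
  names(seqs) <- sub("\\s.*$", "", names(ss))
  genome(seqs)
}

#' Write a genome to FASTA
#' @param g A `genome`.
#' @param path Output file.
#' @param width Line width.
#' @export
write_fasta <- function(g, path, width = 70L) {
  stopifnot(inherits(g, "genome"))
  ss <- Biostrings::DNAStringSet(g$seqs)
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}

#' Read a BED file (0-based half-open intervals)
#'
#' Columns beyond chrom/start/end are retained (`name`, `score`, `strand`,
#' then `extra1`, ...).
#'
#' @param path BED file (>= 3 tab-separated columns, no header).
#' @return data.frame with columns `chrom`, `start`, `end`, plus extras.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  dt <- data.table::fread(path, header = FALSE, sep = "\t", fill = TRUE,
                          data.table = FALSE, colClasses = list(character = 1))
  if (ncol(dt) < 3) stop("BED needs >= 3 columns: ", path)
  std <- c("chrom", "start", "end", "name", "score", "strand")
  n <- ncol(dt)
  nm <- std[seq_len(min(n, 6L))]
  if (n > 6) nm <- c(nm, paste0("extra", seq_len(n - 6L)))
  names(dt) <- nm
  dt$start <- as.integer(dt$start)
  dt$end <- as.integer(dt$end)
  bad <- which(!(dt$start >= 0L & dt$start < dt$end))
  if (length(bad))
    stop("invalid interval (start >= end or negative) at line ", bad[1],
         " of ", path)
  dt
}

#' Write intervals to BED
#' @param intervals data.frame with `chrom`, `start`, `end` and optional
#'   further columns.
#' @param path Output file.
#' @export
write_bed <- function(intervals, path) {
  stopifnot(all(c("chrom", "start", "end") %in% names(intervals)))
  data.table::fwrite(intervals, path, sep = "\t", col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read a VCF-like SNP table
#'
#' Expects tab-separated columns CHROM, POS (1-based), ID, REF, ALT with or
#' without a header line. Multi-nucleotide records are skipped with a
#' warning; records whose REF does not match the genome are excluded and
#' counted (attribute `n_ref_mismatch`).
#'
#' @param path SNP table.
#' @param genome A `genome` used to validate REF alleles.
#' @return data.frame `id`, `chrom`, `pos`, `ref`, `alt` with attributes
#'   `n_ref_mismatch` and `n_skipped_mnv`.
#' @export
read_snp_table <- function(path, genome) {
  if (!file.exists(path)) stop("no such file: ", path)
  dt <- data.table::fread(path, header = "auto", sep = "\t",
                          data.table = FALSE)
  if (ncol(dt) < 5) stop("SNP table needs >= 5 columns")
  names(dt)[1:5] <- c("chrom", "pos", "id", "ref", "alt")
  dt <- dt[, 1:5]
  dt$chrom <- as.character(dt$chrom)
  dt$pos <- as.integer(dt$pos)
  dt$ref <- toupper(as.character(dt$ref))
  dt$alt <- toupper(as.character(dt$alt))
  mnv <- nchar(dt$ref) != 1L | nchar(dt$alt) != 1L
  if (any(mnv)) {
    warning(sum(mnv), " non-SNV record(s) skipped")
    dt <- dt[!mnv, , drop = FALSE]
  }
  gbase <- mapply(function(ch, p) get_base(genome, ch, p), dt$chrom, dt$pos)
  mism <- gbase != dt$ref
  if (any(mism))
    message(sum(mism), " SNP(s) excluded: REF does not match genome")
  out <- dt[!mism, c("id", "chrom", "pos", "ref", "alt"), drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_ref_mismatch") <- sum(mism)
  attr(out, "n_skipped_mnv") <- sum(mnv)
  out
}

#' Write a SNP table
#' @param snps data.frame `id`, `chrom`, `pos`, `ref`, `alt`.
#' @param path Output file.
#' @export
write_snp_table <- function(snps, path) {
  out <- snps[, c("chrom", "pos", "id", "ref", "alt")]
  data.table::fwrite(out, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Reference base at a 1-based position
#' @param g A `genome`.
#' @param chrom Chromosome name.
#' @param pos 1-based position.
#' @return Single-character base.
#' @export
get_base <- function(g, chrom, pos) {
  s <- g$seqs[[chrom]]
  if (is.null(s)) stop("unknown chromosome: ", chrom)
  if (pos < 1L || pos > nchar(s)) stop("position off chromosome: ", pos)
  substr(s, pos, pos)
}

#' One-hot encode a DNA sequence
#'
#' Channel order A, C, G, T; an N base encodes as an all-zero row.
#'
#' @param sequence Character scalar over A,C,G,T,N.
#' @return L x 4 binary matrix with column names A,C,G,T.
#' @export
one_hot_encode <- function(sequence) {
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  idx <- match(chars, c("A", "C", "G", "T"))
  if (any(is.na(idx) & chars != "N"))
    stop("invalid character in sequence: ",
         paste(unique(chars[is.na(idx) & chars != "N"]), collapse = ""))
  m <- matrix(0, nrow = length(chars), ncol = 4,
              dimnames = list(NULL, c("A", "C", "G", "T")))
  ok <- !is.na(idx)
  m[cbind(which(ok), idx[ok])] <- 1
  m
}

#' Extract a fixed-length window centered on a position
#'
#' For even `length` the window is left-biased: it starts at
#' `center - length/2` (0-based) and covers `length` bases.
#'
#' @param g A `genome`.
#' @param chrom Chromosome.
#' @param center 0-based center coordinate.
#' @param length Window length (default 2000).
#' @return Character scalar of exactly `length` bases.
#' @export
extract_window <- function(g, chrom, center, length = 2000L) {
  s <- g$seqs[[chrom]]
  if (is.null(s)) stop("unknown chromosome: ", chrom)
  start <- as.integer(center) - length %/% 2L  # 0-based
  end <- start + length                        # exclusive
  if (start < 0L || end > nchar(s))
    stop("window [", start, ",", end, ") off chromosome ", chrom)
  substr(s, start + 1L, end)
}

#' Reverse complement of a DNA string
#' @param sequence Character scalar.
#' @return Reverse complement (N maps to N).
#' @export
reverse_complement <- function(sequence) {
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(toupper(sequence), "",
         fixed = TRUE)[[1]]), collapse = ""))
}

# intervals (0-based half-open) -> IRanges (1-based closed)
.as_iranges <- function(df) {
  IRanges::IRanges(start = df$start + 1L, end = df$end)
}

# per-chromosome merged intersection of two interval sets;
# returns data.frame chrom/start/end (0-based half-open)
.intersect_intervals <- function(a, b) {
  chroms <- intersect(unique(a$chrom), unique(b$chrom))
  out <- lapply(chroms, function(ch) {
    ra <- IRanges::reduce(.as_iranges(a[a$chrom == ch, , drop = FALSE]))
    rb <- IRanges::reduce(.as_iranges(b[b$chrom == ch, , drop = FALSE]))
    ri <- IRanges::intersect(ra, rb)
    if (length(ri) == 0) return(NULL)
    data.frame(chrom = ch, start = IRanges::start(ri) - 1L,
               end = IRanges::end(ri), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(chrom = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE)
  out[order(out$chrom, out$start), , drop = FALSE]
}

# merge overlapping intervals within a data.frame
.reduce_intervals <- function(df) {
  if (nrow(df) == 0) return(df[, c("chrom", "start", "end")])
  out <- lapply(split(df, df$chrom), function(d) {
    r <- IRanges::reduce(.as_iranges(d))
    data.frame(chrom = d$chrom[1], start = IRanges::start(r) - 1L,
               end = IRanges::end(r), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$chrom, out$start), , drop = FALSE]
}

# TRUE for each point (chrom, pos0) falling inside any interval (half-open)
.point_in_intervals <- function(chrom, pos0, intervals) {
  res <- logical(length(chrom))
  for (ch in unique(chrom)) {
    iv <- intervals[intervals$chrom == ch, , drop = FALSE]
    sel <- chrom == ch
    if (nrow(iv) == 0) { res[sel] <- FALSE; next }
    q <- IRanges::IRanges(start = pos0[sel] + 1L, width = 1L)
    res[sel] <- IRanges::overlapsAny(q, .as_iranges(iv))
  }
  res
}
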