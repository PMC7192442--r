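# Hybrid per-nucleotide encoding: a token sequence over the IUPAC alphabet
# paired with the per-million-normalized ATAC depth at every position of the
# evaluation window.

#' The nucleotide token vocabulary
#'
#' Ordered symbol list used by the embedding layer: a padding token at index
#' 0 (used for positions past the contig end) followed by the 15 IUPAC
#' nucleotide codes.
#'
#' @return a named integer vector mapping symbol to token index (0-based).
#' @export
iupac_vocabulary <- function() {
  syms <- c("PAD", "A", "C", "G", "T", "N", "R", "Y", "S", "W", "K", "M",
            "B", "D", "H", "V")
  stats::setNames(seq_along(syms) - 1L, syms)
}

# 256-entry lookup from character code to token index; unknowns are NA and
# remapped to N by tokenize().
.token_lut <- local({
  lut <- rep(NA_integer_, 256)
  vocab <- c(A = 1L, C = 2L, G = 3L, T = 4L, N = 5L, R = 6L, Y = 7L,
             S = 8L, W = 9L, K = 10L, M = 11L, B = 12L, D = 13L, H = 14L,
             V = 15L)
  for (s in names(vocab)) {
    lut[utf8ToInt(s)] <- vocab[[s]]
    lut[utf8ToInt(tolower(s))] <- vocab[[s]]
  }
  lut
})

#' Tokenize a nucleotide sequence
#'
#' Maps each character (case-insensitively) to its vocabulary index.
#' Characters outside the IUPAC alphabet are mapped to `N`'s index with a
#' warning.
#'
#' @param sequence a single nucleotide string.
#' @return an integer vector of token indices, same length as the sequence.
#' @export
tokenize <- function(sequence) {
  if (nchar(sequence) == 0) return(integer(0))
  codes <- utf8ToInt(sequence)
  tok <- .token_lut[codes]
  if (anyNA(tok)) {
    warning(sum(is.na(tok)), " non-IUPAC character(s) mapped to N")
    tok[is.na(tok)] <- 5L
  }
  tok
}

#' Encode a corpus's evaluation windows as a hybrid dataset
#'
#' For every OCR window, pairs the tokenized genomic sequence with the
#' per-bp normalized ATAC depth.  Positions past the contig end get the
#' padding token (index 0) and zero signal, so every record has exactly the
#' window width.
#'
#' @param corpus a [build_corpus()] result.
#' @param genome an indexed FASTA path, [Rsamtools::FaFile] or
#'   [Biostrings::DNAStringSet].
#' @return an object of class `hybrid_dataset`: a list with `tokens`
#'   (integer matrix, width x n), `signal` (numeric matrix, width x n),
#'   `label` (integer 0/1 vector; 1 = positive) and `meta` (a data.frame
#'   with cell type, chromosome and window coordinates).
#' @export
encode_windows <- function(corpus, genome) {
  stopifnot(inherits(corpus, "cell_corpus"))
  if (!corpus$track$normalized) stop("corpus track must be normalized")
  windows <- corpus$windows
  n <- length(windows)
  W <- if (n) unique(GenomicRanges::width(windows)) else 0L
  seqs <- fetch_sequence(genome, windows)
  tokens <- matrix(0L, nrow = W, ncol = n)
  if (n) tokens[] <- vapply(seqs, tokenize, integer(W), USE.NAMES = FALSE)
  signal <- window_signal_matrix(corpus$track, windows)
  # beyond-contig positions: padding token and (already) zero signal
  if (is.character(genome)) genome <- Rsamtools::FaFile(genome)
  sl <- if (methods::is(genome, "DNAStringSet")) {
    stats::setNames(Biostrings::width(genome), names(genome))
  } else {
    GenomeInfoDb::seqlengths(GenomeInfoDb::seqinfo(genome))
  }
  clen <- unname(sl[as.character(GenomicRanges::seqnames(windows))])
  over <- which(GenomicRanges::end(windows) > clen)
  for (i in over) {
    pad_from <- clen[i] - GenomicRanges::start(windows)[i] + 2L
    tokens[max(pad_from, 1L):W, i] <- 0L
    signal[max(pad_from, 1L):W, i] <- 0
  }
  label <- as.integer(corpus$ocrs$label == "positive")
  meta <- data.frame(
    cell_type = rep(corpus$cell_type, n),
    chrom = as.character(GenomicRanges::seqnames(windows)),
    win_start = GenomicRanges::start(windows) - 1L,  # 0-based half-open
    win_end = GenomicRanges::end(windows),
    tss_overlap = corpus$ocrs$tss_overlap,
    mean_atac_signal = corpus$ocrs$mean_atac_signal,
    stringsAsFactors = FALSE)
  structure(list(tokens = tokens, signal = signal, label = label,
                 meta = meta),
            class = "hybrid_dataset")
}

#' @export
print.hybrid_dataset <- function(x, ...) {
  cat("hybrid_dataset:", ncol(x$tokens), "windows of width",
      nrow(x$tokens), "-", sum(x$label == 1L), "positive\n")
  invisible(x)
}

#' Combine hybrid datasets row-wise
#'
#' @param ... `hybrid_dataset` objects with identical window widths.
#' @return a single `hybrid_dataset`.
#' @export
combine_datasets <- function(...) {
  parts <- list(...)
  if (length(parts) == 1 && is.list(parts[[1]]) &&
      !inherits(parts[[1]], "hybrid_dataset"))
    parts <- parts[[1]]
  stopifnot(length(parts) >= 1)
  W <- unique(vapply(parts, function(p) nrow(p$tokens), integer(1)))
  if (length(W) != 1) stop("window widths differ across datasets")
  structure(list(
    tokens = do.call(cbind, lapply(parts, `[[`, "tokens")),
    signal = do.call(cbind, lapply(parts, `[[`, "signal")),
    label = unlist(lapply(parts, `[[`, "label"), use.names = FALSE),
    meta = do.call(rbind, lapply(parts, `[[`, "meta"))),
    class = "hybrid_dataset")
}

#' Subset a hybrid dataset
#'
#' @param x a `hybrid_dataset`.
#' @param i integer or logical index over records.
#' @param ... unused.
#' @return the subsetted `hybrid_dataset`.
#' @export
`[.hybrid_dataset` <- function(x, i, ...) {
  structure(list(tokens = x$tokens[, i, drop = FALSE],
                 signal = x$signal[, i, drop = FALSE],
                 label = x$label[i],
                 meta = x$meta[i, , drop = FALSE]),
            class = "hybrid_dataset")
}

.vocab_symbols <- c("PAD", "A", "C", "G", "T", "N", "R", "Y", "S", "W",
                    "K", "M", "B", "D", "H", "V")

#' Serialize an encoded dataset to a columnar text file
#'
#' One record per line: cell type, chromosome, 0-based window start/end,
#' label, the token string (padding written as `.`), and the comma-separated
#' signal vector.  Readable back with [read_encoded()] without access to the
#' genome.
#'
#' @param dataset a `hybrid_dataset`.
#' @param path output file path.
#' @param digits decimal digits kept for the signal values.
#' @return `path`, invisibly.
#' @export
write_encoded <- function(dataset, path, digits = 5) {
  chars <- c(".", "A", "C", "G", "T", "N", "R", "Y", "S", "W", "K", "M",
             "B", "D", "H", "V")
  n <- ncol(dataset$tokens)
  tok_str <- vapply(seq_len(max(n, 0)), function(i)
    paste(chars[dataset$tokens[, i] + 1L], collapse = ""), character(1))
  sig_str <- vapply(seq_len(max(n, 0)), function(i)
    paste(round(dataset$signal[, i], digits), collapse = ","), character(1))
  dt <- data.table::data.table(
    cell_type = dataset$meta$cell_type, chrom = dataset$meta$chrom,
    win_start = dataset$meta$win_start, win_end = dataset$meta$win_end,
    label = dataset$label, tokens = tok_str, signal = sig_str)
  data.table::fwrite(dt, path, sep = "\t", col.names = TRUE, quote = FALSE)
  invisible(path)
}

#' Read a serialized encoded dataset
#'
#' @param path a file written by [write_encoded()].
#' @return a `hybrid_dataset`.
#' @export
read_encoded <- function(path) {
  dt <- data.table::fread(path, header = TRUE, sep = "\t",
                          colClasses = list(character = c("cell_type", "chrom",
                                                          "tokens", "signal")))
  n <- nrow(dt)
  W <- if (n) nchar(dt$tokens[1]) else 0L
  chars <- c(".", "A", "C", "G", "T", "N", "R", "Y", "S", "W", "K", "M",
             "B", "D", "H", "V")
  lut <- rep(NA_integer_, 256)
  for (i in seq_along(chars)) lut[utf8ToInt(chars[i])] <- i - 1L
  tokens <- matrix(0L, nrow = W, ncol = n)
  signal <- matrix(0, nrow = W, ncol = n)
  for (i in seq_len(n)) {
    tokens[, i] <- lut[utf8ToInt(dt$tokens[i])]
    signal[, i] <- as.numeric(strsplit(dt$signal[i], ",", fixed = TRUE)[[1]])
  }
  meta <- data.frame(cell_type = dt$cell_type, chrom = dt$chrom,
                     win_start = dt$win_start, win_end = dt$win_end,
                     stringsAsFactors = FALSE)
  structure(list(tokens = tokens, signal = signal,
                 label = as.integer(dt$label), meta = meta),
            class = "hybrid_dataset")
}
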