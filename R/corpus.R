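# Corpus construction: from per-replicate peak calls and coverage to a
# labeled set of OCRs with fixed-width evaluation windows.

#' Reads-per-million normalize a coverage track
#'
#' Multiplies every per-bp depth by `1e6 / total_mapped_reads`.
#'
#' @param track a raw [coverage_track()].
#' @return the normalized track (`normalized = TRUE`).
#' @export
normalize_track <- function(track) {
  stopifnot(inherits(track, "coverage_track"))
  if (track$normalized) stop("track is already normalized")
  if (track$total_mapped_reads <= 0)
    stop("total_mapped_reads must be positive to normalize")
  track$cov <- track$cov * (1e6 / track$total_mapped_reads)
  track$normalized <- TRUE
  track
}

# Pad every chromosome's run-length vector with zeros up to `lengths[chrom]`,
# adding all-zero chromosomes that are missing entirely.
.pad_cov <- function(cov, lengths) {
  out <- lapply(names(lengths), function(chrom) {
    want <- lengths[[chrom]]
    if (chrom %in% names(cov)) {
      r <- cov[[chrom]]
      if (length(r) < want) r <- c(r, S4Vectors::Rle(0, want - length(r)))
      r
    } else {
      S4Vectors::Rle(0, want)
    }
  })
  do.call(IRanges::RleList, stats::setNames(out, names(lengths)))
}

.cov_lengths <- function(covs) {
  all <- unique(unlist(lapply(covs, names)))
  sapply(all, function(chrom)
    max(vapply(covs, function(cv)
      if (chrom %in% names(cv)) length(cv[[chrom]]) else 0L, numeric(1))))
}

#' Average several normalized coverage tracks position-wise
#'
#' At every nucleotide the output depth is the arithmetic mean of the input
#' depths, with a track that has no run at a position contributing zero (the
#' denominator is always the number of tracks).  The result carries the
#' sentinel `total_mapped_reads = 0` and stays `normalized = TRUE`.
#'
#' @param tracks a list of normalized [coverage_track()]s.
#' @return a [coverage_track()].
#' @export
average_tracks <- function(tracks) {
  stopifnot(length(tracks) >= 1)
  if (!all(vapply(tracks, function(t) isTRUE(t$normalized), logical(1))))
    stop("all tracks must be normalized before averaging")
  lens <- .cov_lengths(lapply(tracks, `[[`, "cov"))
  total <- .pad_cov(tracks[[1]]$cov, lens)
  for (t in tracks[-1]) total <- total + .pad_cov(t$cov, lens)
  coverage_track(total / length(tracks), total_mapped_reads = 0,
                 normalized = TRUE, strand = tracks[[1]]$strand)
}

# Position-wise sum of coverage (used to combine nascent strands).
.sum_tracks <- function(tracks) {
  lens <- .cov_lengths(lapply(tracks, `[[`, "cov"))
  total <- .pad_cov(tracks[[1]]$cov, lens)
  for (t in tracks[-1]) total <- total + .pad_cov(t$cov, lens)
  coverage_track(total, 0, normalized = tracks[[1]]$normalized, strand = "*")
}

#' Union of replicate peak calls
#'
#' Returns the minimal sorted set of disjoint intervals covering exactly
#' the union of all input peaks: maximal runs of covered bases.  Peaks
#' separated by even a 1 bp gap stay distinct; abutting peaks form one
#' covered run and therefore one OCR.
#'
#' @param peak_sets a list of `GRanges`, one per replicate (SRR).
#' @return a `GRanges` sorted by (chromosome, start), no metadata.
#' @export
union_peaks <- function(peak_sets) {
  stopifnot(is.list(peak_sets), length(peak_sets) >= 1)
  all <- do.call(c, lapply(peak_sets, GenomicRanges::granges))
  all <- GenomeInfoDb::sortSeqlevels(all)  # order-independent output
  GenomicRanges::reduce(GenomicRanges::sort(all), ignore.strand = TRUE)
}

#' Fixed-width evaluation window centered on each OCR
#'
#' The window of width `W` (default 1 kbp) is centered on the OCR midpoint:
#' in 0-based half-open coordinates the center is `floor((start + end) / 2)`
#' and the window spans `[center - W/2, center + W/2)`.  Windows that would
#' start before the chromosome are shifted right to start at 0, preserving
#' width; overhang past the contig end is handled downstream by padding.
#'
#' @param ocrs a `GRanges` of OCR intervals.
#' @param W even window width in bp.
#' @return a `GRanges` of width-`W` windows, parallel to `ocrs`.
#' @export
make_window <- function(ocrs, W = 1000L) {
  stopifnot(W %% 2 == 0, W > 0)
  c0 <- (GenomicRanges::start(ocrs) - 1L + GenomicRanges::end(ocrs)) %/% 2L
  start1 <- c0 - W %/% 2L + 1L           # 1-based window start
  start1 <- pmax(start1, 1L)             # left-clamp, width preserved
  GenomicRanges::GRanges(GenomicRanges::seqnames(ocrs),
                         IRanges::IRanges(start = start1, width = W))
}

#' Label OCRs by overlap with nascent-transcription calls
#'
#' An OCR is `"positive"` if its interval (not its window) overlaps, by at
#' least one base, any active-transcription call or any bidirectional-
#' transcript call; `"negative"` otherwise.  Adding call regions can only
#' turn negatives positive.
#'
#' @param ocrs a `GRanges` of OCR intervals.
#' @param fstitch_regions `GRanges` of active-transcription segment calls.
#' @param tfit_regions `GRanges` of bidirectional-transcript calls.
#' @return a factor with levels `positive`, `negative`, parallel to `ocrs`.
#' @export
label_ocrs <- function(ocrs, fstitch_regions, tfit_regions) {
  # call sets may legitimately cover disjoint chromosome subsets; the
  # seqlevel-merge warnings from combining them carry no information here
  calls <- suppressWarnings(c(GenomicRanges::granges(fstitch_regions),
                              GenomicRanges::granges(tfit_regions)))
  hit <- suppressWarnings(
    GenomicRanges::countOverlaps(ocrs, calls, minoverlap = 1L,
                                 ignore.strand = TRUE)) > 0
  factor(ifelse(hit, "positive", "negative"),
         levels = c("positive", "negative"))
}

#' Flag OCRs overlapping annotated transcription start sites
#'
#' @param ocrs a `GRanges` of OCR intervals.
#' @param tss_intervals a `GRanges` of TSS intervals (often 1 bp).
#' @return a logical vector parallel to `ocrs`.
#' @export
flag_tss <- function(ocrs, tss_intervals) {
  if (length(tss_intervals) == 0) return(rep(FALSE, length(ocrs)))
  suppressWarnings(
    GenomicRanges::countOverlaps(ocrs, tss_intervals, minoverlap = 1L,
                                 ignore.strand = TRUE)) > 0
}

#' Per-bp signal matrix over a set of equal-width windows
#'
#' Extracts the coverage track's depth at every position of every window,
#' treating positions outside any run (including past the contig end) as
#' zero.
#'
#' @param track a [coverage_track()].
#' @param windows a `GRanges` of equal-width windows.
#' @return a numeric matrix, `width x n_windows`, columns in window order.
#' @export
window_signal_matrix <- function(track, windows) {
  stopifnot(inherits(track, "coverage_track"))
  W <- unique(GenomicRanges::width(windows))
  if (length(W) > 1) stop("windows must have equal widths")
  n <- length(windows)
  out <- matrix(0, nrow = W, ncol = max(n, 0))
  if (n == 0) return(out)
  chrom <- as.character(GenomicRanges::seqnames(windows))
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    ends <- GenomicRanges::end(windows)[idx]
    need <- max(ends)
    r <- if (ch %in% names(track$cov)) track$cov[[ch]] else S4Vectors::Rle(0, 0)
    if (length(r) < need) r <- c(r, S4Vectors::Rle(0, need - length(r)))
    v <- IRanges::Views(r, start = GenomicRanges::start(windows)[idx],
                        end = ends)
    out[, idx] <- t(as.matrix(v))  # one row per view; all in bounds
  }
  out
}

#' Mean normalized depth over each evaluation window
#'
#' Arithmetic mean of the per-bp depth across the full window width;
#' positions with no coverage run count as zero.
#'
#' @param track a normalized [coverage_track()].
#' @param windows a `GRanges` of windows.
#' @return a numeric vector parallel to `windows`.
#' @export
mean_window_signal <- function(track, windows) {
  stopifnot(inherits(track, "coverage_track"))
  n <- length(windows)
  if (n == 0) return(numeric(0))
  out <- numeric(n)
  chrom <- as.character(GenomicRanges::seqnames(windows))
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    ends <- GenomicRanges::end(windows)[idx]
    need <- max(ends)
    r <- if (ch %in% names(track$cov)) track$cov[[ch]] else S4Vectors::Rle(0, 0)
    if (length(r) < need) r <- c(r, S4Vectors::Rle(0, need - length(r)))
    v <- IRanges::Views(r, start = GenomicRanges::start(windows)[idx],
                        end = ends)
    out[idx] <- IRanges::viewMeans(v)
  }
  out
}

#' Build the labeled OCR corpus for one cell type
#'
#' The full per-cell-type pipeline: blacklist-filter each replicate's peak
#' calls, take the union across replicates to define OCRs, per-million
#' normalize each replicate's coverage and average position-wise, then for
#' every OCR define its centered evaluation window, label it by overlap with
#' the transcription calls, flag TSS overlap, and record the mean normalized
#' ATAC depth (and, when nascent coverage is supplied, the mean nascent
#' depth) over the window.
#'
#' @param peak_sets list of `GRanges`, one per replicate (SRR).
#' @param tracks list of raw [coverage_track()]s, parallel to `peak_sets`.
#' @param cell_type cell-type name.
#' @param fstitch_regions,tfit_regions transcription-call `GRanges` (see
#'   [label_ocrs()]).
#' @param tss optional TSS `GRanges`.
#' @param blacklist optional excluded-region `GRanges`.
#' @param nascent_tracks optional list of raw nascent [coverage_track()]s
#'   (e.g. plus and minus strand); they are normalized, summed across
#'   strands, and averaged into `mean_nascent_signal`.
#' @param W evaluation-window width in bp.
#' @return an object of class `cell_corpus`: a list with elements
#'   `cell_type`, `ocrs` (a `GRanges` with metadata columns `label`,
#'   `tss_overlap`, `mean_atac_signal`, `mean_nascent_signal`), `windows`
#'   (a parallel width-`W` `GRanges`), `track` (the combined normalized
#'   coverage), `nascent_track` (or `NULL`) and `n_srrs`.
#' @export
build_corpus <- function(peak_sets, tracks, cell_type,
                         fstitch_regions, tfit_regions,
                         tss = NULL, blacklist = NULL,
                         nascent_tracks = NULL, W = 1000L) {
  stopifnot(is.list(peak_sets), is.list(tracks))
  if (length(peak_sets) != length(tracks))
    stop("each peak set needs a matching coverage track (",
         length(peak_sets), " peak sets vs ", length(tracks), " tracks)")
  if (length(peak_sets) == 0) stop("at least one replicate is required")

  if (!is.null(blacklist)) {
    n_before <- sum(vapply(peak_sets, length, integer(1)))
    peak_sets <- lapply(peak_sets, subtract_blacklist, blacklist = blacklist)
    n_after <- sum(vapply(peak_sets, length, integer(1)))
    if (n_before > n_after)
      message(n_before - n_after, " replicate peaks dropped by blacklist")
  }
  ocrs <- union_peaks(peak_sets)
  combined <- average_tracks(lapply(tracks, normalize_track))
  windows <- make_window(ocrs, W = W)
  ocrs$label <- label_ocrs(ocrs, fstitch_regions, tfit_regions)
  ocrs$tss_overlap <- flag_tss(ocrs, if (is.null(tss)) GenomicRanges::GRanges() else tss)
  ocrs$mean_atac_signal <- mean_window_signal(combined, windows)
  nascent <- NULL
  if (!is.null(nascent_tracks) && length(nascent_tracks) > 0) {
    nascent <- .sum_tracks(lapply(nascent_tracks, normalize_track))
    ocrs$mean_nascent_signal <- mean_window_signal(nascent, windows)
  } else {
    ocrs$mean_nascent_signal <- NA_real_
  }
  message(cell_type, ": ", length(ocrs), " OCRs (",
          sum(ocrs$label == "positive"), " positive)")
  structure(list(cell_type = cell_type, ocrs = ocrs, windows = windows,
                 track = combined, nascent_track = nascent,
                 n_srrs = length(peak_sets)),
            class = "cell_corpus")
}

#' @export
print.cell_corpus <- function(x, ...) {
  cat("cell_corpus:", x$cell_type, "-", length(x$ocrs), "OCRs,",
      sum(x$ocrs$label == "positive"), "positive,",
      x$n_srrs, "replicate(s)\n")
  invisible(x)
}

#' Export a corpus to plain-text files
#'
#' Writes a BED6+ table of evaluation windows (chrom, window start/end,
#' label, mean ATAC signal, cell type, TSS flag; 0-based half-open) and the
#' combined normalized coverage as bedGraph.
#'
#' @param corpus a [build_corpus()] result.
#' @param dir output directory (created if needed).
#' @return named character vector of the written paths, invisibly.
#' @export
write_corpus <- function(corpus, dir) {
  stopifnot(inherits(corpus, "cell_corpus"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  bed <- file.path(dir, paste0(corpus$cell_type, "_ocrs.bed"))
  bg <- file.path(dir, paste0(corpus$cell_type, "_combined.bedGraph"))
  dt <- data.table::data.table(
    chrom = as.character(GenomicRanges::seqnames(corpus$windows)),
    start = GenomicRanges::start(corpus$windows) - 1L,
    end = GenomicRanges::end(corpus$windows),
    label = as.character(corpus$ocrs$label),
    mean_signal = corpus$ocrs$mean_atac_signal,
    cell_type = corpus$cell_type,
    tss = as.integer(corpus$ocrs$tss_overlap))
  data.table::fwrite(dt, bed, sep = "\t", col.names = FALSE, quote = FALSE)
  write_bedgraph(corpus$track, bg)
  invisible(c(ocrs = bed, coverage = bg))
}
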