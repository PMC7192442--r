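#' @useDynLib peaktx, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @import methods
NULL

# Internal coordinate convention: every GRanges in this package is 1-based
# closed (the Bioconductor convention).  All file formats handled here (BED,
# narrowPeak, bedGraph) are 0-based half-open on disk; readers add 1 to the
# start, writers subtract it.  Overlap means an intersection of >= 1 bp, so
# touching intervals ([a,b) next to [b,c) on disk) never overlap.

.default_chromosomes <- function() c(paste0("chr", 1:22), "chrX", "chrY")

# Drop records on chromosomes outside `chromosomes` (e.g. chrM, scaffolds),
# with a message stating how many were ignored.  NULL keeps everything.
.filter_chromosomes <- function(gr, chromosomes, what = "records") {
  if (is.null(chromosomes)) return(gr)
  keep <- as.character(GenomicRanges::seqnames(gr)) %in% chromosomes
  if (!all(keep)) {
    message(sum(!keep), " ", what,
            " on chromosomes outside the configured list ignored")
    gr <- gr[keep]
    GenomeInfoDb::seqlevels(gr) <- intersect(GenomeInfoDb::seqlevels(gr),
                                             unique(as.character(GenomicRanges::seqnames(gr))))
  }
  gr
}

.check_coords <- function(start0, end0, path) {
  if (anyNA(start0) || anyNA(end0)) {
    bad <- which(is.na(start0) | is.na(end0))[1]
    stop("non-integer coordinate at line ", bad, " of ", path)
  }
  if (any(end0 <= start0)) {
    bad <- which(end0 <= start0)[1]
    stop("start >= end at line ", bad, " of ", path)
  }
  if (any(start0 < 0)) {
    bad <- which(start0 < 0)[1]
    stop("negative start at line ", bad, " of ", path)
  }
  invisible(TRUE)
}

#' Read a MACS2 narrowPeak (or plain BED) file of peak calls
#'
#' Parses the ENCODE 10-column narrowPeak format.  Files with only the first
#' 6 BED columns are accepted, with the narrowPeak-specific fields defaulted
#' (`signal_value = 0`, `p_value = q_value = -1`, `summit_offset = -1`).
#' Coordinates are converted from the file's 0-based half-open convention to
#' a 1-based closed [GenomicRanges::GRanges]; input order is preserved.
#'
#' @param path path to a narrowPeak/BED file (tab-separated, no header).
#' @param chromosomes character vector of chromosome names to keep, or `NULL`
#'   to keep all.  Records on other chromosomes (chrM, unplaced scaffolds) are
#'   dropped with a message.
#' @return a `GRanges` with metadata columns `name`, `score`, `signal_value`,
#'   `p_value`, `q_value` and `summit_offset` (offset from peak start, or -1
#'   when absent).
#' @export
read_narrowpeak <- function(path, chromosomes = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0) return(.empty_peaks())
  dt <- data.table::fread(path, header = FALSE, sep = "\t", fill = TRUE,
                          colClasses = list(character = 1))
  nc <- ncol(dt)
  if (nc < 6 && nc != 3)
    stop("expected >= 6 (or 3) tab-separated columns in ", path,
         ", found ", nc)
  start0 <- suppressWarnings(as.integer(dt[[2]]))
  end0   <- suppressWarnings(as.integer(dt[[3]]))
  .check_coords(start0, end0, path)
  n <- nrow(dt)
  col <- function(i, default) if (nc >= i) dt[[i]] else rep(default, n)
  strand <- as.character(col(6, "."))
  strand[!strand %in% c("+", "-")] <- "*"
  gr <- GenomicRanges::GRanges(
    seqnames = dt[[1]],
    ranges = IRanges::IRanges(start = start0 + 1L, end = end0),
    strand = strand,
    name = as.character(col(4, ".")),
    score = as.integer(col(5, 0L)),
    signal_value = as.numeric(col(7, 0)),
    p_value = as.numeric(col(8, -1)),
    q_value = as.numeric(col(9, -1)),
    summit_offset = as.integer(col(10, -1L)))
  bad <- which(gr$summit_offset != -1L &
               (gr$summit_offset < 0L |
                gr$summit_offset >= GenomicRanges::width(gr)))
  if (length(bad))
    stop("summit offset outside peak at line ", bad[1], " of ", path)
  .filter_chromosomes(gr, chromosomes, "peaks")
}

.empty_peaks <- function() {
  gr <- GenomicRanges::GRanges()
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    name = character(), score = integer(), signal_value = numeric(),
    p_value = numeric(), q_value = numeric(), summit_offset = integer())
  gr
}

#' Write peaks as a 10-column narrowPeak file
#'
#' The inverse of [read_narrowpeak()]: coordinates go back to 0-based
#' half-open, fields are tab-separated, lines newline-terminated, no header.
#'
#' @param peaks a `GRanges`, ideally with the metadata columns produced by
#'   [read_narrowpeak()]; missing columns are defaulted.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_narrowpeak <- function(peaks, path) {
  n <- length(peaks)
  mc <- S4Vectors::mcols(peaks)
  pick <- function(nm, default) if (nm %in% names(mc)) mc[[nm]] else rep(default, n)
  strand <- as.character(GenomicRanges::strand(peaks))
  strand[strand == "*"] <- "."
  dt <- data.table::data.table(
    chrom = as.character(GenomicRanges::seqnames(peaks)),
    start = GenomicRanges::start(peaks) - 1L,
    end = GenomicRanges::end(peaks),
    name = pick("name", "."),
    score = pick("score", 0L),
    strand = strand,
    signal_value = pick("signal_value", 0),
    p_value = pick("p_value", -1),
    q_value = pick("q_value", -1),
    summit_offset = pick("summit_offset", -1L))
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a BED3/BED6 file of genomic intervals
#'
#' @inheritParams read_narrowpeak
#' @return a `GRanges` (with `name` and `score` columns when the file has
#'   6 columns).
#' @export
read_bed <- function(path, chromosomes = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0) return(GenomicRanges::GRanges())
  dt <- data.table::fread(path, header = FALSE, sep = "\t", fill = TRUE,
                          colClasses = list(character = 1))
  start0 <- suppressWarnings(as.integer(dt[[2]]))
  end0   <- suppressWarnings(as.integer(dt[[3]]))
  .check_coords(start0, end0, path)
  gr <- GenomicRanges::GRanges(dt[[1]],
                               IRanges::IRanges(start0 + 1L, end0))
  if (ncol(dt) >= 6) {
    strand <- as.character(dt[[6]])
    strand[!strand %in% c("+", "-")] <- "*"
    GenomicRanges::strand(gr) <- strand
  }
  if (ncol(dt) >= 4) gr$name <- as.character(dt[[4]])
  if (ncol(dt) >= 5) gr$score <- suppressWarnings(as.numeric(dt[[5]]))
  .filter_chromosomes(gr, chromosomes, "intervals")
}

#' Write intervals as BED
#'
#' Emits BED3 or, when `name`/`score`/strand information is present, BED6.
#' Coordinates are written 0-based half-open.
#'
#' @param gr a `GRanges`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(gr, path) {
  dt <- data.table::data.table(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr))
  mc <- S4Vectors::mcols(gr)
  strand <- as.character(GenomicRanges::strand(gr))
  if ("name" %in% names(mc) || "score" %in% names(mc) || any(strand != "*")) {
    strand[strand == "*"] <- "."
    dt$name <- if ("name" %in% names(mc)) mc$name else "."
    dt$score <- if ("score" %in% names(mc)) mc$score else 0
    dt$strand <- strand
  }
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Construct a per-nucleotide coverage track
#'
#' A coverage track is a run-length encoded per-chromosome depth map
#' (an [IRanges::RleList]) together with the library's total mapped read
#' count, a flag saying whether depths have been reads-per-million
#' normalized, and the strand the track belongs to (`"*"` for unstranded
#' ATAC coverage, `"+"`/`"-"` for stranded nascent coverage).
#'
#' @param cov an `RleList` of non-negative per-bp depths, one element per
#'   chromosome.
#' @param total_mapped_reads positive integer; 0 is the sentinel used for
#'   derived (averaged) tracks.
#' @param normalized logical; `TRUE` once depths are reads-per-million.
#' @param strand one of `"*"`, `"+"`, `"-"`.
#' @return an object of class `coverage_track`.
#' @export
coverage_track <- function(cov, total_mapped_reads, normalized = FALSE,
                           strand = "*") {
  stopifnot(methods::is(cov, "RleList"),
            length(total_mapped_reads) == 1, total_mapped_reads >= 0,
            strand %in% c("*", "+", "-"))
  structure(list(cov = cov,
                 total_mapped_reads = as.double(total_mapped_reads),
                 normalized = isTRUE(normalized),
                 strand = strand),
            class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat("coverage_track:", length(x$cov), "chromosomes;",
      if (x$normalized) "per-million normalized;" else "raw;",
      "total mapped reads:", format(x$total_mapped_reads, big.mark = ","),
      "; strand:", x$strand, "\n")
  invisible(x)
}

#' Read a 4-column bedGraph coverage file
#'
#' Runs must be non-overlapping; positions absent from every run have depth
#' zero.  Negative values are only accepted with `allow_negative = TRUE`
#' (the common convention for minus-strand nascent coverage); their absolute
#' value is stored and the track's strand is set to `"-"` unless another
#' strand is given.
#'
#' @param path path to the bedGraph file.
#' @param total_mapped_reads positive integer, the library size used later
#'   for per-million normalization.
#' @param allow_negative logical; accept negative depth values (stored as
#'   absolute values).
#' @param strand strand to record on the track; defaults to `"-"` when
#'   negative values are allowed, else `"*"`.
#' @param seqlengths optional named integer vector of chromosome lengths,
#'   used to size the run-length vectors (so downstream window extraction
#'   sees explicit zeros up to the contig end).
#' @param chromosomes see [read_narrowpeak()].
#' @return a [coverage_track()] with `normalized = FALSE`.
#' @export
read_bedgraph <- function(path, total_mapped_reads, allow_negative = FALSE,
                          strand = if (allow_negative) "-" else "*",
                          seqlengths = NULL, chromosomes = NULL) {
  if (length(total_mapped_reads) != 1 || is.na(total_mapped_reads) ||
      total_mapped_reads <= 0)
    stop("total_mapped_reads must be a positive integer")
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) > 0) {
    dt <- data.table::fread(path, header = FALSE, sep = "\t",
                            colClasses = list(character = 1))
    if (ncol(dt) != 4) stop("expected 4 bedGraph columns in ", path)
    start0 <- suppressWarnings(as.integer(dt[[2]]))
    end0 <- suppressWarnings(as.integer(dt[[3]]))
    .check_coords(start0, end0, path)
    value <- as.numeric(dt[[4]])
    if (any(value < 0)) {
      if (!allow_negative)
        stop("negative depth at line ", which(value < 0)[1], " of ", path,
             " (use allow_negative = TRUE for minus-strand coverage)")
      value <- abs(value)
    }
    gr <- GenomicRanges::GRanges(dt[[1]], IRanges::IRanges(start0 + 1L, end0),
                                 value = value)
    gr <- .filter_chromosomes(gr, chromosomes, "bedGraph runs")
    hits <- GenomicRanges::findOverlaps(gr, drop.self = TRUE,
                                        drop.redundant = TRUE)
    if (length(hits) > 0)
      stop("overlapping bedGraph runs in ", path, " (e.g. records ",
           S4Vectors::queryHits(hits)[1], " and ",
           S4Vectors::subjectHits(hits)[1], ")")
  } else {
    gr <- GenomicRanges::GRanges(value = numeric())
  }
  if (!is.null(seqlengths)) {
    sl <- seqlengths
    extra <- setdiff(GenomeInfoDb::seqlevels(gr), names(sl))
    if (length(extra))
      stop("bedGraph chromosome(s) absent from seqlengths: ",
           paste(extra, collapse = ", "))
    GenomeInfoDb::seqlevels(gr) <- names(sl)
    GenomeInfoDb::seqlengths(gr) <- sl
  }
  cov <- GenomicRanges::coverage(gr, weight = gr$value)
  # weighted coverage can leave -1e-16-scale float residue where runs abut
  rv <- S4Vectors::runValue(cov)
  rv[rv < 0] <- 0
  S4Vectors::runValue(cov) <- rv
  coverage_track(cov, total_mapped_reads, normalized = FALSE, strand = strand)
}

#' Write a coverage track as bedGraph
#'
#' Zero-depth runs are omitted, matching the sparse bedGraph convention.
#' Minus-strand tracks are written with negative values so that the file
#' round-trips through `read_bedgraph(..., allow_negative = TRUE)`.
#'
#' @param track a [coverage_track()].
#' @param path output file path.
#' @param digits number of decimal digits for depth values.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path, digits = 4) {
  stopifnot(inherits(track, "coverage_track"))
  pieces <- lapply(names(track$cov), function(chrom) {
    r <- track$cov[[chrom]]
    ends <- cumsum(S4Vectors::runLength(r))
    starts <- c(0L, ends[-length(ends)])
    vals <- S4Vectors::runValue(r)
    keep <- vals != 0
    if (!any(keep)) return(NULL)
    data.table::data.table(chrom = chrom, start = starts[keep],
                           end = ends[keep],
                           value = round(vals[keep], digits))
  })
  dt <- data.table::rbindlist(pieces)
  if (nrow(dt) && track$strand == "-") dt$value <- -dt$value
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Fetch genomic sequence for a set of intervals
#'
#' Sequence is always read from the plus strand and uppercased (soft-masked
#' lowercase bases are folded).  Positions beyond the contig end (or before
#' its start) are padded with `'N'` so the returned strings always have the
#' interval's width.
#'
#' @param genome an [Rsamtools::FaFile], a path to an indexed FASTA, or a
#'   [Biostrings::DNAStringSet].
#' @param intervals a `GRanges`.
#' @return a character vector of uppercase sequences, one per interval.
#' @export
fetch_sequence <- function(genome, intervals) {
  if (is.character(genome)) genome <- Rsamtools::FaFile(genome)
  sl <- if (methods::is(genome, "DNAStringSet")) {
    stats::setNames(Biostrings::width(genome), names(genome))
  } else {
    GenomeInfoDb::seqlengths(GenomeInfoDb::seqinfo(genome))
  }
  chrom <- as.character(GenomicRanges::seqnames(intervals))
  unknown <- setdiff(unique(chrom), names(sl))
  if (length(unknown))
    stop("chromosome(s) not in genome: ", paste(unknown, collapse = ", "))
  len <- unname(sl[chrom])
  s <- GenomicRanges::start(intervals)
  e <- GenomicRanges::end(intervals)
  cs <- pmax(s, 1L)
  ce <- pmin(e, len)
  empty <- ce < cs  # interval entirely outside the contig
  res <- character(length(s))
  res[empty] <- strrep("N", (e - s + 1L)[empty])
  if (any(!empty)) {
    seqs <- if (methods::is(genome, "DNAStringSet")) {
      as.character(Biostrings::subseq(genome[chrom[!empty]],
                                      start = cs[!empty], end = ce[!empty]))
    } else {
      clamped <- GenomicRanges::GRanges(chrom[!empty],
        IRanges::IRanges(start = cs[!empty], end = ce[!empty]))
      as.character(Biostrings::getSeq(genome, clamped))
    }
    res[!empty] <- paste0(strrep("N", (cs - s)[!empty]), seqs,
                          strrep("N", (e - ce)[!empty]))
  }
  toupper(res)
}

#' Drop peaks overlapping blacklist regions
#'
#' Whole-record removal (the `-v` semantics of interval intersection): a peak
#' is kept only if it overlaps no blacklist interval by even a single base.
#' Touching intervals do not overlap.  Input order is preserved and the
#' operation is idempotent.
#'
#' @param peaks a `GRanges` of peak calls.
#' @param blacklist a `GRanges` of excluded regions.
#' @return the subset of `peaks` with zero blacklist overlap.
#' @export
subtract_blacklist <- function(peaks, blacklist) {
  if (length(blacklist) == 0 || length(peaks) == 0) return(peaks)
  peaks[suppressWarnings(
    GenomicRanges::countOverlaps(peaks, blacklist, minoverlap = 1L)) == 0]
}
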