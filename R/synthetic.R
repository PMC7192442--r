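# Fully self-contained synthetic data: genome FASTA, replicate ATAC peak
# calls and coverage, stranded nascent coverage, transcription-call BEDs,
# TSS BED and a ground-truth table.  The generator plants the three signals
# the classifier is meant to exploit: transcribed OCRs are wider
# (sd_pos > sd_neg), carry a fixed sequence motif at their center, and are
# flanked by opposite-strand nascent bumps; untranscribed OCRs are narrower
# and show background only.

#' Synthetic dataset configuration
#'
#' Defaults define the reference study conditions: a 23-contig genome
#' (chr1-chr22, chrX; 200 kb each), four cell types of ~2,000 OCRs each
#' (three for training/testing plus one validation cell type), 29% positive
#' prevalence, positive ATAC bumps of sd 150 bp vs negative 60 bp, a fixed
#' 8-mer motif planted at 80% of positive centers, and strand-separated
#' nascent bumps offset +/-120 bp from positive centers.
#'
#' OCR loci sit on a per-chromosome lattice of slots with jittered centers,
#' shared across cell types; each cell type possesses each locus with
#' probability `presence_rate`, so expected OCRs per cell type is
#' `n_ocrs_per_cell_type` and loci are shared by varying numbers of cell
#' types.  A locus's label, motif and TSS status are locus-level, so cell
#' types agree at shared loci.
#'
#' @param chromosome_lengths named integer vector of contig lengths.
#' @param cell_types cell-type names; the last is conventionally used for
#'   validation.
#' @param n_ocrs_per_cell_type expected OCR count per cell type.
#' @param presence_rate probability a cell type possesses a given locus.
#' @param positive_prevalence fraction of loci labeled positive.
#' @param sd_pos,sd_neg Gaussian ATAC bump sd (bp) for positive/negative
#'   loci; `sd_pos > sd_neg` is the planted width signal.
#' @param amplitude_pos,amplitude_neg bump peak height in raw reads.
#' @param amplitude_jitter lognormal sd of per-OCR, per-replicate amplitude
#'   variation.
#' @param motif fixed literal motif planted at positive centers.
#' @param p_motif probability a positive locus carries the motif.
#' @param nascent_offset distance (bp) of the two nascent bumps from the
#'   center; the plus-strand bump sits downstream, the minus-strand bump
#'   upstream.
#' @param nascent_sd,nascent_amplitude nascent bump shape parameters.
#' @param background_rate per-bp Poisson rate of ATAC background reads.
#' @param nascent_background_rate per-bp Poisson rate of nascent background.
#' @param n_replicates ATAC replicates (SRRs) per cell type.
#' @param call_jitter uniform jitter (bp) applied to transcription-call
#'   boundaries; 0 makes label recovery exact.
#' @param tss_fraction fraction of loci flagged as TSS.
#' @param center_jitter per-cell-type jitter (bp) of shared locus centers.
#' @param total_reads nominal library size declared per replicate (jittered
#'   +/-10%), used for per-million normalization.
#' @param W evaluation-window width (used only to size lattice slots).
#' @param seed integer seed; generation is fully deterministic given it.
#' @return a list of class `synthetic_config`.
#' @export
synthetic_config <- function(
    chromosome_lengths = stats::setNames(rep(200000L, 23),
                                         c(paste0("chr", 1:22), "chrX")),
    cell_types = c("cellA", "cellB", "cellC", "cellV"),
    n_ocrs_per_cell_type = 2000L,
    presence_rate = 0.8,
    positive_prevalence = 0.29,
    sd_pos = 150, sd_neg = 60,
    amplitude_pos = 50, amplitude_neg = 30,
    amplitude_jitter = 0.2,
    motif = "TTGCGCAA", p_motif = 0.8,
    nascent_offset = 120, nascent_sd = 80, nascent_amplitude = 30,
    background_rate = 0.1, nascent_background_rate = 0.02,
    n_replicates = 2L,
    call_jitter = 0L,
    tss_fraction = 0.3,
    center_jitter = 30L,
    total_reads = 1e7,
    W = 1000L,
    seed = 42L) {
  stopifnot(sd_pos > sd_neg, positive_prevalence > 0, positive_prevalence < 1,
            presence_rate > 0, presence_rate <= 1,
            n_replicates >= 1, length(cell_types) >= 2,
            nchar(motif) >= 1, W %% 2 == 0)
  structure(as.list(environment()), class = "synthetic_config")
}

# Lay out loci on a lattice across chromosomes and draw their latent
# properties (label, motif, transcription-call assignment, TSS flag) plus
# the cell-type presence matrix.  Everything downstream derives from this.
plant_loci <- function(config) {
  chroms <- names(config$chromosome_lengths)
  n_loci <- round(config$n_ocrs_per_cell_type / config$presence_rate)
  chrom_of <- rep(chroms, length.out = n_loci)
  margin <- max(config$W / 2, 4 * config$sd_pos) + 10
  centers <- integer(n_loci)
  for (ch in chroms) {
    idx <- which(chrom_of == ch)
    k <- length(idx)
    if (k == 0) next
    L <- config$chromosome_lengths[[ch]]
    slot <- floor(L / k)
    if (slot < 2 * margin + 2)
      stop("contigs too small for ", n_loci, " loci: slot width ", slot,
           " < ", 2 * margin + 2)
    slot_start <- (seq_len(k) - 1L) * slot
    centers[idx] <- as.integer(slot_start + margin +
                               floor(stats::runif(k) * (slot - 2 * margin)))
  }
  label <- stats::rbinom(n_loci, 1, config$positive_prevalence)
  motif_present <- label == 1 & stats::runif(n_loci) < config$p_motif
  in_fstitch <- label == 1 & stats::runif(n_loci) < 0.85
  in_tfit <- label == 1 & stats::runif(n_loci) < 0.6
  neither <- label == 1 & !in_fstitch & !in_tfit
  in_fstitch[neither] <- TRUE  # every positive is covered by >= 1 tool
  tss <- stats::runif(n_loci) < config$tss_fraction
  presence <- matrix(stats::runif(n_loci * length(config$cell_types)) <
                       config$presence_rate,
                     nrow = length(config$cell_types),
                     dimnames = list(config$cell_types, NULL))
  data.frame(locus_id = seq_len(n_loci), chrom = chrom_of,
             center = centers,  # 1-based center position
             label = ifelse(label == 1, "positive", "negative"),
             motif = motif_present, in_fstitch = in_fstitch,
             in_tfit = in_tfit, tss = tss,
             t(presence), stringsAsFactors = FALSE)
}

# Add Gaussian bumps to a per-bp vector in one pass (one vector copy per
# call, not per bump).
.add_bumps <- function(vec, centers, sds, amps, L) {
  for (k in seq_along(centers)) {
    lo <- max(1L, as.integer(centers[k] - 4 * sds[k]))
    hi <- min(L, as.integer(centers[k] + 4 * sds[k]))
    if (lo > hi) next
    x <- lo:hi
    vec[x] <- vec[x] + amps[k] * exp(-((x - centers[k])^2) / (2 * sds[k]^2))
  }
  vec
}

.write_cov <- function(per_chrom, total_reads, path, strand = "*") {
  cov <- do.call(IRanges::RleList,
                 lapply(per_chrom, function(v) S4Vectors::Rle(round(v, 3))))
  track <- coverage_track(cov, total_reads, normalized = FALSE,
                          strand = strand)
  write_bedgraph(track, path)
}

#' Generate a complete synthetic dataset on disk
#'
#' Writes, under `out_dir`: `genome.fa` (+ index; uniform random bases with
#' motifs planted at positive centers), per cell type and replicate an ATAC
#' `narrowPeak` and `bedGraph`, per cell type strand-separated nascent
#' coverage (`minus` written with negative values), active-transcription
#' (`fstitch`) and bidirectional (`tfit`) call BEDs, a shared `tss.bed`, a
#' `truth.tsv` ground-truth table and a `manifest.tsv` listing every
#' coverage file with its declared total mapped reads.  Byte-identical for
#' a fixed seed.
#'
#' @param config a [synthetic_config()].
#' @param out_dir output directory (created; must be empty or absent).
#' @return a list of class `synthetic_bundle` with `dir`, `config`,
#'   `manifest`, `truth` (per cell type, per OCR: interval, label, motif
#'   and TSS flags) and file paths.
#' @export
generate_dataset <- function(config = synthetic_config(),
                             out_dir = tempfile("synthbundle")) {
  stopifnot(inherits(config, "synthetic_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  .with_seed(config$seed, .generate_impl(config, out_dir))
}

.generate_impl <- function(config, out_dir) {
  chroms <- names(config$chromosome_lengths)
  loci <- plant_loci(config)

  # genome with planted motifs
  seqs <- vapply(chroms, function(ch) {
    paste(sample(c("A", "C", "G", "T"), config$chromosome_lengths[[ch]],
                 replace = TRUE), collapse = "")
  }, character(1))
  mlen <- nchar(config$motif)
  for (i in which(loci$motif)) {
    ch <- loci$chrom[i]
    at <- loci$center[i] - mlen %/% 2L
    substr(seqs[[ch]], at, at + mlen - 1L) <- config$motif
  }
  genome <- Biostrings::DNAStringSet(seqs)
  names(genome) <- chroms
  genome_path <- file.path(out_dir, "genome.fa")
  Biostrings::writeXStringSet(genome, genome_path, width = 80L)
  Rsamtools::indexFa(genome_path)

  manifest <- list()
  truth <- list()
  sd_of <- ifelse(loci$label == "positive", config$sd_pos, config$sd_neg)
  amp_of <- ifelse(loci$label == "positive", config$amplitude_pos,
                   config$amplitude_neg)

  for (cell in config$cell_types) {
    has <- which(loci[[cell]])
    lc <- loci[has, , drop = FALSE]
    n <- nrow(lc)
    center <- lc$center + as.integer(round(stats::runif(
      n, -config$center_jitter, config$center_jitter)))
    sdv <- sd_of[has]
    ampv <- amp_of[has]
    max_hw <- rep(0L, n)

    for (rep_i in seq_len(config$n_replicates)) {
      hw <- as.integer(round(2 * sdv) +
                       round(stats::runif(n, -25, 25)))
      hw <- pmax(hw, 20L)
      max_hw <- pmax(max_hw, hw)
      amp <- ampv * exp(stats::rnorm(n, 0, config$amplitude_jitter))
      # peak calls
      peaks <- GenomicRanges::GRanges(lc$chrom,
        IRanges::IRanges(start = center - hw, end = center + hw),
        name = paste0(cell, "_locus", lc$locus_id),
        score = 0L, signal_value = round(amp, 3), p_value = -1,
        q_value = -1, summit_offset = hw)
      np_path <- file.path(out_dir,
                           sprintf("%s_rep%d.narrowPeak", cell, rep_i))
      write_narrowpeak(GenomicRanges::sort(peaks), np_path)
      # coverage
      per_chrom <- lapply(chroms, function(ch) {
        L <- config$chromosome_lengths[[ch]]
        k <- which(lc$chrom == ch)
        .add_bumps(as.numeric(stats::rpois(L, config$background_rate)),
                   center[k], sdv[k], amp[k], L)
      })
      names(per_chrom) <- chroms
      total <- round(config$total_reads * stats::runif(1, 0.9, 1.1))
      bg_path <- file.path(out_dir,
                           sprintf("%s_rep%d.bedGraph", cell, rep_i))
      .write_cov(per_chrom, total, bg_path)
      manifest[[length(manifest) + 1L]] <- data.frame(
        cell_type = cell, role = "atac", replicate = rep_i, strand = "*",
        file = basename(bg_path), peaks = basename(np_path),
        total_reads = total, stringsAsFactors = FALSE)
    }

    # nascent coverage: bidirectional bumps flanking positive centers
    pos <- lc$label == "positive"
    namp <- config$nascent_amplitude *
      exp(stats::rnorm(n, 0, config$amplitude_jitter))
    for (strand in c("+", "-")) {
      per_chrom <- lapply(chroms, function(ch) {
        L <- config$chromosome_lengths[[ch]]
        k <- which(lc$chrom == ch & pos)
        at <- center[k] + (if (strand == "+") config$nascent_offset
                           else -config$nascent_offset)
        .add_bumps(as.numeric(stats::rpois(L, config$nascent_background_rate)),
                   at, rep(config$nascent_sd, length(k)), namp[k], L)
      })
      names(per_chrom) <- chroms
      total <- round(config$total_reads * stats::runif(1, 0.9, 1.1))
      side <- if (strand == "+") "plus" else "minus"
      ng_path <- file.path(out_dir,
                           sprintf("%s_nascent_%s.bedGraph", cell, side))
      .write_cov(per_chrom, total, ng_path, strand = strand)
      manifest[[length(manifest) + 1L]] <- data.frame(
        cell_type = cell, role = "nascent", replicate = 1L, strand = strand,
        file = basename(ng_path), peaks = NA_character_,
        total_reads = total, stringsAsFactors = FALSE)
    }

    # transcription calls over this cell type's positive OCR intervals
    jit <- function(k) if (config$call_jitter > 0)
      as.integer(round(stats::runif(k, -config$call_jitter,
                                    config$call_jitter))) else integer(k) * 0L
    ocr_start <- center - max_hw
    ocr_end <- center + max_hw
    for (tool in c("fstitch", "tfit")) {
      sel <- pos & lc[[paste0("in_", tool)]]
      k <- sum(sel)
      gr <- GenomicRanges::GRanges(lc$chrom[sel],
        IRanges::IRanges(start = pmax(1L, ocr_start[sel] + jit(k)),
                         end = ocr_end[sel] + jit(k)))
      write_bed(GenomicRanges::sort(gr),
                file.path(out_dir, sprintf("%s_%s.bed", cell, tool)))
    }

    truth[[cell]] <- data.frame(
      cell_type = cell, locus_id = lc$locus_id, chrom = lc$chrom,
      start = ocr_start - 1L,  # 0-based half-open like the BED outputs
      end = ocr_end,
      label = lc$label, motif = lc$motif,
      motif_pos = ifelse(lc$motif, lc$center - mlen %/% 2L - 1L, NA_integer_),
      tss = lc$tss, stringsAsFactors = FALSE)
  }

  # TSS: locus-level center points, plus decoys on slot edges far from OCRs
  tss_gr <- GenomicRanges::GRanges(loci$chrom[loci$tss],
    IRanges::IRanges(start = loci$center[loci$tss], width = 1L))
  decoys <- GenomicRanges::GRanges(chroms[seq_len(min(20, length(chroms)))],
    IRanges::IRanges(start = 10L, width = 1L))
  tss_path <- file.path(out_dir, "tss.bed")
  write_bed(GenomicRanges::sort(c(tss_gr, decoys)), tss_path)

  manifest <- do.call(rbind, manifest)
  truth <- do.call(rbind, truth)
  rownames(truth) <- NULL
  data.table::fwrite(manifest, file.path(out_dir, "manifest.tsv"), sep = "\t")
  data.table::fwrite(truth, file.path(out_dir, "truth.tsv"), sep = "\t")

  structure(list(dir = out_dir, config = config, manifest = manifest,
                 truth = truth, genome = genome_path, tss = tss_path,
                 loci = loci),
            class = "synthetic_bundle")
}

#' @export
print.synthetic_bundle <- function(x, ...) {
  cat("synthetic_bundle:", length(unique(x$truth$cell_type)), "cell types,",
      nrow(x$truth), "OCR records in", x$dir, "\n")
  invisible(x)
}

#' Build labeled corpora from a synthetic bundle
#'
#' Runs the real-data ingestion path ([read_narrowpeak()],
#' [read_bedgraph()], [build_corpus()]) on the generated files, one corpus
#' per cell type.
#'
#' @param bundle a [generate_dataset()] result.
#' @param W evaluation-window width.
#' @return a named list of [build_corpus()] objects.
#' @export
load_bundle_corpora <- function(bundle, W = 1000L) {
  stopifnot(inherits(bundle, "synthetic_bundle"))
  sl <- bundle$config$chromosome_lengths
  lapply(stats::setNames(nm = bundle$config$cell_types), function(cell) {
    m <- bundle$manifest[bundle$manifest$cell_type == cell, ]
    atac <- m[m$role == "atac", ]
    peak_sets <- lapply(atac$peaks, function(f)
      read_narrowpeak(file.path(bundle$dir, f)))
    tracks <- lapply(seq_len(nrow(atac)), function(i)
      read_bedgraph(file.path(bundle$dir, atac$file[i]),
                    total_mapped_reads = atac$total_reads[i],
                    seqlengths = sl))
    nas <- m[m$role == "nascent", ]
    nascent_tracks <- lapply(seq_len(nrow(nas)), function(i)
      read_bedgraph(file.path(bundle$dir, nas$file[i]),
                    total_mapped_reads = nas$total_reads[i],
                    allow_negative = nas$strand[i] == "-",
                    strand = nas$strand[i], seqlengths = sl))
    names(nascent_tracks) <- nas$strand
    build_corpus(peak_sets, tracks, cell_type = cell,
                 fstitch_regions = read_bed(
                   file.path(bundle$dir, paste0(cell, "_fstitch.bed"))),
                 tfit_regions = read_bed(
                   file.path(bundle$dir, paste0(cell, "_tfit.bed"))),
                 tss = read_bed(bundle$tss),
                 nascent_tracks = nascent_tracks, W = W)
  })
}

#' Fraction of corpus labels agreeing with the generator's ground truth
#'
#' Matches each corpus OCR to the truth record it overlaps and compares
#' labels.
#'
#' @param corpus a [build_corpus()] result for one cell type.
#' @param bundle the [generate_dataset()] bundle it was built from.
#' @return agreement fraction in `[0, 1]`.
#' @export
label_agreement <- function(corpus, bundle) {
  tr <- bundle$truth[bundle$truth$cell_type == corpus$cell_type, ]
  tr_gr <- GenomicRanges::GRanges(tr$chrom,
                                  IRanges::IRanges(tr$start + 1L, tr$end))
  hits <- GenomicRanges::findOverlaps(corpus$ocrs, tr_gr, minoverlap = 1L)
  stopifnot(length(hits) == length(corpus$ocrs))
  mean(as.character(corpus$ocrs$label[S4Vectors::queryHits(hits)]) ==
         tr$label[S4Vectors::subjectHits(hits)])
}

#' Ablate a synthetic bundle to a single input channel
#'
#' `signal_only` rewrites the genome as all-`N` so the sequence channel is
#' uninformative; `sequence_only` replaces every ATAC coverage file with a
#' constant depth so the signal channel is uninformative.  The original
#' bundle directory is left untouched.
#'
#' @param bundle a [generate_dataset()] result.
#' @param mode `"signal_only"` or `"sequence_only"`.
#' @param out_dir directory for the modified copy.
#' @return a new `synthetic_bundle`.
#' @export
ablate <- function(bundle, mode = c("signal_only", "sequence_only"),
                   out_dir = tempfile(paste0("ablate_", mode[1]))) {
  mode <- match.arg(mode)
  stopifnot(inherits(bundle, "synthetic_bundle"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  file.copy(list.files(bundle$dir, full.names = TRUE), out_dir,
            overwrite = TRUE)
  new <- bundle
  new$dir <- out_dir
  new$genome <- file.path(out_dir, "genome.fa")
  new$tss <- file.path(out_dir, "tss.bed")
  sl <- bundle$config$chromosome_lengths
  if (mode == "signal_only") {
    blank <- Biostrings::DNAStringSet(vapply(names(sl), function(ch)
      strrep("N", sl[[ch]]), character(1)))
    names(blank) <- names(sl)
    file.remove(file.path(out_dir, c("genome.fa.fai")))
    Biostrings::writeXStringSet(blank, new$genome, width = 80L)
    Rsamtools::indexFa(new$genome)
  } else {
    atac <- new$manifest[new$manifest$role == "atac", ]
    flat <- data.table::data.table(
      chrom = names(sl), start = 0L, end = unname(unlist(sl)), value = 1)
    for (f in atac$file)
      data.table::fwrite(flat, file.path(out_dir, f), sep = "\t",
                         col.names = FALSE, quote = FALSE)
  }
  new
}
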