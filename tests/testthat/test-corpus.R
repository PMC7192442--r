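test_that("per-million normalization scales depths by 1e6/total", {
  cov <- IRanges::RleList(chr1 = S4Vectors::Rle(c(0, 3, 3, 0, 6)))
  tr <- coverage_track(cov, 12e6)
  out <- normalize_track(tr)
  expect_true(out$normalized)
  expect_equal(as.numeric(out$cov$chr1), c(0, 0.25, 0.25, 0, 0.5))
  expect_error(normalize_track(out), "already")
  # library size of exactly one million leaves depths unchanged
  id <- normalize_track(coverage_track(cov, 1e6))
  expect_equal(as.numeric(id$cov$chr1), c(0, 3, 3, 0, 6))
})

test_that("peak union merges overlaps but never spans gaps", {
  u <- union_peaks(list(gr("chr1", 100, 200), gr("chr1", 150, 250)))
  expect_equal(GenomicRanges::start(u) - 1L, 100)
  expect_equal(GenomicRanges::end(u), 250)
  u2 <- union_peaks(list(gr("chr1", 100, 200), gr("chr1", 300, 400)))
  expect_length(u2, 2)
  # abutting peaks form one covered run, hence one OCR
  u3 <- union_peaks(list(gr("chr1", 100, 200), gr("chr1", 200, 300)))
  expect_length(u3, 1)
  expect_equal(GenomicRanges::width(u3), 200L)
})

test_that("peak union equals the per-bp coverage oracle; idempotent, order-free", {
  set.seed(3)
  for (rep in 1:40) {
    sets <- lapply(1:3, function(i) random_intervals(30, max_pos = 500))
    u <- union_peaks(sets)
    # oracle: mark every covered bp, re-extract maximal runs per chromosome
    for (ch in c("chr1", "chr2")) {
      covered <- logical(600)
      for (s in sets) {
        sub <- s[as.character(GenomicRanges::seqnames(s)) == ch]
        for (i in seq_along(sub))
          covered[GenomicRanges::start(sub)[i]:GenomicRanges::end(sub)[i]] <- TRUE
      }
      r <- rle(covered)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      want_start <- starts[r$values]
      want_end <- ends[r$values]
      got <- u[as.character(GenomicRanges::seqnames(u)) == ch]
      expect_equal(GenomicRanges::start(got), want_start)
      expect_equal(GenomicRanges::end(got), want_end)
    }
    expect_equal(union_peaks(list(u)), u)                  # idempotent
    expect_equal(union_peaks(rev(sets)), u)                # order-independent
  }
})

test_that("track averaging treats missing coverage as zero depth", {
  t1 <- normalize_track(coverage_track(
    IRanges::RleList(chr1 = S4Vectors::Rle(c(2, 2, 0))), 1e6))
  t2 <- normalize_track(coverage_track(
    IRanges::RleList(chr1 = S4Vectors::Rle(c(4, 0, 6))), 1e6))
  avg <- average_tracks(list(t1, t2))
  expect_equal(as.numeric(avg$cov$chr1), c(3, 1, 3))
  expect_equal(avg$total_mapped_reads, 0)  # derived-track sentinel
  expect_true(avg$normalized)
  # a chromosome absent from one track contributes zeros there
  t3 <- normalize_track(coverage_track(
    IRanges::RleList(chr2 = S4Vectors::Rle(c(8, 8))), 1e6))
  avg2 <- average_tracks(list(t1, t3))
  expect_equal(as.numeric(avg2$cov$chr2), c(4, 4))
  expect_error(average_tracks(list(t1, coverage_track(t2$cov, 1e6))),
               "normalized")
})

test_that("track averaging equals the dense-vector oracle on sparse tracks", {
  set.seed(9)
  L <- 1000
  for (rep in 1:20) {
    dense <- replicate(3, {
      v <- numeric(L)
      for (k in 1:5) {
        at <- sample(L - 50, 1)
        v[at:(at + 49)] <- v[at:(at + 49)] + round(runif(1, 0.5, 4), 2)
      }
      v
    })
    tracks <- lapply(1:3, function(i) normalize_track(coverage_track(
      IRanges::RleList(chr1 = S4Vectors::Rle(dense[, i])), 1e6)))
    avg <- average_tracks(tracks)
    expect_equal(as.numeric(avg$cov$chr1), rowMeans(dense))
  }
})

test_that("evaluation windows are centered with floor rounding and clamped", {
  w <- make_window(gr("chr1", 10000, 10300))
  expect_equal(GenomicRanges::start(w) - 1L, 9650)
  expect_equal(GenomicRanges::end(w), 10650)
  # near-origin OCR: left-clamped shift preserving width
  w2 <- make_window(gr("chr1", 100, 200))
  expect_equal(GenomicRanges::start(w2) - 1L, 0)
  expect_equal(GenomicRanges::end(w2), 1000)
  # a width-W interval already centered is a fixed point
  w3 <- make_window(gr("chr1", 5000, 6000))
  expect_equal(GenomicRanges::start(w3) - 1L, 5000)
  expect_equal(GenomicRanges::end(w3), 6000)
  expect_true(all(GenomicRanges::width(make_window(random_intervals(50),
                                                   W = 1000L)) == 1000))
})

test_that("labeling is by >=1 bp OCR overlap with either call set", {
  ocr <- gr("chr1", 100, 200)
  expect_equal(as.character(label_ocrs(ocr, gr("chr2", 0, 1000),
                                       gr("chr1", 150, 300))), "positive")
  # touching is not overlap
  expect_equal(as.character(label_ocrs(ocr, gr("chr1", 200, 300),
                                       GenomicRanges::GRanges())), "negative")
})

test_that("labeling matches the nested-loop oracle and is monotone", {
  set.seed(21)
  for (rep in 1:50) {
    ocrs <- random_intervals(50)
    fst <- random_intervals(10)
    tft <- random_intervals(10)
    lab <- label_ocrs(ocrs, fst, tft)
    want <- brute_any_overlap(ocrs, fst) | brute_any_overlap(ocrs, tft)
    expect_equal(lab == "positive", want)
    # monotonicity: adding regions never flips positive -> negative
    lab2 <- label_ocrs(ocrs, c(fst, random_intervals(5)), tft)
    expect_true(all(!(lab == "positive" & lab2 == "negative")))
  }
})

test_that("TSS flagging matches the nested-loop oracle", {
  ocr <- gr("chr1", 100, 200)
  expect_true(flag_tss(ocr, gr("chr1", 150, 151)))
  expect_false(flag_tss(ocr, gr("chr1", 500, 501)))
  expect_false(flag_tss(ocr, GenomicRanges::GRanges()))
  set.seed(33)
  for (rep in 1:50) {
    ocrs <- random_intervals(40)
    tss <- random_intervals(15, max_len = 1)
    expect_equal(flag_tss(ocrs, tss), brute_any_overlap(ocrs, tss))
  }
})

test_that("mean window signal averages per-bp depth over the full width", {
  cov <- IRanges::RleList(chr1 = S4Vectors::Rle(rep(2, 100)))
  tr <- coverage_track(cov, 0, normalized = TRUE)
  expect_equal(mean_window_signal(tr, gr("chr1", 0, 100)), 2)
  # depth on exactly half the window
  cov2 <- IRanges::RleList(chr1 = S4Vectors::Rle(c(rep(4, 50), rep(0, 50))))
  tr2 <- coverage_track(cov2, 0, normalized = TRUE)
  expect_equal(mean_window_signal(tr2, gr("chr1", 0, 100)), 2)
  # windows past the contig end count missing positions as zero
  expect_equal(mean_window_signal(tr2, gr("chr1", 25, 125)), 1)
})

test_that("mean window signal equals densified means on random tracks", {
  set.seed(12)
  for (rep in 1:30) {
    v <- numeric(400)
    for (k in 1:4) {
      at <- sample(350, 1)
      v[at:(at + 49)] <- round(runif(1, 0, 3), 2)
    }
    tr <- coverage_track(IRanges::RleList(chr1 = S4Vectors::Rle(v)), 0, normalized = TRUE)
    s0 <- sample(0:300, 5)
    wins <- gr("chr1", s0, s0 + 100)
    expect_equal(mean_window_signal(tr, wins),
                 vapply(s0, function(s) mean(v[(s + 1):(s + 100)]),
                        numeric(1)))
    # consistency with the full signal matrix
    expect_equal(colMeans(window_signal_matrix(tr, wins)),
                 mean_window_signal(tr, wins))
  }
})

test_that("corpus construction recovers planted structure on synthetic data", {
  bundle <- small_bundle()
  corpora <- small_corpora()
  for (ct in names(corpora)) {
    cc <- corpora[[ct]]
    truth <- bundle$truth[bundle$truth$cell_type == ct, ]
    expect_equal(length(cc$ocrs), nrow(truth))
    expect_equal(label_agreement(cc, bundle), 1.0)
    expect_true(all(GenomicRanges::width(cc$windows) == 1000))
    expect_true(all(cc$ocrs$mean_atac_signal >= 0))
    # OCR intervals are pairwise disjoint (they are a union)
    expect_equal(length(GenomicRanges::reduce(cc$ocrs, min.gapwidth = 0L)),
                 length(cc$ocrs))
    # TSS flags match the generator's truth
    expect_equal(cc$ocrs$tss_overlap, truth$tss[order(factor(truth$chrom,
      levels = GenomeInfoDb::seqlevels(cc$ocrs)), truth$start)])
  }
})

test_that("single-replicate corpus keeps that replicate's peak intervals", {
  bundle <- small_bundle()
  m <- bundle$manifest
  atac <- m[m$cell_type == "cellA" & m$role == "atac", ][1, ]
  peaks <- read_narrowpeak(file.path(bundle$dir, atac$peaks))
  track <- read_bedgraph(file.path(bundle$dir, atac$file), atac$total_reads)
  cc <- suppressMessages(build_corpus(
    list(peaks), list(track), cell_type = "cellA",
    fstitch_regions = GenomicRanges::GRanges(),
    tfit_regions = GenomicRanges::GRanges()))
  want <- GenomicRanges::sort(GenomeInfoDb::sortSeqlevels(
    GenomicRanges::granges(peaks)))
  expect_equal(as.character(GenomicRanges::seqnames(cc$ocrs)),
               as.character(GenomicRanges::seqnames(want)))
  expect_equal(GenomicRanges::start(cc$ocrs), GenomicRanges::start(want))
  expect_equal(GenomicRanges::end(cc$ocrs), GenomicRanges::end(want))
  expect_true(all(cc$ocrs$label == "negative"))  # no call regions given
})

test_that("corpus construction validates replicate pairing", {
  expect_error(suppressMessages(build_corpus(
    list(gr("chr1", 0, 10)), list(), cell_type = "x",
    fstitch_regions = GenomicRanges::GRanges(),
    tfit_regions = GenomicRanges::GRanges())), "matching")
})

test_that("corpus export writes a re-readable window table and coverage", {
  cc <- small_corpora()[[1]]
  dir <- withr::local_tempdir()
  paths <- write_corpus(cc, dir)
  tab <- read.delim(paths[["ocrs"]], header = FALSE)
  expect_equal(nrow(tab), length(cc$ocrs))
  expect_equal(tab[[3]] - tab[[2]], rep(1000L, nrow(tab)))
  back <- read_bedgraph(paths[["coverage"]], 1e6)
  expect_gt(sum(S4Vectors::runValue(back$cov[[1]])), 0)
})
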