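# Minimal three-cell-type corpora for split logic tests: one OCR per
# chromosome, chromosomes chosen to land on either side of the split.
mini_corpus <- function(cell, chroms) {
  ocrs <- gr(chroms, 1000, 1400)
  ocrs$label <- factor(rep("negative", length(chroms)),
                       levels = c("positive", "negative"))
  ocrs$tss_overlap <- FALSE
  ocrs$mean_atac_signal <- 1
  ocrs$mean_nascent_signal <- NA_real_
  structure(list(cell_type = cell, ocrs = ocrs,
                 windows = make_window(ocrs), track = NULL,
                 nascent_track = NULL, n_srrs = 1L),
            class = "cell_corpus")
}

test_that("the LOOT split partitions by cell type and chromosome", {
  corpora <- list(mini_corpus("A", c("chr1", "chr12")),
                  mini_corpus("B", c("chr2", "chr13")),
                  mini_corpus("V", c("chr3", "chr14")))
  s <- suppressMessages(loot_split(corpora, held_out = "B",
                                   validation_cell_type = "V"))
  expect_named(s$train, "A")
  expect_equal(as.character(GenomicRanges::seqnames(s$train$A$ocrs)), "chr1")
  expect_equal(as.character(GenomicRanges::seqnames(s$validation$ocrs)),
               "chr3")
  expect_equal(s$validation$cell_type, "V")
  expect_equal(as.character(GenomicRanges::seqnames(s$test$ocrs)), "chr13")
  expect_equal(s$test$cell_type, "B")
  expect_error(loot_split(corpora, "B", "B"), "differ")
  expect_error(suppressMessages(loot_split(corpora, "Q", "V")), "unknown")
})

test_that("every LOOT configuration is leakage-free on synthetic corpora", {
  corpora <- small_corpora()
  val <- "cellV"
  for (held in setdiff(names(corpora), val)) {
    s <- suppressMessages(loot_split(corpora, held, val))
    # no held-out-cell-type records in training
    for (tc in s$train) expect_false(tc$cell_type == held)
    # brute-force window overlap scan between train and test
    test_w <- s$test$windows
    for (tc in s$train) {
      expect_equal(sum(brute_any_overlap(tc$windows, test_w)), 0)
    }
  }
})

test_that("ROC AUC equals the Mann-Whitney concordance probability", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.4, 0.2), c(1, 1, 0, 0)), 1.0)
  # 3 concordant of 4 positive/negative pairs
  expect_equal(roc_auc(c(0.1, 0.2, 0.3, 0.4), c(0, 1, 0, 1)), 0.75)
  expect_equal(roc_auc(rep(0.5, 10), rep(c(0, 1), 5)), 0.5)
  expect_error(roc_auc(1:4, rep(1, 4)), "single-class")
})

test_that("AUC is antisymmetric and matches an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(77)
  for (rep in 1:20) {
    n <- 60
    lab <- rbinom(n, 1, 0.4)
    if (length(unique(lab)) < 2) next
    sc <- round(runif(n), 2)  # rounded scores force ties
    a <- roc_auc(sc, lab)
    expect_equal(a, as.numeric(pROC::auc(pROC::roc(lab, sc, quiet = TRUE,
                                                   direction = "<"))))
    if (!any(duplicated(sc))) expect_equal(roc_auc(-sc, lab), 1 - a)
  }
})

test_that("weighted F1 reproduces hand-computed confusion examples", {
  expect_equal(weighted_f1(c(1, 1, 0, 0), c(1, 1, 0, 0)), 1.0)
  # F1(pos) = 2/3, F1(neg) = 4/5, balanced weights
  expect_equal(weighted_f1(c(1, 0, 0, 0), c(1, 1, 0, 0)), 11 / 15)
  # all-negative predictions on balanced labels
  expect_equal(weighted_f1(c(0, 0, 0, 0), c(1, 1, 0, 0)), 1 / 3)
})

test_that("weighted F1 is invariant under joint class relabeling", {
  set.seed(31)
  for (rep in 1:30) {
    n <- 40
    lab <- rbinom(n, 1, 0.3)
    pred <- rbinom(n, 1, 0.5)
    expect_equal(weighted_f1(pred, lab), weighted_f1(1 - pred, 1 - lab))
  }
})

test_that("confusion classes form an exhaustive disjoint partition", {
  pred <- c(1, 1, 0, 0, 1)
  lab <- c(1, 0, 0, 1, 1)
  cls <- confusion_classes(pred, lab)
  expect_equal(as.character(cls), c("TP", "FP", "TN", "FN", "TP"))
  expect_equal(sum(table(cls)), 5)
  ocrs <- gr(rep("chr1", 5), 0:4 * 100, 0:4 * 100 + 50)
  by_class <- confusion_classes(pred, lab, ocrs)
  expect_equal(sum(lengths(by_class)), 5)
  expect_named(by_class, c("TP", "TN", "FP", "FN"))
})

test_that("meta-profiles are position-wise means that commute with partition", {
  m <- cbind(c(0, 1, 0), c(2, 3, 2))
  expect_equal(meta_profile(m)$profile, c(1, 2, 1))
  expect_equal(meta_profile(m[, 1, drop = FALSE])$profile, m[, 1])
  set.seed(8)
  sig <- matrix(runif(50 * 40), 50, 40)
  cls <- factor(sample(c("TP", "TN", "FP", "FN"), 40, TRUE),
                levels = c("TP", "TN", "FP", "FN"))
  overall <- meta_profile(sig)$profile
  weighted <- Reduce(`+`, lapply(levels(cls), function(l)
    sum(cls == l) / 40 * meta_profile(sig[, cls == l, drop = FALSE])$profile))
  expect_equal(overall, weighted)
  # stranded profiles average each strand separately
  mp <- meta_profile(sig, minus = 2 * sig)
  expect_equal(mp$minus, 2 * mp$plus)
})

test_that("FWHM measures profile width above the half-maximum", {
  prof <- dnorm(seq(-500, 499), sd = 100)
  expect_equal(fwhm(prof), sum(prof >= max(prof) / 2))
  expect_gt(fwhm(dnorm(seq(-500, 499), sd = 150)),
            fwhm(dnorm(seq(-500, 499), sd = 60)))
})

test_that("sharing counts match the all-pairs overlap oracle", {
  mk <- function(cell, chrom, s0, e0) {
    ocrs <- gr(chrom, s0, e0)
    structure(list(cell_type = cell, ocrs = ocrs,
                   windows = make_window(ocrs), n_srrs = 1L),
              class = "cell_corpus")
  }
  out <- sharing_categories(list(mk("A", "chr1", 100, 200),
                                 mk("B", "chr1", 150, 250),
                                 mk("C", "chr2", 100, 200)))
  expect_equal(out$A, 2L)
  expect_equal(out$B, 2L)
  expect_equal(out$C, 1L)
  set.seed(14)
  for (rep in 1:50) {
    corp <- lapply(c("A", "B", "C"), function(cell) {
      ocrs <- GenomicRanges::reduce(random_intervals(15, max_pos = 400))
      structure(list(cell_type = cell, ocrs = ocrs,
                     windows = NULL, n_srrs = 1L), class = "cell_corpus")
    })
    got <- sharing_categories(corp)
    for (i in 1:3) {
      want <- rep(1L, length(corp[[i]]$ocrs))
      for (j in setdiff(1:3, i))
        want <- want + as.integer(brute_any_overlap(corp[[i]]$ocrs,
                                                    corp[[j]]$ocrs))
      expect_equal(got[[i]], want)
    }
  }
})

test_that("squared correlation matches hand-worked and limiting cases", {
  x <- 1:50
  expect_equal(squared_correlation(x, 2 * x + 1), 1.0)
  expect_equal(squared_correlation(c(1, 2, 3), c(1, 3, 2)), 0.25)
  set.seed(2)
  expect_lt(squared_correlation(rnorm(10000), rnorm(10000)), 0.01)
  expect_error(squared_correlation(c(1, 1, 1), c(1, 2, 3)), "variance")
})

test_that("evaluation reports assemble coherent metrics", {
  set.seed(6)
  n <- 80
  ds <- toy_dataset(matrix(sample(1:4, 30 * n, TRUE), 30, n),
                    matrix(runif(30 * n), 30, n), rbinom(n, 1, 0.4))
  prob <- runif(n)
  rep <- evaluate_predictions(prob, ds)
  expect_s3_class(rep, "eval_report")
  expect_equal(sum(rep$confusion), n)
  expect_equal(rep$auc, roc_auc(prob, ds$label))
  expect_equal(rep$weighted_f1,
               weighted_f1(as.integer(prob > 0.5), ds$label))
  expect_equal(sum(unlist(rep$histograms)), n)
  path <- withr::local_tempfile(fileext = ".json")
  write_eval_report(rep, path)
  back <- jsonlite::read_json(path)
  expect_equal(back$auc, rep$auc)
  expect_equal(is.null(back$profiles$TP), rep$confusion[["TP"]] == 0)
})
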