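# Leave-one-out-training (LOOT) evaluation: chromosome hold-out splitting,
# threshold-free and thresholded metrics, error-class characterization and
# meta-profiles.

.train_chromosomes <- function() paste0("chr", 1:11)
.test_chromosomes <- function() c(paste0("chr", 12:22), "chrX", "chrY")

.subset_corpus <- function(corpus, idx) {
  out <- corpus
  out$ocrs <- corpus$ocrs[idx]
  out$windows <- corpus$windows[idx]
  out
}

#' Leave-one-out-training split
#'
#' Holds one cell type out entirely: training uses chr1-chr11 OCRs from all
#' other cell types except the dedicated validation cell type, validation
#' uses the validation cell type's chr1-chr11 OCRs (the rest of that cell
#' type is discarded), and the test set is the held-out cell type's
#' chr12-chr22, chrX, chrY OCRs.  Because training and test chromosomes are
#' disjoint, no training window can overlap a test window.
#'
#' @param corpora a list of [build_corpus()] objects.
#' @param held_out cell type to test on.
#' @param validation_cell_type cell type reserved for validation.
#' @param train_chroms,test_chroms chromosome name vectors defining the
#'   split (exact string match).
#' @return an object of class `loot_split`: lists `train` (one subset
#'   corpus per training cell type), `validation` and `test` (single subset
#'   corpora), plus the split parameters.
#' @export
loot_split <- function(corpora, held_out, validation_cell_type,
                       train_chroms = .train_chromosomes(),
                       test_chroms = .test_chromosomes()) {
  cells <- vapply(corpora, `[[`, character(1), "cell_type")
  names(corpora) <- cells
  if (held_out == validation_cell_type)
    stop("held-out and validation cell types must differ")
  if (!held_out %in% cells) stop("unknown held-out cell type: ", held_out)
  if (!validation_cell_type %in% cells)
    stop("unknown validation cell type: ", validation_cell_type)
  if (length(intersect(train_chroms, test_chroms)))
    stop("train and test chromosome lists overlap")
  on_chroms <- function(corpus, chroms)
    as.character(GenomicRanges::seqnames(corpus$ocrs)) %in% chroms
  train_cells <- setdiff(cells, c(held_out, validation_cell_type))
  if (length(train_cells) == 0) stop("no cell types left for training")
  train <- lapply(corpora[train_cells], function(cc)
    .subset_corpus(cc, on_chroms(cc, train_chroms)))
  validation <- .subset_corpus(corpora[[validation_cell_type]],
                               on_chroms(corpora[[validation_cell_type]],
                                         train_chroms))
  test <- .subset_corpus(corpora[[held_out]],
                         on_chroms(corpora[[held_out]], test_chroms))
  message("LOOT split (held out ", held_out, "): ",
          sum(vapply(train, function(x) length(x$ocrs), integer(1))),
          " train / ", length(validation$ocrs), " validation / ",
          length(test$ocrs), " test OCRs")
  structure(list(train = train, validation = validation, test = test,
                 held_out = held_out,
                 validation_cell_type = validation_cell_type,
                 train_chroms = train_chroms, test_chroms = test_chroms),
            class = "loot_split")
}

#' ROC area under the curve
#'
#' Computed as the Mann-Whitney concordance probability (the probability
#' that a random positive outranks a random negative, ties counted 0.5),
#' which equals the area under the empirical ROC curve.
#'
#' @param scores numeric prediction scores.
#' @param labels 0/1 labels; both classes must be present.
#' @return the AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% 0:1))
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("AUC undefined: single-class labels")
  r <- rank(scores)  # average ranks handle ties as 0.5
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Class-support-weighted F1 score
#'
#' The F1 score of each class (treating that class as positive) averaged
#' with weights equal to the class's share of the true labels.  A class
#' with an undefined precision or recall contributes F1 = 0.
#'
#' @param predictions 0/1 predicted labels.
#' @param labels 0/1 true labels; non-empty.
#' @return the weighted F1 in `[0, 1]`.
#' @export
weighted_f1 <- function(predictions, labels) {
  predictions <- as.integer(predictions)
  labels <- as.integer(labels)
  stopifnot(length(predictions) == length(labels), length(labels) > 0,
            all(predictions %in% 0:1), all(labels %in% 0:1))
  f1_of <- function(cls) {
    tp <- sum(predictions == cls & labels == cls)
    fp <- sum(predictions == cls & labels != cls)
    fn <- sum(predictions != cls & labels == cls)
    if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  }
  w1 <- mean(labels == 1)
  w1 * f1_of(1L) + (1 - w1) * f1_of(0L)
}

#' Partition predictions into confusion classes
#'
#' @param predictions 0/1 predicted labels.
#' @param labels 0/1 true labels.
#' @param ocrs optional vector-like object parallel to the labels (e.g. a
#'   `GRanges` of OCRs); when given, it is split by class.
#' @return without `ocrs`, a factor with levels TP, TN, FP, FN; with
#'   `ocrs`, a named list mapping each class to the corresponding subset.
#' @export
confusion_classes <- function(predictions, labels, ocrs = NULL) {
  predictions <- as.integer(predictions)
  labels <- as.integer(labels)
  stopifnot(length(predictions) == length(labels))
  cls <- factor(ifelse(labels == 1,
                       ifelse(predictions == 1, "TP", "FN"),
                       ifelse(predictions == 1, "FP", "TN")),
                levels = c("TP", "TN", "FP", "FN"))
  if (is.null(ocrs)) return(cls)
  lapply(stats::setNames(nm = levels(cls)), function(l) ocrs[cls == l])
}

#' Meta-profile: position-wise mean signal over a set of windows
#'
#' The "meta-peak" (for ATAC signal) or "meta-gene" (for stranded nascent
#' signal) aggregate: at every window offset, the arithmetic mean of the
#' signal across all windows.  For stranded input, the plus and minus
#' strands are averaged separately.
#'
#' @param signal a width-x-n matrix of per-bp signal (one column per
#'   window), e.g. a `hybrid_dataset$signal` or [window_signal_matrix()].
#' @param minus optional width-x-n matrix of minus-strand signal; `signal`
#'   is then the plus strand.
#' @return an object of class `meta_profile`: `profile` (or `plus`/`minus`)
#'   and `n`.
#' @export
meta_profile <- function(signal, minus = NULL) {
  stopifnot(is.matrix(signal), ncol(signal) >= 1)
  if (is.null(minus)) {
    structure(list(profile = rowMeans(signal), n = ncol(signal)),
              class = "meta_profile")
  } else {
    stopifnot(is.matrix(minus), all(dim(minus) == dim(signal)))
    structure(list(plus = rowMeans(signal), minus = rowMeans(minus),
                   n = ncol(signal)),
              class = "meta_profile")
  }
}

#' Full width at half maximum of a profile
#'
#' The number of positions at which the profile exceeds the midpoint
#' between its minimum (taken as baseline) and maximum.
#'
#' @param profile a numeric vector or a `meta_profile`.
#' @return width in positions (bp for per-bp profiles).
#' @export
fwhm <- function(profile) {
  if (inherits(profile, "meta_profile")) profile <- profile$profile
  half <- min(profile) + (max(profile) - min(profile)) / 2
  sum(profile >= half)
}

#' Count how many cell types share each OCR
#'
#' An OCR's share count is the number of cell types (including its own)
#' possessing at least one OCR overlapping it by >= 1 bp.  OCRs with count
#' 1 are unique to their cell type; OCRs with count equal to the number of
#' corpora are "common".
#'
#' @param corpora a list of two or more [build_corpus()] objects.
#' @return a named list (by cell type) of integer share counts parallel to
#'   each corpus's OCRs.
#' @export
sharing_categories <- function(corpora) {
  stopifnot(length(corpora) >= 2)
  cells <- vapply(corpora, `[[`, character(1), "cell_type")
  out <- lapply(seq_along(corpora), function(i) {
    counts <- rep(1L, length(corpora[[i]]$ocrs))
    for (j in seq_along(corpora)) {
      if (j == i) next
      counts <- counts + as.integer(suppressWarnings(
        GenomicRanges::countOverlaps(corpora[[i]]$ocrs, corpora[[j]]$ocrs,
                                     minoverlap = 1L,
                                     ignore.strand = TRUE)) > 0)
    }
    counts
  })
  stats::setNames(out, cells)
}

#' Squared Pearson correlation
#'
#' @param x,y numeric vectors of equal length (n >= 3, nonzero variance);
#'   typically per-OCR mean ATAC signal vs mean nascent signal.
#' @return r-squared in `[0, 1]`.
#' @export
squared_correlation <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance: correlation undefined")
  stats::cor(x, y)^2
}

#' Run one LOOT evaluation end to end
#'
#' Splits the corpora with [loot_split()], encodes each subset against the
#' genome, trains the GRU on the pooled training cell types, predicts the
#' held-out cell type's test OCRs and assembles an evaluation report:
#' ROC-AUC, weighted F1 at the given probability threshold, confusion
#' counts, per-class mean-signal histograms and per-class ATAC meta-peak
#' profiles.
#'
#' @param corpora list of [build_corpus()] objects (all cell types).
#' @param genome indexed FASTA path / `FaFile` / `DNAStringSet`.
#' @param held_out cell type to test on.
#' @param validation_cell_type cell type reserved for validation.
#' @param config a [model_config()].
#' @param threshold probability cut for converting scores to labels.
#' @param hist_breaks number of equal-width mean-signal histogram bins.
#' @return an object of class `eval_report`; see Details.
#' @export
run_loot <- function(corpora, genome, held_out, validation_cell_type,
                     config = model_config(), threshold = 0.5,
                     hist_breaks = 40L) {
  split <- loot_split(corpora, held_out, validation_cell_type)
  train_ds <- combine_datasets(lapply(split$train, encode_windows,
                                      genome = genome))
  val_ds <- encode_windows(split$validation, genome)
  test_ds <- encode_windows(split$test, genome)
  model <- train_rnn(train_ds, val_ds, config)
  prob <- predict_rnn(model, test_ds)
  evaluate_predictions(prob, test_ds, model = model, threshold = threshold,
                       hist_breaks = hist_breaks, held_out = held_out)
}

#' Assemble an evaluation report from predicted probabilities
#'
#' @param prob predicted probabilities for the test records.
#' @param test_ds the test `hybrid_dataset`.
#' @param model optional trained model to attach.
#' @param threshold probability cut for the confusion matrix and F1.
#' @param hist_breaks number of mean-signal histogram bins.
#' @param held_out held-out cell type name (metadata only).
#' @return an `eval_report` list: `auc`, `weighted_f1`, `confusion`
#'   (TP/TN/FP/FN counts), `threshold`, `prob`, `labels`, per-class
#'   `histograms` (shared `breaks`), per-class ATAC `profiles`
#'   ([meta_profile()]s) and `model`.
#' @export
evaluate_predictions <- function(prob, test_ds, model = NULL,
                                 threshold = 0.5, hist_breaks = 40L,
                                 held_out = NA_character_) {
  stopifnot(inherits(test_ds, "hybrid_dataset"),
            length(prob) == length(test_ds$label))
  labels <- test_ds$label
  pred <- as.integer(prob > threshold)
  cls <- confusion_classes(pred, labels)
  confusion <- table(cls)
  mean_sig <- test_ds$meta$mean_atac_signal
  breaks <- seq(0, max(mean_sig, 1e-9), length.out = hist_breaks + 1L)
  histograms <- lapply(stats::setNames(nm = levels(cls)), function(l) {
    if (!any(cls == l)) return(rep(0L, hist_breaks))
    graphics::hist(pmin(mean_sig[cls == l], max(breaks)), breaks = breaks,
                   plot = FALSE)$counts
  })
  profiles <- lapply(stats::setNames(nm = levels(cls)), function(l) {
    if (!any(cls == l)) return(NULL)
    meta_profile(test_ds$signal[, cls == l, drop = FALSE])
  })
  structure(list(held_out = held_out,
                 auc = roc_auc(prob, labels),
                 weighted_f1 = weighted_f1(pred, labels),
                 confusion = c(TP = unname(confusion["TP"]),
                               TN = unname(confusion["TN"]),
                               FP = unname(confusion["FP"]),
                               FN = unname(confusion["FN"])),
                 threshold = threshold, prob = prob, labels = labels,
                 breaks = breaks, histograms = histograms,
                 profiles = profiles, model = model),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("eval_report", if (!is.na(x$held_out)) paste0("(held out ", x$held_out, ")"),
      "- AUC", round(x$auc, 4), ", weighted F1", round(x$weighted_f1, 4),
      "\n  confusion:", paste(names(x$confusion), x$confusion,
                              collapse = ", "), "\n")
  invisible(x)
}

#' Serialize an evaluation report to JSON
#'
#' Writes the scalar metrics, confusion counts, histogram bins and
#' meta-profiles (the model is omitted).
#'
#' @param report an `eval_report`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_eval_report <- function(report, path) {
  stopifnot(inherits(report, "eval_report"))
  out <- report[c("held_out", "auc", "weighted_f1", "confusion",
                  "threshold", "breaks", "histograms")]
  out$profiles <- lapply(report$profiles, function(p)
    if (is.null(p)) NULL else list(profile = p$profile, n = p$n))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Evaluate the KDE odds-ratio baseline on a random hold-out
#'
#' Pools every corpus's OCR mean signals, holds out a seeded uniform random
#' fraction for testing (no stratification), fits the baseline on the rest
#' and reports AUC and weighted F1 of the odds-ratio classifier.
#'
#' @param corpora list of [build_corpus()] objects.
#' @param test_fraction fraction of OCRs held out for testing.
#' @param seed integer seed for the uniform split.
#' @return a list with `auc`, `weighted_f1`, `n_test` and the fitted
#'   `baseline`.
#' @export
evaluate_kde_baseline <- function(corpora, test_fraction = 0.1, seed = 1L) {
  mean_sig <- unlist(lapply(corpora, function(cc) cc$ocrs$mean_atac_signal))
  labels <- unlist(lapply(corpora, function(cc)
    as.integer(cc$ocrs$label == "positive")))
  n <- length(labels)
  test_idx <- .with_seed(seed, sample.int(n, size = round(n * test_fraction)))
  baseline <- fit_kde_baseline(mean_sig[-test_idx][labels[-test_idx] == 1],
                               mean_sig[-test_idx][labels[-test_idx] == 0])
  pred <- predict_kde_baseline(baseline, mean_sig[test_idx])
  list(auc = roc_auc(pred$score, labels[test_idx]),
       weighted_f1 = weighted_f1(pred$label, labels[test_idx]),
       n_test = length(test_idx), baseline = baseline)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG afterwards.
.with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}
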