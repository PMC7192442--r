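# The hybrid bidirectional-GRU classifier.

#' Model hyperparameter configuration
#'
#' Defaults are the selected values from the grid search over embedding
#' dimensions \{15, 50, 100\}, dropout rates \{0.1, 0.2, 0.3\}, learning
#' rates \{0.001, 0.0005, 0.0001\} and hidden sizes \{100, 200, 350, 500\}:
#' embedding 50, hidden 100 per direction, dropout 0.1 (applied to the
#' concatenated final states), learning rate 1e-4.  Optimizer (Adam), loss
#' (binary cross-entropy), batch size, epoch cap and early-stopping patience
#' (on validation AUC) are field-standard defaults exposed here.
#'
#' @param embedding_dim dimension of the learned nucleotide embedding.
#' @param hidden_size GRU units per direction.
#' @param dropout dropout rate on the concatenated final states, in (0,1).
#' @param learning_rate Adam learning rate.
#' @param max_epochs maximum training epochs.
#' @param batch_size minibatch size.
#' @param early_stop_patience epochs without validation-AUC improvement
#'   before stopping.
#' @param seed integer seed controlling initialization, shuffling and
#'   dropout; training is bit-reproducible for a fixed seed.
#' @param verbose print per-epoch loss and validation AUC.
#' @return a list of class `model_config`.
#' @export
model_config <- function(embedding_dim = 50L, hidden_size = 100L,
                         dropout = 0.1, learning_rate = 1e-4,
                         max_epochs = 50L, batch_size = 16L,
                         early_stop_patience = 5L, seed = 1L,
                         verbose = FALSE) {
  stopifnot(embedding_dim >= 1, hidden_size >= 1,
            dropout >= 0, dropout < 1,
            learning_rate > 0, learning_rate < 1,
            max_epochs >= 1, batch_size >= 1, early_stop_patience >= 1)
  structure(list(embedding_dim = as.integer(embedding_dim),
                 hidden_size = as.integer(hidden_size),
                 dropout = dropout, learning_rate = learning_rate,
                 max_epochs = as.integer(max_epochs),
                 batch_size = as.integer(batch_size),
                 early_stop_patience = as.integer(early_stop_patience),
                 seed = as.integer(seed),
                 vocab_size = length(iupac_vocabulary()),
                 verbose = isTRUE(verbose)),
            class = "model_config")
}

#' Train the hybrid bidirectional-GRU classifier
#'
#' Each window position feeds the trained nucleotide embedding concatenated
#' with the scalar normalized ATAC depth into a GRU layer per reading
#' direction; the final forward and reverse hidden states are concatenated,
#' passed through dropout and a single sigmoid unit.  Training minimizes
#' binary cross-entropy with Adam, monitors ROC-AUC on the validation set
#' after every epoch, and returns the parameters from the best validation
#' epoch (early stopping).
#'
#' @param train a `hybrid_dataset` with both classes present.
#' @param validation a `hybrid_dataset` with both classes present.
#' @param config a [model_config()].
#' @return an object of class `rnn_model` with elements `params`, `config`,
#'   `history` (per-epoch training loss and validation AUC), `best_epoch`
#'   and `window_width`.
#' @export
train_rnn <- function(train, validation, config = model_config()) {
  stopifnot(inherits(train, "hybrid_dataset"),
            inherits(validation, "hybrid_dataset"),
            inherits(config, "model_config"))
  if (ncol(train$tokens) == 0) stop("empty training set")
  if (length(unique(train$label)) < 2)
    stop("training set contains a single class")
  if (length(unique(validation$label)) < 2)
    stop("validation set contains a single class")
  if (nrow(train$tokens) != nrow(validation$tokens))
    stop("train and validation window widths differ")
  fit <- cpp_gru_train(train$tokens, train$signal, train$label,
                       validation$tokens, validation$signal,
                       validation$label, unclass(config))
  structure(list(params = fit$params, config = config,
                 history = data.frame(epoch = seq_along(fit$loss),
                                      loss = fit$loss,
                                      val_auc = fit$val_auc),
                 best_epoch = fit$best_epoch,
                 best_val_auc = fit$best_val_auc,
                 window_width = nrow(train$tokens)),
            class = "rnn_model")
}

#' @export
print.rnn_model <- function(x, ...) {
  cat("rnn_model: embedding", x$config$embedding_dim, "+ signal, hidden",
      x$config$hidden_size, "x2;", nrow(x$history), "epochs trained, best",
      "epoch", x$best_epoch, "(val AUC", round(x$best_val_auc, 4), ")\n")
  invisible(x)
}

#' Predict transcription-overlap probabilities
#'
#' @param model a trained [train_rnn()] model.
#' @param data a `hybrid_dataset` with the same window width as used in
#'   training.
#' @param batch_size prediction batch size; results are batch-size
#'   independent.
#' @return a numeric vector of probabilities in `[0, 1]`, one per record.
#' @export
predict_rnn <- function(model, data, batch_size = 256L) {
  stopifnot(inherits(model, "rnn_model"), inherits(data, "hybrid_dataset"))
  if (ncol(data$tokens) == 0) return(numeric(0))
  if (nrow(data$tokens) != model$window_width)
    stop("window width ", nrow(data$tokens),
         " does not match the training width ", model$window_width)
  cpp_gru_predict(model$params, data$tokens, data$signal,
                  as.integer(batch_size))
}

#' Save / load a trained model
#'
#' The parameter store is written with R's native serialization and a JSON
#' sidecar records the configuration and vocabulary, so a checkpoint is
#' self-describing.
#'
#' @param model an `rnn_model`.
#' @param path output `.rds` path; the sidecar is written to
#'   `paste0(path, ".json")`.
#' @return `path`, invisibly.
#' @export
save_rnn <- function(model, path) {
  stopifnot(inherits(model, "rnn_model"))
  saveRDS(model, path)
  sidecar <- list(config = unclass(model$config),
                  vocabulary = as.list(iupac_vocabulary()),
                  window_width = model$window_width,
                  best_epoch = model$best_epoch)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname save_rnn
#' @export
load_rnn <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "rnn_model"))
  model
}
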