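# Validation splitting, the shared training entry point, and DDI evaluation:
# per-class and micro-averaged precision/recall/F1 (micro pooled over the four
# positive interaction classes, the DDI detection-and-classification
# convention) plus the 5x5 confusion matrix used for error analysis.

#' Split documents into training and validation sets at the sentence level
#'
#' All candidates of one sentence always land on the same side, so no
#' sentence leaks across the split. The validation side receives
#' `round(frac * n)` sentences (within one sentence of the requested
#' fraction), selected uniformly with the given seed.
#'
#' @param docs list of [ddi_document()] objects.
#' @param frac validation fraction in (0, 1); default 0.10.
#' @param seed integer seed; the same seed reproduces the split exactly.
#' @return list with character vectors `train` and `validation` of sentence
#'   ids.
#' @export
split_validation <- function(docs, frac = 0.10, seed = 1L) {
  if (frac <= 0 || frac >= 1) stopf("frac must be inside (0, 1), got %g", frac)
  if (inherits(docs, "ddi_document")) docs <- list(docs)
  sids <- unlist(lapply(docs, function(d)
    vapply(d$sentences, `[[`, "", "id")), use.names = FALSE)
  n <- length(sids)
  n_val <- max(1L, round(frac * n))
  val <- with_seed(seed, sample(sids, n_val))
  list(train = setdiff(sids, val), validation = sort(val))
}

#' Training configuration
#'
#' @param batch_size mini-batch size (64 for the convolutional model, 16 for
#'   the relation-head model in the reference settings).
#' @param learning_rate Adam step size; `NULL` uses the model's own default.
#' @param max_epochs epoch cap (default 100, with early stopping).
#' @param patience early-stopping patience in epochs on validation micro-F1
#'   (default 10; ties keep the earliest best epoch).
#' @param seed integer seed controlling shuffling, dropout and noise.
#' @param verbose print a progress line after each epoch.
#' @return list of class `train_config`.
#' @export
train_config <- function(batch_size = 64L, learning_rate = NULL,
                         max_epochs = 100L, patience = 10L, seed = 1L,
                         verbose = FALSE) {
  if (batch_size < 1) stopf("batch_size must be >= 1")
  if (!is.null(patience) && patience > max_epochs && max_epochs > 0)
    stopf("patience (%d) exceeds max_epochs (%d)", patience, max_epochs)
  structure(list(batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 max_epochs = as.integer(max_epochs),
                 patience = patience, seed = as.integer(seed),
                 verbose = isTRUE(verbose)),
            class = "train_config")
}

#' Train a DDI extraction model
#'
#' Adam optimization of the cross-entropy, with validation micro-F1 logged
#' after every epoch and the best-on-validation parameters returned (ties
#' broken by the earliest epoch). Gaussian noise and dropout are active only
#' in training passes. The run is fully reproducible given `cfg$seed`;
#' `max_epochs = 0` returns the initialization unchanged.
#'
#' @param model an [mcpcnn_model()] or an [rbert_head()].
#' @param data for the convolutional model, a list with `train` and
#'   `validation` lists of padded `candidate_instance` objects plus `set`
#'   (the [build_channel_set()]); for the relation head, lists of
#'   [preprocess_for_bert()] inputs plus `encoder`.
#' @param cfg a [train_config()].
#' @return list with the trained parameters (`model`+`set`, or
#'   `head`+`encoder`), the epoch `history` data frame, `best_epoch` and
#'   `best_f1`.
#' @export
train_model <- function(model, data, cfg = train_config()) {
  if (length(data$train) == 0) stopf("empty training set")
  with_seed(cfg$seed, {
    if (inherits(model, "mcpcnn_model")) {
      if (is.null(data$set)) stopf("data$set (channel embedding set) is required")
      train_mcpcnn(data$train, data$validation, data$set, model, cfg)
    } else if (inherits(model, "rbert_head")) {
      if (is.null(data$encoder)) stopf("data$encoder is required")
      train_rbert(data$train, data$validation, data$encoder, model, cfg)
    } else stopf("model must be an mcpcnn_model or an rbert_head")
  })
}

prf <- function(tp, fp, fn) {
  p <- if (tp + fp == 0) 0 else tp / (tp + fp)
  r <- if (tp + fn == 0) 0 else tp / (tp + fn)
  f <- if (p + r == 0) 0 else 2 * p * r / (p + r)
  c(precision = p, recall = r, f1 = f)
}

#' Evaluate predicted DDI labels against gold labels
#'
#' Computes one-vs-rest precision/recall/F1 per class, micro-averaged metrics
#' with true/false positives pooled over the four positive classes only
#' (`negative` excluded, the DDI challenge convention), an all-class micro
#' variant and macro averages, and the 5x5 confusion matrix with
#' row-normalized proportions. F1 uses the 0/0 -> 0 convention.
#'
#' @param pred,gold equal-length character vectors over the class schema
#'   `c("negative", "mechanism", "effect", "advice", "int")`.
#' @return object of class `eval_report`: list with `per_class` (data frame),
#'   `micro`, `micro_all`, `macro` (named vectors), `confusion` (counts) and
#'   `confusion_prop` (row proportions).
#' @export
evaluate_predictions <- function(pred, gold) {
  if (length(pred) != length(gold))
    stopf("pred (%d) and gold (%d) differ in length", length(pred), length(gold))
  bad <- setdiff(unique(c(pred, gold)), DDI_CLASSES)
  if (length(bad)) stopf("unknown label(s): %s", paste(bad, collapse = ", "))
  pf <- factor(pred, levels = DDI_CLASSES)
  gf <- factor(gold, levels = DDI_CLASSES)
  conf <- table(gold = gf, predicted = pf)

  per <- t(vapply(DDI_CLASSES, function(cl) {
    tp <- conf[cl, cl]
    fp <- sum(conf[, cl]) - tp
    fn <- sum(conf[cl, ]) - tp
    c(prf(tp, fp, fn), support = sum(conf[cl, ]))
  }, numeric(4)))
  per_class <- data.frame(class = DDI_CLASSES, per, row.names = NULL)

  pool <- function(classes) {
    tp <- sum(vapply(classes, function(cl) conf[cl, cl], 0))
    fp <- sum(vapply(classes, function(cl) sum(conf[, cl]) - conf[cl, cl], 0))
    fn <- sum(vapply(classes, function(cl) sum(conf[cl, ]) - conf[cl, cl], 0))
    prf(tp, fp, fn)
  }
  micro <- pool(DDI_POSITIVE_CLASSES)
  micro_all <- pool(DDI_CLASSES)
  macro <- c(precision = mean(per_class$precision[-1]),
             recall = mean(per_class$recall[-1]),
             f1 = mean(per_class$f1[-1]))
  rs <- rowSums(conf)
  prop <- sweep(conf, 1L, ifelse(rs == 0, 1, rs), `/`)
  structure(list(per_class = per_class, micro = micro, micro_all = micro_all,
                 macro = macro, confusion = unclass(conf),
                 confusion_prop = unclass(prop), n = length(gold)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, digits = 4, ...) {
  cat(sprintf("DDI evaluation over %d instances\n", x$n))
  df <- x$per_class
  df$precision <- round(df$precision, digits)
  df$recall <- round(df$recall, digits)
  df$f1 <- round(df$f1, digits)
  print(df, row.names = FALSE)
  cat(sprintf("micro (positive classes): P=%.4f R=%.4f F1=%.4f\n",
              x$micro["precision"], x$micro["recall"], x$micro["f1"]))
  cat("confusion (gold rows x predicted columns):\n")
  print(x$confusion)
  invisible(x)
}

#' Write an evaluation report to JSON (and the confusion matrix to TSV)
#'
#' @param report an [evaluate_predictions()] result.
#' @param path JSON output path.
#' @param confusion_tsv optional path for a tab-separated confusion matrix.
#' @return `path`, invisibly.
#' @export
write_eval_report <- function(report, path, confusion_tsv = NULL) {
  out <- list(per_class = report$per_class,
              micro = as.list(report$micro),
              micro_all = as.list(report$micro_all),
              macro = as.list(report$macro),
              confusion = report$confusion, n = report$n)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  if (!is.null(confusion_tsv)) {
    m <- report$confusion
    utils::write.table(m, confusion_tsv, sep = "\t", quote = FALSE,
                       col.names = NA)
  }
  invisible(path)
}
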