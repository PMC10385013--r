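# End-to-end plumbing: documents -> filtered, position-encoded, fixed-length
# candidate instances ready for the convolutional model, or marked inputs for
# the relation head.

#' Build model-ready candidate instances from documents
#'
#' Runs [generate_candidates()], [filter_negatives()], [encode_positions()]
#' and [pad_or_truncate()] over every sentence (optionally a subset).
#'
#' @param docs list of [ddi_document()] objects.
#' @param sentence_ids optional character vector restricting to these
#'   sentences (e.g. one side of [split_validation()]).
#' @param anonymization passed to [generate_candidates()].
#' @param synonyms passed to [filter_negatives()].
#' @param max_dist position clipping range.
#' @param max_len padded length.
#' @return list of padded `candidate_instance` objects.
#' @export
corpus_candidates <- function(docs, sentence_ids = NULL,
                              anonymization = "tag", synonyms = NULL,
                              max_dist = 60L, max_len = 150L) {
  if (inherits(docs, "ddi_document")) docs <- list(docs)
  out <- list()
  for (d in docs) for (s in d$sentences) {
    if (!is.null(sentence_ids) && !(s$id %in% sentence_ids)) next
    insts <- generate_candidates(s, anonymization = anonymization)
    if (length(insts) == 0) next
    insts <- filter_negatives(insts, synonyms = synonyms)
    insts <- lapply(insts, function(x)
      pad_or_truncate(encode_positions(x, max_dist), max_len))
    out <- c(out, insts)
  }
  out
}

#' Select the training subset of candidate instances
#'
#' Drops instances flagged by [filter_negatives()] *only* when their label is
#' negative: gold positives are never removed from training.
#'
#' @param instances list of `candidate_instance` objects.
#' @return filtered list.
#' @export
training_instances <- function(instances) {
  Filter(function(x) !(isTRUE(x$filtered) && x$label == "negative"), instances)
}

#' Build marked relation-head inputs from documents
#'
#' Applies [preprocess_for_bert()] to every annotated pair of every sentence.
#' Pairs whose entities cannot be disjointly marked (overlapping first spans)
#' are skipped with a warning.
#'
#' @param docs list of [ddi_document()] objects.
#' @param sentence_ids optional sentence-id subset.
#' @param tokenizer,max_len passed to [preprocess_for_bert()].
#' @return list of `bert_input` objects.
#' @export
corpus_bert_inputs <- function(docs, sentence_ids = NULL,
                               tokenizer = lowercase_tokenizer,
                               max_len = 64L) {
  if (inherits(docs, "ddi_document")) docs <- list(docs)
  out <- list()
  for (d in docs) for (s in d$sentences) {
    if (!is.null(sentence_ids) && !(s$id %in% sentence_ids)) next
    for (p in s$pairs) {
      bi <- tryCatch(
        preprocess_for_bert(s, p, tokenizer = tokenizer, max_len = max_len),
        error = function(e) { warnf("skipping pair '%s': %s", p$id,
                                    conditionMessage(e)); NULL })
      if (!is.null(bi)) out[[length(out) + 1L]] <- bi
    }
  }
  out
}

#' Read a YAML run configuration
#'
#' Convenience loader for experiment configuration files whose keys mirror the
#' reference settings (`batch_size`, `embedding`, `kernels`, `filters`,
#' `dropout`, `adam_lr`, `gaussian_noise`, ...).
#'
#' @param path YAML file path.
#' @return named list.
#' @export
load_run_config <- function(path) yaml::read_yaml(path)
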