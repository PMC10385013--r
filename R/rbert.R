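# Relation head over a pluggable bidirectional encoder. A relation statement
# is the triple (token sequence, entity 1 span, entity 2 span); the two
# entities partition the sentence into five parts (e1, e2 and contexts c0, c1,
# c2). The head pools selected parts of the encoder's hidden states, projects
# and concatenates them into a fixed-length relation representation, applies
# Gaussian noise (training only) and dropout, and classifies with a softmax.
#
# The encoder is an interface, not a dependency: a seeded two-layer
# self-attention encoder ships for CPU-scale experiments, and any function
# (tokens, entity ids) -> hidden matrix — e.g. a pretrained biomedical
# transformer — can be plugged in instead.

#' Entity positional encoding of a marked input
#'
#' Recomputes the `{0,1,2}` id sequence from the stored entity spans: 1
#' exactly on the first entity's tokens, 2 on the second entity's, 0 on all
#' context and control tokens.
#'
#' @param bert_input a [preprocess_for_bert()] result.
#' @return integer vector over the padded token sequence.
#' @export
entity_positional_encoding <- function(bert_input) {
  s1 <- bert_input$spans$e1
  s2 <- bert_input$spans$e2
  if (is.null(s1) || is.null(s2) || s1[1] > s1[2] || s2[1] > s2[2])
    stopf("input has no entity spans")
  if (s1[2] >= s2[1] && s2[2] >= s1[1])
    stopf("entity spans [%d,%d] and [%d,%d] overlap", s1[1], s1[2], s2[1], s2[2])
  ids <- integer(length(bert_input$tokens))
  ids[s1[1]:s1[2]] <- 1L
  ids[s2[1]:s2[2]] <- 2L
  ids
}

#' Pool a span of hidden states into one vector
#'
#' @param h an `n x d` hidden-state matrix.
#' @param span length-2 integer `c(start, end)` (1-based, inclusive). An empty
#'   span (start > end, or `NULL`) pools to the zero vector.
#' @param method `"average"`, `"max"`, `"self_attention"` (softmax of `w'h`
#'   scores weighting the rows; `w = 0` gives the average) or `"start"` (the
#'   span's first row).
#' @param w score vector for self-attention pooling (default zero).
#' @return numeric vector of length `d`. On a single-row span all four
#'   methods return that row.
#' @export
pool_segment <- function(h, span,
                         method = c("average", "max", "self_attention", "start"),
                         w = NULL) {
  method <- match.arg(method)
  d <- ncol(h)
  if (is.null(span) || span[1] > span[2]) return(numeric(d))
  rows <- h[span[1]:span[2], , drop = FALSE]
  switch(method,
    average = colMeans(rows),
    max = apply(rows, 2L, max),
    start = rows[1L, ],
    self_attention = {
      if (is.null(w)) w <- numeric(d)
      a <- softmax(as.vector(rows %*% w))
      as.vector(crossprod(rows, a))
    })
}

#' Configure the relation head
#'
#' @param d encoder hidden size.
#' @param d_proj width of each part's learned affine+tanh projection
#'   (default `d`).
#' @param pooling named list of pooling methods per part; defaults to start
#'   pooling for `[CLS]` and average pooling for the two entities (contexts
#'   average when enabled).
#' @param use_cls,use_entities,use_contexts which parts feed the relation
#'   representation (defaults: CLS and entities on, contexts off).
#' @param interaction `"none"`, `"dot"` (appends `h_e1 * h_e2` elementwise) or
#'   `"absdiff"` (appends `|h_e1 - h_e2|`).
#' @param noise a [noise_config()]; default std 0.3 at the pre-classifier site.
#' @param dropout dropout rate before the classifier (default 0.1).
#' @param seed seed for the projection and classifier initialization.
#' @return object of class `rbert_head`.
#' @export
rbert_head <- function(d, d_proj = d,
                       pooling = list(), use_cls = TRUE, use_entities = TRUE,
                       use_contexts = FALSE,
                       interaction = c("none", "dot", "absdiff"),
                       noise = noise_config(std = 0.3), dropout = 0.1,
                       seed = 1L) {
  interaction <- match.arg(interaction)
  parts <- c(if (use_cls) "cls", if (use_entities) c("e1", "e2"),
             if (use_contexts) c("c0", "c1", "c2"))
  if (length(parts) == 0) stopf("at least one feature source must be enabled")
  pool_default <- list(cls = "start", e1 = "average", e2 = "average",
                       c0 = "average", c1 = "average", c2 = "average")
  pooling <- utils::modifyList(pool_default, pooling)
  hr_len <- length(parts) * d_proj + if (interaction == "none") 0L else d
  with_seed(seed, {
    proj <- lapply(stats::setNames(parts, parts), function(p)
      list(w = glorot_matrix(d, d_proj), b = numeric(d_proj)))
    ws <- glorot_matrix(hr_len, length(DDI_CLASSES))
  })
  attn_w <- lapply(stats::setNames(parts, parts), function(p) numeric(d))
  structure(list(
    d = as.integer(d), d_proj = as.integer(d_proj), parts = parts,
    pooling = pooling, interaction = interaction, proj = proj,
    attn_w = attn_w, ws = ws, b = numeric(length(DDI_CLASSES)),
    hr_len = as.integer(hr_len), noise = noise, dropout = dropout
  ), class = "rbert_head")
}

#' Combine pooled part vectors into a relation representation
#'
#' Each enabled part goes through its learned affine+tanh projection; the
#' projected parts are concatenated, followed by the entity interaction block
#' when configured (`dot`: `h_e1 * h_e2`; `absdiff`: `|h_e1 - h_e2|`). The
#' result length depends only on the head configuration, never on sentence
#' length.
#'
#' @param pooled named list of pooled vectors (`cls`, `e1`, `e2`, optionally
#'   `c0`, `c1`, `c2`).
#' @param head an [rbert_head()].
#' @return numeric relation representation of length `head$hr_len`.
#' @export
combine_features <- function(pooled, head) {
  blocks <- lapply(head$parts, function(p) {
    pr <- head$proj[[p]]
    tanh(as.vector(crossprod(pr$w, pooled[[p]])) + pr$b)
  })
  hr <- unlist(blocks, use.names = FALSE)
  if (head$interaction == "dot") {
    hr <- c(hr, pooled$e1 * pooled$e2)
  } else if (head$interaction == "absdiff") {
    hr <- c(hr, abs(pooled$e1 - pooled$e2))
  }
  hr
}

# -- tiny trainable encoder ---------------------------------------------------

TINY_SPECIALS <- c("[PAD]", "[CLS]", "[SEP]", "[UNK]")

#' Seeded tiny self-attention encoder
#'
#' A small bidirectional encoder for CPU-scale experiments: token + learned
#' position + entity-position embeddings (the entity positional embedding
#' module is part of the input pathway and is fine-tuned with everything
#' else), followed by `n_layers` blocks of single-head scaled dot-product
#' self-attention and a tanh feed-forward, both with residual connections.
#'
#' @param vocab character vector of vocabulary words (control tokens and the
#'   entity markers are added automatically).
#' @param d hidden size (default 16).
#' @param n_layers number of blocks (default 2).
#' @param d_ff feed-forward width (default 32).
#' @param max_len maximum sequence length (default 64).
#' @param markers entity marker strings to include in the vocabulary.
#' @param seed integer seed; the same seed gives bit-identical parameters.
#' @return object of class `tiny_encoder`.
#' @export
tiny_encoder <- function(vocab, d = 16L, n_layers = 2L, d_ff = 32L,
                         max_len = 64L, markers = c("$", "#"), seed = 1L) {
  words <- unique(c(TINY_SPECIALS, markers, vocab))
  with_seed(seed, {
    par <- list(
      e_tok = matrix(stats::rnorm(length(words) * d, 0, 0.1), ncol = d),
      e_pos = matrix(stats::rnorm(max_len * d, 0, 0.1), ncol = d),
      e_ent = matrix(stats::rnorm(3L * d, 0, 0.1), ncol = d),
      layers = lapply(seq_len(n_layers), function(l) list(
        wq = glorot_matrix(d, d), wk = glorot_matrix(d, d),
        wv = glorot_matrix(d, d),
        w1 = glorot_matrix(d, d_ff), b1 = numeric(d_ff),
        w2 = glorot_matrix(d_ff, d), b2 = numeric(d)
      ))
    )
  })
  structure(list(
    index = stats::setNames(seq_along(words), words), words = words,
    d = as.integer(d), n_layers = as.integer(n_layers),
    d_ff = as.integer(d_ff), max_len = as.integer(max_len), par = par
  ), class = "tiny_encoder")
}

#' @export
print.tiny_encoder <- function(x, ...) {
  cat(sprintf("<tiny_encoder: %d layers, d=%d, vocab %d>\n",
              x$n_layers, x$d, length(x$words)))
  invisible(x)
}

encoder_token_ids <- function(enc, tokens) {
  idx <- unname(enc$index[tokens])
  idx[is.na(idx)] <- enc$index[["[UNK]"]]
  idx
}

# Forward pass over the non-pad prefix of a marked input; optionally keeps
# every intermediate needed for backpropagation.
tiny_encoder_forward <- function(enc, tokens, ent_ids, keep_cache = FALSE) {
  n <- length(tokens)
  if (n > enc$max_len)
    stopf("sequence length %d exceeds encoder max_len %d", n, enc$max_len)
  ids <- encoder_token_ids(enc, tokens)
  h <- enc$par$e_tok[ids, , drop = FALSE] +
    enc$par$e_pos[seq_len(n), , drop = FALSE] +
    enc$par$e_ent[ent_ids + 1L, , drop = FALSE]
  scale <- 1 / sqrt(enc$d)
  cache <- list(ids = ids, ent_ids = ent_ids, n = n, layers = list())
  for (l in seq_len(enc$n_layers)) {
    lp <- enc$par$layers[[l]]
    q <- h %*% lp$wq
    k <- h %*% lp$wk
    v <- h %*% lp$wv
    a <- softmax(tcrossprod(q, k) * scale)
    h1 <- h + a %*% v
    u <- tanh(sweep(h1 %*% lp$w1, 2L, lp$b1, `+`))
    h2 <- h1 + sweep(u %*% lp$w2, 2L, lp$b2, `+`)
    if (keep_cache)
      cache$layers[[l]] <- list(h = h, q = q, k = k, v = v, a = a, h1 = h1, u = u)
    h <- h2
  }
  if (keep_cache) list(h = h, cache = cache) else h
}

# Resolve an encoder argument: tiny_encoder object or plain function.
encode_sequence <- function(encoder, tokens, ent_ids) {
  if (inherits(encoder, "tiny_encoder"))
    tiny_encoder_forward(encoder, tokens, ent_ids)
  else if (is.function(encoder)) encoder(tokens, ent_ids)
  else stopf("encoder must be a tiny_encoder or a function(tokens, ent_ids)")
}

rbert_pool_all <- function(h, bert_input, head) {
  spans <- bert_input$spans
  pooled <- list()
  for (p in head$parts) {
    pooled[[p]] <- pool_segment(h, spans[[p]], head$pooling[[p]],
                                w = head$attn_w[[p]])
  }
  if (head$interaction != "none") {
    if (is.null(pooled$e1)) pooled$e1 <- pool_segment(h, spans$e1, "average")
    if (is.null(pooled$e2)) pooled$e2 <- pool_segment(h, spans$e2, "average")
  }
  pooled
}

#' Forward pass of the entity-marker relation model
#'
#' Encodes the non-pad token prefix (entity positional ids are added to the
#' encoder's input embedding pathway), pools the configured sentence parts,
#' combines them into the relation representation, applies Gaussian noise
#' (training only) and dropout, and classifies over the five classes. With
#' `training = FALSE` or noise std 0 the pass is deterministic.
#'
#' @param bert_input a [preprocess_for_bert()] result.
#' @param encoder a [tiny_encoder()] or any `function(tokens, entity_pos_ids)`
#'   returning an `n x d` hidden matrix (one row per token).
#' @param head an [rbert_head()].
#' @param training logical.
#' @return named probability vector over the five classes.
#' @export
rbert_forward <- function(bert_input, encoder, head, training = FALSE) {
  n <- bert_input$length
  tokens <- bert_input$tokens[seq_len(n)]
  ent_ids <- entity_positional_encoding(bert_input)[seq_len(n)]
  h <- encode_sequence(encoder, tokens, ent_ids)
  if (nrow(h) != n)
    stopf("encoder returned %d rows for %d tokens", nrow(h), n)
  pooled <- rbert_pool_all(h, bert_input, head)
  hr <- combine_features(pooled, head)
  if (training && head$noise$site %in% c("pre_classifier", "both"))
    hr <- gaussian_noise(hr, head$noise, TRUE)
  if (training && head$dropout > 0) {
    keep <- (stats::runif(length(hr)) >= head$dropout) / (1 - head$dropout)
    hr <- hr * keep
  }
  o <- as.vector(crossprod(head$ws, hr)) + head$b
  stats::setNames(softmax(o), DDI_CLASSES)
}
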