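fake_bert_input <- function(tokens, e1, e2, n_real = length(tokens),
                            label = "negative") {
  structure(list(
    sentence_id = "f0", pair_id = "f0.p0", tokens = tokens,
    entity_pos_ids = integer(length(tokens)),
    attention_mask = c(rep(1L, n_real), integer(length(tokens) - n_real)),
    spans = list(cls = c(1L, 1L), e1 = e1, e2 = e2,
                 c0 = c(2L, e1[1] - 1L), c1 = c(e1[2] + 1L, e2[1] - 1L),
                 c2 = c(e2[2] + 1L, n_real - 1L)),
    length = n_real, label = label
  ), class = "bert_input")
}

test_that("entity positional encoding marks exactly the two entity spans", {
  bi <- fake_bert_input(letters[1:8], e1 = c(3L, 4L), e2 = c(7L, 7L))
  expect_identical(entity_positional_encoding(bi),
                   c(0L, 0L, 1L, 1L, 0L, 0L, 2L, 0L))
  # overlap and missing spans are rejected
  bad <- fake_bert_input(letters[1:8], e1 = c(3L, 5L), e2 = c(5L, 6L))
  expect_error(entity_positional_encoding(bad), "overlap")
  none <- fake_bert_input(letters[1:8], e1 = c(3L, 2L), e2 = c(7L, 7L))
  expect_error(entity_positional_encoding(none), "no entity spans")
})

test_that("segment pooling implements its four methods", {
  h <- rbind(c(1, 4), c(3, 2))
  expect_equal(pool_segment(h, c(1L, 2L), "average"), c(2, 3))
  expect_equal(pool_segment(h, c(1L, 2L), "max"), c(3, 4))
  expect_equal(pool_segment(h, c(1L, 2L), "start"), c(1, 4))
  # self-attention with w = 0 reduces to the average
  expect_equal(pool_segment(h, c(1L, 2L), "self_attention"), c(2, 3))
  # non-trivial weights prefer the higher-scoring row
  w <- c(10, 0)
  sa <- pool_segment(h, c(1L, 2L), "self_attention", w = w)
  expect_gt(sa[1], 2.9)
  # single-row spans: all methods coincide
  for (m in c("average", "max", "self_attention", "start"))
    expect_equal(pool_segment(h, c(2L, 2L), m), c(3, 2))
  # empty spans pool to zero
  expect_equal(pool_segment(h, c(2L, 1L), "average"), c(0, 0))
})

test_that("combine_features concatenates projections and interactions", {
  head <- rbert_head(d = 4L, d_proj = 3L, seed = 1L)
  pooled <- list(cls = rnorm(4), e1 = rnorm(4), e2 = rnorm(4))
  hr <- combine_features(pooled, head)
  expect_length(hr, 3L * 3L)       # cls, e1, e2 blocks
  expect_identical(head$hr_len, 9L)
  # absdiff appends a zero block when the entity vectors agree
  head2 <- rbert_head(d = 4L, d_proj = 3L, interaction = "absdiff", seed = 1L)
  pooled2 <- pooled
  pooled2$e2 <- pooled2$e1
  hr2 <- combine_features(pooled2, head2)
  expect_length(hr2, 9L + 4L)
  expect_true(all(hr2[10:13] == 0))
  # dot interaction is symmetric in the entity vectors
  head3 <- rbert_head(d = 4L, d_proj = 3L, interaction = "dot", seed = 1L)
  a <- combine_features(pooled, head3)
  swapped <- pooled
  swapped$e1 <- pooled$e2
  swapped$e2 <- pooled$e1
  b <- combine_features(swapped, head3)
  expect_equal(a[10:13], b[10:13])
  expect_error(rbert_head(d = 4L, use_cls = FALSE, use_entities = FALSE),
               "at least one")
})

test_that("the relation representation length ignores sentence length", {
  enc <- tiny_encoder(letters, d = 8L, max_len = 32L, seed = 3L)
  head <- rbert_head(d = 8L, seed = 4L)
  for (n in c(6L, 12L, 20L)) {
    toks <- c("[CLS]", letters[seq_len(n - 3L)], "x", "[SEP]")
    bi <- fake_bert_input(toks, e1 = c(2L, 2L), e2 = c(4L, 4L))
    fwd <- ddigauss:::rbert_forward_train(bi, enc, head, training = FALSE)
    expect_length(combine_features(fwd$pooled, head), head$hr_len)
  }
})

test_that("forward pass is deterministic, normalized and noise-neutral", {
  s <- token_sentence(c("Adrug", "interacts", "strongly", "with", "Bdrug"),
                      list(1L, 5L),
                      pairs = list(drug_pair("tk0.p0", "tk0.e0", "tk0.e1",
                                             ddi = TRUE, itype = "effect")))
  bi <- preprocess_for_bert(s, s$pairs[[1]], max_len = 24L)
  enc <- tiny_encoder(tolower(corpus_vocabulary(list(ddi_document("d", "",
    list(s))))), d = 16L, max_len = 24L, seed = 5L)
  head <- rbert_head(d = 16L, seed = 6L)
  p1 <- rbert_forward(bi, enc, head)
  p2 <- rbert_forward(bi, enc, head)
  expect_identical(p1, p2)
  expect_lt(abs(sum(p1) - 1), 1e-9)
  # sigma = 0 equals a graph with the noise layer disabled, under one seed
  h0 <- head
  h0$noise <- noise_config(std = 0)
  hoff <- head
  hoff$noise <- noise_config(std = 0.3, elem_prob = 0)
  set.seed(12); a <- rbert_forward(bi, enc, h0, training = TRUE)
  set.seed(12); b <- rbert_forward(bi, enc, hoff, training = TRUE)
  expect_identical(a, b)
  # eval mode ignores noise entirely
  expect_identical(rbert_forward(bi, enc, head), rbert_forward(bi, enc, h0))
  # a plain-function encoder is accepted; row-count mismatches are rejected
  fenc <- function(tokens, ent) matrix(0.1, length(tokens), 16L)
  expect_lt(abs(sum(rbert_forward(bi, fenc, head)) - 1), 1e-9)
  bad <- function(tokens, ent) matrix(0.1, 3L, 16L)
  expect_error(rbert_forward(bi, bad, head), "rows")
})

test_that("same seed reproduces the tiny encoder bit for bit", {
  e1 <- tiny_encoder(letters, d = 8L, seed = 9L)
  e2 <- tiny_encoder(letters, d = 8L, seed = 9L)
  expect_identical(e1$par, e2$par)
})

test_that("head training improves fit on a small separable toy set", {
  g <- generate_corpus(synthetic_spec(n_documents = 20L,
                                      sentences_per_document = c(4L, 4L),
                                      drugs_per_sentence = c(2L, 2L),
                                      p_coordination = 0, p_duplicate_name = 0,
                                      seed = 55L))
  docs <- g$documents
  sp <- split_validation(docs, 0.15, seed = 56L)
  tr <- corpus_bert_inputs(docs, sp$train, max_len = 40L)
  va <- corpus_bert_inputs(docs, sp$validation, max_len = 40L)
  enc <- tiny_encoder(tolower(corpus_vocabulary(docs)), d = 16L,
                      max_len = 40L, seed = 57L)
  head <- rbert_head(d = 16L, seed = 58L)
  cfg <- train_config(batch_size = 16L, learning_rate = 2e-3,
                      max_epochs = 12L, patience = 12L, seed = 5L)
  res <- train_model(head, list(train = tr, validation = va, encoder = enc),
                     cfg)
  expect_lt(res$history$train_loss[12], res$history$train_loss[1])
  expect_gte(res$best_f1, 0.6)
  # reproducibility of the whole run
  res2 <- train_model(head, list(train = tr, validation = va, encoder = enc),
                      cfg)
  expect_identical(res$history, res2$history)
})
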