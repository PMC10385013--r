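# Shared fixtures, all built in code.

# The three-drug worked example: "Aminoglutethimide decreases the effect of
# coumarin and warfarin" with its gold pairs (both coumarin pairs interact by
# effect in the original annotation; labels here exercise the label plumbing).
aminoglutethimide_sentence <- function(with_pairs = FALSE) {
  pairs <- if (with_pairs) list(
    drug_pair("s0.p0", "s0.e0", "s0.e1", ddi = TRUE, itype = "effect"),
    drug_pair("s0.p1", "s0.e0", "s0.e2", ddi = TRUE, itype = "effect"),
    drug_pair("s0.p2", "s0.e1", "s0.e2", ddi = FALSE)
  ) else list()
  ddi_sentence(
    "s0", "Aminoglutethimide decreases the effect of coumarin and warfarin",
    entities = list(
      entity_mention("s0.e0", list(c(0L, 16L)), "drug", "Aminoglutethimide"),
      entity_mention("s0.e1", list(c(42L, 49L)), "drug", "coumarin"),
      entity_mention("s0.e2", list(c(55L, 62L)), "drug", "warfarin")),
    pairs = pairs)
}

# Annotated-corpus example sentence with a discontinuous-style long mention.
tetracycline_sentence <- function() {
  txt <- paste0("Tetracycline, a bacteriostatic antibiotic, may antagonize ",
                "the bactericidal effect of penicillin.")
  ddi_sentence(
    "t0", txt,
    entities = list(
      entity_mention("t0.e0", list(c(0L, 11L)), "drug", "Tetracycline"),
      entity_mention("t0.e1", list(c(16L, 40L)), "group",
                     "bacteriostatic antibiotic"),
      entity_mention("t0.e2", list(c(85L, 94L)), "drug", "penicillin")),
    pairs = list(drug_pair("t0.p0", "t0.e0", "t0.e2", ddi = TRUE,
                           itype = "effect")))
}

# Build a sentence from space-joined tokens; entity_tokens maps entity ordinal
# to a token index (1-based). Surfaces are single tokens.
token_sentence <- function(tokens, entity_tokens, pairs = list(),
                           id = "tk0") {
  nch <- nchar(tokens)
  starts <- cumsum(c(0L, nch[-length(nch)] + 1L))
  ents <- lapply(seq_along(entity_tokens), function(k) {
    ti <- entity_tokens[[k]]
    entity_mention(sprintf("%s.e%d", id, k - 1L),
                   list(c(starts[ti], starts[ti] + nch[ti] - 1L)),
                   "drug", tokens[ti])
  })
  ddi_sentence(id, paste(tokens, collapse = " "), entities = ents,
               pairs = pairs)
}

# Minimal one-pair fixture.
minimal_sentence <- function() {
  token_sentence(c("Alphadrug", "inhibits", "Betadrug"), list(1L, 3L),
                 pairs = list(drug_pair("tk0.p0", "tk0.e0", "tk0.e1",
                                        ddi = TRUE, itype = "effect")))
}

minimal_document <- function() ddi_document("d0", "drugbank",
                                            list(minimal_sentence()))

# Tiny embedding channel set over a given vocabulary.
tiny_channel_set <- function(vocab, k = 8L, n_channels = 2L, max_dist = 10L,
                             k_pos = 3L, seed = 42L) {
  tabs <- generate_channel_embeddings(vocab, k = k, n_channels = n_channels,
                                      seed = seed)
  build_channel_set(tabs, max_dist = max_dist, k_pos = k_pos, seed = seed + 1L)
}

# Small synthetic corpus shared by several tests.
small_corpus <- function(n_documents = 10L, seed = 7L, ...) {
  generate_corpus(synthetic_spec(n_documents = n_documents, seed = seed, ...))
}
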