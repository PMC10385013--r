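# Synthetic DDI corpus generation. Every sentence is built from a
# class-specific trigger template around a target drug pair, with optional
# coordination lists (fodder for the coordination filter rule), duplicate-name
# mentions (fodder for the same-drug rule) and extra drug mentions attached by
# non-coordinating connectors. Drug names are pronounceable synthetic
# consonant-vowel strings, not real drug lexicons, and a JSON-serializable
# ledger records every draw so stochastic tests can check the generator's own
# ground truth against what the pipeline recovers.

trigger_templates <- function() {
  list(
    mechanism = c(
      "the half-life of E1 was prolonged in the presence of E2",
      "E1 markedly increases the plasma concentration of E2",
      "E1 reduces the renal clearance of E2"),
    effect = c(
      "E1 may antagonize the sedative effect of E2",
      "E1 potentiates the hypotensive action of E2",
      "pretreatment with E1 enhanced the bradycardia produced by E2"),
    advice = c(
      "E1 should not be administered to patients receiving E2",
      "concomitant use of E1 is not recommended during therapy with E2",
      "caution is required when E1 is given together with E2"),
    int = c(
      "a possible interaction of E1 with E2 has been reported",
      "the interaction of E1 with E2 remains poorly characterized"),
    negative = c(
      "E1 was detected in the specimen that also mentioned E2",
      "patients taking E1 were enrolled before the E2 arm opened",
      "E1 appears in the formulary section that lists E2")
  )
}

#' Class-specific trigger words of the synthetic templates
#'
#' The content words that distinguish each interaction class in generated
#' sentences; the synthetic embedding channels give these words
#' class-correlated offsets so the classification task is learnable by
#' construction.
#'
#' @return named list mapping each positive class to its trigger words.
#' @export
trigger_word_classes <- function() {
  list(
    mechanism = c("half-life", "prolonged", "presence", "increases", "plasma",
                  "concentration", "reduces", "renal", "clearance"),
    effect = c("antagonize", "sedative", "effect", "potentiates",
               "hypotensive", "action", "pretreatment", "enhanced",
               "bradycardia", "produced"),
    advice = c("administered", "receiving", "recommended", "concomitant",
               "therapy", "caution", "required", "together"),
    int = c("interaction", "possible", "reported", "remains", "poorly",
            "characterized")
  )
}

EXTRA_CONNECTORS <- list(c("as", "well", "as"), c("but", "not"),
                         c("independently", "of"))
NEGATIVE_LIST_PREDICATES <- list(
  c("were", "included", "in", "the", "medication", "record"),
  c("were", "dispensed", "on", "the", "same", "day"))

#' Specify a synthetic corpus
#'
#' @param n_documents number of documents.
#' @param sentences_per_document length-2 range; each document draws uniformly.
#' @param class_proportions named probabilities over
#'   `c(mechanism, effect, advice, int, negative)`; must sum to 1.
#' @param drugs_per_sentence length-2 range of drug mentions per sentence
#'   (2-6 supported).
#' @param p_coordination probability a sentence carries a comma/conjunction
#'   drug list (coordination-rule fodder).
#' @param p_duplicate_name probability a sentence carries an extra mention
#'   with the same surface as the first target drug (same-drug-rule fodder).
#' @param vocab_size size of the generated lexicon (drug names plus filler
#'   words); at least 10.
#' @param seed integer seed; generation is fully deterministic given the spec.
#' @return list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_documents = 50L,
                           sentences_per_document = c(3L, 8L),
                           class_proportions = c(mechanism = 0.2, effect = 0.2,
                                                 advice = 0.2, int = 0.2,
                                                 negative = 0.2),
                           drugs_per_sentence = c(2L, 4L),
                           p_coordination = 0.25,
                           p_duplicate_name = 0.05,
                           vocab_size = 300L,
                           seed = 1L) {
  if (n_documents < 1) stopf("n_documents must be >= 1")
  if (vocab_size < 10) stopf("vocabulary size %d is infeasible (need >= 10)",
                             vocab_size)
  if (abs(sum(class_proportions) - 1) > 1e-8)
    stopf("class proportions must sum to 1")
  if (!setequal(names(class_proportions), DDI_CLASSES))
    stopf("class_proportions must be named over {%s}",
          paste(DDI_CLASSES, collapse = ", "))
  if (drugs_per_sentence[1] < 2 || drugs_per_sentence[2] > 6 ||
      drugs_per_sentence[1] > drugs_per_sentence[2])
    stopf("drugs_per_sentence range must be inside [2, 6]")
  if (sentences_per_document[1] < 1 ||
      sentences_per_document[1] > sentences_per_document[2])
    stopf("invalid sentences_per_document range")
  structure(list(
    n_documents = as.integer(n_documents),
    sentences_per_document = as.integer(sentences_per_document),
    class_proportions = class_proportions[DDI_CLASSES],
    drugs_per_sentence = as.integer(drugs_per_sentence),
    p_coordination = p_coordination, p_duplicate_name = p_duplicate_name,
    vocab_size = as.integer(vocab_size), seed = as.integer(seed)
  ), class = "synthetic_spec")
}

# Uniform draw from an integer range (safe when lo == hi, unlike sample()).
sample_range <- function(lo, hi) if (lo >= hi) lo else lo + sample.int(hi - lo + 1L, 1L) - 1L

# Pronounceable consonant-vowel drug names / filler words.
make_cv_words <- function(n, syllables = c(2L, 3L), capitalize = FALSE) {
  onsets <- c("b", "c", "d", "f", "g", "k", "l", "m", "n", "p", "r", "s",
              "t", "v", "z", "tr", "pl", "cl", "br", "dr")
  vowels <- c("a", "e", "i", "o", "u")
  suffix <- c("", "l", "n", "x", "r")
  out <- character(0)
  while (length(out) < n) {
    ns <- sample(syllables[1]:syllables[2], 1L)
    w <- paste0(paste0(sample(onsets, ns, replace = TRUE),
                       sample(vowels, ns, replace = TRUE), collapse = ""),
                sample(suffix, 1L))
    if (capitalize)
      w <- paste0(toupper(substr(w, 1, 1)), substr(w, 2, nchar(w)))
    out <- unique(c(out, w))
  }
  out[seq_len(n)]
}

# Assemble one sentence: returns token vector plus per-token entity ordinal
# (0 = context) and bookkeeping of constructed filter-eligible pairs.
build_sentence_tokens <- function(class, template, drug_names, coordination,
                                  duplicate, fillers) {
  n_drugs <- length(drug_names)
  ent_of <- function(words, ords) list(words = words, ords = ords)
  coordination_pairs <- list()

  if (class == "negative" && coordination) {
    # the whole sentence is a coordination list of all drugs
    words <- character(0)
    ords <- integer(0)
    for (i in seq_len(n_drugs)) {
      if (i > 1) {
        sep <- if (i == n_drugs) "and" else ","
        words <- c(words, sep)
        ords <- c(ords, 0L)
      }
      words <- c(words, drug_names[i])
      ords <- c(ords, i)
    }
    pred <- NEGATIVE_LIST_PREDICATES[[sample.int(length(NEGATIVE_LIST_PREDICATES), 1L)]]
    words <- c(words, pred)
    ords <- c(ords, integer(length(pred)))
    for (i in seq_len(n_drugs - 1L)) for (j in (i + 1L):n_drugs)
      coordination_pairs[[length(coordination_pairs) + 1L]] <- c(i, j)
  } else {
    tmpl <- strsplit(template, " ")[[1]]
    words <- character(0)
    ords <- integer(0)
    for (tk in tmpl) {
      if (tk == "E1") { words <- c(words, drug_names[1]); ords <- c(ords, 1L) }
      else if (tk == "E2") { words <- c(words, drug_names[2]); ords <- c(ords, 2L) }
      else { words <- c(words, tk); ords <- c(ords, 0L) }
    }
    extras <- seq_len(n_drugs)[-(1:2)]
    e2_pos <- which(ords == 2L)
    if (length(extras) > 0) {
      if (coordination && length(extras) >= 2) {
        tail_w <- character(0)
        tail_o <- integer(0)
        for (m in seq_along(extras)) {
          sep <- if (m == length(extras)) "and" else ","
          tail_w <- c(tail_w, sep, drug_names[extras[m]])
          tail_o <- c(tail_o, 0L, extras[m])
        }
        words <- append(words, tail_w, after = e2_pos)
        ords <- append(ords, tail_o, after = e2_pos)
        members <- c(2L, extras)
        for (a in seq_along(members)) for (b in seq_along(members))
          if (a < b)
            coordination_pairs[[length(coordination_pairs) + 1L]] <-
              c(members[a], members[b])
      } else {
        ins_w <- character(0)
        ins_o <- integer(0)
        for (x in extras) {
          conn <- EXTRA_CONNECTORS[[sample.int(length(EXTRA_CONNECTORS), 1L)]]
          ins_w <- c(ins_w, conn, drug_names[x])
          ins_o <- c(ins_o, integer(length(conn)), x)
        }
        words <- append(words, ins_w, after = e2_pos)
        ords <- append(ords, ins_o, after = e2_pos)
      }
    }
  }

  duplicate_pair <- NULL
  if (duplicate) {
    dup_ord <- n_drugs + 1L
    words <- c(words, "as", "documented", "for", drug_names[1])
    ords <- c(ords, 0L, 0L, 0L, dup_ord)
    duplicate_pair <- c(1L, dup_ord)
  }

  if (stats::runif(1) < 0.3) {
    filler <- sample(fillers, 1L)
    words <- c("in", "the", filler, "study", ",", words)
    ords <- c(integer(5L), ords)
  }
  list(words = words, ords = ords,
       coordination_pairs = coordination_pairs,
       duplicate_pair = duplicate_pair)
}

#' Generate a synthetic DDI corpus
#'
#' Each positive sentence embeds exactly one class-specific trigger template
#' around its target pair; negative sentences use distractor predicates or a
#' pure coordination list. With probability `p_coordination` a
#' comma/conjunction drug list is inserted (these pairs are recorded as
#' coordination-eligible) and with `p_duplicate_name` a mention repeating the
#' first target drug's surface is appended. The ledger records every drawn
#' class, template, and filter-eligible pair; the documents validate under
#' the corpus reader/writer and the same seed reproduces the corpus exactly.
#'
#' @param spec a [synthetic_spec()].
#' @return list with `documents` (list of [ddi_document()]) and `ledger`
#'   (sentence table, pair-class counts, coordination/duplicate pair tables,
#'   and the drug/filler lexicons).
#' @export
generate_corpus <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  tmpls <- trigger_templates()
  with_seed(spec$seed, {
    n_names <- max(20L, as.integer(round(spec$vocab_size * 0.4)))
    n_fill <- max(5L, spec$vocab_size - n_names)
    drug_lexicon <- make_cv_words(n_names, capitalize = TRUE)
    fillers <- make_cv_words(n_fill, capitalize = FALSE)

    docs <- vector("list", spec$n_documents)
    sent_rows <- list()
    coord_rows <- list()
    dup_rows <- list()
    pair_counts <- stats::setNames(integer(length(DDI_CLASSES)), DDI_CLASSES)
    s_global <- 0L
    for (di in seq_len(spec$n_documents)) {
      doc_id <- sprintf("SYN.d%03d", di)
      n_sent <- sample_range(spec$sentences_per_document[1],
                             spec$sentences_per_document[2])
      sentences <- vector("list", n_sent)
      for (si in seq_len(n_sent)) {
        s_global <- s_global + 1L
        sid <- sprintf("%s.s%d", doc_id, si - 1L)
        class <- sample(DDI_CLASSES, 1L, prob = spec$class_proportions)
        n_drugs <- sample_range(spec$drugs_per_sentence[1],
                                spec$drugs_per_sentence[2])
        coordination <- stats::runif(1) < spec$p_coordination
        if (coordination && class != "negative" && n_drugs < 4L)
          n_drugs <- min(4L, spec$drugs_per_sentence[2] + 2L)
        if (coordination && class == "negative")
          n_drugs <- max(n_drugs, 3L)
        duplicate <- stats::runif(1) < spec$p_duplicate_name
        names_i <- sample(drug_lexicon, n_drugs)
        tset <- tmpls[[class]]
        t_idx <- sample.int(length(tset), 1L)
        bs <- build_sentence_tokens(class, tset[t_idx], names_i,
                                    coordination, duplicate, fillers)
        # character offsets: tokens joined by single spaces
        nch <- nchar(bs$words)
        startc <- cumsum(c(0L, nch[-length(nch)] + 1L))
        text <- paste(bs$words, collapse = " ")
        ent_ords <- sort(unique(bs$ords[bs$ords > 0L]))
        entities <- lapply(ent_ords, function(o) {
          pos <- which(bs$ords == o)[1]
          st <- startc[pos]
          entity_mention(
            id = sprintf("%s.e%d", sid, o - 1L),
            char_spans = list(c(st, st + nch[pos] - 1L)),
            etype = sample(c("drug", "drug", "drug", "brand", "group"), 1L),
            surface = bs$words[pos])
        })
        eid <- function(o) sprintf("%s.e%d", sid, o - 1L)
        pairs <- list()
        pk <- 0L
        n_ent <- length(ent_ords)
        for (a in seq_len(n_ent - 1L)) for (b in (a + 1L):n_ent) {
          oa <- ent_ords[a]; ob <- ent_ords[b]
          positive <- class != "negative" && oa == 1L && ob == 2L
          pairs[[length(pairs) + 1L]] <- drug_pair(
            id = sprintf("%s.p%d", sid, pk), e1 = eid(oa), e2 = eid(ob),
            ddi = positive, itype = if (positive) class)
          pair_counts[if (positive) class else "negative"] <-
            pair_counts[if (positive) class else "negative"] + 1L
          pk <- pk + 1L
        }
        sentences[[si]] <- ddi_sentence(sid, text, entities, pairs)
        sent_rows[[s_global]] <- data.frame(
          sentence_id = sid, document_id = doc_id, class = class,
          template = t_idx, n_entities = n_ent,
          coordination = coordination, duplicate = duplicate)
        for (cp in bs$coordination_pairs)
          coord_rows[[length(coord_rows) + 1L]] <- data.frame(
            sentence_id = sid, e1 = eid(cp[1]), e2 = eid(cp[2]))
        if (!is.null(bs$duplicate_pair))
          dup_rows[[length(dup_rows) + 1L]] <- data.frame(
            sentence_id = sid, e1 = eid(bs$duplicate_pair[1]),
            e2 = eid(bs$duplicate_pair[2]))
      }
      docs[[di]] <- ddi_document(doc_id,
                                 source_tag = sample(c("drugbank", "medline"), 1L),
                                 sentences = sentences)
    }
  })
  sent_tab <- do.call(rbind, sent_rows)
  ledger <- list(
    spec = unclass(spec),
    sentences = sent_tab,
    sentence_class_counts = as.list(table(factor(sent_tab$class,
                                                 levels = DDI_CLASSES))),
    pair_class_counts = as.list(pair_counts),
    coordination_pairs = if (length(coord_rows)) do.call(rbind, coord_rows)
                         else data.frame(sentence_id = character(0),
                                         e1 = character(0), e2 = character(0)),
    duplicate_pairs = if (length(dup_rows)) do.call(rbind, dup_rows)
                      else data.frame(sentence_id = character(0),
                                      e1 = character(0), e2 = character(0)),
    drug_lexicon = drug_lexicon, fillers = fillers
  )
  list(documents = docs, ledger = ledger)
}

#' Write a generator ledger to JSON
#'
#' @param ledger the `ledger` element of [generate_corpus()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ledger_json <- function(ledger, path) {
  jsonlite::write_json(ledger, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

#' Vocabulary of a corpus
#'
#' All distinct tokens of the sentence texts (under [ddi_tokenize()]) plus the
#' three anonymization anchors.
#'
#' @param docs list of [ddi_document()] objects.
#' @return character vector.
#' @export
corpus_vocabulary <- function(docs) {
  toks <- unlist(lapply(docs, function(d)
    lapply(d$sentences, function(s) ddi_tokenize(s$text))), use.names = FALSE)
  unique(c(ANCHOR_E1, ANCHOR_E2, ANCHOR_OTHER, toks))
}

#' Generate synthetic word-embedding channels
#'
#' Each channel draws Gaussian(0, 1/sqrt(k)) word vectors over a shared
#' vocabulary; words listed in `class_words` additionally receive a
#' class-specific offset direction (shared across channels, with small
#' per-channel jitter), which makes the trigger vocabulary of different
#' classes linearly separable by construction. Row 1 of every table is the
#' zero pad row.
#'
#' @param vocab character vector of words.
#' @param k embedding dimensionality (default 200).
#' @param n_channels number of channels, at most 5.
#' @param seed integer seed; the same seed gives identical tables.
#' @param class_words named list (class -> character vector) of trigger words;
#'   defaults to [trigger_word_classes()].
#' @param offset_norm norm of each class offset direction (default 1.5).
#' @return list of [embedding_table()] objects.
#' @export
generate_channel_embeddings <- function(vocab, k = 200L, n_channels = 5L,
                                        seed = 1L,
                                        class_words = trigger_word_classes(),
                                        offset_norm = 1.5) {
  if (k < 1) stopf("k must be >= 1")
  if (n_channels < 1 || n_channels > 5)
    stopf("n_channels must be between 1 and 5")
  with_seed(seed, {
    dirs <- lapply(class_words, function(ws) {
      v <- stats::rnorm(k)
      v / sqrt(sum(v^2)) * offset_norm
    })
    lapply(seq_len(n_channels), function(ci) {
      m <- matrix(stats::rnorm(length(vocab) * k, 0, 1 / sqrt(k)), ncol = k)
      rownames(m) <- NULL
      for (cl in names(class_words)) {
        rows <- match(intersect(class_words[[cl]], vocab), vocab)
        if (length(rows)) {
          jitter <- stats::rnorm(k, 0, 0.1 / sqrt(k))
          m[rows, ] <- m[rows, , drop = FALSE] +
            matrix(dirs[[cl]] + jitter, length(rows), k, byrow = TRUE)
        }
      }
      embedding_table(vocab, m, name = sprintf("synthetic%d", ci))
    })
  })
}
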