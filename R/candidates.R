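# Candidate-pair generation: anonymization, negative filtering, relative
# position encoding and fixed-length padding for the convolutional model, and
# entity-marker preprocessing for the encoder-based model.

ANCHOR_E1 <- "DRUG1"
ANCHOR_E2 <- "DRUG2"
ANCHOR_OTHER <- "DRUGN"

#' Tokenize sentence text
#'
#' Deterministic whitespace tokenizer that first separates the punctuation
#' characters `. , ; : ( ) " /` into their own tokens.
#'
#' @param text character string.
#' @return character vector of tokens.
#' @export
ddi_tokenize <- function(text) {
  spaced <- gsub("([.,;:()\"/])", " \\1 ", text)
  toks <- strsplit(trimws(spaced), "\\s+")[[1]]
  toks[nzchar(toks)]
}

first_span <- function(entity) entity$char_spans[[1]]

role_symbol <- function(role) c(ANCHOR_E1, ANCHOR_E2, ANCHOR_OTHER)[role]

# Build the anonymized token sequence for one target pair. Entities are
# processed in offset order; each contributes its role symbol, either in place
# of its first-span surface ("replace") or appended after it ("tag", the
# default, matching the corpus worked examples). Discontinuous mentions anchor
# at their first span; later spans stay in the text as context.
anonymize_sentence <- function(sentence, ents, roles, style) {
  text <- sentence$text
  tokens <- character(0)
  mask <- integer(0)
  anon <- character(0)
  pos <- 0L          # next unconsumed character (0-based)
  overlap_targets <- FALSE

  ord <- order(vapply(ents, function(e) first_span(e)[1], 0L))
  for (k in ord) {
    sp <- first_span(ents[[k]])
    role <- roles[k]
    if (sp[1] < pos) {
      # overlaps an already consumed mention
      if (role %in% c(1L, 2L)) {
        overlap_targets <- TRUE
        tokens <- c(tokens, role_symbol(role))
        mask <- c(mask, role)
        anon <- c(anon, " ", role_symbol(role))
      }
      next
    }
    if (sp[1] > pos) {
      ctx <- substr(text, pos + 1L, sp[1])
      ctoks <- ddi_tokenize(ctx)
      tokens <- c(tokens, ctoks)
      mask <- c(mask, integer(length(ctoks)))
      anon <- c(anon, ctx)
    }
    frag <- span_text(text, sp)
    if (style == "tag") {
      ftoks <- c(ddi_tokenize(frag), role_symbol(role))
      anon <- c(anon, frag, " ", role_symbol(role))
    } else {
      ftoks <- role_symbol(role)
      anon <- c(anon, role_symbol(role))
    }
    tokens <- c(tokens, ftoks)
    mask <- c(mask, rep(role, length(ftoks)))
    pos <- sp[2] + 1L
  }
  if (pos < nchar(text)) {
    ctx <- substr(text, pos + 1L, nchar(text))
    ctoks <- ddi_tokenize(ctx)
    tokens <- c(tokens, ctoks)
    mask <- c(mask, integer(length(ctoks)))
    anon <- c(anon, ctx)
  }
  list(tokens = tokens, mask = mask,
       anon_text = trimws(paste(anon, collapse = "")),
       overlap_targets = overlap_targets)
}

#' Generate candidate DDI instances for a sentence
#'
#' Enumerates all unordered entity pairs in offset order — `n` entities yield
#' `n(n-1)/2` candidates — and anonymizes each: the earlier target entity is
#' marked `DRUG1`, the later `DRUG2`, and every other drug mention `DRUGN`.
#' The default `"tag"` style keeps the mention surface and appends the role
#' symbol after it; `"replace"` substitutes the symbol for the surface. Labels
#' come from the sentence's gold pairs; a pair with no gold annotation (or
#' annotated `ddi="false"`) is labeled `negative`.
#'
#' Each returned instance carries the token sequence, the anchor indices
#' `p1 < p2` (positions of the `DRUG1`/`DRUG2` tokens), unclipped relative
#' distances `dist_e1`/`dist_e2` (token index minus anchor index), an entity
#' mask (0 context, 1/2 target mentions, 3 other drugs), and the anonymized
#' display text. Targets whose first spans overlap cannot be disjointly
#' replaced; such instances are flagged `filtered` with reason `same_drug`.
#'
#' @param sentence a [ddi_sentence()].
#' @param anonymization `"tag"` (default) or `"replace"`.
#' @return list of `candidate_instance` objects.
#' @export
generate_candidates <- function(sentence, anonymization = c("tag", "replace")) {
  style <- match.arg(anonymization)
  validate_sentence(sentence)
  ents <- sentence$entities
  n <- length(ents)
  if (n < 2) return(list())
  ord <- order(vapply(ents, function(e) first_span(e)[1], 0L))
  ents <- ents[ord]

  gold <- list()
  for (p in sentence$pairs) {
    key <- paste(sort(c(p$e1, p$e2)), collapse = "\r")
    gold[[key]] <- p
  }

  out <- list()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      roles <- rep(3L, n)
      roles[i] <- 1L
      roles[j] <- 2L
      an <- anonymize_sentence(sentence, ents, roles, style)
      p1 <- which(an$tokens == ANCHOR_E1)[1]
      p2 <- which(an$tokens == ANCHOR_E2)[1]
      key <- paste(sort(c(ents[[i]]$id, ents[[j]]$id)), collapse = "\r")
      gp <- gold[[key]]
      label <- if (!is.null(gp) && gp$ddi) gp$itype else "negative"
      pair_id <- if (!is.null(gp)) gp$id
                 else paste0(sentence$id, ".p", i, "-", j)
      nt <- length(an$tokens)
      inst <- structure(list(
        sentence_id = sentence$id,
        pair_id = pair_id,
        e1_id = ents[[i]]$id, e2_id = ents[[j]]$id,
        e1_surface = ents[[i]]$surface, e2_surface = ents[[j]]$surface,
        tokens = an$tokens,
        entity_mask = an$mask,
        p1 = p1, p2 = p2,
        dist_e1 = seq_len(nt) - p1,
        dist_e2 = seq_len(nt) - p2,
        label = label,
        filtered = an$overlap_targets,
        filter_reason = if (an$overlap_targets) "same_drug" else "none",
        anon_text = an$anon_text,
        pad_mask = rep(FALSE, nt)
      ), class = "candidate_instance")
      out[[length(out) + 1L]] <- inst
    }
  }
  out
}

#' @export
print.candidate_instance <- function(x, ...) {
  cat(sprintf("<candidate %s [%s]%s>\n  %s\n", x$pair_id, x$label,
              if (x$filtered) paste0(" filtered:", x$filter_reason) else "",
              x$anon_text))
  invisible(x)
}

in_same_synonym_group <- function(a, b, synonyms) {
  for (grp in synonyms) {
    g <- tolower(grp)
    if (a %in% g && b %in% g) return(TRUE)
  }
  FALSE
}

#' Flag negative-filter candidates
#'
#' Applies the two negative-instance filtering rules and sets each instance's
#' `filtered`/`filter_reason` fields (labels are never altered, and the
#' operation is idempotent):
#'
#' * `same_drug` — the two target mentions have the same case-folded surface
#'   form, or are listed together in a user-supplied synonym group.
#' * `coordination` — every token strictly between the two target mention
#'   blocks is a comma, the word "and"/"or", or part of another drug mention,
#'   i.e. the pair sits in a pure coordination list.
#'
#' Flagging does not remove anything: training-data assembly drops only
#' *negative*-labeled flagged instances, so gold positives are never lost, and
#' at evaluation time flagged instances can be auto-predicted negative instead
#' of being shown to the model.
#'
#' @param instances list of `candidate_instance` objects.
#' @param synonyms optional list of character vectors, each a group of drug
#'   names treated as the same drug by the first rule.
#' @return the instances with `filtered`/`filter_reason` set.
#' @export
filter_negatives <- function(instances, synonyms = NULL) {
  lapply(instances, function(inst) {
    s1 <- tolower(trimws(inst$e1_surface))
    s2 <- tolower(trimws(inst$e2_surface))
    same <- identical(s1, s2) ||
      (!is.null(synonyms) && in_same_synonym_group(s1, s2, synonyms)) ||
      identical(inst$filter_reason, "same_drug")
    if (same) {
      inst$filtered <- TRUE
      inst$filter_reason <- "same_drug"
      return(inst)
    }
    e1_end <- max(which(inst$entity_mask == 1L))
    e2_start <- min(which(inst$entity_mask == 2L))
    between <- seq_len(length(inst$tokens))
    between <- between[between > e1_end & between < e2_start]
    sep_ok <- inst$tokens[between] %in% c(",", "and", "or") |
      inst$entity_mask[between] > 0L
    if (all(sep_ok)) {
      inst$filtered <- TRUE
      inst$filter_reason <- "coordination"
    } else {
      inst$filtered <- FALSE
      inst$filter_reason <- "none"
    }
    inst
  })
}

#' Clip relative distances
#'
#' Saturates both relative-distance sequences at `±max_dist`, the range the
#' position-embedding tables cover.
#'
#' @param instance a `candidate_instance`.
#' @param max_dist positive integer clipping bound (default 60).
#' @return the instance with `dist_e1`/`dist_e2` clipped and `max_dist` stored.
#' @export
encode_positions <- function(instance, max_dist = 60L) {
  instance$dist_e1 <- pmin(pmax(instance$dist_e1, -max_dist), max_dist)
  instance$dist_e2 <- pmin(pmax(instance$dist_e2, -max_dist), max_dist)
  instance$max_dist <- as.integer(max_dist)
  instance
}

#' Pad or truncate an instance to a fixed length
#'
#' Shorter instances are padded with the reserved `<PAD>` token (embedding row
#' zero); longer instances are truncated to the smallest window containing both
#' anchors, extended symmetrically to `max_len`. Padding positions are flagged
#' in `pad_mask`.
#'
#' @param instance a `candidate_instance`.
#' @param max_len target length in tokens (default 150).
#' @return the fixed-length instance; errors if the two anchors cannot both
#'   fit in `max_len` tokens.
#' @export
pad_or_truncate <- function(instance, max_len = 150L) {
  n <- length(instance$tokens)
  if (n > max_len) {
    needed <- instance$p2 - instance$p1 + 1L
    if (needed > max_len)
      stopf("instance '%s': anchors span %d tokens, cannot fit in max_len=%d",
            instance$pair_id, needed, max_len)
    start <- instance$p1 - (max_len - needed) %/% 2L
    start <- max(1L, min(start, n - max_len + 1L))
    keep <- start:(start + max_len - 1L)
    instance$tokens <- instance$tokens[keep]
    instance$entity_mask <- instance$entity_mask[keep]
    instance$dist_e1 <- instance$dist_e1[keep]
    instance$dist_e2 <- instance$dist_e2[keep]
    instance$pad_mask <- instance$pad_mask[keep]
    instance$p1 <- instance$p1 - start + 1L
    instance$p2 <- instance$p2 - start + 1L
  } else if (n < max_len) {
    extra <- max_len - n
    instance$tokens <- c(instance$tokens, rep(PAD_TOKEN, extra))
    instance$entity_mask <- c(instance$entity_mask, integer(extra))
    instance$dist_e1 <- c(instance$dist_e1, integer(extra))
    instance$dist_e2 <- c(instance$dist_e2, integer(extra))
    instance$pad_mask <- c(instance$pad_mask, rep(TRUE, extra))
  }
  instance$length <- n
  instance
}

#' Default lowercasing tokenizer for the encoder-based model
#'
#' @param text character string.
#' @return lowercased tokens from [ddi_tokenize()].
#' @export
lowercase_tokenizer <- function(text) tolower(ddi_tokenize(text))

#' Preprocess a sentence/pair for the entity-marker relation head
#'
#' Builds the control-token sequence `[CLS] c0 $ e1 $ c1 # e2 # c2 [SEP]`
#' followed by `[PAD]` up to `max_len`. Drug names are *not* anonymized on this
#' path. Entity positional ids are 1 exactly on the first entity's tokens, 2 on
#' the second entity's tokens and 0 everywhere else (markers and control tokens
#' included); the attention mask is 1 up to and including `[SEP]`.
#'
#' @param sentence a [ddi_sentence()].
#' @param pair a [drug_pair()] of this sentence (or a list with `e1`,`e2` ids).
#' @param tokenizer function mapping a text fragment to a character vector of
#'   (sub)tokens; defaults to [lowercase_tokenizer()]. A wordpiece mapper can
#'   be plugged in here.
#' @param max_len padded sequence length (default 64).
#' @param marker_e1,marker_e2 boundary marker strings wrapped around the two
#'   entities (defaults `"$"` and `"#"`).
#' @return an object of class `bert_input` with fields `tokens`,
#'   `entity_pos_ids`, `attention_mask`, `label`, and token-index `spans` for
#'   `cls`, `e1`, `e2`, `c0`, `c1`, `c2` (a span with start > end is empty).
#' @export
preprocess_for_bert <- function(sentence, pair, tokenizer = lowercase_tokenizer,
                                max_len = 64L, marker_e1 = "$", marker_e2 = "#") {
  validate_sentence(sentence)
  eids <- vapply(sentence$entities, `[[`, "", "id")
  ia <- match(pair$e1, eids)
  ib <- match(pair$e2, eids)
  if (is.na(ia) || is.na(ib))
    stopf("pair references entities not in sentence '%s'", sentence$id)
  ea <- sentence$entities[[ia]]
  eb <- sentence$entities[[ib]]
  if (first_span(ea)[1] > first_span(eb)[1]) { tmp <- ea; ea <- eb; eb <- tmp }
  sa <- first_span(ea)
  sb <- first_span(eb)
  if (sb[1] <= sa[2])
    stopf("entities '%s' and '%s' overlap; cannot mark disjointly", ea$id, eb$id)

  text <- sentence$text
  seg_tokens <- function(s, e) {
    if (e < s) character(0) else tokenizer(substr(text, s + 1L, e + 1L))
  }
  c0 <- seg_tokens(0L, sa[1] - 1L)
  t1 <- tokenizer(span_text(text, sa))
  c1 <- seg_tokens(sa[2] + 1L, sb[1] - 1L)
  t2 <- tokenizer(span_text(text, sb))
  c2 <- seg_tokens(sb[2] + 1L, nchar(text) - 1L)
  if (length(t1) == 0) stopf("entity '%s' destroyed by tokenization", ea$id)
  if (length(t2) == 0) stopf("entity '%s' destroyed by tokenization", eb$id)

  span_of <- function(start, len) c(start, start + len - 1L)
  tokens <- "[CLS]"
  spans <- list(cls = c(1L, 1L))
  add <- function(tok) {
    start <- length(tokens) + 1L
    tokens <<- c(tokens, tok)
    span_of(start, length(tok))
  }
  spans$c0 <- add(c0)
  add(marker_e1)
  spans$e1 <- add(t1)
  add(marker_e1)
  spans$c1 <- add(c1)
  add(marker_e2)
  spans$e2 <- add(t2)
  add(marker_e2)
  spans$c2 <- add(c2)
  add("[SEP]")
  n <- length(tokens)
  if (n > max_len)
    stopf("sentence '%s': marked sequence length %d exceeds max_len=%d",
          sentence$id, n, max_len)

  ids <- integer(max_len)
  ids[spans$e1[1]:spans$e1[2]] <- 1L
  ids[spans$e2[1]:spans$e2[2]] <- 2L
  attention <- c(rep(1L, n), integer(max_len - n))
  tokens <- c(tokens, rep("[PAD]", max_len - n))
  label <- if (isTRUE(pair$ddi)) pair$itype else "negative"

  structure(list(
    sentence_id = sentence$id,
    pair_id = pair$id %||% paste0(sentence$id, ".", ea$id, "-", eb$id),
    tokens = tokens, entity_pos_ids = ids, attention_mask = attention,
    spans = spans, length = n, label = label
  ), class = "bert_input")
}

# -- JSON-lines caching of candidate instances --------------------------------

CANDIDATE_FIELDS <- c("sentence_id", "pair_id", "e1_id", "e2_id", "e1_surface",
                      "e2_surface", "tokens", "entity_mask", "p1", "p2",
                      "dist_e1", "dist_e2", "label", "filtered",
                      "filter_reason", "anon_text", "pad_mask")

#' Write candidate instances as JSON lines
#'
#' One instance per line with a stable field order, suitable for caching.
#'
#' @param instances list of `candidate_instance` objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_candidates_jsonl <- function(instances, path) {
  lines <- vapply(instances, function(inst) {
    jsonlite::toJSON(inst[CANDIDATE_FIELDS], auto_unbox = TRUE, digits = NA)
  }, "")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read candidate instances from JSON lines
#'
#' @param path file written by [write_candidates_jsonl()].
#' @return list of `candidate_instance` objects.
#' @export
read_candidates_jsonl <- function(path) {
  lapply(readLines(path, encoding = "UTF-8"), function(line) {
    x <- jsonlite::fromJSON(line, simplifyVector = TRUE)
    x$tokens <- as.character(x$tokens)
    x$entity_mask <- as.integer(x$entity_mask)
    x$dist_e1 <- as.integer(x$dist_e1)
    x$dist_e2 <- as.integer(x$dist_e2)
    x$pad_mask <- as.logical(x$pad_mask)
    structure(x, class = "candidate_instance")
  })
}
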