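# Reading, writing and validating the SemEval-2013 Task 9 DDI XML dialect.
#
# Character offsets follow the corpus convention: 0-based *inclusive* ends, so
# charOffset "0-11" covers 12 characters. Discontinuous mentions use ";" to
# separate spans; their surface form joins the span fragments with one space.

#' Construct an entity mention
#'
#' @param id entity identifier, unique within its sentence.
#' @param char_spans list of length-2 integer vectors `c(start, end)`, 0-based
#'   inclusive character offsets into the sentence text. Discontinuous mentions
#'   have more than one span.
#' @param etype entity type, one of `"drug"`, `"brand"`, `"group"`, `"drug_n"`.
#'   Unknown types are accepted with a warning and mapped to `"drug_n"`.
#' @param surface the mention text; for discontinuous mentions the fragments
#'   joined by a single space.
#' @param attrs passthrough list of unrecognized XML attributes.
#' @return an object of class `entity_mention`.
#' @export
entity_mention <- function(id, char_spans, etype = "drug", surface,
                           attrs = list()) {
  if (!etype %in% ENTITY_TYPES) {
    warnf("entity '%s': unknown type '%s' mapped to drug_n", id, etype)
    etype <- "drug_n"
  }
  char_spans <- lapply(char_spans, function(s) as.integer(s[1:2]))
  structure(
    list(id = as.character(id), char_spans = char_spans, etype = etype,
         surface = as.character(surface), attrs = attrs),
    class = "entity_mention"
  )
}

#' Construct a drug pair annotation
#'
#' @param id pair identifier.
#' @param e1,e2 ids of the two entities (must differ).
#' @param ddi logical, whether the pair interacts.
#' @param itype interaction type for interacting pairs, one of `"mechanism"`,
#'   `"effect"`, `"advice"`, `"int"`; must be `NULL` when `ddi` is `FALSE`.
#' @param attrs passthrough list of unrecognized XML attributes.
#' @return an object of class `drug_pair`.
#' @export
drug_pair <- function(id, e1, e2, ddi = FALSE, itype = NULL, attrs = list()) {
  if (identical(e1, e2)) stopf("pair '%s': e1 and e2 are the same entity id", id)
  if (isTRUE(ddi)) {
    if (is.null(itype) || !itype %in% DDI_POSITIVE_CLASSES)
      stopf("pair '%s': ddi=true requires itype in {%s}", id,
            paste(DDI_POSITIVE_CLASSES, collapse = ", "))
  } else if (!is.null(itype)) {
    stopf("pair '%s': itype must be absent when ddi=false", id)
  }
  structure(
    list(id = as.character(id), e1 = as.character(e1), e2 = as.character(e2),
         ddi = isTRUE(ddi), itype = itype, attrs = attrs),
    class = "drug_pair"
  )
}

#' Construct an annotated sentence
#'
#' @param id sentence identifier, unique within its document.
#' @param text the sentence text.
#' @param entities list of [entity_mention()] objects.
#' @param pairs list of [drug_pair()] objects.
#' @param attrs passthrough list of unrecognized XML attributes.
#' @return an object of class `ddi_sentence`.
#' @export
ddi_sentence <- function(id, text, entities = list(), pairs = list(),
                         attrs = list()) {
  s <- structure(
    list(id = as.character(id), text = as.character(text),
         entities = entities, pairs = pairs, attrs = attrs),
    class = "ddi_sentence"
  )
  validate_sentence(s)
  s
}

#' Construct a document (a set of sentences)
#'
#' @param id document identifier.
#' @param source_tag free-form provenance string (e.g. `"drugbank"`).
#' @param sentences list of [ddi_sentence()] objects.
#' @param attrs passthrough list of unrecognized XML attributes.
#' @return an object of class `ddi_document`.
#' @export
ddi_document <- function(id, source_tag = "", sentences = list(),
                         attrs = list()) {
  ids <- vapply(sentences, `[[`, "", "id")
  if (anyDuplicated(ids))
    stopf("document '%s': duplicated sentence id '%s'", id, ids[duplicated(ids)][1])
  structure(
    list(id = as.character(id), source_tag = as.character(source_tag),
         sentences = sentences, attrs = attrs),
    class = "ddi_document"
  )
}

# Span substring with 0-based inclusive offsets.
span_text <- function(text, span) substr(text, span[1] + 1L, span[2] + 1L)

#' Validate a sentence's entity offsets and pair references
#'
#' Checks the sentence invariants: offsets inside the text, spans sorted and
#' non-overlapping, span fragments reproducing the surface form (fragments of
#' discontinuous mentions joined by a single space), unique entity ids and
#' pairs resolving to entities of this sentence.
#'
#' @param sentence a [ddi_sentence()].
#' @return the sentence, invisibly; errors describe the violated invariant.
#' @export
validate_sentence <- function(sentence) {
  n <- nchar(sentence$text)
  eids <- vapply(sentence$entities, `[[`, "", "id")
  if (anyDuplicated(eids))
    stopf("sentence '%s': duplicated entity id '%s'", sentence$id,
          eids[duplicated(eids)][1])
  for (ent in sentence$entities) {
    if (length(ent$char_spans) == 0)
      stopf("entity '%s': no character spans", ent$id)
    last_end <- -1L
    frags <- character(0)
    for (span in ent$char_spans) {
      if (span[2] < span[1])
        stopf("entity '%s': span end %d < start %d", ent$id, span[2], span[1])
      if (span[1] < 0 || span[2] >= n)
        stopf("entity '%s': span %d-%d outside sentence text (length %d)",
              ent$id, span[1], span[2], n)
      if (span[1] <= last_end)
        stopf("entity '%s': spans overlap or are unsorted", ent$id)
      last_end <- span[2]
      frags <- c(frags, span_text(sentence$text, span))
    }
    joined <- paste(frags, collapse = " ")
    if (!identical(joined, ent$surface))
      stopf("entity '%s': span text '%s' does not match surface '%s'",
            ent$id, joined, ent$surface)
  }
  for (p in sentence$pairs) {
    missing <- setdiff(c(p$e1, p$e2), eids)
    if (length(missing))
      stopf("pair '%s': references missing entity '%s' in sentence '%s'",
            p$id, missing[1], sentence$id)
  }
  invisible(sentence)
}

#' Validate a document
#'
#' @param doc a [ddi_document()].
#' @return the document, invisibly.
#' @export
validate_document <- function(doc) {
  for (s in doc$sentences) validate_sentence(s)
  invisible(doc)
}

parse_char_offset <- function(s) {
  lapply(strsplit(s, ";", fixed = TRUE)[[1]], function(part) {
    se <- as.integer(strsplit(trimws(part), "-", fixed = TRUE)[[1]])
    if (length(se) != 2 || anyNA(se))
      stopf("malformed charOffset '%s'", s)
    se
  })
}

format_char_offset <- function(spans) {
  paste(vapply(spans, function(s) paste0(s[1], "-", s[2]), ""), collapse = ";")
}

extra_attrs <- function(node, known) {
  at <- xml2::xml_attrs(node)
  keep <- setdiff(names(at), known)
  if (length(keep) == 0) list() else as.list(at[keep])
}

#' Read a corpus in the DDI XML dialect
#'
#' Parses `document`/`sentence`/`entity`/`pair` elements. Character offsets
#' (0-based, inclusive ends, `;`-separated for discontinuous mentions) are
#' validated against the sentence text; pairs must reference entities of their
#' sentence. Attributes beyond the dialect's are preserved in each object's
#' `attrs` list. Files are read as UTF-8.
#'
#' @param path path to an XML file whose root is either a single `document` or
#'   a collection of `document` elements.
#' @return list of [ddi_document()] objects.
#' @export
read_ddi_xml <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  xml <- xml2::read_xml(path, encoding = "UTF-8")
  root <- xml2::xml_root(xml)
  doc_nodes <- if (xml2::xml_name(root) == "document") list(root)
               else xml2::xml_find_all(root, ".//document")
  lapply(doc_nodes, function(dn) {
    sent_nodes <- xml2::xml_find_all(dn, "./sentence")
    sentences <- lapply(sent_nodes, function(sn) {
      text <- xml2::xml_attr(sn, "text")
      entities <- lapply(xml2::xml_find_all(sn, "./entity"), function(en) {
        entity_mention(
          id = xml2::xml_attr(en, "id"),
          char_spans = parse_char_offset(xml2::xml_attr(en, "charOffset")),
          etype = xml2::xml_attr(en, "type"),
          surface = xml2::xml_attr(en, "text"),
          attrs = extra_attrs(en, c("id", "charOffset", "type", "text"))
        )
      })
      pairs <- lapply(xml2::xml_find_all(sn, "./pair"), function(pn) {
        ddi <- tolower(xml2::xml_attr(pn, "ddi")) %in% c("true", "1")
        itype <- xml2::xml_attr(pn, "type")
        drug_pair(
          id = xml2::xml_attr(pn, "id"),
          e1 = xml2::xml_attr(pn, "e1"), e2 = xml2::xml_attr(pn, "e2"),
          ddi = ddi,
          itype = if (ddi && !is.na(itype)) itype else NULL,
          attrs = extra_attrs(pn, c("id", "e1", "e2", "ddi", "type"))
        )
      })
      ddi_sentence(id = xml2::xml_attr(sn, "id"), text = text,
                   entities = entities, pairs = pairs,
                   attrs = extra_attrs(sn, c("id", "text")))
    })
    src <- xml2::xml_attr(dn, "source")
    ddi_document(id = xml2::xml_attr(dn, "id"),
                 source_tag = if (is.na(src)) "" else src,
                 sentences = sentences,
                 attrs = extra_attrs(dn, c("id", "source")))
  })
}

#' Write documents to the DDI XML dialect
#'
#' Inverse of [read_ddi_xml()]: `read_ddi_xml(write_ddi_xml(docs))` reproduces
#' `docs` field for field. All invariants are re-validated before anything is
#' written.
#'
#' @param docs list of [ddi_document()] objects.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_ddi_xml <- function(docs, path) {
  if (inherits(docs, "ddi_document")) docs <- list(docs)
  for (d in docs) validate_document(d)
  root <- xml2::xml_new_root("corpus")
  for (d in docs) {
    dattrs <- c(list(id = d$id),
                if (nzchar(d$source_tag)) list(source = d$source_tag),
                d$attrs)
    dn <- xml2::xml_add_child(root, "document")
    do.call(xml2::xml_set_attrs, list(dn, unlist(dattrs)))
    for (s in d$sentences) {
      sn <- xml2::xml_add_child(dn, "sentence")
      xml2::xml_set_attrs(sn, unlist(c(list(id = s$id, text = s$text), s$attrs)))
      for (e in s$entities) {
        en <- xml2::xml_add_child(sn, "entity")
        xml2::xml_set_attrs(en, unlist(c(
          list(id = e$id, charOffset = format_char_offset(e$char_spans),
               type = e$etype, text = e$surface), e$attrs)))
      }
      for (p in s$pairs) {
        pn <- xml2::xml_add_child(sn, "pair")
        xml2::xml_set_attrs(pn, unlist(c(
          list(id = p$id, e1 = p$e1, e2 = p$e2,
               ddi = if (p$ddi) "true" else "false"),
          if (p$ddi) list(type = p$itype), p$attrs)))
      }
    }
  }
  xml2::write_xml(root, path, encoding = "UTF-8")
  invisible(path)
}

#' Corpus summary statistics
#'
#' Counts documents, sentences, entities and pairs, with pairs broken down by
#' interaction class (non-interacting pairs counted as `negative`). The
#' per-class counts always partition the total pair count.
#'
#' @param docs list of [ddi_document()] objects.
#' @return named integer vector with elements `documents`, `sentences`,
#'   `entities`, `pairs`, and one element per class in
#'   `c("mechanism", "effect", "advice", "int", "negative")`.
#' @export
corpus_stats <- function(docs) {
  if (inherits(docs, "ddi_document")) docs <- list(docs)
  out <- c(documents = length(docs), sentences = 0L, entities = 0L, pairs = 0L,
           stats::setNames(integer(length(DDI_CLASSES)), DDI_CLASSES))
  out <- out[c("documents", "sentences", "entities", "pairs",
               "mechanism", "effect", "advice", "int", "negative")]
  for (d in docs) {
    out["sentences"] <- out["sentences"] + length(d$sentences)
    for (s in d$sentences) {
      out["entities"] <- out["entities"] + length(s$entities)
      out["pairs"] <- out["pairs"] + length(s$pairs)
      for (p in s$pairs) {
        cls <- if (p$ddi) p$itype else "negative"
        out[cls] <- out[cls] + 1L
      }
    }
  }
  out
}

#' @export
print.ddi_document <- function(x, ...) {
  cat(sprintf("<ddi_document '%s'%s: %d sentences>\n", x$id,
              if (nzchar(x$source_tag)) paste0(" [", x$source_tag, "]") else "",
              length(x$sentences)))
  invisible(x)
}

#' @export
print.ddi_sentence <- function(x, ...) {
  cat(sprintf("<ddi_sentence '%s': %d entities, %d pairs>\n  %s\n",
              x$id, length(x$entities), length(x$pairs), x$text))
  invisible(x)
}
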