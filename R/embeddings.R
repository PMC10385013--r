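# Word-embedding channels and relative-position embeddings.
#
# An embedding table reserves its first row for the padding token: that row is
# all-zero and padded positions always embed to zero vectors. Several tables
# ("channels", up to five, trained on different corpora in the full-scale
# setting) can be stacked; each keeps its own vocabulary, so a word may be
# in-vocabulary on one channel and out-of-vocabulary on another — the
# multichannel out-of-vocabulary compensation.

#' Construct an embedding table
#'
#' @param words character vector of vocabulary words (without the pad token).
#' @param matrix numeric matrix with `length(words)` rows and `k` columns.
#' @param name channel label.
#' @return object of class `embedding_table` whose `matrix` has a zero pad row
#'   prepended (row 1) and whose `vocab` maps each word to its row index.
#' @export
embedding_table <- function(words, matrix, name = "channel") {
  stopifnot(is.matrix(matrix), nrow(matrix) == length(words), ncol(matrix) > 0)
  m <- rbind(0, matrix)
  rownames(m) <- NULL
  structure(list(
    words = as.character(words),
    vocab = stats::setNames(seq_along(words) + 1L, words),
    matrix = m, k = ncol(matrix), name = name
  ), class = "embedding_table")
}

#' @export
print.embedding_table <- function(x, ...) {
  cat(sprintf("<embedding_table '%s': %d words, k=%d>\n",
              x$name, length(x$words), x$k))
  invisible(x)
}

#' Read a word2vec text-format embedding file
#'
#' Expects a header line `"|V| k"` followed by `|V|` lines `"word v1 ... vk"`.
#' A zero pad row is prepended at row 1. Duplicate words keep the last
#' occurrence, with a warning.
#'
#' @param path file path.
#' @param name channel label (defaults to the file name).
#' @return an [embedding_table()].
#' @export
load_word2vec_text <- function(path, name = basename(path)) {
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) < 1) stopf("%s: empty file", path)
  hdr <- as.integer(strsplit(trimws(lines[1]), "\\s+")[[1]])
  if (length(hdr) != 2 || anyNA(hdr))
    stopf("%s: malformed header '%s'", path, lines[1])
  nv <- hdr[1]; k <- hdr[2]
  if (length(lines) - 1L != nv)
    stopf("%s: header promises %d rows, file has %d", path, nv, length(lines) - 1L)
  words <- character(nv)
  mat <- matrix(0, nv, k)
  for (i in seq_len(nv)) {
    parts <- strsplit(trimws(lines[i + 1L]), "\\s+")[[1]]
    if (length(parts) != k + 1L)
      stopf("%s line %d: expected %d values after the word, found %d",
            path, i + 1L, k, length(parts) - 1L)
    vals <- suppressWarnings(as.numeric(parts[-1]))
    if (anyNA(vals)) stopf("%s line %d: non-numeric vector entry", path, i + 1L)
    words[i] <- parts[1]
    mat[i, ] <- vals
  }
  if (anyDuplicated(words)) {
    dup <- unique(words[duplicated(words)])
    warnf("%s: duplicated word(s) %s; last occurrence wins",
          path, paste(dup, collapse = ", "))
    keep <- !duplicated(words, fromLast = TRUE)
    words <- words[keep]
    mat <- mat[keep, , drop = FALSE]
  }
  embedding_table(words, mat, name = name)
}

#' Write an embedding table in word2vec text format
#'
#' The pad row is not written; [load_word2vec_text()] round-trips the table.
#'
#' @param table an [embedding_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_word2vec_text <- function(table, path) {
  m <- table$matrix[-1, , drop = FALSE]
  rows <- vapply(seq_len(nrow(m)), function(i) {
    paste(table$words[i], paste(sprintf("%.8g", m[i, ]), collapse = " "))
  }, "")
  writeLines(c(paste(nrow(m), table$k), rows), path, useBytes = TRUE)
  invisible(path)
}

#' Assemble a multichannel embedding set
#'
#' Bundles 1-5 word-embedding channels (all sharing the same dimensionality
#' `k`) with two relative-position embedding tables, one per target entity,
#' indexed by the clipped signed distance (`distance + max_dist + 1`). The
#' position tables are initialized from a seeded uniform(-0.05, 0.05); each
#' channel also gets a seeded Gaussian(0, 0.01) out-of-vocabulary vector shared
#' by all of its unknown words (`oov_policy = "gaussian"`, the default;
#' `"zero"` uses the zero vector instead).
#'
#' @param tables list of [embedding_table()] objects (1 to 5).
#' @param max_dist position-embedding distance range (default 60).
#' @param k_pos dimensionality of each position embedding (default 10).
#' @param seed integer seed controlling position tables and OOV vectors.
#' @param oov_policy `"gaussian"` or `"zero"`.
#' @return object of class `channel_embedding_set`.
#' @export
build_channel_set <- function(tables, max_dist = 60L, k_pos = 10L, seed = 1L,
                              oov_policy = c("gaussian", "zero")) {
  oov_policy <- match.arg(oov_policy)
  if (inherits(tables, "embedding_table")) tables <- list(tables)
  if (length(tables) < 1 || length(tables) > 5)
    stopf("between 1 and 5 channels are supported, got %d", length(tables))
  ks <- vapply(tables, `[[`, 0L, "k")
  if (length(unique(ks)) != 1)
    stopf("channels have mixed dimensionalities: %s", paste(ks, collapse = ", "))
  k <- ks[1]
  npos <- 2L * max_dist + 1L
  with_seed(seed, {
    pos_e1 <- matrix(stats::runif(npos * k_pos, -0.05, 0.05), npos, k_pos)
    pos_e2 <- matrix(stats::runif(npos * k_pos, -0.05, 0.05), npos, k_pos)
    oov <- lapply(tables, function(tb) {
      if (oov_policy == "gaussian") stats::rnorm(k, 0, 0.01) else numeric(k)
    })
  })
  structure(list(
    channels = tables, pos_e1 = pos_e1, pos_e2 = pos_e2,
    max_dist = as.integer(max_dist), k_pos = as.integer(k_pos), k = k,
    oov = oov, oov_policy = oov_policy, seed = seed
  ), class = "channel_embedding_set")
}

#' @export
print.channel_embedding_set <- function(x, ...) {
  cat(sprintf("<channel_embedding_set: %d channel(s), k=%d, k_pos=%d, max_dist=%d>\n",
              length(x$channels), x$k, x$k_pos, x$max_dist))
  invisible(x)
}

# Row indices of an instance's tokens in one channel (pad row 1, OOV row 0
# meaning "use the channel's OOV vector").
channel_token_rows <- function(tokens, pad_mask, table) {
  idx <- unname(table$vocab[tokens])
  idx[is.na(idx)] <- 0L
  idx[pad_mask] <- 1L
  idx
}

#' Embed a candidate instance
#'
#' Maps a (padded) instance to one numeric matrix per channel; each row is the
#' token's word vector concatenated with the two position-embedding vectors
#' for its clipped distances to the anchors. Padding rows are all zero.
#'
#' @param instance a padded `candidate_instance` (see [pad_or_truncate()]).
#' @param set a [build_channel_set()] result.
#' @return object of class `embedded_sequence`: list with `channels` (one
#'   `length x (k + 2*k_pos)` matrix per channel), anchors `p1`,`p2`, and
#'   `pad_mask`.
#' @export
embed_instance <- function(instance, set) {
  md <- set$max_dist
  d1 <- pmin(pmax(instance$dist_e1, -md), md) + md + 1L
  d2 <- pmin(pmax(instance$dist_e2, -md), md) + md + 1L
  pos_block <- cbind(set$pos_e1[d1, , drop = FALSE],
                     set$pos_e2[d2, , drop = FALSE])
  pad <- instance$pad_mask
  pos_block[pad, ] <- 0
  channels <- lapply(seq_along(set$channels), function(ci) {
    tb <- set$channels[[ci]]
    idx <- channel_token_rows(instance$tokens, pad, tb)
    w <- matrix(0, length(idx), tb$k)
    known <- idx > 0L
    w[known, ] <- tb$matrix[idx[known], , drop = FALSE]
    if (any(!known)) w[!known, ] <- rep(set$oov[[ci]], each = sum(!known))
    unname(cbind(w, pos_block))
  })
  structure(list(
    channels = channels, p1 = instance$p1, p2 = instance$p2,
    pad_mask = pad, width = set$k + 2L * set$k_pos
  ), class = "embedded_sequence")
}
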