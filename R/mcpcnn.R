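# The multichannel piecewise convolutional model: convolution over all
# embedding channels jointly (channels form a depth axis, so one filter spans
# every channel), piecewise max pooling around the two entity anchors,
# input-level attention, Gaussian noise, dropout and a 5-way softmax.

#' Construct a convolution filter bank
#'
#' One weight tensor per window size `h`, stored as an
#' `(h * input_width * n_channels) x n_filters` matrix whose rows follow the
#' window layout (token offset major, then channel, then feature); biases start
#' at zero and weights from a seeded Glorot uniform.
#'
#' @param input_width per-channel row width (word + position dimensions).
#' @param n_channels number of embedding channels.
#' @param window_sizes integer vector of convolution window sizes
#'   (default `c(3, 5, 7, 9)`).
#' @param n_filters filters per window size (default 128).
#' @param nonlinearity `"tanh"` (default) or `"identity"`.
#' @param seed integer seed for the weight draw.
#' @return object of class `conv_filter_bank`.
#' @export
conv_filter_bank <- function(input_width, n_channels = 1L,
                             window_sizes = c(3L, 5L, 7L, 9L),
                             n_filters = 128L,
                             nonlinearity = c("tanh", "identity"),
                             seed = 1L) {
  nonlinearity <- match.arg(nonlinearity)
  total_w <- input_width * n_channels
  with_seed(seed, {
    weights <- lapply(window_sizes, function(h) glorot_matrix(h * total_w, n_filters))
  })
  names(weights) <- as.character(window_sizes)
  biases <- lapply(weights, function(w) numeric(ncol(w)))
  structure(list(
    window_sizes = as.integer(window_sizes), n_filters = as.integer(n_filters),
    input_width = as.integer(input_width), n_channels = as.integer(n_channels),
    weights = weights, biases = biases, nonlinearity = nonlinearity
  ), class = "conv_filter_bank")
}

apply_nonlinearity <- function(x, nonlinearity) {
  if (nonlinearity == "tanh") tanh(x) else x
}

# Stack an embedded_sequence's channels into one L x (input_width * n_channels)
# matrix; plain matrices pass through.
sequence_matrix <- function(seq) {
  if (inherits(seq, "embedded_sequence")) do.call(cbind, seq$channels)
  else as.matrix(seq)
}

# im2col: rows are windows of h consecutive token rows, flattened.
im2col <- function(x, h) {
  n_w <- nrow(x) - h + 1L
  do.call(cbind, lapply(0:(h - 1L), function(s) x[(1L + s):(n_w + s), , drop = FALSE]))
}

#' Convolve an embedded sequence with a filter bank
#'
#' For each window size `h` the filters slide over every window of `h`
#' consecutive token rows, producing a feature map of length `n - h + 1`
#' (windows made only of padding rows produce `f(b)`).
#'
#' @param seq an `embedded_sequence` (see [embed_instance()]) or a plain
#'   `n x width` numeric matrix.
#' @param bank a [conv_filter_bank()].
#' @return named list (one element per window size) of
#'   `(n - h + 1) x n_filters` feature-map matrices.
#' @export
convolve_windows <- function(seq, bank) {
  x <- sequence_matrix(seq)
  n <- nrow(x)
  lapply(stats::setNames(as.character(bank$window_sizes), names(bank$weights)),
         function(hs) {
    h <- as.integer(hs)
    if (n < h) stopf("sequence length %d is shorter than window size %d", n, h)
    m <- im2col(x, h)
    a <- m %*% bank$weights[[hs]]
    a <- sweep(a, 2L, bank$biases[[hs]], `+`)
    apply_nonlinearity(a, bank$nonlinearity)
  })
}

#' Piecewise max pooling of a feature map
#'
#' Splits the map at the two anchor coordinates into left / between / right
#' segments and takes the maximum of each; an empty segment pools to 0. With
#' `p1 = 0` and `p2 = length(map)` this degenerates to a single global max
#' (with empty outer segments).
#'
#' @param map numeric vector (one feature map) or a `positions x filters`
#'   matrix.
#' @param p1,p2 segment boundaries in map coordinates, `0 <= p1 < p2 <=`
#'   map length: segment 1 is positions `1..p1`, segment 2 is `p1+1..p2`,
#'   segment 3 is `p2+1..end`.
#' @return for a vector, `c(m1, m2, m3)`; for a matrix, a `3 x filters`
#'   matrix of segment maxima.
#' @export
piecewise_max_pool <- function(map, p1, p2) {
  vec <- !is.matrix(map)
  m <- if (vec) matrix(map, ncol = 1) else map
  len <- nrow(m)
  if (p1 >= p2) stopf("piecewise pooling requires p1 < p2 (got %d, %d)", p1, p2)
  if (p1 < 0 || p2 > len)
    stopf("boundaries (%d, %d) outside map of length %d", p1, p2, len)
  seg_max <- function(from, to) {
    if (from > to) return(numeric(ncol(m)))
    apply(m[from:to, , drop = FALSE], 2L, max)
  }
  out <- rbind(seg_max(1L, p1), seg_max(p1 + 1L, p2), seg_max(p2 + 1L, len))
  if (vec) as.vector(out) else out
}

# Pool one feature map using token-coordinate anchors: a window starting at
# token i belongs to segment 1 iff i <= p1, segment 2 iff p1 < i <= p2, and
# segment 3 otherwise; boundaries are clamped to the map length (anchors close
# to the sentence end can leave later segments empty).
pool_feature_map <- function(map, p1, p2) {
  len <- nrow(map)
  b1 <- min(p1, len)
  b2 <- min(p2, len)
  seg_max <- function(from, to) {
    if (from > to) return(numeric(ncol(map)))
    apply(map[from:to, , drop = FALSE], 2L, max)
  }
  rbind(seg_max(1L, b1),
        if (b2 > b1) seg_max(b1 + 1L, b2) else numeric(ncol(map)),
        seg_max(b2 + 1L, len))
}

#' Construct attention parameters
#'
#' Additive input-level attention: each token row `x` is scored as
#' `v' tanh(W' x)`; a masked softmax over the non-pad tokens gives the weights.
#'
#' @param width total row width the attention reads (all channels).
#' @param d_a attention hidden size (default 32).
#' @param seed integer seed.
#' @return object of class `attention_params`.
#' @export
attention_params <- function(width, d_a = 32L, seed = 1L) {
  with_seed(seed, {
    w <- glorot_matrix(width, d_a)
    v <- as.vector(glorot_matrix(d_a, 1L))
  })
  structure(list(w = w, v = v, d_a = as.integer(d_a)),
            class = "attention_params")
}

#' Attention weights over an embedded sequence
#'
#' @param seq an `embedded_sequence` or plain matrix (then `pad_mask` applies).
#' @param params an [attention_params()].
#' @param pad_mask logical vector marking padding rows; taken from `seq` when
#'   it is an `embedded_sequence`.
#' @return numeric vector of weights: non-negative, exactly 0 on pad rows, and
#'   summing to 1 over the non-pad rows. Errors on an all-pad input.
#' @export
attention_weights <- function(seq, params, pad_mask = NULL) {
  x <- sequence_matrix(seq)
  if (is.null(pad_mask))
    pad_mask <- if (inherits(seq, "embedded_sequence")) seq$pad_mask
                else rep(FALSE, nrow(x))
  if (all(pad_mask)) stopf("attention over an all-pad sequence")
  scores <- as.vector(tanh(x %*% params$w) %*% params$v)
  scores[pad_mask] <- -Inf
  alpha <- softmax(scores)
  alpha[pad_mask] <- 0
  alpha / sum(alpha)
}

#' Construct softmax classifier parameters
#'
#' @param m input feature length.
#' @param n_classes number of output classes (default 5: negative plus the
#'   four interaction types).
#' @param dropout dropout rate applied to the input during training
#'   (default 0.45).
#' @param seed integer seed.
#' @return object of class `classifier_params`.
#' @export
classifier_params <- function(m, n_classes = 5L, dropout = 0.45, seed = 1L) {
  with_seed(seed, ws <- glorot_matrix(m, n_classes))
  structure(list(ws = ws, d = numeric(n_classes), dropout = dropout,
                 m = as.integer(m), n_classes = as.integer(n_classes)),
            class = "classifier_params")
}

#' Dropout + softmax classification
#'
#' During training the input features are dropped with probability
#' `params$dropout` (inverted dropout, so expectation is preserved); the output
#' is the softmax over `z W + d`.
#'
#' @param z feature vector of length `m`, or a `batch x m` matrix.
#' @param params a [classifier_params()].
#' @param training logical; dropout is applied only when `TRUE`.
#' @return probability vector over the classes (rows for a matrix input),
#'   named with the class labels.
#' @export
classify <- function(z, params, training = FALSE) {
  zm <- if (is.matrix(z)) z else matrix(z, nrow = 1)
  if (ncol(zm) != params$m)
    stopf("feature length %d does not match classifier input %d",
          ncol(zm), params$m)
  if (training && params$dropout > 0) {
    keep <- matrix(stats::runif(length(zm)) >= params$dropout, nrow(zm))
    zm <- zm * keep / (1 - params$dropout)
  }
  o <- sweep(zm %*% params$ws, 2L, params$d, `+`)
  p <- softmax(o)
  labels <- if (params$n_classes == length(DDI_CLASSES)) DDI_CLASSES
            else as.character(seq_len(params$n_classes))
  colnames(p) <- labels
  if (is.matrix(z)) p else stats::setNames(p[1, ], labels)
}

#' Assemble a multichannel piecewise CNN model
#'
#' Bundles the filter bank, attention, Gaussian-noise configuration and the
#' softmax classifier, with the reference defaults: windows `[3 5 7 9]`,
#' 128 filters each, dropout 0.45, noise std 0.1 at the pre-classifier site,
#' Adam learning rate 3e-4 (used by [train_model()]).
#'
#' @param set a [build_channel_set()] result (fixes the input width).
#' @param window_sizes,n_filters convolution geometry.
#' @param dropout classifier dropout rate.
#' @param noise a [noise_config()].
#' @param attention enable the input attention mechanism.
#' @param attn_dim attention hidden size.
#' @param learning_rate Adam step size used in training.
#' @param seed integer seed for all weight initializations.
#' @return object of class `mcpcnn_model`.
#' @export
mcpcnn_model <- function(set, window_sizes = c(3L, 5L, 7L, 9L),
                         n_filters = 128L, dropout = 0.45,
                         noise = noise_config(std = 0.1),
                         attention = TRUE, attn_dim = 32L,
                         learning_rate = 3e-4, seed = 1L) {
  width <- set$k + 2L * set$k_pos
  n_ch <- length(set$channels)
  m <- 3L * n_filters * length(window_sizes)
  structure(list(
    bank = conv_filter_bank(width, n_ch, window_sizes, n_filters, "tanh",
                            seed = seed),
    attn = if (attention) attention_params(width * n_ch, attn_dim,
                                           seed = seed + 1L) else NULL,
    clf = classifier_params(m, length(DDI_CLASSES), dropout, seed = seed + 2L),
    noise = noise, use_attention = isTRUE(attention),
    learning_rate = learning_rate, seed = as.integer(seed)
  ), class = "mcpcnn_model")
}

#' @export
print.mcpcnn_model <- function(x, ...) {
  cat(sprintf(paste0("<mcpcnn_model: windows [%s] x %d filters, attention %s, ",
                     "noise std %.3g (%s), dropout %.2f>\n"),
              paste(x$bank$window_sizes, collapse = " "), x$bank$n_filters,
              if (x$use_attention) "on" else "off",
              x$noise$std, x$noise$site, x$clf$dropout))
  invisible(x)
}

#' Forward pass of the multichannel piecewise CNN
#'
#' Composition: embed each channel, scale token rows by attention weights
#' (rescaled by the non-pad token count, so a uniform attention is a no-op),
#' optionally perturb the embedded rows (noise site `embedding`), convolve,
#' piecewise-max-pool around the anchors, concatenate the segment maxima into
#' `z`, optionally perturb `z` (noise site `pre_classifier`), then dropout and
#' softmax. With `training = FALSE`, or a noise std of 0, the pass is
#' deterministic and bit-identical to a noise-free graph.
#'
#' @param instance a padded `candidate_instance`.
#' @param set a [build_channel_set()].
#' @param model an [mcpcnn_model()].
#' @param training logical; enables noise and dropout.
#' @return named probability vector over the five classes.
#' @export
mcpcnn_forward <- function(instance, set, model, training = FALSE) {
  seq <- embed_instance(instance, set)
  x <- sequence_matrix(seq)
  if (model$use_attention) {
    alpha <- attention_weights(x, model$attn, seq$pad_mask)
    x <- x * (alpha * sum(!seq$pad_mask))
  }
  if (training && model$noise$site %in% c("embedding", "both")) {
    live <- !seq$pad_mask
    x[live, ] <- gaussian_noise(x[live, , drop = FALSE], model$noise, training)
  }
  maps <- convolve_windows(x, model$bank)
  z <- unlist(lapply(maps, pool_feature_map, p1 = seq$p1, p2 = seq$p2),
              use.names = FALSE)
  if (training && model$noise$site %in% c("pre_classifier", "both"))
    z <- gaussian_noise(z, model$noise, training)
  classify(z, model$clf, training)
}
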