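# Mini-batch training of the multichannel piecewise CNN.
#
# The batched path reproduces mcpcnn_forward() exactly (a property the test
# suite checks) but materializes only the first L_b token rows of each batch,
# where L_b is the longest non-pad length in the batch: padding rows embed to
# zero, so every window beyond the last real token has the constant value
# f(bias), which is folded into the pooling step analytically. Gradients are
# derived by hand; word-embedding channels stay frozen while the position
# tables, attention, filters and classifier are trained with Adam.

# Precompute integer index matrices so each batch is pure matrix algebra.
mcpcnn_prepare_data <- function(instances, set) {
  n <- length(instances)
  if (n == 0) stopf("no instances to prepare")
  L <- length(instances[[1]]$tokens)
  md <- set$max_dist
  lens <- integer(n)
  p1 <- integer(n)
  p2 <- integer(n)
  labels <- integer(n)
  d1 <- matrix(1L, n, L)
  d2 <- matrix(1L, n, L)
  tok <- lapply(set$channels, function(tb) matrix(1L, n, L))
  lookups <- lapply(seq_along(set$channels), function(ci) {
    rbind(set$channels[[ci]]$matrix, set$oov[[ci]])   # last row = OOV vector
  })
  for (i in seq_len(n)) {
    inst <- instances[[i]]
    if (length(inst$tokens) != L)
      stopf("instance '%s' has length %d; all instances must share one padded length",
            inst$pair_id, length(inst$tokens))
    lens[i] <- inst$length %||% sum(!inst$pad_mask)
    p1[i] <- inst$p1
    p2[i] <- inst$p2
    labels[i] <- match(inst$label, DDI_CLASSES)
    d1[i, ] <- pmin(pmax(inst$dist_e1, -md), md) + md + 1L
    d2[i, ] <- pmin(pmax(inst$dist_e2, -md), md) + md + 1L
    for (ci in seq_along(set$channels)) {
      idx <- channel_token_rows(inst$tokens, inst$pad_mask, set$channels[[ci]])
      idx[idx == 0L] <- nrow(lookups[[ci]])
      tok[[ci]][i, ] <- idx
    }
  }
  if (anyNA(labels)) stopf("instance with label outside the class schema")
  list(n = n, L = L, lens = lens, p1 = p1, p2 = p2, labels = labels,
       d1 = d1, d2 = d2, tok = tok, lookups = lookups,
       sentence_ids = vapply(instances, `[[`, "", "sentence_id"),
       filtered = vapply(instances, function(x) isTRUE(x$filtered), TRUE))
}

adam_init <- function(param) list(m = param * 0, v = param * 0)

adam_step <- function(param, grad, state, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$m <- beta1 * state$m + (1 - beta1) * grad
  state$v <- beta2 * state$v + (1 - beta2) * grad * grad
  mhat <- state$m / (1 - beta1^t)
  vhat <- state$v / (1 - beta2^t)
  list(param = param - lr * mhat / (sqrt(vhat) + eps), state = state)
}

# Assemble the embedded, attention-scaled input block for a batch.
# Returns the flattened (B*L_b) x width matrices plus attention caches.
mcpcnn_batch_input <- function(data, batch, set, model, L_b) {
  B <- length(batch)
  w1 <- set$k
  kp <- set$k_pos
  lens <- data$lens[batch]
  flat_len <- rep(lens, each = L_b)
  flat_pos <- rep(seq_len(L_b), B)
  padflat <- flat_pos > flat_len

  d1f <- as.vector(t(data$d1[batch, seq_len(L_b), drop = FALSE]))
  d2f <- as.vector(t(data$d2[batch, seq_len(L_b), drop = FALSE]))
  p1b <- set$pos_e1[d1f, , drop = FALSE]
  p2b <- set$pos_e2[d2f, , drop = FALSE]
  blocks <- vector("list", length(set$channels))
  for (ci in seq_along(set$channels)) {
    tf <- as.vector(t(data$tok[[ci]][batch, seq_len(L_b), drop = FALSE]))
    blocks[[ci]] <- cbind(data$lookups[[ci]][tf, , drop = FALSE], p1b, p2b)
  }
  x <- do.call(cbind, blocks)
  x[padflat, ] <- 0

  cache <- list(x = x, padflat = padflat, d1f = d1f, d2f = d2f, lens = lens,
                B = B, L_b = L_b)
  if (model$use_attention) {
    spre <- x %*% model$attn$w
    s <- tanh(spre)
    sc <- as.vector(s %*% model$attn$v)
    scm <- matrix(sc, nrow = L_b)
    scm[matrix(padflat, nrow = L_b)] <- -Inf
    mx <- apply(scm, 2L, max)
    e <- exp(sweep(scm, 2L, mx, `-`))
    e[matrix(padflat, nrow = L_b)] <- 0
    alpha <- sweep(e, 2L, colSums(e), `/`)
    a <- sweep(alpha, 2L, lens, `*`)
    avec <- as.vector(a)
    cache$s <- s
    cache$alpha <- alpha
    cache$avec <- avec
    cache$xs <- x * avec
  } else {
    cache$xs <- x
  }
  cache
}

# Forward pass over one batch; returns probabilities plus caches for backprop.
mcpcnn_batch_forward <- function(data, batch, set, model, training = FALSE,
                                 keep_cache = FALSE) {
  B <- length(batch)
  max_h <- max(model$bank$window_sizes)
  L_b <- max(max_h, max(data$lens[batch]))
  # materialize max_h - 1 extra pad rows so every window starting at a real
  # token position is computable; windows starting beyond L_b are pad-only
  L_x <- min(data$L, L_b + max_h - 1L)
  inp <- mcpcnn_batch_input(data, batch, set, model, L_x)
  xs <- inp$xs
  if (training && model$noise$site %in% c("embedding", "both")) {
    live <- !inp$padflat
    xs[live, ] <- gaussian_noise(xs[live, , drop = FALSE], model$noise, TRUE)
    inp$xs <- xs
  }
  hs <- as.character(model$bank$window_sizes)
  F <- model$bank$n_filters
  p1 <- data$p1[batch]
  p2 <- data$p2[batch]
  wt <- ncol(xs)
  # fast path: when every window size has the same number of window positions
  # (the usual case, away from the padded-length ceiling), the h shifted row
  # extracts are shared across window sizes and the convolution becomes a sum
  # of per-shift matrix products, avoiding the large im2col blocks
  shared_fast <- L_b <= data$L - max_h + 1L
  shifts <- NULL
  starts_shared <- NULL
  if (shared_fast) {
    n_w_s <- L_b
    starts_shared <- rep((seq_len(B) - 1L) * L_x, each = n_w_s) +
      rep(seq_len(n_w_s), B)
    shifts <- lapply(0:(max_h - 1L), function(s)
      xs[starts_shared + s, , drop = FALSE])
  }
  conv <- list()
  Z <- NULL
  for (hn in hs) {
    h <- as.integer(hn)
    n_wf <- data$L - h + 1L               # conceptual map length at full padding
    n_w <- min(L_b, n_wf)                 # windows starting at materialized rows
    if (shared_fast) {
      starts <- starts_shared
      M <- NULL
      pre <- matrix(model$bank$biases[[hn]], n_w * B, F, byrow = TRUE)
      for (s in 0:(h - 1L))
        pre <- pre + shifts[[s + 1L]] %*%
          model$bank$weights[[hn]][s * wt + seq_len(wt), , drop = FALSE]
    } else {
      starts <- rep((seq_len(B) - 1L) * L_x, each = n_w) + rep(seq_len(n_w), B)
      M <- do.call(cbind, lapply(0:(h - 1L), function(s)
        xs[starts + s, , drop = FALSE]))
      pre <- sweep(M %*% model$bank$weights[[hn]], 2L, model$bank$biases[[hn]], `+`)
    }
    C <- tanh(pre)
    tb <- tanh(model$bank$biases[[hn]])
    Zh <- matrix(0, B, 3L * F)
    IDXh <- matrix(-1L, B, 3L * F)        # -1 empty, 0 pad-constant, else C row
    for (i in seq_len(B)) {
      base <- (i - 1L) * n_w
      b1 <- min(p1[i], n_wf)
      b2 <- min(p2[i], n_wf)
      bounds <- rbind(c(1L, b1), c(b1 + 1L, b2), c(b2 + 1L, n_wf))
      if (b2 <= b1) bounds[2L, ] <- c(1L, 0L)
      row_v <- numeric(3L * F)
      row_i <- integer(3L * F)
      for (j in 1:3) {
        from <- bounds[j, 1]
        to <- bounds[j, 2]
        cols <- (seq_len(F) - 1L) * 3L + j
        if (from > to) { row_i[cols] <- -1L; next }
        to_c <- min(to, n_w)
        if (from <= to_c) {
          sub <- C[base + (from:to_c), , drop = FALSE]
          cm <- col_max_with_index(sub)
          vals <- cm$values
          idxs <- base + from - 1L + cm$index
        } else {
          vals <- rep(-Inf, F)
          idxs <- integer(F)
        }
        if (to > n_w) {                    # pad-only tail windows, value tanh(b)
          use_pad <- tb > vals
          vals[use_pad] <- tb[use_pad]
          idxs[use_pad] <- 0L
        }
        row_v[cols] <- vals
        row_i[cols] <- idxs
      }
      Zh[i, ] <- row_v
      IDXh[i, ] <- row_i
    }
    conv[[hn]] <- list(M = M, C = C, n_w = n_w, starts = starts, idx = IDXh,
                       tb = tb)
    Z <- cbind(Z, Zh)
  }
  Zn <- Z
  if (training && model$noise$site %in% c("pre_classifier", "both"))
    Zn <- gaussian_noise(Zn, model$noise, TRUE)
  if (training && model$clf$dropout > 0) {
    keepm <- matrix(stats::runif(length(Zn)) >= model$clf$dropout, nrow(Zn)) /
      (1 - model$clf$dropout)
  } else keepm <- NULL
  Zd <- if (is.null(keepm)) Zn else Zn * keepm
  logits <- sweep(Zd %*% model$clf$ws, 2L, model$clf$d, `+`)
  P <- softmax(logits)
  out <- list(P = P, Z = Z, Zd = Zd, keepm = keepm)
  if (keep_cache) {
    out$conv <- conv
    out$inp <- inp
    out$shared_fast <- shared_fast
    out$shifts <- shifts
    out$starts_shared <- starts_shared
    out$max_h <- max_h
  }
  out
}

# Gradients for one batch (mean cross-entropy). Returns a named list mirroring
# the trainable parameters.
mcpcnn_batch_backward <- function(data, batch, set, model, fwd) {
  B <- length(batch)
  F <- model$bank$n_filters
  y <- data$labels[batch]
  G <- fwd$P
  G[cbind(seq_len(B), y)] <- G[cbind(seq_len(B), y)] - 1
  G <- G / B

  grads <- list(ws = crossprod(fwd$Zd, G), d = colSums(G))
  dZd <- tcrossprod(G, model$clf$ws)
  dZ <- if (is.null(fwd$keepm)) dZd else dZd * fwd$keepm

  inp <- fwd$inp
  R <- nrow(inp$xs)
  dXs <- matrix(0, R, ncol(inp$xs))
  col0 <- 0L
  grads$weights <- list()
  grads$biases <- list()
  wt <- ncol(inp$xs)
  dshift <- if (isTRUE(fwd$shared_fast))
    vector("list", fwd$max_h) else NULL
  for (hn in names(fwd$conv)) {
    cv <- fwd$conv[[hn]]
    h <- as.integer(hn)
    dZh <- dZ[, col0 + seq_len(3L * F), drop = FALSE]
    col0 <- col0 + 3L * F
    idx <- cv$idx
    dC <- matrix(0, nrow(cv$C), F)
    db_pad <- numeric(F)
    fcols <- matrix(rep(seq_len(F), each = 3L), nrow = B, ncol = 3L * F,
                    byrow = TRUE)
    sel_real <- idx > 0L
    if (any(sel_real))
      dC[cbind(idx[sel_real], fcols[sel_real])] <-
        dC[cbind(idx[sel_real], fcols[sel_real])] + dZh[sel_real]
    sel_pad <- idx == 0L
    if (any(sel_pad)) {
      contrib <- dZh[sel_pad] * (1 - cv$tb[fcols[sel_pad]]^2)
      agg <- rowsum(contrib, fcols[sel_pad])
      ii <- as.integer(rownames(agg))
      db_pad[ii] <- db_pad[ii] + agg[, 1]
    }
    dA <- dC * (1 - cv$C^2)
    grads$biases[[hn]] <- colSums(dA) + db_pad
    if (isTRUE(fwd$shared_fast)) {
      gw <- matrix(0, h * wt, F)
      for (s in 0:(h - 1L)) {
        rows <- s * wt + seq_len(wt)
        gw[rows, ] <- crossprod(fwd$shifts[[s + 1L]], dA)
        contrib <- tcrossprod(dA, model$bank$weights[[hn]][rows, , drop = FALSE])
        dshift[[s + 1L]] <- if (is.null(dshift[[s + 1L]])) contrib
                            else dshift[[s + 1L]] + contrib
      }
      grads$weights[[hn]] <- gw
    } else {
      grads$weights[[hn]] <- crossprod(cv$M, dA)
      dM <- tcrossprod(dA, model$bank$weights[[hn]])
      for (s in 0:(h - 1L)) {
        rs <- cv$starts + s
        dXs[rs, ] <- dXs[rs, ] + dM[, s * wt + seq_len(wt), drop = FALSE]
      }
    }
  }
  if (isTRUE(fwd$shared_fast)) {
    for (s in seq_along(dshift)) {
      if (is.null(dshift[[s]])) next
      rs <- fwd$starts_shared + (s - 1L)
      dXs[rs, ] <- dXs[rs, ] + dshift[[s]]
    }
  }

  if (model$use_attention) {
    x <- inp$x
    dX <- dXs * inp$avec
    davec <- rowSums(dXs * x)
    L_b <- inp$L_b
    dam <- matrix(davec, nrow = L_b)
    dalpha <- sweep(dam, 2L, inp$lens, `*`)
    alpha <- inp$alpha
    dsc <- alpha * sweep(dalpha, 2L, colSums(alpha * dalpha), `-`)
    dscv <- as.vector(dsc)
    grads$attn_v <- as.vector(crossprod(inp$s, dscv))
    dSpre <- tcrossprod(dscv, model$attn$v) * (1 - inp$s^2)
    grads$attn_w <- crossprod(x, dSpre)
    dX <- dX + tcrossprod(dSpre, model$attn$w)
  } else {
    dX <- dXs
  }
  dX[inp$padflat, ] <- 0

  kp <- set$k_pos
  w1 <- set$k
  cw <- w1 + 2L * kp
  n_ch <- length(set$channels)
  c1 <- matrix(0, nrow(dX), kp)
  c2 <- matrix(0, nrow(dX), kp)
  for (ci in seq_len(n_ch)) {
    off <- (ci - 1L) * cw
    c1 <- c1 + dX[, off + w1 + seq_len(kp), drop = FALSE]
    c2 <- c2 + dX[, off + w1 + kp + seq_len(kp), drop = FALSE]
  }
  acc_pos <- function(contrib, groups, nrows) {
    rs <- rowsum(contrib, groups)
    out <- matrix(0, nrows, ncol(contrib))
    out[as.integer(rownames(rs)), ] <- rs
    out
  }
  grads$pos_e1 <- acc_pos(c1, inp$d1f, nrow(set$pos_e1))
  grads$pos_e2 <- acc_pos(c2, inp$d2f, nrow(set$pos_e2))
  grads
}

mcpcnn_loss <- function(P, y) {
  -mean(log(pmax(P[cbind(seq_along(y), y)], 1e-12)))
}

# Batched label prediction (inference mode).
mcpcnn_predict_prepared <- function(data, idx, set, model, batch_size = 64L) {
  ord <- order(data$lens[idx])            # length bucketing for speed
  sorted <- idx[ord]
  preds <- character(length(idx))
  splits <- split(seq_along(sorted), ceiling(seq_along(sorted) / batch_size))
  for (sl in splits) {
    fwd <- mcpcnn_batch_forward(data, sorted[sl], set, model, training = FALSE,
                                keep_cache = FALSE)
    preds[ord[sl]] <- DDI_CLASSES[max.col(fwd$P, ties.method = "first")]
  }
  preds
}

#' Predict labels for candidate instances with a trained CNN model
#'
#' @param instances list of padded `candidate_instance` objects.
#' @param set the [build_channel_set()] used in training (with its trained
#'   position tables).
#' @param model a trained [mcpcnn_model()].
#' @param batch_size forward batch size.
#' @param filtered_as_negative if `TRUE`, instances flagged by
#'   [filter_negatives()] bypass the model and are predicted `negative`.
#' @return character vector of predicted class labels.
#' @export
mcpcnn_predict <- function(instances, set, model, batch_size = 64L,
                           filtered_as_negative = FALSE) {
  data <- mcpcnn_prepare_data(instances, set)
  preds <- mcpcnn_predict_prepared(data, seq_len(data$n), set, model, batch_size)
  if (filtered_as_negative) preds[data$filtered] <- "negative"
  preds
}

# Full training loop. Returns the best-on-validation model, the updated
# channel set (trained position tables) and the per-epoch history.
train_mcpcnn <- function(train_instances, val_instances, set, model, cfg) {
  data_tr <- mcpcnn_prepare_data(train_instances, set)
  data_va <- mcpcnn_prepare_data(val_instances, set)
  lr <- cfg$learning_rate %||% model$learning_rate
  bs <- cfg$batch_size %||% 64L
  hs <- names(model$bank$weights)

  opt <- list(ws = adam_init(model$clf$ws), d = adam_init(model$clf$d),
              pos_e1 = adam_init(set$pos_e1), pos_e2 = adam_init(set$pos_e2))
  for (hn in hs) {
    opt[[paste0("W", hn)]] <- adam_init(model$bank$weights[[hn]])
    opt[[paste0("b", hn)]] <- adam_init(model$bank$biases[[hn]])
  }
  if (model$use_attention) {
    opt$attn_w <- adam_init(model$attn$w)
    opt$attn_v <- adam_init(model$attn$v)
  }

  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_precision = numeric(0), val_recall = numeric(0),
                        val_f1 = numeric(0))
  best <- list(f1 = -Inf, epoch = 0L,
               model = model, set = set)
  step <- 0L
  gold_va <- DDI_CLASSES[data_va$labels]

  if (cfg$max_epochs > 0) for (epoch in seq_len(cfg$max_epochs)) {
    # shuffle, then bucket batches by length (cheap batches materialize fewer
    # token rows) and visit the buckets in random order
    perm <- sample.int(data_tr$n)
    ord <- perm[order(data_tr$lens[perm])]
    batches <- split(ord, ceiling(seq_along(ord) / bs))
    batches <- batches[sample.int(length(batches))]
    epoch_loss <- 0
    for (b in batches) {
      fwd <- mcpcnn_batch_forward(data_tr, b, set, model, training = TRUE,
                                  keep_cache = TRUE)
      loss <- mcpcnn_loss(fwd$P, data_tr$labels[b])
      if (!is.finite(loss))
        stopf("non-finite training loss at epoch %d (lr=%g); aborting", epoch, lr)
      epoch_loss <- epoch_loss + loss * length(b)
      g <- mcpcnn_batch_backward(data_tr, b, set, model, fwd)
      step <- step + 1L
      up <- adam_step(model$clf$ws, g$ws, opt$ws, lr, step)
      model$clf$ws <- up$param; opt$ws <- up$state
      up <- adam_step(model$clf$d, g$d, opt$d, lr, step)
      model$clf$d <- up$param; opt$d <- up$state
      for (hn in hs) {
        up <- adam_step(model$bank$weights[[hn]], g$weights[[hn]],
                        opt[[paste0("W", hn)]], lr, step)
        model$bank$weights[[hn]] <- up$param; opt[[paste0("W", hn)]] <- up$state
        up <- adam_step(model$bank$biases[[hn]], g$biases[[hn]],
                        opt[[paste0("b", hn)]], lr, step)
        model$bank$biases[[hn]] <- up$param; opt[[paste0("b", hn)]] <- up$state
      }
      if (model$use_attention) {
        up <- adam_step(model$attn$w, g$attn_w, opt$attn_w, lr, step)
        model$attn$w <- up$param; opt$attn_w <- up$state
        up <- adam_step(model$attn$v, g$attn_v, opt$attn_v, lr, step)
        model$attn$v <- up$param; opt$attn_v <- up$state
      }
      up <- adam_step(set$pos_e1, g$pos_e1, opt$pos_e1, lr, step)
      set$pos_e1 <- up$param; opt$pos_e1 <- up$state
      up <- adam_step(set$pos_e2, g$pos_e2, opt$pos_e2, lr, step)
      set$pos_e2 <- up$param; opt$pos_e2 <- up$state
    }
    pred_va <- mcpcnn_predict_prepared(data_va, seq_len(data_va$n), set, model, bs)
    rep <- evaluate_predictions(pred_va, gold_va)
    history <- rbind(history, data.frame(
      epoch = epoch, train_loss = epoch_loss / data_tr$n,
      val_precision = rep$micro["precision"], val_recall = rep$micro["recall"],
      val_f1 = rep$micro["f1"]))
    if (isTRUE(cfg$verbose))
      message(sprintf("epoch %d: loss %.4f, val micro-F1 %.4f",
                      epoch, epoch_loss / data_tr$n, rep$micro["f1"]))
    if (rep$micro["f1"] > best$f1) {        # ties keep the earliest epoch
      best <- list(f1 = rep$micro["f1"], epoch = epoch, model = model, set = set)
    }
    if (!is.null(cfg$patience) && epoch - best$epoch >= cfg$patience) break
  }
  rownames(history) <- NULL
  list(model = best$model, set = best$set, history = history,
       best_epoch = best$epoch, best_f1 = unname(best$f1))
}
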