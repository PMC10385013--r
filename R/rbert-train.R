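# Training of the relation head (and, when the tiny encoder is used, of the
# encoder itself) by per-instance backpropagation with mini-batch Adam.

rbert_forward_train <- function(bert_input, encoder, head, training = TRUE) {
  n <- bert_input$length
  tokens <- bert_input$tokens[seq_len(n)]
  ent_ids <- entity_positional_encoding(bert_input)[seq_len(n)]
  trainable_enc <- inherits(encoder, "tiny_encoder")
  if (trainable_enc) {
    ef <- tiny_encoder_forward(encoder, tokens, ent_ids, keep_cache = TRUE)
    h <- ef$h
    enc_cache <- ef$cache
  } else {
    h <- encode_sequence(encoder, tokens, ent_ids)
    enc_cache <- NULL
  }
  pooled <- rbert_pool_all(h, bert_input, head)
  pre <- list()
  blocks <- list()
  for (p in head$parts) {
    pr <- head$proj[[p]]
    pre[[p]] <- as.vector(crossprod(pr$w, pooled[[p]])) + pr$b
    blocks[[p]] <- tanh(pre[[p]])
  }
  hr <- unlist(blocks, use.names = FALSE)
  if (head$interaction == "dot") hr <- c(hr, pooled$e1 * pooled$e2)
  if (head$interaction == "absdiff") hr <- c(hr, abs(pooled$e1 - pooled$e2))
  hr_noised <- if (training && head$noise$site %in% c("pre_classifier", "both"))
    gaussian_noise(hr, head$noise, TRUE) else hr
  keep <- if (training && head$dropout > 0)
    (stats::runif(length(hr)) >= head$dropout) / (1 - head$dropout)
  else rep(1, length(hr))
  hr_d <- hr_noised * keep
  o <- as.vector(crossprod(head$ws, hr_d)) + head$b
  p_out <- softmax(o)
  list(p = p_out, h = h, pooled = pooled, blocks = blocks, hr_d = hr_d,
       keep = keep, enc_cache = enc_cache, trainable_enc = trainable_enc,
       spans = bert_input$spans, n = n)
}

pool_segment_backward <- function(dH, dp, rows_h, span, method, w) {
  if (is.null(span) || span[1] > span[2]) return(list(dH = dH, dw = NULL))
  rows <- span[1]:span[2]
  m <- length(rows)
  dw <- NULL
  if (method == "average") {
    dH[rows, ] <- dH[rows, , drop = FALSE] +
      matrix(dp / m, m, length(dp), byrow = TRUE)
  } else if (method == "start") {
    dH[rows[1], ] <- dH[rows[1], ] + dp
  } else if (method == "max") {
    sub <- rows_h[rows, , drop = FALSE]
    am <- max.col(t(sub), ties.method = "first")
    dH[cbind(rows[am], seq_along(dp))] <- dH[cbind(rows[am], seq_along(dp))] + dp
  } else if (method == "self_attention") {
    sub <- rows_h[rows, , drop = FALSE]
    a <- softmax(as.vector(sub %*% w))
    dA <- as.vector(sub %*% dp)
    dR <- tcrossprod(a, dp)
    ds <- a * (dA - sum(a * dA))
    dw <- as.vector(crossprod(sub, ds))
    dR <- dR + tcrossprod(ds, w)
    dH[rows, ] <- dH[rows, , drop = FALSE] + dR
  }
  list(dH = dH, dw = dw)
}

rbert_backward <- function(fwd, encoder, head, gold_class, grads) {
  K <- length(DDI_CLASSES)
  dlog <- fwd$p
  dlog[gold_class] <- dlog[gold_class] - 1
  grads$head$ws <- grads$head$ws + tcrossprod(fwd$hr_d, dlog)
  grads$head$b <- grads$head$b + dlog
  dhr <- as.vector(head$ws %*% dlog) * fwd$keep

  d <- head$d
  dpooled <- lapply(fwd$pooled, function(v) numeric(length(v)))
  off <- 0L
  for (p in head$parts) {
    blk <- dhr[off + seq_len(head$d_proj)]
    off <- off + head$d_proj
    dpre <- blk * (1 - fwd$blocks[[p]]^2)
    grads$head$proj[[p]]$w <- grads$head$proj[[p]]$w +
      tcrossprod(fwd$pooled[[p]], dpre)
    grads$head$proj[[p]]$b <- grads$head$proj[[p]]$b + dpre
    dpooled[[p]] <- dpooled[[p]] + as.vector(head$proj[[p]]$w %*% dpre)
  }
  if (head$interaction != "none") {
    blk <- dhr[off + seq_len(d)]
    if (head$interaction == "dot") {
      dpooled$e1 <- dpooled$e1 + blk * fwd$pooled$e2
      dpooled$e2 <- dpooled$e2 + blk * fwd$pooled$e1
    } else {
      sg <- sign(fwd$pooled$e1 - fwd$pooled$e2)
      dpooled$e1 <- dpooled$e1 + blk * sg
      dpooled$e2 <- dpooled$e2 - blk * sg
    }
  }

  dH <- matrix(0, fwd$n, d)
  for (p in names(dpooled)) {
    method <- if (p %in% head$parts) head$pooling[[p]] else "average"
    pb <- pool_segment_backward(dH, dpooled[[p]], fwd$h, fwd$spans[[p]],
                                method, head$attn_w[[p]] %||% numeric(d))
    dH <- pb$dH
    if (!is.null(pb$dw) && p %in% head$parts)
      grads$head$attn_w[[p]] <- grads$head$attn_w[[p]] + pb$dw
  }

  if (fwd$trainable_enc) {
    cache <- fwd$enc_cache
    scale <- 1 / sqrt(encoder$d)
    for (l in rev(seq_len(encoder$n_layers))) {
      lc <- cache$layers[[l]]
      lp <- encoder$par$layers[[l]]
      gl <- grads$enc$layers[[l]]
      # feed-forward block: h2 = h1 + tanh(h1 w1 + b1) w2 + b2
      gl$w2 <- gl$w2 + crossprod(lc$u, dH)
      gl$b2 <- gl$b2 + colSums(dH)
      du <- tcrossprod(dH, lp$w2)
      dupre <- du * (1 - lc$u^2)
      gl$w1 <- gl$w1 + crossprod(lc$h1, dupre)
      gl$b1 <- gl$b1 + colSums(dupre)
      dH1 <- dH + tcrossprod(dupre, lp$w1)
      # attention block: h1 = h + softmax(q k' / sqrt(d)) v
      dA <- tcrossprod(dH1, lc$v)
      dV <- crossprod(lc$a, dH1)
      ds <- lc$a * (dA - rowSums(lc$a * dA))
      dQ <- (ds %*% lc$k) * scale
      dK <- (crossprod(ds, lc$q)) * scale
      gl$wq <- gl$wq + crossprod(lc$h, dQ)
      gl$wk <- gl$wk + crossprod(lc$h, dK)
      gl$wv <- gl$wv + crossprod(lc$h, dV)
      dH <- dH1 + tcrossprod(dQ, lp$wq) + tcrossprod(dK, lp$wk) +
        tcrossprod(dV, lp$wv)
      grads$enc$layers[[l]] <- gl
    }
    gtok <- rowsum(dH, cache$ids)
    ii <- as.integer(rownames(gtok))
    grads$enc$e_tok[ii, ] <- grads$enc$e_tok[ii, , drop = FALSE] + gtok
    grads$enc$e_pos[seq_len(fwd$n), ] <-
      grads$enc$e_pos[seq_len(fwd$n), , drop = FALSE] + dH
    gent <- rowsum(dH, cache$ent_ids + 1L)
    jj <- as.integer(rownames(gent))
    grads$enc$e_ent[jj, ] <- grads$enc$e_ent[jj, , drop = FALSE] + gent
  }
  grads
}

rbert_zero_grads <- function(encoder, head, trainable_enc) {
  zero_like <- function(x) x * 0
  g <- list(head = list(
    ws = zero_like(head$ws), b = zero_like(head$b),
    proj = lapply(head$proj, function(p) list(w = zero_like(p$w),
                                              b = zero_like(p$b))),
    attn_w = lapply(head$attn_w, zero_like)
  ))
  if (trainable_enc) {
    g$enc <- list(
      e_tok = zero_like(encoder$par$e_tok),
      e_pos = zero_like(encoder$par$e_pos),
      e_ent = zero_like(encoder$par$e_ent),
      layers = lapply(encoder$par$layers, function(lp) lapply(lp, zero_like))
    )
  }
  g
}

# Walks parameter/gradient/optimizer trees in parallel, applying Adam to every
# numeric leaf.
adam_tree_step <- function(par, grad, st, lr, t) {
  if (is.list(par)) {
    for (nm in names(par)) {
      r <- adam_tree_step(par[[nm]], grad[[nm]], st[[nm]], lr, t)
      par[[nm]] <- r$par
      st[[nm]] <- r$st
    }
    return(list(par = par, st = st))
  }
  if (is.null(st)) st <- adam_init(par)
  up <- adam_step(par, grad, st, lr, t)
  list(par = up$param, st = up$state)
}

#' Predict labels for marked inputs with the relation model
#'
#' @param inputs list of [preprocess_for_bert()] results.
#' @param encoder encoder object or function (see [rbert_forward()]).
#' @param head an [rbert_head()].
#' @return character vector of predicted class labels.
#' @export
rbert_predict <- function(inputs, encoder, head) {
  vapply(inputs, function(bi) {
    p <- rbert_forward(bi, encoder, head, training = FALSE)
    DDI_CLASSES[which.max(p)]
  }, "")
}

# Training loop shared surface with train_mcpcnn: returns best-on-validation
# parameters and per-epoch history.
train_rbert <- function(train_inputs, val_inputs, encoder, head, cfg) {
  trainable_enc <- inherits(encoder, "tiny_encoder")
  lr <- cfg$learning_rate %||% 1e-3
  bs <- cfg$batch_size %||% 16L
  gold_tr <- match(vapply(train_inputs, `[[`, "", "label"), DDI_CLASSES)
  gold_va <- vapply(val_inputs, `[[`, "", "label")
  st <- list(head = NULL, enc = NULL)
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_precision = numeric(0), val_recall = numeric(0),
                        val_f1 = numeric(0))
  best <- list(f1 = -Inf, epoch = 0L, encoder = encoder, head = head)
  step <- 0L
  if (cfg$max_epochs > 0) for (epoch in seq_len(cfg$max_epochs)) {
    ord <- sample.int(length(train_inputs))
    batches <- split(ord, ceiling(seq_along(ord) / bs))
    epoch_loss <- 0
    for (b in batches) {
      grads <- rbert_zero_grads(encoder, head, trainable_enc)
      for (i in b) {
        fwd <- rbert_forward_train(train_inputs[[i]], encoder, head,
                                   training = TRUE)
        loss <- -log(max(fwd$p[gold_tr[i]], 1e-12))
        if (!is.finite(loss))
          stopf("non-finite training loss at epoch %d; aborting", epoch)
        epoch_loss <- epoch_loss + loss
        grads <- rbert_backward(fwd, encoder, head, gold_tr[i], grads)
      }
      scale_tree <- function(x) if (is.list(x)) lapply(x, scale_tree)
                                else x / length(b)
      grads <- scale_tree(grads)
      step <- step + 1L
      r <- adam_tree_step(
        list(head = list(ws = head$ws, b = head$b, proj = head$proj,
                         attn_w = head$attn_w),
             enc = if (trainable_enc) encoder$par),
        grads, st, lr, step)
      head$ws <- r$par$head$ws
      head$b <- r$par$head$b
      head$proj <- r$par$head$proj
      head$attn_w <- r$par$head$attn_w
      if (trainable_enc) encoder$par <- r$par$enc
      st <- r$st
    }
    pred_va <- rbert_predict(val_inputs, encoder, head)
    rep <- evaluate_predictions(pred_va, gold_va)
    history <- rbind(history, data.frame(
      epoch = epoch, train_loss = epoch_loss / length(train_inputs),
      val_precision = rep$micro["precision"], val_recall = rep$micro["recall"],
      val_f1 = rep$micro["f1"]))
    if (isTRUE(cfg$verbose))
      message(sprintf("epoch %d: loss %.4f, val micro-F1 %.4f",
                      epoch, epoch_loss / length(train_inputs),
                      rep$micro["f1"]))
    if (rep$micro["f1"] > best$f1) {
      best <- list(f1 = rep$micro["f1"], epoch = epoch,
                   encoder = encoder, head = head)
    }
    if (!is.null(cfg$patience) && epoch - best$epoch >= cfg$patience) break
  }
  rownames(history) <- NULL
  list(encoder = best$encoder, head = best$head, history = history,
       best_epoch = best$epoch, best_f1 = unname(best$f1))
}
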