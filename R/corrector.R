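# Imprint correction: an attention-based bidirectional character-level
# sequence-to-sequence model. Each detected character enters the encoder as
# the concatenation of its one-hot vocabulary encoding and its normalized
# (x, y) centre — the coordinate encoding that lets the model recover the
# true character order from an unordered, confusion-prone detection set.
# The decoder emits the canonical imprint (front tokens, "_", back tokens)
# one character at a time, maximizing the conditional likelihood
# prod_j p(tgt_j | tgt_<j, src) under teacher forcing. Optionally the pill's
# (shape, colour, form) labels are embedded, summed, and used as the
# encoder's initial hidden state, so the features act as context for the
# imprint.

corrector_sos <- function() length(pill_vocabulary()) + 2L  # 40
corrector_eos <- function() length(pill_vocabulary()) + 1L  # 39

#' Corrector configuration
#'
#' @param embedding_size Character embedding width (default 45).
#' @param hidden_size GRU hidden width (default 256; desk-scale runs use
#'   smaller values).
#' @param context_mode `"none"` or `"features"`: whether (shape, colour,
#'   form) labels condition the encoder's initial hidden state.
#' @param learning_rate Adam learning rate (default 1e-3).
#' @param batch_size Minibatch size (default 50).
#' @param epochs Training epochs.
#' @param max_target_len Maximum target length in tokens (inputs longer than
#'   this are rejected at data load).
#' @param use_coords If `FALSE`, the (x, y) part of the encoding is zeroed at
#'   train and test time (the coordinate-ablation switch).
#' @param seed Integer seed.
#' @return A `corrector_config` list.
#' @export
corrector_config <- function(embedding_size = 45L, hidden_size = 256L,
                             context_mode = c("none", "features"),
                             learning_rate = 1e-3, batch_size = 50L,
                             epochs = 30L, max_target_len = 24L,
                             use_coords = TRUE, seed = 1L) {
  context_mode <- match.arg(context_mode)
  stopifnot(embedding_size > 0, hidden_size > 0, learning_rate > 0,
            max_target_len > 0)
  structure(list(embedding_size = as.integer(embedding_size),
                 hidden_size = as.integer(hidden_size),
                 context_mode = context_mode,
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 max_target_len = as.integer(max_target_len),
                 use_coords = isTRUE(use_coords),
                 seed = as.integer(seed)),
            class = "corrector_config")
}

#' Coordinate-encode a detection sequence
#'
#' Maps each detection to the concatenation of the one-hot encoding of its
#' character over [pill_vocabulary()] and its normalized `(x, y)` centre:
#' a `|V| + 2`-dimensional vector per character, order preserved.
#'
#' @param detections Tibble with `char`, `x`, `y`.
#' @return A numeric matrix with one row per detection and `|V| + 2`
#'   columns (0 rows for empty input).
#' @export
#' @examples
#' encode_sequence(tibble::tibble(char = "M", x = 0.2, y = 0.5))
encode_sequence <- function(detections) {
  vocab <- pill_vocabulary()
  n <- nrow(detections)
  out <- matrix(0, n, length(vocab) + 2L)
  if (n == 0L) return(out)
  idx <- match(detections$char, vocab)
  if (anyNA(idx)) {
    stop("out-of-vocabulary symbol(s): ",
         paste(unique(detections$char[is.na(idx)]), collapse = ", "),
         call. = FALSE)
  }
  out[cbind(seq_len(n), idx)] <- 1
  out[, length(vocab) + 1L] <- detections$x
  out[, length(vocab) + 2L] <- detections$y
  out
}

corrector_init_params <- function(cfg) {
  V <- length(pill_vocabulary())
  E <- cfg$embedding_size; H <- cfg$hidden_size
  p <- list(
    W_embS = init_mat(V + 2L, E),
    ef_W = init_mat(E, 3L * H), ef_U = init_mat(H, 3L * H), ef_b = matrix(0, 1, 3L * H),
    eb_W = init_mat(E, 3L * H), eb_U = init_mat(H, 3L * H), eb_b = matrix(0, 1, 3L * H),
    W_init = init_mat(2L * H, H), b_init = matrix(0, 1, H),
    Wa = init_mat(H, H), Ua = init_mat(2L * H, H), ba = matrix(0, 1, H),
    va = init_mat(H, 1L),
    EmbD = init_mat(V + 2L, E),
    d_W = init_mat(E + 2L * H, 3L * H), d_U = init_mat(H, 3L * H),
    d_b = matrix(0, 1, 3L * H),
    Wo = init_mat(3L * H, V + 1L), bo = matrix(0, 1, V + 1L)
  )
  if (cfg$context_mode == "features") {
    p$ctx_shape <- init_mat(11L, H)
    p$ctx_color <- init_mat(16L, H)
    p$ctx_form <- init_mat(2L, H)
  }
  p
}

add_rows <- function(mat, idx, rows) {
  contrib <- rowsum(rows, group = idx)
  ii <- as.integer(rownames(contrib))
  mat[ii, ] <- mat[ii, , drop = FALSE] + contrib
  mat
}

# Forward (and optionally backward) pass over one padded batch.
# batch: Xlist (length T of B x V+2), mask (B x T), Y_in/Y_out/ymask
# (B x Tt), ctx (B x 3 label indices or NULL).
seq2seq_batch <- function(params, batch, cfg, compute_grads = TRUE) {
  H <- cfg$hidden_size
  Tn <- length(batch$Xlist)
  Tt <- ncol(batch$Y_out)
  B <- nrow(batch$mask)
  eps <- 1e-12

  h0 <- matrix(0, B, H)
  if (!is.null(batch$ctx)) {
    h0 <- params$ctx_shape[batch$ctx[, 1], , drop = FALSE] +
      params$ctx_color[batch$ctx[, 2], , drop = FALSE] +
      params$ctx_form[batch$ctx[, 3], , drop = FALSE]
  }

  Elist <- lapply(batch$Xlist, function(X) X %*% params$W_embS)

  hf <- vector("list", Tn); cache_f <- vector("list", Tn)
  h <- h0
  for (t in seq_len(Tn)) {
    out <- gru_cell_forward(Elist[[t]], h, params$ef_W, params$ef_U, params$ef_b)
    m <- batch$mask[, t]
    h <- m * out$H + (1 - m) * h
    hf[[t]] <- h; cache_f[[t]] <- out$cache
  }
  hb <- vector("list", Tn); cache_b <- vector("list", Tn)
  g <- h0
  for (t in rev(seq_len(Tn))) {
    out <- gru_cell_forward(Elist[[t]], g, params$eb_W, params$eb_U, params$eb_b)
    m <- batch$mask[, t]
    g <- m * out$H + (1 - m) * g
    hb[[t]] <- g; cache_b[[t]] <- out$cache
  }
  Slist <- lapply(seq_len(Tn), function(t) cbind(hf[[t]], hb[[t]]))
  SUa <- lapply(Slist, function(S) S %*% params$Ua)
  h_fin <- hf[[Tn]]; g_fin <- hb[[1]]
  init_in <- cbind(h_fin, g_fin)
  d0 <- tanh(init_in %*% params$W_init +
               matrix(params$b_init, B, H, byrow = TRUE))

  Dprev <- d0
  dec <- vector("list", Tt)
  loss_sum <- 0
  ntok <- sum(batch$ymask)
  for (j in seq_len(Tt)) {
    q <- params$EmbD[batch$Y_in[, j], , drop = FALSE]
    at <- attn_forward(Dprev, Slist, SUa, batch$mask, params$Wa, params$ba,
                       params$va)
    xj <- cbind(q, at$C)
    gout <- gru_cell_forward(xj, Dprev, params$d_W, params$d_U, params$d_b)
    ym <- batch$ymask[, j]
    Dj <- ym * gout$H + (1 - ym) * Dprev
    oin <- cbind(Dj, at$C)
    P <- softmax_rows(oin %*% params$Wo +
                        matrix(params$bo, B, ncol(params$Wo), byrow = TRUE))
    pick <- cbind(seq_len(B), batch$Y_out[, j])
    loss_sum <- loss_sum + sum(-log(P[pick] + eps) * ym)
    dec[[j]] <- list(P = P, pick = pick, oin = oin, at = at, gcache = gout$cache,
                     Dprev = Dprev, ym = ym)
    Dprev <- Dj
  }
  loss <- loss_sum / max(ntok, 1)
  if (!compute_grads) return(list(loss = loss))

  gr <- new.env(parent = emptyenv())
  dD_next <- matrix(0, B, H)
  dS <- lapply(Slist, function(S) S * 0)
  dSUa <- lapply(Slist, function(S) matrix(0, B, H))
  for (j in rev(seq_len(Tt))) {
    st <- dec[[j]]
    dO <- st$P
    dO[st$pick] <- dO[st$pick] - 1
    dO <- dO * (st$ym / max(ntok, 1))
    acc_grad(gr, "Wo", t(st$oin) %*% dO)
    acc_grad(gr, "bo", matrix(colSums(dO), 1))
    doin <- dO %*% t(params$Wo)
    dDj <- doin[, seq_len(H), drop = FALSE] + dD_next
    dC <- doin[, H + seq_len(2L * H), drop = FALSE]
    dH_gru <- st$ym * dDj
    dD_carry <- (1 - st$ym) * dDj
    gb <- gru_cell_backward(dH_gru, st$gcache, params$d_W, params$d_U)
    acc_grad(gr, "d_W", gb$dW); acc_grad(gr, "d_U", gb$dU)
    acc_grad(gr, "d_b", gb$db)
    E <- cfg$embedding_size
    dq <- gb$dX[, seq_len(E), drop = FALSE]
    if (is.null(gr$EmbD)) gr$EmbD <- params$EmbD * 0
    gr$EmbD <- add_rows(gr$EmbD, batch$Y_in[, j], dq)
    dC <- dC + gb$dX[, E + seq_len(2L * H), drop = FALSE]
    ab <- attn_backward(dC, st$at$cache, Slist, params$Wa, params$va, gr)
    for (t in seq_len(Tn)) {
      dS[[t]] <- dS[[t]] + ab$dSdirect[[t]]
      dSUa[[t]] <- dSUa[[t]] + ab$dSUa[[t]]
    }
    dD_next <- gb$dHprev + dD_carry + ab$dDprev
  }
  dd0 <- dD_next
  dpre0 <- dd0 * (1 - d0^2)
  acc_grad(gr, "W_init", t(init_in) %*% dpre0)
  acc_grad(gr, "b_init", matrix(colSums(dpre0), 1))
  dinit <- dpre0 %*% t(params$W_init)
  dh_fin <- dinit[, seq_len(H), drop = FALSE]
  dg_fin <- dinit[, H + seq_len(H), drop = FALSE]

  for (t in seq_len(Tn)) {
    acc_grad(gr, "Ua", t(Slist[[t]]) %*% dSUa[[t]])
    dS[[t]] <- dS[[t]] + dSUa[[t]] %*% t(params$Ua)
  }
  dE <- lapply(Elist, function(e) e * 0)
  # forward-direction unroll
  dcarry <- dh_fin
  dh0_total <- matrix(0, B, H)
  for (t in rev(seq_len(Tn))) {
    dtot <- dS[[t]][, seq_len(H), drop = FALSE] + dcarry
    m <- batch$mask[, t]
    gb <- gru_cell_backward(m * dtot, cache_f[[t]], params$ef_W, params$ef_U)
    acc_grad(gr, "ef_W", gb$dW); acc_grad(gr, "ef_U", gb$dU)
    acc_grad(gr, "ef_b", gb$db)
    dE[[t]] <- dE[[t]] + gb$dX
    dcarry <- (1 - m) * dtot + gb$dHprev
  }
  dh0_total <- dh0_total + dcarry
  # backward-direction unroll
  dcarry <- dg_fin
  for (t in seq_len(Tn)) {
    dtot <- dS[[t]][, H + seq_len(H), drop = FALSE] + dcarry
    m <- batch$mask[, t]
    gb <- gru_cell_backward(m * dtot, cache_b[[t]], params$eb_W, params$eb_U)
    acc_grad(gr, "eb_W", gb$dW); acc_grad(gr, "eb_U", gb$dU)
    acc_grad(gr, "eb_b", gb$db)
    dE[[t]] <- dE[[t]] + gb$dX
    dcarry <- (1 - m) * dtot + gb$dHprev
  }
  dh0_total <- dh0_total + dcarry

  for (t in seq_len(Tn)) {
    acc_grad(gr, "W_embS", t(batch$Xlist[[t]]) %*% dE[[t]])
  }
  if (!is.null(batch$ctx)) {
    if (is.null(gr$ctx_shape)) {
      gr$ctx_shape <- params$ctx_shape * 0
      gr$ctx_color <- params$ctx_color * 0
      gr$ctx_form <- params$ctx_form * 0
    }
    gr$ctx_shape <- add_rows(gr$ctx_shape, batch$ctx[, 1], dh0_total)
    gr$ctx_color <- add_rows(gr$ctx_color, batch$ctx[, 2], dh0_total)
    gr$ctx_form <- add_rows(gr$ctx_form, batch$ctx[, 3], dh0_total)
  }
  grads <- as.list(gr)
  # parameters untouched by this batch get zero gradients
  for (nm in names(params)) {
    if (is.null(grads[[nm]])) grads[[nm]] <- params[[nm]] * 0
  }
  list(loss = loss, grads = grads[names(params)])
}

# Reading order: face (left half first), then text row, then x. Rows are
# recovered by clustering y within a face (rows sit ~0.19 image heights
# apart; coordinate jitter is an order of magnitude smaller), so jitter
# cannot scramble the within-row order the way sorting on raw y would.
sort_detections <- function(detections) {
  n <- nrow(detections)
  if (n <= 1L) return(detections)
  face <- detections$x >= 0.5
  row_id <- integer(n)
  for (f in unique(face)) {
    idx <- which(face == f)
    ys <- sort(detections$y[idx])
    breaks <- c(0, ys[c(diff(ys) > 0.09, FALSE)] + 1e-9, 1 + 1e-9)
    breaks <- unique(breaks)
    row_id[idx] <- findInterval(detections$y[idx], breaks)
  }
  detections[order(face, row_id, detections$x), , drop = FALSE]
}

prepare_pair <- function(source, target, cfg) {
  toks <- tokenize_imprint(target)
  bad <- setdiff(toks, pill_vocabulary())
  if (length(bad) > 0) {
    stop("target '", target, "' contains out-of-vocabulary symbol(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (length(toks) + 1L > cfg$max_target_len) {
    stop("target '", target, "' exceeds max_target_len ", cfg$max_target_len,
         call. = FALSE)
  }
  # sorting by (face, y, x) is itself a use of the coordinates, so the
  # coordinate-ablated model sees the detections in their given order
  src <- if (cfg$use_coords) sort_detections(source) else source
  X <- encode_sequence(src)
  if (!cfg$use_coords) X[, ncol(X) - 1:0] <- 0
  tgt <- c(match(toks, pill_vocabulary()), corrector_eos())
  list(X = X, tgt = tgt)
}

ctx_indices <- function(feature_context) {
  lv <- feature_levels()
  cbind(match(feature_context$shape, lv$shape),
        match(feature_context$color, lv$color),
        match(feature_context$form, lv$form))
}

#' Train the imprint corrector
#'
#' Fits the coordinate-encoded attention seq2seq model on (noisy detections,
#' canonical imprint) pairs by teacher forcing with Adam. Sources are sorted
#' by (face, y, x) before encoding — a convention only; robustness to the
#' true order being scrambled comes from training on shuffled corruptions.
#' Deterministic given the config seed.
#'
#' @param pairs List of training pairs, each a list with `source` (tibble
#'   `char`, `x`, `y`) and `target` (the canonical imprint string).
#' @param feature_context Optional tibble with `shape`, `color`, `form` per
#'   pair; required when `context_mode = "features"`.
#' @param config A [corrector_config()].
#' @return A `corrector_model` with fitted parameters and per-epoch mean
#'   token negative log-likelihood in `loss_history`.
#' @export
train_corrector <- function(pairs, feature_context = NULL,
                            config = corrector_config()) {
  stopifnot(inherits(config, "corrector_config"))
  if (length(pairs) < 1L) stop("no training pairs", call. = FALSE)
  if (config$context_mode == "features") {
    if (is.null(feature_context) || nrow(feature_context) != length(pairs)) {
      stop("context_mode='features' requires feature_context for every pair",
           call. = FALSE)
    }
  }
  prep <- lapply(pairs, function(p) prepare_pair(p$source, p$target, config))
  ctx_all <- if (config$context_mode == "features") ctx_indices(feature_context)
  n <- length(prep)

  withr::with_seed(config$seed, {
    params <- corrector_init_params(config)
    opt <- adam_init(params)
    loss_history <- numeric(config$epochs)
    for (epoch in seq_len(config$epochs)) {
      ord <- sample.int(n)
      losses <- c(); weights <- c()
      for (start in seq(1L, n, by = config$batch_size)) {
        idx <- ord[start:min(start + config$batch_size - 1L, n)]
        batch <- make_batch(prep[idx],
                            if (!is.null(ctx_all)) ctx_all[idx, , drop = FALSE])
        out <- seq2seq_batch(params, batch, config, compute_grads = TRUE)
        if (!is.finite(out$loss)) {
          stop("non-finite corrector loss at epoch ", epoch, call. = FALSE)
        }
        step <- adam_step(params, out$grads, opt, config$learning_rate)
        params <- step$params; opt <- step$state
        losses <- c(losses, out$loss)
        weights <- c(weights, sum(batch$ymask))
      }
      loss_history[epoch] <- sum(losses * weights) / sum(weights)
    }
    structure(list(params = params, config = config,
                   loss_history = loss_history),
              class = "corrector_model")
  })
}

make_batch <- function(prep, ctx = NULL) {
  B <- length(prep)
  Ts <- max(1L, max(vapply(prep, function(p) nrow(p$X), integer(1))))
  Tt <- max(vapply(prep, function(p) length(p$tgt), integer(1)))
  V2 <- length(pill_vocabulary()) + 2L
  Xlist <- lapply(seq_len(Ts), function(t) matrix(0, B, V2))
  mask <- matrix(0, B, Ts)
  Y_in <- matrix(corrector_eos(), B, Tt)
  Y_out <- matrix(corrector_eos(), B, Tt)
  ymask <- matrix(0, B, Tt)
  for (i in seq_len(B)) {
    ni <- nrow(prep[[i]]$X)
    if (ni > 0) {
      for (t in seq_len(ni)) Xlist[[t]][i, ] <- prep[[i]]$X[t, ]
      mask[i, seq_len(ni)] <- 1
    }
    tg <- prep[[i]]$tgt
    Y_in[i, 1L] <- corrector_sos()
    if (length(tg) > 1L) Y_in[i, 2:length(tg)] <- tg[seq_len(length(tg) - 1L)]
    Y_out[i, seq_along(tg)] <- tg
    ymask[i, seq_along(tg)] <- 1
  }
  list(Xlist = Xlist, mask = mask, Y_in = Y_in, Y_out = Y_out, ymask = ymask,
       ctx = ctx)
}

#' Correct a noisy detection set into a canonical imprint
#'
#' Greedy decoding (argmax at each step) until end-of-sequence or the
#' configured maximum length. The output is post-filtered to contain at most
#' one `"_"` (the first is kept). Empty detection sets decode to the empty
#' imprint without error.
#'
#' @param model A `corrector_model`.
#' @param detections Tibble with `char`, `x`, `y`.
#' @param features Optional feature context: a `feature_prediction` or a
#'   list/one-row data frame with `shape`, `color`, `form`. Required when the
#'   model was trained with `context_mode = "features"`.
#' @return The corrected imprint string.
#' @export
correct_imprint <- function(model, detections, features = NULL) {
  stopifnot(inherits(model, "corrector_model"))
  cfg <- model$config
  if (nrow(detections) == 0L) return("")
  src <- if (cfg$use_coords) sort_detections(detections) else detections
  X <- encode_sequence(src)
  if (!cfg$use_coords) X[, ncol(X) - 1:0] <- 0
  ctx <- NULL
  if (cfg$context_mode == "features") {
    if (is.null(features)) {
      stop("this corrector was trained with feature context; supply `features`",
           call. = FALSE)
    }
    f <- if (inherits(features, "feature_prediction")) {
      list(shape = features$shape_label, color = features$color_label,
           form = features$form_label)
    } else as.list(features)
    ctx <- ctx_indices(tibble::tibble(shape = f$shape, color = f$color,
                                      form = f$form))
  }
  toks <- greedy_decode(model$params, X, ctx, cfg)
  # keep only the first underscore
  us <- which(toks == "_")
  if (length(us) > 1L) toks <- toks[-us[-1L]]
  detokenize_imprint(toks)
}

greedy_decode <- function(params, X, ctx, cfg) {
  H <- cfg$hidden_size
  Tn <- nrow(X)
  h0 <- matrix(0, 1, H)
  if (!is.null(ctx)) {
    h0 <- params$ctx_shape[ctx[1, 1], , drop = FALSE] +
      params$ctx_color[ctx[1, 2], , drop = FALSE] +
      params$ctx_form[ctx[1, 3], , drop = FALSE]
  }
  Elist <- lapply(seq_len(Tn), function(t)
    matrix(X[t, ], 1) %*% params$W_embS)
  h <- h0
  hf <- vector("list", Tn)
  for (t in seq_len(Tn)) {
    h <- gru_cell_forward(Elist[[t]], h, params$ef_W, params$ef_U, params$ef_b)$H
    hf[[t]] <- h
  }
  g <- h0
  hb <- vector("list", Tn)
  for (t in rev(seq_len(Tn))) {
    g <- gru_cell_forward(Elist[[t]], g, params$eb_W, params$eb_U, params$eb_b)$H
    hb[[t]] <- g
  }
  Slist <- lapply(seq_len(Tn), function(t) cbind(hf[[t]], hb[[t]]))
  SUa <- lapply(Slist, function(S) S %*% params$Ua)
  mask <- matrix(1, 1, Tn)
  d <- tanh(cbind(hf[[Tn]], hb[[1]]) %*% params$W_init + params$b_init)
  vocab <- pill_vocabulary()
  prev <- corrector_sos()
  out <- character(0)
  for (j in seq_len(cfg$max_target_len)) {
    q <- params$EmbD[prev, , drop = FALSE]
    at <- attn_forward(d, Slist, SUa, mask, params$Wa, params$ba, params$va)
    gout <- gru_cell_forward(cbind(q, at$C), d, params$d_W, params$d_U,
                             params$d_b)
    d <- gout$H
    logits <- cbind(d, at$C) %*% params$Wo + params$bo
    nxt <- which.max(logits)
    if (nxt == corrector_eos()) break
    out <- c(out, vocab[nxt])
    prev <- nxt
  }
  out
}

#' @export
print.corrector_model <- function(x, ...) {
  cat("<corrector_model> E=", x$config$embedding_size, ", H=",
      x$config$hidden_size, ", context=", x$config$context_mode,
      ", final token NLL ", signif(utils::tail(x$loss_history, 1), 4),
      " after ", length(x$loss_history), " epochs\n", sep = "")
  invisible(x)
}
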