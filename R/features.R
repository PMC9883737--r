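# Multitask feature classifier: a shared backbone maps the pill image to a
# feature vector p, and three softmax heads z_s = softmax(w_s p),
# z_c = softmax(w_c p), z_f = softmax(w_f p) classify shape (11), colour (16)
# and form (2). The total loss is the weighted sum of the three per-head
# cross-entropies, with all weights 1 by default.

#' Feature-model configuration
#'
#' @param hidden_dim Backbone output width `h` (>= 8; default 128).
#' @param loss_weights Three positive per-head loss weights (default 1,1,1).
#' @param learning_rate SGD learning rate (default 0.1).
#' @param weight_decay L2 penalty (default 1e-4).
#' @param batch_size Minibatch size (default 10).
#' @param epochs Training epochs.
#' @param input_size Height/width the image is downsampled to before the
#'   backbone.
#' @param seed Integer seed.
#' @return A `feature_config` list.
#' @export
feature_config <- function(hidden_dim = 128L, loss_weights = c(1, 1, 1),
                           learning_rate = 0.1, weight_decay = 1e-4,
                           batch_size = 10L, epochs = 40L,
                           input_size = c(12L, 24L), seed = 1L) {
  stopifnot(hidden_dim >= 8, length(loss_weights) == 3, all(loss_weights > 0),
            learning_rate > 0, weight_decay >= 0)
  structure(list(hidden_dim = as.integer(hidden_dim),
                 loss_weights = as.numeric(loss_weights),
                 learning_rate = learning_rate, weight_decay = weight_decay,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 input_size = as.integer(input_size),
                 seed = as.integer(seed)),
            class = "feature_config")
}

feature_levels <- function() {
  list(shape = pill_shapes(), color = pill_colors(), form = pill_forms())
}

feature_input_vector <- function(image, input_size) {
  small <- resize_image(image, input_size[1], input_size[2])
  # fourth plane: downsampled foreground mask, a clean silhouette signal for
  # the shape head
  mask <- resize_image(array(foreground_mask(image) * 1,
                             dim = c(dim(image)[1:2], 1L)),
                       input_size[1], input_size[2])
  c(as.vector(small) - 0.5, as.vector(mask) - 0.5)
}

feature_backbone <- function(params, X) {
  H1 <- relu_(X %*% params$W0 + matrix(params$b0, nrow(X), ncol(params$W0),
                                       byrow = TRUE))
  # one residual block: p = relu(H1 W1 + b1) + H1
  A <- relu_(H1 %*% params$W1 + matrix(params$b1, nrow(X), ncol(params$W1),
                                       byrow = TRUE))
  P <- A + H1
  list(H1 = H1, A = A, P = P)
}

feature_heads <- function(params, P) {
  list(
    shape = softmax_rows(P %*% params$Ws + matrix(params$bs, nrow(P), ncol(params$Ws), byrow = TRUE)),
    color = softmax_rows(P %*% params$Wc + matrix(params$bc, nrow(P), ncol(params$Wc), byrow = TRUE)),
    form  = softmax_rows(P %*% params$Wf + matrix(params$bf, nrow(P), ncol(params$Wf), byrow = TRUE))
  )
}

#' Weighted multitask classification loss
#'
#' The total loss of the feature recognizer: the per-head cross-entropies of
#' the shape, colour and form probability vectors against the true labels,
#' weighted and summed (`w_s * CE_s + w_c * CE_c + w_f * CE_f`). It is zero
#' only in the limit of probability-1 correct predictions.
#'
#' @param prediction A `feature_prediction` (see [predict_features()]) or a
#'   list with `shape_probs`, `color_probs`, `form_probs`.
#' @param truth Labels: a list/one-row data frame with `shape`, `color`,
#'   `form` (names from the inventories) or integer indices.
#' @param weights Three positive head weights.
#' @return Non-negative scalar loss.
#' @export
#' @examples
#' p <- list(shape_probs = rep(1/11, 11), color_probs = rep(1/16, 16),
#'           form_probs = rep(1/2, 2))
#' multitask_loss(p, list(shape = "round", color = "white", form = "tablet"))
multitask_loss <- function(prediction, truth, weights = c(1, 1, 1)) {
  stopifnot(length(weights) == 3, all(weights > 0))
  lv <- feature_levels()
  probs <- list(shape = prediction$shape_probs, color = prediction$color_probs,
                form = prediction$form_probs)
  truth <- as.list(truth)
  total <- 0
  for (i in seq_along(probs)) {
    feat <- names(probs)[i]
    p <- probs[[feat]]
    lab <- truth[[feat]]
    idx <- if (is.numeric(lab)) as.integer(lab) else match(lab, lv[[feat]])
    if (is.na(idx) || idx < 1L || idx > length(p)) {
      stop("label '", lab, "' out of range for feature '", feat, "'",
           call. = FALSE)
    }
    total <- total + weights[i] * (-log(p[idx]))
  }
  unname(total)
}

#' Train the multitask feature classifier
#'
#' Fits the shared backbone and the three softmax heads by minibatch SGD
#' with weight decay on the summed cross-entropy loss. With
#' `oversample = TRUE`, records are drawn with probability proportional to
#' the product of the inverse frequencies of their three labels, equalizing
#' each class's expected sampling frequency (rare colours/shapes/forms are
#' seen correspondingly more often per epoch). Deterministic given the
#' config seed.
#'
#' @param images List of `h x w x 3` arrays.
#' @param labels Tibble/data frame with columns `shape`, `color`, `form`,
#'   parallel to `images`.
#' @param config A [feature_config()].
#' @param oversample Equalize class sampling frequencies by inverse-frequency
#'   weighting.
#' @return A `feature_model`.
#' @export
train_features <- function(images, labels, config = feature_config(),
                           oversample = FALSE) {
  stopifnot(inherits(config, "feature_config"))
  if (length(images) < 1L) stop("empty training set", call. = FALSE)
  labels <- as.data.frame(labels)
  stopifnot(nrow(labels) == length(images))
  lv <- feature_levels()
  for (feat in names(lv)) {
    bad <- setdiff(unique(labels[[feat]]), lv[[feat]])
    if (length(bad) > 0) stop("unknown ", feat, " label(s): ",
                              paste(bad, collapse = ", "), call. = FALSE)
    missing_cls <- setdiff(lv[[feat]], unique(labels[[feat]]))
    if (length(missing_cls) > 0L) {
      warning("head '", feat, "' has unobserved classes: ",
              paste(missing_cls, collapse = ", "),
              "; it is trained on the remaining classes", call. = FALSE)
    }
  }

  X <- do.call(rbind, lapply(images, feature_input_vector,
                             input_size = config$input_size))
  ys <- match(labels$shape, lv$shape)
  yc <- match(labels$color, lv$color)
  yf <- match(labels$form, lv$form)
  n <- nrow(X)
  h <- config$hidden_dim

  sample_weights <- NULL
  if (oversample) {
    wts <- (1 / table(labels$shape)[labels$shape]) *
      (1 / table(labels$color)[labels$color]) *
      (1 / table(labels$form)[labels$form])
    sample_weights <- as.numeric(wts / sum(wts))
  }

  withr::with_seed(config$seed, {
    params <- list(
      W0 = init_mat(ncol(X), h), b0 = matrix(0, 1, h),
      W1 = init_mat(h, h) * 0.5, b1 = matrix(0, 1, h),
      Ws = init_mat(h, 11L), bs = matrix(0, 1, 11L),
      Wc = init_mat(h, 16L), bc = matrix(0, 1, 16L),
      Wf = init_mat(h, 2L),  bf = matrix(0, 1, 2L)
    )
    loss_history <- numeric(config$epochs)
    oversample_counts <- integer(n)
    for (epoch in seq_len(config$epochs)) {
      ord <- if (oversample) {
        sample.int(n, n, replace = TRUE, prob = sample_weights)
      } else {
        sample.int(n)
      }
      if (epoch == 1L) oversample_counts <- tabulate(ord, nbins = n)
      batch_losses <- c()
      for (start in seq(1L, n, by = config$batch_size)) {
        idx <- ord[start:min(start + config$batch_size - 1L, n)]
        out <- feature_batch_grad(params, X[idx, , drop = FALSE],
                                  ys[idx], yc[idx], yf[idx],
                                  config$loss_weights)
        if (!is.finite(out$loss)) {
          stop("non-finite feature loss at epoch ", epoch, call. = FALSE)
        }
        params <- sgd_step(params, out$grads, config$learning_rate,
                           weight_decay = config$weight_decay)
        batch_losses <- c(batch_losses, out$loss)
      }
      loss_history[epoch] <- mean(batch_losses)
    }
    structure(list(params = params, config = config, levels = lv,
                   loss_history = loss_history,
                   first_epoch_draws = oversample_counts),
              class = "feature_model")
  })
}

feature_batch_grad <- function(params, X, ys, yc, yf, wts) {
  B <- nrow(X)
  bb <- feature_backbone(params, X)
  heads <- feature_heads(params, bb$P)
  eps <- 1e-12
  pick_s <- cbind(seq_len(B), ys)
  pick_c <- cbind(seq_len(B), yc)
  pick_f <- cbind(seq_len(B), yf)
  loss <- wts[1] * -mean(log(heads$shape[pick_s] + eps)) +
          wts[2] * -mean(log(heads$color[pick_c] + eps)) +
          wts[3] * -mean(log(heads$form[pick_f] + eps))

  dZs <- heads$shape; dZs[pick_s] <- dZs[pick_s] - 1; dZs <- wts[1] * dZs / B
  dZc <- heads$color; dZc[pick_c] <- dZc[pick_c] - 1; dZc <- wts[2] * dZc / B
  dZf <- heads$form;  dZf[pick_f] <- dZf[pick_f] - 1; dZf <- wts[3] * dZf / B

  grads <- list(
    Ws = t(bb$P) %*% dZs, bs = matrix(colSums(dZs), 1),
    Wc = t(bb$P) %*% dZc, bc = matrix(colSums(dZc), 1),
    Wf = t(bb$P) %*% dZf, bf = matrix(colSums(dZf), 1)
  )
  dP <- dZs %*% t(params$Ws) + dZc %*% t(params$Wc) + dZf %*% t(params$Wf)
  dA <- dP
  dA[bb$A <= 0] <- 0
  grads$W1 <- t(bb$H1) %*% dA
  grads$b1 <- matrix(colSums(dA), 1)
  dH1 <- dP + dA %*% t(params$W1)   # residual skip + through the block
  dH1[bb$H1 <= 0] <- 0
  grads$W0 <- t(X) %*% dH1
  grads$b0 <- matrix(colSums(dH1), 1)
  list(loss = loss, grads = grads)
}

#' Predict pill features from an image
#'
#' @param model A `feature_model`.
#' @param image An `h x w x 3` array; images whose size differs from the
#'   training geometry are resized (with a message).
#' @return A `feature_prediction`: list with `shape_probs`, `color_probs`,
#'   `form_probs` (named probability vectors summing to 1) and the argmax
#'   labels `shape_label`, `color_label`, `form_label`.
#' @export
predict_features <- function(model, image) {
  stopifnot(inherits(model, "feature_model"))
  x <- matrix(feature_input_vector(image, model$config$input_size), 1)
  bb <- feature_backbone(model$params, x)
  heads <- feature_heads(model$params, bb$P)
  sp <- stats::setNames(as.numeric(heads$shape), model$levels$shape)
  cp <- stats::setNames(as.numeric(heads$color), model$levels$color)
  fp <- stats::setNames(as.numeric(heads$form), model$levels$form)
  structure(
    list(shape_probs = sp, color_probs = cp, form_probs = fp,
         shape_label = names(sp)[which.max(sp)],
         color_label = names(cp)[which.max(cp)],
         form_label = names(fp)[which.max(fp)]),
    class = "feature_prediction"
  )
}

#' @export
print.feature_prediction <- function(x, ...) {
  cat("<feature_prediction> shape=", x$shape_label,
      " (", signif(max(x$shape_probs), 3), "), color=", x$color_label,
      " (", signif(max(x$color_probs), 3), "), form=", x$form_label,
      " (", signif(max(x$form_probs), 3), ")\n", sep = "")
  invisible(x)
}

#' @export
print.feature_model <- function(x, ...) {
  cat("<feature_model> h=", x$config$hidden_dim, ", final training loss ",
      signif(utils::tail(x$loss_history, 1), 4), " after ",
      length(x$loss_history), " epochs\n", sep = "")
  invisible(x)
}
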