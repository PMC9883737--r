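# Single-shot grid character detector. The image is tiled into square grid
# cells; one shared two-layer network (a stride-`cell` convolution with
# kernel `2*cell` followed by a dense head) predicts per cell an objectness
# score, a class distribution over the printable vocabulary, and the box
# (centre offsets within the cell, width and height). This is the same
# predict-everything-in-one-pass family as YOLO, scaled to synthetic desk
# data; the interface is pluggable so a full-scale detector can be swapped in.

detector_vocab <- function() setdiff(pill_vocabulary(), "_")

#' Detector configuration
#'
#' @param grid_size Grid cells along the image height (>= 4); the cell size
#'   is `image_height / grid_size` and must divide it exactly.
#' @param conf_threshold Default objectness threshold for
#'   [detect_characters()].
#' @param learning_rate SGD learning rate (default 1e-2).
#' @param warmup_epochs Linear learning-rate warm-up epochs (default 3).
#' @param batch_size Minibatch size (default 16).
#' @param epochs Training epochs.
#' @param hidden Hidden width of the shared cell network.
#' @param negatives_per_positive Background cells sampled per annotated
#'   character when building the training set.
#' @param aug_per_positive Extra shifted-window copies of each positive cell
#'   added at train time, covering the sub-cell phases of the glyphs.
#' @param seed Integer seed.
#' @return A `detector_config` list.
#' @export
detector_config <- function(grid_size = 12L, conf_threshold = 0.5,
                            learning_rate = 1e-2, warmup_epochs = 3L,
                            batch_size = 16L, epochs = 30L, hidden = 64L,
                            negatives_per_positive = 3L,
                            aug_per_positive = 3L, seed = 1L) {
  stopifnot(grid_size >= 4, conf_threshold >= 0, learning_rate > 0)
  structure(list(grid_size = as.integer(grid_size),
                 conf_threshold = conf_threshold,
                 learning_rate = learning_rate,
                 warmup_epochs = as.integer(warmup_epochs),
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 hidden = as.integer(hidden),
                 negatives_per_positive = as.integer(negatives_per_positive),
                 aug_per_positive = as.integer(aug_per_positive),
                 seed = as.integer(seed)),
            class = "detector_config")
}

# Local-contrast grayscale patches (side 2*cell) centred on grid cells.
# Local contrast (patch minus its median) makes the glyph signal invariant
# to the pill colour under it.
gray_padded <- function(image, cell) {
  h <- dim(image)[1]; w <- dim(image)[2]
  gray <- (image[, , 1] + image[, , 2] + image[, , 3]) / 3
  padded <- matrix(.render_bg, h + 2 * cell, w + 2 * cell)
  padded[cell + seq_len(h), cell + seq_len(w)] <- gray
  padded
}

# Patch for cell (r, c), optionally with a window shift (dy, dx) in pixels
# (used for train-time augmentation of the sub-cell phase).
patch_vec <- function(gp, cell, r, c, dy = 0L, dx = 0L) {
  half <- cell %/% 2
  rows <- (r - 1L) * cell + half + dy + seq_len(2L * cell)
  cols <- (c - 1L) * cell + half + dx + seq_len(2L * cell)
  patch <- gp[rows, cols]
  as.vector(patch - stats::median(patch))
}

# Window of side 2*cell centred on an arbitrary pixel position (original
# image coordinates; gp is padded by `cell` on every side).
patch_at_px <- function(gp, cell, py, px) {
  rows <- round(py) + seq_len(2L * cell)   # original py-cell+1 .. py+cell
  cols <- round(px) + seq_len(2L * cell)
  patch <- gp[rows, cols]
  as.vector(patch - stats::median(patch))
}

# Snap a regressed centre onto the local ink centroid: glyphs are
# high-contrast, so the centroid of the strong-contrast pixels in a
# glyph-sized window recovers the true centre to about a pixel even when the
# box regression lands a cell-boundary case a few pixels off.
refine_center <- function(gp, cell, py, px, hw = 6L, hh = 8L) {
  # triangular weights fade out ink from neighbouring glyphs at the window
  # edge; iterating walks the centre onto the glyph it belongs to
  for (iter in 1:3) {
    rows <- round(py) + cell + (-hh:hh)
    cols <- round(px) + cell + (-hw:hw)
    rows <- rows[rows >= 1 & rows <= nrow(gp)]
    cols <- cols[cols >= 1 & cols <= ncol(gp)]
    patch <- gp[rows, cols, drop = FALSE]
    ctr <- abs(patch - stats::median(patch))
    ctr[ctr < 0.15] <- 0
    if (max(ctr) <= 0) break
    wr <- pmax(0, 1 - abs(rows - cell - py) / (hh + 1))
    wc <- pmax(0, 1 - abs(cols - cell - px) / (hw + 1))
    wt <- ctr * outer(wr, wc)
    if (sum(wt) <= 0) break
    py <- sum(wt * (rows - cell)) / sum(wt)
    px <- sum(wt * t(matrix(cols - cell, length(cols), length(rows)))) / sum(wt)
  }
  c(py, px)
}

cell_patch_matrix <- function(image, cell) {
  h <- dim(image)[1]; w <- dim(image)[2]
  gr <- h %/% cell; gc <- w %/% cell
  gp <- gray_padded(image, cell)
  out <- matrix(0, gr * gc, 4L * cell * cell)
  k <- 1L
  for (r in seq_len(gr)) {
    for (c in seq_len(gc)) {
      out[k, ] <- patch_vec(gp, cell, r, c)
      k <- k + 1L
    }
  }
  out
}

cell_index_grid <- function(h, w, cell) {
  gr <- h %/% cell; gc <- w %/% cell
  list(gr = gr, gc = gc,
       row = rep(seq_len(gr), each = gc),
       col = rep(seq_len(gc), times = gr))
}

detector_forward <- function(params, X) {
  H <- relu_(X %*% params$W1 + matrix(params$b1, nrow(X), length(params$b1),
                                      byrow = TRUE))
  Z <- H %*% params$W2 + matrix(params$b2, nrow(X), length(params$b2),
                                byrow = TRUE)
  list(H = H, Z = Z)
}

#' Train the grid character detector
#'
#' Builds a cell-level training set from annotated images (every cell
#' containing a character centre is a positive with its class and box
#' targets; neighbouring and randomly sampled cells are negatives) and
#' trains the shared cell network by minibatch SGD with a linear
#' learning-rate warm-up. The loss is binary cross-entropy on objectness over
#' all cells plus, over positive cells, class cross-entropy and a box
#' regression penalty. Deterministic given the config seed.
#'
#' @param images List of `h x w x 3` arrays (orientation-normalized renders).
#' @param annotations List of ground-truth box tibbles as returned in
#'   `render_pill()$boxes`, parallel to `images`.
#' @param config A [detector_config()].
#' @return A `detector_model` with the fitted parameters and per-epoch loss
#'   history.
#' @export
train_detector <- function(images, annotations, config = detector_config()) {
  stopifnot(inherits(config, "detector_config"))
  if (length(images) < 1L) stop("empty training set", call. = FALSE)
  stopifnot(length(images) == length(annotations))
  h <- dim(images[[1]])[1]; w <- dim(images[[1]])[2]
  if (h %% config$grid_size != 0L) {
    stop("grid_size must divide the image height", call. = FALSE)
  }
  cell <- h %/% config$grid_size
  vocab <- detector_vocab()
  nv <- length(vocab)

  withr::with_seed(config$seed, {
    rows_X <- list(); rows_lab <- list()
    aug_X <- list(); aug_lab <- list()
    grid <- cell_index_grid(h, w, cell)
    for (i in seq_along(images)) {
      X <- cell_patch_matrix(images[[i]], cell)
      ann <- annotations[[i]]
      pos_cells <- integer(0)
      lab <- NULL
      if (nrow(ann) > 0) {
        cx <- ann$x_center * w; cy <- ann$y_center * h
        cr <- pmin(pmax(ceiling(cy / cell), 1L), grid$gr)
        cc <- pmin(pmax(ceiling(cx / cell), 1L), grid$gc)
        idx <- (cr - 1L) * grid$gc + cc
        cls <- match(ann$char, vocab)
        if (anyNA(cls)) stop("annotation contains a symbol outside the vocabulary",
                             call. = FALSE)
        lab <- data.frame(
          cell = idx, obj = 1, cls = cls,
          dx = cx / cell - (cc - 1L), dy = cy / cell - (cr - 1L),
          bw = ann$width * w / h, bh = ann$height
        )
        # last annotation wins if two characters ever share a cell
        lab <- lab[!duplicated(lab$cell, fromLast = TRUE), , drop = FALSE]
        pos_cells <- lab$cell
        # hard negatives: the 8-neighbourhood of every positive cell
        nb <- c(outer(c(-1L, 0L, 1L), c(-grid$gc, 0L, grid$gc), `+`))
        hard <- setdiff(unique(c(outer(pos_cells, nb, `+`))), pos_cells)
        hard <- hard[hard >= 1L & hard <= nrow(X)]
      } else {
        hard <- integer(0)
      }
      n_rand <- max(4L, config$negatives_per_positive * length(pos_cells))
      rand_neg <- sample(setdiff(seq_len(nrow(X)), c(pos_cells, hard)),
                         min(n_rand, nrow(X) - length(pos_cells) - length(hard)))
      neg <- c(hard, rand_neg)
      keep <- c(pos_cells, neg)
      nlab <- data.frame(cell = neg, obj = 0, cls = NA_integer_,
                         dx = 0, dy = 0, bw = 0, bh = 0)
      rows_X[[i]] <- X[keep, , drop = FALSE]
      rows_lab[[i]] <- rbind(lab, nlab)
      # phase augmentation: re-extract positive patches with shifted windows
      if (!is.null(lab) && nrow(lab) > 0 && config$aug_per_positive > 0) {
        gp <- gray_padded(images[[i]], cell)
        na <- nrow(lab) * config$aug_per_positive
        Xa <- matrix(0, na, ncol(X))
        la <- lab[rep(seq_len(nrow(lab)), each = config$aug_per_positive), ,
                  drop = FALSE]
        sh_max <- max(1L, cell %/% 2 - 1L)
        sdy <- sample(-sh_max:sh_max, na, replace = TRUE)
        sdx <- sample(-sh_max:sh_max, na, replace = TRUE)
        for (a in seq_len(na)) {
          ci <- la$cell[a]
          rr <- (ci - 1L) %/% grid$gc + 1L
          cc2 <- (ci - 1L) %% grid$gc + 1L
          Xa[a, ] <- patch_vec(gp, cell, rr, cc2, sdy[a], sdx[a])
        }
        la$dx <- pmin(pmax(la$dx - sdx / cell, 0), 1)
        la$dy <- pmin(pmax(la$dy - sdy / cell, 0), 1)
        aug_X[[length(aug_X) + 1L]] <- Xa
        aug_lab[[length(aug_lab) + 1L]] <- la
      }
    }
    X <- do.call(rbind, c(rows_X, aug_X))
    lab <- do.call(rbind, c(rows_lab, aug_lab))
    n <- nrow(X)
    din <- ncol(X)
    nout <- 1L + nv + 4L

    params <- list(
      W1 = init_mat(din, config$hidden),
      b1 = matrix(0, 1, config$hidden),
      W2 = init_mat(config$hidden, nout),
      b2 = matrix(0, 1, nout)
    )
    # second stage: a classifier on glyph-centred patches, used at inference
    # to re-classify each surviving detection from a window centred on its
    # regressed box centre (centred glyphs are far easier to separate than
    # arbitrary sub-cell phases)
    ctr_X <- list(); ctr_y <- list()
    for (i in seq_along(images)) {
      ann <- annotations[[i]]
      if (nrow(ann) == 0) next
      gp <- gray_padded(images[[i]], cell)
      cx <- ann$x_center * w; cy <- ann$y_center * h
      cls <- match(ann$char, vocab)
      reps <- 1L + 2L * config$aug_per_positive
      Xa <- matrix(0, nrow(ann) * reps, din)
      ya <- integer(nrow(ann) * reps)
      a <- 1L
      for (j in seq_len(nrow(ann))) {
        # anchor at the ink centroid, exactly as detection-time patches are
        rc <- refine_center(gp, cell, cy[j], cx[j])
        for (rset in seq_len(reps)) {
          jit <- if (rset == 1L) c(0L, 0L) else sample(-2:2, 2L, replace = TRUE)
          Xa[a, ] <- patch_at_px(gp, cell, rc[1] + jit[1], rc[2] + jit[2])
          ya[a] <- cls[j]
          a <- a + 1L
        }
      }
      ctr_X[[length(ctr_X) + 1L]] <- Xa
      ctr_y[[length(ctr_y) + 1L]] <- ya
    }
    Xc <- do.call(rbind, ctr_X)
    yc <- unlist(ctr_y)
    # flatten bias storage as 1 x k matrices for the optimizers
    loss_history <- numeric(config$epochs)
    for (epoch in seq_len(config$epochs)) {
      lr <- config$learning_rate *
        if (epoch <= config$warmup_epochs) epoch / config$warmup_epochs else 1
      ord <- sample.int(n)
      batch_losses <- c()
      for (start in seq(1L, n, by = config$batch_size)) {
        idx <- ord[start:min(start + config$batch_size - 1L, n)]
        out <- detector_batch_grad(params, X[idx, , drop = FALSE],
                                   lab[idx, , drop = FALSE], nv)
        if (!is.finite(out$loss)) {
          stop("non-finite detector loss at epoch ", epoch, call. = FALSE)
        }
        params <- sgd_step(params, out$grads, lr)
        batch_losses <- c(batch_losses, out$loss)
      }
      loss_history[epoch] <- mean(batch_losses)
    }

    cls_hidden <- 2L * config$hidden
    cls_params <- list(
      V1 = init_mat(din, cls_hidden), c1 = matrix(0, 1, cls_hidden),
      V2 = init_mat(cls_hidden, nv), c2 = matrix(0, 1, nv)
    )
    nc <- nrow(Xc)
    for (epoch in seq_len(2L * config$epochs)) {
      ord <- sample.int(nc)
      for (start in seq(1L, nc, by = 32L)) {
        idx <- ord[start:min(start + 31L, nc)]
        out <- classifier_batch_grad(cls_params, Xc[idx, , drop = FALSE],
                                     yc[idx])
        cls_params <- sgd_step(cls_params, out$grads, config$learning_rate)
      }
    }

    structure(list(params = params, cls_params = cls_params, config = config,
                   cell = cell, image_dim = c(h, w), vocab = vocab,
                   loss_history = loss_history),
              class = "detector_model")
  })
}

detector_batch_grad <- function(params, X, lab, nv) {
  B <- nrow(X)
  fw <- detector_forward(params, X)
  Z <- fw$Z; H <- fw$H
  obj_logit <- Z[, 1]
  p_obj <- sigmoid_(obj_logit)
  eps <- 1e-12
  loss_obj <- -mean(lab$obj * log(p_obj + eps) + (1 - lab$obj) * log(1 - p_obj + eps))
  dZ <- matrix(0, B, ncol(Z))
  dZ[, 1] <- (p_obj - lab$obj) / B

  pos <- which(lab$obj == 1)
  loss_cls <- 0; loss_box <- 0
  if (length(pos) > 0) {
    cls_logits <- Z[pos, 1L + seq_len(nv), drop = FALSE]
    P <- softmax_rows(cls_logits)
    pick <- cbind(seq_along(pos), lab$cls[pos])
    loss_cls <- -mean(log(P[pick] + eps))
    dP <- P
    dP[pick] <- dP[pick] - 1
    dZ[pos, 1L + seq_len(nv)] <- dP / length(pos)

    box_logits <- Z[pos, 1L + nv + 1:4, drop = FALSE]
    box_pred <- sigmoid_(box_logits)
    tgt <- cbind(lab$dx[pos], lab$dy[pos], lab$bw[pos], lab$bh[pos])
    diff <- box_pred - tgt
    lambda_box <- 5
    loss_box <- lambda_box * mean(diff^2)
    dZ[pos, 1L + nv + 1:4] <- lambda_box * 2 * diff *
      box_pred * (1 - box_pred) / (length(pos) * 4)
  }
  loss <- loss_obj + loss_cls + loss_box

  grads <- list()
  grads$W2 <- t(H) %*% dZ
  grads$b2 <- matrix(colSums(dZ), 1)
  dH <- dZ %*% t(params$W2)
  dH[H <= 0] <- 0
  grads$W1 <- t(X) %*% dH
  grads$b1 <- matrix(colSums(dH), 1)
  list(loss = loss, grads = grads)
}

classifier_batch_grad <- function(p, X, y) {
  B <- nrow(X)
  H <- relu_(X %*% p$V1 + matrix(p$c1, B, ncol(p$V1), byrow = TRUE))
  P <- softmax_rows(H %*% p$V2 + matrix(p$c2, B, ncol(p$V2), byrow = TRUE))
  pick <- cbind(seq_len(B), y)
  loss <- -mean(log(P[pick] + 1e-12))
  dZ <- P; dZ[pick] <- dZ[pick] - 1; dZ <- dZ / B
  grads <- list(V2 = t(H) %*% dZ, c2 = matrix(colSums(dZ), 1))
  dH <- dZ %*% t(p$V2); dH[H <= 0] <- 0
  grads$V1 <- t(X) %*% dH
  grads$c1 <- matrix(colSums(dH), 1)
  list(loss = loss, grads = grads)
}

classifier_predict <- function(p, X) {
  H <- relu_(X %*% p$V1 + matrix(p$c1, nrow(X), ncol(p$V1), byrow = TRUE))
  P <- softmax_rows(H %*% p$V2 + matrix(p$c2, nrow(X), ncol(p$V2), byrow = TRUE))
  cls <- max.col(P, ties.method = "first")
  list(cls = cls, prob = P[cbind(seq_len(nrow(P)), cls)])
}

#' Detect imprinted characters in a pill image
#'
#' Runs the shared cell network over every grid cell, keeps cells whose
#' objectness probability reaches `conf_threshold`, decodes class and box,
#' and applies greedy non-maximum suppression (IoU 0.45, highest confidence
#' first, ties broken by lower cell index). Detections are returned in
#' reading-order convention — face (left half first), then y, then x — but
#' downstream consumers treat the order as unreliable.
#'
#' @param model A `detector_model`.
#' @param image An orientation-normalized `h x w x 3` array matching the
#'   training geometry.
#' @param conf_threshold Objectness threshold in `[0,1]` (values above 1
#'   yield no detections).
#' @return A tibble with `char`, `x`, `y` (normalized centre coordinates),
#'   `confidence`, sorted by face, then y, then x.
#' @export
detect_characters <- function(model, image,
                              conf_threshold = model$config$conf_threshold) {
  stopifnot(inherits(model, "detector_model"))
  h <- dim(image)[1]; w <- dim(image)[2]
  cell <- model$cell
  X <- cell_patch_matrix(image, cell)
  grid <- cell_index_grid(h, w, cell)
  Z <- detector_forward(model$params, X)$Z
  p_obj <- sigmoid_(Z[, 1])
  keep <- which(p_obj >= conf_threshold)
  empty <- tibble::tibble(char = character(0), x = numeric(0), y = numeric(0),
                          confidence = numeric(0))
  if (length(keep) == 0L) return(empty)
  nv <- length(model$vocab)
  box <- sigmoid_(Z[keep, 1L + nv + 1:4, drop = FALSE])
  cx <- (grid$col[keep] - 1 + box[, 1]) * cell / w
  cy <- (grid$row[keep] - 1 + box[, 2]) * cell / h
  gp <- gray_padded(image, cell)
  for (j in seq_along(keep)) {
    rc <- refine_center(gp, cell, cy[j] * h, cx[j] * w)
    cy[j] <- rc[1] / h
    cx[j] <- rc[2] / w
  }
  Xc <- do.call(rbind, lapply(seq_along(keep), function(j) {
    patch_at_px(gp, cell, cy[j] * h, cx[j] * w)
  }))
  cp <- classifier_predict(model$cls_params, Xc)
  cls <- cp$cls
  # a detection is only as trustworthy as its weaker head
  conf <- pmin(p_obj[keep], cp$prob)
  bw <- box[, 3] * h / w   # width predicted in image-height units
  bh <- box[, 4]
  det <- data.frame(char = model$vocab[cls], x = cx, y = cy,
                    confidence = conf, w = bw, h = bh,
                    cell_index = keep, stringsAsFactors = FALSE)
  det <- det[det$confidence >= conf_threshold, , drop = FALSE]
  if (nrow(det) == 0L) return(empty)
  det <- nms_greedy(det, iou = 0.45, min_dist = 0.8 * cell / h)
  det <- det[order(det$x >= 0.5, det$y, det$x), , drop = FALSE]
  tibble::tibble(char = det$char, x = det$x, y = det$y,
                 confidence = det$confidence)
}

# Greedy NMS by confidence (ties: lower cell index). A detection is
# suppressed if it overlaps a kept one above the IoU threshold or if its
# centre lies within min_dist of a kept centre (in units of image height),
# which collapses cell-boundary double claims whose regressed boxes may not
# overlap.
nms_greedy <- function(det, iou = 0.45, min_dist = 0) {
  ord <- order(-det$confidence, det$cell_index)
  det <- det[ord, , drop = FALSE]
  keep <- logical(nrow(det))
  for (i in seq_len(nrow(det))) {
    if (i == 1L) { keep[1] <- TRUE; next }
    ok <- TRUE
    for (j in which(keep)) {
      close <- sqrt(((det$x[i] - det$x[j]) * 2)^2 +
                      (det$y[i] - det$y[j])^2) < min_dist
      if (close || box_iou(det[i, ], det[j, ]) > iou) { ok <- FALSE; break }
    }
    keep[i] <- ok
  }
  det[keep, , drop = FALSE]
}

box_iou <- function(a, b) {
  ax1 <- a$x - a$w / 2; ax2 <- a$x + a$w / 2
  ay1 <- a$y - a$h / 2; ay2 <- a$y + a$h / 2
  bx1 <- b$x - b$w / 2; bx2 <- b$x + b$w / 2
  by1 <- b$y - b$h / 2; by2 <- b$y + b$h / 2
  iw <- max(0, min(ax2, bx2) - max(ax1, bx1))
  ih <- max(0, min(ay2, by2) - max(ay1, by1))
  inter <- iw * ih
  union <- (ax2 - ax1) * (ay2 - ay1) + (bx2 - bx1) * (by2 - by1) - inter
  if (union <= 0) return(0)
  inter / union
}

#' @export
print.detector_model <- function(x, ...) {
  cat("<detector_model> cell ", x$cell, "px grid, vocab ", length(x$vocab),
      ", final training loss ", signif(utils::tail(x$loss_history, 1), 4),
      " after ", length(x$loss_history), " epochs\n", sep = "")
  invisible(x)
}
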