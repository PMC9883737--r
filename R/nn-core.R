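# Minimal dense neural-network primitives shared by the detector, the
# multitask feature classifier and the seq2seq corrector. Parameters are
# named lists of matrices; gradients mirror the names. All randomness is
# funnelled through explicit seeds so training is a pure function of its
# arguments.

sigmoid_ <- function(x) 1 / (1 + exp(-x))

# Row-wise stable softmax of a matrix.
softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

relu_ <- function(x) pmax(x, 0)

# Uniform(-s, s) initialization in the current RNG stream.
init_mat <- function(nr, nc, s = NULL) {
  if (is.null(s)) s <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -s, s), nr, nc)
}

zeros_like <- function(params) lapply(params, function(p) p * 0)

# In-place-style gradient accumulation on an environment of matrices.
acc_grad <- function(gr, name, value) {
  if (is.null(gr[[name]])) gr[[name]] <- value else gr[[name]] <- gr[[name]] + value
  invisible(NULL)
}

adam_init <- function(params) {
  list(m = zeros_like(params), v = zeros_like(params), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, clip = 5) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  # global gradient-norm clipping stabilizes early recurrent training
  gnorm <- sqrt(sum(vapply(grads, function(g) sum(g^2), numeric(1))))
  scale <- if (is.finite(gnorm) && gnorm > clip) clip / gnorm else 1
  for (nm in names(params)) {
    g <- grads[[nm]] * scale
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

sgd_step <- function(params, grads, lr, weight_decay = 0, clip = 5) {
  gnorm <- sqrt(sum(vapply(grads, function(g) sum(g^2), numeric(1))))
  scale <- if (is.finite(gnorm) && gnorm > clip) clip / gnorm else 1
  for (nm in names(params)) {
    g <- grads[[nm]] * scale
    if (weight_decay > 0) g <- g + weight_decay * params[[nm]]
    params[[nm]] <- params[[nm]] - lr * g
  }
  params
}

# Bilinear resize of an h x w x 3 array to target dimensions.
resize_image <- function(img, out_h, out_w) {
  d <- dim(img)
  if (d[1] == out_h && d[2] == out_w) return(img)
  sx <- matrix((seq_len(out_w) - 0.5) * d[2] / out_w + 0.5, out_h, out_w,
               byrow = TRUE)
  sy <- matrix((seq_len(out_h) - 0.5) * d[1] / out_h + 0.5, out_h, out_w,
               byrow = FALSE)
  sx <- pmin(pmax(sx, 1), d[2])
  sy <- pmin(pmax(sy, 1), d[1])
  out <- array(0, dim = c(out_h, out_w, d[3]))
  for (ch in seq_len(d[3])) {
    out[, , ch] <- bilinear_sample(img[, , ch], sx, sy, fill = 0)
  }
  out
}
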