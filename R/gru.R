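# Batched GRU cell and additive (concat) attention with hand-derived
# backward passes. Weight layout: W (d_in x 3H), U (H x 3H), b (1 x 3H) with
# the three blocks ordered [reset | update | candidate]:
#   r  = sigmoid(X W_r + H U_r + b_r)
#   z  = sigmoid(X W_z + H U_z + b_z)
#   n  = tanh(X W_n + b_n + r * (H U_n))
#   H' = (1 - z) * n + z * H
# Correctness is pinned by finite-difference gradient checks in the tests.

gru_cell_forward <- function(X, Hprev, W, U, b) {
  Hn <- ncol(U) / 3L
  pre_x <- X %*% W + matrix(b, nrow(X), 3L * Hn, byrow = TRUE)
  pre_h <- Hprev %*% U
  i1 <- seq_len(Hn); i2 <- Hn + i1; i3 <- 2L * Hn + i1
  r <- sigmoid_(pre_x[, i1, drop = FALSE] + pre_h[, i1, drop = FALSE])
  z <- sigmoid_(pre_x[, i2, drop = FALSE] + pre_h[, i2, drop = FALSE])
  k <- pre_h[, i3, drop = FALSE]
  n <- tanh(pre_x[, i3, drop = FALSE] + r * k)
  Hnew <- (1 - z) * n + z * Hprev
  list(H = Hnew, cache = list(X = X, Hprev = Hprev, r = r, z = z, n = n, k = k))
}

gru_cell_backward <- function(dH, cache, W, U) {
  r <- cache$r; z <- cache$z; n <- cache$n; k <- cache$k
  Hprev <- cache$Hprev; X <- cache$X
  dz <- dH * (Hprev - n)
  dn <- dH * (1 - z)
  dHprev <- dH * z
  dpre_n <- dn * (1 - n^2)
  dr <- dpre_n * k
  dk <- dpre_n * r
  dpre_r <- dr * r * (1 - r)
  dpre_z <- dz * z * (1 - z)
  dpre_x <- cbind(dpre_r, dpre_z, dpre_n)
  dpre_h <- cbind(dpre_r, dpre_z, dk)
  list(
    dX = dpre_x %*% t(W),
    dHprev = dHprev + dpre_h %*% t(U),
    dW = t(X) %*% dpre_x,
    dU = t(Hprev) %*% dpre_h,
    db = matrix(colSums(dpre_x), 1)
  )
}

# Additive attention over the encoder states S (list over time of B x 2H),
# queried by the previous decoder state. SUa (the projections S_t Ua) is
# precomputed once per batch because it does not depend on the decoder step.
attn_forward <- function(Dprev, Slist, SUa, mask, Wa, ba, va) {
  B <- nrow(Dprev); Tn <- length(Slist)
  base <- Dprev %*% Wa
  E <- matrix(-Inf, B, Tn)
  Ulist <- vector("list", Tn)
  bmat <- matrix(ba, B, length(ba), byrow = TRUE)
  for (t in seq_len(Tn)) {
    u <- tanh(base + SUa[[t]] + bmat)
    Ulist[[t]] <- u
    E[, t] <- as.numeric(u %*% va)
  }
  E[mask == 0] <- -Inf
  mx <- apply(E, 1, max)
  dead <- !is.finite(mx)          # rows with no unmasked position
  mx[dead] <- 0
  ex <- exp(E - mx)
  ex[!is.finite(ex)] <- 0
  denom <- rowSums(ex)
  denom[denom == 0] <- 1
  alpha <- ex / denom
  C <- matrix(0, B, ncol(Slist[[1]]))
  for (t in seq_len(Tn)) C <- C + alpha[, t] * Slist[[t]]
  list(C = C, cache = list(Dprev = Dprev, Ulist = Ulist, alpha = alpha,
                           mask = mask))
}

# Returns dDprev and per-t gradients dSdirect (via alpha * S) plus dSUa
# (to be folded back through Ua by the caller); accumulates dWa, dba, dva
# into the environment `gr`.
attn_backward <- function(dC, cache, Slist, Wa, va, gr) {
  alpha <- cache$alpha; Ulist <- cache$Ulist
  B <- nrow(dC); Tn <- length(Slist)
  dalpha <- matrix(0, B, Tn)
  dSdirect <- vector("list", Tn)
  for (t in seq_len(Tn)) {
    dalpha[, t] <- rowSums(dC * Slist[[t]])
    dSdirect[[t]] <- alpha[, t] * dC
  }
  dE <- alpha * (dalpha - rowSums(dalpha * alpha))
  dE[cache$mask == 0] <- 0
  dbase <- matrix(0, B, ncol(Wa))
  dSUa <- vector("list", Tn)
  for (t in seq_len(Tn)) {
    du <- matrix(va, B, length(va), byrow = TRUE) * dE[, t]  # outer(dE_t, va)
    dpre <- du * (1 - Ulist[[t]]^2)
    acc_grad(gr, "va", t(Ulist[[t]]) %*% dE[, t])
    acc_grad(gr, "ba", matrix(colSums(dpre), 1))
    dbase <- dbase + dpre
    dSUa[[t]] <- dpre
  }
  acc_grad(gr, "Wa", t(cache$Dprev) %*% dbase)
  list(dDprev = dbase %*% t(Wa), dSdirect = dSdirect, dSUa = dSUa)
}
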