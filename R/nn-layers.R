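# Low-level neural-network primitives on dense arrays.
#
# Batched activations are stored as 3-D arrays (batch B, sequence L,
# channels C); flattening the first two dims gives a (B*L) x C matrix whose
# column-major layout matches the array, so every layer reduces to BLAS
# matrix products.  Convolutions use an im2col buffer; inside the attention
# module activations are transposed to sequence-major (L, B, C) layout so
# that each sample is a contiguous row block.  Each *_forward returns the
# output plus the cache its *_backward needs; backward passes return the
# input gradient and the parameter gradients.  Everything is double
# precision.

#' Exponential linear unit
#'
#' \code{x} for \code{x > 0}, \code{alpha * (exp(x) - 1)} otherwise;
#' continuous at 0.
#'
#' @param x Numeric vector/array.
#' @param alpha Positive slope of the negative saturation (default 1).
#' @return Same shape as \code{x}.
#' @examples
#' elu(c(-1, 0, 2))
#' @export
elu <- function(x, alpha = 1) {
  stopifnot(alpha > 0)
  neg <- !(x > 0)
  y <- x
  y[neg] <- alpha * expm1(x[neg])
  y
}

# mask-reusing fast path: cache the negative mask between passes
elu_forward <- function(x, alpha) {
  neg <- !(x > 0)
  y <- x
  y[neg] <- alpha * expm1(x[neg])
  list(out = y, neg = neg)
}

elu_backward <- function(dy, y, cache, alpha) {
  # d/dx = 1 for x>0, alpha*exp(x) = y + alpha otherwise
  dx <- dy
  dx[cache$neg] <- dy[cache$neg] * (y[cache$neg] + alpha)
  dx
}

leaky_relu <- function(x, slope = 0.01) pmax(x, 0) + slope * pmin(x, 0)
leaky_relu_backward <- function(dy, x, slope = 0.01) {
  dy * (slope + (1 - slope) * (x > 0))
}

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Row-wise softmax
#' @param m Numeric matrix.
#' @return Matrix of the same shape; every row sums to 1.
#' @keywords internal
softmax_rows <- function(m) {
  e <- exp(m - m[cbind(seq_len(nrow(m)), max.col(m, ties.method = "first"))])
  e / rowSums(e)
}

# ---- embedding --------------------------------------------------------------

embed_forward <- function(E, ids) {
  # ids: B x L integer matrix of vocabulary ids (0-based); E: V x emb
  b <- nrow(ids); l <- ncol(ids)
  idx <- as.vector(ids) + 1L
  X <- E[idx, , drop = FALSE]
  dim(X) <- c(b, l, ncol(E))
  list(out = X, idx = idx, v = nrow(E))
}

embed_backward <- function(dY, cache) {
  d <- dim(dY)
  dM <- dY; dim(dM) <- c(d[1L] * d[2L], d[3L])
  agg <- rowsum(dM, group = cache$idx)
  dE <- matrix(0, cache$v, d[3L])
  dE[as.integer(rownames(agg)), ] <- agg
  dE
}

# ---- 1-D convolution (same-length padding, im2col) --------------------------
#
# In the flattened (B*Lp, cin) view of the zero-padded input, the rows of
# sequence window k form the contiguous block ((k-1)B + 1) : ((k-1+L)B), so
# im2col assembly and the backward fold are plain row-range operations.
# W is an array (K, cin, cout); aperm to (cin, K, cout) matches the im2col
# column blocks (channels fastest within each kernel tap).

conv1d_forward <- function(X, W, b) {
  dx <- dim(X); B <- dx[1L]; L <- dx[2L]; cin <- dx[3L]
  K <- dim(W)[1L]; cout <- dim(W)[3L]
  pl <- (K - 1L) %/% 2L
  XpM <- matrix(0, B * (L + K - 1L), cin)
  XpM[(pl * B + 1L):((pl + L) * B), ] <- X
  Y <- matrix(rep(b, each = B * L), B * L, cout)
  for (k in seq_len(K)) {
    Y <- Y + XpM[((k - 1L) * B + 1L):((k - 1L + L) * B), , drop = FALSE] %*%
      matrix(W[k, , ], cin, cout)
  }
  dim(Y) <- c(B, L, cout)
  list(out = Y, XpM = XpM, B = B, L = L, K = K, cin = cin, pl = pl)
}

conv1d_backward <- function(dY, W, cache) {
  B <- cache$B; L <- cache$L; K <- cache$K
  cin <- cache$cin; pl <- cache$pl
  cout <- dim(W)[3L]
  dYm <- dY; dim(dYm) <- c(B * L, cout)
  dW <- array(0, dim(W))
  dXpM <- matrix(0, B * (L + K - 1L), cin)
  for (k in seq_len(K)) {
    rng <- ((k - 1L) * B + 1L):((k - 1L + L) * B)
    dW[k, , ] <- crossprod(cache$XpM[rng, , drop = FALSE], dYm)
    dXpM[rng, ] <- dXpM[rng, , drop = FALSE] +
      tcrossprod(dYm, matrix(W[k, , ], cin, cout))
  }
  dX <- dXpM[(pl * B + 1L):((pl + L) * B), , drop = FALSE]
  dim(dX) <- c(B, L, cin)
  list(dX = dX, dW = dW, db = colSums(dYm))
}

# ---- batch normalisation (per channel over batch x sequence) ----------------

bn_forward <- function(X, gamma, beta, training, run_mean, run_var,
                       momentum = 0.1, eps = 1e-5) {
  d <- dim(X); N <- d[1L] * d[2L]; C <- d[3L]
  M <- X; dim(M) <- c(N, C)
  if (training) {
    mu <- colMeans(M)
    v <- pmax(colMeans(M * M) - mu * mu, 0)
    new_mean <- (1 - momentum) * run_mean + momentum * mu
    new_var <- (1 - momentum) * run_var + momentum * v
  } else {
    mu <- run_mean; v <- run_var
    new_mean <- run_mean; new_var <- run_var
  }
  invstd <- 1 / sqrt(v + eps)
  xhat <- (M - rep(mu, each = N)) * rep(invstd, each = N)
  Y <- xhat * rep(gamma, each = N) + rep(beta, each = N)
  dim(Y) <- d
  list(out = Y, xhat = xhat, invstd = invstd, training = training,
       new_mean = new_mean, new_var = new_var, dims = d)
}

bn_backward <- function(dY, gamma, cache) {
  d <- cache$dims; N <- d[1L] * d[2L]; C <- d[3L]
  dM <- dY; dim(dM) <- c(N, C)
  dgamma <- colSums(dM * cache$xhat)
  dbeta <- colSums(dM)
  g <- rep(gamma * cache$invstd, each = N)
  if (cache$training) {
    # gamma factors out of the standard batch-norm backward
    dX <- g * (dM - rep(colMeans(dM), each = N) -
                 cache$xhat * rep(colMeans(dM * cache$xhat), each = N))
  } else {
    dX <- g * dM
  }
  dim(dX) <- d
  list(dX = dX, dgamma = dgamma, dbeta = dbeta)
}

# ---- shared-weight multihead cross-attention --------------------------------

# D: (B, LD, C), P: (B, LP, C).  The drug pass uses Q from D and K,V from P;
# the protein pass uses Q from P and K,V from D with the SAME WQ/WK/WV
# parameters (weight sharing).  Heads split the channel axis into h blocks
# of dh = C/h; scores are scaled by sqrt(dh); heads are re-concatenated and
# projected by W0 (C x C).

# (B, L, C) array -> (L*B, C) matrix with sample b in contiguous rows
.to_seq_major <- function(X, B, L, C) {
  Xp <- aperm(X, c(2L, 1L, 3L))
  dim(Xp) <- c(L * B, C)
  Xp
}

# inverse: (L*B, C) matrix -> (B*L, C) matrix (batch-major flattening)
.to_batch_major <- function(Xp, B, L, C) {
  dim(Xp) <- c(L, B, C)
  X <- aperm(Xp, c(2L, 1L, 3L))
  dim(X) <- c(B * L, C)
  X
}

attn_forward <- function(D, P, WQ, WK, WV, W0, h) {
  dd <- dim(D); dp <- dim(P)
  B <- dd[1L]; LD <- dd[2L]; LP <- dp[2L]; C <- dd[3L]
  if (dp[3L] != C) stop("shape error: channel mismatch between D and P")
  if (C %% h != 0L) stop("shape error: heads must divide channels")
  dh <- C %/% h
  matD <- D; dim(matD) <- c(B * LD, C)
  matP <- P; dim(matP) <- c(B * LP, C)
  qd_all <- matD %*% WQ; kd_all <- matP %*% WK; vd_all <- matP %*% WV
  qp_all <- matP %*% WQ; kp_all <- matD %*% WK; vp_all <- matD %*% WV
  dim(qd_all) <- c(B, LD, C); dim(kd_all) <- c(B, LP, C)
  dim(vd_all) <- c(B, LP, C); dim(qp_all) <- c(B, LP, C)
  dim(kp_all) <- c(B, LD, C); dim(vp_all) <- c(B, LD, C)
  QD <- .to_seq_major(qd_all, B, LD, C); KD <- .to_seq_major(kd_all, B, LP, C)
  VD <- .to_seq_major(vd_all, B, LP, C); QP <- .to_seq_major(qp_all, B, LP, C)
  KP <- .to_seq_major(kp_all, B, LD, C); VP <- .to_seq_major(vp_all, B, LD, C)
  AD <- array(0, c(LD, LP, B, h))
  AP <- array(0, c(LP, LD, B, h))
  ZD <- matrix(0, LD * B, C)
  ZP <- matrix(0, LP * B, C)
  scale <- sqrt(dh)
  for (i in seq_len(h)) {
    ci <- ((i - 1L) * dh + 1L):(i * dh)
    QDh <- QD[, ci, drop = FALSE]; KDh <- KD[, ci, drop = FALSE]
    VDh <- VD[, ci, drop = FALSE]; QPh <- QP[, ci, drop = FALSE]
    KPh <- KP[, ci, drop = FALSE]; VPh <- VP[, ci, drop = FALSE]
    ZDh <- matrix(0, LD * B, dh); ZPh <- matrix(0, LP * B, dh)
    for (b in seq_len(B)) {
      rd <- ((b - 1L) * LD + 1L):(b * LD)
      rp <- ((b - 1L) * LP + 1L):(b * LP)
      A <- softmax_rows(tcrossprod(QDh[rd, , drop = FALSE],
                                   KDh[rp, , drop = FALSE]) / scale)
      AD[, , b, i] <- A
      ZDh[rd, ] <- A %*% VDh[rp, , drop = FALSE]
      Ap <- softmax_rows(tcrossprod(QPh[rp, , drop = FALSE],
                                    KPh[rd, , drop = FALSE]) / scale)
      AP[, , b, i] <- Ap
      ZPh[rp, ] <- Ap %*% VPh[rd, , drop = FALSE]
    }
    ZD[, ci] <- ZDh
    ZP[, ci] <- ZPh
  }
  matZD <- .to_batch_major(ZD, B, LD, C)
  matZP <- .to_batch_major(ZP, B, LP, C)
  MD <- matZD %*% W0; dim(MD) <- c(B, LD, C)
  MP <- matZP %*% W0; dim(MP) <- c(B, LP, C)
  list(MD = MD, MP = MP,
       ADs = AD, APs = AP, QD = QD, KD = KD, VD = VD,
       QP = QP, KP = KP, VP = VP, ZD = matZD, ZP = matZP,
       matD = matD, matP = matP,
       B = B, LD = LD, LP = LP, C = C, h = h, dh = dh)
}

attn_backward <- function(dMD, dMP, WQ, WK, WV, W0, cache) {
  B <- cache$B; LD <- cache$LD; LP <- cache$LP
  C <- cache$C; h <- cache$h; dh <- cache$dh
  scale <- sqrt(dh)
  dmatMD <- dMD; dim(dmatMD) <- c(B * LD, C)
  dmatMP <- dMP; dim(dmatMP) <- c(B * LP, C)
  dW0 <- crossprod(cache$ZD, dmatMD) + crossprod(cache$ZP, dmatMP)
  dZDb <- dmatMD %*% t(W0); dim(dZDb) <- c(B, LD, C)
  dZPb <- dmatMP %*% t(W0); dim(dZPb) <- c(B, LP, C)
  dZD <- .to_seq_major(dZDb, B, LD, C)
  dZP <- .to_seq_major(dZPb, B, LP, C)
  dQD <- matrix(0, LD * B, C); dKD <- matrix(0, LP * B, C)
  dVD <- matrix(0, LP * B, C)
  dQP <- matrix(0, LP * B, C); dKP <- matrix(0, LD * B, C)
  dVP <- matrix(0, LD * B, C)
  for (i in seq_len(h)) {
    ci <- ((i - 1L) * dh + 1L):(i * dh)
    QDh <- cache$QD[, ci, drop = FALSE]; KDh <- cache$KD[, ci, drop = FALSE]
    VDh <- cache$VD[, ci, drop = FALSE]; QPh <- cache$QP[, ci, drop = FALSE]
    KPh <- cache$KP[, ci, drop = FALSE]; VPh <- cache$VP[, ci, drop = FALSE]
    dZDh <- dZD[, ci, drop = FALSE]; dZPh <- dZP[, ci, drop = FALSE]
    dQDh <- matrix(0, LD * B, dh); dKDh <- matrix(0, LP * B, dh)
    dVDh <- matrix(0, LP * B, dh); dQPh <- matrix(0, LP * B, dh)
    dKPh <- matrix(0, LD * B, dh); dVPh <- matrix(0, LD * B, dh)
    for (b in seq_len(B)) {
      rd <- ((b - 1L) * LD + 1L):(b * LD)
      rp <- ((b - 1L) * LP + 1L):(b * LP)
      A <- cache$ADs[, , b, i]; dim(A) <- c(LD, LP)
      dZ <- dZDh[rd, , drop = FALSE]
      dA <- tcrossprod(dZ, VDh[rp, , drop = FALSE])
      dVDh[rp, ] <- crossprod(A, dZ)
      tmp <- dA * A
      dS <- (tmp - A * rowSums(tmp)) / scale
      dQDh[rd, ] <- dS %*% KDh[rp, , drop = FALSE]
      dKDh[rp, ] <- crossprod(dS, QDh[rd, , drop = FALSE])

      Ap <- cache$APs[, , b, i]; dim(Ap) <- c(LP, LD)
      dZp <- dZPh[rp, , drop = FALSE]
      dAp <- tcrossprod(dZp, VPh[rd, , drop = FALSE])
      dVPh[rd, ] <- crossprod(Ap, dZp)
      tmpp <- dAp * Ap
      dSp <- (tmpp - Ap * rowSums(tmpp)) / scale
      dQPh[rp, ] <- dSp %*% KPh[rd, , drop = FALSE]
      dKPh[rd, ] <- crossprod(dSp, QPh[rp, , drop = FALSE])
    }
    dQD[, ci] <- dQDh; dKD[, ci] <- dKDh; dVD[, ci] <- dVDh
    dQP[, ci] <- dQPh; dKP[, ci] <- dKPh; dVP[, ci] <- dVPh
  }
  dmQD <- .to_batch_major(dQD, B, LD, C)
  dmKD <- .to_batch_major(dKD, B, LP, C)
  dmVD <- .to_batch_major(dVD, B, LP, C)
  dmQP <- .to_batch_major(dQP, B, LP, C)
  dmKP <- .to_batch_major(dKP, B, LD, C)
  dmVP <- .to_batch_major(dVP, B, LD, C)
  # shared weights: both passes accumulate into the same gradients
  dWQ <- crossprod(cache$matD, dmQD) + crossprod(cache$matP, dmQP)
  dWK <- crossprod(cache$matP, dmKD) + crossprod(cache$matD, dmKP)
  dWV <- crossprod(cache$matP, dmVD) + crossprod(cache$matD, dmVP)
  dD <- tcrossprod(dmQD, WQ) + tcrossprod(dmKP, WK) + tcrossprod(dmVP, WV)
  dP <- tcrossprod(dmQP, WQ) + tcrossprod(dmKD, WK) + tcrossprod(dmVD, WV)
  dim(dD) <- c(B, LD, C); dim(dP) <- c(B, LP, C)
  list(dD = dD, dP = dP, dWQ = dWQ, dWK = dWK, dWV = dWV, dW0 = dW0)
}

# ---- pooling, dense, dropout ------------------------------------------------

maxpool_forward <- function(X) {
  d <- dim(X); B <- d[1L]; L <- d[2L]; C <- d[3L]
  pool <- matrix(0, B, C)
  idx <- matrix(0L, B, C)
  for (c in seq_len(C)) {
    Xc <- matrix(X[, , c], B, L)
    id <- max.col(Xc, ties.method = "first")
    idx[, c] <- id
    pool[, c] <- Xc[cbind(seq_len(B), id)]
  }
  list(out = pool, idx = idx, dims = d)
}

maxpool_backward <- function(dpool, cache) {
  d <- cache$dims; B <- d[1L]; C <- d[3L]
  dX <- array(0, d)
  for (c in seq_len(C)) {
    dX[cbind(seq_len(B), cache$idx[, c], rep(c, B))] <- dpool[, c]
  }
  dX
}

dense_forward <- function(X, W, b) {
  list(out = X %*% W + rep(b, each = nrow(X)), X = X)
}

dense_backward <- function(dY, W, cache) {
  list(dX = tcrossprod(dY, W), dW = crossprod(cache$X, dY), db = colSums(dY))
}

dropout_forward <- function(X, p, training) {
  if (!training || p <= 0) return(list(out = X, mask = NULL))
  mask <- matrix((stats::runif(length(X)) >= p) / (1 - p), nrow(X), ncol(X))
  list(out = X * mask, mask = mask)
}

dropout_backward <- function(dY, cache) {
  if (is.null(cache$mask)) dY else dY * cache$mask
}
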