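# Vectorized forward/backward passes for the small reference CNN.
#
# All batch tensors are base-R arrays; convolutions are expressed as im2col
# gathers followed by BLAS matrix multiplication, the standard trick that
# keeps a small network fast without compiled code. Layout conventions:
#   input batch X: (h, w, C, B)          activation maps: (h, w, B, F)
#   im2col matrix: (h*w*B) x (9*C), patch offsets outer, channels inner.

.KSIZE <- 3L # 3x3 kernels, padding 1, stride 1 throughout

# gather 3x3 neighborhoods of every pixel into a matrix
.im2col <- function(X) {
  d <- dim(X); h <- d[1]; w <- d[2]; C <- d[3]; B <- d[4]
  P <- array(0, dim = c(h + 2L, w + 2L, C, B))
  P[2:(h + 1L), 2:(w + 1L), , ] <- X
  cols <- matrix(0, h * w * B, 9L * C)
  idx <- 0L
  for (dx in 0:2) {
    for (dy in 0:2) {
      patch <- P[(1L + dy):(h + dy), (1L + dx):(w + dx), , , drop = FALSE]
      cols[, idx * C + seq_len(C)] <- matrix(aperm(patch, c(1, 2, 4, 3)), h * w * B, C)
      idx <- idx + 1L
    }
  }
  cols
}

# scatter-add the column gradient back to input pixels (transpose of .im2col)
.col2im <- function(dcols, h, w, C, B) {
  dP <- array(0, dim = c(h + 2L, w + 2L, C, B))
  idx <- 0L
  for (dx in 0:2) {
    for (dy in 0:2) {
      dm <- dcols[, idx * C + seq_len(C), drop = FALSE]
      dpatch <- aperm(array(dm, dim = c(h, w, B, C)), c(1, 2, 4, 3))
      ys <- (1L + dy):(h + dy); xs <- (1L + dx):(w + dx)
      dP[ys, xs, , ] <- dP[ys, xs, , ] + dpatch
      idx <- idx + 1L
    }
  }
  dP[2:(h + 1L), 2:(w + 1L), , , drop = FALSE]
}

# 2x2 max pooling, stride 2; odd trailing rows/columns are dropped.
# Returns pooled map and the four routing masks for the backward pass
# (ties route to the first matching position, scan order 11, 21, 12, 22).
.maxpool <- function(A) {
  d <- dim(A); h2 <- d[1] %/% 2L; w2 <- d[2] %/% 2L
  i1 <- seq_len(h2) * 2L - 1L; j1 <- seq_len(w2) * 2L - 1L
  a11 <- A[i1, j1, , , drop = FALSE]
  a21 <- A[i1 + 1L, j1, , , drop = FALSE]
  a12 <- A[i1, j1 + 1L, , , drop = FALSE]
  a22 <- A[i1 + 1L, j1 + 1L, , , drop = FALSE]
  m <- pmax(pmax(a11, a21), pmax(a12, a22))
  m11 <- a11 == m
  m21 <- (a21 == m) & !m11
  m12 <- (a12 == m) & !m11 & !m21
  m22 <- !m11 & !m21 & !m12
  list(out = m, masks = list(m11, m21, m12, m22), in_dim = d)
}

.maxpool_backward <- function(pool, dOut) {
  d <- pool$in_dim
  h2 <- dim(dOut)[1]; w2 <- dim(dOut)[2]
  i1 <- seq_len(h2) * 2L - 1L; j1 <- seq_len(w2) * 2L - 1L
  dA <- array(0, dim = d)
  dA[i1, j1, , ] <- dOut * pool$masks[[1]]
  dA[i1 + 1L, j1, , ] <- dOut * pool$masks[[2]]
  dA[i1, j1 + 1L, , ] <- dOut * pool$masks[[3]]
  dA[i1 + 1L, j1 + 1L, , ] <- dOut * pool$masks[[4]]
  dA
}

# full forward pass; returns logits and (optionally) the cache needed by
# .tiny_cnn_backward
.tiny_cnn_forward <- function(params, X, keep_cache = FALSE) {
  d <- dim(X); h <- d[1]; w <- d[2]; B <- d[4]
  f1 <- length(params$conv1.b); f2 <- length(params$conv2.b)

  cols1 <- .im2col(X)
  pre1 <- sweep(cols1 %*% params$conv1.W, 2L, params$conv1.b, `+`)
  act1 <- array(pmax(pre1, 0), dim = c(h, w, B, f1))
  pool1 <- .maxpool(act1)
  h2 <- dim(pool1$out)[1]; w2 <- dim(pool1$out)[2]

  X2 <- aperm(pool1$out, c(1, 2, 4, 3)) # (h2, w2, F1, B)
  cols2 <- .im2col(X2)
  pre2 <- sweep(cols2 %*% params$conv2.W, 2L, params$conv2.b, `+`)
  act2 <- array(pmax(pre2, 0), dim = c(h2, w2, B, f2))
  pool2 <- .maxpool(act2)
  h4 <- dim(pool2$out)[1]; w4 <- dim(pool2$out)[2]

  feats <- matrix(colMeans(matrix(pool2$out, h4 * w4, B * f2)), B, f2)
  logits <- sweep(feats %*% params$head.W, 2L, params$head.b, `+`)

  if (!keep_cache) return(list(logits = logits))
  list(logits = logits, cols1 = cols1, pre1 = pre1, pool1 = pool1,
       cols2 = cols2, pre2 = pre2, pool2 = pool2, feats = feats,
       dims = list(h = h, w = w, h2 = h2, w2 = w2, h4 = h4, w4 = w4,
                   B = B, f1 = f1, f2 = f2))
}

.softmax_rows <- function(logits) {
  z <- logits - apply(logits, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

# mean cross-entropy loss over the batch and its gradient wrt every parameter
.tiny_cnn_loss_grad <- function(params, X, y_onehot) {
  fw <- .tiny_cnn_forward(params, X, keep_cache = TRUE)
  dm <- fw$dims
  p <- .softmax_rows(fw$logits)
  eps <- 1e-12
  loss <- -mean(log(pmax(rowSums(p * y_onehot), eps)))

  dlogits <- (p - y_onehot) / dm$B
  dWh <- crossprod(fw$feats, dlogits)
  dbh <- colSums(dlogits)
  dfeats <- dlogits %*% t(params$head.W)

  dpool2 <- array(rep(as.vector(dfeats) / (dm$h4 * dm$w4), each = dm$h4 * dm$w4),
                  dim = c(dm$h4, dm$w4, dm$B, dm$f2))
  dact2 <- .maxpool_backward(fw$pool2, dpool2)
  dpre2 <- matrix(dact2, dm$h2 * dm$w2 * dm$B, dm$f2) * (fw$pre2 > 0)
  dW2 <- crossprod(fw$cols2, dpre2)
  db2 <- colSums(dpre2)
  dcols2 <- dpre2 %*% t(params$conv2.W)
  dX2 <- .col2im(dcols2, dm$h2, dm$w2, dm$f1, dm$B)
  dpool1 <- aperm(dX2, c(1, 2, 4, 3)) # back to (h2, w2, B, F1)

  dact1 <- .maxpool_backward(fw$pool1, dpool1)
  dpre1 <- matrix(dact1, dm$h * dm$w * dm$B, dm$f1) * (fw$pre1 > 0)
  dW1 <- crossprod(fw$cols1, dpre1)
  db1 <- colSums(dpre1)

  list(loss = loss,
       grads = list(conv1.W = dW1, conv1.b = db1,
                    conv2.W = dW2, conv2.b = db2,
                    head.W = dWh, head.b = dbh))
}
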