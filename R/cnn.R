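# Minimal 1D convolutional network used by the transient peak detector.
#
# Architecture (fixed here, surfaced as configuration on the detector):
#   input window (N samples, robust-z scale)
#   -> conv1d(kernel 7, 8 channels) + ReLU
#   -> conv1d(kernel 5, 16 channels) + ReLU
#   -> flatten -> dense(positions x channels -> 1) -> sigmoid
# The head is position-sensitive on purpose: the classifier must score
# whether a peak sits at the window centre, so translation-invariant
# pooling would erase the signal. Implemented with im2col matrix
# products and manual backpropagation; optimised with Adam on binary
# cross-entropy. All shapes are tiny (windows of 35 samples), so plain
# BLAS is ample.

cnn_init <- function(window, k1 = 7, c1 = 8, k2 = 5, c2 = 16) {
  p1 <- window - k1 + 1
  p2 <- p1 - k2 + 1
  if (p2 < 1) abort_config("Window too short for the convolution stack.")
  he <- function(nr, nc, fan_in) matrix(rnorm(nr * nc, 0, sqrt(2 / fan_in)), nr, nc)
  list(window = window, k1 = k1, c1 = c1, k2 = k2, c2 = c2, p1 = p1, p2 = p2,
       W1 = he(k1, c1, k1), b1 = rep(0, c1),
       W2 = he(k2 * c1, c2, k2 * c1), b2 = rep(0, c2),
       W3 = he(p2 * c2, 1, p2 * c2), b3 = 0)
}

# X: n x window matrix of input windows. Returns cache for backprop.
cnn_forward <- function(net, X) {
  n <- nrow(X)
  X1 <- matrix(0, n * net$p1, net$k1)
  for (o in seq_len(net$k1)) {
    X1[, o] <- as.vector(X[, (seq_len(net$p1)) + o - 1, drop = FALSE])
  }
  Z1 <- sweep(X1 %*% net$W1, 2, net$b1, `+`)
  H1 <- pmax(Z1, 0)
  sel <- lapply(seq_len(net$k2), function(o) {
    unlist(lapply(seq_len(net$p2), function(p) ((p + o - 2) * n + 1):((p + o - 1) * n)))
  })
  X2 <- matrix(0, n * net$p2, net$k2 * net$c1)
  for (o in seq_len(net$k2)) {
    X2[, (o - 1) * net$c1 + seq_len(net$c1)] <- H1[sel[[o]], , drop = FALSE]
  }
  Z2 <- sweep(X2 %*% net$W2, 2, net$b2, `+`)
  H2 <- pmax(Z2, 0)
  # flatten: F[i, (c-1)*p2 + p] = H2[n*(p-1)+i, c]
  Fm <- matrix(0, n, net$p2 * net$c2)
  for (p in seq_len(net$p2)) {
    Fm[, (seq_len(net$c2) - 1) * net$p2 + p] <- H2[((p - 1) * n + 1):(p * n), , drop = FALSE]
  }
  logits <- as.numeric(Fm %*% net$W3) + net$b3
  prob <- 1 / (1 + exp(-logits))
  list(prob = prob, X1 = X1, Z1 = Z1, X2 = X2, Z2 = Z2, Fm = Fm,
       sel = sel, n = n)
}

# Gradient of mean binary cross-entropy w.r.t. all parameters.
cnn_backward <- function(net, cache, y) {
  n <- cache$n
  dlogit <- (cache$prob - y) / n
  gW3 <- crossprod(cache$Fm, dlogit)
  gb3 <- sum(dlogit)
  dF <- dlogit %*% t(net$W3)
  dH2 <- matrix(0, n * net$p2, net$c2)
  for (p in seq_len(net$p2)) {
    dH2[((p - 1) * n + 1):(p * n), ] <- dF[, (seq_len(net$c2) - 1) * net$p2 + p, drop = FALSE]
  }
  dZ2 <- dH2 * (cache$Z2 > 0)
  gW2 <- crossprod(cache$X2, dZ2)
  gb2 <- colSums(dZ2)
  dX2 <- dZ2 %*% t(net$W2)
  dH1 <- matrix(0, nrow(cache$Z1), net$c1)
  for (o in seq_len(net$k2)) {
    dH1[cache$sel[[o]], ] <- dH1[cache$sel[[o]], , drop = FALSE] +
      dX2[, (o - 1) * net$c1 + seq_len(net$c1), drop = FALSE]
  }
  dZ1 <- dH1 * (cache$Z1 > 0)
  gW1 <- crossprod(cache$X1, dZ1)
  gb1 <- colSums(dZ1)
  list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2, W3 = gW3, b3 = gb3)
}

cnn_train <- function(net, X, y, epochs = 30, batch_size = 256, lr = 1e-2) {
  pars <- c("W1", "b1", "W2", "b2", "W3", "b3")
  m <- lapply(pars, function(p) net[[p]] * 0)
  v <- m
  names(m) <- names(v) <- pars
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  step <- 0
  n <- nrow(X)
  loss <- NA_real_
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    losses <- c()
    for (start in seq(1, n, by = batch_size)) {
      idx <- ord[start:min(start + batch_size - 1, n)]
      cache <- cnn_forward(net, X[idx, , drop = FALSE])
      p <- pmin(pmax(cache$prob, 1e-12), 1 - 1e-12)
      losses <- c(losses, -mean(y[idx] * log(p) + (1 - y[idx]) * log(1 - p)))
      g <- cnn_backward(net, cache, y[idx])
      step <- step + 1
      for (pn in pars) {
        m[[pn]] <- beta1 * m[[pn]] + (1 - beta1) * g[[pn]]
        v[[pn]] <- beta2 * v[[pn]] + (1 - beta2) * g[[pn]]^2
        mh <- m[[pn]] / (1 - beta1^step)
        vh <- v[[pn]] / (1 - beta2^step)
        net[[pn]] <- net[[pn]] - lr * mh / (sqrt(vh) + eps)
      }
    }
    loss <- mean(losses)
  }
  list(net = net, final_loss = loss)
}
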