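## Minimal multilayer perceptron with Adam, written in base R matrix algebra.
## Fixed architecture: `depth` equally wide ReLU hidden layers and a 2-class
## softmax output trained with cross-entropy. All stochastic steps
## (initialisation, epoch shuffling) derive from one explicit seed, so a
## fit is bit-reproducible on one machine.

.mlp_init <- function(d_in, width, depth, d_out, seed) {
  set.seed(seed)
  dims <- c(d_in, rep(width, depth), d_out)
  W <- vector("list", length(dims) - 1L)
  b <- vector("list", length(dims) - 1L)
  for (l in seq_along(W)) {
    ## He initialisation, suited to ReLU hidden units
    W[[l]] <- matrix(stats::rnorm(dims[l] * dims[l + 1L],
                                  sd = sqrt(2 / dims[l])),
                     dims[l], dims[l + 1L])
    b[[l]] <- rep(0, dims[l + 1L])
  }
  list(W = W, b = b)
}

.mlp_forward <- function(par, X) {
  L <- length(par$W)
  acts <- vector("list", L + 1L)
  acts[[1L]] <- X
  for (l in seq_len(L - 1L)) {
    Z <- sweep(acts[[l]] %*% par$W[[l]], 2L, par$b[[l]], "+")
    acts[[l + 1L]] <- pmax(Z, 0)
  }
  logits <- sweep(acts[[L]] %*% par$W[[L]], 2L, par$b[[L]], "+")
  ## numerically stable softmax
  logits <- logits - apply(logits, 1L, max)
  expl <- exp(logits)
  probs <- expl / rowSums(expl)
  list(acts = acts, probs = probs)
}

## One Adam update from a mini-batch. Y is an n x 2 one-hot matrix.
.mlp_backward <- function(par, fw, Y) {
  L <- length(par$W)
  n <- nrow(Y)
  grads_W <- vector("list", L)
  grads_b <- vector("list", L)
  delta <- (fw$probs - Y) / n            # softmax + cross-entropy gradient
  for (l in rev(seq_len(L))) {
    grads_W[[l]] <- crossprod(fw$acts[[l]], delta)
    grads_b[[l]] <- colSums(delta)
    if (l > 1L) {
      delta <- (delta %*% t(par$W[[l]])) * (fw$acts[[l]] > 0)
    }
  }
  list(W = grads_W, b = grads_b)
}

.mlp_train <- function(X, y01, width, depth, epochs, batch_size, seed,
                       lr = 1e-3, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  n <- nrow(X)
  Y <- cbind(1 - y01, y01)             # column 1 = class 0, column 2 = class 1
  par <- .mlp_init(ncol(X), width, depth, 2L, seed)
  mW <- lapply(par$W, function(w) w * 0); vW <- mW
  mb <- lapply(par$b, function(b) b * 0); vb <- mb
  step <- 0L
  set.seed(seed + 1L)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    starts <- seq(1L, n, by = batch_size)
    for (s in starts) {
      idx <- ord[s:min(s + batch_size - 1L, n)]
      fw <- .mlp_forward(par, X[idx, , drop = FALSE])
      gr <- .mlp_backward(par, fw, Y[idx, , drop = FALSE])
      step <- step + 1L
      c1 <- 1 - beta1^step
      c2 <- 1 - beta2^step
      for (l in seq_along(par$W)) {
        mW[[l]] <- beta1 * mW[[l]] + (1 - beta1) * gr$W[[l]]
        vW[[l]] <- beta2 * vW[[l]] + (1 - beta2) * gr$W[[l]]^2
        par$W[[l]] <- par$W[[l]] -
          lr * (mW[[l]] / c1) / (sqrt(vW[[l]] / c2) + eps)
        mb[[l]] <- beta1 * mb[[l]] + (1 - beta1) * gr$b[[l]]
        vb[[l]] <- beta2 * vb[[l]] + (1 - beta2) * gr$b[[l]]^2
        par$b[[l]] <- par$b[[l]] -
          lr * (mb[[l]] / c1) / (sqrt(vb[[l]] / c2) + eps)
      }
    }
  }
  par
}

.mlp_predict01 <- function(par, X) {
  fw <- .mlp_forward(par, as.matrix(X))
  as.integer(fw$probs[, 2L] > 0.5)
}
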