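# Multilayer perceptron for binary classification, written as plain R
# matrix operations: ReLU hidden layers, a single sigmoid output unit,
# cross-entropy loss with L2 weight decay, mini-batch Adam.

mlp_init <- function(d, hidden) {
  sizes <- c(d, hidden, 1L)
  lapply(seq_len(length(sizes) - 1), function(k) {
    fan_in <- sizes[k]; fan_out <- sizes[k + 1]
    lim <- sqrt(6 / (fan_in + fan_out))
    list(W = matrix(runif(fan_in * fan_out, -lim, lim), fan_in, fan_out),
         b = rep(0, fan_out))
  })
}

mlp_forward <- function(layers, X) {
  acts <- vector("list", length(layers) + 1)
  acts[[1]] <- X
  A <- X
  for (k in seq_along(layers)) {
    Z <- A %*% layers[[k]]$W
    Z <- sweep(Z, 2, layers[[k]]$b, "+")
    A <- if (k < length(layers)) pmax(Z, 0) else 1 / (1 + exp(-Z))
    acts[[k + 1]] <- A
  }
  acts
}

mlp_fit <- function(X, y01, hidden = c(128, 128), learning_rate = 1e-3,
                    alpha = 1e-4, batch_size = 200, epochs = 100) {
  n <- nrow(X); d <- ncol(X)
  layers <- mlp_init(d, hidden)
  mw <- lapply(layers, function(l) list(W = 0 * l$W, b = 0 * l$b))
  vw <- mw
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  step <- 0
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    starts <- seq(1, n, by = batch_size)
    for (s in starts) {
      idx <- ord[s:min(s + batch_size - 1, n)]
      Xb <- X[idx, , drop = FALSE]
      yb <- y01[idx]
      m <- length(idx)
      acts <- mlp_forward(layers, Xb)
      # output delta for sigmoid + cross-entropy
      delta <- (acts[[length(acts)]] - yb) / m
      grads <- vector("list", length(layers))
      for (k in rev(seq_along(layers))) {
        grads[[k]] <- list(
          W = crossprod(acts[[k]], delta) + alpha * layers[[k]]$W,
          b = colSums(delta)
        )
        if (k > 1) {
          delta <- (delta %*% t(layers[[k]]$W)) * (acts[[k]] > 0)
        }
      }
      step <- step + 1
      for (k in seq_along(layers)) {
        for (nm in c("W", "b")) {
          g <- grads[[k]][[nm]]
          mw[[k]][[nm]] <- b1 * mw[[k]][[nm]] + (1 - b1) * g
          vw[[k]][[nm]] <- b2 * vw[[k]][[nm]] + (1 - b2) * g * g
          mhat <- mw[[k]][[nm]] / (1 - b1^step)
          vhat <- vw[[k]][[nm]] / (1 - b2^step)
          layers[[k]][[nm]] <- layers[[k]][[nm]] -
            learning_rate * mhat / (sqrt(vhat) + eps)
        }
      }
    }
  }
  layers
}

mlp_prob <- function(layers, X) {
  acts <- mlp_forward(layers, X)
  as.numeric(acts[[length(acts)]])
}
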