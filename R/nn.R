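# Minimal 1D convolutional network engine backing the adversarial generator
# and the recognition ensemble. Signals travel as arrays (length x channels x
# batch) through conv/pool stages and as matrices (features x batch) through
# dense stages. All randomness (initialization, shuffling, dropout) uses R's
# RNG so callers get bit-reproducible runs under withr::with_seed().

# slope: fused leaky-rectifier after the convolution (1 = linear, 0 = ReLU)
layer_conv <- function(cin, cout, k, slope = 1) {
  stopifnot(k %% 2 == 1)
  list(type = "conv", k = k, cin = cin, cout = cout, slope = slope,
       W = matrix(rnorm(cout * k * cin, sd = sqrt(2 / (k * cin))), cout, k * cin),
       b = numeric(cout))
}

layer_dense <- function(nin, nout) {
  list(type = "dense", W = matrix(rnorm(nout * nin, sd = sqrt(2 / nin)), nout, nin),
       b = numeric(nout))
}

layer_lrelu <- function(slope = 0.2) list(type = "lrelu", slope = slope)
layer_relu <- function() layer_lrelu(0)
layer_maxpool <- function(size = 2L) list(type = "maxpool", size = as.integer(size))
layer_flatten <- function() list(type = "flatten")
layer_dropout <- function(rate) list(type = "dropout", rate = rate)
layer_tanh <- function() list(type = "tanh")

nn_forward <- function(layers, x, training = FALSE) {
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    res <- switch(l$type,
      conv = {
        if (length(dim(x)) != 3) dim(x) <- c(nrow(x), 1L, ncol(x))
        out <- conv1d_fwd(x, l$W, l$b, l$k, l$slope)
        list(out = out, cache = list(x = x, out = out))
      },
      dense = list(out = l$W %*% x + l$b, cache = x),
      lrelu = {
        fac <- l$slope + (1 - l$slope) * (x > 0)
        list(out = x * fac, cache = fac)
      },
      maxpool = {
        d <- dim(x)
        s <- l$size
        a <- x
        dim(a) <- c(s, length(a) / s)
        m <- a[1, ]
        wh <- rep(1L, ncol(a))
        for (j in seq_len(s)[-1]) {
          up <- a[j, ] > m
          m[up] <- a[j, up]
          wh[up] <- j
        }
        out <- m
        dim(out) <- c(d[1] / s, d[2], d[3])
        list(out = out, cache = list(wh = wh, dims = d))
      },
      flatten = {
        d <- dim(x)
        out <- x
        dim(out) <- c(d[1] * d[2], d[3])
        list(out = out, cache = d)
      },
      dropout = {
        if (training && l$rate > 0) {
          mask <- (runif(length(x)) >= l$rate) / (1 - l$rate)
          list(out = x * mask, cache = mask)
        } else {
          list(out = x, cache = NULL)
        }
      },
      tanh = {
        out <- tanh(x)
        list(out = out, cache = out)
      },
      stop("unknown layer type ", l$type)
    )
    x <- res$out
    caches[[i]] <- res$cache
  }
  list(out = x, caches = caches)
}

# Returns list(grads = per-layer list(W, b) or NULL, dx = input gradient)
nn_backward <- function(layers, caches, dout) {
  grads <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    l <- layers[[i]]
    c_i <- caches[[i]]
    dout <- switch(l$type,
      conv = {
        g <- conv1d_bwd(c_i$x, l$W, c_i$out, dout, l$k, l$slope)
        grads[[i]] <- list(W = g$dW, b = as.numeric(g$db))
        g$dx
      },
      dense = {
        grads[[i]] <- list(W = dout %*% t(c_i), b = rowSums(dout))
        crossprod(l$W, dout)
      },
      lrelu = dout * c_i,
      maxpool = {
        d <- c_i$dims
        s <- l$size
        dx <- matrix(0, s, length(c_i$wh))
        dx[cbind(c_i$wh, seq_along(c_i$wh))] <- as.numeric(dout)
        dim(dx) <- d
        dx
      },
      flatten = {
        dim(dout) <- c_i
        dout
      },
      dropout = {
        if (is.null(c_i)) dout else dout * c_i
      },
      tanh = dout * (1 - c_i^2)
    )
  }
  list(grads = grads, dx = dout)
}

adam_init <- function(layers) {
  list(t = 0L, m = purrr::map(layers, function(l) {
    if (!is.null(l$W)) list(W = l$W * 0, b = l$b * 0) else NULL
  }), v = purrr::map(layers, function(l) {
    if (!is.null(l$W)) list(W = l$W * 0, b = l$b * 0) else NULL
  }))
}

adam_step <- function(layers, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (i in seq_along(layers)) {
    g <- grads[[i]]
    if (is.null(g)) next
    for (p in c("W", "b")) {
      state$m[[i]][[p]] <- beta1 * state$m[[i]][[p]] + (1 - beta1) * g[[p]]
      state$v[[i]][[p]] <- beta2 * state$v[[i]][[p]] + (1 - beta2) * g[[p]]^2
      mhat <- state$m[[i]][[p]] / bc1
      vhat <- state$v[[i]][[p]] / bc2
      layers[[i]][[p]] <- layers[[i]][[p]] - lr * mhat / (sqrt(vhat) + eps)
    }
  }
  list(layers = layers, state = state)
}

softmax_probs <- function(logits) {
  z <- sweep(logits, 2, apply(logits, 2, max))
  e <- exp(z)
  sweep(e, 2, colSums(e), "/")
}

# y: integer class labels in 1..K; logits: (K x B)
softmax_ce <- function(logits, y) {
  p <- softmax_probs(logits)
  B <- ncol(logits)
  idx <- cbind(y, seq_len(B))
  loss <- -mean(log(pmax(p[idx], 1e-12)))
  dlog <- p
  dlog[idx] <- dlog[idx] - 1
  list(loss = loss, grad = dlog / B, probs = p)
}

# logits: (1 x B); target: scalar or length-B vector in [0, 1]
sigmoid_bce <- function(logits, target) {
  s <- 1 / (1 + exp(-logits))
  t <- rep_len(target, length(logits))
  loss <- -mean(t * log(pmax(s, 1e-12)) + (1 - t) * log(pmax(1 - s, 1e-12)))
  list(loss = loss, grad = matrix((s - t) / length(s), nrow = 1))
}
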