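# Independent direct-formula implementations used as oracles, plus shared
# tiny fixtures. Oracles are deliberately naive (explicit loops) and never
# call the code paths they check.

# epsilon rule, one dense layer, explicit loops
oracle_epsilon <- function(a, w, b, R, eps = 0) {
  J <- length(a); K <- length(R)
  z <- numeric(K)
  for (k in 1:K) z[k] <- sum(a * w[, k]) + b[k]
  out <- numeric(J)
  for (j in 1:J) for (k in 1:K) {
    zs <- z[k] + eps * ifelse(z[k] >= 0, 1, -1)
    out[j] <- out[j] + a[j] * w[j, k] / zs * R[k]
  }
  out
}

# alpha-beta rule, one dense layer, explicit loops (bias share absorbed)
oracle_alphabeta <- function(a, w, b, R, alpha = 1, beta = 0) {
  J <- length(a); K <- length(R)
  out <- numeric(J)
  for (k in 1:K) {
    zp <- max(b[k], 0); zn <- min(b[k], 0)
    cp <- numeric(J); cn <- numeric(J)
    for (j in 1:J) {
      v <- a[j] * w[j, k]
      if (v >= 0) { cp[j] <- v; zp <- zp + v } else { cn[j] <- v; zn <- zn + v }
    }
    for (j in 1:J) {
      if (zp != 0) out[j] <- out[j] + alpha * cp[j] / zp * R[k]
      if (zn != 0) out[j] <- out[j] - beta * cn[j] / zn * R[k]
    }
  }
  out
}

# dense-layer equivalent of a small convolution: explicit weight matrix
conv_as_dense <- function(x_hw, w_k, pad = 0) {
  H <- nrow(x_hw); W <- ncol(x_hw)
  kh <- dim(w_k)[1]; kw <- dim(w_k)[2]
  Ho <- H + 2 * pad - kh + 1; Wo <- W + 2 * pad - kw + 1
  Wd <- matrix(0, H * W, Ho * Wo)
  for (wo in 1:Wo) for (ho in 1:Ho) {
    oc <- ho + Ho * (wo - 1)
    for (dj in 1:kw) for (di in 1:kh) {
      ii <- ho - pad + (kh - di)   # flipped-kernel orientation
      jj <- wo - pad + (kw - dj)
      if (ii >= 1 && ii <= H && jj >= 1 && jj <= W)
        Wd[ii + H * (jj - 1), oc] <- Wd[ii + H * (jj - 1), oc] + w_k[di, dj]
    }
  }
  Wd
}

# tiny labelled dataset with a class-dependent localized bump
tiny_bump_dataset <- function(n = 60, len = 32, chans = 4, seed = 42) {
  withr::with_seed(seed, {
    x <- array(rnorm(n * len * chans, 0, 0.3), c(n, len, chans))
    lab <- rep(c("a", "b"), length.out = n)
    for (i in 1:n) {
      pos <- if (lab[i] == "a") 5 else 20
      x[i, pos:(pos + 6), ] <- x[i, pos:(pos + 6), ] + 1.5
    }
    ds <- gait_dataset(x, factor(lab), paste0("s", rep(1:6, length.out = n)),
                       sample_rate = 100)
    split_dataset(standardize(ds), seed = 1)
  })
}

tiny_parallel_graph <- function(input_shape, n_classes) {
  build_architecture("parallel", input_shape, n_classes,
                     list(filters = 2, dense_units = 8,
                          pool = c(2, 2), pool2 = c(2, 2)))
}

make_model <- function(graph, seed = 1) {
  structure(list(graph = graph,
                 weights = gaitxai:::init_weights(graph, seed),
                 classes = as.character(seq_len(graph$n_classes))),
            class = "trained_model")
}

# zero every bias (and neutralize batchnorm) so conservation is exact
zero_biases <- function(model) {
  for (id in names(model$weights)) {
    wb <- model$weights[[id]]
    if (!is.null(wb$b)) model$weights[[id]]$b <- wb$b * 0
    if (!is.null(wb$beta)) {
      model$weights[[id]]$beta <- wb$beta * 0
      model$weights[[id]]$gamma <- wb$gamma * 0 + 1
      model$weights[[id]]$running_mean <- wb$running_mean * 0
      model$weights[[id]]$running_var <- wb$running_var * 0 + 1
    }
  }
  model
}
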