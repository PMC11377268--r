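#' Forward pass through a layer graph
#'
#' Evaluates the graph on a batch of windows, optionally retaining every
#' node's activations (needed by relevance propagation). The forward pass is
#' purely functional in inference mode: batch normalization uses its running
#' moments and dropout is the identity.
#'
#' @param model A [train()]ed model, or a list with `graph` and `weights`.
#' @param x Input: a `(n, window_len, n_channels)` array, a single
#'   `window_len x n_channels` matrix, or a [gait_dataset()].
#' @param training Use batch statistics and dropout (training mode).
#' @param cache Keep per-node activations.
#' @return List with `logits` (n x K, pre-softmax scores), `probs`
#'   (softmax), and when `cache = TRUE` the activation cache (`acts`,
#'   `extra`).
#' @export
forward <- function(model, x, training = FALSE, cache = FALSE) {
  graph <- model$graph; weights <- model$weights
  xin <- as_input_array(x, graph$input_shape)
  acts <- list(); extra <- list()
  for (nd in graph$nodes) {
    p <- if (length(nd$parents)) acts[[nd$parents[1]]]
    out <- switch(nd$kind,
      input = xin,
      conv2d = {
        pd <- conv_padding(nd$params$kernel[1], nd$params$kernel[2],
                           nd$params$padding)
        y <- cpp_conv2d_fw(p, weights[[nd$id]]$w, weights[[nd$id]]$b,
                           nd$params$stride[1], nd$params$stride[2],
                           pd[1], pd[2])
        if (nd$params$activation == "relu") y[y < 0] <- 0
        y
      },
      avgpool = , maxpool = {
        res <- cpp_pool_fw(p, nd$params$window[1], nd$params$window[2],
                           if (nd$kind == "maxpool") 1L else 0L)
        if (nd$kind == "maxpool") extra[[nd$id]] <- res$switches
        res$y
      },
      flatten = {
        d <- dim(p)
        t(matrix(p, prod(d[1:3]), d[4]))
      },
      concat = {
        parts <- lapply(nd$parents, function(q) acts[[q]])
        d1 <- dim(parts[[1]])
        cs <- vapply(parts, function(a) dim(a)[3], numeric(1))
        out <- array(0, c(d1[1], d1[2], sum(cs), d1[4]))
        at <- 0
        for (a in parts) {
          out[, , at + seq_len(dim(a)[3]), ] <- a
          at <- at + dim(a)[3]
        }
        out
      },
      dense = {
        y <- p %*% weights[[nd$id]]$w
        y <- sweep(y, 2, weights[[nd$id]]$b, "+")
        if (nd$params$activation == "relu") y[y < 0] <- 0
        y
      },
      batchnorm = {
        wb <- weights[[nd$id]]; eps <- nd$params$eps
        if (training) {
          bm <- colMeans(p)
          bv <- colMeans(sweep(p, 2, bm)^2)
          istd <- 1 / sqrt(bv + eps)
          xhat <- sweep(sweep(p, 2, bm), 2, istd, "*")
          extra[[nd$id]] <- list(bm = bm, bv = bv, istd = istd, xhat = xhat)
          sweep(sweep(xhat, 2, wb$gamma, "*"), 2, wb$beta, "+")
        } else {
          istd <- 1 / sqrt(wb$running_var + eps)
          xhat <- sweep(sweep(p, 2, wb$running_mean), 2, istd, "*")
          sweep(sweep(xhat, 2, wb$gamma, "*"), 2, wb$beta, "+")
        }
      },
      dropout = {
        if (training && nd$params$rate > 0) {
          mask <- (matrix(runif(length(p)), nrow(p)) >= nd$params$rate) /
            (1 - nd$params$rate)
          extra[[nd$id]] <- mask
          p * mask
        } else p
      },
      softmax = {
        z <- p - apply(p, 1, max)
        e <- exp(z)
        e / rowSums(e)
      })
    acts[[nd$id]] <- out
  }
  logits_id <- logits_node(graph)
  res <- list(logits = acts[[logits_id]], probs = acts[[length(acts)]],
              classes = NULL)
  if (cache) { res$acts <- acts; res$extra <- extra }
  res
}

logits_node <- function(graph) {
  sm <- Filter(function(nd) nd$kind == "softmax", graph$nodes)
  if (length(sm) != 1) abort("graph must have exactly one softmax node")
  sm[[1]]$parents[1]
}

as_input_array <- function(x, input_shape) {
  if (inherits(x, "gait_dataset")) x <- x$values
  if (is.matrix(x)) x <- array(x, c(1, dim(x)))
  if (length(dim(x)) != 3) abort("input must be (n, window_len, n_channels)")
  d <- dim(x)
  if (!all(d[2:3] == input_shape[1:2]))
    abort(sprintf("input windows are %dx%d but the graph expects %dx%d",
                  d[2], d[3], input_shape[1], input_shape[2]))
  a <- aperm(x, c(2, 3, 1))
  dim(a) <- c(d[2], d[3], 1L, d[1])
  a
}

# Backward pass. relu_mode selects the ReLU backward used by gradient
# saliency variants: "grad" (standard: gate by forward activation),
# "deconvnet" (gate by upstream gradient sign), "guided" (both gates).
# In inference mode batchnorm is linear and dropout is the identity.
backward <- function(model, fw, dlogits, training = FALSE,
                     need_param_grads = TRUE, relu_mode = "grad") {
  graph <- model$graph; weights <- model$weights
  acts <- fw$acts; extra <- fw$extra
  d <- list(); grads <- list()
  d[[logits_node(graph)]] <- dlogits
  for (i in rev(seq_along(graph$nodes))) {
    nd <- graph$nodes[[i]]
    if (nd$kind %in% c("softmax", "input")) next
    dout <- d[[nd$id]]
    if (is.null(dout)) next
    p <- nd$parents[1]
    xin <- acts[[p]]
    if (nd$kind %in% c("conv2d", "dense") && nd$params$activation == "relu")
      dout <- relu_backward(dout, acts[[nd$id]], relu_mode)
    if (nd$kind == "conv2d") {
      pd <- conv_padding(nd$params$kernel[1], nd$params$kernel[2],
                         nd$params$padding)
      bw <- cpp_conv2d_bw(xin, weights[[nd$id]]$w, dout,
                          nd$params$stride[1], nd$params$stride[2],
                          pd[1], pd[2], TRUE, need_param_grads)
      if (need_param_grads)
        grads[[nd$id]] <- list(w = bw$dw, b = bw$db)
      d[[p]] <- acc(d[[p]], bw$dx)
    } else if (nd$kind == "dense") {
      if (need_param_grads)
        grads[[nd$id]] <- list(w = crossprod(xin, dout), b = colSums(dout))
      d[[p]] <- acc(d[[p]], dout %*% t(weights[[nd$id]]$w))
    } else if (nd$kind %in% c("avgpool", "maxpool")) {
      s <- dim(xin)
      dx <- cpp_pool_bw(dout, if (nd$kind == "maxpool") extra[[nd$id]]
                        else integer(), s[1], s[2], s[3],
                        nd$params$window[1], nd$params$window[2],
                        if (nd$kind == "maxpool") 1L else 0L)
      d[[p]] <- acc(d[[p]], dx)
    } else if (nd$kind == "flatten") {
      dx <- array(t(dout), dim(xin))
      d[[p]] <- acc(d[[p]], dx)
    } else if (nd$kind == "concat") {
      at <- 0
      for (q in nd$parents) {
        ci <- dim(acts[[q]])[3]
        d[[q]] <- acc(d[[q]], dout[, , at + seq_len(ci), , drop = FALSE])
        at <- at + ci
      }
    } else if (nd$kind == "batchnorm") {
      wb <- weights[[nd$id]]
      if (training) {
        ex <- extra[[nd$id]]; n <- nrow(dout)
        dxhat <- sweep(dout, 2, wb$gamma, "*")
        if (need_param_grads)
          grads[[nd$id]] <- list(gamma = colSums(dout * ex$xhat),
                                 beta = colSums(dout))
        dx <- sweep(dxhat -
                      matrix(colMeans(dxhat), n, ncol(dout), byrow = TRUE) -
                      sweep(ex$xhat, 2, colMeans(dxhat * ex$xhat), "*"),
                    2, ex$istd, "*")
        d[[p]] <- acc(d[[p]], dx)
      } else {
        istd <- 1 / sqrt(wb$running_var + nd$params$eps)
        d[[p]] <- acc(d[[p]], sweep(dout, 2, wb$gamma * istd, "*"))
      }
    } else if (nd$kind == "dropout") {
      dx <- if (training && !is.null(extra[[nd$id]]))
        dout * extra[[nd$id]] else dout
      d[[p]] <- acc(d[[p]], dx)
    }
  }
  list(grads = grads, dx = d[["input"]])
}

relu_backward <- function(dout, out, mode) {
  switch(mode,
    grad = dout * (out > 0),
    deconvnet = dout * (dout > 0),
    guided = dout * (dout > 0) * (out > 0),
    abort(paste0("unknown relu mode: ", mode)))
}

acc <- function(a, b) if (is.null(a)) b else a + b

#' Predict classes or probabilities
#'
#' @param object A trained model.
#' @param newdata A [gait_dataset()], array or matrix of windows.
#' @param type `"class"`, `"prob"` or `"logit"`.
#' @param ... Unused.
#' @return Factor of predicted classes, or a numeric matrix.
#' @method predict trained_model
#' @export
predict.trained_model <- function(object, newdata,
                                  type = c("class", "prob", "logit"), ...) {
  type <- match.arg(type)
  fw <- forward(object, newdata)
  if (type == "logit") return(fw$logits)
  if (type == "prob") {
    colnames(fw$probs) <- object$classes
    return(fw$probs)
  }
  factor(object$classes[max.col(fw$probs, ties.method = "first")],
         levels = object$classes)
}
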