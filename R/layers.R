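#' Typed layer graph
#'
#' A directed acyclic graph of typed layers -- the single representation the
#' forward pass, training and relevance propagation all operate on. Nodes
#' are stored in topological order; every node names its parents. Supported
#' kinds: `input`, `conv2d`, `avgpool`, `maxpool`, `dense`, `flatten`,
#' `concat`, `batchnorm`, `dropout`, `softmax`. Activation functions are
#' monotonically increasing nonlinearities; ReLU is the default.
#'
#' Windows enter as `window_len x n_channels` matrices and are treated as
#' one-channel 2-d images (time x sensor); convolution follows the
#' flipped-kernel (true convolution) orientation.
#'
#' @name layer_graph
NULL

new_layer_graph <- function(input_shape, n_classes, architecture_name) {
  structure(list(nodes = list(), input_shape = input_shape,
                 n_classes = n_classes,
                 architecture_name = architecture_name),
            class = "layer_graph")
}

add_node <- function(graph, id, kind, parents = character(), ...) {
  if (id %in% names(graph$nodes)) abort(paste0("duplicate node id: ", id))
  missing <- setdiff(parents, names(graph$nodes))
  if (length(missing))
    abort(paste0("unknown parent(s): ", paste(missing, collapse = ", ")))
  graph$nodes[[id]] <- list(id = id, kind = kind, parents = parents,
                            params = list(...))
  graph
}

#' @export
print.layer_graph <- function(x, ...) {
  cat(sprintf("<layer_graph> %s: %d nodes, %d stacked layers, input %s, %d classes\n",
              x$architecture_name, length(x$nodes), stacked_layer_count(x),
              paste(x$input_shape, collapse = "x"), x$n_classes))
  for (nd in x$nodes) {
    sh <- nd$out_shape
    cat(sprintf("  %-14s %-9s <- %-24s out %s\n", nd$id, nd$kind,
                paste(nd$parents, collapse = ","),
                paste(sh, collapse = "x")))
  }
  invisible(x)
}

#' Count stacked layers
#'
#' The architecture-size convention counts convolution, pooling and dense
#' layers; normalization, dropout, reshaping and concatenation nodes do not
#' add depth.
#'
#' @param graph A [build_architecture()] graph.
#' @return Integer stacked-layer count.
#' @export
stacked_layer_count <- function(graph) {
  sum(vapply(graph$nodes, function(nd)
    nd$kind %in% c("conv2d", "avgpool", "maxpool", "dense"), logical(1)))
}

conv_padding <- function(kh, kw, mode) {
  if (mode == "valid") return(c(0L, 0L))
  if (kh %% 2 == 0 || kw %% 2 == 0)
    abort("'same' padding requires odd kernel dimensions")
  c((kh - 1L) %/% 2L, (kw - 1L) %/% 2L)
}

# annotate every node with its output shape; spatial shapes are c(H, W, C),
# vector shapes are a single length.
propagate_shapes <- function(graph) {
  for (i in seq_along(graph$nodes)) {
    nd <- graph$nodes[[i]]
    pshapes <- lapply(nd$parents, function(p) graph$nodes[[p]]$out_shape)
    sh <- switch(nd$kind,
      input = graph$input_shape,
      conv2d = {
        s <- pshapes[[1]]
        pd <- conv_padding(nd$params$kernel[1], nd$params$kernel[2],
                           nd$params$padding)
        st <- nd$params$stride
        ho <- (s[1] + 2 * pd[1] - nd$params$kernel[1]) %/% st[1] + 1L
        wo <- (s[2] + 2 * pd[2] - nd$params$kernel[2]) %/% st[2] + 1L
        if (ho < 1 || wo < 1) abort(paste0("kernel does not fit at ", nd$id))
        c(ho, wo, nd$params$filters)
      },
      avgpool = , maxpool = {
        s <- pshapes[[1]]
        w <- nd$params$window
        out <- c(s[1] %/% w[1], s[2] %/% w[2], s[3])
        if (any(out[1:2] < 1)) abort(paste0("pool window too large at ", nd$id))
        out
      },
      flatten = prod(pshapes[[1]]),
      concat = {
        hs <- vapply(pshapes, `[`, numeric(1), 1)
        ws <- vapply(pshapes, `[`, numeric(1), 2)
        if (length(unique(hs)) > 1 || length(unique(ws)) > 1)
          abort(paste0("concat parents disagree on spatial shape at ", nd$id))
        c(hs[1], ws[1], sum(vapply(pshapes, `[`, numeric(1), 3)))
      },
      dense = nd$params$units,
      batchnorm = , dropout = pshapes[[1]],
      softmax = pshapes[[1]],
      abort(paste0("unknown layer kind: ", nd$kind)))
    graph$nodes[[i]]$out_shape <- as.integer(sh)
  }
  graph
}

#' Build one of the gait CNN architectures
#'
#' Three convolutional architectures over `window_len x n_channels` inputs:
#'
#' * `"single"` -- a linear chain of four convolution + average-pooling
#'   pairs and a two-layer dense head: 10 stacked layers.
#' * `"parallel"` -- two inception-style stages; each stage runs four
#'   parallel convolution(+pool) streams with mixed kernel shapes and fuses
#'   them by channel concatenation: 18 stacked layers.
#' * `"quadruplet"` -- four parallel streams with independent weights, two
#'   max-pooling and two average-pooling paths, fused by concatenation.
#'
#' All heads share flatten -> batch normalization -> dropout ->
#' dense(ReLU) -> dense(linear) -> softmax. Filter counts and kernel sizes
#' are configurable through `hyperparams` (the counts are not canonical and
#' default to small values suitable for CPU training).
#'
#' @param name `"single"`, `"parallel"` or `"quadruplet"`.
#' @param input_shape `c(window_len, n_channels)`.
#' @param n_classes Number of output classes.
#' @param hyperparams Optional list: `filters` (per conv for `single`, per
#'   stream otherwise), `dense_units`, `dropout_rate`, `pool` (window),
#'   `kernels` (list of kernel shapes for the parallel streams).
#' @return A `layer_graph` with shapes propagated.
#' @export
build_architecture <- function(name = c("single", "parallel", "quadruplet"),
                               input_shape, n_classes,
                               hyperparams = list()) {
  name <- match.arg(name)
  hp <- utils::modifyList(switch(name,
    single = list(filters = c(16, 32, 64, 64), dense_units = 64,
                  dropout_rate = 0.3, pool = c(2, 2)),
    parallel = list(filters = 8, dense_units = 32, dropout_rate = 0.3,
                    pool = c(4, 2), pool2 = c(4, 2),
                    kernels = list(c(7, 3), c(9, 1), c(5, 3), c(1, 5)),
                    kernels2 = list(c(3, 3), c(3, 1), c(1, 3), c(3, 3))),
    quadruplet = list(filters = 16, dense_units = 32, dropout_rate = 0.3,
                      pool = c(4, 2))), hyperparams)
  g <- new_layer_graph(c(as.integer(input_shape), 1L), as.integer(n_classes),
                       name)
  g <- add_node(g, "input", "input")
  top <- "input"

  if (name == "single") {
    f <- rep_len(hp$filters, 4)
    for (i in 1:4) {
      g <- add_node(g, paste0("conv", i), "conv2d", top, kernel = c(3L, 3L),
                    filters = f[i], stride = c(1L, 1L), padding = "same",
                    activation = "relu")
      g <- add_node(g, paste0("pool", i), "avgpool", paste0("conv", i),
                    window = as.integer(hp$pool))
      top <- paste0("pool", i)
    }
  } else if (name == "parallel") {
    f <- rep_len(hp$filters, 4)
    for (stage in 1:2) {
      outs <- character()
      for (s in 1:4) {
        cid <- sprintf("s%d_conv%d", stage, s)
        pid <- sprintf("s%d_pool%d", stage, s)
        kern <- if (stage == 1) hp$kernels[[s]] else
          (hp$kernels2 %||% hp$kernels)[[s]]
        g <- add_node(g, cid, "conv2d", top,
                      kernel = as.integer(kern), filters = f[s],
                      stride = c(1L, 1L), padding = "same",
                      activation = "relu")
        pw <- if (stage == 1) hp$pool else (hp$pool2 %||% hp$pool)
        g <- add_node(g, pid, "avgpool", cid, window = as.integer(pw))
        outs <- c(outs, pid)
      }
      g <- add_node(g, paste0("concat", stage), "concat", outs)
      top <- paste0("concat", stage)
    }
  } else {
    f <- rep_len(hp$filters, 4)
    pool_kind <- c("maxpool", "maxpool", "avgpool", "avgpool")
    outs <- character()
    for (s in 1:4) {
      c1 <- sprintf("q%d_conv1", s); p1 <- sprintf("q%d_pool1", s)
      c2 <- sprintf("q%d_conv2", s); p2 <- sprintf("q%d_pool2", s)
      g <- add_node(g, c1, "conv2d", "input", kernel = c(3L, 3L),
                    filters = f[s], stride = c(1L, 1L), padding = "same",
                    activation = "relu")
      g <- add_node(g, p1, pool_kind[s], c1, window = as.integer(hp$pool))
      g <- add_node(g, c2, "conv2d", p1, kernel = c(3L, 3L), filters = f[s],
                    stride = c(1L, 1L), padding = "same",
                    activation = "relu")
      g <- add_node(g, p2, pool_kind[s], c2, window = c(2L, 2L))
      outs <- c(outs, p2)
    }
    g <- add_node(g, "concat", "concat", outs)
    top <- "concat"
  }

  g <- add_node(g, "flatten", "flatten", top)
  g <- add_node(g, "bn", "batchnorm", "flatten", momentum = 0.9, eps = 1e-5)
  g <- add_node(g, "drop", "dropout", "bn", rate = hp$dropout_rate)
  g <- add_node(g, "fc1", "dense", "drop", units = as.integer(hp$dense_units),
                activation = "relu")
  g <- add_node(g, "logits", "dense", "fc1", units = as.integer(n_classes),
                activation = "linear")
  g <- add_node(g, "softmax", "softmax", "logits")
  propagate_shapes(g)
}

#' Build a linear softmax classifier graph
#'
#' Flattened windows into a single dense layer -- the "linear model trained
#' by stochastic gradient descent" baseline, expressed in the same layer
#' graph so it shares the training loop.
#'
#' @inheritParams build_architecture
#' @return A `layer_graph`.
#' @export
build_linear_baseline <- function(input_shape, n_classes) {
  g <- new_layer_graph(c(as.integer(input_shape), 1L), as.integer(n_classes),
                       "linear")
  g <- add_node(g, "input", "input")
  g <- add_node(g, "flatten", "flatten", "input")
  g <- add_node(g, "logits", "dense", "flatten",
                units = as.integer(n_classes), activation = "linear")
  g <- add_node(g, "softmax", "softmax", "logits")
  propagate_shapes(g)
}

# Glorot-uniform weights, zero biases; batchnorm starts at identity.
init_weights <- function(graph, seed = 1L) {
  local_seed(derive_seed(seed, 7L), {
    w <- list()
    for (nd in graph$nodes) {
      pshape <- if (length(nd$parents))
        graph$nodes[[nd$parents[1]]]$out_shape
      if (nd$kind == "conv2d") {
        kh <- nd$params$kernel[1]; kw <- nd$params$kernel[2]
        cin <- pshape[3]; cout <- nd$params$filters
        lim <- sqrt(6 / (kh * kw * cin + kh * kw * cout))
        w[[nd$id]] <- list(
          w = array(runif(kh * kw * cin * cout, -lim, lim),
                    c(kh, kw, cin, cout)),
          b = numeric(cout))
      } else if (nd$kind == "dense") {
        fin <- pshape[1]; fout <- nd$params$units
        lim <- sqrt(6 / (fin + fout))
        w[[nd$id]] <- list(w = matrix(runif(fin * fout, -lim, lim), fin, fout),
                           b = numeric(fout))
      } else if (nd$kind == "batchnorm") {
        f <- pshape[1]
        w[[nd$id]] <- list(gamma = rep(1, f), beta = numeric(f),
                           running_mean = numeric(f), running_var = rep(1, f))
      }
    }
    w
  })
}

#' Total trainable parameter count
#' @param model A trained model or a list of weight arrays.
#' @return Integer.
#' @export
parameter_count <- function(model) {
  w <- if (!is.null(model$weights)) model$weights else model
  sum(vapply(w, function(p)
    sum(vapply(p[names(p) %in% c("w", "b", "gamma", "beta")], length,
               numeric(1))), numeric(1)))
}
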