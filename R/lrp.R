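#' Relevance rule assignments
#'
#' Named composites of per-layer relevance rules. LRP redistributes the
#' explained class score backward layer by layer; the rule used at each
#' layer kind is selectable:
#'
#' * `"epsilon"` -- proportional redistribution with an epsilon stabilizer
#'   on every linear layer.
#' * `"alphabeta"` -- positive and negative pre-activation contributions
#'   weighted `alpha` / `-beta` (`alpha - beta = 1`).
#' * `"flat"` -- uniform redistribution over each unit's receptive field.
#' * `"lrp_spf"` -- the "sequential preset A, flat" composite: epsilon
#'   (0.1) on dense layers, alpha-beta (1, 0) on convolutional layers, flat
#'   on the first layer.
#' * `"deep_taylor"` -- alpha-beta (1, 0) everywhere (the z+ rule on ReLU
#'   networks).
#' * `"deep_taylor_bounded"` -- as deep Taylor with the box (zB) rule at
#'   the input layer, using `bounds = c(low, high)`.
#' * `"guided_backprop"`, `"deconvnet"` -- modified-ReLU gradient
#'   backpasses (saliency baselines, not conserving).
#'
#' Pooling layers are always handled by winner-take-all redirection
#' (maxpool) or proportional redistribution (avgpool; uniform under the
#' flat composite); flatten/concat/dropout pass relevance through and batch
#' normalization is folded into the adjacent dense layer before
#' propagation.
#'
#' @param name Composite name (above).
#' @param epsilon Stabilizer for the epsilon rule.
#' @param alpha,beta Alpha-beta rule weights; must satisfy
#'   `alpha - beta = 1`, `alpha >= 1`.
#' @param bounds Input-domain bounds `c(low, high)` for the zB rule.
#' @return A `rule_assignment` list with per-layer-kind rules.
#' @export
make_ruleset <- function(name = c("lrp_spf", "epsilon", "alphabeta", "flat",
                                  "deep_taylor", "deep_taylor_bounded",
                                  "guided_backprop", "deconvnet"),
                         epsilon = 0.1, alpha = 1, beta = 0,
                         bounds = c(-3, 3)) {
  name <- match.arg(name)
  if (abs(alpha - beta - 1) > 1e-12 || alpha < 1)
    abort("alpha-beta rules require alpha - beta = 1 and alpha >= 1")
  if (epsilon < 0) abort("epsilon must be >= 0")
  rs <- switch(name,
    epsilon = list(dense = "epsilon", conv = "epsilon", first = "epsilon"),
    alphabeta = list(dense = "alphabeta", conv = "alphabeta",
                     first = "alphabeta"),
    flat = list(dense = "flat", conv = "flat", first = "flat"),
    lrp_spf = list(dense = "epsilon", conv = "alphabeta", first = "flat"),
    deep_taylor = list(dense = "alphabeta", conv = "alphabeta",
                       first = "alphabeta"),
    deep_taylor_bounded = list(dense = "alphabeta", conv = "alphabeta",
                               first = "zb"),
    guided_backprop = , deconvnet = list(dense = NA, conv = NA, first = NA))
  structure(list(name = name, method = if (name %in%
                   c("guided_backprop", "deconvnet")) "gradient" else "lrp",
                 dense_rule = rs$dense, conv_rule = rs$conv,
                 first_layer_rule = rs$first,
                 epsilon = epsilon, alpha = alpha, beta = beta,
                 bounds = bounds,
                 relu_mode = switch(name, guided_backprop = "guided",
                                    deconvnet = "deconvnet", "grad")),
            class = "rule_assignment")
}

signp <- function(z) ifelse(z >= 0, 1, -1)   # sign with sign(0) = +1
stab <- function(z, eps) z + eps * signp(z)
# relevance/pre-activation ratio; an eliminated unit (R = 0, z = 0) carries
# no relevance rather than NaN
safe_ratio <- function(R, z) {
  s <- R / z
  s[!is.finite(s)] <- 0
  s
}

#' Epsilon relevance rule for a dense layer
#'
#' Redistributes the upper-layer relevance `R_k` to the lower activations in
#' proportion to their contribution `a_j * w_jk` to the pre-activation
#' `z_k = sum_j a_j w_jk + b_k`, stabilized by `epsilon * sign(z_k)`
#' (`sign(0)` taken as +1). Bias relevance is absorbed, not redistributed.
#'
#' @param a Lower-layer activations: vector (J) or matrix (N x J).
#' @param w Weight matrix (J x K).
#' @param b Bias vector (K).
#' @param relevance Upper relevance: vector (K) or matrix (N x K).
#' @param epsilon Stabilizer (>= 0).
#' @return Relevance at the lower layer, same shape as `a`.
#' @export
rule_epsilon <- function(a, w, b, relevance, epsilon = 0) {
  vec <- is.null(dim(a))
  a <- rbind(a); relevance <- rbind(relevance)
  z <- sweep(a %*% w, 2, b, "+")
  s <- safe_ratio(relevance, stab(z, epsilon))
  out <- a * (s %*% t(w))
  if (vec) drop(out) else out
}

#' Alpha-beta relevance rule for a dense layer
#'
#' Positive and negative contributions are redistributed separately with
#' weights `alpha` and `-beta` (`alpha - beta = 1`). The bias share is
#' assigned to the bias term (absorbed), never to the inputs.
#'
#' @inheritParams rule_epsilon
#' @param alpha,beta Rule weights; `alpha - beta` must equal 1.
#' @return Relevance at the lower layer, same shape as `a`.
#' @export
rule_alphabeta <- function(a, w, b, relevance, alpha = 1, beta = 0) {
  if (abs(alpha - beta - 1) > 1e-12)
    abort("alpha - beta must equal 1")
  vec <- is.null(dim(a))
  a <- rbind(a); relevance <- rbind(relevance)
  ap <- pmax(a, 0); an <- pmin(a, 0)
  wp <- pmax(w, 0); wn <- pmin(w, 0)
  zp <- sweep(ap %*% wp + an %*% wn, 2, pmax(b, 0), "+")
  sp <- safe_ratio(relevance, zp)
  out <- alpha * (ap * (sp %*% t(wp)) + an * (sp %*% t(wn)))
  if (beta != 0) {
    zn <- sweep(ap %*% wn + an %*% wp, 2, pmin(b, 0), "+")
    sn <- safe_ratio(relevance, zn)
    out <- out - beta * (ap * (sn %*% t(wn)) + an * (sn %*% t(wp)))
  }
  if (vec) drop(out) else out
}

#' Flat relevance rule
#'
#' Divides each output unit's relevance equally among the inputs of its
#' receptive field, ignoring both activations and weights.
#'
#' @param n_inputs Number of contributing inputs per output unit (dense
#'   layer: the input width).
#' @param relevance Upper relevance: vector (K) or matrix (N x K).
#' @return Relevance at the lower layer (length/width `n_inputs`).
#' @export
rule_flat <- function(n_inputs, relevance) {
  if (n_inputs < 1) abort("empty receptive field")
  vec <- is.null(dim(relevance))
  relevance <- rbind(relevance)
  out <- matrix(rowSums(relevance) / n_inputs, nrow(relevance), n_inputs)
  if (vec) drop(out) else out
}

#' Pooling relevance rule
#'
#' Max pooling redirects each window's relevance entirely to the input that
#' won the forward pass (ties to the lowest index); average pooling
#' redistributes proportionally to the activations (the epsilon rule with
#' uniform weights).
#'
#' @param kind `"max"` or `"avg"`.
#' @param x Input window activations (vector).
#' @param relevance Scalar relevance of the pooled output.
#' @param epsilon Stabilizer for the average case.
#' @return Relevance over the window inputs.
#' @export
rule_pool <- function(kind = c("max", "avg"), x, relevance, epsilon = 0) {
  kind <- match.arg(kind)
  if (kind == "max") {
    out <- numeric(length(x))
    out[which.max(x)] <- relevance
    out
  } else {
    z <- mean(x)
    x * (relevance / stab(z, epsilon)) / length(x)
  }
}

#' Fold batch normalization into the adjacent dense layer
#'
#' Rewrites the model so every batch-normalization node becomes a
#' pass-through and its affine transform is absorbed into the effective
#' weights of the next dense layer (reachable through pass-through nodes
#' only, which are identities in inference mode). Forward outputs are
#' unchanged; relevance rules then see a single linear layer.
#'
#' @param model A trained model.
#' @return The equivalent model without batch-normalization transforms.
#' @export
fold_batchnorm <- function(model) {
  graph <- model$graph
  ids <- names(graph$nodes)
  for (id in ids) {
    nd <- graph$nodes[[id]]
    if (nd$kind != "batchnorm") next
    wb <- model$weights[[id]]
    scale <- wb$gamma / sqrt(wb$running_var + nd$params$eps)
    shift <- wb$beta - wb$running_mean * scale
    # find the consuming dense layer through pass-through nodes
    cur <- id
    repeat {
      child <- Filter(function(x) cur %in% x$parents, graph$nodes)
      if (length(child) != 1)
        abort("batchnorm folding requires a single consumer chain")
      child <- child[[1]]
      if (child$kind == "dense") break
      if (!child$kind %in% c("dropout", "flatten"))
        abort("batchnorm folding requires a downstream dense layer")
      cur <- child$id
    }
    wd <- model$weights[[child$id]]
    model$weights[[child$id]]$w <- wd$w * scale
    model$weights[[child$id]]$b <- wd$b + drop(shift %*% wd$w)
    # neutralize the batchnorm node
    model$weights[[id]] <- list(gamma = rep(1, length(scale)),
                                beta = numeric(length(scale)),
                                running_mean = numeric(length(scale)),
                                running_var = rep(1, length(scale)) -
                                  nd$params$eps)
    model$graph$nodes[[id]]$params$eps <- nd$params$eps
  }
  model
}

# ---- core relevance propagation over a batch ------------------------------

first_linear_nodes <- function(graph) {
  # linear layers whose (only) parent is the input node
  names(Filter(function(nd)
    nd$kind %in% c("conv2d", "dense") && identical(nd$parents, "input"),
    graph$nodes))
}

lrp_propagate <- function(model, x, target_idx, rules) {
  model <- fold_batchnorm(model)
  graph <- model$graph; weights <- model$weights
  fw <- forward(model, x, cache = TRUE)
  n <- nrow(fw$logits)
  lid <- logits_node(graph)
  f_c <- fw$logits[cbind(seq_len(n), target_idx)]
  R0 <- matrix(0, n, ncol(fw$logits))
  R0[cbind(seq_len(n), target_idx)] <- f_c
  rel <- list(); rel[[lid]] <- R0
  firsts <- first_linear_nodes(graph)

  for (i in rev(seq_along(graph$nodes))) {
    nd <- graph$nodes[[i]]
    if (nd$kind %in% c("softmax", "input")) next
    R <- rel[[nd$id]]
    if (is.null(R)) next
    p <- nd$parents[1]
    xin <- fw$acts[[p]]
    rule <- if (nd$id %in% firsts) rules$first_layer_rule
      else if (nd$kind == "conv2d") rules$conv_rule
      else if (nd$kind == "dense") rules$dense_rule
    if (nd$kind %in% c("conv2d", "dense") &&
        (is.null(rule) || is.na(rule)))
      abort(paste0("no relevance rule configured for layer kind at ", nd$id))

    Rp <- switch(nd$kind,
      dense = switch(rule,
        epsilon = rule_epsilon(xin, weights[[nd$id]]$w, weights[[nd$id]]$b,
                               R, rules$epsilon),
        alphabeta = rule_alphabeta(xin, weights[[nd$id]]$w,
                                   weights[[nd$id]]$b, R,
                                   rules$alpha, rules$beta),
        flat = rule_flat(ncol(xin), R),
        zb = zb_dense(xin, weights[[nd$id]]$w, weights[[nd$id]]$b, R,
                      rules$bounds),
        abort(paste0("unknown dense rule: ", rule))),
      conv2d = conv_lrp(xin, weights[[nd$id]]$w, weights[[nd$id]]$b, R, nd,
                        rule, rules),
      avgpool = {
        if (identical(rules$conv_rule, "flat")) {
          # uniform redistribution over the window (flat composite)
          cpp_pool_bw(R, integer(), dim(xin)[1], dim(xin)[2], dim(xin)[3],
                      nd$params$window[1], nd$params$window[2], 0L)
        } else {
          res <- cpp_pool_fw(xin, nd$params$window[1], nd$params$window[2],
                             0L)
          s <- safe_ratio(R, res$y)
          xin * cpp_pool_bw(s, integer(), dim(xin)[1], dim(xin)[2],
                            dim(xin)[3], nd$params$window[1],
                            nd$params$window[2], 0L)
        }
      },
      maxpool = cpp_pool_bw(R, fw$extra[[nd$id]], dim(xin)[1], dim(xin)[2],
                            dim(xin)[3], nd$params$window[1],
                            nd$params$window[2], 1L),
      flatten = array(t(R), dim(xin)),
      concat = {
        at <- 0
        for (q in nd$parents) {
          ci <- dim(fw$acts[[q]])[3]
          rel[[q]] <- acc(rel[[q]], R[, , at + seq_len(ci), , drop = FALSE])
          at <- at + ci
        }
        NULL
      },
      batchnorm = , dropout = R)
    if (nd$kind != "concat") rel[[p]] <- acc(rel[[p]], Rp)
  }
  list(R = rel[["input"]], f_c = f_c, probs = fw$probs, logits = fw$logits)
}

# average-pool flat redistribution is uniform over the window:
# implemented above by distributing R/window_size to each input.

zb_dense <- function(a, w, b, R, bounds) {
  a <- rbind(a); R <- rbind(R)
  L <- matrix(bounds[1], nrow(a), ncol(a))
  H <- matrix(bounds[2], nrow(a), ncol(a))
  wp <- pmax(w, 0); wn <- pmin(w, 0)
  z <- sweep(a %*% w, 2, b, "+") - L %*% wp - H %*% wn
  s <- safe_ratio(R, z)
  a * (s %*% t(w)) - L * (s %*% t(wp)) - H * (s %*% t(wn))
}

conv_lrp <- function(x, w, b, R, nd, rule, rules) {
  pd <- conv_padding(nd$params$kernel[1], nd$params$kernel[2],
                     nd$params$padding)
  st <- nd$params$stride
  bwd <- function(s, wt) cpp_conv2d_bw(x, wt, s, st[1], st[2], pd[1], pd[2],
                                       TRUE, FALSE)$dx
  if (rule == "epsilon") {
    z <- cpp_conv2d_fw(x, w, b, st[1], st[2], pd[1], pd[2])
    s <- safe_ratio(R, stab(z, rules$epsilon))
    x * bwd(s, w)
  } else if (rule == "alphabeta") {
    xp <- pmax(x, 0); xn <- pmin(x, 0)
    wp <- pmax(w, 0); wn <- pmin(w, 0)
    zp <- cpp_conv2d_fw(xp, wp, pmax(b, 0), st[1], st[2], pd[1], pd[2]) +
      cpp_conv2d_fw(xn, wn, numeric(length(b)), st[1], st[2], pd[1], pd[2])
    sp <- safe_ratio(R, zp)
    out <- rules$alpha * (xp * bwd(sp, wp) + xn * bwd(sp, wn))
    if (rules$beta != 0) {
      zn <- cpp_conv2d_fw(xp, wn, pmin(b, 0), st[1], st[2], pd[1], pd[2]) +
        cpp_conv2d_fw(xn, wp, numeric(length(b)), st[1], st[2], pd[1], pd[2])
      sn <- safe_ratio(R, zn)
      out <- out - rules$beta * (xp * bwd(sn, wn) + xn * bwd(sn, wp))
    }
    out
  } else if (rule == "flat") {
    ones_x <- array(1, dim(x))
    ones_w <- array(1, dim(w))
    cnt <- cpp_conv2d_fw(ones_x, ones_w, numeric(dim(w)[4]),
                         st[1], st[2], pd[1], pd[2])
    s <- safe_ratio(R, cnt)
    bwd(s, ones_w)
  } else if (rule == "zb") {
    L <- array(rules$bounds[1], dim(x))
    H <- array(rules$bounds[2], dim(x))
    wp <- pmax(w, 0); wn <- pmin(w, 0)
    z <- cpp_conv2d_fw(x, w, b, st[1], st[2], pd[1], pd[2]) -
      cpp_conv2d_fw(L, wp, numeric(length(b)), st[1], st[2], pd[1], pd[2]) -
      cpp_conv2d_fw(H, wn, numeric(length(b)), st[1], st[2], pd[1], pd[2])
    s <- safe_ratio(R, z)
    x * bwd(s, w) - L * bwd(s, wp) - H * bwd(s, wn)
  } else abort(paste0("unknown conv rule: ", rule))
}

# ---- public API -----------------------------------------------------------

#' Explain a prediction with layer-wise relevance propagation
#'
#' Propagates the chosen class's pre-softmax score backward through the
#' network (the softmax layer is removed and the other class scores are
#' zeroed) under the configured per-layer rules, yielding an input-shaped
#' relevance map. Gradient composites (`guided_backprop`, `deconvnet`)
#' return the modified-ReLU gradient instead.
#'
#' @param model A trained model.
#' @param sample One window (`window_len x n_channels` matrix) or a
#'   `(1, window_len, n_channels)` array.
#' @param target_class Class label (or index) to explain; defaults to the
#'   predicted class.
#' @param rules A [make_ruleset()].
#' @return A `relevance_map`: `scores` (window_len x n_channels),
#'   `target_class`, `rule`, `f_c` (the explained score) and
#'   `conservation_residual`.
#' @export
explain <- function(model, sample, target_class = NULL,
                    rules = make_ruleset("lrp_spf")) {
  if (is.matrix(sample)) sample <- array(sample, c(1, dim(sample)))
  maps <- explain_batch(model, sample, target_class, rules)
  maps[[1]]
}

#' @rdname explain
#' @param x A `(n, window_len, n_channels)` array or [gait_dataset()].
#' @export
explain_batch <- function(model, x, target_class = NULL,
                          rules = make_ruleset("lrp_spf")) {
  xin <- if (inherits(x, "gait_dataset")) x$values else x
  n <- dim(xin)[1]
  if (is.null(target_class)) {
    pred <- predict(model, xin)
    tidx <- match(as.character(pred), model$classes)
  } else if (length(target_class) == 1) {
    tidx <- rep(class_index(model, target_class), n)
  } else tidx <- vapply(target_class, function(tc) class_index(model, tc),
                        numeric(1))

  if (rules$method == "gradient") {
    fw <- forward(model, xin, cache = TRUE)
    f_c <- fw$logits[cbind(seq_len(n), tidx)]
    dl <- matrix(0, n, ncol(fw$logits))
    dl[cbind(seq_len(n), tidx)] <- 1
    bw <- backward(model, fw, dl, need_param_grads = FALSE,
                   relu_mode = rules$relu_mode)
    Rarr <- bw$dx
  } else {
    res <- lrp_propagate(model, xin, tidx, rules)
    Rarr <- res$R
    f_c <- res$f_c
  }
  d <- dim(Rarr)  # (H, W, 1, N)
  lapply(seq_len(n), function(i) {
    sc <- matrix(Rarr[, , 1, i], d[1], d[2])
    rm <- list(scores = sc, target_class = model$classes[tidx[i]],
               rule = rules$name, f_c = f_c[i])
    class(rm) <- "relevance_map"
    rm$conservation_residual <- conservation_residual(rm)
    rm
  })
}

class_index <- function(model, target_class) {
  if (is.numeric(target_class) &&
      !as.character(target_class) %in% model$classes)
    return(as.integer(target_class))
  i <- match(as.character(target_class), model$classes)
  if (is.na(i)) abort(paste0("unknown class: ", target_class))
  i
}

#' Conservation residual of a relevance map
#'
#' Relative absolute deviation of the summed input relevance from the
#' explained class score -- the testable form of the relevance conservation
#' principle. When the explained score is 0 the absolute deviation is
#' returned with attribute `absolute = TRUE`.
#'
#' @param map A `relevance_map`.
#' @return Scalar residual.
#' @export
conservation_residual <- function(map) {
  if (!is.null(map$rule) &&
      map$rule %in% c("guided_backprop", "deconvnet"))
    return(NA_real_)
  dev <- abs(sum(map$scores) - map$f_c)
  if (map$f_c == 0) structure(dev, absolute = TRUE) else dev / abs(map$f_c)
}

#' @export
print.relevance_map <- function(x, ...) {
  cat(sprintf(
    "<relevance_map> %dx%d, class %s, rule %s, f_c %.4f, residual %s\n",
    nrow(x$scores), ncol(x$scores), x$target_class, x$rule, x$f_c,
    ifelse(is.na(x$conservation_residual), "-",
           format(x$conservation_residual, digits = 3))))
  invisible(x)
}
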