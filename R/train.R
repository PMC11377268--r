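#' Training configuration
#'
#' Adam settings and loss for network training. The defaults follow the
#' optimizer configuration used throughout the experiments: learning rate
#' 0.002, first/second-moment decays 0.9/0.999, epsilon 1e-8, categorical
#' cross-entropy, batches of 100 samples, 200 epochs, Glorot-uniform
#' weights with zero bias.
#'
#' @param learning_rate,beta1,beta2,epsilon Adam parameters.
#' @param batch_size Minibatch size.
#' @param epochs Number of passes over the training set.
#' @param seed Seed for initialization and shuffling.
#' @return A `training_config` list.
#' @export
training_config <- function(learning_rate = 0.002, beta1 = 0.9,
                            beta2 = 0.999, epsilon = 1e-8,
                            batch_size = 100L, epochs = 200L, seed = 1L) {
  structure(list(learning_rate = learning_rate, beta1 = beta1, beta2 = beta2,
                 epsilon = epsilon, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), seed = as.integer(seed)),
            class = "training_config")
}

one_hot <- function(labels, classes) {
  y <- matrix(0, length(labels), length(classes))
  y[cbind(seq_along(labels), match(as.character(labels), classes))] <- 1
  y
}

cross_entropy <- function(probs, y) {
  -mean(rowSums(y * log(pmax(probs, 1e-12))))
}

#' Train a layer graph
#'
#' Minimizes categorical cross-entropy with Adam over the dataset's training
#' split, monitoring loss and accuracy on the validation split. Weights are
#' initialized Glorot-uniform with zero biases. Training is deterministic
#' under a fixed seed on a fixed platform. A non-finite loss aborts with
#' diagnostics.
#'
#' @param graph A [build_architecture()] layer graph.
#' @param dataset A standardized, split [gait_dataset()] (or a list with
#'   `x` array and `labels` for raw tensors).
#' @param config A [training_config()].
#' @param verbose Print per-epoch progress.
#' @return A `trained_model`: graph, learned weights, per-epoch `history`
#'   tibble (`epoch`, `train_loss`, `val_loss`, `val_accuracy`), config and
#'   class vocabulary.
#' @export
train <- function(graph, dataset, config = training_config(),
                  verbose = FALSE) {
  stopifnot(inherits(graph, "layer_graph"))
  tr <- dataset_split(dataset, "train")
  has_val <- any(dataset$split == "val", na.rm = TRUE)
  va <- if (has_val) dataset_split(dataset, "val")
  classes <- dataset$classes
  if (graph$n_classes != length(classes))
    abort("graph output width does not match the class vocabulary")

  weights <- init_weights(graph, config$seed)
  model <- structure(list(graph = graph, weights = weights,
                          classes = classes, config = config),
                     class = "trained_model")
  ytr <- one_hot(tr$labels, classes)
  hist <- vector("list", config$epochs)

  # Adam state
  m <- list(); v <- list(); tstep <- 0
  trainable <- names(Filter(Negate(is.null), weights))

  local_seed(derive_seed(config$seed, 11L), {
    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(n_samples(tr))
      nb <- ceiling(length(ord) / config$batch_size)
      ep_loss <- 0
      for (bi in seq_len(nb)) {
        idx <- ord[((bi - 1) * config$batch_size + 1):
                     min(bi * config$batch_size, length(ord))]
        xb <- tr$values[idx, , , drop = FALSE]
        yb <- ytr[idx, , drop = FALSE]
        fw <- forward(model, xb, training = TRUE, cache = TRUE)
        loss <- cross_entropy(fw$probs, yb)
        if (!is.finite(loss))
          abort(sprintf("non-finite loss at epoch %d batch %d", ep, bi))
        ep_loss <- ep_loss + loss * length(idx)
        dlogits <- (fw$probs - yb) / length(idx)
        bw <- backward(model, fw, dlogits, training = TRUE)
        tstep <- tstep + 1
        for (id in names(bw$grads)) {
          for (pn in names(bw$grads[[id]])) {
            key <- paste0(id, ".", pn)
            g <- bw$grads[[id]][[pn]]
            m[[key]] <- if (is.null(m[[key]])) (1 - config$beta1) * g
              else config$beta1 * m[[key]] + (1 - config$beta1) * g
            v[[key]] <- if (is.null(v[[key]])) (1 - config$beta2) * g^2
              else config$beta2 * v[[key]] + (1 - config$beta2) * g^2
            mhat <- m[[key]] / (1 - config$beta1^tstep)
            vhat <- v[[key]] / (1 - config$beta2^tstep)
            model$weights[[id]][[pn]] <-
              model$weights[[id]][[pn]] -
              config$learning_rate * mhat / (sqrt(vhat) + config$epsilon)
          }
        }
        # running batchnorm moments
        for (nd in graph$nodes) {
          if (nd$kind != "batchnorm") next
          ex <- fw$extra[[nd$id]]; mom <- nd$params$momentum
          wb <- model$weights[[nd$id]]
          model$weights[[nd$id]]$running_mean <-
            mom * wb$running_mean + (1 - mom) * ex$bm
          model$weights[[nd$id]]$running_var <-
            mom * wb$running_var + (1 - mom) * ex$bv
        }
      }
      train_loss <- ep_loss / length(ord)
      val_loss <- NA_real_; val_acc <- NA_real_
      if (has_val) {
        fv <- forward(model, va$values)
        yv <- one_hot(va$labels, classes)
        val_loss <- cross_entropy(fv$probs, yv)
        val_acc <- mean(max.col(fv$probs, ties.method = "first") ==
                          match(as.character(va$labels), classes))
      }
      hist[[ep]] <- tibble::tibble(epoch = ep, train_loss = train_loss,
                                   val_loss = val_loss,
                                   val_accuracy = val_acc)
      if (verbose)
        message(sprintf("epoch %3d  loss %.4f  val_acc %s", ep, train_loss,
                        ifelse(is.na(val_acc), "-", sprintf("%.3f", val_acc))))
    }
  })
  model$history <- if (config$epochs > 0) dplyr::bind_rows(hist)
    else tibble::tibble(epoch = integer(), train_loss = numeric(),
                        val_loss = numeric(), val_accuracy = numeric())
  model
}

#' @export
print.trained_model <- function(x, ...) {
  cat(sprintf("<trained_model> %s, %d parameters, %d epochs\n",
              x$graph$architecture_name, parameter_count(x),
              nrow(x$history)))
  if (nrow(x$history)) {
    last <- x$history[nrow(x$history), ]
    cat(sprintf("  final train loss %.4f, val accuracy %s\n", last$train_loss,
                ifelse(is.na(last$val_accuracy), "-",
                       sprintf("%.3f", last$val_accuracy))))
  }
  invisible(x)
}
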