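#' Tidy methods
#'
#' broom-style accessors turning the package's result objects into tibbles
#' ready for dplyr/ggplot2 work.
#'
#' @param x The object.
#' @param ... Unused.
#' @name tidiers
NULL

#' @rdname tidiers
#' @export
tidy.morf_result <- function(x, ...) {
  tibble::tibble(step = seq_along(x$step_accuracies) - 1L,
                 accuracy = x$step_accuracies, order = x$order)
}

#' @rdname tidiers
#' @export
glance.morf_result <- function(x, ...) {
  ds <- decay_statistic(x)
  tibble::tibble(order = x$order, n_steps = x$n_steps,
                 start_accuracy = x$step_accuracies[1],
                 final_accuracy = x$step_accuracies[x$n_steps + 1],
                 mean_decline = ds$mean_decline)
}

#' @rdname tidiers
#' @export
tidy.gait_confusion <- function(x, ...) {
  m <- unclass(x)
  tibble::tibble(true = rep(rownames(m), ncol(m)),
                 pred = rep(colnames(m), each = nrow(m)),
                 n = as.integer(m))
}

#' @rdname tidiers
#' @export
glance.gait_confusion <- function(x, ...) {
  sc <- scores(x)
  macro <- sc[sc$class == "macro", ]
  tibble::tibble(n = sum(x), accuracy = overall_accuracy(x),
                 macro_precision = macro$precision,
                 macro_recall = macro$recall, macro_f1 = macro$f1)
}

#' @rdname tidiers
#' @export
tidy.trained_model <- function(x, ...) x$history

#' @rdname tidiers
#' @export
glance.trained_model <- function(x, ...) {
  last <- if (nrow(x$history)) x$history[nrow(x$history), ] else
    tibble::tibble(train_loss = NA_real_, val_accuracy = NA_real_)
  tibble::tibble(architecture = x$graph$architecture_name,
                 parameters = parameter_count(x),
                 epochs = nrow(x$history),
                 final_train_loss = last$train_loss,
                 final_val_accuracy = last$val_accuracy)
}

#' @rdname tidiers
#' @export
tidy.relevance_map <- function(x, ...) {
  tibble::tibble(frame = rep(seq_len(nrow(x$scores)), ncol(x$scores)),
                 channel = rep(seq_len(ncol(x$scores)),
                               each = nrow(x$scores)),
                 relevance = as.numeric(x$scores))
}

#' @rdname tidiers
#' @export
glance.relevance_map <- function(x, ...) {
  tibble::tibble(target_class = x$target_class, rule = x$rule, f_c = x$f_c,
                 total_relevance = sum(x$scores),
                 conservation_residual = as.numeric(x$conservation_residual))
}

#' @rdname tidiers
#' @export
tidy.sa_curve <- function(x, ...) {
  tibble::tibble(frame = seq_along(x$values), value = x$values,
                 source = x$source)
}

#' @rdname tidiers
#' @export
tidy.event_assignment <- function(x, ...) x$peaks

#' @rdname tidiers
#' @export
tidy.experiment_report <- function(x, ...) x$results
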