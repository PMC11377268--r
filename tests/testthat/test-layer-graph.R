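test_that("convolution follows the flipped-kernel orientation", {
  x <- array(c(1, 2, 3), c(3, 1, 1, 1))
  w <- array(c(1, 2), c(2, 1, 1, 1))
  expect_equal(drop(gaitxai:::cpp_conv2d_fw(x, w, 0, 1L, 1L, 0L, 0L)),
               c(4, 7))
  # identity kernel reproduces the input
  w1 <- array(1, c(1, 1, 1, 1))
  expect_equal(drop(gaitxai:::cpp_conv2d_fw(x, w1, 0, 1L, 1L, 0L, 0L)),
               c(1, 2, 3))
  # all-ones 2x2 kernel on a 2x2 input, valid padding: sum of entries
  x2 <- array(1:4, c(2, 2, 1, 1)); w2 <- array(1, c(2, 2, 1, 1))
  expect_equal(drop(gaitxai:::cpp_conv2d_fw(x2, w2, 0, 1L, 1L, 0L, 0L)), 10)
  # random case vs the explicit dense-matrix oracle
  withr::with_seed(2, {
    xm <- matrix(rnorm(5 * 4), 5, 4)
    wk <- matrix(rnorm(3 * 3), 3, 3)
    y <- gaitxai:::cpp_conv2d_fw(array(xm, c(5, 4, 1, 1)),
                                 array(wk, c(3, 3, 1, 1)), 0,
                                 1L, 1L, 1L, 1L)
    Wd <- conv_as_dense(xm, wk, pad = 1)
    expect_equal(as.numeric(y), as.numeric(as.vector(xm) %*% Wd),
                 tolerance = 1e-12)
  })
})

test_that("architectures reproduce the stacked-layer counts and stream structure", {
  g1 <- build_architecture("single", c(500, 18), 4)
  expect_equal(stacked_layer_count(g1), 10)
  g2 <- build_architecture("parallel", c(500, 18), 4)
  expect_equal(stacked_layer_count(g2), 18)
  g3 <- build_architecture("quadruplet", c(500, 18), 4)
  # four parallel streams with disjoint parameter sets
  w3 <- gaitxai:::init_weights(g3, 1)
  stream_convs <- grep("^q[1-4]_conv", names(w3), value = TRUE)
  expect_length(stream_convs, 8)
  expect_equal(anyDuplicated(stream_convs), 0)
  kinds <- vapply(g3$nodes, `[[`, "", "kind")
  expect_equal(sum(kinds == "maxpool"), 4)
  expect_equal(sum(kinds == "avgpool"), 4)
  expect_error(build_architecture("unknown", c(10, 10), 2))
  # every graph has positive parameter counts
  for (g in list(g1, g2, g3))
    expect_gt(parameter_count(list(weights = gaitxai:::init_weights(g, 1))), 0)
})

test_that("forward pass is functional, normalized and honours degenerate heads", {
  g <- tiny_parallel_graph(c(16, 8), 3)
  m <- make_model(g)
  x <- withr::with_seed(3, array(rnorm(2 * 16 * 8), c(2, 16, 8)))
  fw <- forward(m, x)
  expect_equal(rowSums(fw$probs), c(1, 1), tolerance = 1e-9)
  expect_identical(fw$logits, forward(m, x)$logits)   # purely functional
  # zero-weight, zero-bias head gives uniform class probabilities
  m0 <- m
  m0$weights$logits$w[] <- 0; m0$weights$logits$b[] <- 0
  expect_equal(as.numeric(forward(m0, x)$probs), rep(1 / 3, 6))
  expect_error(forward(m, array(0, c(1, 8, 8))), "expects")
})

test_that("analytic gradients match numerical gradients on a toy graph", {
  g <- tiny_parallel_graph(c(12, 6), 3)
  m <- make_model(g, seed = 2)
  x <- withr::with_seed(4, array(rnorm(2 * 12 * 6), c(2, 12, 6)))
  y <- gaitxai:::one_hot(c("1", "3"), m$classes)
  fw <- forward(m, x, cache = TRUE)
  bw <- gaitxai:::backward(m, fw, (fw$probs - y) / 2)
  lossfn <- function(mm) gaitxai:::cross_entropy(forward(mm, x)$probs, y)
  worst <- 0
  withr::with_seed(5, for (id in names(bw$grads)) {
    for (pn in names(bw$grads[[id]])) {
      ga <- bw$grads[[id]][[pn]]
      for (i in sample(length(ga), min(3, length(ga)))) {
        eps <- 1e-6
        mp <- m; mp$weights[[id]][[pn]][i] <- mp$weights[[id]][[pn]][i] + eps
        mn <- m; mn$weights[[id]][[pn]][i] <- mn$weights[[id]][[pn]][i] - eps
        gn <- (lossfn(mp) - lossfn(mn)) / (2 * eps)
        worst <- max(worst, abs(gn - ga[i]) /
                       max(1e-8, abs(gn) + abs(ga[i])))
      }
    }
  })
  expect_lt(worst, 1e-4)
})

test_that("training descends on separable data, is seeded, and epochs=0 returns the init", {
  ds <- tiny_bump_dataset()
  g <- tiny_parallel_graph(dim(ds$values)[2:3], 2)
  ds$classes <- c("a", "b")
  cfgt <- training_config(epochs = 5, batch_size = 20, seed = 1)
  m <- train(g, ds, cfgt)
  expect_equal(nrow(m$history), 5)
  expect_true(all(diff(m$history$train_loss) < 0))  # strict descent
  m2 <- train(g, ds, cfgt)
  expect_identical(m$weights, m2$weights)           # same seed, same result
  m0 <- train(g, ds, training_config(epochs = 0, seed = 1))
  expect_identical(m0$weights, gaitxai:::init_weights(g, 1))
  expect_equal(nrow(m0$history), 0)
})

test_that("batchnorm distinguishes batch and running statistics", {
  ds <- tiny_bump_dataset()
  g <- tiny_parallel_graph(dim(ds$values)[2:3], 2)
  ds$classes <- c("a", "b")
  m <- train(g, ds, training_config(epochs = 2, batch_size = 20, seed = 1))
  x <- ds$values[1:4, , , drop = FALSE]
  eval_out <- forward(m, x)$logits
  train_out <- withr::with_seed(1, forward(m, x, training = TRUE)$logits)
  expect_false(isTRUE(all.equal(eval_out, train_out)))
  expect_identical(eval_out, forward(m, x)$logits)  # eval mode is stable
})
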