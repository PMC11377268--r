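test_that("epsilon rule matches the direct formula on random small layers", {
  withr::with_seed(10, for (rep in 1:5) {
    a <- rnorm(5); w <- matrix(rnorm(20), 5, 4); b <- rnorm(4); R <- rnorm(4)
    for (eps in c(0, 0.01, 0.5))
      expect_equal(rule_epsilon(a, w, b, R, eps),
                   oracle_epsilon(a, w, b, R, eps), tolerance = 1e-10)
  })
  # stabilizer keeps z = 0 finite
  out <- rule_epsilon(c(1, -1), matrix(c(1, 1), 2, 1), 0, 5, epsilon = 0.01)
  expect_true(all(is.finite(out)))
  # exact conservation with eps = 0 on a positive layer
  a <- c(2, 3); w <- matrix(c(1, 1), 2, 1)
  expect_equal(sum(rule_epsilon(a, w, 0, 5)), 5)
})

test_that("alpha-beta rule matches the direct formula and its identities", {
  withr::with_seed(11, for (rep in 1:5) {
    a <- rnorm(5); w <- matrix(rnorm(20), 5, 4); b <- rnorm(4); R <- rnorm(4)
    expect_equal(rule_alphabeta(a, w, b, R, 2, 1),
                 oracle_alphabeta(a, w, b, R, 2, 1), tolerance = 1e-10)
    expect_equal(rule_alphabeta(a, w, b, R, 1, 0),
                 oracle_alphabeta(a, w, b, R, 1, 0), tolerance = 1e-10)
  })
  # alpha=1/beta=0 on an all-positive layer coincides with epsilon(0)
  withr::with_seed(12, {
    a <- runif(4); w <- matrix(runif(12), 4, 3); R <- runif(3)
    expect_equal(rule_alphabeta(a, w, numeric(3), R, 1, 0),
                 rule_epsilon(a, w, numeric(3), R, 0), tolerance = 1e-10)
    # z+ positivity: non-negative relevance from non-negative R
    out <- rule_alphabeta(rnorm(4), matrix(rnorm(12), 4, 3), rnorm(3),
                          abs(rnorm(3)), 1, 0)
    expect_true(all(out >= -1e-12))
  })
  expect_error(rule_alphabeta(1, matrix(1), 0, 1, 2, 0.5), "alpha")
})

test_that("flat and pooling rules redistribute as documented", {
  expect_equal(rule_flat(3, 6), c(2, 2, 2))
  expect_equal(sum(rule_flat(7, c(2, 3))), 5)         # conserving
  expect_error(rule_flat(0, 1), "receptive")
  expect_equal(rule_pool("max", c(1, 3), 4), c(0, 4)) # winner-take-all
  expect_equal(rule_pool("avg", c(1, 3), 4), c(1, 3)) # proportional
  expect_equal(rule_pool("max", c(2, 2), 4), c(4, 0)) # tie -> first index
})

test_that("explain reproduces the hand-evaluated dense examples", {
  g <- build_linear_baseline(c(2, 1), 2)
  m <- make_model(g)
  m$weights$logits$w <- matrix(c(1, 1, 0, 0), 2, 2)
  m$weights$logits$b <- c(0, 0)
  rs <- make_ruleset("epsilon", epsilon = 0)
  mp <- explain(m, matrix(c(2, 3), 2, 1), target_class = 1, rules = rs)
  expect_equal(as.numeric(mp$scores), c(2, 3))
  expect_equal(mp$f_c, 5)
  expect_equal(as.numeric(mp$conservation_residual), 0, tolerance = 1e-12)
  m$weights$logits$w <- matrix(c(2, -1, 0, 0), 2, 2)
  mp2 <- explain(m, matrix(c(1, 1), 2, 1), target_class = 1, rules = rs)
  expect_equal(as.numeric(mp2$scores), c(2, -1))
  expect_equal(sum(mp2$scores), mp2$f_c)
})

test_that("conv relevance rules agree with the dense-equivalent oracle", {
  # a 4x3 one-channel conv layer rewritten as an explicit dense layer
  withr::with_seed(13, {
    xm <- matrix(abs(rnorm(4 * 3)), 4, 3)
    wk <- matrix(rnorm(9), 3, 3)
    Wd <- conv_as_dense(xm, wk, pad = 1)
    xin <- array(xm, c(4, 3, 1, 1))
    warr <- array(wk, c(3, 3, 1, 1))
    R <- matrix(rnorm(12), 1, 12)
    nd <- list(params = list(kernel = c(3L, 3L), stride = c(1L, 1L),
                             padding = "same"))
    for (spec_ in list(list(rule = "epsilon", args = make_ruleset("epsilon", epsilon = 0.05),
                            oracle = function() oracle_epsilon(as.vector(xm), Wd, numeric(12),
                                                               as.numeric(R), 0.05)),
                       list(rule = "alphabeta", args = make_ruleset("alphabeta", alpha = 2, beta = 1),
                            oracle = function() oracle_alphabeta(as.vector(xm), Wd, numeric(12),
                                                                 as.numeric(R), 2, 1)))) {
      got <- gaitxai:::conv_lrp(xin, warr, numeric(1),
                                array(R, c(4, 3, 1, 1)), nd,
                                spec_$rule, spec_$args)
      expect_equal(as.numeric(got), spec_$oracle(), tolerance = 1e-10)
    }
  })
})

test_that("named composites carry their documented structure", {
  rs <- make_ruleset("lrp_spf")
  expect_equal(rs$first_layer_rule, "flat")
  expect_equal(rs$dense_rule, "epsilon")
  expect_equal(rs$conv_rule, "alphabeta")
  expect_error(make_ruleset("lrp_spf", alpha = 2, beta = 0.5), "alpha")
  expect_error(make_ruleset("nonsense"))
  # guided backprop on an all-positive linear chain equals the plain gradient
  g <- build_linear_baseline(c(3, 1), 2)
  m <- make_model(g)
  m$weights$logits$w <- matrix(abs(rnorm(6)), 3, 2)
  x <- matrix(abs(rnorm(3)), 3, 1)
  mp <- explain(m, x, target_class = 2, rules = make_ruleset("guided_backprop"))
  expect_equal(as.numeric(mp$scores), m$weights$logits$w[, 2])
  # bounded deep Taylor stays finite
  mpb <- explain(m, x, target_class = 1,
                 rules = make_ruleset("deep_taylor_bounded",
                                      bounds = range(x)))
  expect_true(all(is.finite(mpb$scores)))
})

test_that("conservation holds through every architecture with zero biases", {
  withr::with_seed(14, {
    x <- array(rnorm(32 * 16), c(1, 32, 16))
    for (arch in c("single", "parallel", "quadruplet")) {
      hp <- if (arch == "single")
        list(filters = 2, dense_units = 4, pool = c(2, 2))
      else list(filters = 2, dense_units = 4, pool = c(2, 2),
                pool2 = c(2, 2))
      g <- build_architecture(arch, c(32, 16), 3, hp)
      m <- zero_biases(make_model(g))
      # flat composite conserves exactly by construction
      mf <- explain(m, x[1, , ], target_class = 2,
                    rules = make_ruleset("flat"))
      expect_lt(as.numeric(mf$conservation_residual), 1e-10)
      # alpha-beta (z+) conserves on zero-bias ReLU stacks
      ma <- explain(m, x[1, , ], target_class = 2,
                    rules = make_ruleset("deep_taylor"))
      expect_lt(as.numeric(ma$conservation_residual), 1e-6)
    }
  })
})

test_that("epsilon residual grows with the stabilizer on a fixed network", {
  g <- tiny_parallel_graph(c(16, 8), 3)
  m <- zero_biases(make_model(g, seed = 6))
  x <- withr::with_seed(7, matrix(abs(rnorm(16 * 8)), 16, 8))
  res <- vapply(c(0.001, 0.1, 2), function(eps) {
    mp <- explain(m, x, target_class = 1,
                  rules = make_ruleset("epsilon", epsilon = eps))
    as.numeric(mp$conservation_residual)
  }, numeric(1))
  expect_true(all(diff(res) > 0))
})

test_that("batchnorm folding leaves the explanation unchanged", {
  ds <- tiny_bump_dataset()
  g <- tiny_parallel_graph(dim(ds$values)[2:3], 2)
  ds$classes <- c("a", "b")
  m <- train(g, ds, training_config(epochs = 2, batch_size = 20, seed = 1))
  x <- ds$values[1, , ]
  mf <- fold_batchnorm(m)
  expect_equal(forward(m, x)$logits, forward(mf, x)$logits,
               tolerance = 1e-10)
  # explaining the pre-folded and explicitly folded models agrees
  mp1 <- explain(m, x, target_class = "b", rules = make_ruleset("lrp_spf"))
  mp2 <- explain(mf, x, target_class = "b", rules = make_ruleset("lrp_spf"))
  expect_equal(mp1$scores, mp2$scores, tolerance = 1e-8)
})

test_that("relevance is scale-covariant in the explained logit's weights", {
  g <- build_linear_baseline(c(4, 2), 2)
  m <- make_model(g, seed = 8)
  x <- withr::with_seed(9, matrix(rnorm(8), 4, 2))
  rs <- make_ruleset("epsilon", epsilon = 0)
  base <- explain(m, x, target_class = 1, rules = rs)
  m2 <- m
  m2$weights$logits$w[, 1] <- 3 * m2$weights$logits$w[, 1]
  m2$weights$logits$b[1] <- 3 * m2$weights$logits$b[1]
  scaled <- explain(m2, x, target_class = 1, rules = rs)
  expect_equal(scaled$scores, 3 * base$scores, tolerance = 1e-10)
})

test_that("missing rule configuration is a configuration error", {
  g <- build_linear_baseline(c(2, 1), 2)
  m <- make_model(g)
  rs <- make_ruleset("epsilon")
  rs$dense_rule <- NA
  rs$first_layer_rule <- NA
  expect_error(explain(m, matrix(1:2, 2, 1), target_class = 1, rules = rs),
               "rule")
})
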