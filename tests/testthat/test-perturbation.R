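test_that("region tiling covers the window with the expected block counts", {
  g <- tile_regions(c(500, 18), c(7, 7))
  expect_length(g$regions, ceiling(500 / 7) * ceiling(18 / 7))  # 72 x 3
  expect_length(tile_regions(c(100, 116), c(7, 7))$regions, 15 * 17)
  expect_length(tile_regions(c(10, 10), c(10, 10))$regions, 1)
  expect_error(tile_regions(c(5, 5), c(10, 10)), "larger")
  # disjoint cover
  seen <- matrix(0, 500, 18)
  for (rg in g$regions) seen[rg$rows, rg$cols] <- seen[rg$rows, rg$cols] + 1
  expect_true(all(seen == 1))
})

test_that("region scores are block sums", {
  grid <- tile_regions(c(14, 6), c(7, 7))
  uni <- matrix(1, 14, 6)
  expect_equal(region_scores(uni, grid),
               vapply(grid$regions, function(rg)
                 length(rg$rows) * length(rg$cols), numeric(1)))
  conc <- matrix(0, 14, 6); conc[1:7, 1:6] <- 5
  expect_equal(which.max(region_scores(conc, grid)), 1L)
  withr::with_seed(15, {
    m <- matrix(rnorm(84), 14, 6)
    expect_equal(region_scores(m, grid),
                 vapply(grid$regions, function(rg)
                   sum(m[rg$rows, rg$cols]), numeric(1)))
  })
})

test_that("MoRF curves start at the unperturbed accuracy and are seeded", {
  ds <- tiny_bump_dataset()
  g <- tiny_parallel_graph(dim(ds$values)[2:3], 2)
  ds$classes <- c("a", "b")
  m <- train(g, ds, training_config(epochs = 4, batch_size = 20, seed = 1))
  te <- dataset_split(ds, "test")
  maps <- explain_batch(m, te$values, target_class = te$labels,
                        rules = make_ruleset("lrp_spf"))
  grid <- tile_regions(dim(te$values)[2:3], c(7, 7))
  acc0 <- mean(predict(m, te) == te$labels)
  cur <- morf_curve(m, te, maps, grid, n_steps = 5, seed = 3)
  expect_equal(cur$step_accuracies[1], acc0)
  expect_length(cur$step_accuracies, 6)
  expect_true(all(cur$step_accuracies >= 0 & cur$step_accuracies <= 1))
  expect_identical(cur$step_accuracies,
                   morf_curve(m, te, maps, grid, 5, seed = 3)$step_accuracies)
  rnd <- morf_curve(m, te, NULL, grid, 5, order = "random", seed = 3)
  expect_equal(rnd$step_accuracies[1], acc0)
  expect_warning(morf_curve(m, te, maps, grid, n_steps = 1e4, seed = 1),
                 "clipped")
})

fake_curve <- function(acc, order = "morf")
  structure(list(order = order, step_accuracies = acc,
                 n_steps = length(acc) - 1), class = "morf_result")

test_that("decay statistic summarizes centred decline and baseline gaps", {
  flat <- fake_curve(rep(0.9, 6))
  expect_equal(decay_statistic(flat, flat)$step_differences, rep(0, 6))
  lin <- fake_curve(seq(1, 0.5, by = -0.1))
  expect_equal(decay_statistic(lin)$mean_decline, 0.1)
  withr::with_seed(16, {
    a <- fake_curve(runif(6)); b <- fake_curve(runif(6))
    d <- decay_statistic(a, b)
    expect_equal(d$step_differences, b$step_accuracies - a$step_accuracies)
    cen <- a$step_accuracies - mean(a$step_accuracies)
    expect_equal(d$mean_decline, -mean(diff(cen)))
  })
  expect_error(decay_statistic(fake_curve(1:3 / 3), fake_curve(1:4 / 4)),
               "steps")
})

test_that("model and method selection prefer the steepest early decay", {
  flat <- fake_curve(rep(0.9, 16))
  steep <- fake_curve(c(0.9, seq(0.85, 0.15, length.out = 15)))
  expect_equal(select_model(list(only = steep)), "only")
  expect_equal(select_model(list(flat = flat, steep = steep)), "steep")
  rnd <- fake_curve(rep(0.88, 16), order = "random")
  expect_equal(select_xai_method(list(flat = flat, steep = steep), rnd),
               "steep")
  # centring: adding a constant to every curve leaves the ranking unchanged
  shift <- function(cv, d) fake_curve(cv$step_accuracies + d)
  expect_equal(select_xai_method(list(flat = shift(flat, -0.2),
                                      steep = shift(steep, -0.2)),
                                 shift(rnd, -0.2)), "steep")
  # a method identical to the baseline is never selected over a better one
  expect_equal(select_xai_method(list(same = rnd, steep = steep), rnd),
               "steep")
  expect_error(select_model(list()), "empty")
})
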