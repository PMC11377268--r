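# All drivers run on miniature synthetic datasets: the point is report
# schemas, split contracts and reproducibility, not performance.

tiny_train <- training_config(epochs = 2, batch_size = 30, seed = 1)
tiny_hp <- list(filters = 2, dense_units = 8)

test_that("severity experiment reports one row per model with its confusion", {
  cfg <- generator_config("pd", n_subjects = 2,
                          trials_per_subject_per_class = 4, seed = 30)
  rep <- run_experiment_1(generator = cfg, training = tiny_train,
                          hyperparams = tiny_hp, baselines = "linear",
                          seed = 30)
  expect_s3_class(rep$results, "tbl_df")
  expect_equal(rep$results$model, c("parallel", "linear"))
  expect_true(all(c("accuracy", "macro_f1") %in% names(rep$results)))
  expect_equal(dim(rep$confusions$parallel), c(4, 4))
  expect_match(rep$config_hash, "^[0-9a-f]+$")
})

test_that("cross-subject cognitive experiment exposes the normal-class TP rate", {
  cfg <- generator_config("cognitive", n_subjects = 3,
                          trials_per_subject_per_class = 3, seed = 31)
  rep <- run_experiment_2(generator = cfg, training = tiny_train,
                          hyperparams = tiny_hp, seed = 31)
  expect_equal(dim(rep$confusions[[1]]), c(5, 5))
  expect_true(rep$normal_tp_rate >= 0 && rep$normal_tp_rate <= 1)
  expect_equal(rep$normal_tp_rate,
               scores(rep$confusions[[1]])$recall[1])
})

test_that("per-subject experiment yields one reproducible row per subject", {
  cfg <- generator_config("cognitive", n_subjects = 3,
                          trials_per_subject_per_class = 3, seed = 32)
  rep <- run_experiment_3(generator = cfg, training = tiny_train,
                          hyperparams = tiny_hp, seed = 32)
  expect_equal(nrow(rep$results), 3)
  rep2 <- run_experiment_3(generator = cfg, training = tiny_train,
                           hyperparams = tiny_hp, seed = 32)
  expect_equal(rep$results, rep2$results)
})

test_that("binary transfer experiment fills the group x regime grid", {
  cfg <- generator_config("cognitive", n_subjects = 4,
                          trials_per_subject_per_class = 3, seed = 33)
  regimes <- list(test_1 = list(test_subjects = 1),
                  random = list(fractions = c(0.7, 0.1, 0.2)))
  rep <- run_experiment_4(generator = cfg, training = tiny_train,
                          hyperparams = tiny_hp, regimes = regimes,
                          seed = 33)
  expect_equal(nrow(rep$results), 4 * 2)
  expect_setequal(unique(rep$results$regime), names(regimes))
  # leave-1 regime tests exactly one subject's 2 x 3 samples
  expect_true(all(rep$results$n_test[rep$results$regime == "test_1"] == 6))
})

test_that("tidiers and plots expose the result objects as tibbles and ggplots", {
  cur <- structure(list(order = "morf",
                        step_accuracies = c(1, 0.8, 0.6), n_steps = 2,
                        noise_params = c(0, 1), seed = 1),
                   class = "morf_result")
  td <- tidy(cur)
  expect_equal(td$step, 0:2)
  expect_equal(glance(cur)$final_accuracy, 0.6)
  cm <- confusion(c("a", "b"), c("a", "b"), c("a", "b"))
  expect_equal(nrow(tidy(cm)), 4)
  expect_equal(glance(cm)$accuracy, 1)
  expect_s3_class(autoplot(cur), "ggplot")
  expect_s3_class(autoplot(cm), "ggplot")
  sa <- spatial_average(matrix(1:20, 10, 2))
  expect_s3_class(autoplot(sa), "ggplot")
  expect_equal(nrow(tidy(sa)), 10)
})
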