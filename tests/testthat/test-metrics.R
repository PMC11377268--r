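test_that("confusion matrix counts pairs exactly", {
  cm <- confusion(c("a", "a", "b"), c("a", "b", "b"), c("a", "b"))
  expect_equal(as.vector(unclass(cm)), c(1, 0, 1, 1))
  # perfect prediction is diagonal
  d <- confusion(c("a", "b", "b"), c("a", "b", "b"), c("a", "b"))
  expect_equal(sum(unclass(d)) - sum(diag(unclass(d))), 0)
  # a single sample fills exactly one cell
  s <- confusion("a", "b", c("a", "b"))
  expect_equal(sum(unclass(s)), 1)
  expect_error(confusion("a", "z", c("a", "b")), "vocabulary")
  # brute-force pairwise counting oracle on random labels
  withr::with_seed(18, {
    yt <- sample(letters[1:4], 60, replace = TRUE)
    yp <- sample(letters[1:4], 60, replace = TRUE)
    cm <- unclass(confusion(yt, yp, letters[1:4]))
    for (i in letters[1:4]) for (j in letters[1:4])
      expect_equal(cm[i, j], sum(yt == i & yp == j))
    # row sums = true counts, column sums = predicted counts
    expect_equal(rowSums(cm), as.vector(table(factor(yt, letters[1:4]))),
                 ignore_attr = TRUE)
    expect_equal(colSums(cm), as.vector(table(factor(yp, letters[1:4]))),
                 ignore_attr = TRUE)
  })
})

test_that("per-class scores follow the one-vs-rest formulas", {
  # TP=9, FP=1, FN=1 for class a
  yt <- c(rep("a", 10), rep("b", 10))
  yp <- c(rep("a", 9), "b", "a", rep("b", 9))
  sc <- scores(confusion(yt, yp, c("a", "b")))
  a <- sc[sc$class == "a", ]
  expect_equal(a$precision, 0.9)
  expect_equal(a$recall, 0.9)
  expect_equal(a$f1, 0.9)
  # perfect diagonal scores 1 everywhere
  p <- scores(confusion(yt, yt, c("a", "b")))
  expect_true(all(p[, c("accuracy", "precision", "recall", "f1")] == 1))
  # a class never true and never predicted is defined as 0
  z <- scores(confusion(yt, yp, c("a", "b", "c")))
  expect_equal(unlist(z[z$class == "c", c("precision", "recall", "f1")]),
               c(precision = 0, recall = 0, f1 = 0))
})

test_that("macro F1 is invariant under class relabelling", {
  withr::with_seed(19, {
    yt <- sample(letters[1:3], 50, replace = TRUE)
    yp <- sample(letters[1:3], 50, replace = TRUE)
    f1 <- macro_f1(yt, yp, letters[1:3])
    perm <- c(a = "c", b = "a", c = "b")
    expect_equal(macro_f1(perm[yt], perm[yp], letters[1:3]), f1)
  })
})
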