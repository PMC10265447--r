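test_that("roc_auc matches brute-force pair counting, including ties", {
  for (s in 1:25) {
    n <- withr_seed(s, sample(10:200, 1))
    scores <- withr_seed(s + 100, round(runif(n), 2))  # rounding forces ties
    labels <- withr_seed(s + 200, rbinom(n, 1, 0.4))
    if (length(unique(labels)) < 2) labels[1:2] <- c(0, 1)
    expect_equal(roc_auc(scores, labels), bruteforce_auc(scores, labels))
  }
})

test_that("roc_auc limits and error cases", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(roc_auc(c(0.3, 0.3), c(1, 0)), 0.5)
  expect_error(roc_auc(c(1, 2), c(1, 1)), "both classes")
  expect_error(roc_auc(c(1, 2), c(1, 2)), "labels")
})

test_that("roc_auc is symmetric under score negation without ties", {
  for (s in 1:10) {
    scores <- withr_seed(s, runif(80))
    labels <- withr_seed(s + 50, rbinom(80, 1, 0.5))
    if (length(unique(labels)) < 2) labels[1:2] <- c(0, 1)
    expect_equal(roc_auc(-scores, labels), 1 - roc_auc(scores, labels))
  }
})

test_that("pr_auc matches exhaustive threshold enumeration on small cases", {
  cases <- list(
    list(s = c(0.9, 0.8, 0.7, 0.3, 0.2), y = c(1, 0, 1, 0, 1)),
    list(s = c(0.5, 0.5, 0.4, 0.2), y = c(1, 0, 1, 0)),
    list(s = c(0.9, 0.1), y = c(0, 1)),
    list(s = c(0.7, 0.7, 0.7), y = c(1, 1, 0)),
    list(s = c(0.6, 0.5, 0.4, 0.3, 0.2, 0.1), y = c(0, 0, 1, 1, 0, 1))
  )
  for (cs in cases)
    expect_equal(pr_auc(cs$s, cs$y), bruteforce_prauc(cs$s, cs$y))
  for (s in 1:20) {
    y <- withr_seed(s, rbinom(9, 1, 0.5))
    if (sum(y) == 0) y[1] <- 1
    sc <- withr_seed(s + 30, round(runif(9), 1))
    expect_equal(pr_auc(sc, y), bruteforce_prauc(sc, y))
  }
})

test_that("pr_auc is 1 for perfect ranking and ~prevalence for random scores", {
  expect_equal(pr_auc(c(0.9, 0.8, 0.1, 0.2), c(1, 1, 0, 0)), 1)
  y <- withr_seed(9, rbinom(4000, 1, 0.2))
  sc <- withr_seed(10, runif(4000))
  expect_lt(abs(pr_auc(sc, y) - mean(y)), 0.05)
})

test_that("precision_recall counts and conventions", {
  # TP=2, FP=1, FN=2 at threshold 0.5
  pr <- precision_recall(c(0.9, 0.8, 0.6, 0.2, 0.3), c(1, 1, 0, 1, 1))
  expect_equal(unname(pr), c(2 / 3, 1 / 2))
  expect_equal(unname(precision_recall(c(0.9, 0.9, 0.1), c(1, 1, 0))), c(1, 1))
  expect_equal(unname(precision_recall(c(0.1, 0.2), c(1, 1))), c(0, 0))
})

test_that("mse basics and homogeneity", {
  expect_equal(mse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(mse(c(0, 0), c(1, 3)), 5)
  r1 <- mse(c(1, 4), c(0, 0))
  expect_equal(mse(3 * c(1, 4), c(0, 0)), 9 * r1)
  expect_error(mse(1:3, 1:4), "length")
})

test_that("concordance_index matches brute force and handles ties", {
  expect_equal(concordance_index(c(1, 2, 3), c(10, 20, 30)), 1)
  expect_equal(concordance_index(c(1, 2, 3), c(30, 20, 10)), 0)
  expect_equal(concordance_index(c(1, 2, 3), c(1, 3, 2)), 2 / 3)
  for (s in 1:25) {
    n <- withr_seed(s, sample(5:60, 1))
    true <- withr_seed(s + 10, round(runif(n), 1))
    pred <- withr_seed(s + 20, round(runif(n), 1))
    if (length(unique(true)) < 2) true[1] <- true[1] + 1
    expect_equal(concordance_index(true, pred), bruteforce_ci(true, pred))
  }
  expect_error(concordance_index(c(1, 1), c(1, 2)), "equal")
})

test_that("concordance index reduces to midrank AUC on binary truths", {
  for (s in 1:100) {
    n <- withr_seed(s, sample(10:80, 1))
    y <- withr_seed(s + 100, rbinom(n, 1, 0.5))
    if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
    sc <- withr_seed(s + 200, round(runif(n), 1))
    expect_equal(concordance_index(y, sc), roc_auc(sc, y))
  }
})

test_that("metrics are invariant to simultaneous permutation", {
  sc <- withr_seed(4, runif(60))
  y <- withr_seed(5, rbinom(60, 1, 0.5))
  y[1:2] <- c(0, 1)
  p <- withr_seed(6, sample(60))
  expect_equal(roc_auc(sc[p], y[p]), roc_auc(sc, y))
  expect_equal(pr_auc(sc[p], y[p]), pr_auc(sc, y))
  expect_equal(mse(sc[p], y[p]), mse(sc, y))
  expect_equal(concordance_index(y[p], sc[p]), concordance_index(y, sc))
})

test_that("metric_report appends a mean row", {
  rep <- metric_report(list(data.frame(auc = 0.8, n = 10),
                            data.frame(auc = 0.6, n = 10)))
  expect_equal(nrow(rep), 3)
  expect_equal(rep$auc[3], 0.7)
  expect_equal(rep$fold, c("1", "2", "mean"))
})
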