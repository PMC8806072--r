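test_that("confusion tallies predictions with ties counted positive", {
  cm <- confusion(c(1, 0), c(0.9, 0.1))
  expect_equal(as.numeric(cm), c(1, 1, 0, 0))
  # score exactly at the threshold predicts positive
  cm2 <- confusion(c(1, 0), c(0.5, 0.5))
  expect_equal(cm2$tp, 1L)
  expect_equal(cm2$fp, 1L)
  cm3 <- confusion(c(1, 1, 0, 0), c(0.6, 0.4, 0.6, 0.4))
  expect_equal(as.numeric(cm3[, c("tp", "tn", "fp", "fn")]), c(1, 1, 1, 1))
  expect_error(confusion(c(1, 0), 0.5), "length")
  expect_error(confusion(integer(0), numeric(0)), "Empty")
})

test_that("threshold metrics reproduce hand-evaluated values", {
  perfect <- classification_metrics(list(tp = 50, tn = 50, fp = 0, fn = 0))
  expect_equal(as.numeric(perfect[, c("se", "sp", "acc", "mcc")]),
               c(1, 1, 1, 1))
  m <- classification_metrics(list(tp = 40, tn = 30, fp = 20, fn = 10))
  expect_equal(m$se, 0.8)
  expect_equal(m$sp, 0.6)
  expect_equal(m$acc, 0.7)
  expect_equal(m$mcc, 0.4082, tolerance = 1e-3)
  # exact closed form of the sqrt denominator
  expect_equal(m$mcc, (40 * 30 - 20 * 10) / sqrt(60 * 50 * 50 * 40))
})

test_that("undefined denominators are flagged, not zeroed", {
  m <- classification_metrics(list(tp = 0, tn = 30, fp = 0, fn = 10))
  expect_equal(m$se, 0)
  expect_equal(m$sp, 1)
  expect_true(is.na(m$mcc))
  expect_match(m$undefined, "mcc")
})

test_that("label swap with complementary scores swaps SE/SP and negates MCC", {
  set.seed(19)
  y <- rbinom(60, 1, 0.5)
  s <- runif(60)
  m1 <- classification_metrics(confusion(y, s))
  # complement scores; strict ">" tie-rule mirror uses a nudged threshold
  m2 <- classification_metrics(confusion(1 - y, 1 - s + 1e-9))
  expect_equal(m1$se, m2$sp, tolerance = 1e-6)
  expect_equal(m1$sp, m2$se, tolerance = 1e-6)
  expect_equal(m1$mcc, m2$mcc, tolerance = 1e-6)
})

test_that("auc_score matches examples, the pairwise oracle and pROC", {
  expect_equal(auc_score(c(1, 1, 0, 0), c(0.9, 0.8, 0.2, 0.1)), 1)
  expect_equal(auc_score(c(1, 1, 0, 0), c(0.8, 0.4, 0.6, 0.2)), 0.75)
  expect_equal(auc_score(c(1, 0), c(0.5, 0.5)), 0.5)
  expect_error(auc_score(c(1, 1), c(0.2, 0.3)), "both classes")

  brute_auc <- function(y, s) {
    pos <- s[y == 1]; neg <- s[y == 0]
    tot <- 0
    for (p in pos) for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
    tot / (length(pos) * length(neg))
  }
  set.seed(29)
  for (i in 1:15) {
    n <- sample(10:200, 1)
    y <- c(1, 0, rbinom(n - 2, 1, 0.5))
    s <- round(runif(n), sample(1:3, 1))  # force some ties
    expect_equal(auc_score(y, s), brute_auc(y, s))
  }
  y <- c(1, 0, rbinom(98, 1, 0.5))
  s <- runif(100)
  expect_equal(auc_score(y, s),
               as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                               levels = c(0, 1), direction = "<"))))
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(37)
  y <- c(1, 0, rbinom(58, 1, 0.5))
  s <- runif(60)
  a <- auc_score(y, s)
  expect_equal(auc_score(y, 10 * s - 2), a)
  expect_equal(auc_score(y, exp(s)), a)
  expect_equal(auc_score(y, rank(s)), a)
})

test_that("evaluate_scores and aggregate_metrics build Table-style summaries", {
  set.seed(43)
  reports <- lapply(1:37, function(i) {
    y <- c(1, 0, rbinom(38, 1, 0.5))
    s <- runif(40) + 0.3 * y
    evaluate_scores(y, s, dataset = paste0("set", i))
  })
  agg <- aggregate_metrics(reports)
  expect_equal(nrow(agg), 38L)
  expect_equal(agg$dataset[38], "AVG")
  expect_equal(agg$auc[38], mean(vapply(reports, `[[`, numeric(1), "auc")))
  one <- aggregate_metrics(reports[[1]])
  expect_equal(one$auc[1], one$auc[2])
  expect_equal(aggregate_metrics(list(
    evaluate_scores(c(1, 0), c(0.9, 0.1), dataset = "a"),
    evaluate_scores(c(1, 1, 0), c(0.9, 0.2, 0.4), dataset = "b")
  ))$auc[3], mean(c(1, 0.5)))
})

test_that("roc_points trace the curve consistently with the AUC", {
  y <- c(1, 1, 0, 0)
  s <- c(0.8, 0.4, 0.6, 0.2)
  pts <- roc_points(y, s)
  expect_equal(pts$fpr[1], 0)
  expect_equal(pts$tpr[nrow(pts)], 1)
  # trapezoidal integral equals the rank-based AUC
  trap <- sum(diff(pts$fpr) * (head(pts$tpr, -1) + tail(pts$tpr, -1)) / 2)
  expect_equal(trap, auc_score(y, s))
  p <- plot_roc(y, s)
  expect_s3_class(p, "ggplot")
})
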