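test_that("vote weights follow the closed-form AdaBoost alpha", {
  expect_equal(adaboost_alpha(0.25), 0.5 * log(3))
  expect_equal(adaboost_alpha(0.5), 0)
  expect_equal(adaboost_alpha(0.7), 0)
  expect_true(is.finite(adaboost_alpha(0)))
  expect_gt(adaboost_alpha(0.01), adaboost_alpha(0.1))
})

test_that("weight update places half the mass on misclassified samples", {
  set.seed(13)
  n <- 40
  w <- runif(n); w <- w / sum(w)
  mis <- rbinom(n, 1, 0.3) == 1
  eps <- sum(w[mis])
  w2 <- adaboost_reweight(w, mis, adaboost_alpha(eps))
  expect_equal(sum(w2), 1, tolerance = 1e-12)
  expect_equal(sum(w2[mis]), 0.5, tolerance = 1e-9)
})

test_that("systematic resampling with uniform weights is the identity", {
  set.seed(14)
  expect_identical(circrbp:::systematic_resample(rep(1 / 50, 50)), 1:50)
  # non-uniform weights: counts proportional to n * w within one copy
  w <- c(0.5, rep(0.5 / 49, 49))
  idx <- circrbp:::systematic_resample(w)
  expect_length(idx, 50)
  expect_gte(sum(idx == 1), 25)
})

test_that("boosting rounds reweight as in discrete AdaBoost", {
  prob <- tiny_problem(n_per_class = 15, seed = 105)
  ed <- prob$enc$train
  # fixed deterministic scorer: right on ~3/4 of samples
  set.seed(15)
  base_scores <- ifelse(ed$y == 1, 0.9, 0.1)
  wrong <- sample(length(ed$y), round(length(ed$y) / 4))
  base_scores[wrong] <- 1 - base_scores[wrong]
  scorer <- function(batch) {
    n <- circrbp:::n_batch_samples(batch)
    if (n == length(base_scores)) base_scores else rep(0.5, n)
  }
  ens <- adaboost_train(ed, prob$enc$validation, n_rounds = 2L,
                        base_trainer = fake_base_trainer(scorer),
                        predict_fun = fake_predict, seed = 1L)
  expect_s3_class(ens, "crbp_ensemble")
  expect_equal(ens$epsilons[1], length(wrong) / length(ed$y),
               tolerance = 1e-12)
  expect_equal(ens$alphas[1], adaboost_alpha(ens$epsilons[1]))
  # round 2 sees reweighted data in which the same scorer has error 1/2
  expect_equal(ens$epsilons[2], 0.5, tolerance = 1e-9)
  expect_equal(ens$alphas[2], 0)
  expect_equal(nrow(tidy(ens)), 2L)
})

test_that("a single-round ensemble ranks exactly like its base model", {
  prob <- tiny_problem(n_per_class = 10, seed = 106)
  mc <- tiny_model_config(seed = 2)
  tc <- tiny_train_config(epochs = 2L)
  ens <- adaboost_train(prob$enc$train, prob$enc$validation, n_rounds = 1L,
                        config = mc, tconfig = tc, seed = 31L)
  s_ens <- ensemble_predict(ens, prob$enc$test)
  s_base <- predict_scores(ens$members[[1]], prob$enc$test)
  expect_equal(order(s_ens), order(s_base))
  expect_equal(s_ens, s_base, tolerance = 1e-12)
})

test_that("ensemble scores are the alpha-weighted mean of member scores", {
  mk <- function(s) structure(list(score_fn = function(b) s),
                              class = "fake_member")
  batch <- list(x = list(knf = matrix(0, 1, 84)))
  ens <- structure(
    list(members = list(mk(0.2), mk(0.8)), alphas = c(1, 1),
         epsilons = c(0.1, 0.1), n_rounds = 2L, threshold = 0.5,
         seeds = c(1L, 2L), predict_fun = fake_predict),
    class = "crbp_ensemble"
  )
  expect_equal(ensemble_predict(ens, batch), 0.5)
  ens$alphas <- c(1, 0)
  ens$members <- list(mk(0.9), mk(0.1))
  expect_equal(ensemble_predict(ens, batch), 0.9)
  # all-zero alphas fall back to the unweighted mean
  ens$alphas <- c(0, 0)
  expect_equal(ensemble_predict(ens, batch), 0.5)
  # hard votes threshold member scores first
  ens$alphas <- c(1, 1)
  expect_equal(ensemble_predict(ens, batch, hard_votes = TRUE), 0.5)
  ens$members <- list(mk(0.9), mk(0.6))
  expect_equal(ensemble_predict(ens, batch, hard_votes = TRUE), 1)
})

test_that("ensemble scores are monotone in a positively weighted member", {
  mk <- function(s) structure(list(score_fn = function(b) s),
                              class = "fake_member")
  batch <- list(x = list(knf = matrix(0, 1, 84)))
  base <- structure(
    list(members = list(mk(0.3), mk(0.6)), alphas = c(0.7, 1.3),
         epsilons = c(0.2, 0.1), n_rounds = 2L, threshold = 0.5,
         seeds = c(1L, 2L), predict_fun = fake_predict),
    class = "crbp_ensemble"
  )
  lo <- ensemble_predict(base, batch)
  base$members[[1]] <- mk(0.9)
  hi <- ensemble_predict(base, batch)
  expect_gt(hi, lo)
  expect_true(lo >= 0 && hi <= 1)
})
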