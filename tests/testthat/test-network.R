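test_that("self_attention follows the sigmoid-weighted closed form", {
  # zero input: weights sigmoid(0) = 0.5, output 0.5 * 0 = 0, exactly
  Z <- matrix(0, 5, 8)
  expect_identical(self_attention(Z), Z)
  # single position: output = sigmoid(||x||^2 / sqrt(d)) * x
  x <- matrix(c(0.3, -1.2, 0.5, 2), 1)
  w <- 1 / (1 + exp(-sum(x^2) / sqrt(4)))
  expect_equal(self_attention(x), w * x)
  # shape preservation
  set.seed(3)
  H <- matrix(rnorm(20 * 8), 20, 8)
  expect_equal(dim(self_attention(H)), dim(H))
  expect_error(self_attention(matrix(NaN, 2, 2)), "finite")
})

test_that("default build reports the reference architecture", {
  net <- build_model(model_config(seed = 1),
                     channel_shapes = tiny_shapes(L = 101L, embed_dim = 32L))
  arch <- architecture_summary(net)
  expect_equal(length(unique(grep("^msrb", arch$block, value = TRUE))), 6L)
  pc <- dplyr::filter(arch, grepl("^pc_", layer), type != "bn")
  expect_true(all(pc$size == 128L))
  fusion <- dplyr::filter(arch, layer == "fusion")
  expect_equal(fusion$size, 192L)
  expect_equal(fusion$kernel, 1L)
  drop <- dplyr::filter(arch, type == "dropout")
  expect_equal(nrow(drop), 1L)
  expect_equal(drop$rate, 0.4)
  # 6 blocks x 3 conv layers per branch family
  k3 <- dplyr::filter(arch, type == "conv", branch == "k3")
  k5 <- dplyr::filter(arch, type == "conv", branch == "k5")
  expect_equal(nrow(k3), 18L)
  expect_equal(nrow(k5), 18L)
  expect_s3_class(glance(net), "tbl_df")
  expect_identical(tidy(net), arch)
})

test_that("shallower and deeper MSRB cascades both build and run", {
  x <- tiny_problem(n_per_class = 6, seed = 90)$enc$train
  for (k in c(1L, 2L, 3L)) {
    net <- build_model(tiny_model_config(n_msrb = k), tiny_shapes())
    s <- predict_scores(net, x)
    expect_length(s, length(x$y))
    expect_true(all(s > 0 & s < 1))
  }
})

test_that("prediction is deterministic and equivariant to batch order", {
  prob <- tiny_problem(n_per_class = 8, seed = 91)
  net <- build_model(tiny_model_config(), tiny_shapes())
  ed <- prob$enc$train
  s1 <- predict_scores(net, ed)
  s2 <- predict_scores(net, ed)
  expect_identical(s1, s2)
  perm <- sample(length(ed$y))
  sp <- predict_scores(net, circrbp:::encoded_subset(ed, perm))
  expect_equal(sp, s1[perm], tolerance = 1e-12)
  expect_true(all(s1 > 0 & s1 < 1))
})

test_that("missing channels and shape mismatches are rejected", {
  net <- build_model(tiny_model_config(), tiny_shapes())
  ed <- tiny_problem(n_per_class = 8, seed = 92)$enc$train
  x_bad <- ed$x
  x_bad$anf <- NULL
  expect_error(predict_scores(net, x_bad), "anf")
  x_bad2 <- ed$x
  x_bad2$eiip <- x_bad2$eiip[, 1:10, , drop = FALSE]
  expect_error(predict_scores(net, x_bad2), "mismatch")
})

test_that("analytic gradients agree with central differences", {
  prob <- tiny_problem(n_per_class = 8, seed = 93)
  ed <- prob$enc$train
  sub <- circrbp:::encoded_subset(ed, 1:4)
  net <- build_model(tiny_model_config(dropout_rate = 0), tiny_shapes())
  fw <- circrbp:::network_forward(net, sub$x, training = TRUE,
                                  want_cache = TRUE)
  p <- 1 / (1 + exp(-fw$logit))
  G <- circrbp:::network_backward(net, sub$x, fw$caches,
                                  (p - sub$y) / length(sub$y))
  loss_at <- function(m) {
    f <- circrbp:::network_forward(m, sub$x, training = TRUE,
                                   want_cache = FALSE)
    circrbp:::bce_loss(f$logit, sub$y)
  }
  set.seed(5)
  # probe a spread of units: conv, bn, gru and dense parameters
  for (nm in c("pc_eiip", "shallow_bn", "msrb1_comb", "gru_fwd", "out")) {
    tn <- sample(names(G[[nm]]), 1)
    i <- sample(length(G[[nm]][[tn]]), 1)
    eps <- 1e-5
    m2 <- net
    m2$P[[nm]][[tn]][i] <- m2$P[[nm]][[tn]][i] + eps
    up <- loss_at(m2)
    m2$P[[nm]][[tn]][i] <- m2$P[[nm]][[tn]][i] - 2 * eps
    dn <- loss_at(m2)
    num <- (up - dn) / (2 * eps)
    expect_equal(G[[nm]][[tn]][i], num, tolerance = 1e-4)
  }
})

test_that("one optimisation step moves every trainable layer", {
  prob <- tiny_problem(n_per_class = 6, seed = 94)
  net <- build_model(tiny_model_config(dropout_rate = 0), tiny_shapes())
  fit <- train_model(net, prob$enc$train, prob$enc$validation,
                     tiny_train_config(epochs = 1L))
  before <- net$P
  after <- fit$model$P
  moved <- vapply(names(before), function(nm) {
    tns <- circrbp:::trainable_tensors(before[[nm]]$type)
    if (length(tns) == 0) return(TRUE)
    any(vapply(tns, function(tt) {
      any(abs(before[[nm]][[tt]] - after[[nm]][[tt]]) > 0)
    }, logical(1)))
  }, logical(1))
  expect_true(all(moved))
})
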