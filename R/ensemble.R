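# Discrete AdaBoost over network base learners. Weighted training is
# realised by resampling: each round draws a bootstrap of the training set
# with probability proportional to the current sample weights and trains a
# fresh base model on it, leaving the base trainer unchanged.

#' AdaBoost vote weight for a given weighted error
#'
#' `alpha = 0.5 * log((1 - eps) / eps)` with `eps` clipped to
#' `[1e-10, 1 - 1e-10]`; rounds no better than chance (`eps >= 0.5`) are
#' floored at 0 so the member keeps zero vote.
#'
#' @param eps Weighted training error in `[0, 1]`.
#' @return Non-negative vote weight.
#' @examples
#' adaboost_alpha(0.25)  # 0.5 * log(3)
#' @export
adaboost_alpha <- function(eps) {
  eps <- pmin(pmax(eps, 1e-10), 1 - 1e-10)
  pmax(0, 0.5 * log((1 - eps) / eps))
}

#' AdaBoost sample-weight update
#'
#' Multiplies misclassified samples by `exp(alpha)` and correctly
#' classified ones by `exp(-alpha)`, then renormalises to sum 1. With
#' `alpha` computed from the exact weighted error, the updated mass on the
#' misclassified samples equals 1/2.
#'
#' @param w Current sample weights (sum 1).
#' @param misclassified Logical vector.
#' @param alpha Vote weight of the round.
#' @return Updated weights summing to 1.
#' @export
adaboost_reweight <- function(w, misclassified, alpha) {
  w <- w * exp(ifelse(misclassified, alpha, -alpha))
  w / sum(w)
}

#' Train an AdaBoost ensemble of base networks
#'
#' Starts from uniform sample weights. Each round resamples the training
#' set proportionally to the weights, trains a fresh base model, computes
#' the weighted 0/1 error at threshold 0.5 on the *original* training set,
#' assigns the vote weight [adaboost_alpha()], and reweights the samples
#' with [adaboost_reweight()].
#'
#' @param train,val Encoded labelled datasets (see [encode_dataset()]).
#' @param n_rounds Number of boosting rounds (default 3).
#' @param config A [model_config()] for the base networks.
#' @param tconfig A [train_config()] for the base trainer.
#' @param seed Master seed; per-round seeds are derived from it.
#' @param base_trainer Optional replacement trainer
#'   `function(train, val, round_seed) -> member`; the default builds and
#'   trains a [build_model()] network.
#' @param predict_fun Function `(member, encoded_dataset) -> scores`;
#'   defaults to [predict_scores()].
#' @param quiet Suppress per-round log lines.
#' @return An object of class `crbp_ensemble` with members, vote weights
#'   (`alphas`), weighted errors (`epsilons`) and the decision threshold.
#' @export
adaboost_train <- function(train, val, n_rounds = 3L,
                           config = model_config(),
                           tconfig = train_config(),
                           seed = 1L,
                           base_trainer = NULL,
                           predict_fun = predict_scores,
                           quiet = TRUE) {
  n_rounds <- check_count(n_rounds, "n_rounds")
  if (is.null(train$y) || length(unique(train$y)) < 2) {
    abort("Training data must be labelled with both classes present.")
  }
  if (is.null(base_trainer)) {
    base_trainer <- function(train_sub, val_sub, round_seed) {
      mc <- config
      mc$seed <- round_seed
      L <- dim(train_sub$x$eiip)[2]
      shapes <- list(
        knf = c(1L, ncol(train_sub$x$knf)),
        doc2vec = c(1L, ncol(train_sub$x$doc2vec)),
        eiip = c(L, 1L), ncp = c(L, 3L), anf = c(L, 1L)
      )
      tc <- tconfig
      tc$seed <- derive_seed(round_seed, 17L)
      net <- build_model(mc, shapes)
      fit <- train_model(net, train_sub, val_sub, tc)
      m <- fit$model
      attr(m, "history") <- fit$history
      m
    }
  }
  n <- length(train$y)
  w <- rep(1 / n, n)
  members <- vector("list", n_rounds)
  alphas <- numeric(n_rounds)
  epsilons <- numeric(n_rounds)
  seeds <- integer(n_rounds)
  for (t in seq_len(n_rounds)) {
    round_seed <- derive_seed(seed, 100L + t)
    seeds[t] <- round_seed
    res_idx <- with_seed(derive_seed(seed, 200L + t), systematic_resample(w))
    member <- base_trainer(encoded_subset(train, res_idx), val, round_seed)
    scores <- predict_fun(member, train)
    pred <- as.integer(scores >= 0.5)
    mis <- pred != train$y
    eps <- sum(w[mis])
    alpha <- adaboost_alpha(eps)
    w <- adaboost_reweight(w, mis, alpha)
    members[[t]] <- member
    alphas[t] <- alpha
    epsilons[t] <- eps
    if (!quiet) {
      message(sprintf("round %d: weighted error %.4f, alpha %.4f",
                      t, eps, alpha))
    }
  }
  structure(
    list(members = members, alphas = alphas, epsilons = epsilons,
         n_rounds = n_rounds, threshold = 0.5, seeds = seeds,
         predict_fun = predict_fun),
    class = "crbp_ensemble"
  )
}

#' Score samples with an AdaBoost ensemble
#'
#' Alpha-weighted mean of the members' continuous sigmoid scores,
#' `sum(alpha_t * s_t) / sum(alpha_t)`, so the output remains a
#' probability-like score in `[0, 1]`. If every vote weight is 0 the plain
#' mean is used. With `hard_votes = TRUE` the members contribute their 0/1
#' decisions instead (strict discrete-AdaBoost semantics).
#'
#' @param ensemble A [adaboost_train()] ensemble.
#' @param batch An encoded dataset or channel list.
#' @param hard_votes Use thresholded member decisions instead of scores.
#' @return Numeric scores in `[0, 1]`.
#' @export
ensemble_predict <- function(ensemble, batch, hard_votes = FALSE) {
  stopifnot(inherits(ensemble, "crbp_ensemble"))
  if (length(ensemble$members) == 0) abort("Empty ensemble.")
  S <- vapply(ensemble$members, function(m) {
    s <- ensemble$predict_fun(m, batch)
    if (hard_votes) as.numeric(s >= ensemble$threshold) else s
  }, numeric(n_batch_samples(batch)))
  if (is.null(dim(S))) S <- matrix(S, nrow = 1)
  a <- ensemble$alphas
  if (sum(a) <= 0) a <- rep(1, length(ensemble$members))
  as.numeric(S %*% a) / sum(a)
}

# Systematic (low-variance) resampling proportional to the sample weights:
# each sample receives close to n * w_i copies, with a single shared
# uniform offset. With exactly uniform weights this reduces to the identity
# sample, so the first boosting round trains on the full training set.
systematic_resample <- function(w) {
  n <- length(w)
  u <- (runif(1) + seq_len(n) - 1) / n
  cw <- cumsum(w) / sum(w)
  findInterval(u, cw, left.open = TRUE) + 1L
}

n_batch_samples <- function(batch) {
  x <- if (!is.null(batch$x)) batch$x else batch
  nrow(x$knf)
}

#' @export
tidy.crbp_ensemble <- function(x, ...) {
  tibble(round = seq_len(x$n_rounds), alpha = x$alphas,
         epsilon = x$epsilons, seed = x$seeds)
}

#' @export
glance.crbp_ensemble <- function(x, ...) {
  tibble(n_rounds = x$n_rounds, alpha_total = sum(x$alphas),
         mean_epsilon = mean(x$epsilons), threshold = x$threshold)
}

#' @export
print.crbp_ensemble <- function(x, ...) {
  cat(sprintf("<crbp_ensemble> %d rounds, alphas: %s\n", x$n_rounds,
              paste(sprintf("%.3f", x$alphas), collapse = ", ")))
  invisible(x)
}
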