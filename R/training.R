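# Single-model training: Adam on binary cross-entropy with configurable
# learning-rate schedules, early stopping on validation loss, and per-epoch
# history logging.

#' Training configuration
#'
#' Defaults follow the reference setup: Adam with initial learning rate
#' 0.001, 30 training epochs (raiseable to the 200-epoch schedule horizon),
#' batch size 50, early stopping on validation loss.
#'
#' @param base_lr Initial learning rate (default 0.001).
#' @param schedule One of `"adam_default"` (constant base rate, Adam's own
#'   adaptation), `"step"`, `"linear"`, `"polynomial"`, `"fixed"`.
#' @param epochs Training epochs (default 30).
#' @param max_epochs Schedule horizon (default 200); `epochs <= max_epochs`.
#' @param batch_size Mini-batch size (default 50).
#' @param patience Early-stopping patience in epochs (default 5).
#' @param min_delta Minimum validation-loss improvement (default 1e-4).
#' @param gamma,step_size Step-schedule decay factor and period.
#' @param power Polynomial-schedule exponent.
#' @param seed Seed controlling shuffling and dropout.
#' @return A list of class `crbp_train_config`.
#' @export
train_config <- function(base_lr = 0.001, schedule = "adam_default",
                         epochs = 30L, max_epochs = 200L, batch_size = 50L,
                         patience = 5L, min_delta = 1e-4,
                         gamma = 0.5, step_size = 10L, power = 2,
                         seed = 1L) {
  if (base_lr <= 0) abort("`base_lr` must be positive.")
  epochs <- check_count(epochs, "epochs")
  max_epochs <- check_count(max_epochs, "max_epochs")
  if (epochs > max_epochs) abort("`epochs` must be <= `max_epochs`.")
  structure(
    list(base_lr = base_lr, schedule = schedule, epochs = epochs,
         max_epochs = max_epochs,
         batch_size = check_count(batch_size, "batch_size"),
         patience = check_count(patience, "patience"),
         min_delta = min_delta, gamma = gamma,
         step_size = check_count(step_size, "step_size"), power = power,
         seed = as.integer(seed)),
    class = "crbp_train_config"
  )
}

#' Learning rate at a given epoch
#'
#' Schedules: `fixed` and `adam_default` are constant at `base_lr` (for
#' `adam_default` the per-parameter adaptation is left to Adam itself);
#' `step` decays by `gamma` every `step_size` epochs; `linear` decays to 0
#' at `max_epochs`; `polynomial` decays as `(1 - epoch/max_epochs)^power`.
#'
#' @param schedule Schedule name.
#' @param epoch 0-based epoch index.
#' @param base_lr Initial learning rate.
#' @param max_epochs Horizon for the decaying schedules.
#' @param gamma,step_size,power Schedule hyperparameters.
#' @return The learning rate (a single number).
#' @examples
#' lr_at("step", 25, 0.001, gamma = 0.5, step_size = 10)  # 0.001 * 0.5^2
#' @export
lr_at <- function(schedule, epoch, base_lr, max_epochs = 200L,
                  gamma = 0.5, step_size = 10L, power = 2) {
  if (epoch < 0) abort("`epoch` must be >= 0.")
  switch(schedule,
    fixed = base_lr,
    adam_default = base_lr,
    step = base_lr * gamma^(epoch %/% step_size),
    linear = base_lr * (1 - epoch / max_epochs),
    polynomial = base_lr * (1 - epoch / max_epochs)^power,
    abort(sprintf("Unknown learning-rate schedule '%s'.", schedule))
  )
}

# Numerically stable binary cross-entropy on logits.
bce_loss <- function(logit, y) {
  mean(pmax(logit, 0) - logit * y + log1p(exp(-abs(logit))))
}

init_adam <- function(P) {
  lapply(P, function(u) {
    tn <- trainable_tensors(u$type)
    if (length(tn) == 0) return(NULL)
    setNames(lapply(tn, function(t) list(m = 0 * u[[t]], v = 0 * u[[t]])), tn)
  })
}

adam_step <- function(P, G, A, lr, t, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  for (nm in names(G)) {
    tn <- trainable_tensors(P[[nm]]$type)
    for (tt in tn) {
      g <- G[[nm]][[tt]]
      st <- A[[nm]][[tt]]
      st$m <- beta1 * st$m + (1 - beta1) * g
      st$v <- beta2 * st$v + (1 - beta2) * g^2
      mhat <- st$m / (1 - beta1^t)
      vhat <- st$v / (1 - beta2^t)
      P[[nm]][[tt]] <- P[[nm]][[tt]] - lr * mhat / (sqrt(vhat) + eps)
      A[[nm]][[tt]] <- st
    }
  }
  list(P = P, A = A)
}

#' Train a base network
#'
#' Minimises binary cross-entropy with Adam. The validation set monitors
#' convergence: training stops early when the validation loss has not
#' improved by `min_delta` for `patience` consecutive epochs, and the
#' weights achieving the best validation loss are restored.
#'
#' @param model A [build_model()] network.
#' @param train,val Encoded datasets (see [encode_dataset()]) with labels;
#'   must be disjoint and each contain both classes.
#' @param config A [train_config()].
#' @param quiet Suppress per-epoch log lines (default TRUE).
#' @return An object of class `crbp_fit`: list with `model` (trained
#'   network, best-validation weights restored) and `history` (one tibble
#'   row per completed epoch: losses, accuracies, learning rate).
#' @export
train_model <- function(model, train, val, config = train_config(),
                        quiet = TRUE) {
  stopifnot(inherits(model, "crbp_network"),
            inherits(config, "crbp_train_config"))
  for (ds in list(train, val)) {
    if (is.null(ds$y) || length(ds$y) == 0) abort("Empty or unlabelled split.")
    if (length(unique(ds$y)) < 2) {
      abort("Each split must contain both classes.")
    }
  }
  n <- length(train$y)
  hist_rows <- list()
  state <- with_seed(config$seed, {
    A <- init_adam(model$P)
    t_step <- 0L
    best_val <- Inf
    best_P <- model$P
    wait <- 0L
    for (epoch in seq_len(config$epochs)) {
      lr <- lr_at(config$schedule, epoch - 1L, config$base_lr,
                  config$max_epochs, config$gamma, config$step_size,
                  config$power)
      idx <- sample(n)
      ep_loss <- 0; ep_acc <- 0; ep_n <- 0L
      for (start in seq.int(1L, n, by = config$batch_size)) {
        bidx <- idx[start:min(n, start + config$batch_size - 1L)]
        sub <- encoded_subset(train, bidx)
        fw <- network_forward(model, sub$x, training = TRUE,
                              want_cache = TRUE)
        model$P <- fw$P  # batch-norm running statistics
        p <- sigmoid_(fw$logit)
        loss <- bce_loss(fw$logit, sub$y)
        dlogit <- (p - sub$y) / length(bidx)
        G <- network_backward(model, sub$x, fw$caches, dlogit)
        t_step <- t_step + 1L
        up <- adam_step(model$P, G, A, lr, t_step)
        model$P <- up$P
        A <- up$A
        nb <- length(bidx)
        ep_loss <- ep_loss + loss * nb
        ep_acc <- ep_acc + sum((p >= 0.5) == sub$y)
        ep_n <- ep_n + nb
      }
      val_eval <- evaluate_loss(model, val)
      hist_rows[[epoch]] <- tibble(
        epoch = epoch, lr = lr,
        train_loss = ep_loss / ep_n, train_acc = ep_acc / ep_n,
        val_loss = val_eval$loss, val_acc = val_eval$acc
      )
      if (!quiet) {
        message(sprintf(
          "epoch %3d  lr %.5f  train loss %.4f acc %.3f | val loss %.4f acc %.3f",
          epoch, lr, ep_loss / ep_n, ep_acc / ep_n, val_eval$loss,
          val_eval$acc
        ))
      }
      if (val_eval$loss < best_val - config$min_delta) {
        best_val <- val_eval$loss
        best_P <- model$P
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= config$patience) break
      }
    }
    list(best_P = best_P, best_val = best_val)
  })
  model$P <- state$best_P
  structure(
    list(model = model, history = dplyr::bind_rows(hist_rows),
         best_val_loss = state$best_val, config = config),
    class = "crbp_fit"
  )
}

# Loss and accuracy of a model on an encoded dataset (inference mode).
evaluate_loss <- function(model, ds, batch_size = 256L) {
  n <- length(ds$y)
  logits <- numeric(n)
  for (start in seq.int(1L, n, by = batch_size)) {
    idx <- start:min(n, start + batch_size - 1L)
    sub <- encoded_subset(ds, idx)
    logits[idx] <- network_forward(model, sub$x)$logit
  }
  p <- sigmoid_(logits)
  list(loss = bce_loss(logits, ds$y), acc = mean((p >= 0.5) == ds$y))
}

#' @export
tidy.crbp_fit <- function(x, ...) x$history

#' @export
glance.crbp_fit <- function(x, ...) {
  h <- x$history
  tibble(
    epochs_run = nrow(h),
    best_val_loss = x$best_val_loss,
    final_train_loss = h$train_loss[nrow(h)],
    final_train_acc = h$train_acc[nrow(h)],
    final_val_acc = h$val_acc[nrow(h)]
  )
}

#' Plot a training history
#'
#' @param object A `crbp_fit` from [train_model()].
#' @param ... Unused.
#' @return A ggplot object with loss and accuracy traces per epoch.
#' @export
autoplot.crbp_fit <- function(object, ...) {
  long <- object$history %>%
    dplyr::select("epoch", "train_loss", "val_loss", "train_acc", "val_acc") %>%
    tidyr::pivot_longer(-"epoch", names_to = c("split", "metric"),
                        names_sep = "_") %>%
    dplyr::mutate(metric = dplyr::recode(.data$metric, loss = "loss",
                                         acc = "accuracy"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$value,
                                     colour = .data$split)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::theme_minimal() +
    ggplot2::labs(y = NULL)
}
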