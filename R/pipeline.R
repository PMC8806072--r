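# End-to-end pipeline: redundancy filter -> stratified split -> embedding
# training -> encoding -> AdaBoost training -> held-out evaluation, with
# optional artifact output (metrics TSV, history CSV, checkpoint, manifest).

#' Default pipeline configuration
#'
#' Nested configuration consumed by [run_pipeline()] and the `train`
#' command. Unknown keys are rejected on resolution.
#'
#' @return Nested named list with sections `redundancy`, `split`,
#'   `embedding`, `model`, `train`, `ensemble` and a global `seed`.
#' @export
pipeline_config <- function() {
  list(
    redundancy = list(threshold = 0.8),
    split = list(train_fraction = 0.8, val_fraction_of_train = 0.2),
    embedding = list(k = 10L, embed_dim = 32L, window = 5L, epochs = 20L,
                     negative = 5L, stride = 1L, min_count = 1L),
    model = unclass(model_config())[
      setdiff(names(unclass(model_config())), "seed")],
    train = unclass(train_config())[
      setdiff(names(unclass(train_config())), "seed")],
    ensemble = list(n_rounds = 3L),
    seed = 1L
  )
}

# Merge a user configuration into the defaults, rejecting unknown keys.
resolve_pipeline_config <- function(user = list()) {
  base <- pipeline_config()
  if (length(user) == 0) return(base)
  bad_top <- setdiff(names(user), names(base))
  if (length(bad_top) > 0) {
    abort(paste0("Unknown config key(s): ", paste(bad_top, collapse = ", ")))
  }
  for (sec in names(user)) {
    if (sec == "seed") {
      base$seed <- as.integer(user$seed)
      next
    }
    bad <- setdiff(names(user[[sec]]), names(base[[sec]]))
    if (length(bad) > 0) {
      abort(paste0("Unknown config key(s) in '", sec, "': ",
                   paste(bad, collapse = ", ")))
    }
    base[[sec]] <- modifyList(base[[sec]], user[[sec]])
  }
  base
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("[%s] %s", name, conditionMessage(e)))
  })
}

#' Run the full training pipeline on a labelled record table
#'
#' @param records Tibble with `id`, `sequence`, `label` (1 = binding site).
#' @param config Nested configuration (see [pipeline_config()]); partial
#'   lists are merged into the defaults.
#' @param out_dir Optional output directory for artifacts: `metrics.tsv`,
#'   `history.csv`, `ensemble.rds` checkpoint, `manifest.json` and the
#'   resolved `config.yaml`.
#' @param dataset Dataset name used in the metrics report.
#' @param quiet Suppress stage log lines.
#' @return List with `ensemble`, `embedding`, `splits`, `test_scores`,
#'   `metrics` (test-split report), `history` (per member and epoch) and
#'   the resolved `config`.
#' @export
run_pipeline <- function(records, config = list(), out_dir = NULL,
                         dataset = "synthetic", quiet = TRUE) {
  cfg <- resolve_pipeline_config(config)
  say <- function(...) if (!quiet) message(sprintf(...))
  stage("input", {
    stopifnot(is.data.frame(records))
    if (!all(c("id", "sequence", "label") %in% names(records))) {
      abort("`records` must have columns id, sequence, label.")
    }
  })
  say("redundancy filter at identity >= %.2f", cfg$redundancy$threshold)
  filtered <- stage("redundancy_filter",
                    redundancy_filter(records, cfg$redundancy$threshold))
  say("kept %d / %d records", nrow(filtered), nrow(records))
  splits <- stage("split", split_dataset(
    filtered, cfg$split$train_fraction, cfg$split$val_fraction_of_train,
    seed = derive_seed(cfg$seed, 11L)
  ))
  say("split: %d train / %d val / %d test", nrow(splits$train),
      nrow(splits$validation), nrow(splits$test))
  embedding <- stage("embedding", rlang::exec(
    train_embedding, splits$train,
    !!!cfg$embedding, seed = derive_seed(cfg$seed, 12L)
  ))
  enc <- stage("encoding", lapply(splits, encode_dataset, embedding = embedding))
  mc <- rlang::exec(model_config, !!!cfg$model,
                    seed = derive_seed(cfg$seed, 13L))
  tc <- rlang::exec(train_config, !!!cfg$train,
                    seed = derive_seed(cfg$seed, 14L))
  say("training AdaBoost ensemble: %d round(s)", cfg$ensemble$n_rounds)
  ensemble <- stage("ensemble", adaboost_train(
    enc$train, enc$validation, n_rounds = cfg$ensemble$n_rounds,
    config = mc, tconfig = tc, seed = derive_seed(cfg$seed, 15L),
    quiet = quiet
  ))
  scores <- stage("evaluation", ensemble_predict(ensemble, enc$test))
  metrics <- evaluate_scores(enc$test$y, scores, dataset = dataset)
  say("test AUC %.4f, ACC %.4f", metrics$auc, metrics$acc)
  history <- member_histories(ensemble)
  result <- list(ensemble = ensemble, embedding = embedding,
                 splits = splits, test_scores = scores, metrics = metrics,
                 history = history, config = cfg)
  if (!is.null(out_dir)) {
    stage("artifacts", write_pipeline_artifacts(result, out_dir))
  }
  result
}

member_histories <- function(ensemble) {
  rows <- lapply(seq_along(ensemble$members), function(i) {
    h <- attr(ensemble$members[[i]], "history")
    if (is.null(h)) return(NULL)
    h$round <- i
    h
  })
  dplyr::bind_rows(rows)
}

write_pipeline_artifacts <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_tsv_plain(result$metrics, file.path(out_dir, "metrics.tsv"))
  if (nrow(result$history %||% tibble()) > 0) {
    utils::write.csv(result$history, file.path(out_dir, "history.csv"),
                     row.names = FALSE)
  }
  save_checkpoint(result$ensemble, result$embedding,
                  file.path(out_dir, "ensemble.rds"))
  manifest <- list(
    package = "circrbp",
    checkpoint_version = "circrbp-checkpoint-1",
    alphas = result$ensemble$alphas,
    epsilons = result$ensemble$epsilons,
    round_seeds = result$ensemble$seeds,
    seed = result$config$seed,
    n_test = result$metrics$n
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  yaml::write_yaml(result$config, file.path(out_dir, "config.yaml"))
  invisible(out_dir)
}

write_tsv_plain <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Save / load an ensemble checkpoint
#'
#' The checkpoint bundles the ensemble (members, alphas, seeds), the
#' paragraph-vector embedding model and a version stamp.
#'
#' @param ensemble A [adaboost_train()] ensemble.
#' @param embedding The [train_embedding()] model used for encoding.
#' @param path Checkpoint file path (RDS).
#' @return `path` (save) or the checkpoint list (load), invisibly/visibly.
#' @export
save_checkpoint <- function(ensemble, embedding, path) {
  # predict_fun may be a closure over package internals; store its name
  # semantics implicitly by dropping it and restoring the default on load.
  ens <- ensemble
  ens$predict_fun <- NULL
  saveRDS(list(version = "circrbp-checkpoint-1", ensemble = ens,
               embedding = embedding,
               window_length = infer_window_length(ensemble)),
          path)
  invisible(path)
}

infer_window_length <- function(ensemble) {
  m <- ensemble$members[[1]]
  if (inherits(m, "crbp_network")) m$L else NA_integer_
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) abort(sprintf("Checkpoint '%s' does not exist.", path))
  ck <- tryCatch(readRDS(path), error = function(e) {
    abort(sprintf("Checkpoint '%s' is unreadable or corrupted: %s",
                  path, conditionMessage(e)))
  })
  if (!is.list(ck) || !identical(ck$version, "circrbp-checkpoint-1")) {
    abort(sprintf(
      "Checkpoint '%s' has an incompatible version (expected %s).",
      path, "circrbp-checkpoint-1"
    ))
  }
  ck$ensemble$predict_fun <- predict_scores
  class(ck$ensemble) <- "crbp_ensemble"
  ck
}
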