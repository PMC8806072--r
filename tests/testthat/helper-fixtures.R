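# Shared fixtures: everything is generated in code at test time.

write_tmp_fasta <- function(lines) {
  tf <- tempfile(fileext = ".fa")
  writeLines(lines, tf)
  tf
}

random_seq <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# A very small encoded dataset (window 41 nt, 6-nt consensus motif) plus
# matching tiny model/training configurations, used by every test that has
# to train a real network.
tiny_problem <- function(n_per_class = 30, seed = 303) {
  records <- generate_dataset(
    n_per_class, n_per_class, window_length = 41L,
    motif = motif_spec("ACGGAG", occupancy = 1), seed = seed
  )
  splits <- split_dataset(records, seed = seed)
  emb <- train_embedding(splits$train, k = 4L, embed_dim = 8L, epochs = 5L,
                         seed = seed + 1L)
  enc <- lapply(splits, encode_dataset, embedding = emb)
  list(records = records, splits = splits, embedding = emb, enc = enc)
}

tiny_model_config <- function(seed = 7L, dropout_rate = 0.1, n_msrb = 1L) {
  model_config(
    per_channel_filters = 4L, n_msrb = n_msrb, msrb_filters = 8L,
    msrb_conv_layers = 1L, fusion_filters = 8L, dropout_rate = dropout_rate,
    gru_units = 4L, dense_units = 8L, seed = seed
  )
}

tiny_shapes <- function(L = 41L, embed_dim = 8L) {
  list(knf = c(1L, 84L), doc2vec = c(1L, embed_dim),
       eiip = c(L, 1L), ncp = c(L, 3L), anf = c(L, 1L))
}

tiny_train_config <- function(epochs = 3L, seed = 11L, ...) {
  train_config(base_lr = 0.005, epochs = epochs, batch_size = 16L,
               patience = 10L, seed = seed, ...)
}

# Deterministic stand-in base learner for AdaBoost math tests: scores each
# sample by a fixed hash of its id, independent of the training data.
fake_base_trainer <- function(score_fn) {
  function(train_sub, val_sub, round_seed) {
    structure(list(score_fn = score_fn), class = "fake_member")
  }
}

fake_predict <- function(member, batch) {
  member$score_fn(batch)
}
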