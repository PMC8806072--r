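# Paragraph-vector (PV-DM) embeddings over k-mer "words".
#
# Each sequence is a document whose words are its overlapping 10-mers. The
# distributed-memory model predicts each centre word from the mean of a
# symmetric word-context window plus the document vector, trained with
# negative sampling. Updates are vectorised per document (one parameter
# update per document per epoch), which keeps training deterministic and
# fast on a single CPU; at the corpus sizes this package targets the
# behaviour matches per-token SGD.

sigmoid_ <- function(x) 1 / (1 + exp(-x))

#' Train a PV-DM paragraph-vector embedding on a sequence corpus
#'
#' @param corpus Tibble with a `sequence` column, or a character vector of
#'   sequences. Every sequence must have length >= `k`.
#' @param k k-mer word length (default 10).
#' @param embed_dim Embedding dimension (default 32).
#' @param window Symmetric context-window half-width in words (default 5).
#' @param min_count Minimum word frequency kept in the vocabulary (default 1).
#' @param epochs Training epochs (default 20).
#' @param negative Negative samples per centre word (default 5).
#' @param stride Token stride (default 1, i.e. overlapping words).
#' @param seed Integer seed; fixed seed gives identical models.
#' @return An object of class `pv_dm_model` holding word input/output
#'   matrices, the vocabulary, and the hyperparameters.
#' @export
train_embedding <- function(corpus, k = 10L, embed_dim = 32L, window = 5L,
                            min_count = 1L, epochs = 20L, negative = 5L,
                            stride = 1L, seed = 1L) {
  seqs <- if (is.data.frame(corpus)) corpus$sequence else corpus
  if (length(seqs) == 0) abort("`corpus` must contain at least one sequence.")
  if (any(nchar(seqs) < k)) {
    abort(sprintf("All corpus sequences must have length >= k = %d.", k))
  }
  k <- check_count(k, "k"); embed_dim <- check_count(embed_dim, "embed_dim")
  epochs <- check_count(epochs, "epochs")
  docs_tok <- lapply(seqs, tokenize_kmers, k = k, stride = stride)
  vocab_tab <- table(unlist(docs_tok))
  vocab_tab <- vocab_tab[vocab_tab >= min_count]
  vocab <- names(vocab_tab)
  V <- length(vocab)
  if (V == 0) abort("Vocabulary is empty after min_count filtering.")
  doc_ids <- lapply(docs_tok, function(tok) {
    ids <- match(tok, vocab)
    ids[!is.na(ids)]
  })
  counts <- as.numeric(vocab_tab)
  neg_prob <- counts^0.75
  neg_prob <- neg_prob / sum(neg_prob)
  D <- embed_dim
  n_docs <- length(doc_ids)
  state <- with_seed(seed, {
    w_in <- matrix(runif(V * D, -0.5, 0.5) / D, V, D)
    docvecs <- matrix(runif(n_docs * D, -0.5, 0.5) / D, n_docs, D)
    w_out <- matrix(0, V, D)
    lr0 <- 0.025; lr_min <- 1e-4
    total <- epochs * n_docs
    step <- 0L
    for (ep in seq_len(epochs)) {
      for (d in seq_len(n_docs)) {
        lr <- max(lr_min, lr0 * (1 - step / total))
        upd <- pvdm_doc_step(doc_ids[[d]], docvecs[d, ], w_in, w_out,
                             window, negative, neg_prob)
        if (!is.null(upd)) {
          docvecs[d, ] <- docvecs[d, ] - lr * upd$d_doc
          w_out[upd$out_ids, ] <- w_out[upd$out_ids, , drop = FALSE] -
            lr * upd$d_out
          w_in[upd$in_ids, ] <- w_in[upd$in_ids, , drop = FALSE] -
            lr * upd$d_in
        }
        step <- step + 1L
      }
    }
    list(w_in = w_in, w_out = w_out, docvecs = docvecs)
  })
  structure(
    list(
      w_in = state$w_in, w_out = state$w_out,
      vocab = vocab, neg_prob = neg_prob,
      k = k, embed_dim = D, window = window, negative = negative,
      stride = stride, epochs = epochs, seed = as.integer(seed),
      version = "circrbp-pvdm-1"
    ),
    class = "pv_dm_model"
  )
}

# One vectorised PV-DM pass over a single document. Returns gradients for
# the doc vector, the touched output vectors and the touched input vectors,
# or NULL for documents with no in-vocabulary tokens.
pvdm_doc_step <- function(tok, docvec, w_in, w_out, window, negative,
                          neg_prob) {
  m <- length(tok)
  if (m == 0) return(NULL)
  D <- length(docvec)
  T_in <- w_in[tok, , drop = FALSE]
  ws <- window_sum_excl(T_in, window)
  idx <- seq_len(m)
  n_ctx <- pmin(idx + window, m) - pmax(idx - window, 1L)
  denom <- n_ctx + 1  # context words + the document vector
  ctx <- (ws + matrix(docvec, m, D, byrow = TRUE)) / denom
  out_pos <- w_out[tok, , drop = FALSE]
  g_pos <- sigmoid_(rowSums(ctx * out_pos)) - 1
  neg <- matrix(sample.int(length(neg_prob), m * negative, replace = TRUE,
                           prob = neg_prob), m, negative)
  d_ctx <- g_pos * out_pos
  d_out_rows <- g_pos * ctx
  out_rows_id <- tok
  for (j in seq_len(negative)) {
    nj <- neg[, j]
    collide <- nj == tok
    out_neg <- w_out[nj, , drop = FALSE]
    g_neg <- sigmoid_(rowSums(ctx * out_neg))
    g_neg[collide] <- 0
    d_ctx <- d_ctx + g_neg * out_neg
    d_out_rows <- rbind(d_out_rows, g_neg * ctx)
    out_rows_id <- c(out_rows_id, nj)
  }
  d_out_agg <- rowsum(d_out_rows, out_rows_id)
  g_scaled <- d_ctx / denom
  d_in_pos <- window_sum_excl(g_scaled, window)   # adjoint of the window sum
  d_in_agg <- rowsum(d_in_pos, tok)
  list(
    d_doc = colSums(g_scaled),
    out_ids = as.integer(rownames(d_out_agg)), d_out = d_out_agg,
    in_ids = as.integer(rownames(d_in_agg)), d_in = d_in_agg
  )
}

# Sum of rows within a symmetric window of half-width w, excluding the row
# itself. Self-adjoint, so it also backpropagates context-mean gradients.
window_sum_excl <- function(X, w) {
  m <- nrow(X)
  cs <- apply(X, 2, cumsum)
  if (m == 1L) cs <- matrix(cs, nrow = 1)
  idx <- seq_len(m)
  hi <- pmin(idx + w, m)
  lo <- pmax(idx - w, 1L)
  hi_cs <- cs[hi, , drop = FALSE]
  lo_cs <- matrix(0, m, ncol(X))
  sel <- lo > 1L
  if (any(sel)) lo_cs[sel, ] <- cs[lo[sel] - 1L, , drop = FALSE]
  hi_cs - lo_cs - X
}

#' Infer a paragraph vector for one sequence
#'
#' Freezes the word matrices of a trained PV-DM model and gradient-descends
#' a fresh document vector for the given sequence. Deterministic for a fixed
#' `inference_seed`.
#'
#' @param sequence Nucleotide string of length >= `model$k`.
#' @param model A [train_embedding()] model.
#' @param epochs Inference epochs (default 10).
#' @param inference_seed Seed for the inference RNG (default 1).
#' @return A `1 x embed_dim` numeric matrix.
#' @export
encode_doc2vec <- function(sequence, model, epochs = 10L,
                           inference_seed = 1L) {
  if (!inherits(model, "pv_dm_model")) {
    abort("`model` must be a trained pv_dm_model (see train_embedding()).")
  }
  infer_doc_vectors(sequence, model, epochs = epochs,
                    inference_seed = inference_seed)
}

#' @rdname encode_doc2vec
#' @param sequences Character vector of sequences (rows of the result).
#' @export
infer_doc_vectors <- function(sequences, model, epochs = 10L,
                              inference_seed = 1L) {
  D <- model$embed_dim
  out <- matrix(0, length(sequences), D)
  for (i in seq_along(sequences)) {
    tok <- tokenize_kmers(sequences[i], k = model$k, stride = model$stride)
    ids <- match(tok, model$vocab)
    ids <- ids[!is.na(ids)]
    out[i, ] <- with_seed(inference_seed, {
      docvec <- runif(D, -0.5, 0.5) / D
      if (length(ids) > 0) {
        m <- length(ids)
        T_in <- model$w_in[ids, , drop = FALSE]
        ws <- window_sum_excl(T_in, model$window)
        idx <- seq_len(m)
        n_ctx <- pmin(idx + model$window, m) - pmax(idx - model$window, 1L)
        denom <- n_ctx + 1
        out_pos <- model$w_out[ids, , drop = FALSE]
        lr0 <- 0.025; lr_min <- 1e-4
        for (ep in seq_len(epochs)) {
          lr <- max(lr_min, lr0 * (1 - (ep - 1) / epochs))
          ctx <- (ws + matrix(docvec, m, D, byrow = TRUE)) / denom
          g_pos <- sigmoid_(rowSums(ctx * out_pos)) - 1
          d_ctx <- g_pos * out_pos
          neg <- matrix(sample.int(length(model$neg_prob), m * model$negative,
                                   replace = TRUE, prob = model$neg_prob),
                        m, model$negative)
          for (j in seq_len(model$negative)) {
            nj <- neg[, j]
            out_neg <- model$w_out[nj, , drop = FALSE]
            g_neg <- sigmoid_(rowSums(ctx * out_neg))
            g_neg[nj == ids] <- 0
            d_ctx <- d_ctx + g_neg * out_neg
          }
          docvec <- docvec - lr * colSums(d_ctx / denom)
        }
      }
      docvec
    })
  }
  out
}
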