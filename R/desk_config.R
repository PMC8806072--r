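#' Desk-scale pipeline configuration
#'
#' A reduced configuration for CPU-scale verification runs on synthetic
#' datasets of a few hundred windows: a narrower network (16 per-channel
#' filters, two multiscale residual blocks of two convolution layers at 16
#' filters, 32-filter fusion, 16 GRU units), lighter dropout (0.1), a
#' shorter word length for the paragraph-vector vocabulary (k = 6, so that
#' a few hundred sequences share a vocabulary; 10-mer words are nearly
#' unique per sequence at this corpus size and degrade into per-sequence
#' fingerprints), and Adam at 0.005 with batch size 16 for 10 epochs. The
#' full-scale defaults of [model_config()] and [train_config()] are
#' unchanged.
#'
#' @param seed Global pipeline seed.
#' @param n_rounds Boosting rounds (default 1).
#' @param epochs Training epochs (default 10).
#' @return A nested configuration list for [run_pipeline()].
#' @export
desk_config <- function(seed = 1L, n_rounds = 1L, epochs = 10L) {
  list(
    model = list(per_channel_filters = 16L, n_msrb = 2L, msrb_filters = 16L,
                 msrb_conv_layers = 2L, fusion_filters = 32L,
                 gru_units = 16L, dense_units = 16L, dropout_rate = 0.1),
    train = list(base_lr = 0.005, epochs = as.integer(epochs),
                 batch_size = 16L, patience = 10L),
    embedding = list(k = 6L),
    ensemble = list(n_rounds = as.integer(n_rounds)),
    seed = as.integer(seed)
  )
}
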