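# The base classifier: per-channel convolutions over the five feature
# encodings, concatenation into a single position-by-feature tensor, a
# shallow convolution, a cascade of multiscale residual blocks (MSRB) with
# hierarchical feature fusion, a 1x1 fusion convolution, dropout, a
# bidirectional GRU, sigmoid self-attention, global average pooling and a
# dense sigmoid head.

CHANNEL_NAMES <- c("knf", "doc2vec", "eiip", "ncp", "anf")

#' Model architecture configuration
#'
#' Defaults follow the reference architecture: 128 convolution filters per
#' feature channel, a shallow convolution of kernel 3, six cascaded
#' multiscale residual blocks of three convolution layers at 64 filters
#' (parallel kernel-3 and kernel-5 branches), hierarchical fusion of all
#' block outputs into a 1x1 convolution with 192 filters, dropout 0.4, a
#' bidirectional GRU with 64 units per direction, and a dense head.
#'
#' @param per_channel_filters Filters of the per-channel input convolutions.
#' @param per_channel_kernel Kernel size of the per-channel convolutions.
#' @param shallow_kernel Kernel size of the shallow convolution (default 3).
#' @param n_msrb Number of multiscale residual blocks (default 6).
#' @param msrb_filters Filters inside each MSRB (default 64).
#' @param msrb_conv_layers Convolution layers per MSRB branch (default 3).
#' @param msrb_kernels Kernel sizes of the two parallel MSRB branches.
#' @param fusion_filters Filters of the 1x1 fusion convolution (default 192).
#' @param dropout_rate Dropout rate after fusion (default 0.4).
#' @param gru_units GRU units per direction (default 64).
#' @param dense_units Hidden dense layer sizes before the sigmoid output.
#' @param seed Seed for weight initialisation.
#' @return A list of class `crbp_model_config`.
#' @export
model_config <- function(per_channel_filters = 128L, per_channel_kernel = 3L,
                         shallow_kernel = 3L, n_msrb = 6L, msrb_filters = 64L,
                         msrb_conv_layers = 3L, msrb_kernels = c(3L, 5L),
                         fusion_filters = 192L, dropout_rate = 0.4,
                         gru_units = 64L, dense_units = 64L, seed = 1L) {
  cfg <- list(
    per_channel_filters = check_count(per_channel_filters, "per_channel_filters"),
    per_channel_kernel = check_count(per_channel_kernel, "per_channel_kernel"),
    shallow_kernel = check_count(shallow_kernel, "shallow_kernel"),
    n_msrb = check_count(n_msrb, "n_msrb"),
    msrb_filters = check_count(msrb_filters, "msrb_filters"),
    msrb_conv_layers = check_count(msrb_conv_layers, "msrb_conv_layers"),
    msrb_kernels = vapply(msrb_kernels, check_count, integer(1),
                          what = "msrb_kernels"),
    fusion_filters = check_count(fusion_filters, "fusion_filters"),
    dropout_rate = dropout_rate,
    gru_units = check_count(gru_units, "gru_units"),
    dense_units = vapply(dense_units, check_count, integer(1),
                         what = "dense_units"),
    seed = as.integer(seed)
  )
  if (dropout_rate < 0 || dropout_rate >= 1) {
    abort("`dropout_rate` must lie in [0, 1).")
  }
  structure(cfg, class = "crbp_model_config")
}

#' Build the base network
#'
#' Constructs the full graph with seeded Glorot-uniform weights. Channel
#' shapes fix the input dimensions: global channels (`knf`, `doc2vec`) are
#' a single feature row; per-position channels (`eiip`, `ncp`, `anf`) have
#' one row per nucleotide. After their own convolutions, global channels
#' are tiled along the position axis so all five concatenate on the feature
#' axis.
#'
#' @param config A [model_config()].
#' @param channel_shapes Named list with the per-sample shape of each of
#'   the five channels, e.g. `list(knf = c(1, 84), doc2vec = c(1, 32),
#'   eiip = c(101, 1), ncp = c(101, 3), anf = c(101, 1))`.
#' @return An object of class `crbp_network`.
#' @export
build_model <- function(config = model_config(), channel_shapes) {
  stopifnot(inherits(config, "crbp_model_config"))
  missing_ch <- setdiff(CHANNEL_NAMES, names(channel_shapes))
  if (length(missing_ch) > 0) {
    abort(paste0("Missing channel shape(s): ",
                 paste(missing_ch, collapse = ", ")))
  }
  L <- channel_shapes$eiip[1]
  if (is.na(L) || L < 1) abort("Zero-length sequence axis.")
  C <- config$per_channel_filters
  Fm <- config$msrb_filters
  arch <- list()
  P <- list()
  add <- function(name, unit, block, kernel = NA_integer_,
                  size = NA_integer_, rate = NA_real_, branch = NA_character_) {
    P[[name]] <<- unit
    arch[[length(arch) + 1L]] <<- tibble(
      layer = name, type = unit$type %||% "op", block = block,
      kernel = as.integer(kernel), size = as.integer(size),
      rate = rate, branch = branch
    )
  }
  with_seed(config$seed, {
    # per-channel feature convolutions (global channels use a dense map,
    # the positional analogue of a kernel-1 convolution on a length-1 axis)
    add("pc_knf", init_dense(channel_shapes$knf[2], C), "input", 1L, C)
    add("pc_knf_bn", init_bn(C), "input")
    add("pc_doc2vec", init_dense(channel_shapes$doc2vec[2], C), "input", 1L, C)
    add("pc_doc2vec_bn", init_bn(C), "input")
    for (ch in c("eiip", "ncp", "anf")) {
      add(paste0("pc_", ch),
          init_conv(config$per_channel_kernel, channel_shapes[[ch]][2], C),
          "input", config$per_channel_kernel, C)
      add(paste0("pc_", ch, "_bn"), init_bn(C), "input")
    }
    add("shallow", init_conv(config$shallow_kernel, 5L * C, Fm),
        "shallow", config$shallow_kernel, Fm)
    add("shallow_bn", init_bn(Fm), "shallow")
    for (i in seq_len(config$n_msrb)) {
      blk <- paste0("msrb", i)
      for (br in c("a", "b")) {
        kk <- config$msrb_kernels[if (br == "a") 1L else 2L]
        f_in <- Fm
        for (l in seq_len(config$msrb_conv_layers)) {
          nm <- paste0(blk, "_", br, l)
          add(nm, init_conv(kk, f_in, Fm), blk, kk, Fm,
              branch = paste0("k", kk))
          add(paste0(nm, "_bn"), init_bn(Fm), blk, branch = paste0("k", kk))
          f_in <- Fm
        }
      }
      add(paste0(blk, "_comb"), init_conv(1L, 2L * Fm, Fm), blk, 1L, Fm)
      add(paste0(blk, "_comb_bn"), init_bn(Fm), blk)
      add(paste0(blk, "_proj"), init_conv(1L, Fm, Fm), blk, 1L, Fm)
    }
    add("fusion", init_conv(1L, config$n_msrb * Fm, config$fusion_filters),
        "fusion", 1L, config$fusion_filters)
    add("fusion_bn", init_bn(config$fusion_filters), "fusion")
    P[["dropout"]] <- list(type = "dropout", rate = config$dropout_rate)
    arch[[length(arch) + 1L]] <- tibble(
      layer = "dropout", type = "dropout", block = "fusion",
      kernel = NA_integer_, size = NA_integer_,
      rate = config$dropout_rate, branch = NA_character_
    )
    add("gru_fwd", init_gru(config$fusion_filters, config$gru_units),
        "recurrent", NA, config$gru_units)
    add("gru_bwd", init_gru(config$fusion_filters, config$gru_units),
        "recurrent", NA, config$gru_units)
    arch[[length(arch) + 1L]] <- tibble(
      layer = "self_attention", type = "attention", block = "attention",
      kernel = NA_integer_, size = 2L * config$gru_units,
      rate = NA_real_, branch = NA_character_
    )
    f_in <- 2L * config$gru_units
    for (i in seq_along(config$dense_units)) {
      add(paste0("head", i), init_dense(f_in, config$dense_units[i]),
          "head", NA, config$dense_units[i])
      f_in <- config$dense_units[i]
    }
    add("out", init_dense(f_in, 1L), "head", NA, 1L)
  })
  structure(
    list(config = config, channel_shapes = channel_shapes, L = L,
         P = P, arch = dplyr::bind_rows(arch)),
    class = "crbp_network"
  )
}

# Check a batch against the build-time channel shapes.
check_batch <- function(model, x) {
  present <- vapply(CHANNEL_NAMES, function(ch) !is.null(x[[ch]]),
                    logical(1))
  if (!all(present)) {
    abort(paste0("Batch is missing channel(s): ",
                 paste(CHANNEL_NAMES[!present], collapse = ", ")))
  }
  cs <- model$channel_shapes
  if (ncol(x$knf) != cs$knf[2] || ncol(x$doc2vec) != cs$doc2vec[2]) {
    abort("Global channel width does not match the build-time shapes.")
  }
  for (ch in c("eiip", "ncp", "anf")) {
    d <- dim(x[[ch]])
    if (d[2] != cs[[ch]][1] || d[3] != cs[[ch]][2]) {
      abort(sprintf("Channel '%s' shape mismatch with build-time shapes.", ch))
    }
  }
  invisible(TRUE)
}

# Full forward pass. Returns the pre-sigmoid logit per sample and, when
# `want_cache`, everything needed for the backward pass. BN running-stat
# updates are returned in `P` and must be written back by the caller during
# training.
network_forward <- function(model, x, training = FALSE, want_cache = FALSE) {
  check_batch(model, x)
  P <- model$P
  cfg <- model$config
  L <- model$L
  B <- nrow(x$knf)
  cc <- list()
  cbr <- function(name, X3, is_conv = TRUE) {
    # conv (or dense) -> batch norm -> relu with cache bookkeeping
    if (is_conv) {
      f1 <- conv_fw(P[[name]], X3)
      Ym <- flat3(f1$Y)
    } else {
      f1 <- dense_fw(P[[name]], X3)
      Ym <- f1$Y
    }
    bn <- bn_fw(P[[paste0(name, "_bn")]], Ym, training)
    P[[paste0(name, "_bn")]] <<- bn$unit
    rl <- relu_fw(bn$Y)
    if (want_cache) {
      cc[[name]] <<- list(main = f1$cache, bn = bn$cache, relu = rl$cache)
    }
    if (is_conv) unflat3(rl$Y, B, L) else rl$Y
  }
  knf_t <- tile_fw(cbr("pc_knf", x$knf, is_conv = FALSE), L)
  d2v_t <- tile_fw(cbr("pc_doc2vec", x$doc2vec, is_conv = FALSE), L)
  eiip <- cbr("pc_eiip", x$eiip)
  ncp <- cbr("pc_ncp", x$ncp)
  anf <- cbr("pc_anf", x$anf)
  Zc <- cat3(list(knf_t, d2v_t, eiip, ncp, anf))
  Z <- cbr("shallow", Zc)
  msrb_out <- vector("list", cfg$n_msrb)
  for (i in seq_len(cfg$n_msrb)) {
    blk <- paste0("msrb", i)
    a <- Z
    for (l in seq_len(cfg$msrb_conv_layers)) a <- cbr(paste0(blk, "_a", l), a)
    b <- Z
    for (l in seq_len(cfg$msrb_conv_layers)) b <- cbr(paste0(blk, "_b", l), b)
    comb <- cbr(paste0(blk, "_comb"), cat3(list(a, b)))
    pr <- conv_fw(P[[paste0(blk, "_proj")]], Z)
    if (want_cache) cc[[paste0(blk, "_proj")]] <- pr$cache
    Z <- comb + pr$Y
    msrb_out[[i]] <- Z
  }
  fused <- cbr("fusion", cat3(msrb_out))
  dr <- dropout_fw(fused, cfg$dropout_rate, training)
  if (want_cache) cc[["dropout"]] <- dr$cache
  gf <- gru_fw(P$gru_fwd, dr$Y, seq_len(L))
  gb <- gru_fw(P$gru_bwd, dr$Y, rev(seq_len(L)))
  if (want_cache) {
    cc[["gru_fwd"]] <- gf$cache
    cc[["gru_bwd"]] <- gb$cache
  }
  Hcat <- cat3(list(gf$Y, gb$Y))
  at <- attn_fw(Hcat)
  if (want_cache) cc[["attention"]] <- at$cache
  gp <- gap_fw(at$Y)
  if (want_cache) cc[["gap"]] <- gp$cache
  h <- gp$Y
  for (i in seq_along(cfg$dense_units)) {
    nm <- paste0("head", i)
    fd <- dense_fw(P[[nm]], h)
    rl <- relu_fw(fd$Y)
    if (want_cache) cc[[nm]] <- list(main = fd$cache, relu = rl$cache)
    h <- rl$Y
  }
  fo <- dense_fw(P$out, h)
  if (want_cache) cc[["out"]] <- fo$cache
  list(logit = as.numeric(fo$Y), P = P, caches = if (want_cache) cc else NULL)
}

# Backward pass through the full graph; `dlogit` is dLoss/dlogit per sample.
# Returns gradients keyed like model$P.
network_backward <- function(model, x, caches, dlogit) {
  P <- model$P
  cfg <- model$config
  L <- model$L
  B <- length(dlogit)
  G <- list()
  cbr_bw <- function(name, dY, is_conv = TRUE) {
    cache <- caches[[name]]
    dm <- relu_bw(cache$relu, if (is_conv) flat3(dY) else dY)
    bw <- bn_bw(P[[paste0(name, "_bn")]], cache$bn, dm)
    G[[paste0(name, "_bn")]] <<- bw$g
    if (is_conv) {
      cb <- conv_bw(P[[name]], cache$main, unflat3(bw$dX, B, L))
      G[[name]] <<- cb$g
      cb$dX
    } else {
      db <- dense_bw(P[[name]], cache$main, bw$dX)
      G[[name]] <<- db$g
      db$dX
    }
  }
  dY <- matrix(dlogit, ncol = 1)
  db <- dense_bw(P$out, caches$out, dY)
  G[["out"]] <- db$g
  dh <- db$dX
  for (i in rev(seq_along(cfg$dense_units))) {
    nm <- paste0("head", i)
    dm <- relu_bw(caches[[nm]]$relu, dh)
    dd <- dense_bw(P[[nm]], caches[[nm]]$main, dm)
    G[[nm]] <- dd$g
    dh <- dd$dX
  }
  dA <- gap_bw(caches$gap, dh)
  dHcat <- attn_bw(caches$attention, dA)
  parts <- split3(dHcat, c(cfg$gru_units, cfg$gru_units))
  bf <- gru_bw(P$gru_fwd, caches$gru_fwd, parts[[1]])
  bb <- gru_bw(P$gru_bwd, caches$gru_bwd, parts[[2]])
  G[["gru_fwd"]] <- bf$g
  G[["gru_bwd"]] <- bb$g
  dDrop <- bf$dX + bb$dX
  dFused <- dropout_bw(caches$dropout, dDrop)
  dMSRB <- cbr_bw("fusion", dFused)
  msrb_parts <- split3(dMSRB, rep(cfg$msrb_filters, cfg$n_msrb))
  dZ <- array(0, dim(msrb_parts[[1]]))
  for (i in rev(seq_len(cfg$n_msrb))) {
    blk <- paste0("msrb", i)
    dZi <- dZ + msrb_parts[[i]]
    pb <- conv_bw(P[[paste0(blk, "_proj")]], caches[[paste0(blk, "_proj")]],
                  dZi)
    G[[paste0(blk, "_proj")]] <- pb$g
    dcomb_in <- cbr_bw(paste0(blk, "_comb"), dZi)
    ab <- split3(dcomb_in, c(cfg$msrb_filters, cfg$msrb_filters))
    da <- ab[[1]]
    for (l in rev(seq_len(cfg$msrb_conv_layers))) {
      da <- cbr_bw(paste0(blk, "_a", l), da)
    }
    dbr <- ab[[2]]
    for (l in rev(seq_len(cfg$msrb_conv_layers))) {
      dbr <- cbr_bw(paste0(blk, "_b", l), dbr)
    }
    dZ <- pb$dX + da + dbr
  }
  dZc <- cbr_bw("shallow", dZ)
  C <- cfg$per_channel_filters
  ch_parts <- split3(dZc, rep(C, 5L))
  cbr_bw("pc_knf", tile_bw(ch_parts[[1]]), is_conv = FALSE)
  cbr_bw("pc_doc2vec", tile_bw(ch_parts[[2]]), is_conv = FALSE)
  cbr_bw("pc_eiip", ch_parts[[3]])
  cbr_bw("pc_ncp", ch_parts[[4]])
  cbr_bw("pc_anf", ch_parts[[5]])
  G
}

#' Predict binding-site scores for encoded samples
#'
#' Runs the forward pass in inference mode (dropout disabled, batch norm
#' using running statistics) and returns the sigmoid output per sample.
#'
#' @param model A built (optionally trained) [build_model()] network.
#' @param batch An encoded dataset (from [encode_dataset()]) or its `x`
#'   channel list.
#' @param batch_size Samples per forward chunk (default 128).
#' @return Numeric vector of scores strictly in (0, 1).
#' @export
predict_scores <- function(model, batch, batch_size = 128L) {
  stopifnot(inherits(model, "crbp_network"))
  x <- if (!is.null(batch$x)) batch$x else batch
  n <- nrow(x$knf)
  out <- numeric(n)
  for (start in seq.int(1L, n, by = batch_size)) {
    idx <- start:min(n, start + batch_size - 1L)
    sub <- encoded_subset(list(x = x, ids = rep("", n), y = NULL), idx)
    fw <- network_forward(model, sub$x, training = FALSE, want_cache = FALSE)
    out[idx] <- sigmoid_(fw$logit)
  }
  out
}

#' Ordered architecture summary
#'
#' One row per layer with type, block, kernel size and filter/unit count.
#'
#' @param model A [build_model()] network.
#' @return A tibble.
#' @export
architecture_summary <- function(model) {
  stopifnot(inherits(model, "crbp_network"))
  model$arch
}

#' @export
tidy.crbp_network <- function(x, ...) architecture_summary(x)

#' @export
glance.crbp_network <- function(x, ...) {
  n_par <- sum(vapply(x$P, function(u) {
    sum(vapply(trainable_tensors(u$type), function(tn) length(u[[tn]]),
               numeric(1)))
  }, numeric(1)))
  tibble(
    n_parameters = n_par,
    n_msrb = x$config$n_msrb,
    per_channel_filters = x$config$per_channel_filters,
    fusion_filters = x$config$fusion_filters,
    gru_units = x$config$gru_units,
    dropout_rate = x$config$dropout_rate,
    window_length = x$L
  )
}

#' @export
print.crbp_network <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "<crbp_network> %d MSRBs, %d-filter channel convs, %d-filter fusion, %s parameters\n",
    g$n_msrb, g$per_channel_filters, g$fusion_filters,
    format(g$n_parameters, big.mark = ",")
  ))
  invisible(x)
}
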