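# Synthetic benchmark generator: fixed-length windows over A/C/G/T with a
# class-discriminative motif planted in positives. Emulates the structure of
# CLIP-seq-derived binding-site windows (101 nt, balanced classes) so the
# whole pipeline can be exercised without external data.

#' Build a position weight matrix from a consensus string
#'
#' Each column puts `match_prob` on the consensus base and spreads the rest
#' uniformly over the other three bases; `match_prob = 1` gives a hard
#' consensus motif.
#'
#' @param consensus Nucleotide string over A/C/G/T.
#' @param match_prob Probability of the consensus base per position.
#' @return A 4 x m column-stochastic matrix with rownames A, C, G, T.
#' @export
consensus_pwm <- function(consensus, match_prob = 1) {
  check_alphabet(consensus, "consensus")
  if (match_prob < 0 || match_prob > 1) abort("`match_prob` must be in [0,1].")
  ch <- seq_chars(consensus)
  pwm <- matrix((1 - match_prob) / 3, 4, length(ch),
                dimnames = list(BASES, NULL))
  pwm[cbind(match(ch, BASES), seq_along(ch))] <- match_prob
  pwm
}

#' Specify a planted motif
#'
#' @param pwm A 4 x m column-stochastic matrix (rows A, C, G, T), or a
#'   consensus string (converted via [consensus_pwm()]).
#' @param occupancy Probability in `[0, 1]` that a positive window carries a
#'   motif instance (default 1).
#' @param match_prob Consensus match probability, used only when `pwm` is a
#'   string.
#' @return An object of class `motif_spec`.
#' @export
motif_spec <- function(pwm, occupancy = 1, match_prob = 1) {
  if (is.character(pwm)) pwm <- consensus_pwm(pwm, match_prob)
  if (!is.matrix(pwm) || nrow(pwm) != 4) {
    abort("`pwm` must be a 4 x m matrix (rows A, C, G, T) or a consensus string.")
  }
  if (any(abs(colSums(pwm) - 1) > 1e-8) || any(pwm < 0)) {
    abort("PWM columns must be non-negative and sum to 1.")
  }
  if (occupancy < 0 || occupancy > 1) abort("`occupancy` must be in [0, 1].")
  rownames(pwm) <- BASES
  structure(list(pwm = pwm, occupancy = occupancy, width = ncol(pwm)),
            class = "motif_spec")
}

#' Sample an i.i.d. background sequence
#'
#' @param length Sequence length.
#' @param background Probability 4-vector over A, C, G, T (default uniform).
#' @return A nucleotide string. Uses the current RNG stream; seed at the
#'   call site (see [generate_dataset()]).
#' @export
sample_background <- function(length, background = rep(0.25, 4)) {
  length <- check_count(length, "length")
  if (!is.numeric(background) || length(background) != 4 ||
      any(background < 0) || abs(sum(background) - 1) > 1e-8) {
    abort("`background` must be a probability 4-vector over A, C, G, T.")
  }
  paste(sample(BASES, length, replace = TRUE, prob = background),
        collapse = "")
}

#' Plant a motif instance into a sequence
#'
#' Samples one motif instance column-wise from the PWM and writes it over
#' the sequence at a uniformly random valid offset. The sequence length is
#' unchanged.
#'
#' @param sequence Nucleotide string.
#' @param motif A [motif_spec()].
#' @return List with `sequence` (modified string) and `offset` (1-based
#'   start of the planted instance).
#' @export
plant_motif <- function(sequence, motif) {
  stopifnot(inherits(motif, "motif_spec"))
  L <- nchar(sequence)
  m <- motif$width
  if (m >= L) abort("Motif is longer than (or as long as) the window.")
  inst <- vapply(seq_len(m), function(j) {
    sample(BASES, 1, prob = motif$pwm[, j])
  }, character(1))
  offset <- sample.int(L - m + 1L, 1)
  ch <- seq_chars(sequence)
  ch[offset:(offset + m - 1L)] <- inst
  list(sequence = paste(ch, collapse = ""), offset = offset)
}

#' Generate a labelled synthetic binding-site dataset
#'
#' Produces `n_pos` positive and `n_neg` negative windows of equal length.
#' Positives carry a motif instance with probability `occupancy` (from the
#' motif spec) at a uniformly random offset; negatives are pure background.
#' A generation manifest (seed, spec, planted offsets) is attached as the
#' `"manifest"` attribute.
#'
#' @param n_pos,n_neg Class sizes.
#' @param window_length Window length in nt (default 101).
#' @param background Background base probabilities (default uniform).
#' @param motif A [motif_spec()]; default is a hard 8-nt consensus
#'   `"ACGGAGGT"` planted in every positive.
#' @param markov1 If `TRUE`, use an order-1 Markov background whose
#'   transition matrix mildly favours self-transitions, mimicking the
#'   dinucleotide structure of real transcripts.
#' @param seed Integer seed; identical spec + seed gives byte-identical
#'   output.
#' @return Tibble with columns `id`, `sequence`, `label` (1 = positive),
#'   with attribute `manifest`.
#' @export
generate_dataset <- function(n_pos, n_neg, window_length = 101L,
                             background = rep(0.25, 4),
                             motif = motif_spec("ACGGAGGT", occupancy = 1),
                             markov1 = FALSE, seed = 1L) {
  n_pos <- check_count(n_pos, "n_pos"); n_neg <- check_count(n_neg, "n_neg")
  window_length <- check_count(window_length, "window_length")
  stopifnot(inherits(motif, "motif_spec"))
  if (motif$width >= window_length) {
    abort("Motif must be shorter than the window.")
  }
  res <- with_seed(seed, {
    draw <- function() {
      if (markov1) sample_markov1(window_length, background)
      else sample_background(window_length, background)
    }
    offsets <- rep(NA_integer_, n_pos)
    pos <- character(n_pos)
    for (i in seq_len(n_pos)) {
      s <- draw()
      if (runif(1) <= motif$occupancy) {
        pl <- plant_motif(s, motif)
        s <- pl$sequence
        offsets[i] <- pl$offset
      }
      pos[i] <- s
    }
    neg <- vapply(seq_len(n_neg), function(i) draw(), character(1))
    list(pos = pos, neg = neg, offsets = offsets)
  })
  records <- tibble(
    id = c(sprintf("pos_%04d", seq_len(n_pos)),
           sprintf("neg_%04d", seq_len(n_neg))),
    sequence = c(res$pos, res$neg),
    label = c(rep(1L, n_pos), rep(0L, n_neg))
  )
  attr(records, "manifest") <- list(
    seed = as.integer(seed), n_pos = n_pos, n_neg = n_neg,
    window_length = window_length, background = background,
    motif_consensus = paste(BASES[apply(motif$pwm, 2, which.max)],
                            collapse = ""),
    occupancy = motif$occupancy, markov1 = markov1,
    planted_offsets = res$offsets
  )
  records
}

# Order-1 Markov chain background with self-transition bias 0.4 (other
# bases share the remainder in proportion to `background`).
sample_markov1 <- function(length, background) {
  ch <- character(length)
  ch[1] <- sample(BASES, 1, prob = background)
  for (i in seq.int(2L, length.out = length - 1L)) {
    p <- background * 0.6
    p[match(ch[i - 1L], BASES)] <- p[match(ch[i - 1L], BASES)] + 0.4
    ch[i] <- sample(BASES, 1, prob = p / sum(p))
  }
  paste(ch, collapse = "")
}
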