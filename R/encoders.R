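# Five sequence feature channels. Per-position channels (EIIP, NCP, ANF)
# have one row per nucleotide; global channels (KNF, paragraph vector) are
# 1-row matrices. All encoders assume T-normalised sequences (U -> T done
# at FASTA import).

# Electron-ion interaction pseudopotential values per nucleotide.
EIIP_TABLE <- c(A = 0.1260, T = 0.1335, C = 0.1340, G = 0.0806)

# Chemical-property triples in the order (ring structure, chemical
# function, hydrogen bond): purine/amino/weak-bond coded 1.
NCP_TABLE <- rbind(
  A = c(1, 1, 1),
  C = c(0, 1, 0),
  G = c(1, 0, 0),
  T = c(0, 0, 1)
)

#' All k-mers over A/C/G/T in lexicographic order
#' @param k Word length.
#' @return Character vector of length `4^k`.
#' @export
kmer_universe <- function(k) {
  k <- check_count(k, "k")
  grids <- rev(rep(list(BASES), k))
  sort(do.call(paste0, expand.grid(grids, stringsAsFactors = FALSE)))
}

#' k-nucleotide frequency (KNF) encoding
#'
#' Overlapping k-mer composition for each `k` in `ks`: counts over the
#' `4^k` alphabet in lexicographic order, normalised by the number of
#' overlapping k-mers (`L - k + 1`), and concatenated across `ks`. The
#' default `ks = 1:3` yields a 4 + 16 + 64 = 84-dimensional global channel.
#'
#' @param sequence Nucleotide string over A/C/G/T.
#' @param ks Integer vector of word lengths (default `1:3`).
#' @return A 1-row named numeric matrix; each k-block sums to 1.
#' @examples
#' encode_knf("ACGT")[, 1:4]
#' @export
encode_knf <- function(sequence, ks = 1:3) {
  check_alphabet(sequence)
  L <- nchar(sequence)
  if (L < max(ks)) {
    abort(sprintf("Sequence of length %d is shorter than k = %d.", L, max(ks)))
  }
  blocks <- lapply(ks, function(k) {
    kmers <- substring(sequence, seq_len(L - k + 1L), seq_len(L - k + 1L) + k - 1L)
    tab <- table(factor(kmers, levels = kmer_universe(k)))
    as.numeric(tab) / (L - k + 1L)
  })
  values <- matrix(unlist(blocks), nrow = 1)
  colnames(values) <- unlist(lapply(ks, kmer_universe))
  values
}

#' Electron-ion interaction pseudopotential (EIIP) encoding
#'
#' Maps each nucleotide to its EIIP free-electron-energy value:
#' A = 0.1260, T = 0.1335, C = 0.1340, G = 0.0806.
#'
#' @param sequence Nucleotide string over A/C/G/T.
#' @return An `L x 1` numeric matrix.
#' @examples
#' encode_eiip("AATCCGA")
#' @export
encode_eiip <- function(sequence) {
  check_alphabet(sequence)
  matrix(unname(EIIP_TABLE[seq_chars(sequence)]), ncol = 1)
}

#' Nucleotide chemical property (NCP/CCN) encoding
#'
#' Three binary chemical characteristics per position, in the order
#' (ring structure, chemical function, hydrogen bond): purines (A, G) have
#' ring = 1; amino bases (A, C) have function = 1; weak hydrogen-bonding
#' bases (A, T) have bond = 1. Hence A -> (1,1,1), T -> (0,0,1),
#' C -> (0,1,0), G -> (1,0,0).
#'
#' @param sequence Nucleotide string over A/C/G/T.
#' @return An `L x 3` numeric matrix; flattened row-major it gives the
#'   conventional 3L-element chemical-property vector.
#' @examples
#' encode_ncp("AATCCGA")
#' @export
encode_ncp <- function(sequence) {
  check_alphabet(sequence)
  m <- NCP_TABLE[seq_chars(sequence), , drop = FALSE]
  dimnames(m) <- list(NULL, c("ring", "func", "hbond"))
  m
}

#' Accumulated nucleotide frequency (ANF) encoding
#'
#' Position j carries the density of its own nucleotide within the prefix
#' `s_1..s_j`: `ANF(j) = #\{t <= j : s_t = s_j\} / j`. Values lie in (0, 1];
#' a homopolymer is identically 1.
#'
#' @param sequence Nucleotide string over A/C/G/T.
#' @return An `L x 1` numeric matrix.
#' @examples
#' encode_anf("AATC")
#' @export
encode_anf <- function(sequence) {
  check_alphabet(sequence)
  ch <- seq_chars(sequence)
  L <- length(ch)
  counts <- vapply(BASES, function(b) cumsum(ch == b), numeric(L))
  if (L == 1L) counts <- matrix(counts, nrow = 1)
  own <- counts[cbind(seq_len(L), match(ch, BASES))]
  matrix(own / seq_len(L), ncol = 1)
}

#' Tokenize a sequence into overlapping k-mer words
#'
#' Slides a window of length `k` along the sequence at the given stride.
#' With the defaults (k = 10, stride = 1) a 101-nt window yields 92
#' overlapping 10-mer "words" for the paragraph-vector embedding.
#'
#' @param sequence Nucleotide string.
#' @param k Word length (default 10).
#' @param stride Step between word starts (default 1).
#' @return Character vector of k-mers, order preserved.
#' @export
tokenize_kmers <- function(sequence, k = 10L, stride = 1L) {
  check_string(sequence, "sequence")
  k <- check_count(k, "k")
  stride <- check_count(stride, "stride")
  L <- nchar(sequence)
  if (L < k) {
    abort(sprintf("Sequence of length %d is shorter than k = %d.", L, k))
  }
  starts <- seq.int(1L, L - k + 1L, by = stride)
  substring(sequence, starts, starts + k - 1L)
}

#' Encode one record into all five feature channels
#'
#' @param record One-row tibble (or list) with `id` and `sequence`.
#' @param embedding A trained [train_embedding()] model.
#' @return An object of class `encoded_sample`: list with `record_id` and
#'   `channels` (named list `knf`, `doc2vec`, `eiip`, `ncp`, `anf` with
#'   shapes `1 x 84`, `1 x embed_dim`, `L x 1`, `L x 3`, `L x 1`).
#' @export
encode_all <- function(record, embedding) {
  seqc <- record$sequence
  check_alphabet(seqc)
  channels <- list(
    knf = encode_knf(seqc),
    doc2vec = encode_doc2vec(seqc, embedding),
    eiip = encode_eiip(seqc),
    ncp = encode_ncp(seqc),
    anf = encode_anf(seqc)
  )
  structure(list(record_id = record$id, channels = channels),
            class = "encoded_sample")
}

#' Encode a record table into stacked channel arrays
#'
#' Batches [encode_all()] over a record tibble, producing the array
#' structure consumed by the network: global channels as `n x d` matrices
#' and per-position channels as `n x L x d` arrays.
#'
#' @param records Tibble with `id`, `sequence` and optionally `label`.
#' @param embedding A trained [train_embedding()] model.
#' @return List with elements `x` (named list of channel arrays), `ids`,
#'   and `y` (integer labels or NULL).
#' @export
encode_dataset <- function(records, embedding) {
  stopifnot(is.data.frame(records), nrow(records) > 0)
  lens <- nchar(records$sequence)
  if (length(unique(lens)) != 1) {
    abort("All sequences must have equal length for batched encoding.")
  }
  L <- lens[1]
  n <- nrow(records)
  knf <- t(vapply(records$sequence, function(s) encode_knf(s)[1, ],
                  numeric(84)))
  d2v <- infer_doc_vectors(records$sequence, embedding)
  eiip <- array(0, c(n, L, 1))
  ncp <- array(0, c(n, L, 3))
  anf <- array(0, c(n, L, 1))
  for (i in seq_len(n)) {
    s <- records$sequence[i]
    eiip[i, , 1] <- encode_eiip(s)
    ncp[i, , ] <- encode_ncp(s)
    anf[i, , 1] <- encode_anf(s)
  }
  rownames(knf) <- NULL
  list(
    x = list(knf = knf, doc2vec = d2v, eiip = eiip, ncp = ncp, anf = anf),
    ids = records$id,
    y = if ("label" %in% names(records)) as.integer(records$label) else NULL
  )
}

# Subset an encoded dataset by sample index.
encoded_subset <- function(ed, idx) {
  list(
    x = list(
      knf = ed$x$knf[idx, , drop = FALSE],
      doc2vec = ed$x$doc2vec[idx, , drop = FALSE],
      eiip = ed$x$eiip[idx, , , drop = FALSE],
      ncp = ed$x$ncp[idx, , , drop = FALSE],
      anf = ed$x$anf[idx, , , drop = FALSE]
    ),
    ids = ed$ids[idx],
    y = if (!is.null(ed$y)) ed$y[idx] else NULL
  )
}
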