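#' Read nucleotide sequences from a FASTA file
#'
#' Reads a (single- or multi-line) FASTA file into a tibble of sequence
#' records. Sequences are upper-cased and RNA `U` is normalised to `T`.
#' Characters outside the IUPAC subset `A/C/G/T/U/N` are an error. `N` bases
#' are rejected by default; with `n_policy = "random"` each `N` is replaced
#' by a base drawn uniformly at random under `seed` (useful for messy public
#' FASTA files).
#'
#' @param path Path to a FASTA file.
#' @param label Optional binary label (0/1) attached to every record, e.g.
#'   1 for a positives file and 0 for a negatives file.
#' @param n_policy Either `"error"` (default) or `"random"`.
#' @param seed Integer seed used only when `n_policy = "random"`.
#' @return A tibble with columns `id`, `sequence` and (if `label` is given)
#'   `label`.
#' @examples
#' tf <- tempfile(fileext = ".fa")
#' writeLines(c(">w1", "ACGU", ">w2", "GGTT"), tf)
#' read_fasta(tf)
#' @export
read_fasta <- function(path, label = NULL, n_policy = c("error", "random"),
                       seed = 1L) {
  n_policy <- match.arg(n_policy)
  check_string(path, "path")
  if (!file.exists(path)) {
    abort(sprintf("FASTA file '%s' does not exist.", path))
  }
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) abort(sprintf("Failed to parse FASTA '%s': %s",
                                      path, conditionMessage(e)))
  )
  ids <- sub("\\s.*$", "", names(set))
  seqs <- toupper(as.character(set))
  seqs <- chartr("U", "T", seqs)
  bad <- regmatches(seqs, regexpr("[^ACGTN]", seqs))
  if (length(unlist(bad)) > 0) {
    abort(sprintf(
      "FASTA '%s' contains character '%s' outside the A/C/G/T/U/N alphabet.",
      path, unlist(bad)[1]
    ))
  }
  if (any(grepl("N", seqs, fixed = TRUE))) {
    if (n_policy == "error") {
      abort(sprintf(
        "FASTA '%s' contains N bases; use n_policy = \"random\" to impute.",
        path
      ))
    }
    seqs <- with_seed(seed, vapply(seqs, impute_n, character(1)))
  }
  if (anyDuplicated(ids)) {
    abort(sprintf("Duplicated FASTA id '%s' in '%s'.",
                  ids[duplicated(ids)][1], path))
  }
  if (any(!nzchar(seqs))) abort(sprintf("Empty sequence in '%s'.", path))
  out <- tibble(id = unname(ids), sequence = unname(seqs))
  if (!is.null(label)) {
    if (!label %in% c(0, 1)) abort("`label` must be 0 or 1.")
    out$label <- as.integer(label)
  }
  out
}

impute_n <- function(seq) {
  ch <- seq_chars(seq)
  idx <- which(ch == "N")
  if (length(idx) > 0) ch[idx] <- sample(BASES, length(idx), replace = TRUE)
  paste(ch, collapse = "")
}

#' Write sequence records to a FASTA file
#'
#' Writes one `>id` header plus a single sequence line per record, so that
#' identical record tables always produce byte-identical files.
#'
#' @param records Tibble with columns `id` and `sequence`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  stopifnot(is.data.frame(records), all(c("id", "sequence") %in% names(records)))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste0(">", records$id, "\n", records$sequence), con, sep = "\n")
  invisible(path)
}

#' Extract a fixed-length window centred on a position
#'
#' Returns the subsequence `[center - flank, center + flank]` (0-based,
#' inclusive), the standard peak-centred window: a CLIP-seq peak centre is
#' extended by `flank` nucleotides in both directions, giving a window of
#' `2 * flank + 1` nt (101 nt with the default `flank = 50`). Windows that
#' would overhang either end of the sequence are an error; no padding or
#' circular wrap-around is applied.
#'
#' @param sequence A nucleotide string.
#' @param center 0-based centre index.
#' @param flank Non-negative flank length in nt (default 50).
#' @return A string of length `2 * flank + 1`.
#' @examples
#' extract_window("ACGTA", center = 2, flank = 1)
#' @export
extract_window <- function(sequence, center, flank = 50L) {
  check_string(sequence, "sequence")
  center <- check_count(center, "center", min = 0L)
  flank <- check_count(flank, "flank", min = 0L)
  L <- nchar(sequence)
  if (center >= L) abort("`center` must be a 0-based index into `sequence`.")
  lo <- center - flank
  hi <- center + flank
  if (lo < 0) {
    abort(sprintf(
      "Window [%d, %d] overhangs the left end of a length-%d sequence.",
      lo, hi, L
    ))
  }
  if (hi >= L) {
    abort(sprintf(
      "Window [%d, %d] overhangs the right end of a length-%d sequence.",
      lo, hi, L
    ))
  }
  substr(sequence, lo + 1L, hi + 1L)
}

#' Remove redundant sequences by greedy identity clustering
#'
#' Greedy stand-in for CD-HIT on equal-length windows: records are scanned in
#' input order and a record is discarded iff its identity with an already
#' retained record is `>= threshold`, where identity is
#' `1 - hamming_distance / length`. Retained records keep their original
#' order. Because all windows have equal length, exact Hamming identity is a
#' faithful substitute for alignment-based identity.
#'
#' @param records Tibble with columns `id`, `sequence` (all equal length).
#' @param threshold Identity threshold in (0, 1]; default 0.8.
#' @return The retained subset of `records`, original order preserved.
#' @export
redundancy_filter <- function(records, threshold = 0.8) {
  stopifnot(is.data.frame(records), "sequence" %in% names(records))
  if (nrow(records) == 0) return(records)
  if (!is.numeric(threshold) || threshold <= 0 || threshold > 1) {
    abort("`threshold` must lie in (0, 1].")
  }
  lens <- nchar(records$sequence)
  if (length(unique(lens)) != 1) {
    abort("redundancy_filter requires equal-length sequences (fixed windows).")
  }
  L <- lens[1]
  # character matrix: rows = positions, cols = records
  mat <- matrix(unlist(strsplit(records$sequence, "", fixed = TRUE)),
                nrow = L)
  keep <- integer(0)
  for (i in seq_len(nrow(records))) {
    redundant <- FALSE
    if (length(keep) > 0) {
      ident <- colMeans(mat[, keep, drop = FALSE] == mat[, i])
      redundant <- any(ident >= threshold)
    }
    if (!redundant) keep <- c(keep, i)
  }
  records[keep, , drop = FALSE]
}

#' Split a labelled dataset into train / validation / test sets
#'
#' Deterministic, class-stratified split. First `train_fraction` of each
#' class goes to train+validation and the remainder to test; the
#' train+validation part is then split again, with `val_fraction_of_train`
#' of it held out for validation. With the defaults this is the usual
#' 80/20 train/test split followed by an 80/20 train/validation split of
#' the training portion (64/16/20 overall).
#'
#' @param records Tibble with columns `id`, `sequence`, `label` (0/1).
#' @param train_fraction Fraction of each class assigned to train+validation.
#' @param val_fraction_of_train Fraction of the training portion held out for
#'   validation.
#' @param seed Integer seed; fixed seed gives identical partitions.
#' @return Named list of tibbles `train`, `validation`, `test`.
#' @export
split_dataset <- function(records, train_fraction = 0.8,
                          val_fraction_of_train = 0.2, seed = 1L) {
  stopifnot(is.data.frame(records), "label" %in% names(records))
  check_fraction(train_fraction, "train_fraction")
  check_fraction(val_fraction_of_train, "val_fraction_of_train")
  labs <- sort(unique(records$label))
  if (!identical(as.integer(labs), c(0L, 1L))) {
    abort("`records` must contain both classes (labels 0 and 1).")
  }
  counts <- table(records$label)
  if (any(counts < 5)) abort("Need at least 5 records per class to split.")
  assign_class <- function(idx, class_seed) {
    n <- length(idx)
    idx <- with_seed(class_seed, sample(idx))
    n_trval <- round(n * train_fraction)
    n_val <- round(n_trval * val_fraction_of_train)
    list(
      train = idx[seq_len(n_trval - n_val)],
      validation = idx[seq(n_trval - n_val + 1, length.out = n_val)],
      test = idx[seq(n_trval + 1, length.out = n - n_trval)]
    )
  }
  parts0 <- assign_class(which(records$label == 0L), derive_seed(seed, 0L))
  parts1 <- assign_class(which(records$label == 1L), derive_seed(seed, 1L))
  out <- lapply(c("train", "validation", "test"), function(p) {
    idx <- sort(c(parts0[[p]], parts1[[p]]))
    records[idx, , drop = FALSE]
  })
  names(out) <- c("train", "validation", "test")
  attr(out, "split") <- list(train_fraction = train_fraction,
                             val_fraction_of_train = val_fraction_of_train,
                             seed = as.integer(seed))
  out
}
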