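#' @noRd
NULL

BASES <- c("A", "C", "G", "T")

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG stream afterwards. All stochastic package operations go
# through this so that a single integer seed fully determines results.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  expr
}

# Derive a child seed from a parent seed and a stream index, kept inside
# 32-bit integer range.
derive_seed <- function(seed, stream) {
  as.integer((as.double(seed) * 1103L + 7919L * stream) %% 2147483647)
}

check_string <- function(x, what) {
  if (!is.character(x) || length(x) != 1L || is.na(x)) {
    abort(sprintf("`%s` must be a single string.", what))
  }
  x
}

check_count <- function(x, what, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min ||
      x != as.integer(x)) {
    abort(sprintf("`%s` must be a single integer >= %d.", what, min))
  }
  as.integer(x)
}

check_fraction <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0 || x >= 1) {
    abort(sprintf("`%s` must lie strictly between 0 and 1.", what))
  }
  as.double(x)
}

# Validate a sequence over the A/C/G/T alphabet, naming the first offender.
check_alphabet <- function(sequence, what = "sequence") {
  if (!nzchar(sequence)) {
    abort(sprintf("`%s` must be a non-empty nucleotide string.", what))
  }
  bad <- regmatches(sequence, regexpr("[^ACGT]", sequence))
  if (length(bad) > 0) {
    abort(sprintf(
      "`%s` contains character '%s' outside the A/C/G/T alphabet.", what, bad
    ))
  }
  invisible(sequence)
}

seq_chars <- function(sequence) strsplit(sequence, "", fixed = TRUE)[[1]]

`%||%` <- function(a, b) if (is.null(a)) b else a
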