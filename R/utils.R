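#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `code` under `set.seed(seed)` and restores the caller's random state
#' afterwards, so package functions never leak changes to the global RNG.
#'
#' @param seed integer scalar seed.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @examples
#' with_seed(1, runif(2))
#' @export
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("`seed` must be a single number")
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a reproducible per-stage seed from a master seed
#'
#' Stages of the pipeline draw their own seeds from the run's master seed via
#' a fixed affine hash, so any stage can be rerun in isolation with the same
#' randomness it saw inside the full run.
#'
#' @param master integer master seed.
#' @param stage integer stage index (>= 1).
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
stage_seed <- function(master, stage) {
  m <- 2147483647                      # 2^31 - 1, Mersenne prime
  ((as.numeric(master) %% m) * 48271 + 11 * as.numeric(stage)) %% m
}

# Phred+33 helpers -----------------------------------------------------------

phred_encode <- function(q) {
  vapply(q, function(x) intToUtf8(pmin(pmax(x, 0L), 93L) + 33L), character(1))
}

phred_decode <- function(s) {
  lapply(s, function(x) if (nchar(x) == 0L) integer(0) else utf8ToInt(x) - 33L)
}

# Single-string variants (internal hot paths).
phred_decode1 <- function(s) if (nchar(s) == 0L) integer(0) else utf8ToInt(s) - 33L

#' Longest single-nucleotide run in a sequence
#' @param seq character vector of sequences.
#' @return integer vector of maximal run lengths (0 for empty strings).
#' @keywords internal
max_homopolymer_run <- function(seq) {
  vapply(seq, function(s) {
    if (nchar(s) == 0L) return(0L)
    r <- rle(strsplit(s, "", fixed = TRUE)[[1]])
    max(r$lengths)
  }, integer(1), USE.NAMES = FALSE)
}

DNA_BASES <- c("A", "C", "G", "T")

random_dna <- function(n, max_run = 4L) {
  # Draw a uniform random sequence while never exceeding `max_run` identical
  # consecutive bases; keeps natural homopolymers well below the QC threshold
  # so long runs are only ever planted deliberately.
  out <- character(n)
  run <- 0L
  prev <- ""
  draws <- sample(DNA_BASES, n, replace = TRUE)
  alt <- sample(DNA_BASES, n, replace = TRUE)
  for (i in seq_len(n)) {
    b <- draws[i]
    if (b == prev && run >= max_run) {
      b <- alt[i]
      while (b == prev) b <- sample(DNA_BASES, 1L)
    }
    if (b == prev) run <- run + 1L else { run <- 1L; prev <- b }
    out[i] <- b
  }
  paste(out, collapse = "")
}

seq_to_chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]
chars_to_seq <- function(x) paste(x, collapse = "")

revcomp <- function(s) {
  chartr("ACGTN", "TGCAN", vapply(s, function(x) {
    paste(rev(seq_to_chars(x)), collapse = "")
  }, character(1), USE.NAMES = FALSE))
}
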