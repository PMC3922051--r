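# Independent brute-force oracles used across the suite.  These deliberately
# avoid the package's own code paths: plain loops, plain arithmetic.

BASES <- c("A", "C", "G", "T")

phred_chr <- function(q) intToUtf8(q + 33)
`%+%` <- function(a, b) paste0(a, b)

rand_dna <- function(n) paste(sample(BASES, n, replace = TRUE), collapse = "")

hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# all-offsets Hamming scan
bf_find_match <- function(sequence, pattern, max_mm) {
  n <- nchar(sequence); m <- nchar(pattern)
  if (m > n) return(integer(0))
  hits <- integer(0)
  for (off in 1:(n - m + 1)) {
    if (hamming(substr(sequence, off, off + m - 1), pattern) <= max_mm)
      hits <- c(hits, off)
  }
  hits
}

# exhaustive optimal global alignment score by recursion (tiny inputs only)
bf_align_score <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  memo <- new.env(hash = TRUE)
  rec <- function(i, j) {
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    v <- if (i == 0 && j == 0) 0
    else if (i == 0) j * gap
    else if (j == 0) i * gap
    else max(rec(i - 1, j - 1) +
               (if (substr(a, i, i) == substr(b, j, j)) match else mismatch),
             rec(i - 1, j) + gap,
             rec(i, j - 1) + gap)
    memo[[key]] <- v
    v
  }
  rec(nchar(a), nchar(b))
}

# substitute a fraction of positions (never to the same base)
mutate_seq <- function(s, rate) {
  ch <- strsplit(s, "")[[1]]
  k <- rbinom(1, length(ch), rate)
  if (k > 0) {
    pos <- sample(length(ch), k)
    for (i in pos) ch[i] <- sample(setdiff(BASES, ch[i]), 1)
  }
  paste(ch, collapse = "")
}

# alignment sum-of-pairs score, counted column by column
sp_score <- function(rows, match = 1, mismatch = -1, gap = -2) {
  m <- do.call(rbind, strsplit(unname(rows), ""))
  total <- 0
  for (col in seq_len(ncol(m))) {
    x <- m[, col]
    for (i in 1:(length(x) - 1)) for (j in (i + 1):length(x)) {
      if (x[i] == "-" && x[j] == "-") next
      total <- total +
        if (x[i] == "-" || x[j] == "-") gap
        else if (x[i] == x[j]) match else mismatch
    }
  }
  total
}

# planted-kingdom accuracy of a clade assignment (truth named by query id)
label_accuracy <- function(assignments, truth) {
  tr <- truth[assignments$query]
  hit <- mapply(function(lab, t) {
    lab != "NOVEL" && t %in% strsplit(lab, "+", fixed = TRUE)[[1]]
  }, assignments$label, tr)
  mean(hit)
}
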