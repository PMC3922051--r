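#' Progressive multiple sequence alignment
#'
#' Aligns sequences progressively along a guide tree using profile-profile
#' Needleman-Wunsch with linear gaps.  When no guide tree is supplied, one is
#' built by UPGMA (average-linkage) clustering of shared k-mer distances.
#' The procedure is deterministic.
#'
#' @param sequences named character vector of >= 2 DNA sequences.
#' @param guide optional `hclust` object to use as guide tree.
#' @param match,mismatch,gap scoring parameters.
#' @param k k-mer size for the guide-tree distance.
#' @return An `msa`: named character vector of equal-length gapped rows.
#' @export
progressive_msa <- function(sequences, guide = NULL,
                            match = 1, mismatch = -1, gap = -2, k = 6L) {
  n <- length(sequences)
  if (n < 2L) stop("need at least 2 sequences")
  if (is.null(names(sequences)) || anyDuplicated(names(sequences)))
    stop("sequences must have unique names")
  if (n == 2L) {
    al <- nw_align_cpp(sequences[1], sequences[2], match, mismatch, gap)
    out <- c(al$aligned_a, al$aligned_b)
    names(out) <- names(sequences)
    return(structure(out, class = "msa"))
  }
  if (is.null(guide)) guide <- kmer_guide_tree(sequences, k)
  if (!inherits(guide, "hclust")) stop("guide must be an hclust object")

  blocks <- vector("list", n)          # per original sequence: singleton block
  for (i in seq_len(n)) {
    b <- sequences[i]
    names(b) <- names(sequences)[i]
    blocks[[i]] <- b
  }
  merged <- vector("list", nrow(guide$merge))
  getb <- function(id) if (id < 0) blocks[[-id]] else merged[[id]]
  for (s in seq_len(nrow(guide$merge))) {
    merged[[s]] <- merge_blocks(getb(guide$merge[s, 1]),
                                getb(guide$merge[s, 2]),
                                match, mismatch, gap)
  }
  out <- merged[[length(merged)]][names(sequences)]
  structure(out, class = "msa")
}

kmer_guide_tree <- function(sequences, k = 6L) {
  sets <- lapply(sequences, kmer_set, k = k)
  n <- length(sequences)
  D <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      shared <- sum(sets[[i]] %in% sets[[j]])
      D[i, j] <- D[j, i] <-
        1 - shared / max(1L, min(length(sets[[i]]), length(sets[[j]])))
    }
  }
  hclust(as.dist(D), method = "average")
}

msa_profile <- function(rows) {
  mat <- msa_encode(rows)
  L <- ncol(mat)
  prof <- matrix(0, 5, L)
  for (code in 0:4) prof[code + 1, ] <- colMeans(mat == code)
  # ambiguous bases (code 5) contribute equally to the four bases
  amb <- colMeans(mat == 5L)
  prof[1:4, ] <- prof[1:4, ] + rep(amb / 4, each = 4)
  prof
}

# rows of an alignment -> integer matrix: A,C,G,T = 0..3, gap = 4, other = 5
msa_encode <- function(rows) {
  codes <- c(A = 0L, C = 1L, G = 2L, T = 3L, `-` = 4L)
  t(vapply(rows, function(r) {
    x <- seq_to_chars(r)
    v <- codes[x]
    v[is.na(v)] <- 5L
    unname(v)
  }, integer(nchar(rows[1]))))
}

merge_blocks <- function(a, b, match, mismatch, gap) {
  moves <- profile_align_cpp(msa_profile(a), msa_profile(b),
                             match, mismatch, gap)
  L <- length(moves)
  idx_a <- which(moves != 2L)
  idx_b <- which(moves != 1L)
  expand <- function(rows, idx) {
    vapply(rows, function(r) {
      out <- rep("-", L)
      out[idx] <- seq_to_chars(r)
      chars_to_seq(out)
    }, character(1))
  }
  c(expand(a, idx_a), expand(b, idx_b))
}

#' @export
print.msa <- function(x, ...) {
  cat(sprintf("Multiple alignment: %d sequences x %d columns\n",
              length(x), nchar(x[1])))
  invisible(x)
}

#' Trim gap-dominated terminal alignment blocks
#'
#' Removes the maximal leading and trailing runs of columns whose gap
#' fraction exceeds `max_gap_fraction`, emulating the trimming of alignment
#' regions that extend beyond the amplicon reads.  Interior columns are never
#' touched, so degapping still recovers (possibly truncated) input sequences.
#'
#' @param msa an [progressive_msa()] result.
#' @param max_gap_fraction columns with a gap fraction above this are
#'   trimmable (default 0.9).
#' @return The trimmed `msa` (attribute `n_trimmed` records removed columns).
#' @export
trim_alignment <- function(msa, max_gap_fraction = 0.9) {
  mat <- msa_encode(msa)
  gapfrac <- colMeans(mat == 4L)
  bad <- gapfrac > max_gap_fraction
  L <- length(bad)
  from <- 1L
  while (from <= L && bad[from]) from <- from + 1L
  to <- L
  while (to >= 1L && bad[to]) to <- to - 1L
  if (from > to) stop("trimming removed every alignment column")
  out <- substr(msa, from, to)
  names(out) <- names(msa)
  attr(out, "n_trimmed") <- L - (to - from + 1L)
  class(out) <- "msa"
  out
}
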