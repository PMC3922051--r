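#' Rarefy a count vector to a fixed depth
#'
#' Draws exactly `depth` reads without replacement from the multiset of reads
#' implied by the counts, so each OTU's subsampled count follows the
#' multivariate hypergeometric distribution.  Deterministic given `seed`.
#'
#' @param counts non-negative integer vector (optionally named by OTU).
#' @param depth number of reads to keep; must not exceed `sum(counts)`.
#' @param seed integer seed.
#' @return Integer vector of the same length and names, summing to `depth`.
#' @export
rarefy_counts <- function(counts, depth, seed = 1) {
  n <- sum(counts)
  if (depth > n)
    stop(sprintf("rarefaction depth %d exceeds library size %d%s",
                 depth, n,
                 if (!is.null(attr(counts, "sample"))) paste0(" for sample ", attr(counts, "sample")) else ""))
  with_seed(seed, {
    pool <- rep(seq_along(counts), counts)
    draw <- sample(pool, depth)
    out <- tabulate(draw, nbins = length(counts))
    names(out) <- names(counts)
    out
  })
}

#' Shannon diversity index (bits)
#'
#' `H = -sum(p_i * log2(p_i))` over OTUs with nonzero counts.  Base 2 by
#' default; natural log available via `base = exp(1)`.
#'
#' @param counts non-negative count vector with positive sum.
#' @param base logarithm base (default 2).
#' @return Shannon index.
#' @examples
#' shannon(c(4, 4, 4, 4))  # 2 bits
#' @export
shannon <- function(counts, base = 2) {
  n <- sum(counts)
  if (length(counts) == 0L || n <= 0) stop("counts must have a positive sum")
  p <- counts[counts > 0] / n
  -sum(p * log(p, base = base))
}

#' Chao1 species richness estimator
#'
#' Bias-corrected form `S_obs + n1 * (n1 - 1) / (2 * (n2 + 1))`, where `n1`
#' and `n2` are the singleton and doubleton OTU counts; the correction keeps
#' the estimator defined when no doubletons are observed.  The classic
#' `n1^2 / (2 * n2)` form is available via `bias_corrected = FALSE`.
#'
#' @param counts non-negative count vector with positive sum.
#' @param bias_corrected use the bias-corrected form (default).
#' @return Estimated richness (always `>= S_obs`).
#' @examples
#' chao1(c(1, 1, 2, 5))  # 4 + 2 * 1 / (2 * 2) = 4.5
#' @export
chao1 <- function(counts, bias_corrected = TRUE) {
  if (sum(counts) <= 0) stop("counts must have a positive sum")
  s_obs <- sum(counts > 0)
  n1 <- sum(counts == 1)
  n2 <- sum(counts == 2)
  if (bias_corrected) s_obs + n1 * (n1 - 1) / (2 * (n2 + 1))
  else if (n2 > 0) s_obs + n1^2 / (2 * n2)
  else s_obs + n1 * (n1 - 1) / 2   # classic form degenerates; fall back
}

#' Good's coverage estimator
#'
#' `C = 1 - n1 / N`: the estimated probability that the next sequenced read
#' belongs to an already-observed OTU.
#'
#' @param counts non-negative count vector with positive sum.
#' @return Coverage in `[0, 1]`.
#' @export
goods_coverage <- function(counts) {
  n <- sum(counts)
  if (n <= 0) stop("counts must have a positive sum")
  1 - sum(counts == 1) / n
}

#' Per-sample diversity summary after rarefying to the smallest library
#'
#' Rarefies every sample to the depth of the smallest non-empty library and
#' reports reads, observed OTUs, Shannon index (bits), Chao1 and Good's
#' coverage — the standard per-sample diversity panel for a 3%-dissimilarity
#' OTU table.
#'
#' @param table an `otu_table` (typically at level 0.03).
#' @param seed integer seed for the rarefaction draw.
#' @param replicates number of rarefaction draws to average (default 1 for
#'   exact reproducibility of the table as written).
#' @return A `diversity_summary` data frame with one row per sample.
#' @export
diversity_table <- function(table, seed = 1, replicates = 1) {
  stopifnot(inherits(table, "otu_table"))
  libs <- colSums(table$counts)
  if (any(libs == 0)) {
    warning("excluding samples with no qualified reads: ",
            paste(names(libs)[libs == 0], collapse = ", "))
  }
  keep <- names(libs)[libs > 0]
  if (!length(keep)) stop("no sample has a positive read count")
  depth <- min(libs[keep])
  rows <- lapply(seq_along(keep), function(i) {
    sid <- keep[i]
    v <- table$counts[, sid]
    reps <- vapply(seq_len(replicates), function(r) {
      rv <- rarefy_counts(v, depth, seed = stage_seed(seed, (i - 1) * replicates + r))
      c(sum(rv > 0), shannon(rv), chao1(rv), goods_coverage(rv))
    }, numeric(4))
    m <- rowMeans(reps)
    data.frame(sample_id = sid, reads = unname(libs[sid]),
               depth = depth, otus = m[1], shannon = m[2],
               chao1 = m[3], goods_coverage = m[4],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("diversity_summary", "data.frame")
  out
}

#' Write the diversity summary as TSV
#'
#' @param div a [diversity_table()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_diversity <- function(div, path) {
  df <- as.data.frame(div)
  df$shannon <- sprintf("%.4f", df$shannon)
  df$chao1 <- sprintf("%.2f", df$chao1)
  df$goods_coverage <- sprintf("%.4f", df$goods_coverage)
  write_tsv(df, path)
}
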