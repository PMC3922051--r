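#' Optimal global pairwise alignment
#'
#' Needleman-Wunsch alignment under linear gap scoring with deterministic
#' traceback (diagonal preferred, then a gap in the second sequence, then a
#' gap in the first).
#'
#' @param a,b DNA strings (nonempty).
#' @param match,mismatch,gap scoring parameters (defaults +1/-1/-2).
#' @return A `pairwise_alignment` list with `aligned_a`, `aligned_b`,
#'   `score`.
#' @examples
#' global_align("ACGT", "ACG")
#' @export
global_align <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  if (!nchar(a) || !nchar(b)) stop("sequences must be nonempty")
  out <- nw_align_cpp(a, b, match, mismatch, gap)
  structure(out, class = "pairwise_alignment")
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat(x$aligned_a, "\n", x$aligned_b, "\n", sep = "")
  cat(sprintf("score %g, identity %.3f\n", x$score, pairwise_identity(x)))
  invisible(x)
}

#' Fraction of identical columns in a pairwise alignment
#'
#' Matches divided by alignment columns, excluding columns that fall in a
#' terminal gap of either sequence, so that length differences between an
#' amplicon read and a longer centroid do not dominate the identity.
#'
#' @param alignment a [global_align()] result (or a list with `aligned_a`,
#'   `aligned_b`).
#' @return Identity in `[0, 1]`.
#' @export
pairwise_identity <- function(alignment) {
  a <- utf8ToInt(alignment$aligned_a)
  b <- utf8ToInt(alignment$aligned_b)
  if (length(a) != length(b)) stop("aligned strings must have equal length")
  gapc <- utf8ToInt("-")
  n <- length(a)
  # terminal gap extents in either row
  lead <- function(x) { r <- which(x != gapc); if (length(r)) r[1] - 1L else n }
  trail <- function(x) { r <- which(x != gapc); if (length(r)) n - r[length(r)] else n }
  from <- 1L + max(lead(a), lead(b))
  to <- n - max(trail(a), trail(b))
  if (from > to) return(0)
  idx <- from:to
  sum(a[idx] == b[idx]) / length(idx)
}

#' Dereplicate per-sample reads into unique sequences with counts
#'
#' @param sample_reads named list of data frames (`read_id`, `sequence`),
#'   one per sample, as produced by [run_qc()].
#' @return List with `sequence` (unique sequences), `counts` (matrix
#'   sequences x samples) and `members` (list of read ids per sequence).
#' @export
dereplicate <- function(sample_reads) {
  seqs <- unique(unlist(lapply(sample_reads, `[[`, "sequence"), use.names = FALSE))
  counts <- matrix(0L, length(seqs), length(sample_reads),
                   dimnames = list(NULL, names(sample_reads)))
  for (s in seq_along(sample_reads)) {
    t <- table(factor(sample_reads[[s]]$sequence, levels = seqs))
    counts[, s] <- as.integer(t)
  }
  members <- lapply(seqs, function(sq) {
    unlist(lapply(sample_reads, function(df) df$read_id[df$sequence == sq]),
           use.names = FALSE)
  })
  list(sequence = seqs, counts = counts, members = members)
}

# Conservative shared k-mer prefilter: a centroid that cannot possibly reach
# the identity threshold is skipped without alignment.  Each substitution or
# indel destroys at most k of the shorter sequence's k-mer occurrences, so a
# qualifying pair must share (as a multiset, which is what repetitive
# sequences require) at least (Lmin - k + 1) - k * (ceil(level * Lmax) + 1)
# k-mer occurrences.
kmer_set <- function(seq, k = 8L) {
  n <- nchar(seq)
  if (n < k) return(table(character(0)))
  table(substring(seq, 1:(n - k + 1L), k:n))
}

kmer_can_match <- function(tab_a, tab_b, la, lb, level, k = 8L) {
  need <- (min(la, lb) - k + 1L) - k * (ceiling(level * max(la, lb)) + 1L)
  if (need <= 0L) return(TRUE)
  common <- intersect(names(tab_a), names(tab_b))
  if (!length(common)) return(FALSE)
  sum(pmin(tab_a[common], tab_b[common])) >= need
}

#' Greedy abundance-ordered centroid clustering into OTUs
#'
#' Unique sequences are processed in decreasing total-count order (ties:
#' longer first, then lexicographic).  Each sequence joins the first existing
#' centroid whose pairwise identity (see [pairwise_identity()]) is at least
#' `1 - level`, and otherwise founds a new centroid.  The procedure is fully
#' deterministic, so the same input always yields the same OTU table.
#'
#' @param derep a [dereplicate()] result (or a list with `sequence`,
#'   `counts`, optionally `members`).
#' @param level dissimilarity level in `(0, 1)`: 0.03 for diversity work,
#'   0.20 for phylogenetic classification.
#' @param match,mismatch,gap alignment scoring (see [global_align()]).
#' @param kmer_prefilter skip alignments that provably cannot reach the
#'   identity threshold using a shared 8-mer bound; behaviorally invisible.
#' @return An `otu_table`: list with `level`, `otus` (data frame `otu_id`,
#'   `centroid`, `representative`, `total`), `counts` (matrix OTUs x
#'   samples), `members` (per OTU: data frame of member sequences with their
#'   per-sample counts), and `read_ids` when the input carries them.
#' @export
cluster_greedy <- function(derep, level, match = 1, mismatch = -1, gap = -2,
                          kmer_prefilter = TRUE) {
  if (!is.numeric(level) || level <= 0 || level >= 1)
    stop("level must lie in (0, 1)")
  seqs <- derep$sequence
  counts <- derep$counts
  n <- length(seqs)
  samples <- colnames(counts)
  if (n == 0L) {
    return(structure(list(level = level,
                          otus = data.frame(otu_id = character(0),
                                            centroid = character(0),
                                            representative = character(0),
                                            total = integer(0)),
                          counts = matrix(0L, 0, length(samples),
                                          dimnames = list(NULL, samples)),
                          members = list()),
                     class = "otu_table"))
  }
  totals <- rowSums(counts)
  ord <- order(-totals, -nchar(seqs), seqs)
  threshold <- 1 - level

  centroid_idx <- integer(0)
  assignment <- integer(n)
  ksets <- if (kmer_prefilter) lapply(seqs, kmer_set) else NULL

  for (i in ord) {
    hit <- 0L
    for (ci in seq_along(centroid_idx)) {
      c_i <- centroid_idx[ci]
      if (kmer_prefilter &&
          !kmer_can_match(ksets[[i]], ksets[[c_i]],
                          nchar(seqs[i]), nchar(seqs[c_i]), level)) next
      al <- nw_align_cpp(seqs[i], seqs[c_i], match, mismatch, gap)
      if (pairwise_identity(al) >= threshold) { hit <- ci; break }
    }
    if (hit == 0L) {
      centroid_idx <- c(centroid_idx, i)
      assignment[i] <- length(centroid_idx)
    } else {
      assignment[i] <- hit
    }
  }

  n_otu <- length(centroid_idx)
  otu_ids <- sprintf("OTU%s_%04d", sub("^0\\.", "", format(level)), seq_len(n_otu))
  cmat <- matrix(0L, n_otu, ncol(counts), dimnames = list(otu_ids, samples))
  members <- vector("list", n_otu)
  for (k in seq_len(n_otu)) {
    idx <- which(assignment == k)
    cmat[k, ] <- colSums(counts[idx, , drop = FALSE])
    members[[k]] <- data.frame(sequence = seqs[idx],
                               total = totals[idx],
                               is_centroid = idx == centroid_idx[k],
                               stringsAsFactors = FALSE)
    if (!is.null(derep$members))
      members[[k]]$read_ids <- I(derep$members[idx])
  }
  names(members) <- otu_ids
  otus <- data.frame(otu_id = otu_ids,
                     centroid = seqs[centroid_idx],
                     representative = NA_character_,
                     total = as.integer(rowSums(cmat)),
                     stringsAsFactors = FALSE)
  tab <- structure(list(level = level, otus = otus, counts = cmat,
                        members = members),
                   class = "otu_table")
  pick_representatives(tab)
}

#' Select the most-abundant member sequence as each OTU's representative
#'
#' Ties are broken in favour of the centroid, then lexicographically.
#'
#' @param table an `otu_table`.
#' @return The table with the `representative` column filled in.
#' @export
pick_representatives <- function(table) {
  stopifnot(inherits(table, "otu_table"))
  for (k in seq_along(table$members)) {
    m <- table$members[[k]]
    ord <- order(-m$total, -m$is_centroid, m$sequence)
    table$otus$representative[k] <- m$sequence[ord[1]]
  }
  table
}

#' Remove singleton OTUs
#'
#' Drops OTUs whose total count across all samples is exactly one; such
#' single-read OTUs are uninformative for phylogenetic placement and are
#' removed before classification.
#'
#' @param table an `otu_table`.
#' @return The filtered table, with attribute `n_removed`.
#' @export
drop_singletons <- function(table) {
  stopifnot(inherits(table, "otu_table"))
  keep <- table$otus$total > 1L
  out <- table
  out$otus <- table$otus[keep, , drop = FALSE]
  out$counts <- table$counts[keep, , drop = FALSE]
  out$members <- table$members[keep]
  rownames(out$otus) <- NULL
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' @export
print.otu_table <- function(x, ...) {
  cat(sprintf("OTU table at %.0f%% dissimilarity: %d OTUs, %d samples, %d reads\n",
              100 * x$level, nrow(x$otus), ncol(x$counts), sum(x$counts)))
  invisible(x)
}

#' Write an OTU table's membership, counts and representatives
#'
#' @param table an `otu_table`.
#' @param out_dir output directory.
#' @param prefix file name prefix (default derived from the level).
#' @return Named vector of written paths.
#' @export
write_otu_table <- function(table, out_dir,
                            prefix = sprintf("otu_%s", sub("^0\\.", "", format(table$level)))) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  counts_df <- data.frame(otu_id = rownames(table$counts),
                          as.data.frame(table$counts),
                          stringsAsFactors = FALSE, check.names = FALSE)
  memb <- do.call(rbind, lapply(names(table$members), function(oid) {
    m <- table$members[[oid]]
    data.frame(otu_id = oid, sequence = m$sequence, total = m$total,
               is_centroid = as.integer(m$is_centroid),
               stringsAsFactors = FALSE)
  }))
  if (is.null(memb))
    memb <- data.frame(otu_id = character(0), sequence = character(0),
                       total = integer(0), is_centroid = integer(0))
  paths <- c(counts = file.path(out_dir, paste0(prefix, "_counts.tsv")),
             members = file.path(out_dir, paste0(prefix, "_members.tsv")),
             representatives = file.path(out_dir, paste0(prefix, "_representatives.fasta")))
  write_tsv(counts_df, paths[["counts"]])
  write_tsv(memb, paths[["members"]])
  write_fasta(data.frame(id = table$otus$otu_id,
                         sequence = table$otus$representative),
              paths[["representatives"]])
  paths
}
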