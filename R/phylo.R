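#' Jukes-Cantor distance between two aligned rows
#'
#' The observed mismatch proportion `p` over shared (both ungapped) columns
#' is transformed as `d = -(3/4) * log(1 - 4p/3)`.  Saturated pairs
#' (`p >= 0.75`) and transformed values above 5 are capped at `d_max = 5`;
#' pairs sharing fewer than 20 columns are flagged unreliable.
#'
#' @param row_i,row_j equal-length gapped sequence strings.
#' @param d_max cap for saturated distances.
#' @return Distance (attribute `unreliable` when the overlap is short).
#' @export
jc_distance <- function(row_i, row_j, d_max = 5) {
  if (nchar(row_i) != nchar(row_j)) stop("rows must have equal length")
  cnt <- msa_pair_counts_cpp(msa_encode(c(row_i, row_j)), seq_len(nchar(row_i)))
  shared <- cnt$shared[1, 2]
  if (shared == 0) stop("no shared ungapped columns")
  p <- cnt$mismatch[1, 2] / shared
  d <- jc_transform(p, d_max)
  if (shared < 20) attr(d, "unreliable") <- TRUE
  d
}

jc_transform <- function(p, d_max = 5) {
  # evaluate the log only below saturation to avoid NaN from log(<= 0)
  d <- -0.75 * log(1 - 4 * pmin(p, 0.749) / 3)
  d[p >= 0.75] <- d_max
  pmin(d, d_max)
}

#' Jukes-Cantor distance matrix from a multiple alignment
#'
#' @param msa an `msa` (named, equal-length gapped rows).
#' @param d_max cap for saturated distances.
#' @param cols optional 1-based column indices (used by the bootstrap to
#'   resample columns with replacement).
#' @return Symmetric distance matrix with a logical `unreliable` attribute
#'   marking pairs sharing fewer than 20 columns.
#' @export
jc_dist_matrix <- function(msa, d_max = 5, cols = NULL) {
  mat <- msa_encode(msa)
  if (is.null(cols)) cols <- seq_len(ncol(mat))
  jc_dist_from_encoded(mat, cols, names(msa), d_max)
}

jc_dist_from_encoded <- function(mat, cols, ids, d_max = 5) {
  cnt <- msa_pair_counts_cpp(mat, as.integer(cols))
  shared <- cnt$shared
  p <- cnt$mismatch / pmax(shared, 1)
  D <- jc_transform(p, d_max)
  D[shared == 0] <- d_max
  diag(D) <- 0
  dimnames(D) <- list(ids, ids)
  unrel <- shared < 20
  diag(unrel) <- FALSE
  attr(D, "unreliable") <- unrel
  D
}

#' Neighbor-joining tree reconstruction
#'
#' Canonical neighbor joining (Saitou-Nei Q criterion with the standard
#' branch-length and distance updates).  Ties in the Q matrix are broken by
#' the lexicographically smallest pair of cluster labels (each cluster
#' labelled by its smallest member taxon), which makes the topology
#' deterministic and independent of the input row order; negative branch
#' lengths are clamped to zero with the deficit moved to the sibling edge.
#' On an additive distance matrix the output tree reproduces the input path
#' lengths exactly.
#'
#' @param dm symmetric distance matrix with zero diagonal; row/column names
#'   become tip labels.
#' @return An unrooted `phylo` tree (from the \pkg{ape} package).
#' @export
nj_tree <- function(dm) {
  dm <- as.matrix(dm)
  n <- nrow(dm)
  if (n < 3L) stop("need at least 3 taxa")
  if (!isTRUE(all.equal(dm, t(dm), tolerance = 1e-8)))
    stop("distance matrix must be symmetric")
  labels <- rownames(dm)
  if (is.null(labels)) labels <- paste0("t", seq_len(n))

  nwk <- labels                       # newick fragment per active node
  lab <- labels                       # smallest member taxon per active node
  D <- dm
  fmt <- function(x) sprintf("%.12g", x)

  while (nrow(D) > 3L) {
    m <- nrow(D)
    r <- rowSums(D)
    Q <- (m - 2) * D - outer(r, r, `+`)
    diag(Q) <- Inf
    # break exact ties by the smallest cluster-label pair so the result does
    # not depend on input row order
    idx <- which(Q <= min(Q) + 1e-12 * max(1, abs(min(Q))), arr.ind = TRUE)
    idx <- idx[idx[, 1] < idx[, 2], , drop = FALSE]
    key1 <- pmin(lab[idx[, 1]], lab[idx[, 2]])
    key2 <- pmax(lab[idx[, 1]], lab[idx[, 2]])
    pick <- order(key1, key2)[1]
    i <- idx[pick, 1]; j <- idx[pick, 2]

    li <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    lj <- D[i, j] - li
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }
    new_nwk <- sprintf("(%s:%s,%s:%s)", nwk[i], fmt(li), nwk[j], fmt(lj))

    du <- 0.5 * (D[i, ] + D[j, ] - D[i, j])
    keep <- setdiff(seq_len(m), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], du[keep]), c(du[keep], 0))
    lab <- c(lab[keep], min(lab[i], lab[j]))
    nwk <- c(nwk[keep], new_nwk)
    D <- D2
  }

  d12 <- D[1, 2]; d13 <- D[1, 3]; d23 <- D[2, 3]
  l <- c((d12 + d13 - d23) / 2, (d12 + d23 - d13) / 2, (d13 + d23 - d12) / 2)
  # non-additive input can push a terminal length negative at the final star;
  # clamp and spread the deficit over the two sibling edges
  for (k in 1:3) {
    if (l[k] < 0) {
      others <- setdiff(1:3, k)
      l[others] <- l[others] + l[k] / 2
      l[k] <- 0
    }
  }
  l <- pmax(l, 0)
  txt <- sprintf("(%s:%s,%s:%s,%s:%s);",
                 nwk[1], fmt(l[1]), nwk[2], fmt(l[2]), nwk[3], fmt(l[3]))
  ape::read.tree(text = txt)
}

#' Neighbor-joining tree with bootstrap supports
#'
#' Builds the full-data Jukes-Cantor + neighbor-joining tree, midpoint-roots
#' it, then resamples alignment columns with replacement `n_replicates`
#' times, rebuilds a tree per replicate, and attaches to each internal node
#' the fraction of replicates containing its bipartition.  Deterministic
#' given `seed`.
#'
#' @param msa an `msa` with >= 4 rows.
#' @param n_replicates number of bootstrap replicates (>= 1).
#' @param seed integer seed.
#' @param root midpoint-root the reference tree (default `TRUE`).
#' @param d_max saturation cap for the distance transform.
#' @return A `phylo` tree whose `node.label` holds supports in `[0, 1]`.
#' @export
bootstrap_support <- function(msa, n_replicates = 100, seed = 1,
                              root = TRUE, d_max = 5) {
  if (length(msa) < 4L) stop("need at least 4 sequences")
  if (n_replicates < 1L) stop("n_replicates must be >= 1")
  mat <- msa_encode(msa)
  L <- ncol(mat)
  ids <- names(msa)
  ref <- nj_tree(jc_dist_from_encoded(mat, seq_len(L), ids, d_max))
  if (root) ref <- phangorn::midpoint(ref)

  trees <- with_seed(seed, {
    lapply(seq_len(n_replicates), function(b) {
      cols <- sample.int(L, L, replace = TRUE)
      nj_tree(jc_dist_from_encoded(mat, cols, ids, d_max))
    })
  })
  class(trees) <- "multiPhylo"
  counts <- ape::prop.clades(ref, trees, rooted = FALSE)
  support <- counts / n_replicates
  support[is.na(support)] <- 0
  support[1] <- 1                     # root bipartition is trivially present
  ref$node.label <- support
  attr(ref, "n_replicates") <- n_replicates
  ref
}

#' Assign OTU representatives to reference clades
#'
#' Each query tip is labelled by the reference kingdoms found in the smallest
#' clade that (a) contains the query and at least one reference sequence and
#' (b) has bootstrap support of at least `min_support`.  Queries whose
#' smallest such clade is the whole tree, and queries on suspiciously long
#' terminal branches (longer than the `long_branch_quantile` quantile of
#' reference terminal branches — a long-branch-attraction guard), are
#' labelled `NOVEL`.
#'
#' @param tree rooted `phylo` with bootstrap supports in `node.label`
#'   (see [bootstrap_support()]).
#' @param reference_labels named character vector: reference tip id ->
#'   kingdom label.  Tips not named here are treated as queries.
#' @param min_support minimum clade support (default 0.5).
#' @param long_branch_quantile quantile of reference terminal branch lengths
#'   used as the long-branch yardstick (default 0.95).
#' @param long_branch_factor multiplier applied to that quantile before a
#'   query is flagged (default 2).  Amplicon-derived queries are routinely
#'   somewhat more divergent than curated references, so the factor keeps
#'   ordinary divergence unflagged while still catching alien sequences
#'   whose branches are an order of magnitude longer.
#' @param dm optional distance matrix used to report each query's nearest
#'   reference; defaults to patristic distances from the tree.
#' @return A `clade_assignment` data frame: `query`, `label`, `support`,
#'   `long_branch`, `nearest_ref`, `nearest_dist`.
#' @export
assign_clades <- function(tree, reference_labels, min_support = 0.5,
                          long_branch_quantile = 0.95,
                          long_branch_factor = 2, dm = NULL) {
  stopifnot(inherits(tree, "phylo"))
  tips <- tree$tip.label
  refs <- intersect(tips, names(reference_labels))
  if (!length(refs)) stop("tree contains no reference sequences")
  queries <- setdiff(tips, refs)
  ntip <- length(tips)
  root <- ntip + 1L

  support <- suppressWarnings(as.numeric(tree$node.label))
  support[is.na(support)] <- 0
  node_support <- function(node) {
    if (node == root) 1 else support[node - ntip]
  }

  parent <- integer(max(tree$edge))
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  desc <- phangorn::Descendants(tree, type = "tips")

  term_len <- numeric(ntip)
  tip_edges <- tree$edge[, 2] <= ntip
  term_len[tree$edge[tip_edges, 2]] <- tree$edge.length[tip_edges]
  # yardstick branches come from the reference-only subtree: in the joint
  # tree, queries attaching next to a reference deflate its terminal branch
  # toward zero, which would make the yardstick depend on the queries
  ref_term <- term_len[match(refs, tips)]
  if (length(queries) && length(refs) >= 3) {
    pruned <- ape::drop.tip(tree, queries)
    if (!is.null(pruned)) {
      np <- length(pruned$tip.label)
      pt <- numeric(np)
      pe <- pruned$edge[, 2] <= np
      pt[pruned$edge[pe, 2]] <- pruned$edge.length[pe]
      ref_term <- pt[match(refs, pruned$tip.label)]
    }
  }
  lb_cut <- long_branch_factor *
    quantile(ref_term, long_branch_quantile, names = FALSE)

  if (is.null(dm)) dm <- ape::cophenetic.phylo(tree)

  rows <- lapply(queries, function(q) {
    qi <- match(q, tips)
    nd <- dm[q, refs]
    nearest <- refs[which.min(nd)]
    long_branch <- term_len[qi] > lb_cut
    label <- "NOVEL"; sup <- NA_real_
    if (!long_branch) {
      node <- parent[qi]
      repeat {
        in_clade <- intersect(tips[desc[[node]]], refs)
        if (length(in_clade) && node_support(node) >= min_support) {
          if (node == root) break      # whole tree: stays NOVEL
          label <- paste(sort(unique(reference_labels[in_clade])),
                         collapse = "+")
          sup <- node_support(node)
          break
        }
        if (node == root) break
        node <- parent[node]
      }
    }
    data.frame(query = q, label = label, support = sup,
               long_branch = long_branch, nearest_ref = nearest,
               nearest_dist = min(nd), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("clade_assignment", "data.frame")
  out
}

#' @export
print.clade_assignment <- function(x, ...) {
  cat(sprintf("Clade assignment of %d query OTUs (%d NOVEL)\n",
              nrow(x), sum(x$label == "NOVEL")))
  print(sort(table(x$label), decreasing = TRUE))
  invisible(x)
}

#' Per-sample clade read-percentage matrix
#'
#' Tallies, for each sample, the percentage of its reads whose OTU carries
#' each clade label; rows sum to 100.
#'
#' @param assignments a [assign_clades()] result covering every OTU in the
#'   table.
#' @param table the `otu_table` the assignments refer to (typically the
#'   20%-dissimilarity table after [drop_singletons()]).
#' @return Matrix samples x clade labels of read percentages.
#' @export
clade_abundance_matrix <- function(assignments, table) {
  stopifnot(inherits(table, "otu_table"))
  otus <- rownames(table$counts)
  missing <- setdiff(otus, assignments$query)
  if (length(missing))
    stop("unassigned OTUs: ", paste(missing, collapse = ", "))
  labels <- assignments$label[match(otus, assignments$query)]
  libs <- colSums(table$counts)
  if (any(libs == 0)) {
    warning("dropping samples with no reads at this level: ",
            paste(names(libs)[libs == 0], collapse = ", "))
  }
  keep <- libs > 0
  ulab <- sort(unique(labels))
  agg <- t(rowsum(table$counts[, keep, drop = FALSE], group = labels))
  out <- matrix(0, sum(keep), length(ulab),
                dimnames = list(colnames(table$counts)[keep], ulab))
  out[, colnames(agg)] <- agg
  100 * out / rowSums(out)
}

#' High-level phylogeny-based classification of OTU representatives
#'
#' Combines query representatives and the reference panel, aligns them,
#' trims gap-dominated terminal columns, computes Jukes-Cantor distances,
#' builds the bootstrap-supported neighbor-joining tree, and assigns each
#' query to a reference clade.
#'
#' @param representatives named character vector: OTU id -> representative
#'   sequence.
#' @param panel a `reference_panel` (or data frame with `id`, `kingdom`,
#'   `sequence`).
#' @param n_replicates bootstrap replicates (default 100; a publication-grade
#'   run would use 1000).
#' @param min_support minimum clade support (default 0.5).
#' @param seed integer seed.
#' @param max_gap_fraction terminal-column trim threshold.
#' @return List with `msa`, `dm`, `tree`, `assignments`.
#' @export
classify_representatives <- function(representatives, panel,
                                     n_replicates = 100, min_support = 0.5,
                                     seed = 1, max_gap_fraction = 0.9) {
  if (is.null(names(representatives)))
    stop("representatives must be named by OTU id")
  if (any(names(representatives) %in% panel$id))
    stop("OTU ids collide with reference ids")
  seqs <- c(representatives, structure(panel$sequence, names = panel$id))
  msa <- progressive_msa(seqs)
  msa <- trim_alignment(msa, max_gap_fraction)
  dm <- jc_dist_matrix(msa)
  tree <- bootstrap_support(msa, n_replicates = n_replicates, seed = seed)
  ref_labels <- structure(panel$kingdom, names = panel$id)
  assignments <- assign_clades(tree, ref_labels, min_support = min_support,
                               dm = dm)
  list(msa = msa, dm = dm, tree = tree, assignments = assignments)
}
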