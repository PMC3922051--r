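#' Bray-Curtis dissimilarity between sample abundance profiles
#'
#' `BC(x, y) = sum(|x - y|) / sum(x + y)`, computed for every pair of rows.
#'
#' @param mat samples x features abundance matrix (non-negative rows, each
#'   with a positive sum).
#' @return Symmetric dissimilarity matrix in `[0, 1]` with zero diagonal.
#' @examples
#' bray_curtis(rbind(a = c(6, 2), b = c(2, 2)))  # 1/3 off-diagonal
#' @export
bray_curtis <- function(mat) {
  mat <- as.matrix(mat)
  if (any(mat < 0)) stop("abundances must be non-negative")
  zero <- rowSums(mat) == 0
  if (any(zero))
    stop("all-zero abundance row(s): ",
         paste(rownames(mat)[zero], collapse = ", "))
  d <- vegan::vegdist(mat, method = "bray")
  out <- as.matrix(d)
  dimnames(out) <- list(rownames(mat), rownames(mat))
  out
}

#' Principal coordinates analysis (classical metric scaling)
#'
#' Double-centers `-D^2 / 2`, eigendecomposes, and scales eigenvectors by the
#' square roots of their eigenvalues.  Negative eigenvalues (possible for
#' non-Euclidean dissimilarities such as Bray-Curtis) are reported but
#' excluded from the variance-explained denominator.
#'
#' @param dm symmetric dissimilarity matrix (or `dist`).
#' @param k number of axes to retain (`< n` samples).
#' @param lingoes apply the Lingoes additive correction (adds a constant to
#'   squared off-diagonal dissimilarities so all eigenvalues become
#'   non-negative); default `FALSE` — negative eigenvalues are reported, not
#'   hidden.
#' @return An `ordination`: list with `points` (n x k coordinate matrix),
#'   `eig` (all eigenvalues, decreasing), and `variance` (proportion of
#'   positive-eigenvalue variance per retained axis).
#' @export
pcoa <- function(dm, k = 2, lingoes = FALSE) {
  dm <- as.matrix(dm)
  n <- nrow(dm)
  if (k >= n) stop("k must be smaller than the number of samples")
  if (lingoes) {
    # cmdscale warns when fewer than k eigenvalues are positive; here only
    # the eigenvalue spectrum is wanted
    eig0 <- suppressWarnings(cmdscale(as.dist(dm), k = n - 1, eig = TRUE)$eig)
    c1 <- max(0, -min(eig0))
    if (c1 > 0) {
      d2 <- dm^2 + 2 * c1
      diag(d2) <- 0
      dm <- sqrt(d2)
    }
  }
  sc <- cmdscale(as.dist(dm), k = k, eig = TRUE)
  pts <- sc$points
  # cmdscale can return fewer columns than requested in degenerate cases
  if (ncol(pts) < k) {
    pts <- cbind(pts, matrix(0, n, k - ncol(pts)))
  }
  colnames(pts) <- paste0("axis", seq_len(k))
  eig <- sort(sc$eig, decreasing = TRUE)
  pos <- sum(eig[eig > 0])
  variance <- if (pos > 0) pmax(eig[seq_len(k)], 0) / pos else rep(0, k)
  structure(list(points = pts, eig = eig, variance = variance),
            class = "ordination")
}

#' @export
print.ordination <- function(x, ...) {
  cat(sprintf("PCoA ordination: %d samples, %d axes\n",
              nrow(x$points), ncol(x$points)))
  cat("variance explained:",
      paste(sprintf("%.1f%%", 100 * x$variance), collapse = ", "), "\n")
  invisible(x)
}

#' Silhouette-style separation of labelled sample groups
#'
#' Mean silhouette width of the samples over Euclidean distances on the first
#' two ordination axes: near 1 when the groups form tight, mutually distant
#' clusters, near 0 (or negative) when they overlap.
#'
#' @param ordination a [pcoa()] result.
#' @param groups character/factor of group labels, one per sample.
#' @return Mean silhouette width.
#' @export
group_separation <- function(ordination, groups) {
  pts <- ordination$points[, 1:2, drop = FALSE]
  if (length(groups) != nrow(pts)) stop("one group label per sample required")
  if (any(table(groups) == 0) || length(unique(groups)) < 2)
    stop("need at least two non-empty groups")
  d <- dist(pts)
  if (all(d == 0)) stop("all samples are coincident; separation is undefined")
  sil <- cluster::silhouette(as.integer(factor(groups)), d)
  mean(sil[, "sil_width"])
}

#' Write ordination coordinates and eigenvalues as TSV
#'
#' @param ordination a [pcoa()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_ordination <- function(ordination, path) {
  k <- ncol(ordination$points)
  coords <- apply(ordination$points, 2, function(x) sprintf("%.6g", x))
  if (is.null(dim(coords))) coords <- matrix(coords, nrow = 1)
  df <- data.frame(sample_id = c(rownames(ordination$points),
                                 "(eigenvalue)", "(variance_fraction)"),
                   rbind(coords,
                         sprintf("%.6g", ordination$eig[seq_len(k)]),
                         sprintf("%.6g", ordination$variance)),
                   stringsAsFactors = FALSE, check.names = FALSE)
  names(df)[-1] <- colnames(ordination$points)
  write_tsv(df, path)
}

#' Covariance PCA of a clade percentage matrix
#'
#' Alternative to [pcoa()] on Bray-Curtis: a plain principal component
#' analysis of the (centered, unscaled) clade percentage matrix.  Offered
#' for comparison because ordination of clade profiles is described
#' interchangeably as "PCA" and as dissimilarity-based ordination in the
#' survey literature; the two emphasise different structure.
#'
#' @param mat samples x clades percentage matrix.
#' @param k axes to retain.
#' @return An `ordination` (see [pcoa()]).
#' @export
clade_pca <- function(mat, k = 2) {
  mat <- as.matrix(mat)
  if (k >= nrow(mat)) stop("k must be smaller than the number of samples")
  pc <- stats::prcomp(mat, center = TRUE, scale. = FALSE)
  eig <- pc$sdev^2
  kk <- min(k, ncol(pc$x))
  pts <- pc$x[, seq_len(kk), drop = FALSE]
  if (kk < k) pts <- cbind(pts, matrix(0, nrow(mat), k - kk))
  colnames(pts) <- paste0("axis", seq_len(k))
  structure(list(points = pts, eig = eig,
                 variance = eig[seq_len(k)] / sum(eig)),
            class = "ordination")
}
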