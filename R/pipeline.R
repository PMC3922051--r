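#' Read / write a kingdom-labelled reference panel as FASTA
#'
#' Headers carry the kingdom after a pipe: `>id|kingdom`.
#'
#' @param panel a `reference_panel` (or data frame with `id`, `kingdom`,
#'   `sequence`).
#' @param path FASTA file.
#' @return `write_reference_fasta()`: `path`, invisibly;
#'   `read_reference_fasta()`: a `reference_panel` data frame.
#' @export
write_reference_fasta <- function(panel, path) {
  ids <- paste(panel$id, panel$kingdom, sep = "|")
  write_fasta(structure(panel$sequence, names = ids), path)
}

#' @rdname write_reference_fasta
#' @export
read_reference_fasta <- function(path) {
  x <- read_fasta(path)
  parts <- strsplit(x$id, "|", fixed = TRUE)
  if (any(lengths(parts) != 2L))
    stop("reference headers must look like >id|kingdom")
  panel <- data.frame(id = vapply(parts, `[`, "", 1L),
                      kingdom = vapply(parts, `[`, "", 2L),
                      sequence = x$sequence, stringsAsFactors = FALSE)
  class(panel) <- c("reference_panel", "data.frame")
  panel
}

#' Configuration of a full pipeline run
#'
#' @param fastq multiplexed FASTQ path.
#' @param mapping barcode mapping TSV path.
#' @param references reference panel FASTA path (`>id|kingdom` headers).
#' @param out_dir output directory.
#' @param qc a [qc_params()].
#' @param probeset a [probe_set()].
#' @param levels clustering dissimilarity levels: first for diversity,
#'   second for phylogenetic classification.
#' @param bootstrap bootstrap replicates for the classification tree.
#' @param min_support minimum clade support.
#' @param seed master seed; per-stage seeds are derived with [stage_seed()].
#' @param drop_ids optional path to a file of OTU ids (one per line) to
#'   exclude before classification, standing in for manual alignment
#'   curation.
#' @return A `run_config` list.
#' @export
run_config <- function(fastq, mapping, references, out_dir,
                       qc = qc_params(), probeset = probe_set(),
                       levels = c(0.03, 0.20), bootstrap = 100,
                       min_support = 0.5, seed = 1, drop_ids = NULL) {
  if (any(levels <= 0 | levels >= 1)) stop("levels must lie in (0, 1)")
  if (length(levels) != 2L) stop("exactly two clustering levels are required")
  structure(list(fastq = fastq, mapping = mapping, references = references,
                 out_dir = out_dir, qc = qc, probeset = probeset,
                 levels = levels, bootstrap = bootstrap,
                 min_support = min_support, seed = seed,
                 drop_ids = drop_ids),
            class = "run_config")
}

#' Run the full amplicon analysis pipeline
#'
#' Executes QC (demultiplexing, quality filters, probe screen), clustering at
#' the diversity level with a rarefied diversity summary, clustering at the
#' classification level with singleton removal, phylogeny-based clade
#' assignment, and Bray-Curtis/PCoA ordination of the clade abundance
#' matrix.  All outputs are plain-text tables, FASTA/Newick files under
#' `out_dir`; rerunning with the same configuration reproduces them
#' byte-identically.
#'
#' @param config a [run_config()].
#' @return A `run_manifest`: per-stage read/OTU counts, derived seeds, and
#'   md5 checksums of every output file.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  for (f in c(config$fastq, config$mapping, config$references)) {
    if (!file.exists(f)) stop("input file does not exist: ", f)
  }
  out <- config$out_dir
  if (!dir.exists(out) && !dir.create(out, recursive = TRUE))
    stop("cannot create output directory: ", out)

  reads <- read_fastq(config$fastq)
  mapping <- read_mapping(config$mapping)
  panel <- read_reference_fasta(config$references)
  manifest <- list(package_version = as.character(utils::packageVersion("brine18s")),
                   seed = config$seed, n_input_reads = nrow(reads))

  # stage 1: QC ------------------------------------------------------------
  qc <- run_qc(reads, mapping, config$qc, config$probeset)
  write_qc(qc, out)
  manifest$n_qualified <- sum(qc$report$qualified)
  manifest$n_rejected <- sum(qc$report$input) - manifest$n_qualified
  if (manifest$n_qualified == 0) stop("stage qc: no read passed")

  # stage 2: clustering + diversity at the fine level ----------------------
  derep <- dereplicate(qc$qualified)
  t_div <- cluster_greedy(derep, config$levels[1])
  write_otu_table(t_div, out)
  manifest$n_otus_diversity <- nrow(t_div$otus)
  manifest$reads_in_otus_diversity <- sum(t_div$counts)
  div_seed <- stage_seed(config$seed, 2)
  manifest$seed_diversity <- div_seed
  div <- diversity_table(t_div, seed = div_seed)
  write_diversity(div, file.path(out, "diversity.tsv"))

  # stage 3: clustering at the classification level ------------------------
  t_cls <- cluster_greedy(derep, config$levels[2])
  manifest$n_otus_classification <- nrow(t_cls$otus)
  manifest$reads_in_otus_classification <- sum(t_cls$counts)
  t_cls <- drop_singletons(t_cls)
  manifest$n_singletons_removed <- attr(t_cls, "n_removed")
  if (!is.null(config$drop_ids)) {
    drop <- readLines(config$drop_ids)
    keep <- !(rownames(t_cls$counts) %in% drop)
    t_cls$otus <- t_cls$otus[keep, , drop = FALSE]
    t_cls$counts <- t_cls$counts[keep, , drop = FALSE]
    t_cls$members <- t_cls$members[keep]
    manifest$n_dropped_by_id <- sum(!keep)
  }
  write_otu_table(t_cls, out, prefix = "otu_classify")
  if (nrow(t_cls$otus) < 1) stop("stage classify: no OTU left to classify")

  # stage 4: phylogeny-based classification --------------------------------
  reps <- structure(t_cls$otus$representative, names = t_cls$otus$otu_id)
  cls_seed <- stage_seed(config$seed, 4)
  manifest$seed_classification <- cls_seed
  cls <- classify_representatives(reps, panel,
                                  n_replicates = config$bootstrap,
                                  min_support = config$min_support,
                                  seed = cls_seed)
  write_fasta(structure(unclass(cls$msa), names = names(cls$msa)),
              file.path(out, "classification_msa.fasta"))
  tr <- cls$tree
  tr$node.label <- sprintf("%.3f", tr$node.label)
  ape::write.tree(tr, file.path(out, "classification_tree.nwk"))
  asg <- cls$assignments
  asg$support <- ifelse(is.na(asg$support), "NA", sprintf("%.3f", asg$support))
  asg$nearest_dist <- sprintf("%.6f", asg$nearest_dist)
  asg$long_branch <- as.integer(asg$long_branch)
  write_tsv(asg, file.path(out, "clade_assignments.tsv"))
  manifest$n_clades <- length(unique(cls$assignments$label))
  manifest$n_novel <- sum(cls$assignments$label == "NOVEL")

  cam <- clade_abundance_matrix(cls$assignments, t_cls)
  cam_df <- data.frame(sample_id = rownames(cam),
                       as.data.frame(signif(cam, 8)),
                       stringsAsFactors = FALSE, check.names = FALSE)
  write_tsv(cam_df, file.path(out, "clade_matrix.tsv"))

  # stage 5: ordination -----------------------------------------------------
  bc <- bray_curtis(cam)
  bc_df <- data.frame(sample_id = rownames(bc),
                      as.data.frame(signif(bc, 8)),
                      stringsAsFactors = FALSE, check.names = FALSE)
  write_tsv(bc_df, file.path(out, "braycurtis.tsv"))
  k <- min(2L, nrow(bc) - 1L)
  ord <- pcoa(bc, k = k)
  write_ordination(ord, file.path(out, "ordination.tsv"))
  manifest$pc_variance <- ord$variance

  files <- sort(list.files(out, full.names = TRUE))
  files <- files[basename(files) != "manifest.tsv"]
  manifest$md5 <- tools::md5sum(files)
  names(manifest$md5) <- basename(files)
  class(manifest) <- "run_manifest"
  writeLines(c("#key\tvalue",
               paste(rep(names(manifest), lengths(manifest)),
                     unlist(lapply(manifest, function(x) {
                       if (!is.null(names(x)))
                         paste(names(x), unname(x), sep = ":") else as.character(x)
                     })), sep = "\t")),
             file.path(out, "manifest.tsv"))
  manifest
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("Pipeline run manifest\n")
  cat(sprintf("  input reads       %d\n", x$n_input_reads))
  cat(sprintf("  qualified reads   %d\n", x$n_qualified))
  cat(sprintf("  OTUs (diversity)  %d\n", x$n_otus_diversity))
  cat(sprintf("  OTUs (classify)   %d (%d singletons removed)\n",
              x$n_otus_classification, x$n_singletons_removed))
  cat(sprintf("  clade labels      %d (%d NOVEL OTUs)\n", x$n_clades, x$n_novel))
  cat(sprintf("  PC1+PC2 variance  %.1f%%\n", 100 * sum(x$pc_variance)))
  invisible(x)
}
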