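#' Generate a kingdom-labelled 18S reference panel
#'
#' Builds a synthetic multi-kingdom reference panel by mutating one root
#' sequence per kingdom away from a common ancestor, so that pairwise
#' divergence between kingdoms is approximately `inter_divergence` and within
#' a kingdom approximately `intra_divergence`.  Every sequence carries the
#' forward-primer site and both internal probe sites (Euk381, Euk422) verbatim
#' at fixed offsets, giving the probe screen a built-in positive control.
#' The default dimensions mirror a typical curated panel: 23 kingdoms (or
#' equivalent top-level groups) with five representatives each.
#'
#' @param n_kingdoms number of kingdom labels.
#' @param per_kingdom sequences per kingdom.
#' @param seq_length template length in nt (>= 200).
#' @param inter_divergence approximate pairwise divergence between kingdoms.
#' @param intra_divergence approximate pairwise divergence within a kingdom;
#'   must satisfy `0 < intra < inter < 0.75`.
#' @param seed integer seed; the panel is deterministic given the seed.
#' @param probeset a [probe_set()] giving the primer/probe motifs to plant.
#' @return A `reference_panel`: data frame with columns `id`, `kingdom`,
#'   `sequence`, plus attributes recording the planted motif offsets.
#' @examples
#' p <- generate_reference_panel(3, 2, 300, 0.3, 0.03, seed = 1)
#' table(p$kingdom)
#' @export
generate_reference_panel <- function(n_kingdoms = 23, per_kingdom = 5,
                                     seq_length = 600,
                                     inter_divergence = 0.30,
                                     intra_divergence = 0.03,
                                     seed = 1,
                                     probeset = probe_set()) {
  if (!(intra_divergence > 0 && intra_divergence < inter_divergence &&
        inter_divergence < 0.75))
    stop("divergences must satisfy 0 < intra < inter < 0.75")
  if (seq_length < 200) stop("seq_length must be >= 200")
  if (n_kingdoms < 1 || per_kingdom < 1)
    stop("n_kingdoms and per_kingdom must be positive")

  primer <- probeset$forward_primer
  probes <- probeset$probes
  primer_at <- 1L
  p1_at <- min(361L, seq_length - 55L)            # Euk381-like offset
  p2_at <- p1_at + 41L                            # Euk422-like offset
  motif_at <- list(forward_primer = primer_at,
                   probe1 = p1_at, probe2 = p2_at)
  protected <- c(seq(primer_at, primer_at + nchar(primer) - 1L),
                 seq(p1_at, p1_at + nchar(probes[[1]]) - 1L),
                 seq(p2_at, p2_at + nchar(probes[[2]]) - 1L))

  with_seed(seed, {
    master <- seq_to_chars(random_dna(seq_length))
    master[seq(primer_at, length.out = nchar(primer))] <- seq_to_chars(primer)
    master[seq(p1_at, length.out = nchar(probes[[1]]))] <- seq_to_chars(probes[[1]])
    master[seq(p2_at, length.out = nchar(probes[[2]]))] <- seq_to_chars(probes[[2]])

    ids <- character(0); kingdoms <- character(0); seqs <- character(0)
    for (k in seq_len(n_kingdoms)) {
      klab <- sprintf("K%02d", k)
      root <- mutate_chars(master, inter_divergence / 2, protected)
      for (j in seq_len(per_kingdom)) {
        member <- mutate_chars(root, intra_divergence / 2, protected)
        ids <- c(ids, sprintf("%s_r%d", klab, j))
        kingdoms <- c(kingdoms, klab)
        seqs <- c(seqs, chars_to_seq(member))
      }
    }
    panel <- data.frame(id = ids, kingdom = kingdoms, sequence = seqs,
                        stringsAsFactors = FALSE)
    attr(panel, "motif_at") <- motif_at
    attr(panel, "probeset") <- probeset
    attr(panel, "seq_length") <- seq_length
    class(panel) <- c("reference_panel", "data.frame")
    panel
  })
}

# Substitute a Bernoulli(rate) fraction of unprotected sites, never writing a
# base equal to the old one and never extending a homopolymer beyond 6 nt.
mutate_chars <- function(chars, rate, protected) {
  n <- length(chars)
  eligible <- setdiff(seq_len(n), protected)
  k <- rbinom(1L, length(eligible), rate)
  if (k == 0L) return(chars)
  pos <- sample(eligible, k)
  for (i in pos) {
    cand <- sample(setdiff(DNA_BASES, chars[i]))
    for (b in cand) {
      chars[i] <- b
      lo <- max(1L, i - 6L); hi <- min(n, i + 6L)
      r <- rle(chars[lo:hi])
      if (max(r$lengths) <= 6L) break
    }
  }
  chars
}

#' @export
print.reference_panel <- function(x, ...) {
  cat(sprintf("Reference panel: %d sequences, %d kingdoms, length %d nt\n",
              nrow(x), length(unique(x$kingdom)), attr(x, "seq_length")))
  invisible(x)
}

#' Configuration for the synthetic 454 amplicon simulator
#'
#' Describes a multiplexed pyrosequencing library: the barcoded samples, the
#' per-sample community composition over a reference panel, the sequencing
#' error model, and the fractions of reads planted with specific QC
#' violations so that downstream filters can be scored against ground truth.
#'
#' @param samples data frame with `sample_id` and 8-nt `barcode` columns
#'   (unique barcodes); defaults to the seven-site design of
#'   [default_mapping()].
#' @param n_reads reads per sample (scalar or one value per sample).
#' @param composition optional samples x panel-entries matrix of mixture
#'   weights (rows sum to 1).  If `NULL`, a log-normal taxon abundance
#'   profile is drawn per sample.
#' @param sub_rate per-base substitution error rate.
#' @param homopolymer_rate probability of a +/-1 indel at each homopolymer
#'   run of >= 3 nt (the dominant 454 error mode).
#' @param quality list with `q_start`, `q_end`, `noise`: per-base Phred
#'   qualities decay linearly from `q_start` at the first base to `q_end` at
#'   the last, plus uniform integer noise in `[-noise, noise]`.
#' @param false_amplicon_fraction fraction of reads replaced by non-rRNA
#'   amplicons (rejection-sampled to sit >= 3 mismatches from both probes at
#'   every offset).
#' @param short_read_fraction fraction of reads truncated below 150 nt.
#' @param ambiguous_base_fraction fraction of reads given >= 1 `N`.
#' @param homopolymer_fraction fraction of reads given a > 6 nt base run.
#' @param lowq_fraction fraction of reads given a 50-nt low-quality window.
#' @param bad_barcode_fraction fraction of reads with a corrupted barcode.
#' @param revcomp_fraction fraction of reads emitted reverse-complemented
#'   (default 0: 454 amplicon reads run 5' to 3' from the barcoded forward
#'   primer).  Such reads present no barcode at their start and are counted
#'   against the barcode rule downstream.
#' @param seed master seed; every random choice in the simulation derives
#'   from it.
#' @return A `sim_config` object (a validated list).
#' @export
sim_config <- function(samples = default_mapping(),
                       n_reads = 500,
                       composition = NULL,
                       sub_rate = 0.005,
                       homopolymer_rate = 0.02,
                       quality = list(q_start = 38, q_end = 28, noise = 1),
                       false_amplicon_fraction = 0,
                       short_read_fraction = 0,
                       ambiguous_base_fraction = 0,
                       homopolymer_fraction = 0,
                       lowq_fraction = 0,
                       bad_barcode_fraction = 0,
                       revcomp_fraction = 0,
                       seed = 1) {
  validate_mapping(samples)
  if (any(nchar(samples$barcode) != 8L))
    stop("sample barcodes must be exactly 8 nt")
  ns <- nrow(samples)
  if (length(n_reads) == 1L) n_reads <- rep(n_reads, ns)
  if (length(n_reads) != ns || any(n_reads < 1))
    stop("n_reads must be positive, scalar or one value per sample")
  fr <- c(false_amplicon = false_amplicon_fraction,
          short = short_read_fraction,
          ambiguous = ambiguous_base_fraction,
          homopolymer = homopolymer_fraction,
          lowq = lowq_fraction,
          bad_barcode = bad_barcode_fraction,
          revcomp = revcomp_fraction)
  if (any(fr < 0 | fr > 1) || sum(fr) > 1)
    stop("violation fractions must lie in [0,1] and sum to at most 1")
  if (!is.null(composition)) {
    composition <- as.matrix(composition)
    if (nrow(composition) != ns) stop("composition needs one row per sample")
    if (any(composition < 0) || any(abs(rowSums(composition) - 1) > 1e-8))
      stop("composition rows must be non-negative and sum to 1")
  }
  structure(list(samples = samples, n_reads = as.integer(n_reads),
                 composition = composition, sub_rate = sub_rate,
                 homopolymer_rate = homopolymer_rate, quality = quality,
                 fractions = fr, seed = seed),
            class = "sim_config")
}

#' Simulate a multiplexed 454-style amplicon read set with ground truth
#'
#' Each read is `barcode + forward primer + template-derived insert`, where
#' the insert is the template downstream of the primer site with substitution
#' errors and homopolymer +/-1 indels applied.  Per-base qualities follow the
#' configured linear decay.  Exactly `floor(fraction * n_reads)` reads per
#' sample are planted with each configured violation (the remainder are
#' clean); planted violations are mutually exclusive, and clean reads are
#' rejection-sampled so they never violate a QC rule by accident.  The whole
#' simulation is deterministic given `config$seed`.
#'
#' @param panel a [generate_reference_panel()] result (or any
#'   `reference_panel`).
#' @param config a [sim_config()].
#' @return An `amplicon_sim` list with elements `reads` (data frame
#'   `read_id`, `sequence`, `quality`), `truth` (data frame `read_id`,
#'   `sample_id`, `template_id`, `violation` — empty string for clean reads),
#'   `mapping`, and `config`.
#' @export
simulate_reads <- function(panel, config) {
  stopifnot(inherits(config, "sim_config"))
  if (!nrow(panel)) stop("reference panel is empty")
  probeset <- attr(panel, "probeset")
  if (is.null(probeset)) probeset <- probe_set()
  primer <- probeset$forward_primer
  probes <- probeset$probes
  np <- nrow(panel)
  tmpl_chars <- lapply(panel$sequence, seq_to_chars)
  insert_chars <- lapply(tmpl_chars, function(x) x[-seq_len(nchar(primer))])
  barcodes <- config$samples$barcode

  with_seed(config$seed, {
    all_reads <- vector("list", nrow(config$samples))
    all_truth <- vector("list", nrow(config$samples))

    for (s in seq_len(nrow(config$samples))) {
      sid <- config$samples$sample_id[s]
      bc <- config$samples$barcode[s]
      n <- config$n_reads[s]
      w <- if (is.null(config$composition)) {
        x <- rlnorm(np, 0, 1.5); x / sum(x)
      } else config$composition[s, ]
      tpl <- sample.int(np, n, replace = TRUE, prob = w)

      vio <- rep("", n)
      counts <- floor(config$fractions * n)
      ord <- sample.int(n)
      at <- 0L
      for (v in names(counts)) {
        if (counts[[v]] > 0L) {
          vio[ord[(at + 1L):(at + counts[[v]])]] <- toupper(v)
          at <- at + counts[[v]]
        }
      }
      vio[vio == "FALSE_AMPLICON"] <- "NO_PROBE"
      vio[vio == "AMBIGUOUS"] <- "AMBIG"

      seqs <- character(n); quals <- character(n)
      truth_tpl <- panel$id[tpl]
      for (i in seq_len(n)) {
        ins <- simulate_insert(insert_chars[[tpl[i]]], config, probes)
        v <- vio[i]
        this_bc <- bc
        lowq <- FALSE
        if (v == "NO_PROBE") {
          ins <- random_nonprobe_insert(length(ins), probes)
          truth_tpl[i] <- NA_character_
        } else if (v == "SHORT") {
          keep <- sample(100:149, 1L) - nchar(bc) - nchar(primer)
          ins <- ins[seq_len(keep)]
        } else if (v == "AMBIG") {
          ins[sample(length(ins), sample(1:3, 1L))] <- "N"
        } else if (v == "HOMOPOLYMER") {
          ins <- plant_homopolymer(ins, panel, nchar(primer))
        } else if (v == "LOWQ") {
          lowq <- TRUE
        } else if (v == "BAD_BARCODE") {
          this_bc <- corrupt_barcode(bc, barcodes)
        }
        read <- paste0(this_bc, primer, chars_to_seq(ins))
        if (v == "REVCOMP") read <- revcomp(read)
        seqs[i] <- read
        quals[i] <- simulate_quality(nchar(read), config$quality, lowq,
                                     nchar(this_bc) + nchar(primer))
      }
      ids <- sprintf("%s_%05d", sid, seq_len(n))
      all_reads[[s]] <- data.frame(read_id = ids, sequence = seqs,
                                   quality = quals, stringsAsFactors = FALSE)
      all_truth[[s]] <- data.frame(read_id = ids, sample_id = sid,
                                   template_id = truth_tpl, violation = vio,
                                   stringsAsFactors = FALSE)
    }
    reads <- do.call(rbind, all_reads)
    truth <- do.call(rbind, all_truth)
    # emulate multiplexed sequencing order
    ord <- sample.int(nrow(reads))
    reads <- reads[ord, , drop = FALSE]
    rownames(reads) <- rownames(truth) <- NULL
    structure(list(reads = reads, truth = truth,
                   mapping = config$samples, config = config),
              class = "amplicon_sim")
  })
}

# Apply the error model to one template insert; resample the error draw if it
# accidentally produces a planted-violation signature (long homopolymer or a
# read whose probes are both destroyed), so clean reads stay clean.
simulate_insert <- function(chars, config, probes) {
  for (attempt in 1:25) {
    x <- chars
    k <- rbinom(1L, length(x), config$sub_rate)
    if (k > 0L) {
      pos <- sample(length(x), k)
      for (i in pos) x[i] <- sample(setdiff(DNA_BASES, x[i]), 1L)
    }
    if (config$homopolymer_rate > 0) x <- apply_hp_indels(x, config$homopolymer_rate)
    s <- chars_to_seq(x)
    if (max_homopolymer_run(s) > 6L) next
    if (length(find_approx_match(s, probes[[1]], 2L)) == 0L &&
        length(find_approx_match(s, probes[[2]], 2L)) == 0L) next
    return(x)
  }
  chars  # error-free fallback; unreachable in practice at default rates
}

apply_hp_indels <- function(x, rate) {
  r <- rle(x)
  hit <- which(r$lengths >= 3L)
  if (!length(hit)) return(x)
  hit <- hit[runif(length(hit)) < rate]
  if (!length(hit)) return(x)
  delta <- sample(c(-1L, 1L), length(hit), replace = TRUE)
  r$lengths[hit] <- pmax(1L, r$lengths[hit] + delta)
  inverse.rle(r)
}

# Rejection-sample a random non-rRNA insert: >= 3 mismatches to both probes
# at every offset, no ambiguity codes, no > 6 nt homopolymer run.
random_nonprobe_insert <- function(len, probes) {
  repeat {
    s <- random_dna(len)
    if (length(find_approx_match(s, probes[[1]], 2L)) == 0L &&
        length(find_approx_match(s, probes[[2]], 2L)) == 0L)
      return(seq_to_chars(s))
  }
}

plant_homopolymer <- function(ins, panel, primer_len) {
  # place a 7-nt run outside the planted probe windows
  m <- attr(panel, "motif_at")
  forbid <- integer(0)
  if (!is.null(m)) {
    ps <- attr(panel, "probeset")$probes
    forbid <- c(seq(m$probe1 - primer_len - 7L, m$probe1 - primer_len + nchar(ps[[1]])),
                seq(m$probe2 - primer_len - 7L, m$probe2 - primer_len + nchar(ps[[2]])))
  }
  ok <- setdiff(seq_len(length(ins) - 7L), forbid)
  at <- sample(ok, 1L)
  b <- sample(DNA_BASES, 1L)
  ins[at:(at + 6L)] <- b
  ins
}

corrupt_barcode <- function(bc, all_barcodes) {
  chars <- seq_to_chars(bc)
  repeat {
    i <- sample(length(chars), 1L)
    b <- sample(setdiff(DNA_BASES, chars[i]), 1L)
    out <- chars; out[i] <- b
    out <- chars_to_seq(out)
    if (!(out %in% all_barcodes)) return(out)
  }
}

simulate_quality <- function(len, q, lowq, head_len) {
  base <- round(seq(q$q_start, q$q_end, length.out = len))
  if (q$noise > 0)
    base <- base + sample.int(2L * q$noise + 1L, len, replace = TRUE) - q$noise - 1L
  base <- pmin(pmax(base, 2L), 40L)
  if (lowq) {
    start <- sample(seq(head_len + 1L, len - 50L), 1L)
    base[start:(start + 49L)] <- 10L
  }
  phred_encode(list(base))
}

#' @export
print.amplicon_sim <- function(x, ...) {
  cat(sprintf("Synthetic amplicon library: %d reads, %d samples\n",
              nrow(x$reads), nrow(x$mapping)))
  tab <- table(factor(x$truth$violation,
                      levels = c("", "NO_PROBE", "SHORT", "AMBIG", "HOMOPOLYMER",
                                 "LOWQ", "BAD_BARCODE", "REVCOMP")))
  names(tab)[1] <- "clean"
  print(tab)
  invisible(x)
}

#' Write a simulated library to disk as a reusable fixture
#'
#' Emits the multiplexed FASTQ, the barcode mapping TSV and the per-read
#' ground-truth TSV; the files round-trip losslessly through [read_fixture()].
#'
#' @param sim an [simulate_reads()] result.
#' @param out_dir output directory (created if missing).
#' @return Named character vector of the written paths.
#' @export
write_fixture <- function(sim, out_dir) {
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", out_dir)
  paths <- c(fastq = file.path(out_dir, "reads.fastq"),
             mapping = file.path(out_dir, "mapping.tsv"),
             truth = file.path(out_dir, "ground_truth.tsv"))
  write_fastq(sim$reads, paths[["fastq"]])
  write_mapping(sim$mapping, paths[["mapping"]])
  tr <- sim$truth
  tr$template_id[is.na(tr$template_id)] <- "NONE"
  write_tsv(tr, paths[["truth"]])
  paths
}

#' @rdname write_fixture
#' @param dir directory previously written by `write_fixture()`.
#' @return `read_fixture()`: list with `reads`, `mapping`, `truth`.
#' @export
read_fixture <- function(dir) {
  truth <- read_tsv(file.path(dir, "ground_truth.tsv"))
  if (nrow(truth)) {
    truth$template_id[truth$template_id == "NONE"] <- NA_character_
    truth$violation[is.na(truth$violation)] <- ""
  }
  list(reads = read_fastq(file.path(dir, "reads.fastq")),
       mapping = read_mapping(file.path(dir, "mapping.tsv")),
       truth = truth)
}

#' Community compositions for habitat archetypes
#'
#' Builds a per-sample mixture matrix over the panel in which samples sharing
#' an archetype (e.g. mat-like, interface-like, sediment-like) draw from the
#' same dominant kingdom subset with mild per-sample log-normal jitter, while
#' different archetypes emphasize disjoint kingdom subsets.  This emulates the
#' strong habitat partitioning seen across brine-pool sampling sites.
#'
#' @param panel a `reference_panel`.
#' @param groups named character vector: sample_id -> archetype label.
#' @param seed integer seed.
#' @param dominance weight multiplier for an archetype's own kingdoms.
#' @return A samples x panel-entries composition matrix (rows sum to 1) whose
#'   rownames are the sample ids.
#' @export
community_archetypes <- function(panel, groups, seed = 1, dominance = 50) {
  kingdoms <- unique(panel$kingdom)
  archs <- unique(unname(groups))
  if (length(kingdoms) < length(archs))
    stop("need at least one kingdom per archetype")
  assign_k <- split(kingdoms, rep_len(seq_along(archs), length(kingdoms)))
  names(assign_k) <- archs
  with_seed(seed, {
    base <- lapply(archs, function(a) {
      w <- rlnorm(nrow(panel), 0, 1)
      w[panel$kingdom %in% assign_k[[a]]] <-
        w[panel$kingdom %in% assign_k[[a]]] * dominance
      w / sum(w)
    })
    names(base) <- archs
    comp <- t(vapply(names(groups), function(sid) {
      w <- base[[groups[[sid]]]] * rlnorm(nrow(panel), 0, 0.2)
      w / sum(w)
    }, numeric(nrow(panel))))
    rownames(comp) <- names(groups)
    comp
  })
}
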