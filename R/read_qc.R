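#' Quality-control parameters for 454 amplicon reads
#'
#' Defaults follow the classic pyrosequencing filter set: reject reads with a
#' mean quality below 25, any 50-bp window of mean quality below 25, one or
#' more ambiguous bases, fewer than 150 bp, a homopolymer run longer than
#' 6 bp, or an incomplete barcode.  Barcode and primer matching are exact;
#' the 2-mismatch tolerance applies only to the internal probes.
#'
#' @param min_mean_quality Phred threshold for the mean-quality and
#'   windowed-quality rules.
#' @param quality_window sliding window length in nt.
#' @param max_ambiguous maximum number of ambiguous bases tolerated.
#' @param min_length minimum read length in nt.
#' @param max_homopolymer maximum tolerated single-base run length.
#' @param barcode_mismatches mismatches allowed when demultiplexing.
#' @param probe_max_mismatches mismatches allowed when locating a probe.
#' @param window_truncate truncate reads at the first failing quality window
#'   instead of rejecting them (default `FALSE`; rejection keeps the
#'   qualified set an exact function of the thresholds).
#' @param trim_reverse trim the read at the reverse-primer site when the
#'   (reverse-complemented) reverse primer is found in the insert (default
#'   `FALSE`; V1-V3 reads rarely run through it).
#' @return A `qc_params` object.
#' @export
qc_params <- function(min_mean_quality = 25, quality_window = 50,
                      max_ambiguous = 0, min_length = 150,
                      max_homopolymer = 6, barcode_mismatches = 0,
                      probe_max_mismatches = 2, window_truncate = FALSE,
                      trim_reverse = FALSE) {
  p <- list(min_mean_quality = min_mean_quality,
            quality_window = as.integer(quality_window),
            max_ambiguous = as.integer(max_ambiguous),
            min_length = as.integer(min_length),
            max_homopolymer = as.integer(max_homopolymer),
            barcode_mismatches = as.integer(barcode_mismatches),
            probe_max_mismatches = as.integer(probe_max_mismatches),
            window_truncate = isTRUE(window_truncate),
            trim_reverse = isTRUE(trim_reverse))
  if (any(unlist(p[1:7]) < 0)) stop("all thresholds must be non-negative")
  if (p$min_length <= 0) stop("min_length must be positive")
  structure(p, class = "qc_params")
}

#' Find approximate occurrences of a pattern by Hamming distance
#'
#' Scans every window of `sequence` of the pattern's length and reports the
#' 1-based start positions whose Hamming distance to `pattern` is at most
#' `max_mismatches`.  No indels are considered; an ambiguous base (`N`) in
#' the sequence counts as a mismatch.
#'
#' @param sequence subject DNA string.
#' @param pattern query DNA string (no longer than the subject for any hit).
#' @param max_mismatches tolerated mismatch count.
#' @return Integer vector of 1-based start offsets (empty when the pattern is
#'   longer than the sequence).
#' @examples
#' find_approx_match("AAATCCGGAGAGGGAGCCTT", "TCCGGAGAGGGAGCC", 0)
#' @export
find_approx_match <- function(sequence, pattern, max_mismatches = 0) {
  n <- nchar(sequence); m <- nchar(pattern)
  if (m == 0L) stop("pattern must be nonempty")
  if (m > n) return(integer(0))
  s <- utf8ToInt(sequence)
  p <- utf8ToInt(pattern)
  k <- n - m + 1L
  mism <- integer(k)
  for (j in seq_len(m)) {
    mism <- mism + (s[j:(j + k - 1L)] != p[j])
  }
  which(mism <= max_mismatches)
}

#' Demultiplex reads by barcode prefix
#'
#' Assigns each read to the unique sample whose barcode matches the read's
#' prefix within `barcode_mismatches` mismatches, then trims the barcode
#' (and its quality values).  Reads matching no barcode, or more than one at
#' the minimal distance, go to the unassigned set.  The resulting partition
#' is exhaustive and disjoint.
#'
#' @param reads data frame with `read_id`, `sequence`, `quality`.
#' @param mapping data frame with `sample_id`, `barcode` (unique, equal
#'   length).
#' @param barcode_mismatches allowed mismatches (default 0: the barcode must
#'   be complete and exact).
#' @return List with `samples` (named list of trimmed read data frames, one
#'   per sample, possibly empty) and `unassigned`.
#' @export
demultiplex <- function(reads, mapping, barcode_mismatches = 0) {
  validate_mapping(mapping)
  bl <- nchar(mapping$barcode[1])
  nb <- nrow(mapping)
  nr <- nrow(reads)
  if (nr == 0L) {
    samples <- lapply(seq_len(nb), function(b) reads)
    names(samples) <- mapping$sample_id
    return(list(samples = samples, unassigned = reads))
  }
  # pad so reads shorter than the barcode compare as all-mismatch
  prefix <- substr(paste0(reads$sequence, strrep("?", bl)), 1L, bl)
  dist <- matrix(0L, nr, nb)
  for (b in seq_len(nb)) {
    bc <- utf8ToInt(mapping$barcode[b])
    d <- integer(nr)
    for (j in seq_len(bl)) {
      cj <- utf8ToInt(paste(substr(prefix, j, j), collapse = ""))
      d <- d + (cj != bc[j])
    }
    dist[, b] <- d
  }
  best <- apply(dist, 1L, min)
  nbest <- rowSums(dist == best)
  assigned <- best <= barcode_mismatches & nbest == 1L
  which_bc <- max.col(-dist, ties.method = "first")

  trim <- function(df) {
    df$sequence <- substr(df$sequence, bl + 1L, nchar(df$sequence))
    df$quality <- substr(df$quality, bl + 1L, nchar(df$quality))
    df
  }
  samples <- lapply(seq_len(nb), function(b) {
    trim(reads[assigned & which_bc == b, , drop = FALSE])
  })
  names(samples) <- mapping$sample_id
  list(samples = samples,
       unassigned = reads[!assigned, , drop = FALSE])
}

#' Apply the read-level quality filters
#'
#' Tests the rules in a fixed order and reports the first failure, so every
#' read has exactly one rejection reason: mean quality (`LOWQ_MEAN`), sliding
#' window quality (`LOWQ_WINDOW`), ambiguous bases (`AMBIG`), minimum length
#' (`SHORT`), homopolymer runs (`HOMOPOLYMER`).  An empty sequence fails as
#' `SHORT`.  The window rule is skipped for reads shorter than the window.
#'
#' @param sequence read sequence (barcode already trimmed or not; the rules
#'   are position-agnostic).
#' @param quality Phred+33 quality string of equal length.
#' @param params a [qc_params()].
#' @return `"PASS"` or the failure reason.
#' @export
quality_filter <- function(sequence, quality, params = qc_params()) {
  if (nchar(sequence) == 0L) return("SHORT")
  q <- phred_decode1(quality)
  if (length(q) != nchar(sequence))
    stop("quality string length must equal sequence length")
  if (mean(q) < params$min_mean_quality) return("LOWQ_MEAN")
  w <- params$quality_window
  if (length(q) >= w) {
    cs <- cumsum(c(0, q))
    wmeans <- (cs[(w + 1L):length(cs)] - cs[1:(length(cs) - w)]) / w
    if (any(wmeans < params$min_mean_quality)) return("LOWQ_WINDOW")
  }
  n_amb <- nchar(sequence) - nchar(gsub("[^ACGT]", "", sequence))
  if (n_amb > params$max_ambiguous) return("AMBIG")
  if (nchar(sequence) < params$min_length) return("SHORT")
  if (max_homopolymer_run(sequence) > params$max_homopolymer) return("HOMOPOLYMER")
  "PASS"
}

#' Screen a demultiplexed read for the primer and internal probes
#'
#' A genuine 18S amplicon read must begin with the complete forward primer
#' (exact match) and carry at least one of the internal probes downstream of
#' it within `probe_max_mismatches` mismatches; otherwise it is flagged as a
#' false-positive (non-rRNA) amplicon.
#'
#' @param sequence read sequence with the barcode already trimmed.
#' @param probeset a [probe_set()].
#' @param params a [qc_params()].
#' @return List with `status` (`"KEEP"` or `"DROP"`), `reason` (`NA`,
#'   `"NO_PRIMER"` or `"NO_PROBE"`), and `insert` (the primer-trimmed
#'   retained sequence, `NA` when dropped).
#' @export
probe_screen <- function(sequence, probeset = probe_set(),
                         params = qc_params()) {
  primer <- probeset$forward_primer
  if (!startsWith(sequence, primer))
    return(list(status = "DROP", reason = "NO_PRIMER", insert = NA_character_))
  insert <- substr(sequence, nchar(primer) + 1L, nchar(sequence))
  for (p in probeset$probes) {
    if (length(find_approx_match(insert, p, params$probe_max_mismatches))) {
      if (params$trim_reverse) {
        hit <- find_approx_match(insert, revcomp(probeset$reverse_primer),
                                 params$probe_max_mismatches)
        if (length(hit)) insert <- substr(insert, 1L, hit[1] - 1L)
      }
      return(list(status = "KEEP", reason = NA_character_, insert = insert))
    }
  }
  list(status = "DROP", reason = "NO_PROBE", insert = NA_character_)
}

QC_REASONS <- c("BARCODE", "LOWQ_MEAN", "LOWQ_WINDOW", "AMBIG", "SHORT",
                "HOMOPOLYMER", "NO_PRIMER", "NO_PROBE")

#' Truncate a read before its first low-quality window
#'
#' Alternative to rejecting on the windowed-quality rule: the read is cut
#' just before the first sliding window whose mean quality falls below the
#' threshold.  The truncated read then continues through the remaining
#' filters (and may still fail the length rule).
#'
#' @param sequence,quality read and Phred+33 quality string.
#' @param params a [qc_params()].
#' @return List with truncated `sequence` and `quality`.
#' @export
truncate_low_quality <- function(sequence, quality, params = qc_params()) {
  q <- phred_decode1(quality)
  w <- params$quality_window
  if (length(q) >= w) {
    cs <- cumsum(c(0, q))
    wmeans <- (cs[(w + 1L):length(cs)] - cs[1:(length(cs) - w)]) / w
    bad <- which(wmeans < params$min_mean_quality)
    if (length(bad)) {
      cut <- bad[1] - 1L
      sequence <- substr(sequence, 1L, cut)
      quality <- substr(quality, 1L, cut)
    }
  }
  list(sequence = sequence, quality = quality)
}

#' Run the full QC stage on a multiplexed read set
#'
#' Demultiplexes, applies the quality filters and the primer/probe screen,
#' and returns per-sample qualified inserts together with a per-reason
#' rejection report.  Each read is counted exactly once: either as qualified
#' or under the first rule it fails, so for every sample
#' `input = qualified + sum(rejected)`.
#'
#' @param reads data frame with `read_id`, `sequence`, `quality`.
#' @param mapping barcode mapping data frame.
#' @param params a [qc_params()].
#' @param probeset a [probe_set()].
#' @return A `qc_result` list: `qualified` (named list of data frames with
#'   `read_id`, `sequence` — primer-trimmed inserts per sample), `report`
#'   (data frame sample x reason counts, with an `(unassigned)` row holding
#'   barcode failures), and `rejected_ids` (named by reason).
#' @export
run_qc <- function(reads, mapping, params = qc_params(),
                   probeset = probe_set()) {
  dm <- demultiplex(reads, mapping, params$barcode_mismatches)
  reasons <- QC_REASONS
  report <- data.frame(sample_id = c(mapping$sample_id, "(unassigned)"),
                       input = 0L, stringsAsFactors = FALSE)
  for (r in reasons) report[[r]] <- 0L
  report$qualified <- 0L
  rownames(report) <- report$sample_id
  report["(unassigned)", "input"] <- nrow(dm$unassigned)
  report["(unassigned)", "BARCODE"] <- nrow(dm$unassigned)
  rejected_ids <- list(BARCODE = dm$unassigned$read_id)

  qualified <- list()
  for (sid in mapping$sample_id) {
    df <- dm$samples[[sid]]
    n <- nrow(df)
    report[sid, "input"] <- n
    keep_id <- character(0); keep_seq <- character(0)
    if (n) {
      for (i in seq_len(n)) {
        if (params$window_truncate) {
          tq <- truncate_low_quality(df$sequence[i], df$quality[i], params)
          df$sequence[i] <- tq$sequence
          df$quality[i] <- tq$quality
        }
        res <- quality_filter(df$sequence[i], df$quality[i], params)
        if (res == "PASS") {
          ps <- probe_screen(df$sequence[i], probeset, params)
          if (ps$status == "KEEP") {
            keep_id <- c(keep_id, df$read_id[i])
            keep_seq <- c(keep_seq, ps$insert)
          } else {
            report[sid, ps$reason] <- report[sid, ps$reason] + 1L
            rejected_ids[[ps$reason]] <- c(rejected_ids[[ps$reason]], df$read_id[i])
          }
        } else {
          report[sid, res] <- report[sid, res] + 1L
          rejected_ids[[res]] <- c(rejected_ids[[res]], df$read_id[i])
        }
      }
    }
    report[sid, "qualified"] <- length(keep_id)
    qualified[[sid]] <- data.frame(read_id = keep_id, sequence = keep_seq,
                                   stringsAsFactors = FALSE)
  }
  rownames(report) <- NULL
  structure(list(qualified = qualified, report = report,
                 rejected_ids = rejected_ids, params = params),
            class = "qc_result")
}

#' @export
print.qc_result <- function(x, ...) {
  cat("Amplicon QC result\n")
  print(x$report, row.names = FALSE)
  invisible(x)
}

#' Write the QC stage outputs
#'
#' Emits one FASTA of qualified inserts per sample plus `qc_report.tsv`.
#'
#' @param qc a [run_qc()] result.
#' @param out_dir output directory.
#' @return Named vector of written paths.
#' @export
write_qc <- function(qc, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  paths <- c(report = file.path(out_dir, "qc_report.tsv"))
  write_tsv(qc$report, paths[["report"]])
  for (sid in names(qc$qualified)) {
    p <- file.path(out_dir, paste0("qualified_", sid, ".fasta"))
    df <- qc$qualified[[sid]]
    write_fasta(data.frame(id = df$read_id, sequence = df$sequence),
                p)
    paths[[paste0("fasta_", sid)]] <- p
  }
  paths
}
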