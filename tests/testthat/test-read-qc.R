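test_that("demultiplexing assigns barcoded reads to the right samples", {
  mapping <- default_mapping()
  mk <- function(seqs) data.frame(read_id = paste0("r", seq_along(seqs)),
                                  sequence = seqs,
                                  quality = strrep("I", nchar(seqs)),
                                  stringsAsFactors = FALSE)
  reads <- mk(c(paste0("ATGCAGTC", strrep("ACGT", 10)),    # NDW barcode
                paste0("NNNNNNNN", strrep("ACGT", 10))))
  dm <- demultiplex(reads, mapping)
  expect_equal(dm$samples$NDW$read_id, "r1")
  expect_equal(substr(dm$samples$NDW$sequence, 1, 4), "ACGT")  # barcode trimmed
  expect_equal(dm$unassigned$read_id, "r2")
  expect_error(demultiplex(reads, rbind(mapping, mapping[1, ])), "duplicate")
})

test_that("demultiplexing equals brute-force prefix comparison on random reads", {
  mapping <- default_mapping()
  set.seed(31)
  n <- 1000
  bc <- sample(c(mapping$barcode, vapply(1:5, function(i) rand_dna(8), "")),
               n, replace = TRUE)
  reads <- data.frame(read_id = sprintf("r%04d", 1:n),
                      sequence = paste0(bc, vapply(1:n, function(i) rand_dna(30), "")),
                      quality = strrep("I", 38), stringsAsFactors = FALSE)
  dm <- demultiplex(reads, mapping)
  # oracle: exact prefix match
  for (s in seq_len(nrow(mapping))) {
    expected <- reads$read_id[startsWith(reads$sequence, mapping$barcode[s])]
    expect_setequal(dm$samples[[mapping$sample_id[s]]]$read_id, expected)
  }
  total <- sum(vapply(dm$samples, nrow, 1L)) + nrow(dm$unassigned)
  expect_equal(total, n)
})

test_that("quality filters fire in order with one reason per read", {
  q30 <- function(n) strrep(phred_chr(30), n)
  expect_equal(quality_filter(strrep("ACGT", 50), q30(200)), "PASS")
  expect_equal(quality_filter(strrep("ACGT", 37) %+% "A", strrep(phred_chr(40), 149)),
               "SHORT")
  seq7 <- paste0(strrep("ACGT", 40), "AAAAAAA", strrep("CGT", 10))
  expect_equal(quality_filter(seq7, q30(nchar(seq7))), "HOMOPOLYMER")
  seq6 <- paste0(strrep("ACGT", 40), "AAAAAA", strrep("CGT", 10))
  expect_equal(quality_filter(seq6, q30(nchar(seq6))), "PASS")
  # mean-quality rule precedes everything else
  expect_equal(quality_filter(strrep("ACGT", 50), strrep(phred_chr(20), 200)),
               "LOWQ_MEAN")
  # a single low window in an otherwise good read
  q <- c(rep(35, 100), rep(10, 50), rep(35, 50))
  expect_equal(quality_filter(strrep("ACGT", 50), paste(vapply(q, phred_chr, ""), collapse = "")),
               "LOWQ_WINDOW")
  expect_equal(quality_filter(paste0(strrep("ACGT", 40), "N"), q30(161)), "AMBIG")
  expect_equal(quality_filter("", ""), "SHORT")
})

test_that("per-reason QC counts equal the generator's ground truth", {
  sim <- violation_sim(n_reads = 50, seed = 19)
  qc <- run_qc(sim$reads, sim$mapping)
  rep <- qc$report
  truth_counts <- table(sim$truth$violation)
  expect_equal(sum(rep$BARCODE), unname(truth_counts[["BAD_BARCODE"]]))
  expect_equal(sum(rep$LOWQ_MEAN) + sum(rep$LOWQ_WINDOW),
               unname(truth_counts[["LOWQ"]]))
  expect_equal(sum(rep$AMBIG), unname(truth_counts[["AMBIG"]]))
  expect_equal(sum(rep$SHORT), unname(truth_counts[["SHORT"]]))
  expect_equal(sum(rep$HOMOPOLYMER), unname(truth_counts[["HOMOPOLYMER"]]))
  expect_equal(sum(rep$NO_PROBE), unname(truth_counts[["NO_PROBE"]]))
  expect_equal(sum(rep$NO_PRIMER), 0)
  expect_equal(sum(rep$qualified), unname(truth_counts[names(truth_counts) == ""]))
  # conservation: every read counted exactly once
  reasons <- c("BARCODE", "LOWQ_MEAN", "LOWQ_WINDOW", "AMBIG", "SHORT",
               "HOMOPOLYMER", "NO_PRIMER", "NO_PROBE")
  expect_equal(rep$input, rep$qualified + rowSums(rep[, reasons]))
})

test_that("probe detection has perfect precision and recall on ground truth", {
  sim <- violation_sim(n_reads = 50, seed = 23)
  qc <- run_qc(sim$reads, sim$mapping)
  flagged <- sort(qc$rejected_ids$NO_PROBE)
  truth <- sort(sim$truth$read_id[sim$truth$violation == "NO_PROBE"])
  expect_identical(flagged, truth)     # precision = recall = 1
})

test_that("approximate matching equals the exhaustive Hamming scan", {
  probe <- probe_set()$probes[["Euk381"]]
  x <- paste0("AACGT", probe, "GGTTA")
  expect_equal(find_approx_match(x, probe, 0), 6)

  # exactly-2 vs exactly-3 substitutions at a known offset
  set.seed(41)
  host <- rand_dna(100)
  pat <- rand_dna(15)
  plant <- function(p, k) {
    ch <- strsplit(p, "")[[1]]
    pos <- sample(15, k)
    for (i in pos) ch[i] <- sample(setdiff(BASES, ch[i]), 1)
    paste(ch, collapse = "")
  }
  x2 <- paste0(substr(host, 1, 37), plant(pat, 2), substr(host, 53, 100))
  x3 <- paste0(substr(host, 1, 37), plant(pat, 3), substr(host, 53, 100))
  expect_true(38 %in% find_approx_match(x2, pat, 2))
  expect_false(38 %in% find_approx_match(x3, pat, 2))

  # randomized equivalence with the brute-force oracle
  set.seed(47)
  for (i in 1:200) {
    s <- rand_dna(sample(20:120, 1))
    p <- rand_dna(sample(5:15, 1))
    mm <- sample(0:3, 1)
    expect_identical(find_approx_match(s, p, mm), bf_find_match(s, p, mm))
  }
  expect_identical(find_approx_match("ACGT", "ACGTACGT", 2), integer(0))
})

test_that("probe screen keeps true reads and drops primer/probe failures", {
  p <- small_panel()
  tmpl <- p$sequence[1]
  res <- probe_screen(tmpl)
  expect_equal(res$status, "KEEP")
  expect_equal(res$insert, substr(tmpl, 21, nchar(tmpl)))

  broken <- paste0("T", substr(tmpl, 2, nchar(tmpl)))
  expect_equal(probe_screen(broken)$reason, "NO_PRIMER")

  set.seed(53)
  ps <- probe_set()
  repeat {
    junk <- rand_dna(200)
    if (length(bf_find_match(junk, ps$probes[[1]], 2)) == 0 &&
        length(bf_find_match(junk, ps$probes[[2]], 2)) == 0) break
  }
  fake <- paste0(ps$forward_primer, junk)
  expect_equal(probe_screen(fake)$reason, "NO_PROBE")
})

test_that("loosening thresholds is monotone in the expected direction", {
  sim <- violation_sim(n_reads = 30, seed = 29)
  qc2 <- run_qc(sim$reads, sim$mapping, qc_params(probe_max_mismatches = 2))
  qc4 <- run_qc(sim$reads, sim$mapping, qc_params(probe_max_mismatches = 4))
  expect_gte(sum(qc4$report$qualified), sum(qc2$report$qualified))

  qs <- run_qc(sim$reads, sim$mapping, qc_params(min_length = 100))
  ql <- run_qc(sim$reads, sim$mapping, qc_params(min_length = 200))
  expect_lte(sum(ql$report$qualified), sum(qs$report$qualified))
})

test_that("window truncation keeps the good head of a low-tail read", {
  good <- 200; bad <- 60
  seq <- strrep("ACGT", (good + bad) / 4)
  qual <- paste0(strrep(phred_chr(35), good), strrep(phred_chr(8), bad))
  params <- qc_params()
  expect_equal(quality_filter(seq, qual, params), "LOWQ_WINDOW")
  tq <- truncate_low_quality(seq, qual, params)
  expect_lt(nchar(tq$sequence), good + bad)
  expect_gte(nchar(tq$sequence), 150)
  expect_equal(quality_filter(tq$sequence, tq$quality, params), "PASS")
})

test_that("reverse-primer trimming cuts read-through inserts", {
  ps <- probe_set()
  insert <- paste0(strrep("AC", 30), ps$probes[[1]], strrep("GT", 30))
  readthrough <- paste0(ps$forward_primer, insert,
                        chartr("ACGT", "TGCA",
                               paste(rev(strsplit(ps$reverse_primer, "")[[1]]),
                                     collapse = "")),
                        "ACGTACGT")
  res <- probe_screen(readthrough, ps, qc_params(trim_reverse = TRUE))
  expect_equal(res$status, "KEEP")
  expect_equal(res$insert, insert)
  # flag off: nothing trimmed
  res2 <- probe_screen(readthrough, ps, qc_params())
  expect_gt(nchar(res2$insert), nchar(insert))
})

test_that("reverse-complement reads are emitted on request and go unassigned", {
  p <- small_panel()
  cfg <- sim_config(n_reads = 20, revcomp_fraction = 0.1, seed = 77)
  sim <- simulate_reads(p, cfg)
  rc <- sim$truth$read_id[sim$truth$violation == "REVCOMP"]
  expect_length(rc, 7 * 2)
  dm <- demultiplex(sim$reads, sim$mapping)
  expect_true(all(rc %in% dm$unassigned$read_id))
})
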