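# Shared synthetic fixtures, built once per test run.

# small 3-kingdom panel for quick generator/QC tests
small_panel <- function(seed = 1) {
  generate_reference_panel(n_kingdoms = 3, per_kingdom = 2, seq_length = 300,
                           inter_divergence = 0.30, intra_divergence = 0.03,
                           seed = seed)
}

# a library with every violation class planted at 10%
violation_sim <- function(n_reads = 50, seed = 7, panel = small_panel()) {
  cfg <- sim_config(n_reads = n_reads, seed = seed,
                    false_amplicon_fraction = 0.10,
                    short_read_fraction = 0.10,
                    ambiguous_base_fraction = 0.10,
                    homopolymer_fraction = 0.10,
                    lowq_fraction = 0.10,
                    bad_barcode_fraction = 0.10)
  simulate_reads(panel, cfg)
}

# queries derived from panel members at a given extra divergence, with truth
make_queries <- function(panel, n, divergence, seed) {
  set.seed(seed)
  qs <- character(n); truth <- character(n)
  for (i in seq_len(n)) {
    j <- sample(nrow(panel), 1)
    truth[i] <- panel$kingdom[j]
    qs[i] <- mutate_seq(panel$sequence[j], divergence)
  }
  names(qs) <- sprintf("Q%03d", seq_len(n))
  names(truth) <- names(qs)
  list(queries = qs, truth = truth)
}
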