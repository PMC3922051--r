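# One small end-to-end fixture shared by the pipeline tests.
pipeline_fixture <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    dir <- tempfile("pipe_fixture_")
    panel <- generate_reference_panel(4, 2, 350, 0.30, 0.04, seed = 301)
    groups <- c(Mat = "mat", NDW = "sediment", DBI = "interface",
                DS3 = "sediment", DS6 = "sediment", BS8 = "sediment",
                BS9 = "interface")
    comp <- community_archetypes(panel, groups, seed = 302)
    cfg <- sim_config(n_reads = 40, composition = comp, seed = 303,
                      false_amplicon_fraction = 0.05, lowq_fraction = 0.05)
    sim <- simulate_reads(panel, cfg)
    write_fixture(sim, dir)
    write_reference_fasta(panel, file.path(dir, "refs.fasta"))
    cache <<- list(dir = dir, sim = sim, groups = groups)
    cache
  }
})

run_once <- function(out, seed = 311) {
  fx <- pipeline_fixture()
  cfg <- run_config(fastq = file.path(fx$dir, "reads.fastq"),
                    mapping = file.path(fx$dir, "mapping.tsv"),
                    references = file.path(fx$dir, "refs.fasta"),
                    out_dir = out, bootstrap = 30, seed = seed)
  run_pipeline(cfg)
}

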