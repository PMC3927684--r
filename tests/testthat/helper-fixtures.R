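# Shared fixtures, built once per test run (in code, no stored data).

.fixture_env <- new.env(parent = emptyenv())

memo <- function(name, build) {
  if (!exists(name, envir = .fixture_env))
    assign(name, build(), envir = .fixture_env)
  get(name, envir = .fixture_env)
}

# the default stated-world fixture: 200 kb, seed 42
fix_small <- function() memo("small", function() {
  g <- build_genome(sim_config(seed = 42))
  list(genome = g, pset = partition_on_gaps(g$records))
})

# mu = 0, single 2 kb TE family inserted exactly 12 times (region fixture)
fix_te12 <- function() memo("te12", function() {
  cfg <- sim_config(genome_length = 200000, n_te_families = 1,
                    te_length_range = c(2000, 2000), te_copy_numbers = 12,
                    mu = 0, tandem_specs = list(), segdup_specs = list(),
                    n_gaps = 0, seed = 11)
  g <- build_genome(cfg)
  list(genome = g, pset = partition_on_gaps(g$records))
})

fix_te12_k1000 <- function() memo("te12_k1000", function() {
  count_kmers(fix_te12()$pset, 1000)
})

# many-family power-law fixture with a populated FD tail (mu = 0)
fix_fd <- function() memo("fd", function() {
  cfg <- sim_config(genome_length = 300000, n_te_families = 60,
                    te_length_range = c(100, 1000), copy_alpha = 2,
                    copy_max = 30, mu = 0, tandem_specs = list(),
                    segdup_specs = list(), n_gaps = 0, seed = 33)
  list(genome = build_genome(cfg),
       pset = partition_on_gaps(build_genome(cfg)$records))
})
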