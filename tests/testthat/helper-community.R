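# Shared fixtures, built in code.  Small communities are memoized so
# several test files can reuse them without re-simulating.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_env))
    assign(key, force(expr), envir = .fixture_env)
  get(key, envir = .fixture_env)
}

# compact 4-genome community (3 bacteria + host) for module-level tests
small_community <- function() {
  memo("small", {
    g <- list(
      genome_model("alpha", 0.30, 60000, 20, divergence = 0.1),
      genome_model("beta",  0.50, 60000,  4, divergence = 0.2),
      genome_model("gamma", 0.62, 60000, 60, divergence = 0.1,
                   shared = TRUE, coverage_mean_b = 50),
      genome_model("host",  0.41, 80000,  5, divergence = 0,
                   shared = TRUE, kingdom = "Eukaryota"))
    simulate_community(community_spec(g, seed = 101))
  })
}

# 5-genome community with many contigs per genome, for SOM hold-out tests
som_community <- function() {
  memo("som", {
    g <- list(
      genome_model("g1", 0.30, 400000, 10),
      genome_model("g2", 0.42, 400000, 10),
      genome_model("g3", 0.55, 400000, 10),
      genome_model("g4", 0.65, 400000, 10),
      genome_model("host", 0.48, 400000, 10, kingdom = "Eukaryota"))
    simulate_community(community_spec(g, seed = 7))
  })
}

default_pipeline_run <- function() {
  memo("default_run", {
    com <- simulate_community(default_community(1))
    list(community = com, pipeline = run_pipeline(com, seed = 1))
  })
}

# independent reverse complement for oracles (no Biostrings, no package code)
oracle_revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
}
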