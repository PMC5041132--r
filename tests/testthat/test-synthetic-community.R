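# Generator contracts: GC targeting, determinism, fragmentation accounting,
# annotation planting and read simulation.

test_that("simulated genomes hit their GC target and are deterministic", {
  m0 <- genome_model("flat", 0.5, 10000, 10, markov_order = 0L)
  s0 <- simulate_genome(m0, 11)
  gc0 <- sum(strsplit(s0, "")[[1]] %in% c("G", "C")) / nchar(s0)
  expect_gte(gc0, 0.48)
  expect_lte(gc0, 0.52)

  m <- genome_model("lowgc", 0.209, 50000, 10)
  s <- simulate_genome(m, 42)
  expect_equal(nchar(s), 50000)
  gc <- sum(strsplit(s, "")[[1]] %in% c("G", "C")) / nchar(s)
  expect_lt(abs(gc - 0.209), 0.02)

  expect_identical(simulate_genome(m, 42), s)
  expect_false(identical(simulate_genome(m, 43), s))
})

test_that("GC recovery holds for every genome of a community at >=50 kb", {
  targets <- c(0.25, 0.4, 0.55, 0.7)
  for (i in seq_along(targets)) {
    m <- genome_model(paste0("g", i), targets[i], 50000, 5)
    s <- simulate_genome(m, 100 + i)
    gc <- sum(strsplit(s, "")[[1]] %in% c("G", "C")) / nchar(s)
    expect_lt(abs(gc - targets[i]), 0.02)
  }
})

test_that("markov_order above 5 is rejected", {
  expect_error(genome_model("x", 0.5, 20000, 5, markov_order = 6L),
               "markov_order")
})

test_that("fragmentation conserves length and respects sharing", {
  com <- small_community()
  tr <- com$truth
  # total contig length per genome close to genome length (edge loss < 1 kb)
  for (g in unique(tr$genome_id)) {
    glen <- com$spec$genomes[[which(vapply(com$spec$genomes, `[[`, "",
                                           "genome_id") == g)]]$genome_length
    expect_lte(glen - sum(tr$length[tr$genome_id == g]), 1000)
  }
  # unique genomes have zero sample-B coverage, shared have positive depth
  covb <- com$coverage_b
  uniq_ids <- tr$contig_id[tr$sample == "A"]
  shared_ids <- tr$contig_id[tr$sample == "both"]
  expect_true(all(covb$depth[covb$contig_id %in% uniq_ids] == 0))
  expect_true(all(covb$depth[covb$contig_id %in% shared_ids] > 0))
  # contigs reconstruct the genome sequence
  i <- which(tr$genome_id == "alpha")[1]
  expect_identical(as.character(com$contigs[[tr$contig_id[i]]]),
                   substr(com$genomes[["alpha"]], tr$start[i], tr$end[i]))
})

test_that("equal-length genomes yield comparable contig counts", {
  g <- list(genome_model("a", 0.35, 80000, 5),
            genome_model("b", 0.55, 80000, 5),
            genome_model("host", 0.45, 80000, 5, kingdom = "Eukaryota"))
  fc <- fragment_and_cover(community_spec(g, seed = 5))
  counts <- table(fc$truth$genome_id)
  expect_lt(max(counts) / min(counts), 2.5)
})

test_that("community generation is deterministic and truth-closed", {
  g <- list(genome_model("a", 0.35, 30000, 5),
            genome_model("host", 0.45, 30000, 5, kingdom = "Eukaryota"))
  c1 <- simulate_community(community_spec(g, seed = 31))
  c2 <- simulate_community(community_spec(g, seed = 31))
  expect_identical(as.character(c1$contigs), as.character(c2$contigs))
  expect_identical(c1$hits, c2$hits)
  expect_identical(c1$expression, c2$expression)
  # truth closure: every emitted record maps into the truth tables
  expect_setequal(names(c1$contigs), c1$truth$contig_id)
  expect_setequal(c1$orfs$orf_id, c1$truth_orfs$orf_id)
  expect_true(all(c1$hits$orf_id %in% c1$truth_orfs$orf_id))
  expect_true(all(c1$markers$orf_id %in% c1$truth_orfs$orf_id))
  expect_true(all(c1$expression$gene_id %in% c1$truth_orfs$orf_id))
  expect_false(anyDuplicated(c1$truth$contig_id) > 0)
  expect_false(anyDuplicated(c1$truth_orfs$orf_id) > 0)
})

test_that("divergence controls the fraction of ORFs with hits", {
  g <- list(genome_model("dark", 0.30, 150000, 5, divergence = 0.8),
            genome_model("lit", 0.55, 150000, 5, divergence = 0),
            genome_model("host", 0.45, 30000, 5, kingdom = "Eukaryota"))
  com <- simulate_community(community_spec(g, seed = 13))
  to <- com$truth_orfs
  frac_dark <- mean(to$has_hit[to$genome_id == "dark"])
  expect_lt(abs(frac_dark - 0.2), 0.06)
  expect_true(all(to$has_hit[to$genome_id == "lit"]))
  # every hit of the fully classifiable genome points at its true genus
  lit_taxon <- to$taxon[to$genome_id == "lit"][1]
  best <- com$hits[com$hits$orf_id %in% to$orf_id[to$genome_id == "lit"], ]
  best <- best[order(best$orf_id, -best$bitscore), ]
  best <- best[!duplicated(best$orf_id), ]
  expect_true(all(best$taxid == lit_taxon))
})

test_that("marker planting is one per genome with injectable duplications", {
  g <- list(genome_model("a", 0.35, 60000, 5),
            genome_model("host", 0.45, 30000, 5, kingdom = "Eukaryota"))
  com <- simulate_community(community_spec(g, seed = 17),
                            duplicate_markers = list(a = c("SCM05")))
  tab <- table(com$markers$marker_id)
  expect_equal(unname(tab[["SCM05"]]), 2L)
  expect_true(all(tab[names(tab) != "SCM05"] == 1L))
  # host gets no markers
  horfs <- com$truth_orfs$orf_id[com$truth_orfs$genome_id == "host"]
  expect_false(any(com$markers$orf_id %in% horfs))
})

test_that("read simulation tiles at the requested depth", {
  m <- genome_model("g", 0.45, 20000, 10)
  s <- simulate_genome(m, 3)
  rd <- simulate_reads(s, 30, read_length = 100, insert_size = 2000,
                       seed = 3)
  expect_equal(length(rd$r1) + length(rd$r2), 6000)
  expect_true(all(Biostrings::width(rd$r1) == 100))
  expect_true(grepl("/1$", names(rd$r1)[1]))
  # mates are revcomp substrings of the genome
  expect_true(grepl(as.character(rd$r1[[1]]), s, fixed = TRUE))
  rc2 <- as.character(Biostrings::reverseComplement(rd$r2[[1]]))
  expect_true(grepl(rc2, s, fixed = TRUE))
  # zero coverage -> empty
  empty <- simulate_reads(s, 0, seed = 3)
  expect_length(empty$r1, 0)
  expect_error(simulate_reads(s, 10, read_length = 30000), "read_length")
})

test_that("circular read simulation spans the origin", {
  m <- genome_model("g", 0.45, 20000, 10)
  s <- simulate_genome(m, 3)
  rd <- simulate_reads(s, 30, read_length = 100, insert_size = 2000,
                       seed = 3, circular = TRUE)
  # some forward mates must not be substrings of the linear genome
  r1 <- as.character(rd$r1)
  inside <- vapply(r1[1:500], function(x) grepl(x, s, fixed = TRUE),
                   logical(1))
  expect_true(any(!inside))
  # but all are substrings of the doubled genome
  dbl <- paste0(s, s)
  expect_true(all(vapply(r1[1:500][!inside],
                         function(x) grepl(x, dbl, fixed = TRUE),
                         logical(1))))
})
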