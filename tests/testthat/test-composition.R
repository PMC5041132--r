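# Tetranucleotide vectors and SOM-based contig assignment.

test_that("canonical folding yields 136 classes (enumeration oracle)", {
  # oracle: enumerate all 256 tetramers independently and fold
  bases <- c("A", "C", "G", "T")
  all4 <- apply(expand.grid(bases, bases, bases, bases), 1, paste,
                collapse = "")
  folded <- unique(pmin(all4, vapply(all4, oracle_revcomp, "")))
  expect_length(folded, 136)
  expect_setequal(canonical_tetramers(), folded)
})

test_that("tnf is strand-invariant, normalized and length-gated", {
  set.seed(6)
  seqs <- vapply(1:5, function(i)
    paste(sample(c("A", "C", "G", "T"), 4000, replace = TRUE,
                 prob = c(0.3, 0.2, 0.2, 0.3)), collapse = ""), "")
  x <- tnf(Biostrings::DNAStringSet(setNames(seqs, paste0("s", 1:5))))
  expect_equal(dim(x), c(5L, 136L))
  expect_equal(unname(rowSums(x)), rep(1, 5))
  # exact strand invariance
  rc <- vapply(seqs, oracle_revcomp, "")
  xrc <- tnf(Biostrings::DNAStringSet(setNames(rc, paste0("s", 1:5))))
  expect_equal(unname(x), unname(xrc))
  # homopolymer puts all mass on canonical AAAA
  xa <- tnf(strrep("A", 5000))
  expect_equal(unname(xa[1, "AAAA"]), 1)
  # ambiguous windows are skipped, not counted
  xn <- tnf(paste0(strrep("A", 3000), "N", strrep("A", 3000)))
  expect_equal(unname(xn[1, "AAAA"]), 1)
  expect_error(tnf("ACGT"), "min_length")
})

test_that("SOM training is deterministic with decreasing quantization error", {
  com <- small_community()
  x <- tnf(com$contigs)
  cb <- train_som(x, epochs = 30, seed = 4)
  expect_true(all(diff(cb$qe) <= 1e-12))
  expect_lt(cb$qe[30], cb$qe[1])
  cb2 <- train_som(x, epochs = 30, seed = 4)
  expect_identical(cb$prototypes, cb2$prototypes)
  # degenerate input: all prototypes converge to the repeated vector
  xx <- x[rep(1, 12), , drop = FALSE]
  rownames(xx) <- sprintf("r%02d", 1:12)
  cbx <- train_som(xx, grid = c(2, 2), epochs = 20, seed = 1)
  expect_lt(max(abs(sweep(cbx$prototypes, 2, x[1, ]))), 1e-6)
  expect_error(train_som(x[1:5, ]), "at least 10")
  expect_error(train_som(x[1:10, ], grid = c(20, 20)), "10x")
})

test_that("a query identical to a labeled contig inherits its cluster", {
  com <- small_community()
  x <- tnf(com$contigs)
  tr <- com$truth
  gen <- tr$genome_id[match(rownames(x), tr$contig_id)]
  cb <- train_som(x, epochs = 30, seed = 4)
  # pick the labeled contig sitting closest to its best-matching prototype,
  # which is guaranteed inside any percentile acceptance radius
  d <- label_and_assign(cb, x, gen, x)$distance
  i <- which.min(d)
  asn <- label_and_assign(cb, x, gen, x[i, , drop = FALSE])
  expect_identical(asn$cluster, gen[i])
})

test_that("held-out contigs assign accurately; novel genomes stay out", {
  com <- som_community()
  x <- tnf(com$contigs)
  tr <- com$truth
  gen <- tr$genome_id[match(rownames(x), tr$contig_id)]
  set.seed(1)
  lab_idx <- unlist(lapply(split(seq_len(nrow(x)), gen), function(i)
    sample(i, max(2, round(0.3 * length(i))))))
  q_idx <- setdiff(seq_len(nrow(x)), lab_idx)
  cb <- train_som(x, epochs = 40, seed = 1)
  asn <- label_and_assign(cb, x[lab_idx, , drop = FALSE], gen[lab_idx],
                          x[q_idx, , drop = FALSE])
  len <- tr$length[match(rownames(x)[q_idx], tr$contig_id)]
  big <- len >= 5000
  correct <- !is.na(asn$cluster) & asn$cluster == gen[q_idx]
  wrong <- !is.na(asn$cluster) & asn$cluster != gen[q_idx]
  expect_gte(mean(correct[big]), 0.9)
  expect_lte(mean(wrong[big]), 0.02)

  # contigs from a genome absent from every cluster stay unassigned
  novel <- simulate_genome(genome_model("novel", 0.36, 50000, 5,
                                        markov_order = 2L), 999)
  chunks <- substring(novel, seq(1, 45001, by = 5000),
                      seq(5000, 50000, by = 5000))
  nx <- tnf(Biostrings::DNAStringSet(setNames(chunks,
                                              paste0("nv", 1:10))))
  nasn <- label_and_assign(cb, x[lab_idx, , drop = FALSE], gen[lab_idx], nx)
  expect_gte(mean(is.na(nasn$cluster)), 0.8)

  # raising the acceptance percentile never unassigns a query
  prev <- asn
  for (pct in c(97, 99, 100)) {
    cur <- label_and_assign(cb, x[lab_idx, , drop = FALSE], gen[lab_idx],
                            x[q_idx, , drop = FALSE],
                            distance_percentile = pct)
    was <- prev$contig_id[!is.na(prev$cluster)]
    expect_true(all(!is.na(cur$cluster[cur$contig_id %in% was])))
    prev <- cur
  }
})

test_that("a cluster outvoted on every neuron is flagged unusable", {
  com <- small_community()
  x <- tnf(com$contigs)
  cb <- train_som(x, epochs = 10, seed = 2)
  # one "ghost" contig sharing its BMU with two same-vector rivals can win
  # no neuron, so its cluster label is unusable
  lx <- rbind(x[1, ], x[1, ], x[1, ])
  rownames(lx) <- c("a1", "a2", "g1")
  expect_warning(
    label_and_assign(cb, lx, c("A", "A", "ghost"), x[2, , drop = FALSE]),
    "ghost")
})
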