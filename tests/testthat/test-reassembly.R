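# Read recruitment, greedy overlap assembly and the iterative loop.

make_toy <- function(len = 20000, seed = 5, circular = TRUE,
                     coverage = 30) {
  m <- genome_model("toy", 0.45, max(len, 10000), 10)
  m$genome_length <- as.integer(len)
  gen <- simulate_genome(m, seed)
  reads <- simulate_reads(gen, coverage, read_length = 100,
                          insert_size = 2500, seed = seed + 1,
                          circular = circular)
  list(genome = gen, reads = reads)
}

test_that("k-mer recruitment finds true reads and their mates", {
  toy <- make_toy(len = 10000, circular = FALSE, coverage = 10)
  idx <- kmer_index(substr(toy$genome, 1, 2000), 31)
  expect_error(kmer_index("ACGT", 30), "odd")
  rec <- recruit_reads(idx, toy$reads)
  # a read that is an exact contig substring is recruited
  probe <- list(r1 = Biostrings::DNAStringSet(substr(toy$genome, 501, 600)),
                r2 = Biostrings::DNAStringSet(strrep("A", 100)))
  expect_true(recruit_reads(idx, probe))
  # mate-rescue: only /1 matches but the pair is recruited (verified by
  # brute force that /2 shares no k-mer)
  r2 <- as.character(probe$r2[[1]])
  r2km <- substring(r2, 1:70, 31:100)
  expect_false(any(pmin(r2km, vapply(r2km, oracle_revcomp, "")) %in%
                   idx$kmers$kmer))
  # a random read with no shared k-mer is not recruited
  set.seed(8)
  rand <- paste(sample(c("A", "C", "G", "T"), 100, TRUE), collapse = "")
  randkm <- substring(rand, 1:70, 31:100)
  stopifnot(!any(pmin(randkm, vapply(randkm, oracle_revcomp, "")) %in%
                 idx$kmers$kmer))
  probe2 <- list(r1 = Biostrings::DNAStringSet(rand),
                 r2 = Biostrings::DNAStringSet(rand))
  expect_false(recruit_reads(idx, probe2))
  # recruitment respects pairs within the real read set
  pos_truth <- vapply(as.character(toy$reads$r1), function(r)
    grepl(r, substr(toy$genome, 1, 2000), fixed = TRUE), logical(1))
  expect_true(all(rec[pos_truth]))
})

test_that("greedy assembly reconstructs a linear sequence", {
  toy <- make_toy(len = 5000, circular = FALSE, coverage = 30)
  pool <- c(as.character(toy$reads$r1), as.character(toy$reads$r2))
  asm <- reassemble(pool)
  lens <- Biostrings::width(asm$contigs)
  expect_equal(length(asm$contigs), 1)
  expect_gte(max(lens), 5000 - 100)
  # reconstruction is exact up to reverse complement
  ctg <- as.character(asm$contigs[[1]])
  rc <- as.character(Biostrings::reverseComplement(asm$contigs[[1]]))
  expect_true(grepl(ctg, toy$genome, fixed = TRUE) ||
              grepl(rc, toy$genome, fixed = TRUE))
  expect_false(asm$circular[1])
  # two non-overlapping reads give two contigs
  two <- reassemble(c(substr(toy$genome, 1, 100),
                      substr(toy$genome, 2001, 2100)))
  expect_equal(length(two$contigs), 2)
})

test_that("external assembler mode shells out and parses FASTA", {
  sh <- tempfile(fileext = ".sh")
  writeLines(c("#!/bin/sh", "cp \"$1\" \"$2\""), sh)
  Sys.chmod(sh, "0755")
  asm <- reassemble(c("ACGTACGTACGT"), mode = "external",
                    external_cmd = paste(sh, "{reads}", "{out}"))
  expect_equal(as.character(asm$contigs[[1]]), "ACGTACGTACGT")
  expect_error(reassemble("ACGT", mode = "external",
                          external_cmd = "false {reads} {out}"),
               "exited")
})

test_that("iteration recovers a circular genome from a small seed", {
  toy <- make_toy(len = 20000, seed = 5, circular = TRUE, coverage = 30)
  seed_ctg <- substr(toy$genome, 3001, 5000)
  res <- iterate_reassembly(seed_ctg, toy$reads, max_iter = 10)
  expect_lte(nrow(res$log), 5)
  expect_equal(length(res$contigs), 1)
  expect_true(res$circular[1])
  expect_equal(Biostrings::width(res$contigs), 20000)
  # sequence identity up to rotation / reverse complement
  ctg <- as.character(res$contigs[[1]])
  dbl <- paste0(toy$genome, toy$genome)
  rc <- as.character(Biostrings::reverseComplement(res$contigs[[1]]))
  expect_true(grepl(ctg, dbl, fixed = TRUE) || grepl(rc, dbl, fixed = TRUE))
  # recruited read counts grow monotonically on error-free data
  expect_true(all(diff(res$log$recruited_reads) >= 0))
  # reproducible
  res2 <- iterate_reassembly(seed_ctg, toy$reads, max_iter = 10)
  expect_identical(res$log$total_length, res2$log$total_length)
})

test_that("degenerate iteration inputs terminate as specified", {
  toy <- make_toy(len = 10000, circular = FALSE, coverage = 5)
  # seed sharing no k-mer with any read: one iteration, seeds unchanged
  set.seed(12)
  alien <- paste(sample(c("A", "C", "G", "T"), 2000, TRUE), collapse = "")
  idx <- kmer_index(alien, 31)
  if (!any(recruit_reads(idx, toy$reads))) {
    res <- iterate_reassembly(alien, toy$reads)
    expect_equal(nrow(res$log), 1)
    expect_equal(res$log$recruited_reads, 0L)
    expect_identical(as.character(res$contigs[[1]]), alien)
  }
  # tol = 1 always stops after the first iteration
  seed_ctg <- substr(toy$genome, 1, 2000)
  res1 <- iterate_reassembly(seed_ctg, toy$reads, tol = 1)
  expect_equal(nrow(res1$log), 1)
  expect_error(iterate_reassembly(character(0), toy$reads), "empty")
})
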