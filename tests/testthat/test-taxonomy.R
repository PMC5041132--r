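# Windowed LCA, per-rank majority voting and the kingdom filter, checked
# against brute-force oracles on the toy taxonomy.

tree <- toy_taxonomy()

# independent oracle: LCA = deepest common element of the ancestor sets
oracle_lca <- function(tree, ids) {
  paths <- lapply(ids, function(i) tax_ancestors(tree, i))
  common <- Reduce(intersect, paths)
  common[length(common)]
}

test_that("single, sibling and empty hit sets classify as specified", {
  expect_identical(
    lca_classify_orf(data.frame(taxid = "B_p1_c1_g1", bitscore = 100),
                     tree)$taxon,
    "B_p1_c1_g1")
  # sibling genera within the window resolve to their common class
  sib <- lca_classify_orf(
    data.frame(taxid = c("B_p1_c1_g1", "B_p1_c1_g2"),
               bitscore = c(100, 98)), tree, window = 0.1)
  expect_identical(sib$taxon,
                   oracle_lca(tree, c("B_p1_c1_g1", "B_p1_c1_g2")))
  expect_identical(sib$taxon, "B_p1_c1")
  empty <- lca_classify_orf(
    data.frame(taxid = character(0), bitscore = numeric(0)), tree)
  expect_true(is.na(empty$taxon))
})

test_that("the bitscore window and e-value prefilter gate hits", {
  h <- data.frame(taxid = c("B_p1_c1_g1", "E_p1_c1_g1"),
                  bitscore = c(100, 80), evalue = c(1e-30, 1e-30))
  # 80 < 0.9 * 100: outside the 10% window, genus call stands
  expect_identical(lca_classify_orf(h, tree)$taxon, "B_p1_c1_g1")
  # widen the window and the LCA jumps to the root
  expect_identical(lca_classify_orf(h, tree, window = 0.5)$taxon, "1")
  # weak e-value hits are dropped before windowing
  h$evalue[1] <- 1e-3
  expect_identical(lca_classify_orf(h, tree)$taxon, "E_p1_c1_g1")
  # unknown taxid skipped with a warning
  h2 <- data.frame(taxid = c("nope", "B_p1_c1_g1"), bitscore = c(100, 99))
  expect_warning(r <- lca_classify_orf(h2, tree), "absent")
  expect_identical(r$taxon, "B_p1_c1_g1")
})

test_that("windowed LCA equals the ancestor-set oracle exhaustively", {
  genera <- tree$nodes$node_id[tree$nodes$rank == "genus" &
                               startsWith(tree$nodes$node_id, "B")]
  for (k in 1:3) {
    sets <- utils::combn(genera, k)
    for (j in seq_len(ncol(sets))) {
      ids <- sets[, j]
      got <- lca_classify_orf(
        data.frame(taxid = ids, bitscore = rep(100, k)), tree)$taxon
      expect_identical(got, oracle_lca(tree, ids))
    }
  }
  # larger hit sets: random draws across both kingdoms
  all_nodes <- tree$nodes$node_id[tree$nodes$rank != "root"]
  set.seed(1)
  for (r in 1:200) {
    ids <- sample(all_nodes, sample(4:5, 1))
    got <- lca_classify_orf(
      data.frame(taxid = ids, bitscore = rep(50, length(ids))), tree)$taxon
    expect_identical(got, oracle_lca(tree, ids))
  }
})

test_that("majority vote follows plurality with tie-stop per rank", {
  b <- c("B_p1_c1_g1", "B_p1_c2_g1", "B_p2_c1_g1")
  e <- "E_p1_c1_g1"
  # plurality at kingdom
  v <- contig_majority_vote(c(b, e), tree)
  expect_identical(v$per_rank$taxon[v$per_rank$rank == "kingdom"], "B")
  # kingdom tie -> unclassified
  v2 <- contig_majority_vote(c("B_p1_c1_g1", "E_p1_c1_g1"), tree)
  expect_true(is.na(v2$taxon))
  expect_equal(nrow(v2$per_rank), 0)
  # descent: kingdom B (3), phylum {p1:2, p2:1}, class within p1 tie
  v3 <- contig_majority_vote(c(b, e), tree)
  expect_identical(v3$taxon, "B_p1")
  # all ORFs unclassified -> unclassified contig
  v4 <- contig_majority_vote(c(NA_character_, NA_character_), tree)
  expect_true(is.na(v4$taxon))
  expect_error(contig_majority_vote(character(0), tree), "no ORFs")
})

test_that("majority vote is permutation-invariant and path-consistent", {
  taxa <- c("B_p1_c1_g1", "B_p1_c1_g1", "B_p1_c2_g3", "B_p2_c1_g1",
            "E_p1_c1_g1", NA)
  set.seed(2)
  ref <- contig_majority_vote(taxa, tree)
  for (i in 1:10) {
    v <- contig_majority_vote(sample(taxa), tree)
    expect_identical(v$taxon, ref$taxon)
    expect_identical(v$per_rank$taxon, ref$per_rank$taxon)
  }
  # winners on successive ranks form a root-to-node path
  anc <- tax_ancestors(tree, ref$taxon)
  expect_true(all(ref$per_rank$taxon %in% anc))
  # vote fractions lie in (0, 1]
  expect_true(all(ref$per_rank$vote_fraction > 0 &
                  ref$per_rank$vote_fraction <= 1))
})

test_that("kingdom filter keeps Bacteria and records removal reasons", {
  cc <- data.frame(
    contig_id = c("c1", "c2", "c3", "c4"),
    taxon = c("B_p1_c1_g1", "E_p1", NA, NA),
    kingdom = c("B", "E", NA, NA),
    rank = c("genus", "phylum", NA, NA),
    n_orfs = c(3L, 2L, 1L, 0L),
    n_classified = c(3L, 2L, 0L, 0L))
  f <- kingdom_filter(cc, tree)
  expect_identical(f$kept, "c1")
  expect_setequal(f$removed$contig_id, c("c2", "c3", "c4"))
  expect_identical(f$removed$reason[f$removed$contig_id == "c2"],
                   "kingdom_Eukaryota")
  expect_identical(f$removed$reason[f$removed$contig_id == "c4"], "no_orfs")
  # empty input -> empty output
  f0 <- kingdom_filter(cc[0, ], tree)
  expect_length(f0$kept, 0)
})

test_that("a zero-divergence host is fully removed by the kingdom filter", {
  com <- small_community()
  oc <- classify_orfs(com$hits, tree)
  cc <- classify_contigs(oc, com$orfs[, c("orf_id", "contig_id")], tree)
  f <- kingdom_filter(cc, tree)
  host_ctg <- com$truth$contig_id[com$truth$genome_id == "host"]
  with_orfs <- intersect(host_ctg, com$orfs$contig_id)
  expect_true(all(with_orfs %in% f$removed$contig_id))
})

test_that("taxonomy validation rejects malformed trees", {
  bad <- data.frame(node_id = c("1", "a"), parent_id = c("1", "b"),
                    rank = c("root", "kingdom"), name = c("r", "a"))
  expect_error(taxonomy_tree(bad), "parent_id")
  tworoot <- data.frame(node_id = c("1", "2"), parent_id = c("1", "2"),
                        rank = c("root", "root"), name = c("r", "r2"))
  expect_error(taxonomy_tree(tworoot), "exactly one")
  # NCBI-style dump import round-trips
  nodes <- tempfile(); names <- tempfile()
  writeLines(c("1\t|\t1\t|\troot\t|", "2\t|\t1\t|\tkingdom\t|"), nodes)
  writeLines(c("1\t|\troot\t|\t\t|\tscientific name\t|",
               "2\t|\tBacteria\t|\t\t|\tscientific name\t|"), names)
  tr <- read_taxonomy_ncbi(nodes, names, c("root", "kingdom"))
  expect_identical(tax_name_of(tr, "2"), "Bacteria")
})
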