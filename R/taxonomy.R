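# Taxonomy tree handling, windowed-LCA ORF classification, contig majority
# vote and the kingdom-level filter.

#' Construct a taxonomy tree
#'
#' Builds a validated taxonomy from a node table.  The root must be
#' self-parented; every node must reach the root; ranks must descend
#' monotonically along any root-to-leaf path.
#'
#' @param nodes data.frame with columns `node_id`, `parent_id`, `rank`,
#'   `name`.  IDs may be integers or strings.
#' @param rank_order character vector giving ranks from root to leaf.  Ranks
#'   used in `nodes` must all appear here.
#' @return An object of class `taxonomy_tree`.
#' @examples
#' tree <- toy_taxonomy()
#' tree
#' @export
taxonomy_tree <- function(nodes,
                          rank_order = c("root", "kingdom", "phylum",
                                         "class", "genus")) {
  stopifnot(is.data.frame(nodes),
            all(c("node_id", "parent_id", "rank", "name") %in% names(nodes)))
  nodes$node_id <- as.character(nodes$node_id)
  nodes$parent_id <- as.character(nodes$parent_id)
  if (anyDuplicated(nodes$node_id))
    stop("duplicated node_id in taxonomy")
  if (!all(nodes$rank %in% rank_order))
    stop("rank(s) not in rank_order: ",
         paste(setdiff(nodes$rank, rank_order), collapse = ", "))
  root <- nodes$node_id[nodes$node_id == nodes$parent_id]
  if (length(root) != 1L)
    stop("taxonomy must have exactly one self-parented root")
  idx <- match(nodes$parent_id, nodes$node_id)
  if (anyNA(idx))
    stop("parent_id not present as node_id")
  # check reachability and rank monotonicity from every node
  rank_num <- match(nodes$rank, rank_order)
  for (i in seq_len(nrow(nodes))) {
    j <- i
    steps <- 0L
    while (nodes$node_id[j] != root) {
      p <- idx[j]
      if (rank_num[p] >= rank_num[j])
        stop("rank does not decrease towards root at node ", nodes$node_id[j])
      j <- p
      steps <- steps + 1L
      if (steps > nrow(nodes)) stop("cycle detected in taxonomy")
    }
  }
  structure(list(nodes = nodes, root = root, rank_order = rank_order,
                 parent_idx = idx),
            class = "taxonomy_tree")
}

#' @export
print.taxonomy_tree <- function(x, ...) {
  cat("taxonomy_tree:", nrow(x$nodes), "nodes, root =",
      x$nodes$name[x$nodes$node_id == x$root],
      "\nranks:", paste(x$rank_order, collapse = " > "), "\n")
  invisible(x)
}

#' Read a taxonomy from a TSV node table
#'
#' Expects columns `node_id`, `parent_id`, `rank`, `name` (with header).
#' NCBI-style `nodes.dmp`/`names.dmp` pairs can be imported with
#' [read_taxonomy_ncbi()].
#'
#' @param path file path.
#' @param rank_order see [taxonomy_tree()].
#' @return `taxonomy_tree`.
#' @export
read_taxonomy <- function(path, rank_order = c("root", "kingdom", "phylum",
                                               "class", "genus")) {
  df <- utils::read.delim(path, colClasses = "character")
  taxonomy_tree(df, rank_order)
}

#' Import an NCBI-style nodes.dmp/names.dmp taxonomy
#'
#' Reads the pipe-delimited dump format (`\t|\t` separators).  Only the
#' scientific name is kept from `names.dmp`.  Ranks not listed in
#' `rank_order` cause an error, so supply the full NCBI rank ladder when
#' importing real dumps.
#'
#' @param nodes_dmp,names_dmp file paths.
#' @param rank_order ranks from root to leaf.
#' @return `taxonomy_tree`.
#' @export
read_taxonomy_ncbi <- function(nodes_dmp, names_dmp, rank_order) {
  nl <- readLines(nodes_dmp)
  nf <- strsplit(nl, "\t\\|\t?")
  nodes <- data.frame(node_id = vapply(nf, `[`, "", 1L),
                      parent_id = vapply(nf, `[`, "", 2L),
                      rank = vapply(nf, `[`, "", 3L))
  ml <- readLines(names_dmp)
  mf <- strsplit(ml, "\t\\|\t?")
  sci <- vapply(mf, function(x) identical(trimws(x[4L]), "scientific name"),
                logical(1))
  nm <- data.frame(node_id = vapply(mf[sci], `[`, "", 1L),
                   name = vapply(mf[sci], `[`, "", 2L))
  nodes$name <- nm$name[match(nodes$node_id, nm$node_id)]
  taxonomy_tree(nodes, rank_order)
}

#' Path from the root to a node
#'
#' @param tree `taxonomy_tree`.
#' @param node_id single node ID.
#' @return character vector of node IDs, root first, `node_id` last.
#' @export
tax_ancestors <- function(tree, node_id) {
  i <- match(as.character(node_id), tree$nodes$node_id)
  if (is.na(i)) stop("node ", node_id, " not in taxonomy")
  path <- character(0)
  repeat {
    path <- c(tree$nodes$node_id[i], path)
    if (tree$nodes$node_id[i] == tree$root) break
    i <- tree$parent_idx[i]
  }
  path
}

#' Lowest common ancestor of a set of nodes
#'
#' @param tree `taxonomy_tree`.
#' @param node_ids character/integer vector of node IDs (length >= 1).
#' @return single node ID.
#' @export
tax_lca <- function(tree, node_ids) {
  node_ids <- unique(as.character(node_ids))
  paths <- lapply(node_ids, function(id) tax_ancestors(tree, id))
  depth <- min(lengths(paths))
  lca <- tree$root
  for (d in seq_len(depth)) {
    level <- vapply(paths, `[`, "", d)
    if (length(unique(level)) != 1L) break
    lca <- level[1L]
  }
  lca
}

#' Project a node onto a rank
#'
#' Returns the ancestor-or-self of `node_id` at `rank`, or `NA` when the
#' node sits above that rank (it cannot vote there).
#'
#' @param tree `taxonomy_tree`.
#' @param node_id single node ID.
#' @param rank rank label present in `tree$rank_order`.
#' @return node ID or `NA_character_`.
#' @export
tax_at_rank <- function(tree, node_id, rank) {
  path <- tax_ancestors(tree, node_id)
  ranks <- tree$nodes$rank[match(path, tree$nodes$node_id)]
  hit <- path[ranks == rank]
  if (length(hit) == 0L) NA_character_ else hit
}

tax_rank_of <- function(tree, node_id) {
  tree$nodes$rank[match(as.character(node_id), tree$nodes$node_id)]
}

tax_name_of <- function(tree, node_id) {
  tree$nodes$name[match(as.character(node_id), tree$nodes$node_id)]
}

#' Classify one ORF by windowed lowest common ancestor
#'
#' Hits are pre-filtered at `max_evalue`; hits whose bitscore is within
#' `window` of the best retained bitscore (score >= (1 - window) * max) are
#' kept and their LCA in the tree is returned.  No usable hits gives an
#' unclassified result (taxon `NA`).  Hits whose taxon is absent from the
#' tree are dropped with a warning.
#'
#' @param hits data.frame with columns `taxid`, `bitscore` and optionally
#'   `evalue`; may have zero rows.
#' @param tree `taxonomy_tree`.
#' @param window fraction in (0, 1]: the relative bitscore window.
#' @param max_evalue e-value pre-filter (ignored when `hits` lacks an
#'   `evalue` column).
#' @return list with `taxon` (node ID or `NA`), `n_hits` (hits supporting
#'   the call).
#' @export
lca_classify_orf <- function(hits, tree, window = 0.1, max_evalue = 1e-5) {
  stopifnot(window > 0, window <= 1)
  if (nrow(hits) == 0L)
    return(list(taxon = NA_character_, n_hits = 0L))
  if ("evalue" %in% names(hits))
    hits <- hits[hits$evalue <= max_evalue, , drop = FALSE]
  known <- as.character(hits$taxid) %in% tree$nodes$node_id
  if (any(!known)) {
    warning("dropping ", sum(!known), " hit(s) with taxid absent from tree")
    hits <- hits[known, , drop = FALSE]
  }
  if (nrow(hits) == 0L)
    return(list(taxon = NA_character_, n_hits = 0L))
  keep <- hits$bitscore >= (1 - window) * max(hits$bitscore)
  hits <- hits[keep, , drop = FALSE]
  list(taxon = tax_lca(tree, hits$taxid), n_hits = nrow(hits))
}

#' Classify every ORF in a homology hit table
#'
#' @param hit_table data.frame with columns `orf_id`, `taxid`, `bitscore`
#'   and optionally `evalue` (outfmt-6-like).
#' @param tree `taxonomy_tree`.
#' @inheritParams lca_classify_orf
#' @return data.frame `orf_id`, `taxon` (NA = unclassified), `n_hits`.
#' @export
classify_orfs <- function(hit_table, tree, window = 0.1, max_evalue = 1e-5) {
  split_idx <- split(seq_len(nrow(hit_table)), hit_table$orf_id)
  res <- lapply(split_idx, function(i)
    lca_classify_orf(hit_table[i, , drop = FALSE], tree,
                     window = window, max_evalue = max_evalue))
  data.frame(orf_id = names(split_idx),
             taxon = vapply(res, function(x) x$taxon, ""),
             n_hits = vapply(res, function(x) x$n_hits, 0L),
             row.names = NULL)
}

#' Decide a contig's taxonomy by per-rank majority vote of its ORFs
#'
#' Ranks are walked from just below the root towards the leaves.  At each
#' rank every classified ORF projects its taxon onto that rank (ORFs
#' classified above the rank abstain); the plurality taxon wins only if it
#' strictly beats every rival (ties leave the rank undecided) and descent
#' continues only among ORFs consistent with the winner.  The final taxon is
#' the winner of the deepest decided rank.
#'
#' @param orf_taxa character vector of ORF taxon node IDs (`NA` =
#'   unclassified ORF); must have length >= 1.
#' @param tree `taxonomy_tree`.
#' @return list with `per_rank` (data.frame `rank`, `taxon`, `votes`,
#'   `vote_fraction`) and `taxon` (final node ID, or `NA` when even the
#'   kingdom rank is undecided).
#' @export
contig_majority_vote <- function(orf_taxa, tree) {
  if (length(orf_taxa) == 0L) stop("contig has no ORFs")
  voters <- orf_taxa[!is.na(orf_taxa)]
  ranks <- setdiff(tree$rank_order, tree$rank_order[1L])
  per_rank <- data.frame(rank = character(0), taxon = character(0),
                         votes = integer(0), vote_fraction = numeric(0))
  final <- NA_character_
  for (rk in ranks) {
    if (length(voters) == 0L) break
    proj <- vapply(voters, function(t) tax_at_rank(tree, t, rk), "")
    votes <- table(proj[!is.na(proj)])
    if (length(votes) == 0L) break
    top <- max(votes)
    winners <- names(votes)[votes == top]
    if (length(winners) != 1L) break           # tie: rank undecided
    final <- winners
    per_rank <- rbind(per_rank, data.frame(
      rank = rk, taxon = winners, votes = as.integer(top),
      vote_fraction = top / sum(votes)))
    voters <- voters[!is.na(proj) & proj == winners]
  }
  list(per_rank = per_rank, taxon = final)
}

#' Classify contigs from ORF classifications
#'
#' @param orf_classes data.frame from [classify_orfs()].
#' @param orf_map data.frame with columns `orf_id`, `contig_id` mapping ORFs
#'   to contigs (e.g. from [read_orf_gff()]).  Contigs present in `orf_map`
#'   but with no classified ORFs are reported unclassified.
#' @param tree `taxonomy_tree`.
#' @return data.frame with one row per contig: `contig_id`, `taxon`,
#'   `kingdom`, `rank`, `n_orfs`, `n_classified`.
#' @export
classify_contigs <- function(orf_classes, orf_map, tree) {
  taxon <- orf_classes$taxon[match(orf_map$orf_id, orf_classes$orf_id)]
  groups <- split(taxon, orf_map$contig_id)
  rows <- lapply(names(groups), function(cid) {
    v <- contig_majority_vote(groups[[cid]], tree)
    data.frame(contig_id = cid,
               taxon = v$taxon,
               kingdom = if (nrow(v$per_rank)) v$per_rank$taxon[1L]
                         else NA_character_,
               rank = if (is.na(v$taxon)) NA_character_
                      else tax_rank_of(tree, v$taxon),
               n_orfs = length(groups[[cid]]),
               n_classified = sum(!is.na(groups[[cid]])))
  })
  do.call(rbind, rows)
}

#' Remove non-bacterial contigs
#'
#' Retains contigs whose kingdom-rank winner is Bacteria (optionally also
#' Archaea); contigs classified as Eukaryota or unclassified at the kingdom
#' level are removed, with reasons recorded.  Contigs with zero ORFs are
#' removed but flagged (`reason = "no_orfs"`) so composition-based binning
#' may rescue them downstream.
#'
#' @param contig_classes data.frame from [classify_contigs()]; contigs with
#'   no ORFs may be included with `n_orfs = 0`.
#' @param tree `taxonomy_tree`.
#' @param keep_archaea also retain kingdom Archaea (default FALSE).
#' @return list with `kept` (character vector of contig IDs) and `removed`
#'   (data.frame `contig_id`, `reason`).
#' @export
kingdom_filter <- function(contig_classes, tree, keep_archaea = FALSE) {
  wanted <- "Bacteria"
  if (keep_archaea) wanted <- c(wanted, "Archaea")
  kname <- ifelse(is.na(contig_classes$kingdom), NA_character_,
                  tax_name_of(tree, contig_classes$kingdom))
  keep <- !is.na(kname) & kname %in% wanted
  reason <- ifelse(contig_classes$n_orfs == 0L, "no_orfs",
            ifelse(is.na(kname), "unclassified_kingdom",
                   paste0("kingdom_", kname)))
  list(kept = contig_classes$contig_id[keep],
       removed = data.frame(contig_id = contig_classes$contig_id[!keep],
                            reason = reason[!keep]))
}

#' The packaged toy taxonomy
#'
#' A small balanced four-rank tree (two kingdoms, three phyla each, two
#' classes per phylum, three genera per class) used by the synthetic
#' community generator and the test suite.
#'
#' @return `taxonomy_tree`.
#' @export
toy_taxonomy <- function() {
  read_taxonomy(system.file("extdata", "toy_taxonomy.tsv",
                            package = "darkbin", mustWork = TRUE))
}
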