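# Ground-truthed synthetic community generator.  Genomes are emitted from
# seeded, genome-specific Markov chains whose per-context emission
# probabilities are constrained so that P(G or C) equals the target GC at
# every position; fragmentation, coverage noise, ORF tiling, homology hits,
# planted single-copy markers, expression counts and paired reads are all
# derived deterministically from the community seed.

BASES <- c("A", "C", "G", "T")

#' Describe one genome of a synthetic community
#'
#' @param genome_id label.
#' @param target_gc GC fraction in `[0, 1]`.
#' @param genome_length genome size in bp; must be at least ten times
#'   `min_contig_length` (1 kb).
#' @param coverage_mean mean sequencing depth in sample A (> 0).
#' @param coverage_mean_b mean depth in sample B; only used when
#'   `shared = TRUE` (default: same as `coverage_mean`).
#' @param markov_order order of the emission Markov chain (0--5); order 2 by
#'   default so genomes are separable by tetranucleotide frequency.
#' @param shared TRUE when the genome is present in both samples.
#' @param kingdom `"Bacteria"` or `"Eukaryota"`.
#' @param divergence fraction in `[0, 1]` of ORFs that get *no* classifiable
#'   homology hit (1 = fully dark).
#' @param taxon true genus node ID in the toy taxonomy (assigned
#'   automatically by [community_spec()] when `NA`).
#' @return A `genome_model` list.
#' @export
genome_model <- function(genome_id, target_gc, genome_length, coverage_mean,
                         coverage_mean_b = coverage_mean, markov_order = 2L,
                         shared = FALSE, kingdom = "Bacteria",
                         divergence = 0.1, taxon = NA_character_) {
  stopifnot(target_gc >= 0, target_gc <= 1,
            genome_length >= 10 * 1000,
            coverage_mean > 0,
            kingdom %in% c("Bacteria", "Eukaryota"),
            divergence >= 0, divergence <= 1)
  if (markov_order > 5L) stop("markov_order > 5 not supported")
  structure(list(genome_id = genome_id, target_gc = target_gc,
                 genome_length = as.integer(genome_length),
                 coverage_mean = coverage_mean,
                 coverage_mean_b = coverage_mean_b,
                 markov_order = as.integer(markov_order), shared = shared,
                 kingdom = kingdom, divergence = divergence, taxon = taxon),
            class = "genome_model")
}

#' Describe a two-sample synthetic community
#'
#' Exactly one genome must be a Eukaryota host.  Unassigned true taxa are
#' drawn (deterministically, from `seed`) without replacement from the genus
#' tips of the toy taxonomy matching each genome's kingdom.
#'
#' @param genomes list of [genome_model()]s (host included).
#' @param seed integer master seed; together with the spec it fully
#'   determines every emitted file.
#' @param contig_meanlog,contig_sdlog lognormal contig-length parameters
#'   (default median 8 kb, sigma 0.7).
#' @param min_contig_length floor on contig length (default 1 kb).
#' @param coverage_sdlog lognormal sigma of multiplicative coverage noise.
#' @return A `community_spec` list.
#' @export
community_spec <- function(genomes, seed = 1L,
                           contig_meanlog = log(8000), contig_sdlog = 0.7,
                           min_contig_length = 1000L,
                           coverage_sdlog = 0.15) {
  stopifnot(length(genomes) > 0,
            all(vapply(genomes, inherits, TRUE, "genome_model")))
  kingdoms <- vapply(genomes, `[[`, "", "kingdom")
  if (sum(kingdoms == "Eukaryota") != 1L)
    stop("community must contain exactly one Eukaryota host genome")
  ids <- vapply(genomes, `[[`, "", "genome_id")
  if (anyDuplicated(ids)) stop("duplicated genome_id")
  tree <- toy_taxonomy()
  genera <- tree$nodes[tree$nodes$rank == "genus", ]
  kingdom_of <- function(id)
    tax_name_of(tree, tax_ancestors(tree, id)[2L])
  genera$kingdom <- vapply(genera$node_id, kingdom_of, "")
  set.seed(seed)
  for (kg in unique(kingdoms)) {
    need <- which(kingdoms == kg &
                  is.na(vapply(genomes, `[[`, "", "taxon")))
    pool <- genera$node_id[genera$kingdom == kg]
    if (length(need) > length(pool))
      stop("not enough toy-taxonomy genera for kingdom ", kg)
    pick <- sample(pool, length(need))
    for (i in seq_along(need)) genomes[[need[i]]]$taxon <- pick[i]
  }
  structure(list(genomes = genomes, seed = as.integer(seed),
                 contig_meanlog = contig_meanlog, contig_sdlog = contig_sdlog,
                 min_contig_length = as.integer(min_contig_length),
                 coverage_sdlog = coverage_sdlog),
            class = "community_spec")
}

#' Default synthetic community
#'
#' Emulates the study design the pipeline targets: seven sample-unique
#' bacteria whose GC% and mean coverage follow the published bin table of
#' the bryozoan ovicell metagenome (GC 20.9--60.3%, coverage 2.3--27.2x),
#' one shared gammaproteobacterium-like symbiont present in both samples,
#' and one high-GC-variance eukaryotic host genome present in both samples.
#' Divergence levels give the two most divergent bins mostly unclassifiable
#' ORFs (~20% of ORFs with hits for the low-GC genome).
#'
#' Genome lengths are desk-scale stand-ins (60--300 kb) preserving the
#' relative ordering of the real bins.
#'
#' @param seed master seed.
#' @return `community_spec`.
#' @export
default_community <- function(seed = 1L) {
  g <- list(
    genome_model("flavo",          0.338,  80000,  3.3, divergence = 0.10),
    genome_model("chromatiales",   0.504, 120000,  2.4, divergence = 0.15),
    genome_model("divgenome",      0.347,  90000, 20.8, divergence = 0.55),
    genome_model("endozoicomonas", 0.453, 100000,  7.0, divergence = 0.10),
    genome_model("lowgc",          0.209,  60000, 27.2, divergence = 0.80),
    genome_model("rickettsiales",  0.216,  60000,  2.3, divergence = 0.60),
    genome_model("phaeo",          0.603, 100000,  2.9, divergence = 0.20),
    genome_model("endobugula",     0.470, 100000, 15.0, coverage_mean_b = 20.0,
                 shared = TRUE, divergence = 0.20),
    genome_model("host",           0.400, 300000,  3.0, coverage_mean_b = 4.0,
                 shared = TRUE, kingdom = "Eukaryota", divergence = 0.05))
  community_spec(g, seed = seed)
}

#' Simulate one genome sequence
#'
#' Emits a sequence from a Markov chain of the model's order.  At every
#' position the probability of emitting G or C equals `target_gc` exactly
#' (so realized GC is unbiased at any length); the split G-vs-C and A-vs-T
#' is context-specific and drawn from the genome's own RNG stream, which
#' makes tetranucleotide profiles genome-specific.
#'
#' @param model [genome_model()].
#' @param seed integer seed.
#' @return single character string of length `genome_length`.
#' @examples
#' m <- genome_model("g", 0.5, 10000, 10, markov_order = 0)
#' s <- simulate_genome(m, 42)
#' nchar(s)
#' @export
simulate_genome <- function(model, seed) {
  stopifnot(inherits(model, "genome_model"))
  if (model$markov_order > 5L) stop("markov_order > 5 not supported")
  set.seed(seed)
  k <- model$markov_order
  n <- model$genome_length
  gc <- model$target_gc
  nctx <- 4L^k
  # context-specific within-GC and within-AT splits (logit-normal around 1/2)
  gshare <- stats::plogis(stats::rnorm(nctx, 0, 1.0))
  ashare <- stats::plogis(stats::rnorm(nctx, 0, 1.0))
  u1 <- stats::runif(n)
  u2 <- stats::runif(n)
  out <- integer(n)
  ctx <- 1L
  mod <- if (k > 0L) 4L^(k - 1L) else 1L
  for (i in seq_len(n)) {
    s <- if (u1[i] < gc) {
      if (u2[i] < gshare[ctx]) 3L else 2L      # G or C
    } else {
      if (u2[i] < ashare[ctx]) 1L else 4L      # A or T
    }
    out[i] <- s
    if (k > 0L) ctx <- ((ctx - 1L) %% mod) * 4L + s
  }
  paste(BASES[out], collapse = "")
}

gc_fraction <- function(seq) {
  b <- Biostrings::letterFrequency(Biostrings::DNAStringSet(seq),
                                   letters = c("G", "C"))
  as.numeric(rowSums(b)) / nchar(seq)
}

revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# split [1, n] into fragments with lognormal lengths; terminal fragments
# shorter than the floor are dropped (edge loss)
fragment_lengths <- function(n, meanlog, sdlog, floor_len) {
  lens <- integer(0)
  left <- n
  while (left >= floor_len) {
    l <- max(floor_len, round(stats::rlnorm(1, meanlog, sdlog)))
    l <- min(l, left)
    if (l >= floor_len) lens <- c(lens, l)
    left <- left - l
  }
  lens
}

#' Fragment genomes into contigs and assign noisy coverages
#'
#' Each genome is tiled by contigs with lognormal lengths, so contig counts
#' are proportional to genome length.  Per-contig coverage is the genome
#' mean perturbed by multiplicative lognormal noise.  Shared genomes (and
#' the host) get nonzero sample-B coverage with near-complete breadth;
#' sample-unique genomes get zero.
#'
#' @param spec [community_spec()].
#' @return list with `contigs` (named [Biostrings::DNAStringSet]),
#'   `coverage` (data.frame `contig_id`, `coverage`; sample A), `coverage_b`
#'   (data.frame `contig_id`, `depth`, `breadth`), `truth` (data.frame
#'   `contig_id`, `genome_id`, `start`, `end`, `length`, `gc`, `sample`),
#'   `genomes` (named character vector of full genome sequences), and the
#'   `spec`.
#' @export
fragment_and_cover <- function(spec) {
  stopifnot(inherits(spec, "community_spec"))
  if (length(spec$genomes) == 0L) stop("empty genome list")
  set.seed(spec$seed)
  gseeds <- sample.int(.Machine$integer.max - 1L, length(spec$genomes))
  genomes <- vapply(seq_along(spec$genomes), function(i)
    simulate_genome(spec$genomes[[i]], gseeds[i]), "")
  names(genomes) <- vapply(spec$genomes, `[[`, "", "genome_id")

  set.seed(spec$seed + 1L)
  rows <- list()
  seqs <- character(0)
  counter <- 0L
  for (i in seq_along(spec$genomes)) {
    m <- spec$genomes[[i]]
    lens <- fragment_lengths(m$genome_length, spec$contig_meanlog,
                             spec$contig_sdlog, spec$min_contig_length)
    ends <- cumsum(lens)
    starts <- ends - lens + 1L
    for (j in seq_along(lens)) {
      counter <- counter + 1L
      cid <- sprintf("ctg%05d", counter)
      s <- substr(genomes[[m$genome_id]], starts[j], ends[j])
      seqs[cid] <- s
      cov_a <- m$coverage_mean * stats::rlnorm(1, 0, spec$coverage_sdlog)
      if (m$shared) {
        depth_b <- m$coverage_mean_b * stats::rlnorm(1, 0, spec$coverage_sdlog)
        breadth_b <- stats::runif(1, 0.95, 1.0)
      } else {
        depth_b <- 0
        breadth_b <- 0
      }
      rows[[counter]] <- data.frame(
        contig_id = cid, genome_id = m$genome_id,
        start = starts[j], end = ends[j], length = lens[j],
        gc = gc_fraction(s),
        sample = if (m$shared) "both" else "A",
        coverage = cov_a, depth_b = depth_b, breadth_b = breadth_b)
    }
  }
  truth <- do.call(rbind, rows)
  contigs <- Biostrings::DNAStringSet(seqs)
  list(contigs = contigs,
       coverage = truth[, c("contig_id", "coverage")],
       coverage_b = data.frame(contig_id = truth$contig_id,
                               depth = truth$depth_b,
                               breadth = truth$breadth_b),
       truth = truth[, c("contig_id", "genome_id", "start", "end",
                         "length", "gc", "sample")],
       genomes = genomes, spec = spec)
}

#' Plant ORFs, homology hits, single-copy markers and expression counts
#'
#' ORFs tile every contig (600--1200 bp genes separated by short gaps).
#' A fraction `1 - divergence` of each genome's ORFs receives homology hits
#' to the genome's true genus (occasionally joined by a weaker sibling-genus
#' hit); bitscores and percent identities decrease with divergence.  Forty
#' toy single-copy markers (`SCM01`--`SCM40`) are planted once per bacterial
#' genome on distinct ORFs; duplications can be injected for contamination
#' testing.  Per-gene expression counts follow a negative binomial with a
#' lognormal rate, and genes with a hit are assigned one of eight functional
#' categories while hitless genes are `"unassigned"`.
#'
#' @param community result of [fragment_and_cover()].
#' @param duplicate_markers named list `genome_id -> character vector` of
#'   marker IDs to plant a second time (contamination injection).
#' @param n_markers number of toy markers (default 40).
#' @return list with `orfs` (data.frame `orf_id`, `contig_id`, `start`,
#'   `end`, `strand`, `length`), `hits` (`orf_id`, `taxid`, `bitscore`,
#'   `pident`, `evalue`), `markers` (`orf_id`, `marker_id`, `evalue`,
#'   `score`), `expression` (`gene_id`, `count`, `length`, `category`,
#'   `bin`), `marker_set` (character vector), and `truth_orfs` (`orf_id`,
#'   `contig_id`, `genome_id`, `taxon`, `has_hit`, `annotated`).
#' @export
plant_annotations <- function(community, duplicate_markers = list(),
                              n_markers = 40L) {
  spec <- community$spec
  truth <- community$truth
  set.seed(spec$seed + 2L)
  models <- stats::setNames(spec$genomes,
                            vapply(spec$genomes, `[[`, "", "genome_id"))
  tree <- toy_taxonomy()
  marker_set <- sprintf("SCM%02d", seq_len(n_markers))

  orf_rows <- list()
  for (r in seq_len(nrow(truth))) {
    cid <- truth$contig_id[r]
    clen <- truth$length[r]
    pos <- 1L
    k <- 0L
    while (pos + 599L <= clen) {
      glen <- sample(600:1200, 1L)
      glen <- min(glen, clen - pos + 1L)
      if (glen < 300L) break
      k <- k + 1L
      orf_rows[[length(orf_rows) + 1L]] <- data.frame(
        orf_id = sprintf("%s_orf%03d", cid, k), contig_id = cid,
        genome_id = truth$genome_id[r],
        start = pos, end = pos + glen - 1L,
        strand = sample(c("+", "-"), 1L), length = glen)
      pos <- pos + glen + sample(50:150, 1L)
    }
  }
  orfs <- do.call(rbind, orf_rows)

  # homology hits
  hit_rows <- list()
  has_hit <- logical(nrow(orfs))
  sibling_of <- function(taxon) {
    parent <- tax_ancestors(tree, taxon)
    parent <- parent[length(parent) - 1L]
    sibs <- tree$nodes$node_id[tree$nodes$parent_id == parent &
                               tree$nodes$node_id != taxon]
    if (length(sibs)) sample(sibs, 1L) else taxon
  }
  for (i in seq_len(nrow(orfs))) {
    m <- models[[orfs$genome_id[i]]]
    if (stats::runif(1) >= m$divergence) {
      has_hit[i] <- TRUE
      base_score <- 60 + 250 * (1 - m$divergence) * stats::runif(1, 0.8, 1.2)
      pid <- min(99.9, 100 * (0.30 + 0.65 * (1 - m$divergence)) +
                         stats::rnorm(1, 0, 2))
      hit_rows[[length(hit_rows) + 1L]] <- data.frame(
        orf_id = orfs$orf_id[i], taxid = m$taxon,
        bitscore = round(base_score, 1), pident = round(pid, 1),
        evalue = 10^stats::runif(1, -60, -20))
      if (stats::runif(1) < 0.3) {      # weaker sibling-genus hit
        hit_rows[[length(hit_rows) + 1L]] <- data.frame(
          orf_id = orfs$orf_id[i], taxid = sibling_of(m$taxon),
          bitscore = round(base_score * stats::runif(1, 0.6, 0.95), 1),
          pident = round(pid * stats::runif(1, 0.8, 0.98), 1),
          evalue = 10^stats::runif(1, -40, -10))
      }
    }
  }
  hits <- do.call(rbind, hit_rows)

  # single-copy markers, one per marker per bacterial genome
  marker_rows <- list()
  for (gid in names(models)) {
    if (models[[gid]]$kingdom != "Bacteria") next
    gorfs <- orfs$orf_id[orfs$genome_id == gid]
    n_avail <- length(gorfs)
    plant <- marker_set[seq_len(min(n_markers, n_avail))]
    on <- sample(gorfs, length(plant))
    extra <- duplicate_markers[[gid]]
    if (!is.null(extra)) {
      stopifnot(all(extra %in% plant))
      on2 <- sample(setdiff(gorfs, on), length(extra))
      plant <- c(plant, extra)
      on <- c(on, on2)
    }
    marker_rows[[length(marker_rows) + 1L]] <- data.frame(
      orf_id = on, marker_id = plant,
      evalue = 10^stats::runif(length(plant), -60, -15),
      score = round(stats::rnorm(length(plant), 150, 15), 1))
  }
  markers <- do.call(rbind, marker_rows)
  rownames(markers) <- NULL

  # expression counts for bacterial genes
  categories <- c("translation", "folding_sorting_degradation",
                  "nucleotide_metabolism", "energy_metabolism",
                  "cell_growth_death", "membrane_transport",
                  "replication_repair", "signal_transduction")
  bact <- orfs$genome_id %in% names(models)[
    vapply(models, `[[`, "", "kingdom") == "Bacteria"]
  expr_orfs <- orfs[bact, , drop = FALSE]
  rate <- expr_orfs$length / 1000 * exp(stats::rnorm(nrow(expr_orfs), 0, 1)) * 30
  counts <- stats::rnbinom(nrow(expr_orfs), mu = rate, size = 2)
  annotated <- has_hit[bact]
  category <- ifelse(annotated,
                     sample(categories, nrow(expr_orfs), replace = TRUE),
                     "unassigned")
  expression <- data.frame(gene_id = expr_orfs$orf_id, count = counts,
                           length = expr_orfs$length, category = category,
                           bin = expr_orfs$genome_id)

  truth_orfs <- data.frame(
    orf_id = orfs$orf_id, contig_id = orfs$contig_id,
    genome_id = orfs$genome_id,
    taxon = vapply(orfs$genome_id, function(g) models[[g]]$taxon, ""),
    has_hit = has_hit,
    annotated = has_hit)
  list(orfs = orfs[, c("orf_id", "contig_id", "start", "end", "strand",
                       "length")],
       hits = hits, markers = markers, expression = expression,
       marker_set = marker_set, truth_orfs = truth_orfs)
}

#' Simulate error-free (or uniformly erroneous) paired reads
#'
#' Fragments of `insert_size` are placed uniformly on the genome (wrapping
#' across the origin when `circular = TRUE`) at the depth requested;
#' `read_length` bases are read inward from both fragment ends, the second
#' mate reverse-complemented.
#'
#' @param sequence genome sequence (character).
#' @param coverage target depth; 0 gives empty output.
#' @param read_length,insert_size read and fragment lengths in bp.
#' @param seed integer seed.
#' @param circular treat the genome as circular.
#' @param error_rate uniform substitution probability per base.
#' @return list of two named [Biostrings::DNAStringSet]s (`r1`, `r2`), read
#'   names carrying `/1` and `/2` suffixes.
#' @export
simulate_reads <- function(sequence, coverage, read_length = 100L,
                           insert_size = 2500L, seed = 1L, circular = FALSE,
                           error_rate = 0) {
  n <- nchar(sequence)
  if (read_length > n) stop("read_length exceeds genome length")
  insert_size <- min(insert_size, n)
  set.seed(seed)
  n_pairs <- round(n * coverage / (2 * read_length))
  if (n_pairs == 0L)
    return(list(r1 = Biostrings::DNAStringSet(),
                r2 = Biostrings::DNAStringSet()))
  if (circular) {
    starts <- sample.int(n, n_pairs, replace = TRUE)
    doubled <- paste0(sequence, substr(sequence, 1L, insert_size))
    frags <- substr(rep(doubled, n_pairs), starts, starts + insert_size - 1L)
  } else {
    starts <- sample.int(n - insert_size + 1L, n_pairs, replace = TRUE)
    frags <- substr(rep(sequence, n_pairs), starts, starts + insert_size - 1L)
  }
  r1 <- substr(frags, 1L, read_length)
  r2 <- revcomp_chr(substr(frags, insert_size - read_length + 1L,
                           insert_size))
  if (error_rate > 0) {
    mutate <- function(reads) {
      vapply(reads, function(s) {
        hit <- which(stats::runif(nchar(s)) < error_rate)
        if (length(hit)) {
          ch <- strsplit(s, "")[[1]]
          ch[hit] <- sample(BASES, length(hit), replace = TRUE)
          s <- paste(ch, collapse = "")
        }
        s
      }, "", USE.NAMES = FALSE)
    }
    r1 <- mutate(r1)
    r2 <- mutate(r2)
  }
  ids <- sprintf("read%06d", seq_len(n_pairs))
  r1 <- Biostrings::DNAStringSet(r1)
  names(r1) <- paste0(ids, "/1")
  r2 <- Biostrings::DNAStringSet(r2)
  names(r2) <- paste0(ids, "/2")
  list(r1 = r1, r2 = r2)
}

#' Generate a complete synthetic community
#'
#' Convenience wrapper running [fragment_and_cover()] then
#' [plant_annotations()].
#'
#' @param spec [community_spec()].
#' @param ... passed to [plant_annotations()].
#' @return list combining both results (class `synthetic_community`).
#' @export
simulate_community <- function(spec, ...) {
  fc <- fragment_and_cover(spec)
  ann <- plant_annotations(fc, ...)
  structure(c(fc, ann), class = "synthetic_community")
}

#' @export
print.synthetic_community <- function(x, ...) {
  cat("synthetic_community:", length(x$spec$genomes), "genomes,",
      length(x$contigs), "contigs,", nrow(x$orfs), "ORFs, seed",
      x$spec$seed, "\n")
  invisible(x)
}

#' Write a synthetic community to disk
#'
#' Emits `contigs.fasta`, `coverage_a.tsv`, `coverage_b.tsv`, `orfs.gff3`,
#' `hits.tsv`, `markers.tsv`, `expression.tsv`, `marker_set.txt`,
#' `truth_contigs.tsv` and `truth_orfs.tsv` into `dir`.
#'
#' @param community result of [simulate_community()].
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_community <- function(community, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tsv <- function(df, f)
    utils::write.table(df, file.path(dir, f), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  Biostrings::writeXStringSet(community$contigs,
                              file.path(dir, "contigs.fasta"))
  tsv(community$coverage, "coverage_a.tsv")
  tsv(community$coverage_b, "coverage_b.tsv")
  write_orf_gff(community$orfs, file.path(dir, "orfs.gff3"))
  tsv(community$hits, "hits.tsv")
  tsv(community$markers, "markers.tsv")
  tsv(community$expression, "expression.tsv")
  writeLines(community$marker_set, file.path(dir, "marker_set.txt"))
  tsv(community$truth, "truth_contigs.tsv")
  tsv(community$truth_orfs, "truth_orfs.tsv")
  invisible(dir)
}
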