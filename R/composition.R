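# Canonical tetranucleotide frequencies and the toroidal self-organizing
# map used to hand non-marker contigs to mixture-derived clusters.

#' Canonical tetranucleotides
#'
#' All 256 tetramers folded under reverse-complement equivalence; each
#' equivalence class is represented by its lexicographically smaller member.
#' There are 136 classes (120 pairs + 16 palindromes).
#'
#' @return sorted character vector of length 136.
#' @export
canonical_tetramers <- function() {
  kmers <- all_kmer_strings(c("A", "C", "G", "T"), 4L)
  rc <- revcomp_chr(kmers)
  sort(unique(pmin(kmers, rc)))
}

all_kmer_strings <- function(alphabet, width) {
  out <- alphabet
  for (i in seq_len(width - 1L))
    out <- as.vector(outer(out, alphabet, paste0))
  out
}

#' Tetranucleotide frequency vectors
#'
#' Counts all overlapping 4-mers on the given strand (windows containing
#' non-ACGT characters are skipped), folds each into its canonical
#' representative and normalizes to frequencies.  By construction
#' `tnf(s) == tnf(reverse_complement(s))` exactly.
#'
#' @param contigs [Biostrings::DNAStringSet] (or a single character
#'   string).
#' @param min_length contigs shorter than this are dropped (default
#'   3000 bp; below that TNF is noisy).  Passing a single short sequence is
#'   an error.
#' @return numeric matrix, one row per retained contig, 136 columns named
#'   by canonical tetramer; rows sum to 1.
#' @export
tnf <- function(contigs, min_length = 3000L) {
  if (is.character(contigs))
    contigs <- Biostrings::DNAStringSet(stats::setNames(contigs,
      if (is.null(names(contigs))) sprintf("seq%d", seq_along(contigs))
      else names(contigs)))
  single <- length(contigs) == 1L
  keep <- Biostrings::width(contigs) >= min_length
  if (single && !keep) stop("sequence shorter than min_length")
  contigs <- contigs[keep]
  counts <- Biostrings::oligonucleotideFrequency(contigs, width = 4L)
  canon <- canonical_tetramers()
  fold <- pmin(colnames(counts), revcomp_chr(colnames(counts)))
  m <- matrix(0, nrow(counts), length(canon),
              dimnames = list(names(contigs), canon))
  for (j in seq_along(fold))
    m[, fold[j]] <- m[, fold[j]] + counts[, j]
  tot <- rowSums(m)
  if (any(tot == 0)) stop("sequence with no countable 4-mers")
  m / tot
}

# squared toroidal grid distances between all neuron pairs
grid_dist2 <- function(rows, cols, toroidal = TRUE) {
  coords <- expand.grid(r = seq_len(rows), c = seq_len(cols))
  dr <- abs(outer(coords$r, coords$r, "-"))
  dc <- abs(outer(coords$c, coords$c, "-"))
  if (toroidal) {
    dr <- pmin(dr, rows - dr)
    dc <- pmin(dc, cols - dc)
  }
  dr^2 + dc^2
}

# index of best-matching unit for each row of x
bmu_of <- function(x, proto) {
  d2 <- outer(rowSums(x^2), rep(1, nrow(proto))) +
        outer(rep(1, nrow(x)), rowSums(proto^2)) -
        2 * x %*% t(proto)
  list(bmu = max.col(-d2, ties.method = "first"),
       dist = sqrt(pmax(apply(d2, 1, min), 0)))
}

#' Train a toroidal self-organizing map
#'
#' Batch SOM: every epoch each input is mapped to its best-matching unit
#' and prototypes are recomputed as neighborhood-weighted means, with a
#' Gaussian neighborhood whose radius shrinks geometrically from half the
#' larger grid dimension to 0.5.  Deterministic under a fixed seed
#' (prototypes initialize from jittered random input rows).
#'
#' @param x numeric matrix of composition vectors (>= 10 rows).
#' @param grid integer `c(rows, cols)`; default sizes the map to about
#'   `5 * sqrt(n)` neurons, near-square.
#' @param epochs training epochs (default 40).
#' @param seed integer seed.
#' @param toroidal wrap the grid edges (default TRUE).
#' @return object of class `som_codebook`: `prototypes` (neurons x dims),
#'   `rows`, `cols`, `toroidal`, `qe` (mean quantization error per epoch).
#' @export
train_som <- function(x, grid = NULL, epochs = 40L, seed = 1L,
                      toroidal = TRUE) {
  stopifnot(is.matrix(x))
  n <- nrow(x)
  if (n < 10L) stop("need at least 10 vectors to train a map")
  if (is.null(grid)) {
    neurons <- max(4, round(5 * sqrt(n)))
    rows <- max(2L, round(sqrt(neurons)))
    cols <- max(2L, ceiling(neurons / rows))
    grid <- c(rows, cols)
  }
  rows <- grid[1L]; cols <- grid[2L]
  m <- rows * cols
  if (m > 10L * n) stop("grid larger than 10x the sample size")
  set.seed(seed)
  # classic linear initialization: prototypes span the first two principal
  # components of the data (deterministic; training then only improves fit)
  ctr <- colMeans(x)
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE, rank. = 2L)
  coords <- expand.grid(r = seq_len(rows), c = seq_len(cols))
  u <- (coords$r - (rows + 1) / 2) / max(1, (rows - 1) / 2)
  v <- (coords$c - (cols + 1) / 2) / max(1, (cols - 1) / 2)
  sd1 <- pc$sdev[1L]
  sd2 <- if (length(pc$sdev) > 1L) pc$sdev[2L] else pc$sdev[1L]
  proto <- matrix(ctr, m, ncol(x), byrow = TRUE) +
    2 * sd1 * u %*% t(pc$rotation[, 1L]) +
    2 * sd2 * v %*% t(pc$rotation[, min(2L, ncol(pc$rotation))])
  gd2 <- grid_dist2(rows, cols, toroidal)
  sigma0 <- max(rows, cols) / 2
  sigma_end <- 0.5
  decay <- (sigma_end / sigma0)^(1 / max(1, epochs - 1))
  qe <- numeric(epochs)
  for (e in seq_len(epochs)) {
    sigma <- sigma0 * decay^(e - 1)
    b <- bmu_of(x, proto)
    h <- exp(-gd2 / (2 * sigma^2))        # m x m neighborhood kernel
    w <- h[, b$bmu, drop = FALSE]         # m x n weights
    denom <- rowSums(w)
    proto_new <- (w %*% x) / denom
    nz <- denom > 0
    proto[nz, ] <- proto_new[nz, ]
    qe[e] <- mean(bmu_of(x, proto)$dist)  # error at end of epoch
  }
  structure(list(prototypes = proto, rows = rows, cols = cols,
                 toroidal = toroidal, qe = qe),
            class = "som_codebook")
}

#' @export
print.som_codebook <- function(x, ...) {
  cat("som_codebook:", x$rows, "x", x$cols,
      if (x$toroidal) "toroidal" else "planar", "grid,",
      ncol(x$prototypes), "dims; final QE",
      signif(utils::tail(x$qe, 1), 4), "\n")
  invisible(x)
}

#' Label map neurons from marker contigs and assign query contigs
#'
#' Each neuron is labeled by the majority cluster among marker contigs
#' whose best-matching unit it is (exact ties leave it unlabeled); neurons
#' no marker contig maps to inherit the label of the nearest labeled neuron
#' in prototype space.  A query contig inherits its best-matching unit's
#' cluster iff its distance to that prototype is at most the
#' `distance_percentile` of the labeled contigs' own BMU distances within
#' that cluster; otherwise it stays unassigned, which keeps contigs from
#' genomes absent from every cluster out of the bins.
#'
#' @param codebook `som_codebook`.
#' @param labeled_x TNF matrix of marker (labeled) contigs.
#' @param labels vector of cluster IDs, one per row of `labeled_x`.
#' @param query_x TNF matrix of contigs to assign.
#' @param distance_percentile percentile (0--100) of labeled distances used
#'   as the per-cluster acceptance radius (default 95).
#' @return data.frame `contig_id`, `cluster` (NA = unassigned),
#'   `distance`.
#' @export
label_and_assign <- function(codebook, labeled_x, labels, query_x,
                             distance_percentile = 95) {
  stopifnot(nrow(labeled_x) == length(labels))
  proto <- codebook$prototypes
  lb <- bmu_of(labeled_x, proto)
  neuron_label <- rep(NA_character_, nrow(proto))
  for (j in unique(lb$bmu)) {
    tab <- table(as.character(labels[lb$bmu == j]))
    top <- names(tab)[tab == max(tab)]
    if (length(top) == 1L) neuron_label[j] <- top
  }
  labeled_neurons <- which(!is.na(neuron_label))
  if (length(labeled_neurons) == 0L)
    stop("no neuron could be labeled (all ties)")
  unusable <- setdiff(unique(as.character(labels)), neuron_label)
  if (length(unusable))
    warning("cluster(s) winning no neuron, label unusable: ",
            paste(unusable, collapse = ", "))
  # propagate to unlabeled neurons from nearest labeled prototype
  for (j in which(is.na(neuron_label))) {
    d2 <- rowSums((proto[labeled_neurons, , drop = FALSE] -
                   matrix(proto[j, ], length(labeled_neurons),
                          ncol(proto), byrow = TRUE))^2)
    nearest <- labeled_neurons[d2 == min(d2)]
    lbs <- unique(neuron_label[nearest])
    if (length(lbs) == 1L) neuron_label[j] <- lbs
  }
  # per-cluster acceptance radius from labeled contigs' BMU distances
  radius <- tapply(lb$dist, as.character(labels),
                   stats::quantile, probs = distance_percentile / 100,
                   names = FALSE)
  qb <- bmu_of(query_x, proto)
  cl <- neuron_label[qb$bmu]
  ok <- !is.na(cl) & qb$dist <= radius[cl]
  data.frame(contig_id = rownames(query_x),
             cluster = ifelse(ok, cl, NA_character_),
             distance = qb$dist,
             row.names = NULL)
}
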