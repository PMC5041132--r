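# Iterative targeted reassembly: canonical k-mer read recruitment against a
# growing contig set, greedy overlap reassembly, loop to convergence.

canonical_kmers <- function(seqs, k) {
  out <- lapply(seqs, function(s) {
    n <- nchar(s)
    if (n < k) return(character(0))
    km <- substring(s, seq_len(n - k + 1L), seq_len(n - k + 1L) + k - 1L)
    km[!grepl("[^ACGT]", km)]
  })
  km <- unlist(out, use.names = FALSE)
  if (length(km) == 0L) return(character(0))
  pmin(km, revcomp_chr(km))
}

# canonical k-mers of many (mostly equal-length) sequences, vectorized by
# offset; returns data.table(id, kmer)
seq_kmer_table <- function(seqs, k) {
  n <- nchar(seqs)
  ids <- integer(0)
  kms <- list()
  for (L in unique(n)) {
    if (L < k) next
    ii <- which(n == L)
    nk <- L - k + 1L
    km <- lapply(seq_len(nk), function(j) substr(seqs[ii], j, j + k - 1L))
    ids <- c(ids, rep(ii, times = nk))
    kms[[length(kms) + 1L]] <- unlist(km, use.names = FALSE)
  }
  if (length(ids) == 0L)
    return(data.table::data.table(id = integer(0), kmer = character(0)))
  kmer <- unlist(kms, use.names = FALSE)
  ok <- !grepl("[^ACGT]", kmer)
  dt <- data.table::data.table(id = ids[ok], kmer = kmer[ok])
  dt$kmer <- pmin(dt$kmer, revcomp_chr(dt$kmer))
  dt
}

#' Build a k-mer recruitment index over a contig set
#'
#' @param contigs character vector or [Biostrings::DNAStringSet].
#' @param k odd k-mer size in 15--63 (default 31).
#' @return object of class `recruitment_index`.
#' @export
kmer_index <- function(contigs, k = 31L) {
  if (k %% 2L == 0L || k < 15L || k > 63L)
    stop("k must be odd and within 15..63")
  if (methods::is(contigs, "DNAStringSet")) contigs <- as.character(contigs)
  km <- unique(canonical_kmers(contigs, k))
  dt <- data.table::data.table(kmer = km, key = "kmer")
  structure(list(k = as.integer(k), kmers = dt), class = "recruitment_index")
}

#' Recruit read pairs sharing a k-mer with the index
#'
#' A read is recruited when it shares at least one canonical k-mer with the
#' index; when either mate of a pair is recruited, both are.
#'
#' @param index `recruitment_index`.
#' @param reads list with `r1`, `r2` [Biostrings::DNAStringSet]s (equal
#'   lengths).
#' @return logical vector over pairs (TRUE = recruited).
#' @export
recruit_reads <- function(index, reads) {
  r1 <- as.character(reads$r1)
  r2 <- as.character(reads$r2)
  stopifnot(length(r1) == length(r2))
  if (length(r1) == 0L) return(logical(0))
  k <- index$k
  hit <- function(seqs) {
    dt <- seq_kmer_table(seqs, k)
    if (nrow(dt) == 0L) return(integer(0))
    found <- index$kmers[dt, on = "kmer", nomatch = NULL]
    unique(found$id)
  }
  rec <- logical(length(r1))
  rec[hit(r1)] <- TRUE
  rec[hit(r2)] <- TRUE
  rec
}

# overlap index: every min_overlap-mer of every read orientation, keyed by
# the k-mer, carrying (sequence row, end position within the read)
build_overlap_index <- function(seqs, ov) {
  n <- nchar(seqs)
  rid <- integer(0)
  endpos <- integer(0)
  kms <- list()
  for (L in unique(n)) {
    if (L < ov) next
    ii <- which(n == L)
    nk <- L - ov + 1L
    km <- lapply(seq_len(nk), function(j) substr(seqs[ii], j, j + ov - 1L))
    rid <- c(rid, rep(ii, times = nk))
    endpos <- c(endpos, rep(seq_len(nk) + ov - 1L, each = length(ii)))
    kms[[length(kms) + 1L]] <- unlist(km, use.names = FALSE)
  }
  dt <- data.table::data.table(kmer = unlist(kms, use.names = FALSE),
                               rid = rid, endpos = endpos)
  data.table::setkey(dt, kmer)
  dt
}

# extend the right end of `contig` greedily by maximal unique overlaps;
# detects circularity when the extension re-crosses the contig's 5' end
extend_right <- function(contig, seqs, idx, ov, used) {
  prefix <- substr(contig, 1L, ov)
  repeat {
    n <- nchar(contig)
    suffix <- substr(contig, n - ov + 1L, n)
    cand <- idx[list(suffix), on = "kmer", nomatch = NULL]
    cand <- cand[!used[cand$rid]]
    if (nrow(cand) == 0L) break
    # verify full prefix/suffix agreement and require net extension
    ok <- logical(nrow(cand))
    for (i in seq_len(nrow(cand))) {
      e <- cand$endpos[i]
      r <- seqs[cand$rid[i]]
      ok[i] <- nchar(r) > e && e <= n &&
        substr(r, 1L, e) == substr(contig, n - e + 1L, n)
    }
    cand <- cand[ok]
    if (nrow(cand) == 0L) break
    best <- cand[cand$endpos == max(cand$endpos)]
    ext <- unique(substring(seqs[best$rid], best$endpos + 1L))
    if (length(ext) != 1L) break          # ambiguous: stop (repeat edge)
    contig <- paste0(contig, ext)
    used[best$rid] <- TRUE
    # circular join: the 5'-end ov-mer reappears inside the newly added
    # window; everything from that occurrence on is a second lap
    win_start <- max(2L, n - ov + 2L)
    w <- regexpr(prefix, substr(contig, win_start, nchar(contig)),
                 fixed = TRUE)
    if (w > 0L) {
      join <- win_start + as.integer(w) - 1L
      contig <- substr(contig, 1L, join - 1L)
      return(list(contig = contig, used = used, circular = TRUE))
    }
  }
  list(contig = contig, used = used, circular = FALSE)
}

#' Greedy overlap reassembly of a read set
#'
#' Internal mode: seeds at the highest-multiplicity unused read and extends
#' both contig ends by maximal unique overlaps of at least `min_overlap`
#' (both read orientations considered); ambiguity (two maximal candidates
#' with different extensions) stops the extension.  A contig whose ends
#' overlap by at least `min_overlap` is flagged circular and the duplicated
#' end trimmed.  Reads contained in a finished contig are consumed before
#' the next seed is chosen.  Repeats longer than `min_overlap` are outside
#' this assembler's scope; use the external mode for real data.
#'
#' External mode: runs a user command (templated with `{reads}` and
#' `{out}`, FASTA in/out) and parses its contigs.
#'
#' @param reads character vector or [Biostrings::DNAStringSet].
#' @param mode `"internal"` or `"external"`.
#' @param min_overlap minimum (and seed) overlap length, default 50.
#' @param external_cmd command template for `mode = "external"`.
#' @return list with `contigs` ([Biostrings::DNAStringSet]) and `circular`
#'   (logical per contig; all FALSE for external mode).
#' @export
reassemble <- function(reads, mode = c("internal", "external"),
                       min_overlap = 50L, external_cmd = NULL) {
  mode <- match.arg(mode)
  if (methods::is(reads, "DNAStringSet")) reads <- as.character(reads)
  reads <- unname(reads)
  if (length(reads) == 0L) stop("no reads to assemble")
  if (mode == "external") {
    rf <- tempfile(fileext = ".fasta")
    of <- tempfile(fileext = ".fasta")
    rs <- Biostrings::DNAStringSet(reads)
    names(rs) <- sprintf("read%06d", seq_along(rs))
    Biostrings::writeXStringSet(rs, rf)
    cmd <- gsub("{reads}", rf, gsub("{out}", of, external_cmd,
                                    fixed = TRUE), fixed = TRUE)
    status <- system(cmd)
    if (status != 0L) stop("external assembler exited with status ", status)
    ctg <- Biostrings::readDNAStringSet(of)
    return(list(contigs = ctg, circular = rep(FALSE, length(ctg))))
  }
  ov <- as.integer(min_overlap)
  # multiplicity for coverage-based seeding
  mult <- table(reads)
  uniq <- names(mult)
  seqs <- c(uniq, revcomp_chr(uniq))              # both orientations
  nb <- length(uniq)
  idx <- build_overlap_index(seqs, ov)
  used <- logical(length(seqs))
  mark_used <- function(used, i) {                # both orientations
    j <- if (i > nb) i - nb else i
    used[c(j, j + nb)] <- TRUE
    used
  }
  contigs <- character(0)
  circular <- logical(0)
  ordv <- order(-as.integer(mult))
  for (s in ordv) {
    if (used[s]) next
    contig <- seqs[s]
    used <- mark_used(used, s)
    # extend right, then left (as right end of the reverse complement)
    res <- extend_right(contig, seqs, idx, ov, used)
    for (i in which(res$used & !used)) used <- mark_used(used, i)
    circ <- res$circular
    contig <- res$contig
    if (!circ) {
      contig <- revcomp_chr(contig)
      res <- extend_right(contig, seqs, idx, ov, used)
      for (i in which(res$used & !used)) used <- mark_used(used, i)
      circ <- res$circular
      contig <- revcomp_chr(res$contig)
    }
    # consume reads contained in the contig (either orientation)
    both <- paste0(contig, if (circ) substr(contig, 1L,
                                            max(nchar(seqs))) else "")
    for (w in unique(nchar(uniq))) {
      cand <- which(!used[seq_len(nb)] & nchar(uniq) == w)
      if (length(cand) == 0L || w > nchar(both)) next
      pd <- Biostrings::PDict(c(uniq[cand], revcomp_chr(uniq[cand])))
      cnt <- Biostrings::countPDict(pd, Biostrings::DNAString(both))
      hit <- cand[which(cnt[seq_along(cand)] +
                        cnt[seq_along(cand) + length(cand)] > 0)]
      for (i in hit) used <- mark_used(used, i)
    }
    contigs <- c(contigs, contig)
    circular <- c(circular, circ)
  }
  out <- Biostrings::DNAStringSet(contigs)
  names(out) <- sprintf("reasm_%03d", seq_along(out))
  list(contigs = out, circular = circular)
}

#' Iterative targeted reassembly
#'
#' Starting from seed contigs, repeatedly recruit reads sharing canonical
#' k-mers with the current contig set and reassemble them, rebuilding the
#' index from the new contigs every round.  Stops when the relative change
#' in total assembled length falls below `tol` or after `max_iter` rounds.
#' If a round recruits no reads the seeds are returned unchanged.
#'
#' @param seeds character vector or [Biostrings::DNAStringSet].
#' @param reads list with `r1`, `r2` [Biostrings::DNAStringSet]s.
#' @param k recruitment k-mer size (default 31).
#' @param min_overlap assembler minimum overlap (default 50).
#' @param max_iter maximum rounds (default 10).
#' @param tol relative total-length change below which iteration stops
#'   (default 0.005).
#' @return list with `contigs`, `circular`, and `log` (data.frame
#'   `iteration`, `recruited_reads`, `contigs`, `total_length`, `n50`).
#' @export
iterate_reassembly <- function(seeds, reads, k = 31L, min_overlap = 50L,
                               max_iter = 10L, tol = 0.005) {
  if (methods::is(seeds, "DNAStringSet")) seeds <- as.character(seeds)
  if (length(seeds) == 0L) stop("empty seed set")
  current <- seeds
  circular <- rep(FALSE, length(seeds))
  log_rows <- list()
  prev_len <- sum(nchar(current))
  for (it in seq_len(max_iter)) {
    idx <- kmer_index(current, k)
    rec <- recruit_reads(idx, reads)
    if (!any(rec)) {
      log_rows[[it]] <- data.frame(iteration = it, recruited_reads = 0L,
                                   contigs = length(current),
                                   total_length = prev_len,
                                   n50 = n50(nchar(current)))
      break
    }
    pool <- c(as.character(reads$r1[rec]), as.character(reads$r2[rec]))
    asm <- reassemble(pool, mode = "internal", min_overlap = min_overlap)
    current <- as.character(asm$contigs)
    if (length(current) == 0L)
      stop("assembly collapsed to zero contigs at iteration ", it)
    circular <- asm$circular
    total <- sum(nchar(current))
    log_rows[[it]] <- data.frame(iteration = it,
                                 recruited_reads = 2L * sum(rec),
                                 contigs = length(current),
                                 total_length = total,
                                 n50 = n50(nchar(current)))
    if (abs(total - prev_len) / total < tol) break
    prev_len <- total
  }
  out <- Biostrings::DNAStringSet(current)
  names(out) <- sprintf("bin_%03d", seq_along(out))
  list(contigs = out, circular = circular,
       log = do.call(rbind, log_rows))
}
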