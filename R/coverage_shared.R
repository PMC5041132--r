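# Shared-vs-unique contig partitioning from second-sample coverage.

#' Partition contigs into shared and sample-unique pools
#'
#' A contig is "shared" (also present in the second sample) iff its mean
#' depth and covered fraction in that sample both reach the thresholds
#' (`>=` convention).  Contigs missing from the profile count as zero.
#'
#' @param contig_ids character vector of contigs to partition.
#' @param profile data.frame with `contig_id`, `depth`, `breadth` (mean
#'   depth and fraction of positions covered in the second sample).
#' @param min_depth minimum mean depth (default 1.0).
#' @param min_fraction minimum covered fraction (default 0.5).
#' @return list with `shared`, `unique` (character vectors) and
#'   `thresholds`.
#' @export
identify_shared <- function(contig_ids, profile, min_depth = 1.0,
                            min_fraction = 0.5) {
  if (min_depth < 0 || min_fraction < 0) stop("negative threshold")
  i <- match(contig_ids, profile$contig_id)
  depth <- ifelse(is.na(i), 0, profile$depth[i])
  breadth <- ifelse(is.na(i), 0, profile$breadth[i])
  shared <- depth >= min_depth & breadth >= min_fraction
  list(shared = contig_ids[shared], unique = contig_ids[!shared],
       thresholds = c(min_depth = min_depth, min_fraction = min_fraction))
}

cigar_ref_span <- function(cigar) {
  ops <- gregexpr("\\d+[MIDNSHP=X]", cigar)
  vapply(regmatches(cigar, ops), function(x) {
    op <- substring(x, nchar(x))
    len <- as.integer(substring(x, 1L, nchar(x) - 1L))
    sum(len[op %in% c("M", "D", "N", "=", "X")])
  }, 0L)
}

#' Compute per-contig depth and breadth from a SAM alignment
#'
#' Parses SAM text directly (header lines skipped); only primary, mapped
#' alignments contribute (secondary 0x100 and supplementary 0x800 records
#' are ignored to avoid repeat-driven false sharing).  Reference spans come
#' from the CIGAR string; depth is aligned bases over contig length and
#' breadth the fraction of positions covered at least once.
#'
#' @param sam_path SAM file.
#' @param contig_lengths named integer vector (all contigs of the assembly;
#'   contigs without reads get depth and breadth 0).
#' @return data.frame `contig_id`, `depth`, `breadth`.
#' @export
coverage_from_alignment <- function(sam_path, contig_lengths) {
  lines <- readLines(sam_path)
  lines <- lines[!startsWith(lines, "@")]
  out <- data.frame(contig_id = names(contig_lengths), depth = 0,
                    breadth = 0)
  if (length(lines) == 0L) return(out)
  f <- strsplit(lines, "\t")
  flag <- as.integer(vapply(f, `[`, "", 2L))
  rname <- vapply(f, `[`, "", 3L)
  pos <- as.integer(vapply(f, `[`, "", 4L))
  cigar <- vapply(f, `[`, "", 6L)
  keep <- bitwAnd(flag, 0x4L) == 0L & bitwAnd(flag, 0x100L) == 0L &
          bitwAnd(flag, 0x800L) == 0L & rname != "*"
  f <- f[keep]; rname <- rname[keep]; pos <- pos[keep]; cigar <- cigar[keep]
  if (any(!rname %in% names(contig_lengths)))
    stop("alignment references contig absent from assembly: ",
         paste(unique(setdiff(rname, names(contig_lengths))), collapse = ", "))
  span <- cigar_ref_span(cigar)
  for (cid in unique(rname)) {
    sel <- rname == cid
    ir <- IRanges::IRanges(start = pos[sel], width = span[sel])
    cov <- IRanges::coverage(ir, width = contig_lengths[[cid]])
    j <- out$contig_id == cid
    out$depth[j] <- sum(as.numeric(S4Vectors::runValue(cov)) *
                        S4Vectors::runLength(cov)) / contig_lengths[[cid]]
    out$breadth[j] <- sum(S4Vectors::runLength(cov)[
                          S4Vectors::runValue(cov) > 0]) /
                      contig_lengths[[cid]]
  }
  out
}
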