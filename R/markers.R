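# Single-copy marker detection and bin completeness/redundancy scoring.

#' Detect single-copy markers per contig
#'
#' Each ORF contributes at most one marker: its best-scoring hit among
#' markers in the set that pass the cutoff (per-marker score cutoff from the
#' set when given, otherwise the e-value cutoff).  ORF hits are then
#' aggregated to a per-contig marker multiset.
#'
#' @param marker_hits data.frame `orf_id`, `marker_id`, `evalue`, `score`
#'   (from [read_marker_hits()] or the simulator).
#' @param marker_set character vector of accessions, or data.frame
#'   `marker_id`, `cutoff` from [read_marker_set()].
#' @param orf_map data.frame `orf_id`, `contig_id`.
#' @param max_evalue e-value cutoff applied when a marker has no explicit
#'   score cutoff (default 1e-10).
#' @return data.frame `contig_id`, `marker_id`, `count`.
#' @export
detect_markers <- function(marker_hits, marker_set, orf_map,
                           max_evalue = 1e-10) {
  if (is.data.frame(marker_set)) {
    cutoffs <- stats::setNames(marker_set$cutoff, marker_set$marker_id)
    accs <- marker_set$marker_id
  } else {
    accs <- marker_set
    cutoffs <- stats::setNames(rep(NA_real_, length(accs)), accs)
  }
  unknown <- !marker_hits$marker_id %in% accs
  if (any(unknown)) {
    warning("skipping ", sum(unknown),
            " hit(s) to markers absent from the set")
    marker_hits <- marker_hits[!unknown, , drop = FALSE]
  }
  co <- cutoffs[marker_hits$marker_id]
  pass <- ifelse(is.na(co), marker_hits$evalue <= max_evalue,
                 marker_hits$score >= co)
  marker_hits <- marker_hits[pass, , drop = FALSE]
  if (nrow(marker_hits) == 0L)
    return(data.frame(contig_id = character(0), marker_id = character(0),
                      count = integer(0)))
  # best-scoring marker per ORF
  ord <- order(marker_hits$orf_id, -marker_hits$score)
  marker_hits <- marker_hits[ord, , drop = FALSE]
  best <- marker_hits[!duplicated(marker_hits$orf_id), , drop = FALSE]
  best$contig_id <- orf_map$contig_id[match(best$orf_id, orf_map$orf_id)]
  agg <- stats::aggregate(list(count = best$orf_id),
                          by = list(contig_id = best$contig_id,
                                    marker_id = best$marker_id),
                          FUN = length)
  agg[order(agg$contig_id, agg$marker_id), ]
}

#' Build a bin's marker profile
#'
#' @param contig_markers data.frame from [detect_markers()].
#' @param contig_ids contigs belonging to the bin.
#' @return named integer vector marker -> occurrence count.
#' @export
bin_marker_profile <- function(contig_markers, contig_ids) {
  sel <- contig_markers[contig_markers$contig_id %in% contig_ids, ,
                        drop = FALSE]
  if (nrow(sel) == 0L) return(stats::setNames(integer(0), character(0)))
  tapply(sel$count, sel$marker_id, sum)
}

#' Bin completeness from single-copy markers
#'
#' 100 x (distinct markers present at least once) / (size of the marker
#' set), reported to one decimal.
#'
#' @param profile named counts (marker -> occurrences), as from
#'   [bin_marker_profile()].
#' @param marker_set character vector of accessions (or data.frame with a
#'   `marker_id` column).
#' @return percentage, rounded to 1 decimal.
#' @export
completeness <- function(profile, marker_set) {
  if (is.data.frame(marker_set)) marker_set <- marker_set$marker_id
  if (length(marker_set) == 0L) stop("empty marker set")
  present <- names(profile)[profile >= 1L]
  round(100 * length(unique(intersect(present, marker_set))) /
          length(unique(marker_set)), 1)
}

#' Duplicated-marker count (bin redundancy)
#'
#' Number of distinct markers occurring two or more times in the profile.
#'
#' @param profile named counts (marker -> occurrences).
#' @return integer.
#' @export
redundancy <- function(profile) {
  if (length(profile) == 0L) return(0L)
  sum(profile >= 2L)
}
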