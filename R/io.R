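# Readers/writers for the pipeline's file surfaces.  Standard formats go
# through Biostrings / rtracklayer; tabular surfaces are plain TSV.

#' Write ORF calls as GFF3
#'
#' @param orfs data.frame with `orf_id`, `contig_id`, `start`, `end`,
#'   `strand` (1-based inclusive coordinates).
#' @param path output file.
#' @export
write_orf_gff <- function(orfs, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = orfs$contig_id,
    ranges = IRanges::IRanges(start = orfs$start, end = orfs$end),
    strand = orfs$strand)
  S4Vectors::mcols(gr)$type <- "CDS"
  S4Vectors::mcols(gr)$source <- "darkbin"
  S4Vectors::mcols(gr)$phase <- 0L
  S4Vectors::mcols(gr)$ID <- orfs$orf_id
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read ORF calls from GFF3
#'
#' ORF IDs are taken from the `ID` attribute.
#'
#' @param path GFF3 file.
#' @return data.frame `orf_id`, `contig_id`, `start`, `end`, `strand`,
#'   `length`.
#' @export
read_orf_gff <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  data.frame(orf_id = as.character(S4Vectors::mcols(gr)$ID),
             contig_id = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr),
             end = GenomicRanges::end(gr),
             strand = as.character(GenomicRanges::strand(gr)),
             length = GenomicRanges::width(gr))
}

#' Read an outfmt-6-like homology hit table
#'
#' Expects a header line with at least `orf_id` (or `qseqid`), `taxid` (or
#' `staxid`), `bitscore`, and optionally `pident`, `evalue`.
#'
#' @param path TSV file.
#' @return data.frame with normalized column names.
#' @export
read_hits <- function(path) {
  df <- utils::read.delim(path)
  nm <- names(df)
  nm[nm == "qseqid"] <- "orf_id"
  nm[nm == "staxid"] <- "taxid"
  names(df) <- nm
  stopifnot(all(c("orf_id", "taxid", "bitscore") %in% names(df)))
  df$taxid <- as.character(df$taxid)
  df
}

#' Read a simple coverage TSV
#'
#' @param path TSV with header; first column contig IDs, remaining columns
#'   numeric (e.g. `coverage`, or `depth` and `breadth`).
#' @return data.frame.
#' @export
read_coverage <- function(path) {
  utils::read.delim(path)
}

#' Read a HMMER domtblout marker hit table
#'
#' Parses the whitespace-delimited per-domain table (`--domtblout`),
#' skipping `#` comment lines.  Maps target name -> `marker_id`, query
#' name -> `orf_id`, full-sequence E-value and score.
#'
#' @param path domtblout file.
#' @return data.frame `orf_id`, `marker_id`, `evalue`, `score`.
#' @export
read_domtblout <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  if (length(lines) == 0L)
    return(data.frame(orf_id = character(0), marker_id = character(0),
                      evalue = numeric(0), score = numeric(0)))
  f <- strsplit(trimws(lines), "[ \t]+")
  data.frame(orf_id = vapply(f, `[`, "", 4L),
             marker_id = vapply(f, `[`, "", 1L),
             evalue = as.numeric(vapply(f, `[`, "", 7L)),
             score = as.numeric(vapply(f, `[`, "", 8L)))
}

#' Read a marker hit table (TSV or domtblout)
#'
#' TSV files must have a header with `orf_id`, `marker_id`, `evalue`,
#' `score`; anything starting with `#` is treated as domtblout.
#'
#' @param path file path.
#' @return data.frame `orf_id`, `marker_id`, `evalue`, `score`.
#' @export
read_marker_hits <- function(path) {
  first <- readLines(path, n = 1L)
  if (startsWith(first, "#") || !grepl("orf_id", first))
    return(read_domtblout(path))
  utils::read.delim(path)
}

#' Read a marker set file
#'
#' One accession per line; an optional tab-separated second column gives a
#' per-marker score cutoff.
#'
#' @param path file path.
#' @param default_cutoff used for markers without an explicit cutoff
#'   (interpreted as a minimum score; `NA` disables score cutoffs).
#' @return data.frame `marker_id`, `cutoff`.
#' @export
read_marker_set <- function(path, default_cutoff = NA_real_) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  f <- strsplit(lines, "\t")
  data.frame(marker_id = vapply(f, `[`, "", 1L),
             cutoff = vapply(f, function(x)
               if (length(x) > 1L) as.numeric(x[2L]) else default_cutoff,
               0))
}

#' Write paired reads as FASTQ
#'
#' @param reads list with `r1`, `r2` [Biostrings::DNAStringSet]s (as from
#'   [simulate_reads()]).
#' @param prefix output prefix; writes `<prefix>_1.fastq`,
#'   `<prefix>_2.fastq`.
#' @return the two paths, invisibly.
#' @export
write_fastq_pair <- function(reads, prefix) {
  paths <- paste0(prefix, c("_1.fastq", "_2.fastq"))
  for (i in 1:2) {
    x <- reads[[i]]
    q <- Biostrings::BStringSet(vapply(Biostrings::width(x), function(w)
      strrep("I", w), ""))
    Biostrings::writeXStringSet(x, paths[i], format = "fastq", qualities = q)
  }
  invisible(paths)
}

#' Read paired FASTQ files
#'
#' @param path1,path2 FASTQ files for /1 and /2 mates.
#' @return list with `r1`, `r2` [Biostrings::DNAStringSet]s.
#' @export
read_fastq_pair <- function(path1, path2) {
  list(r1 = Biostrings::readDNAStringSet(path1, format = "fastq"),
       r2 = Biostrings::readDNAStringSet(path2, format = "fastq"))
}
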