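# Assembly statistics, per-bin summary reports, and the staged pipeline
# orchestrator (classify -> filter -> shared -> markers -> GMM -> SOM ->
# report).

#' N50 of a set of contig lengths
#'
#' The smallest length L such that contigs of length >= L together contain
#' at least half the total bases.  Returned in the units of the input.
#'
#' @param lengths numeric vector (nonempty).
#' @return single numeric.
#' @examples
#' n50(c(10, 20, 30, 40))   # 30
#' @export
n50 <- function(lengths) {
  if (length(lengths) == 0L) stop("empty length list")
  s <- sort(lengths, decreasing = TRUE)
  s[which(cumsum(s) >= sum(s) / 2)[1L]]
}

#' Summarize one genome bin
#'
#' Size, N50 and longest contig follow assembly-table conventions (Mbp to 3
#' decimals, kbp to 1); coverage and GC% are length-weighted means;
#' completeness and duplicated markers come from the bin's single-copy
#' marker profile.
#'
#' @param bin_id label.
#' @param contig_ids contigs in the bin (nonempty).
#' @param contigs [Biostrings::DNAStringSet] holding at least those
#'   contigs.
#' @param coverage data.frame `contig_id`, `coverage`.
#' @param contig_markers data.frame from [detect_markers()].
#' @param marker_set character vector of marker accessions.
#' @return one-row data.frame: `bin_id`, `contigs`, `size_mbp`, `n50_kbp`,
#'   `longest_kbp`, `coverage`, `gc_pct`, `completeness`,
#'   `duplicated_markers`.
#' @export
bin_summary <- function(bin_id, contig_ids, contigs, coverage,
                        contig_markers, marker_set) {
  if (length(contig_ids) == 0L) stop("empty bin")
  sel <- contigs[contig_ids]
  lens <- Biostrings::width(sel)
  cov <- coverage$coverage[match(contig_ids, coverage$contig_id)]
  if (anyNA(cov)) stop("missing coverage for contig(s) in bin ", bin_id)
  fr <- Biostrings::letterFrequency(sel, letters = c("G", "C"))
  gc <- rowSums(fr) / lens
  profile <- bin_marker_profile(contig_markers, contig_ids)
  data.frame(bin_id = bin_id,
             contigs = length(contig_ids),
             size_mbp = round(sum(lens) / 1e6, 3),
             n50_kbp = round(n50(lens) / 1000, 1),
             longest_kbp = round(max(lens) / 1000, 1),
             coverage = round(sum(cov * lens) / sum(lens), 1),
             gc_pct = round(100 * sum(gc * lens) / sum(lens), 1),
             completeness = completeness(profile, marker_set),
             duplicated_markers = redundancy(profile))
}

#' Default pipeline parameters
#'
#' @param window LCA bitscore window (fraction of best).
#' @param max_evalue homology-hit e-value pre-filter.
#' @param keep_archaea retain Archaea at the kingdom filter.
#' @param min_depth,min_fraction shared-pool coverage thresholds.
#' @param marker_evalue marker-hit e-value cutoff.
#' @param k_range candidate mixture component counts.
#' @param min_posterior mixture assignment threshold.
#' @param som_min_length minimum contig length for composition vectors.
#' @param som_epochs SOM training epochs.
#' @param distance_percentile SOM acceptance-radius percentile.
#' @param log_coverage log10-transform coverage features.
#' @return named list.
#' @export
pipeline_params <- function(window = 0.1, max_evalue = 1e-5,
                            keep_archaea = FALSE, min_depth = 1.0,
                            min_fraction = 0.5, marker_evalue = 1e-10,
                            k_range = 1:12, min_posterior = 0.5,
                            som_min_length = 3000L, som_epochs = 40L,
                            distance_percentile = 95,
                            log_coverage = TRUE) {
  list(window = window, max_evalue = max_evalue,
       keep_archaea = keep_archaea, min_depth = min_depth,
       min_fraction = min_fraction, marker_evalue = marker_evalue,
       k_range = k_range, min_posterior = min_posterior,
       som_min_length = som_min_length, som_epochs = som_epochs,
       distance_percentile = distance_percentile,
       log_coverage = log_coverage)
}

#' Load pipeline inputs from files
#'
#' @param paths named list/character vector with entries `contigs` (FASTA),
#'   `coverage` (TSV `contig_id`, `coverage`), `coverage_b` (TSV
#'   `contig_id`, `depth`, `breadth`), `orfs` (GFF3), `hits` (TSV),
#'   `marker_hits` (TSV or domtblout), `marker_set` (text), `taxonomy`
#'   (TSV; omit to use the packaged toy taxonomy).
#' @return input list as consumed by [run_pipeline()].
#' @export
load_pipeline_inputs <- function(paths) {
  tree <- if (!is.null(paths$taxonomy)) read_taxonomy(paths$taxonomy)
          else toy_taxonomy()
  list(contigs = Biostrings::readDNAStringSet(paths$contigs),
       coverage = read_coverage(paths$coverage),
       coverage_b = read_coverage(paths$coverage_b),
       orfs = read_orf_gff(paths$orfs),
       hits = read_hits(paths$hits),
       marker_hits = read_marker_hits(paths$marker_hits),
       marker_set = read_marker_set(paths$marker_set)$marker_id,
       tree = tree)
}

#' Run the staged deconvolution pipeline
#'
#' Stages run in order: `classify` (windowed-LCA ORF classification, contig
#' majority vote, kingdom filter), `shared` (second-sample coverage
#' partition), `markers` (single-copy marker detection), `gmm` (GC/coverage
#' mixture binning of marker contigs), `som` (composition-based assignment
#' of the remaining contigs), `report` (per-bin summaries and the contig
#' disposition ledger).  Every contig receives exactly one final
#' disposition: `removed`, `shared`, `binned` or `unassigned`.
#'
#' @param input a `synthetic_community` (from [simulate_community()]), the
#'   list returned by [load_pipeline_inputs()], or a named list of file
#'   paths (forwarded to [load_pipeline_inputs()]).
#' @param params list from [pipeline_params()].
#' @param stages character vector of stages to run (prefix order is
#'   enforced; later stages require earlier ones).
#' @param seed integer seed controlling the mixture fit and SOM training.
#' @return object of class `darkbin_pipeline`.
#' @export
run_pipeline <- function(input, params = pipeline_params(),
                         stages = c("classify", "shared", "markers",
                                    "gmm", "som", "report"),
                         seed = 1L) {
  all_stages <- c("classify", "shared", "markers", "gmm", "som", "report")
  stopifnot(all(stages %in% all_stages))
  stages <- all_stages[all_stages %in% stages]
  if (!identical(stages, all_stages[seq_along(stages)]))
    stop("stages must form a prefix of: ",
         paste(all_stages, collapse = ", "))
  if (inherits(input, "synthetic_community")) {
    input <- list(contigs = input$contigs, coverage = input$coverage,
                  coverage_b = input$coverage_b, orfs = input$orfs,
                  hits = input$hits, marker_hits = input$markers,
                  marker_set = input$marker_set, tree = toy_taxonomy())
  } else if (!is.null(input$contigs) && is.character(input$contigs)) {
    input <- load_pipeline_inputs(input)
  }
  tree <- input$tree
  contigs <- input$contigs
  res <- list(params = params, seed = seed, stages = stages)
  log <- list()
  run_stage <- function(s) s %in% stages

  ## classify
  orf_map <- input$orfs[, c("orf_id", "contig_id")]
  orf_classes <- classify_orfs(input$hits, tree, window = params$window,
                               max_evalue = params$max_evalue)
  # contigs with no ORF rows still need a classification record
  no_orf <- setdiff(names(contigs), orf_map$contig_id)
  contig_classes <- classify_contigs(orf_classes, orf_map, tree)
  if (length(no_orf))
    contig_classes <- rbind(contig_classes, data.frame(
      contig_id = no_orf, taxon = NA_character_, kingdom = NA_character_,
      rank = NA_character_, n_orfs = 0L, n_classified = 0L))
  filt <- kingdom_filter(contig_classes, tree,
                         keep_archaea = params$keep_archaea)
  res$contig_classes <- contig_classes
  res$removed <- filt$removed
  res$bacterial <- filt$kept
  log$classify <- c(contigs = length(contigs),
                    bacterial = length(filt$kept),
                    removed = nrow(filt$removed))
  if (!run_stage("shared")) return(finish_pipeline(res, contigs, log))

  ## shared
  part <- identify_shared(res$bacterial, input$coverage_b,
                          min_depth = params$min_depth,
                          min_fraction = params$min_fraction)
  res$shared <- part$shared
  res$unique_pool <- part$unique
  log$shared <- c(shared = length(part$shared),
                  unique = length(part$unique))
  if (!run_stage("markers")) return(finish_pipeline(res, contigs, log))

  ## markers
  cm <- detect_markers(input$marker_hits, input$marker_set, orf_map,
                       max_evalue = params$marker_evalue)
  res$contig_markers <- cm
  res$marker_set <- input$marker_set
  marker_contigs <- intersect(unique(cm$contig_id), res$unique_pool)
  log$markers <- c(marker_contigs = length(marker_contigs))
  if (!run_stage("gmm")) return(finish_pipeline(res, contigs, log))

  ## gmm on marker-containing unique contigs
  feats <- build_features(contigs[marker_contigs], input$coverage,
                          log_coverage = params$log_coverage)
  k_range <- params$k_range[params$k_range <=
                            floor(length(marker_contigs) / 2)]
  fit <- fit_mixture(feats, k_range = k_range, seed = seed)
  gmm_assign <- assign_clusters(fit, min_posterior = params$min_posterior)
  res$features <- feats
  res$fit <- fit
  res$gmm_assign <- gmm_assign
  log$gmm <- c(k = fit$k,
               assigned = sum(!is.na(gmm_assign$cluster)))
  if (!run_stage("som")) return(finish_pipeline(res, contigs, log))

  ## som: assign remaining unique-pool contigs by composition
  pool_tnf <- tnf(contigs[res$unique_pool],
                  min_length = params$som_min_length)
  labeled_ids <- gmm_assign$contig_id[!is.na(gmm_assign$cluster)]
  labeled_ids <- intersect(labeled_ids, rownames(pool_tnf))
  query_ids <- setdiff(rownames(pool_tnf), labeled_ids)
  som_assign <- data.frame(contig_id = character(0),
                           cluster = character(0), distance = numeric(0))
  codebook <- NULL
  if (length(labeled_ids) >= 2L && length(query_ids) > 0L &&
      nrow(pool_tnf) >= 10L) {
    codebook <- train_som(pool_tnf, epochs = params$som_epochs,
                          seed = seed)
    labels <- gmm_assign$cluster[match(labeled_ids, gmm_assign$contig_id)]
    som_assign <- label_and_assign(
      codebook, pool_tnf[labeled_ids, , drop = FALSE], labels,
      pool_tnf[query_ids, , drop = FALSE],
      distance_percentile = params$distance_percentile)
  }
  res$codebook <- codebook
  res$som_assign <- som_assign
  log$som <- c(queries = length(query_ids),
               assigned = sum(!is.na(som_assign$cluster)))

  ## membership with provenance
  som_hit <- som_assign[!is.na(som_assign$cluster), , drop = FALSE]
  membership <- rbind(
    data.frame(contig_id = labeled_ids,
               cluster = as.character(gmm_assign$cluster[
                 match(labeled_ids, gmm_assign$contig_id)]),
               provenance = rep("gmm", length(labeled_ids))),
    data.frame(contig_id = som_hit$contig_id,
               cluster = som_hit$cluster,
               provenance = rep("som", nrow(som_hit))))
  res$membership <- membership
  res$log <- log
  if (!run_stage("report")) return(finish_pipeline(res, contigs, log))

  ## report
  bins <- lapply(sort(unique(membership$cluster)), function(cl) {
    ids <- membership$contig_id[membership$cluster == cl]
    bin_summary(paste0("bin_", cl), ids, contigs, input$coverage,
                cm, input$marker_set)
  })
  res$report <- do.call(rbind, bins)
  finish_pipeline(res, contigs, log)
}

# attach the disposition ledger and class
finish_pipeline <- function(res, contigs, log) {
  ids <- names(contigs)
  disp <- rep("unassigned", length(ids))
  names(disp) <- ids
  if (!is.null(res$removed)) disp[res$removed$contig_id] <- "removed"
  if (!is.null(res$shared)) disp[res$shared] <- "shared"
  if (!is.null(res$membership)) disp[res$membership$contig_id] <- "binned"
  res$disposition <- data.frame(contig_id = ids, disposition = unname(disp))
  res$log <- log
  structure(res, class = "darkbin_pipeline")
}

#' @export
print.darkbin_pipeline <- function(x, ...) {
  cat("darkbin_pipeline (seed", x$seed, ")\n")
  tab <- table(x$disposition$disposition)
  cat("dispositions:",
      paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  if (!is.null(x$report)) {
    cat("bins:\n")
    print(x$report, row.names = FALSE)
  }
  invisible(x)
}

#' Write pipeline outputs
#'
#' Emits `report.tsv`, `report.json`, `disposition.tsv` and a per-stage
#' `run_log.txt` under `dir`.
#'
#' @param pipeline `darkbin_pipeline`.
#' @param dir output directory.
#' @export
write_report <- function(pipeline, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(pipeline$report))
    utils::write.table(pipeline$report, file.path(dir, "report.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(pipeline$disposition,
                     file.path(dir, "disposition.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(seed = pipeline$seed, log = pipeline$log,
                            report = pipeline$report),
                       file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  writeLines(vapply(names(pipeline$log), function(s)
    paste0(s, ": ", paste(names(pipeline$log[[s]]), pipeline$log[[s]],
                          sep = "=", collapse = " ")), ""),
    file.path(dir, "run_log.txt"))
  invisible(dir)
}
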