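# GC/coverage feature construction and Gaussian mixture binning with BIC
# model selection.  The mixture machinery is mclust; this module owns the
# feature transform, the k-range scan surface and posterior-threshold
# assignment.

#' Build the (GC%, coverage) feature matrix
#'
#' Features are GC on the 0--100 scale and log10 coverage (the log
#' transform can be disabled), each standardized to zero mean and unit
#' variance.  Standardization parameters are retained so features are
#' invertible.
#'
#' @param contigs a named [Biostrings::DNAStringSet] (GC computed from
#'   sequence) or a data.frame with `contig_id` and `gc` (fraction in
#'   `[0,1]`).
#' @param coverage data.frame `contig_id`, `coverage`; all strictly
#'   positive.
#' @param log_coverage log10-transform coverage before standardizing
#'   (default TRUE).
#' @return object of class `darkbin_features`: list with `x` (matrix,
#'   rownames = contig IDs, columns `gc`, `cov`), `center`, `scale`,
#'   `log_coverage`.
#' @export
build_features <- function(contigs, coverage, log_coverage = TRUE) {
  if (methods::is(contigs, "DNAStringSet")) {
    fr <- Biostrings::letterFrequency(contigs, letters = c("G", "C"))
    gc <- 100 * rowSums(fr) / Biostrings::width(contigs)
    ids <- names(contigs)
  } else {
    gc <- 100 * contigs$gc
    ids <- contigs$contig_id
  }
  cov <- coverage$coverage[match(ids, coverage$contig_id)]
  if (anyNA(cov)) stop("missing coverage for contig(s)")
  if (any(cov <= 0)) stop("coverage must be > 0 for all contigs")
  if (length(ids) < 2L) stop("need at least two contigs to standardize")
  cv <- if (log_coverage) log10(cov) else cov
  x <- cbind(gc = gc, cov = cv)
  rownames(x) <- ids
  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  if (any(scl == 0)) scl[scl == 0] <- 1
  x <- scale(x, center = ctr, scale = scl)
  attr(x, "scaled:center") <- NULL
  attr(x, "scaled:scale") <- NULL
  structure(list(x = x, center = ctr, scale = scl,
                 log_coverage = log_coverage),
            class = "darkbin_features")
}

#' Fit Gaussian mixtures over a range of component counts
#'
#' For every k in `k_range` a full-covariance Gaussian mixture is fitted by
#' EM (via mclust, hierarchical-agglomeration initialization) and the model
#' minimizing BIC is selected.  Covariances are unconstrained (`"VVV"`) by
#' default because GC/coverage clusters are typically elongated; spherical
#' or diagonal families tend to shave elongated clouds into spurious extra
#' components at small n.  k values where EM degenerates are skipped (NA in
#' the BIC table) with a warning.
#'
#' @param features `darkbin_features` from [build_features()], or a bare
#'   numeric matrix.
#' @param k_range candidate component counts (default 1:15).
#' @param seed integer seed (EM initialization is deterministic but seeded
#'   for contract clarity).
#' @param model_names mclust covariance parameterizations to consider
#'   (default `"VVV"`; pass `NULL` for mclust's full model family).
#' @return object of class `darkbin_mixturefit`: `k`, `weights`, `means`
#'   (d x k), `covariances` (d x d x k), `responsibilities` (n x k),
#'   `bic_table` (conventional minimize-form BIC per k), `model_name`, and
#'   the underlying `mclust` fit.
#' @importFrom mclust Mclust mclustBIC
#' @export
fit_mixture <- function(features, k_range = 1:15, seed = 1L,
                        model_names = "VVV") {
  x <- if (inherits(features, "darkbin_features")) features$x else features
  if (nrow(x) < 2L * max(k_range))
    stop("need at least 2*max(k_range) observations")
  set.seed(seed)
  fit <- Mclust(x, G = k_range, modelNames = model_names, verbose = FALSE)
  if (is.null(fit)) stop("mixture fitting failed for all k")
  bic_mat <- -fit$BIC                     # mclust maximizes; flip sign
  bic_per_k <- apply(bic_mat, 1, function(r)
    if (all(is.na(r))) NA_real_ else min(r, na.rm = TRUE))
  if (anyNA(bic_per_k))
    warning("EM degenerate for k = ",
            paste(k_range[is.na(bic_per_k)], collapse = ", "),
            "; skipped")
  z <- fit$z
  if (is.null(z)) z <- matrix(1, nrow(x), 1L)
  rownames(z) <- rownames(x)
  structure(list(k = fit$G,
                 weights = fit$parameters$pro,
                 means = fit$parameters$mean,
                 covariances = fit$parameters$variance$sigma,
                 responsibilities = z,
                 bic_table = stats::setNames(bic_per_k, k_range),
                 model_name = fit$modelName,
                 loglik = fit$loglik,
                 mclust = fit),
            class = "darkbin_mixturefit")
}

#' @export
print.darkbin_mixturefit <- function(x, ...) {
  cat("darkbin_mixturefit: k =", x$k, "(", x$model_name, "),",
      nrow(x$responsibilities), "contigs\n")
  invisible(x)
}

#' Assign contigs to mixture components by posterior responsibility
#'
#' A contig joins its argmax-responsibility component iff that
#' responsibility reaches `min_posterior`; otherwise it stays unassigned.
#' Exact posterior ties break to the lowest component index.
#'
#' @param fit `darkbin_mixturefit`.
#' @param min_posterior threshold in `[0, 1]` (default 0.5).
#' @return data.frame `contig_id`, `cluster` (integer or NA), `posterior`.
#' @export
assign_clusters <- function(fit, min_posterior = 0.5) {
  z <- fit$responsibilities
  best <- apply(z, 1, which.max)          # first index on ties
  post <- z[cbind(seq_len(nrow(z)), best)]
  data.frame(contig_id = rownames(z),
             cluster = ifelse(post >= min_posterior, best, NA_integer_),
             posterior = post,
             row.names = NULL)
}

#' Export a mixture fit summary as JSON
#'
#' @param fit `darkbin_mixturefit`.
#' @param path output file.
#' @export
write_mixture_json <- function(fit, path) {
  jsonlite::write_json(list(k = fit$k, model = fit$model_name,
                            weights = fit$weights,
                            means = fit$means,
                            bic = as.list(fit$bic_table)),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
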