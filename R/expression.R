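# RPKMO expression normalization: reads per kilobase of gene per million
# reads aligning to annotated ORFs in a given genome bin.  Normalizing to
# ORF-aligned reads (rather than the whole library) removes both
# between-gene length effects and the influence of rRNA coverage.

#' Per-gene RPKMO
#'
#' `RPKMO_g = c_g / ((L_g / 1000) * (T / 1e6))` with `T` the total read
#' count over the bin's annotated ORFs.
#'
#' @param genes data.frame with `gene_id`, `count`, `length` and optionally
#'   `category` (missing/NA categories become `"unassigned"`).
#' @return data.frame `gene_id`, `count`, `length`, `category`, `rpkmo`.
#' @export
rpkmo <- function(genes) {
  stopifnot(all(c("gene_id", "count", "length") %in% names(genes)),
            all(genes$count >= 0), all(genes$length > 0))
  total <- sum(genes$count)
  if (total == 0) stop("no reads aligned to the bin's ORFs (T = 0)")
  category <- if ("category" %in% names(genes)) genes$category
              else rep(NA_character_, nrow(genes))
  category[is.na(category) | category == ""] <- "unassigned"
  data.frame(gene_id = genes$gene_id, count = genes$count,
             length = genes$length, category = category,
             rpkmo = genes$count / ((genes$length / 1000) * (total / 1e6)))
}

#' RPKMO share per functional category
#'
#' `share(cat) = sum of RPKMO over genes in cat / total RPKMO`; shares over
#' all categories (including `"unassigned"`) sum to one.
#'
#' @param table data.frame from [rpkmo()].
#' @return data.frame `category`, `share`, sorted by decreasing share.
#' @export
rpkmo_share <- function(table) {
  stopifnot(nrow(table) > 0)
  total <- sum(table$rpkmo)
  if (total == 0) stop("all RPKMO values are zero")
  s <- tapply(table$rpkmo, table$category, sum) / total
  out <- data.frame(category = names(s), share = as.numeric(s),
                    row.names = NULL)
  out[order(-out$share), ]
}

#' Annotation summary for a bin
#'
#' @param ledger data.frame listing every predicted protein-coding gene of
#'   the bin with a logical `annotated` column (or the counts directly via
#'   `annotated`/`total` arguments).
#' @param bin_id label for the output.
#' @return data.frame `bin_id`, `total_genes`, `annotated_genes`,
#'   `annotated_pct` (one decimal).
#' @export
annotation_summary <- function(ledger, bin_id = "bin") {
  if (nrow(ledger) == 0L) stop("empty gene ledger")
  stopifnot("annotated" %in% names(ledger))
  total <- nrow(ledger)
  ann <- sum(ledger$annotated)
  data.frame(bin_id = bin_id, total_genes = total, annotated_genes = ann,
             annotated_pct = round(100 * ann / total, 1))
}
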