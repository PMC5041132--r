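# Taxonomic novelty calls from 16S rRNA identity to the closest reference,
# using fixed per-rank minimum-identity cutoffs.

#' Default 16S identity cutoffs per rank
#'
#' Minimum percent identity for a sequence to be assignable at each rank:
#' species 98.7, genus 94.5, family 86.5, order 82.0, class 78.5, phylum
#' 75.0 (Yarza-style thresholds; strictly decreasing down the ranks).
#'
#' @return named numeric vector, deepest rank first.
#' @export
default_rank_cutoffs <- function() {
  c(species = 98.7, genus = 94.5, family = 86.5, order = 82.0,
    class = 78.5, phylum = 75.0)
}

#' Call novelty rank from a 16S identity
#'
#' The deepest rank whose cutoff is at or below the identity is assignable
#' (`>=` convention: identity exactly at a cutoff assigns that rank); the
#' implied novelty is the rank immediately below the assignable one.
#' Identity below the phylum cutoff is novel at the phylum level or above.
#'
#' @param identity_pct percent identity in `[0, 100]`; vectorized.
#' @param cutoffs named vector as from [default_rank_cutoffs()]; must be
#'   strictly decreasing.
#' @return data.frame `identity`, `assignable_rank` (`"none"` when below
#'   every cutoff), `novelty` (`"none"` when assignable at the deepest
#'   rank).
#' @export
call_novelty <- function(identity_pct, cutoffs = default_rank_cutoffs()) {
  if (any(identity_pct < 0 | identity_pct > 100))
    stop("identity outside [0, 100]")
  if (any(diff(cutoffs) >= 0))
    stop("cutoffs must be strictly decreasing from deepest rank")
  ranks <- names(cutoffs)
  assignable <- vapply(identity_pct, function(id) {
    ok <- which(id >= cutoffs)
    if (length(ok)) ranks[min(ok)] else "none"
  }, "")
  novelty <- vapply(assignable, function(a) {
    if (a == "none") paste0(ranks[length(ranks)], "_or_above")
    else if (a == ranks[1L]) "none"
    else ranks[match(a, ranks) - 1L]
  }, "", USE.NAMES = FALSE)
  data.frame(identity = identity_pct, assignable_rank = assignable,
             novelty = novelty)
}

#' Annotate a bin identity table with novelty calls
#'
#' @param identities data.frame `bin_id`, `identity` (and anything else,
#'   carried through).
#' @param cutoffs see [call_novelty()].
#' @return input with `assignable_rank` and `novelty` columns appended.
#' @export
novelty_table <- function(identities, cutoffs = default_rank_cutoffs()) {
  calls <- call_novelty(identities$identity, cutoffs)
  cbind(identities, calls[, c("assignable_rank", "novelty")])
}
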