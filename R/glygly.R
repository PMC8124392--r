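#' @title GlyGly (diGly) site filtering and summaries
#' @description Filters for the site-level evidence of ubiquitination: the
#'   Gly-Gly remnant left on a modified lysine after tryptic digestion.
#'   Sites annotate substrate records; they play no role in substrate
#'   calling itself.
#' @name glygly
NULL

#' Filter GlyGly site rows
#'
#' Removes reverse (decoy) hits, potential contaminants, sites with no
#' intensity in any sample, and sites whose localization probability falls
#' below `min_probability` (a site at exactly the threshold is kept). Row
#' order is preserved; each removed row is counted once under the first
#' matching reason.
#'
#' @param rows A `glygly_table` from [read_glygly_sites()].
#' @param min_probability Minimum localization probability (default 0.75).
#' @return A list with `kept` (the retained `glygly_table`) and
#'   `removal_log` (named counts: `reverse`, `contaminant`, `no_intensity`,
#'   `low_probability`).
#' @export
filter_glygly <- function(rows, min_probability = 0.75) {
  stopifnot(inherits(rows, "glygly_table"),
            min_probability >= 0, min_probability <= 1)
  labels <- attr(rows, "sample_labels")
  intens <- as.matrix(rows[labels])
  all_zero <- rowSums(intens > 0) == 0L
  reasons <- rep(NA_character_, nrow(rows))
  pick <- function(cond, reason) {
    hit <- cond & is.na(reasons)
    reasons[hit] <<- reason
  }
  pick(rows$reverse, "reverse")
  pick(rows$contaminant, "contaminant")
  pick(all_zero, "no_intensity")
  pick(rows$localization_prob < min_probability, "low_probability")
  keep <- is.na(reasons)
  removal_log <- vapply(
    c("reverse", "contaminant", "no_intensity", "low_probability"),
    function(r) sum(reasons == r, na.rm = TRUE), integer(1))
  kept <- rows[keep, , drop = FALSE]
  rownames(kept) <- NULL
  attr(kept, "sample_labels") <- labels
  attr(kept, "design") <- attr(rows, "design")
  class(kept) <- class(rows)
  list(kept = kept, removal_log = removal_log)
}

#' Summarize GlyGly sites per protein
#'
#' @param kept A filtered `glygly_table`.
#' @return A named list mapping protein identifier to the sorted vector of
#'   unique 1-based site positions.
#' @examples
#' \dontrun{
#' sites_per_protein(filter_glygly(gg)$kept)
#' }
#' @export
sites_per_protein <- function(kept) {
  stopifnot(inherits(kept, "glygly_table"))
  if (!nrow(kept)) return(structure(list(), names = character(0)))
  lapply(split(kept$position, kept$protein_id),
         function(p) sort(unique(as.integer(p))))
}
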