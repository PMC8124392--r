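#' @title MaxQuant-dialect table input/output
#' @description Readers and writers for protein-group (`proteinGroups`-style)
#'   and GlyGly-site tables. The dialect conventions honoured here: columns
#'   are tab-separated with a header row; the flag columns `Reverse`,
#'   `Potential contaminant` and `Only identified by site` encode TRUE as the
#'   literal `"+"` and FALSE as anything else (usually blank); an LFQ
#'   intensity of 0 means "not quantified"; gene-name cells may hold a
#'   semicolon-separated list, of which the first symbol is kept.
#' @name tables_io
NULL

pg_flag_cols <- c(
  reverse = "Reverse",
  contaminant = "Potential contaminant",
  only_by_site = "Only identified by site"
)

parse_flag <- function(x) {
  !is.na(x) & trimws(as.character(x)) == "+"
}

first_gene <- function(x) {
  x <- as.character(x)
  x[is.na(x)] <- ""
  vapply(strsplit(x, ";", fixed = TRUE),
         function(p) if (length(p)) trimws(p[[1]]) else "",
         character(1))
}

# Parse a numeric column; empty cells become `fill`; anything else
# non-numeric is a hard error reported with its file line number
# (header = line 1, so data row i = line i + 1).
parse_numeric_col <- function(x, col, fill = 0) {
  x <- trimws(as.character(x))
  x[is.na(x) | x == ""] <- NA_character_
  val <- suppressWarnings(as.numeric(x))
  bad <- which(!is.na(x) & is.na(val))
  if (length(bad)) {
    stop(sprintf("non-numeric value %s in column '%s' at line %d",
                 dQuote(x[bad[1]]), col, bad[1] + 1L), call. = FALSE)
  }
  val[is.na(val)] <- fill
  val
}

require_columns <- function(header, wanted, path) {
  missing <- setdiff(wanted, header)
  if (length(missing)) {
    stop(sprintf("file '%s' lacks required column(s): %s", path,
                 paste(sQuote(missing), collapse = ", ")), call. = FALSE)
  }
}

read_tsv_raw <- function(path) {
  utils::read.delim(path, check.names = FALSE, colClasses = "character",
                    na.strings = NULL, quote = "", stringsAsFactors = FALSE)
}

#' Read a MaxQuant-dialect protein-group table
#'
#' Parses a tab-separated `proteinGroups`-style file into a validated
#' protein-group table. One `LFQ intensity <label>` column must exist for
#' every sample label of the design; `"+"` in a flag column is TRUE and any
#' other content FALSE; empty numeric cells parse as 0, and LFQ 0 encodes a
#' protein that was not quantified in that sample.
#'
#' @param path Path to a tab-separated file with a header row.
#' @param design An [experiment_design()].
#' @return A data frame of class `"protein_group_table"` with columns
#'   `protein_ids` (semicolon-separated accessions), `gene_name` (first
#'   symbol of the gene-name list), `description`, `unique_peptides`,
#'   `reverse`, `contaminant`, `only_by_site`, and one numeric LFQ column per
#'   sample label (named by the bare label). Attributes: `sample_labels`,
#'   `design`.
#' @seealso [write_protein_groups()], [filter_rows()]
#' @export
read_protein_groups <- function(path, design) {
  assert_design(design)
  raw <- read_tsv_raw(path)
  labels <- design$sample_label
  lfq_cols <- paste("LFQ intensity", labels)
  require_columns(names(raw),
                  c("Protein IDs", "Gene names", "Unique peptides",
                    unname(pg_flag_cols), lfq_cols),
                  path)
  out <- data.frame(
    protein_ids = as.character(raw[["Protein IDs"]]),
    gene_name = first_gene(raw[["Gene names"]]),
    description = if ("Protein names" %in% names(raw))
      as.character(raw[["Protein names"]]) else "",
    unique_peptides = as.integer(parse_numeric_col(raw[["Unique peptides"]],
                                                   "Unique peptides")),
    reverse = parse_flag(raw[[pg_flag_cols[["reverse"]]]]),
    contaminant = parse_flag(raw[[pg_flag_cols[["contaminant"]]]]),
    only_by_site = parse_flag(raw[[pg_flag_cols[["only_by_site"]]]]),
    stringsAsFactors = FALSE
  )
  for (i in seq_along(labels)) {
    v <- parse_numeric_col(raw[[lfq_cols[i]]], lfq_cols[i])
    if (any(v < 0 | !is.finite(v))) {
      stop(sprintf("column '%s' contains negative or non-finite LFQ values",
                   lfq_cols[i]), call. = FALSE)
    }
    out[[labels[i]]] <- v
  }
  attr(out, "sample_labels") <- labels
  attr(out, "design") <- design
  class(out) <- c("protein_group_table", "data.frame")
  out
}

#' Write a protein-group table back to MaxQuant dialect
#'
#' Inverse of [read_protein_groups()]: emits a tab-separated file with the
#' canonical column names so that reading it back reproduces the table
#' field-for-field. Numeric values are written with 17 significant digits so
#' doubles round-trip exactly.
#'
#' @param table A `protein_group_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_protein_groups <- function(table, path) {
  labels <- attr(table, "sample_labels")
  out <- data.frame(
    `Protein IDs` = table$protein_ids,
    `Gene names` = table$gene_name,
    `Protein names` = table$description,
    `Unique peptides` = table$unique_peptides,
    check.names = FALSE, stringsAsFactors = FALSE
  )
  for (lab in labels) {
    out[[paste("LFQ intensity", lab)]] <- fmt_full(table[[lab]])
  }
  out[[pg_flag_cols[["reverse"]]]] <- ifelse(table$reverse, "+", "")
  out[[pg_flag_cols[["contaminant"]]]] <- ifelse(table$contaminant, "+", "")
  out[[pg_flag_cols[["only_by_site"]]]] <- ifelse(table$only_by_site, "+", "")
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a MaxQuant-dialect GlyGly (diGly) site table
#'
#' Each row is one candidate ubiquitination site: the Gly-Gly remnant left on
#' a lysine after tryptic digestion. Positions are 1-based residue indices
#' and the localization probability (the search engine's confidence that the
#' modification sits on the reported residue) must lie in \[0, 1\].
#'
#' @inheritParams read_protein_groups
#' @return A data frame of class `"glygly_table"` with columns `protein_id`,
#'   `gene_name`, `position`, `localization_prob`, `reverse`, `contaminant`
#'   and one intensity column per sample label.
#' @export
read_glygly_sites <- function(path, design) {
  assert_design(design)
  raw <- read_tsv_raw(path)
  labels <- design$sample_label
  int_cols <- paste("Intensity", labels)
  require_columns(names(raw),
                  c("Protein", "Gene names", "Position",
                    "Localization prob", "Reverse", "Potential contaminant",
                    int_cols),
                  path)
  out <- data.frame(
    protein_id = as.character(raw[["Protein"]]),
    gene_name = first_gene(raw[["Gene names"]]),
    position = as.integer(parse_numeric_col(raw[["Position"]], "Position")),
    localization_prob = parse_numeric_col(raw[["Localization prob"]],
                                          "Localization prob"),
    reverse = parse_flag(raw[["Reverse"]]),
    contaminant = parse_flag(raw[["Potential contaminant"]]),
    stringsAsFactors = FALSE
  )
  if (any(out$position < 1L)) {
    stop("GlyGly site positions must be >= 1", call. = FALSE)
  }
  if (any(out$localization_prob < 0 | out$localization_prob > 1)) {
    stop("localization probabilities must lie in [0, 1]", call. = FALSE)
  }
  for (i in seq_along(labels)) {
    v <- parse_numeric_col(raw[[int_cols[i]]], int_cols[i])
    if (any(v < 0 | !is.finite(v))) {
      stop(sprintf("column '%s' contains negative or non-finite intensities",
                   int_cols[i]), call. = FALSE)
    }
    out[[labels[i]]] <- v
  }
  attr(out, "sample_labels") <- labels
  attr(out, "design") <- design
  class(out) <- c("glygly_table", "data.frame")
  out
}

#' Write a GlyGly site table in MaxQuant dialect
#'
#' @param table A `glygly_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_glygly_sites <- function(table, path) {
  labels <- attr(table, "sample_labels")
  out <- data.frame(
    Protein = table$protein_id,
    `Gene names` = table$gene_name,
    Position = table$position,
    `Localization prob` = fmt_full(table$localization_prob),
    check.names = FALSE, stringsAsFactors = FALSE
  )
  for (lab in labels) {
    out[[paste("Intensity", lab)]] <- fmt_full(table[[lab]])
  }
  out[["Reverse"]] <- ifelse(table$reverse, "+", "")
  out[["Potential contaminant"]] <- ifelse(table$contaminant, "+", "")
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

# %.17g preserves every double bit-exactly through a text round trip;
# decimal point only, never locale-dependent.
fmt_full <- function(x) {
  if (is.numeric(x)) sprintf("%.17g", x) else as.character(x)
}

#' Write any tabular result as RFC-4180 CSV
#'
#' Floats are written at full precision (17 significant digits) so that a
#' write/read round trip preserves values bit-exactly; rows keep their input
#' order; an empty result yields a header-only file.
#'
#' @param results A data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_results_csv <- function(results, path) {
  stopifnot(is.data.frame(results))
  out <- as.data.frame(results, stringsAsFactors = FALSE)
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- fmt_full(out[[j]])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}
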