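#' @title Queryable DUB-substrate store
#' @description A local, file-backed equivalent of a DUB substrate database:
#'   differential results are ingested *unfiltered*, and the user's
#'   thresholds are applied only at query time, so the same store answers
#'   both conservative and permissive definitions of "substrate". Two
#'   logical tables mirror the usual schema: `experiments` (one row per
#'   silencing experiment, with methodological metadata) and `evidence` (one
#'   row per DUB/protein pair).
#' @name dubase_store
NULL

evidence_cols <- c("experiment_id", "dub_name", "gene_name", "description",
                   "log2_fc", "p_value", "unique_peptides", "protein_id",
                   "provenance")

empty_evidence <- function() {
  data.frame(experiment_id = character(0), dub_name = character(0),
             gene_name = character(0), description = character(0),
             log2_fc = numeric(0), p_value = numeric(0),
             unique_peptides = integer(0), protein_id = character(0),
             provenance = character(0), stringsAsFactors = FALSE)
}

empty_experiments <- function() {
  data.frame(experiment_id = character(0), dub_name = character(0),
             cell = character(0), organism = character(0),
             method = character(0), conditions = character(0),
             files = character(0), stringsAsFactors = FALSE)
}

#' Create an empty substrate store
#'
#' @param thresholds Session thresholds applied at query time until changed
#'   with [set_thresholds()].
#' @return An object of class `"dubase_store"`.
#' @export
dubase_store <- function(thresholds = default_thresholds()) {
  structure(list(experiments = empty_experiments(),
                 evidence = empty_evidence(),
                 thresholds = thresholds,
                 default_thresholds = thresholds),
            class = "dubase_store")
}

#' @export
print.dubase_store <- function(x, ...) {
  cat(sprintf("dubase_store: %d experiment(s), %d evidence record(s)\n",
              nrow(x$experiments), nrow(x$evidence)))
  cat(sprintf("session thresholds: |log2 FC| >= %g, p < %g, unique peptides >= %d, direction %s\n",
              x$thresholds$min_abs_log2_fc, x$thresholds$max_p,
              x$thresholds$min_unique_peptides, x$thresholds$direction))
  invisible(x)
}

#' Ingest substrate records into the store
#'
#' All records are stored unfiltered; thresholds act only at query time.
#' Records from published summary tables typically lack p-values and
#' unique-peptide counts; such fields may be `NA` and then pass the
#' corresponding query filters vacuously (the query attaches a notice).
#'
#' @param store A [dubase_store()].
#' @param records Data frame with at least `dub_name`, `gene_name`,
#'   `description`, `log2_fc`; optional `p_value`, `unique_peptides`,
#'   `protein_id`, `provenance` (default `"pipeline"`).
#' @param experiment_id Unique experiment identifier; re-ingesting an
#'   existing id is an error.
#' @param meta Named list of methodological metadata (`cell`, `organism`,
#'   `method`, `conditions`, `files`).
#' @return The updated store.
#' @export
dubase_ingest <- function(store, records, experiment_id, meta = list()) {
  stopifnot(inherits(store, "dubase_store"), is.data.frame(records))
  need <- c("dub_name", "gene_name", "description", "log2_fc")
  missing <- setdiff(need, names(records))
  if (length(missing)) {
    stop("records lack column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (experiment_id %in% store$experiments$experiment_id) {
    stop(sprintf("experiment '%s' already ingested", experiment_id),
         call. = FALSE)
  }
  n <- nrow(records)
  opt <- function(col, default) {
    if (col %in% names(records)) records[[col]] else rep(default, n)
  }
  ev <- data.frame(
    experiment_id = rep(experiment_id, n),
    dub_name = as.character(records$dub_name),
    gene_name = as.character(records$gene_name),
    description = as.character(records$description),
    log2_fc = as.numeric(records$log2_fc),
    p_value = as.numeric(opt("p_value", NA_real_)),
    unique_peptides = as.integer(opt("unique_peptides", NA_integer_)),
    protein_id = as.character(opt("protein_id", NA_character_)),
    provenance = as.character(opt("provenance", "pipeline")),
    stringsAsFactors = FALSE
  )
  key <- paste(toupper(ev$dub_name), toupper(ev$gene_name))
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1]
    stop(sprintf("duplicate (DUB, gene) pair within experiment '%s': %s",
                 experiment_id, d), call. = FALSE)
  }
  if (nrow(ev)) store$evidence <- rbind(store$evidence, ev)
  grab <- function(k) if (!is.null(meta[[k]])) as.character(meta[[k]]) else NA_character_
  store$experiments <- rbind(store$experiments, data.frame(
    experiment_id = experiment_id,
    dub_name = if (length(unique(ev$dub_name)) == 1L) ev$dub_name[1] else NA_character_,
    cell = grab("cell"), organism = grab("organism"), method = grab("method"),
    conditions = grab("conditions"), files = grab("files"),
    stringsAsFactors = FALSE))
  rownames(store$evidence) <- rownames(store$experiments) <- NULL
  store
}

#' Ingest a full differential result for one DUB
#'
#' Convenience wrapper around [dubase_ingest()] that stores every tested
#' protein (not only the called substrates), as required for query-time
#' thresholding and for volcano plots showing sub-threshold identifications.
#'
#' @param store A [dubase_store()].
#' @param results A `differential_result` data frame.
#' @param dub_name Silenced DUB gene symbol.
#' @param experiment_id Experiment identifier (default `<dub_name>_screen`).
#' @param meta Methodological metadata, as in [dubase_ingest()].
#' @return The updated store.
#' @export
dubase_ingest_differential <- function(store, results, dub_name,
                                       experiment_id = paste0(dub_name, "_screen"),
                                       meta = list()) {
  stopifnot(inherits(results, "differential_result"))
  recs <- data.frame(
    dub_name = dub_name,
    gene_name = results$gene_name,
    description = results$description,
    log2_fc = results$log2_fc,
    p_value = results$p_value,
    unique_peptides = results$unique_peptides,
    protein_id = results$row_key,
    provenance = "pipeline",
    stringsAsFactors = FALSE
  )
  # protein groups without a gene symbol cannot be queried by gene; key them
  # by accession instead so the (DUB, gene) uniqueness constraint holds
  blank <- !nzchar(recs$gene_name)
  recs$gene_name[blank] <- recs$protein_id[blank]
  dubase_ingest(store, recs, experiment_id, meta)
}

passes_store_thresholds <- function(ev, thresholds) {
  fc_ok <- threshold_direction_ok(ev$log2_fc, thresholds)
  p_ok <- is.na(ev$p_value) | ev$p_value < thresholds$max_p
  up_ok <- is.na(ev$unique_peptides) |
    ev$unique_peptides >= thresholds$min_unique_peptides
  fc_ok & p_ok & up_ok
}

query_notice <- function(ev, pass) {
  vac <- pass & (is.na(ev$p_value) | is.na(ev$unique_peptides))
  if (any(vac)) {
    sprintf("%d record(s) lack p-value or unique-peptide fields and pass those filters vacuously",
            sum(vac))
  } else NULL
}

#' Query the substrates of one DUB
#'
#' Returns the evidence records of `dub_name` (case-insensitive exact match)
#' passing the thresholds, sorted by descending log2 fold change. An unknown
#' DUB yields an empty result with a notice attribute.
#'
#' @param store A [dubase_store()].
#' @param dub_name DUB gene symbol.
#' @param thresholds Optional [default_thresholds()]; defaults to the
#'   store's session thresholds.
#' @return Data frame of evidence records; attribute `"notice"` carries any
#'   per-query notices.
#' @export
query_by_dub <- function(store, dub_name, thresholds = NULL) {
  stopifnot(inherits(store, "dubase_store"))
  thresholds <- thresholds %||% store$thresholds
  ev <- store$evidence[toupper(store$evidence$dub_name) == toupper(dub_name), ,
                       drop = FALSE]
  notices <- character(0)
  if (!nrow(ev)) notices <- sprintf("no records for DUB '%s'", dub_name)
  pass <- passes_store_thresholds(ev, thresholds)
  notices <- c(notices, query_notice(ev, pass))
  out <- ev[pass, , drop = FALSE]
  out <- out[order(-out$log2_fc, out$gene_name), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "notice") <- notices
  out
}

#' Query the DUBs regulating one protein
#'
#' @param store A [dubase_store()].
#' @param gene_name Substrate gene symbol (case-insensitive exact match).
#' @param thresholds As in [query_by_dub()].
#' @return Data frame of evidence records (including `dub_name`), sorted by
#'   descending log2 fold change.
#' @export
query_by_substrate <- function(store, gene_name, thresholds = NULL) {
  stopifnot(inherits(store, "dubase_store"))
  thresholds <- thresholds %||% store$thresholds
  ev <- store$evidence[toupper(store$evidence$gene_name) == toupper(gene_name), ,
                       drop = FALSE]
  notices <- character(0)
  if (!nrow(ev)) notices <- sprintf("no records for gene '%s'", gene_name)
  pass <- passes_store_thresholds(ev, thresholds)
  notices <- c(notices, query_notice(ev, pass))
  out <- ev[pass, , drop = FALSE]
  out <- out[order(-out$log2_fc, out$dub_name), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "notice") <- notices
  out
}

#' Set or reset the store's session thresholds
#'
#' Thresholds persist on the store and govern every subsequent query until
#' changed again.
#'
#' @param store A [dubase_store()].
#' @param thresholds A [default_thresholds()] object.
#' @return The updated store.
#' @export
set_thresholds <- function(store, thresholds) {
  stopifnot(inherits(store, "dubase_store"), inherits(thresholds, "thresholds"))
  store$thresholds <- thresholds
  store
}

#' @rdname set_thresholds
#' @export
reset_thresholds <- function(store) {
  store$thresholds <- store$default_thresholds
  store
}

#' Volcano dataset for one DUB, including sub-threshold records
#'
#' @param store A [dubase_store()].
#' @param dub_name DUB gene symbol.
#' @param thresholds As in [query_by_dub()].
#' @return Data frame with one row per ingested record of the DUB: `gene`,
#'   `description`, `log2_fc`, `neg_log10_p` (`NA` when no p-value was
#'   ingested) and `passes_thresholds`.
#' @export
volcano_for_dub <- function(store, dub_name, thresholds = NULL) {
  stopifnot(inherits(store, "dubase_store"))
  thresholds <- thresholds %||% store$thresholds
  ev <- store$evidence[toupper(store$evidence$dub_name) == toupper(dub_name), ,
                       drop = FALSE]
  p <- ev$p_value
  p[!is.na(p) & p == 0] <- .Machine$double.xmin
  out <- data.frame(
    gene = ev$gene_name,
    description = ev$description,
    log2_fc = ev$log2_fc,
    neg_log10_p = -log10(p),
    passes_thresholds = passes_store_thresholds(ev, thresholds),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' The bundled published substrate summary table
#'
#' Loads the transcription of the published five-DUB substrate table (USP1,
#' USP7, USP9X, USP11, USP42; 56 rows) shipped with the package: DUB, gene,
#' description and log2 fold change (silenced/control). p-values and
#' unique-peptide counts are not part of the printed table and are absent.
#'
#' @return Data frame with columns `dub_name`, `gene_name`, `description`,
#'   `log2_fc`, `provenance` (`"paper_table"`).
#' @export
dubase_table1 <- function() {
  path <- system.file("extdata", "dub_substrates_table.csv",
                      package = "dubscreen", mustWork = TRUE)
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  out$provenance <- "paper_table"
  out
}

#' Build a store pre-loaded with the published substrate table
#'
#' One experiment per DUB, annotated with the shared methodological
#' metadata (HEK293 cells, biotin pull-down of biotinylatable ubiquitin,
#' label-free quantification).
#'
#' @param thresholds Session thresholds for the new store.
#' @return A [dubase_store()] holding all 56 published records.
#' @export
dubase_store_from_table1 <- function(thresholds = default_thresholds()) {
  tab <- dubase_table1()
  store <- dubase_store(thresholds)
  meta <- list(cell = "HEK293", organism = "Homo sapiens",
               method = "bioUb biotin pull-down + LFQ",
               conditions = "control siRNA vs DUB siRNA, triplicates",
               files = "published summary table")
  for (dub in unique(tab$dub_name)) {
    store <- dubase_ingest(store, tab[tab$dub_name == dub, , drop = FALSE],
                           experiment_id = paste0(dub, "_published"),
                           meta = meta)
  }
  store
}

`%||%` <- function(a, b) if (is.null(a)) b else a
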