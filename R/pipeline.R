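#' @title End-to-end screen analysis
#' @description One call orchestrating the full workflow: read (or accept)
#'   a protein-group table, filter rows, log2-transform, impute, test
#'   differential ubiquitination, call substrates, run QC, filter GlyGly
#'   sites and ingest everything into a queryable store — deterministically
#'   given a seed, with per-stage row counts logged.
#' @name cli
NULL

#' Run the full substrate-screening pipeline
#'
#' @param protein_groups A `protein_group_table`, or a path to a
#'   MaxQuant-dialect file (then `design` is required to read it).
#' @param design An [experiment_design()]; taken from the table attribute if
#'   omitted.
#' @param glygly Optional `glygly_table` or path.
#' @param thresholds A [default_thresholds()] object.
#' @param imputation List with `width`, `downshift`, `mode` for [impute()].
#' @param panel A [qc_panel()].
#' @param correction Multiple-testing correction passed to
#'   [compute_differential()]: `"none"` (standard) or `"bh"`.
#' @param min_probability GlyGly localization-probability cutoff.
#' @param seed Integer seed for the imputation draws.
#' @param out_dir If non-NULL, all result tables are written there as CSV
#'   (plus the imputation mask and correlation matrix).
#' @param strict_qc Stop with an error if the QC report fails.
#' @param verbose Log per-stage row counts with [message()].
#' @return A list with `filtered`, `removal_log`, `matrix`, `differential`,
#'   `initial_selection`, `putative_substrates`, `qc_report`, `correlation`,
#'   `volcano`, `glygly_kept`, `glygly_removal_log`, `sites`, `store`.
#' @examples
#' \dontrun{
#' syn <- generate_synthetic(synthetic_config(seed = 7L))
#' res <- run_pipeline(syn$protein_groups, glygly = syn$glygly, seed = 7L)
#' nrow(res$putative_substrates)
#' }
#' @export
run_pipeline <- function(protein_groups, design = NULL, glygly = NULL,
                         thresholds = default_thresholds(),
                         imputation = list(width = 0.3, downshift = 1.8,
                                           mode = "per_column"),
                         panel = qc_panel(), correction = c("none", "bh"),
                         min_probability = 0.75,
                         seed = 1L, out_dir = NULL, strict_qc = FALSE,
                         verbose = TRUE) {
  say <- function(...) if (verbose) message(sprintf(...))
  if (is.character(protein_groups)) {
    if (is.null(design)) stop("`design` is required to read a file", call. = FALSE)
    protein_groups <- read_protein_groups(protein_groups, design)
  }
  design <- design %||% attr(protein_groups, "design")
  assert_design(design)
  dub_name <- attr(design, "dub_name")
  say("input: %d protein groups, %d samples", nrow(protein_groups),
      nrow(design))

  flt <- filter_rows(protein_groups)
  say("filter_rows: %d kept, removed {%s}", nrow(flt$table),
      paste(names(flt$removal_log), flt$removal_log, sep = "=", collapse = ", "))

  im <- log2_transform(flt$table)
  im <- impute(im, width = imputation$width %||% 0.3,
               downshift = imputation$downshift %||% 1.8,
               mode = imputation$mode %||% "per_column", seed = seed)
  say("impute: %d of %d cells imputed", sum(im$imputed_mask),
      length(im$imputed_mask))

  diff <- compute_differential(im, flt$table, dub_name = dub_name,
                               qc_genes = qc_panel_genes(panel),
                               thresholds = thresholds,
                               correction = match.arg(correction))
  calls <- call_substrates(diff, thresholds)
  say("differential: %d tested, %d initial selection, %d putative substrates",
      nrow(diff), nrow(calls$initial_selection),
      nrow(calls$putative_substrates))

  qc <- qc_report(diff, panel, thresholds)
  say("qc: %s", if (qc$pass) "pass" else
    paste("FAIL:", paste(qc$offenders, collapse = ", ")))
  if (strict_qc && !qc$pass) {
    stop("QC failed: ", paste(qc$offenders, collapse = ", "), call. = FALSE)
  }
  corr <- replicate_correlation(im)
  volc <- volcano_dataset(diff)

  gg_kept <- NULL; gg_log <- NULL; sites <- NULL
  if (!is.null(glygly)) {
    if (is.character(glygly)) glygly <- read_glygly_sites(glygly, design)
    gg <- filter_glygly(glygly, min_probability)
    gg_kept <- gg$kept; gg_log <- gg$removal_log
    sites <- sites_per_protein(gg_kept)
    say("glygly: %d of %d sites kept (%d proteins)", nrow(gg_kept),
        nrow(glygly), length(sites))
  }

  store <- dubase_store(thresholds)
  store <- dubase_ingest_differential(
    store, diff, dub_name,
    experiment_id = attr(design, "experiment_id"),
    meta = list(method = "bioUb biotin pull-down + LFQ",
                conditions = sprintf("control siRNA vs si%s, %d+%d replicates",
                                     dub_name,
                                     sum(design$condition == "control"),
                                     sum(design$condition == "silenced"))))

  res <- list(filtered = flt$table, removal_log = flt$removal_log,
              matrix = im, differential = diff,
              initial_selection = calls$initial_selection,
              putative_substrates = calls$putative_substrates,
              qc_report = qc, correlation = corr, volcano = volc,
              glygly_kept = gg_kept, glygly_removal_log = gg_log,
              sites = sites, store = store)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_results_csv(as.data.frame(diff), file.path(out_dir, "differential.csv"))
    write_results_csv(calls$initial_selection,
                      file.path(out_dir, "initial_selection.csv"))
    write_results_csv(calls$putative_substrates,
                      file.path(out_dir, "putative_substrates.csv"))
    write_results_csv(volc, file.path(out_dir, "volcano.csv"))
    write_qc_report_json(qc, file.path(out_dir, "qc_report.json"))
    utils::write.csv(data.frame(row_key = im$row_keys,
                                im$imputed_mask, check.names = FALSE),
                     file.path(out_dir, "imputation_mask.csv"),
                     row.names = FALSE)
    utils::write.csv(corr, file.path(out_dir, "replicate_correlation.csv"))
    if (!is.null(gg_kept)) {
      write_results_csv(as.data.frame(gg_kept),
                        file.path(out_dir, "glygly_filtered.csv"))
    }
    say("results written to %s", out_dir)
  }
  res
}

#' Run the pipeline from a YAML configuration file
#'
#' The configuration mirrors the [run_pipeline()] arguments:
#'
#' ```yaml
#' inputs:
#'   protein_groups: proteinGroups.tsv
#'   glygly: glygly.tsv        # optional
#' design:
#'   dub_name: USP9X
#'   control: [Ctr_1, Ctr_2, Ctr_3]
#'   silenced: [siUSP9X_1, siUSP9X_2, siUSP9X_3]
#' thresholds: {min_abs_log2_fc: 1, max_p: 0.05, min_unique_peptides: 2,
#'              direction: up}
#' imputation: {width: 0.3, downshift: 1.8, mode: per_column}
#' glygly: {min_probability: 0.75}
#' seed: 1
#' out_dir: results/
#' ```
#'
#' @param config_path Path to the YAML file.
#' @param ... Overrides passed on to [run_pipeline()].
#' @return See [run_pipeline()].
#' @export
run_pipeline_config <- function(config_path, ...) {
  cfg <- yaml::read_yaml(config_path)
  if (is.null(cfg$inputs$protein_groups) || is.null(cfg$design$dub_name)) {
    stop("config must define inputs.protein_groups and design.dub_name",
         call. = FALSE)
  }
  des <- do.call(experiment_design, c(
    list(dub_name = cfg$design$dub_name),
    cfg$design[intersect(names(cfg$design),
                         c("control", "silenced", "experiment_id"))]))
  thr <- do.call(default_thresholds,
                 cfg$thresholds %||% list())
  run_pipeline(protein_groups = cfg$inputs$protein_groups,
               design = des,
               glygly = cfg$inputs$glygly,
               thresholds = thr,
               imputation = cfg$imputation %||% list(),
               correction = cfg$correction$method %||% "none",
               min_probability = cfg$glygly$min_probability %||% 0.75,
               seed = cfg$seed %||% 1L,
               out_dir = cfg$out_dir,
               strict_qc = isTRUE(cfg$strict_qc),
               ...)
}
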