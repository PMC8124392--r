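#' @title Synthetic label-free proteomics data with ground truth
#' @description Generates MaxQuant-dialect protein-group and GlyGly-site
#'   tables with the statistical structure the analysis assumes: log-normal
#'   protein abundances, replicate noise, a spiked substrate subset enriched
#'   in the silenced condition, abundance-dependent (missing-not-at-random)
#'   dropout, unaffected high-abundance QC proteins, and decoy /
#'   contaminant rows. Ground-truth labels allow recovery scoring of the
#'   full pipeline.
#' @name synthetic_data
NULL

#' Configuration of the synthetic generator
#'
#' Defaults emulate one mid-depth triplicate DUB-silencing screen: ~2000
#' quantifiable proteins, 40 substrates gaining +2 log2 units (a 4-fold LFQ
#' increase) upon silencing, 10 proteins losing the same amount, log2
#' abundances centred at 26 with SD 2.5, replicate noise SD 0.3, and a
#' logistic detection model dropping values around log2 intensity 22.5.
#'
#' @param n_proteins Number of substrate + null rows (QC, decoy and
#'   contaminant rows come on top).
#' @param n_substrates Number of proteins with increased ubiquitination upon
#'   silencing.
#' @param effect_log2 Log2 effect added to the silenced condition of
#'   substrates (length 1, or a range `c(lo, hi)` sampled uniformly).
#' @param n_down Number of proteins with decreased ubiquitination (effect
#'   `-mean(effect_log2)`).
#' @param base_mean,base_sd Mean and SD of the true log2 abundances.
#' @param replicate_sd SD of the per-replicate measurement noise (log2).
#' @param n_reps Replicates per condition.
#' @param dropout_midpoint,dropout_slope Logistic detection model: a value v
#'   is observed with probability `plogis((v - midpoint) / slope)`.
#' @param n_decoys Number of reverse-database decoy rows.
#' @param n_contaminants Number of potential-contaminant rows.
#' @param qc_panel_included Include the QC rows (ACACA, HLCS, MCCC1, PC,
#'   PCCA, UBB, AVD) at high abundance (`base_mean + 3`) with zero effect.
#' @param unique_peptide_lambda Unique peptide counts are
#'   `1 + Poisson(lambda)`.
#' @param dub_name Silenced DUB gene symbol used for sample labels.
#' @param seed Integer seed; the whole dataset is reproducible from it.
#' @return A list of class `"synthetic_config"`.
#' @export
synthetic_config <- function(n_proteins = 2000L, n_substrates = 40L,
                             effect_log2 = 2.0, n_down = 10L,
                             base_mean = 26, base_sd = 2.5,
                             replicate_sd = 0.3, n_reps = 3L,
                             dropout_midpoint = 22.5, dropout_slope = 1.5,
                             n_decoys = 20L, n_contaminants = 15L,
                             qc_panel_included = TRUE,
                             unique_peptide_lambda = 6,
                             dub_name = "USP9X", seed = 1L) {
  cfg <- list(n_proteins = as.integer(n_proteins),
              n_substrates = as.integer(n_substrates),
              effect_log2 = effect_log2, n_down = as.integer(n_down),
              base_mean = base_mean, base_sd = base_sd,
              replicate_sd = replicate_sd, n_reps = as.integer(n_reps),
              dropout_midpoint = dropout_midpoint,
              dropout_slope = dropout_slope,
              n_decoys = as.integer(n_decoys),
              n_contaminants = as.integer(n_contaminants),
              qc_panel_included = isTRUE(qc_panel_included),
              unique_peptide_lambda = unique_peptide_lambda,
              dub_name = dub_name, seed = as.integer(seed))
  if (cfg$n_substrates + cfg$n_down > cfg$n_proteins) {
    stop("n_substrates + n_down must not exceed n_proteins", call. = FALSE)
  }
  if (cfg$base_sd <= 0 || cfg$replicate_sd <= 0 || cfg$dropout_slope <= 0) {
    stop("all standard deviations and slopes must be positive", call. = FALSE)
  }
  if (cfg$n_reps < 2L) stop("need at least 2 replicates", call. = FALSE)
  if (!length(cfg$effect_log2) %in% 1:2) {
    stop("effect_log2 must be a single value or a range c(lo, hi)",
         call. = FALSE)
  }
  class(cfg) <- "synthetic_config"
  cfg
}

synthetic_qc_genes <- c("ACACA", "HLCS", "MCCC1", "PC", "PCCA", "UBB", "AVD")

#' Generate a synthetic screen dataset
#'
#' Per protein i, a true log2 abundance `a_i ~ Normal(base_mean, base_sd^2)`
#' is drawn; the value of replicate r in condition c is
#' `a_i + effect_i * [c == silenced] + Normal(0, replicate_sd^2)`. Each value
#' is observed with probability `plogis((value - midpoint) / slope)` (so
#' dropout concentrates at low abundance); unobserved cells get LFQ 0. QC
#' rows are placed at `base_mean + 3`, carry no effect and are always
#' observed. Decoy rows carry the reverse flag and contaminant rows the
#' contaminant flag. A GlyGly table holds 1-3 sites per up-substrate with
#' localization probabilities Uniform(0.5, 1).
#'
#' @param config A [synthetic_config()].
#' @return A list with elements `protein_groups` (a `protein_group_table`),
#'   `glygly` (a `glygly_table`), `truth` (data frame: `gene_name`, `label`
#'   in substrate_up / substrate_down / null / qc / decoy / contaminant,
#'   `true_effect_log2`) and `design`.
#' @export
generate_synthetic <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  cfg <- config
  design <- experiment_design(cfg$dub_name,
                              control = paste0("Ctr_", seq_len(cfg$n_reps)),
                              silenced = paste0("si", cfg$dub_name, "_",
                                                seq_len(cfg$n_reps)))
  n_null <- cfg$n_proteins - cfg$n_substrates - cfg$n_down
  qc <- if (cfg$qc_panel_included) synthetic_qc_genes else character(0)
  label <- c(rep("substrate_up", cfg$n_substrates),
             rep("substrate_down", cfg$n_down),
             rep("null", n_null),
             rep("qc", length(qc)),
             rep("decoy", cfg$n_decoys),
             rep("contaminant", cfg$n_contaminants))
  n_total <- length(label)
  gene <- character(n_total)
  gene[label == "substrate_up"] <- sprintf("SUB%04d", seq_len(cfg$n_substrates))
  gene[label == "substrate_down"] <- sprintf("DWN%04d", seq_len(cfg$n_down))
  gene[label == "null"] <- sprintf("NUL%04d", seq_len(n_null))
  gene[label == "qc"] <- qc
  gene[label == "decoy"] <- sprintf("REV%04d", seq_len(cfg$n_decoys))
  gene[label == "contaminant"] <- sprintf("CON%04d", seq_len(cfg$n_contaminants))
  acc <- sprintf("S%05d", seq_len(n_total))
  acc[label == "decoy"] <- paste0("REV__", acc[label == "decoy"])
  acc[label == "contaminant"] <- paste0("CON__", acc[label == "contaminant"])

  effect <- numeric(n_total)
  eff <- cfg$effect_log2
  effect[label == "substrate_up"] <- if (length(eff) == 2L) {
    stats::runif(cfg$n_substrates, eff[1], eff[2])
  } else rep(eff, cfg$n_substrates)
  effect[label == "substrate_down"] <- -mean(eff)

  abund <- stats::rnorm(n_total, cfg$base_mean, cfg$base_sd)
  abund[label == "qc"] <- cfg$base_mean + 3

  n_samp <- 2L * cfg$n_reps
  is_sil <- design$condition == "silenced"
  true_val <- outer(abund, rep(0, n_samp), `+`) +
    outer(effect, as.numeric(is_sil)) +
    matrix(stats::rnorm(n_total * n_samp, 0, cfg$replicate_sd),
           n_total, n_samp)
  p_obs <- stats::plogis((true_val - cfg$dropout_midpoint) / cfg$dropout_slope)
  observed <- matrix(stats::runif(n_total * n_samp), n_total, n_samp) < p_obs
  observed[label == "qc", ] <- TRUE
  lfq <- ifelse(observed, 2^true_val, 0)

  pg <- data.frame(
    protein_ids = acc,
    gene_name = gene,
    description = paste("Synthetic protein", gene),
    unique_peptides = 1L + stats::rpois(n_total, cfg$unique_peptide_lambda),
    reverse = label == "decoy",
    contaminant = label == "contaminant",
    only_by_site = FALSE,
    stringsAsFactors = FALSE
  )
  for (j in seq_len(n_samp)) pg[[design$sample_label[j]]] <- lfq[, j]
  attr(pg, "sample_labels") <- design$sample_label
  attr(pg, "design") <- design
  class(pg) <- c("protein_group_table", "data.frame")

  # GlyGly sites: 1-3 per up-substrate, localization prob Uniform(0.5, 1)
  sub_idx <- which(label == "substrate_up")
  n_sites <- if (length(sub_idx)) sample(1:3, length(sub_idx), replace = TRUE)
             else integer(0)
  site_row <- rep(sub_idx, n_sites)
  gg <- data.frame(
    protein_id = acc[site_row],
    gene_name = gene[site_row],
    position = if (length(site_row))
      sample(5:800, length(site_row), replace = TRUE) else integer(0),
    localization_prob = stats::runif(length(site_row), 0.5, 1),
    reverse = rep(FALSE, length(site_row)),
    contaminant = rep(FALSE, length(site_row)),
    stringsAsFactors = FALSE
  )
  for (j in seq_len(n_samp)) {
    gg[[design$sample_label[j]]] <- if (length(site_row))
      lfq[site_row, j] * stats::runif(length(site_row), 0.01, 0.1) else numeric(0)
  }
  attr(gg, "sample_labels") <- design$sample_label
  attr(gg, "design") <- design
  class(gg) <- c("glygly_table", "data.frame")

  truth <- data.frame(gene_name = gene, label = label,
                      true_effect_log2 = effect, stringsAsFactors = FALSE)
  list(protein_groups = pg, glygly = gg, truth = truth, design = design)
}

#' Write a synthetic dataset to disk
#'
#' Emits `proteinGroups.tsv`, `glygly.tsv` and `truth.csv` under `dir`.
#'
#' @param data Output of [generate_synthetic()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the three paths, invisibly.
#' @export
write_synthetic <- function(data, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(protein_groups = file.path(dir, "proteinGroups.tsv"),
             glygly = file.path(dir, "glygly.tsv"),
             truth = file.path(dir, "truth.csv"))
  write_protein_groups(data$protein_groups, paths[["protein_groups"]])
  write_glygly_sites(data$glygly, paths[["glygly"]])
  write_results_csv(data$truth, paths[["truth"]])
  invisible(paths)
}

#' Score substrate recovery against ground truth
#'
#' Direction-aware scoring of an up-substrate call set: sensitivity is the
#' fraction of true up-substrates recovered; the false-discovery proportion
#' is the fraction of called genes that are not true up-substrates.
#'
#' @param called Character vector of called gene names.
#' @param truth Truth data frame from [generate_synthetic()].
#' @return A list with `sensitivity` and `false_discovery_proportion`.
#' @export
score_recovery <- function(called, truth) {
  if (!all(called %in% truth$gene_name)) {
    stop("truth does not cover all called genes", call. = FALSE)
  }
  up <- truth$gene_name[truth$label == "substrate_up"]
  called <- unique(called)
  list(
    sensitivity = if (length(up)) length(intersect(called, up)) / length(up)
                  else NA_real_,
    false_discovery_proportion =
      length(setdiff(called, up)) / max(1L, length(called))
  )
}
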