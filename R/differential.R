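#' @title Differential ubiquitination analysis
#' @description Per-protein fold changes and two-tailed Student's t-tests on
#'   the imputed log2 intensity matrix, volcano-plot datasets, and the
#'   three-criterion rule that promotes differentially ubiquitinated
#'   proteins to putative DUB substrates.
#' @name differential
NULL

#' Substrate-calling thresholds
#'
#' The defaults are the screen's canonical criteria: a 2-fold LFQ increase
#' (log2 fold change >= 1) that is statistically significant (p < 0.05), a
#' minimum of 2 unique peptides, and the `"up"` direction (increased
#' ubiquitination upon silencing). The fold-change and unique-peptide
#' comparisons are inclusive; the p-value comparison is strict.
#'
#' @param min_abs_log2_fc Minimum absolute log2 fold change (inclusive).
#' @param max_p Maximum p-value (exclusive).
#' @param min_unique_peptides Minimum number of unique peptides (inclusive).
#' @param direction One of `"up"`, `"down"`, `"both"`.
#' @return A list of class `"thresholds"`.
#' @export
default_thresholds <- function(min_abs_log2_fc = 1, max_p = 0.05,
                               min_unique_peptides = 2L,
                               direction = c("up", "down", "both")) {
  direction <- match.arg(direction)
  stopifnot(min_abs_log2_fc >= 0, max_p > 0, max_p <= 1,
            min_unique_peptides >= 0)
  structure(list(min_abs_log2_fc = min_abs_log2_fc, max_p = max_p,
                 min_unique_peptides = as.integer(min_unique_peptides),
                 direction = direction),
            class = "thresholds")
}

#' Two-sample Student's t-test (pooled variance)
#'
#' Equal-variance two-sample t-test with `length(x) + length(y) - 2` degrees
#' of freedom and a two-tailed p-value. The sign convention is t > 0 when
#' `mean(x) > mean(y)`; in the screen `x` is the DUB-silenced condition and
#' `y` the control. Degenerate inputs with zero pooled variance return
#' t = 0, p = 1 when the means agree, and p equal to the smallest
#' representable positive double (with a warning) when they differ.
#'
#' @param x,y Numeric vectors of length >= 2.
#' @return A list with elements `t` and `p`.
#' @examples
#' student_t_test(c(2, 3, 4), c(1, 2, 3))
#' @export
student_t_test <- function(x, y) {
  stopifnot(length(x) >= 2L, length(y) >= 2L)
  vx <- stats::var(x); vy <- stats::var(y)
  if (vx == 0 && vy == 0) {
    if (mean(x) == mean(y)) return(list(t = 0, p = 1))
    warning("zero pooled variance with unequal means; reporting smallest positive p",
            call. = FALSE)
    return(list(t = sign(mean(x) - mean(y)) * Inf, p = .Machine$double.xmin))
  }
  fit <- stats::t.test(x, y, var.equal = TRUE)
  p <- fit$p.value
  if (p == 0) p <- .Machine$double.xmin
  list(t = unname(fit$statistic), p = p)
}

#' Per-protein differential ubiquitination results
#'
#' For every protein in the (filtered, imputed) matrix, computes the mean
#' log2 intensity per condition, the log2 fold change (silenced minus
#' control), the pooled-variance t statistic and two-tailed p-value, the
#' number of imputed replicates per condition, and a display category:
#'
#' * `qc_protein` — gene belongs to the QC panel (endogenously biotinylated
#'   carboxylases, ubiquitin, avidin); never callable as a substrate.
#' * `silenced_dub` — the silenced DUB itself, expected to drop.
#' * `up` / `down` — passes `|log2 FC| >= min_abs_log2_fc` and
#'   `p < max_p` in that direction.
#' * `not_significant` — everything else.
#'
#' Category precedence is `qc_protein` > `silenced_dub` > the rest.
#'
#' @param matrix A fully imputed `intensity_matrix`.
#' @param table The row-filtered `protein_group_table` the matrix came from
#'   (same rows, same order).
#' @param dub_name Gene symbol of the silenced DUB; if absent from the table
#'   a warning is emitted.
#' @param qc_genes Character vector of QC gene symbols; defaults to
#'   [qc_panel_genes()] of the default [qc_panel()].
#' @param thresholds A [default_thresholds()] object used for the up/down
#'   category assignment.
#' @param correction `"none"` (default) reports and thresholds raw t-test
#'   p-values, the screen's standard behaviour. `"bh"` additionally computes
#'   Benjamini-Hochberg adjusted p-values (`p_adjusted`) and uses them for
#'   category assignment and downstream calling — a deliberately stricter
#'   deviation from the standard workflow.
#' @return A data frame of class `"differential_result"` with one row per
#'   protein: `row_key`, `gene_name`, `description`, `log2_fc`, `p_value`,
#'   `t_statistic`, `mean_control`, `mean_silenced`, `n_imputed_control`,
#'   `n_imputed_silenced`, `unique_peptides`, `category` (and `p_adjusted`
#'   when `correction = "bh"`).
#' @export
compute_differential <- function(matrix, table, dub_name,
                                 qc_genes = qc_panel_genes(),
                                 thresholds = default_thresholds(),
                                 correction = c("none", "bh")) {
  correction <- match.arg(correction)
  stopifnot(inherits(matrix, "intensity_matrix"),
            inherits(table, "protein_group_table"))
  if (any(is.na(matrix$values))) {
    stop("matrix still contains missing values; run impute() first",
         call. = FALSE)
  }
  if (nrow(table) != nrow(matrix$values)) {
    stop("matrix and table disagree on the number of proteins", call. = FALSE)
  }
  design <- matrix$design
  ctrl <- design_labels(design, "control")
  sil <- design_labels(design, "silenced")
  vals <- matrix$values
  mask <- matrix$imputed_mask
  mean_ctrl <- rowMeans(vals[, ctrl, drop = FALSE])
  mean_sil <- rowMeans(vals[, sil, drop = FALSE])
  n_imp_ctrl <- rowSums(mask[, ctrl, drop = FALSE])
  n_imp_sil <- rowSums(mask[, sil, drop = FALSE])
  tt <- lapply(seq_len(nrow(vals)), function(i) {
    student_t_test(vals[i, sil], vals[i, ctrl])
  })
  res <- data.frame(
    row_key = matrix$row_keys,
    gene_name = table$gene_name,
    description = table$description,
    log2_fc = mean_sil - mean_ctrl,
    p_value = vapply(tt, `[[`, numeric(1), "p"),
    t_statistic = vapply(tt, `[[`, numeric(1), "t"),
    mean_control = mean_ctrl,
    mean_silenced = mean_sil,
    n_imputed_control = as.integer(n_imp_ctrl),
    n_imputed_silenced = as.integer(n_imp_sil),
    unique_peptides = table$unique_peptides,
    stringsAsFactors = FALSE
  )
  rownames(res) <- NULL
  if (correction == "bh") {
    res$p_adjusted <- stats::p.adjust(res$p_value, method = "BH")
  }
  p_eff <- if (correction == "bh") res$p_adjusted else res$p_value
  is_qc <- res$gene_name %in% qc_genes
  is_dub <- res$gene_name == dub_name & !is_qc
  if (!any(res$gene_name == dub_name)) {
    warning(sprintf("silenced DUB '%s' not detected in the table", dub_name),
            call. = FALSE)
  }
  sig <- p_eff < thresholds$max_p
  cat_ <- rep("not_significant", nrow(res))
  cat_[sig & res$log2_fc >= thresholds$min_abs_log2_fc] <- "up"
  cat_[sig & res$log2_fc <= -thresholds$min_abs_log2_fc] <- "down"
  cat_[is_dub] <- "silenced_dub"
  cat_[is_qc] <- "qc_protein"
  res$category <- cat_
  attr(res, "dub_name") <- dub_name
  attr(res, "n_reps") <- c(control = length(ctrl), silenced = length(sil))
  class(res) <- c("differential_result", "data.frame")
  res
}

#' Imputation-count criterion for substrate calls
#'
#' A protein's quantification is trusted when at least one condition
#' contains no imputed replicates at all, or when each condition contains at
#' most one imputed replicate.
#'
#' @param n_imp_ctrl,n_imp_sil Number of imputed replicates per condition
#'   (vectorized).
#' @param n_reps Replicate count per condition (used for validation only).
#' @return Logical vector: TRUE where the criterion holds.
#' @examples
#' imputation_rule(0, 3, 3)  # TRUE: control fully observed
#' imputation_rule(2, 1, 3)  # FALSE
#' @export
imputation_rule <- function(n_imp_ctrl, n_imp_sil, n_reps = 3L) {
  if (any(n_imp_ctrl < 0 | n_imp_ctrl > n_reps) ||
      any(n_imp_sil < 0 | n_imp_sil > n_reps)) {
    stop("imputed counts must lie in [0, n_reps]", call. = FALSE)
  }
  (n_imp_ctrl == 0 | n_imp_sil == 0) | (n_imp_ctrl <= 1 & n_imp_sil <= 1)
}

threshold_direction_ok <- function(log2_fc, thresholds) {
  switch(thresholds$direction,
         up = log2_fc >= thresholds$min_abs_log2_fc,
         down = log2_fc <= -thresholds$min_abs_log2_fc,
         both = abs(log2_fc) >= thresholds$min_abs_log2_fc)
}

sort_calls <- function(df) {
  df[order(-abs(df$log2_fc), df$p_value, df$gene_name), , drop = FALSE]
}

#' Call putative DUB substrates with the three-criterion rule
#'
#' The initial selection holds every protein with a significant fold change
#' in the requested direction (criterion 1). Putative substrates are the
#' subset that additionally carries at least `min_unique_peptides` unique
#' peptides (criterion 2) and passes the [imputation_rule()] (criterion 3).
#' QC-panel proteins and the silenced DUB itself are never callable. Both
#' lists are sorted by descending absolute fold change, ties broken by
#' ascending p-value then gene name.
#'
#' @param results A `differential_result` data frame.
#' @param thresholds A [default_thresholds()] object.
#' @return A list with data frames `initial_selection` and
#'   `putative_substrates` (the latter a subset of the former).
#' @export
call_substrates <- function(results, thresholds = default_thresholds()) {
  stopifnot(inherits(results, "differential_result"))
  n_reps <- attr(results, "n_reps")
  if (is.null(n_reps)) n_reps <- c(control = 3L, silenced = 3L)
  callable <- !(results$category %in% c("qc_protein", "silenced_dub"))
  p_eff <- results$p_adjusted %||% results$p_value
  initial <- callable &
    threshold_direction_ok(results$log2_fc, thresholds) &
    p_eff < thresholds$max_p
  keep_rule <- imputation_rule(results$n_imputed_control,
                               results$n_imputed_silenced,
                               max(n_reps))
  putative <- initial &
    results$unique_peptides >= thresholds$min_unique_peptides &
    keep_rule
  ini <- sort_calls(as.data.frame(results)[initial, , drop = FALSE])
  put <- sort_calls(as.data.frame(results)[putative, , drop = FALSE])
  rownames(ini) <- rownames(put) <- NULL
  list(initial_selection = ini, putative_substrates = put)
}

#' Volcano-plot dataset
#'
#' One record per differential result: gene, description, log2 fold change,
#' -log10 p-value and the display category. A p-value of 0 (not produced by
#' the t-test, but possible in degenerate data) is replaced by the smallest
#' representable positive double before the log.
#'
#' @param results A `differential_result` data frame.
#' @return A data frame with columns `gene`, `description`, `log2_fc`,
#'   `neg_log10_p`, `category`.
#' @export
volcano_dataset <- function(results) {
  stopifnot(inherits(results, "differential_result"))
  p <- results$p_value
  p[p == 0] <- .Machine$double.xmin
  data.frame(
    gene = results$gene_name,
    description = results$description,
    log2_fc = results$log2_fc,
    neg_log10_p = -log10(p),
    category = results$category,
    stringsAsFactors = FALSE
  )
}
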