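# Small in-code fixtures shared across test files.

tiny_design <- function(dub = "USP9X", n = 3L) {
  experiment_design(dub,
                    control = paste0("Ctr_", seq_len(n)),
                    silenced = paste0("si", dub, "_", seq_len(n)))
}

# Build a protein_group_table directly, bypassing file I/O.
# lfq: matrix proteins x samples (columns in design order).
make_pg_table <- function(lfq, gene = sprintf("G%03d", seq_len(nrow(lfq))),
                          unique_peptides = rep(5L, nrow(lfq)),
                          reverse = rep(FALSE, nrow(lfq)),
                          contaminant = rep(FALSE, nrow(lfq)),
                          only_by_site = rep(FALSE, nrow(lfq)),
                          design = tiny_design()) {
  stopifnot(ncol(lfq) == nrow(design))
  tab <- data.frame(protein_ids = sprintf("P%03d", seq_len(nrow(lfq))),
                    gene_name = gene,
                    description = paste("protein", gene),
                    unique_peptides = as.integer(unique_peptides),
                    reverse = reverse, contaminant = contaminant,
                    only_by_site = only_by_site,
                    stringsAsFactors = FALSE)
  for (j in seq_len(ncol(lfq))) tab[[design$sample_label[j]]] <- lfq[, j]
  attr(tab, "sample_labels") <- design$sample_label
  attr(tab, "design") <- design
  class(tab) <- c("protein_group_table", "data.frame")
  tab
}

# A differential_result built from a filtered table + imputed matrix, with
# the intensities chosen so fold changes / p-values are easy to reason about.
make_differential <- function(lfq_log2, design = tiny_design(), ...) {
  tab <- make_pg_table(2^lfq_log2, design = design, ...)
  im <- impute(log2_transform(tab), seed = 1L)
  suppressWarnings(
    compute_differential(im, tab, dub_name = attr(design, "dub_name")))
}

# Build a glygly_table directly.
make_gg_table <- function(protein = "P1", position = 5L, prob = 0.9,
                          intensity = NULL,
                          reverse = FALSE, contaminant = FALSE,
                          design = tiny_design()) {
  n <- max(length(protein), length(position), length(prob))
  tab <- data.frame(protein_id = rep_len(protein, n),
                    gene_name = rep_len(protein, n),
                    position = as.integer(rep_len(position, n)),
                    localization_prob = rep_len(prob, n),
                    reverse = rep_len(reverse, n),
                    contaminant = rep_len(contaminant, n),
                    stringsAsFactors = FALSE)
  if (is.null(intensity)) intensity <- matrix(1000, n, nrow(design))
  for (j in seq_len(nrow(design))) tab[[design$sample_label[j]]] <- intensity[, j]
  attr(tab, "sample_labels") <- design$sample_label
  attr(tab, "design") <- design
  class(tab) <- c("glygly_table", "data.frame")
  tab
}

# Independent closed-form pooled-variance t-test used as the oracle.
oracle_t <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp2 <- ((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2)
  t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
  list(t = t, p = 2 * pt(-abs(t), df = nx + ny - 2))
}

quiet_pipeline <- function(...) {
  suppressWarnings(run_pipeline(..., verbose = FALSE))
}
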