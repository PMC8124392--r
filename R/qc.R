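#' @title Quality control and reproducibility diagnostics
#' @description Sanity checks exploiting the biology of the biotin
#'   pull-down: endogenously biotinylated carboxylases (ACACA, HLCS, MCCC1,
#'   PC, PCCA) report on the amount of biological material, ubiquitin on the
#'   total ubiquitinated material, and avidin on the affinity resin — none
#'   should change between control and DUB-silenced samples. Replicate
#'   agreement is assessed with Pearson correlation on observed (never
#'   imputed) intensities and with identification-overlap counts.
#' @name qc_repro
NULL

#' QC gene panel
#'
#' @param carboxylases Endogenously biotinylated carboxylase gene symbols.
#' @param ubiquitin Identifiers matched as ubiquitin. The ectopic
#'   biotinylatable ubiquitin construct is not a UniProt entry, so the set
#'   is configurable; the defaults cover the human ubiquitin-coding genes.
#' @param avidin Identifiers matched as avidin.
#' @return A list of class `"qc_panel"`.
#' @export
qc_panel <- function(carboxylases = c("ACACA", "HLCS", "MCCC1", "PC", "PCCA"),
                     ubiquitin = c("UBB", "UBC", "UBA52", "RPS27A"),
                     avidin = "AVD") {
  structure(list(carboxylases = carboxylases, ubiquitin = ubiquitin,
                 avidin = avidin),
            class = "qc_panel")
}

#' All gene symbols of a QC panel
#' @param panel A [qc_panel()].
#' @return Character vector.
#' @export
qc_panel_genes <- function(panel = qc_panel()) {
  unique(unlist(panel, use.names = FALSE))
}

#' QC report on panel proteins
#'
#' Lists the fold change and p-value of each detected panel member and flags
#' those that are significant at the given thresholds (in either direction).
#' The report passes when no detected member is significant; members absent
#' from the data are reported as not detected, not as failures. An empty or
#' fully undetected panel passes vacuously, with a warning.
#'
#' @param results A `differential_result` data frame.
#' @param panel A [qc_panel()].
#' @param thresholds A [default_thresholds()] object.
#' @return A list of class `"qc_report"`: `members` (data frame with `gene`,
#'   `role`, `detected`, `log2_fc`, `p_value`, `significant`), `pass`
#'   (logical), `offenders` (gene symbols driving a failure).
#' @export
qc_report <- function(results, panel = qc_panel(),
                      thresholds = default_thresholds()) {
  stopifnot(inherits(results, "differential_result"),
            inherits(panel, "qc_panel"))
  genes <- qc_panel_genes(panel)
  role <- rep(names(panel), lengths(panel))[match(genes, unlist(panel, use.names = FALSE))]
  idx <- match(genes, results$gene_name)
  detected <- !is.na(idx)
  if (!any(detected)) {
    warning("no QC panel member detected; QC passes vacuously", call. = FALSE)
  }
  fc <- ifelse(detected, results$log2_fc[idx], NA_real_)
  p <- ifelse(detected, results$p_value[idx], NA_real_)
  significant <- detected & abs(fc) >= thresholds$min_abs_log2_fc &
    p < thresholds$max_p
  members <- data.frame(gene = genes, role = role, detected = detected,
                        log2_fc = fc, p_value = p,
                        significant = significant,
                        stringsAsFactors = FALSE)
  structure(list(members = members,
                 pass = !any(significant),
                 offenders = genes[significant]),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("QC report:", if (x$pass) "PASS" else
    paste0("FAIL (", paste(x$offenders, collapse = ", "), ")"), "\n")
  print(x$members, row.names = FALSE)
  invisible(x)
}

#' Write a QC report as JSON
#' @param report A [qc_report()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_qc_report_json <- function(report, path) {
  stopifnot(inherits(report, "qc_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, na = "null", pretty = TRUE)
  invisible(path)
}

#' Replicate Pearson correlation on observed intensities
#'
#' Pairwise Pearson coefficients between sample columns of the log2
#' intensity matrix, computed over pairwise-complete *observed* values:
#' imputed cells are excluded so the imputation model cannot inflate a
#' data-quality metric. Pairs sharing fewer than `min_common` observed
#' proteins are reported as `NA`.
#'
#' @param matrix An `intensity_matrix` (imputed or not).
#' @param min_common Minimum number of jointly observed proteins per pair.
#' @return A symmetric samples x samples matrix with unit diagonal.
#' @export
replicate_correlation <- function(matrix, min_common = 3L) {
  stopifnot(inherits(matrix, "intensity_matrix"))
  vals <- matrix$values
  vals[matrix$imputed_mask] <- NA_real_
  n <- ncol(vals)
  out <- diag(1, n)
  dimnames(out) <- list(colnames(vals), colnames(vals))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- !is.na(vals[, i]) & !is.na(vals[, j])
      out[i, j] <- out[j, i] <-
        if (sum(ok) >= min_common) {
          stats::cor(vals[ok, i], vals[ok, j])
        } else NA_real_
    }
  }
  out
}

#' Venn region counts for identification overlap
#'
#' Counts, for 2 to 5 named sets, how many elements fall in each of the
#' 2^k - 1 regions of the Venn diagram. Regions are labelled by the sorted
#' set names joined with `"&"`; a label names the sets an element belongs to
#' exactly (e.g. `"A"` = only in A, `"A&B"` = in A and B but no other set).
#'
#' @param id_sets Named list of 2-5 vectors (coerced to sets).
#' @return Named integer vector over all non-empty regions; the counts sum
#'   to the size of the union.
#' @examples
#' overlap_counts(list(A = c(1, 2), B = c(2, 3)))
#' @export
overlap_counts <- function(id_sets) {
  k <- length(id_sets)
  if (k < 2L || k > 5L) stop("need between 2 and 5 sets", call. = FALSE)
  if (is.null(names(id_sets)) || any(!nzchar(names(id_sets)))) {
    stop("sets must be named", call. = FALSE)
  }
  id_sets <- lapply(id_sets, unique)
  nm <- sort(names(id_sets))
  id_sets <- id_sets[nm]
  universe <- unique(unlist(id_sets, use.names = FALSE))
  membership <- vapply(id_sets, function(s) universe %in% s,
                       logical(length(universe)))
  if (length(universe) == 1L) membership <- matrix(membership, nrow = 1L,
                                                   dimnames = list(NULL, nm))
  region <- apply(membership, 1L, function(b) paste(nm[b], collapse = "&"))
  labels <- unlist(lapply(seq_len(k), function(m) {
    utils::combn(nm, m, paste, collapse = "&")
  }))
  counts <- table(factor(region, levels = labels))
  out <- as.integer(counts)
  names(out) <- labels
  out
}

#' Containment of the smaller of two identification sets in the larger
#'
#' @param set_a,set_b Non-empty vectors (coerced to sets).
#' @return `|A intersect B| / min(|A|, |B|)`, in \[0, 1\].
#' @export
pairwise_containment <- function(set_a, set_b) {
  set_a <- unique(set_a); set_b <- unique(set_b)
  if (!length(set_a) || !length(set_b)) {
    stop("both sets must be non-empty", call. = FALSE)
  }
  length(intersect(set_a, set_b)) / min(length(set_a), length(set_b))
}
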