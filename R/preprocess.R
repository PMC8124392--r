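#' @title Row filtering, log2 transform and left-censored imputation
#' @description The standard preprocessing applied to a protein-group table
#'   before differential testing: remove decoy / contaminant /
#'   identified-by-site rows and rows without evidence, transform LFQ
#'   intensities to log2, and replace missing values with draws from a
#'   normal distribution downshifted below the observed one — a model of
#'   expression below the instrument's detection limit.
#' @name preprocess
NULL

#' Remove protein-group rows that cannot be quantified
#'
#' Drops reverse (decoy) hits, potential contaminants, proteins only
#' identified by a modification site, proteins with no unique peptides and
#' proteins never quantified in any sample (all LFQ values 0). Each removed
#' row is counted once in the removal log, under the first matching reason
#' in that order.
#'
#' @param table A `protein_group_table` from [read_protein_groups()].
#' @return A list with elements `table` (the retained rows, same class and
#'   attributes) and `removal_log` (named integer vector with counts for
#'   `reverse`, `contaminant`, `only_by_site`, `no_unique_peptides`,
#'   `no_intensity`).
#' @examples
#' \dontrun{
#' flt <- filter_rows(pg)
#' flt$removal_log
#' }
#' @export
filter_rows <- function(table) {
  stopifnot(inherits(table, "protein_group_table"))
  labels <- attr(table, "sample_labels")
  lfq <- as.matrix(table[labels])
  all_zero <- rowSums(lfq > 0) == 0L
  reasons <- rep(NA_character_, nrow(table))
  pick <- function(cond, reason) {
    hit <- cond & is.na(reasons)
    reasons[hit] <<- reason
  }
  pick(table$reverse, "reverse")
  pick(table$contaminant, "contaminant")
  pick(table$only_by_site, "only_by_site")
  pick(table$unique_peptides == 0L, "no_unique_peptides")
  pick(all_zero, "no_intensity")
  keep <- is.na(reasons)
  removal_log <- vapply(
    c("reverse", "contaminant", "only_by_site", "no_unique_peptides",
      "no_intensity"),
    function(r) sum(reasons == r, na.rm = TRUE), integer(1))
  kept <- table[keep, , drop = FALSE]
  rownames(kept) <- NULL
  attr(kept, "sample_labels") <- labels
  attr(kept, "design") <- attr(table, "design")
  class(kept) <- class(table)
  list(table = kept, removal_log = removal_log)
}

#' Log2-transform LFQ intensities into an intensity matrix
#'
#' LFQ values of 0 encode "not quantified" and become missing (`NA`);
#' positive values become their log2. The returned object carries a boolean
#' imputation mask (all `FALSE` until [impute()] runs).
#'
#' @param table A row-filtered `protein_group_table`.
#' @return An object of class `"intensity_matrix"`: a list with `values`
#'   (proteins x samples numeric matrix, log2 scale), `imputed_mask`
#'   (logical matrix of the same shape), `row_keys` (protein identifiers),
#'   `sample_labels` and `design`.
#' @export
log2_transform <- function(table) {
  stopifnot(inherits(table, "protein_group_table"))
  labels <- attr(table, "sample_labels")
  lfq <- as.matrix(table[labels])
  values <- ifelse(lfq > 0, log2(lfq), NA_real_)
  keys <- make.unique(table$protein_ids, sep = "#")
  dimnames(values) <- list(keys, labels)
  structure(
    list(values = values,
         imputed_mask = matrix(FALSE, nrow(values), ncol(values),
                               dimnames = dimnames(values)),
         row_keys = keys,
         sample_labels = labels,
         design = attr(table, "design")),
    class = "intensity_matrix"
  )
}

#' @export
print.intensity_matrix <- function(x, ...) {
  cat(sprintf("intensity_matrix: %d proteins x %d samples; %d missing, %d imputed\n",
              nrow(x$values), ncol(x$values), sum(is.na(x$values)),
              sum(x$imputed_mask)))
  invisible(x)
}

#' Impute missing values from a downshifted normal distribution
#'
#' Missing log2 intensities are assumed to reflect abundance below the
#' detection limit and are replaced by draws from a narrowed normal
#' distribution shifted below the observed values. With observed mean m and
#' standard deviation s (per sample column by default), each missing cell is
#' drawn independently from Normal(m - downshift * s, (width * s)^2). The
#' defaults `width = 0.3` and `downshift = 1.8` are the Perseus-style values
#' used by this workflow.
#'
#' Draws come from a single seeded generator consumed in row-major cell
#' order, so results are reproducible across platforms given `seed`.
#'
#' @param matrix An `intensity_matrix` that has not been imputed yet.
#' @param width Width of the imputation distribution, as a multiple of the
#'   observed standard deviation (> 0).
#' @param downshift Downshift of its mean, in units of the observed standard
#'   deviation (>= 0).
#' @param mode `"per_column"` (default) computes m and s per sample column
#'   from that column's observed values; `"whole_matrix"` uses the observed
#'   values of the entire matrix.
#' @param seed Optional integer seed for the random draws.
#' @return The `intensity_matrix` with no missing values and `imputed_mask`
#'   marking exactly the replaced cells. Observed cells are untouched.
#' @examples
#' \dontrun{
#' im <- impute(log2_transform(flt$table), seed = 1L)
#' }
#' @export
impute <- function(matrix, width = 0.3, downshift = 1.8,
                   mode = c("per_column", "whole_matrix"), seed = NULL) {
  stopifnot(inherits(matrix, "intensity_matrix"))
  mode <- match.arg(mode)
  if (any(matrix$imputed_mask)) {
    stop("matrix has already been imputed", call. = FALSE)
  }
  if (!(is.numeric(width) && width > 0)) stop("`width` must be > 0", call. = FALSE)
  if (!(is.numeric(downshift) && downshift >= 0)) {
    stop("`downshift` must be >= 0", call. = FALSE)
  }
  vals <- matrix$values
  obs <- !is.na(vals)
  if (sum(obs) < 2L) {
    stop("fewer than 2 observed values in the whole matrix; cannot impute",
         call. = FALSE)
  }
  m_all <- mean(vals[obs])
  s_all <- stats::sd(vals[obs])
  col_ids <- colnames(vals)
  if (is.null(col_ids)) col_ids <- as.character(seq_len(ncol(vals)))
  if (mode == "per_column") {
    mu <- sd_ <- numeric(ncol(vals))
    for (j in seq_len(ncol(vals))) {
      v <- vals[obs[, j], j]
      if (length(v) < 2L) {
        warning(sprintf(
          "column '%s' has %d observed value(s); falling back to whole-matrix statistics",
          col_ids[j], length(v)), call. = FALSE)
        mu[j] <- m_all - downshift * s_all
        sd_[j] <- width * s_all
      } else {
        mu[j] <- mean(v) - downshift * stats::sd(v)
        sd_[j] <- width * stats::sd(v)
      }
    }
  } else {
    mu <- rep(m_all - downshift * s_all, ncol(vals))
    sd_ <- rep(width * s_all, ncol(vals))
  }
  if (!is.null(seed)) set.seed(seed)
  # row-major order: sort missing cells by (row, column)
  miss <- which(!obs, arr.ind = TRUE)
  if (nrow(miss)) {
    ord <- order(miss[, "row"], miss[, "col"])
    miss <- miss[ord, , drop = FALSE]
    draws <- stats::rnorm(nrow(miss), mean = mu[miss[, "col"]],
                          sd = sd_[miss[, "col"]])
    vals[miss] <- draws
    matrix$imputed_mask[miss] <- TRUE
  }
  matrix$values <- vals
  matrix
}
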