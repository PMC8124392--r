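#' Describe a control vs DUB-silenced experiment design
#'
#' An experiment compares biotin pull-downs from cells treated with a control
#' (scramble) siRNA against cells in which one deubiquitinase (DUB) has been
#' silenced. The default layout is the triplicate design used throughout the
#' package: three control and three silenced replicates.
#'
#' @param dub_name Gene symbol of the silenced DUB (e.g. `"USP9X"`).
#' @param control Character vector of control sample labels. Each label must
#'   match an `LFQ intensity <label>` column of the protein-group table the
#'   design is applied to.
#' @param silenced Character vector of DUB-silenced sample labels.
#' @param experiment_id Free-text identifier of the experiment.
#'
#' @return A data frame of class `"experiment_design"` with columns
#'   `sample_label`, `condition` (`"control"` or `"silenced"`) and
#'   `replicate_index`, plus attributes `dub_name` and `experiment_id`.
#' @examples
#' experiment_design("USP9X")
#' @export
experiment_design <- function(dub_name,
                              control = paste0("Ctr_", 1:3),
                              silenced = paste0("si", dub_name, "_", 1:3),
                              experiment_id = paste0(dub_name, "_screen")) {
  stopifnot(is.character(dub_name), length(dub_name) == 1L, nzchar(dub_name))
  if (length(control) < 2L || length(silenced) < 2L) {
    stop("need at least 2 samples per condition", call. = FALSE)
  }
  labels <- c(control, silenced)
  if (anyDuplicated(labels)) {
    stop("sample labels must be unique: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "),
         call. = FALSE)
  }
  design <- data.frame(
    sample_label = labels,
    condition = rep(c("control", "silenced"), c(length(control), length(silenced))),
    replicate_index = c(seq_along(control), seq_along(silenced)),
    stringsAsFactors = FALSE
  )
  attr(design, "dub_name") <- dub_name
  attr(design, "experiment_id") <- experiment_id
  class(design) <- c("experiment_design", "data.frame")
  design
}

#' @export
print.experiment_design <- function(x, ...) {
  cat("Experiment design:", attr(x, "experiment_id"),
      "(silenced DUB:", attr(x, "dub_name"), ")\n")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

design_labels <- function(design, condition = NULL) {
  if (is.null(condition)) return(design$sample_label)
  design$sample_label[design$condition == condition]
}

assert_design <- function(design) {
  if (!inherits(design, "experiment_design")) {
    stop("`design` must be created with experiment_design()", call. = FALSE)
  }
  invisible(design)
}
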