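#' Sample design for a two-condition phosphoproteomics study
#'
#' Builds and validates the sample design underlying all downstream analyses:
#' two conditions (break-proficient `SPO11` versus catalytically dead
#' `spo11-YF`), replicated cultures, and one or two acquisition methods
#' (`DDA`, `DIA`). Each method is analysed as its own 3-versus-3 (at
#' defaults) block.
#'
#' @param sample_id Character vector of unique sample identifiers.
#' @param condition Character vector, each `"SPO11"` or `"spo11-YF"`.
#' @param replicate Integer vector of replicate indices (1-based).
#' @param method Character vector, each `"DDA"` or `"DIA"`.
#'
#' @return A tibble with class `phospho_design` and columns `sample_id`,
#'   `condition`, `replicate`, `method`.
#'
#' @examples
#' study_design()
#' @export
phospho_design <- function(sample_id, condition, replicate, method) {
  design <- tibble::tibble(
    sample_id = as.character(sample_id),
    condition = as.character(condition),
    replicate = as.integer(replicate),
    method    = as.character(method)
  )
  validate_design(design)
}

#' @rdname phospho_design
#' @param n_replicates Replicates per condition for the default design.
#' @param methods Acquisition methods to include.
#' @export
study_design <- function(n_replicates = 3, methods = c("DDA", "DIA")) {
  grid <- expand.grid(
    replicate = seq_len(n_replicates),
    condition = c("SPO11", "spo11-YF"),
    method = methods,
    stringsAsFactors = FALSE
  )
  phospho_design(
    sample_id = sprintf(
      "%s_%s_r%d", grid$method,
      ifelse(grid$condition == "SPO11", "SPO11", "spo11YF"),
      grid$replicate
    ),
    condition = grid$condition,
    replicate = grid$replicate,
    method = grid$method
  )
}

#' @rdname phospho_design
#' @param design A data frame with the four design columns.
#' @export
validate_design <- function(design) {
  design <- tibble::as_tibble(design)
  required <- c("sample_id", "condition", "replicate", "method")
  missing_cols <- setdiff(required, names(design))
  if (length(missing_cols) > 0) {
    stop("design is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(design$sample_id)) {
    stop("design sample_ids must be unique", call. = FALSE)
  }
  bad_cond <- setdiff(unique(design$condition), c("SPO11", "spo11-YF"))
  if (length(bad_cond) > 0) {
    stop("unknown condition(s): ", paste(bad_cond, collapse = ", "),
         call. = FALSE)
  }
  bad_method <- setdiff(unique(design$method), c("DDA", "DIA"))
  if (length(bad_method) > 0) {
    stop("unknown method(s): ", paste(bad_method, collapse = ", "),
         call. = FALSE)
  }
  key <- paste(design$condition, design$replicate, design$method)
  if (anyDuplicated(key)) {
    stop("each (condition, replicate, method) combination may appear at most once",
         call. = FALSE)
  }
  for (m in unique(design$method)) {
    sub <- design[design$method == m, ]
    if (length(unique(sub$condition)) < 2) {
      stop("method ", m, " must have samples in both conditions", call. = FALSE)
    }
  }
  class(design) <- unique(c("phospho_design", class(design)))
  design
}

#' Intensity table container
#'
#' The central data structure: a numeric matrix of intensities (rows are
#' phosphosites, phosphopeptides or proteins; columns are samples) with
#' `NA` marking missing observations, a row-annotation tibble, the sample
#' design, and the current intensity scale. The scale moves only forward
#' through `raw` -> `ppm` -> `log2` (see [normalize_ppm()] and
#' [log2_transform()]).
#'
#' @param values Numeric matrix, rows x samples; `NA` = not detected.
#'   Negative values are rejected.
#' @param rows Tibble of row annotations; for site-level tables the columns
#'   `protein`, `position`, `residue`, `localization_prob`, `flags` are
#'   expected, for peptide-level tables `sequence`, `phospho_offset`,
#'   `protein`.
#' @param design A [phospho_design()] whose `sample_id`s match
#'   `colnames(values)` exactly (order included).
#' @param scale One of `"raw"`, `"ppm"`, `"log2"`.
#' @param level One of `"site"`, `"peptide"`, `"protein"`.
#'
#' @return An object of class `phospho_set`.
#' @export
phospho_set <- function(values, rows, design,
                        scale = c("raw", "ppm", "log2"),
                        level = c("site", "peptide", "protein")) {
  scale <- match.arg(scale)
  level <- match.arg(level)
  design <- validate_design(design)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (nrow(values) != nrow(rows)) {
    stop("values and rows disagree on row count", call. = FALSE)
  }
  if (is.null(colnames(values))) colnames(values) <- design$sample_id
  if (!identical(colnames(values), design$sample_id)) {
    stop("column names of values must equal design$sample_id in order",
         call. = FALSE)
  }
  if (any(values < 0, na.rm = TRUE)) {
    stop("intensities must be nonnegative", call. = FALSE)
  }
  structure(
    list(values = values, rows = tibble::as_tibble(rows),
         design = design, scale = scale, level = level),
    class = "phospho_set"
  )
}

#' @export
print.phospho_set <- function(x, ...) {
  cat(sprintf(
    "<phospho_set> %d %s rows x %d samples [scale: %s]\n",
    nrow(x$values), x$level, ncol(x$values), x$scale
  ))
  cat(sprintf(
    "  methods: %s | conditions: %s\n",
    paste(unique(x$design$method), collapse = ", "),
    paste(unique(x$design$condition), collapse = ", ")
  ))
  miss <- mean(is.na(x$values))
  cat(sprintf("  missing: %.1f%%\n", 100 * miss))
  invisible(x)
}

#' @export
dim.phospho_set <- function(x) dim(x$values)

#' Subset a phospho_set by row index
#'
#' @param x A `phospho_set`.
#' @param i Integer or logical row index.
#' @return A `phospho_set` with the selected rows, annotations kept in step.
#' @export
subset_rows <- function(x, i) {
  stopifnot(inherits(x, "phospho_set"))
  phospho_set(x$values[i, , drop = FALSE], x$rows[i, , drop = FALSE],
              x$design, scale = x$scale, level = x$level)
}

#' Restrict a phospho_set to one acquisition method
#'
#' @param x A `phospho_set`.
#' @param method `"DDA"` or `"DIA"`.
#' @return A `phospho_set` whose design and columns hold only that method's
#'   samples.
#' @export
restrict_method <- function(x, method) {
  stopifnot(inherits(x, "phospho_set"))
  keep <- x$design$method == method
  if (!any(keep)) stop("no samples for method ", method, call. = FALSE)
  design <- x$design[keep, , drop = FALSE]
  phospho_set(x$values[, design$sample_id, drop = FALSE], x$rows, design,
              scale = x$scale, level = x$level)
}

# Observed-value indicator used by both analysis arms: a value is "present"
# when it is non-missing (zeros are converted to NA at read time).
detection_matrix <- function(x) {
  !is.na(x$values)
}
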