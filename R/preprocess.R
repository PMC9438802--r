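#' Normalize each sample to parts per million
#'
#' Scales every sample column so that its observed (non-missing) intensities
#' sum to one million, making columns comparable across runs of different
#' total ion current. Missing entries stay missing. DDA and DIA tables are
#' normalized independently — each method was measured and analysed as its
#' own block — so restrict to one method first if the table holds both.
#'
#' @param x A `phospho_set` at scale `"raw"`.
#' @return The `phospho_set` at scale `"ppm"`.
#' @export
normalize_ppm <- function(x) {
  stopifnot(inherits(x, "phospho_set"))
  if (x$scale != "raw") {
    stop("normalize_ppm expects a raw-scale table (got ", x$scale, ")",
         call. = FALSE)
  }
  values <- x$values
  totals <- colSums(values, na.rm = TRUE)
  empty <- totals == 0
  if (any(empty)) {
    warning("column(s) with no observed values left all-missing: ",
            paste(colnames(values)[empty], collapse = ", "), call. = FALSE)
    totals[empty] <- NA_real_
  }
  values <- sweep(values, 2, totals, "/") * 1e6
  out <- x
  out$values <- values
  out$scale <- "ppm"
  out
}

#' Log2-transform intensities
#'
#' Every observed value v becomes log2(v); missing stays missing. No
#' pseudocount is added: zeros must already have been recorded as missing
#' at read time, and a zero at this stage is an error rather than a silent
#' -Inf.
#'
#' @param x A `phospho_set` at scale `"ppm"`.
#' @return The `phospho_set` at scale `"log2"`.
#' @export
log2_transform <- function(x) {
  stopifnot(inherits(x, "phospho_set"))
  if (x$scale != "ppm") {
    stop("log2_transform expects a ppm-scale table (got ", x$scale, ")",
         call. = FALSE)
  }
  if (any(x$values == 0, na.rm = TRUE)) {
    stop("zero intensity at log step: zeros must be converted to missing at read time",
         call. = FALSE)
  }
  out <- x
  out$values <- log2(x$values)
  out$scale <- "log2"
  out
}

#' Remove rows with too many missing measurements
#'
#' Quality filter applied per acquisition method before classification:
#' rows with more than `max_missing` missing values across the method's
#' samples are removed (at the 3 + 3 defaults, a site must be observed in
#' at least 3 of the 6 measurements). Values are never altered, only row
#' membership; a site may pass in one method and fail in the other.
#'
#' @param x A `phospho_set` restricted to a single method.
#' @param max_missing Maximum missing values tolerated per row (default 3).
#' @return The filtered `phospho_set`.
#' @export
filter_min_detection <- function(x, max_missing = 3) {
  stopifnot(inherits(x, "phospho_set"))
  if (length(unique(x$design$method)) > 1) {
    stop("filter_min_detection expects a single-method table; use restrict_method()",
         call. = FALSE)
  }
  n_missing <- rowSums(is.na(x$values))
  subset_rows(x, n_missing <= max_missing)
}
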