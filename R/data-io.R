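#' Read a site-level phosphoproteomics report
#'
#' Parses a tab-separated site-level report (one row per phosphosite) into a
#' [phospho_set()]. The `"sty-sites"` dialect expects the columns `protein`,
#' `position`, `residue`, `localization_prob`, `contaminant`, `reverse`,
#' plus one intensity column per design sample named by its `sample_id`.
#' Upstream search engines write 0 for "not detected"; by default zeros are
#' recorded as missing at read time so that missingness is preserved for the
#' presence/absence arm.
#'
#' Identification-quality filtering is deliberately *not* applied here; see
#' [filter_flagged()] and [filter_localization()].
#'
#' @param path Path to a TSV file.
#' @param design A [phospho_design()].
#' @param dialect Report dialect; only `"sty-sites"` is defined for
#'   site-level reports. Unknown dialects are rejected, never guessed.
#' @param zero_as_missing Convert intensity 0 to missing (default `TRUE`).
#' @return A `phospho_set` at scale `"raw"`, level `"site"`.
#' @export
read_site_report <- function(path, design, dialect = "sty-sites",
                             zero_as_missing = TRUE) {
  design <- validate_design(design)
  if (!identical(dialect, "sty-sites")) {
    stop("unknown site-report dialect: ", dialect, call. = FALSE)
  }
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("protein", "position", "residue", "localization_prob",
                "contaminant", "reverse")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols) > 0) {
    stop("site report is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  extra <- setdiff(names(tab), c(required, design$sample_id))
  if (length(extra) > 0) {
    stop("intensity column(s) not matching any design sample: ",
         paste(extra, collapse = ", "), call. = FALSE)
  }
  missing_samples <- setdiff(design$sample_id, names(tab))
  if (length(missing_samples) > 0) {
    stop("site report is missing intensity column(s) for design sample(s): ",
         paste(missing_samples, collapse = ", "), call. = FALSE)
  }
  rows <- tibble::tibble(
    protein = as.character(tab$protein),
    position = as.integer(tab$position),
    residue = as.character(tab$residue),
    localization_prob = as.numeric(tab$localization_prob),
    contaminant = parse_flag(tab$contaminant),
    reverse = parse_flag(tab$reverse)
  )
  if (nrow(rows) > 0 && any(!rows$residue %in% c("S", "T", "Y"))) {
    stop("phosphoacceptor residue must be one of S, T, Y", call. = FALSE)
  }
  values <- as.matrix(tab[, design$sample_id, drop = FALSE])
  storage.mode(values) <- "double"
  if (any(values < 0, na.rm = TRUE)) {
    stop("intensities must be nonnegative", call. = FALSE)
  }
  if (zero_as_missing) values[values == 0] <- NA_real_
  rownames(values) <- NULL
  phospho_set(values, rows, design, scale = "raw", level = "site")
}

#' Read a peptide-level phosphoproteomics report
#'
#' Parses the `"collapsed-peptides"` dialect (one row per phosphopeptide):
#' columns `sequence`, `phospho_offsets` (semicolon-separated 1-based
#' within-peptide positions), `protein`, plus one intensity column per
#' design sample. Offsets beyond the peptide length are a record-level
#' validation error.
#'
#' @inheritParams read_site_report
#' @return A `phospho_set` at scale `"raw"`, level `"peptide"`. Its `rows`
#'   tibble carries `sequence`, `phospho_offsets` (list column of integer
#'   vectors) and `protein`.
#' @export
read_peptide_report <- function(path, design, zero_as_missing = TRUE) {
  design <- validate_design(design)
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(
                           phospho_offsets = readr::col_character(),
                           .default = readr::col_guess()
                         ))
  required <- c("sequence", "phospho_offsets", "protein")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols) > 0) {
    stop("peptide report is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  missing_samples <- setdiff(design$sample_id, names(tab))
  if (length(missing_samples) > 0) {
    stop("peptide report is missing intensity column(s) for design sample(s): ",
         paste(missing_samples, collapse = ", "), call. = FALSE)
  }
  offsets <- lapply(strsplit(as.character(tab$phospho_offsets), ";",
                             fixed = TRUE),
                    function(v) as.integer(v))
  seqs <- as.character(tab$sequence)
  for (i in seq_along(seqs)) {
    off <- offsets[[i]]
    if (length(off) == 0 || anyNA(off) || any(off < 1) ||
        any(off > nchar(seqs[i]))) {
      stop(sprintf(
        "row %d: phospho offset out of bounds for peptide '%s'", i, seqs[i]
      ), call. = FALSE)
    }
  }
  rows <- tibble::tibble(
    sequence = seqs,
    phospho_offsets = offsets,
    protein = as.character(tab$protein)
  )
  values <- as.matrix(tab[, design$sample_id, drop = FALSE])
  storage.mode(values) <- "double"
  if (any(values < 0, na.rm = TRUE)) {
    stop("intensities must be nonnegative", call. = FALSE)
  }
  if (zero_as_missing) values[values == 0] <- NA_real_
  rownames(values) <- NULL
  phospho_set(values, rows, design, scale = "raw", level = "peptide")
}

parse_flag <- function(x) {
  if (is.logical(x)) return(ifelse(is.na(x), FALSE, x))
  x <- as.character(x)
  x[is.na(x)] <- ""
  x %in% c("+", "TRUE", "true", "1")
}

#' Remove contaminant and reverse-search rows
#'
#' Rows flagged as contaminants or as hits from the reversed-decoy search
#' are removed; row order is otherwise preserved. Idempotent.
#'
#' @param x A site-level `phospho_set` whose rows carry `contaminant` and
#'   `reverse` logical columns.
#' @return The filtered `phospho_set`.
#' @export
filter_flagged <- function(x) {
  stopifnot(inherits(x, "phospho_set"))
  if (!all(c("contaminant", "reverse") %in% names(x$rows))) {
    stop("rows lack contaminant/reverse flag columns", call. = FALSE)
  }
  keep <- !(x$rows$contaminant | x$rows$reverse)
  subset_rows(x, keep)
}

#' Filter phosphosites on localization probability
#'
#' Retains sites whose phosphate-localization probability is at least
#' `min_prob`. The threshold is inclusive (a probability of exactly 0.9
#' passes at the default), matching the upstream tool's convention.
#' Applied only where a probability column exists (site-level reports);
#' peptide-level tables without one pass through unchanged.
#'
#' @param x A `phospho_set`.
#' @param min_prob Minimum localization probability; default 0.9.
#' @return The filtered `phospho_set`.
#' @export
filter_localization <- function(x, min_prob = 0.9) {
  stopifnot(inherits(x, "phospho_set"))
  if (!"localization_prob" %in% names(x$rows)) return(x)
  keep <- !is.na(x$rows$localization_prob) &
    x$rows$localization_prob >= min_prob
  subset_rows(x, keep)
}

#' Read a proteome from FASTA
#'
#' @param path Path to an (uncompressed) amino-acid FASTA file.
#' @return A named character vector, one sequence per accession. Accessions
#'   are the first whitespace-delimited token of each header. Duplicate
#'   accessions are an error.
#' @export
read_fasta <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  acc <- sub("\\s.*$", "", names(aa))
  if (anyDuplicated(acc)) {
    stop("duplicate FASTA accession(s): ",
         paste(unique(acc[duplicated(acc)]), collapse = ", "), call. = FALSE)
  }
  stats::setNames(as.character(aa), acc)
}

#' Write a proteome to FASTA
#'
#' @param proteome Named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(proteome, path) {
  aa <- Biostrings::AAStringSet(unlist(proteome))
  names(aa) <- names(proteome)
  Biostrings::writeXStringSet(aa, path)
  invisible(path)
}

#' Read per-protein disorder intervals
#'
#' Three-column tab-separated file: `protein`, `start`, `end`. Coordinates
#' are 1-based and closed on both ends — a documented divergence from
#' genomic BED, chosen to match protein residue numbering.
#'
#' @param path Path to the interval file (with header).
#' @param proteome Optional named proteome; when supplied, intervals
#'   extending beyond the protein are an error.
#' @return A tibble with columns `protein`, `start`, `end`.
#' @export
read_disorder <- function(path, proteome = NULL) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("protein", "start", "end")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols) > 0) {
    stop("disorder file is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  out <- tibble::tibble(
    protein = as.character(tab$protein),
    start = as.integer(tab$start),
    end = as.integer(tab$end)
  )
  if (any(out$start < 1) || any(out$end < out$start)) {
    stop("disorder intervals must satisfy 1 <= start <= end", call. = FALSE)
  }
  if (!is.null(proteome)) {
    len <- nchar(proteome)[out$protein]
    bad <- is.na(len) | out$end > len
    if (any(bad)) {
      stop("disorder interval(s) beyond protein length for: ",
           paste(unique(out$protein[bad]), collapse = ", "), call. = FALSE)
    }
  }
  out
}

#' Write a result table as TSV
#'
#' Floating-point columns are serialized with 6 significant digits by
#' default; pass `digits = NA` for full precision (used by the synthetic
#' report writers so that round-trips are exact).
#'
#' @param tab A data frame.
#' @param path Output path.
#' @param digits Significant digits for double columns, or `NA` to keep
#'   full precision.
#' @return `path`, invisibly.
#' @export
write_table <- function(tab, path, digits = 6) {
  tab <- tibble::as_tibble(tab)
  if (!is.na(digits)) {
    is_dbl <- vapply(tab, is.double, logical(1))
    tab[is_dbl] <- lapply(tab[is_dbl], signif, digits = digits)
  }
  readr::write_tsv(tab, path, na = "NA", progress = FALSE)
  invisible(path)
}

#' Write and read site-call tables
#'
#' Calls are serialized as TSV with `method_provenance` joined by `";"`.
#'
#' @param calls A site-call tibble as produced by [classify_sites()] or
#'   [merge_methods()].
#' @param path File path.
#' @return `write_calls()` returns `path` invisibly; `read_calls()` returns
#'   the call tibble with `method_provenance` restored to a list column.
#' @export
write_calls <- function(calls, path) {
  out <- calls
  if ("method_provenance" %in% names(out)) {
    out$method_provenance <- vapply(
      out$method_provenance, paste, character(1), collapse = ";"
    )
  }
  write_table(out, path)
}

#' @rdname write_calls
#' @export
read_calls <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if ("method_provenance" %in% names(tab)) {
    prov <- as.character(tab$method_provenance)
    prov[is.na(prov)] <- ""
    tab$method_provenance <- lapply(strsplit(prov, ";", fixed = TRUE),
                                    function(v) v[nzchar(v)])
  }
  tibble::as_tibble(tab)
}

#' Write site- and peptide-level reports (synthetic-study emitters)
#'
#' Inverse of [read_site_report()] / [read_peptide_report()]: missing
#' intensities are written as 0 (the upstream "not detected" convention)
#' and flags as `"+"` marks.
#'
#' @param x A `phospho_set` at scale `"raw"`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_site_report <- function(x, path) {
  stopifnot(inherits(x, "phospho_set"), x$level == "site", x$scale == "raw")
  values <- x$values
  values[is.na(values)] <- 0
  tab <- tibble::tibble(
    protein = x$rows$protein,
    position = x$rows$position,
    residue = x$rows$residue,
    localization_prob = x$rows$localization_prob,
    contaminant = ifelse(x$rows$contaminant, "+", ""),
    reverse = ifelse(x$rows$reverse, "+", "")
  )
  write_table(dplyr::bind_cols(tab, tibble::as_tibble(values)), path,
              digits = NA)
}

#' @rdname write_site_report
#' @export
write_peptide_report <- function(x, path) {
  stopifnot(inherits(x, "phospho_set"), x$level == "peptide",
            x$scale == "raw")
  values <- x$values
  values[is.na(values)] <- 0
  tab <- tibble::tibble(
    sequence = x$rows$sequence,
    phospho_offsets = vapply(x$rows$phospho_offsets, paste, character(1),
                             collapse = ";"),
    protein = x$rows$protein
  )
  write_table(dplyr::bind_cols(tab, tibble::as_tibble(values)), path,
              digits = NA)
}
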