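#' Presence/absence classification of detection patterns
#'
#' The qualitative arm. A site observed (non-zero, non-missing raw
#' intensity) in every replicate of the break-proficient condition and in
#' none of the break-deficient replicates is called fully DNA
#' break-dependent (`break_dependent_qual`); the converse pattern is called
#' lost in response to breaks (`lost_qual`). Every other detection pattern
#' is left qualitatively unclassified (`NA`). Of the 64 possible patterns in
#' a 3 + 3 design, exactly one yields each qualitative label. Runs on
#' pre-normalization detection status, one acquisition method at a time.
#'
#' @param x A single-method `phospho_set` at scale `"raw"`.
#' @return Character vector: `"break_dependent_qual"`, `"lost_qual"`, or
#'   `NA`, one per row.
#' @export
classify_presence_absence <- function(x) {
  stopifnot(inherits(x, "phospho_set"))
  if (x$scale != "raw") {
    stop("presence/absence runs on raw detection status", call. = FALSE)
  }
  if (length(unique(x$design$method)) > 1) {
    stop("one method at a time; use restrict_method()", call. = FALSE)
  }
  det <- detection_matrix(x)
  spo11 <- x$design$sample_id[x$design$condition == "SPO11"]
  yf <- x$design$sample_id[x$design$condition == "spo11-YF"]
  all_spo11 <- rowSums(det[, spo11, drop = FALSE]) == length(spo11)
  none_spo11 <- rowSums(det[, spo11, drop = FALSE]) == 0
  all_yf <- rowSums(det[, yf, drop = FALSE]) == length(yf)
  none_yf <- rowSums(det[, yf, drop = FALSE]) == 0
  lab <- rep(NA_character_, nrow(det))
  lab[all_spo11 & none_yf] <- "break_dependent_qual"
  lab[all_yf & none_spo11] <- "lost_qual"
  lab
}

#' Collapse a phosphopeptide table to phosphosite level
#'
#' Maps each phosphopeptide to protein coordinates by locating its sequence
#' in the proteome: the site position is peptide_start - 1 + phospho_offset.
#' Peptides whose sequence occurs more than once in their protein (or not at
#' all) cannot be placed unambiguously and are dropped with a warning; a
#' residue disagreement between peptide and protein is an error. Multiple
#' peptides covering the same site are combined by summing per-sample
#' intensities over observed values, so a site counts as observed in a
#' sample whenever at least one contributing peptide is. Peptides with
#' several phospho offsets contribute to each site independently.
#'
#' @param x A peptide-level `phospho_set` at scale `"raw"`.
#' @param proteome Named character vector of protein sequences.
#' @return A site-level `phospho_set` at scale `"raw"`. Collapsed rows carry
#'   `localization_prob = NA` (peptide reports have none) and clean flags.
#' @export
collapse_peptides_to_sites <- function(x, proteome) {
  stopifnot(inherits(x, "phospho_set"), x$level == "peptide")
  if (x$scale != "raw") {
    stop("collapse expects raw-scale peptide intensities", call. = FALSE)
  }
  n <- nrow(x$values)
  site_key <- character(0)
  site_rows <- list()
  acc_values <- list()
  dropped <- 0L
  for (i in seq_len(n)) {
    prot_acc <- x$rows$protein[i]
    pep <- x$rows$sequence[i]
    prot <- unname(proteome[prot_acc])
    if (is.na(prot)) {
      dropped <- dropped + 1L
      next
    }
    hits <- gregexpr(pep, prot, fixed = TRUE)[[1]]
    if (hits[1] == -1 || length(hits) > 1) {
      dropped <- dropped + 1L
      next
    }
    start <- as.integer(hits[1])
    for (off in x$rows$phospho_offsets[[i]]) {
      pos <- start - 1L + off
      res <- substr(pep, off, off)
      if (substr(prot, pos, pos) != res) {
        stop(sprintf(
          "residue mismatch: peptide '%s' offset %d claims %s but %s position %d is %s",
          pep, off, res, prot_acc, pos, substr(prot, pos, pos)
        ), call. = FALSE)
      }
      key <- paste(prot_acc, pos, res, sep = "|")
      j <- match(key, site_key)
      v <- x$values[i, ]
      if (is.na(j)) {
        site_key <- c(site_key, key)
        site_rows[[length(site_key)]] <- tibble::tibble(
          protein = prot_acc, position = pos, residue = res,
          localization_prob = NA_real_,
          contaminant = FALSE, reverse = FALSE
        )
        acc_values[[length(site_key)]] <- v
      } else {
        prev <- acc_values[[j]]
        both <- !is.na(prev) & !is.na(v)
        prev[both] <- prev[both] + v[both]
        prev[is.na(prev) & !is.na(v)] <- v[is.na(prev) & !is.na(v)]
        acc_values[[j]] <- prev
      }
    }
  }
  if (dropped > 0) {
    warning(dropped,
            " peptide(s) dropped: unmapped or ambiguous in their protein",
            call. = FALSE)
  }
  values <- do.call(rbind, c(acc_values,
                             list(matrix(numeric(0), 0, ncol(x$values)))))
  colnames(values) <- colnames(x$values)
  rows <- if (length(site_rows) > 0) dplyr::bind_rows(site_rows) else
    tibble::tibble(protein = character(0), position = integer(0),
                   residue = character(0), localization_prob = numeric(0),
                   contaminant = logical(0), reverse = logical(0))
  phospho_set(values, rows, x$design, scale = "raw", level = "site")
}

#' Run both classification arms for one acquisition method
#'
#' Orchestrates the per-method pipeline on a raw site-level table that has
#' already passed identification-quality filters ([filter_flagged()],
#' [filter_localization()]):
#' \enumerate{
#'   \item qualitative presence/absence labels on raw detection status for
#'     all rows (regardless of the missingness filter);
#'   \item the missingness filter (at most `max_missing` missing of the
#'     method's samples), ppm normalisation, log2 transform, and the
#'     moderated test with Benjamini-Hochberg control on the eligible rows;
#'   \item one label per site. A site that qualifies quantitatively keeps
#'     the quantitative label (the more informative call) and any
#'     qualitative evidence is recorded in `qual_label`; sites unscored by
#'     the quantitative arm take their qualitative label; sites with
#'     neither are `unchanged` if tested, otherwise `unclassifiable`.
#' }
#'
#' @param x A single-method site-level `phospho_set` at scale `"raw"`.
#' @param alpha Adjusted-p cutoff for the quantitative arm (default 0.1).
#' @param max_missing Missingness-filter threshold (default 3 of 6).
#' @return A tibble of site calls: site key columns, `label`, `qual_label`,
#'   `method_provenance` (list column), and the quantitative statistics.
#' @export
classify_sites <- function(x, alpha = 0.1, max_missing = 3) {
  stopifnot(inherits(x, "phospho_set"), x$level == "site")
  method <- unique(x$design$method)
  if (length(method) > 1) {
    stop("one method at a time; use restrict_method()", call. = FALSE)
  }
  qual <- classify_presence_absence(x)
  key <- paste(x$rows$protein, x$rows$position, x$rows$residue, sep = "|")

  filtered <- filter_min_detection(x, max_missing = max_missing)
  res <- moderated_two_group_test(log2_transform(normalize_ppm(filtered)))
  res$quant_label <- classify_quantitative(res, alpha = alpha)
  fkey <- paste(res$protein, res$position, res$residue, sep = "|")
  idx <- match(key, fkey)

  quant_label <- res$quant_label[idx]
  label <- dplyr::case_when(
    !is.na(quant_label) & quant_label != "unchanged" ~ quant_label,
    !is.na(qual) ~ qual,
    !is.na(quant_label) ~ "unchanged",
    TRUE ~ "unclassifiable"
  )
  tibble::tibble(
    protein = x$rows$protein,
    position = x$rows$position,
    residue = x$rows$residue,
    label = label,
    qual_label = qual,
    method_provenance = rep(list(method), length(label)),
    log2fc = res$log2fc[idx],
    t_mod = res$t_mod[idx],
    p = res$p[idx],
    adj_p = res$adj_p[idx]
  )
}

label_direction <- function(label) {
  dplyr::case_when(
    label %in% c("break_dependent_quant", "break_dependent_qual") ~
      "break_dependent",
    label %in% c("lost_quant", "lost_qual") ~ "lost",
    TRUE ~ label
  )
}

#' Merge site calls from two acquisition methods
#'
#' Takes the union of the two call sets keyed by (protein, position,
#' residue). Provenance is the union of methods contributing a call for the
#' site; the merged label is the more informative of the two (quantitative
#' over qualitative, any directional call over `unchanged`/
#' `unclassifiable`). Sites called break-dependent by one method and lost by
#' the other are flagged `conflict` and excluded from the break-dependent
#' set — a method is never silently preferred. When no conflicts occur the
#' merged break-dependent set obeys |A ∪ B| = |A| + |B| − |A ∩ B|.
#'
#' @param calls_a,calls_b Call tibbles from [classify_sites()] (typically
#'   DDA and DIA).
#' @return A merged call tibble with columns `protein`, `position`,
#'   `residue`, `label`, `label_a`, `label_b`, `method_provenance`.
#' @export
merge_methods <- function(calls_a, calls_b) {
  keyed <- function(calls, suffix) {
    tibble::tibble(
      key = paste(calls$protein, calls$position, calls$residue, sep = "|"),
      protein = calls$protein, position = calls$position,
      residue = calls$residue,
      label = calls$label,
      prov = calls$method_provenance
    )
  }
  a <- keyed(calls_a)
  b <- keyed(calls_b)
  if (anyDuplicated(a$key) || anyDuplicated(b$key)) {
    stop("duplicate site keys within a method's calls", call. = FALSE)
  }
  keys <- union(a$key, b$key)
  ia <- match(keys, a$key)
  ib <- match(keys, b$key)
  label_a <- a$label[ia]
  label_b <- b$label[ib]
  dir_a <- label_direction(label_a)
  dir_b <- label_direction(label_b)

  rank <- function(lab) {
    dplyr::case_when(
      lab %in% c("break_dependent_quant", "lost_quant") ~ 3L,
      lab %in% c("break_dependent_qual", "lost_qual") ~ 2L,
      lab == "unchanged" ~ 1L,
      TRUE ~ 0L
    )
  }
  conflict <- !is.na(dir_a) & !is.na(dir_b) &
    ((dir_a == "break_dependent" & dir_b == "lost") |
       (dir_a == "lost" & dir_b == "break_dependent"))
  pick_a <- is.na(label_b) | (!is.na(label_a) & rank(label_a) >= rank(label_b))
  label <- ifelse(conflict, "conflict",
                  ifelse(pick_a, label_a, label_b))
  prov <- mapply(function(x, y) {
    sort(unique(c(if (is.null(x)) character(0) else x,
                  if (is.null(y)) character(0) else y)))
  }, a$prov[ia], b$prov[ib], SIMPLIFY = FALSE)
  tibble::tibble(
    protein = ifelse(is.na(ia), b$protein[ib], a$protein[ia]),
    position = ifelse(is.na(ia), b$position[ib], a$position[ia]),
    residue = ifelse(is.na(ia), b$residue[ib], a$residue[ia]),
    label = label,
    label_a = label_a,
    label_b = label_b,
    method_provenance = prov
  )
}

#' Extract the break-dependent site set from merged calls
#'
#' @param calls A call tibble.
#' @return The subset of rows whose label direction is break-dependent
#'   (quantitative or qualitative); `conflict` rows are excluded.
#' @export
break_dependent_sites <- function(calls) {
  calls[label_direction(calls$label) %in% "break_dependent", , drop = FALSE]
}

#' @rdname break_dependent_sites
#' @export
lost_sites <- function(calls) {
  calls[label_direction(calls$label) %in% "lost", , drop = FALSE]
}
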