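#' Iterative motif extraction (motif-x style)
#'
#' Greedy extraction of over-represented (position, residue) patterns from
#' foreground windows relative to a background set, following the motif-x
#' scheme. Extraction runs separately for each central phosphoacceptor
#' (S and T, and Y when present) and the motifs are reported jointly —
#' S/TQ-type and RxxT-type motifs imply centre-specific extraction.
#'
#' Within one centre the algorithm iterates:
#' \enumerate{
#'   \item for every non-centre position and residue, compute the binomial
#'     upper-tail p-value of the foreground count given the background
#'     frequency of that residue at that position;
#'   \item fix the most significant pair with p < `p_cutoff` and foreground
#'     count >= `min_count` (ties broken by smaller p, then larger count,
#'     then position, then residue — fully deterministic);
#'   \item restrict foreground and background to windows matching the fixed
#'     pair and recurse until no pair qualifies;
#'   \item emit the motif, remove its matching windows from both sets, and
#'     restart.
#' }
#' Pad characters (`'_'`) never participate in counts.
#'
#' @param fg Character vector of foreground windows (equal odd widths).
#' @param bg Character vector of background windows (same width as `fg`);
#'   conventionally all detected phosphosites in the study.
#' @param p_cutoff Binomial p-value threshold to fix a position (default
#'   0.05).
#' @param min_count Minimum foreground support for a fixed position;
#'   default `max(5, ceiling(0.05 * length(fg)))`.
#' @return A tibble of motifs: `centre`, `fixed` (list column of tibbles
#'   with `offset`, `residue`), `pattern` (human-readable, e.g.
#'   `"...RxxTQ..."` style string), `fg_matches`, `bg_matches`, `score`
#'   (sum over extraction steps of -log10 binomial p) and
#'   `fold_enrichment` (foreground over background match rate).
#' @export
motif_x <- function(fg, bg, p_cutoff = 0.05, min_count = NULL) {
  if (length(fg) == 0 || length(bg) == 0) {
    stop("foreground and background must be nonempty", call. = FALSE)
  }
  if (length(unique(nchar(c(fg, bg)))) != 1) {
    stop("all windows must share one width", call. = FALSE)
  }
  if (is.null(min_count)) min_count <- max(5, ceiling(0.05 * length(fg)))
  flank <- (nchar(fg[1]) - 1) %/% 2
  n_fg_total <- length(fg)
  n_bg_total <- length(bg)
  centres <- intersect(c("S", "T", "Y"), unique(window_residue(fg, 0)))
  motifs <- list()
  for (centre in centres) {
    fg_c <- fg[window_residue(fg, 0) == centre]
    bg_c <- bg[window_residue(bg, 0) == centre]
    if (length(bg_c) == 0) next
    repeat {
      found <- extract_one_motif(fg_c, bg_c, flank, p_cutoff, min_count)
      if (is.null(found)) break
      motifs[[length(motifs) + 1]] <- tibble::tibble(
        centre = centre,
        fixed = list(found$fixed),
        pattern = motif_pattern(centre, found$fixed, flank),
        fg_matches = found$fg_matches,
        bg_matches = found$bg_matches,
        score = found$score,
        fold_enrichment =
          (found$fg_matches / n_fg_total) / (found$bg_matches / n_bg_total)
      )
      keep_fg <- !matches_motif(fg_c, found$fixed, flank)
      keep_bg <- !matches_motif(bg_c, found$fixed, flank)
      fg_c <- fg_c[keep_fg]
      bg_c <- bg_c[keep_bg]
      if (length(fg_c) == 0 || length(bg_c) == 0) break
    }
  }
  if (length(motifs) == 0) {
    return(tibble::tibble(
      centre = character(0), fixed = list(), pattern = character(0),
      fg_matches = integer(0), bg_matches = integer(0),
      score = numeric(0), fold_enrichment = numeric(0)
    ))
  }
  dplyr::bind_rows(motifs)
}

# One full greedy recursion: returns NULL when no position qualifies at the
# first step, otherwise the fixed set and summary statistics.
extract_one_motif <- function(fg, bg, flank, p_cutoff, min_count) {
  fixed <- tibble::tibble(offset = integer(0), residue = character(0))
  score <- 0
  repeat {
    step <- best_position(fg, bg, flank, fixed, p_cutoff, min_count)
    if (is.null(step)) break
    fixed <- dplyr::bind_rows(fixed, step[c("offset", "residue")])
    score <- score - log10(max(step$p, .Machine$double.xmin))
    fg <- fg[matches_motif(fg, fixed, flank)]
    bg <- bg[matches_motif(bg, fixed, flank)]
    if (length(bg) == 0) break
  }
  if (nrow(fixed) == 0) return(NULL)
  list(fixed = fixed, fg_matches = length(fg), bg_matches = length(bg),
       score = score)
}

# Scan all (offset != 0, residue) pairs; binomial upper tail of the fg count
# at the bg frequency. Deterministic tie-break: smaller p, larger count,
# smaller offset, then residue alphabetically.
best_position <- function(fg, bg, flank, fixed, p_cutoff, min_count) {
  best <- NULL
  n_fg <- length(fg)
  for (off in setdiff(-flank:flank, c(0L, fixed$offset))) {
    fg_res <- window_residue(fg, off)
    bg_res <- window_residue(bg, off)
    fg_res <- fg_res[fg_res != "_"]
    bg_res <- bg_res[bg_res != "_"]
    if (length(bg_res) == 0) next
    for (res in sort(unique(fg_res))) {
      k <- sum(fg_res == res)
      if (k < min_count) next
      p_bg <- sum(bg_res == res) / length(bg_res)
      # a residue absent from the background would give p = 0 for any
      # foreground count; floor its frequency at the resolution of the
      # background sample instead of letting the test degenerate
      if (p_bg == 0) p_bg <- 1 / (length(bg_res) + 1)
      p <- stats::pbinom(k - 1, n_fg, p_bg, lower.tail = FALSE)
      if (p >= p_cutoff) next
      cand <- list(offset = off, residue = res, p = p, count = k)
      if (is.null(best) ||
          p < best$p ||
          (p == best$p && k > best$count) ||
          (p == best$p && k == best$count && off < best$offset) ||
          (p == best$p && k == best$count && off == best$offset &&
             res < best$residue)) {
        best <- cand
      }
    }
  }
  best
}

matches_motif <- function(windows, fixed, flank) {
  ok <- rep(TRUE, length(windows))
  for (i in seq_len(nrow(fixed))) {
    ok <- ok & window_residue(windows, fixed$offset[i]) == fixed$residue[i]
  }
  ok
}

motif_pattern <- function(centre, fixed, flank) {
  slots <- rep(".", 2 * flank + 1)
  slots[flank + 1] <- tolower(centre)
  for (i in seq_len(nrow(fixed))) {
    slots[flank + 1 + fixed$offset[i]] <- fixed$residue[i]
  }
  paste(slots, collapse = "")
}
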