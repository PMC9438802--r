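#' Extract the sequence window around a phosphosite
#'
#' Returns the string of `2 * flank + 1` residues centred on the
#' phosphoacceptor, padded with `'_'` where the window runs past a protein
#' terminus. Positions are 1-based on the protein sequence as given in the
#' FASTA; no coordinate arithmetic across isoforms is attempted.
#'
#' @param proteome Named character vector of protein sequences.
#' @param protein Accession.
#' @param position 1-based residue index of the phosphoacceptor.
#' @param flank Residues on each side (default 3).
#' @return A character scalar of odd width with the phosphoacceptor at the
#'   centre.
#' @export
extract_window <- function(proteome, protein, position, flank = 3) {
  prot <- unname(proteome[protein])
  if (is.na(prot)) {
    stop("protein not in proteome: ", protein, call. = FALSE)
  }
  len <- nchar(prot)
  if (position < 1 || position > len) {
    stop(sprintf("position %d beyond %s (length %d)", position, protein, len),
         call. = FALSE)
  }
  centre <- substr(prot, position, position)
  if (!centre %in% c("S", "T", "Y")) {
    stop(sprintf("residue at %s:%d is %s, not a phosphoacceptor",
                 protein, position, centre), call. = FALSE)
  }
  lo <- position - flank
  hi <- position + flank
  core <- substr(prot, max(lo, 1), min(hi, len))
  pad_l <- strrep("_", max(0, 1 - lo))
  pad_r <- strrep("_", max(0, hi - len))
  paste0(pad_l, core, pad_r)
}

#' Vectorised window extraction for a site table
#'
#' @param proteome Named character vector of sequences.
#' @param sites Data frame with `protein` and `position` columns.
#' @inheritParams extract_window
#' @return Character vector of windows, one per site row.
#' @export
extract_windows <- function(proteome, sites, flank = 3) {
  mapply(function(p, pos) extract_window(proteome, p, pos, flank = flank),
         sites$protein, sites$position, USE.NAMES = FALSE)
}

window_residue <- function(windows, offset) {
  flank <- (nchar(windows[1]) - 1) %/% 2
  substr(windows, flank + 1 + offset, flank + 1 + offset)
}

#' Classify a window against the kinase consensus motifs
#'
#' Tests the three consensus contexts of the meiotic DNA break response:
#' `S/TQ` (Mec1/Tel1, the ATR/ATM orthologs: S or T followed by Q),
#' `RxxS/T` (Mek1: R three residues upstream), and the hybrid `RxxTQE`
#' (central T with R at -3, Q at +1 and E at +2), which by construction
#' implies both parent motifs.
#'
#' @param window A sequence window of odd width >= 7 (flank >= 3).
#' @return Character vector: the subset of
#'   `c("S/TQ", "RxxS/T", "RxxTQE")` the window satisfies (possibly empty).
#' @export
classify_consensus <- function(window) {
  m <- consensus_matrix(window)
  colnames(m)[m[1, ]]
}

#' @rdname classify_consensus
#' @param windows Character vector of windows (equal widths).
#' @return `consensus_matrix()` returns a logical matrix, one row per
#'   window, columns `S/TQ`, `RxxS/T`, `RxxTQE`.
#' @export
consensus_matrix <- function(windows) {
  if (length(windows) == 0) {
    return(matrix(logical(0), 0, 3,
                  dimnames = list(NULL, c("S/TQ", "RxxS/T", "RxxTQE"))))
  }
  flank <- (nchar(windows[1]) - 1) %/% 2
  if (flank < 3) stop("windows must have flank >= 3", call. = FALSE)
  centre <- window_residue(windows, 0)
  p1 <- window_residue(windows, 1)
  p2 <- window_residue(windows, 2)
  m3 <- window_residue(windows, -3)
  stq <- centre %in% c("S", "T") & p1 == "Q"
  rxxst <- centre %in% c("S", "T") & m3 == "R"
  rxxtqe <- centre == "T" & m3 == "R" & p1 == "Q" & p2 == "E"
  matrix(c(stq, rxxst, rxxtqe), ncol = 3,
         dimnames = list(NULL, c("S/TQ", "RxxS/T", "RxxTQE")))
}

#' Residue-by-position composition of a window set
#'
#' @param windows Character vector of equal-width windows.
#' @return An integer matrix: rows are the 20 amino acids plus `'_'`,
#'   columns are relative positions `-flank..+flank`; each cell counts
#'   windows with that residue at that position. Column sums over the 20
#'   amino acids equal the number of windows minus pads at that position.
#' @export
position_frequencies <- function(windows) {
  aas <- c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "_")
  if (length(windows) == 0) {
    return(matrix(0L, length(aas), 0, dimnames = list(aas, NULL)))
  }
  flank <- (nchar(windows[1]) - 1) %/% 2
  offs <- -flank:flank
  out <- matrix(0L, length(aas), length(offs),
                dimnames = list(aas, as.character(offs)))
  for (j in seq_along(offs)) {
    res <- window_residue(windows, offs[j])
    tab <- table(factor(res, levels = aas))
    out[, j] <- as.integer(tab)
  }
  out
}

#' Upper-tail hypergeometric enrichment test
#'
#' P(X >= k) for X ~ Hypergeometric drawing `n` items from a population of
#' `N` containing `K` successes. Used e.g. to test whether break-dependent
#' RxxS/T sites are enriched for threonine as the phosphoacceptor relative
#' to all detected RxxS/T sites.
#'
#' @param k Observed successes in the draw.
#' @param K Successes in the population.
#' @param n Draw size.
#' @param N Population size.
#' @return The upper-tail p-value.
#' @export
hypergeom_test <- function(k, K, n, N) {
  stopifnot(k >= 0, K >= 0, n >= 0, N >= 0, K <= N, n <= N, k <= n)
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' In-silico tryptic digestion
#'
#' Cleaves C-terminal to K or R, suppressed when the next residue is P
#' (standard trypsin specificity). `missed = m` returns all peptides with
#' at most `m` internal retained cleavage sites; the 0-missed peptides tile
#' the protein exactly.
#'
#' @param sequence Amino-acid string.
#' @param missed Maximum missed cleavages (default 0).
#' @return A tibble: `start`, `end` (1-based closed), `sequence`,
#'   `missed_cleavages`.
#' @export
digest_trypsin <- function(sequence, missed = 0) {
  n <- nchar(sequence)
  if (n == 0) {
    return(tibble::tibble(start = integer(0), end = integer(0),
                          sequence = character(0),
                          missed_cleavages = integer(0)))
  }
  chars <- strsplit(sequence, "")[[1]]
  cut_after <- which(chars %in% c("K", "R"))
  cut_after <- cut_after[cut_after < n & chars[cut_after + 1] != "P"]
  cut_after <- c(cut_after[cut_after < n], n)
  starts <- c(1L, utils::head(cut_after, -1) + 1L)
  ends <- cut_after
  n_pep <- length(starts)
  out <- list()
  for (m in 0:missed) {
    i <- seq_len(n_pep - m)
    if (length(i) == 0) break
    out[[m + 1]] <- tibble::tibble(
      start = starts[i], end = ends[i + m],
      sequence = substring(sequence, starts[i], ends[i + m]),
      missed_cleavages = m
    )
  }
  dplyr::arrange(dplyr::bind_rows(out), .data$start, .data$missed_cleavages)
}

#' Tryptic peptide covering a phosphosite, with detectability flags
#'
#' Finds the unique zero-missed-cleavage tryptic peptide containing
#' `position` and annotates mass-spectrometric detectability: peptides
#' shorter than 6 residues are flagged `too_small` (below the usual
#' identifiable range) and peptides longer than 40 are flagged `large`
#' (recovered at low frequency). Numbering follows the supplied sequence as
#' given; for proteins conventionally numbered on the mature chain
#' (histones), pass the mature, initiator-Met-removed sequence — the tool
#' never second-guesses numbering.
#'
#' @param proteome Named character vector of sequences.
#' @param protein Accession.
#' @param position 1-based residue index.
#' @return A one-row tibble: `protein`, `start`, `end`, `sequence`,
#'   `length`, `flag` (`"too_small"`, `"large"`, or `"ok"`).
#' @export
peptide_for_site <- function(proteome, protein, position) {
  prot <- unname(proteome[protein])
  if (is.na(prot)) {
    stop("protein not in proteome: ", protein, call. = FALSE)
  }
  if (position < 1 || position > nchar(prot)) {
    stop("position beyond protein length", call. = FALSE)
  }
  peps <- digest_trypsin(prot, missed = 0)
  hit <- peps[peps$start <= position & peps$end >= position, , drop = FALSE]
  len <- nchar(hit$sequence)
  tibble::tibble(
    protein = protein, start = hit$start, end = hit$end,
    sequence = hit$sequence, length = len,
    flag = if (len < 6) "too_small" else if (len > 40) "large" else "ok"
  )
}

#' Count sites with a near neighbour on the same protein
#'
#' A site is counted when at least one *other* site in the input lies on
#' the same protein within `window` residues (inclusive). Symmetric in the
#' pair and invariant to input order.
#'
#' @param sites Data frame with `protein` and `position` columns (distinct
#'   sites).
#' @param window Maximum residue separation (default 5).
#' @return A list: `count` (sites with a neighbour) and `pairs` (tibble of
#'   site pairs within the window, each pair once).
#' @export
proximity_count <- function(sites, window = 5) {
  sites <- tibble::as_tibble(sites)[, c("protein", "position")]
  sites <- dplyr::distinct(sites)
  pairs <- dplyr::inner_join(sites, sites, by = "protein",
                             relationship = "many-to-many",
                             suffix = c("_1", "_2"))
  pairs <- pairs[pairs$position_1 < pairs$position_2 &
                   pairs$position_2 - pairs$position_1 <= window, ,
                 drop = FALSE]
  near_key <- unique(c(paste(pairs$protein, pairs$position_1),
                       paste(pairs$protein, pairs$position_2)))
  list(
    count = sum(paste(sites$protein, sites$position) %in% near_key),
    pairs = tibble::as_tibble(pairs)
  )
}

#' Fraction of sites inside long disordered regions
#'
#' @param sites Data frame with `protein` and `position`.
#' @param intervals Disorder intervals ([read_disorder()]): `protein`,
#'   `start`, `end`, 1-based closed.
#' @param min_len Only intervals strictly longer than this count
#'   (default 30, i.e. length >= 31).
#' @return The fraction of input sites falling inside a qualifying
#'   interval (0 when there are no sites).
#' @export
disorder_overlap <- function(sites, intervals, min_len = 30) {
  sites <- tibble::as_tibble(sites)
  if (nrow(sites) == 0) return(0)
  intervals <- intervals[(intervals$end - intervals$start + 1) > min_len, ,
                         drop = FALSE]
  inside <- vapply(seq_len(nrow(sites)), function(i) {
    hits <- intervals$protein == sites$protein[i] &
      intervals$start <= sites$position[i] &
      intervals$end >= sites$position[i]
    any(hits)
  }, logical(1))
  mean(inside)
}

#' Distribution of sites per protein
#'
#' @param sites Data frame with a `protein` column (one row per site).
#' @return A tibble `n_sites`, `n_proteins`: how many proteins carry each
#'   site count. The sum of `n_proteins` equals the number of distinct
#'   proteins.
#' @export
sites_per_protein <- function(sites) {
  if (nrow(sites) == 0) {
    return(tibble::tibble(n_sites = integer(0), n_proteins = integer(0)))
  }
  counts <- table(sites$protein)
  hist <- table(as.integer(counts))
  tibble::tibble(
    n_sites = as.integer(names(hist)),
    n_proteins = as.integer(hist)
  )
}

#' Conserved N-terminal tail of mature yeast histone H3
#'
#' The first 20 residues of histone H3 after removal of the initiator
#' methionine, in the conventional mature numbering used for histone
#' modifications (T11 is the 11th residue of this string). This tail is
#' invariant across eukaryotes. It suffices for tryptic-detectability
#' analysis of the N-terminal sites because the 0-missed-cleavage peptides
#' covering them lie entirely inside it.
#'
#' @return A single-element named character vector (accession `"H3"`).
#' @export
mature_h3_tail <- function() {
  c(H3 = "ARTKQTARKSTGGKAPRKQL")
}

#' Synthetic stand-in for the Hop1 tryptic architecture around T318
#'
#' A fully synthetic 605-residue sequence (the length of Hop1) built so
#' that its zero-missed-cleavage tryptic map around position 318 matches
#' the documented situation for the meiotic checkpoint adaptor Hop1: T318
#' sits in a TQE context on a 49-residue tryptic peptide (residues
#' 301-349), far above the length range recovered efficiently by shotgun
#' proteomics. Everything outside that peptide is generic filler cut into
#' short tryptic blocks. This is *not* the real Hop1 sequence; it exists so
#' the detectability analysis of long peptides can be exercised without
#' external sequence databases.
#'
#' @return A single-element named character vector (accession
#'   `"synthetic_Hop1"`).
#' @export
synthetic_hop1_standin <- function() {
  block <- "ANDESGILQK"                  # 10-mer tryptic unit ending in K
  fill <- function(n) substr(strrep("ANDESGILQV", ceiling(n / 10)), 1, n)
  nterm <- strrep(block, 30)             # residues 1..300, K at 300
  long_pep <- paste0(fill(17), "TQE", fill(28), "K")  # 301..349, T at 318
  cterm <- paste0(strrep(block, 25), "ANDESG")        # 350..605
  seq <- paste0(nterm, long_pep, cterm)
  stopifnot(nchar(seq) == 605, substr(seq, 318, 318) == "T")
  c(synthetic_Hop1 = seq)
}
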