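#' Configuration of a synthetic phosphoproteomics study
#'
#' Defines the ground truth of a simulated two-condition,
#' three-replicate, two-method study. Planted sites fall into five effect
#' classes:
#' \describe{
#'   \item{fully_dependent}{phosphorylation structurally absent without
#'     breaks (never a signal in spo11-YF, not merely dropout) — the class
#'     the presence/absence arm exists for;}
#'   \item{induced}{present in both conditions, `delta` log2 units higher
#'     with breaks;}
#'   \item{lost_full}{structurally absent in the break-proficient
#'     condition;}
#'   \item{lost_quant}{`delta` log2 units lower with breaks;}
#'   \item{constitutive}{no condition effect (the null class).}
#' }
#' Missingness is missing-not-at-random: each measurement is observed with
#' probability `plogis((x - midpoint) / slope)` on the latent log2
#' intensity `x`, per acquisition method, so low-abundance signals
#' preferentially drop out and all-present/all-absent patterns arise
#' naturally. A hard detection threshold is the slope-to-zero limit.
#'
#' Defaults describe a realistic bench-scale study: 2,000 sites of which
#' 200 are break-dependent (100 fully dependent, 100 induced), 50 are lost
#' (25 structurally, 25 quantitatively) and 1,750 are constitutive;
#' `delta = 1.5` log2 units; between-site abundance spread `sigma_b = 1.2`
#' around `mu0 = 20` (log2 raw intensity) and replicate noise
#' `sigma_e = 0.4`; moderate MNAR dropout with the DIA channel slightly
#' more sensitive than DDA. Motif planting writes the consensus contexts
#' into break-dependent windows so that, together with chance occurrences
#' at background residue frequencies, about 19% of break-dependent sites
#' carry an S/TQ context and about 28% an RxxS/T context — the fractions
#' characteristic of the meiotic break response.
#'
#' @param n_proteins Number of synthetic proteins.
#' @param protein_length Two-element range of protein lengths (uniform).
#' @param n_sites Named integer vector of per-class site counts.
#' @param delta Condition effect size in log2 units.
#' @param mu0,sigma_b Mean and SD of per-site base log2 abundance.
#' @param sigma_e Replicate noise SD (log2).
#' @param dropout Named list per method, each `c(midpoint=, slope=)` of the
#'   logistic detection curve on latent log2 intensity. `midpoint = -Inf`
#'   disables dropout.
#' @param plant Named vector of motif-planting probabilities for
#'   break-dependent sites: `q_plus1` (Q at +1), `r_minus3` (R at -3),
#'   `centre_t` (force a T centre when planting R at -3).
#' @param n_flagged,n_low_localization Extra artifact rows (contaminant or
#'   reverse hits; sub-threshold localization) added to the site report to
#'   exercise the identification-quality filters; not part of the truth.
#' @param kr_period When not `NULL`, place K/R deterministically every
#'   `kr_period` residues (and nowhere else) to control tryptic peptide
#'   lengths; otherwise residues are drawn from yeast-like frequencies.
#' @return A list with class `truth_config`.
#' @export
truth_config <- function(n_proteins = 150,
                         protein_length = c(250, 600),
                         n_sites = c(fully_dependent = 100, induced = 100,
                                     lost_full = 25, lost_quant = 25,
                                     constitutive = 1750),
                         delta = 1.5,
                         mu0 = 20, sigma_b = 1.2, sigma_e = 0.4,
                         dropout = list(
                           DDA = c(midpoint = 17.5, slope = 0.8),
                           DIA = c(midpoint = 17.0, slope = 0.8)
                         ),
                         plant = c(q_plus1 = 0.155, r_minus3 = 0.247,
                                   centre_t = 0.8),
                         n_flagged = 20, n_low_localization = 30,
                         kr_period = NULL) {
  stopifnot(all(n_sites >= 0), sigma_b > 0 || sigma_b == 0, sigma_e >= 0,
            all(plant >= 0 & plant <= 1))
  required_classes <- c("fully_dependent", "induced", "lost_full",
                        "lost_quant", "constitutive")
  if (!setequal(names(n_sites), required_classes)) {
    stop("n_sites must name exactly the five effect classes", call. = FALSE)
  }
  structure(
    list(n_proteins = n_proteins, protein_length = protein_length,
         n_sites = n_sites[required_classes], delta = delta, mu0 = mu0,
         sigma_b = sigma_b, sigma_e = sigma_e, dropout = dropout,
         plant = plant, n_flagged = n_flagged,
         n_low_localization = n_low_localization, kr_period = kr_period),
    class = "truth_config"
  )
}

# Approximate S. cerevisiae amino-acid frequencies.
yeast_aa_freq <- function() {
  c(A = 0.055, C = 0.013, D = 0.058, E = 0.065, F = 0.045, G = 0.050,
    H = 0.022, I = 0.066, K = 0.073, L = 0.096, M = 0.021, N = 0.061,
    P = 0.044, Q = 0.039, R = 0.044, S = 0.090, T = 0.059, V = 0.056,
    W = 0.010, Y = 0.034)
}

#' Generate a synthetic proteome
#'
#' Random amino-acid sequences with yeast-like composition, or with
#' deterministic K/R spacing when `kr_period` is set (useful for
#' controlling tryptic peptide lengths). Deterministic given the seed;
#' sequences are drawn protein by protein, so enlarging `n_proteins`
#' appends proteins without perturbing earlier ones.
#'
#' @param config A [truth_config()].
#' @param seed Integer seed.
#' @return Named character vector of sequences (`sp001`, `sp002`, ...).
#' @export
generate_proteome <- function(config, seed) {
  set.seed(seed)
  freq <- yeast_aa_freq()
  out <- character(config$n_proteins)
  for (i in seq_len(config$n_proteins)) {
    len <- sample(config$protein_length[1]:config$protein_length[2], 1)
    if (is.null(config$kr_period)) {
      out[i] <- paste(sample(names(freq), len, replace = TRUE, prob = freq),
                      collapse = "")
    } else {
      alphabet <- setdiff(names(freq), c("K", "R", "P"))
      f2 <- freq[alphabet] / sum(freq[alphabet])
      chars <- sample(alphabet, len, replace = TRUE, prob = f2)
      at <- seq(config$kr_period, len, by = config$kr_period)
      chars[at] <- sample(c("K", "R"), length(at), replace = TRUE)
      out[i] <- paste(chars, collapse = "")
    }
  }
  names(out) <- sprintf("sp%03d", seq_len(config$n_proteins))
  out
}

#' Plant the ground-truth phosphosites
#'
#' Places the configured number of sites per effect class on S/T residues
#' of the proteome, edits break-dependent windows to plant consensus
#' contexts at the configured probabilities (Q at +1; R at -3, with a T
#' centre), draws each site's base log2 abundance, and returns both the
#' truth table and the (possibly edited) proteome that every truth window
#' is guaranteed to match.
#'
#' @param config A [truth_config()].
#' @param proteome Named character vector from [generate_proteome()].
#' @param seed Integer seed.
#' @return A list: `truth` (tibble: `protein`, `position`, `residue`,
#'   `class`, `effect`, `mu_site`, `window`) and `proteome` (with planted
#'   motifs applied).
#' @export
generate_truth <- function(config, proteome, seed) {
  set.seed(seed)
  n_total <- sum(config$n_sites)
  chars <- strsplit(proteome, "")
  cand <- dplyr::bind_rows(lapply(names(chars), function(acc) {
    st <- which(chars[[acc]] %in% c("S", "T"))
    # keep a full flank inside the protein so planting never crosses termini
    st <- st[st > 7 & st <= length(chars[[acc]]) - 7]
    tibble::tibble(protein = acc, position = st)
  }))
  if (nrow(cand) < n_total) {
    stop("proteome has too few S/T residues for the requested site count",
         call. = FALSE)
  }
  # greedy selection with a minimum same-protein spacing of 8 residues so
  # that one site's planted context (-3..+1) can never rewrite another
  # site's acceptor or window
  perm <- cand[sample.int(nrow(cand)), ]
  kept_pos <- stats::setNames(vector("list", length(proteome)),
                              names(proteome))
  keep <- logical(nrow(perm))
  n_kept <- 0L
  for (i in seq_len(nrow(perm))) {
    acc <- perm$protein[i]
    pos <- perm$position[i]
    if (length(kept_pos[[acc]]) == 0 ||
        all(abs(kept_pos[[acc]] - pos) >= 8)) {
      kept_pos[[acc]] <- c(kept_pos[[acc]], pos)
      keep[i] <- TRUE
      n_kept <- n_kept + 1L
      if (n_kept == n_total) break
    }
  }
  if (n_kept < n_total) {
    stop("could not place the requested sites at minimum spacing; ",
         "enlarge the proteome", call. = FALSE)
  }
  picked <- perm[keep, ]
  picked <- picked[order(match(picked$protein, names(proteome)),
                         picked$position), ]
  classes <- rep(names(config$n_sites), config$n_sites)
  classes <- sample(classes, n_total)
  dependent <- classes %in% c("fully_dependent", "induced")

  plant_q <- dependent & stats::runif(n_total) < config$plant[["q_plus1"]]
  plant_r <- dependent & stats::runif(n_total) < config$plant[["r_minus3"]]
  want_t <- plant_r & stats::runif(n_total) < config$plant[["centre_t"]]

  for (i in seq_len(n_total)) {
    acc <- picked$protein[i]
    pos <- picked$position[i]
    if (want_t[i]) chars[[acc]][pos] <- "T"
    if (plant_q[i]) chars[[acc]][pos + 1] <- "Q"
    if (plant_r[i]) chars[[acc]][pos - 3] <- "R"
  }
  proteome_out <- stats::setNames(
    vapply(chars, paste, character(1), collapse = ""), names(proteome)
  )
  effect <- dplyr::case_when(
    classes == "induced" ~ config$delta,
    classes == "lost_quant" ~ -config$delta,
    TRUE ~ 0
  )
  truth <- tibble::tibble(
    protein = picked$protein,
    position = picked$position,
    residue = vapply(seq_len(n_total), function(i) {
      chars[[picked$protein[i]]][picked$position[i]]
    }, character(1)),
    class = classes,
    effect = effect,
    mu_site = config$mu0 + stats::rnorm(n_total, 0, config$sigma_b),
    window = NA_character_
  )
  truth$window <- extract_windows(proteome_out, truth, flank = 7)
  list(truth = truth, proteome = proteome_out)
}

#' Generate raw intensity tables for both acquisition methods
#'
#' For each site, condition, replicate and method, the latent log2
#' intensity is `mu_site + condition_effect + N(0, sigma_e)`; structurally
#' absent measurements (fully_dependent in spo11-YF, lost_full in SPO11)
#' carry no signal at all, as opposed to dropout. Each latent value is then
#' observed with probability `plogis((x - midpoint) / slope)` for its
#' method, and observed values are emitted as raw intensities `2^x`
#' (rounded to 6 significant digits, the usual export precision). The DDA
#' output is a site-level table (with artifact rows appended per the
#' config); the DIA output is a peptide-level table whose rows are the
#' 0-missed-cleavage tryptic peptides carrying each site, exercising
#' [collapse_peptides_to_sites()].
#'
#' @param truth_obj List from [generate_truth()] (`truth` + `proteome`).
#' @param design A two-method [phospho_design()].
#' @param config The [truth_config()].
#' @param seed Integer seed.
#' @return A list: `dda` (site-level `phospho_set`, raw), `dia_peptides`
#'   (peptide-level `phospho_set`, raw).
#' @export
generate_intensities <- function(truth_obj, design, config, seed) {
  truth <- truth_obj$truth
  proteome <- truth_obj$proteome
  design <- validate_design(design)
  if (!setequal(unique(design$method), c("DDA", "DIA"))) {
    stop("design must contain both DDA and DIA samples", call. = FALSE)
  }
  if (!setequal(names(config$dropout), c("DDA", "DIA"))) {
    stop("config dropout must name both methods", call. = FALSE)
  }
  method_values <- function(method, sub_seed) {
    set.seed(sub_seed)
    sub <- design[design$method == method, ]
    n <- nrow(truth)
    drop <- config$dropout[[method]]
    values <- matrix(NA_real_, n, nrow(sub),
                     dimnames = list(NULL, sub$sample_id))
    for (j in seq_len(nrow(sub))) {
      cond <- sub$condition[j]
      structural_absent <-
        (truth$class == "fully_dependent" & cond == "spo11-YF") |
        (truth$class == "lost_full" & cond == "SPO11")
      eff <- if (cond == "SPO11") truth$effect else rep(0, n)
      x <- truth$mu_site + eff + stats::rnorm(n, 0, config$sigma_e)
      p_obs <- stats::plogis((x - drop[["midpoint"]]) / drop[["slope"]])
      observed <- !structural_absent & stats::runif(n) < p_obs
      values[observed, j] <- signif(2^x[observed], 6)
    }
    list(values = values, design = sub)
  }

  dda <- method_values("DDA", seed)
  set.seed(seed + 1L)
  rows <- tibble::tibble(
    protein = truth$protein, position = truth$position,
    residue = truth$residue,
    localization_prob = round(stats::runif(nrow(truth), 0.9, 1), 4),
    contaminant = FALSE, reverse = FALSE
  )
  # artifact rows: flagged and sub-threshold-localization decoys
  art <- artifact_rows(config, proteome, ncol(dda$values),
                       colnames(dda$values))
  dda_set <- phospho_set(rbind(dda$values, art$values),
                         dplyr::bind_rows(rows, art$rows),
                         dda$design, scale = "raw", level = "site")

  dia <- method_values("DIA", seed + 2L)
  pep <- peptide_rows_for_sites(truth, proteome)
  dia_set <- phospho_set(dia$values[pep$site_idx, , drop = FALSE],
                         pep$rows, dia$design,
                         scale = "raw", level = "peptide")
  list(dda = dda_set, dia_peptides = dia_set)
}

# Map every truth site to its 0-missed tryptic peptide; one peptide row per
# site (offset within the peptide), skipping sites whose peptide is not
# unique in its protein (they could not be collapsed back).
peptide_rows_for_sites <- function(truth, proteome) {
  digests <- lapply(proteome, digest_trypsin)
  keep <- integer(0)
  rows <- list()
  for (i in seq_len(nrow(truth))) {
    d <- digests[[truth$protein[i]]]
    hit <- which(d$start <= truth$position[i] & d$end >= truth$position[i])
    pep <- d$sequence[hit]
    n_occ <- length(gregexpr(pep, proteome[[truth$protein[i]]],
                             fixed = TRUE)[[1]])
    if (n_occ != 1) next
    keep <- c(keep, i)
    rows[[length(rows) + 1]] <- tibble::tibble(
      sequence = pep,
      phospho_offsets = list(as.integer(truth$position[i] - d$start[hit] + 1L)),
      protein = truth$protein[i]
    )
  }
  list(site_idx = keep, rows = dplyr::bind_rows(rows))
}

artifact_rows <- function(config, proteome, n_samples, sample_ids) {
  n_art <- config$n_flagged + config$n_low_localization
  if (n_art == 0) {
    return(list(
      values = matrix(numeric(0), 0, n_samples,
                      dimnames = list(NULL, sample_ids)),
      rows = tibble::tibble(protein = character(0), position = integer(0),
                            residue = character(0),
                            localization_prob = numeric(0),
                            contaminant = logical(0), reverse = logical(0))
    ))
  }
  accs <- sample(names(proteome), n_art, replace = TRUE)
  pos <- vapply(accs, function(a) {
    st <- which(strsplit(proteome[[a]], "")[[1]] %in% c("S", "T"))
    sample(st, 1)
  }, integer(1))
  res <- vapply(seq_len(n_art), function(i) {
    substr(proteome[[accs[i]]], pos[i], pos[i])
  }, character(1))
  flagged <- seq_len(n_art) <= config$n_flagged
  rows <- tibble::tibble(
    protein = accs, position = as.integer(pos), residue = res,
    localization_prob = ifelse(flagged,
                               round(stats::runif(n_art, 0.9, 1), 4),
                               round(stats::runif(n_art, 0.3, 0.89), 4)),
    contaminant = flagged & stats::runif(n_art) < 0.5,
    reverse = FALSE
  )
  rows$reverse <- flagged & !rows$contaminant
  values <- matrix(signif(2^stats::rnorm(n_art * n_samples, 18, 1), 6),
                   n_art, n_samples, dimnames = list(NULL, sample_ids))
  list(values = values, rows = rows)
}

#' Generate a complete synthetic study
#'
#' Convenience wrapper chaining [generate_proteome()], [generate_truth()]
#' and [generate_intensities()] with sub-seeds derived from one master
#' seed.
#'
#' @param config A [truth_config()].
#' @param seed Master integer seed.
#' @param design Sample design; defaults to the 3-replicate two-method
#'   [study_design()].
#' @return A list: `proteome`, `truth`, `dda`, `dia_peptides`, `design`,
#'   `config`, `seed`.
#' @export
simulate_study <- function(config = truth_config(), seed = 1,
                           design = study_design()) {
  base <- as.integer(seed) %% 214748L
  proteome0 <- generate_proteome(config, seed = base * 10L + 1L)
  tr <- generate_truth(config, proteome0, seed = base * 10L + 2L)
  tabs <- generate_intensities(tr, design, config, seed = base * 10L + 3L)
  list(proteome = tr$proteome, truth = tr$truth,
       dda = tabs$dda, dia_peptides = tabs$dia_peptides,
       design = design, config = config, seed = seed)
}

#' Score recovered site calls against the planted truth
#'
#' @param calls A call tibble ([classify_sites()] or [merge_methods()]).
#' @param truth The truth tibble from [generate_truth()].
#' @return A list: `confusion` (truth classes x call labels, with an
#'   `unclassified` column for truth sites absent from the calls or
#'   carrying no label) and `metrics` (tibble with per-class sensitivity
#'   for the directional classes, specificity for the constitutive class,
#'   and the false-discovery proportion among break-dependent calls).
#' @export
evaluate_recovery <- function(calls, truth) {
  truth_key <- paste(truth$protein, truth$position, truth$residue, sep = "|")
  call_key <- paste(calls$protein, calls$position, calls$residue, sep = "|")
  idx <- match(truth_key, call_key)
  label <- calls$label[idx]
  label[is.na(label)] <- "unclassified"
  label_levels <- c("break_dependent_quant", "break_dependent_qual",
                    "lost_quant", "lost_qual", "unchanged",
                    "unclassifiable", "conflict", "unclassified")
  class_levels <- c("fully_dependent", "induced", "lost_full", "lost_quant",
                    "constitutive")
  confusion <- table(
    truth = factor(truth$class, levels = class_levels),
    call = factor(label, levels = label_levels)
  )
  direction <- label_direction(label)
  truth_dep <- truth$class %in% c("fully_dependent", "induced")
  called_dep <- direction == "break_dependent"
  # break-dependent calls on rows not in the truth table cannot be scored
  # (none are emitted by the generator); FDP is over truth-matched calls
  metrics <- tibble::tibble(
    class = c(class_levels, "break_dependent_calls"),
    n = c(as.integer(table(factor(truth$class, levels = class_levels))),
          sum(called_dep)),
    value = c(
      mean(called_dep[truth$class == "fully_dependent"]),
      mean(called_dep[truth$class == "induced"]),
      mean((direction == "lost")[truth$class == "lost_full"]),
      mean((direction == "lost")[truth$class == "lost_quant"]),
      mean((!called_dep & direction != "lost")[truth$class == "constitutive"]),
      if (any(called_dep)) mean(!truth_dep[called_dep]) else 0
    ),
    metric = c("sensitivity", "sensitivity", "sensitivity", "sensitivity",
               "specificity", "fdp")
  )
  list(confusion = confusion, metrics = metrics)
}

#' Run the full calling pipeline on a synthetic study
#'
#' Filters, classifies per method (DDA at site level; DIA collapsed from
#' peptides), and merges — the same path a real study takes.
#'
#' @param study A list from [simulate_study()].
#' @param alpha Adjusted-p cutoff (default 0.1).
#' @param max_missing Missingness-filter threshold (default 3).
#' @return A list: `calls_dda`, `calls_dia`, `merged`.
#' @export
run_pipeline <- function(study, alpha = 0.1, max_missing = 3) {
  dda <- filter_localization(filter_flagged(study$dda))
  calls_dda <- classify_sites(dda, alpha = alpha, max_missing = max_missing)
  dia_sites <- collapse_peptides_to_sites(study$dia_peptides, study$proteome)
  calls_dia <- classify_sites(dia_sites, alpha = alpha,
                              max_missing = max_missing)
  merged <- merge_methods(calls_dda, calls_dia)
  list(calls_dda = calls_dda, calls_dia = calls_dia, merged = merged)
}
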