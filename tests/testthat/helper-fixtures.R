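# Shared fixtures: a tiny single-method design and a hand-sized site table.

dda_design <- function() {
  d <- study_design()
  d[d$method == "DDA", ]
}

# A 5-site, 6-sample raw table with controlled detection patterns.
# Rows: 1 all-present, 2 present-SPO11-only, 3 present-YF-only,
#       4 patchy (2 of 6), 5 all-present with a fold change.
tiny_site_set <- function() {
  design <- dda_design()
  values <- rbind(
    c(100, 110, 105, 95, 100, 102),
    c(200, 210, 190, NA, NA, NA),
    c(NA, NA, NA, 300, 310, 290),
    c(150, NA, NA, NA, 160, NA),
    c(800, 820, 790, 210, 190, 200)
  )
  colnames(values) <- design$sample_id
  rows <- tibble::tibble(
    protein = c("pA", "pA", "pB", "pB", "pC"),
    position = c(10L, 25L, 7L, 40L, 3L),
    residue = c("S", "T", "S", "T", "S"),
    localization_prob = c(0.99, 0.95, 0.91, 0.90, 0.97),
    contaminant = FALSE,
    reverse = FALSE
  )
  phospho_set(values, rows, design, scale = "raw", level = "site")
}

# Deterministic log2-scale table for the moderated test: n rows, 3 + 3.
fixed_log2_set <- function(n = 100, seed = 42, delta = 0) {
  design <- dda_design()
  set.seed(seed)
  values <- matrix(rnorm(n * 6, mean = 10, sd = 1), n, 6)
  values[, 1:3] <- values[, 1:3] + delta
  colnames(values) <- design$sample_id
  rows <- tibble::tibble(
    protein = sprintf("p%03d", seq_len(n)),
    position = rep(10L, n), residue = rep("S", n),
    localization_prob = rep(1, n), contaminant = FALSE, reverse = FALSE
  )
  phospho_set(values, rows, design, scale = "log2", level = "site")
}

# Minimal call tibble for merge tests.
make_calls <- function(keys, label) {
  tibble::tibble(
    protein = sub(":.*", "", keys),
    position = as.integer(sub(".*:", "", keys)),
    residue = "S",
    label = label,
    qual_label = NA_character_,
    method_provenance = rep(list("DDA"), length(keys))
  )
}
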