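small_config <- function(...) {
  truth_config(
    n_proteins = 20,
    n_sites = c(fully_dependent = 10, induced = 10, lost_full = 5,
                lost_quant = 5, constitutive = 70),
    n_flagged = 4, n_low_localization = 4, ...
  )
}

test_that("generators are deterministic under a fixed seed", {
  a <- simulate_study(small_config(), seed = 7)
  b <- simulate_study(small_config(), seed = 7)
  expect_identical(a$proteome, b$proteome)
  expect_identical(a$truth, b$truth)
  expect_identical(a$dda$values, b$dda$values)
  expect_identical(a$dia_peptides$values, b$dia_peptides$values)
  c <- simulate_study(small_config(), seed = 8)
  expect_false(identical(a$dda$values, c$dda$values))
})

test_that("an empty proteome and zero sites are valid degenerate cases", {
  cfg <- truth_config(n_proteins = 0,
                      n_sites = c(fully_dependent = 0, induced = 0,
                                  lost_full = 0, lost_quant = 0,
                                  constitutive = 0))
  expect_equal(length(generate_proteome(cfg, seed = 1)), 0)
})

test_that("periodic K/R spacing bounds all tryptic peptide lengths", {
  cfg <- truth_config(n_proteins = 5, protein_length = c(60, 100),
                      kr_period = 5)
  prot <- generate_proteome(cfg, seed = 9)
  for (s in prot) {
    expect_true(all(nchar(digest_trypsin(s)$sequence) <= 5))
  }
})

test_that("truth sites exist in the emitted proteome with planted windows", {
  cfg <- small_config(plant = c(q_plus1 = 1, r_minus3 = 0, centre_t = 0))
  st <- simulate_study(cfg, seed = 11)
  # every truth site matches the proteome residue
  for (i in seq_len(nrow(st$truth))) {
    expect_equal(
      substr(st$proteome[[st$truth$protein[i]]], st$truth$position[i],
             st$truth$position[i]),
      st$truth$residue[i]
    )
  }
  # plant probability 1: every break-dependent window has Q at +1
  dep <- st$truth$class %in% c("fully_dependent", "induced")
  expect_true(all(window_q <- substr(st$truth$window[dep], 9, 9) == "Q"))
  # plant probability 0: background Q frequency at +1 among the rest
  other_q <- mean(substr(st$truth$window[!dep], 9, 9) == "Q")
  expect_lt(other_q, 0.25)
  # class counts in truth equal the configuration
  expect_equal(as.list(table(st$truth$class)[names(cfg$n_sites)]),
               as.list(cfg$n_sites))
})

test_that("fully dependent sites are structural zeros under any dropout", {
  st <- simulate_study(small_config(), seed = 13)
  yf <- st$design$sample_id[st$design$condition == "spo11-YF" &
                              st$design$method == "DDA"]
  fd <- which(st$truth$class == "fully_dependent")
  expect_true(all(is.na(st$dda$values[fd, yf])))
  spo11 <- st$design$sample_id[st$design$condition == "SPO11" &
                                 st$design$method == "DDA"]
  lf <- which(st$truth$class == "lost_full")
  expect_true(all(is.na(st$dda$values[lf, spo11])))
})

test_that("raising the dropout midpoint never increases observed entries", {
  cfg_lo <- small_config()
  cfg_hi <- small_config(dropout = list(DDA = c(midpoint = 19, slope = 0.8),
                                        DIA = c(midpoint = 19, slope = 0.8)))
  n_obs <- function(cfg) {
    st <- simulate_study(cfg, seed = 17)
    sum(!is.na(st$dda$values))
  }
  expect_gte(n_obs(cfg_lo), n_obs(cfg_hi))
})

test_that("the noiseless, dropout-free limit gives exact quantitative recovery", {
  cfg <- truth_config(
    n_proteins = 40,
    n_sites = c(fully_dependent = 0, induced = 30, lost_full = 0,
                lost_quant = 0, constitutive = 170),
    sigma_e = 0,
    dropout = list(DDA = c(midpoint = -Inf, slope = 0.8),
                   DIA = c(midpoint = -Inf, slope = 0.8)),
    n_flagged = 0, n_low_localization = 0
  )
  st <- simulate_study(cfg, seed = 19)
  # the arm is exact on the latent log2 intensities themselves; total-sum
  # scaling would re-introduce a (noiseless, hence "significant")
  # compositional offset, so it is bypassed for this oracle
  x <- st$dda
  x$values <- log2(x$values)
  x$scale <- "log2"
  res <- moderated_two_group_test(x)
  lab <- classify_quantitative(res)
  expect_true(all(lab[st$truth$class == "induced"] ==
                    "break_dependent_quant"))
  expect_true(all(lab[st$truth$class == "constitutive"] == "unchanged"))
})

test_that("the DIA peptide table collapses back onto the truth sites", {
  st <- simulate_study(small_config(), seed = 23)
  sites <- collapse_peptides_to_sites(st$dia_peptides, st$proteome)
  skey <- paste(sites$rows$protein, sites$rows$position, sites$rows$residue)
  tkey <- paste(st$truth$protein, st$truth$position, st$truth$residue)
  expect_true(all(skey %in% tkey))
  # nearly all truth sites are representable (only ambiguous peptides drop)
  expect_gte(mean(tkey %in% skey), 0.9)
  # detection is preserved: a site is observed where its peptide is
  p <- st$dia_peptides$rows
  pep_key <- vapply(seq_len(nrow(p)), function(j) {
    start <- regexpr(p$sequence[j], st$proteome[[p$protein[j]]],
                     fixed = TRUE)[1]
    off <- p$phospho_offsets[[j]][1]
    paste(p$protein[j], start - 1 + off, substr(p$sequence[j], off, off))
  }, character(1))
  i <- match(skey, pep_key)
  expect_identical(unname(is.na(sites$values)),
                   unname(is.na(st$dia_peptides$values[i, , drop = FALSE])))
})

test_that("recovery metrics match a hand-counted fixture", {
  truth <- tibble::tibble(
    protein = sprintf("p%d", 1:10), position = 1:10, residue = "S",
    class = c(rep("fully_dependent", 3), rep("induced", 2),
              rep("constitutive", 5)),
    effect = 0, mu_site = 20, window = NA
  )
  calls <- make_calls(sprintf("p%d:%d", 1:10, 1:10), c(
    "break_dependent_qual", "break_dependent_qual", "unclassifiable",
    "break_dependent_quant", "unchanged",
    "unchanged", "unchanged", "break_dependent_quant", "unchanged",
    "unchanged"
  ))
  ev <- evaluate_recovery(calls, truth)
  m <- ev$metrics
  expect_equal(m$value[m$class == "fully_dependent"], 2 / 3)
  expect_equal(m$value[m$class == "induced"], 1 / 2)
  expect_equal(m$value[m$class == "constitutive"], 4 / 5)
  expect_equal(m$value[m$class == "break_dependent_calls"], 1 / 4)
  expect_equal(sum(ev$confusion), 10)
  expect_equal(unname(rowSums(ev$confusion)), c(3, 2, 0, 0, 5))
})

test_that("empty calls put every truth site in the unclassified column", {
  truth <- tibble::tibble(
    protein = "p1", position = 1:4, residue = "S",
    class = c("fully_dependent", "induced", "constitutive", "lost_full"),
    effect = 0, mu_site = 20, window = NA
  )
  ev <- evaluate_recovery(make_calls(character(0), character(0)), truth)
  expect_equal(sum(ev$confusion[, "unclassified"]), 4)
})
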