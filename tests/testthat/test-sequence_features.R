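test_that("windows are extracted with terminal padding", {
  prot <- c(pA = "MKSQEFG", pB = "STQRK")
  expect_equal(extract_window(prot, "pA", 3), "_MKSQEF")
  expect_equal(extract_window(prot, "pB", 1), "___STQR")
  expect_equal(extract_window(prot, "pA", 3, flank = 1), "KSQ")
  # interior site with full flanks: no padding
  prot2 <- c(pC = "AAATAAA")
  expect_equal(extract_window(prot2, "pC", 4), "AAATAAA")
  expect_error(extract_window(prot, "pA", 99), "beyond")
  expect_error(extract_window(prot, "pA", 2), "phosphoacceptor")
  expect_error(extract_window(prot, "nope", 1), "not in proteome")
})

test_that("consensus classification matches the motif definitions", {
  expect_equal(classify_consensus("KLASQEF"), "S/TQ")
  expect_equal(classify_consensus("RGGTALD"), "RxxS/T")
  expect_setequal(classify_consensus("RGGTQEA"),
                  c("S/TQ", "RxxS/T", "RxxTQE"))
  expect_equal(length(classify_consensus("AAASAAA")), 0)
  # central Y is none of the S/T consensi
  expect_equal(length(classify_consensus("RGGYQEA")), 0)
  # RxxSQE is not the hybrid (T centre required)
  expect_setequal(classify_consensus("RGGSQEA"), c("S/TQ", "RxxS/T"))
})

test_that("the hybrid motif implies both parents on random windows", {
  set.seed(23)
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  # random windows plus hybrid-enriched ones so the implication fires
  ws <- c(
    replicate(400, paste(c(sample(aas, 3, TRUE), sample(c("S", "T", "Y"), 1),
                           sample(aas, 3, TRUE)), collapse = "")),
    replicate(100, paste(c("R", sample(aas, 2, TRUE), "T", "Q", "E",
                           sample(aas, 1)), collapse = ""))
  )
  m <- consensus_matrix(ws)
  expect_gt(sum(m[, "RxxTQE"]), 0)
  expect_true(all(!m[, "RxxTQE"] | (m[, "S/TQ"] & m[, "RxxS/T"])))
  # and per-window classification agrees with the matrix form
  for (w in sample(ws, 50)) {
    expect_setequal(classify_consensus(w), colnames(m)[consensus_matrix(w)[1, ]])
  }
})

test_that("position frequencies count residues by offset", {
  m <- position_frequencies(c("KLASQEF"))
  expect_equal(sum(m), 7)
  expect_equal(m["Q", "1"], 1L)
  expect_equal(m["K", "-3"], 1L)
  expect_equal(sum(position_frequencies(character(0))), 0)
  # pads are tracked separately so residue column sums exclude them
  m2 <- position_frequencies(c("__ASQEF", "KLASQEF"))
  expect_equal(m2["_", "-3"], 1L)
  expect_equal(sum(m2[rownames(m2) != "_", "-3"]), 1)
  # a planted majority is the argmax at its position
  set.seed(2)
  aas <- strsplit("ACDEFGHIKMNPQRVWY", "")[[1]]
  ws <- replicate(40, paste(
    c(sample(aas, 2, TRUE), "L", "S", sample(aas, 3, TRUE)), collapse = ""))
  m3 <- position_frequencies(ws)
  expect_equal(names(which.max(m3[, "-1"])), "L")
})

test_that("hypergeometric enrichment equals exhaustive enumeration", {
  expect_equal(hypergeom_test(5, 5, 5, 10), 1 / choose(10, 5))
  expect_equal(hypergeom_test(0, 5, 5, 10), 1)
  # enumeration oracle over all parameter tuples with N <= 12
  for (N in 1:12) for (K in 0:N) for (n in 0:N) for (k in 0:min(n, K)) {
    p_enum <- sum(vapply(k:min(n, K), function(j) {
      choose(K, j) * choose(N - K, n - j)
    }, numeric(1))) / choose(N, n)
    expect_equal(hypergeom_test(k, K, n, N), p_enum, tolerance = 1e-12)
  }
})

test_that("tryptic digestion follows K/R specificity with proline suppression", {
  expect_equal(digest_trypsin("AKCDERFK")$sequence, c("AK", "CDER", "FK"))
  expect_equal(digest_trypsin("AKPDER")$sequence, "AKPDER")
  expect_equal(digest_trypsin("KKK")$sequence, c("K", "K", "K"))
  expect_equal(digest_trypsin("AAA")$sequence, "AAA")
  d1 <- digest_trypsin("AKCDERFK", missed = 1)
  expect_true("AKCDER" %in% d1$sequence)
  expect_true("CDERFK" %in% d1$sequence)
  expect_equal(sum(d1$missed_cleavages == 1), 2)
})

test_that("zero-missed peptides tile random sequences exactly", {
  set.seed(29)
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  for (i in 1:300) {
    s <- paste(sample(aas, sample(1:80, 1), TRUE), collapse = "")
    d <- digest_trypsin(s)
    expect_equal(paste(d$sequence, collapse = ""), s)
    expect_equal(d$start[1], 1)
    expect_equal(d$end[nrow(d)], nchar(s))
  }
})

test_that("H3 T11 lies on a five-residue peptide flagged too small", {
  pep <- peptide_for_site(mature_h3_tail(), "H3", 11)
  expect_equal(pep$sequence, "STGGK")
  expect_equal(pep$length, 5)
  expect_equal(pep$flag, "too_small")
})

test_that("the synthetic Hop1 stand-in places T318 on a 49-residue peptide", {
  prot <- synthetic_hop1_standin()
  expect_equal(nchar(prot[[1]]), 605)
  pep <- peptide_for_site(prot, "synthetic_Hop1", 318)
  expect_equal(pep$length, 49)
  expect_equal(pep$flag, "large")
  expect_equal(substr(prot[[1]], 318, 318), "T")
})

test_that("peptide detectability flags follow the length bounds", {
  prot <- c(p = "AKCDERFK")
  pep <- peptide_for_site(prot, "p", 4)
  expect_equal(pep$sequence, "CDER")
  expect_equal(pep$length, 4)
  expect_equal(pep$flag, "too_small")
})

test_that("proximity counting is inclusive at the window and per protein", {
  sites <- tibble::tibble(protein = c("a", "a"), position = c(10, 15))
  expect_equal(proximity_count(sites)$count, 2)  # delta = 5 counts
  sites$position <- c(10, 16)
  expect_equal(proximity_count(sites)$count, 0)
  sites2 <- tibble::tibble(protein = c("a", "b"), position = c(10, 15))
  expect_equal(proximity_count(sites2)$count, 0)
})

test_that("proximity counting is invariant to row order", {
  set.seed(37)
  sites <- tibble::tibble(
    protein = sample(letters[1:5], 60, TRUE),
    position = sample(1:80, 60, TRUE)
  ) |> dplyr::distinct()
  ref <- proximity_count(sites)$count
  for (i in 1:5) {
    expect_equal(proximity_count(sites[sample(nrow(sites)), ])$count, ref)
  }
})

test_that("disorder overlap requires intervals strictly longer than 30", {
  sites <- tibble::tibble(protein = "a", position = 15)
  iv31 <- tibble::tibble(protein = "a", start = 1, end = 31)
  iv30 <- tibble::tibble(protein = "a", start = 1, end = 30)
  expect_equal(disorder_overlap(sites, iv31), 1)
  expect_equal(disorder_overlap(sites, iv30), 0)
  expect_equal(disorder_overlap(sites, iv31[0, ]), 0)
  two <- tibble::tibble(protein = c("a", "a"), position = c(15, 200))
  expect_equal(disorder_overlap(two, iv31), 0.5)
})

test_that("sites-per-protein histogram margins equal the protein count", {
  s <- tibble::tibble(protein = c("a", "a", "a"))
  expect_equal(sites_per_protein(s),
               tibble::tibble(n_sites = 3L, n_proteins = 1L))
  expect_equal(nrow(sites_per_protein(s[0, ])), 0)
  s2 <- tibble::tibble(protein = c("a", "b", "b"))
  h <- sites_per_protein(s2)
  expect_equal(h$n_proteins, c(1L, 1L))
  expect_equal(sum(h$n_proteins), 2)
})
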