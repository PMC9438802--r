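test_that("variance prior is recovered from its generative model", {
  set.seed(101)
  n <- 2000
  d0 <- 4
  s0_sq <- 1
  df <- 4
  sigma_sq <- s0_sq * d0 / rchisq(n, d0)
  s_sq <- sigma_sq * rchisq(n, df) / df
  prior <- estimate_variance_prior(s_sq, df)
  expect_lt(abs(prior$d0 - d0) / d0, 0.15)
  expect_lt(abs(prior$s0_sq - s0_sq) / s0_sq, 0.10)
})

test_that("identical variances drive the prior df to the cap", {
  prior <- estimate_variance_prior(rep(2, 50), df = 4)
  expect_equal(prior$d0, 1e6)
  # in the infinite-d0 limit the scale solves E[log s^2] exactly
  expect_equal(prior$s0_sq, exp(log(2) - digamma(2) + log(2)),
               tolerance = 1e-6)
  # numerically indistinct rows must not crash
  prior2 <- estimate_variance_prior(c(1, 1 + 1e-12), df = 4)
  expect_equal(prior2$d0, 1e6)
})

test_that("too few usable rows is an error pointing at the t fallback", {
  expect_error(estimate_variance_prior(1.5, df = 4), "ordinary t")
  expect_error(estimate_variance_prior(c(0, -1, NA), df = 4), "ordinary t")
})

test_that("prior estimation agrees with limma's squeezeVar fit", {
  skip_if_not_installed("limma")
  set.seed(202)
  s_sq <- 0.5 * 6 / rchisq(500, 6) * rchisq(500, 4) / 4
  prior <- estimate_variance_prior(s_sq, df = 4)
  fit <- limma::squeezeVar(s_sq, df = 4)
  expect_equal(prior$d0, fit$df.prior, tolerance = 0.02)
  expect_equal(prior$s0_sq, fit$var.prior, tolerance = 0.02)
})

test_that("with d0 = 0 the moderated test is the ordinary pooled t-test", {
  x <- fixed_log2_set(n = 100, seed = 5, delta = 0.5)
  res <- moderated_two_group_test(
    x, prior = structure(list(d0 = 0, s0_sq = 1, n_rows = 0L),
                         class = "variance_prior")
  )
  # closed-form pooled two-sample t, computed independently per row
  for (i in seq_len(nrow(x$values))) {
    a <- x$values[i, 1:3]
    b <- x$values[i, 4:6]
    sp <- sqrt(((2) * var(a) + (2) * var(b)) / 4)
    t_ref <- (mean(a) - mean(b)) / (sp * sqrt(1 / 3 + 1 / 3))
    p_ref <- 2 * pt(abs(t_ref), 4, lower.tail = FALSE)
    expect_equal(res$t_mod[i], t_ref, tolerance = 1e-12)
    expect_equal(res$p[i], p_ref, tolerance = 1e-12)
    expect_equal(res$df_total[i], 4)
  }
})

test_that("a capped prior equal to the sample variance leaves t unchanged", {
  x <- fixed_log2_set(n = 1, seed = 9, delta = 1)
  res0 <- moderated_two_group_test(
    x, prior = structure(list(d0 = 0, s0_sq = 1, n_rows = 0L),
                         class = "variance_prior"))
  res_inf <- moderated_two_group_test(
    x, prior = structure(list(d0 = 1e12, s0_sq = res0$s_sq[1], n_rows = 0L),
                         class = "variance_prior"))
  expect_equal(res_inf$t_mod[1], res0$t_mod[1], tolerance = 1e-6)
})

test_that("posterior variance lies between sample and prior variance", {
  x <- fixed_log2_set(n = 200, seed = 31)
  res <- moderated_two_group_test(x)
  pr <- estimate_variance_prior(res$s_sq, res$df)
  lo <- pmin(res$s_sq, pr$s0_sq)
  hi <- pmax(res$s_sq, pr$s0_sq)
  distinct <- abs(res$s_sq - pr$s0_sq) > 1e-12
  expect_true(all(res$s_post_sq[distinct] > lo[distinct]))
  expect_true(all(res$s_post_sq[distinct] < hi[distinct]))
  expect_true(all(res$adj_p >= res$p))
})

test_that("identical group means give log2fc 0, t 0, p 1", {
  x <- fixed_log2_set(n = 1, seed = 1)
  x$values[1, ] <- c(5, 6, 7, 7, 6, 5)
  res <- moderated_two_group_test(x)
  expect_equal(res$log2fc[1], 0)
  expect_equal(res$t_mod[1], 0)
  expect_equal(res$p[1], 1)
})

test_that("rows with under two observations per condition are unscored", {
  x <- fixed_log2_set(n = 3, seed = 2)
  x$values[1, 4:6] <- NA            # 3 vs 0
  x$values[2, c(2, 3, 4)] <- NA     # 1 vs 2
  res <- moderated_two_group_test(x)
  expect_false(res$eligible[1])
  expect_false(res$eligible[2])
  expect_true(res$eligible[3])
  expect_true(all(is.na(res$p[1:2])))
})

test_that("moderated results match limma's eBayes on a complete matrix", {
  skip_if_not_installed("limma")
  x <- fixed_log2_set(n = 300, seed = 77, delta = 0.3)
  res <- moderated_two_group_test(x)
  design_mat <- cbind(1, x$design$condition == "SPO11")
  fit <- limma::eBayes(limma::lmFit(x$values, design_mat))
  expect_equal(res$log2fc, unname(fit$coefficients[, 2]), tolerance = 1e-10)
  expect_equal(res$t_mod, unname(fit$t[, 2]), tolerance = 1e-6)
  expect_equal(res$p, unname(fit$p.value[, 2]), tolerance = 1e-6)
})

test_that("BH adjustment equals the brute-force step-up definition", {
  brute_bh <- function(p) {
    m <- length(p)
    o <- order(p)
    adj <- p[o] * m / seq_len(m)
    adj <- rev(cummin(rev(adj)))
    pmin(adj, 1)[order(o)]
  }
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(55)
  for (i in 1:50) {
    p <- runif(sample(1:200, 1))^sample(1:3, 1)
    expect_equal(bh_adjust(p), brute_bh(p))
  }
})

test_that("quantitative labels follow the cutoff and fold-change sign", {
  res <- tibble::tibble(
    adj_p = c(0.05, 0.05, 0.2, NA, 0.1),
    log2fc = c(1.2, -0.8, 3, 1, 2)
  )
  expect_equal(
    classify_quantitative(res, alpha = 0.1),
    c("break_dependent_quant", "lost_quant", "unchanged", NA, "unchanged")
  )
})

test_that("under the global null the adjusted-significant fraction is controlled", {
  x <- fixed_log2_set(n = 2000, seed = 13)
  res <- moderated_two_group_test(x)
  frac <- mean(res$adj_p < 0.1)
  se <- sqrt(0.1 * 0.9 / 2000)
  expect_lte(frac, 0.1 + 3 * se)
})

test_that("protein differential analysis recovers planted proteins", {
  x <- fixed_log2_set(n = 400, seed = 21)
  x$level <- "protein"
  x$values[1:4, 1:3] <- x$values[1:4, 1:3] + 4  # four up-shifted proteins
  res <- protein_differential(x)
  hits <- which(res$label == "break_dependent_quant")
  expect_true(all(1:4 %in% hits))
  # discoveries are dominated by the planted proteins (FDR-level leakage ok)
  expect_lte(length(setdiff(hits, 1:4)), 4)
})

test_that("bootstrap set-shift is reproducible and contains its own null", {
  set.seed(3)
  lfc <- setNames(rnorm(500, 0, 0.1), sprintf("q%03d", 1:500))
  r1 <- bootstrap_set_shift(lfc, names(lfc), B = 200, seed = 10)
  r2 <- bootstrap_set_shift(lfc, names(lfc), B = 200, seed = 10)
  expect_identical(r1$draws, r2$draws)
  expect_equal(r1$observed, median(lfc))
  expect_false(r1$outside_ci)  # the whole population is its own null
  expect_error(bootstrap_set_shift(lfc, character(0), B = 10, seed = 1),
               "empty")
  expect_error(bootstrap_set_shift(lfc, "nope", B = 10, seed = 1),
               "not quantified")
})

test_that("a planted median shift is detected", {
  set.seed(4)
  lfc <- setNames(rnorm(2000, 0, 0.1), sprintf("q%04d", 1:2000))
  planted <- sprintf("q%04d", 1:50)
  lfc[planted] <- rnorm(50, 0.5, 0.1)
  r <- bootstrap_set_shift(lfc, planted, B = 1000, seed = 99)
  expect_true(r$outside_ci)
  expect_gt(r$observed, r$ci_high)
})
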