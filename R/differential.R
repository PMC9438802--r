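#' Estimate the empirical-Bayes variance prior
#'
#' Fits the scaled inverse-chi-square prior sigma^2 ~ s0^2 * d0 / chi^2_d0
#' underlying variance moderation, by method of moments on log(s^2): under
#' the hierarchical model s^2 / sigma^2 ~ chi^2_df / df, log(s^2) is a
#' location-shifted sum of log-chi-square terms whose mean and variance are
#' digamma/trigamma expressions in df and d0; matching the observed moments
#' gives (d0, s0^2). When the between-row spread of log(s^2) is no larger
#' than its pure sampling component, the moments imply an infinite prior
#' degrees of freedom; d0 is then capped at `d0_max` (complete shrinkage to
#' a common variance).
#'
#' @param s_sq Numeric vector of per-row residual variances (> 0).
#' @param df Residual degrees of freedom per row (recycled if length 1).
#' @param d0_max Cap for the prior degrees of freedom (default 1e6).
#' @return A list with class `variance_prior`: `d0`, `s0_sq`, and `n_rows`
#'   used.
#' @export
estimate_variance_prior <- function(s_sq, df, d0_max = 1e6) {
  if (length(df) == 1) df <- rep(df, length(s_sq))
  ok <- is.finite(s_sq) & s_sq > 0 & is.finite(df) & df >= 1
  s_sq <- s_sq[ok]
  df <- df[ok]
  if (length(s_sq) < 2) {
    stop("need at least 2 rows with positive variance and df >= 1; ",
         "fall back to the ordinary t-test", call. = FALSE)
  }
  z <- log(s_sq)
  # centre out the known sampling-distribution mean of log(chi2_df / df)
  e <- z - digamma(df / 2) + log(df / 2)
  e_mean <- mean(e)
  n <- length(e)
  e_var <- sum((e - e_mean)^2) / (n - 1)
  excess <- e_var - mean(trigamma(df / 2))
  if (is.finite(excess) && excess > trigamma(d0_max / 2)) {
    d0 <- 2 * trigamma_inverse(excess)
    d0 <- min(d0, d0_max)
    s0_sq <- exp(e_mean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- d0_max
    s0_sq <- exp(e_mean)
  }
  structure(list(d0 = d0, s0_sq = s0_sq, n_rows = n),
            class = "variance_prior")
}

# Newton solve of trigamma(y) = x; trigamma is convex decreasing on (0, Inf)
# so iteration on 1/trigamma converges fast from the large-y asymptote.
trigamma_inverse <- function(x) {
  if (x <= 0) return(Inf)
  y <- 0.5 + 1 / x
  for (i in 1:60) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2)
    y <- y + dif
    if (abs(dif) < 1e-10 * y) break
  }
  y
}

#' @export
print.variance_prior <- function(x, ...) {
  cat(sprintf("<variance_prior> d0 = %.4g, s0^2 = %.4g (from %d rows)\n",
              x$d0, x$s0_sq, x$n_rows))
  invisible(x)
}

#' Moderated two-group test on log2 intensities
#'
#' The quantitative arm: for every row with at least two observed values in
#' each condition, computes the SPO11-minus-spo11-YF mean difference on the
#' log2 scale, the pooled residual variance, and a moderated t-statistic
#' whose variance is shrunk toward the prior:
#' \deqn{s_{post}^2 = (d_0 s_0^2 + df\, s^2) / (d_0 + df)}
#' \deqn{t = \Delta / (s_{post} \sqrt{1/n_1 + 1/n_2})}
#' with two-sided p-values from a t distribution on df + d0 degrees of
#' freedom. With d0 = 0 this reduces exactly to the ordinary pooled-variance
#' two-sample t-test. Rows failing the eligibility rule (fewer than two
#' observed values in either condition) are returned unscored and routed to
#' the qualitative arm. Benjamini-Hochberg adjustment is applied across the
#' tested rows of this table only (one family per method and level).
#'
#' @param x A single-method `phospho_set` at scale `"log2"`.
#' @param prior A `variance_prior`, or `NULL` to estimate it from the
#'   eligible rows of `x`.
#' @return A tibble with one row per input row: row annotations, `n_spo11`,
#'   `n_yf`, `eligible`, `log2fc`, `s_sq`, `df`, `s_post_sq`, `t_mod`,
#'   `df_total`, `p`, `adj_p`. Unscored rows carry `NA` statistics.
#' @export
moderated_two_group_test <- function(x, prior = NULL) {
  stopifnot(inherits(x, "phospho_set"))
  if (x$scale != "log2") {
    stop("moderated test expects log2-scale values", call. = FALSE)
  }
  if (length(unique(x$design$method)) > 1) {
    stop("one method at a time; use restrict_method()", call. = FALSE)
  }
  g1 <- x$design$sample_id[x$design$condition == "SPO11"]
  g2 <- x$design$sample_id[x$design$condition == "spo11-YF"]
  v1 <- x$values[, g1, drop = FALSE]
  v2 <- x$values[, g2, drop = FALSE]
  n1 <- rowSums(!is.na(v1))
  n2 <- rowSums(!is.na(v2))
  eligible <- n1 >= 2 & n2 >= 2
  m1 <- rowMeans(v1, na.rm = TRUE)
  m2 <- rowMeans(v2, na.rm = TRUE)
  rss <- function(v, m) rowSums((v - m)^2, na.rm = TRUE)
  df <- n1 + n2 - 2
  s_sq <- ifelse(eligible & df > 0,
                 (rss(v1, m1) + rss(v2, m2)) / pmax(df, 1), NA_real_)
  log2fc <- ifelse(eligible, m1 - m2, NA_real_)
  if (is.null(prior)) {
    prior <- tryCatch(
      estimate_variance_prior(s_sq[eligible & s_sq > 0],
                              df[eligible & s_sq > 0]),
      error = function(e) {
        # degenerate table (e.g. noiseless synthetic limit): ordinary t
        structure(list(d0 = 0, s0_sq = 0, n_rows = 0L),
                  class = "variance_prior")
      }
    )
  }
  d0 <- prior$d0
  s0_sq <- prior$s0_sq
  s_post_sq <- ifelse(eligible, (d0 * s0_sq + df * s_sq) / (d0 + df),
                      NA_real_)
  se <- sqrt(s_post_sq * (1 / n1 + 1 / n2))
  # a zero standard error (zero residual and prior variance) gives an exact
  # verdict: t = 0 for an exactly-zero difference, +-Inf otherwise
  t_mod <- ifelse(eligible,
                  ifelse(se > 0, log2fc / se,
                         ifelse(log2fc == 0, 0, sign(log2fc) * Inf)),
                  NA_real_)
  df_total <- ifelse(eligible, df + d0, NA_real_)
  p <- ifelse(eligible, 2 * stats::pt(abs(t_mod), df_total,
                                      lower.tail = FALSE), NA_real_)
  # identical group means give t = 0 and hence p = 1 exactly
  p <- pmin(p, 1)
  adj_p <- rep(NA_real_, length(p))
  adj_p[eligible] <- bh_adjust(p[eligible])
  dplyr::bind_cols(
    x$rows,
    tibble::tibble(
      n_spo11 = n1, n_yf = n2, eligible = eligible,
      log2fc = log2fc, s_sq = s_sq, df = df,
      s_post_sq = s_post_sq, t_mod = t_mod, df_total = df_total,
      p = p, adj_p = adj_p
    )
  )
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p Numeric vector of p-values.
#' @return Adjusted p-values in (0, 1], same order as the input.
#' @export
bh_adjust <- function(p) {
  stats::p.adjust(p, method = "BH")
}

#' Label rows from the quantitative arm
#'
#' A tested row is `break_dependent_quant` when its adjusted p-value is
#' below `alpha` with a positive log2 fold change (enriched in the
#' break-proficient condition), `lost_quant` with a negative one, and
#' `unchanged` otherwise. Unscored rows get `NA` (they belong to the
#' qualitative arm).
#'
#' @param results Tibble from [moderated_two_group_test()].
#' @param alpha Adjusted-p-value cutoff (default 0.1).
#' @return Character vector of labels aligned with `results`.
#' @export
classify_quantitative <- function(results, alpha = 0.1) {
  lab <- rep(NA_character_, nrow(results))
  tested <- !is.na(results$adj_p)
  lab[tested] <- "unchanged"
  sig <- tested & results$adj_p < alpha
  lab[sig & results$log2fc > 0] <- "break_dependent_quant"
  lab[sig & results$log2fc < 0] <- "lost_quant"
  lab
}

#' Protein-level differential abundance
#'
#' The same moderated machinery applied to a protein-level table; the
#' Benjamini-Hochberg family is the protein table alone.
#'
#' @param x A single-method `phospho_set` (level `"protein"`) at scale
#'   `"raw"` or `"log2"`; raw tables are ppm-normalized and log2-transformed
#'   first.
#' @param alpha Adjusted-p-value cutoff (default 0.1).
#' @return The [moderated_two_group_test()] tibble with a `label` column.
#' @export
protein_differential <- function(x, alpha = 0.1) {
  stopifnot(inherits(x, "phospho_set"))
  if (x$scale == "raw") x <- log2_transform(normalize_ppm(x))
  res <- moderated_two_group_test(x)
  res$label <- classify_quantitative(res, alpha = alpha)
  res
}

#' Bootstrap test for a protein set's median fold-change shift
#'
#' Compares the median log2 fold change of a query set of proteins against
#' the distribution of medians of `B` equal-sized sets drawn without
#' replacement from all quantified proteins. The observed median is called
#' shifted when it falls outside the central 95% of the bootstrap draws.
#'
#' @param protein_log2fc Named numeric vector: log2 fold change per
#'   quantified protein accession.
#' @param query_set Character vector of accessions; must be a subset of
#'   `names(protein_log2fc)` and nonempty.
#' @param B Number of bootstrap draws (default 1000).
#' @param seed Integer seed; draws are reproducible given the seed.
#' @param statistic `"median"` (default) or `"mean"`.
#' @return A list with class `bootstrap_result`: `observed`, `n_set`,
#'   `draws`, `ci_low`, `ci_high`, `outside_ci`, `seed`, `statistic`.
#' @export
bootstrap_set_shift <- function(protein_log2fc, query_set, B = 1000, seed,
                                statistic = c("median", "mean")) {
  statistic <- match.arg(statistic)
  stat_fun <- if (statistic == "median") stats::median else mean
  if (length(query_set) == 0) stop("query set is empty", call. = FALSE)
  missing_prot <- setdiff(query_set, names(protein_log2fc))
  if (length(missing_prot) > 0) {
    stop("query protein(s) not quantified: ",
         paste(utils::head(missing_prot, 5), collapse = ", "), call. = FALSE)
  }
  observed <- stat_fun(protein_log2fc[query_set])
  n_set <- length(query_set)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  draws <- vapply(seq_len(B), function(b) {
    stat_fun(sample(protein_log2fc, n_set, replace = FALSE))
  }, numeric(1))
  if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                 envir = globalenv())
  ci <- stats::quantile(draws, c(0.025, 0.975), names = FALSE, type = 7)
  structure(
    list(observed = observed, n_set = n_set, draws = draws,
         ci_low = ci[1], ci_high = ci[2],
         outside_ci = observed < ci[1] || observed > ci[2],
         seed = seed, statistic = statistic),
    class = "bootstrap_result"
  )
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf(
    "<bootstrap_result> observed %s = %.4g over %d proteins\n  95%% CI of %d draws: [%.4g, %.4g] -> %s\n",
    x$statistic, x$observed, x$n_set, length(x$draws), x$ci_low, x$ci_high,
    if (x$outside_ci) "OUTSIDE (shifted)" else "inside (not shifted)"
  ))
  invisible(x)
}
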