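# Sensitivity diagnostics: Cochran's Q / I2 heterogeneity, the Egger
# intercept test for directional pleiotropy, the MR-PRESSO global and
# per-SNP outlier tests, and leave-one-out influence analysis.

#' Cochran's Q heterogeneity test
#'
#' With reference `"ivw"`, `Q = sum(w_j * (theta_j - theta_ivw_fixed)^2)`
#' over the per-SNP Wald ratios (df = J - 1); with reference `"egger"`,
#' `Q = sum((beta_out_j - a - b * beta_exp_j)^2 / se_out_j^2)` about the
#' Egger fit on exposure-positive oriented pairs (df = J - 2). P-value from
#' the chi-square distribution; `I2 = max(0, (Q - df) / Q)` (0 when Q = 0),
#' the fraction of variance across ratios attributable to heterogeneity.
#'
#' @param hset a [harmonized_set()].
#' @param reference `"ivw"` or `"egger"`.
#' @return list (class `heterogeneity_result`): method, q, df, pval, i2.
#' @export
cochran_q <- function(hset, reference = c("ivw", "egger")) {
  reference <- match.arg(reference)
  p <- .pairs_of(hset)
  J <- nrow(p)
  if (reference == "ivw") {
    if (J < 2) stop_bimr("Cochran's Q (ivw) needs at least 2 instruments")
    rs <- .ratio_stats(p)
    beta <- sum(rs$w * rs$theta) / sum(rs$w)
    q <- sum(rs$w * (rs$theta - beta)^2)
    df <- J - 1
  } else {
    if (J < 3) stop_bimr("Cochran's Q (egger) needs at least 3 instruments")
    s <- ifelse(p$beta_exp < 0, -1, 1)
    fit <- stats::lm(p$beta_out * s ~ I(p$beta_exp * s),
                     weights = 1 / p$se_out^2)
    q <- sum(stats::resid(fit)^2 / p$se_out^2)
    df <- J - 2
  }
  structure(
    list(method = reference, q = q, df = df,
         pval = pmin(pmax(stats::pchisq(q, df, lower.tail = FALSE),
                          .Machine$double.xmin), 1),
         i2 = if (q > 0) max(0, (q - df) / q) else 0),
    class = "heterogeneity_result"
  )
}

#' Egger intercept test for directional pleiotropy
#'
#' The intercept of the MR-Egger regression estimates the average pleiotropic
#' effect of the instruments on the outcome; a two-sided t test (J - 2 df)
#' of intercept = 0.
#'
#' @param hset a [harmonized_set()]; needs >= 3 pairs.
#' @return list: intercept, se, pval.
#' @export
egger_intercept_test <- function(hset) {
  mr_egger(hset)$intercept
}

#' MR-PRESSO global and outlier tests
#'
#' The observed statistic is the leave-one-out residual sum of squares
#' `RSS = sum_j (beta_out_j - theta_(-j) * beta_exp_j)^2 / se_out_j^2`,
#' where `theta_(-j)` is the IVW estimate excluding SNP j. Its null
#' distribution is simulated parametrically: each replicate draws
#' `beta_exp* ~ N(beta_exp_j, se_exp_j)` and
#' `beta_out* ~ N(theta_(-j) * beta_exp_j, se_out_j)` and recomputes the
#' statistic in full. Empirical p-values use the add-one rule
#' `(1 + #{sim >= obs}) / (n_sim + 1)` so they are never zero; per-SNP
#' residuals are compared the same way and SNPs with Bonferroni-adjusted
#' per-SNP p below `outlier_level / J` are flagged as pleiotropic outliers.
#'
#' @param hset a [harmonized_set()]; needs >= 4 pairs.
#' @param n_sim number of null simulations (>= 100); default 1000.
#' @param seed RNG seed.
#' @param outlier_level family-wise outlier level; default 0.05.
#' @return list (class `presso_result`): global_rss_obs, global_pval,
#'   outlier_snp_ids, per_snp_pvals, n_sim, seed.
#' @export
mr_presso <- function(hset, n_sim = 1000, seed = 1, outlier_level = 0.05) {
  p <- .pairs_of(hset)
  J <- nrow(p)
  if (J < 4) stop_bimr("MR-PRESSO needs at least 4 instruments")
  if (n_sim < 100) stop_bimr("n_sim must be >= 100")
  if (1 / (n_sim + 1) > outlier_level / J)
    warning("n_sim too small to resolve the Bonferroni outlier level ",
            signif(outlier_level / J, 3), call. = FALSE)

  loo_ivw <- function(be, bo) {
    w <- be^2 / p$se_out^2
    th <- bo / be
    (sum(w * th) - w * th) / (sum(w) - w)
  }
  theta_mj <- loo_ivw(p$beta_exp, p$beta_out)
  res_obs <- (p$beta_out - theta_mj * p$beta_exp)^2 / p$se_out^2
  rss_obs <- sum(res_obs)

  set.seed(seed)
  be_star <- matrix(stats::rnorm(n_sim * J, rep(p$beta_exp, each = n_sim),
                                 rep(p$se_exp, each = n_sim)), n_sim, J)
  bo_star <- matrix(stats::rnorm(n_sim * J,
                                 rep(theta_mj * p$beta_exp, each = n_sim),
                                 rep(p$se_out, each = n_sim)), n_sim, J)
  se_out_m <- matrix(p$se_out, n_sim, J, byrow = TRUE)
  w_star <- be_star^2 / se_out_m^2
  wt_star <- bo_star * be_star / se_out_m^2   # = w* x theta*
  theta_mj_star <- (rowSums(wt_star) - wt_star) /
    (rowSums(w_star) - w_star)
  res_sim <- (bo_star - theta_mj_star * be_star)^2 / se_out_m^2
  rss_sim <- rowSums(res_sim)

  global_pval <- (1 + sum(rss_sim >= rss_obs)) / (n_sim + 1)
  per_snp <- (1 + colSums(res_sim >= matrix(res_obs, n_sim, J, byrow = TRUE))) /
    (n_sim + 1)
  names(per_snp) <- p$snp_id
  structure(
    list(global_rss_obs = rss_obs, global_pval = global_pval,
         outlier_snp_ids = p$snp_id[per_snp < outlier_level / J],
         per_snp_pvals = per_snp, n_sim = n_sim, seed = seed),
    class = "presso_result"
  )
}

#' Leave-one-out influence analysis
#'
#' Re-estimates the IVW effect J times, omitting one instrument at a time.
#' A row is flagged influential when its 95% CI excludes the full-set point
#' estimate, indicating that single SNP drives the pooled result.
#'
#' @param hset a [harmonized_set()]; needs >= 3 pairs.
#' @param effects_model passed to [mr_ivw()].
#' @return list (class `loo_table`): `$rows` data.frame (omitted_snp_id,
#'   beta, se, ci_low, ci_high, pval, influential) and `$full_estimate`.
#' @export
leave_one_out <- function(hset, effects_model = "multiplicative_random") {
  p <- .pairs_of(hset)
  J <- nrow(p)
  if (J < 3) stop_bimr("leave-one-out needs at least 3 instruments")
  full <- mr_ivw(p, effects_model)
  rows <- do.call(rbind, lapply(seq_len(J), function(j) {
    est <- mr_ivw(p[-j, ], effects_model)
    data.frame(omitted_snp_id = p$snp_id[j], beta = est$beta, se = est$se,
               ci_low = est$ci_low, ci_high = est$ci_high, pval = est$pval,
               influential = full$beta < est$ci_low | full$beta > est$ci_high,
               stringsAsFactors = FALSE)
  }))
  structure(list(rows = rows, full_estimate = full), class = "loo_table")
}

#' Full sensitivity suite for one harmonized analysis
#'
#' Bundles Cochran's Q (IVW and Egger references), the Egger intercept test,
#' MR-PRESSO and leave-one-out, each run only when its instrument-count
#' minimum is met.
#'
#' @param hset a [harmonized_set()].
#' @param config an [mr_config()]; uses `presso_n_sim`,
#'   `presso_outlier_level`, `effects_model`, `seed`.
#' @return list with elements `q_ivw`, `q_egger`, `egger_intercept`,
#'   `presso`, `loo` (absent entries are `NULL`).
#' @export
sensitivity_suite <- function(hset, config = mr_config()) {
  J <- nrow(.pairs_of(hset))
  out <- list(q_ivw = NULL, q_egger = NULL, egger_intercept = NULL,
              presso = NULL, loo = NULL)
  if (J >= 2) out$q_ivw <- cochran_q(hset, "ivw")
  if (J >= 3) {
    out$q_egger <- cochran_q(hset, "egger")
    out$egger_intercept <- egger_intercept_test(hset)
    out$loo <- leave_one_out(hset, config$effects_model)
  }
  if (J >= 4)
    out$presso <- mr_presso(hset, config$presso_n_sim,
                            derive_seed(config$seed, "presso"),
                            config$presso_outlier_level)
  out
}
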