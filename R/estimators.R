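# Causal-effect estimators on a harmonized set: per-SNP Wald ratios combined
# by inverse-variance weighting, MR-Egger regression, the weighted median,
# and simple/weighted mode-based estimation.

MR_METHOD_ORDER <- c("egger", "weighted_median", "ivw", "simple_mode",
                     "weighted_mode")

# IVW weights and Wald ratios shared by several estimators.
# w_j = beta_exp_j^2 / se_out_j^2 so that sum(w * theta) / sum(w) equals the
# zero-intercept weighted regression slope of beta_out on beta_exp with
# weights 1 / se_out^2.
.ratio_stats <- function(pairs) {
  if (any(pairs$beta_exp == 0))
    stop_bimr("degenerate instrument: beta_exp = 0")
  list(theta = pairs$beta_out / pairs$beta_exp,
       se = pairs$se_out / abs(pairs$beta_exp),
       w = pairs$beta_exp^2 / pairs$se_out^2)
}

.pairs_of <- function(hset) {
  if (inherits(hset, "harmonized_set")) hset$pairs else as.data.frame(hset)
}

# assemble a one-row estimate table
.mr_estimate <- function(method, beta, se, pval, n_snp, ci_low, ci_high) {
  data.frame(method = method, n_snp = n_snp, beta = beta, se = se,
             ci_low = ci_low, ci_high = ci_high,
             or = exp(beta), or_low = exp(ci_low), or_high = exp(ci_high),
             pval = pval, stringsAsFactors = FALSE)
}

#' Per-SNP Wald ratio
#'
#' The single-instrument causal estimate `beta_out / beta_exp` with the
#' first-order delta-method standard error `se_out / |beta_exp|` (exposure-
#' side sampling noise is ignored, the standard two-sample convention).
#'
#' @param beta_exp,beta_out aligned per-allele effects; vectorized.
#' @param se_out outcome standard errors.
#' @return list with `theta` and `se`.
#' @export
wald_ratio <- function(beta_exp, beta_out, se_out) {
  if (any(beta_exp == 0)) stop_bimr("degenerate instrument: beta_exp = 0")
  list(theta = beta_out / beta_exp, se = se_out / abs(beta_exp))
}

#' Inverse-variance-weighted estimate
#'
#' The weighted mean of per-SNP Wald ratios with weights
#' `beta_exp^2 / se_out^2`. Under `"fixed"` the SE is `1/sqrt(sum(w))`; under
#' `"multiplicative_random"` (default) the fixed SE is inflated by
#' `max(1, sqrt(Q / (J - 1)))` with Q Cochran's heterogeneity statistic at
#' the IVW estimate, so the two models coincide absent overdispersion.
#' P-value from the standard normal; 95% CI is `beta +/- 1.96 * se`.
#'
#' @param hset a [harmonized_set()] (or a pairs data.frame); needs >= 2 pairs.
#' @param effects_model `"multiplicative_random"` or `"fixed"`.
#' @return one-row data.frame (method, n_snp, beta, se, ci_low, ci_high,
#'   or, or_low, or_high, pval).
#' @export
mr_ivw <- function(hset, effects_model = c("multiplicative_random", "fixed")) {
  effects_model <- match.arg(effects_model)
  p <- .pairs_of(hset)
  J <- nrow(p)
  if (J < 2) stop_bimr("IVW needs at least 2 instruments (use wald_ratio)")
  rs <- .ratio_stats(p)
  beta <- sum(rs$w * rs$theta) / sum(rs$w)
  se <- sqrt(1 / sum(rs$w))
  if (effects_model == "multiplicative_random") {
    q <- sum(rs$w * (rs$theta - beta)^2)
    se <- se * max(1, sqrt(q / (J - 1)))
  }
  .mr_estimate("ivw", beta, se, z_pval(beta / se), J,
               beta - 1.96 * se, beta + 1.96 * se)
}

#' MR-Egger regression
#'
#' Weighted regression `beta_out = intercept + slope * beta_exp` with weights
#' `1 / se_out^2`, after orienting every pair so the exposure effect is
#' non-negative (Egger is not invariant to per-SNP sign conventions). The
#' intercept estimates the average directional pleiotropy; a non-zero value
#' indicates the IVW estimate is biased. Standard errors use multiplicative
#' overdispersion with the residual scale floored at 1; inference is t-based
#' with J - 2 degrees of freedom.
#'
#' @param hset a [harmonized_set()]; needs >= 3 pairs.
#' @return list with `$slope` (one-row estimate table) and `$intercept`
#'   (list: intercept, se, pval).
#' @export
mr_egger <- function(hset) {
  p <- .pairs_of(hset)
  J <- nrow(p)
  if (J < 3) stop_bimr("MR-Egger needs at least 3 instruments")
  s <- ifelse(p$beta_exp < 0, -1, 1)
  bx <- p$beta_exp * s
  by <- p$beta_out * s
  fit <- stats::lm(by ~ bx, weights = 1 / p$se_out^2)
  sm <- summary(fit)
  est <- stats::coef(fit)
  # unit-dispersion SEs scaled by max(1, residual scale)
  se_unit <- sqrt(diag(sm$cov.unscaled))
  disp <- max(1, sm$sigma)
  se <- se_unit * disp
  df <- J - 2
  tq <- stats::qt(0.975, df)
  slope <- .mr_estimate("egger", est[2], se[2], t_pval(est[2] / se[2], df), J,
                        est[2] - tq * se[2], est[2] + tq * se[2])
  intercept <- list(intercept = unname(est[1]), se = unname(se[1]),
                    pval = unname(t_pval(est[1] / se[1], df)))
  list(slope = slope, intercept = intercept)
}

# weighted median of values x with weights w: linear interpolation of the
# mid-point cumulative weight across the order statistics at probability 0.5
.weighted_median_est <- function(x, w) {
  ord <- order(x)
  x <- x[ord]
  w <- w[ord] / sum(w)
  cw <- cumsum(w) - w / 2
  if (cw[1] >= 0.5) return(x[1])
  J <- length(x)
  if (cw[J] <= 0.5) return(x[J])
  below <- max(which(cw < 0.5))
  x[below] + (x[below + 1] - x[below]) * (0.5 - cw[below]) /
    (cw[below + 1] - cw[below])
}

# parametric bootstrap SE: resample each ratio from Normal(theta_j, se_j),
# re-apply the estimator with the original weights, take the SD
.bootstrap_se <- function(theta, se_theta, w, est_fun, n_boot, seed) {
  set.seed(seed)
  J <- length(theta)
  reps <- vapply(seq_len(n_boot), function(b) {
    est_fun(stats::rnorm(J, theta, se_theta), w)
  }, numeric(1))
  stats::sd(reps)
}

#' Weighted-median estimate
#'
#' Orders the per-SNP Wald ratios and takes the weighted median (linear
#' interpolation of the cumulative IVW weight at 50%). Consistent when valid
#' instruments carry a majority of the weight, hence robust to up to 50%
#' pleiotropic weight. SE via a seeded parametric bootstrap that resamples
#' each ratio from a normal with its delta-method SE.
#'
#' @param hset a [harmonized_set()]; needs >= 3 pairs.
#' @param n_boot bootstrap replicates (>= 100); default 1000.
#' @param seed RNG seed for the bootstrap.
#' @return one-row estimate table.
#' @export
mr_weighted_median <- function(hset, n_boot = 1000, seed = 1) {
  p <- .pairs_of(hset)
  J <- nrow(p)
  if (J < 3) stop_bimr("weighted median needs at least 3 instruments")
  if (n_boot < 100) stop_bimr("n_boot must be >= 100")
  rs <- .ratio_stats(p)
  beta <- .weighted_median_est(rs$theta, rs$w)
  se <- .bootstrap_se(rs$theta, rs$se, rs$w, .weighted_median_est,
                      n_boot, seed)
  .mr_estimate("weighted_median", beta, se, z_pval(beta / se), J,
               beta - 1.96 * se, beta + 1.96 * se)
}

# mode of the normal-kernel density over ratios evaluated at the ratios
# themselves; bandwidth h = phi * 0.9 * min(sd, iqr/1.349) * J^(-1/5),
# with weighted spread measures when weights are supplied
.mode_est <- function(phi) {
  function(theta, w) {
    J <- length(theta)
    wn <- w / sum(w)
    if (all(theta == theta[1])) return(theta[1])
    sd_ <- weighted_sd(theta, w)
    iqr_ <- diff(weighted_quantile(theta, w, c(0.25, 0.75)))
    cand <- c(sd_, iqr_ / 1.349)
    cand <- cand[cand > 0]
    if (!length(cand)) return(theta[1])
    h <- phi * 0.9 * min(cand) * J^(-1 / 5)
    dens <- vapply(theta, function(t0) sum(wn * stats::dnorm(t0, theta, h)),
                   numeric(1))
    mean(theta[dens >= max(dens) - 1e-12])
  }
}

#' Mode-based estimate (simple or weighted)
#'
#' The argmax of a normal-kernel density over the per-SNP Wald ratios,
#' evaluated at the ratios themselves; consistent when the largest cluster
#' of instruments is valid (zero modal pleiotropy). The simple mode uses
#' equal weights; the weighted mode uses the IVW weights for both the
#' density and the bandwidth's spread measures. Bandwidth
#' `h = phi * 0.9 * min(sd, IQR/1.349) * J^(-1/5)`. SE via the same seeded
#' parametric bootstrap as the weighted median. If all ratios coincide that
#' common value is returned.
#'
#' @param hset a [harmonized_set()]; needs >= 3 pairs.
#' @param weighted use IVW weights (`TRUE`) or equal weights (`FALSE`).
#' @param phi bandwidth multiplier; default 1.
#' @param n_boot,seed bootstrap control.
#' @return one-row estimate table.
#' @export
mr_mode <- function(hset, weighted = FALSE, phi = 1, n_boot = 1000, seed = 1) {
  p <- .pairs_of(hset)
  J <- nrow(p)
  if (J < 3) stop_bimr("mode estimators need at least 3 instruments")
  rs <- .ratio_stats(p)
  w <- if (weighted) rs$w else rep(1, J)
  est_fun <- .mode_est(phi)
  beta <- est_fun(rs$theta, w)
  se <- .bootstrap_se(rs$theta, rs$se, w, est_fun, n_boot, seed)
  method <- if (weighted) "weighted_mode" else "simple_mode"
  .mr_estimate(method, beta, se, z_pval(beta / se), J,
               beta - 1.96 * se, beta + 1.96 * se)
}

#' Run the five-method estimator table
#'
#' Produces the standard results-table rows, in order: MR-Egger, weighted
#' median, IVW (the primary estimator), simple mode, weighted mode. Methods
#' whose instrument-count minimum is not met (Egger/median/modes need 3,
#' IVW needs 2) are omitted rather than aborting the table; with a single
#' pair the Wald ratio is reported instead.
#'
#' @param hset a [harmonized_set()].
#' @param config an [mr_config()]; uses `effects_model`, `n_boot`, `phi`,
#'   `seed` and `methods`.
#' @return data.frame with one row per available method.
#' @export
run_all_methods <- function(hset, config = mr_config()) {
  p <- .pairs_of(hset)
  J <- nrow(p)
  methods <- config$methods %||% MR_METHOD_ORDER
  if (J == 1) {
    wr <- wald_ratio(p$beta_exp, p$beta_out, p$se_out)
    return(.mr_estimate("wald", wr$theta, wr$se, z_pval(wr$theta / wr$se), 1,
                        wr$theta - 1.96 * wr$se, wr$theta + 1.96 * wr$se))
  }
  rows <- list()
  try_method <- function(name, fun) {
    if (!name %in% methods) return()
    est <- tryCatch(fun(), error = function(e) NULL)
    if (!is.null(est)) rows[[name]] <<- est
  }
  try_method("egger", function() mr_egger(hset)$slope)
  try_method("weighted_median", function()
    mr_weighted_median(hset, config$n_boot,
                       derive_seed(config$seed, "weighted_median")))
  try_method("ivw", function() mr_ivw(hset, config$effects_model))
  try_method("simple_mode", function()
    mr_mode(hset, weighted = FALSE, phi = config$phi, n_boot = config$n_boot,
            seed = derive_seed(config$seed, "simple_mode")))
  try_method("weighted_mode", function()
    mr_mode(hset, weighted = TRUE, phi = config$phi, n_boot = config$n_boot,
            seed = derive_seed(config$seed, "weighted_mode")))
  out <- do.call(rbind, rows[intersect(MR_METHOD_ORDER, names(rows))])
  rownames(out) <- NULL
  out
}
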