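# Orchestration of the bidirectional analysis: configuration, per-direction
# execution with gating, Bonferroni significance tiers, and report rendering.

#' Analysis configuration
#'
#' Central bag of thresholds and tuning constants with the conventional
#' defaults: genome-wide significance 5e-8, LD clumping at r2 < 0.01 within
#' 5 Mb, weak-instrument cut F < 10, at least 5 instruments per analysis,
#' palindrome ambiguity window (0.42, 0.58), multiplicative-random-effects
#' IVW, 1000 bootstrap / MR-PRESSO replicates.
#'
#' @param p_threshold instrument significance threshold.
#' @param clump_r2,clump_window_bp LD clumping parameters.
#' @param f_min weak-instrument F threshold.
#' @param min_snps minimum instrument count to attempt an analysis.
#' @param palindrome_policy default palindrome handling for [run_direction()].
#' @param palindrome_policy_forward,palindrome_policy_reverse per-direction
#'   policies used by [run_bidirectional()]: forward analyses drop all
#'   palindromic instruments; reverse analyses drop only those with
#'   intermediate allele frequency.
#' @param eaf_window palindromic ambiguity window.
#' @param effects_model IVW effects model.
#' @param methods which estimators [run_all_methods()] reports.
#' @param n_boot bootstrap replicates for median/mode SEs.
#' @param phi mode bandwidth multiplier.
#' @param presso_n_sim,presso_outlier_level MR-PRESSO control.
#' @param sensitivity run the sensitivity suite inside [run_direction()].
#' @param n_tests number of tests for the Bonferroni tier (`NULL`: decided by
#'   the caller, e.g. the number of analyses in a batch).
#' @param alpha,suggestive_alpha significance levels for the tiers.
#' @param seed master seed; per-analysis seeds are derived from it.
#' @return a list of class `mr_config`.
#' @export
mr_config <- function(p_threshold = 5e-8,
                      clump_r2 = 0.01,
                      clump_window_bp = 5e6,
                      f_min = 10,
                      min_snps = 5,
                      palindrome_policy = "drop_intermediate",
                      palindrome_policy_forward = "drop_all",
                      palindrome_policy_reverse = "drop_intermediate",
                      eaf_window = c(0.42, 0.58),
                      effects_model = "multiplicative_random",
                      methods = MR_METHOD_ORDER,
                      n_boot = 1000,
                      phi = 1,
                      presso_n_sim = 1000,
                      presso_outlier_level = 0.05,
                      sensitivity = TRUE,
                      n_tests = NULL,
                      alpha = 0.05,
                      suggestive_alpha = 0.05,
                      seed = 1) {
  structure(as.list(environment()), class = "mr_config")
}

#' Bonferroni significance tier
#'
#' `threshold_strong = alpha / n_tests`; p-values below it are strong
#' evidence, those between it and `suggestive_alpha` are suggestive, the
#' rest null. With the conventional 25-test correction the strong threshold
#' is 0.05 / 25 = 0.002.
#'
#' @param pval two-sided p-value.
#' @param n_tests number of tests corrected for (>= 1).
#' @param alpha family-wise level; default 0.05.
#' @param suggestive_alpha nominal level for the suggestive tier.
#' @return list: tier ("strong", "suggestive" or "null"), threshold_strong,
#'   threshold_suggestive.
#' @export
classify_significance <- function(pval, n_tests, alpha = 0.05,
                                  suggestive_alpha = 0.05) {
  stopifnot(n_tests >= 1)
  thr <- alpha / n_tests
  tier <- if (pval < thr) "strong"
          else if (pval < suggestive_alpha) "suggestive"
          else "null"
  list(tier = tier, threshold_strong = thr,
       threshold_suggestive = suggestive_alpha)
}

.skipped_result <- function(exposure_id, outcome_id, reason, audit) {
  structure(
    list(exposure_id = exposure_id, outcome_id = outcome_id,
         skipped = TRUE, skip_reason = reason, audit = audit,
         harmonized = NULL, estimates = NULL, sensitivity = NULL),
    class = "direction_result"
  )
}

#' Run one exposure -> outcome analysis
#'
#' Executes the full chain: instrument selection ([select_instruments()]),
#' the minimum-instrument gate, harmonization ([harmonize_datasets()]), the
#' five-method estimate table and the sensitivity suite. Analyses failing
#' the gate, or losing all instruments in harmonization, return a skipped
#' result with the reason instead of aborting a batch.
#'
#' @param exposure,outcome `summary_dataset`s.
#' @param ld optional [ld_table()].
#' @param exclusions confounder-associated SNP IDs to remove.
#' @param config an [mr_config()].
#' @return list of class `direction_result`: ids, `skipped`/`skip_reason`,
#'   `audit`, `harmonized`, `estimates`, `sensitivity`.
#' @export
run_direction <- function(exposure, outcome, ld = NULL,
                          exclusions = character(), config = mr_config()) {
  cfg <- config
  cfg$seed <- derive_seed(config$seed, exposure$trait_id, outcome$trait_id)
  iv <- select_instruments(exposure, ld, exclusions, cfg)
  audit <- iv$audit
  if (!check_min_instruments(iv, cfg$min_snps))
    return(.skipped_result(exposure$trait_id, outcome$trait_id,
                           sprintf("fewer than %d instruments (%d selected)",
                                   cfg$min_snps, nrow(iv$members)), audit))
  hset <- tryCatch(
    harmonize_datasets(iv, outcome, cfg$palindrome_policy, cfg$eaf_window),
    error = function(e) NULL
  )
  if (is.null(hset))
    return(.skipped_result(exposure$trait_id, outcome$trait_id,
                           "no instruments survived harmonization", audit))
  if (nrow(hset$removed))
    audit <- rbind(audit, data.frame(snp_id = hset$removed$snp_id,
                                     stage = "harmonize",
                                     reason = hset$removed$reason))
  rownames(audit) <- NULL
  estimates <- run_all_methods(hset, cfg)
  sens <- if (isTRUE(cfg$sensitivity)) sensitivity_suite(hset, cfg) else NULL
  structure(
    list(exposure_id = exposure$trait_id, outcome_id = outcome$trait_id,
         skipped = FALSE, skip_reason = NA_character_, audit = audit,
         harmonized = hset, estimates = estimates, sensitivity = sens),
    class = "direction_result"
  )
}

#' @export
print.direction_result <- function(x, ...) {
  cat(sprintf("<direction_result> %s -> %s\n", x$exposure_id, x$outcome_id))
  if (x$skipped) {
    cat("  skipped:", x$skip_reason, "\n")
  } else {
    ivw <- x$estimates[x$estimates$method == "ivw", ]
    if (nrow(ivw))
      cat(sprintf("  IVW: beta %.4f (OR %.3f, 95%% CI %.3f-%.3f), p = %.3g, %d SNPs\n",
                  ivw$beta, ivw$or, ivw$or_low, ivw$or_high, ivw$pval, ivw$n_snp))
  }
  invisible(x)
}

#' Run both causal directions
#'
#' Two independent analyses with instrument selection redone from scratch
#' per direction: `trait_a -> trait_b` (forward, palindromic instruments
#' dropped unconditionally) and `trait_b -> trait_a` (reverse, only
#' intermediate-frequency palindromes dropped).
#'
#' @param trait_a,trait_b `summary_dataset`s; each must contain association
#'   records for both its own instruments and the other trait's.
#' @param ld optional [ld_table()].
#' @param exclusions_a,exclusions_b per-trait confounder exclusion lists.
#' @param config an [mr_config()].
#' @return list with elements `forward` and `reverse` (direction_result).
#' @export
run_bidirectional <- function(trait_a, trait_b, ld = NULL,
                              exclusions_a = character(),
                              exclusions_b = character(),
                              config = mr_config()) {
  cfg_f <- config
  cfg_f$palindrome_policy <- config$palindrome_policy_forward
  cfg_r <- config
  cfg_r$palindrome_policy <- config$palindrome_policy_reverse
  list(
    forward = run_direction(trait_a, trait_b, ld, exclusions_a, cfg_f),
    reverse = run_direction(trait_b, trait_a, ld, exclusions_b, cfg_r)
  )
}

.sensitivity_row <- function(s) {
  g <- function(x, f) if (is.null(x)) NA_real_ else f(x)
  data.frame(
    q_ivw = g(s$q_ivw, function(x) x$q),
    q_ivw_p = g(s$q_ivw, function(x) x$pval),
    q_egger = g(s$q_egger, function(x) x$q),
    q_egger_p = g(s$q_egger, function(x) x$pval),
    i2 = g(s$q_ivw, function(x) x$i2),
    egger_intercept = g(s$egger_intercept, function(x) x$intercept),
    egger_intercept_p = g(s$egger_intercept, function(x) x$pval),
    presso_global_p = g(s$presso, function(x) x$global_pval),
    presso_outliers = if (is.null(s$presso)) NA_character_ else
      paste(s$presso$outlier_snp_ids, collapse = ","),
    stringsAsFactors = FALSE
  )
}

#' Render analysis reports
#'
#' Writes, per completed analysis, `methods.tsv` (the five-method table with
#' OR and 95% CI), `sensitivity.tsv`, `loo.tsv` and `audit.tsv` into a
#' subdirectory named `<exposure>__<outcome>`, plus a combined
#' `summary.json` at the top level. Skipped analyses appear in the JSON
#' with their reason and get only their audit file. Output is deterministic
#' given deterministic inputs.
#'
#' @param results a `direction_result` or list of them.
#' @param out_dir output directory (created if needed).
#' @param n_tests Bonferroni divisor for the significance tier; defaults to
#'   the number of analyses in `results`.
#' @return the path to `summary.json`, invisibly.
#' @export
render_report <- function(results, out_dir, n_tests = NULL) {
  if (inherits(results, "direction_result")) results <- list(results)
  n_tests <- n_tests %||% length(results)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop_bimr("cannot create directory ", out_dir)

  wtsv <- function(df, path)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)

  summary_list <- lapply(results, function(r) {
    name <- paste0(r$exposure_id, "__", r$outcome_id)
    sub <- file.path(out_dir, name)
    dir.create(sub, showWarnings = FALSE)
    wtsv(r$audit, file.path(sub, "audit.tsv"))
    entry <- list(exposure = r$exposure_id, outcome = r$outcome_id,
                  skipped = r$skipped)
    if (r$skipped) {
      entry$reason <- r$skip_reason
      return(entry)
    }
    est <- r$estimates
    est$or_ci95 <- sprintf("%.2f (%.2f-%.2f)", est$or, est$or_low, est$or_high)
    wtsv(est[, c("method", "n_snp", "beta", "se", "or_ci95", "pval")],
         file.path(sub, "methods.tsv"))
    if (!is.null(r$sensitivity)) {
      wtsv(.sensitivity_row(r$sensitivity), file.path(sub, "sensitivity.tsv"))
      if (!is.null(r$sensitivity$loo))
        wtsv(r$sensitivity$loo$rows, file.path(sub, "loo.tsv"))
    }
    ivw <- est[est$method == "ivw", ]
    if (nrow(ivw)) {
      tier <- classify_significance(ivw$pval, n_tests)
      entry$n_snp <- ivw$n_snp
      entry$ivw <- list(beta = ivw$beta, se = ivw$se, or = ivw$or,
                        or_low = ivw$or_low, or_high = ivw$or_high,
                        pval = ivw$pval, tier = tier$tier)
    }
    if (!is.null(r$sensitivity)) {
      s <- r$sensitivity
      if (!is.null(s$q_ivw))
        entry$heterogeneity <- list(q = s$q_ivw$q, pval = s$q_ivw$pval,
                                    i2 = s$q_ivw$i2)
      if (!is.null(s$egger_intercept))
        entry$pleiotropy <- list(intercept = s$egger_intercept$intercept,
                                 pval = s$egger_intercept$pval)
      if (!is.null(s$presso))
        entry$presso <- list(global_pval = s$presso$global_pval,
                             outliers = as.list(s$presso$outlier_snp_ids))
    }
    entry
  })
  names(summary_list) <- vapply(results, function(r)
    paste0(r$exposure_id, "__", r$outcome_id), character(1))
  json_path <- file.path(out_dir, "summary.json")
  jsonlite::write_json(list(n_tests = n_tests, analyses = summary_list),
                       json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(json_path)
}
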