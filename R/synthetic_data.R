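# Ground-truth generator for two-sample GWAS summary statistics.
# Summary statistics are simulated directly (no individual-level genotypes):
# two-sample MR consumes only summary data, and independent exposure/outcome
# noise realizes the non-overlapping-samples assumption by construction.

#' Simulation configuration
#'
#' Defaults emulate the serum-protein -> disease setting the package
#' targets: a continuous exposure GWAS of 21,758 individuals, a binary
#' outcome GWAS of 127,442, 15 instruments. Per-SNP true exposure effects
#' are `b_j ~ N(0, exposure_effect_sd^2)`, floored in magnitude at
#' `min_instrument_z` exposure standard errors so every instrument clears
#' the genome-wide significance and F > 10 screens by construction (true
#' F around `min_instrument_z^2`, typical of protein-QTL instruments).
#' Standard errors follow the sampling-variance counterpart of the
#' variance-explained formula, `se = 1 / sqrt(2 * eaf * (1 - eaf) * N)`.
#' A pleiotropic effect `a_j ~ N(pleiotropy_mean, pleiotropy_sd^2)` is added
#' to the true outcome effect `theta * b_j` with probability
#' `pleiotropy_prob`, independently of `b_j` (so the InSIDE assumption
#' holds; `pleiotropy_mean != 0` gives directional, `= 0` balanced
#' pleiotropy). Instruments are placed 20 Mb apart across chromosomes, so
#' they are LD-independent (the post-clumping world).
#'
#' @param n_snps number of instruments.
#' @param n_exposure,n_outcome GWAS sample sizes.
#' @param theta true causal effect of exposure on outcome.
#' @param maf_range EAF sampling range.
#' @param exposure_effect_sd SD of raw true exposure effects.
#' @param min_instrument_z instrument-strength floor in exposure-SE units.
#' @param pleiotropy_prob,pleiotropy_mean,pleiotropy_sd pleiotropy regime.
#' @param palindromic_fraction fraction of instruments given A/T or C/G
#'   allele pairs.
#' @param strand_flip_fraction fraction of non-palindromic instruments whose
#'   outcome alleles are reported on the opposite strand.
#' @param null_snp_count non-associated background SNPs added to both
#'   datasets (dropped by the significance screen).
#' @param seed RNG seed; identical configs give byte-identical output.
#' @param exposure_id,outcome_id trait labels.
#' @param exposure_type,outcome_type trait types.
#' @param snp_id_offset offset for generated rs numbers, for composing
#'   scenarios with disjoint SNP sets.
#' @param pos_offset base-pair shift added to every generated position, so
#'   composed SNP sets do not share clumping windows.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_snps = 15,
                       n_exposure = 21758,
                       n_outcome = 127442,
                       theta = 0,
                       maf_range = c(0.05, 0.5),
                       exposure_effect_sd = 0.15,
                       min_instrument_z = 10,
                       pleiotropy_prob = 0,
                       pleiotropy_mean = 0,
                       pleiotropy_sd = 0,
                       palindromic_fraction = 0,
                       strand_flip_fraction = 0,
                       null_snp_count = 0,
                       seed = 1,
                       exposure_id = "sim_exposure",
                       outcome_id = "sim_outcome",
                       exposure_type = "continuous",
                       outcome_type = "binary",
                       snp_id_offset = 0,
                       pos_offset = 0) {
  stopifnot(n_snps >= 1, maf_range[1] > 0, maf_range[2] < 1,
            pleiotropy_prob >= 0, pleiotropy_prob <= 1,
            palindromic_fraction >= 0, palindromic_fraction <= 1,
            strand_flip_fraction >= 0, strand_flip_fraction <= 1)
  structure(as.list(environment()), class = "sim_config")
}

NONPALINDROMIC_PAIRS <- matrix(c("A", "C", "A", "G", "T", "C", "T", "G",
                                 "C", "A", "G", "A", "C", "T", "G", "T"),
                               ncol = 2, byrow = TRUE)
PALINDROMIC_PAIRS <- matrix(c("A", "T", "T", "A", "C", "G", "G", "C"),
                            ncol = 2, byrow = TRUE)

#' Simulate a two-sample GWAS summary-statistic pair
#'
#' Generates exposure and outcome `summary_dataset`s under the model of
#' [sim_config()], together with the generating truth: the causal effect,
#' per-SNP true exposure effects, and the identities of pleiotropic,
#' palindromic, and strand-flipped SNPs. Outcome records for flipped SNPs
#' carry strand-complemented alleles (numbers unchanged, as the flip is pure
#' reporting convention); harmonization must recover exactly the injected
#' flips.
#'
#' @param config a [sim_config()].
#' @return list: `exposure`, `outcome` (summary_datasets), `truth` (list:
#'   theta, per_snp_true_effects, pleiotropic_snp_ids, palindromic_snp_ids,
#'   flipped_snp_ids, seed).
#' @export
simulate_pair <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  J <- config$n_snps
  total <- J + config$null_snp_count
  is_instrument <- c(rep(TRUE, J), rep(FALSE, config$null_snp_count))
  snp_id <- sprintf("rs%d", 1000000 + config$snp_id_offset + seq_len(total))
  chrom <- as.character(((seq_len(total) - 1L) %% 22L) + 1L)
  pos <- 1000000L + as.integer(config$pos_offset) +
    ((seq_len(total) - 1L) %/% 22L) * 20000000L

  eaf <- stats::runif(total, config$maf_range[1], config$maf_range[2])
  se_exp <- 1 / sqrt(2 * eaf * (1 - eaf) * config$n_exposure)
  se_out <- 1 / sqrt(2 * eaf * (1 - eaf) * config$n_outcome)

  b_raw <- stats::rnorm(total, 0, config$exposure_effect_sd)
  b <- ifelse(b_raw == 0, 1, sign(b_raw)) *
    pmax(abs(b_raw), config$min_instrument_z * se_exp)
  b[!is_instrument] <- 0

  pleio_flag <- is_instrument &
    stats::rbinom(total, 1, config$pleiotropy_prob) == 1
  a <- ifelse(pleio_flag,
              stats::rnorm(total, config$pleiotropy_mean,
                           config$pleiotropy_sd), 0)
  # directional pleiotropy is defined on the exposure-increasing allele: a_j
  # keeps its mean in the coding where b_j > 0 (a_j stays independent of
  # |b_j|, so InSIDE holds and Egger remains consistent)
  true_out <- config$theta * b + a * ifelse(b < 0, -1, 1)

  beta_exp <- b + stats::rnorm(total, 0, se_exp)
  beta_out <- true_out + stats::rnorm(total, 0, se_out)

  # allele pairs: first n_pal instruments (a seeded sample) are palindromic
  n_pal <- round(config$palindromic_fraction * J)
  pal_idx <- if (n_pal > 0) sample(seq_len(J), n_pal) else integer(0)
  alleles <- NONPALINDROMIC_PAIRS[
    sample(nrow(NONPALINDROMIC_PAIRS), total, replace = TRUE), , drop = FALSE]
  if (length(pal_idx))
    alleles[pal_idx, ] <- PALINDROMIC_PAIRS[
      sample(nrow(PALINDROMIC_PAIRS), length(pal_idx), replace = TRUE), ,
      drop = FALSE]

  # strand flips apply to non-palindromic instruments only (complementing a
  # palindromic pair is the identity)
  flippable <- setdiff(which(is_instrument), pal_idx)
  n_flip <- round(config$strand_flip_fraction * length(flippable))
  flip_idx <- if (n_flip > 0) sample(flippable, n_flip) else integer(0)
  out_alleles <- alleles
  if (length(flip_idx))
    out_alleles[flip_idx, ] <- cbind(STRAND_COMPLEMENT[alleles[flip_idx, 1]],
                                     STRAND_COMPLEMENT[alleles[flip_idx, 2]])

  mk_records <- function(beta, se, n, allele_mat) {
    data.frame(
      snp_id = snp_id, chrom = chrom, pos = pos,
      effect_allele = allele_mat[, 1], other_allele = allele_mat[, 2],
      eaf = eaf, beta = beta, se = se, pval = z_pval(beta / se), n = n,
      stringsAsFactors = FALSE
    )
  }
  exposure <- summary_dataset(
    mk_records(beta_exp, se_exp, config$n_exposure, alleles),
    config$exposure_id, config$exposure_type)
  outcome <- summary_dataset(
    mk_records(beta_out, se_out, config$n_outcome, out_alleles),
    config$outcome_id, config$outcome_type)

  truth <- list(
    theta = config$theta,
    per_snp_true_effects = setNames(b[is_instrument], snp_id[is_instrument]),
    pleiotropic_snp_ids = snp_id[pleio_flag],
    palindromic_snp_ids = snp_id[sort(pal_idx)],
    flipped_snp_ids = snp_id[sort(flip_idx)],
    eaf = setNames(eaf[is_instrument], snp_id[is_instrument]),
    seed = config$seed
  )
  list(exposure = exposure, outcome = outcome, truth = truth)
}

#' Compose a bidirectional scenario from two one-direction simulations
#'
#' Builds two trait datasets, each holding its own instruments plus the
#' other direction's effects, so that [run_bidirectional()] can select
#' instruments per direction from scratch. `config_ab` generates trait A's
#' instruments and their effects on B (causal effect `config_ab$theta`);
#' `config_ba` does the reverse with a disjoint SNP set (its
#' `snp_id_offset` is shifted automatically when it collides).
#'
#' @param config_ab,config_ba [sim_config()]s for the two directions.
#' @return list: `trait_a`, `trait_b` (summary_datasets), `truth_ab`,
#'   `truth_ba`.
#' @export
simulate_bidirectional <- function(config_ab, config_ba) {
  if (config_ba$snp_id_offset == config_ab$snp_id_offset)
    config_ba$snp_id_offset <- config_ab$snp_id_offset +
      (config_ab$n_snps + config_ab$null_snp_count) * 1000 + 500000
  if (config_ba$pos_offset == config_ab$pos_offset)
    config_ba$pos_offset <- config_ab$pos_offset + 7000000L
  sim_ab <- simulate_pair(config_ab)
  sim_ba <- simulate_pair(config_ba)
  trait_a <- summary_dataset(
    rbind(sim_ab$exposure$records, sim_ba$outcome$records),
    config_ab$exposure_id, config_ab$exposure_type)
  trait_b <- summary_dataset(
    rbind(sim_ab$outcome$records, sim_ba$exposure$records),
    config_ab$outcome_id, config_ab$outcome_type)
  list(trait_a = trait_a, trait_b = trait_b,
       truth_ab = sim_ab$truth, truth_ba = sim_ba$truth)
}

#' Simulate correlated instrument blocks for clumping tests
#'
#' Places `block_size` SNPs per block within 1 kb of each other and tabulates
#' `within_r2` for every within-block pair; blocks sit on distinct
#' chromosomes. Exists solely to exercise [ld_clump()].
#'
#' @param n_blocks,block_size block geometry.
#' @param within_r2 tabulated r2 within a block.
#' @param seed RNG seed.
#' @return list: `records` (a records data.frame with p-values), `ld`
#'   (an [ld_table()]).
#' @export
simulate_ld_blocks <- function(n_blocks = 3, block_size = 4, within_r2 = 0.9,
                               seed = 1) {
  set.seed(seed)
  total <- n_blocks * block_size
  block <- rep(seq_len(n_blocks), each = block_size)
  snp_id <- sprintf("rs%d", 5000000 + seq_len(total))
  records <- data.frame(
    snp_id = snp_id, chrom = as.character(block),
    pos = 1000000L + (seq_len(total) - 1L) %% block_size * 250L,
    effect_allele = "A", other_allele = "G",
    eaf = stats::runif(total, 0.1, 0.5),
    beta = stats::rnorm(total, 0.1, 0.01),
    se = 0.01,
    pval = stats::runif(total, 1e-20, 1e-9),
    n = 20000L, stringsAsFactors = FALSE
  )
  pairs <- do.call(rbind, lapply(seq_len(n_blocks), function(bl) {
    ids <- snp_id[block == bl]
    cmb <- utils::combn(ids, 2)
    data.frame(snp_a = cmb[1, ], snp_b = cmb[2, ], r2 = within_r2,
               stringsAsFactors = FALSE)
  }))
  list(records = records, ld = ld_table(pairs))
}

#' Replicate batches for calibration, power, bias and coverage
#'
#' Runs `n_reps` independent [simulate_pair()] + [run_direction()] cycles
#' with per-replicate seeds derived from `config$seed`, and collects per-
#' replicate estimates and p-values. Sensitivity diagnostics are switched
#' off inside the loop (only estimator output is summarized) and Cochran's
#' Q is computed directly; set `methods` to the estimators you need - the
#' bootstrap-based ones dominate the cost.
#'
#' @param config a [sim_config()]; `theta = 0` gives a null (type-I error)
#'   batch, `theta != 0` a power/recovery batch.
#' @param n_reps number of replicates.
#' @param methods estimators to run each replicate.
#' @param mr_cfg base [mr_config()] for the per-replicate analysis.
#' @param n_boot bootstrap size for median/mode SEs inside the batch.
#' @return data.frame with one row per replicate: per-method `*_beta`,
#'   `*_se`, `*_pval`, Q statistics and the replicate's instrument count.
#' @export
simulate_null_batch <- function(config, n_reps, methods = "ivw",
                                mr_cfg = mr_config(), n_boot = 200) {
  rows <- vector("list", n_reps)
  for (i in seq_len(n_reps)) {
    cfg_i <- config
    cfg_i$seed <- derive_seed(config$seed, "rep", i)
    sim <- simulate_pair(cfg_i)
    run_cfg <- mr_cfg
    run_cfg$sensitivity <- FALSE
    run_cfg$methods <- methods
    run_cfg$n_boot <- n_boot
    run_cfg$seed <- cfg_i$seed
    res <- run_direction(sim$exposure, sim$outcome, config = run_cfg)
    row <- list(rep = i, seed = cfg_i$seed)
    if (res$skipped) {
      row$n_snp <- 0L
      rows[[i]] <- as.data.frame(row)
      next
    }
    row$n_snp <- nrow(res$harmonized$pairs)
    for (m in methods) {
      est <- res$estimates[res$estimates$method == m, ]
      if (nrow(est)) {
        row[[paste0(m, "_beta")]] <- est$beta
        row[[paste0(m, "_se")]] <- est$se
        row[[paste0(m, "_pval")]] <- est$pval
        row[[paste0(m, "_covered")]] <-
          est$ci_low <= config$theta && config$theta <= est$ci_high
      }
    }
    if ("egger" %in% methods) {
      eint <- egger_intercept_test(res$harmonized)
      row$egger_intercept <- eint$intercept
      row$egger_intercept_pval <- eint$pval
    }
    q <- cochran_q(res$harmonized, "ivw")
    row$q <- q$q
    row$q_pval <- q$pval
    rows[[i]] <- as.data.frame(row)
  }
  # pad replicates that skipped so rbind keeps a stable schema
  cols <- unique(unlist(lapply(rows, names)))
  out <- do.call(rbind, lapply(rows, function(r) {
    miss <- setdiff(cols, names(r))
    for (m in miss) r[[m]] <- NA
    r[, cols]
  }))
  rownames(out) <- NULL
  out
}
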