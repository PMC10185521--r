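# Instrument selection: genome-wide significance, confounder exclusion,
# greedy LD clumping, instrument-strength statistics and the weak-instrument
# and minimum-count gates.

#' Filter records at a significance threshold
#'
#' Keeps records with `pval < p_threshold` (strict inequality: the
#' genome-wide convention prints "P < 5e-8"), preserving input order.
#'
#' @param dataset a `summary_dataset` or a records data.frame.
#' @param p_threshold significance threshold in (0, 1); default 5e-8.
#' @return the retained records (data.frame).
#' @export
select_significant <- function(dataset, p_threshold = 5e-8) {
  stopifnot(p_threshold > 0, p_threshold < 1)
  rec <- if (inherits(dataset, "summary_dataset")) dataset$records else dataset
  out <- rec[rec$pval < p_threshold, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Remove SNPs on a confounder exclusion list
#'
#' Confounder screening is an explicit user-supplied ID list (e.g. hits from
#' a phenome-wide lookup), not a live database query. Removals are recorded
#' in the `"removed"` attribute with reason `"confounder"`.
#'
#' @param records records data.frame.
#' @param excluded_ids character vector of SNP IDs to drop.
#' @return retained records; removed rows in `attr(, "removed")`.
#' @export
apply_exclusion_list <- function(records, excluded_ids) {
  drop <- records$snp_id %in% excluded_ids
  out <- records[!drop, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "removed") <- data.frame(
    snp_id = records$snp_id[drop],
    reason = rep("confounder", sum(drop)),
    stringsAsFactors = FALSE
  )
  out
}

#' Read a one-ID-per-line exclusion list
#'
#' Lines starting with `#` (and inline `#` comments) are ignored.
#'
#' @param path text file path.
#' @return character vector of SNP IDs.
#' @export
read_exclusion_list <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines[nzchar(lines)]
}

#' Greedy LD clumping
#'
#' Records are visited in ascending p-value order; a record is accepted iff
#' every already-accepted record on the same chromosome within `window_bp`
#' has tabulated pairwise `r2 < r2_threshold`. Pairs on different chromosomes
#' or outside the window count as r2 = 0; pairs inside the window but absent
#' from the LD table are treated as r2 = 0 with a warning. Output is sorted
#' by genomic position.
#'
#' @param records records data.frame.
#' @param ld an [ld_table()] (or `NULL` for an empty table).
#' @param r2_threshold clump threshold in (0, 1); default 0.01.
#' @param window_bp clump window in base pairs; default 5 Mb.
#' @return retained records sorted by (chrom, pos); removed rows in
#'   `attr(, "removed")`.
#' @export
ld_clump <- function(records, ld = NULL, r2_threshold = 0.01,
                     window_bp = 5e6) {
  stopifnot(r2_threshold > 0, r2_threshold < 1, window_bp > 0)
  if (is.null(ld)) ld <- ld_table()
  ord <- order(records$pval)
  accepted <- integer(0)
  removed_idx <- integer(0)
  n_missing <- 0L
  for (i in ord) {
    conflict <- FALSE
    for (j in accepted) {
      if (records$chrom[i] != records$chrom[j]) next
      if (abs(records$pos[i] - records$pos[j]) > window_bp) next
      r2 <- ld_r2(ld, records$snp_id[i], records$snp_id[j])
      if (is.na(r2)) {
        n_missing <- n_missing + 1L
        r2 <- 0
      }
      if (r2 >= r2_threshold) {
        conflict <- TRUE
        break
      }
    }
    if (conflict) removed_idx <- c(removed_idx, i) else accepted <- c(accepted, i)
  }
  if (n_missing > 0)
    warning(n_missing, " within-window SNP pair(s) absent from the LD table;",
            " treated as r2 = 0", call. = FALSE)
  out <- records[accepted, , drop = FALSE]
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "removed") <- data.frame(
    snp_id = records$snp_id[removed_idx],
    reason = rep("ld_clump", length(removed_idx)),
    stringsAsFactors = FALSE
  )
  out
}

#' Variance in the trait explained by one SNP
#'
#' `R2 = 2 * EAF * (1 - EAF) * beta^2`, the additive variance explained under
#' Hardy-Weinberg for a standardized trait.
#'
#' @param eaf effect-allele frequency in (0, 1); vectorized.
#' @param beta per-allele effect; vectorized.
#' @return R2 values in [0, 1).
#' @export
compute_r2 <- function(eaf, beta) {
  stopifnot(all(eaf > 0), all(eaf < 1))
  r2 <- 2 * eaf * (1 - eaf) * beta^2
  if (any(r2 >= 1))
    stop_bimr("variance explained >= 1 for some SNP; invalid instrument")
  r2
}

#' Instrument-strength F-statistic
#'
#' `F = (N - 2) * R2 / (1 - R2)`: the single-instrument F of a regression of
#' the trait on the SNP dosage explaining a fraction R2 of the variance.
#'
#' @param n GWAS sample size (>= 3); vectorized.
#' @param r2 variance explained in [0, 1); vectorized.
#' @return non-negative F values.
#' @export
compute_f <- function(n, r2) {
  stopifnot(all(n >= 3))
  if (any(r2 < 0) || any(r2 >= 1)) stop_bimr("r2 must lie in [0, 1)")
  (n - 2) * r2 / (1 - r2)
}

#' Per-SNP instrument-strength statistics
#'
#' @param records records data.frame (uses `eaf`, `beta`, `n`).
#' @return data.frame `(snp_id, r2, f_stat)`.
#' @export
instrument_strength <- function(records) {
  r2 <- compute_r2(records$eaf, records$beta)
  data.frame(snp_id = records$snp_id, r2 = r2,
             f_stat = compute_f(records$n, r2),
             stringsAsFactors = FALSE)
}

#' Construct an instrument set
#'
#' @param exposure_id trait label of the exposure.
#' @param members data.frame of instrument records with `r2` and `f_stat`
#'   columns appended.
#' @param audit data.frame `(snp_id, stage, reason)` of all removals.
#' @return object of class `instrument_set`.
#' @export
instrument_set <- function(exposure_id, members, audit = NULL) {
  structure(
    list(exposure_id = exposure_id, members = members,
         audit = audit %||% data.frame(snp_id = character(),
                                       stage = character(),
                                       reason = character())),
    class = "instrument_set"
  )
}

#' @export
print.instrument_set <- function(x, ...) {
  cat(sprintf("<instrument_set> %s: %d instruments (%d removed)\n",
              x$exposure_id, nrow(x$members), nrow(x$audit)))
  invisible(x)
}

#' Remove weak instruments
#'
#' Drops members with `f_stat < f_min`; the boundary F = `f_min` is kept
#' (the rule removes instruments with F strictly less than ten).
#'
#' @param members records data.frame carrying `f_stat` (see
#'   [instrument_strength()]).
#' @param f_min weak-instrument threshold; default 10.
#' @param exposure_id trait label for the resulting set.
#' @return an [instrument_set()].
#' @export
filter_weak <- function(members, f_min = 10, exposure_id = "exposure") {
  weak <- members$f_stat < f_min
  audit <- data.frame(
    snp_id = members$snp_id[weak],
    stage = rep("strength", sum(weak)),
    reason = rep("weak_instrument", sum(weak)),
    stringsAsFactors = FALSE
  )
  kept <- members[!weak, , drop = FALSE]
  rownames(kept) <- NULL
  instrument_set(exposure_id, kept, audit)
}

#' Minimum-instrument gate
#'
#' An analysis proceeds only with at least `min_snps` instruments; exposures
#' below the gate are skipped rather than estimated.
#'
#' @param iv_set an `instrument_set`.
#' @param min_snps minimum member count; default 5.
#' @return `TRUE` iff the gate passes.
#' @export
check_min_instruments <- function(iv_set, min_snps = 5) {
  nrow(iv_set$members) >= min_snps
}

#' Full instrument-selection chain
#'
#' significance filter -> confounder exclusion -> LD clumping ->
#' strength statistics -> weak-instrument filter, with a per-removal audit
#' trail `(snp_id, stage, reason)`.
#'
#' @param dataset exposure `summary_dataset`.
#' @param ld optional [ld_table()].
#' @param exclusions character vector of confounder-associated SNP IDs.
#' @param config an [mr_config()] list (uses `p_threshold`, `clump_r2`,
#'   `clump_window_bp`, `f_min`).
#' @return an [instrument_set()].
#' @export
select_instruments <- function(dataset, ld = NULL, exclusions = character(),
                               config = mr_config()) {
  rec0 <- dataset$records
  sig <- select_significant(dataset, config$p_threshold)
  ns <- setdiff(rec0$snp_id, sig$snp_id)
  audit <- data.frame(
    snp_id = ns,
    stage = rep("significance", length(ns)),
    reason = rep("not_significant", length(ns)),
    stringsAsFactors = FALSE
  )
  excl <- apply_exclusion_list(sig, exclusions)
  rm_excl <- attr(excl, "removed")
  if (nrow(rm_excl))
    audit <- rbind(audit, cbind(rm_excl[, "snp_id", drop = FALSE],
                                stage = "confounder",
                                reason = rm_excl$reason))
  clumped <- ld_clump(excl, ld, config$clump_r2, config$clump_window_bp)
  rm_clump <- attr(clumped, "removed")
  if (nrow(rm_clump))
    audit <- rbind(audit, cbind(rm_clump[, "snp_id", drop = FALSE],
                                stage = "ld_clump", reason = rm_clump$reason))
  if (nrow(clumped) == 0L)
    return(instrument_set(dataset$trait_id,
                          cbind(clumped, r2 = numeric(0), f_stat = numeric(0)),
                          audit))
  stats <- instrument_strength(clumped)
  members <- cbind(clumped, stats[, c("r2", "f_stat")])
  out <- filter_weak(members, config$f_min, dataset$trait_id)
  out$audit <- rbind(audit, out$audit)
  rownames(out$audit) <- NULL
  out
}
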