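# Allele harmonization: align exposure and outcome records to a common
# effect allele, resolving allele swaps and strand flips and removing
# ambiguous palindromic SNPs.

STRAND_COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C")

#' Is an allele pair palindromic?
#'
#' A/T and C/G pairs read the same on both strands, so the strand of the
#' reporting GWAS cannot be inferred from the alleles.
#'
#' @param effect_allele,other_allele single characters in A/C/G/T; vectorized.
#' @return logical.
#' @export
is_palindromic <- function(effect_allele, other_allele) {
  unname(STRAND_COMPLEMENT[effect_allele] == other_allele)
}

#' Harmonize one exposure/outcome record pair
#'
#' Aligns the outcome record to the exposure's effect allele:
#' same orientation -> no action; swapped alleles -> negate the outcome beta
#' and reflect its EAF (`sign_flip`); alleles matching only after
#' complementing both outcome alleles -> `strand_flip` (possibly combined
#' with a sign flip). Palindromic SNPs cannot be resolved by strand: under
#' `drop_all` they are always removed; under `drop_intermediate` they are
#' removed only when either EAF falls inside `eaf_window` (ambiguous), and
#' otherwise oriented so both EAFs lie on the same side of 0.5.
#' Irreconcilable alleles are removed with reason `allele_mismatch`.
#'
#' @param exp,out single records (1-row data.frames or lists) with the same
#'   `snp_id`.
#' @param palindrome_policy `"drop_intermediate"` (default) or `"drop_all"`.
#' @param eaf_window ambiguity window for palindromic SNPs; default
#'   `c(0.42, 0.58)`.
#' @return a list: either `$pair` (snp_id, beta_exp, se_exp, beta_out,
#'   se_out, eaf_exp, eaf_out, action) or `$removed` (the reason).
#' @export
harmonize_pair <- function(exp, out,
                           palindrome_policy = c("drop_intermediate", "drop_all"),
                           eaf_window = c(0.42, 0.58)) {
  palindrome_policy <- match.arg(palindrome_policy)
  if (exp$snp_id != out$snp_id)
    stop_bimr("snp_id mismatch: ", exp$snp_id, " vs ", out$snp_id)

  pair <- function(beta_out, eaf_out, action) {
    list(pair = data.frame(
      snp_id = exp$snp_id,
      beta_exp = exp$beta, se_exp = exp$se,
      beta_out = beta_out, se_out = out$se,
      eaf_exp = exp$eaf, eaf_out = eaf_out,
      action = action, stringsAsFactors = FALSE
    ))
  }
  removed <- function(reason) list(removed = reason)

  ea_e <- exp$effect_allele; oa_e <- exp$other_allele
  ea_o <- out$effect_allele; oa_o <- out$other_allele

  if (is_palindromic(ea_e, oa_e)) {
    # outcome alleles must form the same pair (its complement is itself)
    if (!setequal(c(ea_o, oa_o), c(ea_e, oa_e)))
      return(removed("allele_mismatch"))
    if (palindrome_policy == "drop_all")
      return(removed("palindromic"))
    inside <- function(f) f > eaf_window[1] & f < eaf_window[2]
    if (inside(exp$eaf) || inside(out$eaf))
      return(removed("palindromic_intermediate_eaf"))
    # orient by EAF agreement: both frequencies on the same side of 0.5
    if ((exp$eaf - 0.5) * (out$eaf - 0.5) < 0)
      return(pair(-out$beta, 1 - out$eaf, "sign_flip"))
    return(pair(out$beta, out$eaf, "none"))
  }

  if (ea_o == ea_e && oa_o == oa_e)
    return(pair(out$beta, out$eaf, "none"))
  if (ea_o == oa_e && oa_o == ea_e)
    return(pair(-out$beta, 1 - out$eaf, "sign_flip"))
  cea <- unname(STRAND_COMPLEMENT[ea_o]); coa <- unname(STRAND_COMPLEMENT[oa_o])
  if (cea == ea_e && coa == oa_e)
    return(pair(out$beta, out$eaf, "strand_flip"))
  if (cea == oa_e && coa == ea_e)
    return(pair(-out$beta, 1 - out$eaf, "strand_flip_and_sign"))
  removed("allele_mismatch")
}

#' Construct a harmonized exposure/outcome set
#'
#' Container consumed by every estimator: per-SNP aligned exposure and
#' outcome effects referring to the same effect allele.
#'
#' @param beta_exp,se_exp,beta_out,se_out aligned effects and standard errors.
#' @param snp_id optional SNP IDs (defaults to `snp_1..J`).
#' @param eaf_exp,eaf_out optional aligned EAFs.
#' @param action harmonization actions (default `"none"`).
#' @param exposure_id,outcome_id trait labels.
#' @param removed data.frame `(snp_id, reason)` of instruments lost during
#'   harmonization.
#' @return object of class `harmonized_set`.
#' @export
harmonized_set <- function(beta_exp, se_exp, beta_out, se_out,
                           snp_id = NULL, eaf_exp = NA_real_,
                           eaf_out = NA_real_, action = "none",
                           exposure_id = "exposure", outcome_id = "outcome",
                           removed = NULL) {
  J <- length(beta_exp)
  stopifnot(length(se_exp) == J, length(beta_out) == J, length(se_out) == J,
            all(se_exp > 0), all(se_out > 0))
  pairs <- data.frame(
    snp_id = snp_id %||% paste0("snp_", seq_len(J)),
    beta_exp = beta_exp, se_exp = se_exp,
    beta_out = beta_out, se_out = se_out,
    eaf_exp = eaf_exp, eaf_out = eaf_out, action = action,
    stringsAsFactors = FALSE
  )
  structure(
    list(exposure_id = exposure_id, outcome_id = outcome_id, pairs = pairs,
         removed = removed %||% data.frame(snp_id = character(),
                                           reason = character())),
    class = "harmonized_set"
  )
}

#' @export
print.harmonized_set <- function(x, ...) {
  cat(sprintf("<harmonized_set> %s -> %s: %d pairs, %d removed\n",
              x$exposure_id, x$outcome_id, nrow(x$pairs), nrow(x$removed)))
  invisible(x)
}

#' Harmonize an instrument set against an outcome dataset
#'
#' Applies [harmonize_pair()] to every instrument found in the outcome
#' dataset; instruments absent from it are removed with reason
#' `missing_in_outcome` (no proxy lookup).
#'
#' @param iv_set an [instrument_set()].
#' @param outcome outcome `summary_dataset`.
#' @inheritParams harmonize_pair
#' @return a [harmonized_set()].
#' @export
harmonize_datasets <- function(iv_set, outcome,
                               palindrome_policy = c("drop_intermediate", "drop_all"),
                               eaf_window = c(0.42, 0.58)) {
  palindrome_policy <- match.arg(palindrome_policy)
  members <- iv_set$members
  out_rec <- outcome$records
  pairs <- list()
  removed <- list()
  for (i in seq_len(nrow(members))) {
    m <- members[i, ]
    hit <- which(out_rec$snp_id == m$snp_id)
    if (!length(hit)) {
      removed[[length(removed) + 1L]] <-
        data.frame(snp_id = m$snp_id, reason = "missing_in_outcome",
                   stringsAsFactors = FALSE)
      next
    }
    h <- harmonize_pair(m, out_rec[hit[1], ], palindrome_policy, eaf_window)
    if (!is.null(h$pair)) {
      pairs[[length(pairs) + 1L]] <- h$pair
    } else {
      removed[[length(removed) + 1L]] <-
        data.frame(snp_id = m$snp_id, reason = h$removed,
                   stringsAsFactors = FALSE)
    }
  }
  removed_df <- if (length(removed)) do.call(rbind, removed) else
    data.frame(snp_id = character(), reason = character())
  if (!length(pairs))
    stop_bimr("no instruments survived harmonization for ",
              iv_set$exposure_id, " -> ", outcome$trait_id)
  pdf <- do.call(rbind, pairs)
  harmonized_set(pdf$beta_exp, pdf$se_exp, pdf$beta_out, pdf$se_out,
                 snp_id = pdf$snp_id, eaf_exp = pdf$eaf_exp,
                 eaf_out = pdf$eaf_out, action = pdf$action,
                 exposure_id = iv_set$exposure_id,
                 outcome_id = outcome$trait_id, removed = removed_df)
}
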