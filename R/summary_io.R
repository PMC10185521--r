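# Reading, validating and writing GWAS summary-statistic and LD tables.
# The canonical on-disk dialect is plain TSV (pre-extracted GWAS exports),
# never GWAS-VCF; a column map makes arbitrary headers ingestible.

VALID_ALLELES <- c("A", "C", "G", "T")

#' @rdname read_summary_stats
#' @format NULL
SUMMARY_COLUMNS <- c("snp_id", "chrom", "pos", "effect_allele", "other_allele",
                     "eaf", "beta", "se", "pval", "n")

#' Construct a GWAS summary-statistic dataset
#'
#' A `summary_dataset` holds one GWAS's per-SNP association records for a
#' single trait: alleles, effect-allele frequency (EAF), additive effect
#' `beta` (log-odds for binary traits, SD units for normalized continuous
#' traits), its standard error, p-value and sample size.
#'
#' @param records data.frame with columns `snp_id, chrom, pos, effect_allele,
#'   other_allele, eaf, beta, se, pval, n`.
#' @param trait_id label for the trait (e.g. a GWAS accession).
#' @param trait_type `"continuous"` or `"binary"`.
#' @param audit optional data.frame of dropped rows `(snp_id, reason)`.
#' @return an object of class `summary_dataset`.
#' @export
summary_dataset <- function(records, trait_id,
                            trait_type = c("continuous", "binary"),
                            audit = NULL) {
  trait_type <- match.arg(trait_type)
  records <- as.data.frame(records)[, SUMMARY_COLUMNS]
  if (anyDuplicated(records$snp_id))
    stop_bimr("duplicate snp_id in dataset '", trait_id, "'")
  rownames(records) <- NULL
  structure(
    list(trait_id = trait_id, trait_type = trait_type, records = records,
         audit = audit %||% data.frame(snp_id = character(),
                                       reason = character())),
    class = "summary_dataset"
  )
}

#' @export
print.summary_dataset <- function(x, ...) {
  cat(sprintf("<summary_dataset> %s (%s): %d SNPs, %d dropped on read\n",
              x$trait_id, x$trait_type, nrow(x$records), nrow(x$audit)))
  invisible(x)
}

# per-row invariant check; returns the first violated reason or NA
.record_violation <- function(r) {
  if (is.na(r$snp_id) || !nzchar(r$snp_id)) return("missing_snp_id")
  if (is.na(r$effect_allele) || is.na(r$other_allele) ||
      !(r$effect_allele %in% VALID_ALLELES) ||
      !(r$other_allele %in% VALID_ALLELES)) return("invalid_allele")
  if (r$effect_allele == r$other_allele) return("identical_alleles")
  if (is.na(r$eaf) || r$eaf <= 0 || r$eaf >= 1) return("eaf_out_of_range")
  if (is.na(r$beta)) return("missing_beta")
  if (is.na(r$se) || r$se <= 0) return("nonpositive_se")
  if (is.na(r$pval) || r$pval <= 0 || r$pval > 1) return("pval_out_of_range")
  if (is.na(r$n) || r$n < 3) return("n_too_small")
  NA_character_
}

#' Read a GWAS summary-statistic TSV
#'
#' Reads a tab-separated table with a header row, maps its columns onto the
#' canonical fields, uppercases alleles, and drops (with an audit trail) any
#' row violating the record invariants: single-nucleotide A/C/G/T alleles,
#' `effect_allele != other_allele`, `se > 0`, `0 < eaf < 1`, `0 < pval <= 1`,
#' `n >= 3`. Rows whose p-value disagrees with the normal approximation
#' `2*pnorm(-|beta/se|)` by more than two orders of magnitude trigger a
#' validation warning but are kept.
#'
#' @param path TSV file path.
#' @param column_map named character vector mapping canonical field names
#'   (see `SUMMARY_COLUMNS`) to the file's column headers; defaults to the
#'   canonical names themselves.
#' @param trait_id,trait_type passed to [summary_dataset()].
#' @return a `summary_dataset`; dropped rows are recorded in `$audit`.
#' @export
read_summary_stats <- function(path, column_map = NULL, trait_id = basename(path),
                               trait_type = c("continuous", "binary")) {
  trait_type <- match.arg(trait_type)
  if (!file.exists(path)) stop_bimr("file not found: ", path)
  raw <- utils::read.delim(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, check.names = FALSE)
  cmap <- setNames(SUMMARY_COLUMNS, SUMMARY_COLUMNS)
  if (!is.null(column_map)) cmap[names(column_map)] <- column_map
  missing_cols <- cmap[!cmap %in% names(raw)]
  if (length(missing_cols))
    stop_bimr("missing mapped column(s): ", paste(missing_cols, collapse = ", "))

  rec <- data.frame(
    snp_id        = as.character(raw[[cmap["snp_id"]]]),
    chrom         = as.character(raw[[cmap["chrom"]]]),
    pos           = as.integer(raw[[cmap["pos"]]]),
    effect_allele = toupper(as.character(raw[[cmap["effect_allele"]]])),
    other_allele  = toupper(as.character(raw[[cmap["other_allele"]]])),
    eaf           = as.numeric(raw[[cmap["eaf"]]]),
    beta          = as.numeric(raw[[cmap["beta"]]]),
    se            = as.numeric(raw[[cmap["se"]]]),
    pval          = as.numeric(raw[[cmap["pval"]]]),
    n             = as.numeric(raw[[cmap["n"]]]),
    stringsAsFactors = FALSE
  )

  reasons <- vapply(seq_len(nrow(rec)),
                    function(i) .record_violation(rec[i, ]), character(1))
  keep <- is.na(reasons)
  audit <- data.frame(snp_id = rec$snp_id[!keep], reason = reasons[!keep],
                      stringsAsFactors = FALSE)
  rec <- rec[keep, , drop = FALSE]
  if (nrow(rec) == 0L)
    stop_bimr("no valid rows in ", path)

  # soft consistency check: reported p vs normal-approximation p
  p_norm <- z_pval(rec$beta / rec$se)
  off <- abs(log10(pmax(rec$pval, 1e-320)) - log10(pmax(p_norm, 1e-320))) > 2
  if (any(off))
    warning(sum(off), " row(s) have p-values inconsistent with beta/se by >2",
            " orders of magnitude", call. = FALSE)

  summary_dataset(rec, trait_id, trait_type, audit = audit)
}

#' Write a summary-statistic dataset as canonical TSV
#'
#' Column order is `snp_id, chrom, pos, effect_allele, other_allele, eaf,
#' beta, se, pval, n`. Numeric fields are written with 17 significant digits
#' so that `read_summary_stats(write_summary_stats(x))` is the identity,
#' including extreme p-values (e.g. 5e-300).
#'
#' @param dataset a `summary_dataset`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_summary_stats <- function(dataset, path) {
  stopifnot(inherits(dataset, "summary_dataset"))
  out <- dataset$records
  for (col in c("eaf", "beta", "se", "pval"))
    out[[col]] <- sprintf("%.17g", out[[col]])
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct / read a pairwise LD table
#'
#' Stores r-squared between SNP pairs under an unordered key (the pair is
#' normalized so `snp_a <= snp_b`); duplicate pairs keep the maximum r2,
#' which is the conservative choice for clumping. `r2(x, x)` is treated as 1
#' by [ld_r2()].
#'
#' @param pairs data.frame with columns `snp_a, snp_b, r2`.
#' @return an object of class `ld_table`.
#' @export
ld_table <- function(pairs = data.frame(snp_a = character(),
                                        snp_b = character(),
                                        r2 = numeric())) {
  pairs <- as.data.frame(pairs)[, c("snp_a", "snp_b", "r2")]
  pairs$r2 <- as.numeric(pairs$r2)
  if (nrow(pairs) && (any(is.na(pairs$r2)) || any(pairs$r2 < 0) || any(pairs$r2 > 1)))
    stop_bimr("r2 outside [0, 1] in LD table")
  if (nrow(pairs) == 0L) {
    pairs$snp_a <- as.character(pairs$snp_a)
    pairs$snp_b <- as.character(pairs$snp_b)
    return(structure(list(pairs = pairs), class = "ld_table"))
  }
  a <- pmin(as.character(pairs$snp_a), as.character(pairs$snp_b))
  b <- pmax(as.character(pairs$snp_a), as.character(pairs$snp_b))
  key <- paste(a, b, sep = "\r")
  r2 <- tapply(pairs$r2, key, max)
  keys <- names(r2)
  split_keys <- strsplit(keys, "\r", fixed = TRUE)
  tab <- data.frame(
    snp_a = vapply(split_keys, `[[`, character(1), 1),
    snp_b = vapply(split_keys, `[[`, character(1), 2),
    r2 = as.numeric(r2),
    stringsAsFactors = FALSE
  )
  rownames(tab) <- NULL
  structure(list(pairs = tab), class = "ld_table")
}

#' @rdname ld_table
#' @param path TSV file with columns `snp_a, snp_b, r2` (plink `--r2` output
#'   reshaped to three columns).
#' @export
read_ld_table <- function(path) {
  if (!file.exists(path)) stop_bimr("file not found: ", path)
  raw <- utils::read.delim(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  need <- c("snp_a", "snp_b", "r2")
  if (!all(need %in% names(raw)))
    stop_bimr("LD table must have columns: ", paste(need, collapse = ", "))
  ld_table(raw)
}

#' @rdname ld_table
#' @param ld an `ld_table`.
#' @param snp_a,snp_b SNP identifiers.
#' @return `ld_r2()`: the tabulated r2, 1 for a SNP with itself, or `NA`
#'   when the pair is absent from the table.
#' @export
ld_r2 <- function(ld, snp_a, snp_b) {
  if (snp_a == snp_b) return(1)
  a <- pmin(snp_a, snp_b)
  b <- pmax(snp_a, snp_b)
  hit <- ld$pairs$snp_a == a & ld$pairs$snp_b == b
  if (any(hit)) ld$pairs$r2[hit][1] else NA_real_
}
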