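# Fixture builders shared across test files. Everything is generated in
# code; nothing is read from disk except through temp files written here.

# a small, fully valid records data.frame
make_records <- function(n = 5, seed = 1, chrom = NULL, pos = NULL,
                         pval = NULL, beta = NULL) {
  set.seed(seed)
  eaf <- runif(n, 0.1, 0.5)
  beta <- beta %||% rnorm(n, 0.1, 0.02)
  se <- runif(n, 0.005, 0.02)
  data.frame(
    snp_id = sprintf("rs%03d", seq_len(n)),
    chrom = chrom %||% as.character(rep_len(1:22, n)),
    pos = pos %||% (1000000L + seq_len(n) * 10000000L),
    effect_allele = rep_len(c("A", "C", "T", "G"), n),
    other_allele = rep_len(c("G", "T", "C", "A"), n),
    eaf = eaf, beta = beta, se = se,
    pval = pval %||% (2 * pnorm(-abs(beta / se))),
    n = 20000L,
    stringsAsFactors = FALSE
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

make_dataset <- function(n = 5, trait_id = "trait", trait_type = "continuous",
                         ...) {
  summary_dataset(make_records(n, ...), trait_id, trait_type)
}

# one-row record constructor for harmonization cases
rec1 <- function(snp_id = "rs1", ea, oa, beta = 0.1, se = 0.01, eaf = 0.3,
                 chrom = "1", pos = 1000L, n = 20000L) {
  data.frame(snp_id = snp_id, chrom = chrom, pos = pos,
             effect_allele = ea, other_allele = oa, eaf = eaf, beta = beta,
             se = se, pval = 2 * pnorm(-abs(beta / se)), n = n,
             stringsAsFactors = FALSE)
}

# harmonized set straight from effect vectors (theta_j = bo_j / be_j)
hset_from <- function(beta_exp, beta_out, se_out, se_exp = NULL) {
  harmonized_set(beta_exp, se_exp %||% rep(0.01, length(beta_exp)),
                 beta_out, se_out)
}

# harmonized set with prescribed Wald ratios and IVW weights (se_out = 1)
hset_theta_w <- function(theta, w) {
  be <- sqrt(w)
  harmonized_set(be, rep(0.01, length(w)), theta * be, rep(1, length(w)))
}

write_tsv <- function(df, path = tempfile(fileext = ".tsv")) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
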