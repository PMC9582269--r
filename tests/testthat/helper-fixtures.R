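# fixtures built in code: small ratio panels, harmonized sets, and random
# summary-statistics tables used across the suite

make_ratios <- function(ratio, se_ratio) {
  tibble::tibble(rsid = sprintf("rs%03d", seq_along(ratio)),
                 ratio = ratio, se_ratio = se_ratio)
}

make_pairs <- function(beta_exp, se_exp, beta_out, se_out) {
  tibble::tibble(rsid = sprintf("rs%03d", seq_along(beta_exp)),
                 beta_exp = beta_exp, se_exp = se_exp,
                 beta_out = beta_out, se_out = se_out)
}

random_pairs <- function(k, seed) {
  set.seed(seed)
  make_pairs(beta_exp = runif(k, 0.02, 0.2),
             se_exp = runif(k, 0.005, 0.02),
             beta_out = rnorm(k, 0, 0.05),
             se_out = runif(k, 0.01, 0.05))
}

random_sumstats_df <- function(n, seed) {
  set.seed(seed)
  df <- data.frame(rsid = sprintf("rs%06d", sample.int(1e6, n)),
                   chrom = as.character(sample(1:22, n, replace = TRUE)),
                   pos = sample.int(1e8, n),
                   effect_allele = sample(c("A", "C", "G", "T"), n,
                                          replace = TRUE),
                   eaf = runif(n, 0.01, 0.99),
                   beta = rnorm(n, 0, 0.1),
                   se = runif(n, 1e-4, 0.05),
                   pval = runif(n),
                   n = sample.int(1e6, n),
                   stringsAsFactors = FALSE)
  # pick a different other allele per row
  df$other_allele <- vapply(df$effect_allele, function(a) {
    sample(setdiff(c("A", "C", "G", "T"), a), 1)
  }, character(1), USE.NAMES = FALSE)
  df[, c("rsid", "chrom", "pos", "effect_allele", "other_allele", "eaf",
         "beta", "se", "pval", "n")]
}

# one-row sumstats-shaped record builder for harmonization cases
snp_row <- function(rsid, ea, oa, eaf, beta, se = 0.01, chrom = "1",
                    pos = 1e6, pval = 1e-8, n = 1e5) {
  data.frame(rsid = rsid, chrom = chrom, pos = pos, effect_allele = ea,
             other_allele = oa, eaf = eaf, beta = beta, se = se,
             pval = pval, n = n, stringsAsFactors = FALSE)
}

as_stats <- function(df, name = "trait", type = "binary") {
  summr::sumstats(df, trait_name = name, trait_type = type)
}

# effect pairs straight from a synthetic dataset (alleles are identical by
# construction, so harmonization is the identity map)
synth_pairs <- function(d) {
  tibble::tibble(rsid = d$exposure$rsid,
                 beta_exp = d$exposure$beta,
                 se_exp = d$exposure$se,
                 beta_out = d$outcome$beta,
                 se_out = d$outcome$se)
}

synth_ivw <- function(d) {
  summr::ivw_mre(summr::wald_ratios(synth_pairs(d)))
}
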