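#' Configuration for the synthetic two-sample GWAS generator
#'
#' Defaults encode the study conditions the pipeline is validated under: a
#' 12-instrument panel for a binary exposure measured in a study of
#' 350,000, a binary outcome study of 500,000 with a 10% case fraction,
#' and a true causal effect of ln(1.1) on the log-odds scale. Common
#' variants (minor-allele frequencies 0.05-0.45) with per-allele effect
#' scale 0.02 give instruments whose strength (F statistics in the tens to
#' low hundreds) matches what genome-wide-suggestive panels for psychiatric
#' exposures look like in practice.
#'
#' @param k number of independent instruments (>= 3).
#' @param n_exp,n_out exposure- and outcome-study sample sizes.
#' @param case_frac_out outcome case fraction in (0, 1).
#' @param theta true causal effect (log-odds per unit exposure liability).
#' @param maf_range range of effect-allele frequencies, within (0, 0.5\].
#' @param gamma_scale SD of the true per-SNP exposure effects.
#' @param pleiotropy list with `mode` (`"none"`, `"balanced"`,
#'   `"directional"`), `mu_alpha` (mean direct SNP-outcome effect;
#'   forced to 0 for balanced), `sd_alpha`, `frac_invalid` (proportion of
#'   instruments carrying a pleiotropic path).
#' @param seed integer seed; every draw flows from it.
#' @return A `synth_config` list.
#' @export
synth_config <- function(k = 12, n_exp = 350000, n_out = 500000,
                         case_frac_out = 0.1, theta = log(1.1),
                         maf_range = c(0.05, 0.45), gamma_scale = 0.02,
                         pleiotropy = list(mode = "none", mu_alpha = 0,
                                           sd_alpha = 0, frac_invalid = 0),
                         seed = 1L) {
  stopifnot(k >= 3, n_exp > 2, n_out > 2,
            case_frac_out > 0, case_frac_out < 1,
            length(maf_range) == 2, maf_range[1] > 0,
            maf_range[1] <= maf_range[2], maf_range[2] <= 0.5,
            gamma_scale > 0)
  pl <- utils::modifyList(list(mode = "none", mu_alpha = 0, sd_alpha = 0,
                               frac_invalid = 0), pleiotropy)
  stopifnot(pl$mode %in% c("none", "balanced", "directional"),
            pl$frac_invalid >= 0, pl$frac_invalid <= 1)
  if (pl$mode == "balanced") pl$mu_alpha <- 0
  if (pl$mode == "none") pl$frac_invalid <- 0
  structure(list(k = as.integer(k), n_exp = n_exp, n_out = n_out,
                 case_frac_out = case_frac_out, theta = theta,
                 maf_range = maf_range, gamma_scale = gamma_scale,
                 pleiotropy = pl, seed = as.integer(seed)),
            class = "synth_config")
}

# instrument-significance threshold on |gamma|/se at p < 5e-7 (two-sided)
INSTRUMENT_Z <- qnorm(1 - 2.5e-7)

draw_gammas <- function(k, se_exp, gamma_scale, max_tries = 1000L) {
  # rejection-sample true effects until each instrument is
  # genome-wide-suggestive (p < 5e-7) at the exposure sample size
  gamma <- rep(NA_real_, k)
  need <- seq_len(k)
  tries <- 0L
  while (length(need) > 0) {
    tries <- tries + 1L
    if (tries > max_tries) {
      stop("instrument rejection sampling failed after ", max_tries,
           " rounds; increase gamma_scale or n_exp", call. = FALSE)
    }
    cand <- rnorm(length(need), 0, gamma_scale)
    ok <- abs(cand) / se_exp[need] > INSTRUMENT_Z
    gamma[need[ok]] <- cand[ok]
    need <- need[!ok]
  }
  # oriented to the exposure-increasing allele, the convention instrument
  # tables are reported in (half-normal effect sizes)
  abs(gamma)
}

synth_sumstats <- function(rsid, chrom, pos, eaf, beta, se, n, trait, type) {
  sumstats(tibble(rsid = rsid, chrom = chrom, pos = pos,
                  effect_allele = "A", other_allele = "G", eaf = eaf,
                  beta = beta, se = se,
                  pval = pmax(2 * pnorm(-abs(beta) / se),
                              .Machine$double.xmin),
                  n = n),
           trait_name = trait, trait_type = type)
}

#' Generate a synthetic two-sample GWAS dataset
#'
#' Simulates directly on the summary-statistic scale: allele frequencies
#' uniform over `maf_range`; true exposure effects rejection-sampled to be
#' genome-wide-suggestive and oriented to the exposure-increasing allele
#' (as instrument tables are reported); exposure standard errors
#' \eqn{1/\sqrt{2f(1-f)N_{exp}}}; outcome standard errors include the
#' binary-trait case-fraction inflation
#' \eqn{1/\sqrt{2f(1-f)N_{out}\phi(1-\phi)}}; observed effects are the true
#' effects plus independent Gaussian noise at those standard errors, with
#' the outcome mean \eqn{\theta\gamma_j + \alpha_j} where \eqn{\alpha_j} is
#' the (possibly zero) pleiotropic path. Exposure and outcome noise are
#' independent, mirroring non-overlapping study samples. Instruments sit on
#' distinct chromosomes, so they are unlinked by construction; alleles are
#' non-palindromic.
#'
#' @param cfg a [synth_config()].
#' @return List with `exposure` and `outcome` (`sumstats` objects) and
#'   `truth` (tibble of per-SNP `gamma`, `alpha`, the causal `theta`, and
#'   the true Wald `ratio_true`).
#' @export
generate_gwas <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(cfg$seed)
  k <- cfg$k
  rsid <- sprintf("rs%07d", seq_len(k))
  chrom <- as.character(rep_len(1:22, k))
  pos <- 1e6 + 1e6 * (seq_len(k) - 1) %/% 22
  maf <- runif(k, cfg$maf_range[1], cfg$maf_range[2])
  se_exp <- 1 / sqrt(2 * maf * (1 - maf) * cfg$n_exp)
  se_out <- 1 / sqrt(2 * maf * (1 - maf) * cfg$n_out *
                       cfg$case_frac_out * (1 - cfg$case_frac_out))
  gamma <- draw_gammas(k, se_exp, cfg$gamma_scale)
  pl <- cfg$pleiotropy
  invalid <- runif(k) < pl$frac_invalid
  alpha <- ifelse(invalid, rnorm(k, pl$mu_alpha, pl$sd_alpha), 0)
  beta_exp <- rnorm(k, gamma, se_exp)
  beta_out <- rnorm(k, cfg$theta * gamma + alpha, se_out)
  list(
    exposure = synth_sumstats(rsid, chrom, pos, maf, beta_exp, se_exp,
                              cfg$n_exp, "synthetic_exposure", "binary"),
    outcome = synth_sumstats(rsid, chrom, pos, maf, beta_out, se_out,
                             cfg$n_out, "synthetic_outcome", "binary"),
    truth = tibble(rsid = rsid, gamma = gamma, alpha = alpha,
                   theta = cfg$theta,
                   ratio_true = (cfg$theta * gamma + alpha) / gamma)
  )
}

#' Generate a synthetic dataset with two correlated exposures
#'
#' Extends [generate_gwas()] to the multivariable setting: `k1` SNPs
#' instrument the first exposure and `k2` the second, each
#' genome-wide-suggestive for its own exposure, with cross-trait true
#' effects drawn so that the two exposures' per-SNP effects have
#' correlation `rho_gamma`. The outcome mean is
#' \eqn{\theta_1\gamma_{1j} + \theta_2\gamma_{2j}}. Setting
#' `rho_gamma = a` (equal effect scales) makes the second exposure behave
#' as a mediator with exposure-to-mediator effect `a`, which is how the
#' mediation fixtures are built.
#'
#' @param cfg1,cfg2 [synth_config()]s for the two exposures (seeds: all
#'   draws flow from `cfg1$seed`; `cfg2`'s seed is ignored).
#' @param theta1,theta2 direct effects of each exposure on the outcome.
#' @param rho_gamma correlation of the true per-SNP effects, |rho| < 1.
#' @return List with `exposure1`, `exposure2`, `outcome` (`sumstats`),
#'   `instruments1`, `instruments2` (rsids), and `truth`.
#' @export
generate_mvmr <- function(cfg1, cfg2 = cfg1, theta1, theta2, rho_gamma = 0) {
  stopifnot(inherits(cfg1, "synth_config"), inherits(cfg2, "synth_config"),
            abs(rho_gamma) < 1)
  set.seed(cfg1$seed)
  k1 <- cfg1$k; k2 <- cfg2$k; k <- k1 + k2
  rsid <- sprintf("rs%07d", seq_len(k))
  chrom <- as.character(rep_len(1:22, k))
  pos <- 1e6 + 1e6 * (seq_len(k) - 1) %/% 22
  maf <- runif(k, cfg1$maf_range[1], cfg1$maf_range[2])
  se_exp1 <- 1 / sqrt(2 * maf * (1 - maf) * cfg1$n_exp)
  se_exp2 <- 1 / sqrt(2 * maf * (1 - maf) * cfg2$n_exp)
  se_out <- 1 / sqrt(2 * maf * (1 - maf) * cfg1$n_out *
                       cfg1$case_frac_out * (1 - cfg1$case_frac_out))

  own1 <- seq_len(k1)
  own2 <- k1 + seq_len(k2)
  gamma1 <- numeric(k); gamma2 <- numeric(k)
  gamma1[own1] <- draw_gammas(k1, se_exp1[own1], cfg1$gamma_scale)
  gamma2[own2] <- draw_gammas(k2, se_exp2[own2], cfg2$gamma_scale)
  # cross-trait effects with the requested correlation
  gamma2[own1] <- rho_gamma * (cfg2$gamma_scale / cfg1$gamma_scale) *
    gamma1[own1] +
    sqrt(1 - rho_gamma^2) * rnorm(k1, 0, cfg2$gamma_scale)
  gamma1[own2] <- rho_gamma * (cfg1$gamma_scale / cfg2$gamma_scale) *
    gamma2[own2] +
    sqrt(1 - rho_gamma^2) * rnorm(k2, 0, cfg1$gamma_scale)

  beta_exp1 <- rnorm(k, gamma1, se_exp1)
  beta_exp2 <- rnorm(k, gamma2, se_exp2)
  mu_out <- theta1 * gamma1 + theta2 * gamma2
  beta_out <- rnorm(k, mu_out, se_out)
  list(
    exposure1 = synth_sumstats(rsid, chrom, pos, maf, beta_exp1, se_exp1,
                               cfg1$n_exp, "synthetic_exposure1", "binary"),
    exposure2 = synth_sumstats(rsid, chrom, pos, maf, beta_exp2, se_exp2,
                               cfg2$n_exp, "synthetic_exposure2", "binary"),
    outcome = synth_sumstats(rsid, chrom, pos, maf, beta_out, se_out,
                             cfg1$n_out, "synthetic_outcome", "binary"),
    instruments1 = rsid[own1],
    instruments2 = rsid[own2],
    truth = tibble(rsid = rsid, gamma1 = gamma1, gamma2 = gamma2,
                   theta1 = theta1, theta2 = theta2)
  )
}
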