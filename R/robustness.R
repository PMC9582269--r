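#' Cochran Q heterogeneity statistic with I-squared banding
#'
#' Measures over-dispersion of the per-SNP Wald ratios around the pooled
#' estimate: \eqn{Q = \sum_j w_j (r_j - \beta)^2} with inverse-variance
#' weights, referred to a chi-square with k - 1 degrees of freedom.
#' I-squared expresses the excess as a percentage of Q, banded at 25% and
#' 50%; the 50% boundary is assigned to the moderate band.
#'
#' @param ratios tibble from [wald_ratios()]; at least 2 rows.
#' @param beta_pooled pooled estimate (defaults to the IVW mean).
#' @return Tibble with `q`, `df`, `pval`, `i2` (percentage), `band`.
#' @export
cochran_q <- function(ratios, beta_pooled = ivw_fixed_beta(ratios)) {
  k <- nrow(ratios)
  if (k < 2) stop("heterogeneity requires at least 2 instruments",
                  call. = FALSE)
  w <- 1 / ratios$se_ratio^2
  q <- sum(w * (ratios$ratio - beta_pooled)^2)
  df <- k - 1
  i2 <- if (q > 0) max(0, (q - df) / q) * 100 else 0
  band <- if (i2 <= 25) "low" else if (i2 <= 50) "moderate" else "high"
  tibble(q = q, df = as.integer(df),
         pval = pchisq(q, df, lower.tail = FALSE), i2 = i2, band = band)
}

presso_loo_stats <- function(rmat, w) {
  # leave-one-out IVW betas and weighted squared residuals, vectorized over
  # the columns of rmat (each column one dataset of k ratios)
  sw <- sum(w)
  swr <- colSums(w * rmat)
  b_loo <- (matrix(swr, nrow(rmat), ncol(rmat), byrow = TRUE) - w * rmat) /
    (sw - w)
  d <- w * (rmat - b_loo)^2
  list(d = d, rss = colSums(d))
}

#' MR-PRESSO: residual-sum-of-squares pleiotropy test with outlier
#' correction
#'
#' The observed statistic is the inverse-variance-weighted sum of squared
#' differences between each SNP's outcome effect and the prediction from
#' the IVW estimate computed without that SNP. Its null distribution is
#' simulated by drawing outcome effects from their leave-one-out
#' predictions with the observed standard errors and recomputing the
#' statistic on each draw. The global empirical p is floored at
#' 1/(nsim + 1). Per-SNP outlier tests use the same construction per
#' observation with Bonferroni correction across instruments; flagged
#' outliers are removed and the IVW estimate recomputed, and a distortion
#' test (exploratory) compares the raw-vs-corrected displacement with the
#' displacement obtained by removing random instrument subsets of the same
#' size.
#'
#' @param pairs a `harmonized` tibble (dropped rows ignored) or data frame
#'   with `rsid`, `beta_exp`, `beta_out`, `se_out`; at least 4 rows. A
#'   warning is emitted for panels of 10 or fewer instruments, where the
#'   test is underpowered.
#' @param nsim number of null simulations.
#' @param seed integer seed.
#' @param outlier_alpha familywise level for the Bonferroni outlier test.
#' @return List with `global_rss`, `global_p`, `outlier_rsids`, `outlier_p`
#'   (named, Bonferroni-adjusted), `corrected` (IVW estimate without
#'   outliers, or `NULL` when none are flagged), `distortion_p` (or `NULL`).
#' @export
mr_presso <- function(pairs, nsim = 1000, seed, outlier_alpha = 0.05) {
  if ("status" %in% names(pairs)) pairs <- harmonized_kept(pairs)
  k <- nrow(pairs)
  if (k < 4) stop("MR-PRESSO requires at least 4 instruments", call. = FALSE)
  if (k <= 10) warning("MR-PRESSO applied to 10 or fewer instruments; ",
                       "the test is designed for larger panels",
                       call. = FALSE)
  if (missing(seed)) stop("seed is required", call. = FALSE)
  ratios <- wald_ratios(pairs)
  r <- ratios$ratio
  w <- pairs$beta_exp^2 / pairs$se_out^2   # ratio-scale weights, 1/se_out^2
                                           # on the outcome-effect scale
  obs <- presso_loo_stats(matrix(r, ncol = 1), w)
  se_ratio0 <- pairs$se_out / abs(pairs$beta_exp)

  set.seed(seed)
  b_loo_obs <- drop((sum(w * r) - w * r) / (sum(w) - w))
  draws <- matrix(rnorm(k * nsim, mean = b_loo_obs, sd = se_ratio0),
                  nrow = k)
  sim <- presso_loo_stats(draws, w)

  global_p <- (1 + sum(sim$rss >= obs$rss)) / (nsim + 1)
  outlier_p_raw <- (1 + rowSums(sim$d >= obs$d[, 1])) / (nsim + 1)
  outlier_p <- pmin(1, outlier_p_raw * k)
  names(outlier_p) <- pairs$rsid
  outliers <- pairs$rsid[outlier_p < outlier_alpha]

  corrected <- NULL
  distortion_p <- NULL
  if (length(outliers) == k) {
    stop("all instruments flagged as outliers; correction refused",
         call. = FALSE)
  }
  if (length(outliers) > 0) {
    keep <- !(ratios$rsid %in% outliers)
    corrected <- ivw_mre(ratios[keep, , drop = FALSE])
    raw <- ivw_mre(ratios)
    obs_disp <- (raw$beta - corrected$beta) / abs(corrected$beta)
    n_out <- length(outliers)
    sim_disp <- vapply(seq_len(nsim), function(i) {
      drop_idx <- sample.int(k, n_out)
      b_sub <- ivw_fixed_beta(ratios[-drop_idx, , drop = FALSE])
      (raw$beta - b_sub) / abs(b_sub)
    }, numeric(1))
    distortion_p <- (1 + sum(abs(sim_disp) >= abs(obs_disp))) / (nsim + 1)
  }
  list(global_rss = obs$rss, global_p = global_p,
       outlier_rsids = outliers, outlier_p = outlier_p,
       corrected = corrected, distortion_p = distortion_p)
}

#' Leave-one-out sensitivity analysis
#'
#' Re-estimates the IVW model k times, each excluding one instrument, to
#' check that no single SNP drives the pooled inference. A row is flagged
#' influential when its confidence interval and the full-panel interval
#' disagree about excluding the null.
#'
#' @param pairs a `harmonized` tibble (dropped rows ignored) or data frame
#'   usable by [wald_ratios()]; at least 3 rows.
#' @param se_mode passed to [wald_ratios()].
#' @return Tibble with one row per left-out rsid (`rsid`, `beta`, `se`,
#'   `ci_low`, `ci_high`, `pval`, `k`, `influential`), with the full-panel
#'   estimate attached as attribute `"full"`.
#' @export
leave_one_out <- function(pairs, se_mode = "first_order") {
  ratios <- wald_ratios(pairs, se_mode)
  k <- nrow(ratios)
  if (k < 3) stop("leave-one-out requires at least 3 instruments",
                  call. = FALSE)
  full <- ivw_mre(ratios)
  full_sig <- full$ci_low > 0 || full$ci_high < 0
  rows <- lapply(seq_len(k), function(j) {
    est <- ivw_mre(ratios[-j, , drop = FALSE])
    sig <- est$ci_low > 0 || est$ci_high < 0
    tibble(rsid = ratios$rsid[j], beta = est$beta, se = est$se,
           ci_low = est$ci_low, ci_high = est$ci_high, pval = est$pval,
           k = est$k, influential = sig != full_sig)
  })
  out <- do.call(rbind, rows)
  attr(out, "full") <- full
  out
}
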