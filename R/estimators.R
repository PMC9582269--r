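# 95% CI multiplier used throughout the estimate tables (fixed constant by
# contract: ci_low = beta - 1.96 se, ci_high = beta + 1.96 se)
CI_Z <- 1.96

mr_estimate <- function(method, beta, se, pval, k) {
  tibble(method = method, k = as.integer(k), beta = beta, se = se,
         ci_low = beta - CI_Z * se, ci_high = beta + CI_Z * se,
         pval = pval,
         or = exp(beta), or_low = exp(beta - CI_Z * se),
         or_high = exp(beta + CI_Z * se))
}

#' Per-SNP Wald ratio estimates
#'
#' The Wald ratio divides the SNP-outcome effect by the SNP-exposure
#' effect; its standard error comes from the Delta method. The first-order
#' SE ignores uncertainty in the exposure effect (`se_out / |beta_exp|`),
#' matching the convention of the standard two-sample MR software; the
#' second-order SE adds the exposure-effect term.
#'
#' @param pairs a `harmonized` tibble (or any data frame with `rsid`,
#'   `beta_exp`, `se_exp`, `beta_out`, `se_out`); dropped rows are ignored.
#' @param se_mode `"first_order"` or `"second_order"`.
#' @return Tibble with `rsid`, `ratio`, `se_ratio`.
#' @export
wald_ratios <- function(pairs, se_mode = c("first_order", "second_order")) {
  se_mode <- match.arg(se_mode)
  if ("status" %in% names(pairs)) pairs <- harmonized_kept(pairs)
  if (any(pairs$beta_exp == 0)) {
    stop("degenerate instrument: beta_exp = 0 for ",
         paste(pairs$rsid[pairs$beta_exp == 0], collapse = ", "),
         call. = FALSE)
  }
  ratio <- pairs$beta_out / pairs$beta_exp
  se_ratio <- if (se_mode == "first_order") {
    pairs$se_out / abs(pairs$beta_exp)
  } else {
    sqrt(pairs$se_out^2 / pairs$beta_exp^2 +
           pairs$beta_out^2 * pairs$se_exp^2 / pairs$beta_exp^4)
  }
  tibble(rsid = pairs$rsid, ratio = ratio, se_ratio = se_ratio)
}

#' Inverse-variance-weighted estimate under multiplicative random effects
#'
#' Pools Wald ratios with inverse-variance weights. The fixed-effect
#' standard error is inflated by the square root of the mean residual
#' chi-square (Cochran Q over its degrees of freedom), floored at 1 so the
#' random-effects SE never shrinks below the fixed-effect SE; the p-value
#' uses the normal reference. With a single ratio the function falls back
#' to that Wald estimate with a warning.
#'
#' @param ratios tibble from [wald_ratios()] (`ratio`, `se_ratio`).
#' @return A one-row estimate tibble (method `ivw_mre`) with attribute
#'   `"q"` holding the Cochran Q of the fixed-effect fit.
#' @export
ivw_mre <- function(ratios) {
  k <- nrow(ratios)
  if (k < 1) stop("no instruments available for IVW", call. = FALSE)
  if (k < 2) {
    warning("only one instrument: IVW falls back to the single Wald ratio",
            call. = FALSE)
    est <- mr_estimate("wald", ratios$ratio, ratios$se_ratio,
                       2 * pnorm(-abs(ratios$ratio / ratios$se_ratio)), 1L)
    attr(est, "q") <- 0
    return(est)
  }
  w <- 1 / ratios$se_ratio^2
  beta <- sum(w * ratios$ratio) / sum(w)
  se_fixed <- sqrt(1 / sum(w))
  q <- sum(w * (ratios$ratio - beta)^2)
  scale <- max(1, sqrt(q / (k - 1)))
  se <- se_fixed * scale
  est <- mr_estimate("ivw_mre", beta, se, 2 * pnorm(-abs(beta / se)), k)
  attr(est, "q") <- q
  est
}

ivw_fixed_beta <- function(ratios) {
  w <- 1 / ratios$se_ratio^2
  sum(w * ratios$ratio) / sum(w)
}

boot_median_se <- function(ratios, weights, boot_reps, seed) {
  if (boot_reps < 2) return(NA_real_)
  set.seed(seed)
  k <- nrow(ratios)
  draws <- matrix(rnorm(boot_reps * k, mean = rep(ratios$ratio, each = boot_reps),
                        sd = rep(ratios$se_ratio, each = boot_reps)),
                  nrow = boot_reps)
  meds <- apply(draws, 1, function(r) weighted_median_point(r, weights))
  sd(meds)
}

weighted_median_point <- function(ratio, w) {
  ord <- order(ratio)
  r <- ratio[ord]
  wn <- w[ord] / sum(w)
  s <- cumsum(wn) - wn / 2
  if (0.5 <= s[1]) return(r[1])
  if (0.5 >= s[length(s)]) return(r[length(r)])
  stats::approx(s, r, xout = 0.5)$y
}

#' Simple median estimator
#'
#' The unweighted median of the Wald ratios; consistent when at least half
#' of the instruments are valid. The standard error is the standard
#' deviation of the median over seeded parametric resamples
#' (`ratio* ~ Normal(ratio_j, se_ratio_j)`).
#'
#' @param ratios tibble from [wald_ratios()]; at least 3 instruments.
#' @param boot_reps number of parametric bootstrap replicates.
#' @param seed integer seed for the bootstrap.
#' @return A one-row estimate tibble (method `simple_median`).
#' @export
simple_median <- function(ratios, boot_reps = 1000, seed) {
  k <- nrow(ratios)
  if (k < 3) stop("simple median requires at least 3 instruments",
                  call. = FALSE)
  if (missing(seed)) stop("seed is required for the bootstrap", call. = FALSE)
  beta <- median(ratios$ratio)
  se <- boot_median_se(ratios, rep(1, k), boot_reps, seed)
  pval <- if (is.na(se)) NA_real_ else 2 * pnorm(-abs(beta / se))
  est <- mr_estimate("simple_median", beta, if (is.na(se)) NA_real_ else se,
                     pval, k)
  est
}

#' Weighted median estimator
#'
#' Orders the Wald ratios and interpolates the ratio at standardized
#' cumulative inverse-variance weight 0.5; consistent when at least half of
#' the total weight comes from valid instruments. Reduces exactly to the
#' simple median under equal weights. Bootstrap SE as in
#' [simple_median()].
#'
#' @inheritParams simple_median
#' @return A one-row estimate tibble (method `weighted_median`).
#' @export
weighted_median <- function(ratios, boot_reps = 1000, seed) {
  k <- nrow(ratios)
  if (k < 3) stop("weighted median requires at least 3 instruments",
                  call. = FALSE)
  if (missing(seed)) stop("seed is required for the bootstrap", call. = FALSE)
  w <- 1 / ratios$se_ratio^2
  beta <- weighted_median_point(ratios$ratio, w)
  se <- boot_median_se(ratios, w, boot_reps, seed)
  pval <- if (is.na(se)) NA_real_ else 2 * pnorm(-abs(beta / se))
  mr_estimate("weighted_median", beta, if (is.na(se)) NA_real_ else se,
              pval, k)
}

wls_fit <- function(X, y, w, df_resid) {
  XtW <- t(X * w)
  xtx <- XtW %*% X
  coefs <- solve(xtx, XtW %*% y)
  resid <- y - X %*% coefs
  rss_w <- sum(w * resid^2)
  sigma <- sqrt(rss_w / df_resid)
  cov_unit <- solve(xtx)
  se <- sqrt(diag(cov_unit)) * max(1, sigma)
  list(coef = drop(coefs), se = se, sigma = sigma)
}

#' MR-Egger regression
#'
#' Weighted least squares of the outcome effects on the exposure effects
#' with an unconstrained intercept, weights `1/se_out^2`, after orienting
#' all exposure effects positive (pairs with negative `beta_exp` have both
#' effects negated). The slope is the pleiotropy-adjusted causal estimate;
#' a nonzero intercept indicates directional horizontal pleiotropy.
#' Standard errors are inflated by the residual standard deviation when it
#' exceeds 1; p-values use the t distribution with k - 2 degrees of
#' freedom.
#'
#' @param pairs a `harmonized` tibble (dropped rows ignored) or data frame
#'   with `beta_exp`, `se_exp`, `beta_out`, `se_out`; at least 3 rows.
#' @return List with `slope` and `intercept`, each a one-row estimate
#'   tibble.
#' @export
egger <- function(pairs) {
  if ("status" %in% names(pairs)) pairs <- harmonized_kept(pairs)
  k <- nrow(pairs)
  if (k < 3) stop("MR-Egger requires at least 3 instruments", call. = FALSE)
  flip <- pairs$beta_exp < 0
  bx <- ifelse(flip, -pairs$beta_exp, pairs$beta_exp)
  by <- ifelse(flip, -pairs$beta_out, pairs$beta_out)
  w <- 1 / pairs$se_out^2
  fit <- wls_fit(cbind(intercept = 1, slope = bx), by, w, k - 2)
  pvals <- 2 * pt(-abs(fit$coef / fit$se), df = k - 2)
  list(
    slope = mr_estimate("egger_slope", fit$coef[["slope"]],
                        fit$se[["slope"]], pvals[["slope"]], k),
    intercept = mr_estimate("egger_intercept", fit$coef[["intercept"]],
                            fit$se[["intercept"]], pvals[["intercept"]], k)
  )
}

#' All univariable estimators on one harmonized set
#'
#' @param h a `harmonized` tibble.
#' @param se_mode Delta-method order for Wald ratio SEs.
#' @param boot_reps,seed bootstrap settings for the median estimators.
#' @return Estimate tibble with one row per method (`ivw_mre`,
#'   `simple_median`, `weighted_median`, `egger_slope`, `egger_intercept`).
#' @export
mr_all_methods <- function(h, se_mode = "first_order", boot_reps = 1000,
                           seed) {
  ratios <- wald_ratios(h, se_mode)
  eg <- egger(h)
  rbind(ivw_mre(ratios),
        simple_median(ratios, boot_reps, seed),
        weighted_median(ratios, boot_reps, seed + 1L),
        eg$slope, eg$intercept)
}
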