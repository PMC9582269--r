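mediation_result <- function(method, beta_total, beta_direct, beta_indirect,
                             se_indirect) {
  prop <- if (is.na(beta_total) || beta_total == 0) NA_real_ else
    beta_indirect / beta_total
  if (!is.na(prop) && (prop < 0 || prop > 1)) {
    warning("proportion mediated outside [0, 1] (inconsistent mediation): ",
            sprintf("%.3f", prop), "; reported as-is", call. = FALSE)
  }
  tibble(method = method, beta_total = beta_total, beta_direct = beta_direct,
         beta_indirect = beta_indirect, se_indirect = se_indirect,
         prop_mediated = prop)
}

#' Product-of-coefficients mediation decomposition
#'
#' Two-step MR mediation: the indirect effect is the product of the
#' exposure-to-mediator estimate `a` and the mediator-to-outcome estimate
#' `b` (the latter from multivariable MR adjusting for the exposure), with
#' the Delta-method standard error
#' \eqn{\sqrt{a^2 se_b^2 + b^2 se_a^2}}. The proportion mediated divides
#' the indirect effect by the total effect; it is undefined (reported `NA`)
#' when the total effect is zero, and a negative product (suppression) is
#' reported as-is, never clipped.
#'
#' @param a one-row estimate tibble for the exposure-to-mediator effect.
#' @param b one-row estimate tibble for the mediator-to-outcome direct
#'   effect.
#' @param total one-row estimate tibble for the total exposure-to-outcome
#'   effect.
#' @return One-row mediation tibble (method `product`): `beta_total`,
#'   `beta_direct` (total minus indirect), `beta_indirect`, `se_indirect`,
#'   `prop_mediated`.
#' @export
mediate_product <- function(a, b, total) {
  beta_indirect <- a$beta * b$beta
  se_indirect <- sqrt(a$beta^2 * b$se^2 + b$beta^2 * a$se^2)
  mediation_result("product", total$beta, total$beta - beta_indirect,
                   beta_indirect, se_indirect)
}

#' Difference-method mediation decomposition
#'
#' The indirect effect is the total effect minus the direct effect from
#' multivariable MR adjusting for the mediator, so direct + indirect
#' recomposes the total exactly. The standard error uses the independence
#' approximation \eqn{\sqrt{se_{total}^2 + se_{direct}^2}} — the covariance
#' between the two estimates is not estimable from two-sample summary data,
#' so this SE is conservative and flagged as approximate.
#'
#' @param total one-row estimate tibble for the total effect.
#' @param direct one-row estimate tibble for the direct effect (e.g. the
#'   primary-exposure row of [mvmr_ivw()]).
#' @return One-row mediation tibble (method `difference`) with attribute
#'   `"se_approximation"` = `"independence"`.
#' @export
mediate_difference <- function(total, direct) {
  beta_indirect <- total$beta - direct$beta
  se_indirect <- sqrt(total$se^2 + direct$se^2)
  out <- mediation_result("difference", total$beta, direct$beta,
                          beta_indirect, se_indirect)
  attr(out, "se_approximation") <- "independence"
  out
}
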