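align_to_reference <- function(ref_row, stats_df, rs) {
  # align a record from another study onto the reference effect allele;
  # returns c(beta, se, eaf) or NULL when absent / irreconcilable
  i <- match(rs, stats_df$rsid)
  if (is.na(i)) return(NULL)
  o <- stats_df[i, ]
  if (!all(is_simple_allele(c(o$effect_allele, o$other_allele)))) return(NULL)
  orientation <- align_alleles(ref_row$effect_allele, ref_row$other_allele,
                               o$effect_allele, o$other_allele)
  if (orientation == "mismatch") return(NULL)
  if (orientation == "same") c(o$beta, o$se, o$eaf)
  else c(-o$beta, o$se, 1 - o$eaf)
}

#' Assemble a harmonized panel for multivariable MR
#'
#' Takes the union of the two exposures' (pre-clumped) instrument sets,
#' jointly re-clumps it with the same configuration used for univariable
#' selection (each SNP entering with its smallest p across the two
#' exposures), and retains SNPs with associations in all three studies,
#' harmonized to the primary exposure's effect alleles. SNPs unresolvable
#' in any study are dropped.
#'
#' @param exposure1,exposure2,outcome `sumstats` objects (primary exposure,
#'   adjustment exposure, outcome).
#' @param instruments1,instruments2 instrument rsids for each exposure.
#' @param ld an `ld_matrix` or `NULL`.
#' @param cfg a [clump_config()].
#' @return An `mvmr_panel` tibble: `rsid`, `beta_exp1`, `se_exp1`,
#'   `beta_exp2`, `se_exp2`, `beta_out`, `se_out`; at least 3 rows or an
#'   error.
#' @export
build_mvmr_panel <- function(exposure1, exposure2, outcome,
                             instruments1, instruments2,
                             ld = NULL, cfg = clump_config()) {
  e1 <- as.data.frame(exposure1)
  e2 <- as.data.frame(exposure2)
  out <- as.data.frame(outcome)
  union_ids <- union(instruments1, instruments2)

  # joint re-clump: each union SNP enters with its best p across exposures
  p1 <- e1$pval[match(union_ids, e1$rsid)]
  p2 <- e2$pval[match(union_ids, e2$rsid)]
  best_p <- pmin(p1, p2, na.rm = TRUE)
  src <- ifelse(!is.na(p1) & (is.na(p2) | p1 <= p2), "e1", "e2")
  pos <- ifelse(src == "e1", e1$pos[match(union_ids, e1$rsid)],
                e2$pos[match(union_ids, e2$rsid)])
  chrom <- ifelse(src == "e1", e1$chrom[match(union_ids, e1$rsid)],
                  e2$chrom[match(union_ids, e2$rsid)])
  joint <- sumstats(tibble(rsid = union_ids, chrom = chrom, pos = pos,
                           effect_allele = "A", other_allele = "G",
                           eaf = 0.5, beta = 1, se = 1, pval = best_p,
                           n = 1000),
                    trait_name = "joint", trait_type = "continuous")
  clumped <- clump(joint, ld,
                   clump_config(p_threshold = 1 - 1e-12,
                                r2_threshold = cfg$r2_threshold,
                                window_kb = cfg$window_kb))

  rows <- lapply(clumped, function(rs) {
    ref_src <- if (rs %in% e1$rsid) e1 else e2
    ref <- ref_src[match(rs, ref_src$rsid), ]
    if (!all(is_simple_allele(c(ref$effect_allele, ref$other_allele)))) {
      return(NULL)
    }
    a1 <- if (identical(ref_src, e1)) c(ref$beta, ref$se, ref$eaf) else
      align_to_reference(ref, e1, rs)
    a2 <- align_to_reference(ref, e2, rs)
    ao <- align_to_reference(ref, out, rs)
    if (is.null(a1) || is.null(a2) || is.null(ao)) return(NULL)
    tibble(rsid = rs, beta_exp1 = a1[1], se_exp1 = a1[2],
           beta_exp2 = a2[1], se_exp2 = a2[2],
           beta_out = ao[1], se_out = ao[2])
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) < 3) {
    stop("insufficient MVMR panel: fewer than 3 SNPs with associations in ",
         "all three studies", call. = FALSE)
  }
  panel <- do.call(rbind, rows)
  structure(panel, class = c("mvmr_panel", class(panel)))
}

#' Multivariable inverse-variance-weighted regression
#'
#' Weighted least squares of the outcome effects on the exposure-effect
#' columns with no intercept and weights `1/se_out^2`; the coefficient on
#' the primary exposure is its direct effect, holding the adjustment
#' exposure fixed. Standard errors are inflated by the residual standard
#' deviation when it exceeds 1; p-values use the t distribution with
#' k - p residual degrees of freedom. A rank-deficient design (e.g. an
#' all-zero exposure column) raises a collinearity error naming the
#' exposure; near-collinear exposure effects (|correlation| > 0.95) emit a
#' warning.
#'
#' @param panel an `mvmr_panel` (or data frame with `beta_exp1`,
#'   optionally `beta_exp2`, `beta_out`, `se_out`).
#' @return Estimate tibble with one row per exposure (methods
#'   `mvmr_direct_exp1`, `mvmr_direct_exp2`), with attribute
#'   `"conditional_f"` giving each exposure's conditional F statistic.
#' @export
mvmr_ivw <- function(panel) {
  exp_cols <- intersect(c("beta_exp1", "beta_exp2"), names(panel))
  X <- as.matrix(as.data.frame(panel)[, exp_cols, drop = FALSE])
  y <- panel$beta_out
  w <- 1 / panel$se_out^2
  k <- nrow(X)
  p <- ncol(X)
  if (k < p + 1) stop("MVMR requires at least p + 1 SNPs", call. = FALSE)
  qrX <- qr(sqrt(w) * X)
  if (qrX$rank < p) {
    col_bad <- exp_cols[!(seq_len(p) %in% qrX$pivot[seq_len(qrX$rank)])]
    stop("collinear or degenerate exposure column(s): ",
         paste(col_bad, collapse = ", "), call. = FALSE)
  }
  if (p == 2) {
    rho <- suppressWarnings(stats::cor(X[, 1], X[, 2]))
    if (is.finite(rho) && abs(rho) > 0.95) {
      warning("exposure effects are near-collinear (|r| = ",
              sprintf("%.3f", abs(rho)), "); direct effects are unstable",
              call. = FALSE)
    }
  }
  fit <- wls_fit(X, y, w, k - p)
  pvals <- 2 * pt(-abs(fit$coef / fit$se), df = k - p)
  est <- do.call(rbind, lapply(seq_len(p), function(j) {
    mr_estimate(paste0("mvmr_direct_", sub("beta_", "", exp_cols[j])),
                unname(fit$coef[j]), unname(fit$se[j]), unname(pvals[j]), k)
  }))
  # conditional instrument strength: F of each exposure's effects after
  # regressing out the other exposure's effects (unit weights)
  cond_f <- vapply(seq_len(p), function(j) {
    xj <- X[, j]
    if (p == 1) return(mean(xj^2 / panel[[sub("beta", "se", exp_cols[j])]]^2))
    other <- X[, -j, drop = FALSE]
    res <- stats::lm.fit(other, xj)$residuals
    mean(res^2 / panel[[sub("beta", "se", exp_cols[j])]]^2)
  }, numeric(1))
  names(cond_f) <- exp_cols
  attr(est, "conditional_f") <- cond_f
  est
}
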