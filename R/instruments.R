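#' Build a pairwise LD matrix from r-squared triplets
#'
#' Represents the linkage-disequilibrium structure of a reference panel as a
#' symmetric matrix of pairwise r-squared values with unit diagonal. Pairs
#' absent from the input are treated as unlinked (r-squared 0) by
#' [ld_lookup()], with a one-time warning from [clump()].
#'
#' @param pairs data frame with columns `rsid_a`, `rsid_b`, `r2`.
#' @return An `ld_matrix`: a symmetric numeric matrix with rsid dimnames.
#' @export
ld_matrix <- function(pairs) {
  stopifnot(all(c("rsid_a", "rsid_b", "r2") %in% names(pairs)))
  r2 <- as.numeric(pairs$r2)
  if (any(is.na(r2) | r2 < 0 | r2 > 1)) {
    stop("LD r2 values must lie in [0, 1]", call. = FALSE)
  }
  ids <- sort(unique(c(as.character(pairs$rsid_a), as.character(pairs$rsid_b))))
  m <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  ia <- match(as.character(pairs$rsid_a), ids)
  ib <- match(as.character(pairs$rsid_b), ids)
  m[cbind(ia, ib)] <- r2
  m[cbind(ib, ia)] <- r2
  diag(m) <- 1
  structure(m, class = c("ld_matrix", "matrix", "array"))
}

#' Read an LD matrix from a TSV of triplets
#'
#' @param path TSV with header `rsid_a`, `rsid_b`, `r2`.
#' @return An `ld_matrix`.
#' @export
read_ld_matrix <- function(path) {
  ld_matrix(read.delim(path, sep = "\t", header = TRUE,
                       stringsAsFactors = FALSE))
}

#' Pairwise r-squared with absent pairs treated as unlinked
#'
#' @param ld an `ld_matrix`, or `NULL` for a panel with no LD information.
#' @param a,b rsid character vectors (recycled).
#' @return Numeric vector of r-squared values; 0 where either rsid is
#'   absent from the matrix.
#' @export
ld_lookup <- function(ld, a, b) {
  if (is.null(ld)) return(rep(0, max(length(a), length(b))))
  ids <- rownames(ld)
  ia <- match(a, ids)
  ib <- match(b, ids)
  out <- rep(0, max(length(ia), length(ib)))
  ok <- !is.na(ia) & !is.na(ib)
  out[ok] <- ld[cbind(ia[ok], ib[ok])]
  out
}

#' Clumping configuration
#'
#' @param p_threshold genome-wide significance cut applied before clumping.
#' @param r2_threshold LD cut: a candidate within the window with r-squared
#'   at or above this value against a retained index SNP is discarded.
#' @param window_kb distance window in kilobases around the index SNP.
#' @return A `clump_config` list.
#' @export
clump_config <- function(p_threshold = 5e-7, r2_threshold = 0.01,
                         window_kb = 10000) {
  stopifnot(p_threshold > 0, p_threshold < 1,
            r2_threshold >= 0, r2_threshold <= 1, window_kb > 0)
  structure(list(p_threshold = p_threshold, r2_threshold = r2_threshold,
                 window_kb = window_kb), class = "clump_config")
}

#' Select independent instruments by greedy LD clumping
#'
#' Repeatedly takes the smallest-p SNP below the significance threshold and
#' discards every remaining SNP on the same chromosome within the distance
#' window whose r-squared with it is at or above the LD threshold. Ties in
#' p are broken by ascending position, then rsid, for determinism. SNPs
#' absent from the LD matrix are assumed unlinked (with a warning), which
#' matches permissive clumping against an incomplete reference panel.
#'
#' @param stats a `sumstats` object.
#' @param ld an `ld_matrix` or `NULL` (all pairs unlinked).
#' @param cfg a [clump_config()].
#' @return Character vector of retained rsids, ordered by ascending p.
#' @export
clump <- function(stats, ld = NULL, cfg = clump_config()) {
  stopifnot(inherits(cfg, "clump_config"))
  cand <- as.data.frame(stats)[, c("rsid", "chrom", "pos", "pval")]
  cand <- cand[cand$pval < cfg$p_threshold, , drop = FALSE]
  if (nrow(cand) == 0) {
    stop("no instruments: no SNP passes p < ", format(cfg$p_threshold),
         call. = FALSE)
  }
  if (!is.null(ld)) {
    absent <- setdiff(cand$rsid, rownames(ld))
    if (length(absent) > 0) {
      warning(length(absent), " SNP(s) absent from the LD matrix treated as ",
              "unlinked (r2 = 0)", call. = FALSE)
    }
  }
  cand <- cand[order(cand$pval, cand$pos, cand$rsid), , drop = FALSE]
  kept <- character(0)
  while (nrow(cand) > 0) {
    idx <- cand[1, ]
    kept <- c(kept, idx$rsid)
    cand <- cand[-1, , drop = FALSE]
    if (nrow(cand) == 0) break
    same_chr <- cand$chrom == idx$chrom
    in_window <- same_chr & abs(cand$pos - idx$pos) <= cfg$window_kb * 1000
    linked <- in_window &
      ld_lookup(ld, cand$rsid, rep(idx$rsid, nrow(cand))) >= cfg$r2_threshold
    cand <- cand[!linked, , drop = FALSE]
  }
  kept
}

#' Per-SNP variance in the exposure explained by a variant
#'
#' Computes \eqn{R^2 = \frac{2f(1-f)\beta^2}{2f(1-f)\beta^2 + 2f(1-f) N se^2}}
#' where `f` is the effect-allele frequency, so the instrument's share of
#' phenotypic variance depends on the estimated effect, its precision, and
#' the study size.
#'
#' @param eaf effect-allele frequency, strictly inside (0, 1).
#' @param beta per-allele effect estimate.
#' @param se its standard error (> 0).
#' @param n study sample size (> 1).
#' @return Variance explained in \[0, 1); zero iff `beta` is zero.
#' @export
snp_r2 <- function(eaf, beta, se, n) {
  if (any(eaf <= 0 | eaf >= 1)) {
    stop("undefined instrument: eaf must lie strictly inside (0, 1)",
         call. = FALSE)
  }
  stopifnot(all(se > 0), all(n > 1))
  num <- 2 * eaf * (1 - eaf) * beta^2
  den <- num + 2 * eaf * (1 - eaf) * n * se^2
  num / den
}

#' Instrument-strength F statistic
#'
#' \eqn{F = R^2 (N - 2) / (1 - R^2)}; values above 10 are the conventional
#' bound for adequately strong instruments.
#'
#' @param r2 variance explained, in \[0, 1).
#' @param n sample size (> 2).
#' @return Nonnegative F statistic, monotone in both arguments.
#' @export
f_stat <- function(r2, n) {
  if (any(r2 < 0 | r2 >= 1)) stop("r2 must lie in [0, 1)", call. = FALSE)
  stopifnot(all(n > 2))
  r2 * (n - 2) / (1 - r2)
}

#' Instrument strength table for a set of SNPs
#'
#' @param stats a `sumstats` object.
#' @param rsids instruments to evaluate (default: all rows).
#' @return Tibble with `rsid`, `r2` and `f_stat` per instrument.
#' @export
instrument_strength <- function(stats, rsids = stats$rsid) {
  rows <- as.data.frame(stats)[match(rsids, stats$rsid), , drop = FALSE]
  if (anyNA(rows$rsid)) stop("rsid(s) absent from summary statistics",
                             call. = FALSE)
  r2 <- snp_r2(rows$eaf, rows$beta, rows$se, rows$n)
  tibble(rsid = rows$rsid, r2 = r2, f_stat = f_stat(r2, rows$n))
}

#' A-priori power of a two-sample MR test with a binary outcome
#'
#' Uses the standard non-centrality approximation for an
#' inverse-variance-weighted test of a binary outcome:
#' \eqn{\lambda = N \cdot R^2 \cdot \phi(1-\phi) \cdot \log(OR)^2} with
#' case fraction \eqn{\phi}, and power
#' \eqn{1 - \Phi(z_{1-\alpha/2} - \sqrt\lambda) +
#' \Phi(-z_{1-\alpha/2} - \sqrt\lambda)}. This is an approximation to the
#' calculators commonly used for study design, exact as the per-instrument
#' effects shrink.
#'
#' @param total_r2 variance of the exposure explained by the instrument set.
#' @param n_outcome outcome-study sample size.
#' @param case_fraction proportion of cases in the outcome study, in (0, 1).
#' @param or_alt odds ratio under the alternative (per unit exposure).
#' @param alpha two-sided test size.
#' @return Power in \[0, 1\]; equals `alpha` when `total_r2` is 0 or
#'   `or_alt` is 1.
#' @export
apriori_power <- function(total_r2, n_outcome, case_fraction, or_alt,
                          alpha = 0.05) {
  stopifnot(total_r2 >= 0, total_r2 < 1, n_outcome > 0,
            case_fraction > 0, case_fraction < 1, or_alt > 0,
            alpha > 0, alpha < 1)
  lambda <- n_outcome * total_r2 * case_fraction * (1 - case_fraction) *
    log(or_alt)^2
  z <- qnorm(1 - alpha / 2)
  1 - pnorm(z - sqrt(lambda)) + pnorm(-z - sqrt(lambda))
}
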